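#' Deviation score of one subject's EMG-force relationship
#'
#' Runs the full preprocessing chain on every repetition of one
#' (subject, gesture) pair, estimates force with the supplied target
#' network, and records the per-repetition RMSE (percent of normalized
#' force); the subject score is the mean over repetitions. Under a model
#' calibrated on healthy data, an elevated score flags an abnormal
#' EMG-force relationship.
#'
#' @param model a trained `lstm_estimator` for the recordings' gesture.
#' @param recordings list of `recording`s sharing one subject and
#'   gesture.
#' @param ... forwarded to [preprocess_recording()].
#' @return a `deviation_score`: list with `subject_id`, `gesture`,
#'   `group`, `rep_rmse` (per-repetition RMSE, named by repetition) and
#'   `subject_rmse` (their mean).
#' @export
subject_deviation <- function(model, recordings, ...) {
  stopifnot(length(recordings) >= 1L)
  subj <- unique(vapply(recordings, `[[`, character(1), "subject_id"))
  gest <- unique(vapply(recordings, `[[`, character(1), "gesture"))
  if (length(subj) != 1L || length(gest) != 1L) {
    stop_named("mixed_recordings",
               "recordings must share one subject and one gesture")
  }
  rep_rmse <- c()
  for (rec in recordings) {
    ss <- preprocess_recording(rec, ...)
    if (nrow(ss$windows) == 0L) {
      warning(sprintf("%s %s rep %d: no windows, skipped",
                      rec$subject_id, rec$gesture, rec$repetition))
      next
    }
    pred <- predict(model, ss)
    rep_rmse[as.character(rec$repetition)] <- rmse_pct(ss$targets, pred)
  }
  if (length(rep_rmse) == 0L) {
    stop_named("no_valid_windows",
               "no repetition produced any valid window")
  }
  structure(
    list(subject_id = subj, gesture = gest,
         group = recordings[[1]]$group, rep_rmse = rep_rmse,
         subject_rmse = mean(rep_rmse)),
    class = "deviation_score"
  )
}

#' @export
print.deviation_score <- function(x, ...) {
  cat(sprintf("<deviation_score> %s %s: %.2f%% over %d repetition(s)\n",
              x$subject_id, x$gesture, x$subject_rmse,
              length(x$rep_rmse)))
  invisible(x)
}

#' Cohort-level assessment report
#'
#' Computes a [subject_deviation()] score for every (subject, gesture)
#' pair of the cohort under the matching target network, summarizes the
#' scores per group (mean, SD, min-max range) and runs the comparison
#' scheme implied by the grouping:
#'
#' * `HCvsCP` - per-gesture Mann-Whitney U between the two groups
#'   (labels from the recordings' `group` field);
#' * `MACS` - per-gesture Kruskal-Wallis over grades, followed by
#'   Dunn-Bonferroni pairwise tests when at least 3 grades are present;
#' * `symptom_type` - per-gesture Kruskal-Wallis over symptom types;
#' * `tracking` - per-gesture per-subject difference between the two
#'   timepoints (no test; the contrast is within subject).
#'
#' @param models a single trained `lstm_estimator`, or a named list of
#'   estimators keyed by gesture label.
#' @param cohort list of `recording`s.
#' @param grouping one of `"HCvsCP"`, `"MACS"`, `"symptom_type"`,
#'   `"tracking"`.
#' @param labels named character vector mapping subject ids to grouping
#'   labels (required for every grouping except `HCvsCP`; for
#'   `tracking`, label recordings' subjects as timepoints, e.g. two
#'   entries `"Exp1"`/`"Exp2"` for the same child recorded twice under
#'   distinct subject ids).
#' @param min_group_n smallest group size admitted to a rank test.
#' @param ... forwarded to [preprocess_recording()].
#' @return an `assessment_report`: list with `scores` (data.frame:
#'   subject, gesture, label, rmse), `summaries` (per gesture x label),
#'   `tests` (per gesture), `grouping`.
#' @export
cohort_report <- function(models, cohort,
                          grouping = c("HCvsCP", "MACS", "symptom_type",
                                       "tracking"),
                          labels = NULL, min_group_n = 3L, ...) {
  grouping <- match.arg(grouping)
  stopifnot(length(cohort) >= 1L)
  key <- paste(vapply(cohort, `[[`, character(1), "subject_id"),
               vapply(cohort, `[[`, character(1), "gesture"), sep = "\r")
  scores <- data.frame()
  for (k in unique(key)) {
    recs <- cohort[key == k]
    gest <- recs[[1]]$gesture
    subj <- recs[[1]]$subject_id
    model <- if (inherits(models, "lstm_estimator")) models
             else models[[gest]] %||%
               stop_named("missing_model",
                          sprintf("no model for gesture %s", gest))
    lab <- if (grouping == "HCvsCP") recs[[1]]$group else labels[subj]
    if (is.null(lab) || is.na(lab)) {
      stop_named("missing_grouping",
                 sprintf("no '%s' label for subject %s", grouping, subj))
    }
    dev <- subject_deviation(model, recs, ...)
    scores <- rbind(scores, data.frame(
      subject = subj, gesture = gest, label = unname(lab),
      rmse = dev$subject_rmse))
  }
  if (length(unique(scores$label)) < 2L) {
    stop_named("single_group",
               sprintf("grouping '%s' needs >= 2 distinct labels", grouping))
  }

  summaries <- do.call(rbind, lapply(
    split(scores, list(scores$gesture, scores$label), drop = TRUE),
    function(d) data.frame(gesture = d$gesture[1], label = d$label[1],
                           n = nrow(d), rmse_mean = mean(d$rmse),
                           rmse_sd = sd(d$rmse), rmse_min = min(d$rmse),
                           rmse_max = max(d$rmse))))
  rownames(summaries) <- NULL

  tests <- list()
  for (g in unique(scores$gesture)) {
    d <- scores[scores$gesture == g, ]
    grp <- split(d$rmse, d$label)
    tests[[g]] <- switch(grouping,
      HCvsCP = {
        if (all(lengths(grp) >= min_group_n) && length(grp) == 2L) {
          cp <- grp[["CP"]] %||% grp[[2]]
          hc <- grp[["HC"]] %||% grp[[1]]
          list(mann_whitney = mann_whitney_u(cp, hc))
        } else list(note = "group too small for a rank test")
      },
      MACS = ,
      symptom_type = {
        ok <- lengths(grp) >= 2L
        if (sum(ok) >= 2L) {
          res <- list(kruskal_wallis = kruskal_wallis(grp[ok]))
          if (sum(ok) >= 3L) res$dunn <- dunn_bonferroni(grp[ok])
          res
        } else list(note = "too few usable groups")
      },
      tracking = {
        means <- vapply(grp, mean, numeric(1))
        list(timepoint_means = means,
             delta = unname(means[length(means)] - means[1]))
      })
  }
  structure(list(scores = scores, summaries = summaries, tests = tests,
                 grouping = grouping),
            class = "assessment_report")
}

#' @export
print.assessment_report <- function(x, ...) {
  cat(sprintf("<assessment_report> grouping %s, %d score(s)\n",
              x$grouping, nrow(x$scores)))
  print(x$summaries)
  invisible(x)
}
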