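#' Transfer-learning strategy
#'
#' Names the calibration scheme used to turn the trained source network
#' into a gesture-specific target network:
#'
#' * `TL1` - transfer all layer parameters, all layers trainable;
#' * `TL2` - transfer all parameters, freeze the first LSTM layer;
#' * `TL3` - transfer all parameters, freeze the first two LSTM layers;
#' * `non_TL` - same architecture, fresh parameters (no transfer);
#' * `source_only` - use the source network as-is, no calibration.
#'
#' Freezing excludes a layer's weights, batch-norm parameters and
#' batch-norm running statistics from all updates.
#'
#' @param name strategy name.
#' @return a `transfer_strategy`: list with `name` and `frozen_depth`
#'   (0, 1, 2; `NA` for `non_TL`/`source_only`).
#' @export
transfer_strategy <- function(name = c("TL1", "TL2", "TL3", "non_TL",
                                       "source_only")) {
  name <- match.arg(name)
  frozen <- switch(name, TL1 = 0L, TL2 = 1L, TL3 = 2L, NA_integer_)
  structure(list(name = name, frozen_depth = frozen),
            class = "transfer_strategy")
}

#' Calibrate a source network on target data
#'
#' Initializes a target network from the trained source network (or from
#' fresh parameters for `non_TL`) and fine-tunes it on the target
#' `sample_set` under the given layer-freezing strategy. Calibration runs
#' a fixed number of epochs (default 50); early stopping applies only
#' when a validation set is supplied.
#'
#' @param source a trained `lstm_estimator`.
#' @param strategy a [transfer_strategy()] (not `source_only`) or its
#'   name.
#' @param data non-empty calibration `sample_set`.
#' @param seed seed for shuffling/dropout (and fresh initialization
#'   under `non_TL`).
#' @param epochs calibration epoch cap.
#' @param val optional validation `sample_set` enabling early stopping.
#' @return the calibrated `lstm_estimator`.
#' @export
calibrate <- function(source, strategy, data, seed = 1L, epochs = 50L,
                      val = NULL) {
  stopifnot(inherits(source, "lstm_estimator"),
            inherits(data, "sample_set"))
  if (is.character(strategy)) strategy <- transfer_strategy(strategy)
  if (strategy$name == "source_only") {
    stop_named("bad_strategy", "source_only means no calibration")
  }
  if (nrow(data$windows) == 0L) {
    stop_named("empty_training_set", "calibration data has no windows")
  }
  if (strategy$name == "non_TL") {
    cfg <- source$config
    cfg$seed <- derive_seed(seed, "non_tl_init")
    est <- build_estimator(cfg, input_len = source$input_len)
    return(train_estimator(est, data, val = val, max_epochs = epochs,
                           seed = seed, frozen_depth = 0L))
  }
  if (strategy$frozen_depth >= length(source$layers)) {
    stop_named("bad_frozen_depth",
               sprintf("%s freezes %d layers but the network has %d",
                       strategy$name, strategy$frozen_depth,
                       length(source$layers)))
  }
  train_estimator(source, data, val = val, max_epochs = epochs,
                  seed = seed, frozen_depth = strategy$frozen_depth)
}

#' Leave-one-subject-out evaluation of a calibration strategy
#'
#' One fold per subject: the held-out subject's windows form the test
#' set, the remaining subjects' windows are split 9:1 (window level) into
#' calibration and validation sets, the source network is calibrated
#' under `strategy`, and test RMSE / R-squared are recorded. With 16
#' subjects this yields the 16-fold protocol whose mean and SD summarize
#' a target network's subject-independent performance.
#'
#' @param samples combined `sample_set` with subject provenance
#'   (>= 2 subjects).
#' @param source trained source `lstm_estimator`.
#' @param strategy a [transfer_strategy()] or its name; `source_only`
#'   skips calibration.
#' @param seed experiment seed (fold-wise seeds are derived from it).
#' @param epochs calibration epoch cap per fold.
#' @return an `experiment_report`: list with `folds` (data.frame:
#'   `fold`, `subject`, `n_test`, `rmse`, `r2`), `summary` (means and
#'   SDs), `strategy`, `seed`.
#' @export
loso_evaluate <- function(samples, source, strategy, seed = 1L,
                          epochs = 50L) {
  stopifnot(inherits(samples, "sample_set"))
  if (is.character(strategy)) strategy <- transfer_strategy(strategy)
  subjects <- unique(samples$provenance$subject)
  if (length(subjects) < 2L) {
    stop_named("too_few_subjects", "LOSO needs >= 2 subjects")
  }
  folds <- data.frame()
  for (k in seq_along(subjects)) {
    subj <- subjects[k]
    test_idx <- samples$provenance$subject == subj
    if (!any(test_idx)) {
      warning(sprintf("subject %s has no windows: fold skipped", subj))
      next
    }
    test <- subset_samples(samples, test_idx)
    rest <- subset_samples(samples, !test_idx)
    est <- if (strategy$name == "source_only") {
      source
    } else {
      sp <- split_samples(rest, ratios = c(9, 1, 0),
                          seed = derive_seed(seed, "loso_split", k))
      # fold hygiene: the held-out subject must not leak into train/val
      stopifnot(!subj %in% sp$train$provenance$subject,
                !subj %in% sp$val$provenance$subject)
      calibrate(source, strategy, sp$train,
                seed = derive_seed(seed, "loso_fit", k),
                epochs = epochs, val = sp$val)
    }
    pred <- predict(est, test)
    folds <- rbind(folds, data.frame(
      fold = k, subject = subj, n_test = nrow(test$windows),
      rmse = rmse_pct(test$targets, pred),
      r2 = r_squared(pred, test$targets)))
  }
  structure(
    list(folds = folds,
         summary = list(rmse_mean = mean(folds$rmse),
                        rmse_sd = sd(folds$rmse),
                        r2_mean = mean(folds$r2),
                        r2_sd = sd(folds$r2)),
         strategy = strategy$name, seed = seed),
    class = "experiment_report"
  )
}

#' @export
print.experiment_report <- function(x, ...) {
  cat(sprintf("<experiment_report> strategy %s: %d fold(s), RMSE %.2f +/- %.2f %%, R2 %.3f\n",
              x$strategy, nrow(x$folds), x$summary$rmse_mean,
              x$summary$rmse_sd %||% NA_real_, x$summary$r2_mean))
  invisible(x)
}

#' Training:test-ratio experiment
#'
#' For each subject-level training:test ratio (e.g. `"15:1"`, `"1:15"`)
#' and each strategy, draws `n_resamples` random subject splits without
#' replacement, calibrates on the training subjects' windows (no
#' validation set) and evaluates on the test subjects' windows. This
#' quantifies how much calibration data a strategy needs: transfer
#' calibration should stay accurate even at `1:15`, where training from
#' scratch degrades.
#'
#' @param samples combined `sample_set` with subject provenance.
#' @param source trained source `lstm_estimator`.
#' @param ratios ratios as `"a:b"` strings or length-2 integer vectors;
#'   `a + b` must not exceed the subject count.
#' @param strategies character vector of strategy names.
#' @param seed experiment seed.
#' @param n_resamples random subject splits per cell (16 in the full
#'   protocol).
#' @param epochs calibration epoch cap.
#' @return a `ratio_report`: list with `runs` (one row per resample) and
#'   `cells` (mean/SD of RMSE per ratio x strategy).
#' @export
ratio_experiment <- function(samples, source,
                             ratios = list("15:1", "14:2", "12:4", "8:8",
                                           "4:12", "2:14", "1:15"),
                             strategies = c("TL1", "non_TL"), seed = 1L,
                             n_resamples = 16L, epochs = 50L) {
  stopifnot(inherits(samples, "sample_set"))
  subjects <- unique(samples$provenance$subject)
  ns <- length(subjects)
  parse_ratio <- function(r) {
    if (is.character(r)) r <- as.integer(strsplit(r, ":")[[1]])
    stopifnot(length(r) == 2L, all(r >= 1L))
    r
  }
  runs <- data.frame()
  for (rat in ratios) {
    r <- parse_ratio(rat)
    if (sum(r) > ns) {
      stop_named("bad_ratio",
                 sprintf("ratio %d:%d exceeds the %d available subjects",
                         r[1], r[2], ns))
    }
    label <- paste0(r[1], ":", r[2])
    for (rs in seq_len(n_resamples)) {
      pick <- with_seed(derive_seed(seed, "ratio", label, rs),
                        sample(subjects, sum(r)))
      train_subj <- pick[seq_len(r[1])]
      test_subj <- pick[r[1] + seq_len(r[2])]
      train <- subset_samples(samples,
                              samples$provenance$subject %in% train_subj)
      test <- subset_samples(samples,
                             samples$provenance$subject %in% test_subj)
      for (strat in strategies) {
        est <- if (strat == "source_only") source
               else calibrate(source, strat, train,
                              seed = derive_seed(seed, "ratio_fit", label,
                                                 rs, strat),
                              epochs = epochs)
        pred <- predict(est, test)
        runs <- rbind(runs, data.frame(
          ratio = label, strategy = strat, resample = rs,
          rmse = rmse_pct(test$targets, pred),
          r2 = r_squared(pred, test$targets)))
      }
    }
  }
  cells <- do.call(rbind, lapply(
    split(runs, list(runs$ratio, runs$strategy), drop = TRUE),
    function(d) data.frame(ratio = d$ratio[1], strategy = d$strategy[1],
                           rmse_mean = mean(d$rmse), rmse_sd = sd(d$rmse),
                           r2_mean = mean(d$r2))))
  rownames(cells) <- NULL
  structure(list(runs = runs, cells = cells, seed = seed),
            class = "ratio_report")
}

#' @export
print.ratio_report <- function(x, ...) {
  cat("<ratio_report>\n")
  print(x$cells)
  invisible(x)
}
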