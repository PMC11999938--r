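#' NMF decomposition of an envelope matrix into activation modes
#'
#' Factorizes the nonnegative envelope matrix `V` (channels x time) as
#' `V ~ t(W) %*% H`, where each row of the mode matrix `W`
#' (modes x channels) is a spatial activation pattern over the grid and
#' each row of the coefficient matrix `H` (modes x time) is that mode's
#' time-varying activation level. The sum of a coefficient row is the
#' mode's activation intensity; the mode with the largest intensity is
#' the primary activation mode, the one contributing most to the force.
#'
#' Fitting uses Lee-Seung multiplicative updates on the Frobenius
#' objective `||V - t(W) H||_F`, whose value is non-increasing at every
#' iteration; factors stay nonnegative by construction. Initialization is
#' seeded uniform random, so the decomposition is reproducible.
#'
#' @param env an `envelope_matrix` (or nonnegative channels x time
#'   matrix).
#' @param rank number of modes, `1 <= rank <= channels`.
#' @param seed integer seed for the random initialization.
#' @param tol relative objective-change convergence tolerance.
#' @param max_iter iteration cap.
#' @return an `activation_decomposition`: list with `weights`
#'   (modes x channels), `coefficients` (modes x time), `intensity`
#'   (per-mode coefficient row sums), `primary_mode`, `objective`
#'   (per-iteration Frobenius error), `channel_ids`.
#' @export
nmf_decompose <- function(env, rank = 2L, seed = 1L, tol = 1e-5,
                          max_iter = 500L) {
  # channel optimization factorizes the amplitude envelope: per-channel
  # min-max normalization would equalize all channels and destroy the
  # activation-intensity information the mode weights carry
  V <- if (inherits(env, "envelope_matrix")) env$raw %||% env$values
       else env
  channel_ids <- if (inherits(env, "envelope_matrix")) env$channel_ids
                 else seq_len(nrow(V))
  stopifnot(is.matrix(V))
  if (any(V < 0)) {
    stop_named("negative_input", "NMF input must be nonnegative")
  }
  C <- nrow(V)
  stopifnot(rank >= 1L, rank <= C)

  eps <- .Machine$double.eps
  scale0 <- sqrt(mean(V) / rank)
  init <- with_seed(derive_seed(seed, "nmf_init"), {
    list(A = matrix(runif(C * rank, 0.1, 1) * scale0, nrow = C),
         H = matrix(runif(rank * ncol(V), 0.1, 1) * scale0, nrow = rank))
  })
  A <- init$A   # C x rank == t(weights)
  H <- init$H   # rank x T

  objective <- numeric(0)
  obj_prev <- Inf
  for (it in seq_len(max_iter)) {
    A <- A * (V %*% t(H)) / (A %*% (H %*% t(H)) + eps)
    H <- H * (t(A) %*% V) / ((t(A) %*% A) %*% H + eps)
    obj <- sqrt(sum((V - A %*% H)^2))
    objective <- c(objective, obj)
    if (is.finite(obj_prev) &&
        abs(obj_prev - obj) <= tol * max(obj_prev, eps)) break
    obj_prev <- obj
  }

  intensity <- rowSums(H)
  structure(
    list(weights = t(A), coefficients = H, intensity = intensity,
         primary_mode = which.max(intensity), objective = objective,
         channel_ids = channel_ids),
    class = "activation_decomposition"
  )
}

#' @export
print.activation_decomposition <- function(x, ...) {
  cat(sprintf("<activation_decomposition> %d mode(s) x %d channels; primary mode %d (intensity %.3g)\n",
              nrow(x$weights), ncol(x$weights), x$primary_mode,
              x$intensity[x$primary_mode]))
  invisible(x)
}

#' Select optimal channels from the primary activation mode
#'
#' Ranks channels by their weight in the primary activation mode and
#' keeps the top quarter (`ceiling(C / 4)` of `C` channels; 16 of a
#' 64-channel montage), ties broken toward the lower channel index. The
#' selection weights are the primary-mode weights of the kept channels,
#' renormalized to sum to 1.
#'
#' @param dec an `activation_decomposition`.
#' @return a `channel_selection`: list with `indices` (selected channel
#'   ids, in rank order) and `weights` (summing to 1).
#' @export
select_optimal_channels <- function(dec) {
  stopifnot(inherits(dec, "activation_decomposition"))
  w <- dec$weights[dec$primary_mode, ]
  if (all(w <= 0)) {
    stop_named("degenerate_decomposition",
               "all primary-mode weights are zero")
  }
  C <- length(w)
  k <- ceiling(C / 4)
  ord <- order(-w, seq_along(w))
  top <- ord[seq_len(k)]
  sel_w <- w[top] / sum(w[top])
  structure(
    list(indices = dec$channel_ids[top], weights = sel_w),
    class = "channel_selection"
  )
}

#' @export
print.channel_selection <- function(x, ...) {
  cat(sprintf("<channel_selection> %d channels: %s\n", length(x$indices),
              paste(utils::head(x$indices, 8L), collapse = ", ")))
  invisible(x)
}

#' Collapse an envelope matrix to one dimension
#'
#' Weighted average of the selected channels' envelopes using the
#' selection weights, followed by min-max normalization, yielding the
#' one-dimensional sEMG envelope the regressor consumes.
#'
#' @param env an `envelope_matrix`.
#' @param sel a `channel_selection` whose indices are a subset of
#'   `env$channel_ids`.
#' @return numeric vector in `[0, 1]`, one sample per time point.
#' @export
collapse_to_envelope <- function(env, sel) {
  stopifnot(inherits(env, "envelope_matrix"),
            inherits(sel, "channel_selection"))
  if (length(sel$indices) == 0L) {
    stop_named("empty_selection", "channel selection is empty")
  }
  rows <- match(sel$indices, env$channel_ids)
  if (anyNA(rows)) {
    stop_named("bad_selection", "selection refers to unknown channels")
  }
  src <- env$raw %||% env$values  # average amplitude envelopes, then Eq. 1
  combined <- as.numeric(crossprod(src[rows, , drop = FALSE],
                                   sel$weights))
  minmax_normalize(combined)
}

#' Run the full preprocessing chain on one recording
#'
#' Convenience wrapper executing the four-stage chain on a single
#' recording: channel screening and repair, optional upsampling,
#' band-pass filtering, PCA spatial filtering, envelope extraction,
#' NMF-based optimal-channel selection, collapse to the one-dimensional
#' envelope, force smoothing/normalization, and sliding-window
#' segmentation.
#'
#' @param rec a `recording`.
#' @param target_fs optional upsampling target (Hz).
#' @param low,high,bp_order band-pass parameters.
#' @param env_cutoff,env_order envelope low-pass parameters.
#' @param rank NMF rank.
#' @param L,step window length and hop (samples).
#' @param screen logical: run channel screening first.
#' @param seed seed for the NMF initialization.
#' @return a `sample_set`; the intermediate one-dimensional envelope,
#'   normalized force and channel selection are attached as attributes
#'   `envelope_1d`, `force_norm`, `selection`, `screen_report`.
#' @export
preprocess_recording <- function(rec, target_fs = NULL, low = 20,
                                 high = 500, bp_order = 100L,
                                 env_cutoff = 5, env_order = 100L,
                                 rank = 2L, L = 500L, step = 500L,
                                 screen = TRUE, seed = 1L) {
  stopifnot(inherits(rec, "recording"))
  screen_report <- NULL
  if (screen) {
    sc <- screen_channels(rec)
    screen_report <- sc$report
    rec <- sc$recording
  }
  if (!is.null(target_fs) && target_fs > rec$fs) {
    rec <- resample_to(rec, target_fs)
  }
  filt <- bandpass_filter(rec$semg, rec$fs, low, high, bp_order)
  filt <- pca_spatial_filter(filt)
  env <- compute_envelope(filt, rec$fs, env_cutoff, env_order,
                          channel_ids = rec$channel_ids)
  dec <- nmf_decompose(env, rank = rank, seed = seed)
  sel <- select_optimal_channels(dec)
  env1d <- collapse_to_envelope(env, sel)
  force_n <- smooth_and_normalize_force(rec$force)
  ss <- segment_samples(env1d, force_n, L = L, step = step,
                        provenance = list(subject = rec$subject_id,
                                          gesture = rec$gesture,
                                          repetition = rec$repetition,
                                          group = rec$group))
  attr(ss, "envelope_1d") <- env1d
  attr(ss, "force_norm") <- force_n
  attr(ss, "selection") <- sel
  attr(ss, "screen_report") <- screen_report
  ss
}

#' Preprocess a cohort of recordings into one sample set
#'
#' Applies [preprocess_recording()] to every recording and concatenates
#' the resulting windows, carrying provenance.
#'
#' @param recordings list of `recording` objects.
#' @param ... forwarded to [preprocess_recording()].
#' @return a combined `sample_set`.
#' @export
preprocess_cohort <- function(recordings, ...) {
  combine_samples(lapply(recordings, preprocess_recording, ...))
}
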