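# -- FIR filtering helpers ----------------------------------------------------

# Hanning-window FIR band-pass design. The upper edge is clipped to
# 0.45 * fs when the nominal edge is not attainable at the given sampling
# rate (e.g. a 500 Hz edge at 1 kHz sampling), keeping the design valid
# before upsampling.
bandpass_fir <- function(fs, low = 20, high = 500, order = 100L) {
  if (fs <= 2 * low) {
    stop_named("bad_sampling_rate",
               sprintf("fs = %g Hz cannot support a %g Hz high-pass edge",
                       fs, low))
  }
  high_eff <- min(high, 0.45 * fs)
  signal::fir1(order, c(low, high_eff) / (fs / 2), type = "pass",
               window = signal::hanning(order + 1L))
}

lowpass_fir <- function(fs, cutoff = 5, order = 100L) {
  stopifnot(fs > 2 * cutoff)
  signal::fir1(order, cutoff / (fs / 2), type = "low",
               window = signal::hanning(order + 1L))
}

# Zero-phase FIR filtering: odd-reflection padding, filter forward and
# backward. The forward pass delays by (ntaps-1)/2 samples and the
# reversed pass undoes it exactly, so envelope and force stay aligned.
fir_filtfilt <- function(b, x) {
  b <- as.numeric(b)  # strip signal's Ma class so filter() dispatches right
  n <- length(x)
  pad <- min(n - 1L, 3L * length(b))
  xp <- c(2 * x[1] - x[(pad + 1L):2L], x, 2 * x[n] - x[(n - 1L):(n - pad)])
  y <- as.numeric(signal::fftfilt(b, xp))        # FFT overlap-add FIR
  y <- rev(as.numeric(signal::fftfilt(b, rev(y))))
  y[(pad + 1L):(pad + n)]
}

#' Band-pass filter a multichannel sEMG matrix
#'
#' Applies a linear-phase FIR band-pass (Hanning window, default
#' 100th order, 20-500 Hz) to every channel, forward-backward so the net
#' phase is zero. When the sampling rate cannot accommodate the nominal
#' upper edge (fs <= 2 * high), the edge is clipped to `0.45 * fs`.
#'
#' @param m channels x time numeric matrix.
#' @param fs sampling rate in Hz; must exceed `2 * low`.
#' @param low,high band edges in Hz.
#' @param order FIR order (number of taps minus one).
#' @return filtered matrix, same shape.
#' @export
bandpass_filter <- function(m, fs, low = 20, high = 500, order = 100L) {
  stopifnot(is.matrix(m))
  b <- bandpass_fir(fs, low, high, order)
  out <- m
  for (ch in seq_len(nrow(m))) out[ch, ] <- fir_filtfilt(b, m[ch, ])
  out
}

# -- Channel screening ---------------------------------------------------------

#' Screen and repair defective channels
#'
#' Flags channels failing any of three quality criteria and replaces each
#' flagged channel by the mean of its valid 4-neighbourhood on the
#' electrode grid (falling back to the mean of the valid channels of its
#' grid when no neighbour survives):
#'
#' * `variance` - sample variance below `var_floor` (flatlined channel);
#' * `clipping` - more than `clip_frac` of samples within 0.1% of the
#'   channel's absolute maximum (railed amplifier);
#' * `rms_outlier` - log-RMS further than `rms_k` MADs from the median
#'   log-RMS of the channels of the same grid (gross noise or a dead
#'   contact; the log scale makes the criterion amplitude-ratio based).
#'
#' @param rec a `recording` with at least 4 channels.
#' @param criteria named list overriding `var_floor` (default `1e-12`),
#'   `clip_frac` (default 0.1) and `rms_k` (default 5).
#' @return list with `report` (data.frame: `channel`, `flagged`,
#'   `criterion`, `repaired`) and `recording` (the repaired copy).
#' @export
screen_channels <- function(rec, criteria = list()) {
  stopifnot(inherits(rec, "recording"))
  C <- nrow(rec$semg)
  if (C < 4L) stop_named("too_few_channels", "screening needs >= 4 channels")
  crit <- utils::modifyList(
    list(var_floor = 1e-12, clip_frac = 0.1, rms_k = 5, mad_floor = 0.05),
    criteria)

  v <- apply(rec$semg, 1L, var)
  amax <- apply(abs(rec$semg), 1L, max)
  clipped <- vapply(seq_len(C), function(ch) {
    if (amax[ch] == 0) return(1)
    mean(abs(rec$semg[ch, ]) >= 0.999 * amax[ch])
  }, numeric(1))
  rms <- sqrt(rowMeans(rec$semg^2))
  log_rms <- log10(pmax(rms, .Machine$double.xmin))
  co <- channel_coords(rec$grid)
  rms_out <- logical(C)
  for (g in unique(co$grid)) {
    idx <- co$channel[co$grid == g]
    med <- median(log_rms[idx])
    # MAD floored at `mad_floor` log10 units (~12% in amplitude) so a
    # grid of near-identical quiet channels does not flag hairline
    # amplitude differences
    dev <- max(mad(log_rms[idx]), crit$mad_floor)
    rms_out[idx] <- abs(log_rms[idx] - med) > crit$rms_k * dev
  }

  why <- character(C)
  why[rms_out] <- "rms_outlier"
  why[clipped > crit$clip_frac] <- "clipping"
  why[v < crit$var_floor] <- "variance"
  flagged <- why != ""
  if (mean(flagged) > 0.5) {
    stop_named("recording_unusable",
               sprintf("%d of %d channels defective: recording unusable",
                       sum(flagged), C))
  }

  out <- rec
  repaired <- character(C)
  for (ch in which(flagged)) {
    nb <- setdiff(grid_neighbours(rec$grid, ch), which(flagged))
    if (length(nb) > 0) {
      out$semg[ch, ] <- colMeans(rec$semg[nb, , drop = FALSE])
      repaired[ch] <- paste0("neighbours:", paste(nb, collapse = "+"))
    } else {
      valid <- setdiff(co$channel[co$grid == co$grid[ch]], which(flagged))
      out$semg[ch, ] <- colMeans(rec$semg[valid, , drop = FALSE])
      repaired[ch] <- "grid_mean"
    }
  }
  list(
    report = data.frame(channel = seq_len(C), flagged = flagged,
                        criterion = why, repaired = repaired),
    recording = out
  )
}

# -- Resampling ---------------------------------------------------------------

#' Upsample a recording by linear interpolation
#'
#' Interpolates every sEMG channel and the force trace linearly in time
#' onto the target sampling grid, preserving total duration. Only
#' upsampling is supported; mixed-rate datasets are brought up to the
#' highest rate before filtering.
#'
#' @param rec a `recording`.
#' @param target_fs target rate in Hz, `>= rec$fs`.
#' @return the resampled `recording` (identical input when
#'   `target_fs == rec$fs`).
#' @export
resample_to <- function(rec, target_fs) {
  stopifnot(inherits(rec, "recording"))
  if (target_fs < rec$fs) {
    stop_named("downsampling_unsupported",
               "only upsampling is supported (target_fs >= fs)")
  }
  if (target_fs == rec$fs) return(rec)
  n <- ncol(rec$semg)
  t_old <- (seq_len(n) - 1L) / rec$fs
  t_new <- seq(0, t_old[n], by = 1 / target_fs)
  out <- rec
  out$semg <- t(vapply(seq_len(nrow(rec$semg)), function(ch) {
    approx(t_old, rec$semg[ch, ], xout = t_new)$y
  }, numeric(length(t_new))))
  out$force$values <- approx(t_old, rec$force$values, xout = t_new)$y
  out$force$fs <- target_fs
  out$fs <- target_fs
  out
}

# -- PCA spatial filtering ----------------------------------------------------

#' PCA spatial filter
#'
#' Decomposes the multichannel signal into as many principal components
#' as channels (time samples as observations, channels as variables) and
#' reconstructs it after removing the component with the highest
#' explained variance - assumed to carry redundant common-mode
#' information - and the component with the lowest explained variance -
#' assumed to carry measurement noise.
#'
#' @param m channels x time matrix with at least 3 channels.
#' @param drop `"extremes"` (default) removes the top and bottom
#'   components; `"none"` keeps all components (full reconstruction,
#'   useful for verifying the decomposition).
#' @return filtered matrix, same shape.
#' @export
pca_spatial_filter <- function(m, drop = c("extremes", "none")) {
  stopifnot(is.matrix(m))
  drop <- match.arg(drop)
  C <- nrow(m)
  if (C < 3L) stop_named("too_few_channels", "PCA filter needs >= 3 channels")
  X <- t(m)                      # T x C, channels as variables
  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu)
  eg <- eigen(crossprod(Xc) / (nrow(Xc) - 1L), symmetric = TRUE)
  keep <- if (drop == "extremes") seq_len(C)[-c(1L, C)] else seq_len(C)
  V <- eg$vectors[, keep, drop = FALSE]
  Xr <- Xc %*% V %*% t(V)
  t(sweep(Xr, 2L, mu, `+`))
}

# -- Envelope extraction ------------------------------------------------------

#' Extract the normalized envelope matrix
#'
#' Full-wave rectification followed by FIR low-pass filtering (Hanning
#' window, default 100th order, 5 Hz cutoff, applied forward-backward)
#' and per-channel min-max normalization onto `[0, 1]`. A channel whose
#' envelope is constant (degenerate bounds) is set to all zeros with a
#' warning.
#'
#' @param m channels x time matrix (band-pass filtered sEMG).
#' @param fs sampling rate in Hz.
#' @param cutoff low-pass cutoff in Hz.
#' @param order FIR order.
#' @param channel_ids optional channel labels.
#' @return an `envelope_matrix`: list with `values` (channels x time in
#'   `[0, 1]`), `raw` (the amplitude envelope before normalization, the
#'   input to NMF channel optimization — per-channel normalization would
#'   erase the between-channel activation-intensity differences the mode
#'   weights encode), `fs`, `channel_ids`, `x_min`, `x_max` (the
#'   per-channel normalization bounds).
#' @export
compute_envelope <- function(m, fs, cutoff = 5, order = 100L,
                             channel_ids = seq_len(nrow(m))) {
  stopifnot(is.matrix(m))
  b <- lowpass_fir(fs, cutoff, order)
  C <- nrow(m)
  env <- m
  raw <- m
  x_min <- x_max <- numeric(C)
  for (ch in seq_len(C)) {
    e <- pmax(0, fir_filtfilt(b, abs(m[ch, ])))  # clamp filter ripple
    raw[ch, ] <- e
    x_min[ch] <- min(e)
    x_max[ch] <- max(e)
    if (x_max[ch] <= x_min[ch]) {
      warning(sprintf("channel %s: constant envelope, set to zeros",
                      channel_ids[ch]))
      env[ch, ] <- 0
    } else {
      env[ch, ] <- (e - x_min[ch]) / (x_max[ch] - x_min[ch])
    }
  }
  structure(
    list(values = env, raw = raw, fs = fs, channel_ids = channel_ids,
         x_min = x_min, x_max = x_max),
    class = "envelope_matrix"
  )
}

#' @export
print.envelope_matrix <- function(x, ...) {
  cat(sprintf("<envelope_matrix> %d ch x %d samples @ %g Hz\n",
              nrow(x$values), ncol(x$values), x$fs))
  invisible(x)
}

# -- Force conditioning and segmentation --------------------------------------

#' Smooth and normalize a force trace
#'
#' Zero-phase centred moving average (default 0.05 s window, removing
#' measurement burrs) followed by min-max normalization onto `[0, 1]`.
#' Edges are handled by replicate-padding so the trace keeps its length.
#'
#' @param force a `force_trace` or numeric vector.
#' @param fs sampling rate in Hz (taken from the trace if omitted).
#' @param window_s smoothing window in seconds.
#' @return numeric vector in `[0, 1]`, same length as the input.
#' @export
smooth_and_normalize_force <- function(force, fs = NULL, window_s = 0.05) {
  if (inherits(force, "force_trace")) {
    fs <- force$fs
    x <- force$values
  } else {
    stopifnot(!is.null(fs))
    x <- as.numeric(force)
  }
  stopifnot(all(is.finite(x)))
  w <- max(1L, round(window_s * fs))
  if (w %% 2L == 0L) w <- w + 1L
  n <- length(x)
  half <- (w - 1L) %/% 2L
  xp <- c(rep(x[1], half), x, rep(x[n], half))
  sm <- as.numeric(stats::filter(xp, rep(1 / w, w), sides = 2L))
  sm <- sm[(half + 1L):(half + n)]
  minmax_normalize(sm)
}

#' Segment an envelope/force pair into training samples
#'
#' Slides a window of `L` samples with hop `step` over the time-aligned
#' one-dimensional envelope and normalized force; each window becomes one
#' (envelope segment, force target) sample, the target being the mean of
#' the normalized force over the window. A trailing partial window is
#' discarded; a trace shorter than `L` yields an empty set with a
#' warning.
#'
#' @param envelope numeric vector, the one-dimensional sEMG envelope.
#' @param force numeric vector, the normalized force, same length.
#' @param L window length in samples.
#' @param step hop in samples.
#' @param provenance named list (`subject`, `gesture`, `repetition`,
#'   `group`) attached to every window.
#' @return a `sample_set`: list with `windows` (n x L matrix), `targets`
#'   (length n), `L`, `step` and `provenance` (data.frame, one row per
#'   window).
#' @export
segment_samples <- function(envelope, force, L = 500L, step = 500L,
                            provenance = list()) {
  stopifnot(length(envelope) == length(force), L >= 1L, step >= 1L)
  n <- length(envelope)
  starts <- if (n < L) integer(0) else seq(1L, n - L + 1L, by = step)
  if (length(starts) == 0L) {
    warning(sprintf("trace of %d samples shorter than window L=%d: empty sample set",
                    n, L))
  }
  windows <- matrix(0, nrow = length(starts), ncol = L)
  targets <- numeric(length(starts))
  for (i in seq_along(starts)) {
    idx <- starts[i]:(starts[i] + L - 1L)
    windows[i, ] <- envelope[idx]
    targets[i] <- mean(force[idx])
  }
  prov <- data.frame(
    subject = rep(provenance$subject %||% NA_character_, length(starts)),
    gesture = rep(provenance$gesture %||% NA_character_, length(starts)),
    repetition = rep(provenance$repetition %||% NA_integer_, length(starts)),
    group = rep(provenance$group %||% NA_character_, length(starts)),
    window = seq_along(starts),
    stringsAsFactors = FALSE
  )
  structure(list(windows = windows, targets = targets, L = as.integer(L),
                 step = as.integer(step), provenance = prov),
            class = "sample_set")
}

#' @export
print.sample_set <- function(x, ...) {
  cat(sprintf("<sample_set> %d windows of %d samples (%d subject(s))\n",
              nrow(x$windows), x$L,
              length(unique(stats::na.omit(x$provenance$subject)))))
  invisible(x)
}

#' Combine sample sets
#'
#' @param sets list of `sample_set` objects with equal `L`.
#' @return a single `sample_set` with rows concatenated.
#' @export
combine_samples <- function(sets) {
  sets <- Filter(function(s) nrow(s$windows) > 0, sets)
  stopifnot(length(sets) >= 1L)
  L <- unique(vapply(sets, function(s) s$L, integer(1)))
  stopifnot(length(L) == 1L)
  structure(
    list(windows = do.call(rbind, lapply(sets, `[[`, "windows")),
         targets = unlist(lapply(sets, `[[`, "targets"), use.names = FALSE),
         L = L, step = sets[[1]]$step,
         provenance = do.call(rbind, lapply(sets, `[[`, "provenance"))),
    class = "sample_set"
  )
}

#' Subset a sample set by window index
#' @param ss a `sample_set`.
#' @param idx logical or integer window index.
#' @return the subset `sample_set`.
#' @export
subset_samples <- function(ss, idx) {
  structure(
    list(windows = ss$windows[idx, , drop = FALSE],
         targets = ss$targets[idx], L = ss$L, step = ss$step,
         provenance = ss$provenance[idx, , drop = FALSE]),
    class = "sample_set"
  )
}
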