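#' Generate a prescribed force profile
#'
#' Builds the target force trajectory a subject is asked to track during
#' one effort. Four force modes are supported, mirroring the protocols of
#' typical isometric-contraction experiments:
#'
#' * `increasing_plateau` - linear ramp from 0 to `amp` over `ramp_s`
#'   seconds, then held at `amp` for the remainder (e.g. 3 s up, 3 s hold).
#' * `sine` - half-rectified sine between 0 and `amp` with period
#'   `period_s` seconds.
#' * `constant` - held at `amp` throughout (e.g. a constant 40% MVC).
#' * `random` - a smooth, nonnegative, band-limited (<= 1 Hz) trajectory
#'   the subject improvises; generated by spline interpolation through
#'   uniformly random control points placed 0.5 s apart.
#'
#' Amplitudes are fractions of maximum voluntary contraction (MVC), so
#' `amp = 0.6` means a 60% MVC effort.
#'
#' @param mode one of `"increasing_plateau"`, `"sine"`, `"constant"`,
#'   `"random"`.
#' @param duration_s trace duration in seconds (> 0).
#' @param fs sampling rate in Hz (> 0).
#' @param params named list of mode parameters: `amp` (all modes),
#'   `ramp_s` (increasing_plateau, default 3), `period_s` (sine,
#'   default 5).
#' @param seed integer seed; only the `random` mode consumes randomness,
#'   but the argument is accepted for every mode for interface uniformity.
#' @return an object of class `force_trace`: list with `values`
#'   (numeric, `round(duration_s * fs)` samples), `fs`, `mode`, `params`.
#' @examples
#' ft <- generate_force_profile("increasing_plateau", 6, 2000,
#'                              list(ramp_s = 3, amp = 0.6))
#' length(ft$values) # 12000
#' @export
generate_force_profile <- function(mode, duration_s, fs,
                                   params = list(), seed = 1L) {
  modes <- c("increasing_plateau", "sine", "constant", "random")
  if (!is.character(mode) || length(mode) != 1L || !(mode %in% modes)) {
    stop_named("bad_force_mode",
               sprintf("unknown force mode '%s'", paste(mode, collapse = ",")))
  }
  if (!is.numeric(duration_s) || duration_s <= 0) {
    stop_named("bad_duration", "duration_s must be positive")
  }
  if (!is.numeric(fs) || fs <= 0) {
    stop_named("bad_sampling_rate", "fs must be positive")
  }
  n <- round(duration_s * fs)
  t <- (seq_len(n) - 1L) / fs
  amp <- params$amp %||% 0.6

  values <- switch(mode,
    increasing_plateau = {
      ramp_s <- params$ramp_s %||% 3
      n_ramp <- min(n, round(ramp_s * fs))
      v <- rep(amp, n)
      if (n_ramp > 0) v[seq_len(n_ramp)] <- seq(0, amp, length.out = n_ramp)
      v
    },
    sine = {
      period_s <- params$period_s %||% 5
      amp * pmax(0, sin(2 * pi * t / period_s))
    },
    constant = rep(amp, n),
    random = with_seed(derive_seed(seed, "force_random"), {
      step_s <- 0.5 # control point spacing -> spectral content <= ~1 Hz
      knots_t <- seq(0, duration_s + step_s, by = step_s)
      knots_v <- runif(length(knots_t), min = 0.1 * amp, max = amp)
      v <- stats::spline(knots_t, knots_v, xout = t)$y
      pmin(pmax(v, 0), amp)
    })
  )
  stopifnot(all(is.finite(values)))
  structure(
    list(values = values, fs = fs, mode = mode,
         params = utils::modifyList(list(amp = amp), params)),
    class = "force_trace"
  )
}

#' @export
print.force_trace <- function(x, ...) {
  cat(sprintf("<force_trace> mode=%s fs=%g Hz n=%d amp=%.3g\n",
              x$mode, x$fs, length(x$values), x$params$amp))
  invisible(x)
}
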