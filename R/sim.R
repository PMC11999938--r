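#' Synthetic subject profile
#'
#' Bundles the per-subject parameters of the HD-sEMG simulator: how each
#' channel scales the common drive (`gain_map`), where on the electrode
#' grid the muscle activation peaks (`activation_center`, a Gaussian bump
#' of spatial spread `activation_sigma` in electrode units), the exponent
#' of the envelope-force law (`nonlinearity_alpha`: per-channel envelope
#' amplitude is proportional to `force^alpha`), the additive sensor noise
#' level (`noise_sd`), and an optional pathology that perturbs the
#' EMG-force coupling.
#'
#' Pathology models (all scaled by `pathology_strength` in `[0, 1]`):
#' * `tremor` - 5 Hz multiplicative modulation of depth
#'   `0.4 * strength` on the exerted force, with a phase-lagged copy on
#'   the EMG amplitude (electromechanical delay), producing "M"-shaped
#'   efforts and degrading the EMG-force mapping.
#' * `shifted_activation` - the activation bump moves to the next grid
#'   and its coupling exponent is blunted
#'   (`alpha_eff = alpha * (1 - 0.5 * strength)`), emulating compensatory
#'   activation of a muscle misaligned with the measured force.
#' * `coactivation` - a second, force-independent activation bump on
#'   another grid (tonic co-contraction).
#'
#' @param subject_id character label.
#' @param grid a [grid_layout()].
#' @param gain_map per-channel multiplicative gains (> 0), length
#'   `n_channels(grid)`.
#' @param activation_center integer vector `c(grid, row, col)` of the
#'   activation peak.
#' @param activation_sigma spatial spread, in inter-electrode units (> 0).
#' @param nonlinearity_alpha envelope-force exponent (> 0).
#' @param noise_sd additive white-noise standard deviation (>= 0).
#' @param pathology one of `"none"`, `"tremor"`, `"shifted_activation"`,
#'   `"coactivation"`. Must be `"none"` for healthy groups.
#' @param pathology_strength scalar in `[0, 1]` scaling the pathology.
#' @param group cohort label: `"HA"` (healthy adult), `"HC"` (healthy
#'   child) or `"CP"` (cerebral palsy).
#' @return an object of class `subject_profile`.
#' @export
subject_profile <- function(subject_id, grid = grid_layout(),
                            gain_map = rep(1, n_channels(grid)),
                            activation_center = c(1L, 2L, 2L),
                            activation_sigma = 1.2,
                            nonlinearity_alpha = 1,
                            noise_sd = 0.05,
                            pathology = c("none", "tremor",
                                          "shifted_activation",
                                          "coactivation"),
                            pathology_strength = 1,
                            group = c("HC", "HA", "CP")) {
  pathology <- match.arg(pathology)
  group <- match.arg(group)
  stopifnot(length(gain_map) == n_channels(grid), all(gain_map > 0),
            activation_sigma > 0, nonlinearity_alpha > 0, noise_sd >= 0,
            pathology_strength >= 0, pathology_strength <= 1)
  if (group != "CP" && pathology != "none") {
    stop_named("bad_profile", "pathology must be 'none' for HA/HC profiles")
  }
  structure(
    list(subject_id = subject_id, grid = grid, gain_map = gain_map,
         activation_center = as.integer(activation_center),
         activation_sigma = activation_sigma,
         nonlinearity_alpha = nonlinearity_alpha, noise_sd = noise_sd,
         pathology = pathology, pathology_strength = pathology_strength,
         group = group),
    class = "subject_profile"
  )
}

# Gaussian spatial weight bump centred at (grid g0, row r0, col c0);
# channels outside the centre grid get the floor weight only.
spatial_weights <- function(grid, center, sigma, floor_w = 0.1) {
  co <- channel_coords(grid)
  w <- rep(floor_w, nrow(co))
  in_grid <- co$grid == center[1]
  d2 <- (co$row[in_grid] - center[2])^2 + (co$col[in_grid] - center[3])^2
  w[in_grid] <- floor_w + (1 - floor_w) * exp(-d2 / (2 * sigma^2))
  w
}

# Unit-variance band-limited noise carrier (one channel).
emg_carrier <- function(n, fs, low = 20, high = 500) {
  x <- rnorm(n)
  b <- bandpass_fir(fs, low = low, high = high)
  y <- fir_filtfilt(b, x)
  y / max(sd(y), .Machine$double.eps)
}

#' Simulate one HD-sEMG recording
#'
#' Synthesizes a grid-organized multichannel sEMG matrix whose per-channel
#' amplitude tracks the prescribed force: channel `c` carries
#' `gain_c * w_c * force(t)^alpha` times an independent 20-500 Hz
#' band-limited Gaussian carrier, plus white sensor noise of standard
#' deviation `noise_sd`; `w_c` is a Gaussian spatial bump over the grid.
#' Pathologies in the profile perturb the coupling (see
#' [subject_profile()]).
#'
#' @param profile a [subject_profile()].
#' @param force a `force_trace` from [generate_force_profile()].
#' @param seed integer seed; the recording is a deterministic function of
#'   `(profile, force, seed)`.
#' @param gesture gesture label (e.g. `"G1"`).
#' @param repetition repetition index.
#' @return an object of class `recording`: list with `semg`
#'   (channels x time matrix), `force` (`force_trace`, the measured
#'   force, including any tremor), `fs`, `grid`, `gesture`, `subject_id`,
#'   `repetition`, `group`, `channel_ids`.
#' @export
generate_recording <- function(profile, force, seed = 1L,
                               gesture = "G1", repetition = 1L) {
  stopifnot(inherits(profile, "subject_profile"),
            inherits(force, "force_trace"))
  grid <- profile$grid
  C <- n_channels(grid)
  fs <- force$fs
  f <- force$values
  n <- length(f)
  t <- (seq_len(n) - 1L) / fs
  strength <- profile$pathology_strength

  center <- profile$activation_center
  alpha <- profile$nonlinearity_alpha
  f_meas <- f
  f_emg <- f
  if (profile$pathology == "tremor") {
    # mechanical oscillation rides mostly on the output force; the EMG
    # drive carries only a weaker, phase-lagged ripple (electromechanical
    # delay), so the envelope no longer predicts the measured force
    depth <- 0.4 * strength
    trem_hz <- 5
    mod_force <- 1 - depth * (0.5 + 0.5 * sin(2 * pi * trem_hz * t))
    mod_emg <- 1 - 0.5 * depth *
      (0.5 + 0.5 * sin(2 * pi * trem_hz * t - pi / 3))
    f_meas <- f * mod_force
    f_emg <- f * mod_emg
  } else if (profile$pathology == "shifted_activation") {
    center <- c(center[1] %% grid$n_grids + 1L, center[2], center[3])
    alpha <- alpha * (1 - 0.5 * strength)
  }

  w <- spatial_weights(grid, center, profile$activation_sigma)
  drive <- f_emg^alpha

  semg <- with_seed(derive_seed(seed, "recording", profile$subject_id,
                                gesture, repetition), {
    m <- matrix(0, nrow = C, ncol = n)
    for (ch in seq_len(C)) {
      m[ch, ] <- profile$gain_map[ch] * w[ch] * drive * emg_carrier(n, fs)
    }
    if (profile$pathology == "coactivation" && strength > 0) {
      co_center <- c(profile$activation_center[1] %% grid$n_grids + 1L,
                     profile$activation_center[2],
                     profile$activation_center[3])
      w2 <- spatial_weights(grid, co_center, profile$activation_sigma,
                            floor_w = 0)
      co_level <- 0.6 * strength * mean(profile$gain_map) * max(f)^alpha
      for (ch in which(w2 > 1e-3)) {
        m[ch, ] <- m[ch, ] + w2[ch] * co_level * emg_carrier(n, fs)
      }
    }
    if (profile$noise_sd > 0) {
      m <- m + matrix(rnorm(C * n, sd = profile$noise_sd), nrow = C)
    }
    m
  })

  force_out <- force
  force_out$values <- f_meas
  structure(
    list(semg = semg, force = force_out, fs = fs, grid = grid,
         gesture = gesture, subject_id = profile$subject_id,
         repetition = as.integer(repetition), group = profile$group,
         channel_ids = seq_len(C)),
    class = "recording"
  )
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf(
    "<recording> %s %s rep %d: %d ch x %d samples @ %g Hz (%s, force mode %s)\n",
    x$subject_id, x$gesture, x$repetition, nrow(x$semg), ncol(x$semg),
    x$fs, x$group, x$force$mode))
  invisible(x)
}

#' Inject channel faults into a recording
#'
#' Applies controlled channel defects so that channel-quality screening
#' can be exercised: `flatline` zeros the channel, `saturation` clips it
#' at `level` (default: the 75th percentile of its absolute amplitude, so
#' about a quarter of samples rail), `gross_noise` adds white noise of
#' standard deviation `level` (default: 10x the channel's own SD).
#'
#' @param rec a `recording`.
#' @param fault_spec list of faults, each a list with `channel` (index),
#'   `kind` (one of `"flatline"`, `"saturation"`, `"gross_noise"`) and
#'   optional `level`.
#' @param seed integer seed (consumed by `gross_noise` only).
#' @return a modified copy of `rec`; the input is untouched.
#' @export
inject_channel_faults <- function(rec, fault_spec, seed = 1L) {
  stopifnot(inherits(rec, "recording"))
  out <- rec
  C <- nrow(out$semg)
  for (i in seq_along(fault_spec)) {
    fault <- fault_spec[[i]]
    ch <- fault$channel
    if (!is.numeric(ch) || ch < 1 || ch > C) {
      stop_named("bad_channel_index",
                 sprintf("fault channel index %s out of range 1..%d",
                         paste(ch, collapse = ","), C))
    }
    kind <- match.arg(fault$kind,
                      c("flatline", "saturation", "gross_noise"))
    x <- out$semg[ch, ]
    out$semg[ch, ] <- switch(kind,
      flatline = rep(0, length(x)),
      saturation = {
        level <- fault$level %||% unname(quantile(abs(x), 0.75))
        pmin(pmax(x, -level), level)
      },
      gross_noise = with_seed(derive_seed(seed, "fault", i), {
        level <- fault$level %||% (10 * sd(x))
        x + rnorm(length(x), sd = level)
      })
    )
  }
  out
}

#' Simulate a cohort of subjects
#'
#' Draws one [subject_profile()] per subject from group-specific
#' parameter ranges and simulates `reps` recordings per (subject,
#' gesture). Healthy adults (`"HA"`) get the 128-channel 8 x 16 montage
#' and cycle through the four force modes across repetitions, emulating a
#' multi-protocol source dataset; healthy children (`"HC"`) and cerebral
#' palsy subjects (`"CP"`) get the 64-channel 4 x (4 x 4) montage and an
#' increasing-plateau effort to 80% MVC. CP subjects carry a pathology
#' (cycled over tremor / shifted activation / coactivation unless fixed
#' via `pathology`).
#'
#' Profile draws: per-channel gains lognormal(0, 0.15); activation centre
#' uniform over the interior of grid 1; spread `U(1.2, 1.8)` electrodes;
#' coupling exponent alpha `U(0.8, 1.1)` for adults and `U(1.2, 1.5)`
#' for children (the systematic adult-child domain difference that
#' transfer calibration corrects for); noise set to the target
#' per-channel SNR (default 10 dB) relative to the mean bump-channel
#' signal amplitude.
#'
#' @param n_subjects number of subjects (>= 1).
#' @param group `"HA"`, `"HC"` or `"CP"`.
#' @param gestures character vector of gesture labels (or a count).
#' @param reps repetitions per (subject, gesture) (>= 1).
#' @param seed integer master seed; the full cohort is reproducible.
#' @param fs sampling rate in Hz.
#' @param duration_s effort duration in seconds.
#' @param grid a [grid_layout()]; default depends on `group`.
#' @param pathology fix the CP pathology instead of cycling; ignored for
#'   healthy groups.
#' @param pathology_strength pathology scale in `[0, 1]`.
#' @param snr_db target per-channel signal-to-noise ratio in dB.
#' @return list of `recording` objects (length
#'   `n_subjects * length(gestures) * reps`), with the drawn profiles
#'   attached as `attr(, "profiles")`.
#' @export
make_cohort <- function(n_subjects, group, gestures = paste0("G", 1:5),
                        reps = 8L, seed = 1L, fs = 2000, duration_s = 6,
                        grid = NULL, pathology = NULL,
                        pathology_strength = 1, snr_db = 10) {
  if (!(is.character(group) && length(group) == 1L &&
        group %in% c("HA", "HC", "CP"))) {
    stop_named("bad_group", sprintf("unknown group label '%s'",
                                    paste(group, collapse = ",")))
  }
  stopifnot(n_subjects >= 1, reps >= 1)
  if (is.numeric(gestures)) gestures <- paste0("G", seq_len(gestures))
  if (is.null(grid)) {
    grid <- if (group == "HA") grid_layout(8L, 16L, 1L)
            else grid_layout(4L, 4L, 4L)
  }
  amp <- if (group == "HA") 0.6 else 0.8
  pathologies <- c("tremor", "shifted_activation", "coactivation")

  profiles <- lapply(seq_len(n_subjects), function(i) {
    with_seed(derive_seed(seed, "profile", group, i), {
      C <- n_channels(grid)
      gains <- rlnorm(C, 0, 0.15)
      center <- c(1L,
                  sample(seq(2L, max(2L, grid$rows - 1L)), 1L),
                  sample(seq(2L, max(2L, grid$cols - 1L)), 1L))
      sigma <- runif(1, 1.2, 1.8)
      # adults: near-linear envelope-force coupling; children (healthy
      # or CP): steeper nonlinearity -- the systematic domain difference
      # that calibration on child data corrects for
      alpha <- if (group == "HA") runif(1, 0.8, 1.1) else runif(1, 1.2, 1.5)
      path <- if (group == "CP") {
        if (is.null(pathology)) pathologies[(i - 1L) %% 3L + 1L]
        else pathology
      } else "none"
      # per-channel SNR target: noise sd relative to the mean bump-channel
      # signal rms (drive rms about 0.5 * amp^alpha for a ramp-plateau)
      w <- spatial_weights(grid, center, sigma)
      bump <- w > 0.5
      sig_rms <- mean(gains[bump] * w[bump]) * (0.7 * amp)^alpha
      noise_sd <- sig_rms / 10^(snr_db / 20)
      subject_profile(
        subject_id = sprintf("%s%02d", group, i), grid = grid,
        gain_map = gains, activation_center = center,
        activation_sigma = sigma, nonlinearity_alpha = alpha,
        noise_sd = noise_sd, pathology = path,
        pathology_strength = pathology_strength, group = group
      )
    })
  })

  ha_modes <- c("increasing_plateau", "sine", "constant", "random")
  recordings <- list()
  k <- 0L
  for (i in seq_len(n_subjects)) {
    prof <- profiles[[i]]
    for (g in gestures) {
      for (r in seq_len(reps)) {
        mode <- if (group == "HA") ha_modes[(r - 1L) %% 4L + 1L]
                else "increasing_plateau"
        fseed <- derive_seed(seed, "force", prof$subject_id, g, r)
        ft <- generate_force_profile(
          mode, duration_s, fs,
          params = list(amp = amp, ramp_s = duration_s / 2,
                        period_s = duration_s / 1.5),
          seed = fseed
        )
        k <- k + 1L
        recordings[[k]] <- generate_recording(
          prof, ft, seed = derive_seed(seed, "rec", prof$subject_id, g, r),
          gesture = g, repetition = r
        )
      }
    }
  }
  attr(recordings, "profiles") <- profiles
  recordings
}
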