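test_that("force profiles follow their prescribed shapes", {
  ft <- generate_force_profile("increasing_plateau", 6, 2000,
                               list(ramp_s = 3, amp = 0.6))
  expect_length(ft$values, 12000L)
  expect_equal(ft$values[1], 0)
  expect_equal(ft$values[6000], 0.6, tolerance = 1e-12)
  expect_true(all(ft$values[6001:12000] == 0.6))
  expect_true(all(diff(ft$values[1:6000]) > 0))

  fc <- generate_force_profile("constant", 5, 2000, list(amp = 0.4))
  expect_length(fc$values, 10000L)
  expect_true(all(fc$values == 0.4))

  fsin <- generate_force_profile("sine", 5, 500,
                                 list(amp = 0.6, period_s = 2.5))
  expect_gte(min(fsin$values), 0)
  expect_equal(max(fsin$values), 0.6, tolerance = 1e-3)
})

test_that("random force mode is seeded, smooth and band-limited", {
  f1 <- generate_force_profile("random", 20, 200, list(amp = 0.6), seed = 9L)
  f2 <- generate_force_profile("random", 20, 200, list(amp = 0.6), seed = 9L)
  f3 <- generate_force_profile("random", 20, 200, list(amp = 0.6), seed = 10L)
  expect_identical(f1$values, f2$values)
  expect_false(identical(f1$values, f3$values))
  expect_true(all(f1$values >= 0 & f1$values <= 0.6))
  # band-limited: dominant spectral mass below ~1.5 Hz
  sp <- Mod(stats::fft(f1$values - mean(f1$values)))^2
  freqs <- (seq_along(sp) - 1) / 20
  half <- freqs <= 100
  expect_gt(sum(sp[half & freqs <= 1.5]) / sum(sp[half]), 0.95)
})

test_that("invalid force-profile arguments are rejected by name", {
  expect_error(generate_force_profile("triangle", 5, 100), class = "bad_force_mode")
  expect_error(generate_force_profile("sine", -1, 100), class = "bad_duration")
  expect_error(generate_force_profile("sine", 5, 0), class = "bad_sampling_rate")
})

test_that("recordings couple channel envelopes to force", {
  grid <- grid_layout(4L, 4L, 2L)
  prof <- subject_profile("HC01", grid, activation_center = c(1L, 2L, 2L),
                          activation_sigma = 1.5, nonlinearity_alpha = 1,
                          noise_sd = 0, group = "HC")
  # noiseless constant force: rectified low-passed envelope is constant
  # up to filter transients
  fc <- generate_force_profile("constant", 3, 1000, list(amp = 0.4))
  rec <- generate_recording(prof, fc, seed = 1L)
  env <- compute_envelope(bandpass_filter(rec$semg, 1000), 1000)
  core <- env$raw[1, 300:2700]
  expect_lt(stats::sd(core) / mean(core), 0.15)

  # healthy increasing-plateau: mean envelope tracks force
  fp <- generate_force_profile("increasing_plateau", 6, 1000,
                               list(ramp_s = 3, amp = 0.8))
  rec2 <- generate_recording(prof, fp, seed = 2L)
  env2 <- compute_envelope(bandpass_filter(rec2$semg, 1000), 1000)
  rho <- stats::cor(colMeans(env2$raw), fp$values, method = "spearman")
  expect_gt(rho, 0.9)
})

test_that("shifted activation moves the dominant channels to another grid", {
  grid <- grid_layout(4L, 4L, 2L)
  prof <- subject_profile("CP01", grid, activation_center = c(1L, 2L, 2L),
                          activation_sigma = 1.4, noise_sd = 0.01,
                          pathology = "shifted_activation", group = "CP")
  fp <- generate_force_profile("increasing_plateau", 4, 1000,
                               list(ramp_s = 2, amp = 0.8))
  rec <- generate_recording(prof, fp, seed = 3L)
  energy <- rowMeans(rec$semg^2)
  co <- channel_coords(grid)
  expect_equal(co$grid[which.max(energy)], 2L)
})

test_that("channel faults behave as specified and leave the input untouched", {
  prof <- subject_profile("HC01", grid_layout(2L, 2L, 1L),
                          noise_sd = 0.05, group = "HC")
  fp <- generate_force_profile("constant", 2, 500, list(amp = 0.5))
  rec <- generate_recording(prof, fp, seed = 4L)
  orig <- rec$semg

  out <- inject_channel_faults(rec, list(list(channel = 3L, kind = "flatline")))
  expect_equal(stats::var(out$semg[3, ]), 0)
  expect_identical(rec$semg, orig)

  out2 <- inject_channel_faults(rec, list(list(channel = 2L, kind = "saturation")))
  clip <- max(abs(out2$semg[2, ]))
  expect_lt(clip, max(abs(rec$semg[2, ])))
  expect_gte(mean(abs(out2$semg[2, ]) >= clip - 1e-12), 0.2)

  expect_identical(inject_channel_faults(rec, list())$semg, rec$semg)
  expect_error(
    inject_channel_faults(rec, list(list(channel = 99L, kind = "flatline"))),
    class = "bad_channel_index")
})

test_that("cohorts have the right size and are reproducible from the seed", {
  tiny <- grid_layout(2L, 2L, 1L)
  coh <- make_cohort(16, "HC", gestures = paste0("G", 1:5), reps = 8L,
                     seed = 5L, fs = 100, duration_s = 1, grid = tiny)
  expect_length(coh, 640L)
  coh2 <- make_cohort(2, "HC", gestures = "G1", reps = 2L, seed = 6L,
                      fs = 200, duration_s = 1, grid = tiny)
  coh3 <- make_cohort(2, "HC", gestures = "G1", reps = 2L, seed = 6L,
                      fs = 200, duration_s = 1, grid = tiny)
  expect_identical(coh2, coh3)
  expect_error(make_cohort(2, "XX", gestures = "G1", reps = 1L),
               class = "bad_group")
})

test_that("a tremor effort shows repeated force peaks within one repetition", {
  coh <- make_cohort(1, "CP", gestures = "G1", reps = 1L, seed = 7L,
                     fs = 500, duration_s = 6, pathology = "tremor")
  f <- coh[[1]]$force$values
  inner <- f[2:(length(f) - 1)]
  n_max <- sum(inner > f[1:(length(f) - 2)] & inner > f[3:length(f)])
  expect_gte(n_max, 2L)
})

test_that("time-averaged envelope increases strictly with force level", {
  grid <- grid_layout(4L, 4L, 1L)
  prof <- subject_profile("HC01", grid, activation_center = c(1L, 2L, 2L),
                          activation_sigma = 1.5,
                          nonlinearity_alpha = 1.2, noise_sd = 0,
                          group = "HC")
  means <- vapply(c(0.2, 0.4, 0.6), function(level) {
    fc <- generate_force_profile("constant", 2, 1000, list(amp = level))
    rec <- generate_recording(prof, fc, seed = 8L)
    env <- compute_envelope(bandpass_filter(rec$semg, 1000), 1000)
    mean(env$raw[, 300:1700])
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})
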