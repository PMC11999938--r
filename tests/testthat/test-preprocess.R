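test_that("min-max normalization matches its definition and is idempotent", {
  expect_equal(minmax_normalize(c(2, 4, 6)), c(0, 0.5, 1))
  expect_warning(z <- minmax_normalize(rep(3, 5)), "constant")
  expect_equal(z, rep(0, 5))
  x <- rnorm(100)
  once <- minmax_normalize(x)
  expect_equal(minmax_normalize(once), once, tolerance = 1e-12)
  expect_equal(range(once), c(0, 1))
})

test_that("channel screening flags, repairs and reports defective channels", {
  prof <- subject_profile("HC01", grid_layout(4L, 4L, 1L),
                          activation_center = c(1L, 2L, 2L),
                          activation_sigma = 1.5, noise_sd = 0.05,
                          group = "HC")
  fp <- generate_force_profile("increasing_plateau", 3, 500,
                               list(ramp_s = 1.5, amp = 0.8))
  rec <- generate_recording(prof, fp, seed = 1L)

  clean <- screen_channels(rec)
  expect_equal(sum(clean$report$flagged), 0L)
  expect_identical(clean$recording$semg, rec$semg)

  bad <- inject_channel_faults(rec, list(list(channel = 7L, kind = "flatline")))
  sc <- screen_channels(bad)
  expect_true(sc$report$flagged[7])
  expect_equal(sc$report$criterion[7], "variance")
  expect_gt(stats::var(sc$recording$semg[7, ]), 0)

  sat <- inject_channel_faults(rec, list(list(channel = 3L, kind = "saturation",
                                              level = 0.3 * max(abs(rec$semg[3, ])))))
  sc2 <- screen_channels(sat)
  expect_true(sc2$report$flagged[3])
  expect_equal(sc2$report$criterion[3], "clipping")

  noisy <- inject_channel_faults(rec, list(list(channel = 5L, kind = "gross_noise")))
  expect_true(screen_channels(noisy)$report$flagged[5])

  many <- inject_channel_faults(rec, lapply(1:9, function(ch)
    list(channel = ch, kind = "flatline")))
  expect_error(screen_channels(many), class = "recording_unusable")
})

test_that("resampling is exact linear interpolation and refuses downsampling", {
  ramp <- seq(0, 1, length.out = 1000)
  rec <- new_test_recording(rbind(ramp, ramp, 2 * ramp, rep(0.3, 1000)),
                            fs = 1000, force_values = ramp)
  up <- resample_to(rec, 2000)
  expect_equal(up$fs, 2000)
  t_new <- seq(0, 999 / 1000, by = 1 / 2000)
  expect_equal(up$semg[1, ], stats::approx((0:999) / 1000, ramp, t_new)$y,
               tolerance = 1e-12)
  # midpoints are means of neighbours
  mid <- up$semg[1, seq(2, 40, by = 2)]
  expect_equal(mid, (up$semg[1, seq(1, 39, by = 2)] +
                     up$semg[1, seq(3, 41, by = 2)]) / 2, tolerance = 1e-12)
  expect_true(all(abs(up$semg[4, ] - 0.3) < 1e-12))
  expect_identical(resample_to(rec, 1000), rec)
  expect_error(resample_to(rec, 500), class = "downsampling_unsupported")
})

test_that("band-pass filter preserves the passband and rejects the stopband", {
  fs <- 2000
  t <- (0:9999) / fs
  m <- rbind(sin(2 * pi * 100 * t), sin(2 * pi * 2 * t))
  out <- bandpass_filter(m, fs)
  core <- 2000:8000
  amp100 <- max(abs(out[1, core]))
  expect_lt(abs(amp100 - 1), 0.05)
  amp2 <- max(abs(out[2, core]))
  expect_lt(20 * log10(amp2), -20)
  expect_equal(bandpass_filter(matrix(0, 3, 500), fs), matrix(0, 3, 500))
  expect_error(bandpass_filter(m, fs = 30), class = "bad_sampling_rate")
})

test_that("PCA spatial filter removes extreme components and keeps the rest", {
  set.seed(11)
  common <- rnorm(200)
  m <- matrix(rep(common, each = 5), nrow = 5) + matrix(rnorm(1000, sd = 0.01), 5)
  filtered <- pca_spatial_filter(m)
  v_before <- stats::var(colMeans(m))
  v_after <- stats::var(colMeans(filtered))
  expect_lt(v_after / v_before, 0.1)

  m2 <- matrix(rnorm(5 * 200), 5)
  expect_equal(pca_spatial_filter(m2, drop = "none"), m2, tolerance = 1e-8)
  expect_error(pca_spatial_filter(m2[1:2, ]), class = "too_few_channels")
})

test_that("envelope extraction rectifies, smooths, and normalizes per channel", {
  fs <- 1000
  set.seed(12)
  tri <- c(seq(0.2, 1, length.out = 2500), seq(1, 0.2, length.out = 2500))
  carrier <- fir_mat <- matrix(rnorm(5000), 1)
  m <- matrix(tri, 1) * bandpass_filter(carrier, fs)
  env <- compute_envelope(m, fs)
  expect_true(all(env$values >= 0 & env$values <= 1))
  expect_gt(stats::cor(env$raw[1, ], tri), 0.95)

  expect_warning(z <- compute_envelope(matrix(0, 1, 300), fs), "constant")
  expect_true(all(z$values == 0))
})

test_that("force smoothing suppresses spikes and preserves smooth ramps", {
  fs <- 1000
  ramp <- seq(0, 1, length.out = 2000)
  spiked <- ramp
  spiked[1000] <- spiked[1000] + 5   # 1-sample burr of height 5
  s_clean <- smooth_and_normalize_force(ramp, fs = fs)
  s_spike <- smooth_and_normalize_force(spiked, fs = fs)
  # the 0.05 s (51-sample) moving average dilutes the burr ~50-fold
  w <- 51
  expect_lt(max(abs(s_spike - s_clean)), 1.3 * 5 / w)
  expect_equal(range(s_spike), c(0, 1))
  # an already-smooth ramp passes through within 1% away from the edges
  inner <- 100:1900
  expect_lt(max(abs(s_clean[inner] - ramp[inner])), 0.01)
})

test_that("segmentation yields floor(T/L) windows with mean-force targets", {
  env <- runif(10000)
  force <- rep(0.7, 10000)
  ss <- segment_samples(env, force, L = 500L, step = 500L,
                        provenance = list(subject = "S", gesture = "G1",
                                          repetition = 1L, group = "HC"))
  expect_equal(nrow(ss$windows), 20L)
  expect_true(all(ss$targets == 0.7))
  expect_equal(ss$windows[3, ], env[1001:1500])
  expect_warning(empty <- segment_samples(runif(499), runif(499)),
                 "shorter")
  expect_equal(nrow(empty$windows), 0L)
})

test_that("collapse to one dimension is a normalized weighted average", {
  set.seed(13)
  e <- matrix(runif(3 * 400), 3)
  env <- structure(list(values = e, raw = e, fs = 1000, channel_ids = 1:3,
                        x_min = rep(0, 3), x_max = rep(1, 3)),
                   class = "envelope_matrix")
  sel1 <- structure(list(indices = 2L, weights = 1), class = "channel_selection")
  expect_equal(collapse_to_envelope(env, sel1), minmax_normalize(e[2, ]))

  e2 <- rbind(e[1, ], e[1, ])
  env2 <- structure(list(values = e2, raw = e2, fs = 1000, channel_ids = 1:2,
                         x_min = rep(0, 2), x_max = rep(1, 2)),
                    class = "envelope_matrix")
  sel2 <- structure(list(indices = 1:2, weights = c(0.3, 0.7)),
                    class = "channel_selection")
  expect_equal(collapse_to_envelope(env2, sel2), minmax_normalize(e[1, ]))

  out <- collapse_to_envelope(env, structure(
    list(indices = 1:3, weights = rep(1 / 3, 3)), class = "channel_selection"))
  expect_equal(range(out), c(0, 1))
})
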