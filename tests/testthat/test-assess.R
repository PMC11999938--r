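# A small trained model + matching recordings shared by the assessment
# tests: fs 500 Hz, 3 s efforts -> 3 windows of 500 samples per
# repetition.
assess_fixture <- function() {
  cached_fixture("assess", {
    hc <- make_cohort(3, "HC", gestures = "G1", reps = 3L, seed = 91L,
                      fs = 500, duration_s = 3)
    ss <- preprocess_cohort(hc, rank = 2L, seed = 1L)
    cfg <- tiny_config(units = c(16L, 8L), dropout = 0.2, seed = 4L,
                       batch_size = 16L)
    sp <- split_samples(ss, c(9, 1, 0), seed = 2L)
    model <- train_estimator(build_estimator(cfg, 500L), sp$train,
                             val = sp$val, max_epochs = 60L, seed = 3L)
    list(model = model, hc = hc)
  })
}

test_that("a single repetition's deviation equals its own RMSE", {
  fx <- assess_fixture()
  recs <- fx$hc[vapply(fx$hc, function(r)
    r$subject_id == "HC01" && r$repetition == 1L, logical(1))]
  dev <- subject_deviation(fx$model, recs, seed = 1L)
  expect_length(dev$rep_rmse, 1L)
  expect_equal(dev$subject_rmse, unname(dev$rep_rmse[1]))
  expect_gte(dev$subject_rmse, 0)
})

test_that("deviation aggregation is invariant to repetition order", {
  fx <- assess_fixture()
  recs <- fx$hc[vapply(fx$hc, function(r) r$subject_id == "HC02",
                       logical(1))]
  d1 <- subject_deviation(fx$model, recs, seed = 1L)
  d2 <- subject_deviation(fx$model, rev(recs), seed = 1L)
  expect_equal(d1$subject_rmse, d2$subject_rmse, tolerance = 1e-12)
  expect_equal(d1$subject_rmse, mean(d1$rep_rmse))
})

test_that("mixed subjects or gestures are rejected", {
  fx <- assess_fixture()
  mixed <- fx$hc[c(1, 9)]  # recordings from two different subjects
  expect_error(subject_deviation(fx$model, mixed),
               class = "mixed_recordings")
})

test_that("cohort report groups, summarizes and validates labels", {
  fx <- assess_fixture()
  cp <- make_cohort(2, "CP", gestures = "G1", reps = 2L, seed = 92L,
                    fs = 500, duration_s = 3, pathology = "coactivation")
  hc_sub <- fx$hc[vapply(fx$hc, function(r) r$repetition <= 2L,
                         logical(1))]
  rep <- cohort_report(fx$model, c(hc_sub, cp), grouping = "HCvsCP",
                       seed = 1L)
  expect_setequal(unique(rep$scores$label), c("HC", "CP"))
  expect_equal(nrow(rep$scores), 5L)
  expect_true(all(c("rmse_mean", "rmse_min", "rmse_max") %in%
                    names(rep$summaries)))

  expect_error(cohort_report(fx$model, hc_sub, grouping = "HCvsCP"),
               class = "single_group")
  expect_error(cohort_report(fx$model, c(hc_sub, cp), grouping = "MACS"),
               class = "missing_grouping")
})

test_that("tracking grouping reports the between-timepoint change", {
  fx <- assess_fixture()
  t1 <- make_cohort(1, "CP", gestures = "G1", reps = 2L, seed = 93L,
                    fs = 500, duration_s = 3, pathology = "tremor",
                    pathology_strength = 1)
  t2 <- make_cohort(1, "CP", gestures = "G1", reps = 2L, seed = 93L,
                    fs = 500, duration_s = 3, pathology = "tremor",
                    pathology_strength = 0.4)
  t2 <- lapply(t2, function(r) { r$subject_id <- "CP01b"; r })
  rep <- cohort_report(fx$model, c(t1, t2), grouping = "tracking",
                       labels = c(CP01 = "Exp1", CP01b = "Exp2"),
                       seed = 1L)
  expect_true(is.numeric(rep$tests$G1$delta))
  expect_length(rep$tests$G1$timepoint_means, 2L)
})
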