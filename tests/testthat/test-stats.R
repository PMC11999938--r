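# Oracles (oracle_u, oracle_h, oracle_friedman_stat, ...) come from
# helper-oracles.R.

test_that("Mann-Whitney U matches pair counting and exact enumeration", {
  mw <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(mw$statistic, 0)
  expect_equal(mann_whitney_u(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  expect_error(mann_whitney_u(c(1, 2), c(3, 4, 5)),
               class = "too_few_observations")

  set.seed(81)
  for (i in 1:12) {
    a <- sample(1:6, 5, replace = TRUE)  # replacement forces ties
    b <- sample(1:6, 5, replace = TRUE)
    got <- mann_whitney_u(a, b)
    expect_equal(got$statistic, oracle_u(a, b), tolerance = 1e-12)
    expect_equal(got$method, "exact")
    expect_equal(got$p_value, oracle_mw_exact_p(a, b), tolerance = 1e-12)
  }
})

test_that("Mann-Whitney normal approximation agrees with Kruskal-Wallis", {
  set.seed(82)
  for (i in 1:8) {
    a <- runif(7)
    b <- runif(8) + 0.2
    mw <- mann_whitney_u(a, b)
    expect_equal(mw$method, "normal")
    kw <- kruskal_wallis(list(a, b))
    expect_lt(abs(mw$p_value - kw$p_value), 0.02)
  }
})

test_that("Kruskal-Wallis handles identical groups and degenerate input", {
  kw <- kruskal_wallis(list(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3)))
  expect_equal(kw$statistic, 0, tolerance = 1e-12)
  expect_error(kruskal_wallis(list(rep(2, 3), rep(2, 4))),
               class = "degenerate_input")
  expect_error(kruskal_wallis(list(1, 2:3)), class = "too_few_observations")
})

test_that("Kruskal-Wallis H matches the rank-sum oracle with ties", {
  set.seed(83)
  for (i in 1:10) {
    groups <- list(sample(1:5, 3, TRUE), sample(1:5, 3, TRUE),
                   sample(1:5, 3, TRUE))
    if (length(unique(unlist(groups))) == 1L) next
    expect_equal(kruskal_wallis(groups)$statistic, oracle_h(groups),
                 tolerance = 1e-12)
  }
})

test_that("Friedman statistic matches the oracle and its edge cases", {
  const <- matrix(rep(c(2, 2, 2), 4), 4, byrow = TRUE)
  expect_equal(friedman(const)$statistic, 0)
  # balanced within-subject permutations of (1,2,3): uniform rank sums
  balanced <- rbind(c(1, 2, 3), c(2, 3, 1), c(3, 1, 2),
                    c(1, 3, 2), c(3, 2, 1), c(2, 1, 3))
  expect_equal(friedman(balanced)$statistic, 0, tolerance = 1e-12)

  set.seed(84)
  for (i in 1:8) {
    m <- matrix(sample(1:4, 15, TRUE), 5, 3)
    if (all(apply(m, 1, function(r) length(unique(r))) == 1L)) next
    expect_equal(friedman(m)$statistic, oracle_friedman_stat(m),
                 tolerance = 1e-12)
  }
  expect_error(friedman(matrix(c(1, NA, 2, 3, 4, 5), 2)),
               class = "missing_cells")
  expect_error(friedman(matrix(1:4, 2)), class = "too_few_observations")
})

test_that("Dunn-Bonferroni z, alpha and degenerate pairs are correct", {
  res4 <- dunn_bonferroni(list(a = 1:5, b = 6:10, c = 11:15, d = 16:20))
  expect_length(res4, 6L)
  expect_equal(res4[[1]]$alpha_adjusted, 0.05 / 6, tolerance = 1e-12)

  sep <- dunn_bonferroni(list(lo = 1:10, mid = 21:30, hi = 41:50))
  expect_equal(sep[[1]]$alpha_adjusted, 0.05 / 3, tolerance = 1e-12)
  expect_true(all(vapply(sep, function(x) x$p_value, numeric(1)) <
                    0.05 / 3))

  twin <- dunn_bonferroni(list(a = c(1, 3, 5), b = c(1, 3, 5),
                               c = c(10, 12, 14)))
  expect_lt(abs(twin[[1]]$statistic), 1e-12)

  # oracle recomputation of every z
  set.seed(85)
  groups <- list(sample(1:6, 3, TRUE), sample(1:6, 3, TRUE),
                 sample(1:6, 3, TRUE))
  got <- dunn_bonferroni(groups)
  x <- unlist(groups); r <- rank(x); N <- length(x)
  idx <- rep(1:3, lengths(groups))
  rbar <- tapply(r, idx, mean)
  tt <- table(r)
  tie_term <- sum(tt^3 - tt) / (12 * (N - 1))
  k <- 0L
  for (i in 1:2) for (j in (i + 1):3) {
    k <- k + 1L
    se <- sqrt((N * (N + 1) / 12 - tie_term) *
                 (1 / lengths(groups)[i] + 1 / lengths(groups)[j]))
    expect_equal(got[[k]]$statistic, unname((rbar[i] - rbar[j]) / se),
                 tolerance = 1e-12)
  }
  expect_error(dunn_bonferroni(list(1:3, 4:6)), class = "too_few_groups")
})

test_that("the Welch t utility reports a statistic and p-value", {
  res <- welch_t(rnorm(10, 0), rnorm(10, 2))
  expect_true(is.finite(res$statistic))
  expect_true(res$p_value >= 0 && res$p_value <= 1)
})
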