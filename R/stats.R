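# Rank-based group comparisons used by the assessment module. Mid-ranks
# everywhere; variance formulas carry the usual tie corrections.

group_comparison <- function(test, statistic, p_value,
                             alpha_adjusted = NA_real_, method = NA_character_,
                             ...) {
  structure(list(test = test, statistic = statistic, p_value = p_value,
                 alpha_adjusted = alpha_adjusted, method = method, ...),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s: statistic %.4g, p = %.4g%s\n",
              x$test, x$statistic, x$p_value,
              if (!is.na(x$alpha_adjusted))
                sprintf(" (adjusted alpha %.4g)", x$alpha_adjusted) else ""))
  invisible(x)
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum comparison of two independent groups with mid-rank
#' tie handling. The statistic is `U = R1 - n1 (n1 + 1) / 2` for the
#' first group (the number of pairs where an `a` observation exceeds a
#' `b` observation, counting ties as 1/2). For combined sample sizes up
#' to 12 the p-value is computed by exact enumeration of all group
#' assignments (valid under ties, unlike the classical exact tables);
#' larger samples use the tie-corrected normal approximation without
#' continuity correction.
#'
#' @param a,b numeric vectors, each with at least 3 observations.
#' @return a `group_comparison` with `statistic` (U for group `a`),
#'   `p_value` and `method` (`"exact"` or `"normal"`).
#' @export
mann_whitney_u <- function(a, b) {
  if (length(a) < 3L || length(b) < 3L) {
    stop_named("too_few_observations", "each group needs >= 3 observations")
  }
  n1 <- length(a)
  n2 <- length(b)
  N <- n1 + n2
  r <- rank(c(a, b))
  U1 <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  if (N <= 12L) {
    combos <- combn(N, n1)
    Us <- colSums(matrix(r[combos], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- mean(abs(Us - mu) >= abs(U1 - mu) - 1e-9)
    method <- "exact"
  } else {
    ties <- table(r)
    tie_term <- sum(ties^3 - ties) / (N * (N - 1))
    sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term)
    z <- (U1 - mu) / sqrt(sigma2)
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- "normal"
  }
  group_comparison("mann_whitney_u", statistic = U1, p_value = p,
                   method = method, U2 = n1 * n2 - U1, n = c(n1, n2))
}

# Tie-corrected H from pooled ranks and a group-index vector.
kw_h_from_ranks <- function(r, idx, sizes) {
  N <- length(r)
  h <- 12 / (N * (N + 1)) *
    sum(tapply(r, idx, sum)^2 / sizes) - 3 * (N + 1)
  ties <- table(r)
  h / (1 - sum(ties^3 - ties) / (N^3 - N))
}

#' Kruskal-Wallis test
#'
#' Nonparametric one-way comparison of k independent groups
#' (tie-corrected H statistic), the alternative to one-way ANOVA used to
#' compare network structures and severity grades. For pooled samples of
#' up to 10 observations the p-value is computed by exhaustive
#' enumeration of all group assignments (exact under ties); larger
#' samples use the chi-square approximation on k - 1 degrees of freedom.
#'
#' @param groups list of numeric vectors (>= 2 groups, each >= 2
#'   observations).
#' @return a `group_comparison` with the H statistic and p-value.
#' @export
kruskal_wallis <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  if (any(lengths(groups) < 2L)) {
    stop_named("too_few_observations", "each group needs >= 2 observations")
  }
  x <- unlist(groups, use.names = FALSE)
  if (length(unique(x)) == 1L) {
    stop_named("degenerate_input",
               "all observations identical: ranks have zero variance")
  }
  sizes <- lengths(groups)
  g <- factor(rep(seq_along(groups), sizes))
  kt <- stats::kruskal.test(x, g)
  stat <- unname(kt$statistic)
  N <- length(x)
  n_assignments <- exp(lfactorial(N) - sum(lfactorial(sizes)))
  if (N <= 10L && n_assignments <= 20000) {
    r <- rank(x)
    hs <- c()
    assign_rec <- function(remaining, idx_acc) {
      k <- length(idx_acc) + 1L
      if (k > length(sizes)) {
        idx <- integer(N)
        for (gi in seq_along(idx_acc)) idx[idx_acc[[gi]]] <- gi
        hs[length(hs) + 1L] <<- kw_h_from_ranks(r, idx, sizes)
        return(invisible())
      }
      if (k == length(sizes)) {
        assign_rec(integer(0), c(idx_acc, list(remaining)))
      } else {
        for (pick in as.data.frame(combn(remaining, sizes[k]))) {
          assign_rec(setdiff(remaining, pick), c(idx_acc, list(pick)))
        }
      }
    }
    assign_rec(seq_len(N), list())
    p <- mean(hs >= stat - 1e-9)
    method <- "exact_permutation"
  } else {
    p <- kt$p.value
    method <- "chi_square"
  }
  group_comparison("kruskal_wallis", statistic = stat, p_value = p,
                   method = method, df = unname(kt$parameter))
}

#' Friedman test for repeated measures
#'
#' Within-subject rank test across conditions (e.g. the same subjects
#' evaluated under several transfer strategies). When the number of
#' within-subject column permutations is small enough to enumerate
#' (`factorial(k)^n` up to 20000), the p-value is computed by exhaustive
#' permutation of each subject's row (exact under ties); otherwise the
#' chi-square approximation on k - 1 degrees of freedom is used.
#'
#' @param m subjects x conditions numeric matrix, no missing cells, at
#'   least 2 subjects and 3 conditions.
#' @return a `group_comparison` with the Friedman chi-square statistic
#'   and p-value.
#' @export
friedman <- function(m) {
  m <- as.matrix(m)
  if (anyNA(m)) stop_named("missing_cells", "missing cells are not allowed")
  if (ncol(m) < 3L || nrow(m) < 2L) {
    stop_named("too_few_observations",
               "need >= 2 subjects and >= 3 conditions")
  }
  n <- nrow(m)
  k <- ncol(m)
  ft <- stats::friedman.test(m)
  stat <- unname(ft$statistic)
  p <- ft$p.value
  r <- t(apply(m, 1L, rank))
  if (!is.finite(stat)) {
    # complete within-subject ties: 0/0 in the tie-corrected formula;
    # the rank sums are equal, so there is no effect by construction
    if (max(colSums(r)) - min(colSums(r)) < 1e-12) {
      stat <- 0
      p <- 1
    }
  } else if (factorial(k)^n <= 20000) {
    # exact within-subject permutation null: the tie structure (and so
    # the denominator) is permutation-invariant, only the column sums
    # of the rank matrix move
    ties <- apply(r, 1L, function(row) {
      tt <- table(row)
      sum(tt^3 - tt)
    })
    denom <- n * k * (k + 1) - sum(ties) / (k - 1)
    perms <- as.matrix(expand.grid(rep(list(seq_len(k)), k)))
    perms <- perms[apply(perms, 1L, function(pp)
      length(unique(pp)) == k), , drop = FALSE]
    row_variants <- lapply(seq_len(n), function(i)
      matrix(r[i, t(perms)], nrow = nrow(perms), byrow = TRUE))
    combos <- as.matrix(expand.grid(rep(list(seq_len(nrow(perms))), n)))
    S <- matrix(0, nrow(combos), k)
    for (i in seq_len(n)) S <- S + row_variants[[i]][combos[, i], ]
    stats_all <- 12 * rowSums((S - n * (k + 1) / 2)^2) / denom
    p <- mean(stats_all >= stat - 1e-9)
    return(group_comparison("friedman", statistic = stat, p_value = p,
                            method = "exact_permutation",
                            df = unname(ft$parameter)))
  }
  group_comparison("friedman", statistic = stat, p_value = p,
                   method = "chi_square", df = unname(ft$parameter))
}

#' Dunn's post-hoc test with Bonferroni-adjusted significance level
#'
#' Pairwise mean-rank comparisons following a significant Kruskal-Wallis
#' test: `z = (Rbar_i - Rbar_j) / sqrt((N (N + 1) / 12 - T) (1/n_i +
#' 1/n_j))` with tie term `T = sum(t^3 - t) / (12 (N - 1))`. The
#' significance level is Bonferroni-adjusted to `0.05 / choose(k, 2)`
#' (0.0083 for four groups, as used for the MACS-grade comparisons).
#'
#' @param groups list of >= 3 numeric vectors.
#' @return list of `group_comparison` objects, one per pair, each with
#'   `pair`, the z statistic, unadjusted `p_value` and `alpha_adjusted`.
#' @export
dunn_bonferroni <- function(groups) {
  stopifnot(is.list(groups))
  k <- length(groups)
  if (k < 3L) stop_named("too_few_groups", "Dunn's test needs >= 3 groups")
  x <- unlist(groups, use.names = FALSE)
  n <- lengths(groups)
  N <- length(x)
  r <- rank(x)
  gidx <- rep(seq_len(k), n)
  rbar <- tapply(r, gidx, mean)
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  alpha_adj <- 0.05 / choose(k, 2)
  labels <- names(groups) %||% as.character(seq_len(k))
  if (is.null(names(groups))) names(groups) <- labels
  out <- list()
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      se <- sqrt((N * (N + 1) / 12 - tie_term) * (1 / n[i] + 1 / n[j]))
      z <- (rbar[[i]] - rbar[[j]]) / se
      out[[length(out) + 1L]] <- group_comparison(
        "dunn_bonferroni", statistic = unname(z),
        p_value = min(1, 2 * pnorm(-abs(z))),
        alpha_adjusted = alpha_adj, method = "normal",
        pair = c(labels[i], labels[j]))
    }
  }
  out
}

#' Welch two-sample t-test
#'
#' Convenience wrapper for the independent-samples comparison used for
#' group ages (Welch variant by default).
#'
#' @param a,b numeric vectors.
#' @param var_equal pool variances instead of Welch.
#' @return a `group_comparison`.
#' @export
welch_t <- function(a, b, var_equal = FALSE) {
  tt <- stats::t.test(a, b, var.equal = var_equal)
  group_comparison("t_test", statistic = unname(tt$statistic),
                   p_value = tt$p.value, method = tt$method)
}
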