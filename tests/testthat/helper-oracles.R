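# Brute-force oracles: U by pair counting, H and the Friedman statistic
# by direct rank-sum formulas, p-values by exhaustive enumeration or
# permutation. They share no code with the package implementations.

oracle_u <- function(a, b) {
  u <- 0
  for (x in a) for (y in b) u <- u + (x > y) + 0.5 * (x == y)
  u
}

oracle_mw_exact_p <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a)
  mu <- n1 * length(b) / 2
  u_obs <- oracle_u(a, b)
  picks <- combn(length(pooled), n1)
  us <- apply(picks, 2L, function(ix) oracle_u(pooled[ix], pooled[-ix]))
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

oracle_h <- function(groups) {
  x <- unlist(groups)
  N <- length(x)
  r <- rank(x)
  idx <- rep(seq_along(groups), lengths(groups))
  h <- 12 / (N * (N + 1)) *
    sum(tapply(r, idx, sum)^2 / lengths(groups)) - 3 * (N + 1)
  ties <- table(r)
  h / (1 - sum(ties^3 - ties) / (N^3 - N))
}

# Exhaustive permutation p-value for Kruskal-Wallis: every assignment of
# the pooled observations to the group sizes.
oracle_kw_perm_p <- function(groups) {
  x <- unlist(groups)
  sizes <- lengths(groups)
  h_obs <- oracle_h(groups)
  stats_all <- c()
  recurse <- function(remaining, acc) {
    if (length(acc) == length(sizes)) {
      stats_all <<- c(stats_all, oracle_h(lapply(acc, function(i) x[i])))
      return(invisible())
    }
    k <- length(acc) + 1L
    for (pick in as.data.frame(combn(remaining, sizes[k]))) {
      recurse(setdiff(remaining, pick), c(acc, list(pick)))
    }
  }
  recurse(seq_along(x), list())
  mean(stats_all >= h_obs - 1e-9)
}

oracle_friedman_stat <- function(m) {
  r <- t(apply(m, 1L, rank))
  n <- nrow(m); k <- ncol(m)
  ties <- apply(r, 1L, function(row) {
    tt <- table(row)
    sum(tt^3 - tt)
  })
  (12 * sum((colSums(r) - n * (k + 1) / 2)^2)) /
    (n * k * (k + 1) - sum(ties) / (k - 1))
}

# Exhaustive within-subject permutation p-value for the Friedman test.
oracle_friedman_perm_p <- function(m) {
  k <- ncol(m)
  perms <- as.matrix(expand.grid(rep(list(seq_len(k)), k)))
  perms <- perms[apply(perms, 1L, function(p) length(unique(p)) == k), ,
                 drop = FALSE]
  s_obs <- oracle_friedman_stat(m)
  idx <- expand.grid(rep(list(seq_len(nrow(perms))), nrow(m)))
  stats_all <- apply(idx, 1L, function(choice) {
    mm <- m
    for (i in seq_len(nrow(m))) mm[i, ] <- m[i, perms[choice[i], ]]
    oracle_friedman_stat(mm)
  })
  mean(stats_all >= s_obs - 1e-9)
}
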