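# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Permutation-test p-value for a one-way layout: the fraction of label
# permutations whose F statistic (computed from scratch) is >= the observed.
perm_anova_p <- function(groups, n_perm = 2000, seed = 42) {
  set.seed(seed)
  f_stat <- function(values, labels) {
    k <- length(unique(labels))
    ni <- tabulate(labels, k)
    means <- tapply(values, labels, mean)
    grand <- mean(values)
    ssb <- sum(ni * (means - grand)^2)
    ssw <- sum((values - means[labels])^2)
    (ssb / (k - 1)) / (ssw / (length(values) - k))
  }
  values <- unlist(groups)
  labels <- rep(seq_along(groups), lengths(groups))
  obs <- f_stat(values, labels)
  hits <- sum(replicate(n_perm, f_stat(sample(values), labels) >= obs))
  (hits + 1) / (n_perm + 1)
}

# Permutation p for a two-sample comparison using the Welch statistic.
perm_welch_p <- function(a, b, n_perm = 4000, seed = 42) {
  set.seed(seed)
  wstat <- function(x, y) {
    (mean(x) - mean(y)) / sqrt(var(x) / length(x) + var(y) / length(y))
  }
  obs <- abs(wstat(a, b))
  pool <- c(a, b)
  na <- length(a)
  hits <- sum(replicate(n_perm, {
    idx <- sample(length(pool), na)
    abs(wstat(pool[idx], pool[-idx])) >= obs
  }))
  (hits + 1) / (n_perm + 1)
}

# Exhaustive hypergeometric upper tail by enumerating all selections of size
# n from a universe of size N (feasible for N <= 12).
enum_hyper_p <- function(k, K, n, N) {
  sel <- combn(N, n)
  in_term <- seq_len(K)  # term = first K elements, wlog
  hits <- apply(sel, 2, function(s) sum(s %in% in_term) >= k)
  mean(hits)
}

# All set partitions of 1..n (Bell-number enumeration, n <= 8).
all_partitions <- function(n) {
  if (n == 1) return(list(list(1L)))
  smaller <- all_partitions(n - 1L)
  out <- list()
  for (p in smaller) {
    for (i in seq_along(p)) {
      q <- p
      q[[i]] <- c(q[[i]], n)
      out[[length(out) + 1L]] <- q
    }
    out[[length(out) + 1L]] <- c(p, list(n))
  }
  out
}

# Average pairwise Pearson r of a set of profile rows, computed directly.
avg_pairwise_r <- function(profiles, members) {
  if (length(members) < 2) return(NA_real_)
  R <- cor(t(profiles[members, , drop = FALSE]))
  mean(R[upper.tri(R)])
}

# Random triples with spread-out scales, for property tests.
random_triples <- function(n, seed = 1) {
  set.seed(seed)
  m <- matrix(runif(3 * n, -10, 10), ncol = 3)
  m * 10^sample(-2:2, n, replace = TRUE)  # per-row scale
}
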