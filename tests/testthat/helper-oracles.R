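# Independent oracles used to pin expected values. These deliberately avoid
# the package's own code paths: residual regression via lm(), permutation
# resampling, direct summation over contingency cells, and exhaustive 1-D
# split scanning.

# Partial correlation as the correlation of least-squares residuals.
oracle_partial_cor <- function(a, b, c) {
  ra <- stats::resid(stats::lm(a ~ c))
  rb <- stats::resid(stats::lm(b ~ c))
  stats::cor(ra, rb)
}

# Conditional-permutation p-value: permute the residuals of a on cond and
# recompute the residual correlation each time.
oracle_perm_pvalue <- function(a, b, cond, n_perm = 10000L, seed = 1L) {
  ra <- stats::resid(stats::lm(a ~ cond))
  rb <- stats::resid(stats::lm(b ~ cond))
  r_obs <- abs(stats::cor(ra, rb))
  withr::with_seed(seed, {
    perms <- replicate(n_perm, abs(stats::cor(sample(ra), rb)))
  })
  (1 + sum(perms >= r_obs)) / (n_perm + 1)
}

# Conditional mutual information in nats by direct summation over all cells.
oracle_cmi_nats <- function(a, b, c) {
  n <- length(a)
  tab <- table(a, b, c)
  p_abc <- tab / n
  p_c <- apply(tab, 3, sum) / n
  p_ac <- apply(tab, c(1, 3), sum) / n
  p_bc <- apply(tab, c(2, 3), sum) / n
  total <- 0
  for (i in seq_len(dim(tab)[1])) for (j in seq_len(dim(tab)[2])) {
    for (k in seq_len(dim(tab)[3])) {
      p <- p_abc[i, j, k]
      if (p > 0) total <- total + p * log(p * p_c[k] / (p_ac[i, k] * p_bc[j, k]))
    }
  }
  unname(total)
}

# Best 2-partition of a 1-D series by scanning every split of the sorted
# values; returns the two group means.
oracle_best_split_1d <- function(v) {
  sv <- sort(v)
  n <- length(sv)
  best <- list(wss = Inf, centers = NULL)
  for (i in 1:(n - 1)) {
    left <- sv[1:i]; right <- sv[(i + 1):n]
    wss <- sum((left - mean(left))^2) + sum((right - mean(right))^2)
    if (wss < best$wss) best <- list(wss = wss, centers = c(mean(left), mean(right)))
  }
  sort(best$centers)
}

# Shorthand generators for the shipped default scenarios.
chain_cfg <- function(n, seed, ...) {
  continuous_scm_config("chain_x_to_y", n = n, seed = seed, ...)
}

confounded_cfg <- function(n, seed) {
  continuous_scm_config("confounded", beta = 0, delta = 1, gamma = 1,
                        alpha_y = 1, iv_y_levels = c(-2, 0, 2),
                        n = n, seed = seed)
}

oracle_iv <- function(values, source_var) latentiv:::oracle_instrument(values, source_var)
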