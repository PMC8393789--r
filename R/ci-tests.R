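# Conditional-independence tests: the exact t-test for first-order partial
# correlation (continuous data) and a G-test of conditional mutual
# information (discrete data). Both condition on a single variable -- the
# decision procedure never needs larger conditioning sets.

new_ci_test_result <- function(statistic, dof, p_value, test, n) {
  structure(
    list(statistic = statistic, dof = dof, p_value = p_value,
         test = test, n = as.integer(n)),
    class = "liv_ci_test"
  )
}

#' @export
print.liv_ci_test <- function(x, ...) {
  cat(sprintf("Conditional-independence test (%s)\n", x$test))
  cat(sprintf("  statistic = %.4g, df = %g, p = %.4g, n = %d\n",
              x$statistic, x$dof, x$p_value, x$n))
  invisible(x)
}

#' @method tidy liv_ci_test
#' @export
tidy.liv_ci_test <- function(x, ...) {
  tibble::tibble(test = x$test, statistic = x$statistic, dof = x$dof,
                 p_value = x$p_value, n = x$n)
}

#' First-order partial correlation
#'
#' Correlation between `a` and `b` after linearly removing `c`:
#' \deqn{r_{ab.c} = (r_{ab} - r_{ac} r_{bc}) / \sqrt{(1 - r_{ac}^2)(1 - r_{bc}^2)}}
#'
#' Degenerate conventions, in precedence order: if `a` and `b` are exactly
#' collinear the result is their plain correlation (+1 or -1; no amount of
#' conditioning breaks a perfect dependence). Otherwise, if the residual of
#' `a` on `c` (or of `b` on `c`) is identically zero -- the variable is an
#' exact linear function of the conditioning series -- the partial
#' correlation is defined as 0: no variation remains in which a conditional
#' association could live. If `c` is constant the plain Pearson correlation
#' of `a` and `b` is returned (conditioning on a constant is conditioning on
#' nothing).
#'
#' @param a,b Numeric vectors, equal length, each non-constant.
#' @param c Numeric conditioning vector of the same length.
#' @return A correlation in \[-1, 1\].
#' @export
partial_correlation <- function(a, b, c) {
  n <- length(a)
  if (length(b) != n || length(c) != n) stop_length_mismatch(n, length(b), length(c))
  if (n < 3L) stop_insufficient_sample(n, 3L)
  if (is_constant(a)) stop_constant_input("a")
  if (is_constant(b)) stop_constant_input("b")
  r_ab <- cor(a, b)
  # exactly collinear pair: conditioning cannot break a perfect dependence
  if (abs(r_ab) == 1) return(r_ab)
  if (is_constant(c)) return(clamp_cor(r_ab))
  r_ac <- cor(a, c)
  r_bc <- cor(b, c)
  den_a <- 1 - r_ac^2
  den_b <- 1 - r_bc^2
  # |r_ac| = 1 means the residual of a on c is the zero vector
  if (den_a <= 1e-12 || den_b <= 1e-12) return(0)
  clamp_cor((r_ab - r_ac * r_bc) / sqrt(den_a * den_b))
}

clamp_cor <- function(r) max(-1, min(1, r))

#' Exact t-test for conditional independence of continuous series
#'
#' Tests `a` independent of `b` given `cond` through the first-order partial
#' correlation r: the statistic t = r sqrt(df) / sqrt(1 - r^2) is referred to
#' a t distribution with df = n - 3 degrees of freedom (two-sided). Large
#' p-values indicate conditional independence. Rows with a missing value in
#' any of the three series are dropped; if `cond` is constant the test
#' degrades to the marginal correlation test with df = n - 2 (with a
#' warning).
#'
#' @inheritParams partial_correlation
#' @param cond Numeric conditioning vector.
#' @return A `liv_ci_test` result (statistic, dof, p_value, test, n).
#' @export
ci_test_continuous <- function(a, b, cond) {
  n0 <- length(a)
  if (length(b) != n0 || length(cond) != n0) {
    stop_length_mismatch(n0, length(b), length(cond))
  }
  keep <- complete.cases(a, b, cond) & is.finite(a) & is.finite(b) & is.finite(cond)
  a <- as.numeric(a[keep]); b <- as.numeric(b[keep]); cond <- as.numeric(cond[keep])
  n <- length(a)
  if (n < 8L) stop_insufficient_sample(n, 8L)
  if (is_constant(a)) stop_constant_input("a")
  if (is_constant(b)) stop_constant_input("b")
  if (is_constant(cond)) {
    warn("conditioning series is constant; falling back to the marginal correlation test (df = n - 2).",
         class = "liv_warn_constant_cond")
    r <- clamp_cor(cor(a, b))
    df <- n - 2
  } else {
    r <- partial_correlation(a, b, cond)
    df <- n - 3
  }
  if (1 - r^2 <= 0) {
    t_stat <- sign(r) * Inf
    p <- 0
  } else {
    t_stat <- r * sqrt(df) / sqrt(1 - r^2)
    p <- 2 * pt(-abs(t_stat), df = df)
  }
  new_ci_test_result(t_stat, df, p, "partial_corr_t", n)
}

#' G-test of conditional mutual information for discrete series
#'
#' Tests `a` independent of `b` given `cond` for integer- or factor-coded
#' series. The statistic is G = 2 N CMI(a; b | cond), with the conditional
#' mutual information in nats estimated from the empirical three-way
#' contingency table (0 log 0 := 0), referred to a chi-square distribution.
#' Degrees of freedom sum, over the strata of `cond`, the product
#' (rows - 1)(cols - 1) counting only rows and columns with nonzero marginals
#' in that stratum; this zero-margin adjustment keeps the asymptotic
#' chi-square reference usable on sparse tables. A table whose adjusted
#' degrees of freedom are 0 is rejected as degenerate.
#'
#' @param a,b Discrete series (integer, factor or character), equal length,
#'   each with at least 2 observed levels.
#' @param cond Discrete conditioning series.
#' @return A `liv_ci_test` result (statistic, dof, p_value, test, n).
#' @export
ci_test_discrete <- function(a, b, cond) {
  n0 <- length(a)
  if (length(b) != n0 || length(cond) != n0) {
    stop_length_mismatch(n0, length(b), length(cond))
  }
  keep <- !(is.na(a) | is.na(b) | is.na(cond))
  a <- factor(a[keep]); b <- factor(b[keep]); cond <- factor(cond[keep])
  n <- length(a)
  if (n < 1L) stop_insufficient_sample(n, 1L)
  if (nlevels(a) < 2L) stop_constant_input("a")
  if (nlevels(b) < 2L) stop_constant_input("b")
  tab <- table(a, b, cond)
  g <- 0
  dof <- 0L
  for (s in seq_len(dim(tab)[3L])) {
    slice <- tab[, , s]
    ns <- sum(slice)
    if (ns == 0) next
    rs <- rowSums(slice)
    cs <- colSums(slice)
    nz <- slice > 0
    if (any(nz)) {
      expected <- outer(rs, cs) / ns
      g <- g + 2 * sum(slice[nz] * log(slice[nz] / expected[nz]))
    }
    dof <- dof + max(0L, (sum(rs > 0) - 1L) * (sum(cs > 0) - 1L))
  }
  if (dof == 0L) stop_degenerate_table()
  g <- max(0, g)
  p <- pchisq(g, df = dof, lower.tail = FALSE)
  new_ci_test_result(g, dof, p, "cond_mi_g", n)
}

#' Run the conditional-independence test of a given family
#'
#' Dispatches to [ci_test_continuous()] or [ci_test_discrete()]. With
#' `test = "auto"` the discrete test is chosen iff both `a` and `b` have at
#' most 10 distinct observed values.
#'
#' @inheritParams ci_test_continuous
#' @param test One of `"auto"`, `"continuous"`, `"discrete"`.
#' @return A `liv_ci_test` result.
#' @export
ci_test <- function(a, b, cond, test = c("auto", "continuous", "discrete")) {
  test <- match.arg(test)
  if (test == "auto") test <- resolve_test_family(a, b)
  switch(test,
         continuous = ci_test_continuous(a, b, cond),
         discrete = ci_test_discrete(a, b, cond))
}

resolve_test_family <- function(a, b, max_levels = 10L) {
  discrete <- length(unique(a)) <= max_levels && length(unique(b)) <= max_levels
  family <- if (discrete) "discrete" else "continuous"
  inform(sprintf("test family 'auto' resolved to '%s'.", family),
         class = "liv_msg_auto_test")
  family
}
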