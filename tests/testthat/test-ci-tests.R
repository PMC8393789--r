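test_that("partial correlation matches the residual-regression oracle", {
  # identical variables: correlation of a variable with itself is 1
  expect_equal(partial_correlation(c(1, 2, 3, 4), c(1, 2, 3, 4), c(4, 3, 2, 1)), 1)

  # independent draws conditioned on their sum: negative, and equal to the
  # correlation of least-squares residuals
  withr::with_seed(11, {
    a <- rnorm(200); b <- rnorm(200); c <- a + b
  })
  r <- partial_correlation(a, b, c)
  expect_lt(r, 0)
  expect_equal(r, oracle_partial_cor(a, b, c), tolerance = 1e-10)

  # nonlinear dependence survives linear conditioning: a quadratic and a
  # cluster-center-style step function of the same variable stay partially
  # correlated given that variable
  a2 <- as.numeric(1:8)
  b2 <- a2^2
  step2 <- rep(c(2.5, 6.5), each = 4) # 2-cluster center series of a2
  expect_equal(partial_correlation(b2, step2, a2),
               oracle_partial_cor(b2, step2, a2), tolerance = 1e-10)
  expect_gt(abs(partial_correlation(b2, step2, a2)), 0)

  # random instances
  for (r in 1:10) {
    withr::with_seed(100 + r, {
      a <- rnorm(40); b <- 0.5 * a + rnorm(40); c <- runif(40) + 0.3 * a
    })
    expect_equal(partial_correlation(a, b, c), oracle_partial_cor(a, b, c),
                 tolerance = 1e-10)
  }
})

test_that("partial correlation degenerate conventions", {
  withr::with_seed(5, { c <- rnorm(30); b <- rnorm(30) })
  a <- 2 * c + 1 # zero residual after conditioning on c
  expect_identical(partial_correlation(a, b, c), 0)
  # constant conditioning falls back to the plain Pearson correlation
  expect_equal(partial_correlation(a, b, rep(1, 30)), cor(a, b))
  expect_error(partial_correlation(rep(1, 30), b, c),
               class = "liv_error_constant_input")
  expect_error(partial_correlation(b, rep(0, 30), c),
               class = "liv_error_constant_input")
})

test_that("continuous CI test: dependence, missing rows, small samples", {
  withr::with_seed(21, { a <- rnorm(50); cond <- rnorm(50) })
  res <- ci_test_continuous(a, a, cond)
  expect_lt(res$p_value, 1e-10)
  expect_equal(res$dof, 47) # n - 3

  # rows with any missing value are dropped; n counts complete rows
  a2 <- c(a, NA); b2 <- c(a, 1); cond2 <- c(cond, 0.5)
  expect_equal(ci_test_continuous(a2, b2, cond2)$n, 50L)

  expect_error(ci_test_continuous(rnorm(5), rnorm(5), rnorm(5)),
               class = "liv_error_insufficient_sample")
  expect_warning(ci_test_continuous(a, rnorm(50), rep(3, 50)),
                 class = "liv_warn_constant_cond")
})

test_that("continuous CI test agrees with the conditional-permutation oracle", {
  for (r in 1:12) {
    withr::with_seed(300 + r, {
      n <- 30
      cond <- rnorm(n)
      a <- 0.6 * cond + rnorm(n)
      b <- 0.4 * cond + (r %% 3 == 0) * 0.5 * a + rnorm(n)
    })
    p_analytic <- ci_test_continuous(a, b, cond)$p_value
    p_perm <- oracle_perm_pvalue(a, b, cond, n_perm = 4000L, seed = r)
    expect_lt(abs(p_analytic - p_perm), 0.05)
  }
})

test_that("discrete CI test matches brute-force conditional mutual information", {
  # exact in-sample independence: all four cells equal within each stratum
  a <- rep(c(0, 0, 1, 1), 4); b <- rep(c(0, 1, 0, 1), 4)
  cond <- rep(c(0, 1), each = 8)
  res <- ci_test_discrete(a, b, cond)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)

  # deterministic copy: CMI = ln 2 nats, G = 2 N ln 2
  a <- rep(c(0L, 1L), 50)
  res <- ci_test_discrete(a, a, rep(0L, 100))
  expect_equal(res$statistic, 2 * 100 * log(2), tolerance = 1e-10)

  # random 2x2x2 tables against direct summation
  for (r in 1:20) {
    withr::with_seed(400 + r, {
      a <- rbinom(60, 1, 0.5); b <- rbinom(60, 1, runif(1, 0.3, 0.7))
      cond <- rbinom(60, 1, 0.5)
    })
    res <- tryCatch(ci_test_discrete(a, b, cond),
                    liv_error_constant_input = function(e) NULL)
    if (!is.null(res)) {
      expect_equal(res$statistic, 2 * 60 * oracle_cmi_nats(a, b, cond),
                   tolerance = 1e-10)
    }
  }
})

test_that("discrete CI test dof rule and degenerate tables", {
  # strata where a is constant have zero nonzero-margin dof; only the mixed
  # stratum counts, so the total dof is exactly 1
  a <- c(rep(0, 10), rep(1, 10), rep(c(0, 1), 5))
  b <- rep(c(0, 1), 15)
  cond <- rep(c(0, 1, 2), each = 10)
  res <- ci_test_discrete(a, b, cond)
  expect_equal(res$dof, 1)

  # every stratum degenerate: a constant within each stratum of cond = a
  a <- rep(c(0, 1), each = 10)
  b <- rep(c(0, 1), 10)
  expect_error(ci_test_discrete(a, b, a), class = "liv_error_degenerate_table")
})

test_that("CI tests are symmetric in their first two arguments", {
  withr::with_seed(7, {
    a <- rnorm(60); b <- 0.5 * a + rnorm(60); cond <- rnorm(60)
    da <- rbinom(60, 1, 0.5); db <- rbinom(60, 1, 0.4); dc <- rbinom(60, 2, 0.5)
  })
  r1 <- ci_test_continuous(a, b, cond); r2 <- ci_test_continuous(b, a, cond)
  expect_equal(r1$statistic, r2$statistic)
  expect_equal(r1$p_value, r2$p_value)
  d1 <- ci_test_discrete(da, db, dc); d2 <- ci_test_discrete(db, da, dc)
  expect_equal(d1$statistic, d2$statistic)
  expect_equal(d1$p_value, d2$p_value)
  expect_equal(d1$dof, d2$dof)
})

test_that("continuous p-values are affine invariant, discrete label invariant", {
  withr::with_seed(8, {
    a <- rnorm(50); b <- 0.3 * a + rnorm(50); cond <- rnorm(50)
  })
  p0 <- ci_test_continuous(a, b, cond)$p_value
  p1 <- ci_test_continuous(3 * a - 2, -0.5 * b + 7, 10 * cond + 1)$p_value
  expect_equal(p0, p1, tolerance = 1e-12)

  withr::with_seed(9, {
    da <- rbinom(80, 1, 0.5); db <- rbinom(80, 1, 0.4); dc <- rbinom(80, 1, 0.5)
  })
  q0 <- ci_test_discrete(da, db, dc)$p_value
  q1 <- ci_test_discrete(5 - da, 10 * db + 3, 1 - dc)$p_value
  expect_equal(q0, q1, tolerance = 1e-12)
})

test_that("both tests are calibrated under true conditional independence", {
  # continuous: linear-Gaussian null a <- cond -> b
  rej_c <- vapply(1:1000, function(r) {
    withr::with_seed(5000 + r, {
      cond <- rnorm(1000)
      a <- 0.7 * cond + rnorm(1000)
      b <- 0.7 * cond + rnorm(1000)
    })
    ci_test_continuous(a, b, cond)$p_value <= 0.05
  }, logical(1))
  expect_gte(mean(rej_c), 0.03)
  expect_lte(mean(rej_c), 0.07)

  # discrete: product CPTs given the stratum
  rej_d <- vapply(1:1000, function(r) {
    withr::with_seed(6000 + r, {
      cond <- rbinom(1000, 1, 0.5)
      a <- rbinom(1000, 1, ifelse(cond == 1, 0.7, 0.3))
      b <- rbinom(1000, 1, ifelse(cond == 1, 0.6, 0.4))
    })
    ci_test_discrete(a, b, cond)$p_value <= 0.05
  }, logical(1))
  expect_gte(mean(rej_d), 0.03)
  expect_lte(mean(rej_d), 0.07)
})

test_that("auto test family resolves by distinct-value count", {
  withr::with_seed(3, { x <- rnorm(100); d <- rbinom(100, 1, 0.5) })
  expect_message(f1 <- latentiv:::resolve_test_family(d, 1 - d),
                 class = "liv_msg_auto_test")
  expect_identical(f1, "discrete")
  suppressMessages(expect_identical(latentiv:::resolve_test_family(x, d), "continuous"))
})
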