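test_that("cluster_1d degenerate and exact cases", {
  withr::with_seed(1, v <- rnorm(40))
  # single cluster: the all-mean series
  s1 <- cluster_1d(v, 1, seed = 2)
  expect_equal(s1$values, rep(mean(v), 40))
  # one cluster per distinct point: identity
  sN <- cluster_1d(v, 40, seed = 3)
  expect_equal(sort(unique(sN$values)), sort(v))
  expect_equal(sN$values, v)
  # k above the number of distinct values is reduced
  vd <- rep(c(0, 1, 2), each = 5)
  expect_message(sr <- cluster_1d(vd, 10, seed = 4), class = "liv_msg_k_reduced")
  expect_equal(sr$k, 3L)
  # constant input warns and returns the mean series
  expect_warning(sc <- cluster_1d(rep(2, 20), 3, seed = 5),
                 class = "liv_warn_constant_cluster")
  expect_equal(sc$values, rep(2, 20))
})

test_that("cluster_1d finds the optimal 2-partition of two separated blobs", {
  withr::with_seed(42, v <- c(rnorm(100, -5, 0.1), rnorm(100, 5, 0.1)))
  fit <- cluster_1d(v, 2, seed = 7)
  expect_equal(sort(unique(fit$values)), oracle_best_split_1d(v), tolerance = 1e-6)
})

test_that("instrument series values are constant within label classes", {
  withr::with_seed(6, v <- rnorm(120))
  s <- cluster_1d(v, 4, seed = 8)
  per_label <- tapply(s$values, s$labels, function(z) length(unique(z)))
  expect_true(all(per_label == 1))
  expect_lte(length(unique(s$values)), 4)
})

test_that("cluster_2d handles a constant coordinate and k = 1", {
  withr::with_seed(10, v1 <- rnorm(60))
  both <- cluster_2d(v1, rep(3, 60), 4, seed = 11)
  ref <- cluster_1d(v1, 4, seed = 11, source = "joint_x")
  expect_equal(both$x$values, ref$values, tolerance = 1e-9)
  expect_equal(both$y$values, rep(3, 60))

  withr::with_seed(12, v2 <- rnorm(60))
  k1 <- cluster_2d(v1, v2, 1, seed = 13)
  expect_equal(k1$x$values, rep(mean(v1), 60))
  expect_equal(k1$y$values, rep(mean(v2), 60))
})

test_that("cluster_2d recovers well-separated blob centers", {
  withr::with_seed(14, {
    mx <- c(-6, 0, 6); my <- c(5, -5, 0)
    g <- sample(1:3, 300, replace = TRUE)
    v1 <- mx[g] + rnorm(300, 0, 0.3)
    v2 <- my[g] + rnorm(300, 0, 0.3)
  })
  fit <- cluster_2d(v1, v2, 3, seed = 15)
  got <- sort(unique(fit$x$values))
  truth <- sort(tapply(v1, g, mean))
  expect_equal(got, as.numeric(truth), tolerance = 0.05)
})

test_that("build_iv_candidates is deterministic and symmetric on x == y", {
  withr::with_seed(16, x <- c(rnorm(60, -3), rnorm(60, 3)))
  d <- tibble::tibble(x = x, y = x)
  c1 <- build_iv_candidates(d, k = 2, seed = 99)
  c2 <- build_iv_candidates(d, k = 2, seed = 99)
  expect_identical(c1, c2)
  expect_equal(sort(c1$ixx$values), sort(c1$iyy$values))
})

test_that("trimodal series yields centers near the component means", {
  withr::with_seed(17, {
    comp <- sample(c(-2, 0, 2), 400, replace = TRUE)
    x <- comp + rnorm(400, 0, 0.2)
    y <- x + rnorm(400, 0, 0.3)
  })
  cand <- build_iv_candidates(tibble::tibble(x = x, y = y), k = 3, seed = 21)
  centers <- sort(unique(cand$ixx$values))
  expect_length(centers, 3)
  truth <- sort(tapply(x, comp, mean))
  expect_equal(centers, as.numeric(truth), tolerance = 0.1)
})

test_that("select_instruments implements the distance rule and tie-break", {
  mk <- function(values, sd = 1) latentiv:::new_instrument_series(
    values, as.integer(factor(values)), "x_only", length(unique(values)), 0, sd)
  a <- mk(rep(c(-1, 1), 10))
  b <- mk(rep(c(-1, 1), 10))      # identical: dist_x = 0
  c1 <- mk(rep(c(-2, 2), 10))
  c2 <- mk(rep(c(-1, 2), 10))     # differs: dist_y > 0
  sel <- select_instruments(a, b, c1, c2)
  expect_equal(sel$dist_x, 0)
  expect_identical(sel$branch, "x_simpler")
  expect_identical(sel$ix$values, a$values)
  expect_identical(sel$iy$values, c2$values)

  # exact tie goes to the else branch (y_simpler)
  sel_tie <- select_instruments(a, c2, a, c2)
  expect_equal(sel_tie$dist_x, sel_tie$dist_y)
  expect_identical(sel_tie$branch, "y_simpler")
})

test_that("symmetric input through the same seed path ties to y_simpler", {
  withr::with_seed(30, x <- c(rnorm(50, -2), rnorm(50, 2)))
  ixx <- cluster_1d(x, 2, seed = 31)
  iyy <- cluster_1d(x, 2, seed = 31)
  joint <- cluster_2d(x, x, 2, seed = 32)
  sel <- select_instruments(ixx, joint$x, iyy, joint$y)
  expect_equal(sel$dist_x, sel$dist_y)
  expect_identical(sel$branch, "y_simpler")
})

test_that("branch is scale invariant and mirrors under argument swap", {
  withr::with_seed(33, {
    comp <- sample(c(-2, 0, 2), 400, replace = TRUE)
    x <- comp + rnorm(400, 0, 0.2)
    y <- x + rnorm(400, 0, 0.4)
  })
  sel <- approximate_instruments(tibble::tibble(x = x, y = y), k = 3, seed = 44)
  sel_scaled <- approximate_instruments(tibble::tibble(x = 1000 * x, y = y),
                                        k = 3, seed = 44)
  expect_identical(sel$branch, sel_scaled$branch)

  sel_sw <- approximate_instruments(tibble::tibble(x = y, y = x), k = 3, seed = 44)
  if (sel$dist_x != sel$dist_y) {
    expect_identical(sort(c(sel$branch, sel_sw$branch)),
                     c("x_simpler", "y_simpler"))
  }
})

test_that("joint clustering barely moves the cause's centers on trimodal chains", {
  branches <- vapply(1:50, function(r) {
    withr::with_seed(600 + r, {
      comp <- sample(c(-2, 0, 2), 400, replace = TRUE)
      x <- comp + rnorm(400, 0, 0.25)
      y <- x + rnorm(400, 0, 0.5)
    })
    approximate_instruments(tibble::tibble(x = x, y = y), k = 3,
                            seed = 700 + r)$branch
  }, character(1))
  expect_gte(mean(branches == "x_simpler"), 0.9)
})
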