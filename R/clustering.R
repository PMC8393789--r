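# Latent-instrument approximation by clustering. Each observation is mapped
# to the center of its cluster, so an "instrument series" is a step-function
# summary of the variable(s) it was built from: constant within a cluster,
# at most k distinct values. Four candidates are built -- from X alone, from
# Y alone, and the two coordinates of a joint clustering -- and the pair
# actually used is chosen by comparing how much the joint clustering moves
# each marginal one.

new_instrument_series <- function(values, labels, source, k, center_mean, center_sd) {
  structure(
    list(values = as.numeric(values), labels = as.integer(labels),
         source = source, k = as.integer(k),
         scale = list(mean = center_mean, sd = center_sd)),
    class = "liv_instrument_series"
  )
}

#' @export
print.liv_instrument_series <- function(x, ...) {
  cat(sprintf("Instrument series (%s): N = %d, k = %d, %d distinct center values\n",
              x$source, length(x$values), x$k, length(unique(x$values))))
  invisible(x)
}

#' @method tidy liv_instrument_series
#' @export
tidy.liv_instrument_series <- function(x, ...) {
  tibble::tibble(value = x$values, label = x$labels, source = x$source)
}

# k-means++ seeding: first center uniform over distinct rows, then each
# subsequent center sampled with probability proportional to the squared
# distance to the nearest chosen center.
kmeanspp_centers <- function(mat, k) {
  u <- unique(mat)
  centers <- matrix(NA_real_, nrow = k, ncol = ncol(mat))
  centers[1L, ] <- u[sample.int(nrow(u), 1L), , drop = TRUE]
  if (k > 1L) {
    d2 <- rowSums((u - matrix(centers[1L, ], nrow(u), ncol(u), byrow = TRUE))^2)
    for (j in 2:k) {
      probs <- d2 / sum(d2)
      pick <- sample.int(nrow(u), 1L, prob = probs)
      centers[j, ] <- u[pick, , drop = TRUE]
      d2 <- pmin(d2, rowSums((u - matrix(centers[j, ], nrow(u), ncol(u), byrow = TRUE))^2))
    }
  }
  centers
}

# Seeded k-means: k-means++ initialization, `nstart` restarts, keep the
# restart with the lowest within-cluster sum of squares (ties keep the
# earliest restart). Restarts that end with an empty cluster are discarded;
# if all do, k is decremented with a warning.
liv_kmeans <- function(mat, k, seed, nstart = 10L, iter_max = 100L) {
  stopifnot(k >= 1L)
  n_distinct <- nrow(unique(mat))
  if (k > n_distinct) {
    inform(sprintf("k reduced from %d to %d (number of distinct points).", k, n_distinct),
           class = "liv_msg_k_reduced")
    k <- n_distinct
  }
  withr::with_seed(seed, {
    repeat {
      best <- NULL
      for (r in seq_len(nstart)) {
        init <- kmeanspp_centers(mat, k)
        fit <- tryCatch(
          suppressWarnings(kmeans(mat, centers = init, iter.max = iter_max,
                                  algorithm = "Lloyd")),
          error = function(e) NULL
        )
        if (is.null(fit) || any(fit$size == 0L)) next
        if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
      }
      if (!is.null(best)) return(best)
      if (k == 1L) {
        # k = 1 cannot fail: all points in one cluster at the mean
        return(list(cluster = rep(1L, nrow(mat)),
                    centers = matrix(colMeans(mat), 1L),
                    tot.withinss = sum(scale(mat, scale = FALSE)^2),
                    size = nrow(mat)))
      }
      warn(sprintf("all k-means restarts produced an empty cluster; reducing k to %d.", k - 1L),
           class = "liv_warn_k_decremented")
      k <- k - 1L
    }
  })
}

#' Cluster a single series into an instrument candidate
#'
#' k-means on one series; every observation is replaced by the center of its
#' cluster. A constant input cannot be clustered: the all-mean series is
#' returned with a warning (downstream tests reject constant instruments
#' anyway). If `k` exceeds the number of distinct values it is reduced.
#'
#' @param v Numeric vector, finite values.
#' @param k Number of clusters (cluster count caps at the number of distinct
#'   values).
#' @param seed Integer seed; output is deterministic given `(v, k, seed)`.
#' @param source Provenance tag stored on the result.
#' @return A `liv_instrument_series`.
#' @export
cluster_1d <- function(v, k, seed, source = "x_only") {
  if (anyNA(v) || any(!is.finite(v))) stop_format("`v` must be finite.")
  if (is_constant(v)) {
    warn("constant series: returning the all-mean instrument (k = 1).",
         class = "liv_warn_constant_cluster")
    return(new_instrument_series(rep(mean(v), length(v)), rep(1L, length(v)),
                                 source, 1L, mean(v), 0))
  }
  fit <- liv_kmeans(matrix(v, ncol = 1L), k, seed)
  new_instrument_series(fit$centers[fit$cluster, 1L], fit$cluster, source,
                        nrow(fit$centers), mean(v), sd(v))
}

#' Cluster two series jointly; return each coordinate of the centers
#'
#' Both series are z-scored before the joint k-means (so neither unit
#' dominates) and the assigned center coordinates are mapped back to each
#' variable's original units. A constant coordinate is dropped from the
#' clustering (it carries no information) and returned as its all-mean
#' series.
#'
#' @param v1,v2 Numeric vectors of equal length.
#' @inheritParams cluster_1d
#' @return A list with elements `x` (first coordinate, source `"joint_x"`)
#'   and `y` (second coordinate, source `"joint_y"`), both
#'   `liv_instrument_series`.
#' @export
cluster_2d <- function(v1, v2, k, seed) {
  n <- length(v1)
  if (length(v2) != n) stop_length_mismatch(n, length(v2))
  c1 <- is_constant(v1); c2 <- is_constant(v2)
  if (c1 && c2) {
    warn("both series constant: returning all-mean instruments.",
         class = "liv_warn_constant_cluster")
    return(list(
      x = new_instrument_series(rep(mean(v1), n), rep(1L, n), "joint_x", 1L, mean(v1), 0),
      y = new_instrument_series(rep(mean(v2), n), rep(1L, n), "joint_y", 1L, mean(v2), 0)
    ))
  }
  if (c1 || c2) {
    live <- if (c1) v2 else v1
    fit1 <- cluster_1d(live, k, seed, source = if (c1) "joint_y" else "joint_x")
    dead_v <- if (c1) v1 else v2
    dead <- new_instrument_series(rep(mean(dead_v), n), fit1$labels,
                                  if (c1) "joint_x" else "joint_y",
                                  fit1$k, mean(dead_v), 0)
    out <- if (c1) list(x = dead, y = fit1) else list(x = fit1, y = dead)
    return(out)
  }
  m1 <- mean(v1); s1 <- sd(v1)
  m2 <- mean(v2); s2 <- sd(v2)
  mat <- cbind((v1 - m1) / s1, (v2 - m2) / s2)
  fit <- liv_kmeans(mat, k, seed)
  kk <- nrow(fit$centers)
  cx <- fit$centers[fit$cluster, 1L] * s1 + m1
  cy <- fit$centers[fit$cluster, 2L] * s2 + m2
  list(
    x = new_instrument_series(cx, fit$cluster, "joint_x", kk, m1, s1),
    y = new_instrument_series(cy, fit$cluster, "joint_y", kk, m2, s2)
  )
}

#' Build the four instrument candidates
#'
#' Constructs the candidates the selection step chooses from: `ixx`
#' (clustering X alone), `iyy` (Y alone), and `ixxy` / `iyyx` (the X and Y
#' coordinates of a joint clustering). Sub-seeds for the three clustering
#' runs are derived from `seed` by fixed offsets.
#'
#' @param data A data frame whose first two numeric columns are X and Y (see
#'   [as_bivariate()]).
#' @param k Number of clusters (default 15); capped at the number of
#'   distinct values of each clustered input.
#' @param seed Integer master seed.
#' @return A list of four `liv_instrument_series`: `ixx`, `ixxy`, `iyy`,
#'   `iyyx`.
#' @export
build_iv_candidates <- function(data, k = 15L, seed = 1L) {
  s <- as_bivariate(data)
  joint <- cluster_2d(s$x, s$y, k, derive_seed(seed, "cluster_joint"))
  list(
    ixx = cluster_1d(s$x, k, derive_seed(seed, "cluster_x"), source = "x_only"),
    ixxy = joint$x,
    iyy = cluster_1d(s$y, k, derive_seed(seed, "cluster_y"), source = "y_only"),
    iyyx = joint$y
  )
}

# Root-mean-square distance between two center series on the standardized
# scale of their source variable. Both series share the source's units, so
# standardizing divides the raw difference by the source sd; the rms (rather
# than the plain Euclidean norm) makes the distance sample-size-independent.
instrument_distance <- function(s1, s2) {
  if (length(s1$values) != length(s2$values)) {
    stop_length_mismatch(length(s1$values), length(s2$values))
  }
  sds <- c(s1$scale$sd, s2$scale$sd)
  scale_sd <- if (any(sds > 0)) max(sds) else sd(c(s1$values, s2$values))
  if (!isTRUE(scale_sd > 0)) scale_sd <- 1
  sqrt(mean((s1$values - s2$values)^2)) / scale_sd
}

#' Select the instrument pair by the simpler-model criterion
#'
#' Compares how far the joint clustering moved each marginal clustering:
#' `dist_x = dist(ixx, ixxy)` and `dist_y = dist(iyy, iyyx)`, root mean
#' square over observations on the standardized scale. If `dist_x < dist_y`
#' -- Y barely influences how X clusters, so X's instrument can ignore Y --
#' the pair is `IX = ixx`, `IY = iyyx` (branch `x_simpler`); otherwise (ties
#' included) `IX = ixxy`, `IY = iyy` (branch `y_simpler`). Choosing the
#' variable whose clustering needs less help from the other mirrors
#' minimum-description-length reasoning: the simpler model wins.
#'
#' @param ixx,ixxy,iyy,iyyx The four candidates from
#'   [build_iv_candidates()].
#' @return A `liv_instrument_pair`: `ix`, `iy`, `dist_x`, `dist_y`,
#'   `branch`.
#' @export
select_instruments <- function(ixx, ixxy, iyy, iyyx) {
  dist_x <- instrument_distance(ixx, ixxy)
  dist_y <- instrument_distance(iyy, iyyx)
  if (dist_x < dist_y) {
    branch <- "x_simpler"; ix <- ixx; iy <- iyyx
  } else {
    branch <- "y_simpler"; ix <- ixxy; iy <- iyy
  }
  structure(
    list(ix = ix, iy = iy, dist_x = dist_x, dist_y = dist_y, branch = branch),
    class = "liv_instrument_pair"
  )
}

#' @export
print.liv_instrument_pair <- function(x, ...) {
  cat(sprintf("Instrument pair: branch %s (dist_x = %.4g, dist_y = %.4g)\n",
              x$branch, x$dist_x, x$dist_y))
  cat(sprintf("  IX from %s, IY from %s\n", x$ix$source, x$iy$source))
  invisible(x)
}

#' Build and select instruments in one step
#'
#' Runs [build_iv_candidates()] then [select_instruments()].
#'
#' @inheritParams build_iv_candidates
#' @return A `liv_instrument_pair`.
#' @export
approximate_instruments <- function(data, k = 15L, seed = 1L) {
  cand <- build_iv_candidates(data, k = k, seed = seed)
  select_instruments(cand$ixx, cand$ixxy, cand$iyy, cand$iyyx)
}
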