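# The symmetric decision procedure. Forward test: Y independent of IX given
# X -- if it holds (large p), the only consistent directed graph is
# IX -> X -> Y, so X -> Y. Otherwise the mirrored backward test X
# independent of IY given Y decides Y -> X. If both tests reject while X
# and Y are correlated, no instrumented chain explains the data and a
# hidden common cause is inferred.

DIRECTIONS <- c(x_to_y = "x->y", y_to_x = "y->x", common = "common")

new_verdict <- function(direction, p_forward, p_backward, alpha, forced, test) {
  structure(
    list(direction = unname(direction), p_forward = unname(p_forward),
         p_backward = unname(p_backward),
         alpha = alpha, forced = forced, test = test,
         score = if (forced) p_forward - p_backward else NA_real_),
    class = "liv_verdict"
  )
}

#' @export
print.liv_verdict <- function(x, ...) {
  lab <- switch(x$direction,
                "x->y" = "X -> Y", "y->x" = "Y -> X",
                "common" = "hidden common cause (X <- U -> Y)")
  cat(sprintf("Causal verdict: %s%s\n", lab, if (x$forced) " [forced choice]" else ""))
  cat(sprintf("  p(Y ind. IX | X) = %.4g\n", x$p_forward))
  if (is.na(x$p_backward)) {
    cat("  p(X ind. IY | Y) not computed (tree short-circuited)\n")
  } else {
    cat(sprintf("  p(X ind. IY | Y) = %.4g\n", x$p_backward))
  }
  invisible(x)
}

#' @method tidy liv_verdict
#' @export
tidy.liv_verdict <- function(x, ...) {
  tibble::tibble(
    hypothesis = c("y_indep_ix_given_x", "x_indep_iy_given_y"),
    p_value = c(x$p_forward, x$p_backward)
  )
}

#' @method glance liv_verdict
#' @export
glance.liv_verdict <- function(x, ...) {
  tibble::tibble(direction = x$direction, p_forward = x$p_forward,
                 p_backward = x$p_backward, alpha = x$alpha,
                 forced = x$forced, score = x$score, test = x$test)
}

run_ci <- function(a, b, cond, test) {
  if (test == "discrete") ci_test_discrete(a, b, cond) else ci_test_continuous(a, b, cond)
}

resolve_family <- function(test, x, y) {
  if (test == "auto") resolve_test_family(x, y) else test
}

#' Infer the causal direction from a sample and an instrument pair
#'
#' The three-way decision tree: test Y independent of IX given X; a large
#' p-value (`> alpha`) yields X -> Y and the second test is never run. A
#' small one triggers the mirrored test X independent of IY given Y, whose
#' large p-value yields Y -> X. If both reject, a hidden common cause is
#' inferred.
#'
#' @param data Data frame whose first two numeric columns are X and Y.
#' @param ix,iy Instrument series for X and Y (a `liv_instrument_series`, or
#'   a bare numeric vector such as a simulated true instrument).
#' @param alpha Decision threshold on the p-values (default 0.05).
#' @param test `"auto"`, `"continuous"` or `"discrete"`.
#' @return A `liv_verdict`; `p_backward` is `NA` when the tree
#'   short-circuits at the first branch.
#' @export
infer_direction <- function(data, ix, iy, alpha = 0.05,
                            test = c("auto", "continuous", "discrete")) {
  test <- match.arg(test)
  s <- as_bivariate(data)
  stopifnot(alpha > 0, alpha < 1)
  test <- resolve_family(test, s$x, s$y)
  ixv <- instrument_values(ix)
  iyv <- instrument_values(iy)
  p_fwd <- run_ci(s$y, ixv, s$x, test)$p_value
  if (p_fwd > alpha) {
    return(new_verdict(DIRECTIONS["x_to_y"], p_fwd, NA_real_, alpha, FALSE, test))
  }
  p_bwd <- run_ci(s$x, iyv, s$y, test)$p_value
  dir <- if (p_bwd > alpha) DIRECTIONS["y_to_x"] else DIRECTIONS["common"]
  new_verdict(dir, p_fwd, p_bwd, alpha, FALSE, test)
}

#' Forced-choice direction from the p-value difference
#'
#' Always computes both conditional-independence p-values and answers
#' X -> Y iff `p_forward > p_backward` (the evidence for the instrumented
#' chain through X is stronger); never returns a common-cause verdict. An
#' exact tie resolves to X -> Y with a warning. The signed difference
#' `p_forward - p_backward` is kept as `score`.
#'
#' @inheritParams infer_direction
#' @return A `liv_verdict` with `forced = TRUE`.
#' @export
infer_direction_forced <- function(data, ix, iy,
                                   test = c("auto", "continuous", "discrete")) {
  test <- match.arg(test)
  s <- as_bivariate(data)
  test <- resolve_family(test, s$x, s$y)
  p_fwd <- run_ci(s$y, instrument_values(ix), s$x, test)$p_value
  p_bwd <- run_ci(s$x, instrument_values(iy), s$y, test)$p_value
  if (p_fwd == p_bwd) {
    warn("p-values exactly tied; resolving the forced choice to x->y.",
         class = "liv_warn_forced_tie")
    dir <- DIRECTIONS["x_to_y"]
  } else {
    dir <- if (p_fwd > p_bwd) DIRECTIONS["x_to_y"] else DIRECTIONS["y_to_x"]
  }
  new_verdict(dir, p_fwd, p_bwd, alpha = 0.05, forced = TRUE, test = test)
}

instrument_values <- function(iv) {
  if (inherits(iv, "liv_instrument_series")) iv$values else as.numeric(iv)
}

# Verdict from a pair of p-values under tree semantics (used per fold, where
# both p-values are always materialized for the ensemble's tie-break).
tree_direction <- function(p_fwd, p_bwd, alpha) {
  if (p_fwd > alpha) DIRECTIONS["x_to_y"]
  else if (p_bwd > alpha) DIRECTIONS["y_to_x"]
  else DIRECTIONS["common"]
}

#' k-fold ensemble causal inference
#'
#' Rows are randomly permuted (seeded) and split into `k_folds` near-equal
#' folds; the full pipeline -- instrument construction by clustering, then
#' the decision procedure -- runs independently on each fold with a
#' fold-local sub-seed, and the final direction is the majority vote.
#' Averaging a verdict over folds stabilizes a decision that would otherwise
#' hinge on a single pair of p-values. A vote tie is broken by the sign of
#' the summed p-value difference over folds (positive favors X -> Y).
#'
#' @inheritParams infer_direction
#' @param k_folds Number of folds (default 10). `k_folds = 1` is single-shot
#'   inference on the full sample.
#' @param seed Integer master seed; fold sub-seeds are derived by fixed
#'   offsets.
#' @param k_clusters Clusters per instrument (default 15, capped at the
#'   number of distinct values).
#' @param forced Use the forced-choice rule per fold instead of the
#'   three-way tree.
#' @return A `liv_ensemble`: per-fold tibble, vote counts, final direction.
#' @export
ensemble_infer <- function(data, k_folds = 10L, seed = 1L, k_clusters = 15L,
                           alpha = 0.05, test = c("auto", "continuous", "discrete"),
                           forced = FALSE) {
  test <- match.arg(test)
  s <- as_bivariate(data)
  n <- nrow(s)
  if (n < k_folds * 8L) stop_insufficient_sample(n, k_folds * 8L)
  test <- resolve_family(test, s$x, s$y)
  perm <- withr::with_seed(derive_seed(seed, "permute"), sample.int(n))
  fold_id <- rep_len(seq_len(k_folds), n)[order(perm)] # near-equal fold sizes
  folds <- purrr::map(seq_len(k_folds), function(f) {
    fold_rows <- s[fold_id == f, , drop = FALSE]
    fseed <- derive_seed(seed, "fold", f)
    pair <- approximate_instruments(fold_rows, k = k_clusters, seed = fseed)
    p_fwd <- run_ci(fold_rows$y, pair$ix$values, fold_rows$x, test)$p_value
    p_bwd <- run_ci(fold_rows$x, pair$iy$values, fold_rows$y, test)$p_value
    dir <- if (forced) {
      if (p_fwd >= p_bwd) DIRECTIONS["x_to_y"] else DIRECTIONS["y_to_x"]
    } else {
      tree_direction(p_fwd, p_bwd, alpha)
    }
    tibble::tibble(fold = f, n = nrow(fold_rows), branch = pair$branch,
                   dist_x = pair$dist_x, dist_y = pair$dist_y,
                   p_forward = p_fwd, p_backward = p_bwd,
                   direction = unname(dir))
  })
  fold_tbl <- dplyr::bind_rows(folds)
  votes <- table(factor(fold_tbl$direction, levels = unname(DIRECTIONS)))
  final <- vote_winner(votes, sum(fold_tbl$p_forward - fold_tbl$p_backward))
  structure(
    list(folds = fold_tbl, votes = votes, final = final,
         n_folds = as.integer(k_folds), seed = as.integer(seed),
         alpha = alpha, forced = forced, test = test),
    class = "liv_ensemble"
  )
}

# Majority vote; ties resolved by the sign of the summed p-value difference
# (the same evidence the forced-choice rule uses), preferring the favored
# direction, then the other direction, then the common-cause verdict.
vote_winner <- function(votes, p_diff_sum) {
  top <- names(votes)[votes == max(votes)]
  if (length(top) == 1L) return(top)
  pref <- if (p_diff_sum > 0) {
    c(DIRECTIONS["x_to_y"], DIRECTIONS["y_to_x"], DIRECTIONS["common"])
  } else {
    c(DIRECTIONS["y_to_x"], DIRECTIONS["x_to_y"], DIRECTIONS["common"])
  }
  unname(pref[pref %in% top][1L])
}

#' @export
print.liv_ensemble <- function(x, ...) {
  lab <- switch(x$final,
                "x->y" = "X -> Y", "y->x" = "Y -> X",
                "common" = "hidden common cause")
  cat(sprintf("Ensemble causal verdict over %d fold(s): %s\n", x$n_folds, lab))
  v <- x$votes
  cat(sprintf("  votes: x->y %d | y->x %d | common %d\n",
              v[["x->y"]], v[["y->x"]], v[["common"]]))
  invisible(x)
}

#' @method tidy liv_ensemble
#' @export
tidy.liv_ensemble <- function(x, ...) x$folds

#' @method glance liv_ensemble
#' @export
glance.liv_ensemble <- function(x, ...) {
  tibble::tibble(direction = x$final,
                 votes_x_to_y = x$votes[["x->y"]],
                 votes_y_to_x = x$votes[["y->x"]],
                 votes_common = x$votes[["common"]],
                 n_folds = x$n_folds,
                 mean_p_forward = mean(x$folds$p_forward),
                 mean_p_backward = mean(x$folds$p_backward),
                 alpha = x$alpha, forced = x$forced, test = x$test)
}

#' Vote counts per direction for an ensemble verdict
#' @param object A `liv_ensemble`.
#' @param ... Unused.
#' @return A ggplot bar chart of fold votes.
#' @method autoplot liv_ensemble
#' @export
autoplot.liv_ensemble <- function(object, ...) {
  df <- tibble::tibble(direction = names(object$votes),
                       votes = as.integer(object$votes))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$direction, y = .data$votes)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "fold votes",
                  title = sprintf("Ensemble verdict: %s", object$final))
}

#' End-to-end bivariate causal discovery
#'
#' The package's front door: takes a data frame whose first two numeric
#' columns are the observed series, approximates the latent instruments by
#' clustering, and returns the (optionally ensembled, optionally forced)
#' causal verdict.
#'
#' @inheritParams ensemble_infer
#' @param folds Number of folds (default 10); 1 means single-shot.
#' @return A `liv_ensemble`.
#' @export
liv_discover <- function(data, k_clusters = 15L, alpha = 0.05, folds = 10L,
                         test = c("auto", "continuous", "discrete"),
                         forced = FALSE, seed = 1L) {
  ensemble_infer(data, k_folds = folds, seed = seed, k_clusters = k_clusters,
                 alpha = alpha, test = match.arg(test), forced = forced)
}
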