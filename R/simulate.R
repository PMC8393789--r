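# Synthetic-data generators. Three scenario families:
#   * binary Bayesian networks over (IX, X, Y, IY[, U]),
#   * linear-Gaussian structural causal models with discrete-level
#     instruments and an optional Gaussian confounder
#       X = alpha0 + alpha IX + delta U + eps_X
#       Y = beta0  + beta  X + alpha_y IY + gamma U + eps_Y,
#   * two-population mixtures sharing a single mechanism P(Y|X).
# Every generator is a pure function of (config, seed); simulated latents
# are returned as *_true columns for oracle experiments and must never be
# fed to the constructed-instrument inference path.

STRUCTURES <- c("chain_x_to_y", "chain_y_to_x", "confounded")

#' Configuration for the linear-Gaussian structural causal model
#'
#' Parameterizes `X = alpha0 + alpha IX + delta U + eps_X` and
#' `Y = beta0 + beta X + alpha_y IY + gamma U + eps_Y`, with `IX` (`IY`)
#' drawn from a finite level set with mixing weights, `U ~ N(0, u_sd^2)`,
#' and independent Gaussian noises. Chain structures have no confounder
#' (`delta = gamma = 0` is enforced); `chain_y_to_x` is the exact mirror
#' (roles of the two observed series swapped). The default instrument is
#' trimodal, uniform on \{-2, 0, +2\}, so that the cluster assumption holds
#' and constructed instruments can recover it.
#'
#' @param structure One of `"chain_x_to_y"`, `"chain_y_to_x"`,
#'   `"confounded"`.
#' @param alpha0,alpha Intercept and instrument loading of the cause
#'   equation.
#' @param beta0,beta Intercept and cause loading of the effect equation.
#' @param delta,gamma Confounder loadings on X and Y (0 for chains).
#' @param alpha_y Loading of the effect's own instrument IY; defaults to
#'   `alpha` when `iv_y_levels` is given, else 0.
#' @param sigma_x,sigma_y Noise standard deviations (> 0).
#' @param iv_x_levels,iv_x_weights Level set and mixing weights of IX
#'   (weights default to uniform). `NULL` levels mean the instrument is
#'   absent.
#' @param iv_y_levels,iv_y_weights Same for IY.
#' @param u_sd Standard deviation of the confounder U (mean 0).
#' @param n Sample size.
#' @param seed Integer seed.
#' @return A validated `liv_scm_config` list.
#' @export
continuous_scm_config <- function(structure = "chain_x_to_y",
                                  alpha0 = 0, alpha = 1, delta = 0,
                                  beta0 = 0, beta = 1, gamma = 0,
                                  alpha_y = NULL,
                                  sigma_x = 0.5, sigma_y = 0.5,
                                  iv_x_levels = c(-2, 0, 2), iv_x_weights = NULL,
                                  iv_y_levels = NULL, iv_y_weights = NULL,
                                  u_sd = 1, n = 1000L, seed = 1L) {
  structure <- match.arg(structure, STRUCTURES)
  if (structure != "confounded" && (delta != 0 || gamma != 0)) {
    stop_invalid_config("chain structures require delta = gamma = 0.")
  }
  if (sigma_x <= 0 || sigma_y <= 0 || u_sd <= 0) {
    stop_invalid_config("noise standard deviations must be positive.")
  }
  alpha_y <- alpha_y %||% (if (is.null(iv_y_levels)) 0 else alpha)
  cfg <- list(structure = structure, alpha0 = alpha0, alpha = alpha,
              delta = delta, beta0 = beta0, beta = beta, gamma = gamma,
              alpha_y = alpha_y, sigma_x = sigma_x, sigma_y = sigma_y,
              iv_x = normalize_levels(iv_x_levels, iv_x_weights, "iv_x"),
              iv_y = normalize_levels(iv_y_levels, iv_y_weights, "iv_y"),
              u_sd = u_sd, n = as.integer(n), seed = as.integer(seed))
  structure(cfg, class = "liv_scm_config")
}

normalize_levels <- function(levels, weights, what) {
  if (is.null(levels)) return(NULL)
  weights <- weights %||% rep(1 / length(levels), length(levels))
  if (length(weights) != length(levels)) {
    stop_invalid_config(sprintf("%s: weights must match levels.", what))
  }
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-9) {
    stop_invalid_config(sprintf("%s: weights must be nonnegative and sum to 1.", what))
  }
  list(levels = as.numeric(levels), weights = as.numeric(weights))
}

sample_levels <- function(spec, n) {
  if (length(spec$levels) == 1L) rep(spec$levels, n)
  else sample(spec$levels, n, replace = TRUE, prob = spec$weights)
}

#' Simulate from the linear-Gaussian structural causal model
#'
#' Ancestral sampling of the configured structure. `chain_y_to_x` is
#' generated by simulating the mirrored `chain_x_to_y` model and swapping
#' the observed (and latent-instrument) columns.
#'
#' @param cfg A [continuous_scm_config()].
#' @return A tibble with columns `x`, `y` and, when generated, `ix_true`,
#'   `iy_true`, `u_true`; the config is attached as attribute `"config"`.
#' @export
simulate_continuous <- function(cfg) {
  stopifnot(inherits(cfg, "liv_scm_config"))
  if (cfg$structure == "chain_y_to_x") {
    mirrored <- cfg
    mirrored$structure <- "chain_x_to_y"
    out <- simulate_continuous(mirrored)
    cols <- list(x = out$y, y = out$x)
    if ("ix_true" %in% names(out)) cols$iy_true <- out$ix_true
    if ("iy_true" %in% names(out)) cols$ix_true <- out$iy_true
    if ("u_true" %in% names(out)) cols$u_true <- out$u_true
    swapped <- tibble::as_tibble(cols)
    attr(swapped, "config") <- cfg
    return(swapped)
  }
  n <- cfg$n
  withr::with_seed(cfg$seed, {
    ix <- if (!is.null(cfg$iv_x)) sample_levels(cfg$iv_x, n) else NULL
    iy <- if (!is.null(cfg$iv_y)) sample_levels(cfg$iv_y, n) else NULL
    u <- if (cfg$structure == "confounded") rnorm(n, 0, cfg$u_sd) else NULL
    x <- cfg$alpha0 + cfg$alpha * (ix %||% 0) + cfg$delta * (u %||% 0) +
      rnorm(n, 0, cfg$sigma_x)
    y <- cfg$beta0 + cfg$beta * x + cfg$alpha_y * (iy %||% 0) +
      cfg$gamma * (u %||% 0) + rnorm(n, 0, cfg$sigma_y)
    out <- tibble::tibble(x = x, y = y)
    if (!is.null(ix)) out$ix_true <- ix
    if (!is.null(iy)) out$iy_true <- iy
    if (!is.null(u)) out$u_true <- u
    attr(out, "config") <- cfg
    out
  })
}

#' Configuration for the binary Bayesian-network generator
#'
#' Binary variables over the graph implied by `structure`:
#' `chain_x_to_y` is `IX -> X -> Y <- IY`; `confounded` is
#' `IX -> X <- U -> Y <- IY` (no X--Y edge unless the confounder carries
#' it). CPTs are given as probabilities of the value 1:
#' `cpt_x` is `P(X=1 | IX)` (length 2) for chains or `P(X=1 | IX, U)` (2x2
#' matrix, rows = IX, cols = U) when confounded; `cpt_y` is
#' `P(Y=1 | X, IY)` (2x2, rows = X, cols = IY) for chains or
#' `P(Y=1 | IY, U)` when confounded. Defaults use 0.2/0.8-style
#' asymmetries strong enough for the conditional-independence structure to
#' be visible at moderate sample sizes.
#'
#' @param structure One of `"chain_x_to_y"`, `"chain_y_to_x"`,
#'   `"confounded"`.
#' @param p_ix,p_iy Marginal probabilities of the binary instruments.
#' @param p_u Marginal probability of the binary confounder.
#' @param cpt_x,cpt_y Conditional probability tables as described above.
#' @param n Sample size.
#' @param seed Integer seed.
#' @return A validated `liv_bn_config` list.
#' @export
discrete_bn_config <- function(structure = "chain_x_to_y",
                               p_ix = 0.5, p_iy = 0.5, p_u = 0.5,
                               cpt_x = NULL, cpt_y = NULL,
                               n = 1000L, seed = 1L) {
  structure <- match.arg(structure, STRUCTURES)
  if (structure == "confounded") {
    cpt_x <- cpt_x %||% matrix(c(0.2, 0.5, 0.5, 0.8), 2, 2) # rows IX, cols U
    cpt_y <- cpt_y %||% matrix(c(0.2, 0.5, 0.5, 0.8), 2, 2) # rows IY, cols U
    if (!is.matrix(cpt_x) || any(dim(cpt_x) != 2L) ||
        !is.matrix(cpt_y) || any(dim(cpt_y) != 2L)) {
      stop_invalid_config("confounded CPTs must be 2x2 matrices.",
                          class = "liv_error_invalid_cpt")
    }
  } else {
    cpt_x <- cpt_x %||% c(0.2, 0.8)                          # P(X=1 | IX)
    cpt_y <- cpt_y %||% matrix(c(0.15, 0.55, 0.45, 0.85), 2, 2) # rows X, cols IY
    if (length(cpt_x) != 2L || !is.matrix(cpt_y) || any(dim(cpt_y) != 2L)) {
      stop_invalid_config("chain CPTs must be P(X=1|IX) of length 2 and a 2x2 P(Y=1|X,IY).",
                          class = "liv_error_invalid_cpt")
    }
  }
  probs <- c(p_ix, p_iy, p_u, cpt_x, cpt_y)
  if (any(probs < 0 | probs > 1)) {
    stop_invalid_config("all probabilities must lie in [0, 1].",
                        class = "liv_error_invalid_cpt")
  }
  structure(list(structure = structure, p_ix = p_ix, p_iy = p_iy, p_u = p_u,
                 cpt_x = cpt_x, cpt_y = cpt_y, n = as.integer(n),
                 seed = as.integer(seed)),
            class = "liv_bn_config")
}

#' Simulate binary data from the configured Bayesian network
#'
#' Ancestral sampling in topological order. For `chain_x_to_y` the sampled
#' data satisfy Y independent of IX given X exactly in distribution (the
#' instrument reaches Y only through X); `chain_y_to_x` is the mirror.
#'
#' @param cfg A [discrete_bn_config()].
#' @return A tibble of 0/1 integer columns `x`, `y`, `ix_true`, `iy_true`
#'   (and `u_true` when confounded), config attached as attribute.
#' @export
simulate_discrete <- function(cfg) {
  stopifnot(inherits(cfg, "liv_bn_config"))
  if (cfg$structure == "chain_y_to_x") {
    mirrored <- cfg
    mirrored$structure <- "chain_x_to_y"
    mirrored$p_ix <- cfg$p_iy
    mirrored$p_iy <- cfg$p_ix
    out <- simulate_discrete(mirrored)
    out <- tibble::tibble(x = out$y, y = out$x,
                          ix_true = out$iy_true, iy_true = out$ix_true)
    attr(out, "config") <- cfg
    return(out)
  }
  n <- cfg$n
  withr::with_seed(cfg$seed, {
    ix <- rbinom(n, 1L, cfg$p_ix)
    iy <- rbinom(n, 1L, cfg$p_iy)
    if (cfg$structure == "confounded") {
      u <- rbinom(n, 1L, cfg$p_u)
      x <- rbinom(n, 1L, cfg$cpt_x[cbind(ix + 1L, u + 1L)])
      y <- rbinom(n, 1L, cfg$cpt_y[cbind(iy + 1L, u + 1L)])
      out <- tibble::tibble(x = x, y = y, ix_true = ix, iy_true = iy, u_true = u)
    } else {
      x <- rbinom(n, 1L, cfg$cpt_x[ix + 1L])
      y <- rbinom(n, 1L, cfg$cpt_y[cbind(x + 1L, iy + 1L)])
      out <- tibble::tibble(x = x, y = y, ix_true = ix, iy_true = iy)
    }
    attr(out, "config") <- cfg
    out
  })
}

#' Configuration for the two-population mixture generator
#'
#' Two populations P and Q with different cause distributions but a single
#' shared mechanism for the effect: each row belongs to P with probability
#' `lambda`, the cause X is drawn from that population's Gaussian spec, and
#' Y comes from the one linear-Gaussian mechanism `Y = intercept + slope X
#' + N(0, sigma^2)` regardless of population. The population label plays
#' the role of a latent prior on the cause: it is independent of Y given X
#' by construction, while the reverse regression differs across
#' populations.
#'
#' The default populations differ in both location and scale
#' (`P: N(-2, 1)`, `Q: N(+2, 0.5)`): with equal scales the reverse
#' regression of X on Y would have the same slope in both populations
#' (`Var(X)/Var(Y)`) and the anticausal asymmetry would hide entirely in
#' the intercepts; a scale difference makes it visible in the slopes as
#' well.
#'
#' @param lambda Mixture weight of population P, in \[0, 1\].
#' @param p_x_spec,q_x_spec Lists `list(mean=, sd=)` for X in P and Q.
#' @param mechanism List `list(intercept=, slope=, sigma=)`, shared by both
#'   populations.
#' @param n Sample size.
#' @param seed Integer seed.
#' @return A validated `liv_mixture_config` list.
#' @export
mixture_config <- function(lambda = 0.5,
                           p_x_spec = list(mean = -2, sd = 1),
                           q_x_spec = list(mean = 2, sd = 0.5),
                           mechanism = list(intercept = 0, slope = 1, sigma = 0.5),
                           n = 2000L, seed = 1L) {
  if (lambda < 0 || lambda > 1) stop_invalid_config("lambda must lie in [0, 1].")
  if (p_x_spec$sd <= 0 || q_x_spec$sd <= 0 || mechanism$sigma <= 0) {
    stop_invalid_config("standard deviations must be positive.")
  }
  structure(list(lambda = lambda, p_x_spec = p_x_spec, q_x_spec = q_x_spec,
                 mechanism = mechanism, n = as.integer(n), seed = as.integer(seed)),
            class = "liv_mixture_config")
}

#' Simulate from the two-population shared-mechanism mixture
#'
#' @param cfg A [mixture_config()].
#' @return A tibble with columns `x`, `y` and `population` (1 = P, 0 = Q).
#' @export
simulate_mixture <- function(cfg) {
  stopifnot(inherits(cfg, "liv_mixture_config"))
  n <- cfg$n
  withr::with_seed(cfg$seed, {
    pop <- rbinom(n, 1L, cfg$lambda)
    mu <- ifelse(pop == 1L, cfg$p_x_spec$mean, cfg$q_x_spec$mean)
    sdv <- ifelse(pop == 1L, cfg$p_x_spec$sd, cfg$q_x_spec$sd)
    x <- rnorm(n, mu, sdv)
    y <- cfg$mechanism$intercept + cfg$mechanism$slope * x +
      rnorm(n, 0, cfg$mechanism$sigma)
    out <- tibble::tibble(x = x, y = y, population = pop)
    attr(out, "config") <- cfg
    out
  })
}

# Wrap a simulated true latent as an instrument series so oracle
# experiments flow through the same decision code as constructed
# instruments.
oracle_instrument <- function(values, source_var) {
  new_instrument_series(values, as.integer(factor(values)), "oracle",
                        length(unique(values)), mean(source_var),
                        stats::sd(source_var))
}

#' Sweep sample sizes and replicates over simulated scenarios
#'
#' For each (scenario config, n, replicate) the generator runs once and the
#' decision procedure is applied twice: with oracle instruments (the
#' simulated true latents, falling back to joint-clustered candidates for a
#' latent the scenario does not generate) and with instruments constructed
#' from the observed series only. The output is one tidy row per run,
#' suitable for plotting p-value trajectories against n.
#'
#' @param scenarios Named list of scenario configs
#'   ([continuous_scm_config()] or [discrete_bn_config()]); `n` and `seed`
#'   in each config are overridden by the sweep.
#' @param n_values Integer vector of sample sizes (default
#'   `c(10, 50, 100, 500, 1000, 5000, 10000)`).
#' @param reps Replicates per cell.
#' @param master_seed Master seed; per-replicate seeds are derived by fixed
#'   offsets.
#' @param k_clusters Clusters for constructed instruments.
#' @param alpha Decision threshold.
#' @return A `liv_recovery` tibble with columns `scenario`, `n`, `rep`,
#'   `iv_mode`, `p_forward`, `p_backward`, `verdict`.
#' @export
recovery_experiment <- function(scenarios, n_values = c(10L, 50L, 100L, 500L, 1000L,
                                                        5000L, 10000L),
                                reps = 20L, master_seed = 1L,
                                k_clusters = 15L, alpha = 0.05) {
  grid <- tidyr::expand_grid(scenario = names(scenarios),
                             n = as.integer(n_values),
                             rep = seq_len(reps))
  rows <- purrr::pmap(grid, function(scenario, n, rep) {
    cfg <- scenarios[[scenario]]
    cfg$n <- n
    cfg$seed <- derive_seed(master_seed, "replicate", rep * 13L + match(n, n_values))
    sim <- if (inherits(cfg, "liv_bn_config")) simulate_discrete(cfg)
           else simulate_continuous(cfg)
    test <- if (inherits(cfg, "liv_bn_config")) "discrete" else "continuous"
    dplyr::bind_rows(
      recovery_row(sim, "oracle", k_clusters, cfg$seed, alpha, test),
      recovery_row(sim, "constructed", k_clusters, cfg$seed, alpha, test)
    ) |>
      dplyr::mutate(scenario = scenario, n = n, rep = rep, .before = 1L)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("liv_recovery", class(out))
  out
}

recovery_row <- function(sim, iv_mode, k_clusters, seed, alpha, test) {
  obs <- sim[, c("x", "y")]
  tryCatch({
    if (iv_mode == "oracle") {
      # true simulated latents where the scenario generates them; a latent
      # the scenario has no edge for falls back to its joint-clustered
      # candidate, so the backward test is always defined
      ix <- if ("ix_true" %in% names(sim)) oracle_instrument(sim$ix_true, sim$x) else NULL
      iy <- if ("iy_true" %in% names(sim)) oracle_instrument(sim$iy_true, sim$y) else NULL
      if (is.null(ix) || is.null(iy)) {
        cand <- build_iv_candidates(obs, k = k_clusters, seed = seed)
        ix <- ix %||% cand$ixxy
        iy <- iy %||% cand$iyyx
      }
    } else {
      pair <- approximate_instruments(obs, k = k_clusters, seed = seed)
      ix <- pair$ix
      iy <- pair$iy
    }
    p_fwd <- run_ci(obs$y, instrument_values(ix), obs$x, test)$p_value
    p_bwd <- run_ci(obs$x, instrument_values(iy), obs$y, test)$p_value
    tibble::tibble(iv_mode = iv_mode, p_forward = p_fwd, p_backward = p_bwd,
                   verdict = unname(tree_direction(p_fwd, p_bwd, alpha)))
  }, liv_error_insufficient_sample = function(e) {
    tibble::tibble(iv_mode = iv_mode, p_forward = NA_real_,
                   p_backward = NA_real_, verdict = "insufficient_sample")
  }, liv_error_constant_input = function(e) {
    tibble::tibble(iv_mode = iv_mode, p_forward = NA_real_,
                   p_backward = NA_real_, verdict = "degenerate")
  }, liv_error_degenerate_table = function(e) {
    tibble::tibble(iv_mode = iv_mode, p_forward = NA_real_,
                   p_backward = NA_real_, verdict = "degenerate")
  })
}

#' p-value trajectories from a recovery experiment
#'
#' Median forward and backward p-values against sample size, one panel per
#' scenario and instrument mode.
#'
#' @param object A `liv_recovery` table.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot liv_recovery
#' @export
autoplot.liv_recovery <- function(object, ...) {
  df <- object |>
    tidyr::pivot_longer(c("p_forward", "p_backward"),
                        names_to = "hypothesis", values_to = "p_value") |>
    dplyr::group_by(.data$scenario, .data$n, .data$iv_mode, .data$hypothesis) |>
    dplyr::summarise(median_p = median(.data$p_value, na.rm = TRUE),
                     .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$n, y = .data$median_p,
                                   colour = .data$hypothesis,
                                   linetype = .data$iv_mode)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(ggplot2::vars(.data$scenario)) +
    ggplot2::labs(x = "number of observations", y = "median p-value")
}
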