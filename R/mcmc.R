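#' MCMC chain configuration
#'
#' The full-scale analysis configuration is five chains of 100,000
#' iterations with a 50,000 burn-in; the default here is a desk-scale
#' configuration (3 chains of 20,000, burn-in 10,000) that keeps replicate
#' experiments tractable while leaving thousands of retained draws per
#' chain. `paper_scale = TRUE` switches to the full-scale settings.
#'
#' @param n_chains number of chains (>= 2 so between-chain diagnostics are
#'   defined).
#' @param n_iterations iterations per chain.
#' @param burn_in discarded initial iterations (< n_iterations).
#' @param thin keep every `thin`-th post-burn-in draw.
#' @param seed master seed; chain k uses `seed + k`.
#' @param adapt adapt proposal scales during burn-in (frozen afterwards so
#'   the retained chain has the correct stationary distribution).
#' @param paper_scale use 5 chains x 100,000 iterations, burn-in 50,000.
#' @return an object of class `chain_config`.
#' @export
chain_config <- function(n_chains = 3, n_iterations = 20000,
                         burn_in = 10000, thin = 1, seed = 1L,
                         adapt = TRUE, paper_scale = FALSE) {
  if (paper_scale) {
    n_chains <- 5; n_iterations <- 100000; burn_in <- 50000
  }
  stopifnot(n_chains >= 2, thin >= 1, burn_in >= 0,
            burn_in < n_iterations)
  structure(list(n_chains = as.integer(n_chains),
                 n_iterations = as.integer(n_iterations),
                 burn_in = as.integer(burn_in), thin = as.integer(thin),
                 seed = as.integer(seed), adapt = isTRUE(adapt)),
            class = "chain_config")
}

variant_code <- function(variant) {
  match(match.arg(variant, c("M1", "M2", "M3", "M4")),
        c("M1", "M2", "M3", "M4"))
}

#' Sample the posterior of a model variant
#'
#' Adaptive random-walk Metropolis-within-Gibbs: one block per parameter
#' group (a; b; c on the logit scale with Jacobian correction; alpha; beta;
#' person-level random effects; the M4 random-effect precision matrix by a
#' conjugate Wishart Gibbs step; the M3 random-intercept SD on the log
#' scale). Proposal scales adapt toward 0.44 acceptance per scalar block
#' during burn-in and are frozen afterwards. Chains are initialised at
#' a = 1, b = 0, c = prior mean, alpha = beta = 0, random effects 0, with
#' over-dispersed per-chain N(0, 0.5^2) jitter so the Gelman-Rubin
#' diagnostic is meaningful.
#'
#' @param records modelling table with columns `y` (0/1) and `x`
#'   (standardised covariate); see [model_frame()]. May be `NULL` together
#'   with `likelihood = FALSE` for a prior-only run (then `n_records` sets
#'   the number of random-effect units).
#' @param variant model variant, "M1".."M4".
#' @param priors a [prior_spec].
#' @param config a [chain_config].
#' @param likelihood set `FALSE` to switch the likelihood term off and
#'   sample the joint prior (used for prior-recovery checks).
#' @param n_records number of records for a prior-only run with no data.
#' @return an object of class `posterior_draws`: per-chain matrices of
#'   retained draws, per-chain deviance traces, per-chain acceptance rates,
#'   posterior-mean random effects, and the seed/config record.
#' @export
run_mcmc <- function(records, variant = "M1", priors = prior_spec(),
                     config = chain_config(), likelihood = TRUE,
                     n_records = 100L) {
  vc <- variant_code(variant)
  variant <- c("M1", "M2", "M3", "M4")[vc]
  stopifnot(inherits(priors, "prior_spec"), inherits(config, "chain_config"))
  if (is.null(records)) {
    if (likelihood) stop("records required when the likelihood is on",
                         call. = FALSE)
    y <- integer(n_records)
    x <- numeric(n_records)
  } else {
    stopifnot(is.data.frame(records), nrow(records) > 0)
    if (!all(records$y %in% c(0, 1))) stop("`y` must be 0/1", call. = FALSE)
    y <- as.integer(records$y)
    x <- as.numeric(records$x)
    if (!all(is.finite(x))) stop("`x` must be finite", call. = FALSE)
    if (likelihood && length(unique(y)) == 1L) {
      warning("all responses identical: parameters are weakly identified")
    }
  }
  c0 <- priors$c_kappa / (priors$c_kappa + priors$c_tau)
  plist <- unclass(priors)

  # initial state check
  if (likelihood) {
    item0 <- item_parameters(1, max(1e-3, 0), c0)
    tr0 <- trait_model(variant[1], alpha = 0, beta = 0,
                       random_alphas = if (vc >= 3) numeric(length(y)),
                       random_betas = if (vc == 4) numeric(length(y)),
                       re_covariance = if (vc == 4) diag(2))
    if (!is.finite(log_posterior(data.frame(y = y, x = x), item0, tr0,
                                 priors))) {
      stop("non-finite log-posterior at the initial state", call. = FALSE)
    }
  }

  chains <- vector("list", config$n_chains)
  dev <- vector("list", config$n_chains)
  acc <- vector("list", config$n_chains)
  re_means <- vector("list", config$n_chains)
  for (k in seq_len(config$n_chains)) {
    set.seed(config$seed + k)
    jitter <- stats::rnorm(6, 0, 0.5)
    init <- c(a = max(0.05, 1 + jitter[1]),
              b = if (vc == 2) abs(jitter[2]) + 0.05 else jitter[2],
              c = stats::plogis(stats::qlogis(c0) + jitter[3]),
              alpha = jitter[4], beta = jitter[5],
              log_sigma_re = jitter[6] * 0.4)
    res <- run_chain_cpp(y, x, vc, plist, config$n_iterations,
                         config$burn_in, config$thin, unname(init),
                         likelihood, config$adapt)
    cols <- switch(variant,
      M1 = , M2 = c("a", "b", "c", "alpha", "beta"),
      M3 = c("a", "b", "c", "alpha", "beta", "sigma_re"),
      M4 = c("a", "b", "c", "alpha", "beta",
             "tau11", "tau22", "tau12", "re_correlation"))
    colnames(res$draws) <- cols
    chains[[k]] <- res$draws
    dev[[k]] <- res$deviance
    acc[[k]] <- res$accept
    re_means[[k]] <- cbind(alpha_j = res$re_a_mean, beta_j = res$re_b_mean,
                           p_j = res$p_mean)
  }
  re_mean <- Reduce(`+`, re_means) / length(re_means)
  structure(list(variant = variant, chains = chains, deviance = dev,
                 accept = acc, re_mean = re_mean, priors = priors,
                 config = config, likelihood = likelihood),
            class = "posterior_draws")
}

#' @export
print.posterior_draws <- function(x, ...) {
  cat(sprintf("Posterior draws: %s, %d chains x %d retained draws\n",
              x$variant, length(x$chains), nrow(x$chains[[1]])))
  cat("  parameters:", paste(colnames(x$chains[[1]]), collapse = ", "), "\n")
  cat("  mean acceptance:",
      paste(sprintf("%s=%.2f", names(x$accept[[1]]),
                    colMeans(do.call(rbind, x$accept))), collapse = " "),
      "\n")
  invisible(x)
}

#' Pool retained draws across chains
#'
#' @param draws a `posterior_draws` object.
#' @param parameter optional parameter name; if given, returns the pooled
#'   vector for that parameter.
#' @return pooled draw matrix (or vector).
#' @export
pool_draws <- function(draws, parameter = NULL) {
  m <- do.call(rbind, draws$chains)
  if (is.null(parameter)) return(m)
  m[, parameter]
}

#' Posterior means of all sampled parameters
#'
#' @param draws a `posterior_draws` object.
#' @return named numeric vector of posterior means (pooled over chains).
#' @export
posterior_means <- function(draws) {
  colMeans(pool_draws(draws))
}

#' Persist retained draws as long-format CSV
#'
#' One row per (chain, iteration, parameter, value), the interchange
#' layout downstream tools expect.
#'
#' @param draws a `posterior_draws` object.
#' @param path output CSV path.
#' @param thin keep every `thin`-th retained draw (the files get large
#'   otherwise).
#' @return `path`, invisibly.
#' @export
write_draws <- function(draws, path, thin = 10L) {
  stopifnot(inherits(draws, "posterior_draws"), thin >= 1)
  rows <- lapply(seq_along(draws$chains), function(k) {
    m <- draws$chains[[k]]
    keep <- seq(1L, nrow(m), by = as.integer(thin))
    data.frame(chain = k, iteration = keep,
               parameter = rep(colnames(m), each = length(keep)),
               value = as.vector(m[keep, ]),
               stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
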