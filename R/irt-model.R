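#' Three-parameter logistic item response model
#'
#' The response model links a child's latent treatment-seeking propensity
#' \eqn{\theta} to the probability of a positive response (formal-sector fever
#' treatment) through a logistic curve with a lower asymptote:
#' \deqn{P(Y = 1 \mid \theta, a, b, c) = c + (1 - c)\,
#'   \frac{\exp(a\theta - b)}{1 + \exp(a\theta - b)}}
#' where \eqn{a > 0} is the item discrimination, \eqn{b} the item difficulty
#' and \eqn{c \in (0, 1)} the threshold (minimum) probability: even children
#' effectively infinitely far from care retain probability \eqn{c} of being
#' treated. The latent trait is regressed on a standardised covariate,
#' \eqn{\theta_j = \alpha + \beta x_j}, with \eqn{x_j} the z-scored travel
#' time to the nearest formal health facility.
#'
#' @param a discrimination parameter(s), all > 0. May be a vector for a
#'   multidimensional trait; the single-item fever application uses length 1.
#' @param b difficulty parameter(s), same length as `a`.
#' @param c_thresh threshold probability, scalar in (0, 1).
#' @name irt3pl
NULL

#' Item parameter triple
#'
#' Validating constructor for the 3PL item parameters.
#'
#' @inheritParams irt3pl
#' @return An object of class `item_parameters`: list with elements `a`, `b`,
#'   `c`.
#' @export
item_parameters <- function(a, b, c_thresh) {
  if (length(a) != length(b)) {
    stop("`a` and `b` must have the same length", call. = FALSE)
  }
  if (!all(is.finite(a)) || any(a <= 0)) {
    stop("discrimination `a` must be finite and > 0", call. = FALSE)
  }
  if (!all(is.finite(b))) stop("difficulty `b` must be finite", call. = FALSE)
  if (length(c_thresh) != 1L || !is.finite(c_thresh) ||
      c_thresh <= 0 || c_thresh >= 1) {
    stop("threshold `c_thresh` must be a single value in (0, 1)",
         call. = FALSE)
  }
  structure(list(a = as.numeric(a), b = as.numeric(b),
                 c = as.numeric(c_thresh)),
            class = "item_parameters")
}

#' @export
print.item_parameters <- function(x, ...) {
  cat("3PL item parameters\n")
  cat("  a (discrimination):", format(x$a, digits = 4), "\n")
  cat("  b (difficulty):    ", format(x$b, digits = 4), "\n")
  cat("  c (threshold):     ", format(x$c, digits = 4), "\n")
  invisible(x)
}

#' Latent trait regression
#'
#' \eqn{\theta_j = \alpha + \beta x_j}: the person-level propensity as a
#' linear function of the standardised travel-time covariate.
#'
#' @param alpha intercept.
#' @param beta slope on the standardised covariate (negative under distance
#'   decay).
#' @param x standardised covariate value(s).
#' @return `alpha + beta * x`, vectorised over `x`.
#' @export
latent_trait <- function(alpha, beta, x) {
  if (!all(is.finite(alpha)) || !all(is.finite(beta)) || !all(is.finite(x))) {
    stop("latent_trait() requires finite inputs", call. = FALSE)
  }
  alpha + beta * x
}

#' 3PL response probability
#'
#' Evaluates the three-parameter logistic curve at trait value(s) `theta`.
#' With vector item parameters the linear predictor is
#' \eqn{\sum_k (a_k \theta_k - b_k)} over trait dimensions; the fever
#' application is unidimensional. The result lies strictly in \eqn{(c, 1)}
#' and is numerically stable for extreme linear predictors (it saturates at
#' the asymptotes rather than overflowing).
#'
#' @param item an [item_parameters] object.
#' @param theta trait value(s). For scalar items a numeric vector (vectorised
#'   evaluation); for m-dimensional items either a length-m vector or an
#'   n-by-m matrix of trait rows.
#' @return response probabilities in (c, 1).
#' @export
response_probability <- function(item, theta) {
  stopifnot(inherits(item, "item_parameters"))
  m <- length(item$a)
  if (m == 1L) {
    if (is.matrix(theta)) theta <- drop(theta)
    eta <- item$a * theta - item$b
  } else {
    th <- if (is.matrix(theta)) theta else matrix(theta, nrow = 1L)
    if (ncol(th) != m) {
      stop("theta must have one column per trait dimension", call. = FALSE)
    }
    eta <- drop(th %*% item$a) - sum(item$b)
  }
  item$c + (1 - item$c) * stats::plogis(eta)
}

#' Bernoulli log-likelihood of the 3PL model
#'
#' \eqn{\sum_j [y_j \log P_j + (1 - y_j)\log(1 - P_j)]} with
#' \eqn{P_j} the 3PL probability at \eqn{\theta_j}. `records` needs columns
#' `y` (0/1 response) and `x` (standardised covariate). For variants with
#' person-level random effects, `trait` carries the per-record effects.
#'
#' @param records data frame of response records (columns `y`, `x`).
#' @param item an [item_parameters] object.
#' @param trait a [trait_model] object.
#' @return the log-likelihood; `-Inf` (with a warning) if any record has
#'   probability exactly 0 or 1 in disagreement with its response.
#' @export
log_likelihood <- function(records, item, trait) {
  stopifnot(is.data.frame(records), inherits(item, "item_parameters"),
            inherits(trait, "trait_model"))
  if (!all(records$y %in% c(0, 1))) {
    stop("responses `y` must be 0/1", call. = FALSE)
  }
  if (!all(is.finite(records$x))) {
    stop("covariate `x` must be finite", call. = FALSE)
  }
  theta <- trait_values(trait, records$x)
  p <- response_probability(item, theta)
  ll <- sum(ifelse(records$y == 1, log(p), log1p(-p)))
  if (!is.finite(ll)) {
    warning("log-likelihood is -Inf: a record has probability 0 or 1 ",
            "in disagreement with its response")
    return(-Inf)
  }
  ll
}

#' Latent trait regression specification for the four model variants
#'
#' * `M1` fixed intercept and slope, unconstrained difficulty prior.
#' * `M2` as M1 but the difficulty prior is truncated to b > 0.
#' * `M3` person-level random intercepts \eqn{\alpha_j \sim N(\alpha,
#'   \sigma^2_{re})}.
#' * `M4` correlated person-level random intercepts and slopes,
#'   \eqn{(\alpha_j, \beta_j) \sim MVN((\alpha, \beta), \Sigma)}, precision
#'   \eqn{\Sigma^{-1} \sim} Wishart.
#'
#' @param variant one of "M1", "M2", "M3", "M4".
#' @param alpha intercept (hyper-mean for M3/M4).
#' @param beta slope (hyper-mean for M4).
#' @param random_alphas per-record random intercepts (M3/M4 only).
#' @param random_betas per-record random slopes (M4 only).
#' @param re_sd random-intercept standard deviation (M3 only).
#' @param re_covariance 2x2 symmetric positive-definite random-effect
#'   covariance (M4 only).
#' @return an object of class `trait_model`.
#' @export
trait_model <- function(variant = c("M1", "M2", "M3", "M4"),
                        alpha, beta,
                        random_alphas = NULL, random_betas = NULL,
                        re_sd = NULL, re_covariance = NULL) {
  variant <- match.arg(variant)
  stopifnot(is.finite(alpha), is.finite(beta))
  if (variant %in% c("M1", "M2")) {
    if (!is.null(random_alphas) || !is.null(random_betas)) {
      stop("random effects are only allowed for M3/M4", call. = FALSE)
    }
  }
  if (variant %in% c("M3", "M4") && is.null(random_alphas)) {
    stop("random_alphas required for ", variant, call. = FALSE)
  }
  if (variant == "M4") {
    if (is.null(random_betas)) stop("random_betas required for M4",
                                    call. = FALSE)
    if (length(random_betas) != length(random_alphas)) {
      stop("random_alphas and random_betas must have equal length",
           call. = FALSE)
    }
    if (is.null(re_covariance)) stop("re_covariance required for M4",
                                     call. = FALSE)
    check_spd2(re_covariance)
  } else if (!is.null(re_covariance)) {
    stop("re_covariance is only allowed for M4", call. = FALSE)
  }
  if (variant == "M3") {
    if (is.null(re_sd)) re_sd <- 1
    stopifnot(is.finite(re_sd), re_sd > 0)
  }
  structure(list(variant = variant, alpha = alpha, beta = beta,
                 random_alphas = random_alphas, random_betas = random_betas,
                 re_sd = re_sd, re_covariance = re_covariance),
            class = "trait_model")
}

check_spd2 <- function(m) {
  if (!is.matrix(m) || !identical(dim(m), c(2L, 2L)) ||
      abs(m[1, 2] - m[2, 1]) > 1e-10 ||
      m[1, 1] <= 0 || det(m) <= 0) {
    stop("re_covariance must be 2x2 symmetric positive definite",
         call. = FALSE)
  }
  invisible(m)
}

#' Per-record trait values under a trait model
#'
#' @param trait a [trait_model] object.
#' @param x standardised covariate vector.
#' @return numeric vector of \eqn{\theta_j}.
#' @keywords internal
trait_values <- function(trait, x) {
  switch(trait$variant,
    M1 = ,
    M2 = trait$alpha + trait$beta * x,
    M3 = {
      stopifnot(length(trait$random_alphas) == length(x))
      trait$random_alphas + trait$beta * x
    },
    M4 = {
      stopifnot(length(trait$random_alphas) == length(x))
      trait$random_alphas + trait$random_betas * x
    }
  )
}

#' Prior specification for all model variants
#'
#' Defaults follow a weakly-informative reading: truncated-normal
#' \eqn{N(0, 10)I(a > 0)} for discrimination, \eqn{N(0, 10)} for difficulty
#' (variance parameterisation; truncated at 0 under M2), Beta(2, 2) for the
#' threshold (prior mean \eqn{\kappa/(\kappa+\tau)} = 0.5), standard-normal
#' priors for the trait regression intercept and slope, half-normal(0, 1) on
#' the M3 random-intercept SD, and Wishart(identity, 2) on the M4
#' random-effect precision matrix.
#'
#' @param a_mean,a_var truncated-normal hyperparameters for a (truncation at
#'   0).
#' @param b_mean,b_var normal hyperparameters for b.
#' @param c_kappa,c_tau beta-prior shapes for c (both > 0).
#' @param alpha_mean,alpha_var,beta_mean,beta_var normal hyperparameters for
#'   the trait regression coefficients.
#' @param re_sd_scale half-normal scale for the M3 random-intercept SD.
#' @param wishart_scale 2x2 scale matrix for the M4 precision prior.
#' @param wishart_df Wishart degrees of freedom (>= 2; default the number of
#'   random components).
#' @return an object of class `prior_spec`.
#' @export
prior_spec <- function(a_mean = 0, a_var = 10,
                       b_mean = 0, b_var = 10,
                       c_kappa = 2, c_tau = 2,
                       alpha_mean = 0, alpha_var = 1,
                       beta_mean = 0, beta_var = 1,
                       re_sd_scale = 1,
                       wishart_scale = diag(2), wishart_df = 2) {
  stopifnot(a_var > 0, b_var > 0, alpha_var > 0, beta_var > 0,
            c_kappa > 0, c_tau > 0, re_sd_scale > 0, wishart_df >= 2)
  check_spd2(wishart_scale)
  structure(list(a_mean = a_mean, a_var = a_var,
                 b_mean = b_mean, b_var = b_var,
                 c_kappa = c_kappa, c_tau = c_tau,
                 alpha_mean = alpha_mean, alpha_var = alpha_var,
                 beta_mean = beta_mean, beta_var = beta_var,
                 re_sd_scale = re_sd_scale,
                 wishart_scale = wishart_scale, wishart_df = wishart_df),
            class = "prior_spec")
}

# log density of N(mean, var) truncated to (0, Inf)
ltruncnorm <- function(x, mean, var) {
  sd <- sqrt(var)
  ifelse(x <= 0, -Inf,
         stats::dnorm(x, mean, sd, log = TRUE) -
           stats::pnorm(0, mean, sd, lower.tail = FALSE, log.p = TRUE))
}

# log Wishart(V = scale, df) density of a precision matrix P (d = 2),
# normalising constant included
lwishart2 <- function(P, scale, df) {
  d <- 2
  if (det(P) <= 0) return(-Inf)
  Vinv <- solve(scale)
  0.5 * (df - d - 1) * log(det(P)) - 0.5 * sum(diag(Vinv %*% P)) -
    0.5 * df * d * log(2) - 0.5 * df * log(det(scale)) -
    (d * (d - 1) / 4) * log(pi) -
    lgamma(df / 2) - lgamma((df - 1) / 2)
}

#' Joint log-prior density
#'
#' Sum of the log prior densities of all parameters in the variant:
#' truncated normal for a (renormalised over a > 0), normal (M1/M3/M4) or
#' truncated normal (M2) for b, beta for c, normals for the trait regression
#' coefficients, plus hierarchical terms — normal random intercepts and a
#' half-normal SD hyperprior under M3, multivariate-normal random effects
#' with a Wishart log-density on the precision matrix under M4.
#'
#' @inheritParams log_likelihood
#' @param priors a [prior_spec] object.
#' @return the log prior density; `-Inf` for parameters outside the
#'   variant's support.
#' @export
log_prior <- function(item, trait, priors) {
  stopifnot(inherits(item, "item_parameters"), inherits(trait, "trait_model"),
            inherits(priors, "prior_spec"))
  variant <- trait$variant
  if (any(item$a <= 0) || item$c <= 0 || item$c >= 1) return(-Inf)
  if (variant == "M2" && any(item$b <= 0)) return(-Inf)

  lp <- sum(ltruncnorm(item$a, priors$a_mean, priors$a_var))
  lp <- lp + if (variant == "M2") {
    sum(ltruncnorm(item$b, priors$b_mean, priors$b_var))
  } else {
    sum(stats::dnorm(item$b, priors$b_mean, sqrt(priors$b_var), log = TRUE))
  }
  lp <- lp + stats::dbeta(item$c, priors$c_kappa, priors$c_tau, log = TRUE)
  lp <- lp + stats::dnorm(trait$alpha, priors$alpha_mean,
                          sqrt(priors$alpha_var), log = TRUE)
  lp <- lp + stats::dnorm(trait$beta, priors$beta_mean,
                          sqrt(priors$beta_var), log = TRUE)

  if (variant == "M3") {
    if (trait$re_sd <= 0) return(-Inf)
    lp <- lp + sum(stats::dnorm(trait$random_alphas, trait$alpha,
                                trait$re_sd, log = TRUE))
    # half-normal(0, re_sd_scale) on the random-intercept SD
    lp <- lp + log(2) + stats::dnorm(trait$re_sd, 0, priors$re_sd_scale,
                                     log = TRUE)
  } else if (variant == "M4") {
    S <- trait$re_covariance
    P <- solve(S)
    dev_a <- trait$random_alphas - trait$alpha
    dev_b <- trait$random_betas - trait$beta
    n_re <- length(dev_a)
    quad <- P[1, 1] * sum(dev_a^2) + 2 * P[1, 2] * sum(dev_a * dev_b) +
      P[2, 2] * sum(dev_b^2)
    lp <- lp + n_re * (-log(2 * pi) - 0.5 * log(det(S))) - 0.5 * quad
    lp <- lp + lwishart2(P, priors$wishart_scale, priors$wishart_df)
  }
  lp
}

#' Unnormalised log-posterior density
#'
#' `log_likelihood() + log_prior()`; the proportionality constant of the
#' posterior is dropped.
#'
#' @inheritParams log_likelihood
#' @inheritParams log_prior
#' @return the unnormalised log posterior; `-Inf` propagates from either
#'   component.
#' @export
log_posterior <- function(records, item, trait, priors) {
  lp <- log_prior(item, trait, priors)
  if (!is.finite(lp)) return(-Inf)
  lp + log_likelihood(records, item, trait)
}
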