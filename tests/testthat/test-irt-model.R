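test_that("latent trait is the linear regression of ability on the covariate", {
  expect_equal(latent_trait(-0.084, -0.098, 1), -0.182)
  expect_equal(latent_trait(0, 0, 37), 0)
  expect_equal(latent_trait(2, -1, 2), 0)
  expect_equal(latent_trait(1, 2, c(-1, 0, 1)), c(-1, 1, 3))
  expect_error(latent_trait(Inf, 0, 1), "finite")
})

test_that("3PL response probability matches direct evaluation and its limits", {
  expect_equal(response_probability(item_parameters(1, 0, 1e-12), 0), 0.5,
               tolerance = 1e-10)
  # hand evaluation at the national-fit posterior means
  item <- item_parameters(0.704, 0.807, 0.340)
  expect_equal(response_probability(item, 0),
               0.340 + 0.660 * exp(-0.807) / (1 + exp(-0.807)))
  expect_equal(response_probability(item, 0), 0.54363, tolerance = 1e-5)
  # asymptotes: c as theta -> -Inf, 1 as theta -> +Inf
  item2 <- item_parameters(1, 0, 0.3)
  expect_equal(response_probability(item2, -1e6), 0.3, tolerance = 1e-12)
  expect_equal(response_probability(item2, 1e6), 1, tolerance = 1e-12)
  # numerically stable at extreme linear predictors
  expect_true(is.finite(response_probability(item2, 700)))
  expect_true(is.finite(response_probability(item2, -700)))
})

test_that("response probability is strictly increasing in theta when a > 0", {
  set.seed(41)
  for (i in 1:25) {
    item <- item_parameters(a = runif(1, 0.05, 4), b = rnorm(1, 0, 2),
                            c_thresh = runif(1, 0.01, 0.95))
    theta <- sort(rnorm(40, 0, 3))
    p <- response_probability(item, theta)
    expect_true(all(diff(p) > 0))
    expect_true(all(p > item$c & p < 1))
  }
})

test_that("vector item parameters collapse to the scalar path for one item", {
  theta <- seq(-3, 3, by = 0.5)
  scalar <- response_probability(item_parameters(0.9, 0.4, 0.25), theta)
  vector_form <- response_probability(
    item_parameters(a = c(0.9), b = c(0.4), c_thresh = 0.25),
    matrix(theta, ncol = 1))
  expect_equal(vector_form, scalar)
  # two-dimensional plumbing: linear predictor sums over dimensions
  item2 <- item_parameters(a = c(1, 2), b = c(0.5, -0.5), c_thresh = 0.2)
  p <- response_probability(item2, matrix(c(1, 1), nrow = 1))
  expect_equal(p, 0.2 + 0.8 * plogis(1 * 1 - 0.5 + 2 * 1 + 0.5))
})

test_that("item parameter invariants are enforced", {
  expect_error(item_parameters(-1, 0, 0.3), "a")
  expect_error(item_parameters(1, 0, 0), "c_thresh")
  expect_error(item_parameters(1, 0, 1), "c_thresh")
  expect_error(item_parameters(c(1, 2), 0, 0.5), "length")
})

test_that("log-likelihood equals the brute-force Bernoulli oracle", {
  item <- item_parameters(1, 0, 0.2)
  tr <- trait_model("M1", alpha = 0, beta = 0)
  rec1 <- data.frame(y = 1, x = 0)
  p0 <- response_probability(item, 0)
  # one record with parameters making P = 0.5 (c negligible, eta = 0)
  expect_equal(log_likelihood(rec1, item_parameters(1, 0, 1e-12), tr),
               log(0.5), tolerance = 1e-6)
  rec2 <- data.frame(y = c(1, 0), x = c(0, 0))
  # with P = p0 for both records
  expect_equal(log_likelihood(rec2, item, tr), log(p0) + log(1 - p0))

  set.seed(7)
  rec <- data.frame(y = rbinom(20, 1, 0.5), x = rnorm(20))
  item <- item_parameters(0.8, 0.3, 0.25)
  tr <- trait_model("M1", alpha = 0.1, beta = -0.4)
  p <- oracle_3pl(0.8, 0.3, 0.25, 0.1 - 0.4 * rec$x)
  expect_equal(log_likelihood(rec, item, tr), oracle_loglik(rec$y, p),
               tolerance = 1e-10)
  # and agrees with the compiled likelihood used inside the sampler
  expect_equal(log_likelihood(rec, item, tr),
               fevertreat:::loglik_3pl_cpp(as.integer(rec$y),
                                           0.1 - 0.4 * rec$x,
                                           0.8, 0.3, 0.25),
               tolerance = 1e-10)
})

test_that("two identical records at P = 0.5 give 2 log 0.5", {
  # degenerate c -> P pinned at c = 0.5 regardless of theta sign
  item <- item_parameters(1, 0, 0.5 - 1e-13)
  tr <- trait_model("M1", alpha = -50, beta = 0)
  rec <- data.frame(y = c(1, 0), x = c(1, 2))
  expect_equal(log_likelihood(rec, item, tr), 2 * log(0.5),
               tolerance = 1e-6)
})

test_that("log-prior closed forms are correct", {
  # uniform beta prior contributes zero for any c
  pr <- prior_spec(c_kappa = 1, c_tau = 1, alpha_var = 1, beta_var = 1)
  item <- item_parameters(1, 0.5, 0.7)
  tr <- trait_model("M1", alpha = 0, beta = 0)
  lp <- log_prior(item, tr, pr)
  pr2 <- prior_spec(c_kappa = 1, c_tau = 1)
  item2 <- item_parameters(1, 0.5, 0.25)
  expect_equal(lp, log_prior(item2, tr, pr2))  # c plays no role

  # truncated normal: a = 1 under N(1, 1) truncated at 0
  pr3 <- prior_spec(a_mean = 1, a_var = 1)
  base <- log_prior(item_parameters(1, 0.5, 0.7), tr, pr3) -
    log_prior(item_parameters(1e-9, 0.5, 0.7), tr, pr3)
  # direct check of the component instead: difference of truncnorm terms
  tn <- function(x) dnorm(x, 1, 1, log = TRUE) -
    pnorm(0, 1, 1, lower.tail = FALSE, log.p = TRUE)
  expect_equal(base, tn(1) - tn(1e-9), tolerance = 1e-9)
  expect_equal(tn(1), -0.5 * log(2 * pi) - log(pnorm(1)), tolerance = 1e-12)
  expect_equal(tn(1), -0.7464, tolerance = 1e-3)

  # M2 support violation: b <= 0 is impossible a priori
  tr2 <- trait_model("M2", alpha = 0, beta = 0)
  expect_identical(log_prior(item_parameters(1, -0.5, 0.3), tr2,
                             prior_spec()), -Inf)
  expect_true(is.finite(log_prior(item_parameters(1, 0.5, 0.3), tr2,
                                  prior_spec())))
})

test_that("hierarchical prior terms integrate random effects correctly", {
  set.seed(11)
  re <- rnorm(5, -0.2, 0.6)
  tr3 <- trait_model("M3", alpha = -0.2, beta = 0.1, random_alphas = re,
                     re_sd = 0.6)
  pr <- prior_spec()
  lp <- log_prior(item_parameters(1, 0, 0.4), tr3, pr)
  manual <- sum(dnorm(re, -0.2, 0.6, log = TRUE)) +
    log(2) + dnorm(0.6, 0, 1, log = TRUE)
  fixed_part <- log_prior(item_parameters(1, 0, 0.4),
                          trait_model("M1", alpha = -0.2, beta = 0.1), pr)
  expect_equal(lp, fixed_part + manual, tolerance = 1e-10)

  # M4: MVN random effects + Wishart log-density on the precision
  S <- matrix(c(1.2, 0.3, 0.3, 0.8), 2)
  ra <- rnorm(4); rb <- rnorm(4)
  tr4 <- trait_model("M4", alpha = 0, beta = 0, random_alphas = ra,
                     random_betas = rb, re_covariance = S)
  lp4 <- log_prior(item_parameters(1, 0, 0.4), tr4, pr)
  mvn <- sum(vapply(1:4, function(j) {
    v <- c(ra[j], rb[j])
    -log(2 * pi) - 0.5 * log(det(S)) -
      0.5 * drop(t(v) %*% solve(S) %*% v)
  }, numeric(1)))
  fixed_part4 <- log_prior(item_parameters(1, 0, 0.4),
                           trait_model("M1", alpha = 0, beta = 0), pr)
  expect_equal(lp4 - fevertreat:::lwishart2(solve(S), diag(2), 2),
               fixed_part4 + mvn, tolerance = 1e-9)
})

test_that("log-posterior is the sum of its parts and ignores record order", {
  set.seed(3)
  rec <- data.frame(y = rbinom(20, 1, 0.6), x = rnorm(20))
  item <- item_parameters(0.7, 0.8, 0.34)
  tr <- trait_model("M1", alpha = -0.08, beta = -0.1)
  pr <- prior_spec()
  lp <- log_posterior(rec, item, tr, pr)
  expect_equal(lp, log_likelihood(rec, item, tr) + log_prior(item, tr, pr),
               tolerance = 1e-12)
  # brute-force combination of the two independent oracles
  p <- oracle_3pl(0.7, 0.8, 0.34, -0.08 - 0.1 * rec$x)
  expect_equal(lp, oracle_loglik(rec$y, p) + log_prior(item, tr, pr),
               tolerance = 1e-10)
  perm <- rec[sample(nrow(rec)), ]
  expect_equal(log_posterior(perm, item, tr, pr), lp, tolerance = 1e-12)
  # uniform-prior configuration reduces to the likelihood up to a constant
  # independent of the data
  expect_equal(
    log_posterior(rec, item, tr, pr) - log_posterior(rec[0, ], item, tr, pr),
    log_likelihood(rec, item, tr), tolerance = 1e-10)
})
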