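test_that("sampling is deterministic given the seed", {
  fr <- febrile_frame(150, seed = 21)
  f1 <- run_mcmc(fr, "M1", config = desk_config(seed = 5, n_iterations = 1500,
                                                burn_in = 500))
  f2 <- run_mcmc(fr, "M1", config = desk_config(seed = 5, n_iterations = 1500,
                                                burn_in = 500))
  expect_identical(f1$chains, f2$chains)
  expect_identical(f1$deviance, f2$deviance)
})

test_that("stored draws never violate parameter supports", {
  fr <- febrile_frame(200, seed = 22)
  for (v in c("M1", "M2", "M3", "M4")) {
    fit <- run_mcmc(fr, v, config = desk_config(seed = 6, n_iterations = 2000,
                                                burn_in = 1000))
    m <- pool_draws(fit)
    expect_true(all(m[, "a"] > 0), info = v)
    expect_true(all(m[, "c"] > 0 & m[, "c"] < 1), info = v)
    if (v == "M2") expect_true(all(m[, "b"] > 0))
    if (v == "M3") expect_true(all(m[, "sigma_re"] > 0))
    if (v == "M4") {
      expect_true(all(m[, "tau11"] > 0 & m[, "tau22"] > 0))
      expect_true(all(abs(m[, "re_correlation"]) < 1))
    }
    # retained draw count honours (n_iterations - burn_in) / thin
    expect_equal(nrow(fit$chains[[1]]), 1000L)
    # acceptance rates in the adapted band
    acc <- unlist(fit$accept)
    expect_true(all(acc > 0.1 & acc < 0.7), info = v)
  }
})

test_that("prior-only sampling recovers the analytic priors", {
  cfg <- chain_config(n_chains = 2, n_iterations = 130000, burn_in = 5000,
                      thin = 50, seed = 30)
  pr <- prior_spec()
  fit <- run_mcmc(NULL, "M1", priors = pr, config = cfg,
                  likelihood = FALSE, n_records = 10)
  draws <- pool_draws(fit)
  expect_gte(nrow(draws), 5000)
  suppressWarnings({
    ks_c <- ks.test(draws[, "c"], pbeta, pr$c_kappa, pr$c_tau)$p.value
    ks_b <- ks.test(draws[, "b"], pnorm, pr$b_mean, sqrt(pr$b_var))$p.value
    ks_al <- ks.test(draws[, "alpha"], pnorm, pr$alpha_mean,
                     sqrt(pr$alpha_var))$p.value
    ks_be <- ks.test(draws[, "beta"], pnorm, pr$beta_mean,
                     sqrt(pr$beta_var))$p.value
    ptrunc <- function(x) {
      ifelse(x <= 0, 0,
             (pnorm(x, 0, sqrt(10)) - pnorm(0, 0, sqrt(10))) /
               pnorm(0, 0, sqrt(10), lower.tail = FALSE))
    }
    ks_a <- ks.test(draws[, "a"], ptrunc)$p.value
  })
  for (p in c(ks_a, ks_b, ks_c, ks_al, ks_be)) expect_gt(p, 0.01)
})

test_that("weakly identified all-one response vectors trigger a warning", {
  fr <- febrile_frame(60, seed = 23)
  fr$y <- 1L
  expect_warning(
    run_mcmc(fr, "M1", config = desk_config(seed = 2, n_iterations = 600,
                                            burn_in = 300)),
    "identified")
})

test_that("Gelman-Rubin matches the hand-computed closed form", {
  gr <- gelman_rubin(list(c(0, 2), c(1, 3)))
  # W = 2, B = 1, Vhat = 1.5, PSRF = sqrt(0.75)
  expect_equal(gr$psrf_point, sqrt(0.75), tolerance = 1e-12)
  expect_gte(gr$psrf_upper, gr$psrf_point)
})

test_that("Gelman-Rubin is near 1 for stationary chains and permutation-invariant", {
  set.seed(77)
  chains <- list(rnorm(5000), rnorm(5000), rnorm(5000))
  gr <- gelman_rubin(chains)
  expect_gt(gr$psrf_point, 0.99)
  expect_lt(gr$psrf_point, 1.02)
  gr_perm <- gelman_rubin(chains[c(3, 1, 2)])
  expect_equal(gr_perm$psrf_point, gr$psrf_point, tolerance = 1e-12)
  expect_equal(gr_perm$psrf_upper, gr$psrf_upper, tolerance = 1e-12)
  expect_error(gelman_rubin(list(c(1, 1, 1), c(2, 2, 2))), "undefined")
  expect_error(gelman_rubin(list(c(1, 2))), "chains")
})

test_that("Raftery-Lewis reproduces its closed-form minimum sample size", {
  set.seed(55)
  x <- rnorm(6000)
  rl <- raftery_lewis(x, q = 0.025, r = 0.005, s = 0.95)
  expect_equal(rl$n_min, ceiling(qnorm(0.975)^2 * 0.025 * 0.975 / 0.005^2))
  expect_equal(rl$n_min, 3746)
  expect_true(rl$sufficient)
  # i.i.d. chain: dependence factor close to 1
  expect_lt(abs(rl$dependence_factor - 1), 0.5)

  # limiting case: huge tolerated error needs essentially no draws
  rl2 <- raftery_lewis(rnorm(100), q = 0.5, r = 0.5, s = 0.01)
  expect_lte(rl2$n_min, 1)

  # insufficient chain signalled, not thrown
  rl3 <- raftery_lewis(rnorm(100), q = 0.025, r = 0.005, s = 0.95)
  expect_false(rl3$sufficient)
  expect_true(is.na(rl3$n_required))
  # inputs echoed so the settings are never ambiguous
  expect_equal(rl3[c("q", "r", "s")], list(q = 0.025, r = 0.005, s = 0.95))
})

test_that("Raftery-Lewis agrees with the reference implementation on a correlated chain", {
  set.seed(99)
  # AR(1) chain with strong autocorrelation
  x <- as.numeric(arima.sim(list(ar = 0.9), 20000))
  rl <- raftery_lewis(x, q = 0.025, r = 0.0125, s = 0.95)
  ref <- coda::raftery.diag(coda::mcmc(x), q = 0.025, r = 0.0125, s = 0.95)
  res <- ref$resmatrix
  expect_equal(rl$n_required, unname(res[1, "N"]), tolerance = 0.05)
  expect_equal(rl$burn_in_est, unname(res[1, "M"]), tolerance = 0.3)
  expect_equal(rl$n_min, unname(res[1, "Nmin"]))
  expect_gt(rl$dependence_factor, 1)
})

test_that("posterior summaries use type-7 quantiles and an independent oracle", {
  s <- summarise_draws(rep(1, 4))
  expect_equal(s$mean, 1); expect_equal(s$median, 1)
  expect_equal(s$ci_low, 1); expect_equal(s$ci_high, 1)

  s2 <- summarise_draws(as.numeric(1:100))
  expect_equal(s2$median, 50.5)
  expect_equal(s2$ci_low, 3.475)     # 1 + 99 * 0.025
  expect_equal(s2$ci_high, 97.525)   # 1 + 99 * 0.975

  set.seed(8)
  v <- rlnorm(501)
  s3 <- summarise_draws(v)
  sv <- sort(v)
  # hand-rolled linear interpolation at h = (n-1)p + 1
  manual_q <- function(p) {
    h <- (length(sv) - 1) * p + 1
    lo <- floor(h)
    sv[lo] + (h - lo) * (sv[lo + 1] - sv[lo])
  }
  expect_equal(s3$ci_low, manual_q(0.025), tolerance = 1e-12)
  expect_equal(s3$ci_high, manual_q(0.975), tolerance = 1e-12)
  expect_true(s3$ci_low <= s3$median && s3$median <= s3$ci_high)
})

test_that("DIC identities hold exactly and degenerate draws give pD = 0", {
  fr <- febrile_frame(150, seed = 24)
  fit <- run_mcmc(fr, "M1", config = desk_config(seed = 4,
                                                 n_iterations = 1500,
                                                 burn_in = 500))
  d <- dic(fr, fit)
  expect_identical(d$dic - d$dbar - d$pd, 0)
  expect_identical(d$pd - d$dbar + d$dhat, 0)

  # collapse the posterior to a point: every draw identical
  point <- fit
  pm <- posterior_means(fit)
  p_pm <- pm[["c"]] + (1 - pm[["c"]]) *
    plogis(pm[["a"]] * (pm[["alpha"]] + pm[["beta"]] * fr$x) - pm[["b"]])
  point$re_mean[, "p_j"] <- p_pm
  for (k in seq_along(point$chains)) {
    point$chains[[k]][] <- rep(pm, each = nrow(point$chains[[k]]))
    dev_at_pm <- -2 * sum(fr$y * log(p_pm) + (1 - fr$y) * log1p(-p_pm))
    point$deviance[[k]][] <- dev_at_pm
  }
  d0 <- dic(fr, point)
  expect_equal(d0$pd, 0, tolerance = 1e-9)
  expect_equal(d0$dic, d0$dhat, tolerance = 1e-9)
})

test_that("random-effect variants carry more effective parameters than fixed ones", {
  fr <- febrile_frame(400, seed = 25)
  cfg1 <- desk_config(seed = 61, n_iterations = 4000, burn_in = 2000)
  cfg4 <- desk_config(seed = 62, n_iterations = 4000, burn_in = 2000)
  d1 <- dic(fr, run_mcmc(fr, "M1", config = cfg1))
  d4 <- dic(fr, run_mcmc(fr, "M4", config = cfg4))
  expect_gt(d4$pd, d1$pd)
})

test_that("parameter posteriors concentrate near the generating truth", {
  truth <- true_parameters(item = item_parameters(0.7, 0.8, 0.34),
                           alpha = -0.08, beta = -0.10)
  fr <- febrile_frame(2000, truth = truth, seed = 26)
  fit <- run_mcmc(fr, "M1", config = chain_config(3, 20000, 10000, seed = 63))
  s <- summarise_draws(fit)
  rownames(s) <- s$parameter
  true_vals <- c(a = 0.7, b = 0.8, c = 0.34, alpha = -0.08, beta = -0.10)
  for (p in names(true_vals)) {
    expect_gt(true_vals[[p]], s[p, "ci_low"] - 1e-9)
    expect_lt(true_vals[[p]], s[p, "ci_high"] + 1e-9)
  }
  expect_true(all(s$psrf_point < 1.2))
})

test_that("long-format draw export round-trips chain, parameter and value", {
  fr <- febrile_frame(60, seed = 27)
  fit <- run_mcmc(fr, "M1", config = desk_config(seed = 28,
                                                 n_iterations = 600,
                                                 burn_in = 300))
  path <- tempfile(fileext = ".csv")
  write_draws(fit, path, thin = 5)
  d <- read.csv(path)
  expect_equal(names(d), c("chain", "iteration", "parameter", "value"))
  expect_equal(nrow(d), 2 * 5 * 60)  # chains x parameters x kept draws
  sub <- d[d$chain == 2 & d$parameter == "c", ]
  expect_equal(sub$value, unname(fit$chains[[2]][seq(1, 300, 5), "c"]),
               tolerance = 1e-12)
})
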