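# Shared fixtures and independent oracles used across the test files.

# small survey design that still yields a few hundred children
small_design <- function(...) {
  survey_design(n_regions = 3, clusters_per_region = 5,
                children_per_household_mean = 1.0, ...)
}

# modelling table of approximately n febrile children generated from the
# 3PL truth (fever probability 1 so every child enters the table)
febrile_frame <- function(n, truth = true_parameters(
                            item = item_parameters(0.7, 0.8, 0.34),
                            alpha = -0.08, beta = -0.10),
                          seed = 1L) {
  per_cluster_mean <- 22.5  # midpoint of the 15-30 household range
  clusters <- max(2, ceiling(n / per_cluster_mean / 4))
  design <- survey_design(n_regions = 4, clusters_per_region = clusters,
                          children_per_household_mean = 1.0,
                          fever_probability = 1.0)
  fr <- model_frame(generate_survey(design, truth, seed = seed))
  fr[seq_len(min(n, nrow(fr))), , drop = FALSE]
}

# brute-force Bernoulli log-pmf sum, written independently of the package's
# vectorised likelihood path
oracle_loglik <- function(y, p) {
  total <- 0
  for (j in seq_along(y)) {
    total <- total + dbinom(y[j], size = 1, prob = p[j], log = TRUE)
  }
  total
}

# direct scalar evaluation of the 3PL curve
oracle_3pl <- function(a, b, c, theta) {
  e <- exp(a * theta - b)
  c + (1 - c) * e / (1 + e)
}

# pairwise Mann-Whitney concordance with ties counted one half
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

desk_config <- function(seed = 1L, n_iterations = 4000, burn_in = 2000,
                        n_chains = 2) {
  chain_config(n_chains = n_chains, n_iterations = n_iterations,
               burn_in = burn_in, seed = seed)
}
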