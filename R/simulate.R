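#' DHS-style two-stage cluster survey design
#'
#' Describes the sampling frame the simulator emulates: regions, clusters
#' sampled within regions, households sampled within clusters, and children
#' under five enumerated within households. Defaults approximate a national
#' survey of the Namibian scale: 13 regions, 20 clusters per region, 15-30
#' households per cluster and a mean of 0.82 enumerated under-fives per
#' household give an expected roster of about 4.8 thousand children, of whom
#' about 24% report fever. Travel times to the nearest facility are
#' log-normal with a longer rural than urban tail (rural median 45 min,
#' urban median 15 min, sdlog 0.8), which reproduces the wide range of
#' regional mean travel times seen in national data.
#'
#' @param n_regions number of regions.
#' @param clusters_per_region clusters sampled per region.
#' @param households_per_cluster integer range (min, max) of households per
#'   cluster, each within \[1, 1000\].
#' @param children_per_household_mean Poisson mean of enumerated under-fives
#'   per household.
#' @param fever_probability probability a child reports fever in the recall
#'   window.
#' @param urban_fraction probability a cluster is urban.
#' @param travel_time_meanlog named vector `c(urban=, rural=)` of log-median
#'   travel times (minutes) to the nearest dispensary/clinic.
#' @param travel_time_sdlog log-scale SD of travel times.
#' @return an object of class `survey_design`.
#' @export
survey_design <- function(n_regions = 13,
                          clusters_per_region = 20,
                          households_per_cluster = c(15, 30),
                          children_per_household_mean = 0.82,
                          fever_probability = 0.236,
                          urban_fraction = 0.4,
                          travel_time_meanlog = c(urban = log(15),
                                                  rural = log(45)),
                          travel_time_sdlog = 0.8) {
  stopifnot(n_regions >= 1, clusters_per_region >= 1,
            length(households_per_cluster) == 2,
            children_per_household_mean > 0,
            travel_time_sdlog > 0)
  h <- as.integer(households_per_cluster)
  if (h[1] < 1 || h[2] > 1000 || h[1] > h[2]) {
    stop("households_per_cluster must satisfy 1 <= min <= max <= 1000",
         call. = FALSE)
  }
  for (p in c(fever_probability, urban_fraction)) {
    if (!is.finite(p) || p < 0 || p > 1) {
      stop("probabilities must lie in [0, 1]", call. = FALSE)
    }
  }
  if (!setequal(names(travel_time_meanlog), c("urban", "rural"))) {
    stop("travel_time_meanlog needs named entries 'urban' and 'rural'",
         call. = FALSE)
  }
  structure(list(n_regions = as.integer(n_regions),
                 clusters_per_region = as.integer(clusters_per_region),
                 households_per_cluster = h,
                 children_per_household_mean = children_per_household_mean,
                 fever_probability = fever_probability,
                 urban_fraction = urban_fraction,
                 travel_time_meanlog = travel_time_meanlog,
                 travel_time_sdlog = travel_time_sdlog),
            class = "survey_design")
}

#' Ground-truth parameters for the survey simulator
#'
#' The data-generating twin of the fitted model: treatment outcomes are
#' Bernoulli draws from the 3PL response curve evaluated at
#' \eqn{\theta_j = \alpha + \beta x_j} (plus an optional person-level normal
#' random intercept), with \eqn{x_j} the z-scored travel time to the nearest
#' facility. Defaults sit near the posterior means a national fit produces.
#'
#' @param item an [item_parameters] object.
#' @param alpha,beta latent-trait regression intercept and slope.
#' @param random_effect_sd SD of person-level random intercepts; 0 for
#'   fixed-effect generation.
#' @return an object of class `true_parameters`.
#' @export
true_parameters <- function(item = item_parameters(0.704, 0.807, 0.340),
                            alpha = -0.084, beta = -0.098,
                            random_effect_sd = 0) {
  stopifnot(inherits(item, "item_parameters"),
            is.finite(alpha), is.finite(beta),
            is.finite(random_effect_sd), random_effect_sd >= 0)
  structure(list(item = item, alpha = alpha, beta = beta,
                 random_effect_sd = random_effect_sd),
            class = "true_parameters")
}

#' Simulate a DHS-like febrile-child survey with known truth
#'
#' Two-stage generation: clusters within regions (urban/rural assigned per
#' cluster), households within clusters, children within households. Each
#' child draws correlated travel times to the three facility types
#' (dispensary/clinic, health centre, hospital; clinic nearest on average);
#' the minimum — travel time to the nearest formal facility — is z-scored
#' over the febrile children and drives the treatment outcome through the
#' 3PL curve. Fever status is Bernoulli(`fever_probability`); the treatment
#' response is only defined (non-`NA`) for febrile children, mirroring
#' surveys that ask about treatment only after a reported fever episode.
#'
#' @param design a [survey_design].
#' @param truth a [true_parameters].
#' @param seed integer seed; the run is deterministic given the seed.
#' @return an object of class `fever_survey`: list with `records` (one row
#'   per enumerated child), `truth`, `design`, `seed` and `standardisation`
#'   (mean/SD of nearest-facility travel time over febrile children, used to
#'   map minutes to the model covariate).
#' @export
generate_survey <- function(design, truth, seed = 1L) {
  stopifnot(inherits(design, "survey_design"),
            inherits(truth, "true_parameters"))
  if (design$n_regions < 1 || design$clusters_per_region < 1) {
    stop("design must contain at least one region and cluster",
         call. = FALSE)
  }
  set.seed(as.integer(seed))

  n_clusters <- design$n_regions * design$clusters_per_region
  region <- rep(sprintf("R%02d", seq_len(design$n_regions)),
                each = design$clusters_per_region)
  cluster <- sprintf("%s_C%03d", region, rep(seq_len(design$clusters_per_region),
                                             times = design$n_regions))
  urban <- stats::rbinom(n_clusters, 1, design$urban_fraction)
  hh <- design$households_per_cluster
  n_households <- sample(seq(hh[1], hh[2]), n_clusters, replace = TRUE)
  n_children <- stats::rpois(n_clusters,
                             n_households * design$children_per_household_mean)

  idx <- rep(seq_len(n_clusters), n_children)
  n <- length(idx)
  if (n == 0L) stop("design produced zero children; increase sizes",
                    call. = FALSE)

  meanlog <- ifelse(urban[idx] == 1,
                    design$travel_time_meanlog[["urban"]],
                    design$travel_time_meanlog[["rural"]])
  # shared log-normal base + increasing multiplicative offsets give
  # correlated times with clinic <= health centre <= hospital on average
  base <- stats::rlnorm(n, meanlog, design$travel_time_sdlog)
  t_clinic <- base
  t_hc <- base * stats::rlnorm(n, 0.35, 0.20)
  t_hosp <- base * stats::rlnorm(n, 0.70, 0.25)
  nearest <- pmin(t_clinic, t_hc, t_hosp)

  fever <- stats::rbinom(n, 1, design$fever_probability)
  feb <- fever == 1
  if (!any(feb)) stop("no febrile children generated; increase sizes or ",
                      "fever_probability", call. = FALSE)
  std <- list(mean = mean(nearest[feb]), sd = stats::sd(nearest[feb]))
  if (!is.finite(std$sd) || std$sd == 0) std$sd <- 1
  x <- (nearest - std$mean) / std$sd

  theta <- truth$alpha + truth$beta * x
  if (truth$random_effect_sd > 0) {
    theta <- theta + stats::rnorm(n, 0, truth$random_effect_sd)
  }
  p <- response_probability(truth$item, theta)
  treated <- rep(NA_integer_, n)
  treated[feb] <- stats::rbinom(sum(feb), 1, p[feb])

  records <- data.frame(
    child_id = sprintf("K%05d", seq_len(n)),
    region = region[idx],
    cluster = cluster[idx],
    urban = urban[idx],
    travel_time_minutes_clinic = t_clinic,
    travel_time_minutes_health_centre = t_hc,
    travel_time_minutes_hospital = t_hosp,
    fever = fever,
    treated_formal = treated,
    stringsAsFactors = FALSE
  )
  structure(list(records = records, truth = truth, design = design,
                 seed = as.integer(seed), standardisation = std),
            class = "fever_survey")
}

#' @export
print.fever_survey <- function(x, ...) {
  n <- nrow(x$records)
  nf <- sum(x$records$fever == 1)
  cat("Simulated fever treatment-seeking survey\n")
  cat(sprintf("  %d children in %d regions; %d febrile (%.1f%%)\n",
              n, x$design$n_regions, nf, 100 * nf / n))
  if (nf > 0) {
    cat(sprintf("  %.1f%% of febrile children treated in the formal sector\n",
                100 * mean(x$records$treated_formal[x$records$fever == 1])))
  }
  invisible(x)
}

#' Modelling table of febrile children
#'
#' Restricts a survey to febrile children (estimation focuses on children
#' reporting fever) and attaches the model covariate: z-scored travel time
#' in minutes to the nearest formal facility (minimum over facility types).
#' By default the standardisation constants frozen at generation time are
#' used so simulated truth and fitted scale agree; pass a `standardisation`
#' list to override (e.g. a training-set standardisation applied to a
#' hold-out set).
#'
#' @param survey a `fever_survey`, or a raw records data frame in the survey
#'   CSV layout.
#' @param standardisation optional list with elements `mean` and `sd`.
#' @return data frame with columns `child_id`, `region`, `cluster`, `urban`,
#'   `travel_time_minutes`, `x`, `y`.
#' @export
model_frame <- function(survey, standardisation = NULL) {
  records <- if (inherits(survey, "fever_survey")) survey$records else survey
  nearest <- pmin(records$travel_time_minutes_clinic,
                  records$travel_time_minutes_health_centre,
                  records$travel_time_minutes_hospital)
  feb <- records$fever == 1
  if (is.null(standardisation)) {
    standardisation <- if (inherits(survey, "fever_survey")) {
      survey$standardisation
    } else {
      list(mean = mean(nearest[feb]), sd = stats::sd(nearest[feb]))
    }
  }
  out <- data.frame(
    child_id = records$child_id[feb],
    region = records$region[feb],
    cluster = records$cluster[feb],
    urban = records$urban[feb],
    travel_time_minutes = nearest[feb],
    x = (nearest[feb] - standardisation$mean) / standardisation$sd,
    y = as.integer(records$treated_formal[feb]),
    stringsAsFactors = FALSE
  )
  attr(out, "standardisation") <- standardisation
  out
}

#' Write a survey to CSV
#'
#' One header row plus one row per enumerated child; round-trippable by
#' [read_survey()].
#'
#' @param survey a `fever_survey` or its records data frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_survey <- function(survey, path) {
  records <- if (inherits(survey, "fever_survey")) survey$records else survey
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a survey CSV
#'
#' @param path file written by [write_survey()].
#' @return records data frame.
#' @export
read_survey <- function(path) {
  if (!file.exists(path)) stop("no such survey file: ", path, call. = FALSE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Tally headline survey proportions
#'
#' @param survey a `fever_survey` or records data frame.
#' @return list with `n_children`, `n_febrile`, `n_treated`,
#'   `fever_pct` (febrile / enumerated, percent) and `treated_pct`
#'   (formally treated / febrile, percent).
#' @export
tally_survey <- function(survey) {
  records <- if (inherits(survey, "fever_survey")) survey$records else survey
  n <- nrow(records)
  nf <- sum(records$fever == 1)
  nt <- sum(records$treated_formal == 1, na.rm = TRUE)
  list(n_children = n, n_febrile = nf, n_treated = nt,
       fever_pct = 100 * nf / n, treated_pct = 100 * nt / nf)
}
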