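#' Model comparison table
#'
#' One row per fitted variant with its DIC, effective number of parameters
#' and chain count, sorted by DIC ascending (ties broken by variant name).
#'
#' @param dic_results list of `dic_result` objects (see [dic()]).
#' @param n_chains chain counts, recycled across variants.
#' @return data frame with columns `variant`, `dic`, `pd`, `dbar`, `dhat`,
#'   `chains`.
#' @export
model_comparison_table <- function(dic_results, n_chains = NA_integer_) {
  stopifnot(length(dic_results) >= 1)
  tab <- do.call(rbind, lapply(dic_results, function(d) {
    data.frame(variant = d$variant, dic = d$dic, pd = d$pd,
               dbar = d$dbar, dhat = d$dhat, stringsAsFactors = FALSE)
  }))
  tab$chains <- rep_len(n_chains, nrow(tab))
  tab <- tab[order(tab$dic, tab$variant), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Map travel-time minutes to the model covariate
#'
#' @param minutes travel times in minutes.
#' @param standardisation list with `mean` and `sd` (minutes), as attached
#'   to a simulated survey or a [model_frame()].
#' @return standardised covariate values.
#' @export
standardise_minutes <- function(minutes, standardisation) {
  (minutes - standardisation$mean) / standardisation$sd
}

#' Posterior fever-response decay curve
#'
#' For each travel time on the grid, the posterior distribution of the
#' response probability \eqn{P(t) = c + (1-c)\,\mathrm{logistic}(a(\alpha +
#' \beta z(t)) - b)} over the retained draws, summarised as the mean and
#' equal-tailed 95% band. Under distance decay (\eqn{\beta < 0}) the curve
#' falls with travel time toward the threshold floor c.
#'
#' @param draws a `posterior_draws` object (fixed-effect parameters are
#'   used; for hierarchical variants the curve is the population-level one).
#' @param travel_time_grid grid of travel times in minutes.
#' @param standardisation list with `mean` and `sd` mapping minutes to the
#'   model covariate.
#' @param max_draws cap on the number of draws used (subsampled evenly).
#' @return an object of class `response_curve`: data frame with columns
#'   `travel_time_minutes`, `mean`, `ci_low`, `ci_high`.
#' @export
response_curve <- function(draws, travel_time_grid = seq(0, 240, by = 2),
                           standardisation, max_draws = 4000) {
  stopifnot(inherits(draws, "posterior_draws"), all(travel_time_grid >= 0))
  x_grid <- standardise_minutes(travel_time_grid, standardisation)
  if (any(abs(x_grid) > 4)) {
    warning("grid extends more than 4 SD beyond the covariate mean; ",
            "curve values there are extrapolations")
  }
  m <- pool_draws(draws)
  if (nrow(m) > max_draws) {
    m <- m[round(seq(1, nrow(m), length.out = max_draws)), , drop = FALSE]
  }
  # draws x grid matrix of probabilities
  theta <- outer(m[, "alpha"], rep(1, length(x_grid))) +
    outer(m[, "beta"], x_grid)
  eta <- theta * m[, "a"] - m[, "b"]
  p <- m[, "c"] + (1 - m[, "c"]) * stats::plogis(eta)
  qs <- apply(p, 2, stats::quantile, probs = c(0.025, 0.975), type = 7,
              names = FALSE)
  structure(data.frame(travel_time_minutes = travel_time_grid,
                       mean = colMeans(p),
                       ci_low = qs[1, ], ci_high = qs[2, ]),
            class = c("response_curve", "data.frame"))
}

#' Regional treatment-probability summary
#'
#' Evaluates the posterior of the fitted response curve at each region's
#' mean travel time to each facility type, giving the mean and equal-tailed
#' 95% credible interval of the probability of formal fever treatment — the
#' region-by-facility-type summary surface of the analysis.
#'
#' @param draws a `posterior_draws` object.
#' @param region_table data frame with column `region` plus one positive
#'   travel-time column (minutes) per facility type, e.g.
#'   `clinic`, `health_centre`, `hospital`.
#' @param standardisation list with `mean` and `sd` (minutes).
#' @param max_draws cap on the number of draws used.
#' @return data frame with one row per region x facility type: columns
#'   `region`, `facility_type`, `travel_time_minutes`, `mean`, `ci_low`,
#'   `ci_high`.
#' @export
regional_summary <- function(draws, region_table, standardisation,
                             max_draws = 4000) {
  stopifnot(inherits(draws, "posterior_draws"), is.data.frame(region_table),
            "region" %in% names(region_table))
  types <- setdiff(names(region_table), "region")
  if (length(types) == 0) stop("region_table needs facility-type columns",
                               call. = FALSE)
  if (anyNA(region_table) ||
      any(vapply(region_table[types], function(v) any(v <= 0), logical(1)))) {
    stop("travel times must be positive minutes for every region",
         call. = FALSE)
  }
  m <- pool_draws(draws)
  if (nrow(m) > max_draws) {
    m <- m[round(seq(1, nrow(m), length.out = max_draws)), , drop = FALSE]
  }
  rows <- lapply(types, function(ft) {
    minutes <- region_table[[ft]]
    x <- standardise_minutes(minutes, standardisation)
    theta <- outer(m[, "alpha"], rep(1, length(x))) + outer(m[, "beta"], x)
    eta <- theta * m[, "a"] - m[, "b"]
    p <- m[, "c"] + (1 - m[, "c"]) * stats::plogis(eta)
    qs <- apply(p, 2, stats::quantile, probs = c(0.025, 0.975), type = 7,
                names = FALSE)
    data.frame(region = region_table$region, facility_type = ft,
               travel_time_minutes = minutes, mean = colMeans(p),
               ci_low = qs[1, ], ci_high = qs[2, ],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Region table of mean travel times from a survey
#'
#' @param survey a `fever_survey` or records data frame.
#' @return data frame with columns `region`, `clinic`, `health_centre`,
#'   `hospital` (mean minutes over the region's children).
#' @export
region_travel_times <- function(survey) {
  records <- if (inherits(survey, "fever_survey")) survey$records else survey
  agg <- stats::aggregate(
    records[c("travel_time_minutes_clinic",
              "travel_time_minutes_health_centre",
              "travel_time_minutes_hospital")],
    by = list(region = records$region), FUN = mean)
  names(agg) <- c("region", "clinic", "health_centre", "hospital")
  agg
}
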