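#' Standard populations for direct age standardization
#'
#' A standard population is a set of non-negative weights over the 10 age
#' bands of [age_levels()], summing to 1. The packaged fixture
#' `standard_population_synthetic.csv` is a synthetic age distribution
#' shaped like the Australian 2006 both-sexes population aged 50+; it is a
#' stand-in for tests and demos, not official census data.
#'
#' @param path CSV with columns `age_group,weight` (weights are normalized
#'   if they sum to something other than 1 by more than rounding error an
#'   error is raised).
#' @return Named numeric vector of weights over the 10 bands.
#' @export
#' @examples
#' std <- load_standard_population(
#'   system.file("extdata", "standard_population_synthetic.csv",
#'               package = "certadjust"))
#' sum(std)
load_standard_population <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(
    age_group = readr::col_character(), weight = readr::col_double()
  ), progress = FALSE)
  as_standard_population(setNames(df$weight, df$age_group))
}

#' @param weights Named numeric vector over the 10 age bands.
#' @rdname load_standard_population
#' @export
as_standard_population <- function(weights) {
  if (!setequal(names(weights), age_levels())) {
    stop("standard population must cover exactly the bands ",
         paste(age_levels(), collapse = ", "), call. = FALSE)
  }
  weights <- weights[age_levels()]
  if (any(weights < 0)) stop("standard population weights must be >= 0", call. = FALSE)
  if (abs(sum(weights) - 1) > 1e-9) {
    stop("standard population weights must sum to 1 (got ",
         format(sum(weights), digits = 12), ")", call. = FALSE)
  }
  weights
}

#' Age-specific death rates per 100,000
#'
#' Joins death counts to population counts on the given keys and computes
#' `100000 * deaths / population` per cell. Cells present in `deaths` must
#' have positive population.
#'
#' @param deaths Data frame with a `deaths` count column plus key columns
#'   (typically `year`, `age_group`).
#' @param population Data frame with a `population` column and the same keys.
#' @param by Character vector of key columns.
#' @return Tibble of the keys plus `deaths`, `population`, `rate`. Cells in
#'   `population` with no matching deaths get `deaths = 0`.
#' @export
age_specific_rates <- function(deaths, population,
                               by = intersect(names(deaths), names(population))) {
  by <- setdiff(by, c("deaths", "population", "rate"))
  out <- dplyr::left_join(
    tibble::as_tibble(population), tibble::as_tibble(deaths), by = by
  )
  out$deaths[is.na(out$deaths)] <- 0
  bad <- which(!is.finite(out$population) | out$population <= 0)
  if (length(bad) > 0) {
    cell <- paste(vapply(by, function(k) paste0(k, "=", out[[k]][bad[1]]), ""),
                  collapse = ", ")
    stop("non-positive population in cell (", cell, ")", call. = FALSE)
  }
  out$rate <- 1e5 * out$deaths / out$population
  out
}

#' Directly age-standardized death rate
#'
#' Computes the weighted average of age-specific rates with fixed standard
#' weights: `ASDR = sum_a w_a * rate_a`, per 100,000.
#'
#' @param rates Named numeric vector of age-specific rates (names are age
#'   bands), or a data frame with `age_group` and `rate` columns.
#' @param std Standard population weights (see [as_standard_population()]).
#' @param missing_as_zero If TRUE, bands absent from `rates` contribute a
#'   zero rate; the default is to error on missing bands.
#' @return The age-standardized rate (scalar).
#' @export
#' @examples
#' std <- rep(0.1, 10); names(std) <- age_levels()
#' asdr(setNames(rep(200, 10), age_levels()), std)
asdr <- function(rates, std, missing_as_zero = FALSE) {
  std <- as_standard_population(std)
  if (is.data.frame(rates)) {
    rates <- setNames(rates$rate, as.character(rates$age_group))
  }
  missing <- setdiff(age_levels(), names(rates))
  if (length(missing) > 0) {
    if (!missing_as_zero) {
      stop("no rate for age band(s): ", paste(missing, collapse = ", "),
           "; pass missing_as_zero = TRUE to impute zeros", call. = FALSE)
    }
    rates[missing] <- 0
  }
  sum(std * rates[age_levels()])
}

#' ASDR series for a cohort
#'
#' Tabulates deaths by year and age band (optionally within a subset given
#' by `numerator`), computes age-specific rates against `population`, and
#' standardizes each year. The cohort is assumed to belong to a single
#' stratum (one country and sex); population must carry `year`, `age_group`
#' and `population` for that same stratum.
#'
#' @param cohort An `mcod_cohort` restricted to one stratum.
#' @param population Data frame `year,age_group,population` for the stratum.
#' @param std Standard population weights.
#' @param numerator Optional logical vector over records (e.g. dementia-UCOD
#'   indicator); default counts every record.
#' @return Tibble `year,rate` with one row per year of `population`.
#' @export
asdr_series <- function(cohort, population, std, numerator = NULL) {
  if (is.null(numerator)) numerator <- rep(TRUE, nrow(cohort))
  stopifnot(length(numerator) == nrow(cohort))
  sub <- cohort[numerator, ]
  deaths <- dplyr::count(
    tibble::tibble(year = sub$year, age_group = as.character(sub$age_group)),
    .data$year, .data$age_group, name = "deaths"
  )
  pop <- tibble::as_tibble(population)
  pop$age_group <- as.character(pop$age_group)
  cells <- age_specific_rates(deaths, pop[, c("year", "age_group", "population")],
                              by = c("year", "age_group"))
  out <- dplyr::group_by(cells, .data$year) |>
    dplyr::summarise(rate = asdr(setNames(.data$rate, .data$age_group), std),
                     .groups = "drop")
  dplyr::arrange(out, .data$year)
}

#' Percentage of dementia MCOD deaths carrying a cause group
#'
#' For each country, sex and year, the percentage of dementia-MCOD records
#' in which `group` is reported in the given certificate part (1, 2,
#' `"any"`) or selected as the underlying cause (`"ucod"`). The special
#' group `"cvd"` aggregates the ischemic heart disease, stroke and other-CVD
#' groups (ICD-10 I00-I99).
#'
#' @param cohort An `mcod_cohort`, already dementia-MCOD filtered.
#' @param group Cause-group name from the taxonomy, or `"cvd"`.
#' @param part 1, 2, `"any"`, or `"ucod"`.
#' @param taxonomy A `cause_taxonomy`.
#' @return Tibble `country,sex,year,n,pct`.
#' @export
pct_of_mcod <- function(cohort, group, part = 1, taxonomy = default_taxonomy()) {
  if (identical(group, "cvd")) {
    hit <- has_cvd_in_part(cohort, part, taxonomy)
  } else {
    if (!group %in% names(taxonomy)) {
      stop("unknown cause group '", group, "'", call. = FALSE)
    }
    hit <- has_group_in_part(cohort, group, part, taxonomy)
  }
  out <- tibble::tibble(country = cohort$country, sex = cohort$sex,
                        year = cohort$year, hit = hit) |>
    dplyr::group_by(.data$country, .data$sex, .data$year) |>
    dplyr::summarise(n = dplyr::n(), pct = 100 * mean(.data$hit), .groups = "drop")
  dplyr::arrange(out, .data$country, .data$sex, .data$year)
}

has_cvd_in_part <- function(cohort, part, taxonomy) {
  if (identical(part, "ucod")) return(is_cvd_code(cohort$ucod))
  codes <- switch(as.character(part),
    "1" = split_codes(cohort$part1),
    "2" = split_codes(cohort$part2),
    "any" = Map(c, split_codes(cohort$part1), split_codes(cohort$part2)),
    stop("part must be 1, 2, 'any' or 'ucod'", call. = FALSE)
  )
  vapply(codes, function(x) any(is_cvd_code(x)), logical(1))
}

#' Annual rate of change of a rate series
#'
#' Default `"loglinear"` method: ordinary least squares of `log(rate)` on
#' year; the annual percent change is `100 * (exp(slope) - 1)`. The
#' `"endpoint"` method uses only the first and last years:
#' `100 * ((rate_last / rate_first)^(1 / (year_last - year_first)) - 1)`.
#' Both agree exactly on geometric (constant-growth) series.
#'
#' @param year Integer vector of years (>= 2 distinct).
#' @param rate Positive rates, same length.
#' @param method `"loglinear"` (default) or `"endpoint"`.
#' @return A `trend_estimate`: list with `annual_pct_change`, `method`, and
#'   for the log-linear fit the `lm` object as `fit`.
#' @export
#' @examples
#' yrs <- 2006:2016
#' annual_rate_of_change(yrs, 100 * 1.02^(yrs - 2006))$annual_pct_change
annual_rate_of_change <- function(year, rate, method = c("loglinear", "endpoint")) {
  method <- match.arg(method)
  if (is.data.frame(year)) { rate <- year$rate; year <- year$year }
  stopifnot(length(year) == length(rate), length(unique(year)) >= 2)
  if (method == "loglinear") {
    if (any(rate <= 0)) {
      stop("log-linear trend undefined for non-positive rates; ",
           "consider method = 'endpoint' on a positive sub-series", call. = FALSE)
    }
    fit <- lm(log(rate) ~ year)
    est <- 100 * (exp(coef(fit)[["year"]]) - 1)
  } else {
    o <- order(year)
    y0 <- year[o][1]; y1 <- year[o][length(year)]
    r0 <- rate[o][1]; r1 <- rate[o][length(rate)]
    if (r0 <= 0) stop("endpoint trend undefined: first-year rate is not positive",
                      call. = FALSE)
    fit <- NULL
    est <- 100 * ((r1 / r0)^(1 / (y1 - y0)) - 1)
  }
  structure(list(annual_pct_change = unname(est), method = method, fit = fit),
            class = "trend_estimate")
}

#' @export
print.trend_estimate <- function(x, ...) {
  cat(sprintf("<trend_estimate> %+.2f%% per year (%s)\n",
              x$annual_pct_change, x$method))
  invisible(x)
}

#' Cumulative percent change implied by a constant annual rate
#'
#' `100 * ((1 + annual_pct / 100)^n_years - 1)`: compounding a constant
#' annual percent change over `n_years`.
#'
#' @param annual_pct Annual percent change.
#' @param n_years Number of years (>= 1).
#' @return Total percent change over the period.
#' @export
#' @examples
#' cumulative_change(4.2, 10)  # ~51%
cumulative_change <- function(annual_pct, n_years) {
  stopifnot(n_years >= 1)
  100 * ((1 + annual_pct / 100)^n_years - 1)
}

#' Rank of a cause among leading causes of death
#'
#' 1-based descending rank by ASDR; tied causes share the smaller rank.
#'
#' @param asdr_by_cause Named numeric vector of ASDRs.
#' @param focus Name of the cause to rank.
#' @return Integer rank (1 = highest rate).
#' @export
#' @examples
#' rank_leading_causes(c(cvd = 50, cancer = 40, dementia = 45), "dementia")
rank_leading_causes <- function(asdr_by_cause, focus) {
  if (length(asdr_by_cause) == 0) stop("empty cause map", call. = FALSE)
  if (!focus %in% names(asdr_by_cause)) {
    stop("focus cause '", focus, "' not present", call. = FALSE)
  }
  as.integer(1L + sum(asdr_by_cause > asdr_by_cause[[focus]]))
}

# round half away from zero, matching published-table style
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
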