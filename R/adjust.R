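#' Fit the certification model for one stratum
#'
#' Convenience wrapper: builds the design matrix for a dementia-MCOD cohort
#' (one country and sex), takes dementia-UCOD as the outcome, and fits the
#' logistic model by maximum likelihood. The returned fit carries the
#' design metadata needed for counterfactual prediction.
#'
#' @inheritParams build_design
#' @param ... Passed to [fit_logistic()].
#' @return A `certification_fit` with a `$design` element.
#' @export
fit_certification <- function(cohort, taxonomy = default_taxonomy(),
                              year_levels = sort(unique(cohort$year)),
                              include_dementia_placement = FALSE, ...) {
  des <- build_design(cohort, taxonomy, year_levels = year_levels,
                      include_dementia_placement = include_dementia_placement)
  y <- as.numeric(is_dementia_ucod(cohort, taxonomy))
  stratum <- c(country = unique(cohort$country)[1], sex = unique(cohort$sex)[1])
  fit <- fit_logistic(des$x, y, stratum = stratum, ...)
  fit$design <- des[setdiff(names(des), "x")]
  fit$reference_year <- max(des$year_levels)
  fit
}

#' Counterfactual dementia-UCOD probabilities under reference-year practice
#'
#' Predicts each record's probability of dementia being selected as the
#' underlying cause with the model's year effect fixed at `ref_year`: the
#' record's year-indicator block is overwritten with the reference year's
#' indicator and the probability is `plogis(x %*% beta)`. For records from
#' `ref_year` itself this equals the fitted probability.
#'
#' @param fit A `certification_fit` from [fit_certification()] (or
#'   [fit_logistic()] with `design` attached).
#' @param cohort The dementia-MCOD cohort to predict for.
#' @param ref_year Reference year; defaults to the last fitted year.
#' @param taxonomy Taxonomy used when the cohort was fitted.
#' @return Numeric vector of probabilities in (0, 1), one per record.
#' @export
predict_counterfactual <- function(fit, cohort, ref_year = fit$reference_year,
                                   taxonomy = default_taxonomy()) {
  stopifnot(inherits(fit, "certification_fit"))
  if (is.null(fit$design)) {
    stop("fit carries no design metadata; use fit_certification()", call. = FALSE)
  }
  des <- fit$design
  if (!ref_year %in% des$year_levels) {
    stop("reference year ", ref_year, " was not among the fitted years (",
         paste(range(des$year_levels), collapse = "-"), ")", call. = FALSE)
  }
  x <- build_design(cohort, taxonomy, year_levels = des$year_levels,
                    include_dementia_placement = des$include_dementia_placement)$x
  x[, des$year_cols] <- 0
  ref_col <- des$year_cols[as.character(ref_year)]
  if (!is.na(ref_col)) x[, ref_col] <- 1  # NA: ref_year is the reference level
  beta <- fit$coefficients
  beta[is.na(beta)] <- 0  # aliased terms: indicator never observed
  plogis(drop(x %*% beta))
}

#' Adjusted dementia-UCOD ASDR series from per-record probabilities
#'
#' Aggregates counterfactual probabilities into expected death counts per
#' year and age band (the adjusted count of a cell is the sum of its
#' records' probabilities), converts to age-specific rates against the
#' population, and standardizes. With all probabilities equal to 1 this
#' reproduces the dementia-MCOD ASDR; with the model's fitted (not
#' counterfactual) probabilities it reproduces each year's observed
#' dementia-UCOD count exactly, by the maximum-likelihood score equations.
#'
#' @param probabilities One probability per record of `cohort`.
#' @param cohort Dementia-MCOD cohort for one stratum.
#' @param population Data frame `year,age_group,population` for the stratum.
#' @param std Standard population weights.
#' @return Tibble `year,rate`.
#' @export
adjusted_ucod_asdr <- function(probabilities, cohort, population, std) {
  stopifnot(length(probabilities) == nrow(cohort),
            all(probabilities >= 0 & probabilities <= 1))
  deaths <- tibble::tibble(year = cohort$year,
                           age_group = as.character(cohort$age_group),
                           p = probabilities) |>
    dplyr::group_by(.data$year, .data$age_group) |>
    dplyr::summarise(deaths = sum(.data$p), .groups = "drop")
  pop <- tibble::as_tibble(population)
  pop$age_group <- as.character(pop$age_group)
  cells <- age_specific_rates(deaths, pop[, c("year", "age_group", "population")],
                              by = c("year", "age_group"))
  out <- dplyr::group_by(cells, .data$year) |>
    dplyr::summarise(rate = asdr(setNames(.data$rate, .data$age_group), std),
                     .groups = "drop")
  dplyr::arrange(out, .data$year)
}

#' Constant-MCOD rescaling of an adjusted series
#'
#' Emulates a stable rate of dementia reporting anywhere on the death
#' certificate: each year's adjusted UCOD rate is rescaled by the ratio of
#' the reference year's MCOD ASDR to that year's,
#' `out_t = adjusted_t / mcod_t * mcod_ref`. At the reference year the
#' series is unchanged; if the MCOD ASDR is constant the whole series is
#' unchanged.
#'
#' @param adjusted Tibble `year,rate` (adjusted UCOD ASDR).
#' @param mcod Tibble `year,rate` (MCOD ASDR, positive every year).
#' @param ref_year Reference year, present in `mcod`.
#' @return Tibble `year,rate`.
#' @export
constant_mcod_adjust <- function(adjusted, mcod, ref_year) {
  m <- setNames(mcod$rate, mcod$year)
  if (!as.character(ref_year) %in% names(m)) {
    stop("reference year ", ref_year, " absent from the MCOD series", call. = FALSE)
  }
  need <- as.character(adjusted$year)
  if (!all(need %in% names(m))) {
    stop("MCOD series missing year(s): ",
         paste(setdiff(need, names(m)), collapse = ", "), call. = FALSE)
  }
  zero <- need[m[need] <= 0]
  if (length(zero) > 0) {
    stop("MCOD ASDR not positive in year ", zero[1], call. = FALSE)
  }
  tibble::tibble(year = adjusted$year,
                 rate = unname(adjusted$rate / m[need] *
                                 m[[as.character(ref_year)]]))
}

#' Run the full certification adjustment for every stratum
#'
#' For each country-by-sex stratum: computes observed dementia-MCOD and
#' dementia-UCOD ASDR series; fits the per-stratum logistic certification
#' model; predicts counterfactual probabilities under reference-year
#' practice; aggregates them into the adjusted UCOD ASDR; applies the
#' constant-MCOD rescaling; and estimates annual rates of change for all
#' four series.
#'
#' @param cohort An `mcod_cohort` (filtered to dementia MCOD; unfiltered
#'   input is filtered with a message).
#' @param population Data frame `country,sex,year,age_group,population`
#'   (the `country` column may be omitted for single-country data).
#' @param std Standard population weights.
#' @param taxonomy A `cause_taxonomy`.
#' @param ref_year Reference year; default, the last year in the data
#'   (per stratum).
#' @param trend_method Passed to [annual_rate_of_change()].
#' @param include_dementia_placement See [build_design()].
#' @return A named list (one element per stratum `"country.sex"`), each an
#'   `adjusted_series`: list with `stratum`, `series` (tibble
#'   `year,measure,rate` over measures `mcod_asdr`, `ucod_asdr`,
#'   `adjusted_ucod_asdr`, `adjusted_constant_mcod_asdr`), `trends` (tibble
#'   `measure,method,annual_pct_change`), `fit`, and `ref_year`.
#' @export
run_adjustment <- function(cohort, population, std,
                           taxonomy = default_taxonomy(), ref_year = NULL,
                           trend_method = "loglinear",
                           include_dementia_placement = FALSE) {
  if (!all(is_dementia_mcod(cohort, taxonomy))) {
    message("run_adjustment: input contains non-dementia-MCOD records; filtering")
    cohort <- filter_dementia_mcod(cohort, taxonomy)
  }
  pop <- tibble::as_tibble(population)
  if (!"country" %in% names(pop)) pop$country <- unique(cohort$country)[1]

  strata <- unique(cohort[, c("country", "sex")])
  out <- list()
  for (i in seq_len(nrow(strata))) {
    co <- strata$country[i]; sx <- strata$sex[i]
    sub <- cohort[cohort$country == co & cohort$sex == sx, ]
    spop <- pop[pop$country == co & pop$sex == sx,
                c("year", "age_group", "population")]
    if (nrow(spop) == 0) {
      stop("no population rows for stratum ", co, "/", sx, call. = FALSE)
    }
    ry <- if (is.null(ref_year)) max(sub$year) else ref_year
    if (!ry %in% sub$year) {
      stop("reference year ", ry, " outside the data years for stratum ",
           co, "/", sx, call. = FALSE)
    }
    mcod <- asdr_series(sub, spop, std)
    ucod <- asdr_series(sub, spop, std,
                        numerator = is_dementia_ucod(sub, taxonomy))
    fit <- fit_certification(sub, taxonomy,
                             include_dementia_placement = include_dementia_placement)
    prob <- predict_counterfactual(fit, sub, ref_year = ry, taxonomy = taxonomy)
    adj <- adjusted_ucod_asdr(prob, sub, spop, std)
    cmc <- constant_mcod_adjust(adj, mcod, ry)

    series <- dplyr::bind_rows(
      dplyr::mutate(mcod, measure = "mcod_asdr"),
      dplyr::mutate(ucod, measure = "ucod_asdr"),
      dplyr::mutate(adj, measure = "adjusted_ucod_asdr"),
      dplyr::mutate(cmc, measure = "adjusted_constant_mcod_asdr")
    )[, c("measure", "year", "rate")]
    trends <- dplyr::group_by(series, .data$measure) |>
      dplyr::summarise(
        method = trend_method,
        annual_pct_change =
          annual_rate_of_change(.data$year, .data$rate,
                                method = trend_method)$annual_pct_change,
        .groups = "drop")
    message(sprintf(
      "run_adjustment[%s/%s]: n=%d, ref_year=%d, ridge=%g, %d IRLS iterations",
      co, sx, nrow(sub), ry, fit$ridge, fit$iterations))
    out[[paste(co, sx, sep = ".")]] <- structure(
      list(stratum = c(country = co, sex = sx), series = series,
           trends = trends, fit = fit, ref_year = ry),
      class = "adjusted_series")
  }
  out
}

#' @export
print.adjusted_series <- function(x, ...) {
  cat("<adjusted_series> ", paste(names(x$stratum), x$stratum, sep = "=",
                                  collapse = ", "),
      "; reference year ", x$ref_year, "\n", sep = "")
  print(tidyr::pivot_wider(x$trends, names_from = "measure",
                           values_from = "annual_pct_change"))
  invisible(x)
}
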