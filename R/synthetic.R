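#' Synthetic MCOD cohort configuration
#'
#' Bundles everything the generator needs to draw an individual-level
#' dementia-MCOD cohort with known ground truth: the year range and strata,
#' a population schedule by age band, true dementia-MCOD rates, the
#' part-1/part-2 reporting model for dementia and for comorbid cause
#' groups (each with a linear-in-logit time trend), and the true
#' certification coefficients driving dementia-as-UCOD selection.
#'
#' Comorbid groups appear on a certificate independently of each other: in
#' part 1 with probability `p1(t)`, in part 2 with probability `p2(t)`
#' (mutually exclusive placements), both interpolated linearly on the logit
#' scale between a first-year and a last-year value.
#'
#' @param country Stratum country label.
#' @param sexes Character vector of sexes to simulate.
#' @param years Integer vector of contiguous calendar years.
#' @param population_shape Named vector over [age_levels()]: relative size
#'   of each band in the first year.
#' @param population_growth Named vector of annual growth rates per band
#'   (the aging schedule).
#' @param deaths_per_year Target expected dementia-MCOD deaths per year per
#'   stratum in the first year; sets the population scale.
#' @param true_mcod_rate Named vector of true dementia-MCOD death rates per
#'   100,000 by age band.
#' @param mcod_year_multiplier Annual multiplicative trend in the true
#'   rates (1 = flat truth).
#' @param dementia_part1 Length-2 vector: probability that dementia is
#'   reported in part 1 (vs part 2) in the first and last year,
#'   logit-interpolated.
#' @param dementia_codes_weights Named weights over the five dementia codes
#'   used when sampling each record's dementia code.
#' @param comorbidity Named list, one element per cause group:
#'   `list(code =, p1 = c(start, end), p2 = c(start, end))`.
#' @param certification_beta Named vector of true logistic coefficients on
#'   the design terms of [build_design()]; missing terms are zero.
#' @param seed Integer seed (mandatory).
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(country = "SYN",
                             sexes = c("male", "female"),
                             years = 2006:2015,
                             population_shape = default_population_shape(),
                             population_growth = default_population_growth(),
                             deaths_per_year = 5000,
                             true_mcod_rate = default_true_mcod_rate(),
                             mcod_year_multiplier = 1,
                             dementia_part1 = c(0.55, 0.75),
                             dementia_codes_weights =
                               c(F03 = 0.45, G30 = 0.35, F01 = 0.08,
                                 F00 = 0.07, G31 = 0.05),
                             comorbidity = default_comorbidity(),
                             certification_beta = default_certification_beta(years),
                             seed) {
  if (missing(seed)) stop("a seed is mandatory", call. = FALSE)
  years <- sort(as.integer(years))
  stopifnot(all(diff(years) == 1), length(years) >= 2)
  for (g in names(comorbidity)) {
    cm <- comorbidity[[g]]
    probs <- c(cm$p1, cm$p2)
    if (any(probs < 0 | probs > 1) || any(cm$p1 + cm$p2 > 1)) {
      stop("comorbidity probabilities for '", g, "' out of range", call. = FALSE)
    }
  }
  if (any(dementia_part1 < 0 | dementia_part1 > 1)) {
    stop("dementia_part1 probabilities out of range", call. = FALSE)
  }
  stopifnot(all(population_shape > 0), all(true_mcod_rate >= 0))
  structure(list(
    country = country, sexes = sexes, years = years,
    population_shape = population_shape[age_levels()],
    population_growth = population_growth[age_levels()],
    deaths_per_year = deaths_per_year,
    true_mcod_rate = true_mcod_rate[age_levels()],
    mcod_year_multiplier = mcod_year_multiplier,
    dementia_part1 = dementia_part1,
    dementia_codes_weights = dementia_codes_weights,
    comorbidity = comorbidity,
    certification_beta = certification_beta,
    seed = as.integer(seed)
  ), class = "synthetic_config")
}

# age structure of a 50+ population, heaviest at the younger bands
default_population_shape <- function() {
  setNames(c(1400, 1280, 1000, 780, 650, 560, 430, 240, 90, 25) * 1e3,
           age_levels())
}

# older bands grow faster: population aging
default_population_growth <- function() {
  setNames(c(0.010, 0.010, 0.012, 0.012, 0.015, 0.015,
             0.020, 0.025, 0.030, 0.035), age_levels())
}

# dementia-MCOD death rates per 100,000, steeply rising with age
default_true_mcod_rate <- function() {
  setNames(c(3, 8, 20, 60, 160, 420, 1100, 2600, 5500, 9500), age_levels())
}

default_comorbidity <- function() {
  list(
    ischemic_heart_disease = list(code = "I21", p1 = c(0.15, 0.15), p2 = c(0.08, 0.08)),
    stroke                 = list(code = "I63", p1 = c(0.14, 0.14), p2 = c(0.05, 0.05)),
    cancers                = list(code = "C80", p1 = c(0.07, 0.07), p2 = c(0.05, 0.05)),
    pneumonia              = list(code = "J18", p1 = c(0.21, 0.21), p2 = c(0.01, 0.01)),
    chronic_respiratory    = list(code = "J44", p1 = c(0.04, 0.04), p2 = c(0.04, 0.04)),
    ill_defined            = list(code = "R54", p1 = c(0.14, 0.14), p2 = c(0.03, 0.03))
  )
}

# true coefficients: CVD/cancer in part 1 push dementia away from the UCOD,
# pneumonia and ill-defined causes in part 1 push towards it; effects
# increase with age; year effects rise linearly to `year_effect_last`
default_certification_beta <- function(years, year_effect_last = 1.2,
                                       intercept = -0.9) {
  n <- length(years)
  beta <- c(
    "(Intercept)" = intercept,
    part1_ischemic_heart_disease = -1.6, part2_ischemic_heart_disease = -0.5,
    part1_stroke = -1.4,                 part2_stroke = -0.4,
    part1_cancers = -1.8,                part2_cancers = -0.8,
    part1_pneumonia = 0.9,               part2_pneumonia = 0.1,
    part1_chronic_respiratory = -0.8,    part2_chronic_respiratory = -0.3,
    part1_ill_defined = 0.7,             part2_ill_defined = 0.2
  )
  beta <- c(beta, setNames(seq(0.15, 1.35, length.out = 9),
                           paste0("age_", age_levels()[-1])))
  c(beta, setNames(year_effect_last * seq_len(n - 1) / (n - 1),
                   paste0("year_", years[-1])))
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat("<synthetic_config> ", x$country, ", years ", min(x$years), "-",
      max(x$years), ", ", length(x$sexes), " sex strata, ~",
      x$deaths_per_year, " deaths/year/stratum, seed ", x$seed, "\n", sep = "")
  invisible(x)
}

# logit-linear interpolation of a (start, end) probability pair over years
interp_logit <- function(p_pair, years) {
  if (p_pair[1] == p_pair[2]) return(rep(p_pair[1], length(years)))
  f <- (years - min(years)) / (max(years) - min(years))
  lo <- qlogis(pmin(pmax(p_pair, 1e-12), 1 - 1e-12))
  plogis(lo[1] + f * (lo[2] - lo[1]))
}

# population table for one stratum: shape scaled so first-year expected
# deaths hit deaths_per_year, bands growing by the aging schedule
synthetic_population <- function(config) {
  expected_first <- sum(config$population_shape * config$true_mcod_rate) / 1e5
  scale <- config$deaths_per_year / expected_first
  grid <- expand.grid(sex = config$sexes, year = config$years,
                      age_group = age_levels(), stringsAsFactors = FALSE)
  t_idx <- grid$year - min(config$years)
  base <- config$population_shape[grid$age_group] * scale
  growth <- (1 + config$population_growth[grid$age_group])^t_idx
  tibble::tibble(country = config$country, sex = grid$sex, year = grid$year,
                 age_group = grid$age_group,
                 population = unname(base * growth))
}

#' Generate a synthetic MCOD cohort with known truth
#'
#' Draws, per stratum (sex) and year-by-age cell, a Poisson number of
#' dementia-MCOD deaths with mean `population x true rate`; places each
#' death's dementia code in part 1 or part 2; samples comorbid cause groups
#' independently per the reporting model and maps each to its
#' representative ICD-10 code; and assigns dementia-as-UCOD by a Bernoulli
#' draw on the true logistic model. Non-dementia UCODs are sampled from the
#' record's part-1 non-dementia codes (falling back to part 2, then to the
#' ill-defined code R99 when dementia is the only reported cause).
#' Deterministic given `(config, seed)`.
#'
#' @param config A `synthetic_config`.
#' @param seed Overrides `config$seed` if given.
#' @return List with `cohort` (an `mcod_cohort`), `population` (tibble
#'   `country,sex,year,age_group,population`), `standard` (standard-population
#'   weights), and `truth` (a `synthetic_truth`: the config plus the
#'   analytic true MCOD / observed UCOD / reference-year-adjusted ASDR
#'   series).
#' @export
generate_cohort <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(seed)
  pop <- synthetic_population(config)
  std <- synthetic_standard_weights()
  years <- config$years
  t0 <- min(years)
  groups <- names(config$comorbidity)
  beta <- config$certification_beta

  bval <- function(term) if (term %in% names(beta)) beta[[term]] else 0
  age_beta <- vapply(paste0("age_", age_levels()), bval, 0)
  year_beta <- vapply(paste0("year_", years), bval, 0)
  names(age_beta) <- age_levels(); names(year_beta) <- as.character(years)

  p_dem1 <- setNames(interp_logit(config$dementia_part1, years),
                     as.character(years))
  p1_g <- lapply(config$comorbidity,
                 function(cm) setNames(interp_logit(cm$p1, years),
                                       as.character(years)))
  p2_g <- lapply(config$comorbidity,
                 function(cm) setNames(interp_logit(cm$p2, years),
                                       as.character(years)))

  all_records <- vector("list", length(config$sexes))
  for (si in seq_along(config$sexes)) {
    sx <- config$sexes[si]
    spop <- pop[pop$sex == sx, ]
    mult <- config$mcod_year_multiplier^(spop$year - t0)
    lambda <- spop$population * config$true_mcod_rate[spop$age_group] * mult / 1e5
    n_cell <- rpois(length(lambda), lambda)
    n <- sum(n_cell)
    if (n == 0) { all_records[[si]] <- NULL; next }
    year <- rep(spop$year, n_cell)
    age <- rep(spop$age_group, n_cell)
    ykey <- as.character(year)

    dem_code <- sample(names(config$dementia_codes_weights), n, replace = TRUE,
                       prob = config$dementia_codes_weights)
    dem_in_1 <- runif(n) < p_dem1[ykey]

    G <- length(groups)
    u <- matrix(runif(n * G), n, G)
    P1 <- vapply(groups, function(g) p1_g[[g]][ykey], numeric(n))
    P2 <- vapply(groups, function(g) p2_g[[g]][ykey], numeric(n))
    if (n == 1) { P1 <- matrix(P1, 1); P2 <- matrix(P2, 1) }
    in1 <- u < P1
    in2 <- !in1 & u < P1 + P2

    b1 <- vapply(groups, function(g) bval(paste0("part1_", g)), 0)
    b2 <- vapply(groups, function(g) bval(paste0("part2_", g)), 0)
    lp <- bval("(Intercept)") + drop(in1 %*% b1) + drop(in2 %*% b2) +
      age_beta[age] + year_beta[ykey]
    if (bval("part1_dementia") != 0) lp <- lp + bval("part1_dementia") * dem_in_1
    dem_ucod <- runif(n) < plogis(lp)

    codes <- vapply(config$comorbidity, function(cm) cm$code, "")
    collapse <- function(ind) {
      out <- rep("", n)
      for (j in seq_len(G)) {
        hit <- ind[, j]
        out[hit] <- ifelse(nzchar(out[hit]), paste(out[hit], codes[j], sep = ";"),
                           codes[j])
      }
      out
    }
    com1 <- collapse(in1)
    com2 <- collapse(in2)
    part1 <- ifelse(dem_in_1,
                    ifelse(nzchar(com1), paste(dem_code, com1, sep = ";"), dem_code),
                    com1)
    part2 <- ifelse(!dem_in_1,
                    ifelse(nzchar(com2), paste(dem_code, com2, sep = ";"), dem_code),
                    com2)

    # non-dementia UCOD: uniform pick from part-1 comorbid codes, else
    # part-2 comorbid codes, else the ill-defined fallback R99
    pick1 <- pick_random_code(com1)
    pick2 <- pick_random_code(com2)
    ucod <- ifelse(dem_ucod, dem_code,
                   ifelse(!is.na(pick1), pick1,
                          ifelse(!is.na(pick2), pick2, "R99")))

    all_records[[si]] <- tibble::tibble(
      record_id = sprintf("%s-%s-%06d", config$country, substr(sx, 1, 1),
                          seq_len(n)),
      country = config$country, year = year, sex = sx, age_group = age,
      part1 = part1, part2 = part2, ucod = ucod)
  }
  cohort <- as_mcod_cohort(dplyr::bind_rows(all_records),
                           country_label = config$country)
  truth <- synthetic_truth(config, std)
  list(cohort = cohort, population = pop, standard = std, truth = truth)
}

# one uniformly chosen code from each ";"-separated string, NA if empty
pick_random_code <- function(x) {
  lst <- split_codes(x)
  len <- lengths(lst)
  idx <- ifelse(len > 0, floor(runif(length(lst)) * len) + 1, NA_integer_)
  out <- rep(NA_character_, length(lst))
  has <- !is.na(idx)
  out[has] <- mapply(function(v, i) v[[i]], lst[has], idx[has])
  out
}

#' Synthetic standard-population weights
#'
#' The packaged synthetic standard: an age distribution shaped like an
#' Australian 2006 both-sexes population aged 50+, normalized to sum to 1.
#'
#' @return Named weight vector over [age_levels()].
#' @export
synthetic_standard_weights <- function() {
  shape <- default_population_shape()
  as_standard_population(shape / sum(shape))
}

#' Analytic truth for a synthetic configuration
#'
#' Computes, by exact enumeration over comorbidity patterns (no Monte
#' Carlo), the expectation of the dementia-MCOD ASDR, the observed
#' dementia-UCOD ASDR, and the counterfactual (reference-year certification
#' practice) adjusted UCOD ASDR implied by a `synthetic_config`.
#'
#' @param config A `synthetic_config`.
#' @param std Standard weights; defaults to the packaged synthetic standard.
#' @return A `synthetic_truth`: list with `config` and `series` (tibble
#'   `year,measure,rate` over `mcod_asdr`, `ucod_asdr`,
#'   `adjusted_ucod_asdr`).
#' @export
synthetic_truth <- function(config, std = synthetic_standard_weights()) {
  years <- config$years
  mcod <- vapply(years, function(t) {
    r <- config$true_mcod_rate * config$mcod_year_multiplier^(t - min(years))
    asdr(r, std)
  }, 0)
  obs <- true_expected_series(config, std, reference_year = FALSE)
  adj <- true_expected_series(config, std, reference_year = TRUE)
  series <- dplyr::bind_rows(
    tibble::tibble(year = years, measure = "mcod_asdr", rate = mcod),
    tibble::tibble(year = years, measure = "ucod_asdr", rate = obs),
    tibble::tibble(year = years, measure = "adjusted_ucod_asdr", rate = adj)
  )
  structure(list(config = config, series = series), class = "synthetic_truth")
}

#' Expected (counterfactual) dementia-UCOD ASDR series of a configuration
#'
#' The analytic expectation of the adjusted series: for each year and age
#' band, the true MCOD rate times the expected dementia-UCOD probability,
#' where the expectation enumerates every comorbidity placement pattern
#' (each group absent / in part 1 / in part 2) with its year-specific
#' probability, and the model's year effect is fixed at the last year when
#' `reference_year = TRUE` (the counterfactual) or kept at the record's own
#' year otherwise (the observed series).
#'
#' @param config A `synthetic_config`.
#' @param std Standard weights.
#' @param reference_year Fix the year effect at the final year?
#' @return Numeric vector of ASDRs, one per year.
#' @export
true_expected_series <- function(config, std = synthetic_standard_weights(),
                                 reference_year = TRUE) {
  years <- config$years
  groups <- names(config$comorbidity)
  G <- length(groups)
  beta <- config$certification_beta
  bval <- function(term) if (term %in% names(beta)) beta[[term]] else 0
  b1 <- vapply(groups, function(g) bval(paste0("part1_", g)), 0)
  b2 <- vapply(groups, function(g) bval(paste0("part2_", g)), 0)
  age_beta <- vapply(paste0("age_", age_levels()), bval, 0)
  year_beta <- setNames(vapply(paste0("year_", years), bval, 0),
                        as.character(years))

  # states: 0 absent, 1 part 1, 2 part 2
  states <- as.matrix(expand.grid(rep(list(0:2), G)))
  lp_cause <- drop((states == 1) %*% b1 + (states == 2) %*% b2)

  vapply(years, function(t) {
    key <- as.character(t)
    pr <- rep(1, nrow(states))
    for (j in seq_len(G)) {
      cm <- config$comorbidity[[j]]
      p1 <- interp_logit(cm$p1, years)[match(t, years)]
      p2 <- interp_logit(cm$p2, years)[match(t, years)]
      pj <- c(1 - p1 - p2, p1, p2)[states[, j] + 1]
      pr <- pr * pj
    }
    ybeta <- if (reference_year) year_beta[[as.character(max(years))]] else
      year_beta[[key]]
    rate_age <- vapply(age_levels(), function(a) {
      ep <- sum(pr * plogis(bval("(Intercept)") + lp_cause + age_beta[[paste0("age_", a)]] + ybeta))
      mult <- config$mcod_year_multiplier^(t - min(years))
      config$true_mcod_rate[[a]] * mult * ep
    }, 0)
    asdr(setNames(rate_age, age_levels()), std)
  }, 0)
}

#' Named synthetic-cohort presets
#'
#' * `flat_truth` — flat true dementia-MCOD rates and constant comorbidity
#'   reporting, with a steadily rising true year effect in the
#'   certification model: observed UCOD rates rise for certification
#'   reasons alone, so a correct adjustment recovers a flat
#'   constant-MCOD-adjusted trend.
#' * `au_like` — 2006-2016, MCOD ASDR drifting up ~0.5%/year, comorbidity
#'   part-1/part-2 frequencies moving between realistic Australian-style
#'   endpoint values (declining part-1 pneumonia and CVD, rising
#'   ill-defined), and a year effect sized so the observed UCOD ASDR rises
#'   roughly 4%/year.
#' * `us_like` — 2006-2017, faster MCOD growth (~1.3%/year), higher
#'   baseline probability of dementia being the UCOD, gentler year effect:
#'   observed UCOD ASDR rises roughly 3%/year.
#'
#' @param name Preset name.
#' @param seed Seed stored in the config.
#' @param deaths_per_year Expected dementia-MCOD deaths per year per
#'   stratum.
#' @return A `synthetic_config`.
#' @export
preset <- function(name = c("flat_truth", "au_like", "us_like"), seed = 1L,
                   deaths_per_year = 5000) {
  name <- match.arg(name)
  if (name == "flat_truth") {
    return(synthetic_config(country = "SYN", years = 2006:2015,
                            deaths_per_year = deaths_per_year,
                            mcod_year_multiplier = 1, seed = seed))
  }
  if (name == "au_like") {
    years <- 2006:2016
    com <- list(
      ischemic_heart_disease = list(code = "I21", p1 = c(0.169, 0.119), p2 = c(0.092, 0.107)),
      stroke                 = list(code = "I63", p1 = c(0.156, 0.114), p2 = c(0.066, 0.059)),
      cancers                = list(code = "C80", p1 = c(0.084, 0.079), p2 = c(0.064, 0.065)),
      pneumonia              = list(code = "J18", p1 = c(0.260, 0.169), p2 = c(0.009, 0.003)),
      chronic_respiratory    = list(code = "J44", p1 = c(0.047, 0.037), p2 = c(0.038, 0.044)),
      other_respiratory      = list(code = "J98", p1 = c(0.161, 0.190), p2 = c(0.023, 0.020)),
      ill_defined            = list(code = "R54", p1 = c(0.124, 0.147), p2 = c(0.029, 0.038))
    )
    beta <- au_us_beta(years, year_effect_last = 0.85, intercept = -0.9)
    return(synthetic_config(country = "AU", years = years,
                            deaths_per_year = deaths_per_year,
                            mcod_year_multiplier = 1.005,
                            dementia_part1 = c(0.55, 0.75),
                            comorbidity = com, certification_beta = beta,
                            seed = seed))
  }
  years <- 2006:2017
  com <- list(
    ischemic_heart_disease = list(code = "I21", p1 = c(0.139, 0.096), p2 = c(0.074, 0.074)),
    stroke                 = list(code = "I63", p1 = c(0.075, 0.068), p2 = c(0.047, 0.038)),
    cancers                = list(code = "C80", p1 = c(0.052, 0.042), p2 = c(0.040, 0.032)),
    pneumonia              = list(code = "J18", p1 = c(0.124, 0.061), p2 = c(0.012, 0.009)),
    chronic_respiratory    = list(code = "J44", p1 = c(0.046, 0.035), p2 = c(0.047, 0.044)),
    other_respiratory      = list(code = "J98", p1 = c(0.144, 0.123), p2 = c(0.014, 0.015)),
    ill_defined            = list(code = "R54", p1 = c(0.174, 0.175), p2 = c(0.049, 0.064))
  )
  beta <- au_us_beta(years, year_effect_last = 0.48, intercept = -0.4)
  synthetic_config(country = "US", years = years,
                   deaths_per_year = deaths_per_year,
                   mcod_year_multiplier = 1.013,
                   dementia_part1 = c(0.60, 0.72),
                   comorbidity = com, certification_beta = beta, seed = seed)
}

# cause/age effects shared by the au_like and us_like presets
au_us_beta <- function(years, year_effect_last, intercept) {
  n <- length(years)
  beta <- c(
    "(Intercept)" = intercept,
    part1_ischemic_heart_disease = -1.6, part2_ischemic_heart_disease = -0.5,
    part1_stroke = -1.4,                 part2_stroke = -0.4,
    part1_cancers = -1.8,                part2_cancers = -0.8,
    part1_pneumonia = 0.9,               part2_pneumonia = 0.1,
    part1_chronic_respiratory = -0.8,    part2_chronic_respiratory = -0.3,
    part1_other_respiratory = 0.2,       part2_other_respiratory = 0.0,
    part1_ill_defined = 0.7,             part2_ill_defined = 0.2
  )
  beta <- c(beta, setNames(seq(0.15, 1.35, length.out = 9),
                           paste0("age_", age_levels()[-1])))
  c(beta, setNames(year_effect_last * seq_len(n - 1) / (n - 1),
                   paste0("year_", years[-1])))
}

#' Read / write a synthetic configuration as YAML
#'
#' Round-trips every field, including the named coefficient vector and the
#' per-group comorbidity model.
#'
#' @param config A `synthetic_config` (for writing).
#' @param path YAML file path.
#' @return `read_synthetic_config` returns a `synthetic_config`;
#'   `write_synthetic_config` returns `path` invisibly.
#' @export
write_synthetic_config <- function(config, path) {
  stopifnot(inherits(config, "synthetic_config"))
  ser <- unclass(config)
  for (nm in c("population_shape", "population_growth", "true_mcod_rate",
               "dementia_codes_weights", "certification_beta")) {
    ser[[nm]] <- as.list(ser[[nm]])
  }
  yaml::write_yaml(ser, path)
  invisible(path)
}

#' @rdname write_synthetic_config
#' @export
read_synthetic_config <- function(path) {
  raw <- yaml::read_yaml(path)
  for (nm in c("population_shape", "population_growth", "true_mcod_rate",
               "dementia_codes_weights", "certification_beta")) {
    raw[[nm]] <- unlist(raw[[nm]])
  }
  raw$comorbidity <- lapply(raw$comorbidity, function(cm) {
    list(code = cm$code, p1 = as.numeric(unlist(cm$p1)),
         p2 = as.numeric(unlist(cm$p2)))
  })
  do.call(synthetic_config, c(
    raw[c("country", "sexes", "deaths_per_year", "mcod_year_multiplier",
          "dementia_part1", "comorbidity", "seed")],
    list(years = as.integer(unlist(raw$years)),
         population_shape = raw$population_shape,
         population_growth = raw$population_growth,
         true_mcod_rate = raw$true_mcod_rate,
         dementia_codes_weights = raw$dementia_codes_weights,
         certification_beta = raw$certification_beta)
  ))
}
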