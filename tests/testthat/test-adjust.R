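# shared small synthetic run for the adjustment tests
adjust_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sim <- generate_cohort(preset("flat_truth", seed = 5,
                                    deaths_per_year = 800))
      co <- sim$cohort[sim$cohort$sex == "male", ]
      pop <- sim$population[sim$population$sex == "male",
                            c("year", "age_group", "population")]
      fit <- fit_certification(co)
      cache <<- list(co = co, pop = pop, std = sim$standard, fit = fit)
    }
    cache
  }
})

test_that("counterfactual prediction at the reference year equals the fitted probability", {
  f <- adjust_fixture()
  p_cf <- predict_counterfactual(f$fit, f$co)
  ref <- f$fit$reference_year
  in_ref <- f$co$year == ref
  expect_equal(p_cf[in_ref], unname(f$fit$fitted[in_ref]), tolerance = 1e-12)
  expect_true(all(p_cf > 0 & p_cf < 1))
})

test_that("zero year coefficients make the counterfactual equal the fitted probability everywhere", {
  f <- adjust_fixture()
  fit0 <- f$fit
  fit0$coefficients[fit0$design$year_cols] <- 0
  p_cf <- predict_counterfactual(fit0, f$co)
  beta <- fit0$coefficients
  beta[is.na(beta)] <- 0
  x <- build_design(f$co, year_levels = fit0$design$year_levels)$x
  expect_equal(p_cf, unname(plogis(drop(x %*% beta))), tolerance = 1e-12)
})

test_that("year coefficients rising to the reference year can only raise earlier years' probabilities", {
  f <- adjust_fixture()
  fit <- f$fit
  # force a strictly increasing year profile, all else equal
  fit$coefficients[fit$design$year_cols] <-
    seq(0.1, 1, length.out = length(fit$design$year_cols))
  beta <- fit$coefficients
  beta[is.na(beta)] <- 0
  x <- build_design(f$co, year_levels = fit$design$year_levels)$x
  p_fit <- plogis(drop(x %*% beta))
  p_cf <- predict_counterfactual(fit, f$co)
  expect_true(all(p_cf >= p_fit - 1e-12))
})

test_that("a reference year outside the fitted years is an error", {
  f <- adjust_fixture()
  expect_error(predict_counterfactual(f$fit, f$co, ref_year = 2030), "2030")
})

test_that("fitted probabilities reproduce each year's observed dementia-UCOD count (score equations)", {
  f <- adjust_fixture()
  y <- as.numeric(is_dementia_ucod(f$co))
  by_year_fit <- tapply(f$fit$fitted, f$co$year, sum)
  by_year_obs <- tapply(y, f$co$year, sum)
  expect_equal(as.numeric(by_year_fit), as.numeric(by_year_obs),
               tolerance = 1e-6)
  # and per age band, for the same reason
  by_age_fit <- tapply(f$fit$fitted, as.character(f$co$age_group), sum)
  by_age_obs <- tapply(y, as.character(f$co$age_group), sum)
  expect_equal(as.numeric(by_age_fit), as.numeric(by_age_obs),
               tolerance = 1e-6)
})

test_that("probability bounds translate into ASDR bounds", {
  f <- adjust_fixture()
  ones <- rep(1, nrow(f$co))
  mcod <- asdr_series(f$co, f$pop, f$std)
  expect_equal(adjusted_ucod_asdr(ones, f$co, f$pop, f$std)$rate, mcod$rate)
  expect_equal(adjusted_ucod_asdr(rep(0, nrow(f$co)), f$co, f$pop, f$std)$rate,
               rep(0, nrow(mcod)))
  p_cf <- predict_counterfactual(f$fit, f$co)
  adj <- adjusted_ucod_asdr(p_cf, f$co, f$pop, f$std)
  expect_true(all(adj$rate <= mcod$rate))
  expect_true(all(adj$rate >= 0))
})

test_that("constant-MCOD rescaling follows its defining arithmetic", {
  adj <- tibble::tibble(year = 2006:2008, rate = c(50, 52, 54))
  mcod_const <- tibble::tibble(year = 2006:2008, rate = rep(200, 3))
  expect_equal(constant_mcod_adjust(adj, mcod_const, 2008)$rate, adj$rate)
  mcod <- tibble::tibble(year = 2006:2008, rate = c(200, 210, 220))
  out <- constant_mcod_adjust(adj, mcod, 2008)
  expect_equal(out$rate[1], 50 / 200 * 220)
  expect_equal(out$rate[out$year == 2008], adj$rate[adj$year == 2008])
  mcod0 <- tibble::tibble(year = 2006:2008, rate = c(0, 210, 220))
  expect_error(constant_mcod_adjust(adj, mcod0, 2008), "2006")
  expect_error(constant_mcod_adjust(adj, mcod, 2010), "2010")
})

test_that("a null year effect in truth leaves the adjusted series near the observed one", {
  cfg <- preset("flat_truth", seed = 21, deaths_per_year = 1200)
  cfg$certification_beta[grep("^year_", names(cfg$certification_beta))] <- 0
  sim <- generate_cohort(cfg)
  res <- suppressMessages(run_adjustment(sim$cohort, sim$population,
                                         sim$standard))
  for (a in res) {
    obs <- a$series$rate[a$series$measure == "ucod_asdr"]
    adj <- a$series$rate[a$series$measure == "adjusted_ucod_asdr"]
    expect_lt(max(abs(adj - obs) / obs), 0.1)
  }
})

test_that("run_adjustment produces the four series and per-stratum fits", {
  sim <- generate_cohort(preset("flat_truth", seed = 9, deaths_per_year = 500))
  res <- suppressMessages(run_adjustment(sim$cohort, sim$population,
                                         sim$standard))
  expect_named(res, c("SYN.male", "SYN.female"))
  for (a in res) {
    expect_setequal(unique(a$series$measure),
                    c("mcod_asdr", "ucod_asdr", "adjusted_ucod_asdr",
                      "adjusted_constant_mcod_asdr"))
    expect_true(a$fit$converged)
    expect_equal(a$ref_year, 2015)
    wide <- tidyr::pivot_wider(a$series, names_from = "measure",
                               values_from = "rate")
    expect_true(all(wide$adjusted_ucod_asdr <= wide$mcod_asdr))
    cmc <- a$series$rate[a$series$measure == "adjusted_constant_mcod_asdr"]
    adjr <- a$series$rate[a$series$measure == "adjusted_ucod_asdr"]
    expect_equal(cmc[length(cmc)], adjr[length(adjr)])
  }
})
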