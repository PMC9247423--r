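test_that("age-specific rates are deaths over population per 100,000", {
  deaths <- tibble::tibble(year = 2006L, age_group = c("85-89", "90-94"),
                           deaths = c(20, 5))
  pop <- tibble::tibble(year = 2006L, age_group = c("85-89", "90-94"),
                        population = c(10000, 2000))
  out <- age_specific_rates(deaths, pop, by = c("year", "age_group"))
  expect_equal(out$rate[match("85-89", out$age_group)], 200)
  expect_equal(out$rate[match("90-94", out$age_group)], 250)
  # a populated cell with no deaths is a zero rate
  pop2 <- rbind(pop, tibble::tibble(year = 2006L, age_group = "95+",
                                    population = 500))
  out2 <- age_specific_rates(deaths, pop2, by = c("year", "age_group"))
  expect_equal(out2$rate[match("95+", out2$age_group)], 0)
})

test_that("zero or negative population is an error naming the cell", {
  deaths <- tibble::tibble(year = 2006L, age_group = "85-89", deaths = 1)
  pop <- tibble::tibble(year = 2006L, age_group = "85-89", population = 0)
  expect_error(age_specific_rates(deaths, pop, by = c("year", "age_group")),
               "85-89")
})

test_that("direct standardization is the dot product with the standard weights", {
  std <- flat_std()
  # uniform rates are invariant
  expect_equal(asdr(setNames(rep(137.5, 10), age_levels()), std), 137.5)
  # forced two-band arithmetic: weights .6/.4 on rates 100/200
  w <- setNames(c(0.6, 0.4, rep(0, 8)), age_levels())
  r <- setNames(c(100, 200, rep(0, 8)), age_levels())
  expect_equal(asdr(r, as_standard_population(w)), 140)
  # randomized instances against an independent dot-product oracle
  set.seed(42)
  for (i in 1:25) {
    wts <- runif(10); wts <- wts / sum(wts); names(wts) <- age_levels()
    rates <- setNames(runif(10, 0, 5000), sample(age_levels()))
    oracle <- sum(vapply(age_levels(), function(a) wts[[a]] * rates[[a]], 0))
    expect_equal(asdr(rates, wts), oracle)
    # linearity and bounds
    expect_equal(asdr(rates * 3.7, wts), 3.7 * asdr(rates, wts))
    expect_gte(asdr(rates, wts), min(rates))
    expect_lte(asdr(rates, wts), max(rates))
  }
})

test_that("standardization rejects bad weights and missing bands", {
  w <- setNames(rep(0.1, 10), age_levels())
  w[1] <- 0.2  # sums to 1.1
  r <- setNames(rep(100, 10), age_levels())
  expect_error(asdr(r, w), "sum to 1")
  expect_error(asdr(r[-1], flat_std()), "50-54")
  expect_equal(asdr(r[-1], flat_std(), missing_as_zero = TRUE), 90)
})

test_that("percent-of-MCOD tabulations match hand counts", {
  suppressMessages(co <- filter_dementia_mcod(tiny_cohort()))
  # 2006: records r01 r02 r03; IHD (I21) in part 1 only on r02
  ihd1 <- pct_of_mcod(co, "ischemic_heart_disease", part = 1)
  expect_equal(ihd1$pct[ihd1$year == 2006], 100 / 3)
  # 2007: r04 r05 r06; I21 on r06 part 1, I25 on r04 part 2
  expect_equal(ihd1$pct[ihd1$year == 2007], 100 / 3)
  ihd2 <- pct_of_mcod(co, "ischemic_heart_disease", part = 2)
  expect_equal(ihd2$pct[ihd2$year == 2007], 100 / 3)
  # every-record case
  pneu <- pct_of_mcod(co, "pneumonia", part = 1)
  expect_equal(pneu$pct[pneu$year == 2007], 100 / 3)
  all_dem <- pct_of_mcod(co, "dementia", part = "any")
  expect_equal(all_dem$pct, c(100, 100))
})

test_that("dementia-UCOD and non-dementia-UCOD percentages sum to 100 each year", {
  sim <- generate_cohort(preset("flat_truth", seed = 11, deaths_per_year = 300))
  co <- sim$cohort
  dem <- pct_of_mcod(co, "dementia", part = "ucod")
  other <- tibble::tibble(country = co$country, sex = co$sex, year = co$year,
                          hit = !is_dementia_ucod(co)) |>
    dplyr::group_by(country, sex, year) |>
    dplyr::summarise(pct = 100 * mean(hit), .groups = "drop")
  joined <- dplyr::inner_join(dem, other, by = c("country", "sex", "year"))
  expect_equal(joined$pct.x + joined$pct.y, rep(100, nrow(joined)))
})

test_that("trend estimates recover closed-form annual rates of change", {
  yrs <- 2006:2016
  # constant series: 0 under both methods
  expect_equal(annual_rate_of_change(yrs, rep(250, 11))$annual_pct_change, 0)
  expect_equal(annual_rate_of_change(yrs, rep(250, 11),
                                     method = "endpoint")$annual_pct_change, 0)
  # exact exponential: both methods agree at 2.0%/yr
  geom <- 100 * 1.02^(yrs - 2006)
  expect_equal(annual_rate_of_change(yrs, geom)$annual_pct_change, 2)
  expect_equal(annual_rate_of_change(yrs, geom,
                                     method = "endpoint")$annual_pct_change, 2)
  # two-point endpoint: 100 -> 150 over 10 years
  expect_equal(
    annual_rate_of_change(c(2006, 2016), c(100, 150),
                          method = "endpoint")$annual_pct_change,
    100 * (1.5^0.1 - 1))
  # zero rate: log-linear errors and points at the endpoint method
  expect_error(annual_rate_of_change(yrs, c(0, geom[-1])), "endpoint")
})

test_that("compounding identities hold for cumulative change", {
  expect_equal(cumulative_change(0, 25), 0)
  expect_equal(cumulative_change(2, 10), 100 * (1.02^10 - 1))
  expect_equal(cumulative_change(-1, 5), 100 * (0.99^5 - 1))
})

test_that("leading-cause ranking matches a sort-based oracle", {
  expect_identical(rank_leading_causes(c(A = 50, B = 40, dementia = 45),
                                       "dementia"), 2L)
  expect_identical(rank_leading_causes(c(A = 50, dementia = 60), "dementia"), 1L)
  # ties share the smaller rank
  expect_identical(rank_leading_causes(c(A = 50, B = 50, dementia = 50),
                                       "dementia"), 1L)
  expect_error(rank_leading_causes(setNames(numeric(0), character(0)), "x"),
               "empty")
  set.seed(99)
  for (i in 1:25) {
    v <- setNames(runif(10, 0, 100), paste0("c", 1:10))
    focus <- sample(names(v), 1)
    oracle <- match(focus, names(sort(v, decreasing = TRUE)))
    # with distinct values the sort-based rank is the answer
    expect_identical(rank_leading_causes(v, focus), as.integer(oracle))
  }
})
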