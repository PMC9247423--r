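# in-code fixtures shared across test files

# a small hand-written cohort: 6 dementia-MCOD records in one stratum
tiny_cohort <- function() {
  as_mcod_cohort(tibble::tibble(
    record_id = sprintf("r%02d", 1:6),
    year = c(2006L, 2006L, 2006L, 2007L, 2007L, 2007L),
    sex = "male",
    age_group = c("85-89", "90-94", "80-84", "85-89", "95+", "75-79"),
    part1 = c("F03", "I21;J18", "G30;I63", "F01", "J18;F03", "I21"),
    part2 = c("", "G30", "", "I25", "", "F00;N39"),
    ucod = c("F03", "I21", "G30", "F01", "F03", "I21")
  ), country_label = "TST")
}

# uniform 10-band standard weights
flat_std <- function() {
  as_standard_population(setNames(rep(0.1, 10), age_levels()))
}

# population table covering the tiny cohort's stratum
tiny_population <- function(years = 2006:2007, pop = 1e4) {
  expand.grid(year = years, age_group = age_levels(),
              stringsAsFactors = FALSE) |>
    tibble::as_tibble() |>
    dplyr::mutate(population = pop)
}

# small random logistic design with known-ish structure
random_design <- function(n, p, seed) {
  set.seed(seed)
  x <- cbind(`(Intercept)` = 1,
             matrix(rnorm(n * p), n, p,
                    dimnames = list(NULL, paste0("x", seq_len(p)))))
  beta <- c(0.3, rnorm(p, sd = 0.8))
  y <- rbinom(n, 1, plogis(drop(x %*% beta)))
  list(x = x, y = y, beta = beta)
}
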