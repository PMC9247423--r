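#' MCOD death-record cohorts
#'
#' A cohort is a tibble of individual multiple-cause-of-death (MCOD)
#' records, one row per registered death, with columns:
#'
#' * `record_id` — opaque identifier (character)
#' * `country` — stratum label (character)
#' * `year` — calendar year (integer)
#' * `sex` — `"male"` or `"female"`
#' * `age_group` — ordered factor over the 10 bands of [age_levels()]
#' * `part1` — ICD-10 codes of conditions directly leading to death,
#'   semicolon-separated (may be empty)
#' * `part2` — other significant conditions contributing to death,
#'   semicolon-separated (may be empty)
#' * `ucod` — the underlying cause of death selected by coding rules
#'
#' A code reported in both parts of the same certificate is kept in part 1
#' only; at least one code must appear somewhere on the certificate. The
#' selected underlying cause need not appear verbatim among the reported
#' codes (coding rules may substitute codes).
#'
#' @name mcod_cohort
NULL

#' Construct an MCOD cohort from a data frame
#'
#' Validates columns, bands ages, dedupes codes appearing in both parts
#' (part 1 wins), and attaches the `mcod_cohort` class.
#'
#' @param df Data frame with the columns described in [mcod_cohort];
#'   `country` is optional and defaults to `country_label`.
#' @param country_label Free-text label used when `df` has no `country`
#'   column.
#' @return An `mcod_cohort` tibble.
#' @export
as_mcod_cohort <- function(df, country_label = "unspecified") {
  required <- c("record_id", "year", "sex", "age_group", "part1", "part2", "ucod")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("missing required column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  df <- tibble::as_tibble(df)
  if (!"country" %in% names(df)) df$country <- country_label

  bad_sex <- which(!df$sex %in% c("male", "female"))
  if (length(bad_sex) > 0) {
    stop("unknown sex label '", df$sex[bad_sex[1]], "' at row ", bad_sex[1],
         call. = FALSE)
  }
  age <- age_factor(df$age_group)
  bad_age <- which(is.na(age))
  if (length(bad_age) > 0) {
    stop("unknown age_group label '", as.character(df$age_group)[bad_age[1]],
         "' at row ", bad_age[1], " (expected one of ",
         paste(age_levels(), collapse = ", "), ")", call. = FALSE)
  }
  df$age_group <- age
  df$year <- as.integer(df$year)
  df$part1 <- vapply(df$part1, as.character, "", USE.NAMES = FALSE)
  df$part2 <- vapply(df$part2, as.character, "", USE.NAMES = FALSE)
  df$part2 <- dedupe_part2(df$part1, df$part2)

  empty <- which(!nzchar(df$part1) & !nzchar(df$part2))
  if (length(empty) > 0) {
    stop("no cause codes reported at row ", empty[1], call. = FALSE)
  }
  df <- df[, c("record_id", "country", "year", "sex", "age_group",
               "part1", "part2", "ucod")]
  class(df) <- c("mcod_cohort", class(tibble::tibble()))
  df
}

# split a ";"-separated code field into a list of code vectors
split_codes <- function(x) {
  strsplit(ifelse(is.na(x) | !nzchar(x), "", x), ";", fixed = TRUE)
}

join_codes <- function(lst) {
  vapply(lst, paste, "", collapse = ";")
}

# a code listed in both parts is kept in part 1 only
dedupe_part2 <- function(part1, part2) {
  p1 <- split_codes(part1)
  p2 <- split_codes(part2)
  join_codes(Map(setdiff, p2, p1))
}

#' @export
print.mcod_cohort <- function(x, ...) {
  cat("<mcod_cohort> ", nrow(x), " death records, ",
      if (nrow(x)) paste0("years ", min(x$year), "-", max(x$year)) else "empty",
      "\n", sep = "")
  NextMethod()
}

#' Read / write MCOD cohorts in the canonical CSV dialect
#'
#' The canonical file is UTF-8 CSV with header
#' `record_id,year,sex,age_group,part1,part2,ucod` (plus an optional
#' `country` column); `part1`/`part2` hold semicolon-separated ICD-10 codes,
#' and `age_group` labels look like `"85-89"` or `"95+"`. Writing then
#' reading reproduces every field.
#'
#' @param path CSV file path.
#' @param country_label Label used when the file has no `country` column.
#' @param cohort An `mcod_cohort` (for writing).
#' @return `load_records` returns an `mcod_cohort`; `write_records` returns
#'   `path` invisibly.
#' @export
load_records <- function(path, country_label = "unspecified") {
  df <- readr::read_csv(
    path,
    col_types = readr::cols(
      record_id = readr::col_character(),
      year = readr::col_integer(),
      sex = readr::col_character(),
      age_group = readr::col_character(),
      part1 = readr::col_character(),
      part2 = readr::col_character(),
      ucod = readr::col_character(),
      .default = readr::col_character()
    ),
    na = character(), progress = FALSE
  )
  cohort <- as_mcod_cohort(df, country_label = country_label)
  message("loaded ", nrow(cohort), " death records from ", path)
  cohort
}

#' @rdname load_records
#' @export
write_records <- function(cohort, path) {
  stopifnot(inherits(cohort, "mcod_cohort"))
  out <- as.data.frame(cohort)
  out$age_group <- as.character(out$age_group)
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Dementia MCOD and dementia UCOD indicators
#'
#' `is_dementia_mcod()` is TRUE where a dementia code (F00, F01, F03, G30,
#' G31) is reported anywhere on the certificate — part 1 or part 2 — and the
#' decedent is aged 50 or more (guaranteed by the age banding).
#' `is_dementia_ucod()` is TRUE where the selected underlying cause itself
#' classifies as dementia.
#'
#' @param cohort An `mcod_cohort`.
#' @param taxonomy A `cause_taxonomy`.
#' @return Logical vector, one element per record.
#' @export
is_dementia_mcod <- function(cohort, taxonomy = default_taxonomy()) {
  has_group_in_part(cohort, "dementia", part = "any", taxonomy = taxonomy)
}

#' @rdname is_dementia_mcod
#' @export
is_dementia_ucod <- function(cohort, taxonomy = default_taxonomy()) {
  !is.na(classify_code(cohort$ucod, taxonomy)) &
    classify_code(cohort$ucod, taxonomy) == "dementia"
}

# vectorized: does each record carry a code of `group` in the given part?
# part is 1, 2, "any" or "ucod"; malformed codes propagate classify_code's
# error with the offending string
has_group_in_part <- function(cohort, group, part, taxonomy = default_taxonomy()) {
  if (identical(part, "ucod")) {
    cls <- classify_code(cohort$ucod, taxonomy)
    return(!is.na(cls) & cls == group)
  }
  codes <- switch(as.character(part),
    "1" = split_codes(cohort$part1),
    "2" = split_codes(cohort$part2),
    "any" = Map(c, split_codes(cohort$part1), split_codes(cohort$part2)),
    stop("part must be 1, 2, 'any' or 'ucod'", call. = FALSE)
  )
  n <- lengths(codes)
  if (sum(n) == 0) return(rep(FALSE, nrow(cohort)))
  flat <- unlist(codes, use.names = FALSE)
  cls <- classify_code(flat, taxonomy)
  hit <- !is.na(cls) & cls == group
  as.logical(rowsum(as.integer(hit), rep(seq_along(n), n), reorder = TRUE) > 0) |>
    (\(x) { out <- rep(FALSE, length(n)); out[n > 0] <- x; out })()
}

#' Restrict a cohort to dementia MCOD deaths
#'
#' Keeps records aged 50+ with dementia reported anywhere on the
#' certificate; reports the number dropped. Idempotent. Records with
#' dementia as the only reported cause are retained.
#'
#' @inheritParams is_dementia_mcod
#' @return The filtered `mcod_cohort`.
#' @export
filter_dementia_mcod <- function(cohort, taxonomy = default_taxonomy()) {
  keep <- is_dementia_mcod(cohort, taxonomy)
  dropped <- sum(!keep)
  out <- cohort[keep, ]
  message("filter_dementia_mcod: retained ", nrow(out), " of ", nrow(cohort),
          " records (", dropped, " dropped)")
  if (nrow(out) == 0) {
    warning("no dementia MCOD records remain after filtering", call. = FALSE)
  }
  out
}
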