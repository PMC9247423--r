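#' Design matrix for the dementia-as-UCOD certification model
#'
#' Encodes each dementia-MCOD record as: an intercept; one 0/1 indicator
#' per non-dementia cause group for its presence in part 1 and one for part
#' 2; age-band indicators (reference band 50-54); and year indicators
#' (reference level = first year). Cause indicators may co-occur; the age
#' and year blocks are one-hot. Dementia's own part-1/part-2 placement is
#' excluded by default — under coding rules it is nearly deterministic for
#' the outcome and induces separation — but can be added with
#' `include_dementia_placement = TRUE` for sensitivity analysis. Codes that
#' classify to no taxonomy group contribute to no indicator.
#'
#' @param cohort An `mcod_cohort` of dementia-MCOD records.
#' @param taxonomy A `cause_taxonomy`.
#' @param year_levels Integer vector of modelled years; defaults to the
#'   years present, sorted. Records outside these levels are an error.
#' @param age_groups Age-band levels; defaults to [age_levels()].
#' @param include_dementia_placement Add a `part1_dementia` indicator.
#' @return List with `x` (numeric matrix, one row per record), `terms`
#'   (column names), `year_levels`, `age_groups`, and the index of the year
#'   block `year_cols` (named by year, reference year absent).
#' @export
build_design <- function(cohort, taxonomy = default_taxonomy(),
                         year_levels = sort(unique(cohort$year)),
                         age_groups = age_levels(),
                         include_dementia_placement = FALSE) {
  year_levels <- sort(as.integer(year_levels))
  if (!all(cohort$year %in% year_levels)) {
    bad <- setdiff(unique(cohort$year), year_levels)
    stop("record year(s) outside configured levels: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (!all(as.character(cohort$age_group) %in% age_groups)) {
    stop("record age group outside configured levels", call. = FALSE)
  }
  groups <- setdiff(names(taxonomy), "dementia")
  n <- nrow(cohort)

  part_block <- function(codes_str, label, with_dementia) {
    codes <- split_codes(codes_str)
    len <- lengths(codes)
    gset <- if (with_dementia) c(groups, "dementia") else groups
    m <- matrix(0, n, length(gset), dimnames = list(NULL, paste0(label, "_", gset)))
    if (sum(len) > 0) {
      flat <- unlist(codes, use.names = FALSE)
      cls <- classify_code(flat, taxonomy)
      row <- rep(seq_len(n), len)
      keep <- !is.na(cls) & cls %in% gset
      m[cbind(row[keep], match(cls[keep], gset))] <- 1
    }
    m
  }
  x1 <- part_block(cohort$part1, "part1", include_dementia_placement)
  x2 <- part_block(cohort$part2, "part2", FALSE)

  ages <- as.character(cohort$age_group)
  age_ref <- age_groups[1]
  age_cols <- age_groups[-1]
  xa <- matrix(0, n, length(age_cols),
               dimnames = list(NULL, paste0("age_", age_cols)))
  ia <- match(ages, age_cols)
  has_a <- !is.na(ia)
  xa[cbind(which(has_a), ia[has_a])] <- 1

  year_ref <- year_levels[1]
  yr_cols <- year_levels[-1]
  xy <- matrix(0, n, length(yr_cols),
               dimnames = list(NULL, paste0("year_", yr_cols)))
  iy <- match(cohort$year, yr_cols)
  has_y <- !is.na(iy)
  xy[cbind(which(has_y), iy[has_y])] <- 1

  x <- cbind(`(Intercept)` = rep(1, n), x1, x2, xa, xy)
  list(x = x, terms = colnames(x), year_levels = year_levels,
       age_groups = age_groups, year_ref = year_ref,
       year_cols = setNames(match(paste0("year_", yr_cols), colnames(x)), yr_cols),
       include_dementia_placement = include_dementia_placement)
}
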