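#' Cause taxonomies: ICD-10 code intervals mapped to named cause groups
#'
#' A cause taxonomy is an ordered named list mapping a cause-group name to a
#' character vector of 3-character ICD-10 codes and/or closed intervals
#' written `"A00-A09"`. Classification happens at 3-character resolution:
#' 4-character codes inherit the group of their 3-character root. The
#' `dementia` group is fixed by definition to F00, F01, F03, G30 and G31
#' (Alzheimer disease, vascular dementia, unspecified and other dementias);
#' `cvd` is the whole of chapter I (I00-I99) and is kept as a derived
#' super-group rather than a classification target. All other groups must be
#' pairwise disjoint so that every code classifies to at most one group.
#'
#' @name taxonomy
NULL

#' Default cause taxonomy
#'
#' Cause groupings for conditions commonly reported alongside dementia on
#' death certificates: ischemic heart disease I20-I25, stroke I60-I69, other
#' cardiovascular disease (remainder of I00-I99), all cancers C00-C97,
#' pneumonia J12-J18, chronic respiratory disease J40-J47, other respiratory
#' disease (remainder of J00-J99), ill-defined causes R00-R99, renal failure
#' N17-N19, Parkinson disease G20-G21, urinary tract infection N39, diabetes
#' E10-E14, falls W00-W19 and other external-cause injuries. The taxonomy is
#' data, not code: load a YAML file with [load_taxonomy()] to match a
#' different grouping exactly.
#'
#' @return A `cause_taxonomy` object (named list of interval vectors).
#' @export
#' @examples
#' tx <- default_taxonomy()
#' names(tx)
#' classify_code("I21", tx)
default_taxonomy <- function() {
  new_taxonomy(list(
    dementia                = c("F00", "F01", "F03", "G30", "G31"),
    ischemic_heart_disease  = "I20-I25",
    stroke                  = "I60-I69",
    other_cvd               = c("I00-I19", "I26-I59", "I70-I99"),
    cancers                 = "C00-C97",
    pneumonia               = "J12-J18",
    chronic_respiratory     = "J40-J47",
    other_respiratory       = c("J00-J11", "J19-J39", "J48-J99"),
    ill_defined             = "R00-R99",
    renal                   = "N17-N19",
    parkinson               = "G20-G21",
    urinary_tract_infection = "N39",
    diabetes                = "E10-E14",
    falls                   = "W00-W19",
    injuries                = c("V01-V99", "W20-Y89")
  ))
}

dementia_codes <- function() c("F00", "F01", "F03", "G30", "G31")

#' Construct and validate a cause taxonomy
#'
#' @param groups Named list; each element a character vector of 3-character
#'   ICD-10 codes or `"XNN-XMM"` intervals (within one chapter letter).
#' @return A validated `cause_taxonomy`.
#' @export
new_taxonomy <- function(groups) {
  stopifnot(is.list(groups), !is.null(names(groups)), all(nzchar(names(groups))))
  if (!"dementia" %in% names(groups)) {
    stop("taxonomy must contain a 'dementia' group", call. = FALSE)
  }
  if (!setequal(expand_intervals(groups$dementia), dementia_codes())) {
    stop("the 'dementia' group must be exactly F00, F01, F03, G30, G31",
         call. = FALSE)
  }
  roots <- lapply(groups, expand_intervals)
  other <- unlist(roots[setdiff(names(roots), "dementia")], use.names = FALSE)
  dup <- unique(other[duplicated(other)])
  if (length(dup) > 0) {
    stop("taxonomy groups (other than dementia) overlap at: ",
         paste(head(dup, 5), collapse = ", "), call. = FALSE)
  }
  lookup <- character(0)
  for (g in names(roots)) {
    # dementia wins where it overlaps another group's interval
    keep <- if (g == "dementia") roots[[g]] else setdiff(roots[[g]], roots$dementia)
    lookup[keep] <- g
  }
  structure(groups, lookup = lookup, class = "cause_taxonomy")
}

# expand "I20-I25" (or cross-letter "W20-Y89") intervals into 3-char roots,
# closed and lexicographic over A00..Z99
expand_intervals <- function(spec) {
  all_roots <- function() {
    as.vector(t(outer(LETTERS, sprintf("%02d", 0:99), paste0)))
  }
  out <- lapply(spec, function(s) {
    s <- toupper(trimws(s))
    if (grepl("^[A-Z][0-9]{2}$", s)) return(s)
    m <- regmatches(s, regexec("^([A-Z][0-9]{2})-([A-Z][0-9]{2})$", s))[[1]]
    if (length(m) == 0) {
      stop("malformed taxonomy interval: '", s, "'", call. = FALSE)
    }
    if (m[2] > m[3]) stop("taxonomy interval '", s, "' is reversed", call. = FALSE)
    roots <- all_roots()
    roots[roots >= m[2] & roots <= m[3]]
  })
  unique(unlist(out))
}

#' @export
print.cause_taxonomy <- function(x, ...) {
  cat("<cause_taxonomy> ", length(x), " groups\n", sep = "")
  for (g in names(x)) {
    cat("  ", format(g, width = 24), paste(x[[g]], collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Classify ICD-10 codes into cause groups
#'
#' Maps each code to the unique taxonomy group whose intervals contain its
#' 3-character root, or `NA` if the root falls outside every configured
#' interval. Codes must match the ICD-10 lexical pattern: a letter, two
#' digits, then optionally a dot and/or further subcode digits (e.g. `"I21"`,
#' `"N39.0"`, `"I219"`).
#'
#' @param code Character vector of ICD-10 codes.
#' @param taxonomy A `cause_taxonomy`; defaults to [default_taxonomy()].
#' @return Character vector of group names, `NA` where unclassified.
#' @export
#' @examples
#' classify_code(c("G30", "I21", "Z99"))
classify_code <- function(code, taxonomy = default_taxonomy()) {
  stopifnot(inherits(taxonomy, "cause_taxonomy"))
  code <- toupper(trimws(code))
  bad <- !grepl("^[A-Z][0-9]{2}(\\.?[0-9]{1,2})?$", code) | is.na(code)
  if (any(bad)) {
    stop("malformed ICD-10 code(s): ",
         paste(unique(code[bad]), collapse = ", "), call. = FALSE)
  }
  lookup <- attr(taxonomy, "lookup")
  out <- unname(lookup[substr(code, 1, 3)])
  out
}

#' Is a code a cardiovascular disease (I00-I99)?
#'
#' The CVD super-group spans the taxonomy's ischemic heart disease, stroke
#' and other-CVD groups; it is used for the percent-of-MCOD UCOD
#' tabulations, not for classification.
#'
#' @param code Character vector of ICD-10 codes.
#' @return Logical vector.
#' @export
is_cvd_code <- function(code) {
  grepl("^I[0-9]{2}", toupper(trimws(code)))
}

#' Read / write a taxonomy as YAML
#'
#' The file is a YAML mapping from group name to a list of codes or
#' intervals, e.g. `ischemic_heart_disease: [I20-I25]`.
#'
#' @param path File path.
#' @param taxonomy A `cause_taxonomy` (for writing).
#' @return `load_taxonomy` returns a validated `cause_taxonomy`;
#'   `write_taxonomy` returns `path` invisibly.
#' @export
load_taxonomy <- function(path) {
  raw <- yaml::read_yaml(path)
  new_taxonomy(lapply(raw, as.character))
}

#' @rdname load_taxonomy
#' @export
write_taxonomy <- function(taxonomy, path) {
  stopifnot(inherits(taxonomy, "cause_taxonomy"))
  yaml::write_yaml(lapply(unclass(taxonomy), as.character), path)
  invisible(path)
}
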