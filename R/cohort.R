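# Target-drug cohort extraction.
#
# The cohort is selected by drug-name synonym (against DRUGNAME and PROD_AI),
# suspect-role code, and optionally by indication terms attached to the
# matched drug sequence. The 120 mg oncology dose of a drug marketed under
# several brands is selected by brand synonym plus oncology indication, not
# by parsing dose fields.

#' Build a cohort specification
#'
#' @param drug_synonyms character vector of drug-name patterns (matched
#'   case-insensitively against DRUGNAME and PROD_AI after whitespace
#'   normalization). Must be non-empty.
#' @param role_codes allowed FAERS role codes; default `"PS"` (primary
#'   suspect).
#' @param indication_terms indication PT patterns; empty vector disables the
#'   indication filter.
#' @param match_mode `"exact"` or `"substring"`.
#' @param strict_indication when the indication filter is active and a
#'   matched drug has no indication rows: `FALSE` (default) keeps the report,
#'   `TRUE` drops it. Spontaneous-report databases lack indication rows for a
#'   large share of reports, so the permissive default avoids discarding them
#'   silently; both behaviors are logged in the audit counts.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(drug_synonyms,
                        role_codes = "PS",
                        indication_terms = character(),
                        match_mode = c("substring", "exact"),
                        strict_indication = FALSE) {
  match_mode <- match.arg(match_mode)
  drug_synonyms <- norm_text(drug_synonyms)
  drug_synonyms <- drug_synonyms[nzchar(drug_synonyms)]
  if (length(drug_synonyms) == 0L) stop("drug_synonyms must be non-empty")
  role_codes <- toupper(trimws(role_codes))
  bad <- setdiff(role_codes, c("PS", "SS", "C", "I"))
  if (length(bad)) stop("unknown role code(s): ", paste(bad, collapse = ", "))
  structure(
    list(
      drug_synonyms = drug_synonyms,
      role_codes = role_codes,
      indication_terms = norm_text(indication_terms),
      match_mode = match_mode,
      strict_indication = isTRUE(strict_indication)
    ),
    class = "cohort_spec"
  )
}

#' Default denosumab 120 mg (Xgeva) cohort specification
#'
#' Synonyms cover the generic and brand spellings used in FAERS; indication
#' terms cover the licensed oncology uses (bone metastases from solid
#' tumors, giant cell tumor of bone, multiple myeloma and skeletal-related
#' events). The term list is a configurable default, not an authoritative
#' reconstruction of any particular query.
#'
#' @param strict_indication see [cohort_spec()].
#' @return a `cohort_spec`.
#' @export
default_cohort_spec <- function(strict_indication = FALSE) {
  cohort_spec(
    drug_synonyms = c("denosumab (xgeva)", "xgeva", "denosumab"),
    role_codes = "PS",
    indication_terms = c(
      "bone metasta", "metastases to bone", "giant cell tumor",
      "giant cell tumour", "multiple myeloma", "bone cancer", "neoplasm",
      "cancer", "malignant", "skeletal related event"
    ),
    match_mode = "substring",
    strict_indication = strict_indication
  )
}

.match_one <- function(values, patterns, mode) {
  values <- norm_text(values)
  hit <- rep(FALSE, length(values))
  for (p in patterns) {
    hit <- hit | if (mode == "exact") values == p else {
      grepl(p, values, fixed = TRUE)
    }
  }
  hit
}

#' Drug rows matching the cohort drug synonyms
#'
#' A drug record matches when its DRUGNAME or PROD_AI matches any synonym
#' under the spec's match mode (case-insensitive, whitespace-normalized).
#'
#' @param cases a `faers_cases` object.
#' @param spec a `cohort_spec`.
#' @return a `data.table` of matching drug rows (columns `primaryid`,
#'   `drug_seq`, `role_cod`, ...).
#' @export
match_drug <- function(cases, spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  drug <- cases$drug
  if (nrow(drug) == 0L) return(drug[0])
  hit <- .match_one(drug$drugname, spec$drug_synonyms, spec$match_mode)
  if ("prod_ai" %in% names(drug)) {
    hit <- hit | .match_one(drug$prod_ai, spec$drug_synonyms, spec$match_mode)
  }
  drug[hit]
}

#' Cohort membership per report
#'
#' A report is in the cohort when at least one matched drug row has an
#' allowed role code and (when the indication filter is active) an
#' indication row linked to that drug sequence matches an indication term.
#' Reports whose matched drug has no indication rows are kept or dropped
#' per `spec$strict_indication`.
#'
#' @param cases a `faers_cases` object.
#' @param spec a `cohort_spec`.
#' @return a named logical vector over `cases$demo$primaryid`.
#' @export
in_cohort <- function(cases, spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  ids <- cases$demo$primaryid
  out <- stats::setNames(rep(FALSE, length(ids)), ids)
  hits <- match_drug(cases, spec)
  if (nrow(hits) == 0L) return(out)
  hits <- hits[toupper(trimws(role_cod)) %in% spec$role_codes]
  if (nrow(hits) == 0L) return(out)

  if (length(spec$indication_terms) == 0L) {
    out[unique(hits$primaryid)] <- TRUE
    return(out)
  }

  indi <- cases$indi
  hits[, drug_seq := trimws(as.character(drug_seq))]
  if (nrow(indi)) {
    indi <- data.table::copy(indi)
    indi[, indi_drug_seq := trimws(as.character(indi_drug_seq))]
    indi[, .hit := .match_one(indi_pt, spec$indication_terms, "substring")]
    m <- merge(
      hits[, .(primaryid, drug_seq)],
      indi[, .(primaryid, drug_seq = indi_drug_seq, .hit)],
      by = c("primaryid", "drug_seq"), all.x = TRUE
    )
  } else {
    m <- hits[, .(primaryid, drug_seq)]
    m[, .hit := NA]
  }
  # per matched drug: TRUE if some linked indication matches; NA if no rows
  agg <- m[, .(
    any_match = any(.hit %in% TRUE),
    has_rows = any(!is.na(.hit))
  ), by = primaryid]
  ok <- agg$any_match | (!agg$has_rows & !spec$strict_indication)
  out[agg$primaryid[ok]] <- TRUE
  out
}

#' Partition reports into cohort and comparator background
#'
#' @param cases a deduplicated `faers_cases` set.
#' @param spec a `cohort_spec`.
#' @return a list with elements `cohort` and `background` (both
#'   `faers_cases`); every report lands in exactly one of the two.
#' @export
split_background <- function(cases, spec) {
  flag <- in_cohort(cases, spec)
  ids <- names(flag)
  list(
    cohort = subset_cases(cases, ids[flag]),
    background = subset_cases(cases, ids[!flag])
  )
}
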