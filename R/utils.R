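#' @import data.table
#' @keywords internal
"_PACKAGE"

# Silence R CMD check notes for data.table NSE column names.
utils::globalVariables(c(
  "primaryid", "caseid", "fda_dt", "pt", "pt_norm", "soc",
  "drug_seq", "role_cod", "drugname", "prod_ai", "outc_cod", "dsg_drug_seq",
  "start_dt", "indi_drug_seq", "indi_pt", "a", "b", "d", "ror",
  "ror_ci_low", "ror_ci_high", "ror_defined", "ic", "ic025", "ic975",
  "positive_ror", "positive_bcpnn", "positive_both", "ror_grade",
  "bcpnn_grade", "count", "proportion", "N", "is_serious",
  "primary_outcome", "tto_days", "bin", "i.tto_days", "sex",
  "occr_country", "event_dt", "age", "age_cod", "facet", "level", "pct",
  ".hit", "any_match", "has_rows", "weight", "p", "rr", "p_target",
  "expected_ror", "start_date", "start_prec", "event_prec", "event_date",
  ".fda_key", ".pid_key"
))

#' Normalize free text for matching
#'
#' Lower-cases, trims, and collapses internal whitespace. All PT, drug-name
#' and indication comparisons in the package go through this normalization,
#' so matching is case- and whitespace-insensitive.
#'
#' @param x character vector.
#' @return normalized character vector of the same length.
#' @export
norm_text <- function(x) {
  x <- tolower(trimws(as.character(x)))
  gsub("[[:space:]]+", " ", x)
}

#' Parse FAERS-style dates with precision tracking
#'
#' FAERS date fields hold YYYYMMDD, YYYYMM or YYYY digit strings, frequently
#' blank or malformed. Partial dates are never coerced to day precision: each
#' value is parsed to the finest precision it supports and flagged, so that
#' downstream steps (time-to-onset) can require full dates explicitly.
#'
#' @param x character (or numeric) vector of raw date fields.
#' @return a `data.table` with columns `raw`, `precision` (one of
#'   `"day"`, `"month"`, `"year"`, `"invalid"`), and `date` (a `Date`,
#'   `NA` unless precision is `"day"`).
#' @export
parse_faers_date <- function(x) {
  raw <- trimws(as.character(x))
  raw[is.na(raw)] <- ""
  precision <- rep("invalid", length(raw))
  date <- as.Date(rep(NA_integer_, length(raw)), origin = "1970-01-01")

  is8 <- grepl("^[0-9]{8}$", raw)
  is6 <- grepl("^[0-9]{6}$", raw)
  is4 <- grepl("^[0-9]{4}$", raw)

  if (any(is8)) {
    d <- as.Date(raw[is8], format = "%Y%m%d")
    ok <- !is.na(d)
    idx <- which(is8)
    precision[idx[ok]] <- "day"
    date[idx[ok]] <- d[ok]
    # 8 digits but impossible calendar date (e.g. 20230230) stays invalid
  }
  if (any(is6)) {
    mm <- as.integer(substr(raw[is6], 5, 6))
    idx <- which(is6)
    precision[idx[mm >= 1 & mm <= 12]] <- "month"
  }
  precision[is4] <- "year"

  data.table::data.table(raw = raw, precision = precision, date = date)
}

#' Year-precision integer for report-received dates
#'
#' Deduplication compares FDA_DT values as integers; unparseable values are
#' mapped to -1 so they always lose against any real date.
#'
#' @param x raw fda_dt character vector.
#' @return integer vector (YYYYMMDD-style, shorter strings zero-padded on the
#'   right so YYYY < YYYYMM01 < YYYYMMDD comparisons stay sane).
#' @keywords internal
fda_dt_key <- function(x) {
  raw <- trimws(as.character(x))
  raw[is.na(raw)] <- ""
  out <- rep(-1, length(raw))
  dig <- grepl("^[0-9]{4}([0-9]{2}([0-9]{2})?)?$", raw)
  padded <- formatC(raw[dig], width = 8, flag = "-")
  padded <- gsub(" ", "0", padded)
  out[dig] <- as.numeric(padded)
  out
}

# FAERS age-unit codes -> multiplier to years.
.age_unit_factor <- c(
  DEC = 10, YR = 1, MON = 1 / 12, WK = 1 / 52.14, DY = 1 / 365.25,
  HR = 1 / 8766
)

#' Convert FAERS age + unit code to years
#'
#' Applies the FAERS age-unit codes (DEC decades, YR years, MON months,
#' WK weeks, DY days, HR hours). A blank unit is treated as years, the
#' historical FAERS convention; an unrecognized unit yields a missing age.
#'
#' @param age raw age field (character or numeric).
#' @param age_cod raw unit code field.
#' @return numeric vector of ages in years (`NA` where unconvertible).
#' @export
age_in_years <- function(age, age_cod) {
  a <- suppressWarnings(as.numeric(trimws(as.character(age))))
  u <- toupper(trimws(as.character(age_cod)))
  fac <- rep(NA_real_, length(a))
  fac[u == "" | is.na(u)] <- 1
  known <- u %in% names(.age_unit_factor)
  fac[known] <- .age_unit_factor[u[known]]
  out <- a * fac
  out[!is.finite(out) | out < 0] <- NA_real_
  out
}

#' Compare primaryids the FAERS way
#'
#' primaryids are digit strings; comparison is numeric when both sides parse
#' as integers, otherwise lexicographic on right-aligned zero-padded strings.
#' Returns an order key usable with `max`/sorting.
#'
#' @param x character vector of primaryids.
#' @return numeric key where possible, else a comparable padded string; the
#'   return is a list with `num` (numeric or NA) and `chr` (padded string).
#' @keywords internal
primaryid_key <- function(x) {
  x <- trimws(as.character(x))
  num <- suppressWarnings(as.numeric(x))
  w <- max(nchar(x), 1L)
  chr <- formatC(x, width = w, flag = "0")
  list(num = num, chr = chr)
}
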