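# Descriptive surfaces: demographics, seriousness/outcomes, time-to-onset.

.outcome_rank <- c(DE = 1L, LT = 2L, HO = 3L, DS = 4L, CA = 5L, RI = 6L,
                   OT = 7L)

.outcome_labels <- c(
  DE = "Death", LT = "Life-threatening condition", HO = "Hospitalization",
  DS = "Disability", CA = "Congenital anomaly", RI = "Required intervention",
  OT = "Other serious medically important event"
)

.tto_bins <- c("0-90d", "91-180d", "181-360d", ">360d", "missing_invalid")

#' Seriousness classification per report
#'
#' A report is serious when it carries at least one outcome record (the
#' FAERS OUTC table only records the serious outcome categories: death,
#' life-threatening condition, hospitalization, disability, congenital
#' anomaly, required intervention, other serious). The primary outcome is
#' the worst one under the ranking DE > LT > HO > DS > CA > RI > OT.
#' Unknown outcome codes are counted as OT with a warning.
#'
#' @param cases a `faers_cases` object.
#' @return a `data.table` with `primaryid`, `is_serious`, `primary_outcome`
#'   (code, `NA` for non-serious reports), one row per report.
#' @export
classify_serious <- function(cases) {
  outc <- data.table::copy(cases$outc)
  ids <- cases$demo$primaryid
  if (nrow(outc)) {
    outc[, outc_cod := toupper(trimws(outc_cod))]
    unk <- setdiff(unique(outc$outc_cod), names(.outcome_rank))
    unk <- unk[nzchar(unk)]
    if (length(unk)) {
      warning("unknown outcome code(s) counted as OT: ",
              paste(unk, collapse = ", "))
      outc[outc_cod %in% unk, outc_cod := "OT"]
    }
    outc <- outc[nzchar(outc_cod)]
    worst <- outc[, .(primary_outcome =
                        names(.outcome_rank)[min(.outcome_rank[outc_cod])]),
                  by = primaryid]
  } else {
    worst <- data.table::data.table(primaryid = character(),
                                    primary_outcome = character())
  }
  out <- data.table::data.table(primaryid = ids)
  out <- merge(out, worst, by = "primaryid", all.x = TRUE, sort = FALSE)
  out[, is_serious := !is.na(primary_outcome)]
  data.table::setcolorder(out, c("primaryid", "is_serious", "primary_outcome"))
  out[]
}

#' Outcome tabulation
#'
#' Two conventions are offered because spontaneous-report tables attach
#' several outcomes to one report: `"worst"` counts each serious report once
#' under its worst outcome; `"occurrence"` counts every outcome row, so the
#' column can sum to more than the number of reports.
#'
#' @param cases a `faers_cases` object.
#' @param mode `"worst"` or `"occurrence"`.
#' @return a list with `serious`, `non_serious`, and `by_outcome` (a named
#'   integer vector over the seven codes, labeled).
#' @export
outcome_summary <- function(cases, mode = c("worst", "occurrence")) {
  mode <- match.arg(mode)
  cls <- classify_serious(cases)
  counts <- stats::setNames(integer(length(.outcome_rank)),
                            names(.outcome_rank))
  if (mode == "worst") {
    tab <- table(cls$primary_outcome)
  } else {
    outc <- data.table::copy(cases$outc)
    outc[, outc_cod := toupper(trimws(outc_cod))]
    outc[!outc_cod %in% names(.outcome_rank) & nzchar(outc_cod),
         outc_cod := "OT"]
    tab <- table(outc[nzchar(outc_cod), outc_cod])
  }
  counts[names(tab)] <- as.integer(tab)
  list(
    serious = sum(cls$is_serious),
    non_serious = sum(!cls$is_serious),
    by_outcome = stats::setNames(counts,
                                 .outcome_labels[names(counts)]),
    mode = mode
  )
}

.band_age <- function(years) {
  out <- rep("Not specified", length(years))
  out[!is.na(years) & years < 18] <- "< 18"
  out[!is.na(years) & years >= 18 & years < 65] <- "18-64"
  out[!is.na(years) & years >= 65] <- ">= 65"
  out
}

#' Demographic summary of a report cohort
#'
#' Tabulates sex, age band and occurrence country, each facet partitioning
#' the cohort exactly (blanks fall into "Not specified"). Ages are converted
#' to years from the FAERS age-unit codes before banding. Countries beyond
#' the `top_k` most frequent collapse into "Other countries".
#'
#' @param cohort a `faers_cases` object (deduplicated).
#' @param top_k number of countries listed individually.
#' @param digits decimal places for percentages.
#' @return a `data.table` with `facet`, `level`, `count`, `pct` (percent of
#'   all cohort reports).
#' @export
demographics_table <- function(cohort, top_k = 7L, digits = 2L) {
  demo <- cohort$demo
  total <- nrow(demo)
  grab <- function(col) {
    if (col %in% names(demo)) trimws(demo[[col]]) else rep("", total)
  }

  sex <- toupper(grab("sex"))
  sex_lvl <- ifelse(sex == "M", "Male",
                    ifelse(sex == "F", "Female", "Not specified"))

  years <- age_in_years(grab("age"), grab("age_cod"))
  age_lvl <- .band_age(years)

  country <- grab("occr_country")
  country[!nzchar(country)] <- "Not specified"
  tab <- sort(table(country[country != "Not specified"]), decreasing = TRUE)
  keep <- names(utils::head(tab, top_k))
  country_lvl <- ifelse(country %in% c(keep, "Not specified"),
                        country, "Other countries")

  one <- function(facet, lvl) {
    dt <- data.table::as.data.table(table(level = lvl))
    data.table::setnames(dt, "N", "count")
    dt[, facet := facet]
    dt[, pct := round(100 * count / total, digits)]
    dt
  }
  out <- data.table::rbindlist(list(
    one("sex", sex_lvl), one("age", age_lvl), one("country", country_lvl)
  ))
  data.table::setcolorder(out, c("facet", "level", "count", "pct"))
  data.table::setorderv(out, c("facet", "count"), order = c(1L, -1L))
  out[]
}

#' Time-to-onset per report
#'
#' TTO is the number of days between the adverse-event onset date (EVENT_DT
#' in DEMO) and the earliest therapy start date (START_DT in THER) among the
#' therapy rows linked to the report's matched target-drug sequences. Both
#' dates must parse at day precision; a missing, partial, unparseable or
#' negative difference is binned `missing_invalid`. Bins follow the standard
#' 0-90 / 91-180 / 181-360 / >360 day cuts.
#'
#' @param cases a `faers_cases` object (typically the cohort).
#' @param spec a `cohort_spec` identifying the target drug whose therapy
#'   rows anchor the start date.
#' @return a `data.table` with `primaryid`, `tto_days` (integer, `NA` when
#'   not computable) and `bin` (factor over the five bins).
#' @export
compute_tto <- function(cases, spec) {
  ids <- cases$demo$primaryid
  out <- data.table::data.table(primaryid = ids, tto_days = NA_integer_)

  matched <- match_drug(cases, spec)
  if (nrow(matched) && nrow(cases$ther)) {
    matched <- matched[, .(primaryid, drug_seq = trimws(as.character(drug_seq)))]
    ther <- data.table::copy(cases$ther)
    ther[, dsg_drug_seq := trimws(as.character(dsg_drug_seq))]
    ther <- merge(matched, ther,
      by.x = c("primaryid", "drug_seq"),
      by.y = c("primaryid", "dsg_drug_seq")
    )
    if (nrow(ther)) {
      pd <- parse_faers_date(ther$start_dt)
      ther[, `:=`(start_date = pd$date, start_prec = pd$precision)]
      ther <- ther[start_prec == "day"]
    }
    if (nrow(ther)) {
      starts <- ther[, .(start_date = min(start_date)), by = primaryid]

      ed <- parse_faers_date(
        if ("event_dt" %in% names(cases$demo)) cases$demo$event_dt
        else rep("", length(ids))
      )
      ev <- data.table::data.table(
        primaryid = ids, event_date = ed$date, event_prec = ed$precision
      )
      m <- merge(ev[event_prec == "day"], starts, by = "primaryid")
      if (nrow(m)) {
        m[, tto_days := as.integer(event_date - start_date)]
        m <- m[tto_days >= 0]
        out[m, tto_days := i.tto_days, on = "primaryid"]
      }
    }
  }

  out[, bin := data.table::fcase(
    is.na(tto_days), "missing_invalid",
    tto_days <= 90, "0-90d",
    tto_days <= 180, "91-180d",
    tto_days <= 360, "181-360d",
    default = ">360d"
  )]
  out[, bin := factor(bin, levels = .tto_bins)]
  out[]
}

#' Time-to-onset summary
#'
#' Per-bin counts with percentages of the whole cohort (the convention used
#' in report-characteristics tables), plus the computable-TTO fractions
#' among all reports and among serious reports.
#'
#' @param cases a `faers_cases` cohort.
#' @param spec a `cohort_spec` (see [compute_tto()]).
#' @param digits decimal places for percentages.
#' @return a list with `bins` (data.table: `bin`, `count`, `pct`),
#'   `computable` (list: n, pct among all reports) and `computable_serious`
#'   (same among serious reports).
#' @export
tto_summary <- function(cases, spec, digits = 2L) {
  tto <- compute_tto(cases, spec)
  total <- nrow(tto)
  bins <- tto[, .(count = .N), by = bin]
  bins <- merge(data.table::data.table(bin = factor(.tto_bins,
                                                    levels = .tto_bins)),
                bins, by = "bin", all.x = TRUE)
  bins[is.na(count), count := 0L]
  bins[, pct := round(100 * count / total, digits)]

  cls <- classify_serious(cases)
  m <- merge(tto, cls, by = "primaryid")
  n_comp <- sum(!is.na(m$tto_days))
  n_ser <- sum(m$is_serious)
  n_comp_ser <- sum(m$is_serious & !is.na(m$tto_days))
  list(
    bins = bins[],
    computable = list(
      n = n_comp,
      pct = if (total) round(100 * n_comp / total, digits) else NA_real_
    ),
    computable_serious = list(
      n = n_comp_ser,
      pct = if (n_ser) round(100 * n_comp_ser / n_ser, digits) else NA_real_
    )
  )
}
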