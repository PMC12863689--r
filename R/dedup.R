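# FDA case-level deduplication.
#
# Spontaneous reports arrive as follow-up versions of the same case across
# quarters, under the same CASEID but different PRIMARYIDs. The FDA rule
# keeps, within each CASEID, the record with the most recent FDA_DT; ties on
# FDA_DT are broken by the largest PRIMARYID. The rule is applied to the
# pooled multi-quarter DEMO set before any drug filtering.

#' Deduplicate pooled DEMO records at the case level
#'
#' Within each caseid, keeps the record with the most recent FDA_DT
#' (unparseable dates always lose), breaking ties by largest primaryid
#' (numeric comparison when both sides parse as integers, else
#' lexicographic on zero-padded strings). The result is sorted by caseid,
#' so the output is deterministic and invariant to input order.
#'
#' @param demo a data.frame/data.table of DEMO records with columns
#'   `primaryid`, `caseid`, `fda_dt`.
#' @return a `data.table` with exactly one row per distinct caseid, plus an
#'   attribute `dedup_audit` (list with `records_in`, `cases`,
#'   `records_dropped`).
#' @export
deduplicate_demo <- function(demo) {
  demo <- data.table::as.data.table(demo)
  req <- c("primaryid", "caseid", "fda_dt")
  miss <- setdiff(req, names(demo))
  if (length(miss)) stop("DEMO lacks column(s): ", paste(miss, collapse = ", "))

  n_in <- nrow(demo)
  if (n_in == 0L) {
    out <- demo[0]
    data.table::setattr(out, "dedup_audit",
      list(records_in = 0L, cases = 0L, records_dropped = 0L))
    return(out)
  }

  dt <- data.table::copy(demo)
  dt[, caseid := trimws(as.character(caseid))]
  dt[, primaryid := trimws(as.character(primaryid))]
  fda_key <- fda_dt_key(dt$fda_dt)
  pid <- primaryid_key(dt$primaryid)
  # numeric primaryid key where available, else rank of the padded string
  pid_key <- pid$num
  bad <- is.na(pid_key)
  if (any(bad)) pid_key[bad] <- -1e18 + as.numeric(as.factor(pid$chr[bad]))
  dt[, `:=`(.fda_key = fda_key, .pid_key = pid_key)]

  data.table::setorderv(dt, c("caseid", ".fda_key", ".pid_key"))
  out <- dt[, utils::tail(.SD, 1L), by = caseid]
  out[, c(".fda_key", ".pid_key") := NULL]
  data.table::setcolorder(out, names(demo))
  data.table::setorderv(out, "caseid")
  data.table::setattr(out, "dedup_audit", list(
    records_in = n_in,
    cases = nrow(out),
    records_dropped = n_in - nrow(out)
  ))
  out[]
}
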