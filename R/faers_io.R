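# FAERS quarterly ASCII ingestion.
#
# The FAERS dialect is "$"-delimited text with no quoting mechanism; legacy
# quarters contain non-UTF-8 bytes, short lines, and occasional lines with
# embedded "$" beyond the header arity. The reader is tolerant by design:
# short lines are right-padded with blanks, over-long lines are truncated to
# the header arity (with the overflow counted), and the file is decoded as
# Latin-1 with replacement.

# canonical (lower-case) column requirements per table kind
.faers_schema <- list(
  demo = list(
    mandatory = c("primaryid", "caseid", "fda_dt"),
    optional = c("event_dt", "age", "age_cod", "sex", "occr_country")
  ),
  drug = list(
    mandatory = c("primaryid", "drug_seq", "role_cod", "drugname"),
    optional = c("prod_ai")
  ),
  reac = list(mandatory = c("primaryid", "pt"), optional = character()),
  outc = list(mandatory = c("primaryid", "outc_cod"), optional = character()),
  ther = list(
    mandatory = c("primaryid", "dsg_drug_seq", "start_dt"),
    optional = character()
  ),
  indi = list(
    mandatory = c("primaryid", "indi_drug_seq", "indi_pt"),
    optional = character()
  )
)

# documented alias map for pre-2012 legacy column names
.faers_aliases <- c(
  isr = "primaryid", "case" = "caseid", gndr_cod = "sex",
  reporter_country = "occr_country"
)

#' Table kinds understood by the FAERS reader
#' @return character vector of the six table kinds.
#' @export
faers_table_kinds <- function() names(.faers_schema)

#' Read one FAERS-style "$"-delimited table
#'
#' Reads a quarterly ASCII table (DEMO, DRUG, REAC, OUTC, THER or INDI) into
#' a `data.table` with canonical lower-case column names. Lines with fewer
#' fields than the header are right-padded with blanks; lines with more
#' fields (an embedded "$") are truncated to the header arity and counted as
#' overflow. Unknown extra columns are preserved under their own names.
#'
#' @param path path to the text file; first line must be a "$"-delimited
#'   header.
#' @param table_kind one of `faers_table_kinds()`.
#' @return a `data.table`, one row per data line, all columns character.
#'   Attributes `overflow_lines` and `padded_lines` carry the tolerant-parse
#'   counters.
#' @export
read_faers_table <- function(path, table_kind) {
  table_kind <- match.arg(tolower(table_kind), faers_table_kinds())
  if (!file.exists(path)) stop("file not found: ", path)

  con <- file(path, open = "r", encoding = "latin1")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  if (length(lines) == 0L) stop("empty file (no header line): ", path)

  header <- tolower(trimws(strsplit(lines[[1L]], "$", fixed = TRUE)[[1L]]))
  hit <- header %in% names(.faers_aliases)
  header[hit] <- .faers_aliases[header[hit]]

  schema <- .faers_schema[[table_kind]]
  missing_cols <- setdiff(schema$mandatory, header)
  if (length(missing_cols)) {
    stop(
      "table '", table_kind, "' is missing mandatory column(s): ",
      paste(missing_cols, collapse = ", ")
    )
  }

  nc <- length(header)
  body <- lines[-1L]
  body <- body[nzchar(trimws(body))]
  if (length(body) == 0L) {
    warning("no data lines in ", path)
    out <- data.table::as.data.table(
      stats::setNames(rep(list(character()), nc), header)
    )
    data.table::setattr(out, "overflow_lines", 0L)
    data.table::setattr(out, "padded_lines", 0L)
    return(out)
  }

  fields <- strsplit(body, "$", fixed = TRUE)
  nf <- lengths(fields)
  overflow <- sum(nf > nc)
  padded <- sum(nf < nc)
  mat <- vapply(fields, function(f) {
    length(f) <- nc
    f
  }, character(nc))
  mat <- if (nc == 1L) matrix(mat, ncol = 1L) else t(mat)
  mat[is.na(mat)] <- ""
  out <- data.table::as.data.table(mat)
  data.table::setnames(out, header)
  if (overflow > 0L) {
    message(overflow, " line(s) exceeded header arity in ", basename(path),
            "; extra fields dropped")
  }
  data.table::setattr(out, "overflow_lines", as.integer(overflow))
  data.table::setattr(out, "padded_lines", as.integer(padded))
  out[]
}

#' Read and pool a directory of FAERS quarterly tables
#'
#' Looks for files named `DEMO*.txt`, `DRUG*.txt`, ... (case-insensitive)
#' under `dir`, reads each with [read_faers_table()], and row-binds multiple
#' quarters of the same kind.
#'
#' @param dir directory containing the quarterly files.
#' @return a named list of data.tables (class `faers_db`), one element per
#'   table kind found; DEMO is mandatory.
#' @export
read_faers_db <- function(dir) {
  stopifnot(dir.exists(dir))
  db <- list()
  for (kind in faers_table_kinds()) {
    paths <- list.files(dir,
      pattern = paste0("^", kind, ".*\\.txt$"),
      ignore.case = TRUE, full.names = TRUE
    )
    if (length(paths) == 0L) next
    parts <- lapply(sort(paths), read_faers_table, table_kind = kind)
    db[[kind]] <- data.table::rbindlist(parts, use.names = TRUE, fill = TRUE)
  }
  if (is.null(db$demo)) stop("no DEMO table found under ", dir)
  structure(db, class = "faers_db")
}

#' Join per-kind record tables into per-report case bundles
#'
#' Produces exactly one case per DEMO primaryid. Child records (drug,
#' reaction, outcome, therapy, indication) whose primaryid has no DEMO row
#' are dropped and counted as orphans. Reactions are deduplicated to a
#' unique-PT set per report (on normalized text), the counting unit used by
#' the disproportionality statistics.
#'
#' @param tables a `faers_db` or a named list with element `demo` (required)
#'   and optionally `drug`, `reac`, `outc`, `ther`, `indi`.
#' @return an object of class `faers_cases`: a list of data.tables keyed by
#'   primaryid, with attribute `orphans` (named integer vector of dropped
#'   child rows per table).
#' @export
join_cases <- function(tables) {
  if (is.null(tables$demo)) stop("DEMO table is required")
  demo <- data.table::as.data.table(tables$demo)
  demo[, primaryid := trimws(primaryid)]
  if (anyDuplicated(demo$primaryid)) {
    dup <- unique(demo$primaryid[duplicated(demo$primaryid)])
    stop(
      "duplicate primaryid in DEMO after deduplication: ",
      paste(utils::head(dup, 5L), collapse = ", ")
    )
  }
  ids <- demo$primaryid
  orphans <- integer()
  out <- list(demo = demo)
  for (kind in c("drug", "reac", "outc", "ther", "indi")) {
    tb <- tables[[kind]]
    if (is.null(tb)) {
      tb <- data.table::as.data.table(
        stats::setNames(
          rep(list(character()), length(.faers_schema[[kind]]$mandatory)),
          .faers_schema[[kind]]$mandatory
        )
      )
    }
    tb <- data.table::as.data.table(tb)
    tb[, primaryid := trimws(primaryid)]
    keep <- tb$primaryid %in% ids
    orphans[[kind]] <- sum(!keep)
    tb <- tb[keep]
    if (kind == "reac") {
      tb[, pt := trimws(pt)]
      tb <- tb[nzchar(pt)]
      tb[, pt_norm := norm_text(pt)]
      tb <- unique(tb, by = c("primaryid", "pt_norm"))
    }
    out[[kind]] <- tb
  }
  structure(out, class = "faers_cases", orphans = orphans)
}

#' @export
print.faers_cases <- function(x, ...) {
  cat("<faers_cases> ", nrow(x$demo), " reports\n", sep = "")
  for (kind in c("drug", "reac", "outc", "ther", "indi")) {
    cat("  ", kind, ": ", nrow(x[[kind]]), " rows\n", sep = "")
  }
  orph <- attr(x, "orphans")
  if (!is.null(orph) && sum(orph) > 0) {
    cat("  orphan child rows dropped: ", sum(orph), "\n", sep = "")
  }
  invisible(x)
}

#' Number of reports in a case set
#' @param x a `faers_cases` object.
#' @return integer count of reports (DEMO rows).
#' @export
n_reports <- function(x) nrow(x$demo)

#' Extract one report as a self-contained case bundle
#'
#' Mainly a convenience for inspection and tests; pipeline operations are
#' vectorized over the whole case set.
#'
#' @param cases a `faers_cases` object.
#' @param id a primaryid present in the case set.
#' @return a list with elements demo, drugs, reactions, outcomes, therapies,
#'   indications (data.tables filtered to that report).
#' @export
report_case <- function(cases, id) {
  id <- trimws(as.character(id))
  if (!id %in% cases$demo$primaryid) stop("unknown primaryid: ", id)
  list(
    demo = cases$demo[primaryid == id],
    drugs = cases$drug[primaryid == id],
    reactions = cases$reac[primaryid == id],
    outcomes = cases$outc[primaryid == id],
    therapies = cases$ther[primaryid == id],
    indications = cases$indi[primaryid == id]
  )
}

#' Keep a subset of reports from a case set
#'
#' @param cases a `faers_cases` object.
#' @param ids primaryids to retain.
#' @return a `faers_cases` restricted to those reports.
#' @export
subset_cases <- function(cases, ids) {
  ids <- trimws(as.character(ids))
  out <- list(demo = cases$demo[primaryid %in% ids])
  for (kind in c("drug", "reac", "outc", "ther", "indi")) {
    out[[kind]] <- cases[[kind]][primaryid %in% ids]
  }
  structure(out, class = "faers_cases", orphans = attr(cases, "orphans"))
}

#' Write tables back out in the FAERS "$" dialect
#'
#' The inverse of [read_faers_table()]: one header line of "$"-joined column
#' names, then one line per record. Used by the synthetic generator and by
#' the round-trip tests.
#'
#' @param db a `faers_db`, `faers_cases`, or named list of data.frames keyed
#'   by table kind.
#' @param dir output directory (created if needed).
#' @param suffix optional file-name suffix after the kind (e.g. "24Q3").
#' @return invisibly, the named vector of file paths written.
#' @export
write_faers_tables <- function(db, dir, suffix = "") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  for (kind in faers_table_kinds()) {
    tb <- db[[kind]]
    if (is.null(tb)) next
    tb <- data.table::as.data.table(tb)
    drop <- intersect(names(tb), "pt_norm")
    if (length(drop)) tb <- tb[, setdiff(names(tb), drop), with = FALSE]
    path <- file.path(dir, paste0(toupper(kind), suffix, ".txt"))
    lines <- c(
      paste(names(tb), collapse = "$"),
      if (nrow(tb)) do.call(paste, c(lapply(tb, as.character), sep = "$"))
    )
    writeLines(lines, path, useBytes = TRUE)
    paths[[kind]] <- path
  }
  invisible(paths)
}
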