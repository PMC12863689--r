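# MedDRA Preferred Term -> System Organ Class mapping.
#
# MedDRA itself is licensed and cannot ship with the package; real analyses
# supply a licensed export as a tab-delimited file. The package bundles only
# a small synthetic fixture map (see inst/extdata/pt_soc_map_synthetic.tsv)
# covering the terms used in the documentation, examples and tests. Each PT
# is mapped to a single primary SOC; multi-axiality is out of scope.

#' Sentinel returned for unmapped Preferred Terms
#' @export
UNMAPPED_SOC <- "UNMAPPED"

#' Build a PT to SOC map from a data frame
#'
#' @param df data.frame with columns `pt` and `soc` (an optional third
#'   `version` column is ignored beyond the label).
#' @param version_label free-text dictionary version label.
#' @return an object of class `pt_soc_map`.
#' @export
pt_soc_map <- function(df, version_label = "") {
  df <- data.table::as.data.table(df)
  if (!all(c("pt", "soc") %in% names(df))) {
    stop("map needs columns 'pt' and 'soc'")
  }
  df <- df[, .(pt = trimws(pt), soc = trimws(soc))]
  df <- df[nzchar(pt)]
  df[, pt_norm := norm_text(pt)]
  df <- unique(df, by = c("pt_norm", "soc"))
  confl <- df[, .N, by = pt_norm][N > 1L]
  if (nrow(confl)) {
    stop(
      "conflicting SOC assignments for PT(s): ",
      paste(utils::head(df[pt_norm %in% confl$pt_norm, unique(pt)], 10L),
        collapse = ", "
      )
    )
  }
  entries <- stats::setNames(df$soc, df$pt_norm)
  structure(
    list(entries = entries, version_label = version_label),
    class = "pt_soc_map"
  )
}

#' Load a PT to SOC map from a tab-delimited file
#'
#' Expects two or three columns: pt, soc and optionally a version label
#' (taken from the first non-empty value of the third column). A header row
#' is detected when the first line starts with "pt" (case-insensitive).
#' Duplicate rows with the same SOC collapse; duplicates with conflicting
#' SOCs are a hard error naming the PTs.
#'
#' @param path file path.
#' @return a `pt_soc_map`.
#' @export
load_pt_soc_map <- function(path) {
  if (!file.exists(path)) stop("map file not found: ", path)
  dt <- data.table::fread(path,
    sep = "\t", header = FALSE, quote = "",
    colClasses = "character", fill = TRUE
  )
  if (ncol(dt) < 2L) stop("map file needs at least 2 tab-delimited columns")
  if (tolower(trimws(dt[[1L]][1L])) == "pt") dt <- dt[-1L]
  version <- ""
  if (ncol(dt) >= 3L) {
    v <- trimws(dt[[3L]])
    v <- v[nzchar(v)]
    if (length(v)) version <- v[[1L]]
  }
  pt_soc_map(
    data.table::data.table(pt = dt[[1L]], soc = dt[[2L]]),
    version_label = version
  )
}

#' The bundled synthetic PT to SOC fixture map
#'
#' Covers the Preferred Terms used by the package's examples, synthetic
#' vocabulary and tests. It is a stand-in for a licensed MedDRA export, not
#' a substitute for one in real analyses.
#'
#' @return a `pt_soc_map`.
#' @export
bundled_pt_soc_map <- function() {
  load_pt_soc_map(
    system.file("extdata", "pt_soc_map_synthetic.tsv",
      package = "pvmine", mustWork = TRUE
    )
  )
}

#' Look up the SOC of Preferred Terms
#'
#' Pure, total function: lookup is case-insensitive on normalized text;
#' unmapped terms return the [UNMAPPED_SOC] sentinel.
#'
#' @param pt character vector of PT names.
#' @param map a `pt_soc_map`.
#' @return character vector of SOC names (sentinel where unmapped).
#' @export
soc_of <- function(pt, map) {
  stopifnot(inherits(map, "pt_soc_map"))
  out <- unname(map$entries[norm_text(pt)])
  out[is.na(out)] <- UNMAPPED_SOC
  out
}

#' @export
print.pt_soc_map <- function(x, ...) {
  cat("<pt_soc_map> ", length(x$entries), " PTs",
    if (nzchar(x$version_label)) paste0(" (version ", x$version_label, ")"),
    "\n",
    sep = ""
  )
  invisible(x)
}
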