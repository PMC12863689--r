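# Screen for new suspected adverse events.
#
# The screen restricts positive signals to moderate strength or above on the
# Bayesian grade (IC025 > 1.5 under the default cutpoints), removes
# categories that carry no drug-safety meaning (social circumstances,
# product issues, surgical and medical procedures, off-label-use style
# terms), and splits the remainder by presence on the product label.

#' Label PT list
#'
#' @param labeled_pts character vector of PTs present in the product
#'   labeling.
#' @param source_label free-text provenance note.
#' @return object of class `label_pt_list`.
#' @export
label_pt_list <- function(labeled_pts, source_label = "") {
  structure(
    list(
      labeled_pts = unique(norm_text(labeled_pts)),
      source_label = source_label
    ),
    class = "label_pt_list"
  )
}

#' Load a label PT list from a plain-text file
#'
#' One PT per line; blank lines and lines starting with `#` are skipped.
#'
#' @param path file path.
#' @param source_label provenance note (defaults to the file name).
#' @return a `label_pt_list`.
#' @export
load_label_pt_list <- function(path, source_label = basename(path)) {
  if (!file.exists(path)) stop("label list not found: ", path)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  label_pt_list(lines, source_label)
}

#' Exclusion policy for drug-irrelevant signal categories
#'
#' @param excluded_socs SOC names whose signals are dropped before the
#'   novelty split. The default drops social circumstances, product issues,
#'   and surgical/medical procedures.
#' @param excluded_pts individual PTs dropped regardless of SOC (e.g.
#'   off-label-use terms).
#' @return object of class `exclusion_policy`.
#' @export
exclusion_policy <- function(excluded_socs = c(
                               "Social circumstances", "Product issues",
                               "Surgical and medical procedures"
                             ),
                             excluded_pts = c(
                               "Off label use",
                               "Product use in unapproved indication",
                               "Drug ineffective"
                             )) {
  structure(
    list(
      excluded_socs = unique(norm_text(excluded_socs)),
      excluded_pts = unique(norm_text(excluded_pts))
    ),
    class = "exclusion_policy"
  )
}

#' Screen graded signals for new suspected adverse events
#'
#' Retains signals that are positive by both methods, graded at least
#' `min_grade` on the BCPNN scale (optionally on either scale via
#' `require_both_methods = FALSE` applied to ROR too), and not excluded by
#' the policy; then partitions the retained set into label-listed and new
#' suspected PTs.
#'
#' @param records a [signal_table()] output with `soc` filled in.
#' @param label a `label_pt_list`; an empty list flags every retained signal
#'   as new, with a prominent warning.
#' @param policy an [exclusion_policy()].
#' @param min_grade `"weak"`, `"moderate"` (default) or `"high"`.
#' @param require_both_methods when `TRUE`, the ROR grade must also reach
#'   `min_grade`; default `FALSE` keys the strength requirement on the
#'   Bayesian grade only.
#' @return a list with data.tables `retained`, `labeled`, `new_suspected`
#'   and a `counts` list (retained/labeled/new).
#' @export
screen_signals <- function(records, label, policy = exclusion_policy(),
                           min_grade = c("moderate", "weak", "high"),
                           require_both_methods = FALSE) {
  min_grade <- match.arg(min_grade)
  stopifnot(inherits(label, "label_pt_list"),
            inherits(policy, "exclusion_policy"))
  dt <- data.table::as.data.table(records)
  min_g <- factor(min_grade, levels = .grade_levels, ordered = TRUE)

  keep <- dt$positive_both %in% TRUE & dt$bcpnn_grade >= min_g
  if (require_both_methods) keep <- keep & dt$ror_grade >= min_g
  keep <- keep &
    !(norm_text(dt$soc) %in% policy$excluded_socs) &
    !(norm_text(dt$pt) %in% policy$excluded_pts)
  retained <- dt[keep]

  if (length(label$labeled_pts) == 0L) {
    warning("empty label PT list: every retained signal is flagged as new")
  }
  labeled_flag <- norm_text(retained$pt) %in% label$labeled_pts
  list(
    retained = retained,
    labeled = retained[labeled_flag],
    new_suspected = retained[!labeled_flag],
    counts = list(
      retained = nrow(retained),
      labeled = sum(labeled_flag),
      new = sum(!labeled_flag)
    )
  )
}
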