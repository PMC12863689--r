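# Disproportionality statistics.
#
# The counting unit is the (deduplicated report, unique PT) pair. For a
# target PT, the 2x2 contingency table against the database background is
#
#                      target PT   other PTs
#   target drug            a           b        a + b
#   other drugs            c           d        c + d
#                        a + c       b + d      n
#
# where n is the total number of counting units, not the number of reports.
# ROR = ad/(bc) with Woolf 95% CI exp(ln ROR +/- 1.96 * sqrt(1/a+1/b+1/c+1/d)).
# The information component is IC = log2( a*n / ((a+b)(a+c)) ); the default
# implementation is the classic closed-form Bayesian BCPNN with the standard
# reference priors, whose E(IC) +/- 2*sqrt(V(IC)) gives the credibility
# bounds IC025/IC975 used for positivity and grading.

#' Count (report, unique PT) units for cohort and background
#'
#' @param cohort a `faers_cases` set of cohort reports (target drug).
#' @param background a `faers_cases` set of comparator reports.
#' @return a `data.table` with one row per PT observed in the cohort or
#'   background: columns `pt` (canonical spelling, first seen), `pt_norm`,
#'   `a` (cohort reports mentioning the PT), `c` (background reports
#'   mentioning it). Attributes `cohort_units`, `background_units`, `n`
#'   (totals from which b and d derive).
#' @export
count_units <- function(cohort, background) {
  cu <- unique(cohort$reac, by = c("primaryid", "pt_norm"))
  bu <- unique(background$reac, by = c("primaryid", "pt_norm"))
  a_tab <- cu[, .(pt = pt[1L], a = .N), by = pt_norm]
  c_tab <- bu[, .(pt = pt[1L], cc = .N), by = pt_norm]
  out <- merge(a_tab, c_tab, by = "pt_norm", all = TRUE, suffixes = c("", ".bg"))
  out[is.na(a), a := 0L]
  out[is.na(cc), cc := 0L]
  out[is.na(pt), pt := get("pt.bg")]
  if ("pt.bg" %in% names(out)) out[, "pt.bg" := NULL]
  data.table::setnames(out, "cc", "c")
  data.table::setcolorder(out, c("pt", "pt_norm", "a", "c"))
  data.table::setorderv(out, "pt_norm")
  data.table::setattr(out, "cohort_units", nrow(cu))
  data.table::setattr(out, "background_units", nrow(bu))
  data.table::setattr(out, "n", nrow(cu) + nrow(bu))
  out[]
}

#' Assemble one 2x2 contingency table
#'
#' @param a,b,c,d non-negative integer cell counts.
#' @return a list of class `contingency_table` with fields a, b, c, d, n.
#' @export
contingency_table <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(cells < 0) || any(cells != round(cells))) {
    stop("cells must be non-negative integers")
  }
  structure(c(as.list(cells), list(n = sum(cells))),
            class = "contingency_table")
}

#' Reporting odds ratio with Woolf 95% confidence interval
#'
#' Vectorized over cells. When any cell is zero the ratio or its interval is
#' undefined; such rows are flagged `defined = FALSE` (no continuity
#' correction by default; `haldane = TRUE` adds 0.5 to every cell of the
#' affected tables instead).
#'
#' @param a,b,c,d numeric vectors of cell counts (recycled).
#' @param haldane apply the Haldane-Anscombe 0.5 correction to zero-cell
#'   tables instead of flagging them undefined.
#' @return a `data.table` with columns `ror`, `ci_low`, `ci_high`,
#'   `defined`.
#' @export
compute_ror <- function(a, b, c, d, haldane = FALSE) {
  k <- data.table::data.table(a = as.numeric(a), b = as.numeric(b),
                              c = as.numeric(c), d = as.numeric(d))
  zero <- k$a == 0 | k$b == 0 | k$c == 0 | k$d == 0
  defined <- !zero
  if (haldane && any(zero)) {
    k[zero, `:=`(a = a + 0.5, b = b + 0.5, c = c + 0.5, d = d + 0.5)]
    defined <- rep(TRUE, nrow(k))
  }
  ror <- (k$a * k$d) / (k$b * k$c)
  se <- sqrt(1 / k$a + 1 / k$b + 1 / k$c + 1 / k$d)
  ci_low <- exp(log(ror) - 1.96 * se)
  ci_high <- exp(log(ror) + 1.96 * se)
  ror[!defined] <- NA_real_
  ci_low[!defined] <- NA_real_
  ci_high[!defined] <- NA_real_
  data.table::data.table(ror = ror, ci_low = ci_low, ci_high = ci_high,
                         defined = defined)
}

#' Information component (BCPNN) with credibility bounds
#'
#' `mode = "bayes"` (default) computes the classic closed-form Bayesian
#' BCPNN expectation and variance of the IC under the standard reference
#' priors (alpha1 = beta1 = 1, alpha = beta = 2, gamma11 = 1 with gamma
#' scaled to gamma11 (n+alpha)(n+beta) / ((a+b+alpha1)(a+c+beta1))), and
#' reports `ic = E(IC)`, `ic025 = E(IC) - 2 sqrt(V(IC))`,
#' `ic975 = E(IC) + 2 sqrt(V(IC))`. `mode = "raw"` computes the plug-in
#' point estimate log2(a n / ((a+b)(a+c))) with no interval (`NA` bounds;
#' undefined for a = 0).
#'
#' @param a,b,c,d numeric vectors of cell counts (recycled).
#' @param mode `"bayes"` or `"raw"`.
#' @return a `data.table` with columns `ic`, `ic025`, `ic975`, `mode`.
#' @export
compute_ic <- function(a, b, c, d, mode = c("bayes", "raw")) {
  mode <- match.arg(mode)
  a <- as.numeric(a); b <- as.numeric(b)
  c <- as.numeric(c); d <- as.numeric(d)
  n <- a + b + c + d
  if (any(n == 0)) stop("empty contingency table (n = 0)")

  if (mode == "raw") {
    ic <- log2(a * n / ((a + b) * (a + c)))
    ic[a == 0] <- NA_real_
    return(data.table::data.table(ic = ic, ic025 = NA_real_,
                                  ic975 = NA_real_, mode = "raw"))
  }

  alpha1 <- 1; beta1 <- 1
  alpha <- 2; beta <- 2
  gamma11 <- 1
  gamma <- gamma11 * (n + alpha) * (n + beta) /
    ((a + b + alpha1) * (a + c + beta1))
  e_ic <- log2(
    (a + gamma11) * (n + alpha) * (n + beta) /
      ((n + gamma) * (a + b + alpha1) * (a + c + beta1))
  )
  v_ic <- ((n - a + gamma - gamma11) / ((a + gamma11) * (1 + n + gamma)) +
    (n - a - b + alpha - alpha1) / ((a + b + alpha1) * (1 + n + alpha)) +
    (n - a - c + beta - beta1) / ((a + c + beta1) * (1 + n + beta))) /
    log(2)^2
  sd2 <- 2 * sqrt(v_ic)
  data.table::data.table(ic = e_ic, ic025 = e_ic - sd2, ic975 = e_ic + sd2,
                         mode = "bayes")
}

#' Apply the dual positivity criteria
#'
#' A PT is ROR-positive when its case count reaches `min_cases` (default 3)
#' and the lower 95% CI bound of a defined ROR is at least 1; it is
#' BCPNN-positive when IC025 is strictly greater than 0. A signal requires
#' both.
#'
#' @param a case counts.
#' @param ror_ci_low lower ROR CI bounds (`NA` when undefined).
#' @param ror_defined logical, from [compute_ror()].
#' @param ic025 lower IC credibility bounds.
#' @param min_cases minimum case count (default 3).
#' @return a `data.table` with logical columns `positive_ror`,
#'   `positive_bcpnn`, `positive_both`.
#' @export
classify_positive <- function(a, ror_ci_low, ror_defined, ic025,
                              min_cases = 3L) {
  pr <- (a >= min_cases & ror_defined & ror_ci_low >= 1) %in% TRUE
  pb <- (ic025 > 0) %in% TRUE
  data.table::data.table(positive_ror = pr, positive_bcpnn = pb,
                         positive_both = pr & pb)
}

#' Signal-strength grading cutpoints
#'
#' The grade of a positive signal is read from the lower 95% bound: for ROR
#' the lower CI limit (weak 1-50, moderate 50-1000, high >= 1000) and for
#' BCPNN the IC025 (weak 0-1.5, moderate 1.5-3.0, high > 3.0). Each band is
#' left-closed for ROR and right-closed for BCPNN so that the bands
#' partition the positive range exactly.
#'
#' @param ror_cuts increasing cutpoints for the ROR lower bound.
#' @param bcpnn_cuts increasing cutpoints for IC025.
#' @return a list of class `strength_thresholds`.
#' @export
strength_thresholds <- function(ror_cuts = c(1, 50, 1000),
                                bcpnn_cuts = c(0, 1.5, 3.0)) {
  if (any(diff(ror_cuts) <= 0) || any(diff(bcpnn_cuts) <= 0)) {
    stop("cutpoints must be strictly increasing")
  }
  structure(list(ror = ror_cuts, bcpnn = bcpnn_cuts),
            class = "strength_thresholds")
}

.grade_levels <- c("none", "weak", "moderate", "high")

#' Grade signal strength from the lower 95% bounds
#'
#' @param ror_ci_low lower ROR CI bound (NA when undefined).
#' @param ic025 lower IC credibility bound.
#' @param positive_ror,positive_bcpnn positivity flags; non-positive rows
#'   grade `"none"` regardless of the bound.
#' @param thresholds a [strength_thresholds()].
#' @return a list with ordered factors `ror_grade` and `bcpnn_grade`
#'   (levels none < weak < moderate < high).
#' @export
grade_strength <- function(ror_ci_low, ic025, positive_ror, positive_bcpnn,
                           thresholds = strength_thresholds()) {
  stopifnot(inherits(thresholds, "strength_thresholds"))
  rc <- thresholds$ror
  bc <- thresholds$bcpnn
  rg <- rep("none", length(ror_ci_low))
  ok <- positive_ror & !is.na(ror_ci_low)
  rg[ok & ror_ci_low >= rc[1] & ror_ci_low < rc[2]] <- "weak"
  rg[ok & ror_ci_low >= rc[2] & ror_ci_low < rc[3]] <- "moderate"
  rg[ok & ror_ci_low >= rc[3]] <- "high"

  bg <- rep("none", length(ic025))
  ok <- positive_bcpnn & !is.na(ic025)
  bg[ok & ic025 > bc[1] & ic025 <= bc[2]] <- "weak"
  bg[ok & ic025 > bc[2] & ic025 <= bc[3]] <- "moderate"
  bg[ok & ic025 > bc[3]] <- "high"

  list(
    ror_grade = factor(rg, levels = .grade_levels, ordered = TRUE),
    bcpnn_grade = factor(bg, levels = .grade_levels, ordered = TRUE)
  )
}

#' Full per-PT signal table
#'
#' Runs the whole disproportionality stage over a unit-count table: builds
#' each PT's 2x2 cells, computes ROR and IC, applies the positivity criteria
#' (case count a >= 3 and ROR lower CI >= 1; IC025 > 0), and grades
#' strength.
#'
#' @param counts output of [count_units()].
#' @param map optional `pt_soc_map` for the `soc` column.
#' @param ic_mode `"bayes"` or `"raw"` (see [compute_ic()]).
#' @param thresholds a [strength_thresholds()].
#' @param min_cases minimum case count a for ROR positivity (default 3).
#' @param haldane passed to [compute_ror()].
#' @return a `data.table` with one row per PT: `pt`, `soc`, `a`, `b`, `c`,
#'   `d`, `ror`, `ror_ci_low`, `ror_ci_high`, `ror_defined`, `ic`, `ic025`,
#'   `ic975`, `positive_ror`, `positive_bcpnn`, `positive_both`,
#'   `ror_grade`, `bcpnn_grade`.
#' @export
signal_table <- function(counts, map = NULL, ic_mode = "bayes",
                         thresholds = strength_thresholds(),
                         min_cases = 3L, haldane = FALSE) {
  cu <- attr(counts, "cohort_units")
  bu <- attr(counts, "background_units")
  if (is.null(cu) || is.null(bu)) {
    stop("counts must come from count_units()")
  }
  out <- data.table::copy(counts)
  out[, b := cu - a]
  out[, d := bu - out$c]
  ror <- compute_ror(out$a, out$b, out$c, out$d, haldane = haldane)
  ic <- compute_ic(out$a, out$b, out$c, out$d, mode = ic_mode)
  out[, `:=`(
    ror = ror$ror, ror_ci_low = ror$ci_low, ror_ci_high = ror$ci_high,
    ror_defined = ror$defined,
    ic = ic$ic, ic025 = ic$ic025, ic975 = ic$ic975
  )]
  pos <- classify_positive(out$a, out$ror_ci_low, out$ror_defined,
                           out$ic025, min_cases = min_cases)
  out[, `:=`(positive_ror = pos$positive_ror,
             positive_bcpnn = pos$positive_bcpnn,
             positive_both = pos$positive_both)]
  gr <- grade_strength(out$ror_ci_low, out$ic025, out$positive_ror,
                       out$positive_bcpnn, thresholds)
  out[, `:=`(ror_grade = gr$ror_grade, bcpnn_grade = gr$bcpnn_grade)]
  if (!is.null(map)) {
    out[, soc := soc_of(pt, map)]
  } else if (!"soc" %in% names(out)) {
    out[, soc := NA_character_]
  }
  data.table::setcolorder(out, c("pt", "soc", "a", "b", "c", "d"))
  data.table::setattr(out, "cohort_units", cu)
  data.table::setattr(out, "background_units", bu)
  data.table::setattr(out, "n", cu + bu)
  out[]
}

#' Two-method concordance
#'
#' @param ror_positive character vector (or set) of ROR-positive PTs.
#' @param bcpnn_positive character vector of BCPNN-positive PTs.
#' @return a list with `n_ror`, `n_bcpnn`, `overlap` (intersection size) and
#'   `pct` (overlap as a percentage of the ROR-positive set; `NA` when that
#'   set is empty).
#' @export
concordance <- function(ror_positive, bcpnn_positive) {
  r <- unique(norm_text(ror_positive))
  b <- unique(norm_text(bcpnn_positive))
  ov <- length(intersect(r, b))
  list(
    n_ror = length(r), n_bcpnn = length(b), overlap = ov,
    pct = if (length(r)) 100 * ov / length(r) else NA_real_
  )
}

#' Rank signals by frequency or by ROR strength
#'
#' Stable descending sort by case count (`by = "frequency"`) or by the ROR
#' point estimate (`by = "ror"`); ties break alphabetically by PT.
#'
#' @param records a signal table ([signal_table()] output or compatible).
#' @param by `"frequency"` or `"ror"`.
#' @return the reordered `data.table`.
#' @export
rank_signals <- function(records, by = c("frequency", "ror")) {
  by <- match.arg(by)
  dt <- data.table::as.data.table(records)
  key <- if (by == "frequency") dt$a else dt$ror
  dt[order(-xtfrm(key), tolower(pt))]
}

#' Per-SOC distribution of positive signals
#'
#' Counts distinct positive PTs (signal types, not occurrences) per SOC and
#' their share of all positive signals.
#'
#' @param records a signal table; rows with `positive_both = TRUE` are the
#'   signals counted.
#' @param digits decimal places for the proportion (default 2, percentage
#'   scale).
#' @return a `data.table` with `soc`, `count`, `proportion`, sorted by
#'   decreasing count.
#' @export
soc_distribution <- function(records, digits = 2L) {
  dt <- data.table::as.data.table(records)
  pos <- dt[positive_both %in% TRUE]
  total <- length(unique(pos$pt))
  out <- pos[, .(count = length(unique(pt))), by = soc]
  out[, proportion := round(100 * count / total, digits)]
  data.table::setorderv(out, c("count", "soc"), order = c(-1L, 1L))
  out[]
}
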