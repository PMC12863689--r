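# End-to-end orchestration: ingest -> dedup -> cohort -> count -> stats ->
# descriptives -> screen, with an audit log of record counts at every stage.

#' Build a run configuration
#'
#' @param input directory of FAERS-style quarterly tables, or `NULL` when
#'   `simulate` is given.
#' @param simulate optional [sim_config()]; when supplied the input tables
#'   are generated under `out/simulated/` first.
#' @param cohort a [cohort_spec()].
#' @param meddra_map path to a PT->SOC map, or a `pt_soc_map` object.
#' @param label_list path to a label PT file, or a `label_pt_list`.
#' @param policy an [exclusion_policy()].
#' @param thresholds a [strength_thresholds()].
#' @param out output directory for the stage tables and audit log.
#' @param outcome_mode `"worst"` or `"occurrence"` (see [outcome_summary()]).
#' @param ic_mode `"bayes"` or `"raw"`.
#' @param min_grade novelty-screen grade floor.
#' @return a list of class `run_config`, validated (all referenced paths
#'   must exist).
#' @export
run_config <- function(input = NULL, simulate = NULL,
                       cohort = default_cohort_spec(),
                       meddra_map = bundled_pt_soc_map(),
                       label_list = label_pt_list(character()),
                       policy = exclusion_policy(),
                       thresholds = strength_thresholds(),
                       out = tempfile("pvmine_run_"),
                       outcome_mode = "worst",
                       ic_mode = "bayes",
                       min_grade = "moderate") {
  if (is.null(input) && is.null(simulate)) {
    stop("either an input directory or a simulation config is required")
  }
  if (!is.null(input) && !dir.exists(input)) {
    stop("input directory not found: ", input)
  }
  if (is.character(meddra_map)) meddra_map <- load_pt_soc_map(meddra_map)
  if (is.character(label_list)) label_list <- load_label_pt_list(label_list)
  stopifnot(
    inherits(cohort, "cohort_spec"), inherits(meddra_map, "pt_soc_map"),
    inherits(label_list, "label_pt_list"),
    inherits(policy, "exclusion_policy"),
    inherits(thresholds, "strength_thresholds")
  )
  structure(
    list(
      input = input, simulate = simulate, cohort = cohort,
      meddra_map = meddra_map, label_list = label_list, policy = policy,
      thresholds = thresholds, out = out, outcome_mode = outcome_mode,
      ic_mode = ic_mode, min_grade = min_grade
    ),
    class = "run_config"
  )
}

#' Run the full signal-detection pipeline
#'
#' Stages run in order: ingest, dedup, cohort split, unit counting,
#' disproportionality statistics, descriptives, novelty screen. Every stage
#' writes a delimited table under `config$out` and appends its input/output
#' record counts to `audit.tsv`, which therefore forms a non-increasing
#' chain from raw reports through dedup and cohort filtering.
#'
#' @param config a [run_config()].
#' @return invisibly, a list with the in-memory results of every stage
#'   (`cases`, `cohort`, `background`, `signals`, `demographics`,
#'   `outcomes`, `tto`, `soc_dist`, `screen`, `audit`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out, recursive = TRUE, showWarnings = FALSE)
  audit <- data.table::data.table(stage = character(), metric = character(),
                                  value = numeric())
  note <- function(stage, metric, value) {
    audit <<- rbind(audit, data.table::data.table(
      stage = stage, metric = metric, value = as.numeric(value)
    ))
  }

  input <- config$input
  if (!is.null(config$simulate)) {
    input <- file.path(config$out, "simulated")
    simulate_faers(config$simulate, input)
  }

  db <- read_faers_db(input)
  note("ingest", "demo_rows_raw", nrow(db$demo))

  demo <- deduplicate_demo(db$demo)
  aud <- attr(demo, "dedup_audit")
  note("dedup", "cases", aud$cases)
  note("dedup", "records_dropped", aud$records_dropped)

  db$demo <- demo
  cases <- join_cases(db)
  note("join", "reports", n_reports(cases))

  parts <- split_background(cases, config$cohort)
  note("cohort", "cohort_reports", n_reports(parts$cohort))
  note("cohort", "background_reports", n_reports(parts$background))

  counts <- count_units(parts$cohort, parts$background)
  note("count", "cohort_units", attr(counts, "cohort_units"))
  note("count", "total_units", attr(counts, "n"))

  signals <- signal_table(counts, map = config$meddra_map,
                          ic_mode = config$ic_mode,
                          thresholds = config$thresholds)
  note("stats", "pts_tested", nrow(signals))
  note("stats", "positive_both", sum(signals$positive_both))

  demog <- demographics_table(parts$cohort)
  outc <- outcome_summary(parts$cohort, mode = config$outcome_mode)
  tto <- tto_summary(parts$cohort, config$cohort)
  socd <- soc_distribution(signals)
  scr <- screen_signals(signals, config$label_list, config$policy,
                        min_grade = config$min_grade)
  note("screen", "retained", scr$counts$retained)
  note("screen", "new_suspected", scr$counts$new)

  fwrite2 <- function(x, name) {
    data.table::fwrite(x, file.path(config$out, name), sep = "\t")
  }
  fwrite2(signals, "signals.tsv")
  fwrite2(demog, "demographics.tsv")
  fwrite2(tto$bins, "tto_bins.tsv")
  fwrite2(socd, "soc_distribution.tsv")
  fwrite2(scr$retained[, .(pt, soc, a, ror, ror_ci_low, ic, ic025,
                           bcpnn_grade)], "screen_retained.tsv")
  fwrite2(scr$new_suspected[, .(pt, soc, a)], "screen_new_suspected.tsv")
  outc_dt <- data.table::data.table(
    outcome = c("Serious", "Non-serious", names(outc$by_outcome)),
    count = c(outc$serious, outc$non_serious, unname(outc$by_outcome))
  )
  fwrite2(outc_dt, "outcomes.tsv")
  fwrite2(audit, "audit.tsv")

  invisible(list(
    cases = cases, cohort = parts$cohort, background = parts$background,
    counts = counts, signals = signals, demographics = demog,
    outcomes = outc, tto = tto, soc_dist = socd, screen = scr, audit = audit
  ))
}
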