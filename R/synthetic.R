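# Synthetic FAERS-schema database generator.
#
# Generates DEMO/DRUG/REAC/OUTC/THER/INDI tables in the exact "$" dialect
# the reader consumes, with controlled disproportionality: each report is
# drawn i.i.d., belongs to the target-drug arm with probability
# `drug_share`, and mentions each vocabulary PT independently with its
# baseline probability, multiplied in the target arm by the injected
# reporting-rate ratio for that PT. Because a PT's background probability is
# untouched and the other PTs are shared between arms, the expected
# unit-level reporting odds ratio of an injected PT equals its injected
# ratio exactly, which is what the analytic `expected_tables()` oracle
# returns. Case duplication (follow-up versions with later FDA_DT and larger
# PRIMARYID), partial/missing dates, outcome codes and per-bin
# time-to-onset structure are all injectable.

#' Default synthetic PT vocabulary
#'
#' A bone-targeted-therapy flavored vocabulary: PT names, relative weights
#' (heavily skewed, as real spontaneous-report term frequencies are), and a
#' SOC per PT consistent with the bundled fixture map.
#'
#' @return a `data.table` with columns `pt`, `weight`, `soc`.
#' @export
default_sim_vocabulary <- function() {
  data.table::rbindlist(list(
    data.table::data.table(pt = c(
      "Osteonecrosis of jaw", "Bone pain", "Pain in jaw", "Osteonecrosis",
      "Pathological fracture", "Exposed bone in jaw", "Arthralgia",
      "Back pain", "Pain in extremity", "Musculoskeletal pain"
    ), weight = c(2, 6, 2, 1, 1, 0.5, 10, 8, 7, 4),
    soc = "Musculoskeletal and connective tissue disorders"),
    data.table::data.table(pt = c(
      "Fatigue", "Death", "Asthenia", "Pyrexia", "Malaise",
      "Disease progression", "Impaired healing"
    ), weight = c(12, 8, 7, 6, 5, 3, 0.5),
    soc = "General disorders and administration site conditions"),
    data.table::data.table(pt = c(
      "Nausea", "Diarrhea", "Vomiting", "Tooth disorder", "Toothache",
      "Tooth loss", "Constipation"
    ), weight = c(11, 9, 8, 1.5, 1.5, 0.8, 6),
    soc = "Gastrointestinal disorders"),
    data.table::data.table(pt = c(
      "Hypocalcemia", "Hypercalcemia", "Hypophosphatemia",
      "Decreased appetite"
    ), weight = c(1.5, 1, 0.6, 7),
    soc = "Metabolism and nutrition disorders"),
    data.table::data.table(pt = c(
      "Osteomyelitis", "Pneumonia", "Tooth infection", "Periodontitis"
    ), weight = c(1, 7, 0.8, 0.6),
    soc = "Infections and infestations"),
    data.table::data.table(pt = c(
      "Atypical femur fracture", "Femur fracture", "Fall", "Tooth fracture"
    ), weight = c(0.5, 1, 7, 0.5),
    soc = "Injury, poisoning and procedural complications"),
    data.table::data.table(pt = c(
      "Bone giant cell tumor", "Metastases to bone", "Breast cancer metastatic"
    ), weight = c(0.3, 1.2, 1),
    soc = "Neoplasms benign, malignant and unspecified (incl cysts and polyps)"),
    data.table::data.table(pt = c("Dyspnea", "Cough"), weight = c(7, 6),
    soc = "Respiratory, thoracic and mediastinal disorders"),
    data.table::data.table(pt = c("Anemia", "Neutropenia"), weight = c(5, 2),
    soc = "Blood and lymphatic system disorders"),
    data.table::data.table(pt = c("Headache", "Dizziness"), weight = c(8, 7),
    soc = "Nervous system disorders"),
    data.table::data.table(pt = c("Off label use", "Product dose omission issue"),
    weight = c(3, 1), soc = c("Surgical and medical procedures",
                              "Product issues"))
  ))
}

#' Build and validate a synthetic-database configuration
#'
#' Defaults emulate the structure of an oncology bone-targeted-agent cohort
#' inside a spontaneous-report database: about 2.2 unique PTs per report,
#' 77% serious reports with the outcome mix of such cohorts, a
#' time-to-onset layout with an early-onset plus ultra-delayed shape and
#' roughly 71% uncomputable dates, and a 15% follow-up (duplication) rate.
#'
#' @param n_reports number of distinct cases to generate.
#' @param drug_share probability a case is a target-drug (primary suspect)
#'   report.
#' @param vocabulary data.table of `pt`, `weight`, `soc`; weights are
#'   normalized so that the mean number of PTs per report is
#'   `mean_pts_per_report`.
#' @param injections data.table (or data.frame) of `pt`, `rr`: the
#'   reporting-rate-ratio multipliers applied to those PTs in the target
#'   arm.
#' @param mean_pts_per_report expected unique PTs per report.
#' @param dup_rate fraction of cases that receive a follow-up version
#'   (later FDA_DT, larger PRIMARYID, identical content).
#' @param missing_date_rate unused directly; the missing mass lives in
#'   `tto_weights[5]`. Kept as an override: when not `NA`, replaces that
#'   fifth weight (the remaining four are rescaled).
#' @param outcome_profile named probabilities over `none` plus the seven
#'   outcome codes; must sum to 1.
#' @param tto_weights weights over the bins 0-90 / 91-180 / 181-360 / >360
#'   days and missing/invalid; must sum to 1.
#' @param seed integer seed fixing the output byte-for-byte.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_reports = 20000L,
                       drug_share = 0.05,
                       vocabulary = default_sim_vocabulary(),
                       injections = data.table::data.table(
                         pt = c("Osteonecrosis of jaw", "Hypocalcemia",
                                "Bone pain", "Bone giant cell tumor"),
                         rr = c(40, 20, 5, 60)
                       ),
                       mean_pts_per_report = 2.2,
                       dup_rate = 0.15,
                       missing_date_rate = NA_real_,
                       outcome_profile = c(
                         none = 0.2298, OT = 0.4522, HO = 0.1846,
                         DE = 0.0914, DS = 0.0269, LT = 0.0138,
                         RI = 0.0008, CA = 0.0005
                       ),
                       tto_weights = c(0.1046, 0.0288, 0.0439, 0.1082,
                                       0.7145),
                       seed = 1L) {
  vocabulary <- data.table::as.data.table(vocabulary)
  stopifnot(all(c("pt", "weight", "soc") %in% names(vocabulary)))
  injections <- data.table::as.data.table(injections)
  if (nrow(injections)) stopifnot(all(c("pt", "rr") %in% names(injections)))

  if (!is.na(missing_date_rate)) {
    stopifnot(missing_date_rate >= 0, missing_date_rate <= 1)
    w <- tto_weights[1:4]
    tto_weights <- c(w / sum(w) * (1 - missing_date_rate), missing_date_rate)
  }

  cfg <- list(
    n_reports = as.integer(n_reports),
    drug_share = drug_share,
    vocabulary = vocabulary,
    injections = injections,
    mean_pts_per_report = mean_pts_per_report,
    dup_rate = dup_rate,
    outcome_profile = outcome_profile,
    tto_weights = tto_weights,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' @rdname sim_config
#' @param config a `sim_config`.
#' @export
validate_sim_config <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with(config, {
    if (n_reports < 0L) stop("n_reports must be >= 0")
    if (drug_share < 0 || drug_share > 1) stop("drug_share must be in [0,1]")
    if (dup_rate < 0 || dup_rate > 1) stop("dup_rate must be in [0,1]")
    if (abs(sum(outcome_profile) - 1) > 1e-6) {
      stop("outcome_profile must sum to 1")
    }
    if (length(tto_weights) != 5L || abs(sum(tto_weights) - 1) > 1e-6) {
      stop("tto_weights must be 5 weights summing to 1")
    }
    if (any(vocabulary$weight <= 0)) stop("vocabulary weights must be > 0")
    if (nrow(injections)) {
      if (any(injections$rr <= 0)) stop("injection rr must be > 0")
      unknown <- setdiff(norm_text(injections$pt),
                         norm_text(vocabulary$pt))
      if (length(unknown)) {
        stop("injection PT(s) not in vocabulary: ",
             paste(unknown, collapse = ", "))
      }
    }
  })
  probs <- sim_pt_probs(config)
  if (any(probs$p_target > 1)) {
    stop("infeasible per-report PT probability after rr scaling (> 1) for: ",
         paste(probs$pt[probs$p_target > 1], collapse = ", "))
  }
  invisible(config)
}

#' Per-PT per-report probabilities implied by a configuration
#'
#' @param config a `sim_config`.
#' @return data.table with `pt`, `soc`, `p` (background arm probability) and
#'   `p_target` (target arm, i.e. `p * rr`).
#' @export
sim_pt_probs <- function(config) {
  v <- data.table::copy(config$vocabulary)
  v[, p := weight / sum(weight) * config$mean_pts_per_report]
  v[, rr := 1]
  if (nrow(config$injections)) {
    inj <- data.table::copy(config$injections)
    inj[, pt_norm := norm_text(pt)]
    v[norm_text(pt) %in% inj$pt_norm,
      rr := inj$rr[match(norm_text(pt), inj$pt_norm)]]
  }
  v[, p_target := p * rr]
  v[, .(pt, soc, p, rr, p_target)]
}

.sim_countries <- c("US", "JP", "", "DE", "FR", "CA", "NL", "GB", "IT", "AU")
.sim_country_w <- c(0.3133, 0.1749, 0.0764, 0.0644, 0.0487, 0.0457, 0.0348,
                    0.09, 0.08, 0.0718)
.sim_other_drugs <- c("ZOLEDRONIC ACID", "TAMOXIFEN", "LETROZOLE",
                      "PEMBROLIZUMAB", "METHOTREXATE", "PREDNISONE",
                      "ASPIRIN", "METFORMIN", "ATORVASTATIN", "OMEPRAZOLE")
.sim_onc_indications <- c(
  "Breast cancer metastatic", "Prostate cancer metastatic",
  "Bone metastases", "Giant cell tumor of bone", "Multiple myeloma",
  "Lung neoplasm malignant"
)

.rand_date <- function(n, from = "2009-01-01", to = "2024-09-30") {
  lo <- as.integer(as.Date(from))
  hi <- as.integer(as.Date(to))
  as.Date(sample(lo:hi, n, replace = TRUE), origin = "1970-01-01")
}

.fmt_date <- function(d) format(d, "%Y%m%d")

#' Generate a synthetic FAERS-style database
#'
#' Draws the configured number of cases and writes the six quarterly-style
#' tables to `dir` in the "$" dialect. The same seed always produces
#' byte-identical files.
#'
#' @param config a [sim_config()].
#' @param dir output directory; created if needed. When `NULL`, nothing is
#'   written and the tables are only returned.
#' @return invisibly, a `faers_db`-classed list of the six tables (with the
#'   file paths in attribute `paths` when written).
#' @export
simulate_faers <- function(config, dir = NULL) {
  validate_sim_config(config)
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) {
    assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(config$seed)

  n <- config$n_reports
  probs <- sim_pt_probs(config)

  if (n == 0L) {
    db <- list(
      demo = data.table::data.table(
        primaryid = character(), caseid = character(), fda_dt = character(),
        event_dt = character(), age = character(), age_cod = character(),
        sex = character(), occr_country = character()
      ),
      drug = data.table::data.table(
        primaryid = character(), drug_seq = character(),
        role_cod = character(), drugname = character(), prod_ai = character()
      ),
      reac = data.table::data.table(primaryid = character(), pt = character()),
      outc = data.table::data.table(primaryid = character(),
                                    outc_cod = character()),
      ther = data.table::data.table(primaryid = character(),
                                    dsg_drug_seq = character(),
                                    start_dt = character()),
      indi = data.table::data.table(primaryid = character(),
                                    indi_drug_seq = character(),
                                    indi_pt = character())
    )
    class(db) <- "faers_db"
    if (!is.null(dir)) {
      attr(db, "paths") <- write_faers_tables(db, dir)
    }
    return(invisible(db))
  }

  caseid <- as.character(10000000L + seq_len(n))
  target <- stats::runif(n) < config$drug_share
  dup <- stats::runif(n) < config$dup_rate
  final_version <- ifelse(dup, 2L, 1L)
  primaryid <- paste0(caseid, final_version)

  # demographics
  sex <- sample(c("M", "F", ""), n, replace = TRUE,
                prob = c(0.4244, 0.4792, 0.0964))
  age_band <- sample(c("child", "adult", "elderly", "missing"), n,
                     replace = TRUE, prob = c(0.0068, 0.2765, 0.4164, 0.3003))
  age_years <- data.table::fcase(
    age_band == "child", sample(1:17, n, replace = TRUE),
    age_band == "adult", sample(18:64, n, replace = TRUE),
    age_band == "elderly", sample(65:95, n, replace = TRUE),
    default = NA_integer_
  )
  # a slice of reports encode age in decades to exercise unit conversion
  use_dec <- !is.na(age_years) & age_years %% 10 == 0 & stats::runif(n) < 0.3
  age <- ifelse(is.na(age_years), "",
                ifelse(use_dec, as.character(age_years %/% 10),
                       as.character(age_years)))
  age_cod <- ifelse(is.na(age_years), "", ifelse(use_dec, "DEC", "YR"))
  country <- sample(.sim_countries, n, replace = TRUE, prob = .sim_country_w)

  # dates: therapy start, event date from the TTO mixture, FDA receipt
  tto_bin <- sample(1:5, n, replace = TRUE, prob = config$tto_weights)
  start_date <- .rand_date(n, "2010-01-01", "2023-06-30")
  tto_days <- data.table::fcase(
    tto_bin == 1L, sample(0:90, n, replace = TRUE),
    tto_bin == 2L, sample(91:180, n, replace = TRUE),
    tto_bin == 3L, sample(181:360, n, replace = TRUE),
    tto_bin == 4L, sample(361:1200, n, replace = TRUE),
    default = NA_integer_
  )
  event_date <- start_date + tto_days
  event_dt <- ifelse(is.na(tto_days), "", .fmt_date(event_date))
  start_dt <- .fmt_date(start_date)
  # for the missing bin, degrade dates in one of three ways
  miss_kind <- sample(1:3, n, replace = TRUE)
  start_dt[tto_bin == 5L & miss_kind == 1L] <- ""
  start_dt[tto_bin == 5L & miss_kind == 2L] <-
    substr(start_dt[tto_bin == 5L & miss_kind == 2L], 1, 6)
  # kind 3: event blank (already), start full -> still uncomputable
  fda_date <- pmax(start_date, as.Date("2009-01-01")) +
    sample(30:600, n, replace = TRUE)
  fda_dt <- .fmt_date(fda_date)

  demo <- data.table::data.table(
    primaryid = primaryid, caseid = caseid, fda_dt = fda_dt,
    event_dt = event_dt, age = age, age_cod = age_cod, sex = sex,
    occr_country = country
  )
  # follow-up cases also emit their earlier version (smaller primaryid,
  # earlier fda_dt, same content)
  if (any(dup)) {
    early <- demo[dup]
    early[, primaryid := paste0(caseid, 1L)]
    early[, fda_dt := .fmt_date(as.Date(fda_dt, "%Y%m%d") -
                                  sample(30:300, .N, replace = TRUE))]
    demo <- rbind(demo, early)
  }

  # drugs: target arm gets the brand drug as PS; background draws another
  # primary suspect; a small slice of background carries the target drug in
  # a non-suspect role, and a 60 mg-brand sibling with a non-oncology
  # indication exercises the indication filter
  target_name <- sample(c("XGEVA", "DENOSUMAB (XGEVA)", "XGEVA."), n,
                        replace = TRUE, prob = c(0.6, 0.3, 0.1))
  bg_name <- sample(.sim_other_drugs, n, replace = TRUE)
  sibling <- !target & stats::runif(n) < 0.02
  conc_target <- !target & !sibling & stats::runif(n) < 0.01

  drug <- data.table::data.table(
    primaryid = primaryid,
    drug_seq = "1",
    role_cod = "PS",
    drugname = ifelse(target, target_name,
                      ifelse(sibling, "PROLIA", bg_name)),
    prod_ai = ifelse(target | sibling, "DENOSUMAB", "")
  )
  if (any(conc_target)) {
    drug <- rbind(drug, data.table::data.table(
      primaryid = primaryid[conc_target], drug_seq = "2", role_cod = "SS",
      drugname = "XGEVA", prod_ai = "DENOSUMAB"
    ))
  }

  # reactions: independent per-PT Bernoulli draws, rr-scaled in the target arm
  reac_list <- vector("list", nrow(probs))
  for (j in seq_len(nrow(probs))) {
    pj <- ifelse(target, probs$p_target[j], probs$p[j])
    hit <- stats::runif(n) < pj
    if (any(hit)) {
      reac_list[[j]] <- data.table::data.table(
        primaryid = primaryid[hit], pt = probs$pt[j]
      )
    }
  }
  reac <- data.table::rbindlist(reac_list[!vapply(reac_list, is.null,
                                                  logical(1))])
  data.table::setorderv(reac, c("primaryid", "pt"))

  # outcomes: one category per report
  outc_draw <- sample(names(config$outcome_profile), n, replace = TRUE,
                      prob = config$outcome_profile)
  has_outc <- outc_draw != "none"
  outc <- data.table::data.table(
    primaryid = primaryid[has_outc], outc_cod = outc_draw[has_outc]
  )

  ther <- data.table::data.table(
    primaryid = primaryid, dsg_drug_seq = "1", start_dt = start_dt
  )

  indi_pt <- ifelse(
    target, sample(.sim_onc_indications, n, replace = TRUE),
    ifelse(sibling, "Osteoporosis",
           sample(c(.sim_onc_indications, "Hypertension", "Osteoporosis",
                    "Diabetes mellitus"), n, replace = TRUE))
  )
  indi <- data.table::data.table(
    primaryid = primaryid, indi_drug_seq = "1", indi_pt = indi_pt
  )

  # child tables for follow-up versions mirror the final content
  if (any(dup)) {
    dup_ids <- primaryid[dup]
    early_ids <- paste0(caseid[dup], 1L)
    remap <- stats::setNames(early_ids, dup_ids)
    clone <- function(tb) {
      cl <- tb[primaryid %in% dup_ids]
      cl[, primaryid := remap[primaryid]]
      cl
    }
    drug <- rbind(drug, clone(drug))
    reac <- rbind(reac, clone(reac))
    outc <- rbind(outc, clone(outc))
    ther <- rbind(ther, clone(ther))
    indi <- rbind(indi, clone(indi))
  }

  for (tb in list(demo, drug, reac, outc, ther, indi)) {
    data.table::setorderv(tb, intersect(c("primaryid", "drug_seq", "pt",
                                          "outc_cod"), names(tb)))
  }

  db <- list(demo = demo, drug = drug, reac = reac, outc = outc,
             ther = ther, indi = indi)
  class(db) <- "faers_db"
  if (!is.null(dir)) {
    attr(db, "paths") <- write_faers_tables(db, dir)
  }
  invisible(db)
}

#' Analytic expected contingency cells under the generative model
#'
#' Closed-form expectations of the per-PT a/b/c/d counting-unit cells
#' implied by a configuration, for oracle comparison against the pipeline's
#' observed counts. Deduplication removes follow-up versions exactly, so
#' duplication does not enter the expectations.
#'
#' @param config a [sim_config()].
#' @return data.table with `pt`, `a`, `b`, `c`, `d` (expected values) and
#'   `expected_ror`.
#' @export
expected_tables <- function(config) {
  validate_sim_config(config)
  probs <- sim_pt_probs(config)
  n <- config$n_reports
  s <- config$drug_share
  cohort_units <- n * s * sum(probs$p_target)
  bg_units <- n * (1 - s) * sum(probs$p)
  out <- probs[, .(
    pt,
    a = n * s * p_target,
    c = n * (1 - s) * p
  )]
  out[, b := cohort_units - a]
  out[, d := bg_units - out$c]
  out[, expected_ror := (a * d) / (b * out$c)]
  out[]
}
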