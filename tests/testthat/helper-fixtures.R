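# Fixture builders and independent oracles shared across the suite.

# Write a "$"-delimited table file from a list of row vectors.
write_dollar_file <- function(path, header, rows) {
  lines <- c(
    paste(header, collapse = "$"),
    vapply(rows, paste, character(1), collapse = "$")
  )
  writeLines(lines, path)
  path
}

# A small fully-joined fixture database: 3 cases, one qualifying cohort
# report (p1: target drug PS + oncology indication), one target drug in a
# non-suspect role (p2), one unrelated report (p3).
fixture_db <- function() {
  list(
    demo = data.table::data.table(
      primaryid = c("101", "201", "301"),
      caseid = c("1", "2", "3"),
      fda_dt = c("20230105", "20230210", "20230315"),
      event_dt = c("20200131", "", "20210601"),
      age = c("70", "7", ""),
      age_cod = c("YR", "DEC", ""),
      sex = c("F", "M", ""),
      occr_country = c("US", "JP", "")
    ),
    drug = data.table::data.table(
      primaryid = c("101", "201", "201", "301"),
      drug_seq = c("1", "1", "2", "1"),
      role_cod = c("PS", "PS", "SS", "PS"),
      drugname = c("XGEVA", "TAMOXIFEN", "DENOSUMAB (XGEVA)", "ASPIRIN"),
      prod_ai = c("DENOSUMAB", "", "DENOSUMAB", "")
    ),
    reac = data.table::data.table(
      primaryid = c("101", "101", "101", "201", "301"),
      pt = c("Osteonecrosis of jaw", "Hypocalcemia",
             "Osteonecrosis of jaw", "Nausea", "Nausea")
    ),
    outc = data.table::data.table(
      primaryid = c("101", "101", "201"),
      outc_cod = c("HO", "DE", "OT")
    ),
    ther = data.table::data.table(
      primaryid = c("101", "201", "301"),
      dsg_drug_seq = c("1", "1", "1"),
      start_dt = c("20200101", "202001", "20210501")
    ),
    indi = data.table::data.table(
      primaryid = c("101", "201"),
      indi_drug_seq = c("1", "2"),
      indi_pt = c("Breast cancer metastatic", "Osteoporosis")
    )
  )
}

fixture_cases <- function() join_cases(fixture_db())

# minimal two-term PT->SOC map
fixture_map <- function() {
  pt_soc_map(data.frame(
    pt = c("Osteonecrosis of jaw", "Hypocalcemia", "Nausea"),
    soc = c(
      "Musculoskeletal and connective tissue disorders",
      "Metabolism and nutrition disorders",
      "Gastrointestinal disorders"
    )
  ))
}

# Independent brute-force arithmetic for ROR and its Woolf interval,
# written scalar-by-scalar from the 2x2 definition.
ror_oracle <- function(a, b, c, d) {
  if (a == 0 || b == 0 || c == 0 || d == 0) {
    return(list(ror = NA_real_, lo = NA_real_, hi = NA_real_,
                defined = FALSE))
  }
  ror <- (a * d) / (b * c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  list(ror = ror, lo = exp(log(ror) - 1.96 * se),
       hi = exp(log(ror) + 1.96 * se), defined = TRUE)
}

# Independent transcription of the closed-form Bayesian BCPNN moments
# (reference priors alpha1 = beta1 = 1, alpha = beta = 2, gamma11 = 1,
# gamma scaled by the margins), kept deliberately scalar and literal.
bcpnn_oracle <- function(a, b, c, d) {
  n <- a + b + c + d
  g11 <- 1
  g <- g11 * (n + 2) * (n + 2) / ((a + b + 1) * (a + c + 1))
  eic <- log2((a + g11) * (n + 2) * (n + 2) /
                ((n + g) * (a + b + 1) * (a + c + 1)))
  vic <- ((n - a + g - g11) / ((a + g11) * (1 + n + g)) +
            (n - a - b + 2 - 1) / ((a + b + 1) * (1 + n + 2)) +
            (n - a - c + 2 - 1) / ((a + c + 1) * (1 + n + 2))) / log(2)^2
  list(ic = eic, ic025 = eic - 2 * sqrt(vic), ic975 = eic + 2 * sqrt(vic))
}

raw_ic_oracle <- function(a, b, c, d) {
  n <- a + b + c + d
  log2(a * n / ((a + b) * (a + c)))
}
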