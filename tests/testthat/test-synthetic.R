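test_that("zero-report config yields valid header-only tables", {
  dir <- withr::local_tempdir()
  cfg <- sim_config(n_reports = 0, seed = 1)
  simulate_faers(cfg, dir)
  db <- read_faers_db(dir) |> suppressWarnings()
  expect_equal(nrow(db$demo), 0L)
  expect_equal(n_reports(join_cases(db)), 0L)
})

test_that("same seed produces byte-identical files", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  cfg <- sim_config(n_reports = 500, seed = 77)
  simulate_faers(cfg, d1)
  simulate_faers(cfg, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  # and a different seed does not
  simulate_faers(sim_config(n_reports = 500, seed = 78), d2)
  expect_false(identical(readLines(file.path(d1, "DEMO.txt")),
                         readLines(file.path(d2, "DEMO.txt"))))
})

test_that("simulation does not disturb the caller's RNG stream", {
  set.seed(42)
  before <- stats::runif(1)
  set.seed(42)
  invisible(simulate_faers(sim_config(n_reports = 50, seed = 9)))
  expect_identical(stats::runif(1), before)
})

test_that("dup_rate = 0 makes deduplication the identity", {
  db <- simulate_faers(sim_config(n_reports = 300, dup_rate = 0, seed = 5))
  dd <- deduplicate_demo(db$demo)
  expect_equal(nrow(dd), nrow(db$demo))
  expect_setequal(dd$primaryid, db$demo$primaryid)
})

test_that("deduplicated report count equals distinct caseids under stress", {
  db <- simulate_faers(sim_config(n_reports = 2000, dup_rate = 0.3,
                                  seed = 13))
  expect_gt(nrow(db$demo), 2000) # follow-up versions were emitted
  dd <- deduplicate_demo(db$demo)
  expect_equal(nrow(dd), length(unique(db$demo$caseid)))
  # the retained version of a duplicated case is the later one
  dup_cases <- db$demo[, .N, by = caseid][N > 1, caseid]
  kept <- dd[caseid %in% dup_cases]
  orig <- db$demo[caseid %in% dup_cases]
  mx <- orig[, .(mx = max(fda_dt)), by = caseid]
  expect_equal(kept[order(caseid), fda_dt], mx[order(caseid), mx])
})

test_that("infeasible probability after rr scaling fails validation", {
  vocab <- data.table::data.table(pt = c("A", "B"), weight = c(1, 1),
                                  soc = "S")
  expect_error(
    sim_config(
      n_reports = 10, vocabulary = vocab,
      injections = data.table::data.table(pt = "A", rr = 10),
      mean_pts_per_report = 0.4, seed = 1
    ),
    "infeasible"
  )
  expect_error(
    sim_config(injections = data.table::data.table(pt = "No such", rr = 2)),
    "not in vocabulary"
  )
})

test_that("analytic expectations form a null model when rr = 1", {
  cfg <- sim_config(n_reports = 1000, injections = data.table::data.table(
    pt = character(), rr = numeric()
  ), seed = 2)
  exp_tab <- expected_tables(cfg)
  expect_equal(exp_tab$expected_ror, rep(1, nrow(exp_tab)), tolerance = 1e-12)
  # drug_share = 0 empties the target arm
  cfg0 <- sim_config(n_reports = 1000, drug_share = 0, seed = 2)
  exp0 <- expected_tables(cfg0)
  expect_true(all(exp0$a == 0 & exp0$b == 0))
})

test_that("a single injection is recovered at the injected ratio", {
  # expected-cell odds ratio equals rr exactly for a lone injected PT
  cfg <- sim_config(
    n_reports = 50000,
    injections = data.table::data.table(pt = "Hypocalcemia", rr = 10),
    seed = 31
  )
  exp_tab <- expected_tables(cfg)
  expect_equal(exp_tab[pt == "Hypocalcemia", expected_ror], 10,
               tolerance = 1e-9)
  # the injection inflates the cohort's other-event denominator, so
  # non-injected PTs sit slightly below 1 (the masking effect of real
  # disproportionality analyses), never above
  expect_lt(exp_tab[pt == "Nausea", expected_ror], 1)
  expect_gt(exp_tab[pt == "Nausea", expected_ror], 0.85)

  # and the simulated counts agree with the analytic cells
  db <- simulate_faers(cfg)
  db$demo <- deduplicate_demo(db$demo)
  parts <- split_background(join_cases(db), default_cohort_spec())
  counts <- count_units(parts$cohort, parts$background)
  obs <- counts[pt == "Hypocalcemia"]
  expect_equal(obs$a, exp_tab[pt == "Hypocalcemia", a], tolerance = 0.2)
  tab <- signal_table(counts)
  expect_equal(tab[pt == "Hypocalcemia", ror], 10, tolerance = 0.25)
})

test_that("generated non-missing TTO values land in their assigned bin", {
  spec <- default_cohort_spec()
  bins <- c("0-90d", "91-180d", "181-360d", ">360d")
  for (i in seq_along(bins)) {
    w <- rep(0, 5)
    w[i] <- 1
    cfg <- sim_config(n_reports = 300, drug_share = 1, tto_weights = w,
                      dup_rate = 0, seed = 40 + i)
    db <- simulate_faers(cfg)
    cases <- join_cases(db)
    tto <- compute_tto(cases, spec)
    expect_true(all(as.character(tto$bin) == bins[i]), info = bins[i])
  }
  # pure missing mass: nothing computable
  cfg <- sim_config(n_reports = 200, drug_share = 1,
                    tto_weights = c(0, 0, 0, 0, 1), dup_rate = 0, seed = 45)
  tto <- compute_tto(join_cases(simulate_faers(cfg)), spec)
  expect_true(all(as.character(tto$bin) == "missing_invalid"))
})

test_that("missing_date_rate override rescales the TTO mixture", {
  cfg <- sim_config(missing_date_rate = 0.5, seed = 1)
  expect_equal(cfg$tto_weights[5], 0.5)
  expect_equal(sum(cfg$tto_weights), 1)
  w <- c(0.1046, 0.0288, 0.0439, 0.1082)
  expect_equal(cfg$tto_weights[1:4], w / sum(w) * 0.5, tolerance = 1e-12)
})
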