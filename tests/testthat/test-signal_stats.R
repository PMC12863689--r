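test_that("unit counting follows the (report, unique PT) rule", {
  # 1 cohort report with PTs {X, Y}; 1 background report with {X};
  # X listed twice on the cohort report still counts once
  db <- list(
    demo = data.table::data.table(
      primaryid = c("1", "2"), caseid = c("1", "2"),
      fda_dt = c("20230101", "20230101")
    ),
    reac = data.table::data.table(
      primaryid = c("1", "1", "1", "2"),
      pt = c("PT X", "PT Y", "PT X", "PT X")
    )
  )
  cases <- join_cases(db)
  counts <- count_units(subset_cases(cases, "1"), subset_cases(cases, "2"))
  x <- counts[pt == "PT X"]
  expect_equal(x$a, 1L)
  expect_equal(x$c, 1L)
  expect_equal(attr(counts, "cohort_units") - x$a, 1L) # b
  expect_equal(attr(counts, "background_units") - x$c, 0L) # d
  expect_equal(attr(counts, "n"), 3L)

  # empty background: c = 0 everywhere
  empty <- subset_cases(cases, character())
  counts2 <- count_units(cases, empty)
  expect_true(all(counts2$c == 0L))
})

test_that("ROR matches direct arithmetic and flags zero cells", {
  # symmetry: a table with identical cells has ROR 1 and a CI straddling it
  sym <- compute_ror(10, 10, 10, 10)
  expect_equal(sym$ror, 1)
  expect_lt(sym$ci_low, 1)
  expect_gt(sym$ci_high, 1)

  r <- compute_ror(10, 90, 100, 9900)
  expect_equal(r$ror, 11)
  expect_equal(r$ci_low, 5.5595149289, tolerance = 1e-9)
  expect_equal(r$ci_high, 21.7644887274, tolerance = 1e-9)

  z <- compute_ror(3, 0, 5, 100)
  expect_false(z$defined)
  expect_true(is.na(z$ror))
  zh <- compute_ror(3, 0, 5, 100, haldane = TRUE)
  expect_true(zh$defined)
  expect_equal(zh$ror, (3.5 * 100.5) / (0.5 * 5.5))
})

test_that("information component matches direct arithmetic", {
  # exact independence: a*n == (a+b)(a+c)
  expect_equal(compute_ic(1, 9, 9, 81, mode = "raw")$ic, 0)
  expect_equal(compute_ic(10, 90, 100, 9900, mode = "raw")$ic,
               3.1987798641, tolerance = 1e-9)
  expect_true(is.na(compute_ic(0, 5, 5, 100, mode = "raw")$ic))
  expect_error(compute_ic(0, 0, 0, 0), "n = 0")

  bay <- compute_ic(10, 90, 100, 9900)
  expect_equal(bay$ic, 2.3824891373, tolerance = 1e-9)
  expect_equal(bay$ic025, 1.4274187000, tolerance = 1e-9)
  expect_equal(bay$ic975, 3.3375595746, tolerance = 1e-9)
  # the Bayesian estimate shrinks below the raw IC here
  expect_lt(bay$ic, 3.1987798641)
})

test_that("ROR and IC agree with brute-force oracles on random tables", {
  set.seed(101)
  for (i in 1:200) {
    a <- sample(0:50, 1)
    b <- sample(0:500, 1)
    c <- sample(0:500, 1)
    d <- sample(1:5000, 1)
    ro <- ror_oracle(a, b, c, d)
    r <- compute_ror(a, b, c, d)
    expect_equal(r$defined, ro$defined)
    if (ro$defined) {
      expect_equal(r$ror, ro$ror, tolerance = 1e-9)
      expect_equal(r$ci_low, ro$lo, tolerance = 1e-9)
      expect_equal(r$ci_high, ro$hi, tolerance = 1e-9)
    }
    io <- bcpnn_oracle(a, b, c, d)
    ic <- compute_ic(a, b, c, d)
    expect_equal(ic$ic, io$ic, tolerance = 1e-9)
    expect_equal(ic$ic025, io$ic025, tolerance = 1e-9)
    expect_equal(ic$ic975, io$ic975, tolerance = 1e-9)
    if (a > 0) {
      expect_equal(compute_ic(a, b, c, d, mode = "raw")$ic,
                   raw_ic_oracle(a, b, c, d), tolerance = 1e-9)
    }
  }
})

test_that("Bayesian IC shrinks toward 0 relative to raw IC for small counts", {
  # strong association carried by very few reports
  for (a in c(1, 2, 3)) {
    raw <- compute_ic(a, 5, 5, 10000, mode = "raw")$ic
    bay <- compute_ic(a, 5, 5, 10000)$ic
    expect_gt(raw, 0)
    expect_lt(bay, raw)
  }
})

test_that("ROR is strictly increasing in a with other cells fixed", {
  rors <- compute_ror(1:30, 90, 100, 9900)$ror
  expect_true(all(diff(rors) > 0))
})

test_that("positivity applies the dual criteria", {
  counts_like <- function(a, lo, ic025) {
    data.table::data.table(a = a, ror_ci_low = lo, ic025 = ic025)
  }
  pos_ror <- function(dt) dt$a >= 3 & !is.na(dt$ror_ci_low) & dt$ror_ci_low >= 1
  # high-count strongly disproportional term: positive by both
  rec <- counts_like(3082, 380.92, 8.04)
  expect_true(pos_ror(rec) && rec$ic025 > 0)
  # frequent but non-disproportional term: positive by neither
  rec <- counts_like(282, 0.83, -0.27)
  expect_false(pos_ror(rec) || rec$ic025 > 0)
  # below the minimum case count despite a high bound
  rec <- counts_like(2, 5, 1)
  expect_false(pos_ror(rec))
})

test_that("grading reads the lower bounds against the cutpoints", {
  g <- grade_strength(
    ror_ci_low = c(380.92, 1.16, 50, 1000, 0.9, NA),
    ic025 = c(8.04, 1.16, 1.5, 3.0, 3.2, -1),
    positive_ror = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE),
    positive_bcpnn = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE)
  )
  expect_equal(as.character(g$ror_grade),
               c("moderate", "weak", "moderate", "high", "none", "none"))
  expect_equal(as.character(g$bcpnn_grade),
               c("high", "weak", "weak", "moderate", "high", "none"))
})

test_that("every positive bound lands in exactly one grade band", {
  set.seed(5)
  lo <- c(stats::runif(200, 1, 2000), 1, 50, 1000)
  ic <- c(stats::runif(200, 1e-6, 5), 1.5, 3.0, 0.1)
  g <- grade_strength(lo, ic, rep(TRUE, length(lo)), rep(TRUE, length(ic)))
  expect_false(any(g$ror_grade == "none"))
  expect_false(any(g$bcpnn_grade == "none"))
  check <- function(x, cuts, left_closed) {
    band <- if (left_closed) {
      cut(x, c(cuts, Inf), right = FALSE, labels = c("weak", "moderate", "high"))
    } else {
      cut(x, c(cuts, Inf), right = TRUE, labels = c("weak", "moderate", "high"))
    }
    as.character(band)
  }
  expect_equal(as.character(g$ror_grade), check(lo, c(1, 50, 1000), TRUE))
  expect_equal(as.character(g$bcpnn_grade), check(ic, c(0, 1.5, 3), FALSE))
})

test_that("concordance reports overlap counts and the percentage", {
  r <- paste0("pt", 1:320)
  b <- c(paste0("pt", 1:294), paste0("other", 1:40))
  cc <- concordance(r, b)
  expect_equal(cc$overlap, 294L)
  expect_equal(cc$pct, 91.875)
  expect_equal(concordance(r, r)$pct, 100)
  expect_equal(concordance(r, paste0("x", 1:10))$pct, 0)
  expect_true(is.na(concordance(character(), b)$pct))
})

test_that("ranking sorts descending with alphabetical tie-break", {
  recs <- data.table::data.table(
    pt = c("X", "Y", "B", "A"), a = c(5L, 7L, 3L, 3L),
    ror = c(2, 1, 8, 8)
  )
  expect_equal(rank_signals(recs, "frequency")$pt, c("Y", "X", "A", "B"))
  expect_equal(rank_signals(recs, "ror")$pt, c("A", "B", "X", "Y"))

  set.seed(3)
  recs2 <- data.table::data.table(
    pt = replicate(10, paste(sample(letters, 4), collapse = "")),
    a = sample(1:5, 10, replace = TRUE),
    ror = stats::runif(10, 0.5, 30)
  )
  oracle <- recs2[order(-a, tolower(pt))]
  expect_equal(rank_signals(recs2, "frequency")$pt, oracle$pt)
})

test_that("SOC distribution counts distinct positive PTs", {
  recs <- data.table::data.table(
    pt = c("p1", "p2", "p3", "p4"),
    soc = c("S1", "S1", "S2", "S3"),
    positive_both = c(TRUE, TRUE, TRUE, FALSE)
  )
  d <- soc_distribution(recs)
  expect_equal(d[soc == "S1", count], 2L)
  expect_equal(d[soc == "S1", proportion], 66.67)
  expect_false("S3" %in% d$soc)
  single <- soc_distribution(recs[pt == "p1"])
  expect_equal(single$proportion, 100)
})

test_that("signal_table cells are coherent with the unit totals", {
  cfg <- sim_config(n_reports = 3000, seed = 8)
  db <- simulate_faers(cfg)
  db$demo <- deduplicate_demo(db$demo)
  cases <- join_cases(db)
  parts <- split_background(cases, default_cohort_spec())
  counts <- count_units(parts$cohort, parts$background)
  tab <- signal_table(counts, map = bundled_pt_soc_map())
  expect_equal(sum(tab$a), attr(counts, "cohort_units"))
  expect_true(all(tab$a + tab$b + tab$c + tab$d == attr(counts, "n")))
  expect_equal(tab$positive_both, tab$positive_ror & tab$positive_bcpnn)
  # defined rows respect the CI ordering invariant
  ok <- tab[ror_defined == TRUE]
  expect_true(all(ok$ror_ci_low <= ok$ror & ok$ror <= ok$ror_ci_high))
  expect_true(all(tab$ic025 <= tab$ic & tab$ic <= tab$ic975))
})
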