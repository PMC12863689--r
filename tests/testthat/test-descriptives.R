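demo_cases <- function(demo, ...) {
  join_cases(c(list(demo = demo), list(...)))
}

test_that("sex, age and country facets partition the cohort", {
  demo <- data.table::data.table(
    primaryid = as.character(1:4), caseid = as.character(1:4),
    fda_dt = "20230101",
    sex = c("F", "F", "M", ""),
    age = c("70", "7", "30", ""),
    age_cod = c("YR", "DEC", "YR", ""),
    occr_country = c("US", "JP", "", "US")
  )
  cases <- demo_cases(demo)
  tab <- demographics_table(cases)
  expect_equal(tab[facet == "sex" & level == "Female", pct], 50)
  expect_equal(tab[facet == "sex" & level == "Male", pct], 25)
  expect_equal(tab[facet == "sex" & level == "Not specified", pct], 25)
  # age 70 years and age 7 decades both land in the >= 65 band
  expect_equal(tab[facet == "age" & level == ">= 65", count], 2L)
  expect_equal(tab[facet == "age" & level == "18-64", count], 1L)
  for (f in unique(tab$facet)) {
    expect_equal(sum(tab[facet == f, count]), 4L, info = f)
  }
})

test_that("seriousness follows the outcome-record rule and worst ranking", {
  demo <- data.table::data.table(
    primaryid = c("1", "2", "3"), caseid = c("1", "2", "3"),
    fda_dt = "20230101"
  )
  outc <- data.table::data.table(
    primaryid = c("1", "1", "3"),
    outc_cod = c("HO", "DE", "OT")
  )
  cls <- classify_serious(demo_cases(demo, outc = outc))
  expect_equal(cls[primaryid == "1", primary_outcome], "DE")
  expect_true(cls[primaryid == "1", is_serious])
  expect_false(cls[primaryid == "2", is_serious])
  expect_equal(cls[primaryid == "3", primary_outcome], "OT")
  # unknown codes fold into OT with a warning
  outc2 <- rbind(outc, data.table::data.table(primaryid = "2", outc_cod = "ZZ"))
  expect_warning(cls2 <- classify_serious(demo_cases(demo, outc = outc2)),
                 "ZZ")
  expect_equal(cls2[primaryid == "2", primary_outcome], "OT")
})

test_that("adding an outcome record never makes a report non-serious", {
  demo <- data.table::data.table(primaryid = "1", caseid = "1",
                                 fda_dt = "20230101")
  base <- data.table::data.table(primaryid = "1", outc_cod = "HO")
  expect_true(classify_serious(demo_cases(demo, outc = base))$is_serious)
  for (extra in c("DE", "LT", "DS", "CA", "RI", "OT")) {
    more <- rbind(base, data.table::data.table(primaryid = "1",
                                               outc_cod = extra))
    expect_true(classify_serious(demo_cases(demo, outc = more))$is_serious)
  }
})

test_that("outcome tabulation supports worst-case and occurrence modes", {
  demo <- data.table::data.table(
    primaryid = c("1", "2"), caseid = c("1", "2"), fda_dt = "20230101"
  )
  outc <- data.table::data.table(
    primaryid = c("1", "1", "2"), outc_cod = c("HO", "DE", "HO")
  )
  cases <- demo_cases(demo, outc = outc)
  worst <- outcome_summary(cases, mode = "worst")
  expect_equal(unname(worst$by_outcome[["Death"]]), 1L)
  expect_equal(unname(worst$by_outcome[["Hospitalization"]]), 1L)
  expect_equal(sum(worst$by_outcome), worst$serious)
  occ <- outcome_summary(cases, mode = "occurrence")
  expect_equal(unname(occ$by_outcome[["Hospitalization"]]), 2L)
  expect_equal(sum(occ$by_outcome), 3L)
})

tto_fixture <- function(event_dt, start_dt) {
  demo <- data.table::data.table(
    primaryid = "1", caseid = "1", fda_dt = "20230101", event_dt = event_dt
  )
  drug <- data.table::data.table(
    primaryid = "1", drug_seq = "1", role_cod = "PS", drugname = "XGEVA",
    prod_ai = "DENOSUMAB"
  )
  ther <- data.table::data.table(
    primaryid = "1", dsg_drug_seq = "1", start_dt = start_dt
  )
  demo_cases(demo, drug = drug, ther = ther)
}

test_that("time-to-onset needs day-precision dates and a non-negative gap", {
  spec <- cohort_spec("xgeva")
  t1 <- compute_tto(tto_fixture("20200131", "20200101"), spec)
  expect_equal(t1$tto_days, 30L)
  expect_equal(as.character(t1$bin), "0-90d")
  # event before start
  t2 <- compute_tto(tto_fixture("20191231", "20200101"), spec)
  expect_equal(as.character(t2$bin), "missing_invalid")
  # month-precision start date is never coerced to a day
  t3 <- compute_tto(tto_fixture("20200131", "202001"), spec)
  expect_equal(as.character(t3$bin), "missing_invalid")
  # earliest start among several therapy rows anchors the interval
  cases <- tto_fixture("20200701", "20200101")
  cases$ther <- rbind(cases$ther, data.table::data.table(
    primaryid = "1", dsg_drug_seq = "1", start_dt = "20200601"
  ))
  expect_equal(compute_tto(cases, spec)$tto_days, 182L)
})

test_that("bin boundaries follow the 90/180/360 day cuts", {
  spec <- cohort_spec("xgeva")
  days_bin <- function(days) {
    start <- as.Date("2020-01-01")
    cases <- tto_fixture(format(start + days, "%Y%m%d"), "20200101")
    as.character(compute_tto(cases, spec)$bin)
  }
  expect_equal(days_bin(0), "0-90d")
  expect_equal(days_bin(90), "0-90d")
  expect_equal(days_bin(91), "91-180d")
  expect_equal(days_bin(180), "91-180d")
  expect_equal(days_bin(181), "181-360d")
  expect_equal(days_bin(360), "181-360d")
  expect_equal(days_bin(361), ">360d")
})

test_that("TTO summary uses whole-cohort percentages and computable shares", {
  demo <- data.table::data.table(
    primaryid = as.character(1:4), caseid = as.character(1:4),
    fda_dt = "20230101",
    event_dt = c("20200131", "20210401", "", "")
  )
  drug <- data.table::data.table(
    primaryid = as.character(1:4), drug_seq = "1", role_cod = "PS",
    drugname = "XGEVA", prod_ai = "DENOSUMAB"
  )
  ther <- data.table::data.table(
    primaryid = as.character(1:4), dsg_drug_seq = "1",
    start_dt = c("20200101", "20200101", "20200101", "")
  )
  outc <- data.table::data.table(primaryid = c("1", "3"), outc_cod = "HO")
  cases <- demo_cases(demo, drug = drug, ther = ther, outc = outc)
  s <- tto_summary(cases, cohort_spec("xgeva"))
  expect_equal(s$bins[bin == "0-90d", count], 1L)
  expect_equal(s$bins[bin == ">360d", count], 1L)
  expect_equal(s$bins[bin == "missing_invalid", pct], 50)
  expect_equal(sum(s$bins$count), 4L)
  expect_equal(s$computable$n, 2L)
  expect_equal(s$computable$pct, 50)
  # among the two serious reports only report 1 is computable
  expect_equal(s$computable_serious$n, 1L)
  expect_equal(s$computable_serious$pct, 50)

  # all dates missing -> everything in the missing bin
  demo[, event_dt := ""]
  s2 <- tto_summary(demo_cases(demo, drug = drug, ther = ther),
                    cohort_spec("xgeva"))
  expect_equal(s2$bins[bin == "missing_invalid", pct], 100)
})
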