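printedTable1 <- read.csv(faersignalExtdata("hf_table1_counts.csv"),
                          stringsAsFactors = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("cohort partitions sum to the total and percentages are half-up", {
  demo <- rbind(
    makeDemo("1", sex = "M", age = "70", age_cod = "YR", wt = "80",
             wt_cod = "KG", occp_cod = "MD"),
    makeDemo("2", sex = "F", age = "24", age_cod = "MON", occp_cod = "CN"),
    makeDemo("3", sex = "F", age = "40", age_cod = "YR", wt = "220",
             wt_cod = "LBS", occp_cod = "LW"),
    makeDemo("4", sex = "", age = "90", age_cod = "YR", occp_cod = "PH"),
    makeDemo("5", sex = "M", age = "", wt = "45", wt_cod = "KG"),
    makeDemo("6", sex = "F", age = "17", age_cod = "YR", occp_cod = "OT"))
  outc <- rbind(makeOutc("1", "HO"), makeOutc("1", "DE"), makeOutc("2", "OT"),
                makeOutc("3", "CA"), makeOutc("4", "LT"))
  s <- summarizeDemographics(demo, outc, caseIds = as.character(1:6))
  b <- summaryBands(s)
  for (sec in c("Sex", "Age", "Weight", "Occupation", "Country"))
    expect_equal(sum(b$count[b$section == sec]), 6L, info = sec)

  expect_equal(b$count[b$section == "Sex" & b$band == "Male"], 2L)
  # 24 months -> 2 years -> <18; 17 years -> <18
  expect_equal(b$count[b$section == "Age" & b$band == "<18"], 2L)
  expect_equal(b$count[b$section == "Age" & b$band == ">=85"], 1L)
  expect_equal(b$count[b$section == "Age" & b$band == "Unknown"], 1L)
  # 220 lbs -> 99.8 kg -> [50,100)
  expect_equal(b$count[b$section == "Weight" & b$band == "50 >= and <100"], 2L)
  expect_equal(b$count[b$section == "Occupation" &
                         b$band == "Healthcare professional"], 3L)
  # report 1 contributes to both Hospitalization and Death; CA pools into
  # Other Serious Outcome; reports 5 and 6 have no outcome row
  expect_equal(b$count[b$band == "Hospitalization"], 1L)
  expect_equal(b$count[b$band == "Death"], 1L)
  expect_equal(b$count[b$band == "Other Serious Outcome"], 2L)
  expect_equal(b$count[b$section == "Outcome" & b$band == "Unknown"], 2L)
  expect_gte(sum(b$count[b$section == "Outcome"]), 6L)
  # 2/6 -> 33.333 -> 33.3
  expect_equal(b$pct[b$section == "Sex" & b$band == "Male"], 33.3)
  expect_error(summarizeDemographics(demo, outc, character()), "empty")
})

test_that("published band counts reproduce every printed percentage", {
  s <- characteristicSummary(printedTable1, total = 216362L)
  printedPct <- c(43.6, 46.5, 9.9,                 # sex
                  2.0, 30.8, 31.7, 4.4, 31.0,      # age
                  3.2, 20.6, 5.2, 71.0,            # weight
                  62.3, 32.7, 5.0,                 # occupation
                  46.2, 6.9, 5.1, 3.9, 3.8, 3.2, 30.9,  # country
                  40.7, 29.3, 19.5, 6.7, 0.4, 3.3) # outcomes
  expect_equal(summaryBands(s)$pct, printedPct)
})

test_that("derived ratios from published counts match the published values", {
  s <- characteristicSummary(printedTable1, total = 216362L)
  d <- derivedRatios(s)
  expect_equal(d[["male_female_ratio"]], 0.94)
  expect_equal(d[["pct_over65_known_age"]], 52.37)
})

test_that("derived ratios handle symmetry and undefined denominators", {
  mk <- function(male, female, unknownAge = 0L, over65 = 0L, total = NULL) {
    bands <- data.frame(
      section = c("Sex", "Sex", "Age", "Age", "Age"),
      band = c("Male", "Female", "65 >= and <85", ">=85", "Unknown"),
      count = c(male, female, over65, 0L, unknownAge),
      stringsAsFactors = FALSE)
    characteristicSummary(bands, total = total %||% (male + female))
  }
  expect_equal(derivedRatios(mk(10L, 10L))[["male_female_ratio"]], 1.00)
  expect_true(is.na(derivedRatios(mk(10L, 0L))[["male_female_ratio"]]))
  allUnknown <- mk(5L, 5L, unknownAge = 10L, over65 = 0L, total = 10L)
  expect_true(is.na(derivedRatios(allUnknown)[["pct_over65_known_age"]]))
})
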