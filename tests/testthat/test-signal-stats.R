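test_that("contingency cells come from set arithmetic on distinct reports", {
  expect_equal(buildContingency(c("1", "2"), c("2", "3"), as.character(1:4)),
               c(a = 1L, b = 1L, c = 1L, d = 1L))
  all10 <- as.character(1:10)
  expect_equal(buildContingency(all10, all10, all10),
               c(a = 10L, b = 0L, c = 0L, d = 0L))
  expect_equal(buildContingency(c("1", "2", "3"), c("4", "5"), all10),
               c(a = 0L, b = 3L, c = 2L, d = 5L))
  expect_error(buildContingency(c("1", "99"), c("2"), all10), "subset")
  expect_error(buildContingency(c("1"), c("99"), all10), "subset")
})

test_that("the ROR closed form matches hand-evaluated values", {
  sym <- rorSignal(c(a = 5, b = 5, c = 5, d = 5))
  expect_equal(sym$ror, 1.0)
  expect_lt(sym$ci_low, 1); expect_gt(sym$ci_high, 1)
  expect_false(sym$is_signal)

  # frozen from independent closed-form evaluation
  r <- rorSignal(c(a = 10, b = 90, c = 100, d = 9900), "drug x")
  expect_equal(r$ror, 11.0)
  expect_equal(r$ci_low, 5.5595846399, tolerance = 1e-9)
  expect_equal(r$ci_high, 21.7642158248, tolerance = 1e-9)
  expect_true(r$is_signal)
  expect_equal(r$n_reports, 10)
})

test_that("the signal flag needs both CI lower bound > 1 and a >= 3", {
  weak <- rorSignal(c(a = 2, b = 8, c = 10, d = 980))
  expect_false(weak$is_signal)           # a < 3 regardless of CI
  expect_gt(weak$ci_low, 1)
  wide <- rorSignal(c(a = 3, b = 300, c = 30, d = 3000))
  expect_false(wide$is_signal)           # CI spans 1
})

test_that("zero cells give an undefined ROR and no signal, never an error", {
  for (tab in list(c(a = 0, b = 10, c = 10, d = 100),
                   c(a = 10, b = 0, c = 10, d = 100),
                   c(a = 10, b = 10, c = 0, d = 100),
                   c(a = 10, b = 10, c = 10, d = 0))) {
    r <- rorSignal(tab)
    expect_true(is.na(r$ror) && is.na(r$ci_low) && is.na(r$ci_high))
    expect_false(r$is_signal)
  }
})

test_that("ROR is symmetric in drug and event and conserves the margin", {
  set.seed(90)
  for (i in 1:20) {
    n <- sample(20:200, 1)
    ids <- as.character(seq_len(n))
    drugIds <- sample(ids, sample.int(n, 1))
    caseIds <- sample(ids, sample.int(n, 1))
    tab <- buildContingency(drugIds, caseIds, ids)
    expect_equal(sum(tab), n)
    swapped <- buildContingency(caseIds, drugIds, ids)
    expect_equal(rorSignal(tab)$ror, rorSignal(swapped)$ror)
  }
})

test_that("signals equal a brute-force scan of random small databases", {
  set.seed(123)
  for (i in 1:60) {
    n <- sample(10:200, 1)
    reports <- data.frame(id = as.character(seq_len(n)),
                          drug = runif(n) < runif(1, 0.05, 0.6),
                          event = runif(n) < runif(1, 0.05, 0.6))
    got <- rorSignal(buildContingency(reports$id[reports$drug],
                                      reports$id[reports$event],
                                      reports$id))
    want <- oracleRor(reports)
    expect_equal(got$a, want$a); expect_equal(got$d, want$d)
    if (is.na(want$ror)) {
      expect_true(is.na(got$ror))
    } else {
      expect_equal(got$ror, want$ror, tolerance = 1e-12)
      expect_equal(got$ci_low, want$ci_low, tolerance = 1e-12)
      expect_equal(got$ci_high, want$ci_high, tolerance = 1e-12)
    }
    expect_equal(got$is_signal, want$is_signal)
  }
})

test_that("class-level signals pool same-class reports once", {
  atc <- data.frame(ingredient = c("a", "b", "z"), atc2 = c("L01", "L01", "N06"),
                    stringsAsFactors = FALSE)
  drug <- rbind(
    data.frame(primaryid = "1", ingredient = "a", stringsAsFactors = FALSE),
    data.frame(primaryid = "1", ingredient = "b", stringsAsFactors = FALSE),
    data.frame(primaryid = "2", ingredient = "a", stringsAsFactors = FALSE),
    data.frame(primaryid = "3", ingredient = "q", stringsAsFactors = FALSE))
  allIds <- as.character(1:10)
  caseIds <- c("1", "5")
  cls <- classSignal("L01", atc, drug, caseIds, allIds)
  expect_equal(cls$a + cls$b, 2)   # reports 1 (counted once) and 2
  empty <- classSignal("N06", atc, drug, caseIds, allIds)
  expect_equal(empty$a, 0)
  expect_false(empty$is_signal)

  # a single-drug class reduces to that drug's signal
  soloAtc <- data.frame(ingredient = "q", atc2 = "A02",
                        stringsAsFactors = FALSE)
  solo <- classSignal("A02", soloAtc, drug, caseIds, allIds)
  ids <- drug$primaryid[drug$ingredient == "q"]
  direct <- rorSignal(buildContingency(ids, caseIds, allIds))
  expect_equal(solo[, -1], direct[, -1])
})

test_that("planted odds multipliers are recovered from synthetic databases", {
  drugs <- data.frame(
    ingredient = c("rosiglitazone", "lisinopril", "omeprazole"),
    share = c(0.2, 0.4, 0.4), ror = c(8, 1, 1),
    alpha = 191.02, beta = 0.49, stringsAsFactors = FALSE)
  sim <- generateFaers(simConfig(nCases = 50000L, seed = 19L, drugs = drugs,
                                 duplicateRate = 0, brandedFrac = 0))
  cur <- curateReports(sim$tables)
  allIds <- demoTable(cur)$primaryid
  caseIds <- findCaseIds(reacTable(cur),
                         loadCaseDefinition(faersignalExtdata("hf_pt_list.txt")))
  ps <- normalizeDrugNames(selectPrimarySuspect(drugTable(cur)), character())
  sig <- drugSignalTable(ps, caseIds, allIds)
  ror <- sig$ror[sig$entity == "rosiglitazone"]
  expect_gt(ror, 8 * 0.85); expect_lt(ror, 8 * 1.15)
  expect_true(sig$is_signal[sig$entity == "rosiglitazone"])
})
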