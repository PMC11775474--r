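test_that("planted event probability has exactly r times the background odds", {
  expect_equal(plantProbability(1, 0.05), 0.05)
  # frozen from independent evaluation of r p0 / (1 - p0 + r p0)
  expect_equal(plantProbability(12.51, 0.01), 0.1121872478, tolerance = 1e-9)
  expect_gt(plantProbability(1e9, 0.01), 0.9999)   # r -> Inf pushes p1 -> 1
  set.seed(31)
  for (i in 1:25) {
    r <- exp(runif(1, -3, 5)); p0 <- runif(1, 0.001, 0.9)
    p1 <- plantProbability(r, p0)
    expect_equal((p1 / (1 - p1)) / (p0 / (1 - p0)), r, tolerance = 1e-12)
  }
  expect_error(plantProbability(0, 0.5), "positive")
  expect_error(plantProbability(2, 1), "p0")
})

test_that("generation is deterministic in the seed", {
  cfg <- simConfig(nCases = 300L, seed = 99L)
  a <- generateFaers(cfg); b <- generateFaers(cfg)
  for (acc in list(demoTable, drugTable, reacTable, therTable, outcTable))
    expect_identical(acc(a$tables), acc(b$tables))
  c2 <- generateFaers(simConfig(nCases = 300L, seed = 100L))
  expect_false(identical(demoTable(a$tables), demoTable(c2$tables)))
})

test_that("without duplicates every primaryid and caseid is unique", {
  sim <- generateFaers(simConfig(nCases = 500L, seed = 5L,
                                 duplicateRate = 0))
  demo <- demoTable(sim$tables)
  expect_equal(nrow(demo), 500L)
  expect_false(any(duplicated(demo$primaryid)))
  expect_false(any(duplicated(demo$caseid)))
})

test_that("duplicate versions are earlier or tied and content-identical", {
  sim <- generateFaers(simConfig(nCases = 800L, seed = 6L,
                                 duplicateRate = 0.4, tieRate = 0.3))
  demo <- demoTable(sim$tables)
  dup <- demo$caseid[duplicated(demo$caseid)]
  expect_gt(length(dup), 0L)
  for (cid in head(sort(dup), 25)) {
    v <- demo[demo$caseid == cid, ]
    v <- v[order(v$primaryid), ]
    expect_equal(nrow(v), 2L)
    expect_lt(as.numeric(v$primaryid[1]), as.numeric(v$primaryid[2]))
    expect_true(v$fda_dt[1] <= v$fda_dt[2])
    same <- setdiff(names(v), c("primaryid", "fda_dt"))
    expect_equal(v[1, same], v[2, same], ignore_attr = TRUE)
  }
})

test_that("the target-event rate matches the planted probabilities", {
  drugs <- data.frame(ingredient = c("a", "b"), share = c(0.5, 0.5),
                      ror = c(5, 1), alpha = 100, beta = 1,
                      stringsAsFactors = FALSE)
  sim <- generateFaers(simConfig(nCases = 40000L, seed = 8L, drugs = drugs,
                                 p0 = 0.02, duplicateRate = 0))
  truth <- sim$truth
  byDrug <- tapply(truth$isCase, truth$psIngredient, mean)
  expect_equal(unname(byDrug["a"]), plantProbability(5, 0.02),
               tolerance = 0.1)
  expect_equal(unname(byDrug["b"]), 0.02, tolerance = 0.15)
  reac <- reacTable(sim$tables)
  caseIds <- unique(reac$primaryid[reac$pt == "Cardiac failure"])
  expect_equal(length(caseIds), truth$nTargetCases)
})

test_that("a null database rarely raises a signal", {
  drugs <- data.frame(ingredient = c("a", "b", "c", "d"),
                      share = rep(0.25, 4), ror = 1, alpha = 100, beta = 1,
                      stringsAsFactors = FALSE)
  flagged <- 0L; tested <- 0L
  for (seed in 1:20) {
    sim <- generateFaers(simConfig(nCases = 10000L, seed = seed,
                                   drugs = drugs, duplicateRate = 0,
                                   brandedFrac = 0))
    cur <- deduplicateReports(sim$tables)
    allIds <- demoTable(cur)$primaryid
    reac <- reacTable(cur)
    caseIds <- unique(reac$primaryid[reac$pt == "Cardiac failure"])
    ps <- normalizeDrugNames(selectPrimarySuspect(drugTable(cur)),
                             character())
    sig <- drugSignalTable(ps, caseIds, allIds)
    flagged <- flagged + sum(sig$is_signal)
    tested <- tested + nrow(sig)
  }
  expect_lte(flagged / tested, 0.075)
})
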