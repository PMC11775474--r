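test_that("time-to-onset is event date minus earliest suspect start date", {
  demo <- rbind(makeDemo("1", event_dt = "20200111"),
                makeDemo("2", event_dt = "20200101"),
                makeDemo("3", event_dt = "20200301"),
                makeDemo("4", event_dt = ""),
                makeDemo("5", event_dt = "20200301"))
  ther <- rbind(makeTher("1", start_dt = "20200101"),
                makeTher("2", start_dt = "20200111"),   # event before start
                makeTher("3", start_dt = "20200210"),
                makeTher("3", dsg_drug_seq = "2", start_dt = "20200110"),
                makeTher("5", start_dt = ""))           # missing start
  s <- computeTto(ther, demo, caseIds = as.character(1:5))
  # report 3 uses its earliest start (Jan 10): 51 days
  expect_setequal(onsetValues(s), c(10, 51))
  expect_equal(s@nSourceReports, 5L)
  expect_equal(s@nUsable, 2L)
  expect_equal(sum(s@exclusions), 3L)
})

test_that("therapy rows are restricted to suspect drugs when roles are known", {
  demo <- makeDemo("1", event_dt = "20200201")
  drug <- rbind(makeDrug("1", 1, "C", "A"), makeDrug("1", 2, "PS", "B"))
  ther <- rbind(makeTher("1", 1, "20200101"),    # concomitant: ignored
                makeTher("1", 2, "20200122"))
  s <- computeTto(ther, demo, "1", drug = drug)
  expect_equal(onsetValues(s), 10)
})

test_that("month-precision dates impute day 1; year precision is unusable", {
  demo <- rbind(makeDemo("1", event_dt = "202003"),
                makeDemo("2", event_dt = "2020"))
  ther <- rbind(makeTher("1", start_dt = "202001"),
                makeTher("2", start_dt = "20200101"))
  s <- computeTto(ther, demo, c("1", "2"))
  expect_equal(onsetValues(s), 60)   # Mar 1 - Jan 1
  expect_equal(s@exclusions[["missing_event_date"]], 1L)
})

test_that("median and quartiles follow linear interpolation, whole days", {
  expect_equal(medianIqr(10), c(median = 10, q25 = 10, q75 = 10))
  expect_equal(medianIqr(1:5), c(median = 3, q25 = 2, q75 = 4))
  expect_equal(medianIqr(c(1, 2, 3, 10)), c(median = 3, q25 = 2, q75 = 5))
  expect_error(medianIqr(numeric()), "empty")

  set.seed(55)
  draws <- rweibull(200000, shape = 0.49, scale = 191.02)
  q <- medianIqr(draws)
  for (p in c(0.25, 0.5, 0.75)) {
    want <- weibullQuantile(p, 191.02, 0.49)
    got <- unname(q[c("q25", "median", "q75")[match(p, c(0.25, 0.5, 0.75))]])
    # 5% of the closed form, with slack for the whole-day reporting grid
    expect_lt(abs(got - want), max(0.05 * want, 1))
  }
})

test_that("the Weibull MLE recovers parameters and their closed-form median", {
  set.seed(202)
  x <- rweibull(20000, shape = 0.8, scale = 120)
  fit <- fitWeibull(x)
  expect_equal(fit@beta, 0.8, tolerance = 0.03)
  expect_equal(fit@alpha, 120, tolerance = 0.03)
  # alpha (ln 2)^(1/beta) ~ sample median at large n
  expect_equal(fit@alpha * log(2)^(1 / fit@beta), median(x), tolerance = 0.03)
  expect_true(fit@betaCi[1] <= fit@beta && fit@beta <= fit@betaCi[2])
})

test_that("exponential data fit as shape 1 and classify as random failure", {
  set.seed(203)
  x <- stats::rexp(5000, rate = 1 / 50)
  fit <- fitWeibull(x)
  expect_equal(fit@beta, 1, tolerance = 0.05)
  expect_true(fit@betaCi[1] < 1 && fit@betaCi[2] > 1)
  expect_equal(fit@profile, "random failure")
})

test_that("the MLE agrees with an independent fitter", {
  skip_if_not_installed("fitdistrplus")
  set.seed(204)
  x <- rweibull(3000, shape = 0.49, scale = 191.02)
  fit <- fitWeibull(x)
  ref <- fitdistrplus::fitdist(x, "weibull")
  # two different optimizers: iterates agree loosely, and our optimum is
  # at least as good in log-likelihood
  expect_equal(fit@beta, unname(ref$estimate["shape"]), tolerance = 1e-3)
  expect_equal(fit@alpha, unname(ref$estimate["scale"]), tolerance = 1e-3)
  expect_gte(fit@logLik, ref$loglik - 1e-6)
})

test_that("scaling the sample scales alpha and leaves beta fixed", {
  set.seed(205)
  x <- rweibull(2000, shape = 0.6, scale = 90)
  f1 <- fitWeibull(x); f2 <- fitWeibull(x * 7)
  expect_equal(f2@beta, f1@beta, tolerance = 1e-6)
  expect_equal(f2@alpha, 7 * f1@alpha, tolerance = 1e-6)
})

test_that("small samples are refused and a floor is configurable", {
  expect_error(fitWeibull(rweibull(10, 1, 1)), "below the minimum")
  expect_s4_class(fitWeibull(rweibull(25, 1, 1) + 0.01, minN = 20), "WeibullFit")
})

test_that("profile classification partitions the CI space", {
  expect_equal(classifyProfile(c(0.48, 0.49)), "early failure")
  expect_equal(classifyProfile(c(0.9, 1.1)), "random failure")
  expect_equal(classifyProfile(c(1.4, 1.8)), "wear-out failure")
  expect_equal(classifyProfile(c(1.0, 1.2)), "random failure")  # boundary
  set.seed(206)
  for (i in 1:50) {
    ci <- sort(runif(2, 0.2, 2))
    expect_true(classifyProfile(ci) %in%
                  c("early failure", "random failure", "wear-out failure"))
  }
})

test_that("the shape CI covers the truth in most repeated simulations", {
  set.seed(207)
  covered <- 0L
  nSim <- 100L
  for (i in seq_len(nSim)) {
    x <- rweibull(2000, shape = 0.49, scale = 191.02)
    fit <- fitWeibull(x)
    if (fit@betaCi[1] <= 0.49 && 0.49 <= fit@betaCi[2])
      covered <- covered + 1L
  }
  expect_gte(covered, 90L)
})
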