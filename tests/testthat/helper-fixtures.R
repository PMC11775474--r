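# Fixture builders and independent oracles shared across the suite.

# Minimal DEMO row(s); missing fields default to sensible valid values.
makeDemo <- function(primaryid, caseid = primaryid, fda_dt = "20230101",
                     event_dt = NA_character_, age = NA_character_,
                     age_cod = NA_character_, sex = NA_character_,
                     wt = NA_character_, wt_cod = NA_character_,
                     occp_cod = NA_character_, occr_country = "US") {
  data.frame(primaryid = as.character(primaryid),
             caseid = as.character(caseid),
             fda_dt = fda_dt, event_dt = event_dt, age = age,
             age_cod = age_cod, sex = sex, wt = wt, wt_cod = wt_cod,
             occp_cod = occp_cod, occr_country = occr_country,
             stringsAsFactors = FALSE)
}

makeDrug <- function(primaryid, drug_seq = "1", role_cod = "PS",
                     drugname = "DRUG X") {
  data.frame(primaryid = as.character(primaryid),
             drug_seq = as.character(drug_seq), role_cod = role_cod,
             drugname = drugname, stringsAsFactors = FALSE)
}

makeReac <- function(primaryid, pt) {
  data.frame(primaryid = as.character(primaryid), pt = pt,
             stringsAsFactors = FALSE)
}

makeTher <- function(primaryid, dsg_drug_seq = "1", start_dt = "20230101") {
  data.frame(primaryid = as.character(primaryid),
             dsg_drug_seq = as.character(dsg_drug_seq),
             start_dt = start_dt, stringsAsFactors = FALSE)
}

makeOutc <- function(primaryid, outc_cod = "HO") {
  data.frame(primaryid = as.character(primaryid), outc_cod = outc_cod,
             stringsAsFactors = FALSE)
}

makeTables <- function(demo, drug = makeDrug(demo$primaryid),
                       reac = makeReac(demo$primaryid, "Nausea"),
                       ther = NULL, outc = NULL) {
  args <- list(demo = demo, drug = drug, reac = reac)
  if (!is.null(ther)) args$ther <- ther
  if (!is.null(outc)) args$outc <- outc
  do.call(FaersTables, args)
}

# Independent ROR oracle: scans a report-level truth table (one row per
# report, logical drug/event flags), tallies the 2x2 cells by direct
# enumeration, and evaluates the closed form with its own arithmetic.
# Deliberately shares no code with the package.
oracleRor <- function(reports, zcrit = qnorm(0.975)) {
  a <- sum(reports$drug & reports$event)
  b <- sum(reports$drug & !reports$event)
  cc <- sum(!reports$drug & reports$event)
  d <- sum(!reports$drug & !reports$event)
  if (min(a, b, cc, d) == 0)
    return(list(a = a, b = b, c = cc, d = d, ror = NA_real_,
                ci_low = NA_real_, ci_high = NA_real_, is_signal = FALSE))
  ror <- (a / b) / (cc / d)
  halfwidth <- zcrit * sqrt(1 / a + 1 / b + 1 / cc + 1 / d)
  list(a = a, b = b, c = cc, d = d, ror = ror,
       ci_low = ror * exp(-halfwidth), ci_high = ror * exp(halfwidth),
       is_signal = (ror * exp(-halfwidth) > 1) && (a >= 3))
}

# Closed-form Weibull quantile, the oracle for quartile checks.
weibullQuantile <- function(p, alpha, beta) alpha * (-log(1 - p))^(1 / beta)

# Write a case-definition file and return its path.
writePtList <- function(lines, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, "pts.txt")
  writeLines(lines, path)
  path
}
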