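# Synthetic FAERS generator: multi-table quarterly data with planted
# drug-event odds multipliers, Weibull onset intervals, duplicate case
# versions and Table-1-like demographic marginals, so every pipeline stage
# is testable offline. Onset intervals are drawn first and dates derived
# backward from per-case anchor dates, guaranteeing parseable 8-digit
# dates; a configurable fraction of dates is degraded to month precision
# to exercise the imputation path.

.DEFAULT_BG_PTS <- c("Nausea", "Headache", "Dizziness", "Fatigue",
                     "Rash", "Diarrhoea", "Pyrexia", "Vomiting",
                     "Insomnia", "Arthralgia")

.DEFAULT_DRUGS <- data.frame(
  ingredient = c("rosiglitazone", "doxorubicin", "metformin",
                 "atorvastatin", "lisinopril", "omeprazole"),
  share = c(0.05, 0.05, 0.10, 0.20, 0.25, 0.35),
  ror = c(44.47, 9.00, 1.14, 1, 1, 1),
  alpha = rep(191.02, 6),
  beta = rep(0.49, 6),
  stringsAsFactors = FALSE)

#' Configuration for the synthetic FAERS generator
#'
#' Defaults emulate the study conditions: a database where the target
#' condition (heart failure) has background reporting probability
#' \code{p0 = 0.01}, a drug panel with planted reporting odds multipliers
#' taken from published drug-level signals (rosiglitazone 44.47,
#' doxorubicin 9.00, metformin 1.14, the rest null), pooled onset
#' intervals from Weibull(scale 191.02, shape 0.49), demographic and
#' outcome marginals close to the published Table-1 proportions, and a
#' fraction of cases re-emitted as earlier report versions to exercise
#' deduplication.
#'
#' @param nCases number of distinct cases to simulate.
#' @param seed integer seed; all randomness derives from it.
#' @param drugs data.frame with columns \code{ingredient}, \code{share}
#'   (marketing shares, must sum to 1), \code{ror} (planted odds
#'   multiplier for the target event), \code{alpha}, \code{beta} (onset
#'   Weibull parameters, days).
#' @param p0 background probability that a report is a target-event case.
#' @param duplicateRate fraction of cases emitted as two versions.
#' @param tieRate fraction of duplicates whose extra version shares the
#'   same receipt date (exercises the primaryid tie-break).
#' @param monthPrecisionFrac fraction of start/event dates degraded to
#'   month precision.
#' @param missingEventFrac fraction of reports with no event date.
#' @param missingTherFrac fraction of reports with no therapy row.
#' @param concomitantProb probability a report carries one concomitant
#'   (role C) drug row.
#' @param brandedFrac fraction of drug rows written with a brand name the
#'   bundled name map resolves (exercises normalization).
#' @param targetPt preferred term emitted for target events.
#' @param backgroundPts non-target PT pool.
#' @return a validated list of class \code{"SimConfig"}.
#' @export
simConfig <- function(nCases = 10000L, seed = 1L,
                      drugs = .DEFAULT_DRUGS,
                      p0 = 0.01, duplicateRate = 0.1, tieRate = 0.2,
                      monthPrecisionFrac = 0.05, missingEventFrac = 0.3,
                      missingTherFrac = 0.2, concomitantProb = 0.3,
                      brandedFrac = 0.3,
                      targetPt = "Cardiac failure",
                      backgroundPts = .DEFAULT_BG_PTS) {
  stopifnot(nCases >= 1, p0 > 0, p0 < 1,
            all(c("ingredient", "share", "ror", "alpha", "beta") %in%
                  names(drugs)),
            all(drugs$share >= 0), all(drugs$ror > 0),
            all(drugs$alpha > 0), all(drugs$beta > 0))
  if (abs(sum(drugs$share) - 1) > 1e-8)
    stop("drug shares must sum to 1", call. = FALSE)
  for (p in c(duplicateRate, tieRate, monthPrecisionFrac, missingEventFrac,
              missingTherFrac, concomitantProb, brandedFrac))
    stopifnot(p >= 0, p <= 1)
  structure(list(nCases = as.integer(nCases), seed = as.integer(seed),
                 drugs = drugs, p0 = p0, duplicateRate = duplicateRate,
                 tieRate = tieRate, monthPrecisionFrac = monthPrecisionFrac,
                 missingEventFrac = missingEventFrac,
                 missingTherFrac = missingTherFrac,
                 concomitantProb = concomitantProb,
                 brandedFrac = brandedFrac, targetPt = targetPt,
                 backgroundPts = backgroundPts),
            class = "SimConfig")
}

#' Event probability with planted odds multiplier
#'
#' The probability whose odds are \code{r} times the background odds:
#' \code{p1 = r p0 / (1 - p0 + r p0)}.
#'
#' @param r odds multiplier, > 0.
#' @param p0 background event probability, in (0, 1).
#' @return the planted event probability.
#' @examples
#' plantProbability(1, 0.05)      # identity at r = 1
#' plantProbability(12.51, 0.01)
#' @export
plantProbability <- function(r, p0) {
  if (any(r <= 0)) stop("r must be positive", call. = FALSE)
  if (any(p0 <= 0 | p0 >= 1)) stop("p0 must be in (0,1)", call. = FALSE)
  r * p0 / (1 - p0 + r * p0)
}

.fmtDate <- function(d) format(d, "%Y%m%d")

.degradeToMonth <- function(x, mask) {
  x[mask] <- substr(x[mask], 1L, 6L)
  x
}

# brand names resolved by the bundled name map, for ingredients that have one
.BRAND_OF <- c(rosiglitazone = "AVANDIA", doxorubicin = "ADRIAMYCIN",
               metformin = "GLUCOPHAGE", atorvastatin = "LIPITOR",
               omeprazole = "PRILOSEC")

#' Generate a synthetic FAERS quarter
#'
#' One primary-suspect drug per case (drawn by marketing share);
#' target-event status drawn with probability
#' \code{plantProbability(r_drug, p0)}; onset days drawn from the drug's
#' Weibull and dates derived backward from the event date; demographics
#' and outcomes drawn from Table-1-like marginals; duplicate versions
#' perturb only \code{primaryid}/\code{fda_dt} (content identical), which
#' is exactly what the deduplication rule keys on.
#'
#' @param config a [simConfig()] object.
#' @return list with \code{tables} (a [FaersTables-class]) and
#'   \code{truth} (list: \code{drugs} data.frame echoing the planted
#'   parameters, \code{nCases}, \code{nTargetCases}, \code{targetPt}).
#' @export
generateFaers <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  set.seed(config$seed)
  n <- config$nCases
  dg <- config$drugs

  caseid <- as.character(90000000L + seq_len(n))
  pid <- paste0(caseid, "02")   # version 2 = the keeper

  drugIdx <- sample.int(nrow(dg), n, replace = TRUE, prob = dg$share)
  p1 <- plantProbability(dg$ror, config$p0)[drugIdx]
  isCase <- runif(n) < p1

  tto <- pmax(1, ceiling(rweibull(n, shape = dg$beta[drugIdx],
                                  scale = dg$alpha[drugIdx])))
  eventDate <- as.Date("2023-06-30") - sample.int(365L, n, replace = TRUE) + 1L
  startDate <- eventDate - tto
  fdaDate <- eventDate + 15L + sample.int(60L, n, replace = TRUE)

  eventTxt <- .fmtDate(eventDate)
  startTxt <- .fmtDate(startDate)
  degrade <- runif(n) < config$monthPrecisionFrac
  eventTxt <- .degradeToMonth(eventTxt, runif(n) < config$monthPrecisionFrac)
  startTxt <- .degradeToMonth(startTxt, degrade)
  eventTxt[runif(n) < config$missingEventFrac] <- ""

  # demographics: Table-1-like marginals
  sex <- sample(c("M", "F", ""), n, replace = TRUE,
                prob = c(0.436, 0.465, 0.099))
  ageBand <- sample(1:5, n, replace = TRUE,
                    prob = c(0.020, 0.308, 0.317, 0.044, 0.311))
  age <- c(function(k) runif(k, 1, 17), function(k) runif(k, 18, 64),
           function(k) runif(k, 65, 84), function(k) runif(k, 85, 99),
           function(k) rep(NA_real_, k))
  ageVal <- numeric(n)
  for (b in 1:5) ageVal[ageBand == b] <- age[[b]](sum(ageBand == b))
  ageTxt <- ifelse(is.na(ageVal), "", sprintf("%d", round(ageVal)))
  ageCod <- ifelse(is.na(ageVal), "", "YR")

  wtBand <- sample(1:4, n, replace = TRUE,
                   prob = c(0.032, 0.206, 0.052, 0.710))
  wtVal <- numeric(n)
  wtFun <- c(function(k) runif(k, 30, 49), function(k) runif(k, 50, 99),
             function(k) runif(k, 100, 160), function(k) rep(NA_real_, k))
  for (b in 1:4) wtVal[wtBand == b] <- wtFun[[b]](sum(wtBand == b))
  wtTxt <- ifelse(is.na(wtVal), "", sprintf("%.1f", wtVal))
  wtCod <- ifelse(is.na(wtVal), "", "KG")

  occ <- sample(c("MD", "PH", "OT", "CN", "LW", ""), n, replace = TRUE,
                prob = c(0.338, 0.12, 0.165, 0.307, 0.020, 0.050))
  country <- sample(c("US", "JP", "FR", "CA", "DE", "GB", "IT", "ES"), n,
                    replace = TRUE,
                    prob = c(0.462, 0.069, 0.051, 0.039, 0.038, 0.032,
                             0.155, 0.154))

  demo <- data.frame(
    primaryid = pid, caseid = caseid, fda_dt = .fmtDate(fdaDate),
    event_dt = eventTxt, age = ageTxt, age_cod = ageCod, sex = sex,
    wt = wtTxt, wt_cod = wtCod, occp_cod = occ, occr_country = country,
    stringsAsFactors = FALSE)

  # DRUG: one PS row per case (brand name for a fraction), optional C row
  ing <- dg$ingredient[drugIdx]
  brand <- .BRAND_OF[ing]
  useBrand <- !is.na(brand) & runif(n) < config$brandedFrac
  verbatim <- ifelse(useBrand, brand, toupper(ing))
  drugPs <- data.frame(primaryid = pid, drug_seq = "1", role_cod = "PS",
                       drugname = verbatim, stringsAsFactors = FALSE)
  hasCon <- runif(n) < config$concomitantProb
  conIng <- sample(dg$ingredient, n, replace = TRUE)
  drugCon <- data.frame(primaryid = pid[hasCon],
                        drug_seq = rep("2", sum(hasCon)),
                        role_cod = rep("C", sum(hasCon)),
                        drugname = toupper(conIng[hasCon]),
                        stringsAsFactors = FALSE)
  drug <- rbind(drugPs, drugCon)

  # REAC: target PT for cases; 1-2 background PTs for everyone
  nBg <- 1L + (runif(n) < 0.5)
  bg1 <- sample(config$backgroundPts, n, replace = TRUE)
  bg2 <- sample(config$backgroundPts, n, replace = TRUE)
  reac <- rbind(
    data.frame(primaryid = pid[isCase],
               pt = rep(config$targetPt, sum(isCase)),
               stringsAsFactors = FALSE),
    data.frame(primaryid = pid, pt = bg1, stringsAsFactors = FALSE),
    data.frame(primaryid = pid[nBg == 2L], pt = bg2[nBg == 2L],
               stringsAsFactors = FALSE))

  # THER: start date for the PS drug, for reports that have one
  hasTher <- runif(n) >= config$missingTherFrac
  ther <- data.frame(primaryid = pid[hasTher],
                     dsg_drug_seq = rep("1", sum(hasTher)),
                     start_dt = startTxt[hasTher], stringsAsFactors = FALSE)

  # OUTC: independent Bernoulli per outcome code, Table-1-like rates
  outcP <- c(HO = 0.407, DE = 0.293, OT = 0.195, LT = 0.067, DS = 0.004)
  outc <- do.call(rbind, lapply(names(outcP), function(code) {
    hit <- runif(n) < outcP[[code]]
    data.frame(primaryid = pid[hit], outc_cod = rep(code, sum(hit)),
               stringsAsFactors = FALSE)
  }))

  # duplicate versions: earlier fda_dt (or same, to exercise the
  # primaryid tie-break), smaller primaryid, identical content
  isDup <- runif(n) < config$duplicateRate
  isTie <- isDup & runif(n) < config$tieRate
  if (any(isDup)) {
    dupPid <- paste0(caseid[isDup], "01")
    dupFda <- ifelse(isTie[isDup], .fmtDate(fdaDate[isDup]),
                     .fmtDate(fdaDate[isDup] - 30L))
    dupDemo <- demo[isDup, , drop = FALSE]
    dupDemo$primaryid <- dupPid
    dupDemo$fda_dt <- dupFda
    demo <- rbind(demo, dupDemo)
    dupRows <- function(tab) {
      keep <- tab$primaryid %in% pid[isDup]
      out <- tab[keep, , drop = FALSE]
      out$primaryid <- paste0(substr(out$primaryid, 1L, 8L), "01")
      out
    }
    drug <- rbind(drug, dupRows(drug))
    reac <- rbind(reac, dupRows(reac))
    ther <- rbind(ther, dupRows(ther))
    outc <- rbind(outc, dupRows(outc))
  }

  # canonical in-memory form: NA for missing fields (as the readers
  # produce), rows ordered by primaryid, fresh row names
  ord <- function(tab) {
    tab[] <- lapply(tab, function(v) { v[!is.na(v) & v == ""] <- NA_character_; v })
    out <- tab[order(tab$primaryid, method = "radix"), , drop = FALSE]
    rownames(out) <- NULL
    out
  }
  tables <- FaersTables(demo = ord(demo), drug = ord(drug),
                        reac = ord(reac), ther = ord(ther),
                        outc = ord(outc))
  truth <- list(drugs = dg, nCases = n,
                nTargetCases = sum(isCase), targetPt = config$targetPt,
                psIngredient = ing, isCase = isCase)
  list(tables = tables, truth = truth)
}

#' Write the ground truth of a synthetic quarter as CSV
#'
#' @param truth the \code{truth} element returned by [generateFaers()].
#' @param path destination CSV path.
#' @return \code{path}, invisibly.
#' @export
writeGroundTruth <- function(truth, path) {
  dg <- truth$drugs
  dg$n_cases <- truth$nCases
  dg$n_target_cases <- truth$nTargetCases
  write.csv(dg, path, row.names = FALSE)
  invisible(path)
}
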