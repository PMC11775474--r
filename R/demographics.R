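# Table-1-style cohort characteristics: sex, age bands, weight bands,
# reporter occupation, reporter country (top-k + Others), outcomes.
# Percentages are of the cohort total, half-up rounded to one decimal;
# outcome counts may exceed the total (a report can carry several
# outcomes), every other partition sums exactly to the total.

.OUTCOME_LABELS <- c(HO = "Hospitalization", DE = "Death",
                     LT = "Life-threatening", DS = "Disability",
                     OT = "Other Serious Outcome", CA = "Other Serious Outcome",
                     RI = "Other Serious Outcome")

.bandCount <- function(section, labels, counts, total) {
  data.frame(section = section, band = labels, count = as.integer(counts),
             pct = .roundHalfUp(100 * counts / total, 1L),
             stringsAsFactors = FALSE)
}

#' Summarize cohort characteristics (Table-1 style)
#'
#' Partitions the case cohort by sex, age band (years after unit
#' conversion: <18, 18-<65, 65-<85, >=85, unknown), weight band (kg: <50,
#' 50-<100, >=100, unknown), reporter occupation (healthcare professional:
#' physician/pharmacist/other health-professional; non-healthcare:
#' consumer/lawyer; else unknown), reporter country (top \code{topK} plus
#' Others) and outcome (HO/DE/LT/DS mapped to their labels, OT/CA/RI to
#' Other Serious Outcome, reports with no outcome row to Unknown).
#'
#' @param demo deduplicated DEMO data.frame.
#' @param outc OUTC data.frame.
#' @param caseIds primaryids selecting the cohort.
#' @param topK number of countries listed individually (default 6).
#' @return A [CharacteristicSummary-class] object.
#' @export
summarizeDemographics <- function(demo, outc, caseIds, topK = 6L) {
  d <- demo[demo$primaryid %in% caseIds, , drop = FALSE]
  total <- nrow(d)
  if (!total) stop("empty cohort", call. = FALSE)
  bands <- list()

  sex <- toupper(trimws(ifelse(is.na(d$sex), "", d$sex)))
  sexBand <- ifelse(sex == "M", "Male", ifelse(sex == "F", "Female", "Unknown"))
  bands$sex <- .bandCount("Sex", c("Male", "Female", "Unknown"),
                          c(sum(sexBand == "Male"), sum(sexBand == "Female"),
                            sum(sexBand == "Unknown")), total)

  age <- .ageYears(d$age, d$age_cod)
  ageBand <- cut(age, c(-Inf, 18, 65, 85, Inf), right = FALSE,
                 labels = c("<18", "18 >= and <65", "65 >= and <85", ">=85"))
  ageBand <- as.character(ageBand)
  ageBand[is.na(ageBand)] <- "Unknown"
  ageLabels <- c("<18", "18 >= and <65", "65 >= and <85", ">=85", "Unknown")
  bands$age <- .bandCount("Age", ageLabels,
                          vapply(ageLabels, function(b) sum(ageBand == b),
                                 integer(1)), total)

  wt <- .weightKg(d$wt, d$wt_cod)
  wtBand <- cut(wt, c(-Inf, 50, 100, Inf), right = FALSE,
                labels = c("<50", "50 >= and <100", ">=100"))
  wtBand <- as.character(wtBand)
  wtBand[is.na(wtBand)] <- "Unknown"
  wtLabels <- c("<50", "50 >= and <100", ">=100", "Unknown")
  bands$weight <- .bandCount("Weight", wtLabels,
                             vapply(wtLabels, function(b) sum(wtBand == b),
                                    integer(1)), total)

  occ <- toupper(trimws(ifelse(is.na(d$occp_cod), "", d$occp_cod)))
  occBand <- ifelse(occ %in% c("MD", "PH", "OT", "HP"),
                    "Healthcare professional",
                    ifelse(occ %in% c("CN", "LW"),
                           "Non-healthcare professional", "Unknown"))
  occLabels <- c("Healthcare professional", "Non-healthcare professional",
                 "Unknown")
  bands$occupation <- .bandCount("Occupation", occLabels,
                                 vapply(occLabels, function(b)
                                   sum(occBand == b), integer(1)), total)

  country <- trimws(ifelse(is.na(d$occr_country), "", d$occr_country))
  country[!nzchar(country)] <- "Others"
  tabC <- sort(table(country[country != "Others"]), decreasing = TRUE)
  topNames <- head(names(tabC), topK)
  cBand <- ifelse(country %in% topNames, country, "Others")
  cLabels <- c(topNames, "Others")
  bands$country <- .bandCount("Country", cLabels,
                              vapply(cLabels, function(b) sum(cBand == b),
                                     integer(1)), total)

  oc <- outc[outc$primaryid %in% d$primaryid, , drop = FALSE]
  lab <- .OUTCOME_LABELS[toupper(trimws(ifelse(is.na(oc$outc_cod), "",
                                               oc$outc_cod)))]
  lab[is.na(lab)] <- "Other Serious Outcome"
  pairs <- unique(data.frame(primaryid = oc$primaryid, band = lab,
                             stringsAsFactors = FALSE))
  nUnknown <- sum(!d$primaryid %in% oc$primaryid)
  oLabels <- c("Hospitalization", "Death", "Other Serious Outcome",
               "Life-threatening", "Disability", "Unknown")
  oCounts <- vapply(oLabels, function(b) sum(pairs$band == b), integer(1))
  oCounts["Unknown"] <- oCounts["Unknown"] + nUnknown
  bands$outcome <- .bandCount("Outcome", oLabels, oCounts, total)

  obj <- new("CharacteristicSummary", total = as.integer(total),
             bands = do.call(rbind, c(bands, list(make.row.names = FALSE))),
             derived = numeric())
  obj@derived <- derivedRatios(obj)
  obj
}

#' Build a CharacteristicSummary from pre-tabulated band counts
#'
#' Reconstructs the summary object from a published characteristics table
#' (columns \code{section}, \code{band}, \code{count}), recomputing each
#' percentage from its count and the total. Lets derived ratios and
#' percentage checks be run on printed counts without the raw reports.
#'
#' @param bandCounts data.frame with \code{section}, \code{band},
#'   \code{count}.
#' @param total cohort total report count.
#' @return A [CharacteristicSummary-class] object.
#' @export
characteristicSummary <- function(bandCounts, total) {
  stopifnot(all(c("section", "band", "count") %in% names(bandCounts)))
  bands <- data.frame(section = bandCounts$section, band = bandCounts$band,
                      count = as.integer(bandCounts$count),
                      pct = .roundHalfUp(100 * bandCounts$count / total, 1L),
                      stringsAsFactors = FALSE)
  obj <- new("CharacteristicSummary", total = as.integer(total),
             bands = bands, derived = numeric())
  obj@derived <- derivedRatios(obj)
  obj
}

#' Derived cohort ratios
#'
#' \code{male_female_ratio}: male count / female count, half-up to two
#' decimals. \code{pct_over65_known_age}: percentage of reports aged 65 or
#' older among reports with known age, half-up to two decimals. Either is
#' NA when its denominator is zero or the needed bands are absent.
#'
#' @param summary a [CharacteristicSummary-class].
#' @return named numeric vector.
#' @export
derivedRatios <- function(summary) {
  b <- summary@bands
  cnt <- function(section, band) {
    v <- b$count[b$section == section & b$band == band]
    if (length(v)) sum(v) else NA_integer_
  }
  male <- cnt("Sex", "Male"); female <- cnt("Sex", "Female")
  ratio <- if (!is.na(male) && !is.na(female) && female > 0)
    .roundHalfUp(male / female, 2L) else NA_real_
  over65 <- cnt("Age", "65 >= and <85") + cnt("Age", ">=85")
  unknownAge <- cnt("Age", "Unknown")
  knownAge <- summary@total - unknownAge
  pct65 <- if (!is.na(over65) && !is.na(knownAge) && knownAge > 0)
    .roundHalfUp(100 * over65 / knownAge, 2L) else NA_real_
  c(male_female_ratio = ratio, pct_over65_known_age = pct65)
}

#' Write a CharacteristicSummary as CSV
#'
#' Band rows first, then the derived ratios as their own section.
#'
#' @param summary a [CharacteristicSummary-class].
#' @param path destination CSV path.
#' @return \code{path}, invisibly.
#' @export
writeDemographics <- function(summary, path) {
  b <- summary@bands
  d <- summary@derived
  extra <- data.frame(section = "Derived", band = names(d),
                      count = NA_integer_, pct = unname(d),
                      stringsAsFactors = FALSE)
  write.csv(rbind(b, extra), path, row.names = FALSE)
  invisible(path)
}
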