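# Report curation: drop incomplete/incorrect reports, then keep exactly one
# version per case. "Incomplete" = missing primaryid or caseid. "Incorrect" =
# fda_dt missing or unparseable, or age/weight outside plausibility bounds
# after unit conversion (age >= 150 years, weight >= 700 kg).

.AGE_TO_YEARS <- c(DEC = 10, YR = 1, MON = 1 / 12, WK = 1 / 52,
                   DY = 1 / 365.25, HR = 1 / 8766)

# Age in years; NA when value or (unknown) unit is missing/non-numeric.
# A missing unit code is read as years, the FAERS convention.
.ageYears <- function(age, age_cod) {
  val <- suppressWarnings(as.numeric(age))
  unit <- toupper(trimws(ifelse(is.na(age_cod), "YR", age_cod)))
  mult <- .AGE_TO_YEARS[unit]
  mult[is.na(mult)] <- NA_real_
  val * mult
}

.weightKg <- function(wt, wt_cod) {
  val <- suppressWarnings(as.numeric(wt))
  unit <- toupper(trimws(ifelse(is.na(wt_cod), "KG", wt_cod)))
  mult <- c(KG = 1, KGS = 1, LBS = 0.45359237, IB = 0.45359237)[unit]
  mult[is.na(mult)] <- NA_real_
  val * mult
}

.filterToReports <- function(x, keepIds) {
  for (nm in c("drug", "reac", "ther", "outc")) {
    tab <- slot(x, nm)
    tab <- tab[tab$primaryid %in% keepIds, , drop = FALSE]
    rownames(tab) <- NULL
    slot(x, nm) <- tab
  }
  x
}

#' Drop incomplete and incorrect reports
#'
#' Removes DEMO rows missing \code{primaryid} or \code{caseid}
#' (incomplete) and rows whose \code{fda_dt} is missing or unparseable or
#' whose age/weight violate plausibility bounds after unit conversion
#' (incorrect). Detail rows (DRUG/REAC/THER/OUTC) of dropped reports are
#' removed with them. Drop counts accumulate in [curationStats()].
#'
#' @param x a [FaersTables-class] object.
#' @return the filtered \code{FaersTables}.
#' @export
dropInvalidReports <- function(x) {
  demo <- x@demo
  nIn <- nrow(demo)
  incomplete <- is.na(demo$primaryid) | is.na(demo$caseid)

  fda <- parseFaersDate(demo$fda_dt, onError = "na")
  badDate <- is.na(fda$precision) | !fda$ok
  age <- .ageYears(demo$age, demo$age_cod)
  wt <- .weightKg(demo$wt, demo$wt_cod)
  incorrect <- !incomplete &
    (badDate | (!is.na(age) & (age < 0 | age >= 150)) |
       (!is.na(wt) & (wt < 0 | wt >= 700)))

  keep <- !incomplete & !incorrect
  demo <- demo[keep, , drop = FALSE]
  rownames(demo) <- NULL
  x@demo <- demo
  x <- .filterToReports(x, x@demo$primaryid)
  x@curation <- rbind(x@curation, data.frame(
    n_input = nIn,
    n_dropped_incomplete = sum(incomplete),
    n_dropped_incorrect = sum(incorrect),
    n_dropped_duplicate = 0L,
    n_output = sum(keep), stringsAsFactors = FALSE))
  x
}

#' Deduplicate case versions
#'
#' FAERS re-publishes updated versions of a case under the same
#' \code{caseid}. One report per case survives: the version with the most
#' recent \code{fda_dt} (digit-string order, so partial dates rank below
#' full dates sharing their prefix); ties on \code{fda_dt} keep the
#' numerically largest \code{primaryid}. All detail rows of discarded
#' versions are discarded with them. Idempotent.
#'
#' @param x a [FaersTables-class] object with valid ids and receipt dates
#'   (run [dropInvalidReports()] first).
#' @return the deduplicated \code{FaersTables}.
#' @export
deduplicateReports <- function(x) {
  demo <- x@demo
  nIn <- nrow(demo)
  if (nIn) {
    key <- .dateKey(demo$fda_dt)
    pidNum <- suppressWarnings(as.numeric(demo$primaryid))
    # order: per caseid, best version first
    ord <- order(demo$caseid, key, pidNum, demo$primaryid,
                 decreasing = c(FALSE, TRUE, TRUE, TRUE), method = "radix")
    demo <- demo[ord, , drop = FALSE]
    keep <- !duplicated(demo$caseid)
    demo <- demo[keep, , drop = FALSE]
    demo <- demo[order(demo$primaryid, method = "radix"), , drop = FALSE]
    rownames(demo) <- NULL
  }
  nDup <- nIn - nrow(demo)
  x@demo <- demo
  x <- .filterToReports(x, demo$primaryid)
  x@curation <- rbind(x@curation, data.frame(
    n_input = nIn, n_dropped_incomplete = 0L, n_dropped_incorrect = 0L,
    n_dropped_duplicate = nDup, n_output = nrow(demo),
    stringsAsFactors = FALSE))
  x
}

#' Run the full curation sequence
#'
#' [dropInvalidReports()] followed by [deduplicateReports()].
#'
#' @param x a [FaersTables-class] object.
#' @return the curated \code{FaersTables}.
#' @export
curateReports <- function(x) deduplicateReports(dropInvalidReports(x))

#' Write accumulated curation statistics as CSV
#'
#' One row per curation step with the input, per-category drop, and output
#' counts; \code{n_input = n_output + drops} on every row.
#'
#' @param x a curated [FaersTables-class] object.
#' @param path destination CSV path.
#' @return \code{path}, invisibly.
#' @export
writeCurationStats <- function(x, path) {
  write.csv(x@curation, path, row.names = FALSE)
  invisible(path)
}
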