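# Reporting odds ratio (ROR) disproportionality against the whole
# deduplicated database. 2x2 table per drug-event combination:
#       event   no event
# drug    a        b
# other   c        d
# ROR = (a*d)/(b*c); 95% CI = exp(ln ROR +/- 1.96*sqrt(1/a+1/b+1/c+1/d)).
# Signal: CI lower bound > 1 AND a >= 3. Zero cells yield an undefined ROR
# (no continuity correction) and no signal. No multiplicity adjustment.

#' Build a 2x2 drug-event contingency table
#'
#' Counting unit is the distinct deduplicated report. \code{a} = reports
#' with the target drug and the target event, \code{b} = drug without
#' event, \code{c} = event without drug, \code{d} = neither;
#' \code{a+b+c+d} equals the database size.
#'
#' @param targetIds primaryids of reports carrying the target drug (or
#'   drug class).
#' @param caseIds primaryids of target-event reports.
#' @param allIds primaryids of the whole deduplicated database.
#' @return named integer vector \code{c(a=, b=, c=, d=)}.
#' @export
buildContingency <- function(targetIds, caseIds, allIds) {
  targetIds <- unique(targetIds); caseIds <- unique(caseIds)
  allIds <- unique(allIds)
  if (!all(targetIds %in% allIds))
    stop("targetIds must be a subset of allIds", call. = FALSE)
  if (!all(caseIds %in% allIds))
    stop("caseIds must be a subset of allIds", call. = FALSE)
  a <- sum(targetIds %in% caseIds)
  b <- length(targetIds) - a
  cc <- length(caseIds) - a
  d <- length(allIds) - a - b - cc
  c(a = a, b = b, c = cc, d = d)
}

#' ROR disproportionality signal for one 2x2 table
#'
#' When any cell is zero the ROR and CI are undefined (reported NA) and
#' the signal flag is FALSE; otherwise the signal flag is TRUE iff the CI
#' lower bound exceeds 1 and \code{a >= 3}.
#'
#' @param tab named vector from [buildContingency()] (names a, b, c, d).
#' @param entity label for the drug or class (default "").
#' @param level confidence level (default 0.95).
#' @return one-row data.frame: \code{entity}, \code{a}, \code{b}, \code{c},
#'   \code{d}, \code{n_reports} (= a), \code{ror}, \code{ci_low},
#'   \code{ci_high}, \code{is_signal}.
#' @examples
#' rorSignal(c(a = 10, b = 90, c = 100, d = 9900), "example drug")
#' @export
rorSignal <- function(tab, entity = "", level = 0.95) {
  a <- as.numeric(tab[["a"]]); b <- as.numeric(tab[["b"]])
  cc <- as.numeric(tab[["c"]]); d <- as.numeric(tab[["d"]])
  if (any(c(a, b, cc, d) < 0) || any(is.na(c(a, b, cc, d))))
    stop("contingency cells must be non-negative counts", call. = FALSE)
  z <- stats::qnorm(1 - (1 - level) / 2)
  if (any(c(a, b, cc, d) == 0)) {
    ror <- lo <- hi <- NA_real_
    sig <- FALSE
  } else {
    ror <- (a * d) / (b * cc)
    se <- sqrt(1 / a + 1 / b + 1 / cc + 1 / d)
    lo <- exp(log(ror) - z * se)
    hi <- exp(log(ror) + z * se)
    sig <- (lo > 1) && (a >= 3)
  }
  data.frame(entity = entity, a = a, b = b, c = cc, d = d,
             n_reports = a, ror = ror, ci_low = lo, ci_high = hi,
             is_signal = sig, stringsAsFactors = FALSE)
}

.bindSignalRows <- function(rows) {
  out <- if (length(rows))
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  else rorSignal(c(a = 1, b = 1, c = 1, d = 1), "")[0, ]
  out[order(-out$n_reports, out$entity, method = "radix"), , drop = FALSE]
}

# distinct reports per ingredient, as a named list of primaryid vectors
.reportsByIngredient <- function(drug, ingredients) {
  dt <- data.table::as.data.table(drug[, c("primaryid", "ingredient")])
  dt <- unique(dt[dt$ingredient %in% ingredients])
  split(dt$primaryid, dt$ingredient)
}

#' Drug-level ROR signal table
#'
#' One [rorSignal()] row per ingredient, each against the same whole
#' database background.
#'
#' @param drug normalized primary-suspect DRUG data.frame (from
#'   deduplicated reports).
#' @param caseIds target-event primaryids.
#' @param allIds all deduplicated primaryids.
#' @param ingredients ingredients to evaluate; defaults to all in
#'   \code{drug}.
#' @return data.frame of signal rows, sorted by \code{n_reports}
#'   descending then entity.
#' @export
drugSignalTable <- function(drug, caseIds, allIds,
                            ingredients = sort(unique(drug$ingredient))) {
  byIng <- .reportsByIngredient(drug, ingredients)
  rows <- lapply(ingredients, function(ing) {
    ids <- byIng[[ing]]
    if (is.null(ids)) ids <- character()
    rorSignal(buildContingency(ids, caseIds, allIds), entity = ing)
  })
  .bindSignalRows(rows)
}

#' ATC class-level ROR signal
#'
#' The target set is the distinct reports having at least one
#' primary-suspect ingredient mapping to the class; a report with two
#' drugs of the same class counts once.
#'
#' @param classCode ATC level-2 code (e.g. \code{"A10"}).
#' @param atcMap data.frame from [loadAtcMap()].
#' @param drug normalized primary-suspect DRUG data.frame.
#' @param caseIds target-event primaryids.
#' @param allIds all deduplicated primaryids.
#' @return one-row data.frame as [rorSignal()].
#' @export
classSignal <- function(classCode, atcMap, drug, caseIds, allIds) {
  ings <- atcMap$ingredient[atcMap$atc2 == classCode]
  ids <- unique(drug$primaryid[drug$ingredient %in% ings])
  rorSignal(buildContingency(ids, caseIds, allIds), entity = classCode)
}

#' ATC class-level ROR signal table
#'
#' @param drug normalized primary-suspect DRUG data.frame.
#' @param atcMap data.frame from [loadAtcMap()].
#' @param caseIds target-event primaryids.
#' @param allIds all deduplicated primaryids.
#' @param classes class codes to evaluate; defaults to every class that
#'   any ingredient in \code{drug} maps to.
#' @return data.frame of signal rows, sorted by \code{n_reports}
#'   descending then entity.
#' @export
classSignalTable <- function(drug, atcMap, caseIds, allIds, classes = NULL) {
  if (is.null(classes)) {
    present <- atcMap$ingredient %in% unique(drug$ingredient)
    classes <- sort(unique(atcMap$atc2[present]))
  }
  rows <- lapply(classes, classSignal, atcMap = atcMap, drug = drug,
                 caseIds = caseIds, allIds = allIds)
  .bindSignalRows(rows)
}
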