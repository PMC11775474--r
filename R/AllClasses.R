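#' @import methods
#' @importFrom stats median optim quantile rbinom runif rweibull sd setNames
#' @importFrom utils head read.delim write.csv packageVersion
#' @importFrom data.table as.data.table data.table setorderv .N
NULL

.datatable.aware <- TRUE

# Required minimal field set per FAERS table; header names are matched
# case-insensitively after trimming.
.FAERS_TABLES <- c("DEMO", "DRUG", "REAC", "THER", "OUTC")

.REQUIRED_FIELDS <- list(
  DEMO = c("primaryid", "caseid", "fda_dt", "event_dt", "age", "age_cod",
           "sex", "wt", "wt_cod", "occp_cod", "occr_country"),
  DRUG = c("primaryid", "drug_seq", "role_cod", "drugname"),
  REAC = c("primaryid", "pt"),
  THER = c("primaryid", "dsg_drug_seq", "start_dt"),
  OUTC = c("primaryid", "outc_cod")
)

.emptyIngestLog <- function() {
  data.frame(table = character(), file = character(),
             rows_in = integer(), rows_kept = integer(),
             rows_dropped = integer(), stringsAsFactors = FALSE)
}

.emptyCurationStats <- function() {
  data.frame(n_input = integer(), n_dropped_incomplete = integer(),
             n_dropped_incorrect = integer(), n_dropped_duplicate = integer(),
             n_output = integer(), stringsAsFactors = FALSE)
}

#' Container for one quarter (or one database) of FAERS-style tables
#'
#' Holds the five report tables keyed by \code{primaryid}: \code{DEMO}
#' (demographic and administrative information, one row per report version),
#' \code{DRUG} (drug records with role codes), \code{REAC} (MedDRA preferred
#' terms for the adverse events), \code{THER} (therapy start dates) and
#' \code{OUTC} (outcome codes). An ingest log records per-file row
#' conservation and a curation table records report drops (incomplete /
#' incorrect / duplicate) as curation steps are applied.
#'
#' @slot demo,drug,reac,ther,outc data.frames with at least the required
#'   FAERS fields for the respective table (lower-case column names).
#' @slot ingest data.frame with columns \code{table}, \code{file},
#'   \code{rows_in}, \code{rows_kept}, \code{rows_dropped}.
#' @slot curation data.frame with columns \code{n_input},
#'   \code{n_dropped_incomplete}, \code{n_dropped_incorrect},
#'   \code{n_dropped_duplicate}, \code{n_output}; empty until curation runs.
#'
#' @seealso [loadFaersQuarter()], [dropInvalidReports()],
#'   [deduplicateReports()]
#' @export
setClass("FaersTables",
  representation(demo = "data.frame", drug = "data.frame",
                 reac = "data.frame", ther = "data.frame",
                 outc = "data.frame", ingest = "data.frame",
                 curation = "data.frame"),
  prototype(ingest = .emptyIngestLog(), curation = .emptyCurationStats())
)

setValidity("FaersTables", function(object) {
  msgs <- character()
  for (nm in .FAERS_TABLES) {
    tab <- slot(object, tolower(nm))
    missing <- setdiff(.REQUIRED_FIELDS[[nm]], names(tab))
    if (length(missing))
      msgs <- c(msgs, sprintf("%s table lacks required field(s): %s",
                              nm, paste(missing, collapse = ", ")))
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a FaersTables object from five data.frames
#'
#' @param demo,drug,reac,ther,outc data.frames carrying at least the
#'   required fields of the corresponding FAERS table (lower-case names).
#'   \code{ther} and \code{outc} default to empty tables.
#' @param ingest optional ingest log as produced by [readFaersTable()].
#' @return A [FaersTables-class] object.
#' @export
FaersTables <- function(demo, drug, reac,
                        ther = .emptyFaersTable("THER"),
                        outc = .emptyFaersTable("OUTC"),
                        ingest = .emptyIngestLog()) {
  new("FaersTables", demo = demo, drug = drug, reac = reac,
      ther = ther, outc = outc, ingest = ingest,
      curation = .emptyCurationStats())
}

.emptyFaersTable <- function(name) {
  cols <- .REQUIRED_FIELDS[[name]]
  out <- as.data.frame(setNames(rep(list(character()), length(cols)), cols),
                       stringsAsFactors = FALSE)
  out
}

#' @describeIn FaersTables-class the DEMO table (one row per report version)
#' @param x a \code{FaersTables} object
#' @export
demoTable <- function(x) x@demo

#' @describeIn FaersTables-class the DRUG table
#' @export
drugTable <- function(x) x@drug

#' @describeIn FaersTables-class the REAC table
#' @export
reacTable <- function(x) x@reac

#' @describeIn FaersTables-class the THER table
#' @export
therTable <- function(x) x@ther

#' @describeIn FaersTables-class the OUTC table
#' @export
outcTable <- function(x) x@outc

#' @describeIn FaersTables-class per-file row-conservation log
#' @export
ingestLog <- function(x) x@ingest

#' @describeIn FaersTables-class curation drop counts accumulated so far
#' @export
curationStats <- function(x) x@curation

setMethod("show", "FaersTables", function(object) {
  cat("FaersTables object\n")
  for (nm in .FAERS_TABLES)
    cat(sprintf("  %s: %d row(s)\n", nm, nrow(slot(object, tolower(nm)))))
  if (nrow(object@curation)) {
    cs <- object@curation
    cat(sprintf("  curation: %d in, %d incomplete, %d incorrect, %d duplicate, %d out\n",
                sum(cs$n_input), sum(cs$n_dropped_incomplete),
                sum(cs$n_dropped_incorrect), sum(cs$n_dropped_duplicate),
                cs$n_output[nrow(cs)]))
  }
  invisible(NULL)
})

#' Case definition: an SMQ-style preferred-term list
#'
#' A named set of normalized MedDRA preferred terms (PTs), optionally with
#' their numeric PT codes, defining the target condition for case retrieval
#' (narrow-scope SMQ style: exact terms only, no hierarchy traversal).
#'
#' @slot name label, e.g. \code{"cardiac failure SMQ narrow"}.
#' @slot terms character vector of normalized (trimmed, case-folded) PT names.
#' @slot codes numeric vector of MedDRA PT codes (possibly empty).
#'
#' @seealso [loadCaseDefinition()], [ahfDefinition()], [findCaseIds()]
#' @export
setClass("CaseDefinition",
  representation(name = "character", terms = "character", codes = "numeric"))

setValidity("CaseDefinition", function(object) {
  if (length(object@terms) == 0L && length(object@codes) == 0L)
    return("case definition must carry at least one PT term or code")
  if (any(object@terms != .normalizePt(object@terms)))
    return("PT terms must be normalized (trimmed, case-folded)")
  TRUE
})

setMethod("show", "CaseDefinition", function(object) {
  cat(sprintf("CaseDefinition '%s': %d PT term(s), %d code(s)\n",
              object@name, length(object@terms), length(object@codes)))
  invisible(NULL)
})

#' Time-to-onset sample
#'
#' Positive day counts from suspect-drug initiation to event onset, with
#' bookkeeping of how many source reports were examined and why reports
#' were excluded (missing or year-precision dates, non-positive intervals).
#'
#' @slot values numeric vector of onset intervals, days, all > 0.
#' @slot nSourceReports number of case reports examined.
#' @slot nUsable length of \code{values}.
#' @slot exclusions named integer vector of exclusion counts.
#'
#' @seealso [computeTto()], [medianIqr()], [fitWeibull()]
#' @export
setClass("OnsetSample",
  representation(values = "numeric", nSourceReports = "integer",
                 nUsable = "integer", exclusions = "integer"))

setValidity("OnsetSample", function(object) {
  if (any(object@values <= 0)) return("onset values must be positive")
  if (object@nUsable != length(object@values))
    return("nUsable must equal length(values)")
  if (object@nUsable > object@nSourceReports)
    return("nUsable cannot exceed nSourceReports")
  TRUE
})

#' @describeIn OnsetSample-class the onset intervals in days
#' @param x an \code{OnsetSample}
#' @export
onsetValues <- function(x) x@values

setMethod("show", "OnsetSample", function(object) {
  cat(sprintf("OnsetSample: %d usable interval(s) from %d report(s)\n",
              object@nUsable, object@nSourceReports))
  if (any(object@exclusions > 0L)) {
    ex <- object@exclusions[object@exclusions > 0L]
    cat("  excluded:", paste(sprintf("%s=%d", names(ex), ex), collapse = ", "),
        "\n")
  }
  invisible(NULL)
})

#' Maximum-likelihood Weibull fit of a time-to-onset sample
#'
#' Two-parameter Weibull fit with scale \eqn{\alpha} (days) and shape
#' \eqn{\beta}; 95\% Wald intervals computed on the log-parameter scale from
#' the observed information and transformed back. The shape CI classifies
#' the hazard profile: early failure (CI entirely below 1), random failure
#' (CI contains 1), wear-out failure (CI entirely above 1).
#'
#' @slot alpha,beta point estimates (scale in days; shape dimensionless).
#' @slot alphaCi,betaCi length-2 numeric 95\% intervals.
#' @slot n sample size used.
#' @slot logLik maximized log-likelihood.
#' @slot profile one of \code{"early failure"}, \code{"random failure"},
#'   \code{"wear-out failure"}.
#'
#' @seealso [fitWeibull()], [classifyProfile()]
#' @export
setClass("WeibullFit",
  representation(alpha = "numeric", beta = "numeric",
                 alphaCi = "numeric", betaCi = "numeric",
                 n = "integer", logLik = "numeric", profile = "character"))

setValidity("WeibullFit", function(object) {
  if (object@alpha <= 0 || object@beta <= 0)
    return("alpha and beta must be positive")
  if (any(object@alphaCi <= 0) || any(object@betaCi <= 0))
    return("CI bounds must be positive")
  if (diff(object@alphaCi) < 0 || diff(object@betaCi) < 0)
    return("CI bounds must be ordered")
  if (!object@profile %in% c("early failure", "random failure",
                             "wear-out failure"))
    return("unknown failure profile label")
  TRUE
})

setMethod("show", "WeibullFit", function(object) {
  cat(sprintf("WeibullFit (n = %d)\n", object@n))
  cat(sprintf("  scale alpha: %.2f (%.2f-%.2f) days\n",
              object@alpha, object@alphaCi[1], object@alphaCi[2]))
  cat(sprintf("  shape beta:  %.3f (%.3f-%.3f)\n",
              object@beta, object@betaCi[1], object@betaCi[2]))
  cat(sprintf("  profile: %s\n", object@profile))
  invisible(NULL)
})

#' Table-1-style characteristic summary of a report cohort
#'
#' Band counts and percentages for sex, age, weight, reporter occupation,
#' reporter country and outcomes, plus derived ratios (male-to-female ratio,
#' percentage over 65 among known-age reports). Outcome counts may exceed
#' the total because one report can carry several outcomes; all other
#' partitions sum exactly to the total.
#'
#' @slot total cohort report count.
#' @slot bands data.frame with columns \code{section}, \code{band},
#'   \code{count}, \code{pct} (percentage of total, half-up, 1 decimal).
#' @slot derived named numeric vector of derived ratios.
#'
#' @seealso [summarizeDemographics()], [derivedRatios()]
#' @export
setClass("CharacteristicSummary",
  representation(total = "integer", bands = "data.frame",
                 derived = "numeric"))

#' @describeIn CharacteristicSummary-class the band table
#' @param x a \code{CharacteristicSummary}
#' @export
summaryBands <- function(x) x@bands

setMethod("show", "CharacteristicSummary", function(object) {
  cat(sprintf("CharacteristicSummary: %d report(s)\n", object@total))
  for (sec in unique(object@bands$section)) {
    cat(" ", sec, "\n")
    b <- object@bands[object@bands$section == sec, ]
    for (i in seq_len(nrow(b)))
      cat(sprintf("    %-28s %9d (%.1f%%)\n", b$band[i], b$count[i], b$pct[i]))
  }
  if (length(object@derived)) {
    cat("  derived:\n")
    for (nm in names(object@derived))
      cat(sprintf("    %-28s %s\n", nm, format(object@derived[[nm]])))
  }
  invisible(NULL)
})
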