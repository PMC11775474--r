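# End-to-end workflow: load -> drop invalid -> deduplicate -> case finding
# (HF and AHF definitions) -> primary-suspect selection -> name
# normalization -> top-N ranking -> drug- and class-level ROR signals ->
# time-to-onset (median/IQR, Weibull, failure profile) -> demographics.
# All output CSVs are deterministically sorted; the manifest carries the
# config echo and stage counts so runs reconcile and diff cleanly.

#' Path of a bundled resource file
#'
#' Bundled resources: \code{hf_pt_list.txt} (illustrative heart-failure PT
#' list), \code{name_map.tsv} (brand/international/misspelled name to
#' ingredient), \code{atc2_map.tsv} (ingredient to ATC level-2),
#' \code{hf_table1_counts.csv} (published cohort characteristic counts).
#'
#' @param file file name under the package's \code{extdata}.
#' @return absolute path.
#' @export
faersignalExtdata <- function(file) {
  p <- system.file("extdata", file, package = "faersignal")
  if (!nzchar(p)) stop(sprintf("no bundled file '%s'", file), call. = FALSE)
  p
}

.writeSorted <- function(df, path) {
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' @param input a [FaersTables-class] object, or a directory containing a
#'   quarter (then \code{tag} is required).
#' @param tag quarter tag when \code{input} is a directory.
#' @param hfDefinition [CaseDefinition-class] for the main condition;
#'   defaults to the bundled illustrative heart-failure PT list.
#' @param ahfDef [CaseDefinition-class] for the acute subset; defaults to
#'   [ahfDefinition()]. Set NULL to skip the second pass.
#' @param nameMap named vector from [loadNameMap()]; defaults to the
#'   bundled map.
#' @param atcMap data.frame from [loadAtcMap()]; defaults to the bundled
#'   map.
#' @param topN number of top drugs to rank and test (default 50).
#' @param outDir output directory; NULL for no files (results only).
#' @param minWeibullN minimum usable onset sample for the Weibull fit.
#' @return (invisibly) a list with the curated tables, per-definition
#'   results (caseIds, topDrugs, drugSignals, classSignals, tto row,
#'   demographics) and the manifest.
#' @export
runFaersPipeline <- function(input, tag = NULL,
                             hfDefinition = loadCaseDefinition(
                               faersignalExtdata("hf_pt_list.txt"),
                               name = "heart failure (illustrative)"),
                             ahfDef = ahfDefinition(),
                             nameMap = loadNameMap(
                               faersignalExtdata("name_map.tsv")),
                             atcMap = loadAtcMap(
                               faersignalExtdata("atc2_map.tsv")),
                             topN = 50L, outDir = NULL, minWeibullN = 30L) {
  tables <- if (is(input, "FaersTables")) input
            else loadFaersQuarter(input, tag)
  nRaw <- nrow(tables@demo)
  curated <- curateReports(tables)
  allIds <- curated@demo$primaryid

  ps <- selectPrimarySuspect(curated@drug)
  psNorm <- normalizeDrugNames(ps, nameMap)

  defs <- list(hf = hfDefinition)
  if (!is.null(ahfDef)) defs$ahf <- ahfDef

  results <- list()
  for (label in names(defs)) {
    def <- defs[[label]]
    caseIds <- findCaseIds(curated@reac, def)
    top <- rankTopDrugs(psNorm, caseIds, n = topN)
    drugSig <- drugSignalTable(psNorm, caseIds, allIds,
                               ingredients = top$ingredient)
    classes <- sort(unique(atcMap$atc2[
      atcMap$ingredient %in% top$ingredient]))
    classSig <- classSignalTable(psNorm, atcMap, caseIds, allIds,
                                 classes = classes)
    tto <- computeTto(curated@ther, curated@demo, caseIds,
                      drug = curated@drug)
    ttoRow <- ttoSummaryRow(tto, label, minN = minWeibullN)
    demog <- if (length(caseIds))
      summarizeDemographics(curated@demo, curated@outc, caseIds) else NULL
    results[[label]] <- list(definition = def@name, caseIds = caseIds,
                             topDrugs = top, drugSignals = drugSig,
                             classSignals = classSig, onset = tto,
                             ttoRow = ttoRow, demographics = demog)
  }

  manifest <- list(
    package = "faersignal",
    version = as.character(packageVersion("faersignal")),
    top_n = as.integer(topN),
    stages = list(
      reports_raw = nRaw,
      curation = curated@curation,
      reports_deduplicated = length(allIds),
      ps_records = nrow(ps),
      ps_records_normalized = nrow(psNorm),
      ps_dropped_ambiguous = attr(psNorm, "nDroppedAmbiguous")),
    cases = lapply(results, function(r) length(r$caseIds)))

  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    writeCurationStats(curated, file.path(outDir, "curation_stats.csv"))
    for (label in names(results)) {
      r <- results[[label]]
      .writeSorted(r$topDrugs, file.path(outDir,
                                         sprintf("top_drugs_%s.csv", label)))
      .writeSorted(r$drugSignals,
                   file.path(outDir, sprintf("drug_signals_%s.csv", label)))
      .writeSorted(r$classSignals,
                   file.path(outDir, sprintf("class_signals_%s.csv", label)))
      .writeSorted(r$ttoRow, file.path(outDir, sprintf("tto_%s.csv", label)))
      if (!is.null(r$demographics))
        writeDemographics(r$demographics,
                          file.path(outDir,
                                    sprintf("demographics_%s.csv", label)))
    }
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  invisible(list(tables = curated, results = results, manifest = manifest))
}

.cliUsage <- function() {
  paste(
    "usage: faersignal <subcommand> [flags]",
    "",
    "subcommands:",
    "  simulate --out DIR [--seed N] [--n-cases N] [--tag TAG]",
    "      generate a synthetic FAERS quarter (five $-delimited tables",
    "      plus ground_truth.csv)",
    "  run-all --in DIR --tag TAG --out DIR [--top-n N] [--pt-list FILE]",
    "      run the full pipeline on a quarter directory",
    sep = "\n")
}

.cliFlags <- function(args) {
  flags <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[[i]]
    if (!startsWith(a, "--"))
      stop(sprintf("unexpected argument '%s'", a), call. = FALSE)
    if (i == length(args))
      stop(sprintf("flag '%s' needs a value", a), call. = FALSE)
    flags[[substring(a, 3L)]] <- args[[i + 1L]]
    i <- i + 2L
  }
  flags
}

#' Command-line entry point
#'
#' Subcommands: \code{simulate} (write a synthetic quarter) and
#' \code{run-all} (full pipeline on a quarter directory). Designed to be
#' called from the thin \code{inst/exec/faersignal} Rscript wrapper; also
#' callable directly for testing.
#'
#' @param args character vector of command-line arguments.
#' @return exit status, invisibly: 0 on success, non-zero with a message
#'   on stderr otherwise.
#' @export
faersignalCli <- function(args = commandArgs(trailingOnly = TRUE)) {
  status <- tryCatch({
    if (!length(args)) { message(.cliUsage()); return(invisible(2L)) }
    sub <- args[[1L]]
    flags <- .cliFlags(args[-1L])
    if (sub == "simulate") {
      if (is.null(flags$out)) stop("simulate: --out is required", call. = FALSE)
      seed <- as.integer(flags$seed %||% "1")
      nCases <- as.integer(flags[["n-cases"]] %||% "10000")
      tag <- flags$tag %||% "23Q1"
      sim <- generateFaers(simConfig(nCases = nCases, seed = seed))
      writeFaersQuarter(sim$tables, flags$out, tag)
      writeGroundTruth(sim$truth, file.path(flags$out, "ground_truth.csv"))
      0L
    } else if (sub == "run-all") {
      for (f in c("in", "tag", "out"))
        if (is.null(flags[[f]]))
          stop(sprintf("run-all: --%s is required", f), call. = FALSE)
      hfDef <- if (!is.null(flags[["pt-list"]]))
        loadCaseDefinition(flags[["pt-list"]])
      else loadCaseDefinition(faersignalExtdata("hf_pt_list.txt"),
                              name = "heart failure (illustrative)")
      runFaersPipeline(flags[["in"]], tag = flags$tag,
                       hfDefinition = hfDef,
                       topN = as.integer(flags[["top-n"]] %||% "50"),
                       outDir = flags$out)
      0L
    } else {
      message(.cliUsage())
      stop(sprintf("unknown subcommand '%s'", sub), call. = FALSE)
    }
  }, error = function(e) {
    message("faersignal: ", conditionMessage(e))
    1L
  })
  invisible(status)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
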