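# Drug catalog: primary-suspect selection, verbatim-name -> ingredient
# normalization (brand names, international names, misspellings), top-N
# ranking by distinct case reports, and ingredient -> ATC level-2 mapping.
# Combination products are their own catalog entities (a metformin +
# saxagliptin product is not split into components).

#' Token marking a verbatim name as ambiguous in a name map
#'
#' Records whose normalized verbatim name maps to this token are dropped by
#' [normalizeDrugNames()] (e.g. "unknown medication").
#' @export
EXCLUDE_TOKEN <- "EXCLUDE"

.normalizeName <- function(x) tolower(gsub("[[:space:]]+", " ", trimws(x)))

#' Load a drug-name normalization map
#'
#' Two-column tab-delimited text: verbatim name, ingredient name. Keys are
#' normalized; the map must be a function (a key mapping to two different
#' values is an error) and must be idempotent (a value that is itself a key
#' for a different value is an error). Map a verbatim name to
#' \code{EXCLUDE} to declare it ambiguous.
#'
#' @param path map file; \code{#} comments and blank lines ignored.
#' @return named character vector: normalized verbatim -> ingredient.
#' @export
loadNameMap <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 2L
  if (any(bad))
    stop(sprintf("name map '%s': line(s) without two columns: %s",
                 path, paste(lines[bad], collapse = "; ")), call. = FALSE)
  keys <- .normalizeName(vapply(parts, `[`, character(1), 1L))
  vals <- vapply(parts, `[`, character(1), 2L)
  vals <- ifelse(vals == EXCLUDE_TOKEN, vals, .normalizeName(vals))
  if (any(!nzchar(vals)))
    stop("name map values must be non-blank", call. = FALSE)
  dup <- duplicated(keys)
  if (any(dup)) {
    conflict <- tapply(vals, keys, function(v) length(unique(v)) > 1L)
    if (any(conflict))
      stop(sprintf("name map '%s': key(s) map to two values: %s", path,
                   paste(names(conflict)[conflict], collapse = ", ")),
           call. = FALSE)
    keys <- keys[!dup]; vals <- vals[!dup]
  }
  map <- setNames(vals, keys)
  chained <- vals != EXCLUDE_TOKEN & vals %in% keys & map[vals] != vals
  if (any(chained))
    stop(sprintf("name map '%s' is not idempotent for value(s): %s", path,
                 paste(unique(vals[chained]), collapse = ", ")), call. = FALSE)
  map
}

#' Load an ingredient to ATC level-2 map
#'
#' Two-column tab-delimited text: ingredient, ATC level-2 code (letter +
#' two digits, e.g. \code{L01}); several rows per ingredient allowed.
#'
#' @param path map file; \code{#} comments and blank lines ignored.
#' @return data.frame with columns \code{ingredient}, \code{atc2}.
#' @export
loadAtcMap <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 2L
  if (any(bad))
    stop(sprintf("ATC map '%s': line(s) without two columns", path), call. = FALSE)
  ing <- .normalizeName(vapply(parts, `[`, character(1), 1L))
  atc <- toupper(trimws(vapply(parts, `[`, character(1), 2L)))
  badCode <- !grepl("^[A-Z][0-9]{2}$", atc)
  if (any(badCode))
    stop(sprintf("ATC map '%s': invalid level-2 code(s): %s", path,
                 paste(unique(atc[badCode]), collapse = ", ")), call. = FALSE)
  unique(data.frame(ingredient = ing, atc2 = atc, stringsAsFactors = FALSE))
}

#' Keep primary-suspect drug records only
#'
#' @param drug DRUG data.frame with a \code{role_cod} column
#'   (PS / SS / C / I).
#' @return the rows with role PS.
#' @export
selectPrimarySuspect <- function(drug) {
  drug[toupper(trimws(ifelse(is.na(drug$role_cod), "", drug$role_cod))) == "PS",
       , drop = FALSE]
}

#' Normalize drug names to ingredients
#'
#' Adds/overwrites an \code{ingredient} column: the mapped ingredient when
#' the normalized verbatim name is a map key, otherwise the normalized
#' verbatim name itself. Records mapped to [EXCLUDE_TOKEN] (ambiguous
#' names) are dropped; the count is attached as attribute
#' \code{"nDroppedAmbiguous"}. Idempotent.
#'
#' @param drug DRUG data.frame with \code{drugname}.
#' @param nameMap named character vector from [loadNameMap()].
#' @return drug data.frame with an \code{ingredient} column.
#' @export
normalizeDrugNames <- function(drug, nameMap = character()) {
  src <- if ("ingredient" %in% names(drug)) drug$ingredient else drug$drugname
  norm <- .normalizeName(ifelse(is.na(src), "", src))
  mapped <- unname(nameMap[norm])
  ingredient <- ifelse(is.na(mapped), norm, mapped)
  dropAmbiguous <- ingredient == EXCLUDE_TOKEN | !nzchar(ingredient)
  out <- drug[!dropAmbiguous, , drop = FALSE]
  out$ingredient <- ingredient[!dropAmbiguous]
  attr(out, "nDroppedAmbiguous") <- sum(dropAmbiguous)
  out
}

#' Rank the top drugs associated with the target condition
#'
#' For each ingredient, counts the distinct case reports (primaryids in
#' \code{caseIds}) carrying it as a primary-suspect drug; ties on the count
#' are broken by ingredient name ascending.
#'
#' @param drug normalized primary-suspect DRUG data.frame (columns
#'   \code{primaryid}, \code{ingredient}).
#' @param caseIds primaryids of the target-condition cases.
#' @param n number of drugs to return.
#' @return data.frame \code{ingredient}, \code{n_reports}, sorted by count
#'   descending then name.
#' @export
rankTopDrugs <- function(drug, caseIds, n = 50L) {
  if (!is.numeric(n) || length(n) != 1L || n <= 0)
    stop("n must be a positive integer", call. = FALSE)
  dt <- data.table::as.data.table(drug[drug$primaryid %in% caseIds,
                                       c("primaryid", "ingredient")])
  if (!nrow(dt))
    return(data.frame(ingredient = character(), n_reports = integer(),
                      stringsAsFactors = FALSE))
  dt <- unique(dt)
  cnt <- dt[, list(n_reports = .N), by = "ingredient"]
  data.table::setorderv(cnt, c("n_reports", "ingredient"), order = c(-1L, 1L))
  as.data.frame(head(cnt, n))
}

#' Map an ingredient to its ATC level-2 classes
#'
#' @param ingredient single ingredient name.
#' @param atcMap data.frame from [loadAtcMap()].
#' @param warn emit a warning for unmapped ingredients (default TRUE).
#' @return character vector of ATC level-2 codes (possibly empty).
#' @export
mapAtc2 <- function(ingredient, atcMap, warn = TRUE) {
  ing <- .normalizeName(ingredient)
  codes <- sort(unique(atcMap$atc2[atcMap$ingredient == ing]))
  if (!length(codes) && warn)
    warning(sprintf("no ATC level-2 class for ingredient '%s'", ingredient),
            call. = FALSE)
  codes
}
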