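# SMQ-style case retrieval: exact matching of REAC preferred terms against a
# normalized PT list (narrow-scope semantics: no substring or fuzzy match,
# no MedDRA hierarchy traversal).

.normalizePt <- function(x) tolower(gsub("[[:space:]]+", " ", trimws(x)))

#' Load a case definition from a PT list file
#'
#' File format: one preferred term per line, optionally followed by a tab
#' and the numeric MedDRA PT code; \code{#} comment lines and blank lines
#' are ignored. Terms are normalized (trimmed, whitespace-collapsed,
#' case-folded) and duplicates collapsed.
#'
#' @param path PT list file.
#' @param name label for the definition; defaults to the file name.
#' @return A [CaseDefinition-class] object.
#' @export
loadCaseDefinition <- function(path, name = basename(path)) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines))
    stop(sprintf("case definition '%s' is empty", path), call. = FALSE)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  terms <- .normalizePt(vapply(parts, `[`, character(1), 1L))
  codes <- suppressWarnings(as.numeric(vapply(parts, function(p)
    if (length(p) >= 2L) trimws(p[2L]) else NA_character_, character(1))))
  keep <- !duplicated(terms)
  new("CaseDefinition", name = name, terms = sort(unique(terms[keep])),
      codes = sort(unique(codes[!is.na(codes)])))
}

#' The acute heart failure (AHF) three-PT case definition
#'
#' Acute left ventricular failure (10063081), acute right ventricular
#' failure (10063082) and cardiac failure acute (10007556): the narrow
#' preferred-term set used to define acute heart failure.
#'
#' @return A [CaseDefinition-class] with three PTs and their MedDRA codes.
#' @examples
#' ahfDefinition()
#' @export
ahfDefinition <- function() {
  new("CaseDefinition", name = "acute heart failure (3 PTs)",
      terms = c("acute left ventricular failure",
                "acute right ventricular failure",
                "cardiac failure acute"),
      codes = c(10007556, 10063081, 10063082))
}

#' Identify target-condition reports
#'
#' A report (primaryid) is a case iff at least one of its REAC rows matches
#' the definition. Matching precedence: when the REAC row carries a
#' \code{pt_code} and the definition carries codes, the numeric code decides;
#' otherwise the normalized PT string must match exactly. Each report is
#' counted once no matter how many of its PTs match.
#'
#' @param reac REAC data.frame (columns \code{primaryid}, \code{pt},
#'   optionally \code{pt_code}) from deduplicated reports.
#' @param definition a [CaseDefinition-class].
#' @return sorted character vector of matching primaryids.
#' @export
findCaseIds <- function(reac, definition) {
  stopifnot(is(definition, "CaseDefinition"))
  if (!nrow(reac)) return(character())
  hasCode <- if ("pt_code" %in% names(reac) && length(definition@codes)) {
    code <- suppressWarnings(as.numeric(reac$pt_code))
    !is.na(code)
  } else rep(FALSE, nrow(reac))
  hit <- logical(nrow(reac))
  if (any(hasCode)) {
    code <- suppressWarnings(as.numeric(reac$pt_code))
    hit[hasCode] <- code[hasCode] %in% definition@codes
  }
  if (any(!hasCode))
    hit[!hasCode] <- .normalizePt(reac$pt[!hasCode]) %in% definition@terms
  sort(unique(reac$primaryid[hit]))
}
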