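# FAERS ASCII dialect: "$"-delimited, header line first, no quoting or
# escaping. Blank strings, "NULL" and absent fields all map to NA.

.DELIM <- "$"

.normalizeMissing <- function(x) {
  x <- trimws(x)
  x[x == "" | toupper(x) == "NULL"] <- NA_character_
  x
}

.daysInMonth <- c(31L, 29L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)

#' Parse FAERS partial dates
#'
#' FAERS dates are digit strings of 4, 6 or 8 characters (year, year-month,
#' year-month-day). Blank / "NULL" input is a legitimate missing value.
#'
#' @param x character vector of date fields.
#' @param onError \code{"stop"} (default) raises a parse error naming the
#'   offending text; \code{"na"} returns an invalid row (precision NA,
#'   \code{ok = FALSE}) instead, which curation uses to flag incorrect
#'   reports without aborting a load.
#' @return data.frame with one row per input: \code{text}, \code{year},
#'   \code{month}, \code{day} (NA where absent), \code{precision} (one of
#'   \code{"year"}, \code{"month"}, \code{"day"}, or NA for missing input)
#'   and \code{ok} (FALSE only for unparseable non-missing input when
#'   \code{onError = "na"}).
#' @examples
#' parseFaersDate(c("20210115", "202101", "2021", ""))
#' @export
parseFaersDate <- function(x, onError = c("stop", "na")) {
  onError <- match.arg(onError)
  x <- .normalizeMissing(as.character(x))
  n <- length(x)
  year <- month <- day <- rep(NA_integer_, n)
  precision <- rep(NA_character_, n)
  ok <- rep(TRUE, n)

  present <- !is.na(x)
  len <- nchar(x[present])
  digits <- grepl("^[0-9]+$", x[present])
  bad <- !(len %in% c(4L, 6L, 8L)) | !digits
  idx <- which(present)

  yr <- suppressWarnings(as.integer(substr(x[idx], 1L, 4L)))
  mo <- ifelse(len >= 6L,
               suppressWarnings(as.integer(substr(x[idx], 5L, 6L))),
               NA_integer_)
  dy <- ifelse(len == 8L,
               suppressWarnings(as.integer(substr(x[idx], 7L, 8L))),
               NA_integer_)
  bad <- bad | (!is.na(mo) & (mo < 1L | mo > 12L))
  bad <- bad | (!is.na(dy) & (is.na(mo) | dy < 1L | dy > .daysInMonth[pmax(mo, 1L)]))

  if (any(bad) && onError == "stop")
    stop(sprintf("unparseable FAERS date(s): %s",
                 paste(unique(x[idx][bad]), collapse = ", ")), call. = FALSE)

  good <- idx[!bad]
  glen <- len[!bad]
  year[good] <- yr[!bad]
  month[good] <- mo[!bad]
  day[good] <- dy[!bad]
  precision[good] <- c("4" = "year", "6" = "month", "8" = "day")[as.character(glen)]
  ok[idx[bad]] <- FALSE

  data.frame(text = x, year = year, month = month, day = day,
             precision = precision, ok = ok, stringsAsFactors = FALSE)
}

# Digit-string comparison key: lexicographic order of the raw string, so a
# year- or month-precision date ranks below any full date sharing its prefix.
.dateKey <- function(x) {
  x <- .normalizeMissing(as.character(x))
  ifelse(is.na(x), "", x)
}

# Convert a parsed partial date to Date, imputing day 1 (and month 1 is NOT
# allowed: year precision is unusable and yields NA).
.partialToDate <- function(pd) {
  out <- rep(as.Date(NA), nrow(pd))
  usable <- !is.na(pd$precision) & pd$precision %in% c("month", "day") & pd$ok
  d <- ifelse(is.na(pd$day), 1L, pd$day)
  out[usable] <- suppressWarnings(as.Date(sprintf(
    "%04d-%02d-%02d", pd$year[usable], pd$month[usable], d[usable])))
  out
}

.splitDollar <- function(lines) {
  # append a sentinel so trailing empty fields survive strsplit
  parts <- strsplit(paste0(lines, .DELIM, "\x01"), .DELIM, fixed = TRUE)
  lapply(parts, function(p) p[-length(p)])
}

#' Read one FAERS-style ASCII table
#'
#' Reads a dollar-delimited file whose first line is the header. Header
#' fields are matched case-insensitively after trimming; the required
#' minimal field set for \code{name} must be present. Rows whose field
#' count differs from the header (e.g. embedded delimiters) are dropped and
#' counted in the ingest log attached as attribute \code{"ingest"}.
#'
#' @param path file path.
#' @param name table name, one of DEMO, DRUG, REAC, THER, OUTC.
#' @return data.frame with lower-case column names; blank/"NULL" fields are
#'   NA. Attribute \code{"ingest"} is a one-row data.frame with
#'   \code{rows_in}, \code{rows_kept}, \code{rows_dropped}.
#' @export
readFaersTable <- function(path, name) {
  name <- toupper(name)
  name <- match.arg(name, .FAERS_TABLES)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L)
    stop(sprintf("empty file: %s", path), call. = FALSE)
  header <- tolower(trimws(.splitDollar(lines[1L])[[1L]]))
  missing <- setdiff(.REQUIRED_FIELDS[[name]], header)
  if (length(missing))
    stop(sprintf("%s header of '%s' lacks required field(s): %s",
                 name, path, paste(missing, collapse = ", ")), call. = FALSE)

  body <- lines[-1L]
  body <- body[nzchar(trimws(body))]
  rowsIn <- length(body)
  cells <- .splitDollar(body)
  widths <- lengths(cells)
  keep <- widths == length(header)
  kept <- cells[keep]
  if (length(kept)) {
    mat <- matrix(unlist(kept, use.names = FALSE),
                  nrow = length(kept), byrow = TRUE)
    df <- as.data.frame(mat, stringsAsFactors = FALSE)
    names(df) <- header
    df[] <- lapply(df, .normalizeMissing)
  } else {
    df <- as.data.frame(setNames(rep(list(character()), length(header)), header),
                        stringsAsFactors = FALSE)
  }
  attr(df, "ingest") <- data.frame(
    table = name, file = basename(path), rows_in = rowsIn,
    rows_kept = sum(keep), rows_dropped = sum(!keep),
    stringsAsFactors = FALSE)
  df
}

#' Write one FAERS-style ASCII table
#'
#' Inverse of [readFaersTable()]: dollar-delimited, header first, NA
#' rendered as the empty string.
#'
#' @param df data.frame to write.
#' @param path destination path.
#' @return \code{path}, invisibly.
#' @export
writeFaersTable <- function(df, path) {
  cols <- lapply(df, function(v) {
    v <- as.character(v)
    v[is.na(v)] <- ""
    v
  })
  body <- if (nrow(df)) do.call(paste, c(cols, sep = .DELIM)) else character()
  writeLines(c(paste(names(df), collapse = .DELIM), body), path)
  invisible(path)
}

.quarterFile <- function(directory, name, tag) {
  cand <- list.files(directory, full.names = TRUE)
  pat <- sprintf("^%s%s\\.(txt|TXT)$", name, tag)
  hit <- cand[grepl(pat, basename(cand), ignore.case = TRUE)]
  if (length(hit)) hit[1L] else NA_character_
}

#' Load a FAERS quarter directory into a FaersTables object
#'
#' Expects files named \code{DEMO<tag>.txt} etc. (case-insensitive).
#' DEMO, DRUG and REAC are mandatory; a missing THER or OUTC file is
#' tolerated with an empty table and a warning, since some reports carry
#' no therapy or outcome rows.
#'
#' @param directory directory containing the quarter's files.
#' @param tag quarter tag embedded in the file names, e.g. \code{"23Q1"}.
#' @return A [FaersTables-class] object with the ingest log filled in.
#' @export
loadFaersQuarter <- function(directory, tag) {
  if (!dir.exists(directory))
    stop(sprintf("directory not found: %s", directory), call. = FALSE)
  tabs <- list()
  ingest <- .emptyIngestLog()
  for (nm in .FAERS_TABLES) {
    path <- .quarterFile(directory, nm, tag)
    if (is.na(path)) {
      if (nm %in% c("DEMO", "DRUG", "REAC"))
        stop(sprintf("required table %s missing for quarter %s in %s",
                     nm, tag, directory), call. = FALSE)
      warning(sprintf("table %s missing for quarter %s; using empty table",
                      nm, tag), call. = FALSE)
      tabs[[nm]] <- .emptyFaersTable(nm)
    } else {
      df <- readFaersTable(path, nm)
      ingest <- rbind(ingest, attr(df, "ingest"))
      attr(df, "ingest") <- NULL
      tabs[[nm]] <- df
    }
  }
  FaersTables(demo = tabs$DEMO, drug = tabs$DRUG, reac = tabs$REAC,
              ther = tabs$THER, outc = tabs$OUTC, ingest = ingest)
}

#' Write a FaersTables object as a quarter directory
#'
#' @param x a [FaersTables-class] object.
#' @param directory destination directory (created if needed).
#' @param tag quarter tag used in the file names.
#' @return the directory, invisibly.
#' @export
writeFaersQuarter <- function(x, directory, tag) {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  for (nm in .FAERS_TABLES)
    writeFaersTable(slot(x, tolower(nm)),
                    file.path(directory, sprintf("%s%s.txt", nm, tag)))
  invisible(directory)
}
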