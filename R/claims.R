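# Reading and writing delimited claims tables.
#
# The exchange format is one row per dispensed item per visit. Visits
# without any dispensed CHM item (e.g. the index gynecology visit that
# establishes a diagnosis) appear as a single row with an empty item code.

CLAIMS_COLS <- c("patient_id", "visit_id", "visit_date", "birth_date",
                 "specialty", "diagnoses", "therapies", "item_code",
                 "item_name", "item_kind", "dose_g_day", "duration_days")

splitField <- function(x) {
  out <- strsplit(ifelse(is.na(x), "", x), ";", fixed = TRUE)
  lapply(out, function(v) v[nzchar(v)])
}

#' Construct a ChmCohort from visit and item tables
#'
#' Rows are brought into canonical order (visits by `visit_id`, items by
#' `visit_id` then `code`, radix/C collation) so that any row permutation of
#' the inputs yields an identical object.
#'
#' @param visits data.frame with the columns documented in
#'   [ChmCohort-class].
#' @param items data.frame with the item columns; may have zero rows.
#' @return A validated [ChmCohort-class].
#' @export
chmCohort <- function(visits, items) {
  visits <- as.data.frame(visits)[VISIT_COLS]
  items <- as.data.frame(items)[ITEM_COLS]
  for (col in c("visit_id", "patient_id", "specialty", "diagnoses",
                "therapies"))
    visits[[col]] <- as.character(visits[[col]])
  visits <- visits[orderCodes(visits$visit_id), , drop = FALSE]
  if (nrow(items)) {
    for (col in c("visit_id", "code", "name", "kind"))
      items[[col]] <- as.character(items[[col]])
    items <- items[orderCodes(items$visit_id, items$code), , drop = FALSE]
  }
  rownames(visits) <- NULL
  rownames(items) <- NULL
  new("ChmCohort", visits = visits, items = items)
}

#' Read a delimited claims table
#'
#' Parses a CSV/TSV claims table (one row per dispensed item per visit) into
#' a [ChmCohort-class]. Rows sharing a `visit_id` are collapsed into one
#' visit; duplicate item codes within a visit are merged by summing
#' `dose_g_day` and keeping the maximum `duration_days` (claims tables often
#' split one dispense across rows, and support must count an item once per
#' prescription). Row order never affects the result.
#'
#' @param path file path.
#' @param sep field delimiter (default ",").
#' @param colMap optional named character vector mapping the canonical
#'   column names (`patient_id`, `visit_id`, ...) to the names used in the
#'   file.
#' @return A [ChmCohort-class].
#' @export
readClaims <- function(path, sep = ",", colMap = NULL) {
  if (!file.exists(path)) stop("claims file not found: ", path)
  raw <- read.csv(path, sep = sep, colClasses = "character",
                  check.names = FALSE, na.strings = character())
  if (!is.null(colMap)) {
    for (canon in names(colMap)) {
      if (!colMap[[canon]] %in% names(raw))
        stop("claims format error: missing mandatory column '",
             colMap[[canon]], "'")
      names(raw)[names(raw) == colMap[[canon]]] <- canon
    }
  }
  miss <- setdiff(CLAIMS_COLS, names(raw))
  if (length(miss))
    stop("claims format error: missing mandatory column '", miss[1], "'")
  parseDate <- function(x, what) {
    d <- as.Date(x, format = "%Y-%m-%d")
    bad <- which(is.na(d) & nzchar(x))
    if (length(bad))
      stop("claims record error: unparseable ", what, " at data row ",
           bad[1], " ('", x[bad[1]], "')")
    d
  }
  raw$visit_date <- parseDate(raw$visit_date, "visit_date")
  raw$birth_date <- parseDate(raw$birth_date, "birth_date")

  vis <- raw[!duplicated(raw$visit_id),
             c("visit_id", "patient_id", "visit_date", "birth_date",
               "specialty", "diagnoses", "therapies")]
  multi <- tapply(raw$patient_id, raw$visit_id,
                  function(p) length(unique(p)))
  if (any(multi > 1))
    stop("claims format error: visit_id '",
         names(multi)[which(multi > 1)[1]],
         "' is shared by more than one patient_id")

  hasItem <- nzchar(raw$item_code)
  it <- raw[hasItem, c("visit_id", "item_code", "item_name", "item_kind",
                       "dose_g_day", "duration_days")]
  names(it) <- ITEM_COLS
  if (nrow(it)) {
    it$dose_g_day <- as.numeric(it$dose_g_day)
    it$duration_days <- as.numeric(it$duration_days)
    key <- paste(it$visit_id, it$code, sep = "\r")
    if (anyDuplicated(key)) {
      dose <- tapply(it$dose_g_day, key, sum)
      dur <- tapply(it$duration_days, key, max)
      it <- it[!duplicated(key), , drop = FALSE]
      k2 <- paste(it$visit_id, it$code, sep = "\r")
      it$dose_g_day <- as.numeric(dose[k2])
      it$duration_days <- as.numeric(dur[k2])
    }
  }
  chmCohort(vis, it)
}

#' Write a ChmCohort as a delimited claims table
#'
#' Inverse of [readClaims()]: one row per dispensed item, plus one row with
#' an empty item code for each visit without items.
#'
#' @param cohort a [ChmCohort-class].
#' @param path output path.
#' @param sep field delimiter.
#' @return `path`, invisibly.
#' @export
writeClaims <- function(cohort, path, sep = ",") {
  v <- cohort@visits
  it <- cohort@items
  rows <- merge(v, it, by = "visit_id", all.x = TRUE, sort = FALSE)
  out <- data.frame(
    patient_id = rows$patient_id, visit_id = rows$visit_id,
    visit_date = format(rows$visit_date, "%Y-%m-%d"),
    birth_date = format(rows$birth_date, "%Y-%m-%d"),
    specialty = rows$specialty, diagnoses = rows$diagnoses,
    therapies = rows$therapies,
    item_code = ifelse(is.na(rows$code), "", rows$code),
    item_name = ifelse(is.na(rows$name), "", rows$name),
    item_kind = ifelse(is.na(rows$kind), "", rows$kind),
    dose_g_day = ifelse(is.na(rows$code), "", rows$dose_g_day),
    duration_days = ifelse(is.na(rows$code), "", rows$duration_days),
    stringsAsFactors = FALSE)
  out <- out[orderCodes(out$visit_id, out$item_code), , drop = FALSE]
  write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
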