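#' @title Reading and writing the tabular event data
#' @name repleteaudit-io
#' @description
#' All five input tables (labs, repletions, stays, diagnoses, and optional
#' item maps) travel as RFC-4180 CSV with a header row, UTF-8 encoded.
#' Internally the package uses a canonical schema; a `schema_map` translates
#' foreign column names (e.g. raw MIMIC-III v1.4 headers) to canonical ones,
#' and an `item_map` translates laboratory/medication item codes to
#' electrolyte names.
NULL

.canonical_schema <- list(
  lab = list(
    required = c("subject_id", "stay_id", "electrolyte", "charttime", "value"),
    optional = c("value_unit", "flag")
  ),
  repletion = list(
    required = c("subject_id", "stay_id", "electrolyte", "ordertime", "dose"),
    optional = c("dose_unit", "route")
  ),
  stay = list(
    required = c("stay_id", "subject_id", "unit_type", "intime", "outtime",
                 "age_years"),
    optional = c("weight_kg")
  ),
  diagnosis = list(
    required = c("subject_id", "stay_id", "icd9_code", "seq_num"),
    optional = character(0)
  )
)

#' Canonical column names for an event table
#'
#' @param kind one of `"lab"`, `"repletion"`, `"stay"`, `"diagnosis"`.
#' @return list with `required` and `optional` character vectors.
#' @export
canonical_schema <- function(kind) {
  kind <- match.arg(kind, names(.canonical_schema))
  .canonical_schema[[kind]]
}

#' Shipped column mapping from raw MIMIC-III v1.4 headers
#'
#' Maps canonical field names to the column headers of the corresponding
#' MIMIC-III tables (LABEVENTS, INPUTEVENTS_MV, ICUSTAYS, DIAGNOSES_ICD).
#' `age_years` and `unit_type` are not stored verbatim in MIMIC-III
#' (age must be derived from PATIENTS.DOB and ICUSTAYS.INTIME before
#' export); the map expects them pre-computed under `AGE_YEARS` /
#' `FIRST_CAREUNIT`.
#'
#' @param kind table kind as in [canonical_schema()].
#' @return named character vector, names are canonical fields, values the
#'   foreign headers.
#' @export
mimic3_schema_map <- function(kind) {
  kind <- match.arg(kind, names(.canonical_schema))
  switch(kind,
    lab = c(subject_id = "SUBJECT_ID", stay_id = "ICUSTAY_ID",
            electrolyte = "ITEMID", charttime = "CHARTTIME",
            value = "VALUENUM", value_unit = "VALUEUOM", flag = "FLAG"),
    repletion = c(subject_id = "SUBJECT_ID", stay_id = "ICUSTAY_ID",
                  electrolyte = "ITEMID", ordertime = "STARTTIME",
                  dose = "AMOUNT", dose_unit = "AMOUNTUOM",
                  route = "ORDERCATEGORYNAME"),
    stay = c(stay_id = "ICUSTAY_ID", subject_id = "SUBJECT_ID",
             unit_type = "FIRST_CAREUNIT", intime = "INTIME",
             outtime = "OUTTIME", age_years = "AGE_YEARS",
             weight_kg = "WEIGHT_KG"),
    diagnosis = c(subject_id = "SUBJECT_ID", stay_id = "ICUSTAY_ID",
                  icd9_code = "ICD9_CODE", seq_num = "SEQ_NUM")
  )
}

#' Shipped item-code table for MIMIC-III electrolyte items
#'
#' Translates the MIMIC-III ITEMID codes of the serum electrolyte lab tests
#' and the Metavision repletion products to electrolyte names. Combination
#' products are not mapped by default (a phosphate product containing
#' potassium maps to phosphate only); supply your own table to change that.
#'
#' @return `data.frame` with columns `item_code`, `electrolyte`.
#' @export
default_item_map <- function() {
  data.frame(
    item_code = c("50971", "50960", "50970",      # LABEVENTS serum K, Mg, Phos
                  "225166", "227522",             # KCl IV / oral
                  "222011",                       # magnesium sulfate
                  "225834", "225827"),            # K-phos / Na-phos
    electrolyte = c("potassium", "magnesium", "phosphate",
                    "potassium", "potassium",
                    "magnesium",
                    "phosphate", "phosphate"),
    stringsAsFactors = FALSE
  )
}

.new_validation_report <- function(n_read, reasons) {
  reasons <- reasons[reasons > 0]
  structure(
    list(n_rows_read = n_read,
         n_rows_accepted = n_read - sum(reasons),
         n_rows_rejected = sum(reasons),
         rejection_reasons = as.list(reasons)),
    class = "validation_report"
  )
}

#' @export
print.validation_report <- function(x, ...) {
  cat("validation report: ", x$n_rows_read, " rows read, ",
      x$n_rows_accepted, " accepted, ", x$n_rows_rejected, " rejected\n",
      sep = "")
  if (length(x$rejection_reasons)) {
    for (nm in names(x$rejection_reasons))
      cat("  - ", nm, ": ", x$rejection_reasons[[nm]], "\n", sep = "")
  }
  invisible(x)
}

#' Read one of the five event tables
#'
#' Reads a CSV file, renames columns through `schema_map`, coerces and
#' validates every row against the canonical type invariants, and returns
#' the accepted records together with a validation report. Rows that fail a
#' row-level invariant are rejected and counted by reason, never silently
#' dropped; a missing required column is a hard error naming the column.
#'
#' @param path path to a CSV file with a header row.
#' @param kind `"lab"`, `"repletion"`, `"stay"` or `"diagnosis"`.
#' @param schema_map optional named character vector mapping canonical field
#'   names to the file's column headers (see [mimic3_schema_map()]); by
#'   default the file is assumed to already use canonical names.
#' @param item_map optional `data.frame(item_code, electrolyte)` used to
#'   translate item codes found in the electrolyte column (raw MIMIC
#'   exports); unmapped codes reject the row with reason `unknown_item_code`.
#' @param stays optional accepted stay table; when given, lab/repletion rows
#'   timestamped outside their stay's `[intime, outtime]` interval are
#'   rejected with reason `outside_stay_bounds`.
#' @return list with elements `records` (a `data.frame` in canonical schema,
#'   timestamps as POSIXct at minute resolution) and `report`
#'   (a `validation_report`).
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write.csv(data.frame(subject_id = 1, stay_id = 10,
#'                      electrolyte = "potassium",
#'                      charttime = "2001-02-03 06:00:00", value = 3.1),
#'           f, row.names = FALSE)
#' read_events_table(f, "lab")$report
#' @export
read_events_table <- function(path, kind, schema_map = NULL, item_map = NULL,
                              stays = NULL) {
  kind <- match.arg(kind, names(.canonical_schema))
  if (!file.exists(path)) stop("file does not exist: ", path)
  sch <- .canonical_schema[[kind]]
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, stringsAsFactors = FALSE)

  # apply schema map (rename foreign -> canonical); mapping must be total
  # over required fields before any row is processed
  if (!is.null(schema_map)) {
    missing_map <- setdiff(sch$required, names(schema_map))
    if (length(missing_map))
      stop("schema_map does not cover required field(s): ",
           paste(missing_map, collapse = ", "))
    for (canon in names(schema_map)) {
      foreign <- schema_map[[canon]]
      if (foreign %in% names(raw))
        names(raw)[names(raw) == foreign] <- canon
    }
  }
  missing_cols <- setdiff(sch$required, names(raw))
  if (length(missing_cols))
    stop("missing required column(s) in ", path, ": ",
         paste(missing_cols, collapse = ", "))

  n <- nrow(raw)
  keep_cols <- intersect(c(sch$required, sch$optional), names(raw))
  raw <- raw[, keep_cols, drop = FALSE]
  reasons <- integer(0)
  bad <- rep(FALSE, n)
  flag_bad <- function(idx, reason) {
    idx <- idx & !bad
    if (any(idx)) reasons[reason] <<- sum(idx) + (reasons[reason] %||% 0L)
    bad <<- bad | idx
  }

  if (n > 0) {
    # electrolyte / item-code resolution
    if ("electrolyte" %in% names(raw)) {
      el <- trimws(raw$electrolyte)
      if (!is.null(item_map)) {
        mapped <- item_map$electrolyte[match(el, as.character(item_map$item_code))]
        coded <- !(el %in% electrolytes())
        flag_bad(coded & is.na(mapped), "unknown_item_code")
        el[coded & !is.na(mapped)] <- mapped[coded & !is.na(mapped)]
      }
      flag_bad(!(el %in% electrolytes()), "unknown_electrolyte")
      raw$electrolyte <- el
    }
    # timestamps
    for (tc in intersect(c("charttime", "ordertime", "intime", "outtime"),
                         names(raw))) {
      tt <- .parse_timestamp_quiet(raw[[tc]])
      flag_bad(is.na(tt), "unparseable_timestamp")
      raw[[tc]] <- tt
    }
    # numerics
    if ("value" %in% names(raw)) {
      v <- suppressWarnings(as.numeric(raw$value))
      flag_bad(is.na(v), "non_numeric_value")
      flag_bad(!is.na(v) & (!is.finite(v) | v <= 0), "nonpositive_value")
      raw$value <- v
    }
    if ("dose" %in% names(raw)) {
      d <- suppressWarnings(as.numeric(raw$dose))
      flag_bad(is.na(d), "non_numeric_dose")
      flag_bad(!is.na(d) & (!is.finite(d) | d < 0), "negative_dose")
      raw$dose <- d
    }
    if ("age_years" %in% names(raw)) {
      # NA age is allowed here; the cohort age filter excludes it explicitly
      a <- suppressWarnings(as.numeric(raw$age_years))
      flag_bad(!is.na(a) & a < 0, "negative_age")
      raw$age_years <- a
    }
    if ("weight_kg" %in% names(raw))
      raw$weight_kg <- suppressWarnings(as.numeric(raw$weight_kg))
    if ("seq_num" %in% names(raw)) {
      s <- suppressWarnings(as.numeric(raw$seq_num))
      flag_bad(is.na(s) | s < 1 | s != floor(s), "invalid_seq_num")
      raw$seq_num <- as.integer(s)
    }
    if (all(c("intime", "outtime") %in% names(raw)))
      flag_bad(!is.na(raw$intime) & !is.na(raw$outtime) &
                 raw$intime >= raw$outtime, "invalid_stay_interval")
    # optional stay-bounds check for event rows
    tcol <- intersect(c("charttime", "ordertime"), names(raw))
    if (!is.null(stays) && length(tcol) == 1 && "stay_id" %in% names(raw)) {
      i <- match(raw$stay_id, as.character(stays$stay_id))
      inb <- !is.na(i) &
        raw[[tcol]] >= stays$intime[i] & raw[[tcol]] <= stays$outtime[i]
      flag_bad(!is.na(i) & !inb, "outside_stay_bounds")
    }
  }

  records <- raw[!bad, , drop = FALSE]
  rownames(records) <- NULL
  list(records = records, report = .new_validation_report(n, reasons))
}

`%||%` <- function(a, b) {
  if (is.null(a) || length(a) == 0 || (length(a) == 1 && is.na(a))) b else a
}

#' Write a result table as deterministic CSV
#'
#' Columns are written in their current order, timestamps formatted as
#' `YYYY-MM-DD HH:MM:SS`, row names dropped, so that two writes of the same
#' input are byte-identical and event tables round-trip through
#' [read_events_table()].
#'
#' @param records a `data.frame` (may have zero rows).
#' @param path output file path; the directory must exist and be writable.
#' @return invisibly, `path`.
#' @export
write_summary_table <- function(records, path) {
  if (is.null(records)) stop("write_summary_table: records is NULL")
  records <- as.data.frame(records)
  records <- .format_time_cols(records)
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("directory does not exist: ", dir)
  ok <- tryCatch({
    utils::write.csv(records, path, row.names = FALSE, na = "")
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("could not write: ", path)
  invisible(path)
}
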