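#' @title Cohort construction with a full attrition log
#' @name repleteaudit-cohort
#' @description
#' The analyzable cohort is built by an ordered exclusion cascade: stays with
#' neither a lab value nor a repletion are dropped first, then minors, then
#' stays whose first-listed (most relevant, `seq_num == 1`) ICD-9 diagnosis
#' falls in any configured exclusion code set, and finally individual lab
#' values outside physiologic error bounds are removed at the event level.
#' Every step appends a row to the attrition log. Diagnosis rules act on
#' whole stays (encounters); value-error rules act on single events, so the
#' log carries a `level` column and the conservation invariant
#' (final = initial - sum removed, non-increasing remaining) holds within
#' each level.
NULL

.attrition_entry <- function(rule, level, n_removed, n_remaining) {
  data.frame(rule = rule, level = level,
             n_removed = as.integer(n_removed),
             n_remaining = as.integer(n_remaining),
             stringsAsFactors = FALSE)
}

.empty_attrition <- function() {
  structure(
    data.frame(rule = character(0), level = character(0),
               n_removed = integer(0), n_remaining = integer(0),
               stringsAsFactors = FALSE),
    class = c("attrition_log", "data.frame"))
}

.bind_attrition <- function(...) {
  out <- do.call(rbind, Filter(Negate(is.null), list(...)))
  class(out) <- c("attrition_log", "data.frame")
  rownames(out) <- NULL
  out
}

#' @export
print.attrition_log <- function(x, ...) {
  cat("attrition log (", nrow(x), " steps)\n", sep = "")
  for (lv in unique(x$level)) {
    sub <- x[x$level == lv, ]
    cat(" ", lv, "-level:\n", sep = "")
    for (i in seq_len(nrow(sub)))
      cat(sprintf("   %-28s removed %7d  remaining %8d\n",
                  sub$rule[i], sub$n_removed[i], sub$n_remaining[i]))
  }
  invisible(x)
}

#' Exclude stays below a minimum age
#'
#' A stay is retained when `age_years >= minimum_age` ("under" the minimum
#' is a strict comparison, so age exactly at the minimum is retained).
#' Stays with missing age are excluded under the distinct rule
#' `age_missing`.
#'
#' @param stays stay table in canonical schema.
#' @param minimum_age minimum age in years, default 18.
#' @return list with `stays` (retained rows) and `log` (attrition rows).
#' @export
apply_age_filter <- function(stays, minimum_age = 18) {
  missing <- is.na(stays$age_years)
  minor <- !missing & stays$age_years < minimum_age
  kept <- stays[!missing & !minor, , drop = FALSE]
  log <- .bind_attrition(
    .attrition_entry("age_missing", "stay", sum(missing),
                     nrow(stays) - sum(missing)),
    .attrition_entry(sprintf("age_under_%g", minimum_age), "stay",
                     sum(minor), nrow(kept))
  )
  list(stays = kept, log = log)
}

#' Exclude stays by first-listed diagnosis
#'
#' MIMIC-style diagnosis tables rank codes by relevancy (`seq_num`); only
#' the first diagnosis (`seq_num == 1`) is consulted. A stay is removed iff
#' its first diagnosis code is in some rule's code set; rules are applied in
#' the given order and each appends its own attrition row, so a stay removed
#' by an earlier rule is not re-counted by a later one. Stays with no
#' diagnosis at all are excluded under `diagnosis_missing`.
#'
#' @param stays stay table.
#' @param diagnoses diagnosis table in canonical schema.
#' @param exclusion_rules named list; each element is a character vector of
#'   ICD-9 codes, the name is the rule name (e.g. `chf`). May be empty.
#' @return list with `stays` and `log`.
#' @export
apply_diagnosis_exclusions <- function(stays, diagnoses, exclusion_rules) {
  first_dx <- diagnoses[diagnoses$seq_num == 1, , drop = FALSE]
  code <- trimws(as.character(
    first_dx$icd9_code[match(stays$stay_id, first_dx$stay_id)]))
  missing <- is.na(code)
  kept <- !missing
  log <- .attrition_entry("diagnosis_missing", "stay", sum(missing),
                          sum(kept))
  for (rule in names(exclusion_rules)) {
    codes <- trimws(as.character(exclusion_rules[[rule]]))
    if (!length(codes)) stop("exclusion rule '", rule, "' has an empty code set")
    hit <- kept & code %in% codes
    kept <- kept & !hit
    log <- .bind_attrition(log,
      .attrition_entry(paste0("dx_", rule), "stay", sum(hit), sum(kept)))
  }
  list(stays = stays[kept, , drop = FALSE], log = .bind_attrition(log))
}

#' Remove physiologically impossible lab values
#'
#' Values strictly below the lower or strictly above the upper error bound
#' for their electrolyte are removed as recording errors (a value exactly at
#' a bound is retained). Removal is at the event level; one attrition row is
#' logged per electrolyte.
#'
#' @param labs lab table in canonical schema.
#' @param bounds `data.frame(electrolyte, low, high)`; every electrolyte
#'   present in `labs` must have a row, otherwise this is a hard error.
#' @return list with `labs` (retained rows) and `log`.
#' @export
apply_value_error_filter <- function(labs, bounds = default_error_bounds()) {
  present <- unique(labs$electrolyte)
  missing_bounds <- setdiff(present, bounds$electrolyte)
  if (length(missing_bounds))
    stop("no error bounds configured for: ",
         paste(missing_bounds, collapse = ", "))
  i <- match(labs$electrolyte, bounds$electrolyte)
  err <- labs$value < bounds$low[i] | labs$value > bounds$high[i]
  err[is.na(err)] <- TRUE
  log <- NULL
  kept_running <- nrow(labs)
  for (el in intersect(bounds$electrolyte, present)) {
    n_el <- sum(err & labs$electrolyte == el)
    kept_running <- kept_running - n_el
    log <- .bind_attrition(log,
      .attrition_entry(paste0("value_error_", el), "event", n_el,
                       kept_running))
  }
  list(labs = labs[!err, , drop = FALSE], log = .bind_attrition(log))
}

#' Build the analyzable cohort
#'
#' Runs the full exclusion cascade in fixed order: (1) stays lacking both a
#' lab value and a repletion; (2) age filter; (3) diagnosis exclusions in
#' configured order; (4) event-level value-error bounds. Lab and repletion
#' tables are restricted to the surviving stays.
#'
#' @param tables list with elements `labs`, `repletions`, `stays`,
#'   `diagnoses` in canonical schema (as returned by [read_events_table()]
#'   or [generate_cohort()]).
#' @param exclusion_rules named list of ICD-9 code sets, see
#'   [apply_diagnosis_exclusions()]; may be empty to skip.
#' @param minimum_age years, default 18; `NULL` skips the age filter.
#' @param error_bounds see [apply_value_error_filter()]; `NULL` skips.
#' @return object of class `repletion_cohort`: list with `stays`, `labs`,
#'   `repletions`, `diagnoses`, `attrition` (an `attrition_log`).
#' @export
build_cohort <- function(tables, exclusion_rules = list(),
                         minimum_age = 18,
                         error_bounds = default_error_bounds()) {
  stays <- tables$stays; labs <- tables$labs; reps <- tables$repletions
  has_event <- stays$stay_id %in% c(labs$stay_id, reps$stay_id)
  log <- .attrition_entry("no_lab_or_repletion", "stay", sum(!has_event),
                          sum(has_event))
  stays <- stays[has_event, , drop = FALSE]

  if (!is.null(minimum_age)) {
    a <- apply_age_filter(stays, minimum_age)
    stays <- a$stays
    log <- .bind_attrition(log, a$log)
  }
  if (length(exclusion_rules)) {
    d <- apply_diagnosis_exclusions(stays, tables$diagnoses, exclusion_rules)
    stays <- d$stays
    log <- .bind_attrition(log, d$log)
  }
  labs <- labs[labs$stay_id %in% stays$stay_id, , drop = FALSE]
  reps <- reps[reps$stay_id %in% stays$stay_id, , drop = FALSE]
  if (!is.null(error_bounds)) {
    v <- apply_value_error_filter(labs, error_bounds)
    labs <- v$labs
    log <- .bind_attrition(log, v$log)
  }
  structure(
    list(stays = stays, labs = labs, repletions = reps,
         diagnoses = tables$diagnoses[
           tables$diagnoses$stay_id %in% stays$stay_id, , drop = FALSE],
         attrition = .bind_attrition(log)),
    class = "repletion_cohort")
}

#' @export
print.repletion_cohort <- function(x, ...) {
  cat("repletion audit cohort\n")
  cat("  stays:      ", nrow(x$stays), "\n", sep = "")
  cat("  labs:       ", nrow(x$labs), "\n", sep = "")
  cat("  repletions: ", nrow(x$repletions), "\n", sep = "")
  print(x$attrition)
  invisible(x)
}

#' Default ICD-9 exclusion code sets
#'
#' Named code sets for the conditions excluded from the audit cohort:
#' transfusion of packed red cells, rhabdomyolysis, parathyroid disease,
#' sarcoidosis, chronic/acute/end-stage kidney disease, coronary artery
#' disease, congestive heart failure, atrial fibrillation, nutritional
#' deficiency, paralysis, and dialysis procedures. The groupings follow
#' commonly published ICD-9-CM ranges; the sets are deliberately editable
#' configuration, not a fixed claim, and should be reviewed before any
#' real-data use.
#'
#' @return named list of character vectors of ICD-9 codes.
#' @export
default_exclusion_rules <- function() {
  list(
    prbc_transfusion   = c("9904"),
    rhabdomyolysis     = c("72888"),
    parathyroid        = c("2520", "2521", "2528", "2529"),
    sarcoid            = c("135"),
    ckd                = c("5851", "5852", "5853", "5854", "5859"),
    aki                = c("5845", "5846", "5847", "5848", "5849"),
    esrd               = c("5856"),
    cad                = c("41400", "41401", "4140", "4141"),
    chf                = c("4280", "4281", "42820", "42830", "42840", "4289"),
    afib               = c("42731"),
    nutritional_def    = c("260", "261", "262", "263", "2639"),
    paralysis          = c("3449", "34400", "3441"),
    dialysis_procedure = c("3995", "5498")
  )
}
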