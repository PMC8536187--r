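#' Electrolytes covered by the audit
#'
#' The closed set of serum electrolytes handled by every function in the
#' package: potassium (mEq/L), magnesium (mg/dL) and phosphate (mg/dL).
#'
#' @return Character vector of the three electrolyte names.
#' @export
electrolytes <- function() c("potassium", "magnesium", "phosphate")

#' Construct a set of nominal reference ranges
#'
#' A reference range is the laboratory interval within which a serum value is
#' flagged normal; values outside it are flagged abnormal and drive both the
#' below/within/above interpretation table and the near-miss analysis.
#'
#' @param electrolyte character vector of electrolyte names.
#' @param low,high numeric vectors of range bounds, `low < high` elementwise.
#' @param low_inclusive,high_inclusive logical, whether a value exactly at the
#'   bound counts as within range. Defaults to inclusive at both ends, the
#'   usual laboratory convention.
#' @return A `data.frame` of class `"reference_ranges"` with one row per
#'   electrolyte.
#' @seealso [default_reference_ranges()], [classify_value()]
#' @export
reference_ranges <- function(electrolyte, low, high,
                             low_inclusive = TRUE, high_inclusive = TRUE) {
  electrolyte <- match.arg(as.character(electrolyte), electrolytes(),
                           several.ok = TRUE)
  if (anyDuplicated(electrolyte))
    stop("duplicate electrolyte in reference ranges")
  low <- as.numeric(low); high <- as.numeric(high)
  if (any(!is.finite(low)) || any(!is.finite(high)) || any(low >= high))
    stop("reference ranges require finite low < high")
  out <- data.frame(
    electrolyte = electrolyte, low = low, high = high,
    low_inclusive = rep_len(as.logical(low_inclusive), length(electrolyte)),
    high_inclusive = rep_len(as.logical(high_inclusive), length(electrolyte)),
    stringsAsFactors = FALSE
  )
  class(out) <- c("reference_ranges", "data.frame")
  out
}

#' Default nominal reference ranges
#'
#' The nominal ranges used by the MIMIC-III laboratory system: potassium
#' 3.7--5.7 mEq/L, magnesium 2.5--4.5 mg/dL, phosphate 2.5--4.5 mg/dL,
#' inclusive at both bounds.
#'
#' Note that published MIMIC-III summary tables show magnesium "within"
#' group means near 2.0 mg/dL, which is inconsistent with the nominal
#' 2.5--4.5 magnesium range; the range actually applied by that system is
#' not recoverable. Ranges are therefore an explicit argument everywhere
#' they matter, and these defaults are a convenience, not a claim.
#'
#' @return A [reference_ranges()] object.
#' @export
default_reference_ranges <- function() {
  reference_ranges(
    electrolyte = c("potassium", "magnesium", "phosphate"),
    low  = c(3.7, 2.5, 2.5),
    high = c(5.7, 4.5, 4.5)
  )
}

#' Default physiologic error bounds
#'
#' Bounds outside which a serum value is treated as a recording error and
#' removed (strictly: a value exactly at a bound is retained): potassium
#' below 2 or above 7 mEq/L; magnesium below 1 or above 5 mg/dL; phosphate
#' below 0.5 or above 5 mg/dL.
#'
#' @return `data.frame` with columns `electrolyte`, `low`, `high`.
#' @seealso [apply_value_error_filter()]
#' @export
default_error_bounds <- function() {
  data.frame(
    electrolyte = c("potassium", "magnesium", "phosphate"),
    low  = c(2, 1, 0.5),
    high = c(7, 5, 5),
    stringsAsFactors = FALSE
  )
}

.range_row <- function(ranges, electrolyte) {
  i <- match(electrolyte, ranges$electrolyte)
  if (is.na(i))
    stop("no reference range configured for electrolyte '", electrolyte, "'")
  ranges[i, , drop = FALSE]
}

#' Classify a serum value against a reference range
#'
#' @param value numeric vector of serum values; must be finite.
#' @param range a single-row subset of a [reference_ranges()] object (or any
#'   list with `low`, `high`, `low_inclusive`, `high_inclusive`).
#' @return factor with levels `below < within < above`. The function is
#'   monotone: increasing the value never moves the label towards `below`.
#' @examples
#' rng <- default_reference_ranges()
#' classify_value(c(3.0, 3.7, 6.05), rng[rng$electrolyte == "potassium", ])
#' @export
classify_value <- function(value, range) {
  if (any(!is.finite(value)))
    stop("classify_value: non-finite value")
  below <- if (isTRUE(range$low_inclusive[1])) value < range$low[1]
           else value <= range$low[1]
  above <- if (isTRUE(range$high_inclusive[1])) value > range$high[1]
           else value >= range$high[1]
  factor(ifelse(below, "below", ifelse(above, "above", "within")),
         levels = c("below", "within", "above"))
}

# --- shared internal helpers -------------------------------------------------

# time origin for minute arithmetic; all timestamps are timezone-naive
# (stored as UTC) at minute resolution, so only differences are meaningful.
.time_origin <- as.POSIXct("2000-01-01 00:00:00", tz = "UTC")

.floor_minute <- function(t) {
  as.POSIXct(floor(as.numeric(t) / 60) * 60,
             origin = "1970-01-01", tz = "UTC")
}

# numeric minutes since the package origin
.as_minutes <- function(t) {
  as.numeric(difftime(t, .time_origin, units = "mins"))
}

.from_minutes <- function(m) {
  .time_origin + as.difftime(m, units = "mins")
}

.parse_timestamp <- function(x) {
  t <- as.POSIXct(x, tz = "UTC",
                  tryFormats = c("%Y-%m-%d %H:%M:%S", "%Y-%m-%d %H:%M",
                                 "%Y/%m/%d %H:%M:%S", "%Y-%m-%dT%H:%M:%S"))
  .floor_minute(t)
}

.parse_timestamp_quiet <- function(x) {
  out <- rep(.time_origin[NA], length(x))
  ok <- !is.na(x) & nzchar(x)
  if (any(ok)) {
    parsed <- suppressWarnings(tryCatch(.parse_timestamp(x[ok]),
                                        error = function(e) NULL))
    if (is.null(parsed)) {
      # fall back row-by-row so one bad row does not reject the batch
      parsed <- as.POSIXct(vapply(x[ok], function(s) {
        v <- tryCatch(.parse_timestamp(s), error = function(e) NA_real_)
        as.numeric(v)
      }, numeric(1)), origin = "1970-01-01", tz = "UTC")
    }
    out[ok] <- parsed
  }
  out
}

# round-half-up to `digits` decimals (base round() is round-half-even)
.round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

.format_time_cols <- function(df) {
  for (nm in names(df)) {
    if (inherits(df[[nm]], "POSIXct"))
      df[[nm]] <- format(df[[nm]], "%Y-%m-%d %H:%M:%S", tz = "UTC")
  }
  df
}
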