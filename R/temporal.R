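#' @title Circadian workflow and latency analyses
#' @name repleteaudit-temporal
#' @description
#' Hospital routine, not physiology, drives much of the repletion workflow:
#' lab draws cluster around the early-morning round (~06:00) with a smaller
#' evening peak, and orders follow a few hours later. These functions bin
#' events by clock hour, summarise lab-to-order and order-to-follow-up
#' latencies, and track the repletion threshold across the 24-hour day.
#' De-identified ICU timestamps are date-shifted but preserve time of day,
#' so the clock hour of the stored timestamp is used as-is.
NULL

#' Hour-of-day histogram
#'
#' @param times POSIXct vector (or anything [base::format()] renders with
#'   `%H`); each event is binned by its clock hour, `floor` semantics.
#' @return object of class `hour_histogram`: integer vector `counts` named
#'   `"0"`..`"23"` plus `total`.
#' @export
hour_histogram <- function(times) {
  h <- as.integer(format(times, "%H", tz = "UTC"))
  h <- h[!is.na(h)]
  counts <- tabulate(h + 1L, nbins = 24L)
  structure(list(counts = stats::setNames(counts, 0:23),
                 total = sum(counts)),
            class = "hour_histogram")
}

#' @export
print.hour_histogram <- function(x, ...) {
  cat("hour-of-day histogram, n =", x$total, "\n")
  peak <- modal_hour(x)
  cat("  modal hour:", peak, "\n")
  invisible(x)
}

#' @export
plot.hour_histogram <- function(x, main = "events by hour of day", ...) {
  graphics::barplot(x$counts, names.arg = names(x$counts),
                    xlab = "hour of day", ylab = "events", main = main, ...)
}

#' Modal hour of an hour histogram
#'
#' @param x an [hour_histogram()].
#' @return integer 0--23; ties resolve to the earliest hour.
#' @export
modal_hour <- function(x) {
  as.integer(names(x$counts)[which.max(x$counts)])
}

#' Latency summaries per electrolyte
#'
#' Mean, SD and median of the lab-to-order latency (index lab charttime to
#' order placement) and the order-to-follow-up latency, in minutes, over
#' episodes where both endpoints exist. Medians are reported alongside
#' means because the latency distributions are right-skewed.
#'
#' @param episodes episode table or `episode_linkage`.
#' @return `data.frame` with `electrolyte`, `kind`
#'   (`lab_to_order`/`order_to_followup`), `n`, `mean_minutes`,
#'   `sd_minutes`, `median_minutes`; electrolytes with no complete episodes
#'   get `n = 0` and `NA` summaries.
#' @export
latency_summary <- function(episodes) {
  if (inherits(episodes, "episode_linkage")) episodes <- episodes$episodes
  grid <- expand.grid(electrolyte = electrolytes(),
                      kind = c("lab_to_order", "order_to_followup"),
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    el <- grid$electrolyte[i]; kind <- grid$kind[i]
    col <- if (kind == "lab_to_order") "lab_to_order_minutes"
           else "order_to_followup_minutes"
    v <- episodes[[col]][episodes$electrolyte == el]
    v <- v[!is.na(v)]
    data.frame(electrolyte = el, kind = kind, n = length(v),
               mean_minutes = if (length(v)) mean(v) else NA_real_,
               sd_minutes = if (length(v) > 1) stats::sd(v) else NA_real_,
               median_minutes = if (length(v)) stats::median(v) else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Repletion threshold by hour of day
#'
#' Mean +/- SD of the index value per clock hour, separately for repletion
#' episodes (the de-facto threshold that triggered an order) and NR
#' episodes. Hours with no episodes are emitted with `n = 0`.
#'
#' @param episodes episode table or `episode_linkage`.
#' @param electrolyte optional single electrolyte to restrict to.
#' @return `data.frame` with `electrolyte`, `group`
#'   (`repletion`/`non_repletion`), `hour`, `n`, `mean_value`, `sd_value`.
#' @export
threshold_by_hour <- function(episodes, electrolyte = NULL) {
  if (inherits(episodes, "episode_linkage")) episodes <- episodes$episodes
  if (!is.null(electrolyte))
    episodes <- episodes[episodes$electrolyte %in% electrolyte, , drop = FALSE]
  hr <- as.integer(format(episodes$index_time, "%H", tz = "UTC"))
  grp <- ifelse(episodes$scenario == "NR", "non_repletion", "repletion")
  grid <- expand.grid(electrolyte = unique(episodes$electrolyte),
                      group = c("repletion", "non_repletion"),
                      hour = 0:23, stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    sel <- episodes$electrolyte == grid$electrolyte[i] &
      grp == grid$group[i] & hr == grid$hour[i]
    v <- episodes$index_value[sel]
    data.frame(electrolyte = grid$electrolyte[i], group = grid$group[i],
               hour = grid$hour[i], n = length(v),
               mean_value = if (length(v)) mean(v) else NA_real_,
               sd_value = if (length(v) > 1) stats::sd(v) else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$electrolyte, out$group, out$hour), , drop = FALSE] -> out
  rownames(out) <- NULL
  out
}
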