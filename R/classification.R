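#' @title Interpretation tables and repletion fractions
#' @name repleteaudit-classification
#' @description
#' Every episode's pre-order (index) value is labelled below/within/above
#' its nominal reference range, separately for episodes that ended in a
#' repletion and those that did not. The resulting interpretation table
#' (counts, percentages, mean +/- SD per cell) is the audit's headline
#' product: it shows how often orders were placed at values already within
#' or above range ("misses and near-misses").
NULL

#' Build the interpretation table
#'
#' Partitions episodes into cells by electrolyte, scenario group
#' (repletion = `ONE_L_ONE_R` or `MULTI_L_ONE_R`, non-repletion = `NR`) and
#' range label of the index value. Percentages are per (electrolyte, group),
#' half-up rounded to 2 decimals; empty cells are emitted with `n = 0` and
#' `NA` mean/SD.
#'
#' @param episodes episode table or `episode_linkage`.
#' @param ranges a [reference_ranges()] object covering every electrolyte
#'   present (mandatory: see [default_reference_ranges()] for why there is
#'   no implicit default here).
#' @return `data.frame` of class `interpretation_table` with columns
#'   `electrolyte`, `scenario_group`, `label`, `n`, `percent`,
#'   `mean_value`, `sd_value`.
#' @export
interpretation_table <- function(episodes, ranges) {
  if (inherits(episodes, "episode_linkage")) episodes <- episodes$episodes
  if (missing(ranges) || is.null(ranges))
    stop("interpretation_table: reference ranges must be supplied")
  present <- unique(episodes$electrolyte)
  if (length(setdiff(present, ranges$electrolyte)))
    stop("no reference range for: ",
         paste(setdiff(present, ranges$electrolyte), collapse = ", "))
  grp <- ifelse(episodes$scenario == "NR", "non_repletion", "repletion")
  out <- expand.grid(electrolyte = electrolytes(),
                     scenario_group = c("repletion", "non_repletion"),
                     label = c("above", "within", "below"),
                     stringsAsFactors = FALSE)
  out$n <- 0L; out$percent <- NA_real_
  out$mean_value <- NA_real_; out$sd_value <- NA_real_
  for (el in intersect(electrolytes(), present)) {
    lab <- classify_value(episodes$index_value[episodes$electrolyte == el],
                          .range_row(ranges, el))
    g <- grp[episodes$electrolyte == el]
    v <- episodes$index_value[episodes$electrolyte == el]
    for (sg in c("repletion", "non_repletion")) {
      tot <- sum(g == sg)
      for (lb in c("above", "within", "below")) {
        i <- out$electrolyte == el & out$scenario_group == sg & out$label == lb
        sel <- g == sg & lab == lb
        out$n[i] <- sum(sel)
        if (tot > 0) out$percent[i] <- .round_half_up(100 * sum(sel) / tot, 2)
        if (any(sel)) {
          out$mean_value[i] <- mean(v[sel])
          out$sd_value[i] <- stats::sd(v[sel])
        }
      }
    }
  }
  class(out) <- c("interpretation_table", "data.frame")
  out
}

#' @export
print.interpretation_table <- function(x, digits = 2, ...) {
  cat("interpretation of pre-order values (n, %, mean +/- sd)\n")
  for (el in unique(x$electrolyte)) {
    cat(el, ":\n", sep = "")
    sub <- x[x$electrolyte == el, ]
    for (i in seq_len(nrow(sub))) {
      cat(sprintf("  %-13s %-6s n=%7d  %6s%%  %s\n",
                  sub$scenario_group[i], sub$label[i], sub$n[i],
                  ifelse(is.na(sub$percent[i]), "--",
                         format(sub$percent[i], nsmall = 2)),
                  ifelse(is.na(sub$mean_value[i]), "",
                         sprintf("%.2f +/- %.2f", sub$mean_value[i],
                                 sub$sd_value[i] %||% NA))))
    }
  }
  invisible(x)
}

#' Interpretation percentages from printed cell counts
#'
#' Recomputes an interpretation table's percentage column from raw cell
#' counts alone (the worked-example path used to check published summary
#' tables): percentages are per (electrolyte, scenario_group), half-up
#' rounded to 2 decimals.
#'
#' @param counts `data.frame` with columns `electrolyte`, `scenario_group`,
#'   `label`, `n`.
#' @return the same table with a `percent` column appended.
#' @export
interpretation_percentages <- function(counts) {
  counts$percent <- NA_real_
  for (el in unique(counts$electrolyte)) {
    for (sg in unique(counts$scenario_group)) {
      i <- counts$electrolyte == el & counts$scenario_group == sg
      tot <- sum(counts$n[i])
      if (tot > 0)
        counts$percent[i] <- .round_half_up(100 * counts$n[i] / tot, 2)
    }
  }
  counts
}

#' Fraction of lab orders followed by repletion
#'
#' Per electrolyte, the number of repletion episodes divided by the total
#' number of episodes (repletion + NR). Ignored labs inside multi-lab
#' windows are part of their episode and are not counted as separate
#' orders. With zero episodes the fraction is `NA` (undefined), not zero.
#'
#' @param episodes episode table or `episode_linkage`. Alternatively a
#'   count table with columns `electrolyte`, `scenario_group`, `n`
#'   (worked-example path from printed counts).
#' @return `data.frame` with `electrolyte`, `n_repletion`, `n_total`,
#'   `percent` (half-up, 2 decimals).
#' @export
repletion_fraction <- function(episodes) {
  if (inherits(episodes, "episode_linkage")) episodes <- episodes$episodes
  if ("scenario_group" %in% names(episodes) && "n" %in% names(episodes)) {
    agg <- stats::aggregate(n ~ electrolyte + scenario_group, episodes, sum)
    els <- unique(agg$electrolyte)
    n_rep <- vapply(els, function(e)
      sum(agg$n[agg$electrolyte == e & agg$scenario_group == "repletion"]),
      numeric(1))
    n_tot <- vapply(els, function(e) sum(agg$n[agg$electrolyte == e]),
                    numeric(1))
  } else {
    els <- electrolytes()
    n_rep <- vapply(els, function(e)
      sum(episodes$electrolyte == e & episodes$scenario != "NR"), numeric(1))
    n_tot <- vapply(els, function(e) sum(episodes$electrolyte == e),
                    numeric(1))
  }
  data.frame(
    electrolyte = as.character(els),
    n_repletion = as.integer(n_rep),
    n_total = as.integer(n_tot),
    percent = ifelse(n_tot > 0, .round_half_up(100 * n_rep / n_tot, 2),
                     NA_real_),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Near-miss frequency: repletions ordered above range
#'
#' Fraction of repletion episodes whose index value was already above the
#' nominal range -- repletion on top of an elevated level is the audit's
#' "near miss". Equals the `above` cell percentage of the repletion group
#' of [interpretation_table()].
#'
#' @inheritParams interpretation_table
#' @return `data.frame` with `electrolyte`, `n_above`, `n_repletion`,
#'   `percent`.
#' @export
near_miss_frequencies <- function(episodes, ranges) {
  tab <- interpretation_table(episodes, ranges)
  rep_tab <- tab[tab$scenario_group == "repletion", ]
  out <- data.frame(electrolyte = unique(rep_tab$electrolyte),
                    stringsAsFactors = FALSE)
  out$n_above <- vapply(out$electrolyte, function(e)
    sum(rep_tab$n[rep_tab$electrolyte == e & rep_tab$label == "above"]),
    numeric(1))
  out$n_repletion <- vapply(out$electrolyte, function(e)
    sum(rep_tab$n[rep_tab$electrolyte == e]), numeric(1))
  out$percent <- ifelse(out$n_repletion > 0,
                        .round_half_up(100 * out$n_above / out$n_repletion, 2),
                        NA_real_)
  rownames(out) <- NULL
  out
}
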