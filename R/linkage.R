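#' @title 24-hour window linkage of labs to repletion orders
#' @name repleteaudit-linkage
#' @description
#' The audit's unit of analysis is the *episode*: an index lab value,
#' optionally the repletion order it triggered, and optionally the first
#' follow-up lab after the order. Within each (stay, electrolyte) stream,
#' every repletion order is anchored to the latest preceding lab of the same
#' electrolyte within a 24-hour window; when several labs precede the order
#' inside the window, the closest one is the index and the others are
#' recorded as ignored. Orders are assigned greedily in time order so each
#' lab is used or ignored by at most one order. Labs never linked to an
#' order, and with no order in the 24 hours after them, become no-repletion
#' (NR) episodes. The three resulting scenarios are `NR`, `ONE_L_ONE_R`
#' (single lab then one order) and `MULTI_L_ONE_R` (several labs, closest
#' used, others ignored).
NULL

#' Linkage configuration
#'
#' @param window_minutes length of the linkage window in minutes
#'   (default 1440 = 24 h).
#' @param preceding_inclusive should a lab charted at exactly the order time
#'   count as preceding it? Default `TRUE` (charting granularity makes exact
#'   ties common). The follow-up search is always strictly after the order,
#'   so the same draw is never both index and follow-up.
#' @param window_inclusive should a lab exactly `window_minutes` before the
#'   order still qualify? Default `TRUE`.
#' @param same_electrolyte_only when `TRUE` (default) potassium labs anchor
#'   only potassium orders, etc.; `FALSE` links within stay across
#'   electrolytes (for combination products).
#' @return list of class `linkage_config`.
#' @export
linkage_config <- function(window_minutes = 1440,
                           preceding_inclusive = TRUE,
                           window_inclusive = TRUE,
                           same_electrolyte_only = TRUE) {
  stopifnot(is.numeric(window_minutes), window_minutes > 0)
  structure(list(window_minutes = window_minutes,
                 preceding_inclusive = isTRUE(preceding_inclusive),
                 window_inclusive = isTRUE(window_inclusive),
                 same_electrolyte_only = isTRUE(same_electrolyte_only)),
            class = "linkage_config")
}

# group id per (stay, electrolyte) -- or per stay when cross-electrolyte
.linkage_gid <- function(stay_id, electrolyte, config) {
  key <- if (config$same_electrolyte_only)
    paste(stay_id, electrolyte, sep = "\r") else as.character(stay_id)
  key
}

.empty_episodes <- function() {
  data.frame(
    episode_id = integer(0), stay_id = character(0),
    subject_id = character(0), electrolyte = character(0),
    scenario = character(0),
    index_time = .from_minutes(numeric(0)), index_value = numeric(0),
    index_lab_id = integer(0), n_ignored = integer(0),
    order_time = .from_minutes(numeric(0)), dose = numeric(0),
    lab_to_order_minutes = numeric(0),
    followup_time = .from_minutes(numeric(0)), followup_value = numeric(0),
    followup_lab_id = integer(0), order_to_followup_minutes = numeric(0),
    stringsAsFactors = FALSE)
}

#' Match repletion orders to their index labs
#'
#' Core interval matcher. Equivalent to the following greedy procedure:
#' process orders in time order; each order takes every not-yet-used lab of
#' its stream charted at or before the order and within the window; the
#' closest such lab (ties: later charttime, then larger input row number)
#' is the index, the rest are ignored; remaining labs with no order in the
#' window after them are NR episodes. Orders with no qualifying lab are
#' reported in the `unanchored_repletions` side table, never dropped.
#'
#' @param labs lab table (canonical schema); input row order is immaterial
#'   except as the documented tie-break.
#' @param repletions repletion table (canonical schema).
#' @param config a [linkage_config()].
#' @return list of class `episode_linkage` with elements:
#'   `episodes` (one row per episode; follow-up columns all `NA` until
#'   [find_followup_lab()] is applied), `assignments` (one row per input
#'   lab: `lab_row`, `role` in index/ignored/nr, `episode_id`),
#'   `unanchored_repletions`, and `orphan_labs` (labs in no category;
#'   always empty under this matcher, kept so conservation is checkable).
#' @export
match_repletions_to_index_labs <- function(labs, repletions,
                                           config = linkage_config()) {
  w <- config$window_minutes
  nl <- nrow(labs); nr <- nrow(repletions)
  gid_keys <- unique(c(.linkage_gid(labs$stay_id, labs$electrolyte, config),
                       .linkage_gid(repletions$stay_id,
                                    repletions$electrolyte, config)))
  lg <- match(.linkage_gid(labs$stay_id, labs$electrolyte, config), gid_keys)
  rg <- match(.linkage_gid(repletions$stay_id, repletions$electrolyte,
                           config), gid_keys)
  lt <- floor(.as_minutes(labs$charttime))
  rt <- floor(.as_minutes(repletions$ordertime))

  # offset each stream so a single sorted vector supports findInterval
  span <- max(c(lt, rt, 0)) - min(c(lt, rt, 0)) + w + 2
  t0 <- min(c(lt, rt, 0))
  gl <- (lg - 1) * span + (lt - t0)
  gr <- (rg - 1) * span + (rt - t0)

  ro <- order(gr, seq_len(nr))           # orders sorted by group/time/row
  gr_s <- gr[ro]
  # first order at-or-after (or strictly after) each lab
  eps <- if (config$preceding_inclusive) 0.5 else -0.5
  pos <- findInterval(gl - eps, gr_s) + 1L
  cand <- pos >= 1L & pos <= nr
  rep_of_lab <- rep(NA_integer_, nl)
  if (nl && nr) {
    ok <- cand
    ok[ok] <- rg[ro[pos[ok]]] == lg[ok]
    dt <- rep(NA_real_, nl)
    dt[ok] <- rt[ro[pos[ok]]] - lt[ok]
    inw <- if (config$window_inclusive) dt <= w else dt < w
    ok <- ok & !is.na(inw) & inw
    rep_of_lab[ok] <- ro[pos[ok]]        # original repletion row
  }

  # per anchored repletion: labs sorted so the last one is the index
  # (latest charttime, ties broken by larger input row number)
  assigned <- which(!is.na(rep_of_lab))
  o <- assigned[order(rep_of_lab[assigned], lt[assigned], assigned)]
  is_index <- !duplicated(rep_of_lab[o], fromLast = TRUE)
  index_lab <- o[is_index]
  index_rep <- rep_of_lab[index_lab]
  n_lab_of_rep <- tabulate(rep_of_lab[assigned], nbins = max(nr, 1L))

  ep_rep <- .empty_episodes()
  if (length(index_rep)) {
    ord_by_time <- order(rt[index_rep], index_rep)
    index_rep <- index_rep[ord_by_time]; index_lab <- index_lab[ord_by_time]
    n_ign <- n_lab_of_rep[index_rep] - 1L
    ep_rep <- data.frame(
      episode_id = seq_along(index_rep),
      stay_id = as.character(labs$stay_id[index_lab]),
      subject_id = as.character(labs$subject_id[index_lab]),
      electrolyte = repletions$electrolyte[index_rep],
      scenario = ifelse(n_ign > 0L, "MULTI_L_ONE_R", "ONE_L_ONE_R"),
      index_time = .from_minutes(lt[index_lab]),
      index_value = labs$value[index_lab],
      index_lab_id = index_lab,
      n_ignored = n_ign,
      order_time = .from_minutes(rt[index_rep]),
      dose = repletions$dose[index_rep],
      lab_to_order_minutes = rt[index_rep] - lt[index_lab],
      followup_time = .from_minutes(NA_real_),
      followup_value = NA_real_, followup_lab_id = NA_integer_,
      order_to_followup_minutes = NA_real_,
      stringsAsFactors = FALSE)
  }

  nr_labs <- which(is.na(rep_of_lab))
  ep_nr <- .empty_episodes()
  if (length(nr_labs)) {
    ep_nr <- data.frame(
      episode_id = nrow(ep_rep) + seq_along(nr_labs),
      stay_id = as.character(labs$stay_id[nr_labs]),
      subject_id = as.character(labs$subject_id[nr_labs]),
      electrolyte = labs$electrolyte[nr_labs],
      scenario = "NR",
      index_time = .from_minutes(lt[nr_labs]),
      index_value = labs$value[nr_labs],
      index_lab_id = nr_labs,
      n_ignored = 0L,
      order_time = .from_minutes(NA_real_), dose = NA_real_,
      lab_to_order_minutes = NA_real_,
      followup_time = .from_minutes(NA_real_),
      followup_value = NA_real_, followup_lab_id = NA_integer_,
      order_to_followup_minutes = NA_real_,
      stringsAsFactors = FALSE)
  }
  episodes <- rbind(ep_rep, ep_nr)
  rownames(episodes) <- NULL

  ep_of_rep <- rep(NA_integer_, nr)
  ep_of_rep[index_rep] <- seq_along(index_rep)
  role <- rep("nr", nl)
  role[assigned] <- "ignored"
  role[index_lab] <- "index"
  episode_of_lab <- rep(NA_integer_, nl)
  episode_of_lab[assigned] <- ep_of_rep[rep_of_lab[assigned]]
  episode_of_lab[nr_labs] <- episodes$episode_id[
    match(nr_labs, episodes$index_lab_id)]
  assignments <- data.frame(lab_row = seq_len(nl), role = role,
                            episode_id = episode_of_lab,
                            stringsAsFactors = FALSE)

  unanchored <- repletions[is.na(ep_of_rep) & seq_len(nr) > 0, , drop = FALSE]
  structure(list(episodes = episodes, assignments = assignments,
                 unanchored_repletions = unanchored,
                 orphan_labs = labs[integer(0), , drop = FALSE],
                 config = config),
            class = "episode_linkage")
}

#' Scenario label of an episode
#'
#' Total function: `NR` when no repletion is attached, `ONE_L_ONE_R` for a
#' repletion with no ignored labs, `MULTI_L_ONE_R` for a repletion with at
#' least one ignored lab.
#'
#' @param episodes episode table (rows of `episodes` from
#'   [match_repletions_to_index_labs()]).
#' @return character vector of scenario labels.
#' @export
classify_scenario <- function(episodes) {
  has_rep <- !is.na(episodes$order_time)
  ifelse(!has_rep, "NR",
         ifelse(episodes$n_ignored > 0L, "MULTI_L_ONE_R", "ONE_L_ONE_R"))
}

#' Attach the post-repletion follow-up lab
#'
#' For every episode with a repletion, the follow-up is the earliest lab of
#' the same stream charted strictly after the order and no more than
#' `window_minutes` later. A lab may serve simultaneously as follow-up of
#' one episode and as index/NR lab of another (dual role is intended: the
#' next routine draw both checks the last order and triggers the next
#' decision). NR episodes are left untouched.
#'
#' @param linkage an `episode_linkage` from
#'   [match_repletions_to_index_labs()].
#' @param labs the same lab table used for matching.
#' @param config a [linkage_config()]; defaults to the one stored in
#'   `linkage`.
#' @return the `episode_linkage` with follow-up columns filled in.
#' @export
find_followup_lab <- function(linkage, labs, config = linkage$config) {
  ep <- linkage$episodes
  rep_rows <- which(!is.na(ep$order_time))
  if (!length(rep_rows) || !nrow(labs)) return(linkage)
  w <- config$window_minutes
  gid_keys <- unique(c(.linkage_gid(labs$stay_id, labs$electrolyte, config),
                       .linkage_gid(ep$stay_id[rep_rows],
                                    ep$electrolyte[rep_rows], config)))
  lg <- match(.linkage_gid(labs$stay_id, labs$electrolyte, config), gid_keys)
  eg <- match(.linkage_gid(ep$stay_id[rep_rows], ep$electrolyte[rep_rows],
                           config), gid_keys)
  lt <- floor(.as_minutes(labs$charttime))
  et <- floor(.as_minutes(ep$order_time[rep_rows]))
  span <- max(c(lt, et, 0)) - min(c(lt, et, 0)) + w + 2
  t0 <- min(c(lt, et, 0))
  # sort labs by (group, time, row) so ties resolve to the earliest draw,
  # then the smallest row number
  lo <- order((lg - 1) * span + (lt - t0), seq_along(lt))
  gl_s <- ((lg - 1) * span + (lt - t0))[lo]
  ge <- (eg - 1) * span + (et - t0)
  pos <- findInterval(ge + 0.5, gl_s) + 1L      # first lab strictly after
  ok <- pos >= 1L & pos <= length(gl_s)
  ok[ok] <- lg[lo[pos[ok]]] == eg[ok]
  dt <- rep(NA_real_, length(rep_rows))
  dt[ok] <- lt[lo[pos[ok]]] - et[ok]
  ok <- ok & !is.na(dt) & dt <= w
  fu <- lo[pos[ok]]
  rows <- rep_rows[ok]
  ep$followup_time[rows] <- .from_minutes(lt[fu])
  ep$followup_value[rows] <- labs$value[fu]
  ep$followup_lab_id[rows] <- fu
  ep$order_to_followup_minutes[rows] <- dt[ok]
  linkage$episodes <- ep
  linkage
}

#' Link labs and repletions into classified episodes
#'
#' Convenience wrapper: [match_repletions_to_index_labs()] then
#' [find_followup_lab()].
#'
#' @inheritParams match_repletions_to_index_labs
#' @return an `episode_linkage`.
#' @export
link_episodes <- function(labs, repletions, config = linkage_config()) {
  find_followup_lab(
    match_repletions_to_index_labs(labs, repletions, config), labs, config)
}

#' @export
print.episode_linkage <- function(x, ...) {
  tab <- table(x$episodes$scenario)
  cat("episode linkage: ", nrow(x$episodes), " episodes (",
      paste(names(tab), as.integer(tab), sep = "=", collapse = ", "),
      "); ", nrow(x$unanchored_repletions), " unanchored repletions\n",
      sep = "")
  invisible(x)
}

#' Scenario counts and percentages
#'
#' Counts episodes per scenario and electrolyte. Percentages are computed
#' among repletion episodes only (`ONE_L_ONE_R` + `MULTI_L_ONE_R` = 100%);
#' when an electrolyte has no repletion episodes its percentages are `NA`
#' (undefined), never 0/0.
#'
#' @param episodes episode table, or an `episode_linkage`.
#' @return `data.frame` with columns `electrolyte`, `scenario`, `n`,
#'   `pct_of_repletion`.
#' @export
scenario_frequencies <- function(episodes) {
  if (inherits(episodes, "episode_linkage")) episodes <- episodes$episodes
  scen <- c("NR", "ONE_L_ONE_R", "MULTI_L_ONE_R")
  els <- electrolytes()
  out <- expand.grid(electrolyte = els, scenario = scen,
                     stringsAsFactors = FALSE)
  out$n <- mapply(function(e, s)
    sum(episodes$electrolyte == e & episodes$scenario == s),
    out$electrolyte, out$scenario)
  out$pct_of_repletion <- NA_real_
  for (e in els) {
    nrep <- sum(out$n[out$electrolyte == e & out$scenario != "NR"])
    if (nrep > 0) {
      i <- out$electrolyte == e & out$scenario != "NR"
      out$pct_of_repletion[i] <- .round_half_up(100 * out$n[i] / nrep, 2)
    }
  }
  out[order(match(out$electrolyte, els), match(out$scenario, scen)), ,
      drop = FALSE] -> out
  rownames(out) <- NULL
  out
}
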