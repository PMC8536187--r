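# Independent O(n^2) brute-force implementation of the episode matcher and
# follow-up search, written directly from the rules: greedy over repletions
# in time order (ties: input row); each order consumes every unconsumed lab
# of its (stay, electrolyte) stream charted at-or-before the order within
# the window; index = latest consumed lab (ties: later charttime, then
# larger input row); follow-up = earliest lab strictly after the order
# within the window, any lab. Kept loop-based and obvious on purpose.
oracle_link <- function(labs, repletions, window = 1440) {
  origin <- as.POSIXct("2000-01-01", tz = "UTC")
  lt <- floor(as.numeric(difftime(labs$charttime, origin, units = "mins")))
  rt <- floor(as.numeric(difftime(repletions$ordertime, origin,
                                  units = "mins")))
  nl <- length(lt); nr <- length(rt)
  consumed <- rep(FALSE, nl)
  rep_of_lab <- rep(NA_integer_, nl)
  index_of_rep <- rep(NA_integer_, nr)
  for (r in order(rt, seq_len(nr))) {
    qual <- which(!consumed &
                    as.character(labs$stay_id) ==
                      as.character(repletions$stay_id[r]) &
                    labs$electrolyte == repletions$electrolyte[r] &
                    lt <= rt[r] & (rt[r] - lt) <= window)
    if (!length(qual)) next
    consumed[qual] <- TRUE
    rep_of_lab[qual] <- r
    best <- qual[order(lt[qual], qual)]
    index_of_rep[r] <- best[length(best)]
  }
  # follow-ups exist only for anchored orders (those that form an episode)
  followup_of_rep <- vapply(seq_len(nr), function(r) {
    if (is.na(index_of_rep[r])) return(NA_integer_)
    cand <- which(as.character(labs$stay_id) ==
                    as.character(repletions$stay_id[r]) &
                    labs$electrolyte == repletions$electrolyte[r] &
                    lt > rt[r] & (lt - rt[r]) <= window)
    if (!length(cand)) return(NA_integer_)
    cand[order(lt[cand], cand)][1]
  }, integer(1))
  list(rep_of_lab = rep_of_lab, index_of_rep = index_of_rep,
       followup_of_rep = followup_of_rep,
       nr_labs = which(is.na(rep_of_lab)),
       unanchored = which(is.na(index_of_rep)))
}

# canonical comparison form of the package matcher, aligned to oracle output
package_link_canonical <- function(labs, repletions, window = 1440) {
  lk <- link_episodes(labs, repletions, linkage_config(window))
  ep <- lk$episodes
  nl <- nrow(labs); nr <- nrow(repletions)
  rep_of_lab <- rep(NA_integer_, nl)
  index_of_rep <- rep(NA_integer_, nr)
  followup_of_rep <- rep(NA_integer_, nr)
  rep_rows <- which(!is.na(ep$order_time))
  if (length(rep_rows)) {
    origin <- as.POSIXct("2000-01-01", tz = "UTC")
    rt <- floor(as.numeric(difftime(repletions$ordertime, origin,
                                    units = "mins")))
    for (i in rep_rows) {
      # recover the repletion row from stay/electrolyte/ordertime (+dose)
      cand <- which(as.character(repletions$stay_id) == ep$stay_id[i] &
                      repletions$electrolyte == ep$electrolyte[i] &
                      rt == floor(as.numeric(difftime(ep$order_time[i],
                                                      origin,
                                                      units = "mins"))))
      cand <- setdiff(cand, which(!is.na(index_of_rep)))
      r <- cand[1]
      index_of_rep[r] <- ep$index_lab_id[i]
      followup_of_rep[r] <- ep$followup_lab_id[i]
    }
  }
  asn <- lk$assignments
  for (i in which(asn$role != "nr")) {
    epi <- ep[asn$episode_id[i], ]
    cand <- which(!is.na(index_of_rep) & index_of_rep == epi$index_lab_id)
    rep_of_lab[i] <- cand[1]
  }
  list(rep_of_lab = rep_of_lab, index_of_rep = index_of_rep,
       followup_of_rep = followup_of_rep,
       nr_labs = which(asn$role == "nr"),
       unanchored = which(is.na(index_of_rep)))
}

# random small dense instance: heavy window overlap on purpose
random_instance <- function(seed, max_events = 300) {
  set.seed(seed)
  n_stays <- sample(1:3, 1)
  els <- sample(electrolytes(), sample(1:3, 1))
  nl <- sample(2:floor(max_events * 2 / 3), 1)
  nr <- sample(1:floor(max_events / 3), 1)
  origin <- as.POSIXct("2000-01-01", tz = "UTC")
  span <- sample(c(2000, 5000, 50000), 1)
  labs <- data.frame(
    subject_id = 1L,
    stay_id = sample(n_stays, nl, replace = TRUE),
    electrolyte = sample(els, nl, replace = TRUE),
    charttime = origin + sample.int(span, nl, replace = TRUE) * 60,
    value = round(runif(nl, 1, 6), 2),
    stringsAsFactors = FALSE)
  reps <- data.frame(
    subject_id = 1L,
    stay_id = sample(n_stays, nr, replace = TRUE),
    electrolyte = sample(els, nr, replace = TRUE),
    ordertime = origin + sample.int(span, nr, replace = TRUE) * 60,
    dose = 20,
    stringsAsFactors = FALSE)
  list(labs = labs, repletions = reps)
}

expect_matches_oracle <- function(inst, window = 1440) {
  got <- package_link_canonical(inst$labs, inst$repletions, window)
  want <- oracle_link(inst$labs, inst$repletions, window)
  testthat::expect_identical(got$index_of_rep, want$index_of_rep)
  testthat::expect_identical(got$rep_of_lab, want$rep_of_lab)
  testthat::expect_identical(got$followup_of_rep, want$followup_of_rep)
  testthat::expect_identical(got$nr_labs, want$nr_labs)
  testthat::expect_identical(got$unanchored, want$unanchored)
}
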