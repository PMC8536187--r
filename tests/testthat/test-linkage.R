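test_that("the three clinical scenarios come out of hand-built streams", {
  # lone lab, no order within 24 h -> NR
  lk <- link_episodes(make_labs(t_at("06:00"), 3.1), make_reps(t_at("06:00"))[0, ])
  expect_equal(lk$episodes$scenario, "NR")

  # single lab then one order -> 1L->1R, with latency in minutes
  lk <- link_episodes(make_labs(t_at("06:00"), 3.1), make_reps(t_at("09:36")))
  expect_equal(lk$episodes$scenario, "ONE_L_ONE_R")
  expect_equal(lk$episodes$lab_to_order_minutes, 216)

  # labs at 0 h and 2 h, order at 3 h -> ML->1R, closest used, other ignored
  lk <- link_episodes(make_labs(c(t_at("00:00"), t_at("02:00")), c(3.0, 3.2)),
                      make_reps(t_at("03:00")))
  expect_equal(lk$episodes$scenario, "MULTI_L_ONE_R")
  expect_equal(lk$episodes$index_value, 3.2)
  expect_equal(lk$episodes$n_ignored, 1L)
  expect_equal(classify_scenario(lk$episodes), "MULTI_L_ONE_R")

  # order 25 h after the only lab: lab is NR, order goes to the side list
  lk <- link_episodes(make_labs(t_at("00:00"), 3.0),
                      make_reps(t_at("01:00", day = 1)))
  expect_equal(lk$episodes$scenario, "NR")
  expect_equal(nrow(lk$unanchored_repletions), 1)

  # 3 qualifying labs + one order -> two ignored
  lk <- link_episodes(
    make_labs(c(t_at("01:00"), t_at("02:00"), t_at("03:00")), c(3, 3.1, 3.2)),
    make_reps(t_at("04:00")))
  expect_equal(lk$episodes$n_ignored, 2L)
})

test_that("window boundaries: at-order labs precede, follow-ups are strict", {
  # lab at exactly the order time counts as preceding
  lk <- link_episodes(make_labs(t_at("09:00"), 3.1), make_reps(t_at("09:00")))
  expect_equal(lk$episodes$scenario, "ONE_L_ONE_R")
  expect_equal(lk$episodes$lab_to_order_minutes, 0)
  # ... and does not double as its own follow-up
  expect_true(is.na(lk$episodes$followup_value))

  # follow-up = closest lab strictly after the order, within 24 h
  labs <- make_labs(c(t_at("06:00"), t_at("12:00"), t_at("18:00")),
                    c(3.1, 3.8, 4.0))
  lk <- link_episodes(labs, make_reps(t_at("09:00")))
  ep <- lk$episodes[lk$episodes$scenario != "NR", ]
  expect_equal(ep$followup_value, 3.8)
  expect_equal(ep$order_to_followup_minutes, 180)

  # no lab in the 24 h after the order -> follow-up absent
  lk <- link_episodes(make_labs(c(t_at("06:00"), t_at("11:00", day = 2)),
                                c(3.1, 3.8)),
                      make_reps(t_at("09:00")))
  ep <- lk$episodes[lk$episodes$scenario != "NR", ]
  expect_true(is.na(ep$followup_value))

  # a lab exactly 24 h before the order still qualifies (inclusive default)
  lk <- link_episodes(make_labs(t_at("06:00"), 3.1),
                      make_reps(t_at("06:00", day = 1)))
  expect_equal(lk$episodes$scenario, "ONE_L_ONE_R")
  expect_equal(lk$episodes$lab_to_order_minutes, 1440)
})

test_that("every lab lands in exactly one role and output ignores row order", {
  inst <- random_instance(404)
  lk <- link_episodes(inst$labs, inst$repletions)
  roles <- lk$assignments$role
  expect_equal(length(roles), nrow(inst$labs))
  expect_true(all(roles %in% c("index", "ignored", "nr")))
  expect_equal(sum(roles == "index") + nrow(lk$unanchored_repletions),
               nrow(inst$repletions))
  expect_equal(sum(roles == "nr"), sum(lk$episodes$scenario == "NR"))
  expect_equal(nrow(lk$orphan_labs), 0)

  # permuting input rows leaves the episode set identical
  perm <- sample(nrow(inst$labs))
  lk2 <- link_episodes(inst$labs[perm, ], inst$repletions[
    sample(nrow(inst$repletions)), ])
  key <- function(x) {
    e <- x$episodes
    e <- e[order(e$stay_id, e$electrolyte, e$index_time, e$scenario),
           c("stay_id", "electrolyte", "scenario", "index_value",
             "lab_to_order_minutes", "order_to_followup_minutes",
             "followup_value", "n_ignored")]
    rownames(e) <- NULL
    e
  }
  expect_equal(key(lk), key(lk2))
})

test_that("enlarging the window never increases the NR count", {
  for (seed in 1:20) {
    inst <- random_instance(seed, max_events = 120)
    nr_counts <- vapply(c(360, 720, 1440, 2880), function(w)
      sum(link_episodes(inst$labs, inst$repletions,
                        linkage_config(w))$episodes$scenario == "NR"),
      numeric(1))
    expect_true(all(diff(nr_counts) <= 0))
  }
})

test_that("the matcher equals the brute-force oracle on dense random streams", {
  for (seed in 1:60) expect_matches_oracle(random_instance(seed, 120))
  # a couple of non-default windows
  for (seed in 61:70) expect_matches_oracle(random_instance(seed, 80),
                                            window = 600)
})

test_that("scenario frequencies normalise among repletion episodes", {
  ep <- make_episodes("potassium", c("ONE_L_ONE_R", "MULTI_L_ONE_R"),
                      c(3.1, 3.2))
  sf <- scenario_frequencies(ep)
  k <- sf[sf$electrolyte == "potassium" & sf$scenario != "NR", ]
  expect_equal(k$pct_of_repletion, c(50, 50))

  # all-NR: percentages undefined, not 0/0
  sf0 <- scenario_frequencies(make_episodes("potassium", "NR", 3.1))
  expect_true(all(is.na(sf0$pct_of_repletion)))

  # planted 0.6/0.4 singular/multiple mix is recovered
  g <- generate_cohort(generator_params(n_stays = 1500, seed = 21,
                                        scenario_mix = 0.4))
  co <- build_cohort(g$tables, g$params$exclusion_rules)
  sf <- scenario_frequencies(link_episodes(co$labs, co$repletions))
  multi <- sf$n[sf$scenario == "MULTI_L_ONE_R"]
  nrep <- multi + sf$n[sf$scenario == "ONE_L_ONE_R"]
  phat <- sum(multi) / sum(nrep)
  se <- sqrt(0.4 * 0.6 / sum(nrep))
  expect_lt(abs(phat - 0.4), 3 * se + 1e-9)
})
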