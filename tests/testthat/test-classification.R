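k_range <- function() {
  r <- default_reference_ranges()
  r[r$electrolyte == "potassium", ]
}

test_that("classify_value respects bounds, inclusivity and monotonicity", {
  expect_equal(as.character(classify_value(c(3.00, 3.7, 4.2, 5.7, 6.05),
                                           k_range())),
               c("below", "within", "within", "within", "above"))
  excl <- reference_ranges("potassium", 3.7, 5.7, low_inclusive = FALSE,
                           high_inclusive = FALSE)
  expect_equal(as.character(classify_value(c(3.7, 5.7), excl)),
               c("below", "above"))
  expect_error(classify_value(NaN, k_range()), "non-finite")

  # monotone: increasing value never moves the label towards 'below'
  v <- sort(runif(200, 1, 8))
  lab <- as.integer(classify_value(v, k_range()))
  expect_true(all(diff(lab) >= 0))
})

test_that("interpretation table partitions episodes and normalises percents", {
  set.seed(31)
  n <- 500
  ep <- make_episodes("potassium",
                      sample(c("NR", "ONE_L_ONE_R"), n, replace = TRUE),
                      runif(n, 2.5, 6.5))
  tab <- interpretation_table(ep, default_reference_ranges())
  k <- tab[tab$electrolyte == "potassium", ]
  expect_equal(sum(k$n), n)                          # partition completeness
  for (sg in c("repletion", "non_repletion")) {
    p <- k$percent[k$scenario_group == sg]
    expect_lt(abs(sum(p) - 100), 0.02 + 1e-9)
  }
  # permutation invariance
  tab2 <- interpretation_table(ep[sample(n), ], default_reference_ranges())
  expect_equal(tab, tab2)
  # all values inside the range -> 100% within
  ep_in <- make_episodes("potassium", "ONE_L_ONE_R", runif(50, 3.8, 5.5))
  t_in <- interpretation_table(ep_in, default_reference_ranges())
  expect_equal(t_in$percent[t_in$electrolyte == "potassium" &
                              t_in$scenario_group == "repletion" &
                              t_in$label == "within"], 100)
  # ranges are mandatory
  expect_error(interpretation_table(ep), "ranges")
})

test_that("published audit counts reproduce their printed percentages", {
  counts <- read.csv(system.file("extdata",
                                 "mimic3_audit_interpretation_counts.csv",
                                 package = "repleteaudit"))
  pct <- interpretation_percentages(counts)
  get <- function(el, sg, lb)
    pct$percent[pct$electrolyte == el & pct$scenario_group == sg &
                  pct$label == lb]
  expect_equal(get("potassium", "repletion", "above"), 0.38)
  expect_equal(get("potassium", "repletion", "within"), 89.31)
  expect_equal(get("potassium", "repletion", "below"), 10.31)
  expect_equal(get("potassium", "non_repletion", "within"), 86.81)
  expect_equal(get("magnesium", "repletion", "within"), 81.24)
  expect_equal(get("phosphate", "repletion", "below"), 97.63)
})

test_that("repletion fraction counts episodes, not ignored labs", {
  # worked example from published counts: 7166 of 221032 potassium episodes
  counts <- data.frame(
    electrolyte = "potassium",
    scenario_group = c("repletion", "non_repletion"),
    n = c(7166, 213866))
  rf <- repletion_fraction(counts)
  expect_equal(rf$percent, 3.24)

  # episode path: ML->1R ignored labs are inside their episode
  ep <- rbind(make_episodes("potassium", c("MULTI_L_ONE_R", "NR", "NR"),
                            c(3.1, 4, 4.2)))
  ep$n_ignored[1] <- 2L
  rf <- repletion_fraction(ep)
  expect_equal(rf$n_total[rf$electrolyte == "potassium"], 3L)

  # all NR -> 0%; no episodes -> undefined
  expect_equal(repletion_fraction(
    make_episodes("potassium", "NR", 4))$percent[1], 0)
  expect_true(all(is.na(repletion_fraction(
    make_episodes("potassium", "NR", 4)[0, ])$percent)))

  # planted per-window repletion probability is recovered
  set.seed(77)
  n <- 20000
  scen <- ifelse(runif(n) < 0.10, "ONE_L_ONE_R", "NR")
  rf <- repletion_fraction(make_episodes("magnesium", scen, 2))
  phat <- rf$n_repletion[rf$electrolyte == "magnesium"] / n
  expect_lt(abs(phat - 0.10), 3 * sqrt(0.1 * 0.9 / n))
})

test_that("near misses are the above-range share of repletion episodes", {
  set.seed(41)
  vals <- c(rep(6.0, 27), rep(4.0, 6400), rep(3.0, 739))
  ep <- make_episodes("potassium", "ONE_L_ONE_R", vals)
  nm <- near_miss_frequencies(ep, default_reference_ranges())
  expect_equal(nm$percent[nm$electrolyte == "potassium"], 0.38)
  # no above-range repletions -> 0%
  ep2 <- make_episodes("phosphate", "ONE_L_ONE_R", rep(2.0, 10))
  nm2 <- near_miss_frequencies(ep2, default_reference_ranges())
  expect_equal(nm2$percent[nm2$electrolyte == "phosphate"], 0)
  # shuffled copy agrees exactly
  nm3 <- near_miss_frequencies(ep[sample(nrow(ep)), ],
                               default_reference_ranges())
  expect_equal(nm3, nm)
})
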