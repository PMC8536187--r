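test_that("age filter: 'under 18' is strict, missing age is its own reason", {
  stays <- make_stays(4)
  stays$age_years <- c(17.9, 18, 44.2, NA)
  r <- apply_age_filter(stays, 18)
  expect_equal(r$stays$stay_id, c(2L, 3L))
  expect_equal(r$log$n_removed[r$log$rule == "age_missing"], 1L)
  expect_equal(r$log$n_removed[r$log$rule == "age_under_18"], 1L)
})

test_that("only the first-listed diagnosis can exclude a stay", {
  stays <- make_stays(3)
  rules <- list(chf = c("4280", "4281"))
  dx <- rbind(
    make_diagnoses(1L, "4280", 1L),          # first dx excluded
    make_diagnoses(1L, "25000", 2L),
    make_diagnoses(2L, "25000", 1L),         # excluded code only at seq 2
    make_diagnoses(2L, "4280", 2L),
    make_diagnoses(3L, "486", 1L))
  r <- apply_diagnosis_exclusions(stays, dx, rules)
  expect_equal(r$stays$stay_id, c(2L, 3L))
  expect_equal(r$log$n_removed[r$log$rule == "dx_chf"], 1L)
  # empty rule list is the identity
  r0 <- apply_diagnosis_exclusions(stays, dx, list())
  expect_equal(r0$stays$stay_id, stays$stay_id)
  # a stay with no diagnosis at all is excluded with a distinct reason
  r1 <- apply_diagnosis_exclusions(stays, dx[dx$stay_id != 3L, ], list())
  expect_equal(r1$log$n_removed[r1$log$rule == "diagnosis_missing"], 1L)
})

test_that("value error bounds remove strictly-outside values only", {
  labs <- make_labs(rep(t_at("06:00"), 7),
                    values = c(1.9, 2.0, 7.0, 7.1, 3.5, 5.1, 0.5),
                    electrolyte = c(rep("potassium", 5), "magnesium",
                                    "phosphate"))
  r <- apply_value_error_filter(labs)
  expect_equal(r$labs$value, c(2.0, 7.0, 3.5, 0.5))
  expect_equal(sum(r$log$n_removed), 3L)
  # an electrolyte without configured bounds is a hard error
  expect_error(
    apply_value_error_filter(labs,
                             data.frame(electrolyte = "potassium",
                                        low = 2, high = 7)),
    "magnesium")
})

test_that("build_cohort applies the cascade in order with a conservative log", {
  g <- generate_cohort(generator_params(n_stays = 400, seed = 5))
  co <- build_cohort(g$tables, g$params$exclusion_rules)
  log <- co$attrition
  for (lv in unique(log$level)) {
    sub <- log[log$level == lv, ]
    expect_true(all(diff(sub$n_remaining) <= 0))
    init <- sub$n_remaining[1] + sub$n_removed[1]
    expect_equal(sub$n_remaining[nrow(sub)], init - sum(sub$n_removed))
  }
  # planted exclusion counts are recovered exactly
  expect_equal(log$n_removed[log$rule == "age_under_18"],
               g$truth$planted$n_minors)
  expect_equal(sum(log$n_removed[startsWith(log$rule, "dx_")]),
               g$truth$planted$n_dx_excluded)
  expect_equal(sum(log$n_removed[startsWith(log$rule, "value_error_")]),
               g$truth$planted$n_error_values)
  expect_equal(log$n_removed[log$rule == "no_lab_or_repletion"],
               g$truth$planted$n_stays_no_event)

  # idempotence: running the cascade again on its own output changes nothing
  co2 <- build_cohort(list(labs = co$labs, repletions = co$repletions,
                           stays = co$stays, diagnoses = co$diagnoses),
                      g$params$exclusion_rules)
  expect_equal(sum(co2$attrition$n_removed), 0L)
  expect_equal(co2$stays$stay_id, co$stays$stay_id)
  expect_equal(co2$labs$value, co$labs$value)
})

test_that("no rules means identity; non-overlapping rules commute", {
  g <- generate_cohort(generator_params(n_stays = 150, seed = 9))
  co <- build_cohort(g$tables, exclusion_rules = list(), minimum_age = NULL,
                     error_bounds = NULL)
  # only the no-event rule may act
  expect_equal(nrow(co$attrition), 1L)
  expect_equal(nrow(co$stays) + co$attrition$n_removed[1],
               nrow(g$tables$stays))

  rules <- g$params$exclusion_rules[c("chf", "aki")]
  a <- build_cohort(g$tables, rules)
  b <- build_cohort(g$tables, rev(rules))
  expect_setequal(a$stays$stay_id, b$stays$stay_id)
})

test_that("excluded codes at seq_num >= 2 never change the cohort", {
  g <- generate_cohort(generator_params(n_stays = 200, seed = 13))
  co <- build_cohort(g$tables, g$params$exclusion_rules)
  # drop all secondary diagnoses: same cohort
  t2 <- g$tables
  t2$diagnoses <- t2$diagnoses[t2$diagnoses$seq_num == 1, ]
  co2 <- build_cohort(t2, g$params$exclusion_rules)
  expect_equal(co$stays$stay_id, co2$stays$stay_id)
})
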