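test_that("the generator is deterministic given its seed", {
  p <- generator_params(n_stays = 120, seed = 31)
  g1 <- generate_cohort(p)
  g2 <- generate_cohort(p)
  expect_identical(g1$tables, g2$tables)

  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  generate_cohort(p, dir = d1); generate_cohort(p, dir = d2)
  for (f in c("labs.csv", "repletions.csv", "stays.csv", "diagnoses.csv",
              "truth.json"))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))

  # a different seed produces different draws
  g3 <- generate_cohort(generator_params(n_stays = 120, seed = 32))
  expect_false(identical(g1$tables$labs$value, g3$tables$labs$value))
})

test_that("a zero repletion target produces no orders at all", {
  p <- generator_params(n_stays = 150, seed = 2,
                        target_repletion_fraction = c(potassium = 0,
                                                      magnesium = 0,
                                                      phosphate = 0))
  g <- generate_cohort(p)
  expect_equal(nrow(g$tables$repletions), 0)
  expect_equal(g$truth$per_electrolyte$potassium$repletion_fraction_pct, 0)
})

test_that("infeasible repletion targets are rejected with an explanation", {
  expect_error(
    generator_params(target_repletion_fraction = c(potassium = 0.9,
                                                   magnesium = 0.1,
                                                   phosphate = 0.16)),
    "infeasible")
})

test_that("Monte-Carlo draws match the quadrature expectations", {
  p <- generator_params()
  set.seed(55)
  n <- 200000
  for (el in c("potassium", "phosphate")) {
    eb <- p$error_bounds[p$error_bounds$electrolyte == el, ]
    v <- repleteaudit:::.rtrunc_norm(n, p$value_mean[[el]], p$value_sd[[el]],
                                     eb$low, eb$high)
    pr <- p$repletion_base[[el]] *
      plogis((p$repletion_theta[[el]] - v) / p$repletion_slope[[el]])
    se <- sd(pr) / sqrt(n)
    expect_lt(abs(mean(pr) - p$p_bar[[el]]), 3 * se)
    # all genuine values sit inside the physiologic bounds
    expect_true(all(v >= eb$low & v <= eb$high))
  }
  # truncated-lognormal latency mean matches its analytic form
  L <- repleteaudit:::.rtrunc_lnorm(n, p$latency_meanlog[["potassium"]],
                                    p$latency_sdlog, 0, 1440)
  m_an <- repleteaudit:::.trunc_lnorm_mean(p$latency_meanlog[["potassium"]],
                                           p$latency_sdlog, 0, 1440)
  expect_lt(abs(mean(L) - m_an), 3 * sd(L) / sqrt(n))
  expect_true(all(L <= 1440))
})

test_that("planted truth degenerates correctly", {
  # zero post shift -> expected d = 0
  p0 <- generator_params(target_d = c(potassium = 0, magnesium = 0,
                                      phosphate = 0))
  tr0 <- planted_truth(p0)
  expect_equal(tr0$per_electrolyte$potassium$d_cohen, 0)
  # a value distribution entirely inside a wide range -> all mass 'within'
  wide <- reference_ranges(electrolytes(), low = c(0.1, 0.1, 0.1),
                           high = c(10, 10, 10))
  tr_w <- planted_truth(generator_params(), wide)
  expect_equal(unname(tr_w$per_electrolyte$magnesium$cells_repletion["within"]),
               1, tolerance = 1e-9)
})

test_that("generated events respect their stay bounds and the closed sets", {
  g <- generate_cohort(generator_params(n_stays = 200, seed = 77))
  labs <- g$tables$labs; stays <- g$tables$stays
  i <- match(labs$stay_id, stays$stay_id)
  expect_true(all(labs$charttime >= stays$intime[i]))
  expect_true(all(labs$charttime <= stays$outtime[i]))
  expect_true(all(labs$electrolyte %in% electrolytes()))
  expect_true(all(labs$value > 0))
  reps <- g$tables$repletions
  j <- match(reps$stay_id, stays$stay_id)
  expect_true(all(reps$ordertime >= stays$intime[j] &
                    reps$ordertime <= stays$outtime[j]))
  expect_true(all(reps$dose >= 0))
  # exactly one first diagnosis per stay
  dx1 <- g$tables$diagnoses[g$tables$diagnoses$seq_num == 1, ]
  expect_equal(sort(dx1$stay_id), sort(stays$stay_id))
})
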