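test_that("cohens_d: textbook cases, invariances, summary input", {
  expect_equal(cohens_d(c(1, 2, 3), c(1, 2, 3)), 0)
  a <- list(n = 50, mean = 1, sd = 1); b <- list(n = 50, mean = 0, sd = 1)
  expect_equal(cohens_d(a, b), 1.0)
  # raw vectors and their summaries give the same d
  set.seed(8); x <- rnorm(40, 1, 2); y <- rnorm(30, 0, 2)
  expect_equal(cohens_d(x, y), cohens_d(group_stats(x), group_stats(y)))
  # shift and scale invariance
  expect_equal(cohens_d(x + 5, y + 5), cohens_d(x, y))
  expect_equal(cohens_d(3 * x, 3 * y), cohens_d(x, y))
  # zero pooled SD sentinels
  expect_equal(cohens_d(c(1, 1), c(2, 2)), -Inf)
  expect_equal(cohens_d(c(2, 2), c(2, 2)), 0)
})

test_that("students_t matches the classic pooled form and t.test oracle", {
  r <- students_t(c(1, 2, 3), c(3, 4, 5))
  o <- t.test(c(1, 2, 3), c(3, 4, 5), var.equal = TRUE)
  expect_equal(r$t_statistic, unname(o$statistic))
  expect_equal(r$p_value, o$p.value)
  expect_equal(r$df, unname(o$parameter))
  # identical groups: t = 0, p = 1
  r0 <- students_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r0$t_statistic, 0)
  expect_equal(r0$p_value, 1)
  # antisymmetry
  r2 <- students_t(c(3, 4, 5), c(1, 2, 3))
  expect_equal(r2$t_statistic, -r$t_statistic)
  expect_equal(r2$p_value, r$p_value)
  # several random fixtures against the oracle
  set.seed(12)
  for (i in 1:10) {
    x <- rnorm(sample(5:40, 1)); y <- rnorm(sample(5:40, 1), 0.3)
    o <- t.test(x, y, var.equal = TRUE)
    r <- students_t(x, y)
    expect_equal(r$t_statistic, unname(o$statistic), tolerance = 1e-12)
    expect_equal(r$p_value, o$p.value, tolerance = 1e-12)
  }
  # degenerate: zero pooled variance is flagged
  expect_true(students_t(c(1, 1, 1), c(1, 1))$degenerate)
})

test_that("a planted standardised shift is recovered by d-hat", {
  set.seed(99)
  n <- 10000
  pre <- rnorm(n, 0, 1); post <- rnorm(n, 0.5, 1)
  expect_lt(abs(cohens_d(post, pre) - 0.5), 0.05)
})

test_that("pre_post_effect uses complete episodes only, paired and unpaired", {
  set.seed(3)
  n <- 400
  ep <- make_episodes("magnesium", "ONE_L_ONE_R", rnorm(n, 1.8, 0.2),
                      followup_value = NA_real_)
  ep$followup_value <- ep$index_value + 0.3 + rnorm(n, 0, 0.1)
  # some incomplete episodes must not change the result
  ep_aug <- rbind(ep, within(make_episodes("magnesium", "ONE_L_ONE_R",
                                           rnorm(50, 1.8, 0.2)),
                             followup_value <- NA_real_))
  r1 <- pre_post_effect(ep)$magnesium
  r2 <- pre_post_effect(ep_aug)$magnesium
  expect_equal(r1$d_cohen, r2$d_cohen)
  expect_gt(r1$d_cohen, 0)

  # post identical to pre -> d = 0 in both modes
  ep0 <- ep; ep0$followup_value <- ep0$index_value
  expect_equal(pre_post_effect(ep0)$magnesium$d_cohen, 0)
  expect_equal(pre_post_effect(ep0, paired = TRUE)$magnesium$d_cohen, 0)

  # paired d on within-episode differences is far larger here than the
  # unpaired d, since pre and post are strongly correlated
  rp <- pre_post_effect(ep, paired = TRUE)$magnesium
  expect_gt(rp$d_cohen, r1$d_cohen)
  expect_lt(abs(rp$d_cohen - 3), 0.5)    # delta/noise = 0.3/0.1
})

test_that("decision_regression: exact fits, oracle agreement, rank errors", {
  # y = 2x + 1 exactly
  d <- data.frame(x = 1:20, y = 2 * (1:20) + 1)
  fit <- decision_regression(d, "y", "x")
  expect_equal(unname(coef(fit)), c(1, 2), tolerance = 1e-12)
  expect_equal(fit$r_squared, 1)

  # constant outcome: flat fit
  d2 <- data.frame(x = rnorm(30), y = 5)
  fit2 <- decision_regression(d2, "y", "x")
  expect_equal(unname(coef(fit2)["x"]), 0, tolerance = 1e-12)
  expect_equal(fit2$r_squared, 0)

  # random 50 x 5 design against the normal-equations oracle
  set.seed(17)
  X <- matrix(rnorm(250), 50, 5,
              dimnames = list(NULL, paste0("x", 1:5)))
  y <- X %*% c(1, -2, 0.5, 0, 3) + rnorm(50)
  dd <- data.frame(y = as.numeric(y), X)
  fit3 <- decision_regression(dd, "y", paste0("x", 1:5))
  Xd <- cbind(1, X)
  beta <- solve(crossprod(Xd), crossprod(Xd, y))
  expect_equal(unname(coef(fit3)), as.numeric(beta), tolerance = 1e-8)
  # residuals orthogonal to every predictor
  res <- dd$y - Xd %*% beta
  expect_true(all(abs(crossprod(Xd, res)) < 1e-8))
  # the F df pair matches the (k; n-k-1) layout
  expect_equal(fit3$f_df, c(5, 44))

  # collinear design: hard error naming the offending column
  dd$x6 <- dd$x1 + dd$x2
  expect_error(decision_regression(dd, "y", paste0("x", 1:6)), "x6")
})

test_that("threshold_anova: F = t^2 identity, planted offsets, small groups", {
  set.seed(23)
  x <- rnorm(40, 3.8, 0.3); y <- rnorm(35, 3.9, 0.3)
  a <- threshold_anova(c(x, y), rep(c("MICU", "SICU"), c(40, 35)))
  t <- students_t(x, y)
  expect_equal(a$f_statistic, t$t_statistic^2, tolerance = 1e-10)
  expect_equal(a$df1, 1); expect_equal(a$df2, 73)

  # identical data in every group -> F = 0
  a0 <- threshold_anova(rep(3.5, 30), rep(c("A", "B", "C"), 10))
  expect_equal(a0$f_statistic, 0)

  # planted unit offsets are detected at n = 500/group
  g <- rep(c("A", "B", "C"), each = 500)
  v <- rnorm(1500, 3.8 + 0.08 * (as.integer(factor(g)) - 2), 0.4)
  expect_lt(threshold_anova(v, g)$p_value, 0.05)

  # a group with n < 2 is dropped with a warning and df adjusted
  expect_warning(
    a2 <- threshold_anova(c(x, y, 9), c(rep(c("MICU", "SICU"), c(40, 35)),
                                        "HVICU")),
    "HVICU")
  expect_equal(a2$df2, 73)
})

test_that("planted regression coefficients fall within 3 SEs almost always", {
  # 200 seeded replicates; per-coefficient 3-SE coverage ~ 99.7%
  beta <- c(2, -1, 0.5)
  hits <- 0L; total <- 0L
  for (rep_i in 1:200) {
    set.seed(3000 + rep_i)
    X <- matrix(rnorm(100 * 3), 100, 3,
                dimnames = list(NULL, c("a", "b", "c")))
    y <- 1 + X %*% beta + rnorm(100)
    d <- data.frame(y = as.numeric(y), X)
    fit <- decision_regression(d, "y", c("a", "b", "c"))
    cf <- fit$coefficients
    in3 <- abs(cf$estimate[-1] - beta) <= 3 * cf$std_error[-1]
    hits <- hits + sum(in3); total <- total + length(in3)
  }
  expect_gte(hits / total, 0.95)
})
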