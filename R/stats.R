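#' @title Effect sizes, t tests, OLS regression and one-way ANOVA
#' @name repleteaudit-statistics
#' @description
#' Inferential machinery of the audit: groups are summarised as mean +/- SD
#' (sample SD, n-1 denominator); pairs of groups are compared with the
#' pooled-variance two-sample Student t (two-sided p); effect sizes are
#' Cohen's d on the pooled SD; decision factors are screened with ordinary
#' least squares; thresholds across ICU units or medication groups are
#' compared with one-way fixed-effects ANOVA. No multiple-testing
#' correction is applied; the audit works at a flat two-sided 0.05.
NULL

#' Summarise a group of values
#'
#' @param x numeric vector, `NA` removed.
#' @return list of class `group_stats` with `n`, `mean`, `sd`.
#' @export
group_stats <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) stop("group_stats: empty group")
  structure(list(n = length(x), mean = mean(x),
                 sd = if (length(x) > 1) stats::sd(x) else 0),
            class = "group_stats")
}

.as_group_stats <- function(x) {
  if (inherits(x, "group_stats")) return(x)
  if (is.list(x) && all(c("n", "mean", "sd") %in% names(x)))
    return(structure(x[c("n", "mean", "sd")], class = "group_stats"))
  group_stats(as.numeric(x))
}

#' Cohen's d on the pooled standard deviation
#'
#' `d = (mean_a - mean_b) / s_p` with
#' `s_p = sqrt(((n_a-1) sd_a^2 + (n_b-1) sd_b^2) / (n_a + n_b - 2))`.
#' Shift- and scale-invariant. With zero pooled SD the result is 0 for
#' equal means and signed `Inf` otherwise.
#'
#' @param a,b numeric vectors or [group_stats()] objects (summary input is
#'   enough; raw values are never required).
#' @return numeric effect size; the sign matches the sign of
#'   `mean(a) - mean(b)`.
#' @export
cohens_d <- function(a, b) {
  a <- .as_group_stats(a); b <- .as_group_stats(b)
  if (a$n + b$n < 3) stop("cohens_d: need at least 3 observations in total")
  sp2 <- ((a$n - 1) * a$sd^2 + (b$n - 1) * b$sd^2) / (a$n + b$n - 2)
  diff <- a$mean - b$mean
  if (sp2 <= 0) {
    if (diff == 0) return(0)
    return(sign(diff) * Inf)
  }
  diff / sqrt(sp2)
}

#' Pooled-variance two-sample Student t
#'
#' Classic equal-variance form: `df = n_a + n_b - 2`, two-sided p value.
#' Accepts raw vectors or group summaries. A zero pooled variance is
#' flagged as degenerate (`t = 0, p = 1` for equal means; `Inf` otherwise).
#'
#' @inheritParams cohens_d
#' @return list of class `effect_result`: `t_statistic`, `df`, `p_value`,
#'   `d_cohen`, `mean_a`, `mean_b`, `n_a`, `n_b`, `degenerate`.
#' @export
students_t <- function(a, b) {
  a <- .as_group_stats(a); b <- .as_group_stats(b)
  if (a$n < 2 || b$n < 2) stop("students_t: each group needs n >= 2")
  df <- a$n + b$n - 2
  sp2 <- ((a$n - 1) * a$sd^2 + (b$n - 1) * b$sd^2) / df
  diff <- a$mean - b$mean
  degenerate <- sp2 <= 0
  if (degenerate) {
    t <- if (diff == 0) 0 else sign(diff) * Inf
    p <- if (diff == 0) 1 else 0
  } else {
    se <- sqrt(sp2 * (1 / a$n + 1 / b$n))
    t <- diff / se
    p <- 2 * stats::pt(-abs(t), df)
  }
  structure(list(t_statistic = t, df = df, p_value = p,
                 d_cohen = cohens_d(a, b),
                 mean_a = a$mean, mean_b = b$mean, n_a = a$n, n_b = b$n,
                 degenerate = degenerate),
            class = "effect_result")
}

#' @export
print.effect_result <- function(x, ...) {
  cat(sprintf("t(%d) = %.4g, p = %.4g, d = %.4g (means %.4g vs %.4g)%s\n",
              x$df, x$t_statistic, x$p_value, x$d_cohen, x$mean_a, x$mean_b,
              if (isTRUE(x$degenerate)) " [degenerate: zero pooled variance]"
              else ""))
  invisible(x)
}

#' Repletion effectiveness: pre vs post serum values
#'
#' Per electrolyte, compares index (pre) against follow-up (post) values
#' over episodes that carry both, as t, p and Cohen's d. The default is the
#' unpaired pooled-SD form (the two marginal distributions as printed in
#' group-summary tables); `paired = TRUE` instead computes the paired t and
#' d on within-episode differences (`d = mean(post - pre) / sd(post - pre)`).
#'
#' @param episodes episode table or `episode_linkage`.
#' @param paired logical, default `FALSE`.
#' @return named list of `effect_result` (one per electrolyte with >= 2
#'   complete episodes; electrolytes with fewer are reported as `NULL` with
#'   a warning).
#' @export
pre_post_effect <- function(episodes, paired = FALSE) {
  if (inherits(episodes, "episode_linkage")) episodes <- episodes$episodes
  out <- stats::setNames(vector("list", length(electrolytes())),
                         electrolytes())
  for (el in electrolytes()) {
    any_rep <- episodes$electrolyte == el & !is.na(episodes$order_time)
    i <- any_rep & !is.na(episodes$followup_value)
    pre <- episodes$index_value[i]; post <- episodes$followup_value[i]
    if (sum(i) < 2) {
      if (any(any_rep))
        warning("pre_post_effect: fewer than 2 complete episodes for ", el)
      next
    }
    if (paired) {
      dd <- post - pre
      tt <- stats::t.test(dd)  # one-sample t on the within-episode differences
      res <- structure(list(
        t_statistic = unname(tt$statistic), df = unname(tt$parameter),
        p_value = tt$p.value,
        d_cohen = if (stats::sd(dd) > 0) mean(dd) / stats::sd(dd)
                  else if (mean(dd) == 0) 0 else sign(mean(dd)) * Inf,
        mean_a = mean(post), mean_b = mean(pre),
        n_a = length(post), n_b = length(pre),
        degenerate = stats::sd(dd) == 0), class = "effect_result")
    } else {
      res <- students_t(post, pre)
    }
    out[[el]] <- res
  }
  out
}

#' OLS regression of the repletion decision factors
#'
#' Ordinary least squares of an outcome on a set of clinical predictors,
#' reported in the layout of a decision-factor table: coefficient, SE,
#' p-value stars (`*` < 0.1, `**` < 0.05, `***` < 0.01), n, R2, adjusted
#' R2, residual standard error and the overall F with its (k, n-k-1)
#' degrees of freedom. Complete-case analysis; a rank-deficient design is a
#' hard error naming the collinear columns. `stepwise = "addition"` /
#' `"subtraction"` run forward/backward stepwise screening of the predictor
#' list (AIC-based, via [stats::step()]); this screening mode is a
#' convenience, not a canonical method.
#'
#' @param data `data.frame` holding outcome and predictors.
#' @param outcome name of the outcome column. In the audit pipeline this is
#'   the post-repletion serum value by default; a 0/1 repleted indicator
#'   turns the fit into a linear probability model of the decision itself.
#' @param predictors character vector of predictor column names.
#' @param stepwise `"none"` (default), `"addition"` or `"subtraction"`.
#' @return object of class `regression_fit`.
#' @export
decision_regression <- function(data, outcome, predictors,
                                stepwise = c("none", "addition",
                                             "subtraction")) {
  stepwise <- match.arg(stepwise)
  cols <- c(outcome, predictors)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols))
    stop("decision_regression: missing column(s): ",
         paste(missing_cols, collapse = ", "))
  d <- data[stats::complete.cases(data[, cols, drop = FALSE]), cols,
            drop = FALSE]
  k <- length(predictors)
  if (nrow(d) <= k + 1)
    stop("decision_regression: need more observations than predictors + 1")
  fml <- stats::reformulate(predictors, response = outcome)
  X <- stats::model.matrix(fml, d)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    dropped <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop("decision_regression: rank-deficient design; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  fit <- stats::lm(fml, data = d)
  if (stepwise != "none") {
    scope <- list(lower = stats::reformulate("1", response = outcome),
                  upper = fml)
    start <- if (stepwise == "addition")
      stats::lm(stats::reformulate("1", response = outcome), data = d)
    else fit
    fit <- stats::step(start, scope = scope,
                       direction = if (stepwise == "addition") "forward"
                                   else "backward", trace = 0)
  }
  sm <- suppressWarnings(summary(fit))  # silence the perfect-fit notice
  # constant outcome: TSS = 0 and R2 is numerical noise; report a flat fit
  tss <- sum((d[[outcome]] - mean(d[[outcome]]))^2)
  if (tss == 0 || !is.finite(sm$r.squared)) {
    sm$r.squared <- 0; sm$adj.r.squared <- 0
  }
  coefs <- sm$coefficients
  stars <- ifelse(coefs[, 4] < 0.01, "***",
                  ifelse(coefs[, 4] < 0.05, "**",
                         ifelse(coefs[, 4] < 0.1, "*", "")))
  structure(list(
    coefficients = data.frame(
      term = rownames(coefs),
      estimate = coefs[, 1], std_error = coefs[, 2],
      t_value = coefs[, 3], p_value = coefs[, 4], stars = stars,
      row.names = NULL, stringsAsFactors = FALSE),
    n_observations = nrow(d),
    r_squared = sm$r.squared,
    adjusted_r_squared = sm$adj.r.squared,
    residual_std_error = sm$sigma,
    residual_df = fit$df.residual,
    f_statistic = unname(sm$fstatistic[1] %||% NA_real_),
    f_df = c(unname(sm$fstatistic[2] %||% NA_real_),
             unname(sm$fstatistic[3] %||% NA_real_)),
    outcome = outcome,
    lm_fit = fit), class = "regression_fit")
}

#' @export
print.regression_fit <- function(x, ...) {
  cat("OLS decision-factor regression of", x$outcome, "\n")
  cf <- x$coefficients
  for (i in seq_len(nrow(cf)))
    cat(sprintf("  %-18s % .4f %-3s (%.4f)\n", cf$term[i], cf$estimate[i],
                cf$stars[i], cf$std_error[i]))
  cat(sprintf("  Observations %d;  R2 %.3f;  Adjusted R2 %.3f\n",
              x$n_observations, x$r_squared, x$adjusted_r_squared))
  cat(sprintf("  Residual Std. Error %.3f (df = %d)\n",
              x$residual_std_error, x$residual_df))
  if (!is.na(x$f_statistic))
    cat(sprintf("  F Statistic %.3f (df = %d; %d)\n", x$f_statistic,
                as.integer(x$f_df[1]), as.integer(x$f_df[2])))
  invisible(x)
}

#' @export
coef.regression_fit <- function(object, ...) {
  stats::setNames(object$coefficients$estimate, object$coefficients$term)
}

#' One-way fixed-effects ANOVA of repletion thresholds
#'
#' Compares pre-repletion index values across groups (ICU units or
#' medication exposure): `F` with `df = (groups - 1, total - groups)`.
#' Groups with fewer than 2 observations are excluded with a warning and
#' the degrees of freedom adjusted.
#'
#' @param values numeric vector of pre-repletion serum values.
#' @param groups vector of group labels, same length.
#' @return list of class `anova_result`: `f_statistic`, `df1`, `df2`,
#'   `p_value`, `group_means`, `n_groups`.
#' @export
threshold_anova <- function(values, groups) {
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]; groups <- as.character(groups[keep])
  sizes <- table(groups)
  small <- names(sizes)[sizes < 2]
  if (length(small)) {
    warning("threshold_anova: dropping group(s) with n < 2: ",
            paste(small, collapse = ", "))
    keep <- !(groups %in% small)
    values <- values[keep]; groups <- groups[keep]
  }
  if (length(unique(groups)) < 2)
    stop("threshold_anova: need at least 2 groups with n >= 2")
  k <- length(unique(groups))
  if (sum((values - mean(values))^2) == 0) {
    # identical data in every group: no variance to partition
    return(structure(list(f_statistic = 0,
                          df1 = k - 1L, df2 = length(values) - k,
                          p_value = 1,
                          group_means = tapply(values, groups, mean),
                          n_groups = k), class = "anova_result"))
  }
  fit <- stats::lm(values ~ factor(groups))
  av <- stats::anova(fit)
  structure(list(f_statistic = av$`F value`[1],
                 df1 = av$Df[1], df2 = av$Df[2],
                 p_value = av$`Pr(>F)`[1],
                 group_means = tapply(values, groups, mean),
                 n_groups = length(unique(groups))),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("one-way ANOVA: F(%d;%d) = %.3f, p = %.4g\n",
              x$df1, x$df2, x$f_statistic, x$p_value))
  invisible(x)
}
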