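#' @title Synthetic ICU event-stream generator with planted truth
#' @name repleteaudit-synthetic
#' @description
#' Generates MIMIC-shaped lab, repletion, stay and diagnosis tables whose
#' data-generating process is fully known, so every pipeline stage can be
#' validated end-to-end without access to protected health data. The
#' generator emulates: per-stay lab-draw streams with circadian timing (a
#' major early-morning peak and a minor evening peak), repletion decisions
#' driven by a logistic function of the preceding serum value, lognormal
#' order and follow-up latencies truncated at the 24-h window, additive
#' post-repletion level shifts with noise, and exact planted counts of
#' minors, excluded first diagnoses and out-of-bounds error values for the
#' attrition log. Decision windows within one (stay, electrolyte) stream
#' are spaced several days apart so that the planted expectations are exact
#' closed forms; overlapping-window behaviour of the matcher is validated
#' separately against a brute-force oracle.
NULL

# inverse-CDF truncated normal / lognormal draws (exact, vectorised)
.rtrunc_norm <- function(n, mean, sd, lo, hi) {
  plo <- stats::pnorm(lo, mean, sd); phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(plo + stats::runif(n) * (phi - plo), mean, sd)
}

.rtrunc_lnorm <- function(n, meanlog, sdlog, lo, hi) {
  plo <- stats::plnorm(lo, meanlog, sdlog)
  phi <- stats::plnorm(hi, meanlog, sdlog)
  stats::qlnorm(plo + stats::runif(n) * (phi - plo), meanlog, sdlog)
}

# E[X | lo <= X <= hi] for X ~ lognormal(meanlog, sdlog)
.trunc_lnorm_mean <- function(meanlog, sdlog, lo, hi) {
  a <- if (lo <= 0) -Inf else (log(lo) - meanlog) / sdlog
  b <- (log(hi) - meanlog) / sdlog
  num <- exp(meanlog + sdlog^2 / 2) *
    (stats::pnorm(b - sdlog) - stats::pnorm(a - sdlog))
  den <- stats::pnorm(b) - stats::pnorm(a)
  num / den
}

# quadrature grid over the truncated value distribution of one electrolyte
.value_grid <- function(mean, sd, lo, hi, n = 4001) {
  v <- seq(lo, hi, length.out = n)
  f <- stats::dnorm(v, mean, sd) /
    (stats::pnorm(hi, mean, sd) - stats::pnorm(lo, mean, sd))
  list(v = v, f = f, dv = v[2] - v[1])
}

.quad <- function(g, w) sum(g$f * w) * g$dv

#' Generator parameters
#'
#' Constructs and validates the full parameter set of the synthetic
#' generator. Parameters that the audited quantities are stated for --
#' marginal repletion fractions, effect sizes, latency means, the
#' multi-lab scenario share, circadian peaks -- are planted *as those
#' quantities*: the corresponding primitive parameter (logistic base rate,
#' post-repletion shift, lognormal meanlog) is solved once from the
#' closed-form expectation so the stated value is the planted truth.
#'
#' @param n_stays number of ICU stays (default 5275).
#' @param labs_per_stay_mean named numeric, Poisson mean number of decision
#'   windows per stay for each electrolyte.
#' @param value_mean,value_sd named numeric, serum value distribution per
#'   electrolyte (truncated at the physiologic error bounds).
#' @param repletion_theta,repletion_slope logistic decision rule
#'   `p(replete | v) = base * plogis((theta - v) / slope)`; `base` is
#'   solved from `target_repletion_fraction`.
#' @param target_repletion_fraction planted per-episode repletion fraction
#'   (share of lab-order episodes followed by an order).
#' @param target_d planted unpaired pooled-SD Cohen's d of the pre/post
#'   comparison; the additive post shift `delta` is solved from it.
#' @param target_latency_mean,target_followup_mean planted means (minutes)
#'   of the truncated lognormal lab-to-order and order-to-follow-up
#'   latencies; `meanlog` is solved from them (`sdlog` fixed below).
#' @param latency_sdlog,followup_sdlog lognormal shape parameters.
#' @param noise_sd_frac post-repletion noise SD as a fraction of the serum
#'   value SD.
#' @param scenario_mix probability that a decision window contains multiple
#'   labs (the multi-lab scenario share among repletions).
#' @param circadian_peaks,circadian_sds,circadian_weights two-component
#'   clock-hour mixture of the lab-draw times.
#' @param minor_fraction,excluded_dx_fraction,error_value_fraction planted
#'   fractions of under-age stays, excluded first diagnoses and
#'   out-of-bounds error lab values (converted to exact counts).
#' @param error_bounds physiologic bounds used both to truncate genuine
#'   values and to place planted error values outside.
#' @param exclusion_rules named ICD-9 code sets the planted excluded
#'   diagnoses are drawn from.
#' @param seed integer seed; the generator is deterministic given the seed.
#' @return list of class `generator_params` with all primitive parameters
#'   solved (`repletion_base`, `post_delta`, `latency_meanlog`,
#'   `followup_meanlog`).
#' @export
generator_params <- function(
    n_stays = 5275,
    labs_per_stay_mean = c(potassium = 4, magnesium = 2, phosphate = 1),
    value_mean = c(potassium = 3.9, magnesium = 2.0, phosphate = 2.5),
    value_sd = c(potassium = 0.45, magnesium = 0.28, phosphate = 0.60),
    repletion_theta = c(potassium = 3.5, magnesium = 1.8, phosphate = 2.3),
    repletion_slope = c(potassium = 0.30, magnesium = 0.20, phosphate = 0.30),
    target_repletion_fraction = c(potassium = 0.0324, magnesium = 0.1037,
                                  phosphate = 0.1662),
    target_d = c(potassium = 0.32, magnesium = 1.08, phosphate = 0.87),
    target_latency_mean = c(potassium = 217.20, magnesium = 323.29,
                            phosphate = 339.83),
    target_followup_mean = c(potassium = 443.45, magnesium = 643.10,
                             phosphate = 567.13),
    latency_sdlog = 0.6, followup_sdlog = 0.6,
    noise_sd_frac = 0.3,
    scenario_mix = 0.489,
    circadian_peaks = c(6, 18), circadian_sds = c(1.5, 1.5),
    circadian_weights = c(0.7, 0.3),
    minor_fraction = 19 / 5275,
    excluded_dx_fraction = 0.10,
    error_value_fraction = 0.001,
    error_bounds = default_error_bounds(),
    exclusion_rules = default_exclusion_rules(),
    seed = 1L) {
  els <- electrolytes()
  stopifnot(n_stays >= 1, scenario_mix >= 0, scenario_mix <= 1,
            all(value_sd > 0), minor_fraction >= 0, minor_fraction < 1,
            excluded_dx_fraction >= 0, error_value_fraction >= 0,
            minor_fraction + excluded_dx_fraction < 1,
            abs(sum(circadian_weights) - 1) < 1e-8)
  extra_mean <- 1.5                       # extra labs per multi window
  m <- scenario_mix * extra_mean
  base <- delta <- lat_ml <- fu_ml <- p_bar <- var_pre <-
    stats::setNames(numeric(3), els)
  for (el in els) {
    eb <- error_bounds[error_bounds$electrolyte == el, ]
    g <- .value_grid(value_mean[[el]], value_sd[[el]], eb$low, eb$high)
    sig <- stats::plogis((repletion_theta[[el]] - g$v) / repletion_slope[[el]])
    I <- .quad(g, sig)
    frac <- target_repletion_fraction[[el]]
    # episodes per window: repleted (p), follow-up NR (p), plain NR
    # ((1-p)(1+m)); fraction = p / (2p + (1-p)(1+m)) solves in closed form
    q <- frac * (1 + m) / (1 - frac * (1 - m))
    if (q == 0) {
      base[el] <- 0; p_bar[el] <- 0; var_pre[el] <- NA_real_
      delta[el] <- 0
      lat_ml[el] <- stats::uniroot(function(mu)
        .trunc_lnorm_mean(mu, latency_sdlog, 0, 1440) -
          target_latency_mean[[el]], c(log(5), log(5000)))$root
      fu_ml[el] <- stats::uniroot(function(mu)
        .trunc_lnorm_mean(mu, followup_sdlog, 1, 1440) -
          target_followup_mean[[el]], c(log(5), log(8000)))$root
      next
    }
    if (q / I > 1)
      stop("infeasible params: required base repletion probability ",
           round(q / I, 3), " > 1 for ", el,
           " (raise repletion_theta or the slope)")
    base[el] <- q / I
    p_bar[el] <- q
    p_v <- base[el] * sig
    mu_pre <- .quad(g, g$v * p_v) / q
    var_pre[el] <- .quad(g, (g$v - mu_pre)^2 * p_v) / q
    noise <- noise_sd_frac * value_sd[[el]]
    delta[el] <- target_d[[el]] * sqrt(var_pre[el] + noise^2 / 2)
    lat_ml[el] <- stats::uniroot(function(mu)
      .trunc_lnorm_mean(mu, latency_sdlog, 0, 1440) -
        target_latency_mean[[el]],
      c(log(5), log(5000)))$root
    fu_ml[el] <- stats::uniroot(function(mu)
      .trunc_lnorm_mean(mu, followup_sdlog, 1, 1440) -
        target_followup_mean[[el]],
      c(log(5), log(8000)))$root
  }
  structure(list(
    n_stays = as.integer(n_stays),
    labs_per_stay_mean = labs_per_stay_mean,
    value_mean = value_mean, value_sd = value_sd,
    repletion_theta = repletion_theta, repletion_slope = repletion_slope,
    repletion_base = base, p_bar = p_bar, var_pre = var_pre,
    target_repletion_fraction = target_repletion_fraction,
    target_d = target_d,
    target_latency_mean = target_latency_mean,
    target_followup_mean = target_followup_mean,
    latency_meanlog = lat_ml, latency_sdlog = latency_sdlog,
    followup_meanlog = fu_ml, followup_sdlog = followup_sdlog,
    post_delta = delta, noise_sd = noise_sd_frac * value_sd,
    scenario_mix = scenario_mix, extra_mean = extra_mean,
    circadian_peaks = circadian_peaks, circadian_sds = circadian_sds,
    circadian_weights = circadian_weights,
    minor_fraction = minor_fraction,
    excluded_dx_fraction = excluded_dx_fraction,
    error_value_fraction = error_value_fraction,
    error_bounds = error_bounds,
    exclusion_rules = exclusion_rules,
    seed = as.integer(seed)), class = "generator_params")
}

#' Closed-form planted truth for a parameter set
#'
#' Expectations of every audited quantity under the generator's
#' data-generating process, computed by quadrature over the truncated serum
#' value distribution and analytic truncated-lognormal moments -- never by
#' simulation. Used as the reference in planted-parameter recovery tests.
#'
#' @param params a [generator_params()] object.
#' @param ranges reference ranges used for the interpretation-cell
#'   expectations.
#' @return list of class `planted_truth`; per electrolyte: the per-episode
#'   repletion fraction (%), Cohen's d of pre vs post, latency means, and
#'   below/within/above proportions of the repletion group; globally: the
#'   multi-lab scenario share (%), the modal lab hour, and the planted
#'   attrition counts.
#' @export
planted_truth <- function(params, ranges = default_reference_ranges()) {
  els <- electrolytes()
  per_el <- list()
  for (el in els) {
    eb <- params$error_bounds[params$error_bounds$electrolyte == el, ]
    g <- .value_grid(params$value_mean[[el]], params$value_sd[[el]],
                     eb$low, eb$high)
    p_v <- params$repletion_base[[el]] *
      stats::plogis((params$repletion_theta[[el]] - g$v) /
                      params$repletion_slope[[el]])
    p <- .quad(g, p_v)
    m <- params$scenario_mix * params$extra_mean
    frac <- p / (2 * p + (1 - p) * (1 + m))
    rng <- .range_row(ranges, el)
    lab <- classify_value(g$v, rng)
    noise <- params$noise_sd[[el]]
    if (p > 0) {
      cells <- vapply(c("below", "within", "above"), function(lb)
        .quad(g, p_v * (lab == lb)) / p, numeric(1))
      d <- params$post_delta[[el]] /
        sqrt(params$var_pre[[el]] + noise^2 / 2)
    } else {
      cells <- stats::setNames(rep(NA_real_, 3),
                               c("below", "within", "above"))
      d <- NA_real_
    }
    per_el[[el]] <- list(
      repletion_fraction_pct = 100 * frac,
      p_replete_per_window = p,
      d_cohen = d,
      lab_to_order_mean = .trunc_lnorm_mean(params$latency_meanlog[[el]],
                                            params$latency_sdlog, 0, 1440),
      order_to_followup_mean = .trunc_lnorm_mean(
        params$followup_meanlog[[el]], params$followup_sdlog, 1, 1440),
      cells_repletion = cells)
  }
  structure(list(
    per_electrolyte = per_el,
    scenario_multi_pct = 100 * params$scenario_mix,
    peak_hour = as.integer(params$circadian_peaks[1]),
    n_minors = round(params$minor_fraction * params$n_stays),
    n_dx_excluded = round(params$excluded_dx_fraction * params$n_stays)),
    class = "planted_truth")
}

.benign_codes <- c("4019", "25000", "486", "5070", "496", "3051",
                   "2724", "53081")

#' Generate a synthetic audit cohort
#'
#' Draws the four canonical event tables under [generator_params()].
#' Deterministic given `params$seed`: the same parameters produce
#' byte-identical tables. Planted counts (minors, excluded first
#' diagnoses, out-of-bounds error values) are inserted exactly; excluded
#' stays are guaranteed at least one event so the exclusion cascade, not
#' the no-event filter, removes them.
#'
#' @param params a [generator_params()] object.
#' @param dir optional directory; when given, the four tables are written
#'   as CSV (`labs.csv`, `repletions.csv`, `stays.csv`, `diagnoses.csv`)
#'   plus a `truth.json` sidecar.
#' @return list of class `synthetic_cohort` with `tables` (list of four
#'   `data.frame`s in canonical schema), `truth` (the [planted_truth()]
#'   augmented with exact planted counts under `$planted`), and `params`.
#' @export
generate_cohort <- function(params, dir = NULL) {
  stopifnot(inherits(params, "generator_params"))
  set.seed(params$seed)
  n <- params$n_stays
  els <- electrolytes()

  ## --- stays -----------------------------------------------------------
  stay_id <- 30000L + seq_len(n)
  subject_id <- 10000L + seq_len(n)
  unit_type <- sample(c("MICU", "SICU", "CICU", "HVICU", "other"), n,
                      replace = TRUE, prob = c(.30, .25, .15, .10, .20))
  age <- .rtrunc_norm(n, 65, 15, 18, 95)
  n_min <- round(params$minor_fraction * n)
  idx_minor <- sort(sample.int(n, n_min))
  age[idx_minor] <- stats::runif(n_min, 1, 17.5)
  weight <- .rtrunc_norm(n, 80, 15, 40, 160)
  base_day <- sample.int(3650, n, replace = TRUE)      # days from origin
  intime_min <- (base_day * 1440) + sample.int(1440, n, replace = TRUE) - 1L
  midnight <- base_day * 1440

  ## --- diagnoses -------------------------------------------------------
  n_dx <- round(params$excluded_dx_fraction * n)
  idx_dx <- sort(sample(setdiff(seq_len(n), idx_minor), n_dx))
  excluded_pool <- unlist(params$exclusion_rules, use.names = FALSE)
  first_code <- sample(.benign_codes, n, replace = TRUE)
  first_code[idx_dx] <- sample(excluded_pool, n_dx, replace = TRUE)
  diagnoses <- data.frame(subject_id = subject_id, stay_id = stay_id,
                          icd9_code = first_code, seq_num = 1L,
                          stringsAsFactors = FALSE)
  # secondary diagnoses, some with excluded codes: must never matter
  has2 <- stats::runif(n) < 0.3
  if (any(has2)) {
    pool2 <- c(.benign_codes, excluded_pool)
    diagnoses <- rbind(diagnoses, data.frame(
      subject_id = subject_id[has2], stay_id = stay_id[has2],
      icd9_code = sample(pool2, sum(has2), replace = TRUE), seq_num = 2L,
      stringsAsFactors = FALSE))
  }

  ## --- decision windows ------------------------------------------------
  nw_mat <- vapply(els, function(el)
    stats::rpois(n, params$labs_per_stay_mean[[el]]), integer(n))
  # excluded stays must carry at least one event
  forced <- union(idx_minor, idx_dx)
  none <- forced[rowSums(nw_mat[forced, , drop = FALSE]) == 0]
  if (length(none)) nw_mat[none, 1] <- 1L

  win <- do.call(rbind, lapply(seq_along(els), function(j) {
    cnt <- nw_mat[, j]
    if (sum(cnt) == 0) return(NULL)
    data.frame(stay = rep.int(seq_len(n), cnt),
               el = els[j],
               k = sequence(cnt[cnt > 0]), stringsAsFactors = FALSE)
  }))
  nwin <- nrow(win)
  # day gaps: >= 2 days to the first window, >= 4 between windows, so
  # windows (incl. their extras and follow-ups) never interact
  gap_days <- ifelse(win$k == 1, sample(2:3, nwin, replace = TRUE),
                     sample(4:5, nwin, replace = TRUE))
  day_off <- stats::ave(gap_days, paste(win$stay, win$el, sep = "\r"),
                        FUN = cumsum)
  comp <- stats::runif(nwin) < params$circadian_weights[1]
  # peaks are clock-hour bins; centre the mixture mid-bin so "peak hour 6"
  # concentrates in 06:00-06:59
  hrs <- ifelse(comp,
                stats::rnorm(nwin, params$circadian_peaks[1] + 0.5,
                             params$circadian_sds[1]),
                stats::rnorm(nwin, params$circadian_peaks[2] + 0.5,
                             params$circadian_sds[2])) %% 24
  idx_min_of_day <- floor(hrs * 60)
  t_index <- midnight[win$stay] + day_off * 1440 + idx_min_of_day

  el_i <- match(win$el, els)
  v <- .rtrunc_norm(nwin,
                    params$value_mean[el_i], params$value_sd[el_i],
                    params$error_bounds$low[
                      match(win$el, params$error_bounds$electrolyte)],
                    params$error_bounds$high[
                      match(win$el, params$error_bounds$electrolyte)])
  p <- params$repletion_base[el_i] *
    stats::plogis((params$repletion_theta[el_i] - v) /
                    params$repletion_slope[el_i])
  repleted <- stats::runif(nwin) < p

  ## --- orders and follow-ups ------------------------------------------
  nrep <- sum(repleted)
  L <- round(.rtrunc_lnorm(nrep, params$latency_meanlog[el_i[repleted]],
                           params$latency_sdlog, 0, 1440))
  t_order <- t_index[repleted] + L
  Fu <- pmax(1, round(.rtrunc_lnorm(nrep,
                                    params$followup_meanlog[el_i[repleted]],
                                    params$followup_sdlog, 1, 1440)))
  t_fu <- t_order + Fu
  vpre <- v[repleted]
  delta <- params$post_delta[el_i[repleted]]
  noise <- params$noise_sd[el_i[repleted]]
  lo_r <- params$error_bounds$low[
    match(win$el[repleted], params$error_bounds$electrolyte)]
  hi_r <- params$error_bounds$high[
    match(win$el[repleted], params$error_bounds$electrolyte)]
  # post value truncated into the physiologic bounds so the error filter
  # removes exactly the planted errors (truncation virtually never binds)
  plo <- stats::pnorm(lo_r, vpre + delta, noise)
  phi <- stats::pnorm(hi_r, vpre + delta, noise)
  vpost <- stats::qnorm(plo + stats::runif(nrep) * (phi - plo),
                        vpre + delta, noise)

  ## --- extra labs of multi-lab windows --------------------------------
  multi <- stats::runif(nwin) < params$scenario_mix
  n_extra <- ifelse(multi, 1L + stats::rbinom(nwin, 1L, 0.5), 0L)
  Lfull <- rep(NA_real_, nwin); Lfull[repleted] <- L
  ex_rows <- rep(seq_len(nwin), n_extra)
  off_cap <- ifelse(repleted, 1440 - Lfull, NA_real_)[ex_rows]
  off <- ifelse(is.na(off_cap),
                floor(stats::runif(length(ex_rows), 60, 1200)),
                floor(stats::runif(length(ex_rows)) * pmax(off_cap, 1)))
  off <- pmin(off, ifelse(is.na(off_cap), off, off_cap))
  t_extra <- t_index[ex_rows] - off
  v_extra <- .rtrunc_norm(length(ex_rows),
                          params$value_mean[el_i[ex_rows]],
                          params$value_sd[el_i[ex_rows]],
                          params$error_bounds$low[
                            match(win$el[ex_rows],
                                  params$error_bounds$electrolyte)],
                          params$error_bounds$high[
                            match(win$el[ex_rows],
                                  params$error_bounds$electrolyte)])

  ## --- assemble core labs ---------------------------------------------
  labs <- data.frame(
    subject_id = c(subject_id[win$stay], subject_id[win$stay[repleted]],
                   subject_id[win$stay[ex_rows]]),
    stay_id = c(stay_id[win$stay], stay_id[win$stay[repleted]],
                stay_id[win$stay[ex_rows]]),
    electrolyte = c(win$el, win$el[repleted], win$el[ex_rows]),
    tmin = c(t_index, t_fu, t_extra),
    value = c(v, vpost, v_extra),
    stringsAsFactors = FALSE)

  repletions <- data.frame(
    subject_id = subject_id[win$stay[repleted]],
    stay_id = stay_id[win$stay[repleted]],
    electrolyte = win$el[repleted],
    tmin = t_order,
    dose = c(potassium = 20, magnesium = 2, phosphate = 15)[
      el_i[repleted]],
    route = rep("IV", nrep),
    stringsAsFactors = FALSE)

  ## --- stay out-times --------------------------------------------------
  maxev <- rep(intime_min + 1440, length.out = n)
  agg <- tapply(c(labs$tmin, repletions$tmin),
                c(labs$stay_id, repletions$stay_id), max)
  hit <- match(as.integer(names(agg)), stay_id)
  maxev[hit] <- pmax(maxev[hit], as.numeric(agg))
  outtime_min <- maxev + floor(stats::runif(n, 720, 2880))

  ## --- planted error labs ----------------------------------------------
  n_err <- round(params$error_value_fraction * nrow(labs))
  included <- setdiff(unique(win$stay), c(idx_minor, idx_dx))
  err_stay <- sample(included, n_err, replace = TRUE)
  err_el <- sample(els, n_err, replace = TRUE)
  eb_i <- match(err_el, params$error_bounds$electrolyte)
  lo_b <- params$error_bounds$low[eb_i]
  hi_b <- params$error_bounds$high[eb_i]
  low_side <- stats::runif(n_err) < 0.5
  err_val <- ifelse(low_side,
                    stats::runif(n_err, pmax(0.02, lo_b - 1), lo_b - 0.02),
                    stats::runif(n_err, hi_b + 0.02, hi_b + 1.5))
  err_t <- intime_min[err_stay] + 10 +
    floor(stats::runif(n_err) *
            pmax(1, outtime_min[err_stay] - intime_min[err_stay] - 20))
  if (n_err > 0)
    labs <- rbind(labs, data.frame(
      subject_id = subject_id[err_stay], stay_id = stay_id[err_stay],
      electrolyte = err_el, tmin = err_t, value = err_val,
      stringsAsFactors = FALSE))

  ## --- finalise tables --------------------------------------------------
  labs <- labs[order(labs$stay_id, labs$tmin, labs$electrolyte,
                     labs$value), , drop = FALSE]
  labs$charttime <- .from_minutes(labs$tmin)
  labs$value_unit <- c(potassium = "mEq/L", magnesium = "mg/dL",
                       phosphate = "mg/dL")[labs$electrolyte]
  labs$tmin <- NULL
  rownames(labs) <- NULL
  labs <- labs[, c("subject_id", "stay_id", "electrolyte", "charttime",
                   "value", "value_unit")]

  repletions <- repletions[order(repletions$stay_id, repletions$tmin,
                                 repletions$electrolyte), , drop = FALSE]
  repletions$ordertime <- .from_minutes(repletions$tmin)
  repletions$tmin <- NULL
  rownames(repletions) <- NULL
  repletions <- repletions[, c("subject_id", "stay_id", "electrolyte",
                               "ordertime", "dose", "route")]

  stays <- data.frame(
    stay_id = stay_id, subject_id = subject_id, unit_type = unit_type,
    intime = .from_minutes(intime_min), outtime = .from_minutes(outtime_min),
    age_years = round(age, 2), weight_kg = round(weight, 1),
    stringsAsFactors = FALSE)

  truth <- planted_truth(params)
  truth$planted <- list(
    n_minors = n_min, n_dx_excluded = n_dx, n_error_values = n_err,
    n_stays_no_event = sum(rowSums(nw_mat) == 0 &
                             !(seq_len(n) %in% forced)))

  out <- structure(list(
    tables = list(labs = labs, repletions = repletions, stays = stays,
                  diagnoses = diagnoses),
    truth = truth, params = params), class = "synthetic_cohort")

  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    for (nm in names(out$tables))
      write_summary_table(out$tables[[nm]], file.path(dir,
                                                      paste0(nm, ".csv")))
    jsonlite::write_json(.truth_as_json(truth),
                         file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}

.truth_as_json <- function(truth) {
  list(per_electrolyte = truth$per_electrolyte,
       scenario_multi_pct = truth$scenario_multi_pct,
       peak_hour = truth$peak_hour,
       planted = truth$planted,
       n_minors = truth$n_minors,
       n_dx_excluded = truth$n_dx_excluded)
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("synthetic audit cohort: ", nrow(x$tables$stays), " stays, ",
      nrow(x$tables$labs), " labs, ", nrow(x$tables$repletions),
      " repletions (seed ", x$params$seed, ")\n", sep = "")
  invisible(x)
}
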