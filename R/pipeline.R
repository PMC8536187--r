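#' @title End-to-end audit pipeline
#' @name repleteaudit-pipeline
#' @description
#' One call runs the whole audit in fixed stage order -- read, cohort,
#' linkage, classification, statistics, temporal -- writes every result
#' table as CSV into an output directory, and returns the bundle. Given
#' identical inputs and configuration the written tables are
#' byte-identical across runs (the run log, which carries wall-clock
#' timestamps, is the only non-reproducible file).
NULL

#' Pipeline configuration
#'
#' @param paths named list/character with CSV paths for `labs`,
#'   `repletions`, `stays`, `diagnoses`.
#' @param output_dir directory for the result bundle (created if missing).
#' @param schema_map,item_map passed to [read_events_table()].
#' @param exclusion_rules named ICD-9 code sets
#'   ([default_exclusion_rules()]).
#' @param minimum_age years, default 18.
#' @param error_bounds physiologic bounds ([default_error_bounds()]).
#' @param ranges reference ranges ([reference_ranges()]); must cover every
#'   analyzed electrolyte.
#' @param linkage a [linkage_config()].
#' @param electrolytes electrolytes to analyze.
#' @param regression_outcome `"post_value"` (default; OLS of the follow-up
#'   serum value) or `"decision"` (linear probability of the 0/1 repletion
#'   decision).
#' @param seed integer, recorded in the run log (the pipeline itself is
#'   deterministic; the seed matters only when the inputs come from
#'   [generate_cohort()]).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(paths, output_dir,
                            schema_map = NULL, item_map = NULL,
                            exclusion_rules = default_exclusion_rules(),
                            minimum_age = 18,
                            error_bounds = default_error_bounds(),
                            ranges = default_reference_ranges(),
                            linkage = linkage_config(),
                            electrolytes = c("potassium", "magnesium",
                                             "phosphate"),
                            regression_outcome = c("post_value", "decision"),
                            seed = 1L) {
  regression_outcome <- match.arg(regression_outcome)
  need <- c("labs", "repletions", "stays", "diagnoses")
  missing_paths <- setdiff(need, names(paths))
  if (length(missing_paths))
    stop("pipeline_config: missing path(s): ",
         paste(missing_paths, collapse = ", "))
  missing_rng <- setdiff(electrolytes, ranges$electrolyte)
  if (length(missing_rng))
    stop("pipeline_config: no reference range for analyzed electrolyte(s): ",
         paste(missing_rng, collapse = ", "))
  structure(list(paths = paths, output_dir = output_dir,
                 schema_map = schema_map, item_map = item_map,
                 exclusion_rules = exclusion_rules,
                 minimum_age = minimum_age, error_bounds = error_bounds,
                 ranges = ranges, linkage = linkage,
                 electrolytes = electrolytes,
                 regression_outcome = regression_outcome,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Understands the sections `paths:`, `output_dir:`, `exclusions:` (ordered
#' mapping of rule name to code list), `reference_ranges:` (mapping of
#' electrolyte to `[low, high]`), `error_bounds:`, `linkage:`
#' (`window_minutes`, `same_electrolyte_only`), `minimum_age`,
#' `regression_outcome` and `seed`. Relative paths are resolved against the
#' YAML file's directory.
#'
#' @param path YAML file.
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) ifelse(grepl("^(/|[A-Za-z]:)", p), p,
                                file.path(base, p))
  paths <- lapply(y$paths, resolve)
  ranges <- if (!is.null(y$reference_ranges)) {
    els <- names(y$reference_ranges)
    reference_ranges(els,
                     vapply(y$reference_ranges, function(r) r[[1]], 0),
                     vapply(y$reference_ranges, function(r) r[[2]], 0))
  } else default_reference_ranges()
  bounds <- if (!is.null(y$error_bounds)) {
    data.frame(electrolyte = names(y$error_bounds),
               low = vapply(y$error_bounds, function(r) r[[1]], 0),
               high = vapply(y$error_bounds, function(r) r[[2]], 0),
               stringsAsFactors = FALSE)
  } else default_error_bounds()
  lk <- linkage_config(
    window_minutes = y$linkage$window_minutes %||% 1440,
    same_electrolyte_only = y$linkage$same_electrolyte_only %||% TRUE)
  pipeline_config(
    paths = paths,
    output_dir = resolve(y$output_dir %||% "replete_audit_out"),
    exclusion_rules = y$exclusions %||% default_exclusion_rules(),
    minimum_age = y$minimum_age %||% 18,
    error_bounds = bounds, ranges = ranges, linkage = lk,
    electrolytes = unlist(y$electrolytes) %||%
      c("potassium", "magnesium", "phosphate"),
    regression_outcome = y$regression_outcome %||% "post_value",
    seed = y$seed %||% 1L)
}

.stage <- function(log, name, ...) {
  msg <- paste0(format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), " [", name, "] ",
                paste0(..., collapse = ""))
  c(log, msg)
}

#' Run the full audit pipeline
#'
#' Stages, in fixed order: read and validate the four tables; build the
#' cohort (attrition log); link episodes; classify against reference
#' ranges; repletion-effectiveness statistics; temporal analyses;
#' decision-factor regression and threshold ANOVA. Each stage's row counts
#' are logged. A hard error in any stage removes the partially written
#' bundle and aborts with a stage-named message.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list of class `audit_report` with all result
#'   tables; the same tables are written as CSV under `config$output_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out_dir <- config$output_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  written <- character(0)
  log <- character(0)
  emit <- function(df, name) {
    p <- file.path(out_dir, paste0(name, ".csv"))
    write_summary_table(df, p)
    written <<- c(written, p)
    p
  }
  fail <- function(stage, e) {
    unlink(written)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  }

  stage_name <- "read"
  report <- tryCatch({
    log <- .stage(log, "config", "seed=", config$seed)
    stays_r <- read_events_table(config$paths$stays, "stay",
                                 config$schema_map$stay)
    tables <- list(
      stays = stays_r$records,
      labs = read_events_table(config$paths$labs, "lab",
                               config$schema_map$lab, config$item_map,
                               stays = stays_r$records)$records,
      repletions = read_events_table(config$paths$repletions, "repletion",
                                     config$schema_map$repletion,
                                     config$item_map,
                                     stays = stays_r$records)$records,
      diagnoses = read_events_table(config$paths$diagnoses, "diagnosis",
                                    config$schema_map$diagnosis)$records)
    for (nm in names(tables))
      log <- .stage(log, "read", nm, ": ", nrow(tables[[nm]]), " rows")

    stage_name <- "cohort"
    cohort <- build_cohort(tables, config$exclusion_rules,
                           config$minimum_age, config$error_bounds)
    log <- .stage(log, "cohort", nrow(cohort$stays), " stays, ",
                  nrow(cohort$labs), " labs, ", nrow(cohort$repletions),
                  " repletions retained")
    emit(cohort$attrition, "attrition")

    stage_name <- "linkage"
    keep_el <- config$electrolytes
    labs <- cohort$labs[cohort$labs$electrolyte %in% keep_el, , drop = FALSE]
    reps <- cohort$repletions[
      cohort$repletions$electrolyte %in% keep_el, , drop = FALSE]
    linkage <- link_episodes(labs, reps, config$linkage)
    ep <- linkage$episodes
    si <- match(ep$stay_id, as.character(cohort$stays$stay_id))
    ep$unit_type <- cohort$stays$unit_type[si]
    ep$age_years <- cohort$stays$age_years[si]
    ep$weight_kg <- cohort$stays$weight_kg[si]
    linkage$episodes <- ep
    log <- .stage(log, "linkage", nrow(ep), " episodes, ",
                  nrow(linkage$unanchored_repletions),
                  " unanchored repletions")
    emit(ep, "episodes")
    emit(linkage$unanchored_repletions, "unanchored_repletions")
    emit(scenario_frequencies(ep), "scenario_frequencies")

    stage_name <- "classification"
    itab <- interpretation_table(ep, config$ranges)
    emit(itab, "interpretation_table")
    emit(repletion_fraction(ep), "repletion_fraction")
    emit(near_miss_frequencies(ep, config$ranges), "near_miss")

    stage_name <- "statistics"
    effects <- pre_post_effect(ep)
    eff_tab <- do.call(rbind, lapply(names(effects), function(el) {
      r <- effects[[el]]
      if (is.null(r)) return(NULL)
      data.frame(electrolyte = el, n = r$n_a, t_statistic = r$t_statistic,
                 df = r$df, p_value = r$p_value, d_cohen = r$d_cohen,
                 mean_pre = r$mean_b, mean_post = r$mean_a,
                 stringsAsFactors = FALSE)
    }))
    if (is.null(eff_tab)) eff_tab <- data.frame()
    emit(eff_tab, "effects")

    anova_tab <- do.call(rbind, lapply(config$electrolytes, function(el) {
      sub <- ep[ep$electrolyte == el & ep$scenario != "NR", ]
      if (length(unique(sub$unit_type[!is.na(sub$unit_type)])) < 2 ||
          nrow(sub) < 4) return(NULL)
      a <- suppressWarnings(threshold_anova(sub$index_value, sub$unit_type))
      data.frame(electrolyte = el, f_statistic = a$f_statistic,
                 df1 = a$df1, df2 = a$df2, p_value = a$p_value,
                 stringsAsFactors = FALSE)
    }))
    if (is.null(anova_tab)) anova_tab <- data.frame()
    emit(anova_tab, "threshold_anova")

    reg <- list()
    reg_tab <- NULL
    for (el in config$electrolytes) {
      d <- ep[ep$electrolyte == el, , drop = FALSE]
      d$unit_code <- as.numeric(factor(d$unit_type))
      d$repleted <- as.integer(d$scenario != "NR")
      if (config$regression_outcome == "post_value") {
        d <- d[!is.na(d$followup_value), , drop = FALSE]
        outcome <- "followup_value"
      } else outcome <- "repleted"
      preds <- c("index_value", "age_years", "weight_kg", "unit_code")
      preds <- preds[vapply(preds, function(p)
        sum(!is.na(d[[p]])) > 0 && stats::var(d[[p]], na.rm = TRUE) > 0,
        logical(1))]
      if (nrow(d) > length(preds) + 2 && length(preds) > 0) {
        fit <- decision_regression(d, outcome, preds)
        reg[[el]] <- fit
        cf <- fit$coefficients
        cf <- cbind(electrolyte = el, cf,
                    n_observations = fit$n_observations,
                    r_squared = fit$r_squared,
                    adjusted_r_squared = fit$adjusted_r_squared,
                    stringsAsFactors = FALSE)
        reg_tab <- rbind(reg_tab, cf)
      }
    }
    if (is.null(reg_tab)) reg_tab <- data.frame()
    emit(reg_tab, "regression")

    stage_name <- "temporal"
    lab_hours <- hour_histogram(labs$charttime)
    order_hours <- hour_histogram(reps$ordertime)
    hh <- data.frame(hour = 0:23,
                     lab_count = as.integer(lab_hours$counts),
                     order_count = as.integer(order_hours$counts))
    emit(hh, "hour_histograms")
    emit(latency_summary(ep), "latency")
    emit(threshold_by_hour(ep), "threshold_by_hour")
    log <- .stage(log, "done", length(written), " tables written")

    structure(list(
      cohort = cohort, linkage = linkage,
      interpretation = itab,
      repletion_fraction = repletion_fraction(ep),
      near_miss = near_miss_frequencies(ep, config$ranges),
      scenario_frequencies = scenario_frequencies(ep),
      effects = effects, effects_table = eff_tab,
      anova = anova_tab, regression = reg,
      hour_histograms = list(lab = lab_hours, order = order_hours),
      latency = latency_summary(ep),
      threshold_by_hour = threshold_by_hour(ep),
      files = written, config = config),
      class = "audit_report")
  }, error = function(e) fail(stage_name, e))

  writeLines(log, file.path(out_dir, "run.log"))
  invisible(report)
}

#' @export
print.audit_report <- function(x, ...) {
  cat("electrolyte repletion audit report\n")
  print(x$cohort$attrition)
  cat("\nscenario frequencies:\n")
  print(x$scenario_frequencies)
  cat("\nrepletion fractions:\n")
  print(x$repletion_fraction)
  cat("\npre/post effects:\n")
  for (el in names(x$effects))
    if (!is.null(x$effects[[el]])) {
      cat("  ", el, ": ", sep = ""); print(x$effects[[el]])
    }
  invisible(x)
}
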