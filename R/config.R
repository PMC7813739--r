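# Flat key = value configuration surface. Every knob of the pipeline is a
# scalar key so a config file round-trips exactly and unknown keys can be
# rejected by name.

config_param_keys <- function() {
  c("prevalence", "sensitivity_mrm", "specificity_mrm",
    "biopsy_sensitivity", "biopsy_specificity", "cost_mrm", "cost_biopsy",
    "cost_early_surgery", "cost_delayed_surgery", "yearly_cost_tumor",
    "yearly_cost_no_tumor", "utility_no_tumor", "utility_tumor",
    "utility_dead", "qaly_loss_biopsy", "p_death_tumor",
    "p_death_background", "p_recurrence", "p_treatment_success",
    "start_age", "horizon", "discount_rate", "wtp")
}

config_defaults <- function() {
  p <- unclass(mrm_params())
  flat <- p[config_param_keys()]
  c(flat,
    list(
      background_mortality_csv = "",
      discount_convention = "begin",
      half_cycle_correction = FALSE,
      recurrence_negatives = FALSE,
      recurrence_treatment_cost = "early",
      surveillance = "biennial",
      counts_tp = 76, counts_fp = 48, counts_tn = 971, counts_fn = 0,
      dsa_prevalence_low = 0, dsa_prevalence_high = 0.20,
      dsa_sensitivity_low = 0.70, dsa_sensitivity_high = 1.00,
      dsa_specificity_low = 0.70, dsa_specificity_high = 1.00,
      dsa_points = 21,
      reference_cost_tp = 7606.80, reference_cost_fn = 17518.54,
      reference_cost_tn = 1193.16, reference_cost_fp = 1493.16,
      reference_qalys_tp = 4.62, reference_qalys_fn = 3.95,
      reference_qalys_tn = 4.70, reference_qalys_fp = 4.65,
      microsim_n = 0,
      seed = 1,
      out_dir = ".",
      report_digits = 2
    ))
}

parse_config_value <- function(key, value, defaults) {
  template <- defaults[[key]]
  if (is.logical(template)) {
    if (!tolower(value) %in% c("true", "false")) {
      stop(sprintf("config key '%s' must be true or false", key),
           call. = FALSE)
    }
    return(tolower(value) == "true")
  }
  if (is.numeric(template)) {
    v <- suppressWarnings(as.numeric(value))
    if (is.na(v)) {
      stop(sprintf("config key '%s' must be numeric, got '%s'", key, value),
           call. = FALSE)
    }
    return(v)
  }
  value
}

#' Load and validate a pipeline configuration
#'
#' Reads a flat `key = value` text configuration (blank lines and
#' `#` comments ignored). Every omitted key takes its base-case default,
#' so an empty (or absent) file reproduces the published parameter set
#' exactly; unknown keys are rejected with a message naming the key, and
#' all values are validated against their domains on load.
#'
#' @param path Path to a config file, or `NULL` for pure defaults.
#' @return An object of class `run_config`: a list with `params`
#'   ([mrm_params()]), `conventions` ([mrm_conventions()]), `counts`
#'   ([confusion_counts()] or `NULL`), `dsa_ranges`, `dsa_points`,
#'   `reference` (`branch_results`), `microsim_n`, `seed`, `out_dir`,
#'   `report_digits`, and the `flat` key-value list it was built from.
#' @examples
#' cfg <- load_config()
#' cfg$params$discount_rate
#' @export
load_config <- function(path = NULL) {
  defaults <- config_defaults()
  flat <- defaults
  if (!is.null(path)) {
    if (!file.exists(path)) {
      stop("config file not found: ", path, call. = FALSE)
    }
    lines <- readLines(path, warn = FALSE)
    lines <- sub("#.*$", "", lines)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines)]
    for (ln in lines) {
      if (!grepl("=", ln, fixed = TRUE)) {
        stop("malformed config line (expected 'key = value'): ", ln,
             call. = FALSE)
      }
      key <- trimws(sub("=.*$", "", ln))
      value <- trimws(sub("^[^=]*=", "", ln))
      if (!key %in% names(defaults)) {
        stop("unknown config key: ", key, call. = FALSE)
      }
      flat[[key]] <- parse_config_value(key, value, defaults)
    }
  }
  build_run_config(flat)
}

build_run_config <- function(flat) {
  bg <- if (nzchar(flat$background_mortality_csv)) {
    read_mortality_csv(flat$background_mortality_csv)
  } else flat$p_death_background
  par_args <- flat[config_param_keys()]
  par_args$p_death_background <- bg
  params <- do.call(mrm_params, par_args)
  conventions <- mrm_conventions(
    discount_convention = flat$discount_convention,
    half_cycle_correction = flat$half_cycle_correction,
    recurrence_negatives = flat$recurrence_negatives,
    recurrence_treatment_cost = flat$recurrence_treatment_cost,
    surveillance = flat$surveillance
  )
  counts <- if (flat$counts_tp + flat$counts_fp + flat$counts_tn +
                  flat$counts_fn > 0) {
    confusion_counts(flat$counts_tp, flat$counts_fp,
                     flat$counts_tn, flat$counts_fn)
  }
  dsa_ranges <- list(
    prevalence = c(flat$dsa_prevalence_low, flat$dsa_prevalence_high),
    sensitivity_mrm = c(flat$dsa_sensitivity_low,
                        flat$dsa_sensitivity_high),
    specificity_mrm = c(flat$dsa_specificity_low,
                        flat$dsa_specificity_high)
  )
  reference <- branch_values(
    cost = c(TP = flat$reference_cost_tp, FN = flat$reference_cost_fn,
             TN = flat$reference_cost_tn, FP = flat$reference_cost_fp),
    qalys = c(TP = flat$reference_qalys_tp, FN = flat$reference_qalys_fn,
              TN = flat$reference_qalys_tn, FP = flat$reference_qalys_fp))
  if (flat$microsim_n < 0 || flat$microsim_n != round(flat$microsim_n)) {
    stop("microsim_n must be a non-negative integer", call. = FALSE)
  }
  structure(list(params = params, conventions = conventions,
                 counts = counts, dsa_ranges = dsa_ranges,
                 dsa_points = flat$dsa_points, reference = reference,
                 microsim_n = flat$microsim_n, seed = flat$seed,
                 out_dir = flat$out_dir,
                 report_digits = flat$report_digits, flat = flat),
            class = "run_config")
}

#' Write a configuration back to disk
#'
#' Dumps every flat key of a [load_config()] object as `key = value`
#' lines. Numeric values are written losslessly, so loading the dumped
#' file reproduces an identical configuration (round-trip contract).
#'
#' @param config A `run_config`.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  fmt <- function(v) {
    if (is.logical(v)) return(if (v) "true" else "false")
    if (is.numeric(v)) return(sprintf("%.17g", v))
    as.character(v)
  }
  lines <- vapply(names(config$flat),
                  function(k) paste(k, "=", fmt(config$flat[[k]])),
                  character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.run_config <- function(x, ...) {
  cat("Pipeline configuration\n")
  print(x$params)
  print(x$conventions)
  cat(sprintf("  microsim_n = %d, seed = %d, out_dir = '%s'\n",
              as.integer(x$microsim_n), as.integer(x$seed), x$out_dir))
  invisible(x)
}

write_report_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Executes every stage of the evaluation — diagnostic accuracy (when
#' confusion counts are configured), branch Markov evaluation, base case,
#' one-way sensitivity analysis, convention calibration and (optionally)
#' the patient-level microsimulation — and writes one CSV report per
#' stage plus a parameter log to the output directory. Values in the
#' CSVs are kept at full precision (machine-readable layer); rounding to
#' the configured digits is applied only by the print methods. Re-running
#' with the same configuration and seed yields byte-identical files.
#'
#' @param config A `run_config` from [load_config()].
#' @param out_dir Output directory (default from the config); created if
#'   missing.
#' @param verbose Log stage progress and every parameter value to stderr.
#' @return Invisibly, a list with the computed objects and the written
#'   file paths.
#' @export
run_pipeline <- function(config = load_config(), out_dir = NULL,
                         verbose = TRUE) {
  stopifnot(inherits(config, "run_config"))
  out_dir <- out_dir %||% config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (verbose) message("[mrmcea] ", sprintf(...))
  paths <- list()

  # audit log: every parameter value used by this run
  flat <- config$flat
  say("parameters: %s",
      paste(names(flat), vapply(flat, function(v) paste(format(v),
                                                        collapse = ";"),
                                character(1)),
            sep = "=", collapse = ", "))
  par_df <- data.frame(key = names(flat),
                       value = vapply(flat, function(v)
                         if (is.numeric(v)) sprintf("%.17g", v)
                         else as.character(v), character(1)),
                       row.names = NULL)
  paths$parameters <- write_report_csv(par_df,
                                       file.path(out_dir, "parameters.csv"))

  results <- list(config = config)

  if (!is.null(config$counts)) {
    say("stage accuracy: computing diagnostic performance")
    perf <- compute_performance(config$counts)
    acc_df <- data.frame(
      tp = config$counts$tp, fp = config$counts$fp,
      tn = config$counts$tn, fn = config$counts$fn,
      sensitivity = perf$sensitivity, specificity = perf$specificity,
      ppv = perf$ppv, npv = perf$npv, accuracy = perf$accuracy,
      prevalence = perf$prevalence)
    paths$accuracy <- write_report_csv(acc_df,
                                       file.path(out_dir, "accuracy.csv"))
    results$performance <- perf
  }

  say("stage branches: evaluating the four branch Markov models")
  model <- cea_model(config$params, config$conventions)
  paths$branch_results <- write_report_csv(
    as.data.frame(model$branch_results),
    file.path(out_dir, "branch_results.csv"))
  results$model <- model

  say("stage basecase: expected cost %.2f EUR, %.2f QALYs",
      model$base_case$expected_cost, model$base_case$expected_qalys)
  bc_df <- data.frame(expected_cost = model$base_case$expected_cost,
                      expected_qalys = model$base_case$expected_qalys,
                      nmb = model$base_case$nmb,
                      wtp = model$base_case$wtp)
  paths$base_case <- write_report_csv(bc_df,
                                      file.path(out_dir, "base_case.csv"))

  say("stage dsa: one-way sensitivity analysis")
  dsa <- one_way_dsa(config$params, ranges = config$dsa_ranges,
                     n_points = config$dsa_points,
                     mode = "branch-values",
                     branch_results = model$branch_results)
  dsa_ordered <- tornado_order(dsa)
  paths$dsa <- write_report_csv(as.data.frame(dsa_ordered),
                                file.path(out_dir, "dsa.csv"))
  results$dsa <- dsa_ordered

  say("stage calibrate: convention grid search")
  cal <- calibrate_conventions(config$params, config$reference)
  paths$calibration <- write_report_csv(
    cal$report, file.path(out_dir, "calibration.csv"))
  paths$calibration_residuals <- write_report_csv(
    cal$residuals, file.path(out_dir, "calibration_residuals.csv"))
  results$calibration <- cal

  if (config$microsim_n > 0) {
    say("stage microsim: %d patients, seed %d",
        as.integer(config$microsim_n), as.integer(config$seed))
    ms <- simulate_cohort(config$params, config$conventions,
                          n = config$microsim_n, seed = config$seed)
    paths$microsim <- write_report_csv(as.data.frame(ms),
                                       file.path(out_dir, "microsim.csv"))
    results$microsim <- ms
  }

  say("pipeline complete: %d report file(s) in '%s'",
      length(paths), out_dir)
  results$paths <- paths
  invisible(results)
}
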