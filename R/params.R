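# Default distribution-family metadata for probabilistic analyses.
# Carried as tags only: the deterministic analyses in this package never
# draw from them (beta for probabilities/utilities, gamma for costs).
default_distributions <- function() {
  c(prevalence = "beta", sensitivity_mrm = "beta", specificity_mrm = "beta",
    biopsy_sensitivity = "beta", biopsy_specificity = "beta",
    cost_mrm = "gamma", cost_biopsy = "gamma",
    cost_early_surgery = "gamma", cost_delayed_surgery = "gamma",
    yearly_cost_tumor = "gamma", yearly_cost_no_tumor = "gamma",
    utility_no_tumor = "beta", utility_tumor = "beta",
    utility_dead = "beta", qaly_loss_biopsy = "beta",
    p_death_tumor = "beta", p_death_background = "beta",
    p_recurrence = "beta", p_treatment_success = "beta",
    start_age = "beta", horizon = "beta", discount_rate = "beta",
    wtp = "beta")
}

#' Model input parameters for the MRM cost-effectiveness model
#'
#' Builds the full parameter set of the dense-breast MRM evaluation with
#' the published base-case values as defaults. Any subset can be
#' overridden by name; unknown names are rejected.
#'
#' The defaults describe a screening cohort of 32-year-old women at
#' intermediate risk (7% pre-test probability of malignancy), an MRM test
#' with 100% sensitivity and 97% specificity followed by a biopsy assumed
#' perfect, acute costs for the examination (418.50 EUR), biopsy
#' (300 EUR) and early versus delayed surgery (4000 vs 10000 EUR), yearly
#' cancer care costs of 10000 EUR, utilities of 1.0 (no tumor) / 0.7
#' (tumor) / 0 (dead) with a 0.05 QALY biopsy decrement, annual
#' probabilities of cancer death (5.44%), recurrence (4.5%) and treatment
#' success (60%), a 5-year horizon and a 3% annual discount rate with a
#' willingness-to-pay of 100000 EUR/QALY.
#'
#' @param ... Named overrides of any field listed above, plus
#'   `p_death_background` (a single annual probability or a data frame
#'   with columns `age` and `annual_death_probability`) and
#'   `distributions` (named character metadata tags).
#' @return An object of class `mrm_params` (a named list).
#' @examples
#' p <- mrm_params(cost_mrm = 500)
#' p$cost_mrm
#' @export
mrm_params <- function(...) {
  defaults <- list(
    prevalence = 0.07,
    sensitivity_mrm = 1.00,
    specificity_mrm = 0.97,
    biopsy_sensitivity = 1.00,
    biopsy_specificity = 1.00,
    cost_mrm = 418.50,
    cost_biopsy = 300.00,
    cost_early_surgery = 4000.00,
    cost_delayed_surgery = 10000.00,
    yearly_cost_tumor = 10000.00,
    yearly_cost_no_tumor = 0.00,
    utility_no_tumor = 1.0,
    utility_tumor = 0.7,
    utility_dead = 0.0,
    qaly_loss_biopsy = 0.05,
    p_death_tumor = 0.0544,
    p_death_background = 0.0007,
    p_recurrence = 0.045,
    p_treatment_success = 0.60,
    start_age = 32,
    horizon = 5,
    discount_rate = 0.03,
    wtp = 100000,
    distributions = default_distributions()
  )
  over <- list(...)
  if (length(over) > 0 && (is.null(names(over)) || any(names(over) == ""))) {
    stop("all parameter overrides must be named", call. = FALSE)
  }
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown) > 0) {
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  p <- utils::modifyList(defaults, over)
  validate_mrm_params(p)
  structure(p, class = "mrm_params")
}

validate_mrm_params <- function(p) {
  for (nm in c("prevalence", "sensitivity_mrm", "specificity_mrm",
               "biopsy_sensitivity", "biopsy_specificity",
               "utility_no_tumor", "utility_tumor", "utility_dead",
               "qaly_loss_biopsy", "p_death_tumor", "p_recurrence",
               "p_treatment_success")) {
    check_scalar(p[[nm]], nm, 0, 1)
  }
  for (nm in c("cost_mrm", "cost_biopsy", "cost_early_surgery",
               "cost_delayed_surgery", "yearly_cost_tumor",
               "yearly_cost_no_tumor", "wtp")) {
    check_scalar(p[[nm]], nm, 0, Inf)
  }
  check_scalar(p$discount_rate, "discount_rate", 0, Inf)
  check_scalar(p$start_age, "start_age", 0, Inf)
  if (!is.numeric(p$horizon) || p$horizon < 1 ||
      p$horizon != round(p$horizon)) {
    stop("'horizon' must be a positive integer number of years",
         call. = FALSE)
  }
  if (p$p_death_tumor + p$p_treatment_success > 1) {
    stop("p_death_tumor + p_treatment_success must not exceed 1 ",
         "(the cancer-state transition row must be a probability vector)",
         call. = FALSE)
  }
  bg <- p$p_death_background
  if (is.data.frame(bg)) {
    if (!all(c("age", "annual_death_probability") %in% names(bg)) ||
        nrow(bg) == 0 ||
        any(bg$annual_death_probability < 0 |
              bg$annual_death_probability > 1)) {
      stop("background mortality table needs columns 'age' and ",
           "'annual_death_probability' (probabilities in [0, 1])",
           call. = FALSE)
    }
  } else {
    check_scalar(bg, "p_death_background", 0, 1)
  }
  invisible(p)
}

# Annual background (other-cause) death probability at a given age.
# Constant scalar, or table lookup clamped to the table's age range.
background_mortality_at <- function(p_death_background, age) {
  if (!is.data.frame(p_death_background)) return(p_death_background)
  tbl <- p_death_background[order(p_death_background$age), ]
  age <- min(max(age, tbl$age[1], na.rm = TRUE), tbl$age[nrow(tbl)])
  i <- findInterval(age, tbl$age)
  tbl$annual_death_probability[max(i, 1)]
}

#' Read a background-mortality table from CSV
#'
#' Expects columns `age` and `annual_death_probability` (one row per year
#' of age). Ages outside the table range are clamped to its ends.
#'
#' @param path CSV file path.
#' @return A data frame usable as the `p_death_background` parameter.
#' @export
read_mortality_csv <- function(path) {
  tbl <- utils::read.csv(path)
  if (!all(c("age", "annual_death_probability") %in% names(tbl))) {
    stop("mortality CSV must have columns 'age' and ",
         "'annual_death_probability'", call. = FALSE)
  }
  tbl
}

#' @export
print.mrm_params <- function(x, ...) {
  cat("MRM cost-effectiveness model parameters\n")
  for (nm in setdiff(names(x), c("distributions", "p_death_background"))) {
    cat(sprintf("  %-22s %s\n", nm, format(x[[nm]])))
  }
  bg <- x$p_death_background
  cat(sprintf("  %-22s %s\n", "p_death_background",
              if (is.data.frame(bg)) {
                sprintf("age-dependent table (%d rows)", nrow(bg))
              } else format(bg)))
  invisible(x)
}

#' Evaluation conventions for the cohort engine
#'
#' The original analysis was carried out in commercial decision-tree
#' software whose cycle-accounting settings are not published. These knobs
#' make every such setting explicit so [calibrate_conventions()] can
#' search over them. The defaults are begin-of-cycle discounting with
#' rewards on start-of-cycle occupancy (no half-cycle correction),
#' biennial surveillance imaging for test-negative patients, recurrence
#' restricted to patients with a treated cancer, and recurrence treatment
#' charged at the early-surgery cost.
#'
#' @param discount_convention Discount timing: `"begin"`, `"end"` or
#'   `"half-cycle"` (see [discount_factor()]).
#' @param half_cycle_correction Average start/end-of-cycle occupancy for
#'   state rewards.
#' @param recurrence_negatives Should test-negative (TN/FP) patients, who
#'   never had a treated cancer, be exposed to the recurrence hazard?
#' @param recurrence_treatment_cost Surgery cost charged when a recurrence
#'   is treated successfully: `"early"` (4000 EUR class), `"delayed"`
#'   (10000 EUR class) or `"none"`.
#' @param surveillance Follow-up MRM schedule for test-negative patients
#'   within the horizon: `"biennial"` (years 2 and 4), `"annual"`
#'   (years 1-4) or `"none"`.
#' @return An object of class `mrm_conventions`.
#' @export
mrm_conventions <- function(discount_convention = c("begin", "end",
                                                    "half-cycle"),
                            half_cycle_correction = FALSE,
                            recurrence_negatives = FALSE,
                            recurrence_treatment_cost = c("early", "delayed",
                                                          "none"),
                            surveillance = c("biennial", "annual", "none")) {
  structure(list(
    discount_convention = match.arg(discount_convention),
    half_cycle_correction = isTRUE(half_cycle_correction),
    recurrence_negatives = isTRUE(recurrence_negatives),
    recurrence_treatment_cost = match.arg(recurrence_treatment_cost),
    surveillance = match.arg(surveillance)
  ), class = "mrm_conventions")
}

#' @export
print.mrm_conventions <- function(x, ...) {
  cat("Cohort-engine conventions:\n")
  for (nm in names(x)) cat(sprintf("  %-26s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
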