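# Health-state labels shared by all four branch models.
mrm_states <- function() c("NoCancer", "Cancer", "Dead")

# Surveillance MRM cycles (0-based) within the horizon for a schedule.
# The index examination is cycle 0, so follow-ups start at cycle 1.
surveillance_cycles <- function(schedule, horizon) {
  switch(schedule,
         none = integer(0),
         annual = seq_len(horizon - 1),
         biennial = if (horizon >= 3) seq(2, horizon - 1, by = 2)
                    else integer(0))
}

#' Build the Markov model for one diagnostic branch
#'
#' Instantiates the three-state cohort model ("NoCancer", "Cancer",
#' "Dead") for one outcome of the diagnostic decision tree:
#'
#' \describe{
#'   \item{TP}{Immediate successful treatment is assumed: the patient
#'     starts in "NoCancer" after MRM, biopsy and early surgery (all
#'     charged upfront, with the biopsy's one-time QALY decrement), and is
#'     exposed to the yearly recurrence hazard thereafter.}
#'   \item{FN}{The missed cancer persists: the patient starts in "Cancer"
#'     having paid only the MRM fee; treatment success (60\%/yr) moves her
#'     to "NoCancer" and is charged the delayed-surgery cost, reflecting
#'     the more extensive surgery of a late diagnosis.}
#'   \item{TN}{Starts in "NoCancer" with only the MRM fee; follow-up
#'     surveillance MRMs accrue on the schedule set in the conventions.}
#'   \item{FP}{Identical to TN plus the biopsy cost upfront and the
#'     one-time biopsy QALY loss (the biopsy is assumed perfect, so FP
#'     patients are correctly ruled out).}
#' }
#'
#' In the "NoCancer" state the age-dependent background mortality applies;
#' in the "Cancer" state the cancer-specific annual death probability is
#' used alone. The cancer row is success + death + stay = 1.
#'
#' @param branch One of `"TP"`, `"FN"`, `"TN"`, `"FP"`.
#' @param params An [mrm_params()] object.
#' @param conventions An [mrm_conventions()] object.
#' @return A list with elements `spec` ([markov_spec()]), `start_state`,
#'   `upfront_cost`, `upfront_utility`, `n_cycles` and `discount`
#'   ([discount_spec()]), ready for [run_cohort()] or [sim_markov()].
#' @export
build_branch <- function(branch, params = mrm_params(),
                         conventions = mrm_conventions()) {
  if (!is.character(branch) || length(branch) != 1 ||
      !branch %in% c("TP", "FN", "TN", "FP")) {
    stop("unknown branch label; expected one of TP, FN, TN, FP",
         call. = FALSE)
  }
  p <- params
  cv <- conventions
  states <- mrm_states()

  # recurrence hazard applies to patients with a (treated) cancer history:
  # TP always, FN once treated; TN/FP only if the convention switches it on
  recur <- if (branch %in% c("TP", "FN")) {
    p$p_recurrence
  } else if (cv$recurrence_negatives) p$p_recurrence else 0

  transitions <- function(cycle, age) {
    bg <- background_mortality_at(p$p_death_background, age)
    stay_nc <- 1 - recur - bg
    if (stay_nc < 0) {
      stop("recurrence plus background mortality exceed 1", call. = FALSE)
    }
    matrix(c(stay_nc, recur, bg,
             p$p_treatment_success,
             1 - p$p_treatment_success - p$p_death_tumor, p$p_death_tumor,
             0, 0, 1),
           nrow = 3, byrow = TRUE, dimnames = list(states, states))
  }

  # surgery charged when treatment succeeds (Cancer -> NoCancer): the
  # initial tumor of an FN patient needs the delayed (extensive) surgery;
  # a treated recurrence is under surveillance, so the convention decides
  treat_cost <- if (branch == "FN") {
    p$cost_delayed_surgery
  } else {
    switch(cv$recurrence_treatment_cost,
           early = p$cost_early_surgery,
           delayed = p$cost_delayed_surgery,
           none = 0)
  }
  tc <- matrix(0, 3, 3, dimnames = list(states, states))
  tc["Cancer", "NoCancer"] <- treat_cost

  surv <- if (branch %in% c("TN", "FP")) {
    surveillance_cycles(cv$surveillance, p$horizon)
  } else integer(0)
  state_costs <- function(cycle) {
    c(p$yearly_cost_no_tumor +
        if (cycle %in% surv) p$cost_mrm else 0,
      p$yearly_cost_tumor, 0)
  }

  utilities <- c(p$utility_no_tumor, p$utility_tumor, p$utility_dead)

  upfront_cost <- switch(branch,
    TP = p$cost_mrm + p$cost_biopsy + p$cost_early_surgery,
    FN = p$cost_mrm,
    TN = p$cost_mrm,
    FP = p$cost_mrm + p$cost_biopsy)
  # every biopsied patient (positive test) carries the biopsy disutility
  upfront_utility <- if (branch %in% c("TP", "FP")) {
    -p$qaly_loss_biopsy
  } else 0

  spec <- markov_spec(states, transitions, state_costs, utilities,
                      transition_costs = tc, absorbing = "Dead",
                      start_age = p$start_age)
  list(spec = spec,
       start_state = if (branch == "FN") "Cancer" else "NoCancer",
       upfront_cost = upfront_cost,
       upfront_utility = upfront_utility,
       n_cycles = p$horizon,
       discount = discount_spec(p$discount_rate, cv$discount_convention))
}

#' Evaluate the four diagnostic branches
#'
#' Runs the cohort model of every decision-tree branch (TP, FN, TN, FP)
#' and collects the expected discounted cost and QALYs over the horizon.
#' Values are kept at full precision; rounding to two decimals happens
#' only when printing.
#'
#' @inheritParams build_branch
#' @return An object of class `branch_results`: a data frame with columns
#'   `branch`, `expected_cost`, `expected_qalys`; the per-branch
#'   `cohort_result` traces are attached as attribute `"details"`.
#' @examples
#' evaluate_branches(mrm_params())
#' @export
evaluate_branches <- function(params = mrm_params(),
                              conventions = mrm_conventions()) {
  branches <- c("TP", "FN", "TN", "FP")
  details <- lapply(branches, function(b) {
    bb <- build_branch(b, params, conventions)
    run_cohort(bb$spec, bb$start_state, bb$n_cycles, bb$discount,
               bb$upfront_cost, bb$upfront_utility,
               conventions$half_cycle_correction)
  })
  names(details) <- branches
  out <- data.frame(
    branch = branches,
    expected_cost = vapply(details, `[[`, numeric(1), "expected_cost"),
    expected_qalys = vapply(details, `[[`, numeric(1), "expected_qalys"),
    row.names = NULL
  )
  attr(out, "details") <- details
  class(out) <- c("branch_results", "data.frame")
  out
}

#' Assemble branch results from externally supplied values
#'
#' Wraps per-branch cost/QALY values (for instance the published 5-year
#' per-branch results of the original analysis) in the same container
#' returned by [evaluate_branches()], so the decision-tree layer can run
#' on fixed branch values without re-evaluating the Markov models.
#'
#' @param cost,qalys Named numeric vectors with entries `TP`, `FN`, `TN`,
#'   `FP`.
#' @return A `branch_results` data frame.
#' @examples
#' branch_values(cost = c(TP = 7606.80, FN = 17518.54,
#'                        TN = 1193.16, FP = 1493.16),
#'               qalys = c(TP = 4.62, FN = 3.95, TN = 4.70, FP = 4.65))
#' @export
branch_values <- function(cost, qalys) {
  branches <- c("TP", "FN", "TN", "FP")
  if (!all(branches %in% names(cost)) || !all(branches %in% names(qalys))) {
    stop("cost and qalys must be named vectors with entries TP, FN, TN, FP",
         call. = FALSE)
  }
  if (any(cost[branches] < 0)) stop("costs must be >= 0", call. = FALSE)
  out <- data.frame(branch = branches,
                    expected_cost = as.numeric(cost[branches]),
                    expected_qalys = as.numeric(qalys[branches]),
                    row.names = NULL)
  class(out) <- c("branch_results", "data.frame")
  out
}

#' Published per-branch reference results
#'
#' The 5-year discounted per-branch costs and QALYs reported by the
#' original software implementation of this model, used as the calibration
#' reference for the unpublished cycle-accounting conventions (see
#' [calibrate_conventions()]) and as fixed branch values for the
#' decision-tree worked examples.
#'
#' @return A `branch_results` data frame (TP 7606.80 EUR / 4.62 QALYs;
#'   FN 17518.54 / 3.95; TN 1193.16 / 4.70; FP 1493.16 / 4.65).
#' @export
mrm_reference_results <- function() {
  branch_values(cost = c(TP = 7606.80, FN = 17518.54,
                         TN = 1193.16, FP = 1493.16),
                qalys = c(TP = 4.62, FN = 3.95, TN = 4.70, FP = 4.65))
}

#' Diagnostic study confusion counts
#'
#' The prospective dense-breast MRM screening cohort's confusion table
#' (1095 evaluated patients), and the invasive-cancers-only subset with
#' ductal carcinoma in situ excluded.
#'
#' @param invasive_only If `TRUE`, return the invasive-only counts
#'   (63/27/971/0) instead of the full table (76/48/971/0).
#' @return A [confusion_counts()] object.
#' @export
mrm_study_counts <- function(invasive_only = FALSE) {
  if (invasive_only) {
    confusion_counts(tp = 63, fp = 27, tn = 971, fn = 0)
  } else {
    confusion_counts(tp = 76, fp = 48, tn = 971, fn = 0)
  }
}

#' @export
print.branch_results <- function(x, digits = 2, ...) {
  cat("Per-branch 5-year discounted results:\n")
  y <- data.frame(branch = x$branch,
                  expected_cost = round(x$expected_cost, digits),
                  expected_qalys = round(x$expected_qalys, digits))
  print.data.frame(y, row.names = FALSE)
  invisible(x)
}
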