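#' Fit the MRM screening cost-effectiveness model
#'
#' The central evaluator of the package: builds the decision tree over
#' the four diagnostic outcomes of MR-mammography (true/false
#' positive/negative), evaluates the three-state Markov cohort model of
#' every branch over the horizon, and combines them into the base-case
#' expected cost, expected QALYs and net monetary benefit.
#'
#' Supplying `branch_results` (e.g. [mrm_reference_results()]) skips the
#' Markov evaluation and runs the decision-tree layer on fixed per-branch
#' values; this is how the published worked examples are reproduced
#' independently of any cycle-accounting convention.
#'
#' @param params An [mrm_params()] object.
#' @param conventions An [mrm_conventions()] object.
#' @param branch_results Optional fixed `branch_results`
#'   ([branch_values()]); when `NULL` the branch Markov models are
#'   evaluated.
#' @return An object of class `cea_model`: a list with `params`,
#'   `conventions`, `branch_probs`, `branch_results` and `base_case`.
#' @examples
#' m <- cea_model()
#' m
#' coef(m)["wtp"]
#' @seealso [one_way_dsa()], [simulate_cohort()], [calibrate_conventions()]
#' @export
cea_model <- function(params = mrm_params(),
                      conventions = mrm_conventions(),
                      branch_results = NULL) {
  stopifnot(inherits(params, "mrm_params"),
            inherits(conventions, "mrm_conventions"))
  br <- if (is.null(branch_results)) {
    evaluate_branches(params, conventions)
  } else {
    stopifnot(inherits(branch_results, "branch_results"))
    branch_results
  }
  probs <- branch_probabilities(params$prevalence, params$sensitivity_mrm,
                                params$specificity_mrm)
  bc <- base_case(br, probs, params$wtp)
  structure(list(params = params, conventions = conventions,
                 branch_probs = probs, branch_results = br,
                 base_case = bc,
                 fixed_branch_values = !is.null(branch_results)),
            class = "cea_model")
}

#' @export
print.cea_model <- function(x, digits = 2, ...) {
  cat("MRM screening cost-effectiveness model",
      if (x$fixed_branch_values) "(fixed branch values)" else
        "(Markov-evaluated branches)", "\n")
  print(x$branch_results, digits = digits)
  print(x$base_case, digits = digits)
  invisible(x)
}

#' @export
summary.cea_model <- function(object, ...) {
  gain <- qaly_gain(object$branch_results, "TP", "FN")
  structure(list(model = object, qaly_gain_tp_fn = gain),
            class = "summary.cea_model")
}

#' @export
print.summary.cea_model <- function(x, digits = 2, ...) {
  print(x$model, digits = digits)
  cat("Branch probabilities (TP/FN/TN/FP): ",
      paste(round(unclass(x$model$branch_probs), 4), collapse = " / "),
      "\n", sep = "")
  cat(sprintf("QALY gain of timely (TP) over delayed (FN) diagnosis: %s\n",
              formatC(x$qaly_gain_tp_fn, format = "f", digits = digits)))
  invisible(x)
}

#' @export
coef.cea_model <- function(object, ...) {
  p <- object$params
  keep <- vapply(p, function(v) is.numeric(v) && length(v) == 1, logical(1))
  unlist(p[keep])
}

#' Update a fitted cost-effectiveness model
#'
#' Re-evaluates the model with some parameters or conventions replaced.
#'
#' @param object A [cea_model()].
#' @param ... Named parameter overrides (passed to [mrm_params()]).
#' @param conventions Optional replacement [mrm_conventions()].
#' @return A new `cea_model`.
#' @export
update.cea_model <- function(object, ..., conventions = NULL) {
  over <- list(...)
  p <- object$params
  if (length(over) > 0) {
    p <- do.call(mrm_params, utils::modifyList(unclass(p), over))
  }
  cea_model(p, conventions %||% object$conventions)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate patient-level outcomes from a fitted model
#'
#' Runs the patient-level microsimulation ([simulate_cohort()]) under the
#' model's parameters and conventions; the Monte-Carlo oracle for the
#' cohort engine.
#'
#' @param object A [cea_model()].
#' @param nsim Number of simulated patients.
#' @param seed Integer seed.
#' @param ... Passed on to [simulate_cohort()] (e.g. `trajectories`).
#' @return A `microsim_summary`.
#' @export
simulate.cea_model <- function(object, nsim = 10000, seed = 1, ...) {
  simulate_cohort(object$params, object$conventions, n = nsim,
                  seed = seed, ...)
}

#' Tornado plot of a one-way sensitivity analysis
#'
#' Horizontal-bar tornado diagram of expected-cost swings, parameters
#' ordered by impact. Base graphics; never load-bearing for the analysis.
#'
#' @param x A [cea_model()].
#' @param dsa Optional precomputed [one_way_dsa()] result; by default a
#'   branch-values DSA over the standard ranges is run.
#' @param ... Passed to [graphics::barplot()].
#' @return The ordered `dsa_result`, invisibly.
#' @export
plot.cea_model <- function(x, dsa = NULL, ...) {
  if (is.null(dsa)) {
    dsa <- one_way_dsa(x$params, branch_results = x$branch_results)
  }
  ord <- tornado_order(dsa)
  base <- x$base_case$expected_cost
  lo <- pmin(ord$cost_low, ord$cost_high) - base
  hi <- pmax(ord$cost_low, ord$cost_high) - base
  ylim <- range(c(lo, hi, 0))
  graphics::barplot(rbind(lo, hi), beside = TRUE, horiz = TRUE,
                    names.arg = ord$parameter,
                    xlab = "expected cost minus base case (EUR)",
                    xlim = ylim, ...)
  graphics::abline(v = 0, lty = 2)
  invisible(ord)
}
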