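#' Base-case expected value of the diagnostic strategy
#'
#' Probability-weights the per-branch expected costs and QALYs by the
#' decision-tree branch probabilities and computes the net monetary
#' benefit (NMB = WTP x QALYs - cost) at the given willingness-to-pay
#' threshold.
#'
#' @param branch_results A `branch_results` data frame
#'   ([evaluate_branches()] or [branch_values()]).
#' @param branch_probs A [branch_probabilities()] object (must sum to 1).
#' @param wtp Willingness to pay per QALY (currency units).
#' @return An object of class `base_case`: a list with `expected_cost`,
#'   `expected_qalys`, `nmb` and `wtp`.
#' @examples
#' base_case(mrm_reference_results(), branch_probabilities(0.07, 1, 0.97))
#' @export
base_case <- function(branch_results, branch_probs, wtp = 100000) {
  stopifnot(inherits(branch_results, "branch_results"))
  pr <- unclass(branch_probs)
  if (!all(c("TP", "FN", "TN", "FP") %in% names(pr))) {
    stop("branch_probs must have entries TP, FN, TN, FP", call. = FALSE)
  }
  if (abs(sum(pr) - 1) > 1e-9) {
    stop(sprintf("branch probabilities sum to %.12f, not 1", sum(pr)),
         call. = FALSE)
  }
  check_scalar(wtp, "wtp", 0, Inf)
  w <- pr[branch_results$branch]
  cost <- sum(w * branch_results$expected_cost)
  qalys <- sum(w * branch_results$expected_qalys)
  structure(list(expected_cost = cost, expected_qalys = qalys,
                 nmb = wtp * qalys - cost, wtp = wtp),
            class = "base_case")
}

#' @export
print.base_case <- function(x, digits = 2, ...) {
  cat(sprintf(paste0("Base case: expected cost %s EUR, ",
                     "expected outcome %s QALYs\n"),
              formatC(x$expected_cost, format = "f", digits = digits),
              formatC(x$expected_qalys, format = "f", digits = digits)))
  cat(sprintf("Net monetary benefit at WTP %s EUR/QALY: %s EUR\n",
              format(x$wtp, big.mark = ","),
              formatC(x$nmb, format = "f", digits = digits)))
  invisible(x)
}

#' QALY difference between two branches
#'
#' Expected QALYs of branch `a` minus branch `b`; e.g. TP versus FN
#' quantifies the outcome gain of a timely over a delayed diagnosis.
#'
#' @param branch_results A `branch_results` data frame.
#' @param a,b Branch labels.
#' @return Numeric QALY difference (full precision; round for reporting).
#' @examples
#' qaly_gain(mrm_reference_results(), "TP", "FN")
#' @export
qaly_gain <- function(branch_results, a, b) {
  stopifnot(inherits(branch_results, "branch_results"))
  ia <- match(a, branch_results$branch)
  ib <- match(b, branch_results$branch)
  if (is.na(ia) || is.na(ib)) {
    stop("unknown branch label", call. = FALSE)
  }
  branch_results$expected_qalys[ia] - branch_results$expected_qalys[ib]
}

# legal domains for one-way variation
dsa_domain <- function(name) {
  probs <- c("prevalence", "sensitivity_mrm", "specificity_mrm",
             "biopsy_sensitivity", "biopsy_specificity",
             "utility_no_tumor", "utility_tumor", "qaly_loss_biopsy",
             "p_death_tumor", "p_death_background", "p_recurrence",
             "p_treatment_success")
  if (name %in% probs) c(0, 1) else c(0, Inf)
}

#' One-way deterministic sensitivity analysis
#'
#' Re-evaluates the strategy's expected cost and QALYs while varying one
#' input parameter at a time over a range (all others at base case), on an
#' evenly spaced grid including both endpoints. Two modes are available:
#' `"branch-values"` keeps the per-branch results fixed (by default the
#' published reference values) and varies only the decision-tree
#' probabilities — the mode in which the published sensitivity-analysis
#' claims are stated — while `"full-model"` rebuilds and re-runs the
#' branch Markov models at every grid point, which is required when
#' varying cost, utility or transition parameters.
#'
#' @param params Base-case [mrm_params()].
#' @param ranges Named list of `c(low, high)` ranges; the default varies
#'   prevalence over 0-20\% and MRM sensitivity and specificity over
#'   70-100\%, the ranges of the published analysis.
#' @param n_points Grid points per parameter (default 21, endpoints
#'   included; responses linear in each tree probability attain their
#'   extremes at the endpoints).
#' @param mode `"branch-values"` or `"full-model"`.
#' @param branch_results Fixed per-branch values for `"branch-values"`
#'   mode (default [mrm_reference_results()]).
#' @param conventions [mrm_conventions()] for `"full-model"` mode.
#' @return An object of class `dsa_result`: a data frame with one row per
#'   parameter (`parameter`, `low`, `high`, cost/QALYs at each endpoint,
#'   grid extremes, and the cost and QALY swings), with the full
#'   evaluation grid in attribute `"grid"`.
#' @examples
#' dsa <- one_way_dsa(mrm_params())
#' summary(dsa)
#' @export
one_way_dsa <- function(params = mrm_params(),
                        ranges = list(prevalence = c(0, 0.20),
                                      sensitivity_mrm = c(0.70, 1.00),
                                      specificity_mrm = c(0.70, 1.00)),
                        n_points = 21,
                        mode = c("branch-values", "full-model"),
                        branch_results = mrm_reference_results(),
                        conventions = mrm_conventions()) {
  mode <- match.arg(mode)
  stopifnot(inherits(params, "mrm_params"))
  if (length(ranges) == 0 || is.null(names(ranges))) {
    stop("ranges must be a non-empty named list", call. = FALSE)
  }
  tree_pars <- c("prevalence", "sensitivity_mrm", "specificity_mrm")
  for (nm in names(ranges)) {
    if (!nm %in% names(params) || !is.numeric(params[[nm]])) {
      stop("unknown or non-numeric parameter in ranges: ", nm,
           call. = FALSE)
    }
    r <- ranges[[nm]]
    dom <- dsa_domain(nm)
    if (length(r) != 2 || r[1] > r[2] || r[1] < dom[1] || r[2] > dom[2]) {
      stop(sprintf("range for '%s' outside its legal domain [%s, %s]",
                   nm, format(dom[1]), format(dom[2])), call. = FALSE)
    }
    if (mode == "branch-values" && !nm %in% tree_pars) {
      stop("parameter '", nm, "' requires mode = \"full-model\" ",
           "(branch values are held fixed in branch-values mode)",
           call. = FALSE)
    }
  }

  eval_at <- function(nm, value) {
    p <- params
    p[[nm]] <- value
    validate_mrm_params(p)
    br <- if (mode == "full-model") {
      evaluate_branches(p, conventions)
    } else branch_results
    probs <- branch_probabilities(p$prevalence, p$sensitivity_mrm,
                                  p$specificity_mrm)
    bc <- base_case(br, probs, p$wtp)
    c(cost = bc$expected_cost, qalys = bc$expected_qalys)
  }

  grid_rows <- list()
  summ <- list()
  for (nm in names(ranges)) {
    r <- ranges[[nm]]
    vals <- if (r[1] == r[2]) r[1] else seq(r[1], r[2], length.out = n_points)
    res <- vapply(vals, function(v) eval_at(nm, v), numeric(2))
    grid_rows[[nm]] <- data.frame(parameter = nm, value = vals,
                                  expected_cost = res["cost", ],
                                  expected_qalys = res["qalys", ])
    costs <- res["cost", ]; qalys <- res["qalys", ]
    summ[[nm]] <- data.frame(
      parameter = nm, low = r[1], high = r[2],
      cost_low = costs[1], cost_high = costs[length(costs)],
      qaly_low = qalys[1], qaly_high = qalys[length(qalys)],
      cost_min = min(costs), cost_max = max(costs),
      qaly_min = min(qalys), qaly_max = max(qalys),
      cost_swing = abs(costs[length(costs)] - costs[1]),
      qaly_swing = abs(qalys[length(qalys)] - qalys[1])
    )
  }
  out <- do.call(rbind, c(summ, list(make.row.names = FALSE)))
  attr(out, "grid") <- do.call(rbind,
                               c(grid_rows, list(make.row.names = FALSE)))
  attr(out, "mode") <- mode
  class(out) <- c("dsa_result", "data.frame")
  out
}

#' Order a sensitivity analysis for a tornado diagram
#'
#' Sorts the per-parameter rows of a [one_way_dsa()] result by descending
#' cost swing (|cost at high endpoint - cost at low endpoint|); ties keep
#' their input order (stable sort).
#'
#' @param dsa A `dsa_result`.
#' @return The reordered `dsa_result`.
#' @export
tornado_order <- function(dsa) {
  stopifnot(inherits(dsa, "dsa_result"))
  ord <- order(-dsa$cost_swing)  # base order() is stable
  out <- dsa[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "grid") <- attr(dsa, "grid")
  attr(out, "mode") <- attr(dsa, "mode")
  class(out) <- class(dsa)
  out
}

#' @export
print.dsa_result <- function(x, digits = 2, ...) {
  cat("One-way deterministic sensitivity analysis (",
      attr(x, "mode"), " mode)\n", sep = "")
  y <- as.data.frame(x)
  num <- vapply(y, is.numeric, logical(1))
  y[num] <- lapply(y[num], round, digits)
  print.data.frame(y, row.names = FALSE)
  invisible(x)
}

#' @export
summary.dsa_result <- function(object, ...) {
  g <- attr(object, "grid")
  structure(list(
    cost_range = range(g$expected_cost),
    qaly_range = range(g$expected_qalys),
    n_parameters = nrow(object),
    mode = attr(object, "mode")
  ), class = "summary.dsa_result")
}

#' @export
print.summary.dsa_result <- function(x, digits = 2, ...) {
  cat(sprintf("Across all one-way variations (%s mode, %d parameters):\n",
              x$mode, x$n_parameters))
  cat(sprintf("  expected cost  %s to %s EUR\n",
              formatC(x$cost_range[1], format = "f", digits = digits),
              formatC(x$cost_range[2], format = "f", digits = digits)))
  cat(sprintf("  expected QALYs %s to %s\n",
              formatC(x$qaly_range[1], format = "f", digits = digits),
              formatC(x$qaly_range[2], format = "f", digits = digits)))
  invisible(x)
}
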