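#' Patient-level simulation of a Markov specification
#'
#' Simulates `n` independent patient trajectories through a
#' [markov_spec()], drawing yearly transitions from the same matrices and
#' accruing discounted costs and QALYs under the same conventions as the
#' cohort engine [run_cohort()]. The sample means are therefore unbiased
#' Monte-Carlo estimates of the cohort expectations, which makes this
#' function the stochastic oracle for the deterministic engine.
#'
#' @inheritParams run_cohort
#' @param n Number of simulated patients.
#' @param seed Optional seed (caller's RNG state restored).
#' @param keep_states Return the n x (n_cycles + 1) state-label matrix of
#'   trajectories (memory grows with `n`; off by default).
#' @return A list with numeric vectors `cost` and `qalys` (length `n`)
#'   and, if requested, a character matrix `states`.
#' @export
sim_markov <- function(spec, start_state, n_cycles,
                       discount = discount_spec(), n,
                       upfront_cost = 0, upfront_utility = 0,
                       half_cycle_correction = FALSE, seed = NULL,
                       keep_states = FALSE) {
  stopifnot(inherits(spec, "markov_spec"), inherits(discount, "discount_spec"))
  if (!is.numeric(n) || n < 1 || n != round(n)) {
    stop("n must be a positive integer", call. = FALSE)
  }
  k0 <- match(start_state, spec$states)
  if (is.na(k0)) stop("unknown start state '", start_state, "'", call. = FALSE)
  ns <- length(spec$states)

  with_seed(seed, {
    state <- rep.int(k0, n)
    cost <- rep.int(upfront_cost, n)
    qaly <- rep.int(upfront_utility, n)
    states_mat <- if (keep_states) {
      m <- matrix(NA_character_, n, n_cycles + 1)
      m[, 1] <- spec$states[k0]
      m
    }
    for (t in seq_len(n_cycles) - 1L) {
      P <- check_transition_matrix(
        spec$transitions(t, spec$start_age + t), spec, t)
      cumP <- t(apply(P, 1, cumsum))
      u <- stats::runif(n)
      nxt <- rowSums(u > cumP[state, , drop = FALSE]) + 1L
      df <- discount_factor(discount$rate, t, discount$convention)
      sc <- spec$state_costs(t)
      util <- spec$state_utilities
      if (half_cycle_correction) {
        cost <- cost + df * ((sc[state] + sc[nxt]) / 2 +
                               spec$transition_costs[cbind(state, nxt)])
        qaly <- qaly + df * (util[state] + util[nxt]) / 2
      } else {
        cost <- cost + df * (sc[state] +
                               spec$transition_costs[cbind(state, nxt)])
        qaly <- qaly + df * util[state]
      }
      state <- nxt
      if (keep_states) states_mat[, t + 2] <- spec$states[state]
    }
    out <- list(cost = cost, qalys = qaly)
    if (keep_states) out$states <- states_mat
    out
  })
}

mean_se <- function(x) {
  n <- length(x)
  c(mean = mean(x), se = if (n >= 2) stats::sd(x) / sqrt(n) else NA_real_)
}

#' Microsimulation of the full screening strategy
#'
#' Draws each patient's decision-tree branch (TP/FN/TN/FP) from the
#' branch probabilities implied by prevalence, sensitivity and
#' specificity, then simulates her yearly health-state trajectory through
#' the corresponding branch model. Fully reproducible under a fixed seed:
#' one pseudo-random stream drives the run, with patients processed in a
#' fixed order.
#'
#' @param params An [mrm_params()] object.
#' @param conventions An [mrm_conventions()] object.
#' @param n Number of simulated patients.
#' @param seed Integer seed.
#' @param trajectories Also return per-patient, per-cycle trajectory rows
#'   (capped at `max_trajectories` patients to keep outputs desk-scale).
#' @param max_trajectories Cap on exported trajectory patients.
#' @return An object of class `microsim_summary`: a data frame with one
#'   row per branch plus an `overall` row, columns `branch`, `n`,
#'   `mean_cost`, `se_cost`, `mean_qalys`, `se_qalys`. If requested, a
#'   data frame of trajectory rows (`patient_id`, `cycle`, `state`,
#'   `discounted_cost`, `discounted_qaly`) is attached as attribute
#'   `"trajectories"`.
#' @examples
#' simulate_cohort(mrm_params(), n = 500, seed = 7)
#' @export
simulate_cohort <- function(params = mrm_params(),
                            conventions = mrm_conventions(),
                            n, seed = 1, trajectories = FALSE,
                            max_trajectories = 10000) {
  stopifnot(inherits(params, "mrm_params"),
            inherits(conventions, "mrm_conventions"))
  if (!is.numeric(n) || n < 1 || n != round(n)) {
    stop("n must be a positive integer", call. = FALSE)
  }
  probs <- branch_probabilities(params$prevalence, params$sensitivity_mrm,
                                params$specificity_mrm)
  branches <- c("TP", "FN", "TN", "FP")
  with_seed(seed, {
    cs <- cumsum(probs)
    cs[length(cs)] <- 1  # guard against rounding in the final bin
    assign_branch <- branches[
      findInterval(stats::runif(n), cs, left.open = TRUE) + 1L]
    per_branch <- list()
    traj <- list()
    all_cost <- numeric(n)
    all_qaly <- numeric(n)
    for (b in branches) {
      idx <- which(assign_branch == b)
      if (length(idx) == 0) next
      bb <- build_branch(b, params, conventions)
      sim <- sim_markov(bb$spec, bb$start_state, bb$n_cycles, bb$discount,
                        n = length(idx), upfront_cost = bb$upfront_cost,
                        upfront_utility = bb$upfront_utility,
                        half_cycle_correction =
                          conventions$half_cycle_correction,
                        keep_states = trajectories)
      all_cost[idx] <- sim$cost
      all_qaly[idx] <- sim$qalys
      per_branch[[b]] <- idx
      if (trajectories) {
        nkeep <- min(length(idx), max_trajectories)
        if (nkeep > 0) {
          st <- sim$states[seq_len(nkeep), , drop = FALSE]
          traj[[b]] <- data.frame(
            patient_id = rep(idx[seq_len(nkeep)], each = ncol(st)),
            branch = b,
            cycle = rep(0:(ncol(st) - 1), times = nkeep),
            state = as.vector(t(st)),
            discounted_cost = rep(sim$cost[seq_len(nkeep)],
                                  each = ncol(st)),
            discounted_qaly = rep(sim$qalys[seq_len(nkeep)],
                                  each = ncol(st))
          )
        }
      }
    }
    rows <- lapply(branches, function(b) {
      idx <- per_branch[[b]]
      if (is.null(idx)) {
        data.frame(branch = b, n = 0L, mean_cost = NA_real_,
                   se_cost = NA_real_, mean_qalys = NA_real_,
                   se_qalys = NA_real_)
      } else {
        mc <- mean_se(all_cost[idx]); mq <- mean_se(all_qaly[idx])
        data.frame(branch = b, n = length(idx), mean_cost = mc[["mean"]],
                   se_cost = mc[["se"]], mean_qalys = mq[["mean"]],
                   se_qalys = mq[["se"]])
      }
    })
    mc <- mean_se(all_cost); mq <- mean_se(all_qaly)
    rows <- c(rows, list(data.frame(branch = "overall", n = n,
                                    mean_cost = mc[["mean"]],
                                    se_cost = mc[["se"]],
                                    mean_qalys = mq[["mean"]],
                                    se_qalys = mq[["se"]])))
    out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
    class(out) <- c("microsim_summary", "data.frame")
    if (trajectories) {
      attr(out, "trajectories") <-
        do.call(rbind, c(traj, list(make.row.names = FALSE)))
    }
    out
  })
}

#' @export
print.microsim_summary <- function(x, digits = 2, ...) {
  cat("Patient-level microsimulation summary:\n")
  y <- as.data.frame(x)
  num <- vapply(y, is.double, logical(1))
  y[num] <- lapply(y[num], round, digits)
  print.data.frame(y, row.names = FALSE)
  invisible(x)
}

#' Generate a synthetic diagnostic-study dataset
#'
#' Emulates the screening study underlying the model: draws each
#' patient's true disease status from the prevalence and her test result
#' from the test's sensitivity or specificity, returning the per-patient
#' table together with the resulting confusion counts. As `n` grows, the
#' performance metrics computed from the output converge to the
#' generating parameters.
#'
#' @param params An [mrm_params()] object (uses `prevalence`,
#'   `sensitivity_mrm`, `specificity_mrm`).
#' @param n Number of patients.
#' @param seed Integer seed.
#' @return A data frame with columns `patient_id`, `true_status`
#'   (`"diseased"`/`"healthy"`), `test_result` (`"positive"`/
#'   `"negative"`) and `outcome` (`"TP"`/`"FN"`/`"TN"`/`"FP"`), with the
#'   [confusion_counts()] attached as attribute `"counts"`.
#' @examples
#' d <- generate_study_dataset(mrm_params(), n = 1095, seed = 42)
#' compute_performance(attr(d, "counts"))
#' @export
generate_study_dataset <- function(params = mrm_params(), n, seed = 1) {
  stopifnot(inherits(params, "mrm_params"))
  if (!is.numeric(n) || n < 1 || n != round(n)) {
    stop("n must be a positive integer", call. = FALSE)
  }
  with_seed(seed, {
    diseased <- stats::runif(n) < params$prevalence
    positive <- logical(n)
    positive[diseased] <- stats::runif(sum(diseased)) <
      params$sensitivity_mrm
    positive[!diseased] <- stats::runif(sum(!diseased)) >=
      params$specificity_mrm
    outcome <- ifelse(diseased,
                      ifelse(positive, "TP", "FN"),
                      ifelse(positive, "FP", "TN"))
    out <- data.frame(
      patient_id = seq_len(n),
      true_status = ifelse(diseased, "diseased", "healthy"),
      test_result = ifelse(positive, "positive", "negative"),
      outcome = outcome
    )
    attr(out, "counts") <- confusion_counts(
      tp = sum(outcome == "TP"), fp = sum(outcome == "FP"),
      tn = sum(outcome == "TN"), fn = sum(outcome == "FN"))
    out
  })
}
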