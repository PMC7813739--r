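# Random 3-state Markov specifications (two transient states plus an
# absorbing "Dead") for property-style tests of the cohort engine.
# Uses the current RNG stream; callers fix the seed.
random_markov_spec <- function(max_cost = 5000) {
  states <- c("A", "B", "Dead")
  rand_row <- function() {
    w <- stats::rexp(3)
    w / sum(w)
  }
  P <- rbind(rand_row(), rand_row(), c(0, 0, 1))
  dimnames(P) <- list(states, states)
  tc <- matrix(stats::runif(9, 0, max_cost / 5), 3, 3)
  tc[, 3] <- 0  # dying is not billed
  tc[3, ] <- 0
  markov_spec(states, P,
              state_costs = c(stats::runif(2, 0, max_cost), 0),
              state_utilities = c(stats::runif(2), 0),
              transition_costs = tc)
}

# Published per-branch reference values and tree probabilities used by
# the worked examples.
reference_model <- function() {
  cea_model(mrm_params(), branch_results = mrm_reference_results())
}
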