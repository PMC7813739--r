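alive_dead_spec <- function(p_die = 0, cost_alive = 0) {
  markov_spec(c("Alive", "Dead"),
              matrix(c(1 - p_die, p_die, 0, 1), 2, byrow = TRUE),
              state_costs = c(cost_alive, 0),
              state_utilities = c(1, 0))
}

test_that("discount factors follow the stated conventions", {
  expect_identical(discount_factor(0.03, 0, "begin"), 1)
  expect_identical(discount_factor(0, 7, "end"), 1)
  expect_equal(discount_factor(0.03, 2, "begin"), 0.942596,
               tolerance = 1e-6)
  expect_equal(discount_factor(0.03, 0, "end"), 1 / 1.03,
               tolerance = 1e-12)
  expect_equal(discount_factor(0.03, 1, "half-cycle"), 1.03^-1.5,
               tolerance = 1e-12)
  expect_error(discount_factor(-0.01, 1), "non-negative")
  expect_error(discount_factor(0.03, -1), ">= 0")
})

test_that("a full-health cohort accrues the discounted horizon sum", {
  sp <- alive_dead_spec()
  out <- run_cohort(sp, "Alive", 5, discount_spec(0.03, "begin"))
  expect_equal(out$expected_qalys, 4.717098, tolerance = 1e-6)
  expect_equal(out$expected_cost, 0)

  out0 <- run_cohort(sp, "Alive", 5, discount_spec(0))
  expect_equal(out0$expected_qalys, 5, tolerance = 1e-12)

  # upfront quantities are added undiscounted
  out_up <- run_cohort(sp, "Alive", 5, discount_spec(0.03),
                       upfront_cost = 718.5, upfront_utility = -0.05)
  expect_equal(out_up$expected_cost, 718.5)
  expect_equal(out_up$expected_qalys, 4.717098 - 0.05, tolerance = 1e-6)
})

test_that("invalid transition matrices are rejected with the row named", {
  bad_rowsum <- markov_spec(c("A", "Dead"),
                            matrix(c(0.5, 0.4, 0, 1), 2, byrow = TRUE),
                            c(0, 0), c(1, 0))
  expect_error(run_cohort(bad_rowsum, "A", 3, discount_spec()),
               "row 'A' sums")
  bad_neg <- markov_spec(c("A", "Dead"),
                         matrix(c(1.2, -0.2, 0, 1), 2, byrow = TRUE),
                         c(0, 0), c(1, 0))
  expect_error(run_cohort(bad_neg, "A", 3, discount_spec()),
               "outside \\[0, 1\\]")
  not_absorbing <- markov_spec(c("A", "Dead"),
                               matrix(c(1, 0, 0.3, 0.7), 2, byrow = TRUE),
                               c(0, 0), c(1, 0))
  expect_error(run_cohort(not_absorbing, "A", 3, discount_spec()),
               "absorbing")
  expect_error(run_cohort(alive_dead_spec(), "Elsewhere", 3,
                          discount_spec()), "unknown start state")
  expect_error(markov_spec(c("A", "Dead"),
                           diag(2), c(0, 0), c(1, 0.5)),
               "utility 0")
})

test_that("occupancy is conserved and death absorbs on random specs", {
  set.seed(202)
  for (i in 1:25) {
    sp <- random_markov_spec()
    out <- run_cohort(sp, "A", 8, discount_spec(runif(1, 0, 0.1)))
    occ <- as.matrix(out$trace[, sp$states])
    expect_true(all(abs(rowSums(occ) - 1) < 1e-9))
    expect_true(all(diff(occ[, "Dead"]) >= -1e-12))
    expect_true(all(occ >= -1e-12))
  }
})

test_that("expected cost is linear in the state costs", {
  set.seed(7)
  sp <- random_markov_spec()
  P <- sp$transitions(0, NA)
  base_costs <- sp$state_costs(0)
  mk <- function(k) markov_spec(sp$states, P, state_costs = k * base_costs,
                                state_utilities = sp$state_utilities)
  up <- 123.4
  r1 <- run_cohort(mk(1), "A", 6, discount_spec(0.03), upfront_cost = up)
  r2 <- run_cohort(mk(2), "A", 6, discount_spec(0.03), upfront_cost = up)
  expect_equal(r2$expected_cost - up, 2 * (r1$expected_cost - up),
               tolerance = 1e-9)
  expect_equal(r1$expected_qalys, r2$expected_qalys)
})

test_that("discounting more steeply never increases accruals", {
  set.seed(31)
  for (i in 1:10) {
    sp <- random_markov_spec()
    rates <- c(0, 0.03, 0.08, 0.2)
    res <- lapply(rates, function(r)
      run_cohort(sp, "A", 6, discount_spec(r)))
    costs <- vapply(res, `[[`, numeric(1), "expected_cost")
    qalys <- vapply(res, `[[`, numeric(1), "expected_qalys")
    expect_true(all(diff(costs) <= 1e-9))
    expect_true(all(diff(qalys) <= 1e-9))
  }
})

test_that("cohort expectations agree with microsimulation means", {
  set.seed(404)
  for (i in 1:3) {
    sp <- random_markov_spec()
    cohort <- run_cohort(sp, "A", 5, discount_spec(0.03),
                         upfront_cost = 100)
    sim <- sim_markov(sp, "A", 5, discount_spec(0.03), n = 20000,
                      upfront_cost = 100, seed = 1000 + i)
    se_c <- sd(sim$cost) / sqrt(length(sim$cost))
    se_q <- sd(sim$qalys) / sqrt(length(sim$qalys))
    expect_lt(abs(mean(sim$cost) - cohort$expected_cost), 3 * se_c)
    expect_lt(abs(mean(sim$qalys) - cohort$expected_qalys), 3 * se_q)
  }
})

test_that("half-cycle correction averages start and end occupancy", {
  sp <- alive_dead_spec(p_die = 0.5)
  plain <- run_cohort(sp, "Alive", 1, discount_spec(0))
  hcc <- run_cohort(sp, "Alive", 1, discount_spec(0),
                    half_cycle_correction = TRUE)
  expect_equal(plain$expected_qalys, 1)    # full start occupancy
  expect_equal(hcc$expected_qalys, 0.75)   # mean of 1 and 0.5
})
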