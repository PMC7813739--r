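test_that("base case reproduces the published expectation", {
  m <- reference_model()
  bc <- m$base_case
  # 0.07 x 7606.80 + 0.9021 x 1193.16 + 0.0279 x 1493.16
  expect_equal(bc$expected_cost, 1650.4848, tolerance = 1e-9)
  expect_equal(round(bc$expected_cost, 2), 1650.48)
  expect_equal(bc$expected_qalys, 4.693005, tolerance = 1e-9)
  expect_equal(round(bc$expected_qalys, 2), 4.69)
  expect_equal(bc$nmb, 100000 * 4.693005 - 1650.4848, tolerance = 1e-6)
})

test_that("base case degenerate inputs behave", {
  free <- branch_values(cost = c(TP = 0, FN = 0, TN = 0, FP = 0),
                        qalys = c(TP = 4, FN = 3, TN = 5, FP = 4.5))
  probs <- branch_probabilities(0.07, 1, 0.97)
  bc <- base_case(free, probs, wtp = 50000)
  expect_equal(bc$expected_cost, 0)
  expect_equal(bc$nmb, 50000 * bc$expected_qalys)

  # certain TP: the base case is the TP branch
  all_tp <- base_case(mrm_reference_results(),
                      branch_probabilities(1, 1, 0.5))
  expect_equal(all_tp$expected_cost, 7606.80)
  expect_equal(all_tp$expected_qalys, 4.62)

  broken <- structure(c(TP = 0.5, FN = 0.1, TN = 0.2, FP = 0.1),
                      class = "branch_probabilities")
  expect_error(base_case(mrm_reference_results(), broken), "sum")
})

test_that("base case is linear in the branch costs", {
  probs <- branch_probabilities(0.07, 1, 0.97)
  ref <- mrm_reference_results()
  for (k in c(0.5, 3)) {
    scaled <- branch_values(
      cost = setNames(k * ref$expected_cost, ref$branch),
      qalys = setNames(ref$expected_qalys, ref$branch))
    expect_equal(base_case(scaled, probs)$expected_cost,
                 k * base_case(ref, probs)$expected_cost,
                 tolerance = 1e-9)
  }
})

test_that("QALY gains between branches match the published contrasts", {
  ref <- mrm_reference_results()
  expect_equal(round(qaly_gain(ref, "TP", "FN"), 2), 0.67)
  expect_equal(round(qaly_gain(ref, "TN", "FP"), 2), 0.05)
  expect_equal(qaly_gain(ref, "FN", "FN"), 0)
  expect_error(qaly_gain(ref, "TP", "ZZ"), "unknown branch")
})

test_that("one-way DSA over the published ranges matches its claims", {
  dsa <- one_way_dsa(mrm_params())  # branch-values mode, reference values
  g <- attr(dsa, "grid")
  expect_equal(round(max(g$expected_cost), 2), 2483.09)
  expect_lte(max(g$expected_cost), 2500)
  expect_equal(sort(unique(round(range(g$expected_qalys), 2))),
               c(4.68, 4.70))

  # linear responses peak at the range endpoints
  expect_equal(max(g$expected_cost), max(dsa$cost_max), tolerance = 1e-12)
  prev <- g[g$parameter == "prevalence", ]
  expect_true(all(diff(prev$expected_cost) > 0))   # monotone in prevalence
  sens <- g[g$parameter == "sensitivity_mrm", ]
  spec <- g[g$parameter == "specificity_mrm", ]
  expect_true(all(diff(sens$expected_qalys) > 0))
  expect_true(all(diff(spec$expected_qalys) > 0))
})

test_that("DSA validates ranges and modes", {
  expect_error(one_way_dsa(mrm_params(),
                           ranges = list(prevalence = c(-0.1, 0.2))),
               "legal domain")
  expect_error(one_way_dsa(mrm_params(),
                           ranges = list(nonsense = c(0, 1))),
               "unknown")
  expect_error(one_way_dsa(mrm_params(),
                           ranges = list(cost_mrm = c(200, 600))),
               "full-model")
  # degenerate range: a single point equal to direct evaluation
  one <- one_way_dsa(mrm_params(), ranges = list(prevalence = c(0.07, 0.07)))
  expect_equal(one$cost_low, one$cost_high)
  expect_equal(one$cost_low,
               reference_model()$base_case$expected_cost, tolerance = 1e-9)
})

test_that("full-model DSA re-evaluates the Markov models", {
  dsa <- one_way_dsa(mrm_params(), ranges = list(cost_mrm = c(209.25,
                                                              627.75)),
                     n_points = 3, mode = "full-model")
  # every branch pays the examination at least once, so the swing must
  # exceed the fee change itself
  expect_gt(dsa$cost_swing, 627.75 - 209.25)
  expect_gt(dsa$cost_high, dsa$cost_low)
})

test_that("tornado ordering is by cost swing and stable under ties", {
  # prevalence over its published range out-swings the MRM fee +/-50%
  prev_dsa <- one_way_dsa(mrm_params())
  fee_dsa <- one_way_dsa(mrm_params(),
                         ranges = list(cost_mrm = c(209.25, 627.75)),
                         n_points = 5, mode = "full-model")
  both <- rbind(fee_dsa[, names(fee_dsa)],
                prev_dsa[prev_dsa$parameter == "prevalence", ])
  class(both) <- class(prev_dsa)
  attr(both, "mode") <- "mixed"
  ord <- tornado_order(both)
  expect_identical(ord$parameter[1], "prevalence")

  single <- one_way_dsa(mrm_params(),
                        ranges = list(prevalence = c(0, 0.2)))
  expect_identical(tornado_order(single)$parameter, "prevalence")

  flat <- one_way_dsa(mrm_params(),
                      ranges = list(prevalence = c(0.05, 0.05),
                                    sensitivity_mrm = c(1, 1),
                                    specificity_mrm = c(0.97, 0.97)))
  expect_identical(tornado_order(flat)$parameter,
                   c("prevalence", "sensitivity_mrm", "specificity_mrm"))
})
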