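all_conventions <- function() {
  g <- expand.grid(dc = c("begin", "end", "half-cycle"),
                   hcc = c(FALSE, TRUE), rn = c(FALSE, TRUE),
                   rtc = c("early", "delayed", "none"),
                   sv = c("biennial", "annual", "none"),
                   stringsAsFactors = FALSE)
  lapply(seq_len(nrow(g)), function(i)
    mrm_conventions(g$dc[i], g$hcc[i], g$rn[i], g$rtc[i], g$sv[i]))
}

test_that("branch construction follows the decision tree", {
  p <- mrm_params()
  tp <- build_branch("TP", p)
  fn <- build_branch("FN", p)
  tn <- build_branch("TN", p)
  fp <- build_branch("FP", p)

  expect_equal(tp$upfront_cost, 418.50 + 300 + 4000)
  expect_equal(fn$upfront_cost, 418.50)
  expect_equal(tn$upfront_cost, 418.50)
  expect_equal(fp$upfront_cost, tn$upfront_cost + 300)
  expect_equal(fp$upfront_utility, tn$upfront_utility - 0.05)

  expect_identical(fn$start_state, "Cancer")
  expect_identical(tp$start_state, "NoCancer")
  expect_identical(tn$start_state, "NoCancer")

  # cancer-state row: success + stay + death = 1 with the base rates
  P <- fn$spec$transitions(0, 32)
  expect_equal(P["Cancer", "NoCancer"], 0.60)
  expect_equal(P["Cancer", "Dead"], 0.0544)
  expect_equal(sum(P["Cancer", ]), 1, tolerance = 1e-12)
  expect_equal(P["Cancer", "Cancer"], 1 - 0.60 - 0.0544,
               tolerance = 1e-12)

  # delayed surgery is charged when the missed cancer is finally treated
  expect_equal(fn$spec$transition_costs["Cancer", "NoCancer"], 10000)
  expect_equal(tp$spec$transition_costs["Cancer", "NoCancer"], 4000)

  expect_equal(tp$n_cycles, 5)
  expect_error(build_branch("XX", p), "unknown branch")
})

test_that("FP differs from TN by exactly the biopsy under every convention", {
  p <- mrm_params()
  for (cv in all_conventions()) {
    br <- evaluate_branches(p, cv)
    dc <- br$expected_cost[br$branch == "FP"] -
      br$expected_cost[br$branch == "TN"]
    dq <- br$expected_qalys[br$branch == "FP"] -
      br$expected_qalys[br$branch == "TN"]
    expect_equal(dc, p$cost_biopsy, tolerance = 1e-9)
    expect_equal(dq, -p$qaly_loss_biopsy, tolerance = 1e-9)
  }
})

test_that("a timely diagnosis dominates a delayed one", {
  set.seed(88)
  for (i in 1:10) {
    early <- runif(1, 1000, 8000)
    p <- mrm_params(cost_early_surgery = early,
                    cost_delayed_surgery = early + runif(1, 0, 8000),
                    p_death_tumor = runif(1, 0.01, 0.3),
                    p_treatment_success = runif(1, 0.2, 0.6),
                    yearly_cost_tumor = runif(1, 2000, 20000))
    br <- evaluate_branches(p)
    expect_lt(br$expected_cost[br$branch == "TP"],
              br$expected_cost[br$branch == "FN"])
    expect_gt(br$expected_qalys[br$branch == "TP"],
              br$expected_qalys[br$branch == "FN"])
  }
})

test_that("no branch exceeds the discounted full-health ceiling", {
  br <- evaluate_branches(mrm_params())
  expect_true(all(br$expected_qalys <= 4.717098 + 1e-9))
  expect_true(all(br$expected_qalys >= 0))
  expect_true(all(br$expected_cost >= 0))
})

test_that("tumor care costs move FN but not TN when recurrence is off", {
  lo <- evaluate_branches(mrm_params(yearly_cost_tumor = 5000))
  hi <- evaluate_branches(mrm_params(yearly_cost_tumor = 20000))
  expect_gt(hi$expected_cost[hi$branch == "FN"],
            lo$expected_cost[lo$branch == "FN"])
  expect_equal(hi$expected_cost[hi$branch == "TN"],
               lo$expected_cost[lo$branch == "TN"], tolerance = 1e-9)
})

test_that("degenerate parameters collapse to the discounted horizon sum", {
  p <- mrm_params(cost_mrm = 0, cost_biopsy = 0, cost_early_surgery = 0,
                  cost_delayed_surgery = 0, yearly_cost_tumor = 0,
                  yearly_cost_no_tumor = 0, utility_tumor = 1,
                  qaly_loss_biopsy = 0, p_death_tumor = 0,
                  p_death_background = 0)
  br <- evaluate_branches(p)
  expect_true(all(abs(br$expected_cost) < 1e-9))
  expect_true(all(abs(br$expected_qalys - 4.717098) < 1e-5))
})

test_that("age-dependent background mortality is looked up and clamped", {
  tbl <- data.frame(age = 32:36,
                    annual_death_probability = seq(0.001, 0.005, 0.001))
  p <- mrm_params(p_death_background = tbl)
  tn <- build_branch("TN", p)
  expect_equal(tn$spec$transitions(0, 32)["NoCancer", "Dead"], 0.001)
  expect_equal(tn$spec$transitions(0, 35)["NoCancer", "Dead"], 0.004)
  # beyond the table: clamped to the last row
  expect_equal(tn$spec$transitions(0, 60)["NoCancer", "Dead"], 0.005)
  csv <- system.file("extdata", "background_mortality_synthetic.csv",
                     package = "mrmcea")
  expect_equal(read_mortality_csv(csv)$annual_death_probability,
               rep(0.0007, 5))
})
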