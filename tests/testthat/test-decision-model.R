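test_that("QALD computation weights state days by utilities minus AE disutility", {
  params <- rti_trial_parameters()
  dap <- compute_qald(params$strategies$DAP$utility)
  expect_equal(round(dap, 2), 27.94)
  expect_identical(compute_qald(perfect_utility()), 30)
  hand <- list(u_zero = 1.0, u_severe = 0.5, u_moderate = 0.8,
               d_zero = 10, d_severe = 10, d_moderate = 10,
               ae_disutility = 0.12, ae_days = 1)
  expect_equal(compute_qald(hand), 22.88)
})

test_that("QALD is monotone in utilities and adverse-effect days", {
  base <- list(u_zero = 0.95, u_severe = 0.7, u_moderate = 0.85,
               d_zero = 20, d_severe = 3, d_moderate = 7,
               ae_disutility = 0.12, ae_days = 0.1)
  q0 <- compute_qald(base)
  for (f in c("u_zero", "u_severe", "u_moderate")) {
    up <- base; up[[f]] <- base[[f]] + 0.01
    expect_gt(compute_qald(up), q0)
  }
  more_ae <- base; more_ae$ae_days <- 1
  expect_lt(compute_qald(more_ae), q0)
})

test_that("expected adverse-effect days scale with exposure, rate and duration", {
  expect_equal(adverse_event_days(1.00, 0.10, 2), 0.20)
  expect_equal(adverse_event_days(0, 0.10, 2), 0)
  expect_equal(adverse_event_days(0.2357, 0.10, 2), 0.04714)
  expect_error(adverse_event_days(1.5, 0.1, 2))
})

test_that("bundle costing sums unit costs by societal category", {
  params <- rti_trial_parameters()
  empty <- pathway_cost(list(), params$costs)
  expect_identical(unlist(empty), c(healthcare = 0, nonhealthcare_direct = 0,
                                    indirect = 0, amr = 0, total = 0))
  b <- list(pc_visits = 1, antibiotic_courses = 1, visits_with_expenditure = 1,
            work_hours_lost = 2)
  cost <- pathway_cost(b, params$costs)
  expect_equal(cost$total, 50 + 5.20 + 0.20 + 16.50 + 2 * 15.85)  # 103.60
  expect_equal(cost$healthcare, 55.20)
  expect_equal(cost$nonhealthcare_direct, 16.50)
  expect_equal(cost$indirect, 31.70)
  expect_equal(cost$amr, 0.20)
  ed <- pathway_cost(list(ed_minor = 1), params$costs)
  expect_equal(ed$healthcare, 215)
  expect_error(pathway_cost(b, params$costs[-1]), "cost labels")
})

test_that("a two-pathway toy tree matches hand enumeration", {
  st <- toy_strategy(list(
    list(label = "cheap", probability = 0.7,
         bundle = list(extra_pc_visits = 1)),
    list(label = "dear", probability = 0.3,
         bundle = list(extra_pc_visits = 10))
  ))
  params <- toy_params(list(S = st), costs = toy_costs(
    pc_visit = 10, antibiotic = 0, non_antibiotic = 0, ed_minor = 0,
    ed_nonurgent = 0, doctor_time = 0, expenditure = 0, wage = 0, amr = 0
  ))
  res <- evaluate_strategies(params)
  expect_equal(res$cost_total, 0.7 * 10 + 0.3 * 100)  # 37.00
})

test_that("zero unit costs zero every cost while effects are unchanged", {
  params <- rti_trial_parameters()
  zero <- params
  for (nm in names(zero$costs)) zero$costs[[nm]]$base <- 0
  res <- evaluate_strategies(zero)
  expect_equal(res$cost_total, rep(0, 3))
  expect_equal(res$effect_qald, evaluate_strategies(params)$effect_qald)
})

test_that("cost breakdown sums to the total and effects stay in [0, 30]", {
  res <- evaluate_strategies(rti_trial_parameters())
  expect_equal(res$cost_total,
               res$cost_healthcare + res$cost_nonhealthcare_direct +
                 res$cost_indirect + res$cost_amr,
               tolerance = 1e-9)
  expect_true(all(res$effect_qald >= 0 & res$effect_qald <= 30))
})

test_that("tree evaluation equals brute-force terminal-branch enumeration", {
  params <- rti_trial_parameters()
  res <- evaluate_strategies(params)
  for (id in names(params$strategies)) {
    expect_equal(res$cost_total[res$strategy == id],
                 oracle_strategy_cost(params$strategies[[id]],
                                      params$settings, params$costs),
                 tolerance = 1e-9, label = paste("fixture arm", id))
  }
})

test_that("expected cost responds linearly to each unit cost", {
  params <- rti_trial_parameters()
  base <- evaluate_strategies(params)$cost_total
  for (nm in c("pc_visit", "hourly_wage", "amr_per_prescription")) {
    doubled <- params
    doubled$costs[[nm]]$base <- 2 * params$costs[[nm]]$base
    up <- evaluate_strategies(doubled)$cost_total
    halfway <- params
    halfway$costs[[nm]]$base <- 1.5 * params$costs[[nm]]$base
    mid <- evaluate_strategies(halfway)$cost_total
    expect_equal(mid, (base + up) / 2, tolerance = 1e-9, label = nm)
  }
})
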