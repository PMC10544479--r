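zero_dispersion <- function(params) {
  params$settings$psa_cost_cv <- 0
  params$settings$psa_vas_sd_points <- 0
  params$settings$psa_ae_n <- Inf
  params$settings$psa_dirichlet_n <- Inf
  params
}

test_that("tornado at the base value returns the base ICER bit-identically", {
  params <- rti_trial_parameters()
  torn <- run_tornado(params, fraction = 0)
  expect_identical(torn$low_icer, torn$base_icer)
  expect_identical(torn$high_icer, torn$base_icer)
})

test_that("tornado directions reflect which arm each cost loads on", {
  params <- rti_trial_parameters()
  torn <- run_tornado(params)
  expect_identical(attr(torn, "pair"), c("DAP", "NAP"))
  dir <- setNames(torn$direction, torn$parameter)
  # parental time lost to work weighs more on DAP, visits more on NAP
  expect_identical(unname(dir["hourly_wage"]), "increase")
  expect_identical(unname(dir["pc_visit"]), "decrease")
  # identical doctor-time exposure in both frontier arms: no ICER response
  dt <- torn[torn$parameter == "doctor_time", ]
  expect_equal(dt$low_icer, dt$base_icer)
  expect_equal(dt$high_icer, dt$base_icer)
  expect_true(all(diff(torn$impact_width) <= 1e-12))  # tornado ordering
  expect_equal(torn$cum_impact_share[nrow(torn)], 1)
})

test_that("toy two-strategy tornado bounds match closed-form ICER arithmetic", {
  mk <- function(visits_a, visits_b) {
    list(
      A = toy_strategy(list(list(label = "only", probability = 1,
                                 bundle = list(extra_pc_visits = visits_a))),
                       utility = list(u_zero = 1, u_severe = 1, u_moderate = 1,
                                      d_zero = 30, d_severe = 0, d_moderate = 0,
                                      ae_disutility = 0, ae_days = 0)),
      B = toy_strategy(list(list(label = "only", probability = 1,
                                 bundle = list(extra_pc_visits = visits_b))),
                       utility = list(u_zero = 0.9, u_severe = 1, u_moderate = 1,
                                      d_zero = 30, d_severe = 0, d_moderate = 0,
                                      ae_disutility = 0, ae_days = 0))
    )
  }
  costs <- toy_costs(pc_visit = 50, antibiotic = 0, non_antibiotic = 0,
                     ed_minor = 0, ed_nonurgent = 0, doctor_time = 0,
                     expenditure = 0, wage = 0, amr = 0)
  params <- toy_params(mk(3, 1), costs = costs)
  # ICER(A vs B) = (3 - 1) * pc_visit / (30 - 27) = 2v/3
  torn <- run_tornado(params, pair = c("A", "B"))
  row <- torn[torn$parameter == "pc_visit", ]
  expect_equal(row$base_icer, 2 * 50 / 3)
  expect_equal(row$low_icer, 2 * 42.5 / 3)
  expect_equal(row$high_icer, 2 * 57.5 / 3)
  expect_identical(row$direction, "increase")
})

test_that("zero-dispersion PSA draws reproduce the base parameter set", {
  params <- zero_dispersion(rti_trial_parameters())
  set.seed(11)
  drawn <- draw_psa_sample(params)
  expect_equal(drawn$costs, params$costs)
  for (id in names(params$strategies)) {
    expect_equal(drawn$strategies[[id]]$pathways$prob,
                 params$strategies[[id]]$pathways$prob)
    expect_equal(drawn$strategies[[id]]$utility,
                 params$strategies[[id]]$utility)
  }
  expect_equal(drawn$settings$ae_rate_given_antibiotic,
               params$settings$ae_rate_given_antibiotic)
})

test_that("PSA draws respect distribution support and stated moments", {
  params <- rti_trial_parameters()
  set.seed(33)
  ab <- replicate(5000, draw_psa_sample(params)$costs$antibiotic_medication$base)
  expect_true(all(ab >= 0))
  cv <- params$settings$psa_cost_cv
  se <- 5.20 * cv / sqrt(5000)
  expect_lt(abs(mean(ab) - 5.20), 3 * se)

  set.seed(34)
  u <- replicate(2000, draw_psa_sample(params)$strategies$DAP$utility$u_zero)
  expect_true(all(u >= 0 & u <= 1))
  p <- replicate(50, draw_psa_sample(params)$strategies$NAP$pathways$prob)
  expect_true(all(p >= 0))
  expect_equal(colSums(p), rep(1, 50), tolerance = 1e-12)
})

test_that("infeasible beta moment matching errors with the parameter name", {
  expect_error(abxcea:::rbeta_ms(1, 0.5, 0.6, "u_probe"), "u_probe")
})

test_that("PSA runs are reproducible and degenerate to the deterministic result", {
  params <- rti_trial_parameters()
  a <- run_psa(params, iterations = 25, seed = 7)
  b <- run_psa(params, iterations = 25, seed = 7)
  expect_identical(a, b)

  det <- evaluate_strategies(params)
  zd <- run_psa(zero_dispersion(params), iterations = 5, seed = 1)
  for (id in det$strategy) {
    expect_equal(unique(zd$cost[zd$strategy == id]),
                 det$cost_total[det$strategy == id], tolerance = 1e-12)
    expect_equal(unique(zd$effect[zd$strategy == id]),
                 det$effect_qald[det$strategy == id], tolerance = 1e-12)
  }
})

test_that("CE-plane quadrants tally incremental cost/effect signs", {
  mk_psa <- function(dc, de) {
    n <- length(dc)
    out <- tibble::tibble(
      iteration = rep(seq_len(n), 2),
      strategy = rep(c("X", "Y"), each = n),
      cost = c(100 + dc, rep(100, n)),
      effect = c(20 + de, rep(20, n))
    )
    class(out) <- c("psa_results", class(out))
    out
  }
  one <- ce_plane_summary(mk_psa(10, 1), c("X", "Y"), 82.2)
  expect_equal(unname(one$quadrants["I"]), 1)
  four <- ce_plane_summary(mk_psa(c(10, 10, -10, -10), c(1, -1, -1, 1)),
                           c("X", "Y"), 82.2)
  expect_equal(unname(four$quadrants), rep(0.25, 4))
  expect_equal(sum(four$quadrants), 1, tolerance = 1e-9)
  # huge WTP: acceptability approaches the share of iterations with dE > 0
  huge <- ce_plane_summary(mk_psa(c(10, 10, -10, -10), c(1, -1, -1, 1)),
                           c("X", "Y"), 1e9)
  expect_equal(huge$prop_acceptable, 0.5)
})

test_that("acceptability curves are proper probabilities at every WTP", {
  params <- rti_trial_parameters()
  psa <- run_psa(params, iterations = 200, seed = 5)
  grid <- seq(0, 164.4, length.out = 21)
  curve <- ceac(psa, grid)
  probs <- as.matrix(curve[, c("DAP", "IAP", "NAP")])
  expect_true(all(probs >= 0 & probs <= 1))
  expect_equal(unname(rowSums(probs)), rep(1, nrow(curve)), tolerance = 1e-9)
})

test_that("zero-dispersion acceptability is a step set by the deterministic NMB", {
  params <- zero_dispersion(rti_trial_parameters())
  psa <- run_psa(params, iterations = 3, seed = 2)
  curve <- ceac(psa, c(0, 82.2))
  expect_equal(curve$NAP[curve$wtp == 0], 1)    # cheapest wins at WTP 0
  expect_equal(curve$DAP[curve$wtp == 82.2], 1) # highest deterministic NMB
})

test_that("a single-iteration acceptability curve is a 0/1 step function", {
  params <- rti_trial_parameters()
  psa <- run_psa(params, iterations = 1, seed = 9)
  curve <- ceac(psa, seq(0, 164.4, length.out = 15))
  probs <- as.matrix(curve[, c("DAP", "IAP", "NAP")])
  expect_true(all(probs %in% c(0, 1)))
  # direct NMB comparison at each grid point reproduces the winner
  for (i in seq_len(nrow(curve))) {
    nmb <- curve$wtp[i] * psa$effect - psa$cost
    expect_equal(unname(probs[i, ]),
                 as.numeric(nmb == max(nmb))[match(c("DAP", "IAP", "NAP"),
                                                   psa$strategy)])
  }
})
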