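# Shared fixtures and independent oracles.
#
# Toy parameter sets are assembled as raw lists and pushed through the public
# YAML loader so tests exercise the same path as user scenarios. The oracles
# are deliberately naive re-derivations (full enumeration, NMB sweep) kept
# independent of the package's algebraic implementations.

toy_costs <- function(pc_visit = 50, antibiotic = 5.20, non_antibiotic = 2.50,
                      ed_minor = 215, ed_nonurgent = 130, doctor_time = 5,
                      expenditure = 16.50, wage = 15.85, amr = 0.20) {
  list(
    antibiotic_medication = list(base = antibiotic),
    non_antibiotic_medication = list(base = non_antibiotic),
    ed_minor = list(base = ed_minor),
    ed_nonurgent = list(base = ed_nonurgent),
    pc_visit = list(base = pc_visit),
    doctor_time = list(base = doctor_time),
    expenditure_per_visit = list(base = expenditure),
    hourly_wage = list(base = wage),
    amr_per_prescription = list(base = amr)
  )
}

perfect_utility <- function() {
  list(u_zero = 1, u_severe = 1, u_moderate = 1,
       d_zero = 30, d_severe = 0, d_moderate = 0,
       ae_disutility = 0, ae_days = 0)
}

toy_strategy <- function(pathways,
                         baseline = list(pc_visits = 0, doctor_time_units = 0,
                                         antibiotic_courses = 0,
                                         non_antibiotic_courses = 0,
                                         work_hours_per_contact = 0),
                         utility = perfect_utility(),
                         arm_size = 100) {
  list(description = "toy", arm_size = arm_size, baseline = baseline,
       utility = utility, pathways = pathways)
}

toy_params <- function(strategies, costs = toy_costs(),
                       settings = list(), units = "proportion") {
  raw <- list(
    probability_units = units,
    settings = modifyList(
      list(horizon_days = 30, annual_wtp_per_qaly = 30000, wtp_per_qald = 82.2,
           ae_rate_given_antibiotic = 0, ae_duration_days = 2,
           ae_nonab_medication_prob = 0.5, range_fraction = 0.15),
      settings
    ),
    costs = costs,
    strategies = strategies
  )
  path <- tempfile(fileext = ".yaml")
  yaml::write_yaml(raw, path, precision = 15)
  load_parameters(path)
}

# Random single-strategy parameter set for oracle-equivalence sweeps.
random_toy_params <- function() {
  k <- sample(2:6, 1)
  prob <- runif(k)
  prob <- prob / sum(prob)
  pathways <- lapply(seq_len(k), function(i) {
    list(label = paste0("path_", i), probability = prob[i],
         bundle = list(extra_pc_visits = sample(0:3, 1),
                       antibiotic_courses = sample(0:2, 1),
                       non_antibiotic_courses = sample(0:2, 1),
                       ed_minor = sample(0:1, 1),
                       ed_nonurgent = sample(0:1, 1)))
  })
  st <- toy_strategy(
    pathways,
    baseline = list(pc_visits = 1, doctor_time_units = sample(0:1, 1),
                    antibiotic_courses = sample(0:1, 1),
                    non_antibiotic_courses = runif(1, 0, 2),
                    work_hours_per_contact = runif(1, 0, 1.5)),
    utility = list(u_zero = runif(1, 0.9, 1), u_severe = runif(1, 0.5, 0.9),
                   u_moderate = runif(1, 0.7, 0.95),
                   d_zero = 20, d_severe = 4, d_moderate = 6,
                   ae_disutility = 0.12, ae_days = runif(1, 0, 0.3))
  )
  # unit costs at cent precision so the default +-15% range stays ordered
  costs <- toy_costs(pc_visit = round(runif(1, 10, 100), 2),
                     antibiotic = round(runif(1, 1, 10), 2),
                     non_antibiotic = round(runif(1, 1, 5), 2),
                     ed_minor = round(runif(1, 100, 300), 2),
                     ed_nonurgent = round(runif(1, 50, 200), 2),
                     doctor_time = round(runif(1, 0.4, 10), 2),
                     expenditure = round(runif(1, 5, 25), 2),
                     wage = round(runif(1, 8, 30), 2),
                     amr = round(runif(1, 0.1, 1), 2))
  toy_params(list(S = st), costs = costs,
             settings = list(ae_rate_given_antibiotic = runif(1, 0, 0.3)))
}

# Brute-force oracle: expected cost of one strategy by full enumeration of
# every terminal branch -- pathway x adverse-effect indicator x whether the
# adverse effect adds a non-antibiotic course.
oracle_strategy_cost <- function(strategy, settings, costs) {
  base <- strategy$baseline
  ae_rate <- settings$ae_rate_given_antibiotic
  ae_med <- settings$ae_nonab_medication_prob
  total <- 0
  for (i in seq_along(strategy$pathways$label)) {
    p_path <- strategy$pathways$prob[i]
    b <- strategy$pathways$bundles[[i]]
    exposed <- (base$antibiotic_courses + b$antibiotic_courses) >= 1
    p_ae <- if (exposed) ae_rate else 0
    for (ae in 0:1) {
      for (med in 0:1) {
        p_branch <- p_path *
          (if (ae == 1) p_ae else 1 - p_ae) *
          (if (ae == 1) (if (med == 1) ae_med else 1 - ae_med)
           else (if (med == 1) 0 else 1))
        if (p_branch == 0) next
        pc <- base$pc_visits + b$extra_pc_visits + ae
        contacts <- pc + b$ed_minor + b$ed_nonurgent
        bundle <- list(
          pc_visits = pc,
          antibiotic_courses = base$antibiotic_courses + b$antibiotic_courses,
          non_antibiotic_courses = base$non_antibiotic_courses +
            b$non_antibiotic_courses + med,
          ed_minor = b$ed_minor,
          ed_nonurgent = b$ed_nonurgent,
          doctor_time_units = base$doctor_time_units,
          work_hours_lost = base$work_hours_per_contact * contacts,
          visits_with_expenditure = contacts
        )
        total <- total + p_branch * pathway_cost(bundle, costs)$total
      }
    }
  }
  total
}

# NMB-sweep oracle for frontier membership: a strategy lies on the efficiency
# frontier iff it attains the maximal NMB for some willingness-to-pay >= 0.
# Evaluating at 0, beyond the largest pairwise ICER, and at midpoints between
# consecutive pairwise ICERs covers every argmax region exactly.
oracle_frontier_ids <- function(strategy, cost, effect, tol = 1e-9) {
  n <- length(cost)
  icers <- c()
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i < j && effect[i] != effect[j]) {
        r <- (cost[i] - cost[j]) / (effect[i] - effect[j])
        if (r >= 0) icers <- c(icers, r)
      }
    }
  }
  icers <- sort(unique(icers))
  grid <- c(0, if (length(icers)) c(icers[-length(icers)] + diff(icers) / 2,
                                    max(icers) + 1) else 1)
  on_front <- rep(FALSE, n)
  for (l in grid) {
    nmb <- l * effect - cost
    on_front[nmb >= max(nmb) - tol] <- TRUE
  }
  sort(strategy[on_front])
}
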