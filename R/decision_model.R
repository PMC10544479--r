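## Decision-tree evaluation: expected 30-day cost (societal perspective) and
## QALD effectiveness per strategy.
##
## Each strategy arm starts with a baseline visit V0 (with the arm's initial
## medication and, for the delayed/no-prescription arms, the extra minute of
## doctor time spent explaining the strategy). Terminal pathways then add
## resource use with their observed probabilities. Adverse effects of
## antibiotic exposure accrue an additional primary-care visit always and a
## non-antibiotic course with a configurable probability.

#' Quality-adjusted life days of a health-state profile
#'
#' Days in each symptom state weighted by the state utility, minus the
#' disutility accrued over adverse-effect days:
#' `u_zero*d_zero + u_severe*d_severe + u_moderate*d_moderate -
#' ae_disutility*ae_days`, at full precision.
#'
#' @param profile a utility profile: named list with `u_zero`, `u_severe`,
#'   `u_moderate`, `d_zero`, `d_severe`, `d_moderate`, `ae_disutility`,
#'   `ae_days` (as stored per strategy in a `cea_parameters` object).
#' @return QALDs (numeric scalar).
#' @examples
#' compute_qald(list(u_zero = 1, u_severe = 1, u_moderate = 1,
#'                   d_zero = 30, d_severe = 0, d_moderate = 0,
#'                   ae_disutility = 0, ae_days = 0))  # 30: perfect health
#' @export
compute_qald <- function(profile) {
  with(profile,
       u_zero * d_zero + u_severe * d_severe + u_moderate * d_moderate -
         ae_disutility * ae_days)
}

#' Expected adverse-effect days per patient
#'
#' @param p_antibiotic_exposure probability a patient in the arm takes at
#'   least one antibiotic course.
#' @param ae_rate adverse-effect rate among antibiotic-exposed children
#'   (default 0.10).
#' @param ae_duration mean duration of the adverse effect in days (default 2).
#' @return expected adverse-effect days.
#' @examples
#' adverse_event_days(1, 0.10, 2)  # 0.20 for an arm where everyone is exposed
#' @export
adverse_event_days <- function(p_antibiotic_exposure, ae_rate = 0.10,
                               ae_duration = 2) {
  stopifnot(p_antibiotic_exposure >= 0, p_antibiotic_exposure <= 1,
            ae_rate >= 0, ae_rate <= 1, ae_duration >= 0)
  p_antibiotic_exposure * ae_rate * ae_duration
}

#' Cost of a resource-use bundle, by societal cost category
#'
#' Bottom-up costing of one resource bundle: healthcare direct (visits,
#' emergency department contacts, medication, doctor time), non-healthcare
#' direct (out-of-pocket expenditure per in-person contact), indirect (lost
#' work time at the hourly wage, human-capital approach) and the
#' antimicrobial-resistance cost per antibiotic prescription.
#'
#' @param bundle named list of resource counts: `pc_visits`,
#'   `antibiotic_courses`, `non_antibiotic_courses`, `ed_minor`,
#'   `ed_nonurgent`, `doctor_time_units`, `work_hours_lost`,
#'   `visits_with_expenditure`. Missing entries count as zero.
#' @param costs the `costs` element of a `cea_parameters` object (or any named
#'   list of `list(base = ...)` unit costs with the same labels).
#' @return named list: `healthcare`, `nonhealthcare_direct`, `indirect`,
#'   `amr`, `total` (euros).
#' @export
pathway_cost <- function(bundle, costs) {
  missing <- setdiff(REQUIRED_COSTS, names(costs))
  if (length(missing)) {
    stop("unknown/missing cost labels: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  g <- function(f) as.numeric(bundle[[f]] %||% 0)
  u <- function(nm) costs[[nm]]$base

  healthcare <- g("pc_visits") * u("pc_visit") +
    g("ed_minor") * u("ed_minor") +
    g("ed_nonurgent") * u("ed_nonurgent") +
    g("antibiotic_courses") * u("antibiotic_medication") +
    g("non_antibiotic_courses") * u("non_antibiotic_medication") +
    g("doctor_time_units") * u("doctor_time")
  nonhealthcare <- g("visits_with_expenditure") * u("expenditure_per_visit")
  indirect <- g("work_hours_lost") * u("hourly_wage")
  amr <- g("antibiotic_courses") * u("amr_per_prescription")

  list(healthcare = healthcare,
       nonhealthcare_direct = nonhealthcare,
       indirect = indirect,
       amr = amr,
       total = healthcare + nonhealthcare + indirect + amr)
}

## Probability that a patient in the arm takes >= 1 antibiotic course.
antibiotic_exposure <- function(strategy) {
  if ((strategy$baseline$antibiotic_courses %||% 0) > 0) {
    return(1)
  }
  ab_path <- vapply(strategy$pathways$bundles,
                    function(b) b$antibiotic_courses, numeric(1))
  sum(strategy$pathways$prob[ab_path > 0])
}

## Expected per-patient resource bundle for one strategy arm: baseline +
## probability-weighted pathway bundles + adverse-effect accrual. The
## expectation is exact because every cost is linear in resource counts.
expected_bundle <- function(strategy, settings) {
  pw <- strategy$pathways
  ex <- function(f) {
    sum(pw$prob * vapply(pw$bundles, function(b) b[[f]], numeric(1)))
  }
  base <- strategy$baseline
  p_ae <- antibiotic_exposure(strategy) *
    (settings$ae_rate_given_antibiotic %||% 0.10)

  pc_visits <- (base$pc_visits %||% 1) + ex("extra_pc_visits") + p_ae
  ed_minor <- ex("ed_minor")
  ed_nonurgent <- ex("ed_nonurgent")
  contacts <- pc_visits + ed_minor + ed_nonurgent

  list(
    pc_visits = pc_visits,
    antibiotic_courses = (base$antibiotic_courses %||% 0) +
      ex("antibiotic_courses"),
    non_antibiotic_courses = (base$non_antibiotic_courses %||% 0) +
      ex("non_antibiotic_courses") +
      (settings$ae_nonab_medication_prob %||% 0.5) * p_ae,
    ed_minor = ed_minor,
    ed_nonurgent = ed_nonurgent,
    doctor_time_units = base$doctor_time_units %||% 0,
    work_hours_lost = (base$work_hours_per_contact %||% 0) * contacts,
    visits_with_expenditure = contacts
  )
}

#' Evaluate the decision model
#'
#' Computes, for every strategy, the expected per-patient 30-day cost (total
#' and by societal cost category) and the expected QALD effectiveness.
#'
#' @param params a validated `cea_parameters` object.
#' @return a `strategy_results` tibble with columns `strategy`, `cost_healthcare`,
#'   `cost_nonhealthcare_direct`, `cost_indirect`, `cost_amr`, `cost_total`
#'   (euros per patient) and `effect_qald` (QALDs per patient).
#' @examples
#' evaluate_strategies(rti_trial_parameters())
#' @export
evaluate_strategies <- function(params) {
  stopifnot(inherits(params, "cea_parameters"))
  rows <- lapply(params$strategies, function(st) {
    if (is.null(st$pathways$bundles) || !length(st$pathways$bundles)) {
      stop("strategy ", st$id, ": no pathway bundles", call. = FALSE)
    }
    bundle <- expected_bundle(st, params$settings)
    cost <- pathway_cost(bundle, params$costs)
    data.frame(
      strategy = st$id,
      cost_healthcare = cost$healthcare,
      cost_nonhealthcare_direct = cost$nonhealthcare_direct,
      cost_indirect = cost$indirect,
      cost_amr = cost$amr,
      cost_total = cost$total,
      effect_qald = compute_qald(st$utility),
      stringsAsFactors = FALSE
    )
  })
  out <- tibble::as_tibble(do.call(rbind, rows))
  class(out) <- c("strategy_results", class(out))
  out
}

#' @export
print.strategy_results <- function(x, ...) {
  cat("Expected per-patient cost (euros, 2022) and effectiveness (QALDs):\n")
  y <- as.data.frame(x)
  num <- vapply(y, is.numeric, logical(1))
  y[num] <- lapply(y[num], round, 2)
  print(y, row.names = FALSE)
  invisible(x)
}
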