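## Model-parameter containers, YAML I/O and validation.
##
## A `cea_parameters` object bundles everything the decision model needs:
##   settings   - global settings (horizon, WTP, adverse-effect assumptions,
##                PSA iteration count and dispersion defaults, WTP grid)
##   costs      - unit costs in 2022 euros with low/high sensitivity ranges
##   visit_expenditure_components - the per-visit out-of-pocket decomposition
##   strategies - per prescribing strategy: arm size, baseline resource use,
##                a health-state utility profile, and the terminal pathways of
##                the decision tree, each with a probability and a resource
##                bundle
##   generator  - settings for the synthetic individual-patient-data module

REQUIRED_COSTS <- c(
  "antibiotic_medication", "non_antibiotic_medication", "ed_minor",
  "ed_nonurgent", "pc_visit", "doctor_time", "expenditure_per_visit",
  "hourly_wage", "amr_per_prescription"
)

BUNDLE_FIELDS <- c(
  "extra_pc_visits", "antibiotic_courses", "non_antibiotic_courses",
  "ed_minor", "ed_nonurgent"
)

#' Symmetric sensitivity range around a base value
#'
#' Expands a non-negative base value into the (low, high) pair used by the
#' one-way sensitivity analysis, `low = base * (1 - fraction)` and
#' `high = base * (1 + fraction)`, reported at euro-cent precision with
#' half-up rounding.
#'
#' @param base non-negative base value (euros).
#' @param fraction half-width of the range as a proportion in `[0, 1)`;
#'   default 0.15 (i.e. minus 15 percent to plus 15 percent).
#' @return named numeric vector `c(low = , high = )`.
#' @examples
#' apply_range(16.50, 0.15)  # c(low = 14.03, high = 18.98)
#' apply_range(5.20, 0.15)   # c(low = 4.42,  high = 5.98)
#' @export
apply_range <- function(base, fraction = 0.15) {
  if (!is.numeric(base) || any(base < 0)) {
    stop("`base` must be non-negative", call. = FALSE)
  }
  if (!is.numeric(fraction) || fraction < 0 || fraction >= 1) {
    stop("`fraction` must lie in [0, 1)", call. = FALSE)
  }
  c(low = round_money(base * (1 - fraction)),
    high = round_money(base * (1 + fraction)))
}

#' Compose the per-visit out-of-pocket expenditure
#'
#' Non-healthcare direct expenditure attached to every in-person contact:
#' the monetary value of travel and visit time, transport at a per-kilometre
#' rate over an assumed distance, and parking.
#'
#' @param travel_visit_time_value euros per visit for travel + visit time.
#' @param transport_per_km euros per kilometre.
#' @param assumed_km_per_visit kilometres driven per visit.
#' @param parking euros per visit.
#' @return per-visit expenditure in euros.
#' @examples
#' compose_visit_expenditure(10.50, 0.20, 5, 5.00)  # 16.50
#' @export
compose_visit_expenditure <- function(travel_visit_time_value,
                                      transport_per_km,
                                      assumed_km_per_visit,
                                      parking) {
  args <- c(travel_visit_time_value, transport_per_km,
            assumed_km_per_visit, parking)
  if (any(args < 0)) stop("all expenditure components must be >= 0", call. = FALSE)
  travel_visit_time_value + transport_per_km * assumed_km_per_visit + parking
}

#' Load and validate a model parameter set
#'
#' Reads a YAML scenario file into a validated `cea_parameters` object.
#' Pathway probabilities may be given as percentages (`probability_units:
#' percent`), as printed in trial pathway tables; they are converted to
#' proportions, checked to sum to 1 within 0.0005 per strategy (rounding in
#' printed tables leaves sums of 99.99--100.01 percent) and then renormalised
#' to exactly 1 before any evaluation.
#'
#' @param path path to a YAML parameter file.
#' @return a validated `cea_parameters` object.
#' @seealso [rti_trial_parameters()] for the packaged trial scenario,
#'   [write_parameters()] for the inverse operation.
#' @export
load_parameters <- function(path) {
  if (!file.exists(path)) {
    stop("parameter file not found: ", path, call. = FALSE)
  }
  raw <- yaml::read_yaml(path)
  for (section in c("settings", "costs", "strategies")) {
    if (is.null(raw[[section]])) {
      stop("parameter file is missing mandatory section '", section, "'",
           call. = FALSE)
    }
  }
  params <- build_parameters(raw)
  validate_parameters(params)
}

## Assemble a cea_parameters object from the parsed YAML list.
build_parameters <- function(raw) {
  percent <- identical(raw$probability_units %||% "proportion", "percent")

  costs <- lapply(raw$costs, function(cc) {
    base <- as.numeric(cc$base)
    lo_hi <- apply_range(base, raw$settings$range_fraction %||% 0.15)
    list(base = base,
         low = as.numeric(cc$low %||% lo_hi[["low"]]),
         high = as.numeric(cc$high %||% lo_hi[["high"]]))
  })

  strategies <- lapply(names(raw$strategies), function(id) {
    s <- raw$strategies[[id]]
    pw <- s$pathways
    prob <- vapply(pw, function(p) as.numeric(p$probability), numeric(1))
    if (percent) prob <- prob / 100
    bundles <- lapply(pw, function(p) {
      b <- p$bundle %||% list()
      out <- lapply(BUNDLE_FIELDS, function(f) as.numeric(b[[f]] %||% 0))
      names(out) <- BUNDLE_FIELDS
      out
    })
    list(
      id = id,
      description = s$description %||% id,
      arm_size = as.numeric(s$arm_size %||% NA_real_),
      baseline = lapply(s$baseline, as.numeric),
      utility = lapply(s$utility, as.numeric),
      pathways = list(
        label = vapply(pw, function(p) as.character(p$label), character(1)),
        prob = prob,
        prob_sum_raw = sum(prob),
        bundles = bundles
      )
    )
  })
  names(strategies) <- names(raw$strategies)

  structure(
    list(
      settings = raw$settings,
      costs = costs,
      visit_expenditure_components =
        lapply(raw$visit_expenditure_components %||% list(), as.numeric),
      strategies = strategies,
      generator = raw$generator %||% list()
    ),
    class = "cea_parameters"
  )
}

#' Validate a `cea_parameters` object
#'
#' Checks every structural invariant (cost ranges ordered, utilities in
#' `[0, 1]`, state days covering the horizon, pathway probabilities summing to
#' 1 within tolerance, non-negative resource bundles) and renormalises pathway
#' probability vectors to sum exactly to 1. All violations are collected and
#' reported together.
#'
#' @param params a `cea_parameters` object.
#' @param prob_tol tolerance on per-strategy pathway probability sums
#'   (default 0.0005; printed percentage tables sum to 99.99--100.01).
#' @return the validated (renormalised) object, invisibly classed as before.
#' @export
validate_parameters <- function(params, prob_tol = 5e-4) {
  stopifnot(inherits(params, "cea_parameters"))
  problems <- character(0)
  note <- function(...) problems <<- c(problems, paste0(...))

  missing_costs <- setdiff(REQUIRED_COSTS, names(params$costs))
  if (length(missing_costs)) {
    note("missing cost parameters: ", paste(missing_costs, collapse = ", "))
  }
  for (nm in names(params$costs)) {
    cc <- params$costs[[nm]]
    if (cc$base < 0) note("cost '", nm, "': base < 0")
    if (!(cc$low <= cc$base + 1e-9 && cc$base <= cc$high + 1e-9)) {
      note("cost '", nm, "': low <= base <= high violated (",
           cc$low, " / ", cc$base, " / ", cc$high, ")")
    }
  }

  vec <- params$visit_expenditure_components
  if (length(vec)) {
    composed <- compose_visit_expenditure(
      vec$travel_visit_time_value, vec$transport_per_km,
      vec$assumed_km_per_visit, vec$parking
    )
    epv <- params$costs$expenditure_per_visit$base
    if (!is.null(epv) && abs(composed - epv) > 0.005) {
      note("visit expenditure components compose to ", composed,
           " but expenditure_per_visit is ", epv)
    }
  }

  horizon <- params$settings$horizon_days %||% 30
  wtp <- params$settings$wtp_per_qald %||% NA_real_
  annual <- params$settings$annual_wtp_per_qaly %||% NA_real_
  if (is.finite(wtp) && is.finite(annual) && abs(wtp - annual / 365) > 0.05) {
    note("wtp_per_qald (", wtp, ") is not annual_wtp_per_qaly/365 (",
         round(annual / 365, 3), ")")
  }

  for (id in names(params$strategies)) {
    st <- params$strategies[[id]]
    u <- st$utility
    for (f in c("u_zero", "u_severe", "u_moderate", "ae_disutility")) {
      if (u[[f]] < 0 || u[[f]] > 1) {
        note("strategy ", id, ": ", f, " = ", u[[f]], " outside [0, 1]")
      }
    }
    for (f in c("d_zero", "d_severe", "d_moderate", "ae_days")) {
      if (u[[f]] < 0) note("strategy ", id, ": ", f, " < 0")
    }
    dsum <- u$d_zero + u$d_severe + u$d_moderate
    if (abs(dsum - horizon) > 0.05) {
      note("strategy ", id, ": state days sum to ", dsum,
           ", not the ", horizon, "-day horizon (tolerance 0.05)")
    }
    pw <- st$pathways
    if (any(pw$prob < 0)) note("strategy ", id, ": negative pathway probability")
    psum <- sum(pw$prob)
    if (abs(psum - 1) > prob_tol) {
      note("strategy ", id, ": probabilities sum ", format(psum),
           " != 1 (tolerance ", prob_tol, ")")
    } else {
      params$strategies[[id]]$pathways$prob <- pw$prob / psum
    }
    for (b in pw$bundles) {
      if (any(unlist(b) < 0)) note("strategy ", id, ": negative resource count")
    }
  }

  if (length(problems)) {
    stop("parameter validation failed:\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)
  }
  params
}

#' Write a parameter set back to YAML
#'
#' Inverse of [load_parameters()]; a written file loads back to the same
#' values (probabilities are written as proportions at full precision, so no
#' percent round-trip error is introduced).
#'
#' @param params a `cea_parameters` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_parameters <- function(params, path) {
  stopifnot(inherits(params, "cea_parameters"))
  raw <- list(
    probability_units = "proportion",
    settings = params$settings,
    costs = params$costs,
    visit_expenditure_components = as.list(params$visit_expenditure_components),
    strategies = lapply(params$strategies, function(st) {
      list(
        description = st$description,
        arm_size = st$arm_size,
        baseline = st$baseline,
        utility = st$utility,
        pathways = lapply(seq_along(st$pathways$label), function(i) {
          list(label = st$pathways$label[i],
               probability = st$pathways$prob[i],
               bundle = st$pathways$bundles[[i]])
        })
      )
    }),
    generator = params$generator
  )
  yaml::write_yaml(raw, path, precision = 15)
  invisible(path)
}

#' Packaged parameter set of the paediatric RTI prescribing trial
#'
#' Loads the scenario shipped with the package: three prescribing strategies
#' (DAP delayed, IAP immediate, NAP none) for children with uncomplicated
#' respiratory tract infections, with observed decision-tree pathway
#' frequencies, 2022 unit costs with sensitivity ranges, and health-state
#' utility profiles over a 30-day horizon.
#'
#' @return a validated `cea_parameters` object.
#' @examples
#' params <- rti_trial_parameters()
#' evaluate_strategies(params)
#' @export
rti_trial_parameters <- function() {
  path <- system.file("extdata", "rti_trial_parameters.yaml", package = "abxcea")
  if (!nzchar(path)) stop("packaged parameter file not found", call. = FALSE)
  load_parameters(path)
}

#' @export
print.cea_parameters <- function(x, ...) {
  cat("<cea_parameters>\n")
  cat("  horizon:", x$settings$horizon_days %||% 30, "days;",
      "WTP:", x$settings$wtp_per_qald, "euros/QALD\n")
  cat("  unit costs:", length(x$costs), "\n")
  for (id in names(x$strategies)) {
    st <- x$strategies[[id]]
    cat(sprintf("  %s: %d pathways (arm n = %s) - %s\n", id,
                length(st$pathways$label),
                format(st$arm_size), st$description))
  }
  invisible(x)
}
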