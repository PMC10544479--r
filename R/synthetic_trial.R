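## Synthetic individual-patient data (IPD) emulating the trial's statistical
## structure, plus estimation of model inputs back from IPD. Together the two
## close a parameter-recovery loop: generate -> estimate -> evaluate -> rank
## exercises every pipeline stage without any external data.

bundle_of <- function(strategy, pathway_label) {
  i <- match(pathway_label, strategy$pathways$label)
  strategy$pathways$bundles[[i]]
}

#' Generate a synthetic individual-patient-data trial
#'
#' Simulates per-child records for the three prescribing arms: pathway
#' assignment is multinomial with the configured pathway probabilities;
#' severe/moderate symptom durations are truncated normal on `[0, horizon]`
#' whose location is moment-matched so the realised (post-truncation) mean
#' equals the published per-arm mean, with the published SD as the underlying
#' normal's scale; per-state VAS scores are beta on `[0, 100]` with mean `100 x
#' utility`; resource counts follow the pathway's bundle plus the arm
#' baseline; adverse effects are Bernoulli with the configured rate among
#' antibiotic-exposed children only, and add one primary-care visit and
#' sometimes a non-antibiotic course; lost work hours are gamma around the
#' arm's per-contact mean times the number of contacts.
#'
#' @param params a validated `cea_parameters` object carrying a `generator`
#'   section (the packaged scenario does).
#' @param seed integer seed; output is identical across runs with the same
#'   seed.
#' @param n_per_arm optional single number overriding every arm size.
#' @param zero_variance if `TRUE`, durations, VAS scores and hours are set to
#'   their means (degenerate distributions); pathway assignment and
#'   adverse-effect indicators remain random.
#' @return a tibble with one row per child: `id`, `arm`, `age`, `sex`,
#'   `diagnosis`, `pathway`, `severe_days`, `moderate_days`, `zero_days`,
#'   `vas_zero`, `vas_severe`, `vas_moderate`, `antibiotic_courses`,
#'   `non_antibiotic_courses`, `extra_pc_visits`, `ed_minor`, `ed_nonurgent`,
#'   `contacts`, `adverse_effect`, `work_hours_lost`.
#' @export
generate_trial <- function(params, seed = 1L, n_per_arm = NULL,
                           zero_variance = FALSE) {
  stopifnot(inherits(params, "cea_parameters"))
  gen <- params$generator
  if (!length(gen)) stop("no `generator` section in parameters", call. = FALSE)
  set.seed(seed)
  horizon <- params$settings$horizon_days %||% 30
  ae_rate <- params$settings$ae_rate_given_antibiotic %||% 0.10
  ae_nonab <- params$settings$ae_nonab_medication_prob %||% 0.5

  arms <- lapply(names(params$strategies), function(id) {
    s <- params$strategies[[id]]
    n <- n_per_arm %||% s$arm_size
    if (is.null(n) || !is.finite(n) || n <= 0) {
      stop("arm size for ", id, " must be a positive number", call. = FALSE)
    }
    n <- as.integer(n)

    pw <- s$pathways
    path_idx <- sample.int(length(pw$prob), n, replace = TRUE, prob = pw$prob)
    bmat <- vapply(pw$bundles, function(b) unlist(b[BUNDLE_FIELDS]),
                   numeric(length(BUNDLE_FIELDS)))
    rownames(bmat) <- BUNDLE_FIELDS
    bu <- t(bmat[, path_idx, drop = FALSE])

    sv <- gen$severe_days[[id]]
    mo <- gen$moderate_days[[id]]
    sv_sd <- if (zero_variance) 0 else sv$sd
    mo_sd <- if (zero_variance) 0 else mo$sd
    ## the normal's location is moment-matched so the REALISED mean after
    ## truncation at zero equals the published per-arm mean
    severe <- rtruncnorm(n, truncnorm_mu_for_mean(sv$mean, sv_sd, 0, horizon),
                         sv_sd, 0, horizon)
    moderate <- rtruncnorm(n, truncnorm_mu_for_mean(mo$mean, mo_sd, 0, horizon),
                           mo_sd, 0, horizon)
    over <- severe + moderate > horizon
    moderate[over] <- horizon - severe[over]
    zero <- horizon - severe - moderate

    vas_sd <- if (zero_variance) 0 else gen$vas_sd_points %||% 5
    vas <- function(u) {
      100 * rbeta_ms(n, u, vas_sd / 100, "vas")
    }

    ab <- (s$baseline$antibiotic_courses %||% 0) + bu[, "antibiotic_courses"]
    ae <- ifelse(ab >= 1, rbinom(n, 1, ae_rate), 0L)
    ae_extra_med <- ifelse(ae == 1, rbinom(n, 1, ae_nonab), 0L)
    nonab <- rpois(n, s$baseline$non_antibiotic_courses %||% 0) +
      bu[, "non_antibiotic_courses"] + ae_extra_med

    visits <- (s$baseline$pc_visits %||% 1) + bu[, "extra_pc_visits"] + ae
    contacts <- visits + bu[, "ed_minor"] + bu[, "ed_nonurgent"]
    h_mean <- s$baseline$work_hours_per_contact %||% 0
    hours_cv <- if (zero_variance) 0 else gen$hours_cv %||% 0.3
    hours <- rgamma_cv(n, 1, hours_cv) * h_mean * contacts

    age_cfg <- gen$age %||% list(mean = 6.3, sd = 3.0, min = 2, max = 14)
    dx <- gen$diagnosis_counts[[id]]
    diagnosis <- if (is.null(dx)) rep(NA_character_, n) else {
      sample(names(dx), n, replace = TRUE, prob = unlist(dx))
    }

    tibble::tibble(
      arm = id,
      age = rtruncnorm(n, age_cfg$mean, age_cfg$sd, age_cfg$min, age_cfg$max),
      sex = ifelse(runif(n) < (gen$female_prob %||% 0.5), "F", "M"),
      diagnosis = diagnosis,
      pathway = pw$label[path_idx],
      severe_days = severe,
      moderate_days = moderate,
      zero_days = zero,
      vas_zero = vas(s$utility$u_zero),
      vas_severe = vas(s$utility$u_severe),
      vas_moderate = vas(s$utility$u_moderate),
      antibiotic_courses = ab,
      non_antibiotic_courses = nonab,
      extra_pc_visits = bu[, "extra_pc_visits"] + ae,
      ed_minor = bu[, "ed_minor"],
      ed_nonurgent = bu[, "ed_nonurgent"],
      contacts = contacts,
      adverse_effect = as.integer(ae),
      work_hours_lost = hours
    )
  })
  out <- do.call(rbind, arms)
  out <- cbind(tibble::tibble(id = seq_len(nrow(out))), out)
  tibble::as_tibble(out)
}

#' Estimate model inputs from individual-patient data
#'
#' The inverse of [generate_trial()]: turns IPD back into a `cea_parameters`
#' object. Pathway probabilities are the observed per-arm branch frequencies
#' (they sum to 1 exactly); state utilities are the arm means of the per-state
#' VAS scores divided by 100; state days are arm means; adverse-effect days
#' are `exposure x ae_rate x ae_duration` with the observed exposure; the
#' per-contact lost-work time is the arm mean of `work_hours_lost / contacts`;
#' baseline non-antibiotic use is the arm mean net of pathway- and
#' adverse-effect-attributed courses. Unit costs, resource-bundle definitions
#' and global settings are carried over from `template` (they are prices and
#' structure, not estimable from IPD).
#'
#' @param ipd a tibble from [generate_trial()] (or real data with the same
#'   column dictionary).
#' @param template a `cea_parameters` object supplying costs, bundles and
#'   settings; defaults to the packaged trial scenario.
#' @return a validated `cea_parameters` object.
#' @export
estimate_inputs <- function(ipd, template = rti_trial_parameters()) {
  stopifnot(inherits(template, "cea_parameters"))
  needed <- c("arm", "pathway", "severe_days", "moderate_days", "zero_days",
              "vas_zero", "vas_severe", "vas_moderate", "antibiotic_courses",
              "non_antibiotic_courses", "contacts", "work_hours_lost",
              "adverse_effect")
  missing <- setdiff(needed, names(ipd))
  if (length(missing)) {
    stop("IPD is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  p <- template
  ae_rate <- p$settings$ae_rate_given_antibiotic %||% 0.10
  ae_dur <- p$settings$ae_duration_days %||% 2

  for (id in names(p$strategies)) {
    s <- p$strategies[[id]]
    d <- ipd[ipd$arm == id, , drop = FALSE]
    if (!nrow(d)) stop("no IPD records for arm ", id, call. = FALSE)

    counts <- table(factor(d$pathway, levels = s$pathways$label))
    if (sum(counts) < nrow(d)) {
      stop("arm ", id, ": IPD contains pathways unknown to the template",
           call. = FALSE)
    }
    p$strategies[[id]]$pathways$prob <- as.numeric(counts) / nrow(d)
    p$strategies[[id]]$arm_size <- nrow(d)

    exposure <- mean(d$antibiotic_courses >= 1)
    p$strategies[[id]]$utility <- list(
      u_zero = mean(d$vas_zero) / 100,
      u_severe = mean(d$vas_severe) / 100,
      u_moderate = mean(d$vas_moderate) / 100,
      d_zero = mean(d$zero_days),
      d_severe = mean(d$severe_days),
      d_moderate = mean(d$moderate_days),
      ae_disutility = s$utility$ae_disutility,
      ae_days = adverse_event_days(exposure, ae_rate, ae_dur)
    )

    ## net out pathway- and AE-attributed courses to recover the baseline mean
    bmat <- vapply(s$pathways$bundles, function(b) b$non_antibiotic_courses,
                   numeric(1))
    path_nonab <- bmat[match(d$pathway, s$pathways$label)]
    ae_nonab <- (p$settings$ae_nonab_medication_prob %||% 0.5) * d$adverse_effect
    p$strategies[[id]]$baseline$non_antibiotic_courses <-
      max(0, mean(d$non_antibiotic_courses - path_nonab - ae_nonab))
    p$strategies[[id]]$baseline$work_hours_per_contact <-
      mean(d$work_hours_lost / d$contacts)
  }
  validate_parameters(p, prob_tol = 5e-4)
}
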