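## Deterministic (tornado) and probabilistic sensitivity analysis.

## ICER of `pair[1]` versus `pair[2]` on a parameter set.
icer_pair <- function(params, pair) {
  res <- evaluate_strategies(params)
  a <- res[res$strategy == pair[1], ]
  b <- res[res$strategy == pair[2], ]
  if (!nrow(a) || !nrow(b)) stop("unknown strategy in `pair`", call. = FALSE)
  de <- a$effect_qald - b$effect_qald
  if (de == 0) return(NA_real_)
  (a$cost_total - b$cost_total) / de
}

## Default comparison for the tornado: the adjacent frontier increment at
## base case. Requires a unique increment unless a pair is given explicitly.
default_frontier_pair <- function(params) {
  res <- evaluate_strategies(params)
  fr <- frontier(rank_strategies(res, params$settings$wtp_per_qald %||% 0))
  if (nrow(fr) < 2) {
    stop("base-case frontier has a single strategy; supply `pair`",
         call. = FALSE)
  }
  if (nrow(fr) > 2) {
    stop("base-case frontier has several increments; supply `pair`",
         call. = FALSE)
  }
  c(fr$strategy[2], fr$strategy[1])
}

#' One-way tornado sensitivity analysis
#'
#' Sets each unit cost in turn to its low and then its high value (all other
#' parameters at base), re-evaluates the model and recomputes the ICER of the
#' frontier comparison. `direction` is `"increase"` when the ICER rises with
#' the parameter and `"decrease"` otherwise; rows are ordered by descending
#' impact width, the tornado ordering. Effectiveness does not depend on unit
#' costs, so the incremental effect is fixed and the perturbed ICERs are exact
#' linear responses.
#'
#' @param params a validated `cea_parameters` object.
#' @param pair character(2), intervention then comparator; default: the
#'   unique adjacent frontier increment at base case.
#' @param fraction optional proportion overriding the stored low/high ranges
#'   with `base * (1 -/+ fraction)`.
#' @return a `tornado_results` tibble: `parameter`, `low_icer`, `high_icer`,
#'   `base_icer`, `direction`, `impact_width`, `cum_impact_share` (cumulative
#'   normalised share of the summed impact widths — an interpretation, the
#'   quantity has no standard definition), `degenerate` (TRUE when the ICER
#'   was undefined at a perturbed point).
#' @export
run_tornado <- function(params, pair = NULL, fraction = NULL) {
  stopifnot(inherits(params, "cea_parameters"))
  if (is.null(pair)) pair <- default_frontier_pair(params)
  base_icer <- icer_pair(params, pair)
  if (is.na(base_icer)) {
    stop("base-case ICER undefined (zero incremental effect)", call. = FALSE)
  }

  rows <- lapply(names(params$costs), function(nm) {
    cc <- params$costs[[nm]]
    bounds <- if (is.null(fraction)) {
      c(cc$low, cc$high)
    } else {
      as.numeric(apply_range(cc$base, fraction))
    }
    at <- function(value) {
      p <- params
      p$costs[[nm]]$base <- value
      icer_pair(p, pair)
    }
    lo <- at(bounds[1])
    hi <- at(bounds[2])
    degenerate <- is.na(lo) || is.na(hi)
    data.frame(
      parameter = nm,
      low_icer = lo,
      high_icer = hi,
      base_icer = base_icer,
      direction = if (degenerate) NA_character_ else
        if (hi >= lo) "increase" else "decrease",
      impact_width = if (degenerate) NA_real_ else abs(hi - lo),
      degenerate = degenerate,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$impact_width), , drop = FALSE]
  total <- sum(out$impact_width, na.rm = TRUE)
  out$cum_impact_share <- if (total > 0) {
    cumsum(ifelse(is.na(out$impact_width), 0, out$impact_width)) / total
  } else NA_real_
  out <- tibble::as_tibble(out)
  attr(out, "pair") <- pair
  class(out) <- c("tornado_results", class(out))
  out
}

#' Draw one probabilistic-sensitivity-analysis parameter sample
#'
#' Perturbs a parameter set using the conventional distribution families:
#' gamma for unit costs and per-arm lost-work time (matched to the base mean
#' and a coefficient of variation), beta for state utilities and the
#' adverse-effect rate (matched to mean and standard error), and Dirichlet
#' for each strategy's pathway-probability vector (concentration = trial arm
#' size, so each branch's marginal SD matches its binomial standard error).
#' Structural zeros remain zero; zero dispersion returns the base set.
#' Parameters are consumed from the current RNG state in a fixed order
#' (costs, then per strategy: pathway vector, utilities, hours; then the AE
#' rate), so runs are exactly reproducible given a seed.
#'
#' @param params a validated `cea_parameters` object. Dispersion settings are
#'   read from `params$settings`: `psa_cost_cv`, `psa_vas_sd_points`,
#'   `psa_ae_n`, and optionally `psa_dirichlet_n` overriding the per-arm
#'   Dirichlet concentrations (`Inf` makes every distribution degenerate
#'   together with zero CVs, reproducing the deterministic analysis).
#' @return a perturbed `cea_parameters` object.
#' @export
draw_psa_sample <- function(params) {
  stopifnot(inherits(params, "cea_parameters"))
  st <- params$settings
  cost_cv <- st$psa_cost_cv %||% 0
  vas_sd <- st$psa_vas_sd_points %||% 0
  ae_n <- st$psa_ae_n %||% Inf

  p <- params
  for (nm in names(p$costs)) {
    p$costs[[nm]]$base <- rgamma_cv(1, p$costs[[nm]]$base, cost_cv)
  }
  for (id in names(p$strategies)) {
    s <- p$strategies[[id]]
    kappa <- st$psa_dirichlet_n %||%
      (if (is.finite(s$arm_size %||% NA_real_)) s$arm_size else Inf)
    p$strategies[[id]]$pathways$prob <- rdirichlet1(s$pathways$prob, kappa)
    n_arm <- if (is.finite(kappa)) kappa else 140
    for (f in c("u_zero", "u_severe", "u_moderate")) {
      se <- vas_sd / 100 / sqrt(n_arm)
      p$strategies[[id]]$utility[[f]] <-
        rbeta_ms(1, s$utility[[f]], se, paste0(id, ":", f))
    }
    p$strategies[[id]]$baseline$work_hours_per_contact <-
      rgamma_cv(1, s$baseline$work_hours_per_contact %||% 0, cost_cv)
  }
  rate <- st$ae_rate_given_antibiotic %||% 0.10
  se <- if (is.finite(ae_n)) sqrt(rate * (1 - rate) / ae_n) else 0
  p$settings$ae_rate_given_antibiotic <-
    rbeta_ms(1, rate, se, "ae_rate_given_antibiotic")
  p
}

#' Run the probabilistic sensitivity analysis
#'
#' Monte Carlo over [draw_psa_sample()]: all parameters are varied jointly at
#' every iteration and the decision model re-evaluated on the perturbed set.
#'
#' @param params a validated `cea_parameters` object.
#' @param iterations number of Monte Carlo iterations (default from
#'   `params$settings$psa_iterations`, 10 000 in the packaged scenario).
#' @param seed integer seed; the run is exactly reproducible given
#'   `(seed, iterations)`.
#' @return a `psa_results` tibble: `iteration`, `strategy`, `cost`, `effect`,
#'   with the sampled unit costs attached as a matrix in
#'   `attr(, "cost_draws")`.
#' @export
run_psa <- function(params, iterations = NULL, seed = 1L) {
  stopifnot(inherits(params, "cea_parameters"))
  iterations <- iterations %||% params$settings$psa_iterations %||% 10000
  stopifnot(iterations >= 1)
  set.seed(seed)

  ids <- names(params$strategies)
  n_s <- length(ids)
  cost <- matrix(NA_real_, iterations, n_s, dimnames = list(NULL, ids))
  effect <- cost
  cost_draws <- matrix(NA_real_, iterations, length(params$costs),
                       dimnames = list(NULL, names(params$costs)))
  for (it in seq_len(iterations)) {
    p <- draw_psa_sample(params)
    cost_draws[it, ] <- vapply(p$costs, function(cc) cc$base, numeric(1))
    res <- evaluate_strategies(p)
    cost[it, ] <- res$cost_total[match(ids, res$strategy)]
    effect[it, ] <- res$effect_qald[match(ids, res$strategy)]
  }

  out <- tibble::tibble(
    iteration = rep(seq_len(iterations), times = n_s),
    strategy = rep(ids, each = iterations),
    cost = as.vector(cost),
    effect = as.vector(effect)
  )
  attr(out, "cost_draws") <- cost_draws
  attr(out, "seed") <- seed
  attr(out, "wtp") <- params$settings$wtp_per_qald
  class(out) <- c("psa_results", class(out))
  out
}

psa_wide <- function(psa, what = c("cost", "effect")) {
  what <- match.arg(what)
  ids <- unique(psa$strategy)
  m <- sapply(ids, function(id) psa[[what]][psa$strategy == id])
  if (is.null(dim(m))) {
    m <- matrix(m, nrow = 1, dimnames = list(NULL, ids))
  }
  m
}

#' Incremental cost-effectiveness plane summary
#'
#' Tallies PSA iterations by quadrant of the incremental plane for one
#' comparison (incremental effect on the horizontal axis, incremental cost on
#' the vertical): I more effective/more costly, II less effective/more
#' costly, III less effective/less costly, IV more effective/less costly.
#' Boundary convention (documented, measure-zero for continuous draws): a
#' zero incremental effect counts as "not more effective" (quadrant II or III
#' by the cost sign) and a zero incremental cost counts as "more costly";
#' the origin falls in quadrant II.
#'
#' @param psa a `psa_results` object.
#' @param pair character(2): intervention, comparator.
#' @param wtp willingness to pay per QALD for the acceptability proportion.
#' @return list with `pair`, `quadrants` (named proportions `I`..`IV` summing
#'   to 1), `prop_acceptable` (share of iterations where the intervention has
#'   the higher NMB at `wtp`), `prop_below_wtp_in_I` (share of quadrant-I
#'   iterations with ICER below `wtp`), and `n`.
#' @export
ce_plane_summary <- function(psa, pair, wtp) {
  stopifnot(inherits(psa, "psa_results"))
  dc <- psa$cost[psa$strategy == pair[1]] - psa$cost[psa$strategy == pair[2]]
  de <- psa$effect[psa$strategy == pair[1]] - psa$effect[psa$strategy == pair[2]]
  if (!length(dc)) stop("unknown strategy in `pair`", call. = FALSE)
  q <- ifelse(de > 0 & dc >= 0, "I",
       ifelse(de <= 0 & dc >= 0, "II",
       ifelse(de <= 0 & dc < 0, "III", "IV")))
  quad <- vapply(c("I", "II", "III", "IV"),
                 function(k) mean(q == k), numeric(1))
  in_I <- q == "I"
  list(
    pair = pair,
    quadrants = quad,
    prop_acceptable = mean(wtp * de - dc > 0),
    prop_below_wtp_in_I = if (any(in_I)) {
      mean(dc[in_I] / de[in_I] < wtp)
    } else NA_real_,
    n = length(dc)
  )
}

#' Cost-effectiveness acceptability curves
#'
#' For every willingness-to-pay value on a grid, the probability that each
#' strategy is the cost-effective choice, i.e. the fraction of PSA iterations
#' in which it attains the highest net monetary benefit (exact ties split
#' equally).
#'
#' @param psa a `psa_results` object.
#' @param wtp_grid ascending numeric grid of willingness-to-pay values
#'   (euros/QALD).
#' @return a `ceac_curve` tibble: `wtp`, one probability column per strategy;
#'   probabilities sum to 1 at every grid point.
#' @export
ceac <- function(psa, wtp_grid) {
  stopifnot(inherits(psa, "psa_results"), length(wtp_grid) >= 1,
            !is.unsorted(wtp_grid))
  cost <- psa_wide(psa, "cost")
  effect <- psa_wide(psa, "effect")
  ids <- colnames(cost)
  probs <- t(vapply(wtp_grid, function(l) {
    nmb <- l * effect - cost
    best <- nmb == apply(nmb, 1, max)
    win <- best / rowSums(best)  # ties split equally
    colMeans(win)
  }, numeric(length(ids))))
  out <- tibble::as_tibble(cbind(data.frame(wtp = wtp_grid), probs))
  class(out) <- c("ceac_curve", class(out))
  out
}

#' @export
print.tornado_results <- function(x, ...) {
  cat(sprintf("One-way sensitivity of ICER (%s vs %s), base %.2f euros/QALD\n",
              attr(x, "pair")[1], attr(x, "pair")[2], x$base_icer[1]))
  y <- as.data.frame(x)
  num <- vapply(y, is.numeric, logical(1))
  y[num] <- lapply(y[num], round, 2)
  print(y, row.names = FALSE)
  invisible(x)
}

#' @export
print.psa_results <- function(x, ...) {
  it <- max(x$iteration)
  cat(sprintf("PSA: %d iterations x %d strategies (seed %s)\n", it,
              length(unique(x$strategy)), format(attr(x, "seed"))))
  agg <- stats::aggregate(cbind(cost, effect) ~ strategy, data = x, FUN = mean)
  agg$cost <- round(agg$cost, 2); agg$effect <- round(agg$effect, 3)
  cat("Means across iterations:\n")
  print(agg, row.names = FALSE)
  invisible(x)
}
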