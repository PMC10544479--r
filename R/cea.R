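## Incremental cost-effectiveness analysis: cost ranking, strict and extended
## dominance, efficiency-frontier ICERs, net monetary benefit.

#' Net monetary benefit
#'
#' `NMB = wtp * effect - cost`, at full precision.
#'
#' @param cost expected cost (euros).
#' @param effect expected effectiveness (QALDs).
#' @param wtp willingness to pay per QALD (euros).
#' @return net monetary benefit in euros.
#' @examples
#' net_monetary_benefit(100.90, 27.94, 82.2)
#' @export
net_monetary_benefit <- function(cost, effect, wtp) {
  stopifnot(all(wtp >= 0))
  wtp * effect - cost
}

#' Daily willingness-to-pay threshold from an annual one
#'
#' Converts a willingness-to-pay per quality-adjusted life year into euros per
#' quality-adjusted life day, rounded to one decimal: 30 000 euros/QALY
#' becomes 82.2 euros/QALD.
#'
#' @param annual_wtp willingness to pay per QALY (euros, non-negative).
#' @return euros per QALD, one decimal.
#' @export
wtp_per_qald <- function(annual_wtp) {
  if (annual_wtp < 0) stop("`annual_wtp` must be >= 0", call. = FALSE)
  round_money(annual_wtp / 365, 1)
}

#' Rank strategies and classify dominance
#'
#' Orders strategies by ascending cost, removes strictly dominated options
#' (costlier and no more effective than some alternative), then iteratively
#' removes extendedly dominated options (ICER larger than that of the next
#' more effective alternative) until the efficiency-frontier ICERs strictly
#' increase. Incremental quantities and ICERs are computed on full-precision
#' costs and effects. The returned table holds all strategies; dominated rows
#' keep their sign-carrying ICER versus the previous row in cost order (the
#' "all strategies" view), flagged by `status`.
#'
#' @param results a `strategy_results` table from [evaluate_strategies()]
#'   (or any data frame with `strategy`, `cost_total`, `effect_qald`).
#' @param wtp willingness to pay per QALD used for the NMB column.
#' @return a `cea_table` tibble with columns `strategy`, `cost`, `incr_cost`,
#'   `effect`, `incr_effect`, `icer`, `nmb`, `status` (one of `on_frontier`,
#'   `strictly_dominated`, `extendedly_dominated`) and `equivalent_to` (only
#'   non-`NA` for exact cost/effect ties).
#' @examples
#' res <- evaluate_strategies(rti_trial_parameters())
#' rank_strategies(res, wtp = 82.2)
#' @export
rank_strategies <- function(results, wtp) {
  df <- as.data.frame(results)
  stopifnot(all(c("strategy", "cost_total", "effect_qald") %in% names(df)))
  if (anyDuplicated(df$strategy)) {
    stop("duplicate strategy ids", call. = FALSE)
  }
  if (!all(is.finite(df$cost_total)) || !all(is.finite(df$effect_qald))) {
    stop("costs and effects must be finite", call. = FALSE)
  }

  ## ascending cost; ties broken by descending effect so the better option
  ## comes first
  ord <- order(df$cost_total, -df$effect_qald)
  df <- df[ord, , drop = FALSE]
  n <- nrow(df)
  cost <- df$cost_total
  effect <- df$effect_qald

  status <- rep("on_frontier", n)
  equivalent_to <- rep(NA_character_, n)

  ## strict dominance: some other strategy costs no more and is no less
  ## effective, with at least one strict inequality
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (cost[j] <= cost[i] && effect[j] >= effect[i] &&
          (cost[j] < cost[i] || effect[j] > effect[i])) {
        status[i] <- "strictly_dominated"
        break
      }
      if (cost[j] == cost[i] && effect[j] == effect[i]) {
        equivalent_to[i] <- df$strategy[j]
      }
    }
  }

  ## extended dominance: on the surviving chain, drop any strategy whose ICER
  ## versus the previous frontier member is >= the ICER of the next member,
  ## until the frontier ICER sequence strictly increases
  repeat {
    keep <- which(status == "on_frontier")
    if (length(keep) < 3) break
    icers <- diff(cost[keep]) / diff(effect[keep])
    bad <- which(diff(icers) <= 0)
    if (!length(bad)) break
    status[keep[bad[1] + 1]] <- "extendedly_dominated"
  }

  ## incrementals: frontier rows versus the previous frontier row; dominated
  ## rows versus the previous row in cost order (the "all strategies" view)
  incr_cost <- rep(NA_real_, n)
  incr_effect <- rep(NA_real_, n)
  icer <- rep(NA_real_, n)
  prev_frontier <- NA_integer_
  for (i in seq_len(n)) {
    ref <- if (status[i] == "on_frontier") prev_frontier else i - 1L
    if (!is.na(ref) && ref >= 1L) {
      incr_cost[i] <- cost[i] - cost[ref]
      incr_effect[i] <- effect[i] - effect[ref]
      icer[i] <- if (incr_effect[i] != 0) incr_cost[i] / incr_effect[i] else NA_real_
    }
    if (status[i] == "on_frontier") prev_frontier <- i
  }

  out <- tibble::tibble(
    strategy = df$strategy,
    cost = cost,
    incr_cost = incr_cost,
    effect = effect,
    incr_effect = incr_effect,
    icer = icer,
    nmb = net_monetary_benefit(cost, effect, wtp),
    status = status,
    equivalent_to = equivalent_to
  )
  attr(out, "wtp") <- wtp
  class(out) <- c("cea_table", class(out))
  out
}

#' Frontier view of a CEA table
#'
#' Drops dominated rows (the "excluding dominated" presentation).
#'
#' @param cea a `cea_table` from [rank_strategies()].
#' @return the frontier rows only.
#' @export
frontier <- function(cea) {
  stopifnot(inherits(cea, "cea_table"))
  cea[cea$status == "on_frontier", , drop = FALSE]
}

#' @export
print.cea_table <- function(x, ...) {
  cat(sprintf("Cost-effectiveness ranking (WTP %.1f euros/QALD)\n",
              attr(x, "wtp")))
  y <- as.data.frame(x)
  for (col in c("cost", "incr_cost", "icer", "nmb")) y[[col]] <- round(y[[col]], 2)
  for (col in c("effect", "incr_effect")) y[[col]] <- round(y[[col]], 2)
  print(y, row.names = FALSE)
  invisible(x)
}
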