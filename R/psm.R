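## The three-state partitioned survival model: state occupancy from the
## OS/PFS curves with half-cycle correction, per-cycle cost and QALY
## accumulation with discounting, and incremental results.

#' Build the per-cycle state-occupancy trace
#'
#' Occupancy is evaluated at each cycle midpoint (half-cycle correction):
#' `pfs = min(S_pfs, S_os)`, `pd = S_os - pfs`, `dead = 1 - S_os`. The
#' discount weight is `(1 + rate)^(-midpoint years)`. The number of cycles is
#' `ceiling(horizon_years * 365.25 / cycle_days)`. Cycles where the raw
#' progression-free curve exceeded overall survival before capping are
#' counted in the attribute `pfs_capping` (with the maximum violation).
#'
#' @param os_model,pfs_model [surv_model]s (times in months).
#' @param horizon_years Positive horizon.
#' @param cycle_days Cycle length in days (21 by default).
#' @param discount_rate Annual discount rate.
#' @return Data frame of class `psm_trace` with columns `cycle`,
#'   `mid_months`, `pfs`, `pd`, `dead`, `new_deaths`, `disc`.
#' @export
build_trace <- function(os_model, pfs_model, horizon_years,
                        cycle_days = 21, discount_rate = 0.03) {
  stopifnot(horizon_years > 0, cycle_days > 0)
  n <- ceiling(horizon_years * 365.25 / cycle_days)
  mid_months <- (seq_len(n) - 0.5) * cycle_days / DAYS_PER_MONTH
  s_os <- surv_prob(os_model, mid_months)
  s_pfs_raw <- surv_prob(pfs_model, mid_months)
  viol <- pmax(s_pfs_raw - s_os, 0)
  pfs <- pmin(s_pfs_raw, s_os)
  pd <- s_os - pfs
  dead <- 1 - s_os
  tr <- data.frame(cycle = seq_len(n), mid_months = mid_months,
                   pfs = pfs, pd = pd, dead = dead,
                   new_deaths = diff(c(0, dead)),
                   disc = (1 + discount_rate)^(-mid_months / 12))
  attr(tr, "pfs_capping") <- list(n_cycles = sum(viol > 0),
                                  max_violation = max(viol))
  attr(tr, "cycle_days") <- cycle_days
  class(tr) <- c("psm_trace", "data.frame")
  tr
}

## effective per-cycle drug prices given the sampled body-surface area:
## published chemo prices are per cycle at the reference BSA
chemo_price <- function(p, settings) {
  scale <- p[["bsa"]] / settings$bsa_reference
  c(carboplatin = p[["cost_carboplatin"]] * scale,
    cisplatin = p[["cost_cisplatin"]] * scale,
    paclitaxel = p[["cost_paclitaxel"]] * scale)
}

#' Per-cycle cost components of a trace
#'
#' Progression-free occupancy accrues the first-line drugs (bevacizumab,
#' plus atezolizumab in the ABC arm), first-line chemotherapy
#' (paclitaxel plus the cisplatin/carboplatin average) and infusion fees up
#' to the chemotherapy cap, and follow-up visits. Progressed occupancy
#' accrues the second-line mix (pembrolizumab/cemiplimab average for the ICI
#' fraction, paclitaxel/carboplatin average for the chemotherapy fraction,
#' infusion for the treated fractions, supportive care for the
#' best-supportive-care fraction) and follow-up. Imaging, biomarker and
#' routine checkup recur on the monitoring schedule while alive. Hospice
#' accrues per cycle of death-state occupancy (default) or once per incident
#' death, per `hospice_accrual`.
#'
#' @param trace A [build_trace()] result (any subset of rows).
#' @param strategy A [strategy_config].
#' @param inputs An [economic_inputs].
#' @return Matrix (rows = cycles) of cost components in USD.
#' @export
cycle_costs <- function(trace, strategy, inputs) {
  p <- inputs$params
  st <- inputs$settings
  chemo <- chemo_price(p, st)
  first_line_drug <- p[["cost_bevacizumab"]] +
    if (strategy$arm == "ABC") p[["cost_atezolizumab"]] else 0
  chemo1 <- chemo[["paclitaxel"]] +
    (chemo[["cisplatin"]] + chemo[["carboplatin"]]) / 2
  mix <- strategy$second_line_mix
  pd_cycle <- mix[["ici"]] * (p[["cost_pembrolizumab"]] +
                                p[["cost_cemiplimab"]]) / 2 +
    mix[["chemo"]] * (chemo[["paclitaxel"]] + chemo[["carboplatin"]]) / 2 +
    (mix[["ici"]] + mix[["chemo"]]) * p[["cost_infusion"]] +
    mix[["bsc"]] * p[["cost_supportive"]]
  on_chemo <- trace$cycle <= st$chemo_max_cycles
  monitored <- trace$cycle %% st$monitoring_interval == 0
  alive <- trace$pfs + trace$pd
  hospice <- if (st$hospice_accrual == "per_cycle")
    trace$dead * p[["cost_hospice"]]
  else trace$new_deaths * p[["cost_hospice"]]
  cbind(
    first_line = trace$pfs * first_line_drug,
    chemo = trace$pfs * ifelse(on_chemo, chemo1, 0),
    admin = trace$pfs * ifelse(on_chemo, p[["cost_infusion"]], 0),
    second_line = trace$pd * pd_cycle,
    followup = alive * p[["cost_followup"]],
    monitoring = alive * ifelse(monitored,
                                p[["cost_ct_mri"]] + p[["cost_biomarker"]] +
                                  p[["cost_checkup"]], 0),
    hospice = hospice)
}

#' One-time effects applied at model entry
#'
#' Entry cost: incidence-weighted adverse-event management costs plus the
#' DNA test. Entry QALY decrement: incidence-weighted adverse-event
#' disutilities applied for `ae_disutility_cycles` cycles. Only grade >= 3
#' adverse events with incidence >= 5% are in the published table; asthenia
#' carries no published cost and contributes 0 to the entry cost.
#'
#' @inheritParams cycle_costs
#' @return List with `cost` (USD) and `qaly_decrement` (QALY, >= 0).
#' @export
entry_effects <- function(strategy, inputs) {
  p <- inputs$params
  pre <- if (strategy$arm == "ABC") "risk_abc_" else "risk_bc_"
  risks <- p[paste0(pre, AE_LABELS)]
  costs <- p[paste0("cost_ae_", AE_LABELS)]
  dis <- p[paste0("disutil_", AE_LABELS)]
  dur_years <- inputs$settings$ae_disutility_cycles *
    inputs$settings$cycle_days / 365.25
  list(cost = sum(risks * costs) + p[["cost_dna_test"]],
       qaly_decrement = sum(risks * abs(dis)) * dur_years)
}

#' Accumulate discounted cost and QALYs for one arm
#'
#' Discounted cost = entry cost + sum over cycles of the discounted cost
#' components; discounted QALYs = occupancy-weighted utilities times the
#' cycle length in years, discounted at cycle midpoints, minus the entry
#' disutility decrement.
#'
#' @inheritParams cycle_costs
#' @return List of class `cea_fragment`: `arm`, `cost`, `qaly`,
#'   `components` (named cost breakdown incl. entry items).
#' @export
accumulate_outcomes <- function(trace, strategy, inputs) {
  p <- inputs$params
  cc <- cycle_costs(trace, strategy, inputs)
  disc_comp <- colSums(cc * trace$disc)
  entry <- entry_effects(strategy, inputs)
  cycle_years <- attr(trace, "cycle_days") / 365.25
  qaly <- sum(trace$disc * (trace$pfs * p[["utility_pfs"]] +
                              trace$pd * p[["utility_pd"]])) * cycle_years -
    entry$qaly_decrement
  comps <- c(disc_comp, ae_entry = entry$cost - p[["cost_dna_test"]],
             dna_test = p[["cost_dna_test"]])
  structure(list(arm = strategy$arm, cost = sum(comps), qaly = qaly,
                 components = comps),
            class = "cea_fragment")
}

#' Incremental cost-effectiveness of two arm results
#'
#' @param intervention,comparator `cea_fragment`s on the same horizon.
#' @param wtp Willingness-to-pay threshold used for the net-monetary-benefit
#'   summary.
#' @return List of class `cea_result`: per-arm costs and QALYs, increments,
#'   `icer` (NA when flagged), `dominance` (`"dominant"`, `"dominated"`,
#'   `"undefined"` or `NA`), `nmb` and `cost_effective`.
#' @export
compute_icer <- function(intervention, comparator, wtp = 150000) {
  d_cost <- intervention$cost - comparator$cost
  d_qaly <- intervention$qaly - comparator$qaly
  dominance <- NA_character_
  icer <- NA_real_
  if (d_qaly == 0) {
    dominance <- "undefined"
  } else if (d_cost < 0 && d_qaly > 0) {
    dominance <- "dominant"
  } else if (d_cost > 0 && d_qaly < 0) {
    dominance <- "dominated"
  } else {
    icer <- d_cost / d_qaly
  }
  nmb <- wtp * d_qaly - d_cost
  structure(list(intervention = intervention, comparator = comparator,
                 delta_cost = d_cost, delta_qaly = d_qaly, icer = icer,
                 dominance = dominance, wtp = wtp, nmb = nmb,
                 cost_effective = nmb > 0),
            class = "cea_result")
}

#' @export
print.cea_result <- function(x, ...) {
  cat(sprintf("<cea_result> %s vs %s\n", x$intervention$arm,
              x$comparator$arm))
  cat(sprintf("  %s: cost %.2f, QALY %.4f\n", x$intervention$arm,
              x$intervention$cost, x$intervention$qaly))
  cat(sprintf("  %s: cost %.2f, QALY %.4f\n", x$comparator$arm,
              x$comparator$cost, x$comparator$qaly))
  cat(sprintf("  dCost %.2f, dQALY %.4f, ICER %s, NMB@%g %.0f\n",
              x$delta_cost, x$delta_qaly,
              if (is.na(x$icer)) x$dominance else sprintf("%.2f", x$icer),
              x$wtp, x$nmb))
  invisible(x)
}

#' Run the full two-arm comparison
#'
#' Builds both arms' traces from their survival models, accumulates
#' discounted costs and QALYs and returns the incremental result.
#' Deterministic: identical inputs give identical output.
#'
#' @param inputs An [economic_inputs]; its `horizon_years` setting is used
#'   unless overridden.
#' @param intervention,comparator [strategy_config]s.
#' @param horizon_years Optional override of the horizon.
#' @return A `cea_result`.
#' @export
run_comparison <- function(inputs, intervention, comparator,
                           horizon_years = NULL) {
  h <- horizon_years %||% inputs$settings$horizon_years
  frag <- function(strat) {
    tr <- build_trace(strat$os_model, strat$pfs_model, h,
                      cycle_days = inputs$settings$cycle_days,
                      discount_rate = inputs$params[["discount_rate"]])
    accumulate_outcomes(tr, strat, inputs)
  }
  compute_icer(frag(intervention), frag(comparator),
               wtp = inputs$settings$wtp)
}

#' Apply a scenario transformation to economic inputs
#'
#' Pure transformation: price multipliers by canonical parameter name and/or
#' a horizon override; the original object is untouched.
#'
#' @param inputs An [economic_inputs].
#' @param multipliers Named numeric vector of positive multipliers, e.g.
#'   `c(cost_atezolizumab = 0.9)`.
#' @param horizon_years Optional horizon override.
#' @return A modified copy of `inputs`.
#' @export
apply_scenario <- function(inputs, multipliers = NULL, horizon_years = NULL) {
  out <- inputs
  if (!is.null(multipliers)) {
    unknown <- setdiff(names(multipliers), names(out$params))
    if (length(unknown))
      stop("unknown parameter(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    if (any(multipliers <= 0))
      stop("multipliers must be positive", call. = FALSE)
    out$params[names(multipliers)] <-
      out$params[names(multipliers)] * multipliers
  }
  if (!is.null(horizon_years)) out$settings$horizon_years <- horizon_years
  out
}
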