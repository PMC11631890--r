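## Synthetic trial data with known ground truth: simulated per-arm IPD from
## specified survival laws, and Kaplan-Meier fixtures emulating digitized
## figures with periodic numbers-at-risk.

#' Specification of a simulated two-endpoint trial arm
#'
#' Death and latent progression times are drawn independently from the two
#' laws; overall survival is the death time and progression-free survival is
#' `min(progression, death)`, so PFS <= OS holds for every subject.
#' Administrative censoring mimics staggered accrual with a common data
#' cut-off: entry is uniform over `[0, accrual_months]` and follow-up ends at
#' `followup_months` after the accrual start, so censoring times are uniform
#' on `[followup_months - accrual_months, followup_months]`. Defaults mirror
#' a 1:1 phase-III arm (n = 206) observed over ~4.5 years.
#'
#' @param os_model,progression_model [surv_model]s generating death and
#'   latent progression times (months).
#' @param n Subjects in the arm.
#' @param accrual_months,followup_months Censoring window (see above);
#'   `accrual_months = 0` gives fixed censoring at `followup_months`;
#'   `followup_months = Inf` disables censoring.
#' @param arm Label.
#' @return Object of class `trial_sim_spec`.
#' @export
trial_sim_spec <- function(os_model, progression_model, n = 206,
                           accrual_months = 12, followup_months = 54,
                           arm = "arm") {
  stopifnot(inherits(os_model, "surv_model"),
            inherits(progression_model, "surv_model"),
            n >= 1, accrual_months >= 0,
            followup_months >= accrual_months || is.infinite(followup_months))
  structure(list(os_model = os_model, progression_model = progression_model,
                 n = as.integer(n), accrual_months = accrual_months,
                 followup_months = followup_months, arm = arm),
            class = "trial_sim_spec")
}

## inverse-transform sampling from any surv_model via root search on S(t)=u
sample_surv_times <- function(model, n, upper = 5000) {
  u <- stats::runif(n)
  vapply(u, function(ui) {
    if (surv_prob(model, upper) > ui) return(upper)
    stats::uniroot(function(t) surv_prob(model, t) - ui,
                   c(1e-10, upper), tol = 1e-8)$root
  }, numeric(1))
}

#' Simulate per-arm pseudo-IPD for both endpoints
#'
#' @param spec A [trial_sim_spec].
#' @param seed RNG seed (simulations are reproducible given the seed).
#' @return List with elements `os` and `pfs`, each a [pseudo_ipd].
#' @export
simulate_ipd <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "trial_sim_spec"))
  set.seed(seed)
  death <- sample_surv_times(spec$os_model, spec$n)
  prog <- sample_surv_times(spec$progression_model, spec$n)
  pfs <- pmin(prog, death)
  cens <- if (is.infinite(spec$followup_months)) rep(Inf, spec$n)
          else spec$followup_months - stats::runif(spec$n, 0, spec$accrual_months)
  os_time <- pmin(death, cens)
  pfs_time <- pmin(pfs, cens)
  list(os = pseudo_ipd(os_time, as.integer(death <= cens),
                       arm = spec$arm, endpoint = "OS"),
       pfs = pseudo_ipd(pfs_time, as.integer(pfs <= cens),
                        arm = spec$arm, endpoint = "PFS"))
}

#' Generate a digitized-curve fixture from simulated records
#'
#' Evaluates the Kaplan-Meier estimator on a regular grid, optionally
#' perturbs it with uniform pixel noise (re-monotonized), and tabulates
#' numbers at risk at regular intervals - emulating coordinates digitized
#' from a published figure.
#'
#' @param ipd A [pseudo_ipd].
#' @param grid_step Curve sampling step (months).
#' @param risk_interval Spacing of the numbers-at-risk table (months).
#' @param noise_eps Half-width of the uniform digitization noise on the
#'   survival scale (0 for exact values).
#' @param seed RNG seed for the noise.
#' @return A [digitized_curve].
#' @export
generate_km_fixture <- function(ipd, grid_step = 1, risk_interval = 6,
                                noise_eps = 0.005, seed = 1) {
  stopifnot(nrow(ipd) > 0)
  tmax <- max(ipd$time)
  grid <- seq(0, tmax, by = grid_step)
  if (grid[length(grid)] < tmax) grid <- c(grid, tmax)
  s <- km_estimate(ipd, grid)
  if (noise_eps > 0) {
    set.seed(seed)
    s <- pmin(pmax(s + stats::runif(length(s), -noise_eps, noise_eps), 0), 1)
    s[1] <- 1
  }
  rt <- seq(0, tmax, by = risk_interval)
  nr <- vapply(rt, function(t0) sum(ipd$time >= t0), integer(1))
  digitized_curve(grid, s, rt, nr,
                  arm = attr(ipd, "arm"), endpoint = attr(ipd, "endpoint"))
}

#' Simulate a two-arm trial emulating the published study conditions
#'
#' Overall survival follows the published log-logistic laws; latent
#' progression follows the base-case progression-free laws, median-matched
#' to the published 13.7 (ABC) and 10.4 (BC) months.
#'
#' @param n Per-arm sample size.
#' @param seed RNG seed (arms use `seed` and `seed + 1`).
#' @param accrual_months,followup_months Censoring window.
#' @return Named list (`ABC`, `BC`) of [simulate_ipd()] results.
#' @export
simulate_reference_trial <- function(n = 206, seed = 1, accrual_months = 12,
                                     followup_months = 54) {
  models <- base_case_models()
  out <- list()
  seeds <- c(ABC = seed, BC = seed + 1)
  for (arm in c("ABC", "BC")) {
    spec <- trial_sim_spec(models[[arm]]$os, models[[arm]]$pfs, n = n,
                           accrual_months = accrual_months,
                           followup_months = followup_months, arm = arm)
    out[[arm]] <- simulate_ipd(spec, seed = seeds[[arm]])
  }
  out
}
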