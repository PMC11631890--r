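## Maximum-likelihood fitting of the candidate survival laws on pseudo-IPD
## and AIC/BIC model selection.

FLEXSURV_DISTS <- c(exponential = "exp", weibull = "weibull",
                    lognormal = "lnorm", loglogistic = "llogis",
                    gamma = "gamma", gengamma = "gengamma",
                    gompertz = "gompertz")

TRADITIONAL_FAMILIES <- names(FLEXSURV_DISTS)

as_surv_formula <- function(ipd) {
  stopifnot(is.data.frame(ipd), all(c("time", "event") %in% names(ipd)))
  survival::Surv(ipd$time, ipd$event) ~ 1
}

#' Fit a traditional parametric survival family by maximum likelihood
#'
#' Fits one of the seven traditional families (exponential, Weibull,
#' log-normal, log-logistic, gamma, generalized gamma, Gompertz) to
#' (time, event) records. Fitting is delegated to
#' [flexsurv::flexsurvreg()]; parameters are re-expressed in this package's
#' conventions. Non-convergence or optimizer failure returns a flagged
#' [surv_model] with `convergence = FALSE` and a diagnostic message rather
#' than an error.
#'
#' @param ipd A [pseudo_ipd] (data frame with `time` and `event`) containing
#'   at least two events.
#' @param family Family label.
#' @param ... Passed to [flexsurv::flexsurvreg()] (e.g. optimizer control).
#' @return A [surv_model].
#' @export
fit_parametric <- function(ipd, family, ...) {
  family <- match.arg(family, TRADITIONAL_FAMILIES)
  if (sum(ipd$event) < 2)
    return(surv_model(family,
                      failed_params(family), loglik = NA_real_,
                      n_obs = nrow(ipd), convergence = FALSE,
                      diagnostic = "fewer than 2 events: fit under-determined"))
  fit <- tryCatch(
    flexsurv::flexsurvreg(as_surv_formula(ipd), data = ipd,
                          dist = FLEXSURV_DISTS[[family]], ...),
    error = function(e) e)
  if (inherits(fit, "error"))
    return(surv_model(family, failed_params(family), loglik = NA_real_,
                      n_obs = nrow(ipd), convergence = FALSE,
                      diagnostic = conditionMessage(fit)))
  params <- extract_params(family, fit)
  surv_model(family, params, loglik = as.numeric(stats::logLik(fit)),
             n_obs = fit$N,
             convergence = is.null(fit$opt$convergence) ||
               fit$opt$convergence == 0)
}

failed_params <- function(family) {
  nm <- switch(family,
               exponential = "rate",
               weibull = , loglogistic = c("shape", "scale"),
               lognormal = c("meanlog", "sdlog"),
               gamma = , gompertz = c("shape", "rate"),
               gengamma = c("mu", "sigma", "Q"))
  stats::setNames(rep(NA_real_, length(nm)), nm)
}

extract_params <- function(family, fit) {
  est <- stats::setNames(fit$res[, "est"], rownames(fit$res))
  switch(family,
         exponential = c(rate = unname(est["rate"])),
         weibull = c(shape = unname(est["shape"]),
                     scale = unname(est["scale"])),
         lognormal = c(meanlog = unname(est["meanlog"]),
                       sdlog = unname(est["sdlog"])),
         loglogistic = c(shape = unname(est["shape"]),
                         scale = unname(est["scale"])),
         gamma = c(shape = unname(est["shape"]), rate = unname(est["rate"])),
         gengamma = c(mu = unname(est["mu"]), sigma = unname(est["sigma"]),
                      Q = unname(est["Q"])),
         gompertz = c(shape = unname(est["shape"]),
                      rate = unname(est["rate"])))
}

#' Fit a Royston-Parmar spline survival model
#'
#' Flexible parametric fit on the log-cumulative-hazard, log-odds or probit
#' scale with 1-3 interior knots, via [flexsurv::flexsurvspline()]. Knots
#' default to [default_knots()] placement (flexsurv's own rule, equally
#' spaced quantiles of uncensored log event times) and are always stored
#' with the fitted object.
#'
#' @inheritParams fit_parametric
#' @param interior_knots 1, 2 or 3.
#' @param scale_kind `"hazard"`, `"odds"` or `"normal"`.
#' @param knots Optional explicit interior knots on log-time.
#' @param ... Passed to [flexsurv::flexsurvspline()].
#' @return A [surv_model] of family `rp_spline` with `gamma0..gammaM`.
#' @export
fit_rp_spline <- function(ipd, interior_knots, scale_kind = "hazard",
                          knots = NULL, ...) {
  scale_kind <- match.arg(scale_kind, c("hazard", "odds", "normal"))
  stopifnot(interior_knots %in% 0:3)
  if (sum(ipd$event) < interior_knots + 2)
    return(surv_model("rp_spline",
                      stats::setNames(rep(NA_real_, interior_knots + 2),
                                      paste0("gamma", 0:(interior_knots + 1))),
                      knots = seq(0, 1, length.out = max(interior_knots + 2, 2)),
                      scale_kind = scale_kind, n_obs = nrow(ipd),
                      convergence = FALSE,
                      diagnostic = "too few events to identify the spline"))
  args <- list(formula = as_surv_formula(ipd), data = ipd,
               scale = switch(scale_kind, hazard = "hazard", odds = "odds",
                              normal = "normal"), ...)
  if (!is.null(knots)) args$knots <- knots else args$k <- interior_knots
  fit <- tryCatch(do.call(flexsurv::flexsurvspline, args),
                  error = function(e) e)
  if (inherits(fit, "error"))
    return(surv_model("rp_spline",
                      stats::setNames(rep(NA_real_, interior_knots + 2),
                                      paste0("gamma", 0:(interior_knots + 1))),
                      knots = seq(0, 1, length.out = interior_knots + 2),
                      scale_kind = scale_kind, n_obs = nrow(ipd),
                      convergence = FALSE, diagnostic = conditionMessage(fit)))
  gammas <- fit$res[, "est"]
  surv_model("rp_spline",
             stats::setNames(unname(gammas),
                             paste0("gamma", seq_along(gammas) - 1)),
             knots = fit$knots, scale_kind = scale_kind,
             loglik = as.numeric(stats::logLik(fit)), n_obs = fit$N,
             convergence = is.null(fit$opt$convergence) ||
               fit$opt$convergence == 0)
}

#' Fit a restricted cubic spline survival model
#'
#' The restricted-cubic-spline candidates with 3 or 4 total knots are the
#' hazard-scale spline with 1 or 2 interior knots.
#'
#' @inheritParams fit_parametric
#' @param total_knots 3 or 4.
#' @return A [surv_model] of family `rcs`.
#' @export
fit_rcs <- function(ipd, total_knots) {
  stopifnot(total_knots %in% c(3, 4))
  m <- fit_rp_spline(ipd, total_knots - 2L, "hazard")
  m$family <- "rcs"
  m
}

#' Fit a piecewise exponential model (closed-form MLE)
#'
#' The hazard on each interval between `cutpoints` is events divided by
#' person-time in the interval.
#'
#' @inheritParams fit_parametric
#' @param cutpoints Increasing interval cut points (months). Every interval
#'   must contain at least one event.
#' @return A [surv_model] of family `piecewise_exp`.
#' @export
fit_piecewise_exponential <- function(ipd, cutpoints = numeric(0)) {
  if (is.unsorted(cutpoints, strictly = TRUE) && length(cutpoints) > 1)
    stop("`cutpoints` must be strictly increasing", call. = FALSE)
  bounds <- c(0, cutpoints, Inf)
  k <- length(bounds) - 1L
  events <- persontime <- numeric(k)
  for (i in seq_len(k)) {
    lo <- bounds[i]; hi <- bounds[i + 1]
    persontime[i] <- sum(pmax(pmin(ipd$time, hi) - lo, 0))
    events[i] <- sum(ipd$event == 1 & ipd$time > lo & ipd$time <= hi)
  }
  ## events at exactly t = 0 would be lost by the (lo, hi] rule; disallow
  if (any(events == 0)) {
    i <- which(events == 0)[1]
    stop(sprintf("interval %d (%.3g, %.3g] contains no events",
                 i, bounds[i], bounds[i + 1]), call. = FALSE)
  }
  rates <- events / persontime
  ll <- sum(events * log(rates)) - sum(rates * persontime)
  surv_model("piecewise_exp",
             stats::setNames(rates, paste0("rate", seq_len(k))),
             cutpoints = cutpoints, loglik = ll, n_obs = nrow(ipd))
}

FP_POWERS <- c(-2, -1, -0.5, 0, 0.5, 1, 2, 3)

fp_power_sets <- function(degree) {
  if (degree == 1) return(lapply(FP_POWERS, function(p) p))
  out <- list()
  for (i in seq_along(FP_POWERS)) for (j in i:length(FP_POWERS))
    out[[length(out) + 1L]] <- c(FP_POWERS[i], FP_POWERS[j])
  out
}

fp_negloglik <- function(betas, t, d, powers) {
  lh <- fp_log_hazard(t, betas, powers)
  H <- fp_cumhaz(t, betas, powers)
  ll <- sum(d * lh) - sum(H)
  if (!is.finite(ll)) return(1e10)
  -ll
}

#' Fit a fractional-polynomial hazard model
#'
#' The log hazard is a fractional polynomial of time over the conventional
#' power set \{-2, -1, -0.5, 0, 0.5, 1, 2, 3\} (power 0 meaning `ln t`,
#' repeated powers contributing an extra `ln t` factor). All candidate power
#' combinations (8 for degree 1; 36 for degree 2) are fitted by maximum
#' likelihood with numerically integrated cumulative hazard, and the best by
#' likelihood is returned.
#'
#' @inheritParams fit_parametric
#' @param degree 1 or 2.
#' @return A [surv_model] of family `fracpoly` with the selected `powers`.
#' @export
fit_fractional_polynomial <- function(ipd, degree = 1) {
  stopifnot(degree %in% c(1, 2))
  if (sum(ipd$event) < 2)
    return(surv_model("fracpoly", c(beta0 = NA_real_, beta1 = NA_real_),
                      powers = 1, n_obs = nrow(ipd), convergence = FALSE,
                      diagnostic = "fewer than 2 events"))
  t <- ipd$time; d <- ipd$event
  best <- NULL
  for (powers in fp_power_sets(degree)) {
    init <- c(log(sum(d) / sum(t)), rep(0, length(powers)))
    opt <- tryCatch(
      stats::optim(init, fp_negloglik, t = t, d = d, powers = powers,
                   method = "BFGS", control = list(maxit = 500)),
      error = function(e) NULL)
    if (is.null(opt) || !is.finite(opt$value)) next
    if (is.null(best) || opt$value < best$value)
      best <- list(value = opt$value, par = opt$par, powers = powers,
                   conv = opt$convergence == 0)
  }
  if (is.null(best))
    return(surv_model("fracpoly", c(beta0 = NA_real_, beta1 = NA_real_),
                      powers = 1, n_obs = nrow(ipd), convergence = FALSE,
                      diagnostic = "no candidate power set converged"))
  surv_model("fracpoly",
             stats::setNames(best$par, paste0("beta",
                                              seq_along(best$par) - 1)),
             powers = best$powers, loglik = -best$value, n_obs = nrow(ipd),
             convergence = best$conv)
}

#' Akaike and Bayesian information criteria
#'
#' `AIC = -2 loglik + 2 k`; `BIC = -2 loglik + k log(n)`.
#'
#' @param model A fitted [surv_model] with `loglik`, `n_params` and `n_obs`.
#' @return Named numeric vector `c(AIC, BIC)`.
#' @export
information_criteria <- function(model) {
  stopifnot(inherits(model, "surv_model"))
  if (is.na(model$loglik) || is.na(model$n_obs))
    stop("model has no log-likelihood or sample size", call. = FALSE)
  c(AIC = -2 * model$loglik + 2 * model$n_params,
    BIC = -2 * model$loglik + model$n_params * log(model$n_obs))
}

#' Select the best-fitting survival model by information criterion
#'
#' Deterministic ranking: the winner minimizes the chosen criterion, ties
#' broken by fewer parameters, then by candidate order.
#'
#' @param candidates Named (or unnamed) list of fitted [surv_model]s.
#' @param criterion `"AIC"` or `"BIC"`.
#' @return A `model_selection_report`: data frame of label/AIC/BIC/rank plus
#'   attributes `selected` (label) and `selected_model`.
#' @export
select_best_model <- function(candidates, criterion = c("AIC", "BIC")) {
  criterion <- match.arg(criterion)
  if (length(candidates) == 0)
    stop("empty candidate list", call. = FALSE)
  labels <- names(candidates)
  if (is.null(labels))
    labels <- vapply(candidates, function(m) m$family, character(1))
  ok <- vapply(candidates, function(m) isTRUE(m$convergence) &&
                 is.finite(m$loglik), logical(1))
  ic <- t(vapply(candidates, function(m)
    if (isTRUE(m$convergence) && is.finite(m$loglik))
      information_criteria(m) else c(AIC = Inf, BIC = Inf),
    numeric(2)))
  k <- vapply(candidates, function(m) m$n_params, numeric(1))
  ord <- order(ic[, criterion], k, seq_along(candidates))
  report <- data.frame(label = labels, family = vapply(candidates,
                         function(m) m$family, character(1)),
                       n_params = k, loglik = vapply(candidates,
                         function(m) m$loglik, numeric(1)),
                       AIC = ic[, "AIC"], BIC = ic[, "BIC"],
                       converged = ok, row.names = NULL)
  report$rank <- match(seq_len(nrow(report)), ord)
  attr(report, "criterion") <- criterion
  attr(report, "selected") <- labels[ord[1]]
  attr(report, "selected_model") <- candidates[[ord[1]]]
  class(report) <- c("model_selection_report", "data.frame")
  report
}

#' @export
print.model_selection_report <- function(x, ...) {
  cat("Model selection by", attr(x, "criterion"), "- selected:",
      attr(x, "selected"), "\n")
  print.data.frame(x[order(x$rank), ], row.names = FALSE, digits = 6)
  invisible(x)
}

#' Fit the full candidate set used for curve extrapolation
#'
#' Seven traditional families plus the flexible candidates: Royston-Parmar
#' splines (hazard/odds/normal scales, 1-3 interior knots as requested),
#' restricted cubic splines (3 and 4 total knots), fractional polynomials of
#' degree 1 and 2, and a piecewise exponential (cut points at the tertiles
#' of event times unless supplied).
#'
#' @inheritParams fit_parametric
#' @param flexible Include the flexible candidates.
#' @param rp_knots Interior-knot counts for the spline candidates.
#' @param rp_scales Spline scales to include.
#' @param pw_cutpoints Piecewise-exponential cut points (months).
#' @return Named list of [surv_model]s.
#' @export
fit_candidate_set <- function(ipd, flexible = TRUE, rp_knots = 1:3,
                              rp_scales = c("hazard", "odds", "normal"),
                              pw_cutpoints = NULL) {
  out <- list()
  for (fam in TRADITIONAL_FAMILIES) out[[fam]] <- fit_parametric(ipd, fam)
  if (flexible) {
    for (sc in rp_scales) for (k in rp_knots)
      out[[sprintf("rp_%s%d", sc, k)]] <- fit_rp_spline(ipd, k, sc)
    for (tk in c(3, 4))
      out[[sprintf("rcs%d", tk)]] <- fit_rcs(ipd, tk)
    for (dg in c(1, 2))
      out[[sprintf("fp%d", dg)]] <- fit_fractional_polynomial(ipd, dg)
    if (is.null(pw_cutpoints))
      pw_cutpoints <- unname(stats::quantile(ipd$time[ipd$event == 1],
                                             c(1, 2) / 3))
    out[["piecewise_exp"]] <- tryCatch(
      fit_piecewise_exponential(ipd, pw_cutpoints),
      error = function(e) surv_model("piecewise_exp", c(rate1 = NA_real_),
                                     cutpoints = numeric(0),
                                     n_obs = nrow(ipd), convergence = FALSE,
                                     diagnostic = conditionMessage(e)))
  }
  out
}
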