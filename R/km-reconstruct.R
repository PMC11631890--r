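## Reconstruction of pseudo individual-patient data from digitized
## Kaplan-Meier coordinates plus numbers-at-risk (the Guyot algorithm), and
## the product-limit utilities used to validate it.

#' Digitized Kaplan-Meier curve with numbers at risk
#'
#' @param times,surv Digitized step coordinates: times in months (the first
#'   must be 0 with survival 1) and survival probabilities in `[0, 1]`.
#'   Pixel-level noise is tolerated: survival is re-monotonized by running
#'   minimum before use.
#' @param risk_times,n_risk Numbers-at-risk table; counts must be
#'   non-increasing. `n_risk[1]` is the initial cohort size.
#' @param arm,endpoint Labels (e.g. `"ABC"`, `"PFS"`).
#' @return Object of class `digitized_curve`.
#' @export
digitized_curve <- function(times, surv, risk_times, n_risk,
                            arm = "arm", endpoint = "endpoint") {
  stopifnot(length(times) == length(surv), length(risk_times) == length(n_risk))
  if (is.unsorted(times)) stop("`times` must be non-decreasing", call. = FALSE)
  if (any(surv < -1e-9) || any(surv > 1 + 1e-9))
    stop("survival values outside [0, 1]", call. = FALSE)
  if (times[1] != 0 || abs(surv[1] - 1) > 1e-6)
    stop("first coordinate must be S(0) = 1", call. = FALSE)
  if (any(diff(n_risk) > 0))
    stop("numbers at risk must be non-increasing", call. = FALSE)
  if (is.unsorted(risk_times, strictly = TRUE))
    stop("`risk_times` must be strictly increasing", call. = FALSE)
  remono <- cummin(pmin(pmax(surv, 0), 1))
  structure(list(times = as.numeric(times), surv = as.numeric(remono),
                 surv_raw = as.numeric(surv),
                 risk_times = as.numeric(risk_times),
                 n_risk = as.integer(n_risk),
                 n0 = as.integer(n_risk[1]), arm = arm, endpoint = endpoint),
            class = "digitized_curve")
}

#' @export
print.digitized_curve <- function(x, ...) {
  cat(sprintf("<digitized_curve> %s / %s: %d coordinates over %.1f months, n0 = %d, %d risk entries\n",
              x$arm, x$endpoint, length(x$times), max(x$times), x$n0,
              length(x$risk_times)))
  invisible(x)
}

#' Pseudo individual-patient data
#'
#' @param time,event Event/censoring times (months, positive) and status
#'   indicators (1 = event, 0 = censored).
#' @param arm,endpoint Labels.
#' @return A data frame of class `pseudo_ipd`.
#' @export
pseudo_ipd <- function(time, event, arm = "arm", endpoint = "endpoint") {
  stopifnot(length(time) == length(event), all(event %in% c(0, 1)),
            all(time >= 0))
  structure(data.frame(time = as.numeric(time), event = as.integer(event)),
            arm = arm, endpoint = endpoint,
            class = c("pseudo_ipd", "data.frame"))
}

#' Reconstruct pseudo-IPD from a digitized curve (Guyot algorithm)
#'
#' Within each half-open interval between consecutive numbers-at-risk times,
#' the numbers of events and censorings are solved iteratively so that the
#' product-limit estimator of the output tracks the digitized survival steps
#' and the implied number at risk matches the next published count.
#' Censoring times are spread uniformly within each interval. Beyond the last
#' risk-table entry no censoring is assumed before the last digitized event;
#' subjects still at risk at the end of follow-up are censored there. The
#' algorithm contains no randomness: reconstruction is deterministic.
#'
#' @param curve A [digitized_curve] with at least two risk-table entries
#'   (a single entry triggers the no-censoring fallback, flagged in the
#'   attribute `fallback`).
#' @return A [pseudo_ipd] with attribute `n0` (initial cohort size).
#' @export
reconstruct_ipd <- function(curve) {
  stopifnot(inherits(curve, "digitized_curve"))
  tt <- curve$times
  SS <- curve$surv
  rt <- curve$risk_times
  nr <- curve$n_risk
  fallback <- length(rt) < 2
  K <- length(rt)
  ## a digitized value at a risk-table time reflects the events up to and
  ## including that time, while the published count refers to survivors past
  ## it, so coordinates are grouped into half-open intervals (rt_k, rt_{k+1}]
  interval_of <- findInterval(tt, rt, left.open = TRUE)
  interval_of[interval_of == 0] <- 1L
  n_hat <- nr[1]
  km_prev <- 1
  ev_time <- ev_n <- numeric(0)
  cen_time <- numeric(0)
  last_t <- max(tt)
  for (k in seq_len(K)) {
    idx <- which(interval_of == k & tt > 0)
    t_lo <- if (k == 1) 0 else rt[k]
    t_hi <- if (k < K) rt[k + 1] else max(last_t, rt[K])
    n_target <- if (k < K) nr[k + 1] else NA_integer_
    if (!is.na(n_target) && n_target > n_hat)
      stop(sprintf("risk table infeasible in interval %d: %d at risk after %d",
                   k, n_target, n_hat), call. = FALSE)
    ## initial censoring guess: the at-risk drop not explained by the
    ## digitized survival ratio across the interval
    cen_guess <- 0L
    if (!is.na(n_target)) {
      s_lo <- SS[max(which(tt <= t_lo))]
      s_hi <- SS[max(which(tt < t_hi))]
      d_implied <- if (s_lo > 0) round(n_hat * (1 - s_hi / s_lo)) else 0
      cen_guess <- max(0L, min(n_hat, n_hat - n_target - d_implied))
    }
    best <- NULL
    tried <- integer(0)
    repeat {
      res <- sweep_interval(idx, tt, SS, km_prev, n_hat, cen_guess,
                            t_lo, t_hi)
      if (is.na(n_target)) { best <- res; break }
      gap <- res$n_end - n_target
      if (is.null(best) || abs(gap) < abs(best$n_end - n_target)) best <- res
      if (gap == 0L) break
      tried <- c(tried, cen_guess)
      cen_next <- max(0L, min(n_hat, cen_guess + gap))
      if (cen_next %in% tried) break
      cen_guess <- cen_next
    }
    if (!is.na(n_target)) {
      resid <- best$n_end - n_target
      if (resid > 0) {
        ## absorb rounding mismatch as censorings at the interval end
        best$cen_time <- c(best$cen_time, rep(t_hi * (1 - 1e-9), resid))
        best$n_end <- n_target
      } else if (resid < 0) {
        ## digitization noise implied slightly more events than the risk
        ## table permits: take the excess back from the interval's latest
        ## events, within a small budget - larger gaps mean the curve and
        ## table genuinely disagree
        need <- -resid
        if (need > max(2, ceiling(0.02 * n_hat)))
          stop(sprintf(
            "reconstruction infeasible in interval %d: implied censoring negative",
            k), call. = FALSE)
        i <- length(best$ev_n)
        while (need > 0 && i >= 1) {
          take <- min(best$ev_n[i], need)
          best$ev_n[i] <- best$ev_n[i] - take
          need <- need - take
          i <- i - 1
        }
        if (need > 0)
          stop(sprintf(
            "reconstruction infeasible in interval %d: implied censoring negative",
            k), call. = FALSE)
        keep <- best$ev_n > 0
        best$ev_time <- best$ev_time[keep]
        best$ev_n <- best$ev_n[keep]
        rp <- replay_interval(best$ev_time, best$ev_n, best$cen_time,
                              n_hat, km_prev)
        best$n_end <- rp$n_end
        best$km_end <- rp$km_end
      }
    }
    ev_time <- c(ev_time, best$ev_time)
    ev_n <- c(ev_n, best$ev_n)
    cen_time <- c(cen_time, best$cen_time)
    n_hat <- best$n_end
    km_prev <- best$km_end
  }
  times <- c(rep(ev_time, ev_n), cen_time, rep(last_t, n_hat))
  event <- c(rep(1L, sum(ev_n)), rep(0L, length(cen_time)), rep(0L, n_hat))
  ord <- order(times)
  out <- pseudo_ipd(times[ord], event[ord], curve$arm, curve$endpoint)
  attr(out, "n0") <- curve$n0
  attr(out, "fallback") <- fallback
  out
}

## recompute the risk set and product-limit value of an interval from fixed
## event counts and censoring times
replay_interval <- function(ev_time, ev_n, cen_times, n_start, km_prev) {
  n <- n_start
  km <- km_prev
  ci <- 0L
  ncen <- length(cen_times)
  for (i in seq_along(ev_time)) {
    while (ci < ncen && cen_times[ci + 1L] < ev_time[i] && n > 0L) {
      n <- n - 1L
      ci <- ci + 1L
    }
    d <- min(ev_n[i], n)
    if (d > 0L && n > 0L) {
      km <- km * (1 - d / n)
      n <- n - d
    }
  }
  n <- max(0L, n - (ncen - ci))
  list(n_end = n, km_end = km)
}

## one deterministic sweep of an interval given a censoring count:
## censorings are spread uniformly over the interval and removed from the
## risk set as the coordinates are traversed; events at each coordinate are
## chosen so the running product-limit estimate matches the digitized step
sweep_interval <- function(idx, tt, SS, km_prev, n_start, n_cen,
                           t_lo, t_hi) {
  cen_times <- if (n_cen > 0)
    t_lo + seq_len(n_cen) * (t_hi - t_lo) / (n_cen + 1) else numeric(0)
  n <- n_start
  km <- km_prev
  ev_time <- ev_n <- numeric(0)
  ci <- 0L   # censorings consumed so far
  for (i in idx) {
    ti <- tt[i]
    while (ci < n_cen && cen_times[ci + 1L] < ti && n > 0L) {
      n <- n - 1L
      ci <- ci + 1L
    }
    if (n <= 0L) break
    d <- if (km > 0) round(n * (1 - SS[i] / km)) else 0L
    d <- max(0L, min(d, n))
    if (d > 0L) {
      km <- km * (1 - d / n)
      ev_time <- c(ev_time, ti)
      ev_n <- c(ev_n, d)
      n <- n - d
    }
  }
  rem <- max(0L, min(n_cen - ci, n))
  n <- n - rem
  list(ev_time = ev_time, ev_n = ev_n,
       cen_time = cen_times[seq_len(ci + rem)], n_end = n, km_end = km)
}

#' Product-limit (Kaplan-Meier) estimate on a time grid
#'
#' Thin wrapper over [survival::survfit()], evaluated as a right-continuous
#' step function at the requested grid points.
#'
#' @param ipd A non-empty [pseudo_ipd].
#' @param grid Times (months) at which to evaluate the estimator.
#' @return Survival probabilities at `grid`.
#' @export
km_estimate <- function(ipd, grid) {
  stopifnot(nrow(ipd) > 0)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = ipd)
  s <- summary(fit, times = grid, extend = TRUE)
  s$surv
}

#' Fidelity of a reconstruction against its source curve
#'
#' Compares the product-limit estimate of the reconstructed records with the
#' digitized survival values at the digitized times.
#'
#' @param curve The source [digitized_curve].
#' @param ipd The reconstructed [pseudo_ipd] (same arm and endpoint).
#' @param threshold Flag reconstructions whose maximum absolute survival gap
#'   exceeds this value.
#' @return List with `max_gap`, `median_gap`, `flag` and the comparison grid.
#' @export
validate_reconstruction <- function(curve, ipd, threshold = 0.02) {
  stopifnot(inherits(curve, "digitized_curve"), inherits(ipd, "pseudo_ipd"))
  if (!identical(attr(ipd, "arm"), curve$arm) ||
      !identical(attr(ipd, "endpoint"), curve$endpoint))
    stop("arm/endpoint mismatch between curve and ipd", call. = FALSE)
  grid <- curve$times[curve$times <= max(ipd$time)]
  if (length(grid) == 0) stop("no overlapping time grid", call. = FALSE)
  s_hat <- km_estimate(ipd, grid)
  gap <- abs(s_hat - curve$surv[seq_along(grid)])
  list(max_gap = max(gap), median_gap = stats::median(gap),
       flag = max(gap) > threshold, grid = grid,
       threshold = threshold)
}

#' Read and write the digitized-curve CSV dialect
#'
#' Curve files have header `time_months,survival`; risk-table files have
#' header `time_months,n_risk`.
#'
#' @param curve_file,risk_file CSV paths.
#' @param arm,endpoint Labels attached to the result.
#' @return A [digitized_curve].
#' @export
read_digitized_curve <- function(curve_file, risk_file,
                                 arm = "arm", endpoint = "endpoint") {
  cu <- utils::read.csv(curve_file)
  if (!all(c("time_months", "survival") %in% names(cu)))
    stop("curve file must have columns time_months,survival", call. = FALSE)
  rk <- utils::read.csv(risk_file)
  if (!all(c("time_months", "n_risk") %in% names(rk)))
    stop("risk file must have columns time_months,n_risk", call. = FALSE)
  digitized_curve(cu$time_months, cu$survival, rk$time_months, rk$n_risk,
                  arm = arm, endpoint = endpoint)
}

#' @rdname read_digitized_curve
#' @param curve A [digitized_curve] to write.
#' @export
write_digitized_curve <- function(curve, curve_file, risk_file) {
  utils::write.csv(data.frame(time_months = curve$times,
                              survival = curve$surv_raw),
                   curve_file, row.names = FALSE)
  utils::write.csv(data.frame(time_months = curve$risk_times,
                              n_risk = curve$n_risk),
                   risk_file, row.names = FALSE)
  invisible(c(curve_file, risk_file))
}
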