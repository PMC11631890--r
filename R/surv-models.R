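#' @keywords internal
"_PACKAGE"

## Time conventions used throughout: survival time in months,
## 1 month = 30.4375 days, model cycle = 21 days.
DAYS_PER_MONTH <- 30.4375

#' Fitted survival model objects
#'
#' A `surv_model` bundles a survival law (parametric family, Royston-Parmar
#' spline, restricted cubic spline, fractional polynomial or piecewise
#' exponential) with its parameters and, where fitted from data, its
#' log-likelihood and sample size. All times are in months.
#'
#' @param family One of `"exponential"`, `"weibull"`, `"lognormal"`,
#'   `"loglogistic"`, `"gamma"`, `"gengamma"`, `"gompertz"`, `"rp_spline"`,
#'   `"rcs"`, `"fracpoly"`, `"piecewise_exp"`.
#' @param params Named numeric vector of parameters. Naming conventions:
#'   `rate` (exponential); `shape`,`scale` (weibull, loglogistic, gompertz
#'   where `scale` is the rate); `meanlog`,`sdlog` (lognormal);
#'   `shape`,`rate` (gamma); `mu`,`sigma`,`Q` (generalized gamma);
#'   `gamma0..gammaM` (splines); `beta0..betaD` (fractional polynomial);
#'   `rate1..rateK` (piecewise exponential).
#' @param knots For spline families, the full knot vector on log-time
#'   (boundary knots included), strictly increasing.
#' @param scale_kind For spline families, `"hazard"`, `"odds"` or `"normal"`.
#' @param powers For `fracpoly`, the fractional-polynomial powers.
#' @param cutpoints For `piecewise_exp`, interval cut points (months).
#' @param loglik,n_obs Log-likelihood and number of observations when fitted.
#' @param convergence Logical; `FALSE` flags a failed or suspect fit.
#' @param diagnostic Character diagnostic accompanying a failed fit.
#'
#' @return An object of class `surv_model`.
#' @export
surv_model <- function(family, params, knots = NULL, scale_kind = NULL,
                       powers = NULL, cutpoints = NULL,
                       loglik = NA_real_, n_obs = NA_integer_,
                       convergence = TRUE, diagnostic = NULL) {
  family <- match.arg(family, c("exponential", "weibull", "lognormal",
                                "loglogistic", "gamma", "gengamma",
                                "gompertz", "rp_spline", "rcs", "fracpoly",
                                "piecewise_exp"))
  params <- unlist(params)
  if (is.null(names(params)) || any(!nzchar(names(params))))
    stop("`params` must be a fully named numeric vector", call. = FALSE)
  if (family %in% c("rp_spline", "rcs")) {
    if (is.null(knots) || is.null(scale_kind))
      stop("spline models need `knots` and `scale_kind`", call. = FALSE)
    scale_kind <- match.arg(scale_kind, c("hazard", "odds", "normal"))
    if (is.unsorted(knots, strictly = TRUE))
      stop("`knots` must be strictly increasing", call. = FALSE)
    if (length(params) != length(knots))
      stop(sprintf("spline gamma vector has length %d but %d knots imply %d",
                   length(params), length(knots), length(knots)),
           call. = FALSE)
  }
  if (family == "piecewise_exp" && length(params) != length(cutpoints) + 1L)
    stop("piecewise exponential needs one rate per interval", call. = FALSE)
  if (family == "fracpoly" && length(params) != length(powers) + 1L)
    stop("fractional polynomial needs an intercept plus one beta per power",
         call. = FALSE)
  structure(
    list(family = family, params = params, knots = knots,
         scale_kind = scale_kind, powers = powers, cutpoints = cutpoints,
         loglik = loglik, n_params = length(params),
         n_obs = as.integer(n_obs), convergence = isTRUE(convergence),
         diagnostic = diagnostic),
    class = "surv_model")
}

#' @export
print.surv_model <- function(x, ...) {
  cat("<surv_model>", x$family)
  if (!is.null(x$scale_kind))
    cat(sprintf(" (%s scale, %d interior knots)", x$scale_kind,
                length(x$knots) - 2L))
  cat("\n  parameters: ",
      paste(sprintf("%s=%.4g", names(x$params), x$params), collapse = ", "),
      "\n", sep = "")
  if (!is.null(x$knots))
    cat("  knots (log-months):", paste(signif(x$knots, 5), collapse = ", "),
        "\n")
  if (!is.na(x$loglik))
    cat(sprintf("  loglik %.3f on %d parameters (n = %d)\n",
                x$loglik, x$n_params, x$n_obs))
  if (!x$convergence)
    cat("  ** fit did not converge:", x$diagnostic %||% "", "\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Log-logistic survival function
#'
#' `S(t) = 1 / (1 + (t/scale)^shape)`; the median equals `scale`.
#'
#' @param t Time in months, finite and non-negative.
#' @param shape,scale Positive parameters.
#' @return Survival probabilities in `[0, 1]`.
#' @export
loglogistic_survival <- function(t, shape, scale) {
  if (!all(is.finite(t)) || any(t < 0))
    stop("`t` must be finite and non-negative", call. = FALSE)
  if (shape <= 0 || scale <= 0)
    stop("log-logistic `shape` and `scale` must be positive", call. = FALSE)
  1 / (1 + (t / scale)^shape)
}

#' Royston-Parmar restricted cubic spline basis on log time
#'
#' Natural cubic spline basis of Royston and Parmar: column 1 is the
#' intercept, column 2 is `x`, and column `j + 2` is
#' `(x - k_j)_+^3 - lambda_j (x - k_min)_+^3 - (1 - lambda_j)(x - k_max)_+^3`
#' with `lambda_j = (k_max - k_j) / (k_max - k_min)`, for each interior knot
#' `k_j`. The basis is linear beyond the boundary knots.
#'
#' @param x Points on the log-time scale.
#' @param knots Full knot vector (boundary + interior), strictly increasing.
#' @return Matrix with `length(knots)` columns.
#' @export
rp_basis <- function(x, knots) {
  m <- length(knots) - 2L
  kmin <- knots[1L]
  kmax <- knots[length(knots)]
  B <- cbind(1, x)
  if (m > 0L) {
    for (j in seq_len(m)) {
      kj <- knots[j + 1L]
      lam <- (kmax - kj) / (kmax - kmin)
      B <- cbind(B, pmax(x - kj, 0)^3 - lam * pmax(x - kmin, 0)^3 -
                   (1 - lam) * pmax(x - kmax, 0)^3)
    }
  }
  B
}

#' Royston-Parmar spline survival function
#'
#' Evaluates `s(ln t)` on the restricted cubic spline basis and maps it to
#' survival according to the model scale: `exp(-exp(s))` for the
#' log-cumulative-hazard ("hazard") scale, `1/(1 + exp(s))` for the log
#' cumulative odds scale, and `1 - pnorm(s)` for the probit ("normal") scale.
#' `S(0) = 1` is returned explicitly.
#'
#' @param t Time in months, non-negative.
#' @param gammas Spline coefficients, length `length(knots)`.
#' @param knots Full knot vector on log-time.
#' @param scale_kind `"hazard"`, `"odds"` or `"normal"`.
#' @return Survival probabilities in `[0, 1]`.
#' @export
rp_spline_survival <- function(t, gammas, knots, scale_kind = "hazard") {
  scale_kind <- match.arg(scale_kind, c("hazard", "odds", "normal"))
  if (length(gammas) != length(knots))
    stop(sprintf("need %d gammas for %d knots (interior + 2), got %d",
                 length(knots), length(knots), length(gammas)),
         call. = FALSE)
  if (is.unsorted(knots, strictly = TRUE))
    stop("`knots` must be strictly increasing", call. = FALSE)
  out <- numeric(length(t))
  pos <- t > 0
  if (any(pos)) {
    s <- drop(rp_basis(log(t[pos]), knots) %*% gammas)
    out[pos] <- switch(scale_kind,
                       hazard = exp(-exp(s)),
                       odds   = 1 / (1 + exp(s)),
                       normal = stats::pnorm(-s))
  }
  out[!pos] <- 1
  out
}

#' Survival probability of a fitted model
#'
#' @param object A [surv_model].
#' @param t Times in months.
#' @return Survival probabilities.
#' @export
surv_prob <- function(object, t) {
  stopifnot(inherits(object, "surv_model"))
  p <- object$params
  switch(object$family,
    exponential = stats::pexp(t, rate = p[["rate"]], lower.tail = FALSE),
    weibull = stats::pweibull(t, shape = p[["shape"]], scale = p[["scale"]],
                              lower.tail = FALSE),
    lognormal = stats::plnorm(t, meanlog = p[["meanlog"]],
                              sdlog = p[["sdlog"]], lower.tail = FALSE),
    loglogistic = loglogistic_survival(t, p[["shape"]], p[["scale"]]),
    gamma = stats::pgamma(t, shape = p[["shape"]], rate = p[["rate"]],
                          lower.tail = FALSE),
    gengamma = flexsurv::pgengamma(t, mu = p[["mu"]], sigma = p[["sigma"]],
                                   Q = p[["Q"]], lower.tail = FALSE),
    gompertz = flexsurv::pgompertz(t, shape = p[["shape"]],
                                   rate = p[["rate"]], lower.tail = FALSE),
    rp_spline = ,
    rcs = rp_spline_survival(t, unname(p), object$knots, object$scale_kind),
    fracpoly = fp_survival(t, unname(p), object$powers),
    piecewise_exp = pwexp_survival(t, unname(p), object$cutpoints),
    stop("unknown family ", object$family))
}

## piecewise-constant hazard: cumulative hazard is piecewise linear
pwexp_survival <- function(t, rates, cutpoints) {
  bounds <- c(0, cutpoints, Inf)
  H <- vapply(t, function(ti) {
    if (ti <= 0) return(0)
    lo <- bounds[-length(bounds)]
    hi <- bounds[-1]
    sum(rates * pmax(pmin(ti, hi) - lo, 0))
  }, numeric(1))
  exp(-H)
}

## fractional polynomial transform g_p(t): t^p, with ln t for p = 0;
## repeated powers multiply by ln t (Royston-Altman convention)
fp_terms <- function(t, powers) {
  x <- matrix(NA_real_, length(t), length(powers))
  lt <- log(t)
  prev <- NULL
  for (j in seq_along(powers)) {
    p <- powers[j]
    base <- if (p == 0) lt else t^p
    if (!is.null(prev) && j > 1 && powers[j] == powers[j - 1])
      base <- x[, j - 1] * lt
    x[, j] <- base
    prev <- p
  }
  x
}

fp_log_hazard <- function(t, betas, powers) {
  drop(cbind(1, fp_terms(t, powers)) %*% betas)
}

## cumulative hazard via Gauss-Legendre quadrature on (0, t)
fp_cumhaz <- function(t, betas, powers, nodes = 40L) {
  gl <- gauss_legendre(nodes)
  H <- numeric(length(t))
  pos <- which(t > 0)
  if (length(pos)) {
    tp <- t[pos]
    ## map nodes from (-1, 1) to (0, t): u = t (x + 1) / 2
    U <- outer(tp / 2, gl$x + 1)           # n x nodes
    Hmat <- exp(matrix(fp_log_hazard(as.vector(U), betas, powers),
                       nrow = length(tp)))
    H[pos] <- (tp / 2) * drop(Hmat %*% gl$w)
  }
  H
}

fp_survival <- function(t, betas, powers, nodes = 40L) {
  out <- exp(-fp_cumhaz(t, betas, powers, nodes))
  out[t <= 0] <- 1
  out
}

## nodes/weights by Golub-Welsch (symmetric tridiagonal eigendecomposition)
gauss_legendre <- function(n) {
  i <- seq_len(n - 1)
  b <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- b
  J[cbind(i + 1, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  list(x = e$values, w = 2 * e$vectors[1, ]^2)
}

#' Median survival time of a model
#'
#' Smallest time with `S(t) <= 1/2`, found by root search on (0, `upper`).
#'
#' @param object A [surv_model].
#' @param upper Upper search bound in months.
#' @return Median in months (`NA` if the survival stays above 1/2).
#' @export
surv_median <- function(object, upper = 10000) {
  f <- function(t) surv_prob(object, t) - 0.5
  ## scan for the first sign change so multi-crossing (improper) curves
  ## yield the earliest median rather than an arbitrary root
  grid <- exp(seq(log(1e-6), log(upper), length.out = 2000))
  v <- f(grid)
  i <- which(v[-1] * v[-length(v)] <= 0)
  if (!length(i)) return(NA_real_)
  stats::uniroot(f, c(grid[i[1]], grid[i[1] + 1]), tol = 1e-10)$root
}

#' Default interior/boundary knot placement from event times
#'
#' Boundary knots at the minimum and maximum uncensored log event time;
#' interior knots at equally spaced quantiles of the uncensored log event
#' times (1 knot: median; 2: 33rd/67th; 3: 25th/50th/75th percentiles).
#'
#' @param ipd A [pseudo_ipd] with at least `n_interior + 2` distinct event
#'   times.
#' @param n_interior Number of interior knots (1, 2 or 3).
#' @return Numeric knot vector on log-time.
#' @export
default_knots <- function(ipd, n_interior) {
  stopifnot(n_interior %in% 1:3)
  ev <- log(ipd$time[ipd$event == 1])
  if (length(unique(ev)) < n_interior + 2)
    stop("not enough distinct event times to place knots", call. = FALSE)
  probs <- switch(n_interior, 0.5, c(1, 2) / 3, c(1, 2, 3) / 4)
  sort(unique(c(min(ev), stats::quantile(ev, probs, names = FALSE), max(ev))))
}

#' Calibrate spline knots to a target median by a shared log-time shift
#'
#' One-dimensional least squares over a common shift `delta` applied to
#' every knot on the log-time scale: the returned knots minimize
#' `(log median(knots + delta) - log target)^2`. The spline median is not
#' analytic in `delta` (the shift also rescales the linear term), so the
#' problem is solved by a bracketed root search with a least-squares
#' fallback when no exact match exists.
#'
#' @param gammas,base_knots,scale_kind Spline specification (see
#'   [rp_spline_survival]).
#' @param target_median Target median survival (months).
#' @return The shifted knot vector.
#' @export
calibrate_rp_knots <- function(gammas, base_knots, scale_kind,
                               target_median) {
  med_at <- function(delta) {
    surv_median(surv_model("rp_spline", stats::setNames(
      gammas, paste0("gamma", seq_along(gammas) - 1)),
      knots = base_knots + delta, scale_kind = scale_kind))
  }
  f <- function(delta) {
    m <- med_at(delta)
    if (is.na(m)) NA_real_ else log(m) - log(target_median)
  }
  deltas <- seq(-8, 8, length.out = 161)
  v <- vapply(deltas, f, numeric(1))
  ok <- which(!is.na(v))
  if (!length(ok))
    stop("spline survival never reaches 1/2; cannot calibrate", call. = FALSE)
  sgn <- which(diff(sign(v[ok])) != 0)
  delta <- if (length(sgn)) {
    i <- ok[sgn[1]]; j <- ok[sgn[1] + 1]
    stats::uniroot(f, c(deltas[i], deltas[j]), tol = 1e-10)$root
  } else {
    ## no exact match: least-squares minimum over the scanned range
    stats::optimize(function(d) {
      r <- f(d); if (is.na(r)) 1e10 else r^2
    }, range(deltas[ok]))$minimum
  }
  base_knots + delta
}

#' Nested zero-knot form of a Royston-Parmar spline, median-recalibrated
#'
#' With no interior knots the spline reduces to `s(x) = gamma0 + gamma1 x`:
#' a Weibull law on the hazard scale and a log-logistic law on the odds
#' scale, with shape `gamma1` in both cases. When the knot locations of a
#' published spline fit are unavailable, this constructor keeps the printed
#' slope coefficient `gamma1` and recalibrates the scale so the median
#' equals a published median survival. It is the shipped default for running
#' the published progression-free survival coefficients without their knots.
#'
#' @param gamma1 Printed slope coefficient (spline shape parameter).
#' @param median Published median survival in months.
#' @param scale_kind `"hazard"` (Weibull) or `"odds"` (log-logistic).
#' @return A [surv_model] of family `weibull` or `loglogistic`.
#' @export
nested_spline_model <- function(gamma1, median, scale_kind = "hazard") {
  scale_kind <- match.arg(scale_kind, c("hazard", "odds"))
  stopifnot(gamma1 > 0, median > 0)
  if (scale_kind == "hazard") {
    ## S = exp(-H), H = exp(g0) t^g1; median fixes the scale
    scale <- median / log(2)^(1 / gamma1)
    surv_model("weibull", c(shape = gamma1, scale = scale))
  } else {
    surv_model("loglogistic", c(shape = gamma1, scale = median))
  }
}

#' Serialize and restore fitted survival models
#'
#' Round-trip loss-free JSON serialization of a [surv_model].
#'
#' @param model A [surv_model].
#' @param path File path.
#' @return `write_surv_model` returns `path` invisibly; `read_surv_model`
#'   returns the restored [surv_model].
#' @export
write_surv_model <- function(model, path) {
  stopifnot(inherits(model, "surv_model"))
  x <- list(family = model$family,
            param_names = names(model$params),
            param_values = unname(model$params),
            knots = model$knots, scale_kind = model$scale_kind,
            powers = model$powers, cutpoints = model$cutpoints,
            loglik = model$loglik, n_obs = model$n_obs,
            convergence = model$convergence, diagnostic = model$diagnostic)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = I(17), na = "null",
                       null = "null")
  invisible(path)
}

#' @rdname write_surv_model
#' @export
read_surv_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  surv_model(x$family, stats::setNames(x$param_values, x$param_names),
             knots = x$knots, scale_kind = x$scale_kind, powers = x$powers,
             cutpoints = x$cutpoints,
             loglik = x$loglik %||% NA_real_,
             n_obs = x$n_obs %||% NA_integer_,
             convergence = x$convergence %||% TRUE,
             diagnostic = x$diagnostic)
}

## log-likelihood of a surv_model on (time, event) records:
## events contribute log f, censored records log S
loglik_surv_model <- function(model, ipd) {
  t <- ipd$time
  d <- ipd$event
  S <- surv_prob(model, t)
  f <- surv_density(model, t)
  sum(d * log(pmax(f, 1e-300))) + sum((1 - d) * log(pmax(S, 1e-300)))
}

surv_density <- function(model, t) {
  p <- model$params
  switch(model$family,
    exponential = stats::dexp(t, p[["rate"]]),
    weibull = stats::dweibull(t, p[["shape"]], p[["scale"]]),
    lognormal = stats::dlnorm(t, p[["meanlog"]], p[["sdlog"]]),
    loglogistic = flexsurv::dllogis(t, shape = p[["shape"]],
                                    scale = p[["scale"]]),
    gamma = stats::dgamma(t, shape = p[["shape"]], rate = p[["rate"]]),
    gengamma = flexsurv::dgengamma(t, p[["mu"]], p[["sigma"]], p[["Q"]]),
    gompertz = flexsurv::dgompertz(t, p[["shape"]], p[["rate"]]),
    fracpoly = exp(fp_log_hazard(t, unname(p), model$powers)) *
      fp_survival(t, unname(p), model$powers),
    piecewise_exp = {
      bounds <- c(0, model$cutpoints)
      idx <- findInterval(t, bounds)
      unname(p)[idx] * pwexp_survival(t, unname(p), model$cutpoints)
    },
    rp_spline = ,
    rcs = {
      ## f = -dS/dt, via the chain rule on s(ln t)
      eps <- 1e-6
      (surv_prob(model, pmax(t - eps, 0)) - surv_prob(model, t + eps)) /
        (t + eps - pmax(t - eps, 0))
    })
}
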