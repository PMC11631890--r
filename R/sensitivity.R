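## One-way (tornado) and probabilistic sensitivity analysis, and
## cost-effectiveness acceptability curves.

#' Deterministic and probabilistic parameter ranges
#'
#' One row per varied parameter: base value, deterministic bounds and
#' sampling distribution. Defaults to the published table
#' ([table1_parameters()]), excluding parameters with degenerate ranges.
#'
#' @param table Data frame with columns `name`, `base`, `min`, `max`,
#'   `dist` (and optionally `label`).
#' @return A `param_ranges` data frame.
#' @export
param_ranges <- function(table = NULL) {
  if (is.null(table)) {
    table <- table1_parameters()
    table <- table[table$max > table$min, ]
  }
  stopifnot(all(c("name", "base", "min", "max", "dist") %in% names(table)))
  if (any(table$min > table$base | table$base > table$max))
    stop("need min <= base <= max for every range", call. = FALSE)
  if (!all(table$dist %in% c("gamma", "beta", "normal", "fixed")))
    stop("distribution must be gamma, beta, normal or fixed", call. = FALSE)
  class(table) <- c("param_ranges", "data.frame")
  table
}

#' One-way sensitivity analysis with tornado ordering
#'
#' Recomputes the ICER with each parameter at its lower and upper bound,
#' all others held at base, and sorts by bar width (absolute ICER
#' difference). Runs are deterministic. Bounds yielding a dominance flag
#' instead of a finite ICER are capped at `icer_cap` with the flag recorded.
#'
#' @param inputs An [economic_inputs] (base values).
#' @param intervention,comparator [strategy_config]s.
#' @param ranges A [param_ranges].
#' @param horizon_years Optional horizon override.
#' @param icer_cap Magnitude used in place of a dominance-flagged ICER.
#' @return A `tornado` data frame: `name`, `icer_low`, `icer_high`, `width`,
#'   flags, sorted by decreasing width; attribute `base_icer`.
#' @export
owsa_tornado <- function(inputs, intervention, comparator, ranges,
                         horizon_years = NULL, icer_cap = 1e7) {
  stopifnot(inherits(ranges, "param_ranges"))
  unknown <- setdiff(ranges$name, names(inputs$params))
  if (length(unknown))
    stop("range names not model parameters: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  ranges <- align_ranges(ranges, inputs$params)
  base_res <- run_comparison(inputs, intervention, comparator, horizon_years)
  one <- function(name, value) {
    mod <- inputs
    mod$params[[name]] <- value
    res <- run_comparison(mod, intervention, comparator, horizon_years)
    if (is.na(res$icer))
      list(icer = icer_cap * if (res$delta_qaly >= 0) -1 else 1,
           flag = res$dominance)
    else list(icer = res$icer, flag = NA_character_)
  }
  rows <- lapply(seq_len(nrow(ranges)), function(i) {
    lo <- one(ranges$name[i], ranges$min[i])
    hi <- one(ranges$name[i], ranges$max[i])
    data.frame(name = ranges$name[i], base = ranges$base[i],
               low = ranges$min[i], high = ranges$max[i],
               icer_low = lo$icer, icer_high = hi$icer,
               width = abs(hi$icer - lo$icer),
               flag_low = lo$flag, flag_high = hi$flag)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$width), ]
  rownames(out) <- NULL
  attr(out, "base_icer") <- base_res$icer
  attr(out, "wtp") <- inputs$settings$wtp
  class(out) <- c("tornado", "data.frame")
  out
}

## rescale range rows whose base differs from the current parameter value
## (e.g. under a price-multiplier scenario), preserving relative uncertainty
align_ranges <- function(ranges, params) {
  for (i in seq_len(nrow(ranges))) {
    cur <- params[[ranges$name[i]]]
    if (!is.na(cur) && ranges$base[i] != 0 && cur != ranges$base[i]) {
      f <- cur / ranges$base[i]
      ranges$base[i] <- cur
      ranges$min[i] <- ranges$min[i] * f
      ranges$max[i] <- ranges$max[i] * f
    }
  }
  ranges
}

## method-of-moments samplers with mean = base and an SD convention: the
## deterministic range read as a 95% interval (default), or 20% of the mean
psa_sampler <- function(base, min, max, dist, sd_rule = "interval95") {
  sd <- switch(sd_rule,
               interval95 = (max - min) / (2 * 1.96),
               fraction_of_mean = 0.2 * abs(base),
               stop("unknown sd_rule", call. = FALSE))
  if (dist == "fixed" || sd == 0)
    return(function(n) rep(base, n))
  switch(dist,
    gamma = {
      shape <- (base / sd)^2
      rate <- base / sd^2
      function(n) stats::rgamma(n, shape = shape, rate = rate)
    },
    beta = {
      sign <- if (base < 0) -1 else 1
      m <- abs(base)
      if (m <= 0 || m >= 1)
        stop(sprintf("beta distribution needs |base| in (0,1), got %g", base),
             call. = FALSE)
      v <- sd^2
      a <- m * (m * (1 - m) / v - 1)
      b <- a * (1 - m) / m
      if (a <= 0 || b <= 0)
        stop("beta method-of-moments failed: variance too large",
             call. = FALSE)
      function(n) sign * stats::rbeta(n, a, b)
    },
    normal = function(n) stats::rnorm(n, mean = base, sd = sd))
}

#' Draw probabilistic-sensitivity parameter sets
#'
#' Independent draws per parameter: gamma for costs, beta for probabilities,
#' utilities and disutility magnitudes (the sign is restored after
#' sampling), normal for body-surface area; `fixed` rows stay at base.
#' Moments are matched to mean = base and SD = (max - min)/(2 * 1.96).
#'
#' @param ranges A [param_ranges].
#' @param n Number of parameter sets.
#' @param sd_rule `"interval95"` (SD = (max - min)/(2*1.96); default) or
#'   `"fraction_of_mean"` (SD = 20% of the base value).
#' @return Matrix `n x nrow(ranges)` with parameter names as columns.
#' @export
draw_psa_parameters <- function(ranges, n, sd_rule = "interval95") {
  stopifnot(inherits(ranges, "param_ranges"), n >= 1)
  draws <- vapply(seq_len(nrow(ranges)), function(i)
    psa_sampler(ranges$base[i], ranges$min[i], ranges$max[i],
                ranges$dist[i], sd_rule = sd_rule)(n),
    numeric(n))
  if (n == 1) draws <- matrix(draws, nrow = 1)
  colnames(draws) <- ranges$name
  draws
}

#' Probabilistic sensitivity analysis
#'
#' Monte-Carlo propagation: each replicate draws a full parameter set,
#' reruns the model on both arms and records the incremental cost, QALYs and
#' cost-effectiveness at the willingness-to-pay threshold. Survival-model
#' parameters are held fixed (no sampling distribution is published for
#' them), so the state-occupancy traces are computed once and only the
#' economic accumulation is repeated. Range rows whose base differs from the
#' current parameter value (price-multiplier scenarios) are rescaled so the
#' sampled mean follows the scenario. Identical seeds give identical output.
#'
#' @param inputs An [economic_inputs].
#' @param intervention,comparator [strategy_config]s.
#' @param ranges A [param_ranges].
#' @param n_iter Number of Monte-Carlo replicates.
#' @param wtp Willingness-to-pay (defaults to the inputs setting).
#' @param seed RNG seed.
#' @param horizon_years Optional horizon override.
#' @inheritParams draw_psa_parameters
#' @return A `psa_result`: `samples` data frame (`iter`, `delta_cost`,
#'   `delta_qaly`, `cost_effective`), `draws` matrix, `prob_ce`, `wtp`.
#' @export
run_psa <- function(inputs, intervention, comparator, ranges,
                    n_iter = 1000, wtp = NULL, seed = 1,
                    horizon_years = NULL, sd_rule = "interval95") {
  stopifnot(n_iter >= 1)
  wtp <- wtp %||% inputs$settings$wtp
  h <- horizon_years %||% inputs$settings$horizon_years
  ranges <- align_ranges(ranges, inputs$params)
  set.seed(seed)
  draws <- draw_psa_parameters(ranges, n_iter, sd_rule = sd_rule)
  mk_trace <- function(strat) build_trace(
    strat$os_model, strat$pfs_model, h,
    cycle_days = inputs$settings$cycle_days,
    discount_rate = inputs$params[["discount_rate"]])
  tr_i <- mk_trace(intervention)
  tr_c <- mk_trace(comparator)
  d_cost <- d_qaly <- numeric(n_iter)
  for (j in seq_len(n_iter)) {
    mod <- inputs
    mod$params[colnames(draws)] <- draws[j, ]
    fi <- accumulate_outcomes(tr_i, intervention, mod)
    fc <- accumulate_outcomes(tr_c, comparator, mod)
    d_cost[j] <- fi$cost - fc$cost
    d_qaly[j] <- fi$qaly - fc$qaly
  }
  ce <- wtp * d_qaly - d_cost > 0
  structure(list(samples = data.frame(iter = seq_len(n_iter),
                                      delta_cost = d_cost,
                                      delta_qaly = d_qaly,
                                      cost_effective = ce),
                 draws = draws, prob_ce = mean(ce), wtp = wtp,
                 seed = seed, n_iter = n_iter),
            class = "psa_result")
}

#' @export
print.psa_result <- function(x, ...) {
  cat(sprintf("<psa_result> %d iterations; P(cost-effective at %g/QALY) = %.1f%%\n",
              x$n_iter, x$wtp, 100 * x$prob_ce))
  invisible(x)
}

#' Cost-effectiveness acceptability curve
#'
#' Probability of cost-effectiveness as a function of willingness-to-pay:
#' the fraction of replicates with positive net monetary benefit at each
#' grid point.
#'
#' @param psa A `psa_result` (or its `samples` data frame).
#' @param wtp_grid Willingness-to-pay grid (USD/QALY).
#' @return Data frame with `wtp` and `prob_ce`.
#' @export
ceac_curve <- function(psa, wtp_grid = seq(0, 300000, by = 10000)) {
  s <- if (inherits(psa, "psa_result")) psa$samples else psa
  stopifnot(nrow(s) > 0)
  prob <- vapply(wtp_grid, function(w) mean(w * s$delta_qaly - s$delta_cost > 0),
                 numeric(1))
  data.frame(wtp = wtp_grid, prob_ce = prob)
}

#' Sensitivity-analysis plots
#'
#' Tornado diagram, incremental cost-effectiveness scatter and
#' acceptability curve. Requires ggplot2.
#'
#' @param x A `tornado`, `psa_result` or [ceac_curve()] result.
#' @param top Number of tornado bars shown.
#' @param wtp Willingness-to-pay line in the scatter.
#' @return A ggplot object.
#' @export
plot_tornado <- function(x, top = 15) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting", call. = FALSE)
  d <- utils::head(as.data.frame(x), top)
  d$name <- factor(d$name, levels = rev(d$name))
  ggplot2::ggplot(d) +
    ggplot2::geom_segment(ggplot2::aes(x = icer_low, xend = icer_high,
                                       y = name, yend = name),
                          linewidth = 4, colour = "steelblue") +
    ggplot2::geom_vline(xintercept = attr(x, "base_icer"), linetype = 2) +
    ggplot2::geom_vline(xintercept = attr(x, "wtp"), colour = "red") +
    ggplot2::labs(x = "ICER (USD/QALY)", y = NULL)
}

#' @rdname plot_tornado
#' @export
plot_psa_scatter <- function(x, wtp = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting", call. = FALSE)
  wtp <- wtp %||% x$wtp
  ggplot2::ggplot(x$samples, ggplot2::aes(delta_qaly, delta_cost)) +
    ggplot2::geom_point(alpha = 0.4) +
    ggplot2::geom_abline(slope = wtp, intercept = 0, colour = "red") +
    ggplot2::labs(x = "Incremental QALYs", y = "Incremental cost (USD)")
}

#' @rdname plot_tornado
#' @export
plot_ceac <- function(x) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting", call. = FALSE)
  d <- if (inherits(x, "psa_result")) ceac_curve(x) else x
  ggplot2::ggplot(d, ggplot2::aes(wtp, prob_ce)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Willingness-to-pay (USD/QALY)",
                  y = "P(cost-effective)")
}

utils::globalVariables(c("icer_low", "icer_high", "name", "delta_qaly",
                         "delta_cost", "prob_ce"))
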