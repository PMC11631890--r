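test_that("log-logistic survival matches its closed form and domain checks", {
  expect_equal(loglogistic_survival(0, 1.89, 30.33), 1)
  # the median equals the scale parameter
  expect_equal(loglogistic_survival(30.33, 1.89, 30.33), 0.5)
  expect_equal(loglogistic_survival(23.39, 2.05, 23.39), 0.5)
  # independent route via the logistic cdf on the log scale
  t <- c(3, 12, 60, 240)
  expect_equal(loglogistic_survival(t, 2.05, 23.39),
               plogis(2.05 * (log(t) - log(23.39)), lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(loglogistic_survival(240, 2.05, 23.39), 0.0083834,
               tolerance = 1e-4)
  expect_error(loglogistic_survival(5, -1, 10), "positive")
  expect_error(loglogistic_survival(5, 1, 0), "positive")
  expect_error(loglogistic_survival(Inf, 1, 1), "finite")
})

test_that("spline survival degenerates to the nested laws with no interior knots", {
  # gammas (0, 1), hazard scale: ln H = ln t, i.e. Weibull(1, 1)
  k <- c(-2, 3)
  expect_equal(rp_spline_survival(1, c(0, 1), k, "hazard"), exp(-1),
               tolerance = 1e-12)
  tg <- c(0.2, 1, 5, 20, 100)
  expect_equal(rp_spline_survival(tg, c(0, 1), k, "hazard"),
               pweibull(tg, 1, 1, lower.tail = FALSE), tolerance = 1e-12)
  # odds scale (g0, g1) is log-logistic with shape g1, scale exp(-g0/g1)
  g0 <- -3.2; g1 <- 1.4
  expect_equal(rp_spline_survival(tg, c(g0, g1), k, "odds"),
               loglogistic_survival(tg, g1, exp(-g0 / g1)),
               tolerance = 1e-12)
  # t = 0 returns the limit value explicitly
  expect_identical(rp_spline_survival(0, c(0, 1), k, "hazard"), 1)
})

test_that("spline evaluation agrees with an independent truncated-power implementation", {
  g_abc <- c(-5.334, 0.995, -2.079, 3.111, -0.902)
  knots <- log(c(2, 7, 11, 16, 38))   # a plausible knot set on log-months
  tg <- exp(seq(log(0.5), log(120), length.out = 60))
  for (sc in c("hazard", "odds", "normal"))
    expect_equal(rp_spline_survival(tg, g_abc, knots, sc),
                 rp_spline_surv_brute(tg, g_abc, knots, sc),
                 tolerance = 1e-9)
  # structural errors
  expect_error(rp_spline_survival(1, c(0, 1, 2), knots, "hazard"), "gamma")
  expect_error(rp_spline_survival(1, g_abc, rev(knots), "hazard"),
               "increasing")
})

test_that("every family's survival function is a proper survival law", {
  models <- list(
    surv_model("exponential", c(rate = 0.05)),
    surv_model("weibull", c(shape = 1.4, scale = 25)),
    surv_model("lognormal", c(meanlog = 3, sdlog = 0.8)),
    surv_model("loglogistic", c(shape = 1.89, scale = 30.33)),
    surv_model("gamma", c(shape = 2, rate = 0.08)),
    surv_model("gengamma", c(mu = 3.2, sigma = 0.7, Q = 0.9)),
    surv_model("gompertz", c(shape = 0.08, rate = 0.02)),
    surv_model("rp_spline", c(gamma0 = -4.7, gamma1 = 1.3),
               knots = c(0, 3.5), scale_kind = "odds"),
    surv_model("piecewise_exp", c(rate1 = 0.1, rate2 = 0.025),
               cutpoints = 10),
    surv_model("fracpoly", c(beta0 = -3.5, beta1 = 0.4), powers = 0))
  grid <- c(0, exp(seq(log(0.01), log(2000), length.out = 400)))
  for (m in models) {
    s <- surv_prob(m, grid)
    expect_equal(s[1], 1, info = m$family)
    expect_true(all(diff(s) <= 1e-10), info = m$family)
    expect_lt(s[length(s)], 0.02)
    expect_true(all(s >= 0 & s <= 1), info = m$family)
  }
})

test_that("piecewise-exponential survival integrates the step hazard", {
  m <- surv_model("piecewise_exp", c(rate1 = 0.1, rate2 = 0.025),
                  cutpoints = 10)
  expect_equal(surv_prob(m, 10), exp(-1), tolerance = 1e-12)
  expect_equal(surv_prob(m, 30), exp(-1 - 0.025 * 20), tolerance = 1e-12)
})

test_that("knot calibration matches the target median and preserves spacing", {
  g <- c(-4.754, 1.187, -1.09, 1.278)
  base <- log(c(2, 6, 12, 30))
  # targets inside the range reachable by a shared shift of this knot set
  for (target in c(45, 90)) {
    k <- calibrate_rp_knots(unname(g), base, "odds", target)
    m <- surv_model("rp_spline",
                    setNames(g, paste0("gamma", 0:3)), knots = k,
                    scale_kind = "odds")
    expect_equal(surv_median(m), target, tolerance = 1e-6)
    # a shared shift: knot spacing is untouched
    expect_equal(diff(k), diff(base), tolerance = 1e-12)
  }
})

test_that("nested fallback models hit the published medians and slopes", {
  pfs_abc <- nested_spline_model(0.995, 13.7, "hazard")
  pfs_bc <- nested_spline_model(1.187, 10.4, "odds")
  expect_equal(surv_median(pfs_abc), 13.7, tolerance = 1e-6)
  expect_equal(surv_median(pfs_bc), 10.4, tolerance = 1e-6)
  expect_equal(unname(pfs_abc$params["shape"]), 0.995)
  expect_equal(unname(pfs_bc$params["shape"]), 1.187)
  # equivalent to the zero-knot spline with matching coefficients
  tg <- c(1, 5, 13.7, 40, 120)
  g0 <- -0.995 * log(unname(pfs_abc$params["scale"]))
  expect_equal(surv_prob(pfs_abc, tg),
               rp_spline_survival(tg, c(g0, 0.995), c(0, 4), "hazard"),
               tolerance = 1e-12)
})

test_that("fitted models serialize round-trip loss-free", {
  m <- surv_model("rp_spline",
                  c(gamma0 = -5.334, gamma1 = 0.995, gamma2 = -2.079,
                    gamma3 = 3.111, gamma4 = -0.902),
                  knots = log(c(2, 7, 11, 16, 38)), scale_kind = "hazard",
                  loglik = -812.345678901, n_obs = 206)
  path <- tempfile(fileext = ".json")
  write_surv_model(m, path)
  m2 <- read_surv_model(path)
  expect_identical(m2$family, m$family)
  expect_equal(m2$params, m$params, tolerance = 0)
  expect_equal(m2$knots, m$knots, tolerance = 0)
  expect_identical(m2$scale_kind, m$scale_kind)
  expect_equal(m2$loglik, m$loglik, tolerance = 0)
  expect_identical(m2$n_obs, m$n_obs)
  tg <- c(0.5, 5, 50)
  expect_equal(surv_prob(m2, tg), surv_prob(m, tg), tolerance = 0)
  # piecewise and fracpoly round-trip too
  for (m in list(surv_model("piecewise_exp", c(rate1 = .1, rate2 = .02),
                            cutpoints = 10, loglik = -5, n_obs = 12),
                 surv_model("fracpoly", c(beta0 = -3, beta1 = .5),
                            powers = 0.5, loglik = -7, n_obs = 9))) {
    write_surv_model(m, path)
    m2 <- read_surv_model(path)
    expect_equal(surv_prob(m2, c(1, 20)), surv_prob(m, c(1, 20)),
                 tolerance = 0)
  }
})

test_that("surv_model validates its structure", {
  expect_error(surv_model("rp_spline", c(gamma0 = 1, gamma1 = 1),
                          knots = c(0, 1, 2), scale_kind = "hazard"),
               "length")
  expect_error(surv_model("loglogistic", c(1.89, 30.33)), "named")
  expect_error(surv_model("piecewise_exp", c(rate1 = .1), cutpoints = 5),
               "one rate per interval")
})
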