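test_that("maximum-likelihood fits recover generating parameters", {
  # exponential, rate 0.05/month, n = 2000, no censoring
  ipd <- sim_arm(surv_model("exponential", c(rate = 0.05)), 2000, seed = 101)
  fit <- fit_parametric(ipd, "exponential")
  expect_true(fit$convergence)
  expect_equal(unname(fit$params["rate"]), 0.05, tolerance = 0.05)
  # closed form for the exponential MLE: events / total time
  expect_equal(unname(fit$params["rate"]),
               sum(ipd$event) / sum(ipd$time), tolerance = 1e-4)
  # published log-logistic parameters, n = 5000
  ipd <- sim_arm(surv_model("loglogistic", c(shape = 1.89, scale = 30.33)),
                 5000, seed = 102)
  fit <- fit_parametric(ipd, "loglogistic")
  expect_equal(unname(fit$params["shape"]), 1.89, tolerance = 0.05)
  expect_equal(unname(fit$params["scale"]), 30.33, tolerance = 0.05)
})

test_that("a single-event input is flagged, not fitted", {
  ipd <- pseudo_ipd(c(3, 5, 8), c(0, 1, 0))
  fit <- fit_parametric(ipd, "weibull")
  expect_false(fit$convergence)
  expect_match(fit$diagnostic, "under-determined")
})

test_that("the fitted likelihood is at least the likelihood at the truth", {
  truth <- list(
    surv_model("weibull", c(shape = 1.4, scale = 25)),
    surv_model("loglogistic", c(shape = 1.89, scale = 30.33)),
    surv_model("gamma", c(shape = 2, rate = 0.08)))
  for (tm in truth) {
    ipd <- sim_arm(tm, 500, seed = 7, window = 60)
    fit <- fit_parametric(ipd, tm$family)
    expect_gte(fit$loglik + 1e-6, psmcea:::loglik_surv_model(tm, ipd))
    # and the stored loglik matches the direct evaluation at the estimate
    expect_equal(fit$loglik, psmcea:::loglik_surv_model(fit, ipd),
                 tolerance = 1e-6)
  }
})

test_that("spline fits return the advertised number of coefficients", {
  ipd <- sim_arm(surv_model("loglogistic", c(shape = 1.6, scale = 14)),
                 500, seed = 11, window = 54)
  f3 <- fit_rp_spline(ipd, 3, "hazard")
  expect_length(f3$params, 5)           # gamma0..gamma4
  expect_named(f3$params, paste0("gamma", 0:4))
  expect_length(f3$knots, 5)
  f2 <- fit_rp_spline(ipd, 2, "odds")
  expect_length(f2$params, 4)           # gamma0..gamma3
  # knots are serialized with the model: refit reproducibility
  path <- tempfile(fileext = ".json")
  write_surv_model(f3, path)
  f3b <- read_surv_model(path)
  tg <- c(2, 10, 30)
  expect_equal(surv_prob(f3b, tg), surv_prob(f3, tg), tolerance = 0)
})

test_that("nesting identities hold after refitting", {
  ipd <- sim_arm(surv_model("weibull", c(shape = 1.3, scale = 20)),
                 1000, seed = 5, window = 54)
  ctrl <- list(reltol = 1e-16, maxit = 10000)
  grid <- c(1, 2, 5, 10, 20, 40, 80, 160, 240)
  w <- fit_parametric(ipd, "weibull", control = ctrl)
  rp_h <- fit_rp_spline(ipd, 0, "hazard", control = ctrl)
  expect_lt(max(abs(surv_prob(w, grid) - surv_prob(rp_h, grid))), 1e-8)
  ll <- fit_parametric(ipd, "loglogistic", control = ctrl)
  rp_o <- fit_rp_spline(ipd, 0, "odds", control = ctrl)
  expect_lt(max(abs(surv_prob(ll, grid) - surv_prob(rp_o, grid))), 1e-8)
  # one-interval piecewise exponential is the exponential MLE
  e <- fit_parametric(ipd, "exponential", control = ctrl)
  pw <- fit_piecewise_exponential(ipd)
  expect_equal(unname(pw$params["rate1"]), unname(e$params["rate"]),
               tolerance = 1e-6)
  expect_lt(max(abs(surv_prob(e, grid) - surv_prob(pw, grid))), 1e-6)
})

test_that("rp spline with 0 knots recovers a Weibull generator within 5%", {
  ipd <- sim_arm(surv_model("weibull", c(shape = 1.5, scale = 22)),
                 5000, seed = 31, window = 60)
  rp <- fit_rp_spline(ipd, 0, "hazard")
  # map gammas back: H = exp(g0) t^g1 -> shape g1, scale exp(-g0/g1)
  shape_hat <- unname(rp$params["gamma1"])
  scale_hat <- exp(-unname(rp$params["gamma0"]) / shape_hat)
  expect_equal(shape_hat, 1.5, tolerance = 0.05)
  expect_equal(scale_hat, 22, tolerance = 0.05)
})

test_that("piecewise-exponential hazards are events over person-time", {
  # 10 events over 100 person-months, then 5 over 200: hazards 0.10, 0.025
  # (10 events at t = 5: 50 p-m, plus 5 subjects contributing 10 each; then
  #  those 5 have events at t = 50: 5 * 40 p-m beyond the cut)
  ipd <- pseudo_ipd(c(rep(5, 10), rep(50, 5)), rep(1, 15))
  fit <- fit_piecewise_exponential(ipd, cutpoints = 10)
  expect_equal(unname(fit$params), c(0.10, 0.025), tolerance = 1e-12)
  # an empty interval is a structural error naming the interval
  expect_error(fit_piecewise_exponential(ipd, cutpoints = c(10, 60)),
               "interval 3")
  # constant-hazard data: interval hazards agree within Monte-Carlo error
  ipd <- sim_arm(surv_model("exponential", c(rate = 0.06)), 4000, seed = 13)
  fit <- fit_piecewise_exponential(ipd, cutpoints = c(8, 20))
  expect_equal(unname(fit$params), rep(0.06, 3), tolerance = 0.08)
})

test_that("fractional-polynomial search covers the conventional power sets", {
  expect_length(psmcea:::fp_power_sets(1), 8)
  expect_length(psmcea:::fp_power_sets(2), 36)
  # log-time-linear hazard (Weibull) selects power 0 at degree 1
  ipd <- sim_arm(surv_model("weibull", c(shape = 1.5, scale = 20)),
                 1500, seed = 17)
  fp <- fit_fractional_polynomial(ipd, 1)
  expect_identical(fp$powers, 0)
  expect_true(fp$convergence)
  # its maximized likelihood cannot fall below the nested constant hazard
  e <- fit_parametric(ipd, "exponential")
  expect_gte(fp$loglik, e$loglik - 1e-4)
})

test_that("information criteria follow their closed forms", {
  m <- surv_model("weibull", c(shape = 1, scale = 1), loglik = -100,
                  n_obs = 100)
  ic <- information_criteria(m)
  expect_equal(unname(ic["AIC"]), 204)
  expect_equal(unname(ic["BIC"]), 200 + 2 * log(100))
  # identity AIC - BIC = k (2 - ln n) for several models
  for (k in 1:4) {
    m <- surv_model("piecewise_exp",
                    setNames(rep(0.1, k), paste0("rate", 1:k)),
                    cutpoints = head(c(5, 10, 15), k - 1),
                    loglik = -57.3, n_obs = 83)
    ic <- information_criteria(m)
    expect_equal(unname(ic["AIC"] - ic["BIC"]), k * (2 - log(83)),
                 tolerance = 1e-12)
  }
})

test_that("model selection is deterministic with documented tie-breaking", {
  a <- surv_model("exponential", c(rate = 0.1), loglik = -50, n_obs = 40)
  expect_identical(attr(select_best_model(list(only = a)), "selected"),
                   "only")
  # equal loglik: fewer parameters win
  b <- surv_model("weibull", c(shape = 1, scale = 10), loglik = -50,
                  n_obs = 40)
  rep <- select_best_model(list(two = b, one = a), "AIC")
  expect_identical(attr(rep, "selected"), "one")
  expect_error(select_best_model(list()), "empty")
})

test_that("the generating family ranks first among the traditional seven", {
  ipd <- sim_arm(surv_model("loglogistic", c(shape = 1.89, scale = 30.33)),
                 2000, seed = 23, window = 80)
  fits <- lapply(setNames(psmcea:::TRADITIONAL_FAMILIES,
                          psmcea:::TRADITIONAL_FAMILIES),
                 function(f) fit_parametric(ipd, f))
  rep <- select_best_model(fits, "AIC")
  expect_identical(attr(rep, "selected"), "loglogistic")
  expect_true(all(c("AIC", "BIC", "rank") %in% names(rep)))
  expect_equal(sort(rep$rank), seq_len(nrow(rep)))
})
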