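bc <- base_case()

test_that("trace occupancy is conserved and consistent", {
  tr <- build_trace(bc$strategies$ABC$os_model, bc$strategies$ABC$pfs_model,
                    horizon_years = 20)
  expect_equal(nrow(tr), 348)                     # ceil(20 * 365.25 / 21)
  expect_true(all(abs(tr$pfs + tr$pd + tr$dead - 1) <= 1e-12))
  expect_true(all(diff(tr$dead) >= -1e-15))
  expect_true(all(tr$new_deaths >= -1e-15))
  expect_equal(sum(tr$new_deaths), tr$dead[nrow(tr)], tolerance = 1e-12)
  # death fraction approaches the closed form near 240 months
  i <- which.min(abs(tr$mid_months - 240))
  expect_equal(tr$dead[i], 1 - loglogistic_survival(tr$mid_months[i],
                                                    1.89, 30.33),
               tolerance = 1e-12)
  expect_equal(tr$dead[i], 0.980, tolerance = 0.001)
})

test_that("identical OS and PFS models leave nobody in the progressed state", {
  m <- bc$strategies$BC$os_model
  tr <- build_trace(m, m, horizon_years = 10)
  expect_true(all(tr$pd == 0))
})

test_that("capping of PFS above OS is counted, not fatal", {
  heavy <- surv_model("loglogistic", c(shape = 1.1, scale = 40))
  light <- surv_model("exponential", c(rate = 0.1))
  tr <- build_trace(light, heavy, horizon_years = 10)
  expect_true(all(tr$pfs <= 1 - tr$dead + 1e-15))
  expect_gt(attr(tr, "pfs_capping")$n_cycles, 0)
  expect_gt(attr(tr, "pfs_capping")$max_violation, 0)
})

test_that("zero discount rate gives unit weights", {
  tr <- build_trace(bc$strategies$BC$os_model, bc$strategies$BC$pfs_model,
                    horizon_years = 2, discount_rate = 0)
  expect_true(all(tr$disc == 1))
})

test_that("cycle cost components match hand arithmetic", {
  inputs <- bc$inputs
  # a pure-PFS row past the chemotherapy cap in the BC arm: drug cost is
  # bevacizumab only
  tr <- build_trace(bc$strategies$BC$os_model, bc$strategies$BC$pfs_model, 20)
  row <- tr[7, , drop = FALSE]
  row$pfs <- 1; row$pd <- 0; row$dead <- 0; row$new_deaths <- 0
  cc <- cycle_costs(row, bc$strategies$BC, inputs)
  expect_equal(unname(cc[1, "first_line"]), 8617.84)
  expect_equal(unname(cc[1, "chemo"]), 0)
  expect_equal(unname(cc[1, "admin"]), 0)
  expect_equal(unname(cc[1, "second_line"]), 0)
  # a pure-PD row in the ABC arm: published second-line mix
  row$pfs <- 0; row$pd <- 1
  cc <- cycle_costs(row, bc$strategies$ABC, inputs)
  sl_drugs <- 0.03 * (12186.56 + 11178) / 2 + 0.51 * (36.53 + 58.09) / 2
  expect_equal(unname(cc[1, "second_line"]),
               sl_drugs + 0.54 * 186.53 + 0.46 * 4824.06, tolerance = 1e-12)
  expect_equal(sl_drugs, 374.5965, tolerance = 1e-6)
  expect_equal(0.46 * 4824.06, 2219.068, tolerance = 1e-4)
  # hospice under the one-off convention: 0.1 incident deaths
  inputs_pd <- economic_inputs(hospice_accrual = "per_death")
  row$new_deaths <- 0.1; row$dead <- 0.5
  cc <- cycle_costs(row, bc$strategies$ABC, inputs_pd)
  expect_equal(unname(cc[1, "hospice"]), 1126.9)
  # and under per-cycle accrual it follows the death-state occupancy
  cc <- cycle_costs(row, bc$strategies$ABC, bc$inputs)
  expect_equal(unname(cc[1, "hospice"]), 0.5 * 11269)
})

test_that("entry effects reproduce the published adverse-event arithmetic", {
  ee <- entry_effects(bc$strategies$BC, bc$inputs)
  expected_ae <- 0.04 * 1139.04 + 0.07 * 1450.5 + 0.27 * 29643.23 +
    0.06 * 2487.64 + 0.16 * 2637.46
  expect_equal(ee$cost, expected_ae + 760, tolerance = 1e-9)
  expect_equal(expected_ae, 8722.53, tolerance = 1e-3)
  # all risks zero: only the DNA test remains
  p <- bc$inputs$params
  p[grep("^risk_", names(p))] <- 0
  ee0 <- entry_effects(bc$strategies$BC, economic_inputs(params = p))
  expect_equal(ee0$cost, 760)
  expect_equal(ee0$qaly_decrement, 0)
  # anemia has zero disutility: raising its risk leaves the decrement alone
  p <- bc$inputs$params
  p["risk_abc_anemia"] <- 0.99
  ee2 <- entry_effects(bc$strategies$ABC, economic_inputs(params = p))
  expect_equal(ee2$qaly_decrement,
               entry_effects(bc$strategies$ABC, bc$inputs)$qaly_decrement)
})

test_that("QALY accumulation matches closed forms", {
  # utility 1, nobody dies, no discounting, 1-year horizon: 1 QALY
  immortal <- surv_model("exponential", c(rate = 1e-12))
  p <- bc$inputs$params
  p["utility_pfs"] <- 1
  p["discount_rate"] <- 0
  inputs <- economic_inputs(params = p)
  tr <- build_trace(immortal, immortal, horizon_years = 1, discount_rate = 0)
  strat <- strategy_config("BC", immortal, immortal)
  out <- accumulate_outcomes(tr, strat, inputs)
  # 18 cycles of 21 days slightly overshoot one year; compare to exact
  expect_equal(out$qaly + entry_effects(strat, inputs)$qaly_decrement,
               nrow(tr) * 21 / 365.25, tolerance = 1e-9)
  # exponential survival, utility u, discounting: QALY -> u / (lambda + r)
  lam <- 0.05                      # per month
  u <- 0.71
  mexp <- surv_model("exponential", c(rate = lam))
  tr <- build_trace(mexp, mexp, horizon_years = 60, discount_rate = 0.03)
  out <- accumulate_outcomes(tr, strategy_config("BC", mexp, mexp),
                             bc$inputs)
  qaly_exact <- u / (12 * lam + log(1.03))
  expect_equal(out$qaly + entry_effects(strat, bc$inputs)$qaly_decrement,
               qaly_exact, tolerance = 0.01)
})

test_that("incremental results and dominance flags follow their definitions", {
  frag <- function(cost, qaly)
    structure(list(arm = "x", cost = cost, qaly = qaly),
              class = "cea_fragment")
  r <- compute_icer(frag(200, 2), frag(100, 1))
  expect_equal(r$icer, 100)
  # ratio arithmetic at the published increments
  r <- compute_icer(frag(116186.4452, 116186.4452 / 193926.48 + 1),
                    frag(0, 1))
  expect_equal(r$icer, 193926.48, tolerance = 1e-9)
  expect_identical(compute_icer(frag(-1, 2), frag(0, 1))$dominance,
                   "dominant")
  expect_identical(compute_icer(frag(1, 0), frag(0, 1))$dominance,
                   "dominated")
  und <- compute_icer(frag(1, 1), frag(0, 1))
  expect_identical(und$dominance, "undefined")
  expect_true(is.na(und$icer))
})

test_that("the full comparison is deterministic and self-consistent", {
  r1 <- run_comparison(bc$inputs, bc$strategies$ABC, bc$strategies$BC)
  r2 <- run_comparison(bc$inputs, bc$strategies$ABC, bc$strategies$BC)
  expect_identical(r1, r2)
  expect_equal(r1$icer, r1$delta_cost / r1$delta_qaly, tolerance = 1e-12)
  # a strategy against itself: zero increments, undefined ratio
  r0 <- run_comparison(bc$inputs, bc$strategies$BC, bc$strategies$BC)
  expect_equal(r0$delta_cost, 0)
  expect_identical(r0$dominance, "undefined")
})

test_that("scenario transformations are pure and exact", {
  mod <- apply_scenario(bc$inputs, c(cost_atezolizumab = 0.9))
  expect_equal(unname(mod$params["cost_atezolizumab"]), 9064.98)
  expect_equal(unname(bc$inputs$params["cost_atezolizumab"]), 10072.2)
  expect_identical(apply_scenario(bc$inputs), bc$inputs)
  expect_error(apply_scenario(bc$inputs, c(no_such_thing = 0.5)), "unknown")
  expect_error(apply_scenario(bc$inputs, c(cost_atezolizumab = -1)),
               "positive")
})

test_that("cost accumulation is monotone and affine in unit prices", {
  res <- run_comparison(bc$inputs, bc$strategies$ABC, bc$strategies$BC)
  for (nm in c("cost_bevacizumab", "cost_hospice", "cost_supportive",
               "cost_followup")) {
    up <- apply_scenario(bc$inputs, setNames(1.25, nm))
    res_up <- run_comparison(up, bc$strategies$ABC, bc$strategies$BC)
    expect_gte(res_up$intervention$cost, res$intervention$cost)
    expect_gte(res_up$comparator$cost, res$comparator$cost)
    # affine: the exposure implied by a finite difference is slope-exact
    dn <- apply_scenario(bc$inputs, setNames(0.75, nm))
    res_dn <- run_comparison(dn, bc$strategies$ABC, bc$strategies$BC)
    mid <- (res_up$intervention$cost + res_dn$intervention$cost) / 2
    expect_equal(mid, res$intervention$cost, tolerance = 1e-12)
  }
  # raising a utility never decreases QALYs
  up <- apply_scenario(bc$inputs, c(utility_pd = 1.1))
  expect_gte(run_comparison(up, bc$strategies$ABC,
                            bc$strategies$BC)$intervention$qaly,
             res$intervention$qaly)
})

test_that("totals fall with the discount rate and grow with the horizon", {
  res <- function(r, h = 20) {
    p <- bc$inputs$params
    p["discount_rate"] <- r
    run_comparison(economic_inputs(params = p), bc$strategies$ABC,
                   bc$strategies$BC, horizon_years = h)
  }
  r0 <- res(0); r3 <- res(0.03); r8 <- res(0.08)
  expect_true(r0$intervention$cost > r3$intervention$cost)
  expect_true(r3$intervention$cost > r8$intervention$cost)
  expect_true(r0$intervention$qaly > r3$intervention$qaly)
  short <- res(0.03, 4.5)
  expect_true(short$intervention$cost <= r3$intervention$cost)
  expect_true(short$comparator$cost <= r3$comparator$cost)
  expect_true(short$intervention$qaly <= r3$intervention$qaly)
  expect_true(short$comparator$qaly <= r3$comparator$qaly)
})

test_that("the atezolizumab price-multiplier identity holds to 1e-9", {
  res <- run_comparison(bc$inputs, bc$strategies$ABC, bc$strategies$BC)
  m <- 0.9
  res_m <- run_comparison(apply_scenario(bc$inputs,
                                         c(cost_atezolizumab = m)),
                          bc$strategies$ABC, bc$strategies$BC)
  # discounted atezolizumab exposure from the component breakdown
  atezo_share <- 10072.2 / (10072.2 + 8617.84)
  exposure <- unname(res$intervention$components["first_line"]) * atezo_share
  pred <- (res$delta_cost - (1 - m) * exposure) / res$delta_qaly
  expect_equal(res_m$icer, pred, tolerance = 1e-9)
})
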