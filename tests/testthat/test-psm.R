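test_that("three-state partition: definition, boundaries and the cap rule", {
  # exponential rates chosen so S_pfs(1) = 0.6, S_os(1) = 0.8
  pfs <- parsurv("exponential", -log(0.6))
  os <- parsurv("exponential", -log(0.8))
  occ <- state_occupancy(os, pfs, c(0, 1))
  expect_equal(unlist(occ[1, c("pf", "pd", "dead")]), c(pf = 1, pd = 0, dead = 0))
  expect_equal(unlist(occ[2, c("pf", "pd", "dead")]),
               c(pf = 0.6, pd = 0.2, dead = 0.2))
  expect_equal(attr(occ, "n_crossings"), 0)

  # crossing curves: PF is capped at overall survival and PD floors at 0
  occ2 <- state_occupancy(os = parsurv("exponential", -log(0.8)),
                          pfs = parsurv("exponential", -log(0.9)), t = 1)
  expect_equal(occ2$pf, 0.8)
  expect_equal(occ2$pd, 0)
  expect_equal(attr(occ2, "n_crossings"), 1)
})

test_that("occupancy conservation and monotone death over the whole trace", {
  for (pop in c("cps5", "cps10")) {
    run <- run_psm(cea_config(pop), "intervention")
    tr <- run$trace
    expect_true(all(abs(tr$pf + tr$pd + tr$dead - 1) < 1e-12))
    expect_true(all(diff(tr$dead) >= -1e-12))
    expect_true(all(tr$on_treatment <= tr$pf + 1e-12))
    expect_true(all(tr$deaths >= 0))
  }
})

test_that("treatment exposure follows S_pfs below the cap and is 0 above it", {
  cfg <- cea_config()
  pfs <- parsurv("exponential", 0.2)
  ex <- treatment_exposure(pfs, cap = 6.3, settings = cfg$settings)
  expect_equal(ex$exposure[ex$t_mid > 7][1], 0)
  ex_inf <- treatment_exposure(pfs, cap = Inf, settings = cfg$settings)
  expect_equal(ex_inf$exposure, surv_prob(pfs, ex_inf$t_mid))

  # closed form: expected treated months up to a 5-month cap for an
  # exponential PFS with rate 0.2/month is (1 - exp(-1)) / 0.2
  cm <- cfg$settings$cycle_days / 30.4375
  treated_months <- sum(treatment_exposure(pfs, 5, cfg$settings)$exposure) * cm
  expect_equal(treated_months, (1 - exp(-1)) / 0.2, tolerance = 0.005)
})

test_that("degenerate accrual: zero rates give zero cost, zero utility zero QALY", {
  cfg <- cea_config()
  for (nm in names(cfg$costs)) cfg$costs[[nm]] <- 0
  for (arm in names(cfg$strategies)) {
    cfg$strategies[[arm]]$utilities <- list(pf = 0, pd = 0)
    cfg$strategies[[arm]]$ae_probs <- list(neutropenia = 0, anemia = 0)
    for (d in names(cfg$strategies[[arm]]$drugs))
      cfg$strategies[[arm]]$drugs[[d]]$annual_cost <- 0
  }
  run <- run_psm(cfg, "intervention")
  expect_equal(run$accrual$cost_total, 0)
  expect_equal(run$accrual$qaly_total, 0)
  expect_gt(run$accrual$ly_total, 0)
})

test_that("undiscounted life expectancy identity: QALY = LY = integral of S_os", {
  cfg <- cea_config()
  cfg$settings$discount_rate <- 0
  for (arm in names(cfg$strategies)) {
    cfg$strategies[[arm]]$utilities <- list(pf = 1, pd = 1)
    cfg$strategies[[arm]]$ae_probs <- list(neutropenia = 0, anemia = 0)
  }
  run <- run_psm(cfg, "comparator")
  expect_equal(run$accrual$qaly_total, run$accrual$ly_total)
  oracle <- trapz_surv_years(cfg$strategies$comparator$os,
                             cfg$settings$horizon_years * 12)
  expect_equal(run$accrual$ly_total, oracle, tolerance = 0.002)
})

test_that("discounting can only shrink accruals", {
  cfg <- cea_config()
  disc <- run_psm(cfg, "intervention")$accrual
  cfg0 <- cfg; cfg0$settings$discount_rate <- 0
  undisc <- run_psm(cfg0, "intervention")$accrual
  for (nm in names(disc))
    expect_gt(undisc[[nm]], disc[[nm]])
})

test_that("grid convergence: halving the cycle moves totals by < 0.5%", {
  cfg <- cea_config()
  a21 <- run_psm(cfg, "intervention")$accrual
  cfg$settings$cycle_days <- 10.5
  a10 <- run_psm(cfg, "intervention")$accrual
  expect_lt(abs(a10$cost_total / a21$cost_total - 1), 0.005)
  expect_lt(abs(a10$qaly_total / a21$qaly_total - 1), 0.005)
})

test_that("raising any single rate moves its accrual the right way", {
  cfg <- cea_config()
  base <- run_psm(cfg, "intervention")$accrual
  rates <- list(admin = 1226, pf_nonmed = 25925, supportive = 63077,
                pd_drug = 4682, pd_admin = 2018, terminal = 54893,
                ae_cost_neutropenia = 769, ae_cost_anemia = 1494,
                capox_cost = 8959, suge_cost = 59814)
  for (tg in names(rates)) {
    up <- run_psm(cfg, "intervention",
                  overrides = stats::setNames(list(1.5 * rates[[tg]]), tg))
    expect_gt(up$accrual$cost_total, base$cost_total, label = tg)
  }
  up_u <- run_psm(cfg, "intervention", overrides = list(u_pf = 0.9, u_pd = 0.8))
  expect_gt(up_u$accrual$qaly_total, base$qaly_total)
})

test_that("QALYs never exceed life-years, per state and overall", {
  for (arm in c("intervention", "comparator")) {
    a <- run_psm(cea_config(), arm)$accrual
    expect_lte(a$qaly_pf, a$ly_pf)
    expect_lte(a$qaly_pd, a$ly_pd)
    expect_lte(a$qaly_total, a$ly_total)
    # component sums
    expect_equal(a$cost_total,
                 a$cost_pf_med + a$cost_pf_nonmed + a$cost_pd_med +
                   a$cost_pd_nonmed + a$cost_ae)
    expect_equal(a$qaly_total, a$qaly_pf + a$qaly_pd)
    expect_equal(a$ly_total, a$ly_pf + a$ly_pd)
  }
})

test_that("a horizon shorter than one cycle is rejected", {
  cfg <- cea_config()
  cfg$settings$horizon_years <- 0.01
  expect_error(validate_config(cfg), "horizon")
})
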