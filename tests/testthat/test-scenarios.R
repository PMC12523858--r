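test_that("an empty scenario is the base case", {
  cfg <- cea_config()
  base <- cea(cfg)
  row <- run_scenario(cfg, scenario_spec("base"))
  expect_equal(row$delta_cost, base$delta_cost)
  expect_equal(row$delta_effect, base$delta_qaly)
  expect_equal(row$icer, as.numeric(base$icer))
  expect_equal(row$inmb, base$inmb)
})

test_that("unknown scenario overrides are rejected with the valid keys", {
  expect_error(scenario_spec("x", cycle_days = 7), "unknown scenario override")
  expect_error(scenario_spec("x", cycle_days = 7), "valid keys")
})

test_that("incremental effect grows monotonically with the horizon", {
  cfg <- cea_config()
  de <- vapply(c(5, 10, 20, 30, 40), function(h)
    run_scenario(cfg, scenario_spec("h", horizon_years = h))$delta_effect,
    numeric(1))
  expect_true(all(diff(de) > 0))
})

test_that("price rows: ICER falls and INMB rises as the multiplier falls", {
  cfg <- cea_config()
  rows <- do.call(rbind, lapply(c(1, 0.9, 0.8, 0.7, 0.6, 0.5), function(m)
    run_scenario(cfg, scenario_spec("m", price_multiplier = m))))
  expect_true(all(diff(rows$icer) < 0))
  expect_true(all(diff(rows$inmb) > 0))
})

test_that("duration rules are ordered by incremental cost", {
  cfg <- cea_config()
  dc <- vapply(c("median_duration", "median_pfs", "protocol_max",
                 "until_progression"), function(r)
    run_scenario(cfg, scenario_spec(r, duration_rule = r))$delta_cost,
    numeric(1))
  expect_true(all(diff(dc) > 0))
})

test_that("a conversion factor of 1 scales point-denominated costs by 1/0.9198", {
  cfg <- cea_config()
  # isolate the point-denominated components by zeroing the cash-valued ones
  cfg$costs$admin <- 0
  cfg$costs$pd_admin <- 0
  cfg$costs$pd_drug <- 0
  cfg$costs$ae_neutropenia <- 0
  cfg$costs$ae_anemia <- 0
  base <- run_psm(cfg, "comparator")$accrual
  cfg1 <- cfg
  cfg1$settings$conversion_factor <- 1
  alt <- run_psm(cfg1, "comparator")$accrual
  expect_equal(alt$cost_pf_nonmed / base$cost_pf_nonmed, 1 / 0.9198)
  expect_equal(alt$cost_pd_nonmed / base$cost_pd_nonmed, 1 / 0.9198)
})

test_that("survival-block and custom survival overrides take effect", {
  cfg <- cea_config()
  alt <- run_scenario(cfg, scenario_spec("6a", survival = "scenario"))
  base <- run_scenario(cfg, scenario_spec("base"))
  expect_false(isTRUE(all.equal(alt$icer, base$icer)))

  custom <- scenario_spec("6b", survival = list(
    intervention = list(os = parsurv("weibull", c(1.3, 20)))))
  row <- run_scenario(cfg, custom)
  expect_false(isTRUE(all.equal(row$icer, base$icer)))
  expect_error(run_scenario(cfg, scenario_spec("bad", survival = list(
    nonsense = list(os = parsurv("weibull", c(1, 1)))))), "unknown arm")
})

test_that("the full grid returns one labelled row per scenario", {
  grid <- scenario_grid(cea_config())
  expect_equal(nrow(grid), 16)
  expect_true(!anyDuplicated(grid$label))
  expect_true(all(is.finite(grid$icer)))
  # the life-year row values effectiveness in life-years: larger denominator
  expect_gt(grid$delta_effect[grid$label ==
              "1. effectiveness: equal-value life-years gained"],
            grid$delta_effect[grid$label == "0. base case"])
})

test_that("scenario PSA columns appear on request and are reproducible", {
  cfg <- cea_config()
  r1 <- run_scenario(cfg, scenario_spec("base"), psa_n = 60, seed = 3)
  r2 <- run_scenario(cfg, scenario_spec("base"), psa_n = 60, seed = 3)
  expect_equal(r1$prob_ce, r2$prob_ce)
  expect_gte(r1$evpi, 0)
  rly <- run_scenario(cfg, scenario_spec("ly", measure = "ly"),
                      psa_n = 60, seed = 3)
  expect_true(is.finite(rly$prob_ce))
})
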