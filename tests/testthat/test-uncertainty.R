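test_that("sampled moments match the stated distributions (3 Monte Carlo SE)", {
  cfg <- cea_config()
  specs <- parameter_specs(cfg)
  sampled <- specs[specs$dist != "fixed", ]
  set.seed(5)
  n <- 1e5
  x <- sample_parameters(sampled, n)
  for (i in seq_len(nrow(sampled))) {
    s <- sampled[i, ]
    mo <- switch(s$dist,
      normal = c(s$p1, s$p2),
      gamma = c(s$p1, s$p2),
      beta = {
        m <- s$p1 / (s$p1 + s$p2)
        v <- s$p1 * s$p2 / ((s$p1 + s$p2)^2 * (s$p1 + s$p2 + 1))
        c(m, sqrt(v))
      },
      uniform = c((s$p1 + s$p2) / 2, (s$p2 - s$p1) / sqrt(12)))
    expect_lt(abs(mean(x[, s$name]) - mo[1]), 3 * mo[2] / sqrt(n) + 1e-12,
              label = s$name)
  }
  # the beta mean identity from the utility row
  u <- sampled[sampled$name == "u_pf_intervention", ]
  expect_equal(u$p1 / (u$p1 + u$p2), 0.812, tolerance = 0.001)
})

test_that("fixed specifications always return the base value", {
  cfg <- cea_config()
  specs <- parameter_specs(cfg)
  fx <- specs[specs$dist == "fixed", ]
  x <- sample_parameters(fx, 50)
  for (nm in colnames(x)) expect_true(all(x[, nm] == fx$base[fx$name == nm]))
})

test_that("non-positive normal draws are rejected and redrawn", {
  spec <- data.frame(name = "tight", label = "x", target = "os1", arm = "both",
                     base = 0.3, low = 0.1, high = 0.5, dist = "normal",
                     p1 = 0.3, p2 = 0.5)
  set.seed(6)
  x <- sample_parameters(spec, 2000)
  expect_true(all(x > 0))
  expect_gt(attr(x, "n_rejected"), 0)
})

test_that("invalid distribution parameters fail at specification time", {
  spec <- data.frame(name = "bad", label = "x", target = "admin", arm = "both",
                     base = 1, low = 1, high = 1, dist = "gamma",
                     p1 = -1, p2 = 2)
  expect_error(sample_parameters(spec, 10), "invalid distribution")
})

test_that("degenerate bounds yield zero tornado range and rank last", {
  cfg <- cea_config()
  specs <- parameter_specs(cfg)
  degenerate <- specs
  degenerate$low <- degenerate$base
  degenerate$high <- degenerate$base
  tor <- one_way_dsa(cfg, degenerate)
  expect_true(all(tor$inmb_range < 1e-6))

  one <- specs[specs$name %in% c("supportive_cost", "u_pf_intervention",
                                 "discount_rate"), ]
  one[one$name == "supportive_cost", c("low", "high")] <- 63077
  tor2 <- one_way_dsa(cfg, one)
  expect_equal(tor2$name[nrow(tor2)], "supportive_cost")
  expect_lt(tor2$inmb_range[nrow(tor2)], 1e-9)
})

test_that("raising only the comparator's supportive-care cost lowers the ICER", {
  cfg <- cea_config()
  base <- cea(cfg)
  shifted <- cea(cfg, overrides_comparator = list(supportive = 2 * 63077))
  expect_lt(shifted$icer, base$icer)
})

test_that("the most influential inputs are the utilities, drug cost and duration", {
  tor <- one_way_dsa(cea_config())
  top5 <- tor$name[1:5]
  expect_true(any(grepl("^u_pf", top5)))
  expect_true(any(grepl("^u_pd", top5)))
  expect_true("suge_cost" %in% tor$name[1:6])
  expect_true("duration_intervention" %in% tor$name[1:6])
  expect_true("supportive_cost" %in% tor$name[1:8])
})

test_that("an all-fixed PSA collapses to the base case with zero EVPI", {
  cfg <- cea_config()
  specs <- parameter_specs(cfg)
  specs$dist <- "fixed"
  p <- run_psa(cfg, n = 25, seed = 1, specs = specs)
  base <- cea(cfg)
  expect_true(all(abs(p$draws$delta_cost - base$delta_cost) < 1e-9))
  expect_equal(evpi(p, cfg$settings$wtp), 0)
  # CEAC is a unit step at the ICER
  expect_equal(ceac(p, base$icer * 0.99), 0)
  expect_equal(ceac(p, base$icer * 1.01), 1)
})

test_that("two-draw EVPI brute force", {
  fake <- list(draws = data.frame(
    cost_intervention = c(0, 0), qaly_intervention = c(10, -10),
    cost_comparator = c(0, 0), qaly_comparator = c(0, 0),
    delta_cost = c(0, 0), delta_qaly = c(10, -10)))
  expect_equal(evpi(fake, wtp = 1), 5)
  same <- list(draws = data.frame(
    cost_intervention = 1, qaly_intervention = 1,
    cost_comparator = 2, qaly_comparator = 2,
    delta_cost = -1, delta_qaly = -1)[c(1, 1), ])
  expect_equal(evpi(same, wtp = 3), 0)
})

test_that("PSA is reproducible and CEAC endpoints behave", {
  cfg <- cea_config()
  p1 <- run_psa(cfg, n = 120, seed = 9)
  p2 <- run_psa(cfg, n = 120, seed = 9)
  expect_identical(p1$draws, p2$draws)
  expect_identical(p1$ceac, p2$ceac)
  # at wtp 0, acceptability equals the fraction of cost-saving draws
  expect_equal(ceac(p1, 0), mean(p1$draws$delta_cost < 0))
  expect_true(all(p1$ceac$prob_cost_effective >= 0 &
                    p1$ceac$prob_cost_effective <= 1))
  expect_gte(p1$evpi, 0)
})

test_that("seed-to-seed spread of the acceptability estimate is binomial-scale", {
  cfg <- cea_config()
  probs <- vapply(1:3, function(s) run_psa(cfg, n = 400, seed = s)$prob_ce,
                  numeric(1))
  se <- sqrt(mean(probs) * (1 - mean(probs)) / 400)
  expect_lt(max(probs) - min(probs), 6 * se)
})
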