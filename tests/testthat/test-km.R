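test_that("textbook product-limit values", {
  km <- km_estimate(data.frame(time = c(1, 2, 3), event = 1))
  expect_equal(km$survival, c(1, 2/3, 1/3, 0))
  km2 <- km_estimate(data.frame(time = c(1, 2), event = c(1, 0)))
  expect_equal(km2$survival, c(1, 0.5))
  expect_equal(km2$time, c(0, 1))
  # all censored: the constant-1 function
  km3 <- km_estimate(data.frame(time = c(2, 5), event = 0))
  expect_equal(km3$survival, 1)
})

test_that("km_estimate agrees with a brute-force product over risk sets", {
  set.seed(7)
  d <- data.frame(time = round(rexp(100, 0.2), 2),
                  event = rbinom(100, 1, 0.7))
  d$time[d$time == 0] <- 0.01
  km <- km_estimate(d)
  oracle <- brute_km(d$time, d$event)
  expect_equal(km$time, oracle$time)
  expect_equal(km$survival, oracle$survival, tolerance = 1e-12)
})

test_that("trivial reconstructions are forced", {
  flat <- digitized_curve(points = data.frame(time = c(0, 12), survival = 1),
                          risk_table = data.frame(time = c(0, 12),
                                                  n_risk = c(100, 100)))
  ipd <- reconstruct_ipd(flat)
  expect_equal(nrow(ipd), 100)
  expect_equal(sum(ipd$event), 0)
  expect_true(all(ipd$time == 12))

  step <- digitized_curve(points = data.frame(time = c(0, 6, 12),
                                              survival = c(1, 0.5, 0.5)),
                          risk_table = data.frame(time = c(0, 12),
                                                  n_risk = c(10, 5)))
  ipd2 <- reconstruct_ipd(step)
  expect_equal(nrow(ipd2), 10)
  expect_equal(sum(ipd2$event), 5)
  expect_true(all(ipd2$time[ipd2$event == 1] == 6))
  expect_true(all(ipd2$time[ipd2$event == 0] == 12))
})

test_that("round trip: KM of reconstructed IPD reproduces the digitized curve", {
  set.seed(8)
  d <- simulate_ipd(parsurv("loglogistic", c(2.0, 13.3)), n = 300,
                    cutoff = 24, dropout = 0.1)
  fx <- make_km_fixture(d, grid = seq(0, 24, by = 3))
  ipd <- reconstruct_ipd(fx)
  expect_equal(nrow(ipd), 300)
  expect_equal(sum(ipd$event), fx$total_events)   # exact when supplied
  km <- km_estimate(ipd)
  s_hat <- km_step(km = km, t = fx$points$time)
  expect_lt(max(abs(s_hat - fx$points$survival)), 0.02)
})

test_that("reconstruction survives digitization noise", {
  set.seed(9)
  d <- simulate_ipd(parsurv("weibull", c(1.5, 14)), n = 250,
                    cutoff = 30, dropout = 0.15)
  fx <- make_km_fixture(d, grid = seq(0, 30, by = 5), noise = 0.005, seed = 10)
  ipd <- reconstruct_ipd(fx)
  km_true <- km_estimate(d)
  km_rec <- km_estimate(ipd)
  tt <- seq(0, 30, by = 1)
  expect_lt(max(abs(km_step(km_rec, tt) - km_step(km_true, tt))), 0.03)
})

test_that("reconstruction is deterministic", {
  set.seed(12)
  d <- simulate_ipd(parsurv("lognormal", c(2.4, 0.8)), n = 150, cutoff = 20,
                    dropout = 0.2)
  fx <- make_km_fixture(d, grid = seq(0, 20, by = 4))
  expect_identical(reconstruct_ipd(fx), reconstruct_ipd(fx))
})

test_that("inconsistent inputs are rejected with the interval identified", {
  expect_error(
    digitized_curve(points = data.frame(time = c(0, 5), survival = c(1, 0.5)),
                    risk_table = data.frame(time = c(0, 5), n_risk = c(50, 80))),
    "non-increasing")
  bad <- digitized_curve(points = data.frame(time = c(0, 3, 6),
                                             survival = c(1, 0.2, 0.2)),
                         risk_table = data.frame(time = c(0, 6),
                                                 n_risk = c(100, 50)))
  expect_error(reconstruct_ipd(bad), "interval 1")
})

test_that("IPD and digitized curves survive a file round trip", {
  set.seed(13)
  d <- simulate_ipd(parsurv("exponential", 0.1), n = 40, cutoff = 15,
                    arm = "comparator")
  f <- tempfile(fileext = ".csv")
  write_ipd(d, f)
  d2 <- read_ipd(f)
  expect_equal(d2$time, d$time)
  expect_equal(d2$event, d$event)
  expect_equal(d2$arm, d$arm)

  fx <- make_km_fixture(d, grid = c(0, 5, 10, 15))
  fp <- tempfile(fileext = ".csv"); fr <- tempfile(fileext = ".csv")
  write_digitized_curve(fx, fp, fr)
  fx2 <- read_digitized_curve(fp, fr, total_events = fx$total_events)
  expect_equal(fx2$points$survival, fx$points$survival, tolerance = 1e-12)
  expect_equal(fx2$risk_table$n_risk, fx$risk_table$n_risk)
})
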