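# Independent brute-force product-limit estimator: the survival at each
# event time is the running product over risk sets, computed directly from
# the definition (no survfit).
brute_km <- function(time, event) {
  ut <- sort(unique(time[event == 1]))
  s <- 1
  out <- data.frame(time = 0, survival = 1)
  for (t in ut) {
    n_risk <- sum(time >= t)
    d <- sum(time == t & event == 1)
    s <- s * (1 - d / n_risk)
    out <- rbind(out, data.frame(time = t, survival = s))
  }
  out
}

# trapezoid integral of a survival curve over [0, t_max] months, in years
trapz_surv_years <- function(model, t_max, n = 20000, discount = 0) {
  tt <- seq(0, t_max, length.out = n)
  s <- surv_prob(model, tt) * (1 + discount)^(-tt / 12)
  sum((s[-1] + s[-n]) / 2 * diff(tt)) / 12
}

# a config whose only nonzero cost is the rule-based drug: INMB is then
# linear in the price multiplier
linear_price_config <- function() {
  cfg <- cea_config()
  for (nm in names(cfg$costs)) cfg$costs[[nm]] <- 0
  cfg$strategies$intervention$drugs$capox$annual_cost <- 0
  cfg$strategies$comparator$drugs$capox$annual_cost <- 0
  cfg
}

seven_families_fixture <- function() {
  list(
    exponential = parsurv("exponential", 0.08),
    weibull = parsurv("weibull", c(1.4, 14)),
    gamma = parsurv("gamma", c(1.8, 0.12)),
    lognormal = parsurv("lognormal", c(2.5, 0.9)),
    loglogistic = parsurv("loglogistic", c(2.0, 13.3)),
    gompertz = parsurv("gompertz", c(0.05, 0.04)),
    gengamma = parsurv("gengamma", c(2.5, 0.8, 0.5)))
}
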