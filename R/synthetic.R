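#' Simulate right-censored time-to-event data
#'
#' Generates the statistical stand-in for unavailable trial individual
#' patient data: event times are drawn from a [parsurv] model by inverse-CDF
#' sampling, then right-censored by the earlier of an administrative cutoff
#' and (for a random fraction of subjects) a uniformly distributed dropout
#' time.
#'
#' @param model A [parsurv] object (time scale: months).
#' @param n Number of subjects.
#' @param cutoff Administrative censoring time in months (`Inf` for none).
#' @param dropout Fraction in `[0, 1)` of subjects with a dropout time drawn
#'   uniformly on `(0, cutoff)`; requires a finite `cutoff` when positive.
#' @param arm Optional arm label stored in the output.
#' @param seed Optional integer seed (draws are deterministic given it).
#' @return Data frame with columns `time`, `event` (1 = event observed,
#'   0 = censored) and `arm`.
#' @examples
#' d <- simulate_ipd(parsurv("exponential", 0.1), n = 100, cutoff = 10, seed = 1)
#' mean(d$event)  # about 1 - exp(-1)
#' @export
simulate_ipd <- function(model, n, cutoff = Inf, dropout = 0, arm = "arm",
                         seed = NULL) {
  stopifnot(n >= 1, cutoff > 0, dropout >= 0, dropout < 1)
  if (dropout > 0 && !is.finite(cutoff))
    stop("dropout censoring requires a finite cutoff", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  t_event <- surv_quantile(model, stats::runif(n))
  t_cens <- rep(cutoff, n)
  if (dropout > 0) {
    drop <- stats::runif(n) < dropout
    t_drop <- stats::runif(n, 0, cutoff)
    t_cens[drop] <- pmin(t_cens[drop], t_drop[drop])
  }
  event <- as.integer(t_event <= t_cens)
  data.frame(time = pmin(t_event, t_cens), event = event, arm = arm)
}

#' Build a digitized-curve fixture from individual patient data
#'
#' Round-trip partner of [reconstruct_ipd()]: evaluates the true
#' Kaplan-Meier step function of `data` at a reporting grid and attaches the
#' exact at-risk counts at those times, optionally perturbing the survival
#' values with digitization noise.
#'
#' @param data Data frame with columns `time`, `event`.
#' @param grid Increasing report times (months) within the observation
#'   window; 0 is prepended if absent. At-risk counts are taken at grid
#'   times; survival is also reported at every KM step between them so that
#'   the curve keeps its full resolution.
#' @param noise Standard deviation of Gaussian digitization noise added to
#'   survival values (0 = exact). Noisy values are re-monotonized by
#'   [digitized_curve()].
#' @param seed Optional integer seed for the noise.
#' @return A [digitized_curve()] with `total_events` set to the true count.
#' @export
make_km_fixture <- function(data, grid, noise = 0, seed = NULL) {
  if (nrow(data) == 0) stop("empty data", call. = FALSE)
  grid <- sort(unique(c(0, as.numeric(grid))))
  if (max(grid) > max(data$time) + 1e-9)
    stop("grid extends past the observation window", call. = FALSE)
  km <- km_estimate(data)
  step_times <- sort(unique(c(grid, km$time[km$time <= max(grid)])))
  s <- km_step(km, step_times)
  if (noise > 0) {
    if (!is.null(seed)) set.seed(seed)
    keep <- step_times > 0
    s[keep] <- s[keep] + stats::rnorm(sum(keep), 0, noise)
  }
  n_risk <- vapply(grid, function(g) sum(data$time >= g - 1e-12), numeric(1))
  digitized_curve(points = data.frame(time = step_times, survival = s),
                  risk_table = data.frame(time = grid, n_risk = n_risk),
                  total_events = sum(data$event))
}
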