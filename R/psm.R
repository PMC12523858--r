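# Discrete-time grid over the model horizon. State occupancy is evaluated at
# cycle midpoints (second-order accurate, the discrete stand-in for a
# half-cycle correction); treatment exposure at cycle ends (see run_psm).
cycle_grid <- function(settings) {
  cm <- settings$cycle_days / 30.4375           # cycle length in months
  n <- ceiling(settings$horizon_years * 12 / cm)
  lo <- (seq_len(n) - 1) * cm
  hi <- lo + cm
  mid <- lo + cm / 2
  list(n = n, cm = cm, lo = lo, hi = hi, mid = mid,
       cyc_yr = settings$cycle_days / 365.25,
       disc = (1 + settings$discount_rate)^(-mid / 12))
}

#' Partitioned-survival state occupancy
#'
#' The three-state partition at time t: progression-free
#' `pf = min(S_pfs(t), S_os(t))`, progressed `pd = S_os(t) - pf`, and
#' `dead = 1 - S_os(t)`. Where the fitted curves cross (`S_pfs > S_os`,
#' which independent fitting can produce in the extrapolated tail), PF is
#' capped at overall survival; the number of capped time points is reported
#' in the `"n_crossings"` attribute.
#'
#' @param os,pfs [parsurv] models for overall and progression-free survival.
#' @param t Non-negative times (months).
#' @return Data frame with columns `t`, `pf`, `pd`, `dead` (rows sum to 1).
#' @export
state_occupancy <- function(os, pfs, t) {
  s_os <- surv_prob(os, t)
  s_pfs <- surv_prob(pfs, t)
  pf <- pmin(s_pfs, s_os)
  out <- data.frame(t = t, pf = pf, pd = s_os - pf, dead = 1 - s_os)
  attr(out, "n_crossings") <- sum(s_pfs > s_os + 1e-12)
  out
}

#' Per-cycle on-treatment occupancy
#'
#' On-treatment occupancy at time t is `S_pfs(t) * 1{t < cap}` (capped at
#' overall survival when `os` is supplied): patients receive treatment while
#' progression-free and within the stopping time. Each cycle's value is the
#' midpoint occupancy of the treated part of the cycle, weighted by the
#' fraction of the cycle before the cap, so that the implied treated time
#' `sum(exposure) * cycle_years` is a midpoint-rule integral of the capped
#' survival curve.
#'
#' @param pfs A [parsurv] model for progression-free survival.
#' @param cap Stopping time in months (`Inf` = until progression).
#' @param settings A settings list as in [cea_config()] (fields
#'   `cycle_days`, `horizon_years`, `discount_rate`).
#' @param os Optional [parsurv] overall-survival model used to cap PF.
#' @return Data frame with columns `cycle`, `t_mid` and `exposure`.
#' @export
treatment_exposure <- function(pfs, cap, settings, os = NULL) {
  stopifnot(cap > 0)
  g <- cycle_grid(settings)
  ov <- pmax(0, pmin(cap, g$hi) - g$lo)      # treated fraction of each cycle
  t_eval <- g$lo + ov / 2
  s <- surv_prob(pfs, t_eval)
  if (!is.null(os)) s <- pmin(s, surv_prob(os, t_eval))
  data.frame(cycle = seq_len(g$n), t_mid = g$mid, exposure = s * ov / g$cm)
}

# flat per-arm inputs consumed by the engine; `overrides` patches named
# entries (numeric scalars, or survival parameters via os1/os2/pfs1/pfs2)
arm_inputs <- function(cfg, arm, overrides = list()) {
  st <- cfg$strategies[[arm]]
  if (is.null(st)) stop("unknown arm: ", arm, call. = FALSE)
  s <- cfg$settings
  inp <- list(
    arm = arm, name = st$name,
    os = st$os, pfs = st$pfs,
    u_pf = st$utilities$pf, u_pd = st$utilities$pd,
    ae_prob_neutropenia = st$ae_probs$neutropenia,
    ae_prob_anemia = st$ae_probs$anemia,
    ae_cost_neutropenia = cfg$costs$ae_neutropenia,
    ae_cost_anemia = cfg$costs$ae_anemia,
    dis_neutropenia = cfg$disutilities$neutropenia,
    dis_anemia = cfg$disutilities$anemia,
    admin = cfg$costs$admin, pf_nonmed = cfg$costs$pf_nonmed,
    supportive = cfg$costs$supportive, pd_drug = cfg$costs$pd_drug,
    pd_admin = cfg$costs$pd_admin, terminal = cfg$costs$terminal,
    conversion_factor = s$conversion_factor,
    duration = st$duration_caps[[s$duration_rule]])
  drugs <- lapply(names(st$drugs), function(nm) {
    d <- st$drugs[[nm]]
    cap <- if (isTRUE(d$rule_based)) inp$duration else d$cap_months
    cost <- d$annual_cost
    if (isTRUE(d$rule_based)) cost <- cost * s$price_multiplier
    list(name = nm, annual_cost = cost, cap_months = cap,
         rule_based = isTRUE(d$rule_based),
         admin_linked = !isTRUE(d$rule_based))
  })
  names(drugs) <- names(st$drugs)
  inp$drugs <- drugs

  for (nm in names(overrides)) {
    v <- overrides[[nm]]
    if (nm %in% c("os1", "os2", "pfs1", "pfs2")) {
      ep <- if (startsWith(nm, "os")) "os" else "pfs"
      k <- as.integer(substring(nm, nchar(nm)))
      p <- inp[[ep]]$params
      p[k] <- v
      inp[[ep]] <- parsurv(inp[[ep]]$family, unname(p))
    } else if (nm == "suge_cost") {
      for (d in names(inp$drugs))
        if (inp$drugs[[d]]$rule_based)
          inp$drugs[[d]]$annual_cost <- v * cfg$settings$price_multiplier
    } else if (nm == "capox_cost") {
      for (d in names(inp$drugs))
        if (!inp$drugs[[d]]$rule_based) inp$drugs[[d]]$annual_cost <- v
    } else if (nm == "duration") {
      inp$duration <- v
      for (d in names(inp$drugs))
        if (inp$drugs[[d]]$rule_based) inp$drugs[[d]]$cap_months <- v
    } else if (nm %in% names(inp)) {
      inp[[nm]] <- v
    } else {
      stop("unknown override: ", nm, call. = FALSE)
    }
  }
  # duration override must reach rule-based caps even when set before drugs
  inp
}

psm_engine <- function(inp, settings) {
  g <- cycle_grid(settings)
  s_os_b <- surv_prob(inp$os, c(g$lo, g$hi[g$n]))    # cycle bounds, n + 1 values
  s_os_mid <- surv_prob(inp$os, g$mid)
  s_pfs_mid <- surv_prob(inp$pfs, g$mid)
  s_pfs_end <- surv_prob(inp$pfs, g$hi)
  s_os_end <- s_os_b[-1]
  pf <- pmin(s_pfs_mid, s_os_mid)
  pd <- s_os_mid - pf
  dead <- 1 - s_os_mid
  pf_end <- pmin(s_pfs_end, s_os_end)
  deaths <- s_os_b[-(g$n + 1)] - s_os_b[-1]
  n_crossings <- sum(s_pfs_mid > s_os_mid + 1e-12)

  wdisc <- g$disc * g$cyc_yr
  ly_pf <- sum(pf * wdisc)
  ly_pd <- sum(pd * wdisc)

  # whole-cycle treatment caps; exposure measured at cycle end
  expo_yr <- function(cap) {
    k <- if (!is.finite(cap)) g$n else floor(cap / g$cm + 1e-9)
    k <- min(k, g$n)
    if (k <= 0) return(0)
    sum(pf_end[seq_len(k)] * wdisc[seq_len(k)])
  }
  drug_costs <- vapply(inp$drugs, function(d) d$annual_cost * expo_yr(d$cap_months),
                       numeric(1))
  admin_expo <- 0
  for (d in inp$drugs) if (d$admin_linked) admin_expo <- max(admin_expo, expo_yr(d$cap_months))
  if (length(inp$drugs) > 0 && !any(vapply(inp$drugs, `[[`, logical(1), "admin_linked")))
    admin_expo <- max(vapply(inp$drugs, function(d) expo_yr(d$cap_months), numeric(1)))

  cf <- inp$conversion_factor
  ae_probs <- c(inp$ae_prob_neutropenia, inp$ae_prob_anemia)
  ae_costs <- c(inp$ae_cost_neutropenia, inp$ae_cost_anemia)
  ae_dis <- c(inp$dis_neutropenia, inp$dis_anemia)

  cost_pf_med <- sum(drug_costs)
  cost_pf_nonmed <- inp$admin * admin_expo + inp$pf_nonmed * cf * ly_pf
  cost_pd_med <- inp$pd_drug * ly_pd
  cost_pd_nonmed <- inp$supportive * cf * ly_pd + inp$pd_admin * ly_pd +
    inp$terminal * cf / 12 * sum(deaths * g$disc)
  cost_ae <- sum(ae_probs * ae_costs) * g$disc[1]
  dec_ae <- sum(ae_probs * ae_dis) * g$disc[1]

  qaly_pf <- inp$u_pf * ly_pf - dec_ae
  qaly_pd <- inp$u_pd * ly_pd

  on_treatment <- rep(0, g$n)
  for (d in inp$drugs) {
    k <- if (!is.finite(d$cap_months)) g$n else min(floor(d$cap_months / g$cm + 1e-9), g$n)
    if (k > 0) on_treatment[seq_len(k)] <- pf_end[seq_len(k)]
  }

  list(
    trace = data.frame(cycle = seq_len(g$n), t_start = g$lo, t_mid = g$mid,
                       t_end = g$hi, pf = pf, pd = pd, dead = dead,
                       on_treatment = on_treatment, deaths = deaths),
    accrual = list(
      ly_pf = ly_pf, ly_pd = ly_pd, ly_total = ly_pf + ly_pd,
      qaly_pf = qaly_pf, qaly_pd = qaly_pd, qaly_total = qaly_pf + qaly_pd,
      cost_pf_med = cost_pf_med, cost_pf_nonmed = cost_pf_nonmed,
      cost_pd_med = cost_pd_med, cost_pd_nonmed = cost_pd_nonmed,
      cost_ae = cost_ae,
      cost_total = cost_pf_med + cost_pf_nonmed + cost_pd_med +
        cost_pd_nonmed + cost_ae),
    diagnostics = list(
      n_crossings = n_crossings,
      s_os_horizon = unname(s_os_b[g$n + 1]),
      horizon_warning = unname(s_os_b[g$n + 1]) > 0.01))
}

#' Run the partitioned survival model for one strategy
#'
#' Builds the per-cycle state-occupancy trace over the model horizon and
#' accrues discounted life-years, QALYs and costs under the model's accrual
#' rules:
#' \itemize{
#'   \item State occupancy (PF, PD, dead) is evaluated at cycle midpoints;
#'     each cycle's flows are discounted at the midpoint.
#'   \item Drug acquisition and chemotherapy administration costs accrue on
#'     on-treatment occupancy, evaluated at cycle ends, for whole treatment
#'     cycles up to each drug's stopping time (see [cea_config()]).
#'   \item PF non-medication services accrue on PF occupancy; supportive
#'     care, PD medication and PD administration on PD occupancy; terminal
#'     care as one month of its annual rate per incident death.
#'   \item Point-denominated rates (PF non-medication, supportive, terminal)
#'     are multiplied by the fee-schedule conversion factor.
#'   \item Adverse events are one-off: in the first cycle each modeled event
#'     contributes `prob * cost` and a QALY decrement `prob * disutility`.
#' }
#'
#' @param cfg A [cea_config()].
#' @param arm `"intervention"` or `"comparator"`.
#' @param overrides Named list of input patches (used by the sensitivity
#'   analyses), e.g. `list(supportive = 80000)` or `list(os2 = 15)` for the
#'   second overall-survival parameter.
#' @return An object of class `"psm_run"`: list with `trace` (data frame),
#'   `accrual` (named list of discounted totals) and `diagnostics`.
#' @examples
#' run <- run_psm(cea_config(), "comparator")
#' run$accrual$qaly_total
#' @export
run_psm <- function(cfg, arm = c("intervention", "comparator"),
                    overrides = list()) {
  arm <- match.arg(arm)
  validate_config(cfg)
  inp <- arm_inputs(cfg, arm, overrides)
  out <- psm_engine(inp, cfg$settings)
  out$arm <- arm
  out$name <- inp$name
  out$settings <- cfg$settings
  class(out) <- "psm_run"
  out
}

#' @export
print.psm_run <- function(x, ...) {
  a <- x$accrual
  cat(sprintf("Partitioned survival run: %s\n", x$name))
  cat(sprintf("  LY   %6.3f (PF %5.3f, PD %5.3f)\n", a$ly_total, a$ly_pf, a$ly_pd))
  cat(sprintf("  QALY %6.3f (PF %5.3f, PD %5.3f)\n", a$qaly_total, a$qaly_pf, a$qaly_pd))
  cat(sprintf("  Cost %10.0f USD (PF med %.0f, PF non-med %.0f, PD med %.0f, PD non-med %.0f, AE %.0f)\n",
              a$cost_total, a$cost_pf_med, a$cost_pf_nonmed, a$cost_pd_med,
              a$cost_pd_nonmed, a$cost_ae))
  if (x$diagnostics$horizon_warning)
    cat(sprintf("  note: S_os at horizon = %.3f > 0.01; horizon may be short\n",
                x$diagnostics$s_os_horizon))
  invisible(x)
}

#' @export
summary.psm_run <- function(object, ...) print(object)
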