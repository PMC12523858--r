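#' Cost-effectiveness analysis of the two strategies
#'
#' Runs the partitioned survival model for both strategies of a
#' configuration and derives the pairwise comparison: incremental cost,
#' incremental effect (QALYs and life-years), ICER and incremental net
#' monetary benefit at the configured willingness to pay. All deltas use
#' unrounded totals.
#'
#' @param cfg A [cea_config()].
#' @param overrides_intervention,overrides_comparator Optional named input
#'   patches per arm (see [run_psm()]).
#' @return Object of class `"cea"`: the two [run_psm()] results plus
#'   `delta_cost`, `delta_qaly`, `delta_ly`, `icer`, `inmb`, `icer_ly`,
#'   `inmb_ly`, `wtp`.
#' @examples
#' \donttest{
#' res <- cea(cea_config())
#' res$icer
#' }
#' @export
cea <- function(cfg, overrides_intervention = list(),
                overrides_comparator = list()) {
  int <- run_psm(cfg, "intervention", overrides_intervention)
  com <- run_psm(cfg, "comparator", overrides_comparator)
  cq <- compare_strategies(int, com, cfg$settings$wtp, "qaly")
  cl <- compare_strategies(int, com, cfg$settings$wtp, "ly")
  structure(list(
    intervention = int, comparator = com,
    delta_cost = cq$delta_cost, delta_qaly = cq$delta_effect,
    delta_ly = cl$delta_effect,
    icer = cq$icer, inmb = cq$inmb,
    icer_ly = cl$icer, inmb_ly = cl$inmb,
    wtp = cfg$settings$wtp),
    class = "cea")
}

#' Pairwise strategy comparison
#'
#' Computes incremental cost, incremental effect, the incremental
#' cost-effectiveness ratio and incremental net monetary benefit
#' `INMB = delta_effect * wtp - delta_cost`. With
#' `measure = "ly"` effectiveness is measured in unweighted life-years (the
#' equal-value-of-life-years-gained convention, in which a year of survival
#' is valued at full weight regardless of quality of life).
#'
#' @param intervention,comparator [run_psm()] results (or bare accrual
#'   lists) computed under identical settings.
#' @param wtp Willingness to pay per effect unit (USD).
#' @param measure `"qaly"` or `"ly"`.
#' @return Object of class `"ce_comparison"` with `delta_cost`,
#'   `delta_effect`, `icer` (`NA` with attribute `"undefined"` when the
#'   incremental effect is not positive), `inmb`, `measure`, `wtp`.
#' @examples
#' a <- list(cost_total = 200, qaly_total = 2, ly_total = 2.5)
#' b <- list(cost_total = 100, qaly_total = 1, ly_total = 1.5)
#' compare_strategies(a, b, wtp = 50)
#' @export
compare_strategies <- function(intervention, comparator, wtp,
                               measure = c("qaly", "ly")) {
  measure <- match.arg(measure)
  acc <- function(x) if (inherits(x, "psm_run")) x$accrual else x
  ai <- acc(intervention); ac <- acc(comparator)
  dc <- ai$cost_total - ac$cost_total
  de <- if (measure == "qaly") ai$qaly_total - ac$qaly_total
        else ai$ly_total - ac$ly_total
  icer <- if (de > 0) dc / de else structure(NA_real_, undefined = TRUE)
  structure(list(delta_cost = dc, delta_effect = de, icer = icer,
                 inmb = de * wtp - dc, measure = measure, wtp = wtp),
            class = "ce_comparison")
}

#' @export
print.ce_comparison <- function(x, ...) {
  unit <- if (x$measure == "qaly") "QALY" else "LY"
  cat(sprintf("Incremental cost %.0f USD, incremental effect %.4f %s\n",
              x$delta_cost, x$delta_effect, unit))
  if (is.na(x$icer)) cat("ICER undefined (non-positive incremental effect)\n")
  else cat(sprintf("ICER %.0f USD/%s\n", x$icer, unit))
  cat(sprintf("INMB %.0f USD at WTP %.0f USD/%s\n", x$inmb, x$wtp, unit))
  invisible(x)
}

#' @export
print.cea <- function(x, ...) {
  cat(sprintf("%s vs %s\n", x$intervention$name, x$comparator$name))
  cat(sprintf("  Incremental cost  %9.0f USD\n", x$delta_cost))
  cat(sprintf("  Incremental QALY  %9.3f   Incremental LY %7.3f\n",
              x$delta_qaly, x$delta_ly))
  cat(sprintf("  ICER  %9.0f USD/QALY   (%9.0f USD/LY)\n", x$icer, x$icer_ly))
  cat(sprintf("  INMB  %9.0f USD at WTP %s USD/QALY\n", x$inmb,
              format(x$wtp, big.mark = ",")))
  invisible(x)
}

#' @export
summary.cea <- function(object, ...) {
  x <- object
  ai <- x$intervention$accrual; ac <- x$comparator$accrual
  tab <- data.frame(
    intervention = c(ai$cost_total, ai$cost_pf_med, ai$cost_pf_nonmed,
                     ai$cost_pd_med, ai$cost_pd_nonmed, ai$cost_ae,
                     ai$ly_total, ai$ly_pf, ai$ly_pd,
                     ai$qaly_total, ai$qaly_pf, ai$qaly_pd),
    comparator = c(ac$cost_total, ac$cost_pf_med, ac$cost_pf_nonmed,
                   ac$cost_pd_med, ac$cost_pd_nonmed, ac$cost_ae,
                   ac$ly_total, ac$ly_pf, ac$ly_pd,
                   ac$qaly_total, ac$qaly_pf, ac$qaly_pd))
  rownames(tab) <- c("Total cost (USD)", "  PF medication", "  PF non-medication",
                     "  PD medication", "  PD non-medication", "  AE management",
                     "Life-years", "  PF state", "  PD state",
                     "QALYs", "  PF state ", "  PD state ")
  tab$incremental <- tab$intervention - tab$comparator
  print(round(tab, 3))
  cat(sprintf("\nICER %.0f USD/QALY (%0.f USD/LY); INMB %.0f USD at WTP %s\n",
              x$icer, x$icer_ly, x$inmb, format(x$wtp, big.mark = ",")))
  invisible(tab)
}

#' Value-based price threshold for sugemalimab
#'
#' Finds the sugemalimab price multiplier at which the incremental net
#' monetary benefit crosses zero, by bisection on `m` in `[0, 1]` until
#' `|INMB(m)| < tol`. The multiplier scales the drug's annual acquisition
#' cost, which is proportional to the per-vial price (annual cost =
#' price per 600 mg x 2 vials per administration x administrations per
#' year), so the threshold price per 600 mg is `m` times the reference
#' price.
#'
#' @param cfg A [cea_config()].
#' @param duration_rule Optional duration rule override (e.g.
#'   `"until_progression"` for the price required when reimbursement
#'   follows progression).
#' @param wtp Optional willingness-to-pay override (USD/QALY).
#' @param tol Absolute INMB tolerance at the solution (USD).
#' @return Object of class `"price_threshold"`: `multiplier`,
#'   `price_per_600mg`, `reduction_pct`, `inmb`, `already_cost_effective`.
#'   If the strategy is already cost-effective at full price, the multiplier
#'   is 1 and the flag is set; if INMB is still negative at price zero, an
#'   error is raised.
#' @examples
#' \donttest{
#' price_threshold(cea_config())$price_per_600mg
#' }
#' @export
price_threshold <- function(cfg, duration_rule = NULL, wtp = NULL, tol = 0.5) {
  if (!is.null(duration_rule)) cfg$settings$duration_rule <- duration_rule
  if (!is.null(wtp)) cfg$settings$wtp <- wtp
  ref_price <- cfg$settings$sugemalimab_price_per_600mg
  inmb_at <- function(m) {
    cfg$settings$price_multiplier <- m
    cea(cfg)$inmb
  }
  f1 <- inmb_at(1)
  if (f1 >= 0) {
    return(structure(list(multiplier = 1, price_per_600mg = ref_price,
                          reduction_pct = 0, inmb = f1,
                          already_cost_effective = TRUE),
                     class = "price_threshold"))
  }
  f0 <- inmb_at(0)
  if (f0 < 0)
    stop("no solution: INMB is negative even at price zero", call. = FALSE)
  lo <- 0; hi <- 1
  fm <- f0; m <- 0
  for (i in 1:200) {
    m <- (lo + hi) / 2
    fm <- inmb_at(m)
    if (abs(fm) < tol) break
    if (fm > 0) lo <- m else hi <- m
  }
  structure(list(multiplier = m, price_per_600mg = ref_price * m,
                 reduction_pct = 100 * (1 - m), inmb = fm,
                 already_cost_effective = FALSE),
            class = "price_threshold")
}

#' @export
print.price_threshold <- function(x, ...) {
  if (x$already_cost_effective) {
    cat("Already cost-effective at the current price (INMB",
        sprintf("%.0f USD)\n", x$inmb))
  } else {
    cat(sprintf("Threshold price: %.0f USD per 600 mg (multiplier %.3f, a %.0f%% reduction)\n",
                x$price_per_600mg, x$multiplier, x$reduction_pct))
  }
  invisible(x)
}
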