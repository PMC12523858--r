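#' Uncertain-parameter specifications
#'
#' Builds the table of uncertain quantities for the sensitivity analyses:
#' one row per parameter with its base value, one-way bounds (95% CI where
#' available, otherwise +-25%), and the probabilistic distribution
#' (normal for survival parameters, gamma for cost rates, beta for utilities
#' and disutilities, uniform for the fee-schedule conversion factor; the
#' sugemalimab price, adverse-event probabilities, treatment durations and
#' the discount rate are fixed in the probabilistic analysis but still vary
#' one-way). Gamma distributions are parameterized by mean and SD
#' (shape = (mean/sd)^2, scale = sd^2/mean).
#'
#' @param cfg A [cea_config()].
#' @return Data frame with columns `name`, `label`, `target` (engine input
#'   patched by the parameter), `arm` (`"both"` or one arm), `base`, `low`,
#'   `high`, `dist` (`normal`, `gamma`, `beta`, `uniform`, `fixed`), `p1`,
#'   `p2`.
#' @export
parameter_specs <- function(cfg) {
  rowspec <- function(name, label, target, arm, base, low, high, dist, p1 = NA, p2 = NA)
    data.frame(name = name, label = label, target = target, arm = arm,
               base = base, low = low, high = high, dist = dist,
               p1 = p1, p2 = p2, stringsAsFactors = FALSE)
  cat_ <- survival_catalog()
  cat_ <- cat_[cat_$population == cfg$population &
                 cat_$block == cfg$survival_block, ]
  sv <- do.call(rbind, lapply(seq_len(nrow(cat_)), function(i) {
    r <- cat_[i, ]
    pn <- family_info(r$family)$par_names
    rbind(
      rowspec(sprintf("%s_%s_%s", r$endpoint, r$arm, pn[1]),
              sprintf("%s %s %s (%s)", toupper(r$endpoint), pn[1], r$family, r$arm),
              paste0(r$endpoint, "1"), r$arm, r$p1, r$lo1, r$hi1, "normal", r$p1, r$se1),
      rowspec(sprintf("%s_%s_%s", r$endpoint, r$arm, pn[2]),
              sprintf("%s %s %s (%s)", toupper(r$endpoint), pn[2], r$family, r$arm),
              paste0(r$endpoint, "2"), r$arm, r$p2, r$lo2, r$hi2, "normal", r$p2, r$se2))
  }))
  co <- cfg$costs
  st <- cfg$strategies
  dur_i <- st$intervention$duration_caps$median_duration
  dur_c <- st$comparator$duration_caps$median_duration
  rbind(
    sv,
    rowspec("duration_intervention", "Treatment duration, sugemalimab + CAPOX (months)",
            "duration", "intervention", dur_i, 0.75 * dur_i, 1.25 * dur_i, "fixed"),
    rowspec("duration_comparator", "Treatment duration, CAPOX (months)",
            "duration", "comparator", dur_c, 0.75 * dur_c, 1.25 * dur_c, "fixed"),
    rowspec("suge_cost", "Medication cost, sugemalimab (USD/year)",
            "suge_cost", "intervention", 59814, 44860, 74767, "fixed"),
    rowspec("capox_cost", "Medication cost, CAPOX (USD/year)",
            "capox_cost", "both", 8959, 8474, 9444, "gamma", 8959, 247),
    rowspec("admin_cost", "Chemotherapy administration cost (USD/year)",
            "admin", "both", co$admin, 1148, 1303, "gamma", 1226, 39),
    rowspec("pf_nonmed_cost", "PF non-medication cost (USD/year)",
            "pf_nonmed", "both", co$pf_nonmed, 22402, 29449, "gamma", 25925, 1798),
    rowspec("supportive_cost", "Supportive care cost, PD state (USD/year)",
            "supportive", "both", co$supportive, 41234, 84920, "gamma", 63077, 11144),
    rowspec("pd_drug_cost", "PD medication cost (USD/year)",
            "pd_drug", "both", co$pd_drug, 3878, 5485, "gamma", 4682, 410),
    rowspec("pd_admin_cost", "PD chemotherapy administration cost (USD/year)",
            "pd_admin", "both", co$pd_admin, 1551, 2485, "gamma", 2018, 238),
    rowspec("terminal_cost", "Terminal care cost (USD/year)",
            "terminal", "both", co$terminal, 50519, 59266, "gamma", 54893, 2231),
    rowspec("ae_cost_neutropenia", "Neutropenia management cost (USD)",
            "ae_cost_neutropenia", "both", co$ae_neutropenia, 388, 1151, "gamma", 769, 195),
    rowspec("ae_cost_anemia", "Anemia management cost (USD)",
            "ae_cost_anemia", "both", co$ae_anemia, 959, 2029, "gamma", 1494, 273),
    rowspec("ae_prob_neutropenia_intervention", "Neutropenia probability (sugemalimab + CAPOX)",
            "ae_prob_neutropenia", "intervention", 0.141, 0.10575, 0.17625, "fixed"),
    rowspec("ae_prob_anemia_intervention", "Anemia probability (sugemalimab + CAPOX)",
            "ae_prob_anemia", "intervention", 0.183, 0.13725, 0.22875, "fixed"),
    rowspec("ae_prob_neutropenia_comparator", "Neutropenia probability (CAPOX)",
            "ae_prob_neutropenia", "comparator", 0.143, 0.10725, 0.17875, "fixed"),
    rowspec("ae_prob_anemia_comparator", "Anemia probability (CAPOX)",
            "ae_prob_anemia", "comparator", 0.160, 0.12, 0.20, "fixed"),
    rowspec("u_pf_intervention", "Utility, PF state (sugemalimab + CAPOX)",
            "u_pf", "intervention", 0.812, 0.609, 1.0, "beta", 10.74, 2.49),
    rowspec("u_pd_intervention", "Utility, PD state (sugemalimab + CAPOX)",
            "u_pd", "intervention", 0.746, 0.5595, 0.9325, "beta", 14.87, 5.06),
    rowspec("u_pf_comparator", "Utility, PF state (CAPOX)",
            "u_pf", "comparator", 0.798, 0.5985, 0.9975, "beta", 11.62, 2.94),
    rowspec("u_pd_comparator", "Utility, PD state (CAPOX)",
            "u_pd", "comparator", 0.721, 0.54075, 0.90125, "beta", 16.43, 6.36),
    rowspec("dis_neutropenia", "Disutility, neutropenia",
            "dis_neutropenia", "both", 0.2, 0.15, 0.25, "beta", 48.97, 195.89),
    rowspec("dis_anemia", "Disutility, anemia",
            "dis_anemia", "both", 0.07, 0.0525, 0.0875, "beta", 57.09, 758.52),
    rowspec("discount_rate", "Annual discount rate",
            "discount", "both", cfg$settings$discount_rate, 0, 0.05, "fixed"),
    rowspec("conversion_factor", "Fee-schedule conversion factor (TWD/point)",
            "conversion_factor", "both", cfg$settings$conversion_factor,
            0.853, 0.9913, "uniform", 0.853, 0.9913))
}

#' Sample one or more draws from parameter specifications
#'
#' Independent draws per specification row; `fixed` rows return the base
#' value. Normal draws for strictly positive quantities (survival shape and
#' scale parameters) are rejected and redrawn if non-positive; the number of
#' rejections is recorded in the `"n_rejected"` attribute. Beta draws lie in
#' `[0, 1]` by construction.
#'
#' @param specs A [parameter_specs()] data frame (any subset of rows).
#' @param n Number of draws.
#' @return An `n` x `nrow(specs)` numeric matrix, columns named by
#'   `specs$name`.
#' @export
sample_parameters <- function(specs, n = 1) {
  bad <- specs$dist == "gamma" & (specs$p1 <= 0 | specs$p2 <= 0) |
    specs$dist == "beta" & (specs$p1 <= 0 | specs$p2 <= 0) |
    specs$dist == "uniform" & (specs$p1 >= specs$p2) |
    specs$dist == "normal" & (specs$p2 <= 0)
  if (any(bad))
    stop("invalid distribution parameters for: ",
         paste(specs$name[bad], collapse = ", "), call. = FALSE)
  n_rej <- 0L
  out <- vapply(seq_len(nrow(specs)), function(i) {
    s <- specs[i, ]
    switch(s$dist,
      fixed = rep(s$base, n),
      normal = {
        x <- stats::rnorm(n, s$p1, s$p2)
        for (k in 1:100) {
          neg <- x <= 0
          if (!any(neg)) break
          n_rej <<- n_rej + sum(neg)
          x[neg] <- stats::rnorm(sum(neg), s$p1, s$p2)
        }
        x
      },
      gamma = stats::rgamma(n, shape = (s$p1 / s$p2)^2, scale = s$p2^2 / s$p1),
      beta = stats::rbeta(n, s$p1, s$p2),
      uniform = stats::runif(n, s$p1, s$p2),
      stop("unknown distribution: ", s$dist, call. = FALSE))
  }, numeric(n))
  out <- matrix(out, nrow = n)
  colnames(out) <- specs$name
  attr(out, "n_rejected") <- n_rej
  out
}

apply_spec_value <- function(cfg, spec_row, value,
                             ov_int = list(), ov_com = list()) {
  # returns updated list(cfg, ov_int, ov_com)
  tg <- spec_row$target
  if (tg == "discount") {
    cfg$settings$discount_rate <- value
  } else if (spec_row$arm %in% c("both", "intervention"))
    ov_int[[tg]] <- value
  if (tg != "discount" && spec_row$arm %in% c("both", "comparator"))
    ov_com[[tg]] <- value
  list(cfg = cfg, ov_int = ov_int, ov_com = ov_com)
}

#' One-way deterministic sensitivity analysis (tornado)
#'
#' Re-runs the full comparison with each parameter at its lower and upper
#' bound (all others at base) and reports the ICER and INMB at each bound.
#' Rows are ordered by decreasing INMB range, the usual tornado-diagram
#' ordering. Shared parameters (costs, disutilities, conversion factor,
#' discount rate) are moved in both arms simultaneously; arm-specific
#' parameters (survival, utilities, AE probabilities, durations) in their
#' own arm only.
#'
#' @param cfg A [cea_config()].
#' @param specs Parameter table; defaults to [parameter_specs()].
#' @return Data frame of class `"tornado"` with columns `name`, `label`,
#'   `low`, `high`, `icer_low`, `icer_high`, `inmb_low`, `inmb_high`,
#'   `inmb_range`, sorted descending by `inmb_range`.
#' @export
one_way_dsa <- function(cfg, specs = parameter_specs(cfg)) {
  base <- cea(cfg)
  res <- lapply(seq_len(nrow(specs)), function(i) {
    s <- specs[i, ]
    vals <- vapply(c(s$low, s$high), function(v) {
      st <- apply_spec_value(cfg, s, v)
      r <- cea(st$cfg, st$ov_int, st$ov_com)
      c(icer = as.numeric(r$icer), inmb = r$inmb)
    }, numeric(2))
    data.frame(name = s$name, label = s$label, low = s$low, high = s$high,
               icer_low = vals["icer", 1], icer_high = vals["icer", 2],
               inmb_low = vals["inmb", 1], inmb_high = vals["inmb", 2],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$inmb_range <- abs(out$inmb_high - out$inmb_low)
  out <- out[order(-out$inmb_range, out$name), ]
  rownames(out) <- NULL
  attr(out, "base_icer") <- as.numeric(base$icer)
  attr(out, "base_inmb") <- base$inmb
  class(out) <- c("tornado", "data.frame")
  out
}

#' @export
print.tornado <- function(x, n = 10, ...) {
  cat(sprintf("One-way sensitivity analysis (base INMB %.0f USD); top %d of %d parameters:\n",
              attr(x, "base_inmb"), min(n, nrow(x)), nrow(x)))
  print.data.frame(utils::head(cbind(x["label"], round(x[, c("inmb_low",
    "inmb_high", "inmb_range")])), n), row.names = FALSE)
  invisible(x)
}

#' Probabilistic sensitivity analysis
#'
#' Monte Carlo propagation of parameter uncertainty: per iteration every
#' non-fixed parameter is drawn from its [parameter_specs()] distribution
#' and both strategies are re-run. Draws are independent across parameters
#' and across strategies (each strategy receives its own draw of the shared
#' cost, disutility and conversion-factor parameters). Results are fully
#' reproducible given `seed`.
#'
#' @param cfg A [cea_config()].
#' @param n Number of iterations (the reference analysis uses 5000).
#' @param seed Integer seed.
#' @param wtp_grid Willingness-to-pay grid (USD/QALY) for the acceptability
#'   curve.
#' @param specs Optional parameter table override.
#' @return Object of class `"psa_result"`: `draws` (data frame with per-draw
#'   arm costs/effects and deltas), `ceac` (data frame `wtp`,
#'   `prob_cost_effective`), `prob_ce` and `evpi` at the configured WTP,
#'   `seed`, `n`.
#' @examples
#' \donttest{
#' p <- run_psa(cea_config(), n = 200, seed = 1)
#' p$prob_ce
#' }
#' @export
run_psa <- function(cfg, n = 5000, seed = NULL,
                    wtp_grid = seq(0, 150000, by = 1000),
                    specs = parameter_specs(cfg)) {
  stopifnot(n >= 1)
  if (!is.null(seed)) set.seed(seed)
  sampled <- specs[specs$dist != "fixed", , drop = FALSE]
  draws_int <- sample_parameters(sampled[sampled$arm != "comparator", ], n)
  draws_com <- sample_parameters(sampled[sampled$arm != "intervention", ], n)
  spec_int <- sampled[sampled$arm != "comparator", ]
  spec_com <- sampled[sampled$arm != "intervention", ]

  cost_i <- q_i <- cost_c <- q_c <- ly_i <- ly_c <- numeric(n)
  for (k in seq_len(n)) {
    ov_i <- as.list(draws_int[k, ])
    names(ov_i) <- spec_int$target
    ov_c <- as.list(draws_com[k, ])
    names(ov_c) <- spec_com$target
    ri <- run_psm(cfg, "intervention", ov_i)$accrual
    rc <- run_psm(cfg, "comparator", ov_c)$accrual
    cost_i[k] <- ri$cost_total; q_i[k] <- ri$qaly_total; ly_i[k] <- ri$ly_total
    cost_c[k] <- rc$cost_total; q_c[k] <- rc$qaly_total; ly_c[k] <- rc$ly_total
  }
  draws <- data.frame(cost_intervention = cost_i, qaly_intervention = q_i,
                      ly_intervention = ly_i,
                      cost_comparator = cost_c, qaly_comparator = q_c,
                      ly_comparator = ly_c,
                      delta_cost = cost_i - cost_c, delta_qaly = q_i - q_c,
                      delta_ly = ly_i - ly_c)
  ceac_tab <- data.frame(
    wtp = wtp_grid,
    prob_cost_effective = vapply(wtp_grid, function(l)
      mean(draws$delta_qaly * l - draws$delta_cost > 0), numeric(1)))
  out <- structure(list(draws = draws, ceac = ceac_tab,
                        wtp = cfg$settings$wtp, seed = seed, n = n),
                   class = "psa_result")
  out$prob_ce <- ceac(out, cfg$settings$wtp)
  out$evpi <- evpi(out, cfg$settings$wtp)
  out
}

#' Cost-effectiveness acceptability
#'
#' Fraction of PSA draws with positive incremental net monetary benefit at a
#' given willingness to pay.
#'
#' @param psa A [run_psa()] result.
#' @param wtp Willingness to pay (USD/QALY); vectorized.
#' @return Numeric vector of probabilities in `[0, 1]`.
#' @export
ceac <- function(psa, wtp) {
  vapply(wtp, function(l)
    mean(psa$draws$delta_qaly * l - psa$draws$delta_cost > 0), numeric(1))
}

#' Expected value of perfect information (per person)
#'
#' `EVPI = mean(max per-draw NMB) - max(mean NMB)` across the two
#' strategies, with per-arm net monetary benefit `NMB = QALY * wtp - cost`.
#'
#' @param psa A [run_psa()] result.
#' @param wtp Willingness to pay (USD/QALY).
#' @return EVPI in USD per person (non-negative).
#' @export
evpi <- function(psa, wtp) {
  d <- psa$draws
  nmb_i <- d$qaly_intervention * wtp - d$cost_intervention
  nmb_c <- d$qaly_comparator * wtp - d$cost_comparator
  mean(pmax(nmb_i, nmb_c)) - max(mean(nmb_i), mean(nmb_c))
}

#' @export
print.psa_result <- function(x, ...) {
  cat(sprintf("Probabilistic sensitivity analysis: %d iterations (seed %s)\n",
              x$n, ifelse(is.null(x$seed), "none", x$seed)))
  cat(sprintf("  mean incremental cost %.0f USD, mean incremental QALY %.4f\n",
              mean(x$draws$delta_cost), mean(x$draws$delta_qaly)))
  cat(sprintf("  P(cost-effective at %s USD/QALY) = %.1f%%\n",
              format(x$wtp, big.mark = ","), 100 * x$prob_ce))
  cat(sprintf("  EVPI = %.0f USD per person\n", x$evpi))
  invisible(x)
}

#' @export
plot.psa_result <- function(x, which = c("plane", "ceac"), ...) {
  which <- match.arg(which)
  if (which == "plane") {
    plot(x$draws$delta_qaly, x$draws$delta_cost, pch = 16, cex = 0.3,
         col = "steelblue", xlab = "Incremental QALYs",
         ylab = "Incremental cost (USD)",
         main = "Cost-effectiveness plane", ...)
    abline(0, x$wtp, lty = 2)
    abline(h = 0, v = 0, col = "grey70")
  } else {
    plot(x$ceac$wtp, x$ceac$prob_cost_effective, type = "l",
         xlab = "Willingness to pay (USD/QALY)",
         ylab = "Probability cost-effective", ylim = c(0, 1),
         main = "Cost-effectiveness acceptability curve", ...)
    abline(v = x$wtp, lty = 2)
  }
  invisible(x)
}
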