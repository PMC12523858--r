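#' Scenario specification
#'
#' A declarative override set applied on top of a base configuration. An
#' empty specification reproduces the base case exactly.
#'
#' @param label Scenario label.
#' @param measure Effectiveness measure: `"qaly"` (default) or `"ly"` (the
#'   equal-value-of-life-years-gained convention).
#' @param duration_rule Optional duration rule (see [cea_config()]).
#' @param horizon_years Optional horizon override (years).
#' @param price_multiplier Optional sugemalimab price multiplier in `(0, 1]`.
#' @param conversion_factor Optional fee-schedule conversion factor.
#' @param survival Optional survival block: `"base"`, `"scenario"`, or a
#'   named list of [parsurv] models
#'   `list(intervention = list(os = , pfs = ), comparator = ...)` (e.g. the
#'   best-fitting families selected by information criteria).
#' @param population Optional population override (`"cps5"`, `"cps10"`).
#' @param ... Unknown arguments raise an error naming the valid keys.
#' @return Object of class `"scenario_spec"`.
#' @export
scenario_spec <- function(label = "scenario", measure = NULL,
                          duration_rule = NULL, horizon_years = NULL,
                          price_multiplier = NULL, conversion_factor = NULL,
                          survival = NULL, population = NULL, ...) {
  extra <- list(...)
  if (length(extra) > 0)
    stop("unknown scenario override(s): ",
         paste(names(extra), collapse = ", "),
         "; valid keys: measure, duration_rule, horizon_years, ",
         "price_multiplier, conversion_factor, survival, population",
         call. = FALSE)
  if (!is.null(measure)) measure <- match.arg(measure, c("qaly", "ly"))
  structure(list(label = label, measure = measure,
                 duration_rule = duration_rule, horizon_years = horizon_years,
                 price_multiplier = price_multiplier,
                 conversion_factor = conversion_factor,
                 survival = survival, population = population),
            class = "scenario_spec")
}

apply_scenario <- function(cfg, spec) {
  if (!is.null(spec$population) || (!is.null(spec$survival) &&
                                    is.character(spec$survival))) {
    population <- if (is.null(spec$population)) cfg$population else spec$population
    block <- if (is.null(spec$survival) || !is.character(spec$survival))
      cfg$survival_block else spec$survival
    for (arm in names(cfg$strategies)) {
      cfg$strategies[[arm]]$os <- catalog_model(population, block, arm, "os")
      cfg$strategies[[arm]]$pfs <- catalog_model(population, block, arm, "pfs")
    }
    cfg$population <- population
    cfg$survival_block <- block
  }
  if (!is.null(spec$survival) && is.list(spec$survival)) {
    for (arm in names(spec$survival)) {
      if (!arm %in% names(cfg$strategies))
        stop("unknown arm in survival override: ", arm, call. = FALSE)
      for (ep in names(spec$survival[[arm]]))
        cfg$strategies[[arm]][[ep]] <- spec$survival[[arm]][[ep]]
    }
    cfg$survival_block <- "custom"
  }
  if (!is.null(spec$duration_rule)) cfg$settings$duration_rule <- spec$duration_rule
  if (!is.null(spec$horizon_years)) cfg$settings$horizon_years <- spec$horizon_years
  if (!is.null(spec$price_multiplier)) cfg$settings$price_multiplier <- spec$price_multiplier
  if (!is.null(spec$conversion_factor)) cfg$settings$conversion_factor <- spec$conversion_factor
  validate_config(cfg)
}

#' Run one scenario
#'
#' Applies a [scenario_spec()] to the base configuration, runs the base-case
#' comparison and, optionally, a probabilistic sensitivity analysis, and
#' returns one result row.
#'
#' @param cfg Base [cea_config()].
#' @param spec A [scenario_spec()].
#' @param psa_n Number of PSA iterations (0 = deterministic only).
#' @param seed Seed for the PSA.
#' @return One-row data frame: `label`, `delta_cost`, `delta_effect`,
#'   `icer`, `inmb`, and (when `psa_n > 0`) `prob_ce`, `evpi`.
#' @export
run_scenario <- function(cfg, spec = scenario_spec("base case"),
                         psa_n = 0, seed = NULL) {
  cfg2 <- apply_scenario(cfg, spec)
  res <- cea(cfg2)
  measure <- if (is.null(spec$measure)) "qaly" else spec$measure
  row <- data.frame(
    label = spec$label,
    delta_cost = res$delta_cost,
    delta_effect = if (measure == "qaly") res$delta_qaly else res$delta_ly,
    icer = if (measure == "qaly") as.numeric(res$icer) else as.numeric(res$icer_ly),
    inmb = if (measure == "qaly") res$inmb else res$inmb_ly,
    stringsAsFactors = FALSE)
  if (psa_n > 0) {
    psa <- run_psa(cfg2, n = psa_n, seed = seed)
    if (measure == "qaly") {
      row$prob_ce <- psa$prob_ce
      row$evpi <- psa$evpi
    } else {
      d <- psa$draws
      wtp <- cfg2$settings$wtp
      nmb_i <- d$ly_intervention * wtp - d$cost_intervention
      nmb_c <- d$ly_comparator * wtp - d$cost_comparator
      row$prob_ce <- mean(nmb_i > nmb_c)
      row$evpi <- mean(pmax(nmb_i, nmb_c)) - max(mean(nmb_i), mean(nmb_c))
    }
  }
  row
}

#' Scenario grid
#'
#' The full scenario analysis: base case; effectiveness measured in
#' life-years; the three alternative treatment-duration rules; 5/10/20/30
#' year horizons; price multipliers 0.9 to 0.5; a conversion factor of 1
#' (one fee-schedule point = TWD 1 for non-medication services); and the
#' alternative survival block.
#'
#' @param cfg Base [cea_config()].
#' @param psa_n PSA iterations per scenario (0 skips the probabilistic
#'   columns).
#' @param seed PSA seed.
#' @return Data frame with one row per scenario.
#' @export
scenario_grid <- function(cfg, psa_n = 0, seed = NULL) {
  specs <- list(
    scenario_spec("0. base case"),
    scenario_spec("1. effectiveness: equal-value life-years gained", measure = "ly"),
    scenario_spec("2a. duration: median PFS", duration_rule = "median_pfs"),
    scenario_spec("2b. duration: protocol maximum", duration_rule = "protocol_max"),
    scenario_spec("2c. duration: until progression", duration_rule = "until_progression"),
    scenario_spec("3a. horizon: 5 years", horizon_years = 5),
    scenario_spec("3b. horizon: 10 years", horizon_years = 10),
    scenario_spec("3c. horizon: 20 years", horizon_years = 20),
    scenario_spec("3d. horizon: 30 years", horizon_years = 30),
    scenario_spec("4a. price: 90%", price_multiplier = 0.9),
    scenario_spec("4b. price: 80%", price_multiplier = 0.8),
    scenario_spec("4c. price: 70%", price_multiplier = 0.7),
    scenario_spec("4d. price: 60%", price_multiplier = 0.6),
    scenario_spec("4e. price: 50%", price_multiplier = 0.5),
    scenario_spec("5. conversion factor: 1 TWD/point", conversion_factor = 1),
    scenario_spec("6a. alternative survival families", survival = "scenario"))
  out <- do.call(rbind, lapply(specs, function(s)
    run_scenario(cfg, s, psa_n = psa_n, seed = seed)))
  rownames(out) <- NULL
  out
}
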