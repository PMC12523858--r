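# Catalog of fitted survival-model parameters (time in months) for the two
# biomarker populations. Each endpoint has a "base" family (used in the
# reference analysis) and an alternative "scenario" family; "se" feeds the
# probabilistic analysis, "low"/"high" the one-way (tornado) analysis.
survival_catalog <- function() {
  row <- function(population, block, arm, endpoint, family, p1, p2,
                  se1, se2, lo1, hi1, lo2, hi2) {
    data.frame(population = population, block = block, arm = arm,
               endpoint = endpoint, family = family,
               p1 = p1, p2 = p2, se1 = se1, se2 = se2,
               lo1 = lo1, hi1 = hi1, lo2 = lo2, hi2 = hi2,
               stringsAsFactors = FALSE)
  }
  rbind(
    row("cps5", "base", "intervention", "os", "loglogistic",
        1.904, 16.860, 0.129, 1.051, 1.667, 2.174, 14.921, 19.052),
    row("cps5", "base", "comparator", "os", "loglogistic",
        2.004, 13.331, 0.126, 0.776, 1.772, 2.266, 11.894, 14.942),
    row("cps5", "base", "intervention", "pfs", "loglogistic",
        2.212, 9.015, 0.150, 0.503, 1.936, 2.528, 8.082, 10.056),
    row("cps5", "base", "comparator", "pfs", "loglogistic",
        2.445, 7.305, 0.157, 0.362, 2.156, 2.772, 6.629, 8.050),
    row("cps5", "scenario", "intervention", "os", "lognormal",
        2.838, 0.921, 0.066, 0.056, 2.708, 2.967, 0.818, 1.037),
    row("cps5", "scenario", "comparator", "os", "lognormal",
        2.593, 0.862, 0.060, 0.048, 2.476, 2.709, 0.773, 0.961),
    row("cps5", "scenario", "intervention", "pfs", "lognormal",
        2.224, 0.785, 0.058, 0.048, 2.111, 2.337, 0.698, 0.884),
    row("cps5", "scenario", "comparator", "pfs", "lognormal",
        2.005, 0.715, 0.051, 0.040, 1.905, 2.105, 0.640, 0.798),
    row("cps10", "base", "intervention", "os", "lognormal",
        2.912, 0.922, 0.090, 0.077, 2.735, 3.089, 0.783, 1.087),
    row("cps10", "base", "comparator", "os", "lognormal",
        2.538, 0.947, 0.089, 0.071, 2.363, 2.712, 0.818, 1.098),
    row("cps10", "base", "intervention", "pfs", "lognormal",
        2.278, 0.776, 0.079, 0.066, 2.123, 2.433, 0.656, 0.917),
    row("cps10", "base", "comparator", "pfs", "lognormal",
        2.034, 0.777, 0.077, 0.061, 1.884, 2.183, 0.666, 0.906),
    row("cps10", "scenario", "intervention", "os", "loglogistic",
        1.870, 18.193, 0.175, 1.576, 1.557, 2.246, 15.352, 21.559),
    row("cps10", "scenario", "comparator", "os", "loglogistic",
        1.840, 12.808, 0.158, 1.101, 1.555, 2.177, 10.823, 15.159),
    row("cps10", "scenario", "intervention", "pfs", "loglogistic",
        2.193, 9.503, 0.208, 0.741, 1.820, 2.642, 8.156, 11.072),
    row("cps10", "scenario", "comparator", "pfs", "loglogistic",
        2.227, 7.604, 0.198, 0.569, 1.870, 2.652, 6.567, 8.804))
}

catalog_model <- function(population, block, arm, endpoint) {
  cat_ <- survival_catalog()
  r <- cat_[cat_$population == population & cat_$block == block &
              cat_$arm == arm & cat_$endpoint == endpoint, ]
  if (nrow(r) != 1) stop("no catalog entry for ", population, "/", block, "/",
                         arm, "/", endpoint, call. = FALSE)
  parsurv(r$family, c(r$p1, r$p2))
}

#' Model configuration for the sugemalimab + CAPOX analysis
#'
#' Builds the complete, validated model configuration: settings (horizon,
#' cycle length, discounting, willingness to pay, fee-schedule conversion
#' factor), the two treatment strategies with their survival models, drug
#' regimens, utilities and adverse-event profiles, and the shared annual
#' cost rates. All monetary values are 2024 USD; all times are months.
#'
#' Regimen conventions: CAPOX is a fixed 6-cycle protocol (21-day cycles) in
#' both arms, so chemotherapy acquisition and administration costs stop after
#' 6 cycles regardless of the reimbursement rule. The sugemalimab stopping
#' time is governed by `duration_rule`: the trial's median treatment duration
#' (the default, 6.3 months), the median progression-free survival, the
#' protocol maximum of 24 months, or disease progression (no cap). Caps are
#' quantized to whole treatment cycles.
#'
#' @param population `"cps5"` (PD-L1 combined positive score >= 5, the main
#'   trial population) or `"cps10"` (the >= 10 subgroup).
#' @param survival `"base"` for the primary log-logistic (CPS >= 5) /
#'   log-normal (CPS >= 10) models, `"scenario"` for the alternative block.
#' @param duration_rule One of `"median_duration"`, `"median_pfs"`,
#'   `"protocol_max"`, `"until_progression"`.
#' @return A list of class `"cea_config"`.
#' @examples
#' cfg <- cea_config()
#' cfg$settings$wtp
#' @export
cea_config <- function(population = c("cps5", "cps10"),
                       survival = c("base", "scenario"),
                       duration_rule = c("median_duration", "median_pfs",
                                         "protocol_max", "until_progression")) {
  population <- match.arg(population)
  survival <- match.arg(survival)
  duration_rule <- match.arg(duration_rule)
  capox_cap <- 6 * 21 / 30.4375  # 6 cycles of 21 days, in months

  cfg <- list(
    settings = list(
      horizon_years = 40,
      cycle_days = 21,
      discount_rate = 0.03,
      wtp = 101949,                      # 3x Taiwan 2024 GDP per capita, USD/QALY
      conversion_factor = 0.9198,        # TWD cash value per NHI fee-schedule point
      reference_conversion_factor = 0.9198,
      sugemalimab_price_per_600mg = 1720,
      price_multiplier = 1,
      duration_rule = duration_rule),
    population = population,
    survival_block = survival,
    costs = list(                        # annual rates, 2024 USD
      admin = 1226,                      # chemotherapy administration (PF)
      pf_nonmed = 25925,                 # PF non-medication services (point-based)
      supportive = 63077,                # PD supportive care (point-based)
      pd_drug = 4682,                    # PD medication
      pd_admin = 2018,                   # PD chemotherapy administration
      terminal = 54893,                  # terminal care, one month per death (point-based)
      ae_neutropenia = 769,              # one-off management cost per episode
      ae_anemia = 1494),
    disutilities = list(neutropenia = 0.2, anemia = 0.07),
    strategies = list(
      intervention = list(
        name = "sugemalimab + CAPOX",
        os = catalog_model(population, survival, "intervention", "os"),
        pfs = catalog_model(population, survival, "intervention", "pfs"),
        utilities = list(pf = 0.812, pd = 0.746),
        ae_probs = list(neutropenia = 0.141, anemia = 0.183),
        drugs = list(
          sugemalimab = list(annual_cost = 59814, rule_based = TRUE),
          capox = list(annual_cost = 8959, cap_months = capox_cap)),
        duration_caps = list(median_duration = 6.3, median_pfs = 7.72,
                             protocol_max = 24, until_progression = Inf)),
      comparator = list(
        name = "CAPOX",
        os = catalog_model(population, survival, "comparator", "os"),
        pfs = catalog_model(population, survival, "comparator", "pfs"),
        utilities = list(pf = 0.798, pd = 0.721),
        ae_probs = list(neutropenia = 0.143, anemia = 0.160),
        drugs = list(
          capox = list(annual_cost = 8959, cap_months = capox_cap)),
        duration_caps = list(median_duration = 5.2, median_pfs = 6.24,
                             protocol_max = capox_cap, until_progression = Inf))))
  class(cfg) <- "cea_config"
  validate_config(cfg)
}

#' Validate a model configuration
#'
#' Cross-field validation of a [cea_config()]-shaped list. Errors name the
#' offending field.
#'
#' @param cfg A configuration list.
#' @return The validated configuration, invisibly classed `"cea_config"`.
#' @export
validate_config <- function(cfg) {
  chk <- function(cond, field, msg) {
    if (!cond) stop(sprintf("config field '%s': %s", field, msg), call. = FALSE)
  }
  s <- cfg$settings
  required <- c("horizon_years", "cycle_days", "discount_rate", "wtp",
                "conversion_factor", "sugemalimab_price_per_600mg",
                "price_multiplier", "duration_rule")
  miss <- setdiff(required, names(s))
  if (length(miss) > 0)
    stop("missing settings field(s): ", paste(miss, collapse = ", "), call. = FALSE)
  chk(s$horizon_years > 0, "horizon_years", "must be > 0")
  chk(s$cycle_days > 0, "cycle_days", "must be > 0")
  chk(s$horizon_years * 365.25 >= s$cycle_days, "horizon_years",
      "horizon shorter than one cycle")
  chk(s$discount_rate >= 0 && s$discount_rate <= 1, "discount_rate", "must be in [0, 1]")
  chk(s$wtp >= 0, "wtp", "must be >= 0")
  chk(s$conversion_factor > 0 && s$conversion_factor <= 1.2,
      "conversion_factor", "must be in (0, 1.2]")
  chk(s$price_multiplier >= 0, "price_multiplier", "must be >= 0")
  chk(s$duration_rule %in% c("median_duration", "median_pfs", "protocol_max",
                             "until_progression"),
      "duration_rule", "unknown rule")
  for (nm in names(cfg$costs))
    chk(cfg$costs[[nm]] >= 0, paste0("costs.", nm), "must be >= 0")
  for (nm in names(cfg$disutilities))
    chk(cfg$disutilities[[nm]] >= 0 && cfg$disutilities[[nm]] <= 1,
        paste0("disutilities.", nm), "must be in [0, 1]")
  for (arm in names(cfg$strategies)) {
    st <- cfg$strategies[[arm]]
    for (state in c("pf", "pd"))
      chk(st$utilities[[state]] >= 0 && st$utilities[[state]] <= 1,
          sprintf("strategies.%s.utilities.%s", arm, state), "must be in [0, 1]")
    for (nm in names(st$ae_probs))
      chk(st$ae_probs[[nm]] >= 0 && st$ae_probs[[nm]] <= 1,
          sprintf("strategies.%s.ae_probs.%s", arm, nm), "must be in [0, 1]")
    for (nm in names(st$drugs))
      chk(st$drugs[[nm]]$annual_cost >= 0,
          sprintf("strategies.%s.drugs.%s.annual_cost", arm, nm), "must be >= 0")
    for (nm in names(st$duration_caps))
      chk(st$duration_caps[[nm]] > 0,
          sprintf("strategies.%s.duration_caps.%s", arm, nm), "must be > 0")
    if (!inherits(st$os, "parsurv") || !inherits(st$pfs, "parsurv"))
      stop(sprintf("strategies.%s: os/pfs must be parsurv models", arm), call. = FALSE)
  }
  class(cfg) <- "cea_config"
  invisible(cfg)
}

#' @export
print.cea_config <- function(x, ...) {
  s <- x$settings
  cat(sprintf("CEA configuration (%s population, %s survival block)\n",
              x$population, x$survival_block))
  cat(sprintf("  horizon %g y | cycle %g d | discount %.1f%%/y | WTP %s USD/QALY\n",
              s$horizon_years, s$cycle_days, 100 * s$discount_rate,
              format(s$wtp, big.mark = ",")))
  cat(sprintf("  duration rule: %s | price multiplier %.2f | conversion factor %.4f\n",
              s$duration_rule, s$price_multiplier, s$conversion_factor))
  for (arm in names(x$strategies)) {
    st <- x$strategies[[arm]]
    cat(sprintf("  %s: OS %s(%s), PFS %s(%s)\n", st$name,
                st$os$family, paste(round(st$os$params, 3), collapse = ", "),
                st$pfs$family, paste(round(st$pfs$params, 3), collapse = ", ")))
  }
  invisible(x)
}

config_to_list <- function(cfg) {
  x <- unclass(cfg)
  for (arm in names(x$strategies)) {
    for (ep in c("os", "pfs")) {
      m <- x$strategies[[arm]][[ep]]
      x$strategies[[arm]][[ep]] <- list(family = m$family,
                                        params = as.numeric(m$params))
    }
  }
  x
}

list_to_config <- function(x) {
  for (arm in names(x$strategies)) {
    for (ep in c("os", "pfs")) {
      m <- x$strategies[[arm]][[ep]]
      x$strategies[[arm]][[ep]] <- parsurv(m$family, m$params)
    }
    for (d in names(x$strategies[[arm]]$drugs)) {
      dr <- x$strategies[[arm]]$drugs[[d]]
      if (!is.null(dr$cap_months)) dr$cap_months <- as.numeric(dr$cap_months)
      x$strategies[[arm]]$drugs[[d]] <- dr
    }
    caps <- x$strategies[[arm]]$duration_caps
    x$strategies[[arm]]$duration_caps <- lapply(caps, function(v)
      if (is.character(v) && v == "Inf") Inf else as.numeric(v))
  }
  validate_config(x)
  class(x) <- "cea_config"
  x
}

#' Read and write model configurations as JSON
#'
#' `write_config()` serializes a configuration to JSON (infinite duration
#' caps are stored as the string `"Inf"`); `load_config()` reads it back,
#' rejecting unknown top-level keys and re-running full validation, so that
#' `load_config(write_config(cfg, f))` reproduces `cfg`.
#'
#' @param cfg A [cea_config()] object.
#' @param path File path.
#' @return `load_config` returns the validated configuration; `write_config`
#'   returns `cfg` invisibly.
#' @export
write_config <- function(cfg, path) {
  x <- config_to_list(cfg)
  x <- rapply(x, function(v) {
    if (is.numeric(v)) ifelse(is.infinite(v), "Inf", v) else v
  }, how = "replace")
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(cfg)
}

#' @rdname write_config
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  x <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                error = function(e)
                  stop("cannot parse config: ", conditionMessage(e), call. = FALSE))
  known <- c("settings", "population", "survival_block", "costs",
             "disutilities", "strategies")
  unknown <- setdiff(names(x), known)
  if (length(unknown) > 0)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         "; valid keys are: ", paste(known, collapse = ", "), call. = FALSE)
  miss <- setdiff(known, names(x))
  if (length(miss) > 0)
    stop("missing config key(s): ", paste(miss, collapse = ", "), call. = FALSE)
  x <- rapply(x, function(v) {
    if (is.character(v) && length(v) == 1 && identical(v, "Inf")) Inf else v
  }, how = "replace")
  list_to_config(x)
}

#' Run manifest
#'
#' A small provenance record (configuration hash, seed, package version,
#' timestamp, settings echo) attached to exported result tables so that any
#' output can be traced to the exact inputs that produced it.
#'
#' @param cfg A [cea_config()].
#' @param seed The integer seed used for any stochastic step (or `NA`).
#' @return A list of class `"run_manifest"`.
#' @export
run_manifest <- function(cfg, seed = NA_integer_) {
  js <- jsonlite::toJSON(config_to_list(cfg), auto_unbox = TRUE, digits = NA)
  structure(list(
    config_hash = fnv1a(as.character(js)),
    seed = seed,
    package_version = as.character(utils::packageVersion("psmcea")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    settings = cfg$settings,
    population = cfg$population),
    class = "run_manifest")
}

fnv1a <- function(s) {
  # 32-bit FNV-1a over the UTF-8 bytes, reported as 8 hex digits
  bytes <- utf8ToInt(s)
  h <- 2166136261
  p <- 16777619
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(low, b)
    # 32-bit modular multiply without exceeding double precision
    h <- ((h %% 65536) * p + (((h %/% 65536) * p) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%08x", h)
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf("psmcea %s run: config %s, seed %s, %s\n",
              x$package_version, x$config_hash,
              ifelse(is.na(x$seed), "none", x$seed), x$timestamp))
  invisible(x)
}
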