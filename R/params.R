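#' Model parameter registry with base values, ranges and PSA distributions
#'
#' `default_params()` returns the full input set of the gefitinib
#' switch-maintenance cost-effectiveness model: every clinical probability,
#' cost and utility with its base value, plausible range and probabilistic
#' sensitivity analysis (PSA) distribution family; the three Weibull survival
#' curves (control-arm PFS and post-progression overall survival under
#' supportive care and 2nd-line chemotherapy); and the model settings
#' (3-week cycle, 10-year horizon, 3% annual discounting, GPAP drug-pricing
#' rule, willingness-to-pay thresholds equal to three times the 2011
#' per-capita GDP of China and of Shanghai).
#'
#' Costs are 2012 US dollars throughout; no inflation or currency conversion
#' is applied. The gefitinib unit price is stored as printed (base 77.8 at
#' the top of its 38.9--77.8 range). Parameters are sampled in the PSA
#' according to the `distribution` column of the registry: `"lognormal"`
#' (costs), `"beta"` (utilities, probabilities, proportions),
#' `"lognormal_from_ci"` (the PFS hazard ratio, matched to its 95% CI) or
#' `"fixed"`.
#'
#' @return An object of class `cea_params`: a list with elements
#'   * `registry` — tibble with columns `name`, `base`, `low`, `high`,
#'     `distribution`, `units`, `label`;
#'   * `weibull` — named list of [weibull_params()] objects `pfs_control`,
#'     `os_supportive`, `os_secondline`;
#'   * `settings` — named list of model settings (see Details);
#'   * `secondline_mix` — tibble documenting the drug mix behind the
#'     weighted mean 2nd-line cost (kept for sensitivity use; the base case
#'     uses the weighted mean directly).
#'
#' @details Settings and defaults: `cycle_days` (21), `horizon_years` (10),
#' `discount_annual` (0.03), `gpap` (FALSE), `gpap_paid_months` (6),
#' `secondline_cycles` (4, cycles of 2nd-line chemotherapy charged at the
#' chemotherapy price before reverting to the supportive-care cost),
#' `followup_early_interval_months` (4, for years 0-2),
#' `followup_late_interval_months` (12, thereafter), `followup_early_years`
#' (2), `followup_scope` (`"alive"` or `"pfs"`), `hr_egfr_neg` (1: EGFR
#' mutation-negative patients receive routine follow-up only),
#' `half_cycle` (FALSE), `wtp` (named vector, china = 16349.1,
#' shanghai = 38733.3 USD/QALY).
#'
#' @examples
#' p <- default_params()
#' p$weibull$pfs_control
#' param_value(p, "utility_pfs")
#' tidy(p)
#' @seealso [load_config()], [set_param()], [compare_strategies()]
#' @export
default_params <- function() {
  registry <- tibble::tribble(
    ~name,                        ~base,   ~low,    ~high,    ~distribution,       ~units,       ~label,
    "egfr_mutation_freq",         0.50,    0.08,    0.70,     "beta",              "proportion", "Frequency of EGFR mutations",
    "hr_pfs_gefitinib_egfr_pos",  0.17,    0.07,    0.42,     "lognormal_from_ci", "ratio",      "HR of PFS, gefitinib in EGFR mutation-positive",
    "p_secondline",               0.566,   0.26,    0.72,     "beta",              "proportion", "Proportion receiving 2nd-line chemotherapy",
    "p_sae_gefitinib",            0.07,    0.0525,  0.0875,   "beta",              "probability","Probability of SAEs, Gefitinib strategy",
    "p_sae_control",              0.03,    0.0225,  0.0375,   "beta",              "probability","Probability of SAEs, Control strategy",
    "p_sae_platinum",             0.80,    0.60,    1.00,     "beta",              "probability","Probability of SAEs, platinum-based chemotherapy",
    "cost_genotyping",            507.9,   381.0,   634.9,    "lognormal",         "USD",        "Cost of EGFR genotyping",
    "cost_gefitinib_250mg",       77.8,    38.9,    77.8,     "lognormal",         "USD",        "Cost of gefitinib per 250 mg",
    "cost_followup_visit",        55.6,    41.7,    69.4,     "lognormal",         "USD",        "Cost of follow-up per visit",
    "cost_secondline_cycle",      2352.7,  1921.1,  4383.3,   "lognormal",         "USD/cycle",  "Cost of 2nd-line chemotherapy per cycle",
    "cost_endoflife",             3664.3,  21.4,    48750.2,  "lognormal",         "USD",        "Cost of end-of-life palliative care",
    "cost_supportive_cycle",      337.5,   158.7,   793.7,    "lognormal",         "USD/cycle",  "Cost of supportive care per cycle",
    "cost_sae_platinum_cycle",    507.4,   189.7,   825.0,    "lognormal",         "USD/cycle",  "Cost of SAEs in platinum-based chemo per cycle",
    "utility_pfs",                0.65,    0.26,    0.87,     "beta",              "utility",    "Utility of progression-free survival",
    "utility_pd",                 0.47,    0.19,    0.58,     "beta",              "utility",    "Utility of progressed disease"
  )

  weibull <- list(
    pfs_control   = weibull_params(0.1559,  1.045, time_unit = "cycle", adj_r2 = 0.976),
    os_supportive = weibull_params(0.04006, 1.156, time_unit = "week",  adj_r2 = 0.9898),
    os_secondline = weibull_params(0.03897, 1.509, time_unit = "week",  adj_r2 = 0.981)
  )

  settings <- list(
    cycle_days = 21,
    horizon_years = 10,
    discount_annual = 0.03,
    gpap = FALSE,
    gpap_paid_months = 6,
    secondline_cycles = 4,
    followup_early_interval_months = 4,
    followup_late_interval_months = 12,
    followup_early_years = 2,
    followup_scope = "alive",
    hr_egfr_neg = 1,
    half_cycle = FALSE,
    wtp = c(china = 16349.1, shanghai = 38733.3)
  )

  secondline_mix <- tibble::tribble(
    ~drug,        ~share, ~cost_per_cycle,
    "docetaxel",  0.50,   1942.4,
    "gefitinib",  0.20,   1921.1,
    "erlotinib",  0.15,   2265.5,
    "pemetrexed", 0.15,   4383.3
  )

  params <- structure(
    list(registry = registry, weibull = weibull, settings = settings,
         secondline_mix = secondline_mix),
    class = "cea_params"
  )
  validate_params(params)
}

#' Look up or modify a parameter base value
#'
#' @param params A `cea_params` object.
#' @param name Registry parameter name.
#' @return `param_value()` returns the base value; `set_param()` returns the
#'   modified `cea_params` object (revalidated).
#' @examples
#' p <- set_param(default_params(), "cost_gefitinib_250mg", 38.9)
#' param_value(p, "cost_gefitinib_250mg")
#' @export
param_value <- function(params, name) {
  stopifnot(inherits(params, "cea_params"))
  i <- match(name, params$registry$name)
  if (anyNA(i)) {
    abort(paste0("unknown parameter(s): ",
                 paste(name[is.na(i)], collapse = ", ")))
  }
  params$registry$base[i]
}

#' @rdname param_value
#' @param base,low,high New base value and (optionally) range. When only
#'   `base` is supplied the range is widened if needed so that
#'   `low <= base <= high` keeps holding (sensitivity analyses set values at
#'   or beyond the printed range).
#' @export
set_param <- function(params, name, base = NULL, low = NULL, high = NULL) {
  stopifnot(inherits(params, "cea_params"), length(name) == 1)
  i <- match(name, params$registry$name)
  if (is.na(i)) abort(paste0("unknown parameter: ", name))
  if (!is.null(base)) params$registry$base[i] <- base
  if (!is.null(low))  params$registry$low[i]  <- low
  if (!is.null(high)) params$registry$high[i] <- high
  params$registry$low[i]  <- min(params$registry$low[i], params$registry$base[i])
  params$registry$high[i] <- max(params$registry$high[i], params$registry$base[i])
  validate_params(params)
}

#' Modify model settings
#'
#' Convenience wrapper returning a revalidated copy of `params` with the
#' named settings replaced, e.g. `set_settings(p, horizon_years = 5,
#' gpap = TRUE)`.
#'
#' @inheritParams param_value
#' @param ... Named settings to replace.
#' @export
set_settings <- function(params, ...) {
  stopifnot(inherits(params, "cea_params"))
  new <- list(...)
  unknown <- setdiff(names(new), names(params$settings))
  if (length(unknown)) {
    abort(paste0("unknown setting(s): ", paste(unknown, collapse = ", ")))
  }
  params$settings[names(new)] <- new
  validate_params(params)
}

#' Validate a model parameter set
#'
#' Enforces the structural invariants of the parameter registry: ranges
#' bracket base values, probabilities and utilities lie in \[0, 1\], costs
#' are non-negative, Weibull scale and shape are positive, and settings are
#' admissible. Violations are reported with the parameter name and the
#' offending value.
#'
#' @param params A `cea_params` object.
#' @return `params`, invisibly unchanged, if valid; otherwise an error.
#' @export
validate_params <- function(params) {
  stopifnot(inherits(params, "cea_params"))
  reg <- params$registry
  fail <- function(name, what, value) {
    abort(sprintf("invalid parameter '%s': %s (value %s)", name, what,
                  paste(format(value), collapse = ", ")))
  }
  for (i in seq_len(nrow(reg))) {
    r <- reg[i, ]
    if (!is.finite(r$base)) fail(r$name, "base must be finite", r$base)
    if (!(r$low <= r$base && r$base <= r$high)) {
      fail(r$name, "requires low <= base <= high", c(r$low, r$base, r$high))
    }
    if (r$distribution == "beta" && (r$base < 0 || r$base > 1)) {
      fail(r$name, "beta-distributed parameters must lie in [0, 1]", r$base)
    }
    if (grepl("^cost_", r$name) && r$low < 0) {
      fail(r$name, "costs must be non-negative", r$low)
    }
    if (grepl("^utility_", r$name) && r$high > 1) {
      fail(r$name, "utilities are bounded by 1", r$high)
    }
  }
  if (anyDuplicated(reg$name)) {
    abort("duplicated parameter names in registry")
  }
  for (nm in c("pfs_control", "os_supportive", "os_secondline")) {
    wp <- params$weibull[[nm]]
    if (!inherits(wp, "weibull_params")) {
      abort(sprintf("weibull$%s must be a weibull_params object", nm))
    }
  }
  s <- params$settings
  if (s$cycle_days <= 0) abort("cycle_days must be positive")
  if (s$horizon_years <= 0) abort("horizon_years must be positive")
  if (s$discount_annual < 0) abort("discount_annual must be >= 0")
  if (!is.logical(s$gpap)) abort("gpap must be logical")
  if (!s$followup_scope %in% c("alive", "pfs")) {
    abort("followup_scope must be 'alive' or 'pfs'")
  }
  invisible(params)
}

#' @export
print.cea_params <- function(x, ...) {
  s <- x$settings
  cat("<cea_params> gefitinib maintenance cost-effectiveness inputs\n")
  cat(sprintf("  %d registry parameters; cycle %g d; horizon %g y; discount %.0f%%; GPAP %s\n",
              nrow(x$registry), s$cycle_days, s$horizon_years,
              100 * s$discount_annual, if (isTRUE(s$gpap)) "on" else "off"))
  for (nm in names(x$weibull)) {
    wp <- x$weibull[[nm]]
    cat(sprintf("  %-13s scale %.5f shape %.3f per %s\n",
                nm, wp$scale, wp$shape, wp$time_unit))
  }
  invisible(x)
}

#' @method tidy cea_params
#' @export
tidy.cea_params <- function(x, ...) x$registry

# ---- config file I/O --------------------------------------------------------

#' Read or write a model configuration file
#'
#' The configuration is a flat structured-text document (YAML, or JSON by
#' file extension) with up to three top-level maps: `params` (registry
#' overrides; either a bare number replacing the base value or a map with
#' any of `base`, `low`, `high`, `distribution`), `weibull` (per-curve maps
#' with `scale`, `shape`, `time_unit`, `adj_r2`) and `settings`. Fields not
#' present keep the published base-case values of [default_params()]. The
#' shipped default configuration reproducing the published inputs is at
#' `system.file("extdata", "default_config.yaml", package = "gefcea")`.
#'
#' @param path File path; `.yaml`/`.yml` or `.json`.
#' @return `load_config()`: a validated `cea_params`; `write_config()`: the
#'   path, invisibly.
#' @examples
#' cfg <- system.file("extdata", "default_config.yaml", package = "gefcea")
#' p <- load_config(cfg)
#' param_value(p, "utility_pfs")
#' @export
load_config <- function(path) {
  if (!file.exists(path)) abort(paste0("config file not found: ", path))
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  if (!is.list(raw)) abort("config must parse to a mapping")
  unknown <- setdiff(names(raw), c("params", "weibull", "settings"))
  if (length(unknown)) {
    abort(paste0("unknown top-level config key(s): ",
                 paste(unknown, collapse = ", ")))
  }
  params <- default_params()
  for (nm in names(raw$params)) {
    i <- match(nm, params$registry$name)
    if (is.na(nm) || is.na(i)) abort(paste0("unknown parameter in config: ", nm))
    v <- raw$params[[nm]]
    if (is.numeric(v) && length(v) == 1) {
      params$registry$base[i] <- v
    } else if (is.list(v)) {
      for (f in intersect(names(v), c("base", "low", "high"))) {
        params$registry[[f]][i] <- as.numeric(v[[f]])
      }
      if (!is.null(v$distribution)) {
        if (!v$distribution %in% c("lognormal", "beta", "lognormal_from_ci", "fixed")) {
          abort(sprintf("invalid distribution for '%s': %s", nm, v$distribution))
        }
        params$registry$distribution[i] <- v$distribution
      }
    } else {
      abort(paste0("parameter '", nm, "' must be a number or a mapping"))
    }
  }
  for (nm in names(raw$weibull)) {
    if (!nm %in% names(params$weibull)) {
      abort(paste0("unknown weibull curve in config: ", nm))
    }
    old <- params$weibull[[nm]]
    v <- raw$weibull[[nm]]
    params$weibull[[nm]] <- weibull_params(
      scale     = v$scale %||% old$scale,
      shape     = v$shape %||% old$shape,
      time_unit = v$time_unit %||% old$time_unit,
      adj_r2    = v$adj_r2 %||% old$adj_r2
    )
  }
  if (!is.null(raw$settings)) {
    wtp <- raw$settings$wtp
    if (!is.null(wtp)) raw$settings$wtp <- unlist(wtp)
    params$settings <- modifyList(params$settings, raw$settings)
  }
  validate_params(params)
}

#' @rdname load_config
#' @param params A `cea_params` object to serialize.
#' @export
write_config <- function(params, path) {
  validate_params(params)
  reg <- params$registry
  out <- list(
    params = setNames(lapply(seq_len(nrow(reg)), function(i) {
      list(base = reg$base[i], low = reg$low[i], high = reg$high[i],
           distribution = reg$distribution[i])
    }), reg$name),
    weibull = lapply(params$weibull, function(wp) {
      list(scale = wp$scale, shape = wp$shape, time_unit = wp$time_unit,
           adj_r2 = wp$adj_r2)
    }),
    settings = lapply(params$settings, function(x) {
      if (!is.null(names(x))) as.list(x) else x
    })
  )
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    yaml::write_yaml(out, path, precision = 12)
  }
  invisible(path)
}
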