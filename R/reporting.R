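# Tabular report generation (CSV + JSON + run manifest) and ggplot2
# autoplot methods. All monetary values are written at full precision to
# the machine-readable files; the printed tables round to 1 decimal.

write_manifest <- function(command, outdir, settings, extra = list()) {
  manifest <- c(list(
    command = command,
    package = "gefcea",
    version = as.character(packageVersion("gefcea")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    settings = settings
  ), extra)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

.prep_outdir <- function(outdir) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  outdir
}

.manifest_settings <- function(params) {
  s <- params$settings
  s$wtp <- as.list(s$wtp)
  s
}

#' Write a base-case results report
#'
#' Emits `base_case.csv`, `base_case.json` and a run manifest to `outdir`.
#'
#' @param params A `cea_params` object.
#' @param outdir Output directory (created if needed).
#' @param horizons,gpap_modes Passed to [base_case_table()].
#' @return The base-case tibble, invisibly.
#' @export
report_base_case <- function(params, outdir, horizons = c(1, 2, 5, 10),
                             gpap_modes = c(FALSE, TRUE)) {
  .prep_outdir(outdir)
  tab <- base_case_table(params, horizons, gpap_modes)
  write.csv(tab, file.path(outdir, "base_case.csv"), row.names = FALSE)
  jsonlite::write_json(tab, file.path(outdir, "base_case.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_manifest("base-case", outdir, .manifest_settings(params),
                 list(horizons = horizons, gpap_modes = gpap_modes))
  invisible(tab)
}

#' Write a tornado-analysis report
#'
#' Emits `tornado.csv` (param, low/high parameter values, ICER at each,
#' spread) plus a manifest.
#'
#' @inheritParams report_base_case
#' @param horizon_years,gpap Optional setting overrides.
#' @return The `cea_tornado` tibble, invisibly.
#' @export
report_tornado <- function(params, outdir, horizon_years = NULL, gpap = NULL) {
  .prep_outdir(outdir)
  tor <- tornado(params, horizon_years, gpap)
  write.csv(as.data.frame(tor), file.path(outdir, "tornado.csv"),
            row.names = FALSE)
  write_manifest("tornado", outdir, .manifest_settings(params),
                 list(base_icer = attr(tor, "base_icer")))
  invisible(tor)
}

#' Write a two-way sensitivity report
#'
#' Emits `two_way.csv` (frequency, genotyping cost, ICER surface) plus a
#' manifest.
#'
#' @inheritParams report_tornado
#' @param freq_grid,genotyping_cost_grid Passed to [two_way()].
#' @export
report_two_way <- function(params, outdir,
                           freq_grid = seq(0.05, 0.70, by = 0.05),
                           genotyping_cost_grid = seq(100, 900, by = 100),
                           horizon_years = NULL, gpap = NULL) {
  .prep_outdir(outdir)
  surface <- two_way(params, freq_grid, genotyping_cost_grid,
                     horizon_years, gpap)
  write.csv(surface, file.path(outdir, "two_way.csv"), row.names = FALSE)
  write_manifest("two-way", outdir, .manifest_settings(params))
  invisible(surface)
}

#' Write a probabilistic-sensitivity-analysis report
#'
#' Emits `psa_draws.csv` (iteration, incremental cost and QALYs — the
#' cost-effectiveness-plane scatter data), `ceac.csv`, and
#' `ce_probabilities.json` with the probability of cost-effectiveness at
#' the two willingness-to-pay thresholds, plus a manifest.
#'
#' @inheritParams report_tornado
#' @param n_iterations,seed,sd_frac Passed to [run_psa()].
#' @return The `cea_psa` object, invisibly.
#' @export
report_psa <- function(params, outdir, n_iterations = 1000, seed = 1L,
                       gpap = NULL, horizon_years = NULL, sd_frac = 0.25) {
  .prep_outdir(outdir)
  psa <- run_psa(params, n_iterations = n_iterations, seed = seed,
                 gpap = gpap, horizon_years = horizon_years,
                 sd_frac = sd_frac)
  write.csv(tidy(psa), file.path(outdir, "psa_draws.csv"), row.names = FALSE)
  curve <- ceac(psa)
  write.csv(as.data.frame(curve), file.path(outdir, "ceac.csv"),
            row.names = FALSE)
  probs <- lapply(as.list(psa$wtp), function(w) ce_probability(psa, w))
  jsonlite::write_json(probs, file.path(outdir, "ce_probabilities.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_manifest("psa", outdir, .manifest_settings(params),
                 list(n_iterations = n_iterations, seed = seed,
                      sd_frac = sd_frac))
  invisible(psa)
}

#' Export a cohort trace
#'
#' Writes the long-form (cycle, state, fraction) trace as CSV or JSON by
#' file extension.
#'
#' @param trace A `cea_trace`.
#' @param path Output path ending in `.csv` or `.json`.
#' @export
export_trace <- function(trace, path) {
  long <- trace_long(trace)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(long, path, auto_unbox = TRUE, digits = NA)
  } else {
    write.csv(long, path, row.names = FALSE)
  }
  invisible(path)
}

# ---- plots -----------------------------------------------------------------

#' Plot methods for model results
#'
#' `autoplot.cea_trace` draws the state-occupancy area chart;
#' `autoplot.cea_tornado` the tornado diagram (ICER range per parameter,
#' widest on top); `autoplot.cea_psa` the incremental cost-effectiveness
#' plane with the willingness-to-pay thresholds; `autoplot.cea_ceac` the
#' cost-effectiveness acceptability curve.
#'
#' @param object A result object.
#' @param ... Unused.
#' @return A ggplot.
#' @name gefcea-autoplot
NULL

#' @rdname gefcea-autoplot
#' @method autoplot cea_trace
#' @export
autoplot.cea_trace <- function(object, ...) {
  long <- trace_long(object) |>
    mutate(state = factor(.data$state,
                          levels = c("DEATH", "PD_SC", "PD_2L", "PFS")))
  ggplot2::ggplot(long, ggplot2::aes(.data$cycle, .data$fraction,
                                     fill = .data$state)) +
    ggplot2::geom_area() +
    ggplot2::labs(x = "cycle (3 weeks)", y = "fraction of cohort",
                  fill = NULL, title = object$arm$label) +
    ggplot2::theme_minimal()
}

#' @rdname gefcea-autoplot
#' @method autoplot cea_tornado
#' @export
autoplot.cea_tornado <- function(object, ...) {
  d <- as_tibble(object) |>
    mutate(label = factor(.data$label, levels = rev(.data$label)),
           lo = pmin(.data$icer_at_low, .data$icer_at_high),
           hi = pmax(.data$icer_at_low, .data$icer_at_high))
  ggplot2::ggplot(d, ggplot2::aes(y = .data$label)) +
    ggplot2::geom_linerange(ggplot2::aes(xmin = .data$lo, xmax = .data$hi),
                            linewidth = 4, colour = "steelblue") +
    ggplot2::geom_vline(xintercept = attr(object, "base_icer"),
                        linetype = 2) +
    ggplot2::labs(x = "ICER (USD per QALY)", y = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname gefcea-autoplot
#' @method autoplot cea_psa
#' @export
autoplot.cea_psa <- function(object, ...) {
  d <- tidy(object)
  p <- ggplot2::ggplot(d, ggplot2::aes(.data$delta_qaly, .data$delta_cost)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey50") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey50") +
    ggplot2::labs(x = "incremental QALYs", y = "incremental cost (USD)") +
    ggplot2::theme_minimal()
  for (w in object$wtp) {
    p <- p + ggplot2::geom_abline(slope = w, intercept = 0, linetype = 3)
  }
  p
}

#' @rdname gefcea-autoplot
#' @method autoplot cea_ceac
#' @export
autoplot.cea_ceac <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(.data$wtp, .data$probability)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "willingness to pay (USD per QALY)",
                  y = "P(gefitinib cost-effective)") +
    ggplot2::theme_minimal()
}
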