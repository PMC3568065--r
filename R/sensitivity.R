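# One-way (tornado), two-way and probabilistic sensitivity analyses.

#' One-way (tornado) sensitivity analysis
#'
#' Re-runs both strategies with each registry parameter set to its low and
#' to its high value (all others at base) and records the resulting ICER
#' per QALY. Entries are sorted by spread, the absolute difference between
#' the two ICERs.
#'
#' @param params A `cea_params` object.
#' @param horizon_years,gpap Optional setting overrides.
#' @return A `cea_tornado` tibble: `param`, `label`, `low`, `high`,
#'   `icer_at_low`, `icer_at_high`, `spread`, sorted by decreasing spread;
#'   the base-case ICER is attached as attribute `base_icer`. Has an
#'   [autoplot()] method.
#' @examples
#' \donttest{tornado(default_params(), horizon_years = 10)}
#' @export
tornado <- function(params, horizon_years = NULL, gpap = NULL) {
  stopifnot(inherits(params, "cea_params"))
  base_icer <- compare_strategies(params, horizon_years,
                                  gpap)$comparison$icer_qaly
  reg <- params$registry
  rows <- lapply(seq_len(nrow(reg)), function(i) {
    at <- function(v) {
      p <- params
      p$registry$base[i] <- v
      cmp <- tryCatch(compare_strategies(p, horizon_years, gpap),
                      error = function(e) {
                        abort(sprintf("model failed with %s = %g: %s",
                                      reg$name[i], v, conditionMessage(e)))
                      })
      cmp$comparison$icer_qaly
    }
    lo <- at(reg$low[i])
    hi <- at(reg$high[i])
    tibble(param = reg$name[i], label = reg$label[i],
           low = reg$low[i], high = reg$high[i],
           icer_at_low = lo, icer_at_high = hi, spread = abs(hi - lo))
  })
  out <- bind_rows(rows) |> arrange(desc(.data$spread))
  attr(out, "base_icer") <- base_icer
  class(out) <- c("cea_tornado", class(out))
  out
}

#' Two-way sensitivity analysis: EGFR mutation frequency x genotyping cost
#'
#' ICER of the Gefitinib strategy versus Control at every grid point, all
#' other parameters at base.
#'
#' @param params A `cea_params` object.
#' @param freq_grid EGFR mutation frequencies in \[0, 1\].
#' @param genotyping_cost_grid Genotyping costs (USD, >= 0).
#' @param horizon_years,gpap Optional setting overrides.
#' @return Tibble: `egfr_mutation_freq`, `cost_genotyping`, `icer_qaly`.
#' @export
two_way <- function(params, freq_grid = seq(0.05, 0.70, by = 0.05),
                    genotyping_cost_grid = seq(100, 900, by = 100),
                    horizon_years = NULL, gpap = NULL) {
  stopifnot(inherits(params, "cea_params"))
  if (!length(freq_grid) || !length(genotyping_cost_grid)) {
    abort("grids must be non-empty")
  }
  grid <- tidyr::expand_grid(egfr_mutation_freq = freq_grid,
                             cost_genotyping = genotyping_cost_grid)
  grid$icer_qaly <- vapply(seq_len(nrow(grid)), function(i) {
    p <- set_param(params, "egfr_mutation_freq", grid$egfr_mutation_freq[i])
    p <- set_param(p, "cost_genotyping", grid$cost_genotyping[i])
    compare_strategies(p, horizon_years, gpap)$comparison$icer_qaly
  }, numeric(1))
  grid
}

# ---- probabilistic sensitivity analysis ------------------------------------

# moment-matched distribution draws for one registry row; ci_scale scales
# the CI-derived log-SD so that shrinking sd_frac collapses every
# distribution onto its base value
.draw_param <- function(name, base, sd, distribution, low, high, n,
                        ci_scale = 1) {
  switch(
    distribution,
    fixed = rep(base, n),
    lognormal = {
      if (base <= 0 || sd == 0) return(rep(base, n))
      s2 <- log(1 + (sd / base)^2)
      rlnorm(n, meanlog = log(base) - s2 / 2, sdlog = sqrt(s2))
    },
    beta = {
      if (base <= 0 || base >= 1 || sd == 0) return(rep(base, n))
      v_max <- base * (1 - base)
      v <- sd^2
      if (v >= v_max) {            # infeasible moment match: shrink to boundary
        v <- 0.95 * v_max
        rlang::inform(sprintf(
          "PSA: SD for '%s' infeasible for a beta distribution; shrunk to %.4g",
          name, sqrt(v)))
      }
      k <- v_max / v - 1
      rbeta(n, shape1 = base * k, shape2 = (1 - base) * k)
    },
    lognormal_from_ci = {
      # median = base, 95% interval (low, high) on the log scale
      sdlog <- ci_scale * (log(high) - log(low)) / (2 * qnorm(0.975))
      if (sdlog <= 0) return(rep(base, n))
      rlnorm(n, meanlog = log(base), sdlog = sdlog)
    },
    abort(paste0("unknown distribution: ", distribution))
  )
}

#' Sample parameter draws for the probabilistic sensitivity analysis
#'
#' Costs are drawn log-normal moment-matched to mean = base and
#' SD = `sd_frac` x base; utilities, probabilities and proportions are
#' drawn beta with the same moments (SD shrunk to the feasibility boundary
#' with a message if the moment match is infeasible); the PFS hazard ratio
#' is drawn log-normal with median at its base value and 95% interval
#' matching its CI; `"fixed"` parameters are untouched. Weibull scale and
#' shape are held fixed. Reproducible from `seed`.
#'
#' @param params A `cea_params` object.
#' @param n Number of draws.
#' @param seed Integer seed.
#' @param sd_frac Standard deviation as a fraction of the mean (default
#'   0.25, the model's standing assumption). Also scales the CI-derived
#'   hazard-ratio log-SD relative to its default, so `sd_frac -> 0`
#'   collapses the whole PSA onto the base case.
#' @return Tibble with `n` rows, one column per registry parameter.
#' @examples
#' sample_draws(default_params(), n = 3, seed = 7)
#' @export
sample_draws <- function(params, n, seed = 1L, sd_frac = 0.25) {
  stopifnot(inherits(params, "cea_params"), n >= 1)
  reg <- params$registry
  with_local_seed(seed, {
    cols <- lapply(seq_len(nrow(reg)), function(i) {
      .draw_param(reg$name[i], reg$base[i], sd_frac * reg$base[i],
                  reg$distribution[i], reg$low[i], reg$high[i], n,
                  ci_scale = sd_frac / 0.25)
    })
    names(cols) <- reg$name
    as_tibble(cols)
  })
}

#' Run the probabilistic sensitivity analysis
#'
#' For each of `n_iterations` parameter draws (see [sample_draws()]) both
#' strategies are re-evaluated and the incremental cost and QALY pair is
#' recorded. Fully reproducible from `seed`.
#'
#' @inheritParams sample_draws
#' @param n_iterations Number of Monte-Carlo iterations (1000 in the base
#'   analysis).
#' @param horizon_years,gpap Optional setting overrides.
#' @return A `cea_psa`: list with `draws` (tibble: `iteration`, the sampled
#'   parameter values, `delta_cost`, `delta_qaly`), `n_iterations`, `seed`,
#'   `sd_frac`, `gpap`, `horizon_years`, `wtp` and the base-case
#'   `comparison`. Has [tidy()], [glance()] and [autoplot()] (incremental
#'   cost-effectiveness plane) methods.
#' @examples
#' \donttest{run_psa(default_params(), n_iterations = 10, seed = 1, gpap = TRUE)}
#' @export
run_psa <- function(params, n_iterations = 1000, seed = 1L, gpap = NULL,
                    horizon_years = NULL, sd_frac = 0.25) {
  stopifnot(inherits(params, "cea_params"), n_iterations >= 1)
  if (!is.null(horizon_years)) {
    params <- set_settings(params, horizon_years = horizon_years)
  }
  if (!is.null(gpap)) params <- set_settings(params, gpap = gpap)
  draws <- sample_draws(params, n_iterations, seed = seed, sd_frac = sd_frac)
  idx <- match(names(draws), params$registry$name)
  dc <- dq <- numeric(n_iterations)
  for (i in seq_len(n_iterations)) {
    p <- params
    p$registry$base[idx] <- as.numeric(draws[i, ])
    cmp <- tryCatch(compare_strategies(p), error = function(e) {
      abort(sprintf("PSA iteration %d failed: %s", i, conditionMessage(e)))
    })
    dc[i] <- cmp$comparison$delta_cost
    dq[i] <- cmp$comparison$delta_qaly
  }
  structure(list(
    draws = bind_cols(tibble(iteration = seq_len(n_iterations)), draws,
                      tibble(delta_cost = dc, delta_qaly = dq)),
    n_iterations = n_iterations, seed = seed, sd_frac = sd_frac,
    gpap = params$settings$gpap,
    horizon_years = params$settings$horizon_years,
    wtp = params$settings$wtp,
    base_comparison = compare_strategies(params)$comparison
  ), class = "cea_psa")
}

#' @export
print.cea_psa <- function(x, ...) {
  cat(sprintf("<cea_psa> %d iterations (seed %s, SD %.0f%% of mean), %g y horizon, GPAP %s\n",
              x$n_iterations, format(x$seed), 100 * x$sd_frac,
              x$horizon_years, if (isTRUE(x$gpap)) "on" else "off"))
  for (nm in names(x$wtp)) {
    cat(sprintf("  P(cost-effective at $%s/QALY) = %.3f\n",
                format(x$wtp[[nm]], big.mark = ","),
                ce_probability(x, x$wtp[[nm]])))
  }
  invisible(x)
}

#' @method tidy cea_psa
#' @export
tidy.cea_psa <- function(x, ...) {
  x$draws |> select("iteration", "delta_cost", "delta_qaly")
}

#' @method glance cea_psa
#' @export
glance.cea_psa <- function(x, ...) {
  tibble(n_iterations = x$n_iterations, seed = x$seed, gpap = x$gpap,
         horizon_years = x$horizon_years,
         mean_delta_cost = mean(x$draws$delta_cost),
         mean_delta_qaly = mean(x$draws$delta_qaly),
         p_ce_china = ce_probability(x, x$wtp[["china"]]),
         p_ce_shanghai = ce_probability(x, x$wtp[["shanghai"]]))
}

#' Probability of cost-effectiveness at a willingness-to-pay threshold
#'
#' Fraction of PSA draws with positive net monetary health benefit,
#' `wtp * delta_qaly - delta_cost > 0`.
#'
#' @param psa A `cea_psa` from [run_psa()].
#' @param wtp Willingness-to-pay, USD per QALY (vectorized).
#' @export
ce_probability <- function(psa, wtp) {
  stopifnot(inherits(psa, "cea_psa"))
  vapply(wtp, function(w) {
    mean(nmhb(w, psa$draws$delta_cost, psa$draws$delta_qaly) > 0)
  }, numeric(1))
}

#' Cost-effectiveness acceptability curve
#'
#' Probability of cost-effectiveness of the Gefitinib strategy over a grid
#' of willingness-to-pay values (default $0 to $100,000 per QALY in $1,000
#' steps).
#'
#' @inheritParams ce_probability
#' @param wtp_grid Willingness-to-pay grid.
#' @return A `cea_ceac` tibble: `wtp`, `probability`. Has an [autoplot()]
#'   method.
#' @export
ceac <- function(psa, wtp_grid = seq(0, 100000, by = 1000)) {
  stopifnot(inherits(psa, "cea_psa"))
  if (!length(wtp_grid)) abort("wtp_grid must be non-empty")
  out <- tibble(wtp = wtp_grid, probability = ce_probability(psa, wtp_grid))
  class(out) <- c("cea_ceac", class(out))
  out
}
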