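# Discounted accrual of costs and health effects over a cohort trace,
# ICER / net monetary health benefit computation, and the base-case
# summary table across horizons and GPAP modes.
#
# Accrual convention: state membership during cycle t (t = 1..N) is the
# occupancy at the end of cycle t-1 (transitions happen at cycle end), and
# cycle t's costs and QALYs are discounted by discount_factor(t). With
# settings$half_cycle = TRUE, membership is instead the average of the
# start- and end-of-cycle occupancies. The one-time genotyping cost falls
# at cycle 0 and is undiscounted. Life-years are reported undiscounted
# (discounted variants are also returned); costs and QALYs are discounted.

#' Per-cycle discount factor
#'
#' `(1 + annual_rate) ^ (-cycle * cycle_days / 365.25)`.
#'
#' @param cycle Cycle index (vectorized, 0 = model start).
#' @param annual_rate Annual discount rate (>= 0).
#' @param cycle_days Cycle length in days.
#' @examples
#' discount_factor(365.25 / 21, 0.03) # one year: 1 / 1.03
#' @export
discount_factor <- function(cycle, annual_rate = 0.03, cycle_days = 21) {
  if (annual_rate < 0) abort("annual_rate must be >= 0")
  (1 + annual_rate)^(-cycle * cycle_days / DAYS_PER_YEAR)
}

#' Serious-adverse-event cost per cycle for a maintenance arm
#'
#' No direct SAE cost data exist for maintenance therapy, so the model
#' scales the per-cycle SAE cost of platinum-based chemotherapy by the
#' ratio of cumulative SAE probabilities:
#' `cost_sae_platinum_cycle * p_sae_arm / p_sae_platinum`. The resulting
#' cost is charged to progression-free occupants every cycle (SAEs are
#' assumed to occur with the same probability in every cycle).
#'
#' @param p_sae_arm Cumulative SAE probability of the arm (0.07 gefitinib,
#'   0.03 control at base case).
#' @param params A `cea_params` object.
#' @return USD per progression-free occupant per cycle.
#' @examples
#' sae_cost_per_cycle(0.07, default_params()) # 507.4 * 0.07 / 0.80
#' @export
sae_cost_per_cycle <- function(p_sae_arm, params) {
  stopifnot(inherits(params, "cea_params"))
  p_plat <- param_value(params, "p_sae_platinum")
  if (p_plat <= 0) abort("p_sae_platinum must be positive")
  param_value(params, "cost_sae_platinum_cycle") * p_sae_arm / p_plat
}

# membership-during-cycle weights, cycles 1..N, from end-of-cycle occupancy
.during <- function(occ_col, half_cycle) {
  N <- length(occ_col) - 1
  if (half_cycle) (occ_col[1:N] + occ_col[2:(N + 1)]) / 2 else occ_col[1:N]
}

# shared accrual core; returns named list of effects and cost components
.arm_economics <- function(trace, arm, params, gpap = NULL) {
  s <- params$settings
  gpap <- gpap %||% s$gpap
  N <- trace$n_cycles
  cd <- s$cycle_days
  cy <- cd / DAYS_PER_YEAR
  d <- discount_factor(1:N, s$discount_annual, cd)
  occ <- trace$occupancy
  hc <- isTRUE(s$half_cycle)

  pfs_w <- .during(occ$PFS, hc)
  pd_w <- .during(occ$PD_2L + occ$PD_SC, hc)
  alive_w <- pfs_w + pd_w

  u_pfs <- param_value(params, "utility_pfs")
  u_pd <- param_value(params, "utility_pd")
  eff <- list(
    pf_ly = sum(pfs_w) * cy,
    ly = sum(alive_w) * cy,
    pf_ly_disc = sum(pfs_w * d) * cy,
    ly_disc = sum(alive_w * d) * cy,
    qaly = (u_pfs * sum(pfs_w * d) + u_pd * sum(pd_w * d)) * cy,
    qaly_undisc = (u_pfs * sum(pfs_w) + u_pd * sum(pd_w)) * cy
  )

  # --- costs -----------------------------------------------------------
  cost_geno <- if (arm$genotyped) param_value(params, "cost_genotyping") else 0

  cost_drug <- 0
  if (arm$receives_gefitinib) {
    paid_cycles <- if (isTRUE(gpap)) {
      s$gpap_paid_months * DAYS_PER_MONTH / cd   # 6 months ~ 8.696 cycles
    } else Inf
    w <- pmin(pmax(paid_cycles - (1:N - 1), 0), 1)  # prorated boundary cycle
    cost_drug <- sum(cd * param_value(params, "cost_gefitinib_250mg") *
                       w * pfs_w * d)
  }

  p_sae <- param_value(params, if (arm$receives_gefitinib) "p_sae_gefitinib"
                       else "p_sae_control")
  cost_sae <- sae_cost_per_cycle(p_sae, params) * sum(pfs_w * d)

  # follow-up amortized per cycle of survivorship: one visit per 4 months in
  # years 0-2, one per 12 months thereafter
  visits_per_year <- ifelse((1:N) * cy <= s$followup_early_years,
                            12 / s$followup_early_interval_months,
                            12 / s$followup_late_interval_months)
  fu_occ <- if (s$followup_scope == "alive") alive_w else pfs_w
  cost_fu <- param_value(params, "cost_followup_visit") *
    sum(visits_per_year * cy * fu_occ * d)

  # post-progression state costs, factorized per progression-entry cycle:
  # d(tau + k) = d(tau) * d(k) exactly, so the discounted cost of an entry
  # cohort is (entry fraction * d(tau)) times a tail sum over subcohort age
  sub2l <- trace$sub_survival$PD_2L
  subsc <- trace$sub_survival$PD_SC
  w2l <- .during(sub2l, hc)          # membership during age-cycle k
  wsc <- .during(subsc, hc)
  tail_sum <- function(b) {          # per-entry: sum_{k=1..N-tau} b[k]
    cs <- cumsum(b)
    c(rev(cs[seq_len(N - 1)]), 0)
  }
  p2 <- trace$p_secondline
  entry_disc <- trace$prog * d
  price_2l_k <- ifelse(1:N <= s$secondline_cycles,
                       param_value(params, "cost_secondline_cycle"),
                       param_value(params, "cost_supportive_cycle"))
  cost_2l <- p2 * sum(entry_disc * tail_sum(w2l * price_2l_k * d))
  cost_sc <- (1 - p2) *
    sum(entry_disc * tail_sum(wsc * param_value(params, "cost_supportive_cycle") * d))

  # one-time end-of-life cost at each death transition (horizon survivors
  # are censored: no end-of-life cost is charged for them)
  cost_eol <- param_value(params, "cost_endoflife") *
    sum(occ$new_deaths[-1] * d)

  costs <- list(cost_genotyping = cost_geno, cost_gefitinib = cost_drug,
                cost_sae = cost_sae, cost_followup = cost_fu,
                cost_secondline = cost_2l, cost_supportive = cost_sc,
                cost_endoflife = cost_eol)
  costs$cost <- sum(unlist(costs))
  c(eff, costs)
}

#' Accrue discounted health effects over a cohort trace
#'
#' Each alive fraction contributes `cycle_days / 365.25` years per cycle;
#' progression-free occupancy is valued at `utility_pfs`, progressed
#' occupancy at `utility_pd`. Life-years (`pf_ly`, `ly`) are undiscounted;
#' `qaly` is discounted (undiscounted and discounted variants of all three
#' are returned).
#'
#' @param trace A `cea_trace` from [run_arm()].
#' @param params A `cea_params` object.
#' @return One-row tibble: `pf_ly`, `ly`, `qaly`, `pf_ly_disc`, `ly_disc`,
#'   `qaly_undisc`.
#' @export
accrue_effects <- function(trace, params) {
  stopifnot(inherits(trace, "cea_trace"), inherits(params, "cea_params"))
  res <- .arm_economics(trace, trace$arm, params)
  as_tibble(res[c("pf_ly", "ly", "qaly", "pf_ly_disc", "ly_disc",
                  "qaly_undisc")])
}

#' Accrue discounted costs over a cohort trace
#'
#' Sums, with 3% annual discounting: (a) one-time EGFR genotyping at model
#' start if the arm is genotyped; (b) gefitinib at `cycle_days *
#' cost_gefitinib_250mg` per progression-free occupant per cycle, truncated
#' by the GPAP when enabled (patients pay for the first six months of
#' maintenance — about 8.70 cycles, prorated within the fractional cycle —
#' and receive the drug free afterwards); (c) routine follow-up amortized
#' per cycle of survivorship (one visit per 4 months in years 0-2, one per
#' year thereafter); (d) SAE management during PFS via
#' [sae_cost_per_cycle()]; (e) 2nd-line chemotherapy per occupant-cycle for
#' the first `secondline_cycles` (4) cycles after progression entry, the
#' supportive-care cost thereafter; (f) supportive care per occupant-cycle
#' in the supportive-care state; (g) one-time end-of-life cost at each
#' death.
#'
#' @inheritParams accrue_effects
#' @param arm The [arm_spec()] the trace was run under (defaults to the one
#'   recorded in the trace).
#' @param gpap Override the GPAP setting for this accrual.
#' @return One-row tibble with the seven components and their sum `cost`
#'   (2012 USD).
#' @export
accrue_costs <- function(trace, arm = trace$arm, params, gpap = NULL) {
  stopifnot(inherits(trace, "cea_trace"), inherits(arm, "cea_arm"),
            inherits(params, "cea_params"))
  res <- .arm_economics(trace, arm, params, gpap = gpap)
  as_tibble(res[c("cost_genotyping", "cost_gefitinib", "cost_sae",
                  "cost_followup", "cost_secondline", "cost_supportive",
                  "cost_endoflife", "cost")])
}

#' Evaluate a strategy: discounted cost and health outcomes
#'
#' Runs (or takes) a [run_strategy()] composition and weight-averages the
#' arms' accruals.
#'
#' @param strategy `"control"`, `"gefitinib"`, or a `cea_strategy`.
#' @param params A `cea_params` object.
#' @param gpap Override the GPAP setting.
#' @param n_cycles Override the number of cycles.
#' @return One-row tibble: `strategy`, `cost`, `pf_ly`, `ly`, `qaly`,
#'   discounted/undiscounted variants, and the cost components.
#' @examples
#' evaluate_strategy("control", default_params())
#' @export
evaluate_strategy <- function(strategy, params, gpap = NULL, n_cycles = NULL) {
  stopifnot(inherits(params, "cea_params"))
  st <- if (inherits(strategy, "cea_strategy")) strategy
  else run_strategy(strategy, params, n_cycles = n_cycles, ledger = FALSE)
  rows <- lapply(seq_along(st$arms), function(i) {
    as_tibble(.arm_economics(st$traces[[i]], st$arms[[i]], params, gpap = gpap))
  })
  agg <- Reduce(`+`, Map(function(r, w) r * w, rows, st$weights))
  bind_cols(tibble(strategy = st$label), agg)
}

.icer <- function(dc, de) if (is.na(de) || de == 0) NA_real_ else dc / de

#' Compare the Gefitinib strategy with the Control strategy
#'
#' Evaluates both strategies under common settings and reports the
#' incremental cost, QALYs and life-years (gefitinib minus control), the
#' ICERs per QALY and per life-year, and a dominance flag (set when one
#' strategy is both cheaper and more effective).
#'
#' @param params A `cea_params` object.
#' @param horizon_years,gpap Optional overrides of the corresponding
#'   settings.
#' @return A `cea_comparison`: list with `strategies` (two-row tibble from
#'   [evaluate_strategy()]) and `comparison` (one-row tibble with
#'   `delta_cost`, `delta_qaly`, `delta_ly`, `delta_pf_ly`, `icer_qaly`,
#'   `icer_ly`, `nmhb_china`, `nmhb_shanghai`, `dominance`). [tidy()]
#'   returns the comparison row; [glance()] one row combining both
#'   strategies' outcomes.
#' @examples
#' \donttest{
#' cmp <- compare_strategies(default_params(), horizon_years = 10, gpap = TRUE)
#' tidy(cmp)
#' }
#' @export
compare_strategies <- function(params, horizon_years = NULL, gpap = NULL) {
  stopifnot(inherits(params, "cea_params"))
  if (!is.null(horizon_years)) {
    params <- set_settings(params, horizon_years = horizon_years)
  }
  if (!is.null(gpap)) params <- set_settings(params, gpap = gpap)
  N <- n_cycles(params$settings$horizon_years, params$settings$cycle_days)

  # the EGFR mutation-negative stratum follows the control curve when its
  # hazard ratio is 1, so its trace can be shared with the control arm
  ctrl_arm <- arm_spec("control", params$weibull$pfs_control)
  ctrl_trace <- run_arm(ctrl_arm, params, n_cycles = N, ledger = FALSE)
  ctrl <- bind_cols(tibble(strategy = "control"),
                    as_tibble(.arm_economics(ctrl_trace, ctrl_arm, params)))

  freq <- param_value(params, "egfr_mutation_freq")
  hr <- param_value(params, "hr_pfs_gefitinib_egfr_pos")
  pos_arm <- arm_spec("egfr_positive",
                      apply_hazard_ratio(params$weibull$pfs_control, hr),
                      receives_gefitinib = TRUE, genotyped = TRUE)
  pos_trace <- run_arm(pos_arm, params, n_cycles = N, ledger = FALSE)
  neg_arm <- arm_spec("egfr_negative", params$weibull$pfs_control,
                      genotyped = TRUE)
  neg_trace <- if (params$settings$hr_egfr_neg == 1) ctrl_trace
  else run_arm(arm_spec("egfr_negative",
                        apply_hazard_ratio(params$weibull$pfs_control,
                                           params$settings$hr_egfr_neg),
                        genotyped = TRUE), params, n_cycles = N, ledger = FALSE)
  pos <- as_tibble(.arm_economics(pos_trace, pos_arm, params))
  neg <- as_tibble(.arm_economics(neg_trace, neg_arm, params))
  gef <- bind_cols(tibble(strategy = "gefitinib"),
                   freq * pos + (1 - freq) * neg)

  strategies <- bind_rows(ctrl, gef)
  dc <- gef$cost - ctrl$cost
  dq <- gef$qaly - ctrl$qaly
  dly <- gef$ly - ctrl$ly
  dominance <- if (dc < 0 && dq > 0) "gefitinib dominant"
  else if (dc > 0 && dq < 0) "gefitinib dominated"
  else "none"
  wtp <- params$settings$wtp
  comparison <- tibble(
    delta_cost = dc, delta_qaly = dq, delta_ly = dly,
    delta_pf_ly = gef$pf_ly - ctrl$pf_ly,
    icer_qaly = .icer(dc, dq), icer_ly = .icer(dc, dly),
    nmhb_china = nmhb(wtp[["china"]], dc, dq),
    nmhb_shanghai = nmhb(wtp[["shanghai"]], dc, dq),
    dominance = dominance
  )
  structure(list(strategies = strategies, comparison = comparison,
                 horizon_years = params$settings$horizon_years,
                 gpap = params$settings$gpap),
            class = "cea_comparison")
}

#' @export
print.cea_comparison <- function(x, ...) {
  c1 <- x$comparison
  cat(sprintf("<cea_comparison> gefitinib vs control, %g y horizon, GPAP %s\n",
              x$horizon_years, if (isTRUE(x$gpap)) "on" else "off"))
  cat(sprintf("  dCost $%.1f  dQALY %.4f  dLY %.4f  ICER $%.1f/QALY  $%.1f/LY\n",
              c1$delta_cost, c1$delta_qaly, c1$delta_ly, c1$icer_qaly,
              c1$icer_ly))
  if (c1$dominance != "none") cat("  ", c1$dominance, "\n")
  invisible(x)
}

#' @method tidy cea_comparison
#' @export
tidy.cea_comparison <- function(x, ...) x$comparison

#' @method glance cea_comparison
#' @export
glance.cea_comparison <- function(x, ...) {
  bind_cols(tibble(horizon_years = x$horizon_years, gpap = x$gpap),
            x$comparison)
}

#' Net monetary health benefit
#'
#' `wtp * delta_qaly - delta_cost`; positive means the incremental strategy
#' is cost-effective at that willingness-to-pay. Vectorized over `wtp`.
#'
#' @param wtp Willingness-to-pay threshold(s), USD per QALY (>= 0).
#' @param delta_cost,delta_qaly Incremental cost and QALYs.
#' @examples
#' nmhb(16349.1, 7178.2, 0.46)
#' @export
nmhb <- function(wtp, delta_cost, delta_qaly) {
  if (any(wtp < 0)) abort("wtp must be >= 0")
  wtp * delta_qaly - delta_cost
}

#' Base-case summary across horizons and GPAP modes
#'
#' Reproduces the layout of the published base-case table: strategy-level
#' discounted cost, progression-free life-years, overall life-years and
#' QALYs for each horizon, with the incremental cost per QALY and per
#' life-year of the Gefitinib strategy (with and without the GPAP) against
#' Control.
#'
#' @param params A `cea_params` object.
#' @param horizons Horizons in years.
#' @param gpap_modes Logical vector of GPAP modes to evaluate.
#' @return Tibble with columns `horizon_years`, `strategy`, `gpap`, `cost`,
#'   `pf_ly`, `ly`, `qaly`, `icer_qaly`, `icer_ly`.
#' @examples
#' \donttest{base_case_table(default_params(), horizons = c(1, 10))}
#' @export
base_case_table <- function(params, horizons = c(1, 2, 5, 10),
                            gpap_modes = c(FALSE, TRUE)) {
  stopifnot(inherits(params, "cea_params"))
  out <- list()
  for (h in horizons) {
    for (g in gpap_modes) {
      cmp <- compare_strategies(params, horizon_years = h, gpap = g)
      ctrl <- cmp$strategies[1, ]
      gef <- cmp$strategies[2, ]
      if (isTRUE(g == gpap_modes[[1]])) {
        out[[length(out) + 1]] <- tibble(
          horizon_years = h, strategy = "Control", gpap = NA,
          cost = ctrl$cost, pf_ly = ctrl$pf_ly, ly = ctrl$ly,
          qaly = ctrl$qaly, icer_qaly = NA_real_, icer_ly = NA_real_)
      }
      out[[length(out) + 1]] <- tibble(
        horizon_years = h, strategy = "Gefitinib", gpap = g,
        cost = gef$cost, pf_ly = gef$pf_ly, ly = gef$ly, qaly = gef$qaly,
        icer_qaly = cmp$comparison$icer_qaly,
        icer_ly = cmp$comparison$icer_ly)
    }
  }
  bind_rows(out)
}
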