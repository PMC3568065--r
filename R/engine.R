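# Semi-Markov cohort engine over the four health states:
#   PFS -> PD_2L (progressed, 2nd-line chemotherapy)
#       -> PD_SC (progressed, supportive care)
#   both -> DEATH (absorbing)
# Progression-free exits follow the (possibly HR-adjusted) PFS Weibull on
# the model-cycle clock; post-progression death follows the arm-independent
# OS Weibulls on a subcohort clock reset at progression entry (tunnel
# states, implemented by stratifying progressed occupancy by entry cycle).

#' Number of model cycles covering a horizon
#'
#' The cohort is followed for whole 3-week cycles until the horizon year is
#' covered: `ceiling(horizon_years * 365.25 / cycle_days)` (174 cycles for
#' 10 years, 18 for 1 year).
#'
#' @param horizon_years Horizon in years.
#' @param cycle_days Cycle length in days.
#' @export
n_cycles <- function(horizon_years, cycle_days = 21) {
  if (horizon_years <= 0) abort("horizon_years must be positive")
  as.integer(ceiling(horizon_years * DAYS_PER_YEAR / cycle_days))
}

#' Specify one simulated cohort arm
#'
#' An arm is a cohort with a single progression-free survival curve and two
#' cost-relevant flags. The Gefitinib strategy mixes two arms (EGFR
#' mutation-positive on the HR-adjusted curve, mutation-negative on the
#' control curve); the Control strategy is a single arm.
#'
#' @param label Non-empty arm label.
#' @param pfs_params [weibull_params()] for progression-free survival,
#'   after any hazard-ratio adjustment.
#' @param receives_gefitinib Does this arm accrue gefitinib drug cost (and
#'   the gefitinib-arm SAE rate) while progression free?
#' @param genotyped Is the one-time EGFR genotyping cost charged?
#' @return An object of class `cea_arm`.
#' @examples
#' arm_spec("control", default_params()$weibull$pfs_control)
#' @export
arm_spec <- function(label, pfs_params, receives_gefitinib = FALSE,
                     genotyped = FALSE) {
  if (!is.character(label) || !nzchar(label)) abort("label must be non-empty")
  stopifnot(inherits(pfs_params, "weibull_params"))
  structure(list(label = label, pfs_params = pfs_params,
                 receives_gefitinib = isTRUE(receives_gefitinib),
                 genotyped = isTRUE(genotyped)),
            class = "cea_arm")
}

#' Run the cohort model for one arm
#'
#' Deterministic cohort simulation. Cycle 0 places the whole cohort in PFS.
#' At each cycle `t >= 1` the fraction [cycle_transition_prob()] of current
#' PFS occupants progresses and is split `p_secondline : 1 - p_secondline`
#' between 2nd-line chemotherapy and supportive care, tagged with entry
#' cycle `t`; progressed subcohorts then die according to the transition
#' probabilities of their overall-survival Weibull evaluated on the
#' subcohort clock (cycles since progression). There is no transition from
#' the progressed states back to PFS and no direct PFS-to-death channel;
#' DEATH is absorbing.
#'
#' @param arm A [arm_spec()] object.
#' @param params A `cea_params` object.
#' @param n_cycles Number of cycles; defaults to the setting-derived
#'   [n_cycles()].
#' @param ledger Keep the full progression-entry-by-cycle occupancy
#'   matrices (used by invariant checks and the brute-force oracle tests)?
#'   Disabled in the PSA for speed; accruals do not need them.
#' @return A `cea_trace`: list with `occupancy` (tibble over cycles 0..N
#'   with columns `cycle`, `PFS`, `PD_2L`, `PD_SC`, `DEATH`,
#'   `new_progressions`, `new_deaths`), the per-entry-cycle `ledger`
#'   matrices (rows = entry cycle, columns = cycle 0..N), and the
#'   subcohort survival vectors used. Occupancy at every cycle sums to 1.
#' @examples
#' tr <- run_arm(arm_spec("control", default_params()$weibull$pfs_control),
#'               default_params())
#' head(as_tibble(tr))
#' @export
run_arm <- function(arm, params, n_cycles = NULL, ledger = TRUE) {
  stopifnot(inherits(arm, "cea_arm"), inherits(params, "cea_params"))
  s <- params$settings
  N <- as.integer(n_cycles %||% n_cycles(s$horizon_years, s$cycle_days))
  if (N < 1) abort("need at least one cycle")
  p2 <- param_value(params, "p_secondline")

  u_pfs <- units_per_cycle(arm$pfs_params, s$cycle_days)
  S_pfs <- survival_at(arm$pfs_params, u_pfs * (0:N))
  prog <- -diff(S_pfs)                       # new progressions, cycles 1..N

  # survival on the subcohort clock: element k+1 = P(alive k cycles after entry)
  sub <- lapply(params$weibull[c("os_secondline", "os_supportive")],
                function(wp) survival_at(wp, units_per_cycle(wp, s$cycle_days) * (0:N)))
  names(sub) <- c("PD_2L", "PD_SC")

  conv_entries <- function(entry, subsurv) {
    out <- numeric(N)
    for (t in seq_len(N)) {
      out[t] <- sum(entry[seq_len(t)] * subsurv[t - seq_len(t) + 1])
    }
    out
  }
  occ_2l <- conv_entries(prog * p2, sub$PD_2L)
  occ_sc <- conv_entries(prog * (1 - p2), sub$PD_SC)
  nd <- conv_entries(prog * p2, c(0, -diff(sub$PD_2L))) +
    conv_entries(prog * (1 - p2), c(0, -diff(sub$PD_SC)))

  occupancy <- tibble(
    cycle = 0:N,
    PFS = S_pfs,
    PD_2L = c(0, occ_2l),
    PD_SC = c(0, occ_sc),
    DEATH = c(0, cumsum(nd)),
    new_progressions = c(0, prog),
    new_deaths = c(0, nd)
  )
  total <- occupancy$PFS + occupancy$PD_2L + occupancy$PD_SC + occupancy$DEATH
  if (max(abs(total - 1)) > 1e-9) {
    abort("internal error: cohort occupancy does not sum to 1")
  }

  ledgers <- NULL
  if (isTRUE(ledger)) {
    mk <- function(share, subsurv) {
      m <- matrix(0, nrow = N, ncol = N + 1,
                  dimnames = list(entry = 1:N, cycle = 0:N))
      for (tau in seq_len(N)) {
        m[tau, (tau:N) + 1] <- prog[tau] * share * subsurv[seq_len(N - tau + 1)]
      }
      m
    }
    ledgers <- list(PD_2L = mk(p2, sub$PD_2L), PD_SC = mk(1 - p2, sub$PD_SC))
  }

  structure(list(occupancy = occupancy, arm = arm, n_cycles = N,
                 prog = prog, sub_survival = sub, p_secondline = p2,
                 cycle_days = s$cycle_days, ledger = ledgers),
            class = "cea_trace")
}

#' @export
print.cea_trace <- function(x, ...) {
  last <- x$occupancy[nrow(x$occupancy), ]
  cat(sprintf("<cea_trace> arm '%s', %d cycles; final occupancy PFS %.4f, PD %.4f, DEATH %.4f\n",
              x$arm$label, x$n_cycles, last$PFS, last$PD_2L + last$PD_SC,
              last$DEATH))
  invisible(x)
}

#' @method as_tibble cea_trace
#' @export
as_tibble.cea_trace <- function(x, ...) x$occupancy

#' Trace in long (cycle, state, fraction) form
#'
#' @param trace A `cea_trace`.
#' @return Tibble with columns `cycle`, `state`, `fraction` — the export
#'   dialect used by the reporting layer.
#' @export
trace_long <- function(trace) {
  stopifnot(inherits(trace, "cea_trace"))
  trace$occupancy |>
    select("cycle", "PFS", "PD_2L", "PD_SC", "DEATH") |>
    tidyr::pivot_longer(-"cycle", names_to = "state", values_to = "fraction")
}

#' Compose and run a treatment strategy
#'
#' The Control strategy is routine follow-up for all patients: one arm on
#' the control PFS curve, no genotyping, no drug. The Gefitinib strategy
#' genotypes everyone and gives maintenance gefitinib only to the EGFR
#' mutation-positive stratum (weight = mutation frequency), whose PFS
#' hazard is multiplied by the maintenance hazard ratio; the
#' mutation-negative stratum continues routine follow-up on the unadjusted
#' curve (hazard ratio `settings$hr_egfr_neg`, 1 by default). Downstream
#' aggregation is weight-averaged.
#'
#' @param strategy `"control"` or `"gefitinib"`.
#' @param params A `cea_params` object.
#' @param n_cycles,ledger Passed to [run_arm()].
#' @return A `cea_strategy`: list with `label`, `arms`, `weights`, `traces`.
#' @examples
#' st <- run_strategy("gefitinib", default_params())
#' st$weights
#' @export
run_strategy <- function(strategy = c("control", "gefitinib"), params,
                         n_cycles = NULL, ledger = FALSE) {
  strategy <- match.arg(strategy)
  stopifnot(inherits(params, "cea_params"))
  pfs <- params$weibull$pfs_control
  if (strategy == "control") {
    arms <- list(arm_spec("control", pfs))
    weights <- 1
  } else {
    freq <- param_value(params, "egfr_mutation_freq")
    if (freq < 0 || freq > 1) abort("egfr_mutation_freq must be in [0, 1]")
    hr <- param_value(params, "hr_pfs_gefitinib_egfr_pos")
    hr_neg <- params$settings$hr_egfr_neg
    pfs_neg <- if (hr_neg == 1) pfs else apply_hazard_ratio(pfs, hr_neg)
    arms <- list(
      arm_spec("egfr_positive", apply_hazard_ratio(pfs, hr),
               receives_gefitinib = TRUE, genotyped = TRUE),
      arm_spec("egfr_negative", pfs_neg, genotyped = TRUE)
    )
    weights <- c(freq, 1 - freq)
  }
  traces <- lapply(arms, run_arm, params = params, n_cycles = n_cycles,
                   ledger = ledger)
  structure(list(label = strategy, arms = arms, weights = weights,
                 traces = traces),
            class = "cea_strategy")
}

#' @export
print.cea_strategy <- function(x, ...) {
  cat(sprintf("<cea_strategy> %s: %d arm(s), weights %s\n", x$label,
              length(x$arms), paste(format(x$weights), collapse = ", ")))
  invisible(x)
}
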