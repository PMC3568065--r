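p <- base_params()
ctrl_arm <- arm_spec("control", p$weibull$pfs_control)

test_that("discount factors", {
  expect_equal(discount_factor(0, 0.03), 1)
  expect_equal(discount_factor(10, 0), 1)
  expect_equal(discount_factor(365.25 / 21, 0.03), 1 / 1.03)
  expect_error(discount_factor(1, -0.1), ">= 0")
})

test_that("SAE cost scaling from the platinum-chemotherapy reference", {
  expect_equal(sae_cost_per_cycle(0.07, p), 507.4 * 0.07 / 0.80)
  expect_equal(sae_cost_per_cycle(0.07, p), 44.4, tolerance = 1e-3)
  expect_equal(sae_cost_per_cycle(0.03, p), 19.03, tolerance = 1e-3)
  expect_equal(sae_cost_per_cycle(0, p), 0)
  p0 <- set_param(p, "p_sae_platinum", base = 0, low = 0)
  expect_error(sae_cost_per_cycle(0.07, p0), "positive")
})

test_that("unit utilities make QALYs equal discounted life-years", {
  p1 <- set_param(set_param(p, "utility_pfs", 1, high = 1),
                  "utility_pd", 1, high = 1)
  tr <- run_arm(ctrl_arm, p1, n_cycles = 40)
  eff <- accrue_effects(tr, p1)
  expect_equal(eff$qaly, eff$ly_disc)
  expect_equal(eff$qaly_undisc, eff$ly)
  expect_lte(eff$pf_ly, eff$ly)
})

test_that("zero discount rate collapses discounted onto undiscounted accrual", {
  p0 <- set_settings(p, discount_annual = 0)
  tr <- run_arm(ctrl_arm, p0, n_cycles = 40)
  eff <- accrue_effects(tr, p0)
  expect_equal(eff$pf_ly, eff$pf_ly_disc)
  expect_equal(eff$ly, eff$ly_disc)
  expect_equal(eff$qaly, eff$qaly_undisc)
})

test_that("cost accrual is additive and components isolate correctly", {
  gef_arm <- arm_spec("pos", apply_hazard_ratio(p$weibull$pfs_control, 0.17),
                      receives_gefitinib = TRUE, genotyped = TRUE)
  tr <- run_arm(gef_arm, p, n_cycles = 60)
  costs <- accrue_costs(tr, gef_arm, p)
  comp_cols <- setdiff(names(costs), "cost")
  expect_equal(costs$cost, sum(costs[, comp_cols]))
  expect_equal(costs$cost_genotyping, 507.9)   # charged undiscounted at cycle 0

  # end-of-life isolation: the component equals the discounted death stream
  d <- discount_factor(1:60, 0.03)
  expect_equal(costs$cost_endoflife,
               3664.3 * sum(tr$occupancy$new_deaths[-1] * d))

  # drug cost is the discounted progression-free exposure at 21 x unit price
  expect_equal(costs$cost_gefitinib,
               21 * 77.8 * sum(tr$occupancy$PFS[1:60] * d))
})

test_that("2nd-line cost cap agrees with an explicit ledger-matrix accrual", {
  tr <- run_arm(ctrl_arm, p, n_cycles = 60, ledger = TRUE)
  costs <- accrue_costs(tr, ctrl_arm, p)
  d <- discount_factor(1:60, 0.03)
  # membership of entry-cohort tau during cycle t is the ledger value at the
  # end of cycle t-1 (column t); 2nd-line price for the first 4 age-cycles
  by_matrix_2l <- 0
  by_matrix_sc <- 0
  M2 <- tr$ledger$PD_2L
  MS <- tr$ledger$PD_SC
  for (tau in 1:59) {
    for (t in (tau + 1):60) {
      k <- t - tau
      price <- if (k <= 4) 2352.7 else 337.5
      by_matrix_2l <- by_matrix_2l + M2[tau, t] * price * d[t]
      by_matrix_sc <- by_matrix_sc + MS[tau, t] * 337.5 * d[t]
    }
  }
  expect_equal(costs$cost_secondline, by_matrix_2l, tolerance = 1e-10)
  expect_equal(costs$cost_supportive, by_matrix_sc, tolerance = 1e-10)
})

test_that("the GPAP never increases cost and is inert for short exposure", {
  gef_arm <- arm_spec("pos", apply_hazard_ratio(p$weibull$pfs_control, 0.17),
                      receives_gefitinib = TRUE, genotyped = TRUE)
  set.seed(7)
  for (i in 1:5) {
    pi <- set_param(p, "cost_gefitinib_250mg", runif(1, 20, 150))
    tr <- run_arm(gef_arm, pi, n_cycles = 80)
    c_off <- accrue_costs(tr, gef_arm, pi, gpap = FALSE)$cost
    c_on <- accrue_costs(tr, gef_arm, pi, gpap = TRUE)$cost
    expect_lte(c_on, c_off)
  }
  # with a horizon inside the six paid months the GPAP changes nothing
  tr8 <- run_arm(gef_arm, p, n_cycles = 8)
  expect_equal(accrue_costs(tr8, gef_arm, p, gpap = TRUE)$cost,
               accrue_costs(tr8, gef_arm, p, gpap = FALSE)$cost)
})

test_that("raising any cost parameter weakly raises total cost", {
  cost_params <- grep("^cost_", tidy(p)$name, value = TRUE)
  base_costs <- vapply(c("control", "gefitinib"), function(s) {
    evaluate_strategy(s, set_settings(p, horizon_years = 2))$cost
  }, numeric(1))
  for (nm in cost_params) {
    pi <- set_param(set_settings(p, horizon_years = 2), nm,
                    param_value(p, nm) * 1.5)
    for (s in c("control", "gefitinib")) {
      expect_gte(evaluate_strategy(s, pi)$cost + 1e-9, base_costs[[s]])
    }
  }
  # and raising the PFS utility weakly raises QALYs
  pu <- set_param(p, "utility_pfs", 0.8)
  expect_gt(evaluate_strategy("control", set_settings(pu, horizon_years = 2))$qaly,
            evaluate_strategy("control", set_settings(p, horizon_years = 2))$qaly)
})

test_that("comparison arithmetic, dominance and net monetary benefit", {
  cmp <- compare_strategies(p, horizon_years = 2)
  ctrl <- cmp$strategies[cmp$strategies$strategy == "control", ]
  gef <- cmp$strategies[cmp$strategies$strategy == "gefitinib", ]
  expect_equal(cmp$comparison$delta_cost, gef$cost - ctrl$cost)
  expect_equal(cmp$comparison$icer_qaly,
               cmp$comparison$delta_cost / cmp$comparison$delta_qaly)
  expect_equal(cmp$comparison$dominance, "none")
  expect_equal(glance(cmp)$horizon_years, 2)

  # division check on the published rounded increments
  expect_equal(26149.9 / 0.46, 56847.6, tolerance = 1e-5)

  # free gefitinib and no genotyping/SAE/follow-up cost: cheaper and better
  pd <- p
  for (nm in c("cost_gefitinib_250mg", "cost_genotyping",
               "cost_sae_platinum_cycle", "cost_followup_visit")) {
    pd <- set_param(pd, nm, base = 0, low = 0)
  }
  cmp_d <- compare_strategies(pd, horizon_years = 10)
  expect_lt(cmp_d$comparison$delta_cost, 0)
  expect_gt(cmp_d$comparison$delta_qaly, 0)
  expect_equal(cmp_d$comparison$dominance, "gefitinib dominant")

  expect_equal(nmhb(16349.1, 7178.2, 0.46), 16349.1 * 0.46 - 7178.2)
  expect_equal(nmhb(0, 123.4, 0.46), -123.4)
  w <- seq(0, 1e5, 1e4)
  expect_true(all(diff(nmhb(w, 100, 0.2)) > 0))  # increasing in WTP
  expect_error(nmhb(-1, 0, 0), ">= 0")
})

test_that("base-case table is consistent across GPAP modes", {
  tab <- base_case_table(p, horizons = c(1, 2), gpap_modes = c(FALSE, TRUE))
  expect_equal(nrow(tab), 6)  # control + two gefitinib rows per horizon
  gef1 <- tab[tab$strategy == "Gefitinib" & tab$horizon_years == 1, ]
  # GPAP changes costs and ICERs but not health outcomes
  expect_equal(gef1$qaly[1], gef1$qaly[2])
  expect_equal(gef1$ly[1], gef1$ly[2])
  expect_lt(gef1$cost[gef1$gpap], gef1$cost[!gef1$gpap])
  ctrl1 <- tab[tab$strategy == "Control" & tab$horizon_years == 1, ]
  cmp <- compare_strategies(p, horizon_years = 1)
  expect_equal(ctrl1$cost, cmp$strategies$cost[1])
})

test_that("half-cycle correction shifts accruals by about half a cycle", {
  ph <- set_settings(p, half_cycle = TRUE)
  tr <- run_arm(ctrl_arm, p, n_cycles = 60)
  trh <- run_arm(ctrl_arm, ph, n_cycles = 60)
  e0 <- accrue_effects(tr, p)
  eh <- accrue_effects(trh, ph)
  expect_lt(eh$pf_ly, e0$pf_ly)
  expect_equal(eh$pf_ly, e0$pf_ly - 0.5 * (1 - min(trh$occupancy$PFS)) *
                 21 / 365.25, tolerance = 1e-3)
})
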