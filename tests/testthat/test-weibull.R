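pfs <- weibull_params(0.1559, 1.045)

test_that("survival function evaluates the closed form", {
  expect_equal(survival_at(pfs, 0), 1)
  expect_equal(survival_at(pfs, 1), exp(-0.1559))
  expect_equal(survival_at(pfs, 1), 0.8556, tolerance = 1e-4)
  expect_equal(survival_at(weibull_params(0.04006, 1.156), 10),
               exp(-0.04006 * 10^1.156))
  expect_equal(survival_at(weibull_params(0.04006, 1.156), 10),
               0.5634, tolerance = 1e-4)
  expect_error(survival_at(pfs, -1), "non-negative")
  # strictly decreasing in t and in scale
  s <- survival_at(pfs, seq(0.5, 30, by = 0.5))
  expect_true(all(diff(s) < 0))
  expect_true(all(survival_at(weibull_params(0.2, 1.045), 1:10) <
                    survival_at(weibull_params(0.1, 1.045), 1:10)))
})

test_that("per-cycle transition probabilities follow the survival ratio", {
  expect_equal(cycle_transition_prob(pfs, 1), 1 - exp(-0.1559))
  # exponential special case: memoryless, constant across cycles
  expo <- weibull_params(0.3, 1)
  expect_equal(cycle_transition_prob(expo, 1:50),
               rep(1 - exp(-0.3), 50))
  # week- and month-denominated curves convert through units per cycle
  wk <- weibull_params(0.05, 1.2, time_unit = "week")
  u <- 3
  expect_equal(cycle_transition_prob(wk, 4),
               1 - survival_at(wk, u * 4) / survival_at(wk, u * 3))
  expect_error(cycle_transition_prob(pfs, 0), ">= 1")
})

test_that("telescoping identity: prod(1 - P_t) equals S(N)", {
  set.seed(42)
  for (i in 1:20) {
    wp <- weibull_params(runif(1, 0.01, 0.5), runif(1, 0.5, 2.5),
                         time_unit = sample(c("cycle", "week", "month"), 1))
    N <- sample(c(10, 100, 500), 1)
    pt <- cycle_transition_prob(wp, 1:N)
    u <- if (wp$time_unit == "cycle") 1 else if (wp$time_unit == "week") 3
    else 21 / 30.4375
    expect_equal(prod(1 - pt), survival_at(wp, u * N), tolerance = 1e-10)
  }
})

test_that("hazard-ratio adjustment is proportional hazards on the scale", {
  expect_equal(apply_hazard_ratio(pfs, 1), pfs)
  adj <- apply_hazard_ratio(pfs, 0.17)
  expect_equal(adj$scale, 0.1559 * 0.17)
  expect_equal(adj$shape, 1.045)
  # Weibull PH identity: S_hr(t) = S(t)^hr, pointwise
  t <- seq(0.5, 40, by = 0.5)
  for (hr in c(0.17, 0.5, 2)) {
    expect_equal(survival_at(apply_hazard_ratio(pfs, hr), t),
                 survival_at(pfs, t)^hr)
  }
  expect_gt(median_survival(apply_hazard_ratio(pfs, 0.17)),
            median_survival(pfs))
  expect_error(apply_hazard_ratio(pfs, 0), "positive")
  expect_error(apply_hazard_ratio(pfs, -1), "positive")
})

test_that("median survival closed form and calibration helper", {
  expect_equal(median_survival(weibull_params(log(2), 1)), 1)
  expect_equal(median_survival(pfs), 4.17, tolerance = 1e-3)
  expect_equal(median_survival(weibull_params(0.03897, 1.509)),
               6.73, tolerance = 1e-3)
  cal <- calibrate_scale_to_median(weibull_params(0.04006, 1.156), 6.563)
  expect_equal(median_survival(cal), 6.563)
  expect_equal(cal$shape, 1.156)
})

test_that("noiseless Weibull curves are recovered exactly", {
  truth <- weibull_params(0.03897, 1.509)
  km <- tibble::tibble(time = 1:30, survival = survival_at(truth, 1:30))
  fit <- fit_weibull(km)
  expect_equal(fit$params$scale, truth$scale, tolerance = 1e-6)
  expect_equal(fit$params$shape, truth$shape, tolerance = 1e-6)
  expect_equal(fit$adj_r2, 1, tolerance = 1e-9)
  expect_equal(fit$correlation, 1, tolerance = 1e-9)
  expect_equal(tidy(fit)$estimate, c(truth$scale, truth$shape),
               tolerance = 1e-6)
  expect_equal(glance(fit)$median_survival, median_survival(truth),
               tolerance = 1e-6)
})

test_that("fitting rejects unusable curves and deduplicates ties", {
  expect_error(fit_weibull(tibble::tibble(time = 0:3, survival = rep(1, 4))),
               "3 usable points")
  expect_error(fit_weibull(tibble::tibble(time = 1:2,
                                          survival = c(0.9, 0.8))),
               "3 usable points")
  expect_error(fit_weibull(tibble::tibble(time = 1:5,
                                          survival = rep(0.5, 5))),
               "degenerate")
  # tied times keep the last (right-continuous step) value
  truth <- weibull_params(0.1, 1.3)
  clean <- tibble::tibble(time = 1:10, survival = survival_at(truth, 1:10))
  dup <- rbind(tibble::tibble(time = 3, survival = 0.99), clean)
  fit <- fit_weibull(dup)
  expect_equal(fit$params$scale, truth$scale, tolerance = 1e-6)
})

test_that("least-squares fit agrees with maximum likelihood on pseudo-IPD", {
  truth <- weibull_params(0.1559, 1.045)
  cohort <- simulate_cohort(truth, n = 2000, censor_time = 30, seed = 11)
  fit <- fit_weibull(km_estimate(cohort))
  # independent oracle: parametric survreg MLE on the same individual data
  sr <- survival::survreg(survival::Surv(time, event) ~ 1,
                          data = as.data.frame(cohort), dist = "weibull")
  shape_mle <- 1 / sr$scale
  scale_mle <- exp(-coef(sr)[[1]] * shape_mle)
  expect_equal(fit$params$shape, shape_mle, tolerance = 0.1)
  expect_equal(fit$params$scale, scale_mle, tolerance = 0.15)
  # and both are near the truth
  expect_equal(fit$params$scale, truth$scale, tolerance = 0.15)
  expect_equal(fit$params$shape, truth$shape, tolerance = 0.15)
})

test_that("weibull_params validates its inputs", {
  expect_error(weibull_params(-1, 1), "scale")
  expect_error(weibull_params(0.1, 0), "shape")
  expect_error(weibull_params(0.1, 1, adj_r2 = 1.2), "adj_r2")
  expect_error(weibull_params(0.1, 1, time_unit = "fortnight"))
})
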