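# Synthetic pseudo individual-patient data with known Weibull structure.
# Exists so the curve-fitting stage (and the whole pipeline behind it) is
# testable by parameter recovery without any external trial data.

with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Simulate a survival cohort from a known Weibull truth
#'
#' Event times are drawn by inverse transform,
#' \eqn{T = (-\ln U / \lambda)^{1/\gamma}}, then administratively censored
#' at `censor_time` (emulating trial-duration truncation of a Kaplan-Meier
#' curve). Fully reproducible from `seed`; the generator's own RNG state is
#' isolated from the session.
#'
#' @param truth A [weibull_params()] object (the data-generating curve).
#' @param n Number of subjects (>= 1).
#' @param censor_time Administrative censoring time, native time units;
#'   `Inf` for no censoring.
#' @param seed Integer seed.
#' @return A tibble with columns `time` and `event` (TRUE = event observed,
#'   FALSE = censored), carrying `truth`, `censor_time` and `seed` as
#'   attributes.
#' @examples
#' simulate_cohort(weibull_params(log(2), 1), n = 5, censor_time = 3, seed = 1)
#' @export
simulate_cohort <- function(truth, n, censor_time = Inf, seed = 1L) {
  stopifnot(inherits(truth, "weibull_params"))
  if (!is.numeric(n) || length(n) != 1 || n < 1 || n != round(n)) {
    abort("n must be a positive integer")
  }
  if (!is.numeric(censor_time) || censor_time <= 0) {
    abort("censor_time must be positive")
  }
  t_event <- with_local_seed(seed, {
    u <- runif(n)
    (-log(u) / truth$scale)^(1 / truth$shape)
  })
  out <- tibble(time = pmin(t_event, censor_time),
                event = t_event <= censor_time)
  attr(out, "truth") <- truth
  attr(out, "censor_time") <- censor_time
  attr(out, "seed") <- seed
  out
}

#' Kaplan-Meier estimate of a simulated cohort
#'
#' Standard product-limit estimator over the distinct event times, via
#' [survival::survfit()]. The returned step curve starts at (0, 1) and uses
#' the right-continuous convention, the same dialect [fit_weibull()] reads.
#'
#' @param cohort Data frame with columns `time` and `event`, e.g. from
#'   [simulate_cohort()].
#' @return Tibble with columns `time` and `survival`.
#' @examples
#' km_estimate(tibble::tibble(time = 1:3, event = TRUE))
#' @export
km_estimate <- function(cohort) {
  if (!is.data.frame(cohort) || !all(c("time", "event") %in% names(cohort))) {
    abort("cohort must be a data frame with columns 'time' and 'event'")
  }
  if (!any(cohort$event)) abort("no events in cohort: Kaplan-Meier undefined")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1,
                           data = as.data.frame(cohort))
  keep <- fit$n.event > 0
  tibble(time = c(0, fit$time[keep]),
         survival = c(1, fit$surv[keep]))
}
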