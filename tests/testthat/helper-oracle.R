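# Independent brute-force oracle for the cohort engine: enumerate every
# discrete outcome path (progression cycle x pathway x death cycle) and
# accumulate state occupancy per cycle. Deliberately written as explicit
# path enumeration, sharing nothing with the convolution implementation.
brute_force_occupancy <- function(arm, params, N) {
  cd <- params$settings$cycle_days
  p2 <- param_value(params, "p_secondline")
  qp <- cycle_transition_prob(arm$pfs_params, 1:N, cd)
  q_os <- list(
    PD_2L = cycle_transition_prob(params$weibull$os_secondline, 1:N, cd),
    PD_SC = cycle_transition_prob(params$weibull$os_supportive, 1:N, cd)
  )
  w_os <- c(PD_2L = p2, PD_SC = 1 - p2)

  occ <- matrix(0, nrow = N + 1, ncol = 4,
                dimnames = list(0:N, c("PFS", "PD_2L", "PD_SC", "DEATH")))
  add <- function(prob, cycles, state) {
    occ[as.character(cycles), state] <<- occ[as.character(cycles), state] + prob
  }

  # never progress within the horizon
  add(prod(1 - qp), 0:N, "PFS")
  for (tau in 1:N) {
    p_prog <- prod(1 - qp[seq_len(tau - 1)]) * qp[tau]
    add(p_prog, 0:(tau - 1), "PFS")
    for (state in c("PD_2L", "PD_SC")) {
      q <- q_os[[state]]
      p_path <- p_prog * w_os[[state]]
      if (tau < N) {
        for (k in 1:(N - tau)) {
          p_death <- prod(1 - q[seq_len(k - 1)]) * q[k]
          if (k > 1) add(p_path * p_death, tau:(tau + k - 1), state)
          else add(p_path * p_death, tau, state)
          add(p_path * p_death, (tau + k):N, "DEATH")
        }
        p_alive <- prod(1 - q[seq_len(N - tau)])
        add(p_path * p_alive, tau:N, state)
      } else {
        add(p_path, N, state)
      }
    }
  }
  occ
}

# small parameter set used across tests (published base case)
base_params <- function() default_params()
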