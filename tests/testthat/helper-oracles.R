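# Independent oracles used across the suite.  These deliberately re-derive
# quantities by brute force (enumeration, root finding, Markov-chain algebra)
# rather than calling the implementation paths they check.

# Exhaustive enumeration of the constrained backward-criterion minimizer over
# the same log-spaced grid as the implementation, built from scalar calls.
brute_force_stage_min <- function(s_jm2, s_jm1, s_j, p_hat_jm1, interval, cfg) {
  cs <- exp(seq(log(cfg$c_range[1]), log(cfg$c_range[2]), length.out = cfg$grid_size))
  as <- exp(seq(log(cfg$a_range[1]), log(cfg$a_range[2]), length.out = cfg$grid_size))
  best <- NULL
  for (a in as) {       # column-major like the implementation grid
    for (cc in cs) {
      cond <- gpd_condition(gpd_params(cc, a), s_jm1)
      if (!is_admissible(cond$c, cond$a, s_j, s_jm1, interval)) next
      obj <- backward_objective(cc, a, s_jm1, s_jm2, p_hat_jm1)
      if (is.null(best) || obj < best$objective - 1e-15 ||
          (abs(obj - best$objective) <= 1e-15 &&
           (cc < best$c || (cc == best$c && a < best$a)))) {
        best <- list(c = cc, a = a, objective = obj)
      }
    }
  }
  best
}

# Expected failure fraction of the staircase level walk, computed from the
# exact Markov transition structure on the (finite, reachable) level lattice.
staircase_expected_failure_fraction <- function(cfg) {
  # reachable levels: s_ini + delta * j for j in -(K)..K, but the walk reflects
  # off the certain-survival region, so truncate generously
  lv <- cfg$s_ini + cfg$delta * seq(-cfg$K, cfg$K)
  phi <- if (cfg$model == "exponential") {
    ifelse(lv <= 0, 0, 1 - exp(-cfg$par[1] * lv))
  } else {
    pnorm((lv - cfg$par[1]) / cfg$par[2])
  }
  n <- length(lv)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    dn <- max(i - 1, 1); up <- min(i + 1, n)
    P[i, dn] <- P[i, dn] + phi[i]
    P[i, up] <- P[i, up] + (1 - phi[i])
  }
  pi_t <- numeric(n); pi_t[which(lv == cfg$s_ini)] <- 1
  expected_failures <- 0
  for (t in seq_len(cfg$K)) {
    expected_failures <- expected_failures + sum(pi_t * phi)
    pi_t <- as.numeric(pi_t %*% P)
  }
  expected_failures / cfg$K
}

# Numeric inversion of the GPD survival function by root finding (independent
# of gpd_quantile's closed form).
gpd_quantile_numeric <- function(u, params) {
  uniroot(function(x) gpd_sf(x, params) - (1 - u),
          lower = 0, upper = 1e12, tol = 1e-12)$root
}
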