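# Shared fixture builders. Small cohorts keep unit tests fast; the
# acceptance tests build their own, larger cohorts at the scales the
# calibration and recovery studies require.

default_covariates <- c("sex", "age", "height_in", "bmi",
                        "rna_conc", "ratio_260_280", "rna_quality")

small_params <- function(n = 600, n_families = 150, seed = 11,
                         mirna_specs = null_mirna_panel(4), ...) {
  sim_params(n_participants = n, n_families = n_families,
             mirna_specs = mirna_specs, seed = seed, ...)
}

small_cohort <- function(...) {
  simulate_cohort(small_params(...))
}

# Independent step-up BH oracle: direct evaluation of the definition.
brute_force_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- numeric(m)
  running <- Inf
  for (i in m:1) {
    running <- min(running, p[o[i]] * m / i)
    q_sorted[i] <- min(running, 1)
  }
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# Independent adaptive-p oracle: chi-squared(1) quantile recovered through
# the standard-normal quantile identity, chi-squared(2) survival in closed
# form exp(-x/2). Shares no code path with adaptive_p().
oracle_adaptive_p <- function(p_binary, p_continuous) {
  s <- qnorm(p_binary / 2)^2 + qnorm(p_continuous / 2)^2
  exp(-s / 2)
}

# Hypergeometric upper-tail oracle by direct pmf summation.
oracle_hyper_tail <- function(k, K, N, n) {
  kk <- k:min(K, n)
  sum(exp(lchoose(K, kk) + lchoose(N - K, n - kk) - lchoose(N, n)))
}
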