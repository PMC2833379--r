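# Shared fixtures: schemes and random-scheme generators used across tests.

cond10 <- fold_conditions() # 283.15 K

# Wild-type-like three-state scheme assembled from the packaged scenario set
wt_scheme <- function() scenario_scheme("Im7")

wt_truth <- c(k_IU = 1574 / 222.2, m_IU = 4.19 - 1.23,
              k_IN = 253.9, m_IN = 0.75, k_NI = 1.26, m_NI = 0.45)

# Random three-state scheme on the documented parameter scales
# (rates 0.1-1600 s^-1, m-values 0.1-4.5 kJ/mol/M)
random_three_state <- function() {
  k <- exp(stats::runif(4, log(0.1), log(1600)))
  m <- stats::runif(4, 0.1, 1.5)
  three_state_scheme(k[1], m[1], k[2], m[2], k[3], m[3], k[4], m[4])
}

random_two_state <- function() {
  k <- exp(stats::runif(2, log(0.1), log(1600)))
  two_state_scheme(k[1], stats::runif(1, 1, 4), k[2],
                   stats::runif(1, 0.1, 1.5))
}

# Random LEM equilibrium model with a midpoint inside 1.5-6 M
random_equilibrium_model <- function() {
  M <- stats::runif(1, 2, 5)
  d50 <- stats::runif(1, 1.5, 6)
  equilibrium_model(-M * d50, M,
                    baseline_N = c(stats::runif(1, 0.2, 0.6),
                                   stats::runif(1, -0.02, 0.02)),
                    baseline_D = c(stats::runif(1, 0.8, 1.2),
                                   stats::runif(1, -0.02, 0.02)))
}
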