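test_that("rate laws follow the kinetic linear free-energy relationship", {
  # zero-denaturant identity
  expect_equal(rate_at_denaturant(rate_law(253.9, 0.75, "folding"), 0), 253.9)
  # frozen high-precision evaluations of rate0 * exp(-/+ m D / RT)
  expect_equal(rate_at_denaturant(rate_law(1574, 1.23, "folding"), 2, cond10),
               553.608061, tolerance = 1e-8)
  expect_equal(rate_at_denaturant(rate_law(1.26, 0.45, "unfolding"), 8, cond10),
               5.813953, tolerance = 1e-6)
  expect_error(rate_at_denaturant(rate_law(1, 1, "folding"), -0.1), "negative")
  expect_error(rate_law(-5, 1, "folding"), "positive")
  expect_error(rate_law(5, -1, "folding"), "non-negative")
})

test_that("conditions default to 10 degrees C and RT is an exact product", {
  expect_equal(cond10$temperature_K, 283.15)
  expect_equal(cond10$RT, 0.0083145 * 283.15, tolerance = 1e-12)
  expect_error(fold_conditions(temperature_K = -1), "positive")
})

test_that("analytical relaxation rates match a numerical eigendecomposition", {
  withr::with_seed(101, {
    for (i in 1:200) {
      sc <- random_three_state()
      D <- stats::runif(1, 0, 8)
      lam <- relaxation_rates(sc, D, cond10)
      ev <- sort(abs(eigen(rate_matrix(sc, D, cond10),
                           only.values = TRUE)$values),
                 decreasing = TRUE)[1:2]
      expect_equal(lam$lambda_fast, ev[1], tolerance = 1e-9)
      expect_equal(lam$lambda_slow, ev[2], tolerance = 1e-9)
      expect_gte(lam$lambda_fast, lam$lambda_slow)
    }
  })
})

test_that("slow phase vanishes when the native state is disconnected", {
  # k_IN, k_NI -> 0: only the U <-> I relaxation remains
  sc <- three_state_scheme(100, 1, 100, 1, 1e-12, 0.5, 1e-12, 0.5)
  lam <- relaxation_rates(sc, 0)
  expect_equal(lam$lambda_fast, 200, tolerance = 1e-9)
  expect_equal(lam$lambda_slow, 0, tolerance = 1e-9)
})

test_that("slow eigenvalue approaches the pre-equilibrium formula", {
  withr::with_seed(202, {
    for (i in 1:100) {
      k_IN <- exp(stats::runif(1, log(1), log(500)))
      k_NI <- exp(stats::runif(1, log(0.1), log(50)))
      # U <-> I exchange >= 100x faster than the I <-> N step
      fast <- (k_IN + k_NI) * 100 * exp(stats::runif(1, 0, 2))
      K <- exp(stats::runif(1, -2, 3))
      sc <- three_state_scheme(fast, 1, fast / K, 1, k_IN, 0.5, k_NI, 0.5)
      lam <- relaxation_rates(sc, 0)$lambda_slow
      pre <- k_IN * K / (1 + K) + k_NI
      expect_equal(lam, pre, tolerance = 0.01)
    }
  })
  # at 1e4-fold separation the agreement tightens to < 1e-3 relative
  sc <- three_state_scheme(1e4 * 300, 1, 1e4 * 300 / 50, 1, 200, 0.5, 10, 0.5)
  lam <- relaxation_rates(sc, 0)$lambda_slow
  pre <- relaxation_rates(sc, 0, method = "pre_equilibrium")$lambda_slow
  expect_equal(lam, pre, tolerance = 1e-3)
})

test_that("two-state kobs is the branch sum with a convex log-chevron", {
  sc <- scenario_scheme("IV7T")
  expect_equal(two_state_kobs(sc, 0), 279.4 + 3.40, tolerance = 1e-12)
  # symmetric rates put the chevron minimum at zero denaturant
  sym <- two_state_scheme(10, 1, 10, 1)
  D <- seq(0, 8, 0.25)
  expect_equal(which.min(two_state_kobs(sym, D)), 1L)
  # high-denaturant limit: unfolding branch dominates
  hiD <- 8
  kNU <- rate_at_denaturant(sc$rate_laws$NU, hiD)
  kUN <- rate_at_denaturant(sc$rate_laws$UN, hiD)
  expect_lt(kUN / kNU, 0.01)
  expect_equal(two_state_kobs(sc, hiD), kNU, tolerance = 0.01)
  # ln kobs convex in D for random two-state schemes
  withr::with_seed(303, {
    for (i in 1:25) {
      lk <- log(two_state_kobs(random_two_state(), D))
      expect_true(all(diff(lk, differences = 2) > -1e-8))
    }
  })
})

test_that("equilibrium populations obey detailed balance and normalisation", {
  # wild-type-like stability: essentially fully native in water
  pops <- equilibrium_populations(wt_scheme(), 0, cond10)
  expect_gt(pops$p_N, 0.99)
  expect_equal(pops$p_U + pops$p_I + pops$p_N, 1, tolerance = 1e-12)
  # symmetric scheme: equal thirds
  sym <- three_state_scheme(10, 1, 10, 1, 5, 0.5, 5, 0.5)
  pops <- equilibrium_populations(sym, 0)
  expect_equal(unlist(pops[, c("p_U", "p_I", "p_N")]),
               c(p_U = 1, p_I = 1, p_N = 1) / 3, tolerance = 1e-12)
  # population ratios equal exp(-dG/RT) from thermo_summary
  withr::with_seed(404, {
    for (i in 1:50) {
      sc <- random_three_state()
      D <- stats::runif(1, 0, 8)
      pops <- equilibrium_populations(sc, D, cond10)
      # evaluate the D-dependent free energies from the scheme at D
      K_UI <- rate_at_denaturant(sc$rate_laws$UI, D) /
        rate_at_denaturant(sc$rate_laws$IU, D)
      K_IN <- rate_at_denaturant(sc$rate_laws$IN, D) /
        rate_at_denaturant(sc$rate_laws$NI, D)
      expect_equal(pops$p_I / pops$p_U, K_UI, tolerance = 1e-9)
      expect_equal(pops$p_N / pops$p_I, K_IN, tolerance = 1e-9)
    }
  })
})

test_that("thermo summary reproduces published wild-type derived values", {
  ts <- thermo_summary(wt_scheme(), cond10)
  # from K_UI = 222.2 at 283.15 K (printed -12.71 +/- 0.59)
  expect_equal(ts$dG_UI, -12.7214, tolerance = 1e-4)
  expect_equal(ts$dG_UI, -12.71, tolerance = 0.05 / 12.71)
  # adding k_IN = 253.9, k_NI = 1.26 (printed -25.19 +/- 0.65)
  expect_equal(ts$dG_UN, -25.2126, tolerance = 1e-4)
  # beta values from M_UI = 4.19, m_IN = 0.75, m_NI = 0.45 (printed 0.78/0.92)
  expect_equal(ts$beta_I, 4.19 / 5.39, tolerance = 1e-9)
  expect_equal(ts$beta_TS2, 4.94 / 5.39, tolerance = 1e-9)
  expect_equal(round(ts$beta_I, 2), 0.78)
  expect_equal(round(ts$beta_TS2, 2), 0.92)
  # K_UI = 1 gives dG_UI = 0
  unit <- three_state_scheme(10, 1, 10, 1, 5, 0.5, 5, 0.5)
  expect_equal(thermo_summary(unit)$dG_UI, 0)
})

test_that("thermodynamic additivity and beta ordering hold for any scheme", {
  withr::with_seed(505, {
    for (i in 1:50) {
      ts <- thermo_summary(random_three_state(), cond10)
      expect_equal(ts$dG_UN, ts$dG_UI + ts$dG_IN, tolerance = 1e-9)
      expect_true(0 < ts$beta_I && ts$beta_I <= ts$beta_TS2 &&
                    ts$beta_TS2 <= 1)
    }
  })
  # two-state scheme: dG from the rate ratio, beta from the m split
  ts2 <- thermo_summary(scenario_scheme("IV7T"), cond10)
  expect_equal(ts2$dG_UN, -cond10$RT * log(279.4 / 3.40), tolerance = 1e-12)
  expect_equal(ts2$M_UN, 3.27 + 0.68)
  expect_equal(ts2$beta_TS2, 3.27 / 3.95, tolerance = 1e-12)
  expect_true(is.na(ts2$beta_I))
})
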