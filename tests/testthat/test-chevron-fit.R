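test_that("exponential trace fitting recovers exact model parameters", {
  t <- seq(0, 0.2, length.out = 100)
  tr <- data.frame(time_s = t, signal = 0.2 + 0.8 * exp(-50 * t))
  fit <- fit_exponential_trace(tr, 1)
  expect_equal(fit$rates, 50, tolerance = 1e-6)
  expect_equal(fit$amplitudes, 0.8, tolerance = 1e-6)
  expect_equal(fit$offset, 0.2, tolerance = 1e-6)
  expect_equal(fit$initial_signal, 1.0, tolerance = 1e-6)
})

test_that("double-exponential fits resolve well-separated phases in noise", {
  t <- c(seq(0, 0.02, 5e-4), seq(0.025, 1, 5e-3))
  s <- 0.1 + 0.4 * exp(-500 * t) + 0.4 * exp(-5 * t)
  tr <- withr::with_seed(11, data.frame(
    time_s = t, signal = s + stats::rnorm(length(t), 0, 0.01)))
  fit <- fit_exponential_trace(tr, 2)
  expect_equal(fit$rates[1], 500, tolerance = 0.05)
  expect_equal(fit$rates[2], 5, tolerance = 0.05)
  expect_true(all(diff(fit$rates) < 0)) # sorted descending
})

test_that("trace fit preconditions and collapse fallback behave as specified", {
  tr4 <- data.frame(time_s = 1:4, signal = exp(-(1:4)))
  expect_error(fit_exponential_trace(tr4, 2), "at least 7 points")
  # a pure single exponential collapses a two-phase fit
  t <- seq(0, 1, length.out = 80)
  tr <- data.frame(time_s = t, signal = 0.3 + 0.7 * exp(-8 * t))
  expect_warning(fit2 <- fit_exponential_trace(tr, 2), "collapsed")
  expect_equal(fit2$n_phases, 1)
  expect_equal(fit2$rates, 8, tolerance = 1e-4)
})

test_that("signal normalisation maps blank to 0 and reference to 1", {
  expect_equal(normalize_signals(5, 1, 5), 1)
  expect_equal(normalize_signals(1, 1, 5), 0)
  expect_equal(normalize_signals(1 + 0.5 * 4, 1, 5), 0.5)
  expect_error(normalize_signals(2, 3, 3), "blank")
})

test_that("amplitude model reflects burst-phase equilibration", {
  # identical baselines for all states: initial and final signals coincide
  flat <- tibble::tibble(state = c("U", "I", "N"), intercept = 1, slope = 0.01)
  sc <- scenario_scheme("Im7", signal_coeffs = flat)
  amp <- amplitude_model(sc, seq(0, 8, 1), "refolding")
  expect_equal(amp$initial_signal, amp$final_signal, tolerance = 1e-12)
  # K_UI -> 0: initial refolding signal collapses onto the U baseline
  weak <- three_state_scheme(1e-6, 1.23, 1000, 2.96, 250, 0.75, 1.3, 0.45)
  amp <- amplitude_model(weak, 2, "refolding")
  bU <- weak$signal_coeffs$intercept[1] + weak$signal_coeffs$slope[1] * 2
  expect_equal(amp$initial_signal, bU, tolerance = 1e-6)
  # wild-type-like scheme with a bright intermediate: burst-phase signal
  # rise above the unfolded baseline at low denaturant
  sc <- wt_scheme()
  amp <- amplitude_model(sc, 1, "refolding")
  bU1 <- sc$signal_coeffs$intercept[1] + sc$signal_coeffs$slope[1] * 1
  expect_gt(amp$initial_signal, bU1)
  # unfolding experiments start from the native baseline
  ampu <- amplitude_model(sc, 6, "unfolding")
  bN6 <- sc$signal_coeffs$intercept[3] + sc$signal_coeffs$slope[3] * 6
  expect_equal(ampu$initial_signal, bN6)
})

test_that("noise-free three-state chevrons are refitted exactly", {
  dat <- generate_chevron(wt_scheme(), noise = noise_model(0, 0, 0))
  fit <- fit_chevron_three_state(dat)
  est <- stats::setNames(fit$params$estimate, fit$params$term)
  for (nm in names(wt_truth)) {
    expect_equal(unname(est[nm]), unname(wt_truth[nm]), tolerance = 1e-6)
  }
  expect_true(fit$convergence$success)
  # kinetic M_UN is exactly the sum of the fitted m-value magnitudes
  thermo <- stats::setNames(fit$thermo$value, fit$thermo$quantity)
  expect_identical(unname(thermo["M_UN"]),
                   sum(est[c("m_UI", "m_IU", "m_IN", "m_NI")]))
})

test_that("noise-free round trips succeed across random three-state schemes", {
  withr::with_seed(21, {
    for (i in 1:5) {
      # draw schemes with a chevron-like geometry: fast burst phase,
      # observable slow phase
      K_UI <- exp(stats::runif(1, log(10), log(400)))
      sc <- three_state_scheme(1574, 1.23, 1574 / K_UI,
                               stats::runif(1, 2, 3.5),
                               exp(stats::runif(1, log(50), log(500))),
                               stats::runif(1, 0.3, 1),
                               exp(stats::runif(1, log(0.3), log(30))),
                               stats::runif(1, 0.2, 0.8))
      truth <- vapply(sc$rate_laws, function(l) l$rate0, numeric(1))
      dat <- generate_chevron(sc, noise = noise_model(0, 0, 0))
      fit <- fit_chevron_three_state(dat)
      est <- stats::setNames(fit$params$estimate, fit$params$term)
      expect_equal(unname(est["k_IU"]), unname(truth["IU"]),
                   tolerance = 1e-5)
      expect_equal(unname(est["k_IN"]), unname(truth["IN"]),
                   tolerance = 1e-5)
      expect_equal(unname(est["k_NI"]), unname(truth["NI"]),
                   tolerance = 1e-5)
    }
  })
})

test_that("noisy three-state fits recover generating rates within 3 sigma", {
  dat <- generate_chevron(wt_scheme(), noise = noise_model(seed = 42))
  fit <- fit_chevron_three_state(dat, signal_sigma = 0.01)
  est <- stats::setNames(fit$params$estimate, fit$params$term)
  se <- stats::setNames(fit$params$std_error, fit$params$term)
  for (nm in c("k_IU", "k_IN", "k_NI")) {
    z <- abs(log(est[nm]) - log(wt_truth[nm])) / (se[nm] / est[nm])
    expect_lt(z, 3)
  }
})

test_that("fixed parameters are excluded from the fitted covariance", {
  dat <- generate_chevron(wt_scheme(), noise = noise_model(seed = 3))
  fit <- fit_chevron_three_state(dat) # default fixes k_UI, m_UI
  expect_false(any(c("k_UI", "m_UI") %in% colnames(fit$covariance)))
  p <- fit$params
  expect_true(all(p$fixed[p$term %in% c("k_UI", "m_UI")]))
  expect_identical(p$std_error[p$term == "k_UI"], 0)
})

test_that("fixing a parameter at truth never improves on the free optimum", {
  dat <- generate_chevron(wt_scheme(), noise = noise_model(seed = 8))
  free_fit <- fit_chevron_three_state(dat, weighting = "equal",
                                      signal_sigma = 1)
  fixed_fit <- fit_chevron_three_state(
    dat,
    constraints = fit_constraints(fixed = list(k_UI = 1574, m_UI = 1.23,
                                               k_IN = 253.9)),
    weighting = "equal", signal_sigma = 1
  )
  ssr <- function(f) sum(f$residual_blocks$rms^2 * f$residual_blocks$n)
  # allow for optimiser stopping noise in the free fit
  expect_gte(ssr(fixed_fit), ssr(free_fit) * (1 - 0.01))
})

test_that("rate-only datasets fit with a warning and no signal parameters", {
  dat <- generate_chevron(wt_scheme(), noise = noise_model(seed = 4))
  dat$initial_fluor <- NULL
  dat$final_fluor <- NULL
  expect_warning(fit <- fit_chevron_three_state(dat), "rates only")
  expect_false(any(grepl("^sig_", fit$params$term)))
  est <- stats::setNames(fit$params$estimate, fit$params$term)
  expect_equal(unname(est["k_IN"]), 253.9, tolerance = 0.15)
})

test_that("two-state fits recover the marginally stable variant exactly", {
  sc <- scenario_scheme("IV7T")
  dat <- generate_chevron(sc, noise = noise_model(0, 0, 0))
  fit <- fit_chevron_two_state(dat)
  est <- stats::setNames(fit$params$estimate, fit$params$term)
  expect_equal(unname(est["k_UN"]), 279.4, tolerance = 1e-6)
  expect_equal(unname(est["m_UN"]), 3.27, tolerance = 1e-6)
  expect_equal(unname(est["k_NU"]), 3.40, tolerance = 1e-6)
  expect_equal(unname(est["m_NU"]), 0.68, tolerance = 1e-6)
  thermo <- stats::setNames(fit$thermo$value, fit$thermo$quantity)
  # printed -10.38 +/- 0.13
  expect_equal(unname(thermo["dG_UN"]), -10.38, tolerance = 0.05 / 10.38)
})

test_that("unfolding parameters of a stable protein are flagged when only a
           truncated refolding branch is measured", {
  sc <- two_state_scheme(300, 3.3, 0.001, 0.65) # dG_UN ~ -29.7 kJ/mol
  dat <- generate_chevron(sc, refolding_grid = seq(0.75, 4, length.out = 10),
                          unfolding_grid = numeric(0),
                          noise = noise_model(seed = 5))
  fit <- suppressWarnings(fit_chevron_two_state(dat, signal_sigma = 0.01))
  expect_false(fit$identifiable)
  expect_true(any(c("k_NU", "m_NU") %in% fit$unidentified))
})

test_that("an M_UN range constraint steers an otherwise degenerate fit", {
  sc <- wt_scheme()
  dat <- generate_chevron(sc, noise = noise_model(seed = 6))
  fit <- fit_chevron_three_state(
    dat,
    constraints = fit_constraints(fixed = list(k_UI = 1574, m_UI = 1.23),
                                  M_UN_range = c(4.6, 5.2))
  )
  thermo <- stats::setNames(fit$thermo$value, fit$thermo$quantity)
  expect_lte(thermo[["M_UN"]], 5.2 + 1e-3)
  expect_gte(thermo[["M_UN"]], 4.6 - 1e-3)
})

test_that("chevron data validation catches bad inputs", {
  dat <- generate_chevron(wt_scheme(), noise = noise_model(seed = 7))
  bad <- dat
  bad$kobs_s1[5] <- -1
  expect_error(fit_chevron_three_state(bad), "row\\(s\\): 5")
  few <- dat[dat$urea_M > 4, ]
  expect_error(fit_chevron_three_state(few), ">= 3 distinct")
  expect_error(fit_constraints(fixed = list(k_UI = 1), bounds = list(k_UI = c(0, 2))),
               "both fixed and bounded")
})
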