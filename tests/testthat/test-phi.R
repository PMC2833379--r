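test_that("ddG arithmetic and quadrature errors are correct", {
  # the marginally stable N-terminal variant vs wild type: +14.81 kJ/mol
  dd <- delta_delta_g(-10.38, -25.19, 0.13, 0.65)
  expect_equal(dd$estimate, 14.81, tolerance = 1e-9)
  expect_equal(round(dd$estimate, 1), 14.8)
  expect_equal(dd$std_error, sqrt(0.13^2 + 0.65^2), tolerance = 1e-12)
  expect_equal(dd$std_error, 0.6629, tolerance = 1e-4)
  expect_equal(delta_delta_g(-5, -5)$estimate, 0)
})

test_that("phi values recompute published table rows from printed inputs", {
  wt <- scenario_record("Im7")
  # frozen recomputations from the printed dG and k_IN values
  cases <- list(
    list("F15Y", 0.6210, 0.6529),
    list("V16T", 0.7855, 0.8063),
    list("V69T", 1.4550, 1.5265), # a phi > 1 case
    list("F41Y", 0.2126, 0.2774),
    list("V42T", -0.2268, 0.3062),
    list("L19F", 0.3065, 0.4314)
  )
  for (cs in cases) {
    rec <- scenario_record(cs[[1]])
    pI <- phi_i(rec, wt, cond10)
    pT <- phi_ts2(rec, wt, cond10)
    expect_equal(pI$estimate, cs[[2]], tolerance = 5e-4)
    expect_equal(pT$estimate, cs[[3]], tolerance = 5e-4)
    expect_true(pI$determinable)
  }
})

test_that("phi trivia: identical kinetics give zero phi", {
  wt <- scenario_record("Im7")
  # variant differing from the reference only in k_NI: ddG_UI = 0 so
  # phi_I = 0, and the TS2 numerator also vanishes (same k_IN)
  mut <- variant_record("NI-only", dG_UI = wt$dG_UI,
                        dG_UN = wt$dG_UN + 5, k_IN = wt$k_IN)
  expect_equal(phi_i(mut, wt)$estimate, 0)
  expect_equal(phi_ts2(mut, wt)$estimate, 0)
})

test_that("the ND rule suppresses phi for small ddG_UN unless forced", {
  wt <- scenario_record("Im7")
  v27 <- scenario_record("V27T") # ddG_UN = -0.27 kJ/mol
  expect_false(phi_i(v27, wt)$determinable)
  expect_true(is.na(phi_i(v27, wt)$estimate))
  forced <- phi_i(v27, wt, force = TRUE)
  expect_false(forced$determinable)
  expect_true(is.finite(forced$estimate))
})

test_that("delta-method phi errors agree with Monte-Carlo resampling", {
  wt <- scenario_record("Im7")
  f15y <- scenario_record("F15Y")
  pI <- phi_i(f15y, wt, cond10)
  pT <- phi_ts2(f15y, wt, cond10)
  mc <- withr::with_seed(77, {
    n <- 1e5
    draw <- function(r) list(
      dG_UI = stats::rnorm(n, r$dG_UI, r$dG_UI_sd),
      dG_UN = stats::rnorm(n, r$dG_UN, r$dG_UN_sd),
      lnk = stats::rnorm(n, log(r$k_IN), r$k_IN_sd / r$k_IN)
    )
    m <- draw(f15y); w <- draw(wt)
    ddUI <- m$dG_UI - w$dG_UI
    ddUN <- m$dG_UN - w$dG_UN
    list(sd_I = stats::sd(ddUI / ddUN),
         sd_T = stats::sd((ddUI - cond10$RT * (m$lnk - w$lnk)) / ddUN))
  })
  expect_equal(pI$std_error, mc$sd_I, tolerance = 0.1)
  expect_equal(pT$std_error, mc$sd_T, tolerance = 0.1)
})

test_that("ddG_U_TS2 differs from ddG_UI by exactly -RT ln(kIN ratio)", {
  wt <- scenario_record("Im7")
  for (nm in c("F15Y", "V42T", "L19F", "V69F")) {
    rec <- scenario_record(nm)
    sys <- foldphi:::ddg_system(rec, wt, cond10)
    expect_equal(sys$ddG[["U_TS2"]] - sys$ddG[["UI"]],
                 -cond10$RT * log(rec$k_IN / wt$k_IN), tolerance = 1e-12)
  }
})

test_that("phi values are independent of fluorescence signal coefficients", {
  bright <- tibble::tibble(state = c("U", "I", "N"),
                           intercept = c(9, 22, 3.5), slope = c(0.13, -0.2, 0.1))
  a <- thermo_summary(scenario_scheme("Im7"), cond10)
  b <- thermo_summary(scenario_scheme("Im7", signal_coeffs = bright), cond10)
  expect_identical(a, b)
})

test_that("phi classification bins match the published colouring", {
  expect_identical(classify_phi(c(0.62, 0.79, 0.40, 0.21, 1.45, -0.23, 0.90)),
                   c("mid", "high", "low", "low", "high", "low", "high"))
  expect_identical(classify_phi(0.7), "mid") # boundary to the lower bin
  expect_identical(classify_phi(NA_real_), NA_character_)
})

test_that("total m-value QC applies the 10% band strictly", {
  expect_identical(check_m_value(5.39, 5.4), "pass")
  expect_identical(check_m_value(4.6, 5.4), "flag") # curved-chevron variant
  expect_identical(check_m_value(5.94, 5.4), "flag") # boundary is excluded
  expect_identical(check_m_value(4.87, 5.4), "pass")
})

test_that("phi_report reproduces the printed phi columns across both tables", {
  tab <- scenario_table("three_state")
  records <- lapply(tab$variant, scenario_record)
  rep_tbl <- phi_report(records, reference_map = list(default = "Im7"),
                        cond = cond10, m_reference = 5.4)
  # wild type is its own reference: phi columns empty
  wt_row <- rep_tbl[rep_tbl$variant == "Im7", ]
  expect_true(wt_row$is_reference)
  expect_true(is.na(wt_row$phi_I))
  # solvent-exposed control: ND
  v27 <- rep_tbl[rep_tbl$variant == "V27T", ]
  expect_false(v27$determinable)
  expect_identical(v27$phi_I_class, "ND")
  # printed phi regression (variants whose printed dG/k_IN reproduce their
  # printed phi; excludes the pseudo-wild-type-referenced rows, the
  # specially constrained fit and two rows with documented rounding
  # discrepancies)
  check <- c("F15Y", "V16T", "F41Y", "V42T", "V69T", "L19F", "I22F",
             "I54F", "V69F")
  for (nm in check) {
    row <- rep_tbl[rep_tbl$variant == nm, ]
    printed <- tab[tab$variant == nm, ]
    expect_lt(abs(row$phi_I - printed$phi_I), 0.02)
    expect_lt(abs(row$phi_TS2 - printed$phi_TS2), 0.02)
  }
  # m-value QC column: wild-type-like rows pass
  expect_identical(rep_tbl$m_check[rep_tbl$variant == "Im7"], "pass")
})

test_that("phi_report errors on a dangling reference and formats ND cells", {
  recs <- list(scenario_record("F15Y"))
  expect_error(phi_report(recs, reference_map = list(default = "nope")),
               "nope")
  recs <- lapply(c("Im7", "F15Y", "V27T"), scenario_record)
  rep_tbl <- phi_report(recs, reference_map = list(default = "Im7"))
  txt <- format_phi_table(rep_tbl)
  expect_true(any(grepl("ND", txt)))
  expect_true(any(grepl("--", txt)))
})

test_that("pseudo-wild-type references are resolved per variant", {
  wt <- scenario_record("Im7")
  i54v <- variant_record("I54V", dG_UI = -11.5, dG_UN = -16.5, k_IN = 150)
  iv54t <- scenario_record("IV54T")
  rep_tbl <- phi_report(list(wt, i54v, iv54t),
                        reference_map = list(IV54T = "I54V",
                                             default = "Im7"))
  row <- rep_tbl[rep_tbl$variant == "IV54T", ]
  expect_identical(row$reference, "I54V")
  expect_equal(row$ddG_UN, iv54t$dG_UN - i54v$dG_UN, tolerance = 1e-12)
})
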