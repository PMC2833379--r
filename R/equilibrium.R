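#' Two-state equilibrium unfolding model (linear extrapolation method)
#'
#' Parameter container for the standard LEM signal model: the observed signal
#' at denaturant `D` is the population-weighted average of two linear
#' baselines,
#' `S_obs(D) = f_N(D) (a D + b)_N + (1 - f_N(D)) (c D + d)_D`, with
#' `f_N(D) = 1 / (1 + exp((dG_UN + M_UN D) / RT))`. Under the package's sign
#' convention `dG_UN` is negative for a stable protein, so `f_N -> 1` at low
#' denaturant and the midpoint sits at `D_50 = -dG_UN / M_UN`.
#'
#' @param dG_UN Stability free energy in water, kJ mol^-1 (negative = stable).
#' @param M_UN Equilibrium m-value, kJ mol^-1 M^-1 (> 0).
#' @param baseline_N,baseline_D Length-2 vectors `c(intercept, slope)` of the
#'   native and denatured signal baselines.
#' @return An object of class `equilibrium_model`.
#' @examples
#' em <- equilibrium_model(-9.14, 3.72)
#' equilibrium_signal(em, c(0, 2.46, 8)) # native, midpoint, denatured
#' @export
equilibrium_model <- function(dG_UN, M_UN, baseline_N = c(0.35, 0.01),
                              baseline_D = c(0.90, 0.013)) {
  stopifnot(length(baseline_N) == 2, length(baseline_D) == 2)
  if (!is.finite(M_UN) || M_UN <= 0) {
    stop("`M_UN` must be positive.", call. = FALSE)
  }
  structure(
    list(dG_UN = dG_UN, M_UN = M_UN,
         baseline_N = stats::setNames(as.numeric(baseline_N),
                                      c("intercept", "slope")),
         baseline_D = stats::setNames(as.numeric(baseline_D),
                                      c("intercept", "slope"))),
    class = "equilibrium_model"
  )
}

eq_model_of <- function(x) {
  if (inherits(x, "equilibrium_model")) return(x)
  if (inherits(x, "equilibrium_fit")) return(x$model)
  stop("Expected an equilibrium_model or equilibrium_fit.", call. = FALSE)
}

#' Fraction of native molecules predicted by the LEM model
#'
#' @param model An [equilibrium_model()] or `equilibrium_fit`.
#' @param D Denaturant concentration(s), M.
#' @param cond A [fold_conditions()].
#' @return Numeric vector of `f_N` values in (0, 1).
#' @export
fraction_native_model <- function(model, D, cond = fold_conditions()) {
  m <- eq_model_of(model)
  cond <- as_fold_conditions(cond)
  1 / (1 + exp((m$dG_UN + m$M_UN * D) / cond$RT))
}

#' Observed equilibrium signal of the LEM model
#'
#' @inheritParams fraction_native_model
#' @return Numeric vector of model signals.
#' @export
equilibrium_signal <- function(model, D, cond = fold_conditions()) {
  m <- eq_model_of(model)
  fN <- fraction_native_model(m, D, cond)
  bN <- m$baseline_N[["intercept"]] + m$baseline_N[["slope"]] * D
  bD <- m$baseline_D[["intercept"]] + m$baseline_D[["slope"]] * D
  fN * bN + (1 - fN) * bD
}

#' Convert observed signals to fraction native via the fitted baselines
#'
#' The baseline-stripping transformation
#' `f_N = (S_obs - B_D(D)) / (B_N(D) - B_D(D))`: the analytical inverse of
#' the LEM signal model. Noisy data may fall slightly outside `[0, 1]`;
#' values are deliberately not clipped.
#'
#' @param S_obs Observed signal(s).
#' @param model An [equilibrium_model()] or `equilibrium_fit`.
#' @param D Denaturant concentration(s), M, matched to `S_obs`.
#' @return Numeric vector of fraction-native values.
#' @export
fraction_native <- function(S_obs, model, D) {
  m <- eq_model_of(model)
  bN <- m$baseline_N[["intercept"]] + m$baseline_N[["slope"]] * D
  bD <- m$baseline_D[["intercept"]] + m$baseline_D[["slope"]] * D
  if (any(bN == bD)) {
    stop("Native and denatured baselines coincide at some D; ",
         "fraction native is undefined.", call. = FALSE)
  }
  (S_obs - bD) / (bN - bD)
}

#' Fit an equilibrium denaturation curve to the two-state LEM model
#'
#' Least-squares fit of the six-parameter sigmoid-with-linear-baselines model
#' to a denaturation curve (fluorescence or far-UV CD; both probes share this
#' code path). Parameters: `dG_UN`, `M_UN` and the two baseline intercept/
#' slope pairs. Standard errors come from the Gauss-Newton covariance at the
#' optimum. The fit is flagged unidentifiable when the fitted transition
#' midpoint `-dG_UN/M_UN` falls outside the measured denaturant range (the
#' transition is then not bracketed by data).
#'
#' @param curve Data frame with columns `urea_M` and `signal` (>= 10 points).
#' @param cond A [fold_conditions()].
#' @param n_starts Number of optimiser starts (midpoint grid).
#' @return An object of class `equilibrium_fit`: the fitted
#'   [equilibrium_model()], a `params` tibble with 1-sigma errors, the
#'   covariance, `midpoint_M`, `residual_rms`, `identifiable` flag and
#'   convergence metadata. Supports [tidy()], [glance()],
#'   [ggplot2::autoplot()].
#' @examples
#' em <- equilibrium_model(-9.14, 3.72)
#' cv <- generate_equilibrium_curve(em, noise = noise_model(seed = 1))
#' fit_equilibrium_curve(cv)$params
#' @export
fit_equilibrium_curve <- function(curve, cond = fold_conditions(),
                                  n_starts = 5) {
  stopifnot(is.data.frame(curve),
            all(c("urea_M", "signal") %in% names(curve)))
  if (nrow(curve) < 10) {
    stop("Need >= 10 points spanning both baselines and the transition.",
         call. = FALSE)
  }
  cond <- as_fold_conditions(cond)
  D <- curve$urea_M
  y <- curve$signal
  RT <- cond$RT

  p_names <- c("dG_UN", "M_UN", "bN_int", "bN_slope", "bD_int", "bD_slope")
  model_of <- function(th) {
    equilibrium_model(th[["dG_UN"]], max(th[["M_UN"]], 1e-8),
                      baseline_N = c(th[["bN_int"]], th[["bN_slope"]]),
                      baseline_D = c(th[["bD_int"]], th[["bD_slope"]]))
  }
  resid_fn <- function(th) equilibrium_signal(model_of(th), D, cond) - y

  # starts: baselines from the curve ends, midpoint over a grid
  n_lo <- max(3, round(length(D) * 0.2))
  lo <- order(D)[seq_len(n_lo)]
  hi <- order(D, decreasing = TRUE)[seq_len(n_lo)]
  f_lo <- stats::lm(y[lo] ~ D[lo])
  f_hi <- stats::lm(y[hi] ~ D[hi])
  mids <- stats::quantile(D, seq(0.25, 0.75, length.out = n_starts))
  starts <- lapply(mids, function(d50) {
    c(dG_UN = -4 * d50, M_UN = 4,
      bN_int = unname(stats::coef(f_lo)[1]),
      bN_slope = unname(stats::coef(f_lo)[2]),
      bD_int = unname(stats::coef(f_hi)[1]),
      bD_slope = unname(stats::coef(f_hi)[2]))
  })
  lower <- c(-Inf, 1e-6, rep(-Inf, 4)); upper <- rep(Inf, 6)
  names(lower) <- names(upper) <- p_names
  best <- multistart_lm(resid_fn, starts, lower, upper)
  if (!best$success) {
    warning("Equilibrium fit did not converge.", call. = FALSE)
  }
  th <- best$par
  J <- numeric_jacobian(resid_fn, th)
  cv <- gn_covariance(J, resid_fn(th))
  sd_th <- if (cv$identifiable) sqrt(pmax(diag(cv$cov), 0)) else
    rep(NA_real_, 6)

  midpoint <- -th[["dG_UN"]] / th[["M_UN"]]
  identifiable <- cv$identifiable &&
    midpoint > min(D) && midpoint < max(D)

  structure(
    list(
      model = model_of(th),
      params = tibble::tibble(term = p_names, estimate = unname(th[p_names]),
                              std_error = unname(sd_th)),
      covariance = cv$cov,
      midpoint_M = midpoint,
      residual_rms = sqrt(mean(resid_fn(th)^2)),
      identifiable = identifiable,
      data = tibble::as_tibble(curve),
      cond = cond,
      convergence = list(success = best$success,
                         iterations = best$iterations,
                         start_used = best$start_used,
                         n_starts = best$n_starts)
    ),
    class = "equilibrium_fit"
  )
}

#' @export
print.equilibrium_fit <- function(x, ...) {
  est <- stats::setNames(x$params$estimate, x$params$term)
  se <- stats::setNames(x$params$std_error, x$params$term)
  cat(sprintf("<equilibrium_fit> dG_UN = %.2f +/- %.2f kJ/mol, M_UN = %.2f +/- %.2f kJ/mol/M\n",
              est["dG_UN"], se["dG_UN"], est["M_UN"], se["M_UN"]))
  cat(sprintf("  midpoint %.2f M, RMS %.3g%s\n", x$midpoint_M, x$residual_rms,
              if (x$identifiable) "" else "  [UNIDENTIFIABLE]"))
  invisible(x)
}
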