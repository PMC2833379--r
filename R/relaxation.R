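#' Relaxation rates of the on-pathway three-state scheme
#'
#' The rate matrix of U <-> I <-> N has eigenvalues 0, -lambda_slow and
#' -lambda_fast. With `s = k_UI + k_IU + k_IN + k_NI` and
#' `p = k_UI*k_IN + k_UI*k_NI + k_IU*k_NI`, the two non-zero relaxation
#' rates are `(s +/- sqrt(s^2 - 4p)) / 2`. The slow root is evaluated as
#' `2p / (s + sqrt(s^2 - 4p))`, which is algebraically identical but immune
#' to cancellation when the two phases are separated by many orders of
#' magnitude. The slow phase is the observable of a stopped-flow chevron when
#' the U <-> I equilibration is burst-phase complete.
#'
#' `method = "pre_equilibrium"` instead returns the classical approximation
#' `lambda_slow = k_IN * K_UI/(1 + K_UI) + k_NI` (with `K_UI = k_UI/k_IU`
#' evaluated at `D`), valid when U <-> I exchange is much faster than the
#' I <-> N step; `lambda_fast` is then `k_UI + k_IU`.
#'
#' @param scheme A three-state [kinetic_scheme()].
#' @param D Denaturant concentration(s), M.
#' @param cond A [fold_conditions()].
#' @param method `"exact"` (analytical eigenvalues, default) or
#'   `"pre_equilibrium"`.
#' @return A tibble with columns `denaturant_M`, `lambda_fast`, `lambda_slow`
#'   (s^-1), one row per element of `D`.
#' @examples
#' sc <- three_state_scheme(1574, 1.23, 7.084, 2.96, 253.9, 0.75, 1.26, 0.45)
#' relaxation_rates(sc, c(0, 2, 4, 6))
#' @export
relaxation_rates <- function(scheme, D, cond = fold_conditions(),
                             method = c("exact", "pre_equilibrium")) {
  method <- match.arg(method)
  stopifnot(inherits(scheme, "kinetic_scheme"))
  if (scheme$n_states != 3L) {
    stop("`relaxation_rates()` needs a three-state scheme; use ",
         "`two_state_kobs()` for two-state schemes.", call. = FALSE)
  }
  cond <- as_fold_conditions(cond)
  k_UI <- rate_at_denaturant(scheme$rate_laws$UI, D, cond)
  k_IU <- rate_at_denaturant(scheme$rate_laws$IU, D, cond)
  k_IN <- rate_at_denaturant(scheme$rate_laws$IN, D, cond)
  k_NI <- rate_at_denaturant(scheme$rate_laws$NI, D, cond)
  if (method == "pre_equilibrium") {
    K <- k_UI / k_IU
    return(tibble::tibble(
      denaturant_M = D,
      lambda_fast = k_UI + k_IU,
      lambda_slow = k_IN * K / (1 + K) + k_NI
    ))
  }
  s <- k_UI + k_IU + k_IN + k_NI
  p <- k_UI * k_IN + k_UI * k_NI + k_IU * k_NI
  disc <- s^2 - 4 * p
  if (any(disc < 0)) {
    # impossible for positive rates; guards accumulated rounding only
    warning("Discriminant slightly negative; clamped to zero.", call. = FALSE)
    disc <- pmax(disc, 0)
  }
  root <- sqrt(disc)
  tibble::tibble(
    denaturant_M = D,
    lambda_fast = (s + root) / 2,
    lambda_slow = 2 * p / (s + root)
  )
}

#' Observed rate constant of a two-state scheme
#'
#' The single relaxation rate of U <-> N: `k_obs(D) = k_UN(D) + k_NU(D)`.
#' In `ln k_obs` versus denaturant this is the classical V-shaped chevron.
#'
#' @param scheme A two-state [kinetic_scheme()].
#' @param D Denaturant concentration(s), M.
#' @param cond A [fold_conditions()].
#' @return Numeric vector of observed rate constants (s^-1).
#' @export
two_state_kobs <- function(scheme, D, cond = fold_conditions()) {
  stopifnot(inherits(scheme, "kinetic_scheme"))
  if (scheme$n_states != 2L) {
    stop("`two_state_kobs()` needs a two-state scheme.", call. = FALSE)
  }
  cond <- as_fold_conditions(cond)
  rate_at_denaturant(scheme$rate_laws$UN, D, cond) +
    rate_at_denaturant(scheme$rate_laws$NU, D, cond)
}

#' The observable slow relaxation rate of either scheme
#'
#' Dispatches to [relaxation_rates()] (slow eigenvalue) for three-state
#' schemes and to [two_state_kobs()] for two-state schemes; this is the rate
#' a stopped-flow instrument reports after the burst phase.
#'
#' @inheritParams relaxation_rates
#' @return Numeric vector of observed rate constants (s^-1).
#' @export
observed_rate <- function(scheme, D, cond = fold_conditions()) {
  if (scheme$n_states == 3L) {
    relaxation_rates(scheme, D, cond)$lambda_slow
  } else {
    two_state_kobs(scheme, D, cond)
  }
}

#' Equilibrium state populations at given denaturant
#'
#' Populations follow from detailed balance along the pathway:
#' `pU : pI : pN = 1 : K_UI(D) : K_UI(D) * k_IN(D)/k_NI(D)` for a three-state
#' scheme and `pU : pN = 1 : k_UN(D)/k_NU(D)` for a two-state scheme (where
#' `p_I` is reported as 0).
#'
#' @inheritParams relaxation_rates
#' @return A tibble with columns `denaturant_M`, `p_U`, `p_I`, `p_N`; rows
#'   sum to 1.
#' @export
equilibrium_populations <- function(scheme, D, cond = fold_conditions()) {
  stopifnot(inherits(scheme, "kinetic_scheme"))
  cond <- as_fold_conditions(cond)
  if (scheme$n_states == 3L) {
    K_UI <- rate_at_denaturant(scheme$rate_laws$UI, D, cond) /
      rate_at_denaturant(scheme$rate_laws$IU, D, cond)
    K_IN <- rate_at_denaturant(scheme$rate_laws$IN, D, cond) /
      rate_at_denaturant(scheme$rate_laws$NI, D, cond)
    wU <- rep(1, length(D)); wI <- K_UI; wN <- K_UI * K_IN
  } else {
    K_UN <- rate_at_denaturant(scheme$rate_laws$UN, D, cond) /
      rate_at_denaturant(scheme$rate_laws$NU, D, cond)
    wU <- rep(1, length(D)); wI <- rep(0, length(D)); wN <- K_UN
  }
  z <- wU + wI + wN
  tibble::tibble(denaturant_M = D, p_U = wU / z, p_I = wI / z, p_N = wN / z)
}

# 3x3 (or 2x2) generator matrix A with dp/dt = A p, states in scheme$states
# order, at scalar denaturant D. Used by the trace generator and by tests as
# the numerical-eigendecomposition cross-check.
rate_matrix <- function(scheme, D, cond = fold_conditions()) {
  cond <- as_fold_conditions(cond)
  stopifnot(length(D) == 1L)
  r <- lapply(scheme$rate_laws, rate_at_denaturant, D = D, cond = cond)
  if (scheme$n_states == 3L) {
    A <- matrix(0, 3, 3, dimnames = list(scheme$states, scheme$states))
    A["U", "U"] <- -r$UI;          A["U", "I"] <- r$IU
    A["I", "U"] <- r$UI;           A["I", "I"] <- -(r$IU + r$IN)
    A["I", "N"] <- r$NI
    A["N", "I"] <- r$IN;           A["N", "N"] <- -r$NI
  } else {
    A <- matrix(0, 2, 2, dimnames = list(scheme$states, scheme$states))
    A["U", "U"] <- -r$UN; A["U", "N"] <- r$NU
    A["N", "U"] <- r$UN;  A["N", "N"] <- -r$NU
  }
  A
}
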