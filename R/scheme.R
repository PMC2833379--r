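#' Denaturant dependence of a single microscopic rate constant
#'
#' A kinetic linear free-energy relationship: a rate constant `rate0` at zero
#' denaturant together with a kinetic m-value giving its exponential
#' denaturant dependence. Folding rates decrease with denaturant,
#' unfolding rates increase; the m-value is stored as a non-negative
#' magnitude and the sign is carried by `direction`, which prevents silent
#' sign errors when schemes are assembled from fitted parameters.
#'
#' @param rate0 Rate constant at 0 M denaturant (s^-1), > 0.
#' @param m_kin Kinetic m-value magnitude (kJ mol^-1 M^-1), >= 0.
#' @param direction `"folding"` (rate decays with denaturant) or
#'   `"unfolding"` (rate grows).
#' @return An object of class `rate_law`.
#' @examples
#' rl <- rate_law(253.9, 0.75, "folding")
#' rate_at_denaturant(rl, c(0, 2, 4), fold_conditions())
#' @export
rate_law <- function(rate0, m_kin, direction = c("folding", "unfolding")) {
  direction <- match.arg(direction)
  stopifnot(is.numeric(rate0), length(rate0) == 1L,
            is.numeric(m_kin), length(m_kin) == 1L)
  if (!is.finite(rate0) || rate0 <= 0) {
    stop("`rate0` must be a positive rate constant (s^-1).", call. = FALSE)
  }
  if (!is.finite(m_kin) || m_kin < 0) {
    stop("`m_kin` must be a non-negative m-value magnitude.", call. = FALSE)
  }
  structure(list(rate0 = rate0, m_kin = m_kin, direction = direction),
            class = "rate_law")
}

#' Evaluate a rate law at given denaturant concentrations
#'
#' Computes `rate0 * exp(-m_kin * D / RT)` for folding transitions and
#' `rate0 * exp(+m_kin * D / RT)` for unfolding transitions.
#'
#' @param law A [rate_law()].
#' @param D Denaturant concentration(s), M; must be >= 0.
#' @param cond A [fold_conditions()].
#' @return Numeric vector of rate constants (s^-1), strictly positive.
#' @export
rate_at_denaturant <- function(law, D, cond = fold_conditions()) {
  stopifnot(inherits(law, "rate_law"), is.numeric(D))
  cond <- as_fold_conditions(cond)
  if (any(!is.finite(D)) || any(D < 0)) {
    stop("Denaturant concentrations must be finite and non-negative.",
         call. = FALSE)
  }
  sgn <- if (law$direction == "folding") -1 else 1
  law$rate0 * exp(sgn * law$m_kin * D / cond$RT)
}

default_signal_coeffs <- function(n_states) {
  # Synthetic fluorescence baselines (normalised units; the 7.75 M denatured
  # sample defines 1). I is modelled as more fluorescent than U and N, N as
  # quenched, matching the qualitative burst-phase behaviour of a Trp probe
  # that is quenched in the native state.
  all3 <- tibble::tibble(
    state = c("U", "I", "N"),
    intercept = c(0.90, 2.20, 0.35),
    slope = c(0.013, -0.020, 0.010)
  )
  if (n_states == 2L) all3[all3$state != "I", ] else all3
}

validate_signal_coeffs <- function(signal_coeffs, states) {
  sc <- tibble::as_tibble(signal_coeffs)
  need <- c("state", "intercept", "slope")
  if (!all(need %in% names(sc))) {
    stop("`signal_coeffs` needs columns state, intercept, slope.", call. = FALSE)
  }
  if (!setequal(sc$state, states) || anyDuplicated(sc$state)) {
    stop(sprintf("`signal_coeffs` must have exactly one row per state (%s).",
                 paste(states, collapse = ", ")), call. = FALSE)
  }
  sc[match(states, sc$state), need]
}

#' Kinetic scheme for two-state or on-pathway three-state folding
#'
#' A three-state scheme U <-> I <-> N holds rate laws for the four
#' transitions UI, IU (fast exchange with the intermediate) and IN, NI
#' (formation and unfolding of the native state across the rate-limiting
#' transition state). A two-state scheme U <-> N holds UN and NU. Each state
#' additionally carries a linear fluorescence baseline (intercept + slope in
#' denaturant) used by the amplitude model.
#'
#' @param rate_laws Named list of [rate_law()] objects. Names must be exactly
#'   `UI, IU, IN, NI` (three-state) or `UN, NU` (two-state); first-letter
#'   ordering fixes the required direction (`UI`, `IN`, `UN` folding; `IU`,
#'   `NI`, `NU` unfolding).
#' @param signal_coeffs Data frame with columns `state`, `intercept`, `slope`,
#'   one row per state. Defaults to a synthetic set in which I is the most
#'   fluorescent species and N is quenched.
#' @return An object of class `kinetic_scheme` with fields `n_states`,
#'   `rate_laws`, `signal_coeffs`, `states`.
#' @seealso [three_state_scheme()], [two_state_scheme()] for direct
#'   construction from rate constants.
#' @export
kinetic_scheme <- function(rate_laws, signal_coeffs = NULL) {
  nms <- names(rate_laws)
  three <- c("UI", "IU", "IN", "NI")
  two <- c("UN", "NU")
  if (setequal(nms, three)) {
    n_states <- 3L; states <- c("U", "I", "N"); want <- three
  } else if (setequal(nms, two)) {
    n_states <- 2L; states <- c("U", "N"); want <- two
  } else {
    stop("`rate_laws` must be named exactly UI, IU, IN, NI (three-state) ",
         "or UN, NU (two-state).", call. = FALSE)
  }
  rate_laws <- rate_laws[want]
  folding <- c("UI", "IN", "UN")
  for (nm in want) {
    law <- rate_laws[[nm]]
    if (!inherits(law, "rate_law")) {
      stop(sprintf("rate_laws$%s is not a rate_law object.", nm), call. = FALSE)
    }
    expected <- if (nm %in% folding) "folding" else "unfolding"
    if (law$direction != expected) {
      stop(sprintf("Transition %s must have direction '%s'.", nm, expected),
           call. = FALSE)
    }
  }
  if (is.null(signal_coeffs)) signal_coeffs <- default_signal_coeffs(n_states)
  signal_coeffs <- validate_signal_coeffs(signal_coeffs, states)
  structure(
    list(n_states = n_states, states = states, rate_laws = rate_laws,
         signal_coeffs = signal_coeffs),
    class = "kinetic_scheme"
  )
}

#' @rdname kinetic_scheme
#' @param k_UI,m_UI,k_IU,m_IU,k_IN,m_IN,k_NI,m_NI Zero-denaturant rate
#'   constants (s^-1) and kinetic m-value magnitudes (kJ mol^-1 M^-1) of the
#'   four three-state transitions.
#' @export
three_state_scheme <- function(k_UI, m_UI, k_IU, m_IU, k_IN, m_IN, k_NI, m_NI,
                               signal_coeffs = NULL) {
  kinetic_scheme(
    list(
      UI = rate_law(k_UI, m_UI, "folding"),
      IU = rate_law(k_IU, m_IU, "unfolding"),
      IN = rate_law(k_IN, m_IN, "folding"),
      NI = rate_law(k_NI, m_NI, "unfolding")
    ),
    signal_coeffs = signal_coeffs
  )
}

#' @rdname kinetic_scheme
#' @param k_UN,m_UN,k_NU,m_NU Zero-denaturant rate constants and m-value
#'   magnitudes of the two-state transitions.
#' @export
two_state_scheme <- function(k_UN, m_UN, k_NU, m_NU, signal_coeffs = NULL) {
  kinetic_scheme(
    list(
      UN = rate_law(k_UN, m_UN, "folding"),
      NU = rate_law(k_NU, m_NU, "unfolding")
    ),
    signal_coeffs = signal_coeffs
  )
}

#' @export
print.kinetic_scheme <- function(x, ...) {
  cat(sprintf("<kinetic_scheme> %d-state (%s)\n", x$n_states,
              paste(x$states, collapse = " <-> ")))
  for (nm in names(x$rate_laws)) {
    law <- x$rate_laws[[nm]]
    cat(sprintf("  k_%s = %.4g s^-1, m_%s = %.3g kJ/mol/M (%s)\n",
                nm, law$rate0, nm, law$m_kin, law$direction))
  }
  invisible(x)
}

# Rates of every transition at denaturant D (scalar D), as a named vector.
scheme_rates <- function(scheme, D, cond) {
  vapply(scheme$rate_laws, rate_at_denaturant, numeric(length(D)),
         D = D, cond = cond)
}
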