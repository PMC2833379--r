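#' Initial and final fluorescence signals of a kinetic experiment
#'
#' Models the amplitude observables of a stopped-flow chevron experiment.
#' The final (endpoint) signal at denaturant `D` is the population-weighted
#' average of the state baselines at equilibrium. The initial signal of a
#' refolding experiment is the signal after the burst phase, i.e. of the
#' U <-> I pre-equilibrium established within the instrument dead time
#' (populations proportional to 1 and `K_UI(D)`, with N excluded); for a
#' two-state scheme there is no burst phase and the initial refolding signal
#' is the unfolded baseline. The initial signal of an unfolding experiment is
#' the native baseline.
#'
#' @param scheme A [kinetic_scheme()].
#' @param D Denaturant concentration(s), M.
#' @param direction `"refolding"` or `"unfolding"` — the mixing direction.
#' @param cond A [fold_conditions()].
#' @return A tibble with columns `denaturant_M`, `initial_signal`,
#'   `final_signal` (normalised fluorescence units).
#' @export
amplitude_model <- function(scheme, D, direction = c("refolding", "unfolding"),
                            cond = fold_conditions()) {
  direction <- match.arg(direction)
  stopifnot(inherits(scheme, "kinetic_scheme"))
  cond <- as_fold_conditions(cond)
  sc <- scheme$signal_coeffs
  baseline <- function(state, D) {
    i <- match(state, sc$state)
    sc$intercept[i] + sc$slope[i] * D
  }
  pops <- equilibrium_populations(scheme, D, cond)
  final_signal <- pops$p_U * baseline("U", D) + pops$p_N * baseline("N", D)
  if (scheme$n_states == 3L) {
    final_signal <- final_signal + pops$p_I * baseline("I", D)
  }
  if (direction == "refolding") {
    if (scheme$n_states == 3L) {
      K_UI <- rate_at_denaturant(scheme$rate_laws$UI, D, cond) /
        rate_at_denaturant(scheme$rate_laws$IU, D, cond)
      wI <- K_UI / (1 + K_UI)
      initial_signal <- (1 - wI) * baseline("U", D) + wI * baseline("I", D)
    } else {
      initial_signal <- baseline("U", D)
    }
  } else {
    initial_signal <- baseline("N", D)
  }
  tibble::tibble(denaturant_M = D, initial_signal = initial_signal,
                 final_signal = final_signal)
}

#' Normalise raw fluorescence signals to a denatured-state reference
#'
#' Blank-subtracts and rescales raw signals so the denatured reference sample
#' (by convention the 7.75 M urea sample) maps to 1:
#' `(raw - blank) / (reference - blank)`.
#'
#' @param raw Raw signal value(s).
#' @param blank Buffer blank signal.
#' @param reference Raw signal of the denatured reference sample.
#' @return Normalised signal(s); `reference` maps to 1 and `blank` to 0.
#' @export
normalize_signals <- function(raw, blank, reference) {
  stopifnot(is.numeric(raw), is.numeric(blank), is.numeric(reference))
  denom <- reference - blank
  if (any(denom == 0)) {
    stop("Reference signal equals the blank; cannot normalise.", call. = FALSE)
  }
  (raw - blank) / denom
}
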