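#' Thermodynamic summary of a kinetic scheme
#'
#' Converts microscopic rate constants and kinetic m-values into stability
#' free energies, equilibrium m-values and Tanford beta values. Sign
#' convention: a negative free energy means the species to the right of the
#' arrow (the more folded one) is more stable, so a stable native protein has
#' `dG_UN` around -25 kJ mol^-1.
#'
#' For a three-state scheme:
#' \itemize{
#'   \item `dG_UI = -RT ln(k_UI/k_IU)`, `dG_IN = -RT ln(k_IN/k_NI)`,
#'     `dG_UN = dG_UI + dG_IN`
#'   \item `M_UI = m_UI + m_IU`, `M_UN = M_UI + m_IN + m_NI`
#'   \item `beta_I = M_UI / M_UN`,
#'     `beta_TS2 = (M_UI + m_IN) / M_UN` — the fractional solvent burial of
#'     the intermediate and of the rate-limiting transition state relative to
#'     the native state (`beta_T = m_Ux / (m_Ux + m_xN)` with x = I or TS2).
#' }
#' For a two-state scheme `dG_UN = -RT ln(k_UN/k_NU)`,
#' `M_UN = m_UN + m_NU`, `beta_TS2 = m_UN / M_UN`, and the
#' intermediate-specific columns are `NA`.
#'
#' @param scheme A [kinetic_scheme()].
#' @param cond A [fold_conditions()].
#' @return A one-row tibble with columns `n_states`, `K_UI`, `dG_UI`,
#'   `dG_IN`, `dG_UN` (kJ mol^-1), `M_UI`, `M_UN` (kJ mol^-1 M^-1),
#'   `beta_I`, `beta_TS2`.
#' @examples
#' sc <- three_state_scheme(1574, 1.23, 1574 / 222.2, 4.19 - 1.23,
#'                          253.9, 0.75, 1.26, 0.45)
#' thermo_summary(sc) # wild-type-like: dG_UN ~ -25.2 kJ/mol, beta_TS2 ~ 0.92
#' @export
thermo_summary <- function(scheme, cond = fold_conditions()) {
  stopifnot(inherits(scheme, "kinetic_scheme"))
  cond <- as_fold_conditions(cond)
  RT <- cond$RT
  rl <- scheme$rate_laws
  if (scheme$n_states == 3L) {
    K_UI <- rl$UI$rate0 / rl$IU$rate0
    dG_UI <- -RT * log(K_UI)
    dG_IN <- -RT * log(rl$IN$rate0 / rl$NI$rate0)
    M_UI <- rl$UI$m_kin + rl$IU$m_kin
    M_UN <- M_UI + rl$IN$m_kin + rl$NI$m_kin
    tibble::tibble(
      n_states = 3L, K_UI = K_UI,
      dG_UI = dG_UI, dG_IN = dG_IN, dG_UN = dG_UI + dG_IN,
      M_UI = M_UI, M_UN = M_UN,
      beta_I = M_UI / M_UN, beta_TS2 = (M_UI + rl$IN$m_kin) / M_UN
    )
  } else {
    M_UN <- rl$UN$m_kin + rl$NU$m_kin
    tibble::tibble(
      n_states = 2L, K_UI = NA_real_,
      dG_UI = NA_real_, dG_IN = NA_real_,
      dG_UN = -RT * log(rl$UN$rate0 / rl$NU$rate0),
      M_UI = NA_real_, M_UN = M_UN,
      beta_I = NA_real_, beta_TS2 = rl$UN$m_kin / M_UN
    )
  }
}
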