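# Scenario library: published per-variant parameter sets shipped with the
# package, used to parameterise the synthetic-data generators and as the
# printed-value inputs of the phi-value recomputations.

scenario_env <- new.env(parent = emptyenv())

#' The packaged scenario library
#'
#' Published best-fit kinetic and thermodynamic parameters (with 1-sigma
#' errors) for wild-type Im7 and its solvation (Val->Thr, Phe->Tyr) and
#' overpacked (->Phe/Ile) variants at pH 7.0, 10 degrees C, 0.4 M Na2SO4:
#' three-state chevron parameters, the IV7T two-state parameters, and
#' equilibrium-denaturation parameters for the variants characterised only
#' at equilibrium. Fluorescence baseline coefficients attached by
#' [scenario_scheme()] are synthetic defaults, not published quantities.
#'
#' @return Nested list mirroring `inst/extdata/scenarios.json`.
#' @export
scenario_library <- function() {
  if (is.null(scenario_env$lib)) {
    path <- system.file("extdata", "scenarios.json", package = "foldphi",
                        mustWork = TRUE)
    scenario_env$lib <- jsonlite::read_json(path, simplifyVector = FALSE)
  }
  scenario_env$lib
}

sc_val <- function(x) if (is.null(x)) NA_real_ else as.numeric(x[[1]])
sc_sd <- function(x) {
  if (is.null(x) || length(x) < 2 || is.null(x[[2]])) NA_real_
  else as.numeric(x[[2]])
}

#' Tidy view of the scenario library
#'
#' @param type `"three_state"`, `"two_state"` or `"equilibrium"`.
#' @return A tibble with one row per scenario; `<q>` and `<q>_sd` columns
#'   per published quantity.
#' @export
scenario_table <- function(type = c("three_state", "two_state",
                                    "equilibrium")) {
  type <- match.arg(type)
  lib <- scenario_library()[[type]]
  quantities <- switch(type,
    three_state = c("K_UI", "M_UI", "k_IN", "m_IN", "k_NI", "m_NI",
                    "dG_UI", "dG_UN", "phi_I", "phi_TS2", "beta_I",
                    "beta_TS2"),
    two_state = c("k_UN", "m_UN", "k_NU", "m_NU", "dG_UI", "dG_UN",
                  "phi_I", "phi_TS2", "beta_TS2"),
    equilibrium = c("dG_UN", "M_UN")
  )
  rows <- purrr::imap(lib, function(sc, nm) {
    out <- tibble::tibble(variant = nm,
                          position = sc$position %||% NA_character_)
    if (!is.null(sc$set)) out$set <- sc$set
    if (!is.null(sc$probe)) out$probe <- sc$probe
    for (q in quantities) {
      x <- sc[[q]]
      if (identical(x, "ND")) {
        out[[q]] <- NA_real_; out[[paste0(q, "_sd")]] <- NA_real_
        out[[paste0(q, "_nd")]] <- TRUE
      } else {
        out[[q]] <- sc_val(x); out[[paste0(q, "_sd")]] <- sc_sd(x)
        if (q %in% c("phi_I", "phi_TS2")) out[[paste0(q, "_nd")]] <- FALSE
      }
    }
    out
  })
  dplyr::bind_rows(rows)
}

#' Kinetic scheme of a named scenario
#'
#' Converts a scenario's published parameters into a [kinetic_scheme()].
#' For three-state scenarios the fast phase is completed with the fixed
#' wild-type values (`k_UI = 1574`, `m_UI = 1.23`), so
#' `k_IU = k_UI / K_UI` and `m_IU = M_UI - m_UI`.
#'
#' @param name Scenario name, e.g. `"Im7"`, `"F15Y"`, `"IV7T"`.
#' @param signal_coeffs Optional signal baselines (defaults to the package's
#'   synthetic set).
#' @return A [kinetic_scheme()].
#' @examples
#' thermo_summary(scenario_scheme("Im7"))
#' @export
scenario_scheme <- function(name, signal_coeffs = NULL) {
  lib <- scenario_library()
  if (name %in% names(lib$three_state)) {
    sc <- lib$three_state[[name]]
    k_UI <- as.numeric(lib$fixed_fast_phase$k_UI)
    m_UI <- as.numeric(lib$fixed_fast_phase$m_UI)
    three_state_scheme(
      k_UI = k_UI, m_UI = m_UI,
      k_IU = k_UI / sc_val(sc$K_UI), m_IU = sc_val(sc$M_UI) - m_UI,
      k_IN = sc_val(sc$k_IN), m_IN = sc_val(sc$m_IN),
      k_NI = sc_val(sc$k_NI), m_NI = sc_val(sc$m_NI),
      signal_coeffs = signal_coeffs
    )
  } else if (name %in% names(lib$two_state)) {
    sc <- lib$two_state[[name]]
    two_state_scheme(sc_val(sc$k_UN), sc_val(sc$m_UN), sc_val(sc$k_NU),
                     sc_val(sc$m_NU), signal_coeffs = signal_coeffs)
  } else {
    stop(sprintf("Unknown kinetic scenario '%s'.", name), call. = FALSE)
  }
}

#' Variant record of a named scenario (published table values)
#'
#' Builds a [variant_record()] from a scenario's published `dG_UI`,
#' `dG_UN` and `k_IN` values and errors — the inputs of a phi-value
#' recomputation from the printed tables.
#'
#' @param name Scenario name.
#' @return A [variant_record()].
#' @examples
#' phi_i(scenario_record("F15Y"), scenario_record("Im7"))
#' @export
scenario_record <- function(name) {
  lib <- scenario_library()
  if (name %in% names(lib$three_state)) {
    sc <- lib$three_state[[name]]
    m_UN <- sc_val(sc$M_UI) + sc_val(sc$m_IN) + sc_val(sc$m_NI)
    variant_record(name, dG_UI = sc_val(sc$dG_UI), dG_UN = sc_val(sc$dG_UN),
                   k_IN = sc_val(sc$k_IN), dG_UI_sd = sc_sd(sc$dG_UI),
                   dG_UN_sd = sc_sd(sc$dG_UN), k_IN_sd = sc_sd(sc$k_IN),
                   M_UN = m_UN, n_states = 3L,
                   position = sc$position %||% NA_character_)
  } else if (name %in% names(lib$two_state)) {
    sc <- lib$two_state[[name]]
    variant_record(name, dG_UN = sc_val(sc$dG_UN),
                   dG_UN_sd = sc_sd(sc$dG_UN),
                   M_UN = sc_val(sc$m_UN) + sc_val(sc$m_NU), n_states = 2L,
                   position = sc$position %||% NA_character_)
  } else {
    stop(sprintf("Unknown kinetic scenario '%s'.", name), call. = FALSE)
  }
}

#' Equilibrium model of a named scenario
#'
#' @param name Scenario name from the equilibrium set (e.g. `"IV22T"`).
#' @param baseline_N,baseline_D Baselines passed to [equilibrium_model()]
#'   (synthetic defaults).
#' @return An [equilibrium_model()].
#' @export
scenario_equilibrium_model <- function(name, baseline_N = c(0.35, 0.01),
                                       baseline_D = c(0.90, 0.013)) {
  lib <- scenario_library()
  sc <- lib$equilibrium[[name]]
  if (is.null(sc)) {
    stop(sprintf("Unknown equilibrium scenario '%s'.", name), call. = FALSE)
  }
  equilibrium_model(sc_val(sc$dG_UN), sc_val(sc$M_UN),
                    baseline_N = baseline_N, baseline_D = baseline_D)
}
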