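#' A per-variant thermodynamic record for phi-value analysis
#'
#' Collects the quantities a variant contributes to a phi-value comparison:
#' the stability of the intermediate (`dG_UI`) and native state (`dG_UN`),
#' the zero-denaturant folding rate over the rate-limiting barrier (`k_IN`),
#' the total m-value (`M_UN`, for the quality check), their 1-sigma errors,
#' and optionally the covariance among `(dG_UI, dG_UN, ln k_IN)` from a fit.
#' Records can be built by hand (e.g. from published tables) or extracted
#' from a [fit_chevron_three_state()] result with [as_variant_record()].
#'
#' @param name Variant label, e.g. `"F15Y"`.
#' @param dG_UI,dG_UN Free energies, kJ mol^-1 (negative = stable).
#' @param k_IN Zero-denaturant I -> N rate constant, s^-1 (`NA` for
#'   two-state variants).
#' @param dG_UI_sd,dG_UN_sd,k_IN_sd 1-sigma errors (0 when unknown).
#' @param M_UN,M_UN_sd Total m-value and error (kJ mol^-1 M^-1), optional.
#' @param n_states 2 or 3.
#' @param position Structural location label, e.g. `"Helix I"`.
#' @param cov3 Optional 3x3 covariance of `(dG_UI, dG_UN, ln k_IN)`;
#'   defaults to the diagonal built from the sd arguments.
#' @return An object of class `variant_record`.
#' @export
variant_record <- function(name, dG_UI = NA_real_, dG_UN = NA_real_,
                           k_IN = NA_real_, dG_UI_sd = 0, dG_UN_sd = 0,
                           k_IN_sd = 0, M_UN = NA_real_, M_UN_sd = NA_real_,
                           n_states = 3L, position = NA_character_,
                           cov3 = NULL) {
  stopifnot(is.character(name), length(name) == 1L)
  if (is.null(cov3)) {
    ln_k_sd <- if (is.finite(k_IN) && k_IN > 0) k_IN_sd / k_IN else NA_real_
    cov3 <- diag(c(dG_UI_sd, dG_UN_sd, ln_k_sd)^2)
  }
  dimnames(cov3) <- list(c("dG_UI", "dG_UN", "ln_k_IN"),
                         c("dG_UI", "dG_UN", "ln_k_IN"))
  structure(
    list(name = name, position = position, n_states = as.integer(n_states),
         dG_UI = dG_UI, dG_UN = dG_UN, k_IN = k_IN,
         dG_UI_sd = dG_UI_sd, dG_UN_sd = dG_UN_sd, k_IN_sd = k_IN_sd,
         M_UN = M_UN, M_UN_sd = M_UN_sd, cov3 = cov3),
    class = "variant_record"
  )
}

#' Extract a variant record from a chevron fit
#'
#' Pulls `dG_UI`, `dG_UN`, `k_IN` and `M_UN` with their propagated errors out
#' of a fitted chevron, including the full covariance among
#' `(dG_UI, dG_UN, ln k_IN)` so that downstream phi-value errors account for
#' the correlation of the fit parameters within the variant.
#'
#' @param fit A `chevron_fit`.
#' @param name Variant label.
#' @param position Optional structural location label.
#' @return A [variant_record()].
#' @export
as_variant_record <- function(fit, name, position = NA_character_) {
  stopifnot(inherits(fit, "chevron_fit"))
  th <- stats::setNames(fit$thermo$value, fit$thermo$quantity)
  th_sd <- stats::setNames(fit$thermo$std_error, fit$thermo$quantity)
  if (fit$n_states == 3L) {
    pk <- fit$params[fit$params$term == "k_IN", ]
    # covariance of (dG_UI, dG_UN, ln k_IN): dG block from thermo_cov,
    # ln k_IN variance from the fit covariance (log scale); the cross terms
    # are recovered from the internal-parameter covariance
    free <- colnames(fit$covariance)
    cov3 <- NULL
    if (fit$identifiable && "k_IN" %in% free) {
      g <- function(thv) {
        nat <- to_natural(thv)
        full <- c(nat, unlist(fit$constraints$fixed))
        full <- full[chevron_param_names(3L, "sig_U_int" %in% names(full))]
        tsum <- thermo_summary(params_to_scheme(full, 3L), fit$cond)
        c(dG_UI = tsum$dG_UI, dG_UN = tsum$dG_UN, ln_k_IN = log(full[["k_IN"]]))
      }
      th_int <- to_internal(stats::setNames(fit$params$estimate,
                                            fit$params$term))[free]
      G <- numeric_jacobian(g, th_int)
      cov3 <- G %*% fit$covariance %*% t(G)
    }
    variant_record(name, dG_UI = th[["dG_UI"]], dG_UN = th[["dG_UN"]],
                   k_IN = pk$estimate, dG_UI_sd = th_sd[["dG_UI"]],
                   dG_UN_sd = th_sd[["dG_UN"]], k_IN_sd = pk$std_error,
                   M_UN = th[["M_UN"]], M_UN_sd = th_sd[["M_UN"]],
                   n_states = 3L, position = position, cov3 = cov3)
  } else {
    variant_record(name, dG_UN = th[["dG_UN"]], dG_UN_sd = th_sd[["dG_UN"]],
                   M_UN = th[["M_UN"]], M_UN_sd = th_sd[["M_UN"]],
                   n_states = 2L, position = position)
  }
}

#' Mutation-induced change in a stability free energy
#'
#' `ddG = dG(mutant) - dG(reference)`; under the negative-dG convention a
#' destabilising mutation gives a positive `ddG`. Errors combine in
#' quadrature (the two measurements are independent experiments).
#'
#' @param mut_dG,ref_dG Free energies, kJ mol^-1.
#' @param mut_sd,ref_sd 1-sigma errors.
#' @return A one-row tibble with `estimate` and `std_error`.
#' @examples
#' delta_delta_g(-10.38, -25.19, 0.13, 0.65) # IV7T vs wild type: +14.81
#' @export
delta_delta_g <- function(mut_dG, ref_dG, mut_sd = 0, ref_sd = 0) {
  stopifnot(is.finite(mut_dG), is.finite(ref_dG))
  tibble::tibble(estimate = mut_dG - ref_dG,
                 std_error = sqrt(mut_sd^2 + ref_sd^2))
}

# Joint (value, covariance) of (ddG_UI, ddG_UN, ddG_U_TS2) for a
# variant/reference pair; the engine behind phi_i / phi_ts2 / phi_report.
ddg_system <- function(variant, reference, cond) {
  RT <- cond$RT
  v <- c(variant$dG_UI, variant$dG_UN,
         if (is.finite(variant$k_IN)) log(variant$k_IN) else NA_real_)
  r <- c(reference$dG_UI, reference$dG_UN,
         if (is.finite(reference$k_IN)) log(reference$k_IN) else NA_real_)
  ddG_UI <- v[1] - r[1]
  ddG_UN <- v[2] - r[2]
  ddG_U_TS2 <- ddG_UI - RT * (v[3] - r[3])
  # gradients w.r.t. the stacked 6-vector (v1 v2 v3 r1 r2 r3)
  Gm <- rbind(c(1, 0, 0, -1, 0, 0),
              c(0, 1, 0, 0, -1, 0),
              c(1, 0, -RT, -1, 0, RT))
  C6 <- matrix(0, 6, 6)
  cv <- variant$cov3; cr <- reference$cov3
  cv[!is.finite(cv)] <- 0; cr[!is.finite(cr)] <- 0
  C6[1:3, 1:3] <- cv; C6[4:6, 4:6] <- cr
  cov_ddg <- Gm %*% C6 %*% t(Gm)
  list(ddG = c(UI = ddG_UI, UN = ddG_UN, U_TS2 = ddG_U_TS2), cov = cov_ddg)
}

phi_from_system <- function(sys, which = c("I", "TS2"), threshold, force) {
  which <- match.arg(which)
  num_i <- if (which == "I") 1L else 3L
  num <- sys$ddG[[num_i]]
  den <- sys$ddG[["UN"]]
  determinable <- is.finite(den) && abs(den) >= threshold
  if (!is.finite(num) || !is.finite(den)) {
    return(tibble::tibble(estimate = NA_real_, std_error = NA_real_,
                          determinable = FALSE))
  }
  if (den == 0) stop("ddG_UN is zero; phi is undefined.", call. = FALSE)
  if (!determinable && !force) {
    return(tibble::tibble(estimate = NA_real_, std_error = NA_real_,
                          determinable = FALSE))
  }
  phi <- num / den
  g <- c(1 / den, -num / den^2) # d phi / d(num, den)
  C <- sys$cov[c(num_i, 2L), c(num_i, 2L)]
  tibble::tibble(estimate = phi,
                 std_error = sqrt(drop(t(g) %*% C %*% g)),
                 determinable = determinable)
}

#' Phi-value of the folding intermediate
#'
#' `phi_I = ddG_UI / ddG_UN`: the fraction of the mutation's native-state
#' destabilisation already present in the intermediate. Values near 1 mean
#' the probed side-chain environment is native-like in I; near 0,
#' unfolded-like. Negative values (reported unclamped) indicate non-native
#' effects. By default no value is reported when `|ddG_UN|` is below the
#' determinability threshold of 2.5 kJ mol^-1.
#'
#' @param variant,reference [variant_record()]s; both must be three-state.
#' @param cond A [fold_conditions()].
#' @param threshold Determinability threshold on `|ddG_UN|` (kJ mol^-1).
#' @param force Compute a numeric phi even below the threshold.
#' @return A one-row tibble: `estimate`, `std_error` (delta method),
#'   `determinable`.
#' @export
phi_i <- function(variant, reference, cond = fold_conditions(),
                  threshold = 2.5, force = FALSE) {
  stopifnot(inherits(variant, "variant_record"),
            inherits(reference, "variant_record"))
  cond <- as_fold_conditions(cond)
  sys <- ddg_system(variant, reference, cond)
  # phi_I needs only the dG values; mask the k_IN channel
  phi_from_system(sys, "I", threshold, force)
}

#' Phi-value of the rate-limiting transition state
#'
#' `phi_TS2 = [ddG_UI - RT ln(k_IN^mut / k_IN^ref)] / ddG_UN`. The bracketed
#' numerator is the destabilisation of the transition state itself
#' (`ddG_U_TS2`), combining the intermediate's destabilisation with the
#' mutation's effect on the barrier crossing.
#'
#' @inheritParams phi_i
#' @return A one-row tibble: `estimate`, `std_error`, `determinable`.
#' @export
phi_ts2 <- function(variant, reference, cond = fold_conditions(),
                    threshold = 2.5, force = FALSE) {
  stopifnot(inherits(variant, "variant_record"),
            inherits(reference, "variant_record"))
  cond <- as_fold_conditions(cond)
  sys <- ddg_system(variant, reference, cond)
  phi_from_system(sys, "TS2", threshold, force)
}

#' Classify phi-values into low / mid / high bins
#'
#' The conventional colouring bins: low `phi <= 0.4`, mid
#' `0.4 < phi <= 0.7`, high `phi > 0.7`. Boundary values go to the lower bin
#' (the source inequalities are strict on both sides, leaving exact
#' boundaries undefined; assigning them downward is this package's
#' documented tie-break). `NA` inputs classify as `NA`.
#'
#' @param phi Numeric vector of phi-values.
#' @return Character vector: `"low"`, `"mid"`, `"high"` or `NA`.
#' @export
classify_phi <- function(phi) {
  out <- rep(NA_character_, length(phi))
  out[!is.na(phi) & phi <= 0.4] <- "low"
  out[!is.na(phi) & phi > 0.4 & phi <= 0.7] <- "mid"
  out[!is.na(phi) & phi > 0.7] <- "high"
  out
}

#' Total m-value consistency check
#'
#' Flags variants whose total m-value deviates from the reference by more
#' than a fractional tolerance (default 10%), the standard screen for
#' substitutions that alter the amount of surface buried on folding. With a
#' reference of 5.4 kJ mol^-1 M^-1 the pass band is the open interval
#' (4.86, 5.94).
#'
#' @param variant_M_UN Variant total m-value(s), kJ mol^-1 M^-1.
#' @param reference_M_UN Reference total m-value.
#' @param tolerance Fractional tolerance (strict: deviation == tolerance
#'   flags).
#' @return Character vector of `"pass"` / `"flag"`.
#' @examples
#' check_m_value(c(5.39, 4.6, 5.94), 5.4) # pass, flag, flag
#' @export
check_m_value <- function(variant_M_UN, reference_M_UN, tolerance = 0.10) {
  stopifnot(all(variant_M_UN > 0), reference_M_UN > 0)
  dev <- abs(variant_M_UN - reference_M_UN) / reference_M_UN
  ifelse(dev < tolerance - 1e-12, "pass", "flag")
}

#' Build the per-variant phi/ddG report table
#'
#' Assembles one row per variant with its thermodynamics, the ddG values
#' against its reference, phi-values (with the ND rule applied), bin
#' classifications and the m-value quality check. References are resolved
#' via `reference_map`: a named list mapping variant names to reference
#' names, with a `default` entry for everything else (this is how a
#' pseudo-wild-type such as `I54V` is attached to `IV54T`). A record mapped
#' to itself is a reference row and gets no phi columns.
#'
#' @param records List of [variant_record()]s (names taken from the records).
#' @param reference_map Named list, e.g.
#'   `list(IV54T = "I54V", default = "Im7")`.
#' @param cond A [fold_conditions()].
#' @param threshold ND threshold on `|ddG_UN|`, kJ mol^-1.
#' @param m_reference,m_tolerance Reference total m-value and fractional
#'   tolerance for [check_m_value()]; `m_reference = NULL` skips the check.
#' @return A tibble, one row per record, with ddG/phi/beta columns, their
#'   errors, `determinable`, `phi_I_class`/`phi_TS2_class` and `m_check`.
#' @export
phi_report <- function(records, reference_map = list(default = "Im7"),
                       cond = fold_conditions(), threshold = 2.5,
                       m_reference = NULL, m_tolerance = 0.10) {
  cond <- as_fold_conditions(cond)
  stopifnot(is.list(records), length(records) > 0)
  names(records) <- vapply(records, function(r) r$name, character(1))
  resolve <- function(nm) {
    ref <- reference_map[[nm]]
    if (is.null(ref)) ref <- reference_map[["default"]]
    if (is.null(ref)) stop("No reference (and no default) for variant ", nm,
                           call. = FALSE)
    ref
  }
  rows <- lapply(names(records), function(nm) {
    rec <- records[[nm]]
    ref_nm <- resolve(nm)
    if (!ref_nm %in% names(records)) {
      stop(sprintf("Reference '%s' for variant '%s' is not among the records.",
                   ref_nm, nm), call. = FALSE)
    }
    base <- tibble::tibble(
      variant = nm, position = rec$position, reference = ref_nm,
      n_states = rec$n_states,
      dG_UI = rec$dG_UI, dG_UI_sd = rec$dG_UI_sd,
      dG_UN = rec$dG_UN, dG_UN_sd = rec$dG_UN_sd,
      k_IN = rec$k_IN, M_UN = rec$M_UN
    )
    if (ref_nm == nm) {
      return(dplyr::mutate(base,
                           ddG_UI = NA_real_, ddG_UI_sd = NA_real_,
                           ddG_UN = NA_real_, ddG_UN_sd = NA_real_,
                           ddG_U_TS2 = NA_real_, ddG_U_TS2_sd = NA_real_,
                           phi_I = NA_real_, phi_I_sd = NA_real_,
                           phi_TS2 = NA_real_, phi_TS2_sd = NA_real_,
                           determinable = NA, is_reference = TRUE))
    }
    ref <- records[[ref_nm]]
    sys <- ddg_system(rec, ref, cond)
    pI <- phi_from_system(sys, "I", threshold, force = FALSE)
    pT <- phi_from_system(sys, "TS2", threshold, force = FALSE)
    dplyr::mutate(base,
                  ddG_UI = sys$ddG[["UI"]],
                  ddG_UI_sd = sqrt(sys$cov[1, 1]),
                  ddG_UN = sys$ddG[["UN"]],
                  ddG_UN_sd = sqrt(sys$cov[2, 2]),
                  ddG_U_TS2 = sys$ddG[["U_TS2"]],
                  ddG_U_TS2_sd = sqrt(sys$cov[3, 3]),
                  phi_I = pI$estimate, phi_I_sd = pI$std_error,
                  phi_TS2 = pT$estimate, phi_TS2_sd = pT$std_error,
                  determinable = is.finite(sys$ddG[["UN"]]) &&
                    abs(sys$ddG[["UN"]]) >= threshold,
                  is_reference = FALSE)
  })
  out <- dplyr::bind_rows(rows)
  out$phi_I_class <- ifelse(is.na(out$determinable), NA_character_,
                            ifelse(out$determinable, classify_phi(out$phi_I),
                                   "ND"))
  out$phi_TS2_class <- ifelse(is.na(out$determinable), NA_character_,
                              ifelse(out$determinable,
                                     classify_phi(out$phi_TS2), "ND"))
  if (!is.null(m_reference)) {
    out$m_check <- ifelse(is.na(out$M_UN), NA_character_,
                          check_m_value(out$M_UN, m_reference, m_tolerance))
  }
  out
}

#' Format a phi report as an aligned text table
#'
#' @param report A tibble from [phi_report()].
#' @param digits Significant digits for numeric cells.
#' @return Character vector of lines (invisibly printed with `cat`).
#' @export
format_phi_table <- function(report, digits = 4) {
  num <- function(x, sd = NULL) {
    ifelse(is.na(x), "--",
           if (is.null(sd)) signif(x, digits)
           else paste0(signif(x, digits), " +/- ", signif(sd, 2)))
  }
  phi_cell <- function(x, sd, det, is_ref) {
    ifelse(is_ref, "--", ifelse(!is.na(det) & !det, "ND", num(x, sd)))
  }
  df <- data.frame(
    Variant = report$variant,
    dG_UI = num(report$dG_UI, report$dG_UI_sd),
    dG_UN = num(report$dG_UN, report$dG_UN_sd),
    ddG_UN = num(report$ddG_UN, report$ddG_UN_sd),
    Phi_I = phi_cell(report$phi_I, report$phi_I_sd, report$determinable,
                     report$is_reference),
    Phi_TS2 = phi_cell(report$phi_TS2, report$phi_TS2_sd,
                       report$determinable, report$is_reference),
    check.names = FALSE
  )
  lines <- utils::capture.output(print(df, row.names = FALSE))
  lines
}
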