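# CSV/JSON interfaces. Column names are fixed but case-insensitive;
# denaturant concentrations are molar floats with no unit inference.

chevron_cols <- c("variant", "urea_M", "branch", "kobs_s1", "kobs_sigma",
                  "initial_fluor", "final_fluor")

#' Read a chevron dataset from CSV
#'
#' Expects header columns `urea_M` and `kobs_s1` (mandatory), plus optional
#' `variant`, `branch`, `kobs_sigma`, `initial_fluor`, `final_fluor`.
#' Column matching is case-insensitive; unknown columns are dropped with a
#' warning. When `branch` is absent it is assigned by comparing each
#' denaturant value to the location of the chevron minimum (the lowest
#' observed rate). Both LF and CRLF line endings are accepted.
#'
#' @param path CSV file path.
#' @return A tibble in the fitter layout, one row per observation (all
#'   variants stacked; filter on `variant` for multi-variant files).
#' @export
read_chevron_csv <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  names_lc <- tolower(names(raw))
  hit <- match(names_lc, tolower(chevron_cols))
  unknown <- names(raw)[is.na(hit)]
  if (length(unknown)) {
    warning("Ignoring unknown column(s): ", paste(unknown, collapse = ", "),
            call. = FALSE)
  }
  out <- raw[, !is.na(hit), drop = FALSE]
  names(out) <- chevron_cols[hit[!is.na(hit)]]
  miss <- setdiff(c("urea_M", "kobs_s1"), names(out))
  if (length(miss)) {
    stop("Missing mandatory column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!is.numeric(out$urea_M) || !is.numeric(out$kobs_s1)) {
    stop("urea_M and kobs_s1 must be numeric ",
         "(decimal commas are not accepted).", call. = FALSE)
  }
  bad <- which(!is.finite(out$kobs_s1) | out$kobs_s1 <= 0)
  if (length(bad)) {
    stop("Non-positive kobs_s1 in row(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (!"branch" %in% names(out)) {
    d_min <- out$urea_M[which.min(out$kobs_s1)]
    out$branch <- ifelse(out$urea_M <= d_min, "refolding", "unfolding")
    warning("No 'branch' column; assigned by the chevron minimum at ",
            signif(d_min, 3), " M.", call. = FALSE)
  }
  if (!all(c("initial_fluor", "final_fluor") %in% names(out))) {
    warning("No amplitude columns; dataset supports rate-only fits.",
            call. = FALSE)
  }
  tibble::as_tibble(out)
}

#' Write a chevron dataset to CSV
#'
#' @param data Chevron tibble (e.g. from [generate_chevron()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_chevron_csv <- function(data, path) {
  readr::write_csv(data, path)
  invisible(path)
}

#' Read a kinetic trace from CSV
#'
#' @param path CSV with columns `time_s`, `signal` (case-insensitive).
#' @return A tibble with `time_s`, `signal`.
#' @export
read_trace_csv <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  names(raw) <- tolower(names(raw))
  if (!all(c("time_s", "signal") %in% names(raw))) {
    stop("Trace CSV needs columns time_s and signal.", call. = FALSE)
  }
  tibble::as_tibble(raw[, c("time_s", "signal")])
}

#' Read an equilibrium curve from CSV
#'
#' @param path CSV with columns `urea_M`, `signal` and optionally `probe`.
#' @return A tibble.
#' @export
read_equilibrium_csv <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  names(raw) <- tolower(names(raw))
  names(raw)[names(raw) == "urea_m"] <- "urea_M"
  if (!all(c("urea_M", "signal") %in% names(raw))) {
    stop("Equilibrium CSV needs columns urea_M and signal.", call. = FALSE)
  }
  tibble::as_tibble(raw)
}

#' Read fit constraints from a JSON config
#'
#' Accepts the layout
#' `{"fixed": {"k_UI": 1574, "m_UI": 1.23}, "bounds": {"m_NI": [0, 2]},
#' "M_UN_range": [4.6, 5.2]}`.
#'
#' @param path JSON file path.
#' @return A [fit_constraints()].
#' @export
read_fit_constraints <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  fit_constraints(
    fixed = as.list(cfg$fixed %||% list()),
    bounds = lapply(as.list(cfg$bounds %||% list()), as.numeric),
    M_UN_range = if (!is.null(cfg$M_UN_range)) as.numeric(cfg$M_UN_range)
  )
}

#' Write a chevron or equilibrium fit to JSON
#'
#' Serialises parameter estimates, errors, derived thermodynamics and
#' convergence metadata; the file round-trips through
#' [read_fit_json()] into a [variant_record()] for phi analysis.
#'
#' @param fit A `chevron_fit` or `equilibrium_fit`.
#' @param path Output path.
#' @param variant Variant label stored in the file.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path, variant = "variant") {
  if (inherits(fit, "chevron_fit")) {
    rec <- as_variant_record(fit, variant)
    obj <- list(
      type = "chevron_fit", variant = variant, n_states = fit$n_states,
      params = fit$params, thermo = fit$thermo,
      record = list(dG_UI = rec$dG_UI, dG_UI_sd = rec$dG_UI_sd,
                    dG_UN = rec$dG_UN, dG_UN_sd = rec$dG_UN_sd,
                    k_IN = rec$k_IN, k_IN_sd = rec$k_IN_sd,
                    M_UN = rec$M_UN, M_UN_sd = rec$M_UN_sd),
      convergence = fit$convergence[c("success", "iterations", "n_starts",
                                      "multistart_seed")],
      residual_blocks = fit$residual_blocks
    )
  } else if (inherits(fit, "equilibrium_fit")) {
    obj <- list(
      type = "equilibrium_fit", variant = variant,
      params = fit$params, midpoint_M = fit$midpoint_M,
      identifiable = fit$identifiable,
      convergence = fit$convergence[c("success", "iterations", "n_starts")]
    )
  } else {
    stop("`fit` must be a chevron_fit or equilibrium_fit.", call. = FALSE)
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' Read a fit JSON back into a variant record
#'
#' @param path A JSON file written by [write_fit_json()].
#' @return A [variant_record()] (chevron fits) or named list
#'   (equilibrium fits).
#' @export
read_fit_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (identical(obj$type, "chevron_fit")) {
    r <- obj$record
    variant_record(obj$variant,
                   dG_UI = r$dG_UI %||% NA_real_,
                   dG_UN = r$dG_UN %||% NA_real_,
                   k_IN = r$k_IN %||% NA_real_,
                   dG_UI_sd = r$dG_UI_sd %||% 0,
                   dG_UN_sd = r$dG_UN_sd %||% 0,
                   k_IN_sd = r$k_IN_sd %||% 0,
                   M_UN = r$M_UN %||% NA_real_,
                   M_UN_sd = r$M_UN_sd %||% NA_real_,
                   n_states = obj$n_states)
  } else {
    obj
  }
}

#' Read a reference-state map from JSON
#'
#' Layout: `{"reference": {"IV54T": "I54V", "default": "Im7"}}` (or the
#' inner object directly).
#'
#' @param path JSON file path.
#' @return Named list usable as `reference_map` in [phi_report()].
#' @export
read_reference_map <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  as.list(cfg$reference %||% cfg)
}
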