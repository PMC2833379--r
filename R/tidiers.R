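#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a chevron fit
#'
#' @param x A `chevron_fit`.
#' @param ... Unused.
#' @return A tibble with one row per model parameter: `term`, `estimate`,
#'   `std_error`, `fixed`, `at_bound`.
#' @export
tidy.chevron_fit <- function(x, ...) x$params

#' @rdname tidy.chevron_fit
#' @export
tidy.equilibrium_fit <- function(x, ...) x$params

#' One-row summary of a chevron fit
#'
#' @param x A `chevron_fit`.
#' @param ... Unused.
#' @return A one-row tibble: state count, observation count, per-block RMS,
#'   convergence flag and iteration count.
#' @export
glance.chevron_fit <- function(x, ...) {
  rms <- stats::setNames(x$residual_blocks$rms,
                         paste0("rms_", x$residual_blocks$block))
  tibble::tibble(
    n_states = x$n_states,
    n_obs = sum(x$residual_blocks$n),
    !!!as.list(rms),
    identifiable = x$identifiable,
    converged = x$convergence$success,
    iterations = x$convergence$iterations
  )
}

#' @rdname glance.chevron_fit
#' @export
glance.equilibrium_fit <- function(x, ...) {
  tibble::tibble(
    n_obs = nrow(x$data),
    rms = x$residual_rms,
    midpoint_M = x$midpoint_M,
    identifiable = x$identifiable,
    converged = x$convergence$success,
    iterations = x$convergence$iterations
  )
}

#' @rdname tidy.chevron_fit
#' @export
tidy.exp_trace_fit <- function(x, ...) {
  n <- x$n_phases
  tibble::tibble(
    term = c(paste0("k", seq_len(n)), paste0("A", seq_len(n)), "offset"),
    estimate = c(x$rates, x$amplitudes, x$offset),
    std_error = unname(x$sigma[c(paste0("k", seq_len(n)),
                                 paste0("A", seq_len(n)), "offset")])
  )
}
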