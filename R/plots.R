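#' Plot a chevron fit
#'
#' Observed rates (log scale) against denaturant with the fitted slow-phase
#' relaxation rate overlaid; optionally a second panel-style layer of the
#' amplitude data is available via [plot_amplitudes()].
#'
#' @param object A `chevron_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.chevron_fit <- function(object, ...) {
  dat <- object$data
  grid <- seq(min(dat$urea_M), max(dat$urea_M), length.out = 120)
  curve <- tibble::tibble(
    urea_M = grid,
    kobs_s1 = observed_rate(object$scheme, grid, object$cond)
  )
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$urea_M, y = .data$kobs_s1)) +
    ggplot2::geom_line(data = curve, colour = "grey30") +
    ggplot2::geom_point(ggplot2::aes(shape = .data$branch)) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "[urea] (M)", y = expression(k[obs] ~ (s^-1)),
                  shape = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the amplitude observables of a chevron fit
#'
#' Initial and endpoint fluorescence signals with the fitted amplitude
#' model.
#'
#' @param fit A `chevron_fit` fitted with amplitude data.
#' @return A ggplot object.
#' @export
plot_amplitudes <- function(fit) {
  stopifnot(inherits(fit, "chevron_fit"))
  dat <- fit$data
  if (!any(is.finite(dat$initial_fluor)) && !any(is.finite(dat$final_fluor))) {
    stop("Fit has no amplitude data.", call. = FALSE)
  }
  grid <- seq(min(dat$urea_M), max(dat$urea_M), length.out = 120)
  amp_r <- amplitude_model(fit$scheme, grid, "refolding", fit$cond)
  model <- dplyr::bind_rows(
    tibble::tibble(urea_M = grid, signal = amp_r$initial_signal,
                   which = "initial (refolding)"),
    tibble::tibble(urea_M = grid, signal = amp_r$final_signal,
                   which = "final")
  )
  obs <- dplyr::bind_rows(
    tibble::tibble(urea_M = dat$urea_M, signal = dat$initial_fluor,
                   which = paste0("initial (", dat$branch, ")")),
    tibble::tibble(urea_M = dat$urea_M, signal = dat$final_fluor,
                   which = "final")
  )
  obs <- obs[is.finite(obs$signal), ]
  ggplot2::ggplot(obs, ggplot2::aes(x = .data$urea_M, y = .data$signal,
                                    colour = .data$which)) +
    ggplot2::geom_line(data = model) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "[urea] (M)", y = "normalised fluorescence",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot an equilibrium fit
#'
#' @param object An `equilibrium_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.equilibrium_fit <- function(object, ...) {
  dat <- object$data
  grid <- seq(min(dat$urea_M), max(dat$urea_M), length.out = 200)
  curve <- tibble::tibble(
    urea_M = grid,
    signal = equilibrium_signal(object$model, grid, object$cond)
  )
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$urea_M, y = .data$signal)) +
    ggplot2::geom_line(data = curve, colour = "grey30") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "[urea] (M)", y = "signal") +
    ggplot2::theme_minimal()
}

#' Bar chart of phi-values across variants
#'
#' @param report A tibble from [phi_report()].
#' @return A ggplot object (variants with ND or reference rows are dropped).
#' @export
plot_phi_profile <- function(report) {
  long <- tidyr::pivot_longer(
    report[!is.na(report$phi_I) | !is.na(report$phi_TS2), ],
    cols = c("phi_I", "phi_TS2"),
    names_to = "state", values_to = "phi"
  )
  long$sd <- ifelse(long$state == "phi_I", long$phi_I_sd, long$phi_TS2_sd)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$variant, y = .data$phi,
                                     fill = .data$state)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$phi - .data$sd, ymax = .data$phi + .data$sd),
      position = ggplot2::position_dodge(width = 0.9), width = 0.25
    ) +
    ggplot2::labs(x = NULL, y = expression(Phi), fill = NULL) +
    ggplot2::theme_minimal()
}
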