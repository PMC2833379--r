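#' Experimental conditions
#'
#' Bundle of the temperature and gas constant used to convert between rate
#' constants and free energies. All thermodynamic output of the package is in
#' kJ mol^-1, so the gas constant defaults to 0.0083145 kJ mol^-1 K^-1. The
#' default temperature of 283.15 K (10 degrees C) is the standard condition for
#' stopped-flow folding work on the immunity proteins and gives
#' RT = 2.3543 kJ mol^-1.
#'
#' @param temperature_K Absolute temperature in kelvin. Must be positive.
#' @param gas_constant Gas constant in kJ mol^-1 K^-1.
#'
#' @return An object of class `fold_conditions`: a list with elements
#'   `temperature_K`, `gas_constant` and the derived product `RT` (kJ mol^-1).
#' @examples
#' cond <- fold_conditions()
#' cond$RT # 2.354 kJ mol^-1 at 10 degrees C
#' @export
fold_conditions <- function(temperature_K = 283.15, gas_constant = 0.0083145) {
  stopifnot(is.numeric(temperature_K), length(temperature_K) == 1L,
            is.numeric(gas_constant), length(gas_constant) == 1L)
  if (!is.finite(temperature_K) || temperature_K <= 0) {
    stop("`temperature_K` must be a positive, finite number of kelvin.",
         call. = FALSE)
  }
  if (!is.finite(gas_constant) || gas_constant <= 0) {
    stop("`gas_constant` must be positive (kJ mol^-1 K^-1).", call. = FALSE)
  }
  structure(
    list(
      temperature_K = temperature_K,
      gas_constant = gas_constant,
      RT = gas_constant * temperature_K
    ),
    class = "fold_conditions"
  )
}

#' @export
print.fold_conditions <- function(x, ...) {
  cat(sprintf("<fold_conditions> T = %.2f K, R = %.7f kJ/mol/K, RT = %.4f kJ/mol\n",
              x$temperature_K, x$gas_constant, x$RT))
  invisible(x)
}

as_fold_conditions <- function(cond) {
  if (inherits(cond, "fold_conditions")) return(cond)
  if (is.null(cond)) return(fold_conditions())
  stop("`cond` must be a fold_conditions object (see fold_conditions()).",
       call. = FALSE)
}
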