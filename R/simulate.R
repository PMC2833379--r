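#' Noise model for synthetic datasets
#'
#' Observed rate constants get multiplicative lognormal noise (rates span
#' three decades, and chevrons are analysed in log space), fluorescence
#' amplitudes and trace points get additive Gaussian noise on the normalised
#' scale. The defaults (3% relative on rates, 0.01 absolute on signals)
#' emulate well-averaged stopped-flow data.
#'
#' @param kobs_rel_sd Standard deviation of `ln kobs` noise (relative).
#' @param signal_sd Additive sd of amplitude signals (normalised units).
#' @param trace_sd Additive sd of kinetic trace points.
#' @param seed Integer seed; identical seeds reproduce identical datasets
#'   bit-for-bit. `NULL` uses (and advances) the session RNG.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(kobs_rel_sd = 0.03, signal_sd = 0.01,
                        trace_sd = 0.01, seed = NULL) {
  stopifnot(kobs_rel_sd >= 0, signal_sd >= 0, trace_sd >= 0)
  structure(list(kobs_rel_sd = kobs_rel_sd, signal_sd = signal_sd,
                 trace_sd = trace_sd, seed = seed),
            class = "noise_model")
}

with_noise_seed <- function(noise, expr) {
  if (is.null(noise$seed)) expr else withr::with_seed(noise$seed, expr)
}

#' Default denaturant grids of a chevron experiment
#'
#' Refolding observations over 0.75-8.0 M (16 points) and unfolding over
#' 3.0-8.0 M (11 points), mirroring standard urea-dilution practice.
#'
#' @name chevron_grids
#' @return Numeric vector of denaturant concentrations (M).
#' @export
default_refolding_grid <- function() seq(0.75, 8, length.out = 16)

#' @rdname chevron_grids
#' @export
default_unfolding_grid <- function() seq(3, 8, length.out = 11)

#' Generate a synthetic chevron dataset from a kinetic scheme
#'
#' Computes the observable slow relaxation rate and the amplitude-model
#' initial/endpoint signals on the two experimental grids, then applies the
#' noise model. Each observation is labelled with the mixing direction of
#' the grid that produced it (refolding or unfolding), which is what the
#' burst-phase initial-signal model keys on. With a positive rate noise the
#' `kobs_sigma` column carries the known per-point sd.
#'
#' @param scheme A [kinetic_scheme()].
#' @param refolding_grid,unfolding_grid Denaturant grids (M), within
#'   \[0, 10\]. Either may be empty, but not both.
#' @param noise A [noise_model()].
#' @param cond A [fold_conditions()].
#' @param variant Optional variant label column.
#' @return A tibble with columns `variant` (if given), `urea_M`, `branch`,
#'   `kobs_s1`, `kobs_sigma`, `initial_fluor`, `final_fluor` — the layout
#'   the chevron fitters consume.
#' @examples
#' dat <- generate_chevron(scenario_scheme("Im7"),
#'                         noise = noise_model(seed = 1))
#' head(dat)
#' @export
generate_chevron <- function(scheme,
                             refolding_grid = default_refolding_grid(),
                             unfolding_grid = default_unfolding_grid(),
                             noise = noise_model(), cond = fold_conditions(),
                             variant = NULL) {
  stopifnot(inherits(scheme, "kinetic_scheme"),
            inherits(noise, "noise_model"))
  cond <- as_fold_conditions(cond)
  grid <- c(refolding_grid, unfolding_grid)
  if (length(grid) == 0) stop("Both denaturant grids are empty.",
                              call. = FALSE)
  if (any(grid < 0 | grid > 10)) {
    stop("Denaturant grids must lie within [0, 10] M.", call. = FALSE)
  }
  branch <- rep(c("refolding", "unfolding"),
                c(length(refolding_grid), length(unfolding_grid)))
  lam <- observed_rate(scheme, grid, cond)
  amp_r <- amplitude_model(scheme, grid, "refolding", cond)
  amp_u <- amplitude_model(scheme, grid, "unfolding", cond)
  init <- ifelse(branch == "refolding", amp_r$initial_signal,
                 amp_u$initial_signal)
  fin <- amp_r$final_signal
  n <- length(grid)
  out <- with_noise_seed(noise, {
    kobs <- lam * exp(stats::rnorm(n, 0, noise$kobs_rel_sd))
    tibble::tibble(
      urea_M = grid,
      branch = branch,
      kobs_s1 = kobs,
      kobs_sigma = if (noise$kobs_rel_sd > 0) noise$kobs_rel_sd * kobs else
        NA_real_,
      initial_fluor = init + stats::rnorm(n, 0, noise$signal_sd),
      final_fluor = fin + stats::rnorm(n, 0, noise$signal_sd)
    )
  })
  if (!is.null(variant)) out <- dplyr::mutate(out, variant = variant,
                                              .before = 1)
  out
}

#' Generate a synthetic kinetic trace
#'
#' Propagates the full rate matrix from the mixing initial condition
#' (all-unfolded for refolding, all-native for unfolding) by
#' eigendecomposition, converts state populations to fluorescence through
#' the scheme's baselines, and adds Gaussian noise. A three-state scheme
#' yields a double-exponential trace (burst + observable phase); a two-state
#' scheme is exactly single-exponential.
#'
#' @param scheme A [kinetic_scheme()].
#' @param D Final denaturant concentration, M (scalar).
#' @param direction `"refolding"` or `"unfolding"`.
#' @param duration Trace length, s; defaults to `5 / lambda_slow`. A
#'   duration shorter than `3 / lambda_slow` triggers a warning.
#' @param n_points Number of time points (>= 10).
#' @param noise A [noise_model()].
#' @param cond A [fold_conditions()].
#' @return A tibble with columns `time_s`, `signal`; attributes
#'   `denaturant_M` and `direction`.
#' @export
generate_trace <- function(scheme, D, direction = c("refolding", "unfolding"),
                           duration = NULL, n_points = 200,
                           noise = noise_model(), cond = fold_conditions()) {
  direction <- match.arg(direction)
  stopifnot(inherits(scheme, "kinetic_scheme"), length(D) == 1L,
            n_points >= 10)
  cond <- as_fold_conditions(cond)
  lam_slow <- observed_rate(scheme, D, cond)
  if (is.null(duration)) duration <- 5 / lam_slow
  if (duration < 3 / lam_slow) {
    warning("Trace duration covers less than 3 slow-phase lifetimes.",
            call. = FALSE)
  }
  tt <- seq(0, duration, length.out = n_points)
  A <- rate_matrix(scheme, D, cond)
  p0 <- stats::setNames(rep(0, scheme$n_states), scheme$states)
  p0[if (direction == "refolding") "U" else "N"] <- 1
  eg <- eigen(A)
  coef <- solve(eg$vectors, p0)
  P <- Re(eg$vectors %*% (coef * exp(outer(eg$values, tt))))
  sc <- scheme$signal_coeffs
  b <- sc$intercept + sc$slope * D
  signal <- drop(t(P) %*% b)
  out <- with_noise_seed(noise, {
    tibble::tibble(time_s = tt,
                   signal = signal + stats::rnorm(n_points, 0, noise$trace_sd))
  })
  attr(out, "denaturant_M") <- D
  attr(out, "direction") <- direction
  out
}

#' Generate a synthetic equilibrium denaturation curve
#'
#' Evaluates the LEM signal model on a denaturant grid (default 0-8 M in
#' 0.2 M steps) and adds Gaussian noise.
#'
#' @param model An [equilibrium_model()].
#' @param grid Denaturant grid, M (>= 2 points).
#' @param noise A [noise_model()] (`signal_sd` is used).
#' @param cond A [fold_conditions()].
#' @param probe Metadata label: `"fluorescence"` or `"CD225nm"`.
#' @return A tibble with columns `urea_M`, `signal`, `probe`.
#' @export
generate_equilibrium_curve <- function(model, grid = seq(0, 8, by = 0.2),
                                       noise = noise_model(),
                                       cond = fold_conditions(),
                                       probe = "fluorescence") {
  stopifnot(inherits(model, "equilibrium_model"))
  if (length(grid) < 2) {
    stop("Equilibrium grid needs at least two points.", call. = FALSE)
  }
  cond <- as_fold_conditions(cond)
  s <- equilibrium_signal(model, grid, cond)
  with_noise_seed(noise, {
    tibble::tibble(urea_M = grid,
                   signal = s + stats::rnorm(length(grid), 0, noise$signal_sd),
                   probe = probe)
  })
}
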