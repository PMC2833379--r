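#' Constraints for a chevron fit
#'
#' Parameters can be fixed to known values (for three-state fits the fast
#' U <-> I phase is by default fixed to the wild-type continuous-flow values
#' `k_UI = 1574 s^-1`, `m_UI = 1.23 kJ mol^-1 M^-1`), bounded, or the total
#' kinetic m-value `M_UN` (sum of all kinetic m-value magnitudes) can be
#' restricted to a range determined independently by equilibrium
#' denaturation — the treatment needed for variants whose chevron alone does
#' not pin the m-values down.
#'
#' @param fixed Named list of parameter values to hold fixed.
#' @param bounds Named list of length-2 numeric vectors `c(lo, hi)` on the
#'   natural parameter scale.
#' @param M_UN_range Optional `c(lo, hi)` (kJ mol^-1 M^-1) soft constraint on
#'   the total kinetic m-value, enforced by a hinge penalty.
#' @return An object of class `fit_constraints`.
#' @examples
#' fit_constraints(fixed = list(k_UI = 1574, m_UI = 1.23))
#' fit_constraints(M_UN_range = c(4.6, 5.2)) # equilibrium-constrained total m
#' @export
fit_constraints <- function(fixed = list(), bounds = list(),
                            M_UN_range = NULL) {
  if (length(fixed) && is.null(names(fixed))) {
    stop("`fixed` must be a named list.", call. = FALSE)
  }
  if (length(bounds)) {
    if (is.null(names(bounds))) stop("`bounds` must be named.", call. = FALSE)
    for (nm in names(bounds)) {
      b <- bounds[[nm]]
      if (length(b) != 2 || b[1] >= b[2]) {
        stop(sprintf("bounds$%s must be c(lo, hi) with lo < hi.", nm),
             call. = FALSE)
      }
    }
  }
  overlap <- intersect(names(fixed), names(bounds))
  if (length(overlap)) {
    stop("Parameters cannot be both fixed and bounded: ",
         paste(overlap, collapse = ", "), call. = FALSE)
  }
  if (!is.null(M_UN_range)) {
    stopifnot(length(M_UN_range) == 2, M_UN_range[1] < M_UN_range[2])
  }
  structure(list(fixed = fixed, bounds = bounds, M_UN_range = M_UN_range),
            class = "fit_constraints")
}

# ---- data validation ------------------------------------------------------

validate_chevron_data <- function(data, require_both_branches = FALSE) {
  stopifnot(is.data.frame(data))
  need <- c("urea_M", "kobs_s1", "branch")
  miss <- setdiff(need, names(data))
  if (length(miss)) {
    stop("Chevron data is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.finite(data$kobs_s1)) || any(data$kobs_s1 <= 0)) {
    bad <- which(!is.finite(data$kobs_s1) | data$kobs_s1 <= 0)
    stop("Non-positive kobs_s1 in row(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (!all(data$branch %in% c("refolding", "unfolding"))) {
    stop("`branch` must be 'refolding' or 'unfolding'.", call. = FALSE)
  }
  has_ref <- any(data$branch == "refolding")
  has_unf <- any(data$branch == "unfolding")
  if (require_both_branches && !(has_ref && has_unf)) {
    warning("Only one branch present; the missing branch's parameters ",
            "will be unidentifiable.", call. = FALSE)
  }
  if (has_ref && has_unf) {
    d_min_unf <- min(data$urea_M[data$branch == "unfolding"])
    n_low <- length(unique(data$urea_M[data$branch == "refolding" &
                                         data$urea_M < d_min_unf]))
    if (n_low < 3) {
      stop("Refolding observations must span >= 3 distinct denaturant ",
           "values below the unfolding range.", call. = FALSE)
    }
  }
  invisible(data)
}

# ---- parameterisation -----------------------------------------------------

# Full natural-scale parameter names for each scheme type.
chevron_param_names <- function(n_states, with_signals = TRUE) {
  kin <- if (n_states == 3L) {
    c("k_UI", "m_UI", "k_IU", "m_IU", "k_IN", "m_IN", "k_NI", "m_NI")
  } else {
    c("k_UN", "m_UN", "k_NU", "m_NU")
  }
  sig <- if (!with_signals) character(0) else if (n_states == 3L) {
    c("sig_U_int", "sig_U_slope", "sig_I_int", "sig_I_slope",
      "sig_N_int", "sig_N_slope")
  } else {
    c("sig_U_int", "sig_U_slope", "sig_N_int", "sig_N_slope")
  }
  c(kin, sig)
}

is_rate_param <- function(nm) startsWith(nm, "k_")
is_m_param <- function(nm) startsWith(nm, "m_")

to_internal <- function(nat) {
  out <- nat
  r <- is_rate_param(names(nat))
  out[r] <- log(nat[r])
  out
}

to_natural <- function(th) {
  out <- th
  r <- is_rate_param(names(th))
  out[r] <- exp(th[r])
  out
}

# Assemble a kinetic_scheme from a full natural-scale named vector.
params_to_scheme <- function(nat, n_states) {
  sig_states <- if (n_states == 3L) c("U", "I", "N") else c("U", "N")
  have_sig <- all(paste0("sig_", sig_states, "_int") %in% names(nat))
  sc <- if (have_sig) {
    tibble::tibble(
      state = sig_states,
      intercept = unname(nat[paste0("sig_", sig_states, "_int")]),
      slope = unname(nat[paste0("sig_", sig_states, "_slope")])
    )
  } else NULL
  if (n_states == 3L) {
    three_state_scheme(nat[["k_UI"]], nat[["m_UI"]], nat[["k_IU"]],
                       nat[["m_IU"]], nat[["k_IN"]], nat[["m_IN"]],
                       nat[["k_NI"]], nat[["m_NI"]], signal_coeffs = sc)
  } else {
    two_state_scheme(nat[["k_UN"]], nat[["m_UN"]], nat[["k_NU"]],
                     nat[["m_NU"]], signal_coeffs = sc)
  }
}

# Kinetic M_UN (sum of all kinetic m-value magnitudes) from natural params.
params_M_UN <- function(nat, n_states) {
  if (n_states == 3L) {
    nat[["m_UI"]] + nat[["m_IU"]] + nat[["m_IN"]] + nat[["m_NI"]]
  } else {
    nat[["m_UN"]] + nat[["m_NU"]]
  }
}

# ---- heuristic starts -----------------------------------------------------

start_three_state <- function(data, fixed) {
  ref <- data[data$branch == "refolding", ]
  unf <- data[data$branch == "unfolding", ]
  RT <- fold_conditions()$RT
  # unfolding limb at high D is dominated by k_NI(D)
  if (nrow(unf) >= 3) {
    hi <- unf[unf$urea_M >= stats::quantile(unf$urea_M, 0.4), ]
    f <- stats::lm(log(kobs_s1) ~ urea_M, data = hi)
    k_NI <- exp(unname(stats::coef(f)[1]))
    m_NI <- min(max(unname(stats::coef(f)[2]) * RT, 0.05), 2)
  } else {
    k_NI <- 1; m_NI <- 0.5
  }
  # low-denaturant refolding limb approximates k_IN(D) when K_UI >> 1
  lo <- ref[order(ref$urea_M), ][seq_len(min(5, nrow(ref))), ]
  f <- stats::lm(log(kobs_s1) ~ urea_M, data = lo)
  k_IN <- exp(unname(stats::coef(f)[1]))
  m_IN <- min(max(-unname(stats::coef(f)[2]) * RT, 0.05), 2)
  k_UI <- if ("k_UI" %in% names(fixed)) fixed$k_UI else 1500
  m_UI <- if ("m_UI" %in% names(fixed)) fixed$m_UI else 1.2
  c(k_UI = k_UI, m_UI = m_UI, k_IU = k_UI / 100, m_IU = max(4.2 - m_UI, 0.5),
    k_IN = max(k_IN, 1e-3), m_IN = m_IN, k_NI = max(k_NI, 1e-6), m_NI = m_NI)
}

start_two_state <- function(data, fixed) {
  RT <- fold_conditions()$RT
  ref <- data[data$branch == "refolding", ]
  unf <- data[data$branch == "unfolding", ]
  if (nrow(ref) >= 3) {
    lo <- ref[order(ref$urea_M), ][seq_len(min(5, nrow(ref))), ]
    f <- stats::lm(log(kobs_s1) ~ urea_M, data = lo)
    k_UN <- exp(unname(stats::coef(f)[1]))
    m_UN <- min(max(-unname(stats::coef(f)[2]) * RT, 0.05), 6)
  } else {
    k_UN <- 100; m_UN <- 3
  }
  if (nrow(unf) >= 3) {
    hi <- unf[unf$urea_M >= stats::quantile(unf$urea_M, 0.4), ]
    f <- stats::lm(log(kobs_s1) ~ urea_M, data = hi)
    k_NU <- exp(unname(stats::coef(f)[1]))
    m_NU <- min(max(unname(stats::coef(f)[2]) * RT, 0.05), 2)
  } else {
    k_NU <- 1; m_NU <- 0.5
  }
  c(k_UN = max(k_UN, 1e-3), m_UN = m_UN, k_NU = max(k_NU, 1e-6), m_NU = m_NU)
}

start_signals <- function(data, n_states) {
  fin <- data$final_fluor
  ini <- data$initial_fluor
  d <- data$urea_M
  u_lvl <- if (any(!is.na(fin) & d >= 6)) mean(fin[!is.na(fin) & d >= 6]) else 1
  n_lvl <- if (any(!is.na(fin) & d <= 2)) mean(fin[!is.na(fin) & d <= 2]) else 0.4
  out <- c(sig_U_int = u_lvl - 0.01 * 7, sig_U_slope = 0.01,
           sig_N_int = n_lvl, sig_N_slope = 0.01)
  if (n_states == 3L) {
    ref <- data$branch == "refolding" & !is.na(ini)
    i_lvl <- if (any(ref & d <= 2)) mean(ini[ref & d <= 2]) else 2
    out <- c(out, sig_I_int = i_lvl, sig_I_slope = -0.02)
  }
  out[chevron_param_names(n_states)[-(seq_len(2 * n_states))]]
}

# ---- core fitter ----------------------------------------------------------

fit_chevron_impl <- function(data, n_states, constraints, cond, weighting,
                             signal_sigma, n_starts, multistart_seed) {
  cond <- as_fold_conditions(cond)
  validate_chevron_data(data, require_both_branches = TRUE)
  if (!inherits(constraints, "fit_constraints")) {
    stop("`constraints` must be a fit_constraints object.", call. = FALSE)
  }
  weighting <- match.arg(weighting, c("variance", "equal"))

  for (col in c("kobs_sigma", "initial_fluor", "final_fluor")) {
    if (!col %in% names(data)) data[[col]] <- NA_real_
  }
  has_amp <- any(!is.na(data$initial_fluor)) || any(!is.na(data$final_fluor))
  if (!has_amp) {
    warning("No amplitude columns present; fitting rates only.",
            call. = FALSE)
  }

  p_names <- chevron_param_names(n_states, with_signals = has_amp)
  fixed <- constraints$fixed
  bad_fix <- setdiff(names(fixed), p_names)
  if (length(bad_fix)) {
    stop("Unknown fixed parameter(s): ", paste(bad_fix, collapse = ", "),
         call. = FALSE)
  }
  free_names <- setdiff(p_names, names(fixed))

  D <- data$urea_M
  ln_kobs <- log(data$kobs_s1)
  i_init <- which(!is.na(data$initial_fluor))
  i_fin <- which(!is.na(data$final_fluor))
  refold <- data$branch == "refolding"

  # per-point sigmas (NA where unknown -> filled by weighting scheme)
  sig_rate <- if (any(!is.na(data$kobs_sigma))) {
    data$kobs_sigma / data$kobs_s1 # sd of ln kobs for relative errors
  } else {
    rep(NA_real_, nrow(data))
  }
  sig_amp <- if (!is.null(signal_sigma)) signal_sigma else NA_real_

  # Fast numeric-only evaluation of the model blocks (identical maths to
  # observed_rate()/amplitude_model(), which unit tests cross-check; avoids
  # per-iteration object construction inside the optimiser).
  RT <- cond$RT
  model_blocks <- function(nat_full) {
    if (n_states == 3L) {
      kUI <- nat_full[["k_UI"]] * exp(-nat_full[["m_UI"]] * D / RT)
      kIU <- nat_full[["k_IU"]] * exp(nat_full[["m_IU"]] * D / RT)
      kIN <- nat_full[["k_IN"]] * exp(-nat_full[["m_IN"]] * D / RT)
      kNI <- nat_full[["k_NI"]] * exp(nat_full[["m_NI"]] * D / RT)
      s <- kUI + kIU + kIN + kNI
      p <- kUI * kIN + kUI * kNI + kIU * kNI
      lam <- 2 * p / (s + sqrt(pmax(s^2 - 4 * p, 0)))
      out <- list(ln_rate = log(lam))
      if (has_amp) {
        K_UI <- kUI / kIU
        K_IN <- kIN / kNI
        bU <- nat_full[["sig_U_int"]] + nat_full[["sig_U_slope"]] * D
        bI <- nat_full[["sig_I_int"]] + nat_full[["sig_I_slope"]] * D
        bN <- nat_full[["sig_N_int"]] + nat_full[["sig_N_slope"]] * D
        z <- 1 + K_UI + K_UI * K_IN
        fin <- (bU + K_UI * bI + K_UI * K_IN * bN) / z
        init_r <- (bU + K_UI * bI) / (1 + K_UI)
        out$init <- ifelse(refold, init_r, bN)
        out$fin <- fin
      }
    } else {
      kUN <- nat_full[["k_UN"]] * exp(-nat_full[["m_UN"]] * D / RT)
      kNU <- nat_full[["k_NU"]] * exp(nat_full[["m_NU"]] * D / RT)
      out <- list(ln_rate = log(kUN + kNU))
      if (has_amp) {
        K_UN <- kUN / kNU
        bU <- nat_full[["sig_U_int"]] + nat_full[["sig_U_slope"]] * D
        bN <- nat_full[["sig_N_int"]] + nat_full[["sig_N_slope"]] * D
        fin <- (bU + K_UN * bN) / (1 + K_UN)
        out$init <- ifelse(refold, bU, bN)
        out$fin <- fin
      }
    }
    out
  }

  make_resid <- function(w_rate, w_amp) {
    force(w_rate); force(w_amp)
    function(th) {
      nat <- to_natural(th)
      nat_full <- c(nat, unlist(fixed))[p_names]
      mb <- model_blocks(nat_full)
      r <- (ln_kobs - mb$ln_rate) / w_rate
      if (has_amp) {
        r <- c(r,
               (data$initial_fluor[i_init] - mb$init[i_init]) / w_amp,
               (data$final_fluor[i_fin] - mb$fin[i_fin]) / w_amp)
      }
      if (!is.null(constraints$M_UN_range)) {
        M <- params_M_UN(nat_full, n_states)
        lo <- constraints$M_UN_range[1]; hi <- constraints$M_UN_range[2]
        r <- c(r, 1e3 * max(0, lo - M, M - hi))
      }
      r
    }
  }

  # starts: heuristic first, then Latin-hypercube scatter on the log-rates
  nat_start <- if (n_states == 3L) start_three_state(data, fixed) else
    start_two_state(data, fixed)
  if (has_amp) nat_start <- c(nat_start, start_signals(data, n_states))
  nat_start <- nat_start[p_names]
  th0 <- to_internal(nat_start)[free_names]

  starts <- list(th0)
  rate_free <- free_names[is_rate_param(free_names)]
  if (n_starts > 1 && length(rate_free)) {
    H <- withr::with_seed(multistart_seed,
                          lhs::randomLHS(n_starts - 1, length(rate_free)))
    for (i in seq_len(nrow(H))) {
      thi <- th0
      thi[rate_free] <- th0[rate_free] + (H[i, ] - 0.5) * 2 * 2.3
      starts[[i + 1]] <- thi
    }
  }

  lower <- rep(-Inf, length(free_names)); upper <- rep(Inf, length(free_names))
  names(lower) <- names(upper) <- free_names
  lower[is_m_param(free_names)] <- 0
  for (nm in intersect(names(constraints$bounds), free_names)) {
    b <- constraints$bounds[[nm]]
    if (is_rate_param(nm)) b <- log(b)
    lower[nm] <- b[1]; upper[nm] <- b[2]
  }

  n_pen <- as.integer(!is.null(constraints$M_UN_range))

  # pass 1: per-point sigmas where known, unit weights elsewhere
  w_rate1 <- ifelse(is.na(sig_rate), 1, sig_rate)
  w_amp1 <- if (is.na(sig_amp)) 1 else sig_amp
  resid1 <- make_resid(w_rate1, w_amp1)
  best <- multistart_lm(resid1, starts, lower, upper)
  w_rate <- w_rate1; w_amp <- w_amp1

  if (weighting == "variance" && has_amp &&
      (all(is.na(sig_rate)) || is.na(sig_amp))) {
    # reweight blocks by their pass-1 residual RMS, then refit once
    nat <- to_natural(best$par)
    nat_full <- c(nat, unlist(fixed))[p_names]
    mb <- model_blocks(nat_full)
    rms_rate <- sqrt(mean((ln_kobs - mb$ln_rate)^2))
    rms_amp <- sqrt(mean(c(data$initial_fluor[i_init] - mb$init[i_init],
                           data$final_fluor[i_fin] - mb$fin[i_fin])^2))
    if (all(is.na(sig_rate))) w_rate <- rep(max(rms_rate, 1e-8), nrow(data))
    if (is.na(sig_amp)) w_amp <- max(rms_amp, 1e-8)
    resid2 <- make_resid(w_rate, w_amp)
    best <- multistart_lm(resid2, list(best$par), lower, upper)
    resid_fn <- resid2
  } else {
    resid_fn <- resid1
  }

  th_hat <- best$par
  J <- numeric_jacobian(resid_fn, th_hat)
  r_hat <- resid_fn(th_hat)
  if (n_pen) { # penalty row is a constraint, not data
    J <- J[seq_len(nrow(J) - 1), , drop = FALSE]
    r_hat_data <- r_hat[seq_len(length(r_hat) - 1)]
  } else {
    r_hat_data <- r_hat
  }
  cv <- gn_covariance(J, r_hat_data)

  nat_hat <- to_natural(th_hat)
  nat_full <- c(nat_hat, unlist(fixed))[p_names]
  scheme <- params_to_scheme(nat_full, n_states)

  # natural-scale standard errors (delta method for log-rate parameters)
  sd_int <- if (cv$identifiable) sqrt(pmax(diag(cv$cov), 0)) else
    rep(NA_real_, length(free_names))
  names(sd_int) <- free_names
  # a parameter whose internal-scale sigma exceeds 10 (a factor e^10 on a
  # rate) is practically unidentifiable even when J'J is formally invertible
  weak <- free_names[is.finite(sd_int) & sd_int > 10]
  if (length(weak)) {
    cv$unidentified <- union(cv$unidentified, weak)
    cv$identifiable <- FALSE
  }
  sd_nat <- sd_int
  sd_nat[is_rate_param(free_names)] <-
    nat_hat[is_rate_param(free_names)] * sd_int[is_rate_param(free_names)]

  at_bound <- (is.finite(lower) & th_hat - lower < 1e-6) |
    (is.finite(upper) & upper - th_hat < 1e-6)
  sd_map <- stats::setNames(rep(0, length(p_names)), p_names)
  sd_map[free_names] <- sd_nat[free_names]
  params <- tibble::tibble(
    term = p_names,
    estimate = unname(nat_full[p_names]),
    std_error = unname(sd_map),
    fixed = p_names %in% names(fixed),
    at_bound = p_names %in% free_names[at_bound]
  )

  # thermodynamic quantities with delta-method propagation through the fit
  thermo_fn <- function(th) {
    nat <- to_natural(th)
    full <- c(nat, unlist(fixed))[p_names]
    tsum <- thermo_summary(params_to_scheme(full, n_states), cond)
    unlist(tsum[, setdiff(names(tsum), "n_states")])
  }
  t_hat <- thermo_fn(th_hat)
  keep <- !is.na(t_hat)
  G <- numeric_jacobian(function(th) thermo_fn(th)[keep], th_hat)
  thermo_cov <- if (cv$identifiable) G %*% cv$cov %*% t(G) else
    matrix(NA_real_, sum(keep), sum(keep))
  dimnames(thermo_cov) <- list(names(t_hat)[keep], names(t_hat)[keep])
  thermo <- tibble::tibble(
    quantity = names(t_hat),
    value = unname(t_hat),
    std_error = NA_real_
  )
  thermo$std_error[keep] <- sqrt(pmax(diag(thermo_cov), 0))

  mb <- model_blocks(nat_full)
  res_blocks <- tibble::tibble(
    block = "ln_kobs",
    rms = sqrt(mean((ln_kobs - mb$ln_rate)^2)),
    n = length(ln_kobs)
  )
  if (has_amp) {
    res_blocks <- dplyr::bind_rows(res_blocks, tibble::tibble(
      block = c("initial_signal", "final_signal"),
      rms = c(sqrt(mean((data$initial_fluor[i_init] - mb$init[i_init])^2)),
              sqrt(mean((data$final_fluor[i_fin] - mb$fin[i_fin])^2))),
      n = c(length(i_init), length(i_fin))
    ))
  }

  structure(
    list(
      scheme = scheme,
      n_states = n_states,
      params = params,
      covariance = cv$cov, # internal scale (log rates), free parameters only
      identifiable = cv$identifiable,
      unidentified = cv$unidentified,
      thermo = thermo,
      thermo_cov = thermo_cov,
      residual_blocks = res_blocks,
      data = tibble::as_tibble(data),
      cond = cond,
      constraints = constraints,
      convergence = list(success = best$success,
                         iterations = best$iterations,
                         start_used = best$start_used,
                         n_starts = best$n_starts,
                         multistart_seed = multistart_seed,
                         bound_hit = any(at_bound))
    ),
    class = "chevron_fit"
  )
}

#' Fit a chevron and its amplitudes to the on-pathway three-state scheme
#'
#' Simultaneously fits observed slow-phase rate constants and (when present)
#' initial/endpoint fluorescence signals to the analytical slow relaxation
#' rate and amplitude model of U <-> I <-> N. Rate residuals are taken on
#' `ln kobs` (multiplicative noise; chevrons are analysed in log space),
#' amplitude residuals on the linear normalised scale; the two blocks are
#' weighted by per-point standard deviations when supplied (`kobs_sigma`
#' column, `signal_sigma` argument) and otherwise by their estimated
#' per-block residual variance. Rates are optimised in log space; m-values
#' are bounded below by zero. A Latin-hypercube multistart over the free
#' log-rates guards against local minima.
#'
#' @param data Chevron data frame with columns `urea_M`, `kobs_s1`, `branch`
#'   (`"refolding"`/`"unfolding"`) and optionally `kobs_sigma`,
#'   `initial_fluor`, `final_fluor`.
#' @param constraints A [fit_constraints()]; by default the burst-phase
#'   U -> I step is fixed at `k_UI = 1574 s^-1`, `m_UI = 1.23 kJ mol^-1 M^-1`
#'   and the intermediate's stability is determined by letting `k_IU` float.
#' @param cond A [fold_conditions()].
#' @param weighting `"variance"` (default: blocks weighted by estimated
#'   residual variance when per-point sigmas are absent) or `"equal"`.
#' @param signal_sigma Optional known standard deviation of the normalised
#'   fluorescence signals.
#' @param n_starts Total number of optimiser starts (heuristic start plus
#'   `n_starts - 1` Latin-hypercube perturbations of the log-rates).
#' @param multistart_seed Seed for the Latin-hypercube start design.
#' @return A `chevron_fit` object: fitted [kinetic_scheme()], a `params`
#'   tibble (estimate, 1-sigma standard error, fixed/bound flags), the free-
#'   parameter covariance (log scale for rates), a `thermo` tibble with
#'   propagated errors, per-block residual RMS, and convergence metadata.
#'   Supports [tidy()], [glance()] and [ggplot2::autoplot()].
#' @examples
#' \donttest{
#' sc <- scenario_scheme("Im7")
#' dat <- generate_chevron(sc, noise = noise_model(0, 0, seed = 1))
#' fit <- fit_chevron_three_state(dat)
#' fit$thermo
#' }
#' @export
fit_chevron_three_state <- function(data,
                                    constraints = fit_constraints(
                                      fixed = list(k_UI = 1574, m_UI = 1.23)),
                                    cond = fold_conditions(),
                                    weighting = c("variance", "equal"),
                                    signal_sigma = NULL,
                                    n_starts = 10,
                                    multistart_seed = 1L) {
  fit_chevron_impl(data, 3L, constraints, cond, match.arg(weighting),
                   signal_sigma, n_starts, multistart_seed)
}

#' Fit a chevron to the two-state scheme
#'
#' As [fit_chevron_three_state()] but for a linear (rollover-free) chevron:
#' free parameters `k_UN`, `m_UN`, `k_NU`, `m_NU` plus the U/N signal
#' baselines; `dG_UN` and `M_UN` are derived in the `thermo` table.
#'
#' @inheritParams fit_chevron_three_state
#' @return A `chevron_fit` object (see [fit_chevron_three_state()]).
#' @export
fit_chevron_two_state <- function(data,
                                  constraints = fit_constraints(),
                                  cond = fold_conditions(),
                                  weighting = c("variance", "equal"),
                                  signal_sigma = NULL,
                                  n_starts = 10,
                                  multistart_seed = 1L) {
  fit_chevron_impl(data, 2L, constraints, cond, match.arg(weighting),
                   signal_sigma, n_starts, multistart_seed)
}

#' @export
print.chevron_fit <- function(x, ...) {
  cat(sprintf("<chevron_fit> %d-state, %s (%d iterations, start %d/%d)\n",
              x$n_states,
              if (x$convergence$success) "converged" else "NOT converged",
              x$convergence$iterations, x$convergence$start_used,
              x$convergence$n_starts))
  print(x$params, n = nrow(x$params))
  cat("Thermodynamics:\n")
  print(x$thermo, n = nrow(x$thermo))
  invisible(x)
}
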