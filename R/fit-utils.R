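# Shared nonlinear least-squares plumbing: numerical Jacobians, Gauss-Newton
# covariance, and multistart bookkeeping around minpack.lm::nls.lm.

# Forward-difference Jacobian of a residual function at th (named vector).
numeric_jacobian <- function(resid_fn, th, eps = 1e-6) {
  r0 <- resid_fn(th)
  J <- matrix(0, length(r0), length(th),
              dimnames = list(NULL, names(th)))
  for (j in seq_along(th)) {
    h <- eps * max(abs(th[j]), 1)
    thj <- th
    thj[j] <- thj[j] + h
    J[, j] <- (resid_fn(thj) - r0) / h
  }
  J
}

# Gauss-Newton covariance s^2 (J'J)^-1 from weighted residuals at the
# optimum. Detects (near-)singular J'J via SVD; parameters loading on the
# null space are reported as unidentifiable and the covariance is NA.
gn_covariance <- function(J, resid, n_extra_constraints = 0L) {
  n <- length(resid) - n_extra_constraints
  p <- ncol(J)
  dof <- max(n - p, 1L)
  s2 <- sum(resid^2) / dof
  sv <- svd(crossprod(J))
  tol <- max(sv$d) * 1e-10
  bad <- sv$d < tol
  if (any(bad)) {
    load <- abs(sv$v[, bad, drop = FALSE])
    unident <- colnames(J)[apply(load, 1, max) > 0.3]
    cov <- matrix(NA_real_, p, p, dimnames = list(colnames(J), colnames(J)))
    return(list(cov = cov, s2 = s2, identifiable = FALSE,
                unidentified = unident))
  }
  inv <- sv$v %*% diag(1 / sv$d, p) %*% t(sv$u)
  cov <- s2 * (inv + t(inv)) / 2
  dimnames(cov) <- list(colnames(J), colnames(J))
  list(cov = cov, s2 = s2, identifiable = TRUE, unidentified = character(0))
}

# One nls.lm run; returns par, deviance and convergence info.
run_lm <- function(resid_fn, start, lower = NULL, upper = NULL,
                   maxiter = 200) {
  ctrl <- minpack.lm::nls.lm.control(maxiter = maxiter, ftol = 1e-13,
                                     ptol = 1e-13)
  fit <- tryCatch(
    minpack.lm::nls.lm(par = start, fn = resid_fn, lower = lower,
                       upper = upper, control = ctrl),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    return(list(par = start, deviance = Inf, success = FALSE,
                iterations = 0L, message = "nls.lm error"))
  }
  list(par = structure(fit$par, names = names(start)),
       deviance = fit$deviance,
       success = fit$info %in% 1:4,
       iterations = fit$niter,
       message = fit$message)
}

# Multistart driver: heuristic start first, then optional extra starts.
# Keeps the best converged solution (lowest deviance).
multistart_lm <- function(resid_fn, starts, lower = NULL, upper = NULL) {
  better <- function(a, b) {
    if (is.null(b)) return(TRUE)
    if (a$success != b$success) return(a$success)
    a$deviance < b$deviance
  }
  best <- NULL
  for (i in seq_along(starts)) {
    res <- run_lm(resid_fn, starts[[i]], lower, upper)
    if (better(res, best)) {
      res$start_used <- i
      best <- res
    }
  }
  best$n_starts <- length(starts)
  best
}
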