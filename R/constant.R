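#' Epidemiological equilibrium and selection analysis, constant influx
#'
#' Locates the endemic equilibrium of the resident system under a constant
#' influx of susceptible cells and performs the selection analysis there:
#' at the equilibrium the resident class abundances `(L, Lstar, V)` are a
#' null vector of the projection matrix `M`, class frequencies are the
#' normalised right null vector, reproductive values the left null vector
#' (normalised so `v . f = 1`), and the per-capita viral growth rate is
#' zero. Also returns the equilibrium identity linking the direction of
#' selection on reactivation to the influx: the sign of the averaged
#' gradient on `alpha` equals the sign of `theta0 - a * Vhat * Shat`.
#'
#' @param params A `phage_params` object.
#' @param theta0 Constant influx (cells ml^-1 h^-1).
#' @param strategy A `phage_strategy`.
#' @param tol Relative fixed-point tolerance.
#' @param max_chunks Cap on the number of relaxation chunks.
#' @return A list with `state` (equilibrium densities), `M` (3x3 matrix),
#'   `f`, `v` (named class frequency / reproductive-value vectors), `rw`
#'   (dominant eigenvalue of `M`, ~0), `S_alpha`, `S_phi` (averaged
#'   gradients), `identity_lhs` = `r (1 - kappa * Nhat) - dL`,
#'   `identity_rhs` = `a * Vhat - theta0 / Shat`, and
#'   `selection_sign_driver` = `theta0 - a * Vhat * Shat`.
#' @export
equilibrium_constant <- function(params, theta0, strategy, tol = 1e-10,
                                 max_chunks = 400L) {
  forcing <- forcing_constant(theta0)
  att <- find_attractor(params, forcing, strategy, max_periods = max_chunks,
                        tol = tol)
  if (!att$converged)
    stop("no convergence to a fixed point (metric = ",
         format(att$metric), ")", call. = FALSE)
  y <- att$states[1L, ]
  M <- mutant_matrix(y, params, strategy)
  ev <- eigen(M)
  i1 <- which.max(Re(ev$values))
  rw <- Re(ev$values[i1])
  f <- Re(ev$vectors[, i1])
  if (sum(f) < 0) f <- -f
  f <- f / sum(f)
  evl <- eigen(t(M))
  j1 <- which.max(Re(evl$values))
  v <- Re(evl$vectors[, j1])
  if (sum(v) < 0) v <- -v
  v <- v / sum(v * f)
  names(f) <- c("fL", "fLstar", "fV")
  names(v) <- c("vL", "vLstar", "vV")
  N <- sum(y[c("S", "Sstar", "L", "Lstar")])
  dL_gap <- params$B * v[["vV"]] - v[["vL"]]
  list(state = y, M = M, f = f, v = v, rw = rw,
       S_alpha = dL_gap * f[["fL"]],
       S_phi = -dL_gap * params$a * y[["S"]] * f[["fV"]],
       identity_lhs = params$r * (1 - params$kappa * N) - params$dL,
       identity_rhs = params$a * y[["V"]] - theta0 / y[["S"]],
       selection_sign_driver = theta0 - params$a * y[["V"]] * y[["S"]])
}

#' Sampled ESS curve in a constant environment
#'
#' In a constant environment the averaged selection gradients on
#' reactivation and lysogenisation are proportional with opposite signs,
#' so the evolutionarily singular strategies form a one-dimensional set:
#' every pair `(alpha, phi)` at which the equilibrium reproductive values
#' satisfy `vL - B vV = 0` is singular. For each reactivation rate in
#' `alphas` this samples the curve by root-finding the lysogenisation
#' probability that annuls `B vV - vL` at the corresponding endemic
#' equilibrium.
#'
#' @param params A `phage_params` object.
#' @param theta0 Constant influx.
#' @param alphas Reactivation rates at which to sample the curve.
#' @param phi_range Search interval for the lysogenisation probability.
#' @return A data frame with columns `alpha`, `phi` (NA where no root lies
#'   in `phi_range`) and `residual` (`B vV - vL` at the solution).
#' @export
ess_curve_constant <- function(params = model_params(), theta0 = 50,
                               alphas = c(0.005, 0.01, 0.02, 0.05, 0.1),
                               phi_range = c(0.01, 0.99)) {
  resid <- function(alpha, phi) {
    eq <- equilibrium_constant(params, theta0,
                               strategy_fixed(phi = phi, alpha = alpha))
    params$B * eq$v[["vV"]] - eq$v[["vL"]]
  }
  rows <- lapply(alphas, function(al) {
    r_lo <- tryCatch(resid(al, phi_range[1L]), error = function(e) NA_real_)
    r_hi <- tryCatch(resid(al, phi_range[2L]), error = function(e) NA_real_)
    if (is.na(r_lo) || is.na(r_hi) || r_lo * r_hi > 0)
      return(data.frame(alpha = al, phi = NA_real_, residual = NA_real_))
    root <- stats::uniroot(function(p) resid(al, p), phi_range,
                           tol = 1e-9)
    data.frame(alpha = al, phi = root$root,
               residual = resid(al, root$root))
  })
  do.call(rbind, rows)
}

#' Parameter sweep of the attractor and the selection pattern
#'
#' Re-runs the resident attractor and selection profile for each value of
#' one model parameter and summarises whether the qualitative pattern that
#' drives the evolution of arbitrium plasticity persists: a negative
#' covariance, over the period, between the selection-for-lysis signal
#' `B vV(t) - vL(t)` and the arbitrium concentration `A(t)`. Viral
#' extinction at a parameter value is reported in the table rather than
#' raised as an error.
#'
#' @param params Base `phage_params`.
#' @param forcing A `phage_forcing`.
#' @param strategy The resident `phage_strategy`.
#' @param parameter Name of the swept parameter (a field of
#'   [model_params()]).
#' @param values Numeric vector of parameter values.
#' @param n_points Attractor grid points per period.
#' @param ... Passed to [find_attractor()].
#' @return A data frame with one row per value: `value`, `converged`,
#'   `virus_persists`, `cov_lysis_arbitrium`, `negative_covariance`,
#'   `V_min`, `V_max`, `A_mean`.
#' @export
parameter_sweep <- function(params, forcing, strategy, parameter, values,
                            n_points = 1001L, ...) {
  stopifnot(inherits(params, "phage_params"))
  if (!parameter %in% names(params))
    stop("'parameter' must be one of: ",
         paste(names(params), collapse = ", "), call. = FALSE)
  rows <- lapply(values, function(val) {
    p2 <- unclass(params); p2[[parameter]] <- val
    p2 <- do.call(model_params, p2)
    out <- data.frame(value = val, converged = FALSE,
                      virus_persists = FALSE,
                      cov_lysis_arbitrium = NA_real_,
                      negative_covariance = NA,
                      V_min = NA_real_, V_max = NA_real_,
                      A_mean = NA_real_)
    att <- tryCatch(find_attractor(p2, forcing, strategy,
                                   n_points = n_points, ...),
                    error = function(e) NULL)
    if (is.null(att)) return(out)
    out$converged <- att$converged
    out$V_min <- min(att$states[, "V"])
    out$V_max <- max(att$states[, "V"])
    out$A_mean <- trapezoid_mean(att$states[, "A"], att$times)
    out$virus_persists <- out$V_max > 1e-6 && max(att$states[, "L"]) > 1e-6
    if (!out$virus_persists || !att$converged) return(out)
    prof <- tryCatch(selection_profile(att), error = function(e) NULL)
    if (is.null(prof)) return(out)
    s <- prof$series
    lysis_signal <- p2$B * s$vV - s$vL
    A <- att$states[, "A"]
    w_mean <- function(x) trapezoid_mean(x, att$times)
    covar <- w_mean((lysis_signal - w_mean(lysis_signal)) * (A - w_mean(A)))
    out$cov_lysis_arbitrium <- covar
    out$negative_covariance <- covar < 0
    out
  })
  do.call(rbind, rows)
}
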