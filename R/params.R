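#' Model parameters for the host-phage-arbitrium system
#'
#' Constructs the full parameter set of the epidemiological model of a
#' well-mixed bacterial population infected by a temperate phage whose
#' lysis/lysogeny decisions may respond to host stress (SOS state) and to
#' the concentration of the arbitrium peptide. Defaults are the values used
#' throughout the reference simulations.
#'
#' @param r Replication rate of unstressed cells (h^-1).
#' @param kappa Density-dependence coefficient (ml cells^-1); the per-capita
#'   birth rate is `r * (1 - kappa * N)` with `N` the total cell density.
#' @param a Adsorption rate of virions to cells (ml virus^-1 h^-1).
#' @param sigma Intensity of stress (h^-1): rate at which cells switch to
#'   the stressed (SOS-induced) state in which they cannot reproduce.
#' @param gamma Recovery rate from the stressed state (h^-1).
#' @param dS,dL,dSstar,dLstar Death rates of normal susceptible, normal
#'   lysogenic, stressed susceptible and stressed lysogenic cells (h^-1).
#' @param B Burst size: virions released when a cell lyses.
#' @param dV Death rate of free virions (h^-1).
#' @param piV,piL Arbitrium production rates during lytic infection and
#'   during lysogeny (h^-1).
#' @param dA Environmental degradation rate of arbitrium (h^-1).
#' @param delta Degradation rate of arbitrium by bacterial cells
#'   (per cell density unit, h^-1).
#' @param k Slope of the smoothed Heaviside function used by plastic
#'   reaction norms (dimensionless).
#'
#' @return An object of class `phage_params` (a named list).
#' @seealso [forcing_square()], [strategy_fixed()], [find_attractor()]
#' @examples
#' p <- model_params()
#' p$B
#' model_params(sigma = 0.1)$sigma
#' @export
model_params <- function(r = 1, kappa = 1e-3, a = 1e-4, sigma = 0,
                         gamma = 0.1, dS = 0.1, dL = 0.1, dSstar = 0.1,
                         dLstar = 0.1, B = 10, dV = 0.1, piV = 1, piL = 1,
                         dA = 0, delta = 10, k = 10) {
  p <- list(r = r, kappa = kappa, a = a, sigma = sigma, gamma = gamma,
            dS = dS, dL = dL, dSstar = dSstar, dLstar = dLstar, B = B,
            dV = dV, piV = piV, piL = piL, dA = dA, delta = delta, k = k)
  for (nm in names(p)) {
    val <- p[[nm]]
    if (!is.numeric(val) || length(val) != 1L || !is.finite(val))
      stop("parameter '", nm, "' must be a single finite number",
           call. = FALSE)
    if (val < 0)
      stop("parameter '", nm, "' must be non-negative", call. = FALSE)
  }
  if (p$B < 1) stop("parameter 'B' must be >= 1", call. = FALSE)
  if (p$k <= 0) stop("parameter 'k' must be > 0", call. = FALSE)
  structure(p, class = "phage_params")
}

#' @export
print.phage_params <- function(x, ...) {
  cat("Host-phage-arbitrium model parameters:\n")
  print(unlist(x))
  invisible(x)
}

#' Environmental forcing: constant influx of susceptible cells
#'
#' @param theta0 Constant influx of susceptible cells (cells ml^-1 h^-1).
#' @return A `phage_forcing` object with `mode = "constant"`.
#' @seealso [forcing_square()], [influx()]
#' @export
forcing_constant <- function(theta0 = 50) {
  if (!is.numeric(theta0) || length(theta0) != 1L || theta0 < 0)
    stop("'theta0' must be a single non-negative number", call. = FALSE)
  structure(list(mode = "constant", theta0 = theta0),
            class = "phage_forcing")
}

#' Environmental forcing: square-wave influx of susceptible cells
#'
#' The influx equals `thetaMax` while the fractional phase `(t mod T)/T`
#' lies in `[0, g)` and 0 for the rest of the period, so the period mean is
#' `g * thetaMax` (50 cells ml^-1 h^-1 at the defaults).
#'
#' @param thetaMax Peak influx (cells ml^-1 h^-1).
#' @param g Duty fraction of the period with influx on, in (0, 1].
#' @param T Forcing period (h).
#' @return A `phage_forcing` object with `mode = "square_wave"`.
#' @seealso [influx()], [forcing_breaks()]
#' @export
forcing_square <- function(thetaMax = 250, g = 0.2, T = 40) {
  if (!is.numeric(thetaMax) || length(thetaMax) != 1L || thetaMax < 0)
    stop("'thetaMax' must be a single non-negative number", call. = FALSE)
  if (!is.numeric(g) || length(g) != 1L || g <= 0 || g > 1)
    stop("'g' must be a single number in (0, 1]", call. = FALSE)
  if (!is.numeric(T) || length(T) != 1L || T <= 0)
    stop("'T' must be a single positive number", call. = FALSE)
  structure(list(mode = "square_wave", thetaMax = thetaMax, g = g, T = T),
            class = "phage_forcing")
}

#' @export
print.phage_forcing <- function(x, ...) {
  if (x$mode == "constant") {
    cat("Constant influx: theta0 =", x$theta0, "cells/ml/h\n")
  } else {
    cat("Square-wave influx: thetaMax =", x$thetaMax, ", duty g =", x$g,
        ", period T =", x$T, "h (mean", x$g * x$thetaMax, ")\n")
  }
  invisible(x)
}

#' Influx of susceptible cells at a given time
#'
#' @param t Time(s), non-negative (h).
#' @param forcing A `phage_forcing` object.
#' @return Influx rate(s) (cells ml^-1 h^-1), vectorised over `t`.
#' @examples
#' influx(0, forcing_square())   # 250
#' influx(20, forcing_square())  # 0 (phase 0.5 >= duty 0.2)
#' @export
influx <- function(t, forcing) {
  stopifnot(inherits(forcing, "phage_forcing"))
  if (any(t < 0)) stop("'t' must be non-negative", call. = FALSE)
  if (forcing$mode == "constant") {
    rep(forcing$theta0, length(t))
  } else {
    phase <- (t %% forcing$T) / forcing$T
    ifelse(phase < forcing$g, forcing$thetaMax, 0)
  }
}

#' Discontinuity times of the forcing within an interval
#'
#' Returns the times in `[from, to]` at which the square-wave influx jumps
#' (phase 0 and phase `g` of every period), so that integrators can be
#' restarted there instead of stepping across a discontinuity.
#'
#' @param forcing A `phage_forcing` object.
#' @param from,to Interval bounds (h), `from < to`.
#' @return A sorted numeric vector of interior discontinuity times (empty
#'   for constant forcing).
#' @export
forcing_breaks <- function(forcing, from, to) {
  stopifnot(inherits(forcing, "phage_forcing"), from < to)
  if (forcing$mode == "constant") return(numeric(0))
  T <- forcing$T
  kk <- seq(floor(from / T) - 1, ceiling(to / T) + 1)
  br <- sort(c(kk * T, kk * T + forcing$g * T))
  br[br > from & br < to]
}
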