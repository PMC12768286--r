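STATE_NAMES <- c("S", "Sstar", "L", "Lstar", "V", "A")

# Pack parameters + strategy into the flat vector read by the C kernels.
parms_vector <- function(params, theta, strategy, mode = 0) {
  s <- strategy
  if (s$kind == "fixed") {
    v <- c(unlist(params, use.names = FALSE), theta, 0,
           s$phi, s$phiStar, s$alpha, s$alphaStar,
           0, 0, 0, 0, 1, 1, 1, 1, mode)
  } else {
    thr <- function(x) if (is.na(x)) 1 else x
    v <- c(unlist(params, use.names = FALSE), theta, 1,
           0, 0, 0, 0,
           s$alphaMax, s$phiMax, s$alphaMaxStar, s$phiMaxStar,
           thr(s$Aalpha), thr(s$Aphi), thr(s$AalphaStar), thr(s$AphiStar),
           mode)
  }
  v
}

#' Time derivatives of the resident system
#'
#' Pure-R reference implementation of the resident dynamics: susceptible
#' and lysogenic cells in normal and stressed states, free virions, and
#' the arbitrium concentration. Cell birth applies only to unstressed
#' classes; stress moves cells to the starred classes at rate `sigma` and
#' recovery returns them at rate `gamma`; adsorption of virions to
#' susceptible cells yields lysogeny with probability `phi` (normal) or
#' `phiStar` (stressed) and otherwise an immediate burst of `B` virions;
#' prophage reactivation at rates `alpha`, `alphaStar` also releases `B`
#' virions. Arbitrium is produced during lytic infection (rate `piV` per
#' adsorption) and by lysogens (rate `piL`) and degrades at rate
#' `dA + delta * N`.
#'
#' @param state Named non-negative vector with components `S`, `Sstar`,
#'   `L`, `Lstar`, `V`, `A`.
#' @param t Time (h).
#' @param params A `phage_params` object.
#' @param forcing A `phage_forcing` object.
#' @param strategy A `phage_strategy` object, evaluated at `state["A"]`.
#' @return Named vector of the six time derivatives.
#' @export
resident_rhs <- function(state, t, params, forcing, strategy) {
  state <- state[STATE_NAMES]
  if (any(is.na(state)))
    stop("'state' must contain S, Sstar, L, Lstar, V, A", call. = FALSE)
  if (any(state < 0))
    stop("'state' components must be non-negative", call. = FALSE)
  S <- state[["S"]]; Ss <- state[["Sstar"]]
  L <- state[["L"]]; Ls <- state[["Lstar"]]
  V <- state[["V"]]; A <- state[["A"]]
  N <- S + Ss + L + Ls
  tr <- evaluate_strategy(strategy, A, k = params$k)
  theta <- influx(t, forcing)
  grow <- params$r * (1 - params$kappa * N)
  with(params, {
    d <- c(
      S = theta + grow * S - (a * V + dS + sigma) * S + gamma * Ss,
      Sstar = sigma * S - (a * V + dSstar + gamma) * Ss,
      L = grow * L + a * tr$phi * V * S - (tr$alpha + dL + sigma) * L +
        gamma * Ls,
      Lstar = sigma * L + a * tr$phiStar * V * Ss -
        (tr$alphaStar + dLstar + gamma) * Ls,
      V = a * B * V * ((1 - tr$phi) * S + (1 - tr$phiStar) * Ss) +
        (tr$alpha * L + tr$alphaStar * Ls) * B - (a * N + dV) * V,
      A = piV * a * V * (S + Ss) + piL * (L + Ls) - (dA + delta * N) * A
    )
    d
  })
}

# Compiled ODE call with a BDF fallback: lsoda occasionally exhausts its
# step budget on the fast arbitrium relaxation; the stiff solver does not.
ode_call <- function(y, times, func, parms, initfunc, rtol, atol,
                     forcings = NULL, initforc = NULL) {
  out <- suppressWarnings(deSolve::lsoda(
    y = y, times = times, func = func, parms = parms,
    dllname = "lysogeny", initfunc = initfunc, forcings = forcings,
    initforc = initforc, rtol = rtol, atol = atol, maxsteps = 100000))
  if (attr(out, "istate")[1L] < 0)
    out <- deSolve::ode(
      y = y, times = times, func = func, parms = parms, method = "bdf",
      dllname = "lysogeny", initfunc = initfunc, forcings = forcings,
      initforc = initforc, rtol = rtol, atol = min(atol, 1e-12),
      maxsteps = 1000000)
  out
}

# One compiled solver call over [t0, t1] with constant influx theta.
# times = NULL returns the end state only.
solve_segment <- function(y0, t0, t1, theta, params, strategy,
                          rtol, atol, times = NULL) {
  tt <- if (is.null(times)) c(t0, t1) else times
  out <- ode_call(y0, tt, "lys_resident_derivs",
                  parms_vector(params, theta, strategy),
                  "lys_resident_init", rtol, atol)
  if (attr(out, "istate")[1L] < 0)
    stop("ODE integration failed on [", t0, ", ", t1, "]", call. = FALSE)
  out
}

clip_negatives <- function(m, floor = -1e-6) {
  vals <- m[, STATE_NAMES, drop = FALSE]
  if (any(vals < floor))
    stop("state became negative beyond tolerance (min = ",
         format(min(vals)), ")", call. = FALSE)
  vals[vals < 0] <- 0
  m[, STATE_NAMES] <- vals
  m
}

#' Integrate the resident system over a time interval
#'
#' Solves the resident initial-value problem with a stiff-capable
#' integrator, restarting at every discontinuity of the square-wave
#' forcing. Densities that undershoot zero by less than a small tolerance
#' are clipped to zero; larger negativity raises an error.
#'
#' @param y0 Named initial state (`S`, `Sstar`, `L`, `Lstar`, `V`, `A`).
#' @param from,to Time interval (h), `from < to`.
#' @param params,forcing,strategy Model configuration objects.
#' @param times Optional strictly increasing output times in
#'   `[from, to]`; defaults to 201 equally spaced points.
#' @param rtol,atol Relative and absolute integration tolerances.
#' @return A data frame with columns `time`, the six state variables and
#'   `theta` (the influx), of class `phage_trajectory`.
#' @examples
#' y0 <- c(S = 500, Sstar = 0, L = 1, Lstar = 0, V = 1, A = 0)
#' tr <- integrate_resident(y0, 0, 40, model_params(), forcing_square(),
#'                          strategy_fixed(phi = 0.3, alpha = 0.02))
#' head(tr)
#' @export
integrate_resident <- function(y0, from, to, params, forcing, strategy,
                               times = NULL, rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(params, "phage_params"),
            inherits(forcing, "phage_forcing"),
            inherits(strategy, "phage_strategy"))
  if (!(from < to)) stop("'from' must be < 'to'", call. = FALSE)
  y0 <- y0[STATE_NAMES]
  if (any(is.na(y0)) || any(y0 < 0))
    stop("'y0' must be a non-negative state vector", call. = FALSE)
  if (is.null(times)) times <- seq(from, to, length.out = 201L)
  breaks <- forcing_breaks(forcing, from, to)
  edges <- c(from, breaks, to)
  rows <- vector("list", length(edges) - 1L)
  y <- y0
  for (i in seq_len(length(edges) - 1L)) {
    t0 <- edges[i]; t1 <- edges[i + 1L]
    inner <- times[times > t0 & times < t1]
    tt <- unique(c(t0, inner, t1))
    theta <- influx((t0 + t1) / 2, forcing)
    out <- solve_segment(y, t0, t1, theta, params, strategy, rtol, atol,
                         times = tt)
    out <- clip_negatives(out)
    y <- out[nrow(out), STATE_NAMES]
    keep <- out[, "time"] %in% times
    if (i > 1L) keep[1L] <- FALSE  # segment start duplicates previous end
    rows[[i]] <- out[keep, , drop = FALSE]
  }
  m <- do.call(rbind, rows)
  df <- as.data.frame(m)
  names(df)[1L] <- "time"
  df$theta <- influx(df$time, forcing)
  class(df) <- c("phage_trajectory", "data.frame")
  df
}

default_initial_state <- function(params, forcing) {
  theta_mean <- if (forcing$mode == "constant") forcing$theta0
                else forcing$g * forcing$thetaMax
  c(S = theta_mean / max(params$dS, 1e-6), Sstar = 0, L = 1, Lstar = 0,
    V = 1, A = 0)
}

# Advance the state by exactly one forcing period (square wave), restarting
# at the intra-period discontinuity. t0 is a multiple of the period.
advance_one_period <- function(y, t0, params, forcing, strategy, rtol, atol) {
  T <- forcing$T; gT <- forcing$g * forcing$T
  out1 <- solve_segment(y, t0, t0 + gT, forcing$thetaMax, params, strategy,
                        rtol, atol)
  y1 <- clip_negatives(out1)[nrow(out1), STATE_NAMES]
  out2 <- solve_segment(y1, t0 + gT, t0 + T, 0, params, strategy, rtol, atol)
  clip_negatives(out2)[nrow(out2), STATE_NAMES]
}

#' Locate the periodic attractor of the resident system
#'
#' Iterates the period map of the square-wave-forced resident system from
#' an interior initial condition until the state at period boundaries
#' stops changing (max relative change below `tol`), then samples one
#' period densely. Under constant forcing the orbit degenerates to a fixed
#' point, located by integrating in long chunks until stationary, and the
#' returned "period" is a sampling window over which all states are equal.
#'
#' @param params,forcing,strategy Model configuration objects.
#' @param y0 Optional initial state; defaults to susceptible cells at
#'   their influx/death balance with a small viral inoculum.
#' @param max_periods Cap on burn-in periods (or chunks when constant).
#' @param tol Relative tolerance of the period map.
#' @param n_points Number of grid points over the sampled period.
#' @param rtol,atol Integration tolerances.
#' @return A `phage_attractor` object: list with `times` (grid over one
#'   period starting at forcing phase 0), `states` (matrix, one row per
#'   grid time), `period`, `converged`, `metric` (last period-map change),
#'   `periods_used`, and the configuration objects.
#' @examples
#' \donttest{
#' att <- find_attractor(model_params(), forcing_square(),
#'                       strategy_fixed(phi = 0.325, alpha = 0.0197))
#' att$converged
#' }
#' @export
find_attractor <- function(params, forcing, strategy, y0 = NULL,
                           max_periods = 200L, tol = 1e-6,
                           n_points = 2001L, rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(params, "phage_params"),
            inherits(forcing, "phage_forcing"),
            inherits(strategy, "phage_strategy"))
  if (is.null(y0)) y0 <- default_initial_state(params, forcing)
  y0 <- y0[STATE_NAMES]

  if (forcing$mode == "constant") {
    chunk <- 50
    y <- y0; metric <- Inf; used <- 0L
    for (i in seq_len(max_periods)) {
      out <- solve_segment(y, 0, chunk, forcing$theta0, params, strategy,
                           rtol, atol)
      ynew <- clip_negatives(out)[nrow(out), STATE_NAMES]
      metric <- max(abs(ynew - y) / pmax(abs(y), 1e-8))
      y <- ynew; used <- i
      if (metric < tol) break
    }
    T <- 1
    times <- seq(0, T, length.out = n_points)
    states <- matrix(rep(y, each = n_points), nrow = n_points,
                     dimnames = list(NULL, STATE_NAMES))
  } else {
    T <- forcing$T
    y <- y0; metric <- Inf; used <- 0L
    for (i in seq_len(max_periods)) {
      ynew <- advance_one_period(y, 0, params, forcing, strategy, rtol, atol)
      metric <- max(abs(ynew - y) / pmax(abs(y), 1e-8))
      y <- ynew; used <- i
      if (metric < tol) break
    }
    gT <- forcing$g * T
    times <- seq(0, T, length.out = n_points)
    t_on <- unique(c(times[times <= gT], gT))
    t_off <- unique(c(gT, times[times >= gT]))
    out1 <- solve_segment(y, 0, gT, forcing$thetaMax, params, strategy,
                          rtol, atol, times = t_on)
    out1 <- clip_negatives(out1)
    y_mid <- out1[nrow(out1), STATE_NAMES]
    out2 <- solve_segment(y_mid, gT, T, 0, params, strategy, rtol, atol,
                          times = t_off)
    out2 <- clip_negatives(out2)
    m <- rbind(out1[out1[, "time"] %in% times, , drop = FALSE],
               out2[out2[, "time"] %in% times, , drop = FALSE])
    m <- m[!duplicated(m[, "time"]), , drop = FALSE]
    states <- m[, STATE_NAMES, drop = FALSE]
    times <- m[, "time"]
    rownames(states) <- NULL
  }

  structure(list(times = times, states = states, period = T,
                 converged = metric < tol, metric = metric,
                 periods_used = used, params = params, forcing = forcing,
                 strategy = strategy, rtol = rtol, atol = atol),
            class = "phage_attractor")
}

#' @export
print.phage_attractor <- function(x, ...) {
  cat(sprintf(
    "Periodic attractor (%s forcing): period %.4g h, %d grid points\n",
    x$forcing$mode, x$period, length(x$times)))
  cat(sprintf("  converged: %s after %d periods (metric %.3g)\n",
              x$converged, x$periods_used, x$metric))
  rng <- apply(x$states, 2, range)
  cat("  state ranges:\n")
  for (nm in colnames(rng))
    cat(sprintf("    %-6s [%.4g, %.4g]\n", nm, rng[1, nm], rng[2, nm]))
  invisible(x)
}

#' Export a trajectory or attractor to CSV
#'
#' Writes the time grid and state columns (plus the influx `theta`) to a
#' headered CSV file; for attractors a JSON sidecar `<file>.json` records
#' the period and convergence metadata.
#'
#' @param x A `phage_trajectory` or `phage_attractor`.
#' @param file Output CSV path.
#' @return Invisibly, the CSV path.
#' @export
export_csv <- function(x, file) {
  if (inherits(x, "phage_attractor")) {
    df <- data.frame(t = x$times, x$states)
    df$theta <- influx(x$times %% max(x$period, 1e-9), x$forcing)
    utils::write.csv(df, file, row.names = FALSE)
    meta <- list(period = x$period, converged = x$converged,
                 metric = x$metric, periods_used = x$periods_used,
                 forcing = unclass(x$forcing))
    jsonlite::write_json(meta, paste0(file, ".json"), auto_unbox = TRUE,
                         digits = NA)
  } else if (inherits(x, "phage_trajectory")) {
    df <- x
    names(df)[names(df) == "time"] <- "t"
    utils::write.csv(df, file, row.names = FALSE)
  } else {
    stop("'x' must be a phage_trajectory or phage_attractor", call. = FALSE)
  }
  invisible(file)
}
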