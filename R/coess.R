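SCENARIO_NAMES <- c("constant_no_stress", "fluctuating_fixed_no_stress",
                    "fluctuating_fixed_with_stress",
                    "fluctuating_plastic_no_stress",
                    "fluctuating_plastic_with_stress")

#' Define an evolutionary scenario
#'
#' Stages the evolutionary analyses: constant or square-wave influx, with
#' or without host stress, and fixed traits or arbitrium reaction norms.
#' Later stages carry trait values solved in earlier stages as fixed
#' inputs (e.g. the stress stage fixes the normal-cell traits at the
#' no-stress solution, and the plastic stages fix the maximal rates at the
#' fixed-trait solutions).
#'
#' @param name One of `"constant_no_stress"`,
#'   `"fluctuating_fixed_no_stress"`, `"fluctuating_fixed_with_stress"`,
#'   `"fluctuating_plastic_no_stress"`,
#'   `"fluctuating_plastic_with_stress"`.
#' @param forcing Optional `phage_forcing`; defaults to a constant influx
#'   of 50 for the constant scenario and the default square wave
#'   otherwise.
#' @param sigma Stress intensity; defaults to 0.1 for the `with_stress`
#'   scenarios and 0 otherwise.
#' @param fixed Named list of trait values carried over from earlier
#'   stages, overriding the scenario defaults (for fixed-trait scenarios:
#'   `phi`, `phiStar`, `alpha`, `alphaStar`; for plastic scenarios the
#'   maximal rates `alphaMax`, `phiMax`, `alphaMaxStar`, `phiMaxStar`).
#' @return A `phage_scenario` object with elements `name`, `forcing`,
#'   `sigma`, `free` (names of the traits solved for) and `fixed`.
#' @export
scenario <- function(name, forcing = NULL, sigma = NULL, fixed = list()) {
  name <- match.arg(name, SCENARIO_NAMES)
  if (is.null(forcing)) {
    forcing <- if (name == "constant_no_stress") forcing_constant(50)
               else forcing_square()
  }
  if (is.null(sigma)) sigma <- if (grepl("with_stress", name)) 0.1 else 0
  free <- switch(name,
    constant_no_stress = c("alpha", "phi"),
    fluctuating_fixed_no_stress = c("alpha", "phi"),
    fluctuating_fixed_with_stress = c("alphaStar", "phiStar"),
    fluctuating_plastic_no_stress = c("Aalpha", "Aphi"),
    fluctuating_plastic_with_stress = c("Aalpha", "Aphi", "AalphaStar"))
  defaults <- switch(name,
    constant_no_stress = list(phiStar = 0, alphaStar = 0),
    fluctuating_fixed_no_stress = list(phiStar = 0, alphaStar = 0),
    fluctuating_fixed_with_stress = list(),
    fluctuating_plastic_no_stress = list(alphaMaxStar = 0, phiMaxStar = 0),
    fluctuating_plastic_with_stress = list(phiMaxStar = 0))
  required <- switch(name,
    fluctuating_fixed_with_stress = c("alpha", "phi"),
    fluctuating_plastic_no_stress = c("alphaMax", "phiMax"),
    fluctuating_plastic_with_stress = c("alphaMax", "phiMax",
                                        "alphaMaxStar"),
    character(0))
  missing_req <- setdiff(required, names(fixed))
  if (length(missing_req))
    stop("scenario '", name, "' requires the staged trait value(s) ",
         paste(missing_req, collapse = ", "),
         " solved in the earlier stage, via 'fixed'", call. = FALSE)
  defaults[names(fixed)] <- fixed
  bad <- setdiff(names(defaults), valid_trait_names(name))
  if (length(bad))
    stop("unknown fixed trait(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (any(free %in% names(defaults)))
    stop("free and fixed trait sets must be disjoint", call. = FALSE)
  structure(list(name = name, forcing = forcing, sigma = sigma,
                 free = free, fixed = defaults),
            class = "phage_scenario")
}

valid_trait_names <- function(name) {
  if (grepl("plastic", name))
    c("alphaMax", "phiMax", "alphaMaxStar", "phiMaxStar",
      "Aalpha", "Aphi", "AalphaStar", "AphiStar")
  else c("phi", "phiStar", "alpha", "alphaStar")
}

#' @export
print.phage_scenario <- function(x, ...) {
  cat("Evolutionary scenario:", x$name, "\n")
  cat("  sigma =", x$sigma, "; free traits:", paste(x$free, collapse = ", "),
      "\n")
  if (length(x$fixed)) {
    cat("  fixed traits:\n")
    for (nm in names(x$fixed)) cat("    ", nm, "=", x$fixed[[nm]], "\n")
  }
  invisible(x)
}

# Build the resident strategy of a scenario from the free-trait vector x.
scenario_strategy <- function(scn, x) {
  vals <- c(as.list(x), scn$fixed)
  if (grepl("plastic", scn$name)) {
    get0v <- function(nm, d = 0) if (!is.null(vals[[nm]])) vals[[nm]] else d
    strategy_plastic(
      alphaMax = get0v("alphaMax"), Aalpha = get0v("Aalpha", NA_real_),
      phiMax = get0v("phiMax"), Aphi = get0v("Aphi", NA_real_),
      alphaMaxStar = get0v("alphaMaxStar"),
      AalphaStar = get0v("AalphaStar", NA_real_),
      phiMaxStar = get0v("phiMaxStar"),
      AphiStar = get0v("AphiStar", NA_real_))
  } else {
    get0v <- function(nm) if (!is.null(vals[[nm]])) vals[[nm]] else 0
    strategy_fixed(phi = get0v("phi"), phiStar = get0v("phiStar"),
                   alpha = get0v("alpha"), alphaStar = get0v("alphaStar"))
  }
}

trait_bounds <- function(free) {
  lower <- vapply(free, function(nm)
    if (grepl("^A", nm)) 1e-3 else 0, numeric(1))
  upper <- rep(1, length(free))
  names(upper) <- free
  list(lower = lower, upper = upper)
}

default_start <- function(scn) {
  switch(scn$name,
    constant_no_stress = c(alpha = 0.05, phi = 0.4),
    fluctuating_fixed_no_stress = c(alpha = 0.05, phi = 0.4),
    fluctuating_fixed_with_stress = c(alphaStar = 0.05, phiStar = 0.1),
    fluctuating_plastic_no_stress = c(Aalpha = 0.1, Aphi = 0.07),
    fluctuating_plastic_with_stress = c(Aalpha = 0.09, Aphi = 0.07,
                                        AalphaStar = 0.1))
}

# Averaged-gradient function of a scenario: maps the free-trait vector to
# the named vector of period-averaged selection gradients, re-equilibrating
# the resident attractor at each candidate (warm-started).
make_gradient_fn <- function(scn, params, n_points = 2001L,
                             attractor_tol = 1e-6, max_periods = 500L,
                             vtol = 1e-9) {
  params <- do.call(model_params,
                    utils::modifyList(unclass(params),
                                      list(sigma = scn$sigma)))
  warm <- new.env(parent = emptyenv())
  warm$y0 <- NULL
  grad_map <- c(alpha = "S_alpha", phi = "S_phi",
                alphaStar = "S_alphaStar", phiStar = "S_phiStar")
  function(x, return_profile = FALSE) {
    strategy <- scenario_strategy(scn, x)
    att <- tryCatch(
      find_attractor(params, scn$forcing, strategy, y0 = warm$y0,
                     max_periods = max_periods, tol = attractor_tol,
                     n_points = n_points),
      error = function(e) NULL)
    if (is.null(att) || !att$converged ||
        max(att$states[, "V"]) < 1e-8 || max(att$states[, "L"]) < 1e-8) {
      g <- rep(NA_real_, length(scn$free)); names(g) <- scn$free
      return(if (return_profile) list(gradients = g, profile = NULL) else g)
    }
    warm$y0 <- att$states[1L, ]
    prof <- selection_profile(att, vtol = vtol)
    g <- vapply(scn$free, function(nm) {
      if (nm %in% names(grad_map)) prof$averages[[grad_map[[nm]]]]
      else prof$threshold_averages[[nm]]
    }, numeric(1))
    names(g) <- scn$free
    if (return_profile) list(gradients = g, profile = prof) else g
  }
}

# Projected damped Newton with finite-difference Jacobian and box bounds.
# A trait pinned at a bound with an outward-pointing gradient is frozen
# there (boundary optimum); remaining traits are solved to gtol.
newton_box <- function(g_fn, x0, lower, upper, gtol = 1e-7,
                       max_iter = 40L, verbose = FALSE) {
  x <- pmin(pmax(x0, lower), upper)
  n <- length(x)
  frozen <- rep(FALSE, n)
  g <- g_fn(x)
  if (any(is.na(g)))
    stop("gradient evaluation failed at the starting point", call. = FALSE)
  history <- list()
  for (it in seq_len(max_iter)) {
    # freeze bounds with outward gradients; release if gradient turns inward
    at_lo <- x <= lower + 1e-12
    at_hi <- x >= upper - 1e-12
    frozen <- (at_lo & g < 0) | (at_hi & g > 0)
    act <- which(!frozen)
    gact <- g[act]
    history[[it]] <- list(x = x, g = g)
    if (verbose)
      message(sprintf("iter %d: x = %s, g = %s", it,
                      paste(signif(x, 5), collapse = ", "),
                      paste(signif(g, 4), collapse = ", ")))
    if (length(act) == 0L || max(abs(gact)) < gtol) break
    h <- pmax(1e-6, 1e-3 * abs(x[act]))
    J <- matrix(NA_real_, length(act), length(act))
    ok <- TRUE
    for (j in seq_along(act)) {
      hj <- if (x[act[j]] + h[j] > upper[act[j]]) -h[j] else h[j]
      xj <- x; xj[act[j]] <- xj[act[j]] + hj
      gj <- g_fn(xj)
      if (any(is.na(gj))) { ok <- FALSE; break }
      J[, j] <- (gj[act] - gact) / hj
    }
    if (!ok) stop("gradient evaluation failed near x = ",
                  paste(signif(x, 5), collapse = ", "), call. = FALSE)
    step <- tryCatch(-solve(J, gact), error = function(e) -gact)
    lam <- 1
    improved <- FALSE
    for (half in 0:6) {
      xn <- x
      xn[act] <- x[act] + lam * step
      xn <- pmin(pmax(xn, lower), upper)
      gn <- g_fn(xn)
      if (!any(is.na(gn)) &&
          (max(abs(gn[act])) < max(abs(gact)) || max(abs(gn[act])) < gtol)) {
        x <- xn; g <- gn; improved <- TRUE; break
      }
      lam <- lam / 2
    }
    if (!improved) {
      # accept the damped step anyway if finite; otherwise give up
      if (!any(is.na(gn))) { x <- xn; g <- gn } else break
    }
  }
  act <- which(!frozen)
  list(x = x, gradients = g, iterations = it,
       converged = length(act) == 0L || max(abs(g[act])) < gtol,
       boundary = frozen, history = history)
}

#' Solve an evolutionary scenario for its (co)ESS
#'
#' Nested solve: for each candidate trait vector the resident system is
#' re-equilibrated on its periodic attractor, class frequencies and
#' reproductive values are recomputed, and the period-averaged selection
#' gradients of the free traits are driven to zero by a projected damped
#' Newton iteration with box bounds. Traits pinned at a bound with an
#' outward-pointing gradient are reported as boundary optima. For the
#' constant-environment scenario the averaged gradients on reactivation
#' and lysogenisation are proportional with opposite signs, so no isolated
#' ESS exists and a sampled one-dimensional solution curve is returned
#' instead (see [ess_curve_constant()]).
#'
#' @param scn A `phage_scenario`.
#' @param params A `phage_params` object; the scenario's `sigma`
#'   overrides `params$sigma`.
#' @param start Optional named start vector for the free traits.
#' @param n_starts Number of solver starts; starts beyond the first are
#'   drawn uniformly inside the trait boxes to probe uniqueness.
#' @param seed Optional seed for the multi-start draws.
#' @param n_points Attractor grid points per period.
#' @param gtol Solver tolerance on the averaged gradients.
#' @param ... Passed to [make_gradient_fn()] (attractor tolerances).
#' @return A `coess_result`: list with solved `traits` (full named
#'   vector including fixed ones), `residuals` (averaged gradients of the
#'   free traits), `boundary` flags, `converged`, `iterations`,
#'   `strategy`, and `starts` diagnostics (solutions of every start).
#'   For the constant scenario, the element `curve` holds the sampled
#'   solution set.
#' @export
solve_scenario <- function(scn, params = model_params(), start = NULL,
                           n_starts = 1L, seed = NULL, n_points = 2001L,
                           gtol = 1e-7, ...) {
  stopifnot(inherits(scn, "phage_scenario"))
  if (scn$name == "constant_no_stress") {
    curve <- ess_curve_constant(params, scn$forcing$theta0)
    return(structure(list(scenario = scn, curve = curve,
                          converged = any(!is.na(curve$phi)),
                          traits = NULL,
                          note = paste("one-dimensional ESS set: averaged",
                                       "gradients on alpha and phi are",
                                       "proportional in a constant",
                                       "environment")),
                     class = "coess_result"))
  }
  bounds <- trait_bounds(scn$free)
  if (is.null(start)) start <- default_start(scn)
  start <- start[scn$free]
  starts <- list(start)
  if (n_starts > 1L) {
    if (!is.null(seed)) set.seed(seed)
    for (i in seq_len(n_starts - 1L)) {
      lo <- bounds$lower + 0.05 * (bounds$upper - bounds$lower)
      hi <- bounds$lower + 0.5 * (bounds$upper - bounds$lower)
      # draw within the lower half of the box: interior but epidemiologically
      # viable trait magnitudes
      starts[[i + 1L]] <- stats::setNames(stats::runif(length(scn$free),
                                                       lo, hi), scn$free)
    }
  }
  g_fn <- make_gradient_fn(scn, params, n_points = n_points, ...)
  fits <- lapply(starts, function(s0) {
    tryCatch(newton_box(g_fn, s0, bounds$lower, bounds$upper, gtol = gtol),
             error = function(e) list(converged = FALSE, error = conditionMessage(e)))
  })
  okfit <- Filter(function(f) isTRUE(f$converged), fits)
  if (!length(okfit))
    stop("no solver start converged for scenario '", scn$name, "'",
         call. = FALSE)
  best <- okfit[[which.min(vapply(okfit, function(f)
    max(abs(f$gradients)), numeric(1)))]]
  traits <- c(best$x, unlist(scn$fixed))
  strategy <- scenario_strategy(scn, best$x)
  structure(list(scenario = scn, traits = traits,
                 free = best$x, residuals = best$gradients,
                 boundary = best$boundary, converged = best$converged,
                 iterations = best$iterations, strategy = strategy,
                 starts = lapply(fits, function(f)
                   f[intersect(c("x", "gradients", "converged", "error"),
                               names(f))])),
            class = "coess_result")
}

#' Solve a plastic-threshold scenario
#'
#' Convenience wrapper around [solve_scenario()] for the reaction-norm
#' stages, taking the maximal rates (solved in the fixed-trait stages) as
#' fixed inputs and root-finding the arbitrium thresholds. A maximal rate
#' of zero removes the corresponding threshold from the free set, since
#' its averaged gradient is identically zero.
#'
#' @param scn A plastic `phage_scenario`.
#' @param params,... As in [solve_scenario()].
#' @return A `coess_result`.
#' @export
solve_threshold_scenario <- function(scn, params = model_params(), ...) {
  stopifnot(inherits(scn, "phage_scenario"))
  if (!grepl("plastic", scn$name))
    stop("'scn' must be one of the plastic scenarios", call. = FALSE)
  solve_scenario(scn, params = params, ...)
}

#' @export
print.coess_result <- function(x, ...) {
  cat("coESS solve:", x$scenario$name, "\n")
  if (!is.null(x$curve)) {
    cat("  one-dimensional ESS set (", sum(!is.na(x$curve$phi)),
        "sampled points)\n")
    print(utils::head(x$curve))
    return(invisible(x))
  }
  cat("  converged:", x$converged, "in", x$iterations, "iterations\n")
  cat("  solved traits:\n")
  for (nm in names(x$free)) {
    tag <- if (isTRUE(x$boundary[[nm]])) " (boundary optimum)" else ""
    cat(sprintf("    %s = %.4g%s  [residual gradient %.3g]\n", nm,
                x$free[[nm]], tag, x$residuals[[nm]]))
  }
  invisible(x)
}
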