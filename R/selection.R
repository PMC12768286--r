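#' Mutant projection matrix among viral classes
#'
#' Builds the 3x3 matrix of transition rates among the viral classes
#' (prophage in a normal cell `L`, prophage in a stressed cell `Lstar`,
#' free virion `V`) for a rare mutant experiencing the resident densities
#' and the resident arbitrium concentration. Entry (i, j) is the rate of
#' production of mutant phage in class i by a mutant in class j.
#'
#' @param state Named resident state (`S`, `Sstar`, `L`, `Lstar`, `V`,
#'   `A`).
#' @param params A `phage_params` object.
#' @param strategy The mutant `phage_strategy`, evaluated at the resident
#'   `A`.
#' @return A 3x3 matrix with dimnames `c("L", "Lstar", "V")`.
#' @export
mutant_matrix <- function(state, params, strategy) {
  state <- state[STATE_NAMES]
  if (any(is.na(state)) || any(state < 0))
    stop("'state' must be a non-negative resident state", call. = FALSE)
  S <- state[["S"]]; Ss <- state[["Sstar"]]
  N <- S + Ss + state[["L"]] + state[["Lstar"]]
  tr <- evaluate_strategy(strategy, state[["A"]], k = params$k)
  with(params, {
    m <- matrix(c(
      r * (1 - kappa * N) - (tr$alpha + dL + sigma), gamma, a * tr$phi * S,
      sigma, -(tr$alphaStar + dLstar + gamma), a * tr$phiStar * Ss,
      tr$alpha * B, tr$alphaStar * B,
      a * ((1 - tr$phi) * S + (1 - tr$phiStar) * Ss) * B - (a * N + dV)
    ), nrow = 3, byrow = TRUE,
    dimnames = list(c("L", "Lstar", "V"), c("L", "Lstar", "V")))
    m
  })
}

# Trait rates, per-capita resident viral growth rate rw(t) and abundances
# along the attractor grid (vectorised).
resident_series <- function(att) {
  st <- att$states
  p <- att$params
  tr <- evaluate_strategy(att$strategy, st[, "A"], k = p$k)
  N <- rowSums(st[, c("S", "Sstar", "L", "Lstar"), drop = FALSE])
  n <- st[, c("L", "Lstar", "V"), drop = FALSE]
  grow <- p$r * (1 - p$kappa * N)
  dL <- grow * n[, "L"] + p$a * tr$phi * st[, "V"] * st[, "S"] -
    (tr$alpha + p$dL + p$sigma) * n[, "L"] + p$gamma * n[, "Lstar"]
  dLs <- p$sigma * n[, "L"] + p$a * tr$phiStar * st[, "V"] * st[, "Sstar"] -
    (tr$alphaStar + p$dLstar + p$gamma) * n[, "Lstar"]
  dV <- p$a * p$B * st[, "V"] *
    ((1 - tr$phi) * st[, "S"] + (1 - tr$phiStar) * st[, "Sstar"]) +
    (tr$alpha * n[, "L"] + tr$alphaStar * n[, "Lstar"]) * p$B -
    (p$a * N + p$dV) * st[, "V"]
  tot <- rowSums(n)
  list(traits = tr, N = N, n = n, rw = (dL + dLs + dV) / tot)
}

#' Class frequencies of the resident viral population
#'
#' On the attractor the resident abundances of the three viral classes are
#' themselves a (periodic) solution of the linearised class dynamics, so
#' the class-frequency equations are solved exactly by normalising the
#' resident abundances: `f_i(t) = n_i(t) / sum(n(t))`. The per-capita
#' growth rate `rw(t)` of the monomorphic resident viral population is the
#' normalisation that conserves `sum(f) = 1`.
#'
#' @param att A converged `phage_attractor`.
#' @return A list with `times`, matrix `f` (columns `fL`, `fLstar`, `fV`)
#'   and vector `rw`.
#' @export
class_frequencies <- function(att) {
  stopifnot(inherits(att, "phage_attractor"))
  rs <- resident_series(att)
  tot <- rowSums(rs$n)
  if (any(tot <= 0))
    stop("viral population absent on the attractor; frequencies undefined",
         call. = FALSE)
  f <- rs$n / tot
  colnames(f) <- c("fL", "fLstar", "fV")
  list(times = att$times, f = f, rw = rs$rw)
}

# Forcing tables (time, value) for the compiled linear system, in forward
# time or reversed time tau = T - t.
linear_forcings <- function(att, rw, reversed = FALSE) {
  st <- att$states
  tt <- att$times
  series <- list(st[, "S"], st[, "Sstar"],
                 rowSums(st[, c("S", "Sstar", "L", "Lstar"), drop = FALSE]),
                 st[, "A"], rw)
  if (reversed) {
    tau <- max(tt) - rev(tt)
    lapply(series, function(x) cbind(tau, rev(x)))
  } else {
    lapply(series, function(x) cbind(tt, x))
  }
}

# Fundamental matrix of the linearised class dynamics x' = M(t) x along
# the attractor, co-integrated with the resident state so that M is
# evaluated exactly (no interpolation). The mutant strategy parameterises
# M; the resident strategy drives the environment.
fundamental_matrix <- function(att, mutant_strategy = att$strategy,
                               times = att$times) {
  p <- att$params; fo <- att$forcing
  y0 <- c(att$states[1L, ], diag(3))
  run <- function(y, t0, t1, theta, tt) {
    parms <- c(parms_vector(p, theta, att$strategy),
               parms_vector(p, 0, mutant_strategy))
    out <- ode_call(y, tt, "lys_aug_derivs", parms, "lys_aug_init",
                    att$rtol, att$atol)
    if (attr(out, "istate")[1L] < 0)
      stop("augmented integration failed", call. = FALSE)
    out
  }
  if (fo$mode == "constant") {
    out <- run(y0, 0, max(times), fo$theta0, times)
    m <- out
  } else {
    gT <- fo$g * fo$T
    t_on <- unique(c(times[times <= gT], gT))
    t_off <- unique(c(gT, times[times >= gT]))
    out1 <- run(y0, 0, gT, fo$thetaMax, t_on)
    out2 <- run(out1[nrow(out1), -1L], gT, fo$T, 0, t_off)
    m <- rbind(out1[out1[, "time"] %in% times, , drop = FALSE],
               out2[out2[, "time"] %in% times, , drop = FALSE])
    m <- m[!duplicated(m[, "time"]), , drop = FALSE]
  }
  Phi <- array(t(m[, 8:16, drop = FALSE]), dim = c(3, 3, nrow(m)))
  list(times = m[, "time"], Phi = Phi)
}

# One lsoda pass of the compiled linear system over the given times.
solve_linear <- function(y0, times, parms, forcings, rtol, atol) {
  out <- ode_call(y0, times, "lys_linear_derivs", parms,
                  "lys_linear_init", rtol, atol, forcings = forcings,
                  initforc = "lys_linear_forc")
  if (attr(out, "istate")[1L] < 0)
    stop("linear system integration failed", call. = FALSE)
  out
}

#' Reproductive values of the viral classes on the attractor
#'
#' Computes the periodic solution of the adjoint (reproductive-value)
#' dynamics on the attractor, normalised so that `v(t) . f(t) = 1`. The
#' default `"monodromy"` method co-integrates the fundamental matrix of
#' the class dynamics with the resident over one period, takes the left
#' eigenvector of the monodromy map for its dominant (unit) multiplier as
#' the exactly periodic boundary condition, and reconstructs `v(t)` by
#' solving small linear systems at every grid time; this avoids any
#' interpolation of resident densities. The `"sweep"` method integrates
#' the adjoint equations backward in time over repeated periods until the
#' sweep is periodic (the adjoint contracts backward at the subdominant
#' Floquet multiplier) and serves as an independent cross-check. The
#' conservation of `v . f` along the orbit is a property of the adjoint
#' pairing and is reported as an accuracy diagnostic.
#'
#' @param att A converged `phage_attractor`.
#' @param freqs Optional output of [class_frequencies()] (recomputed if
#'   missing).
#' @param method `"monodromy"` (default) or `"sweep"`.
#' @param tol Relative period-to-period tolerance of the backward sweep.
#' @param min_periods,max_periods Bounds on the number of sweeps.
#' @return A list with `times`, matrix `v` (columns `vL`, `vLstar`,
#'   `vV`), `sweeps` used (0 for the monodromy method), `multiplier`
#'   (dominant Floquet multiplier, ~1; monodromy method only) and the
#'   conservation defect `vf_defect` (max |v.f - 1|).
#' @export
reproductive_values <- function(att, freqs = NULL,
                                method = c("monodromy", "sweep"),
                                tol = 1e-9, min_periods = 3L,
                                max_periods = 100L) {
  stopifnot(inherits(att, "phage_attractor"))
  method <- match.arg(method)
  if (is.null(freqs)) freqs <- class_frequencies(att)
  rs <- resident_series(att)
  if (method == "monodromy") {
    fm <- fundamental_matrix(att)
    n_grid <- length(fm$times)
    PhiT <- fm$Phi[, , n_grid]
    ev <- eigen(t(PhiT))
    i1 <- which.max(Re(ev$values))
    multiplier <- Re(ev$values[i1])
    v0 <- Re(ev$vectors[, i1])
    if (sum(v0) < 0) v0 <- -v0
    tot <- rowSums(rs$n)
    vmat <- matrix(NA_real_, n_grid, 3)
    for (i in seq_len(n_grid))
      vmat[i, ] <- (tot[i] / tot[1L]) * solve(t(fm$Phi[, , i]), v0)
    sweeps <- 0L
  } else {
    parms <- parms_vector(att$params, 0, att$strategy, mode = 1)
    forc <- linear_forcings(att, freqs$rw, reversed = TRUE)
    tau <- max(att$times) - rev(att$times)
    tau_ends <- range(tau)
    v <- c(1, 1, 1)
    prev <- v / max(v)
    sweeps <- 0L
    dv_prev <- Inf
    for (i in seq_len(max_periods)) {
      out <- solve_linear(v, tau_ends, parms, forc, att$rtol, att$atol)
      v <- out[nrow(out), -1L]
      cur <- v / max(v)
      dv <- max(abs(cur - prev))
      prev <- cur
      sweeps <- i
      # stop at tolerance or at the noise floor of the interpolated
      # forcings (no further contraction)
      if (i >= min_periods && (dv < tol || dv >= 0.5 * dv_prev)) break
      dv_prev <- dv
    }
    out <- solve_linear(v, tau, parms, forc, att$rtol, att$atol)
    vmat <- out[, -1L, drop = FALSE][rev(seq_len(nrow(out))), ,
                                     drop = FALSE]
    multiplier <- NA_real_
  }
  colnames(vmat) <- c("vL", "vLstar", "vV")
  vf <- rowSums(vmat * freqs$f)
  vmat <- vmat / mean(vf)
  vf_defect <- max(abs(rowSums(vmat * freqs$f) - 1))
  list(times = att$times, v = vmat, sweeps = sweeps,
       multiplier = multiplier, vf_defect = vf_defect)
}

trapezoid_mean <- function(x, times) {
  dt <- diff(times)
  sum(dt * (utils::head(x, -1) + utils::tail(x, -1)) / 2) / sum(dt)
}

#' Period average of an instantaneous selection gradient
#'
#' Trapezoid quadrature of a time series over exactly one period of the
#' attractor grid.
#'
#' @param series Numeric vector on the grid `times`.
#' @param times Strictly increasing grid covering one period.
#' @return The period mean (a scalar).
#' @export
averaged_gradient <- function(series, times) {
  if (length(series) != length(times) || length(times) < 2L)
    stop("'series' and 'times' must be equal-length (>= 2)", call. = FALSE)
  if (any(diff(times) <= 0))
    stop("'times' must be strictly increasing", call. = FALSE)
  trapezoid_mean(series, times)
}

#' Selection profile on the periodic attractor
#'
#' Assembles, on one period of the resident attractor, the class
#' frequencies, reproductive values, per-capita resident growth rate and
#' the instantaneous selection gradients on the four lysis-lysogeny
#' traits:
#' `S_alpha = (B vV - vL) fL`, `S_alphaStar = (B vV - vLstar) fLstar`,
#' `S_phi = -(B vV - vL) a S fV`,
#' `S_phiStar = -(B vV - vLstar) a Sstar fV`,
#' together with their period averages. For plastic strategies the
#' averaged gradients on the arbitrium thresholds and on the maximal
#' rates are included (see [threshold_gradients()]).
#'
#' @param att A converged `phage_attractor`.
#' @param vtol Tolerance of the backward reproductive-value sweep.
#' @return A `selection_profile` object: list with a data frame `series`
#'   (time, fL, fLstar, fV, vL, vLstar, vV, rw and the four instantaneous
#'   gradients) and a named vector `averages`.
#' @export
selection_profile <- function(att, vtol = 1e-9) {
  stopifnot(inherits(att, "phage_attractor"))
  fr <- class_frequencies(att)
  rv <- reproductive_values(att, fr, tol = vtol)
  st <- att$states
  p <- att$params
  f <- fr$f; v <- rv$v
  dL <- p$B * v[, "vV"] - v[, "vL"]
  dLs <- p$B * v[, "vV"] - v[, "vLstar"]
  s_alpha <- dL * f[, "fL"]
  s_alphaStar <- dLs * f[, "fLstar"]
  s_phi <- -dL * p$a * st[, "S"] * f[, "fV"]
  s_phiStar <- -dLs * p$a * st[, "Sstar"] * f[, "fV"]
  series <- data.frame(time = att$times, f, v, rw = fr$rw,
                       S_alpha = s_alpha, S_alphaStar = s_alphaStar,
                       S_phi = s_phi, S_phiStar = s_phiStar)
  avg <- c(S_alpha = averaged_gradient(s_alpha, att$times),
           S_alphaStar = averaged_gradient(s_alphaStar, att$times),
           S_phi = averaged_gradient(s_phi, att$times),
           S_phiStar = averaged_gradient(s_phiStar, att$times))
  prof <- structure(list(series = series, averages = avg,
                         vf_defect = rv$vf_defect, sweeps = rv$sweeps,
                         attractor = att),
                    class = "selection_profile")
  if (att$strategy$kind == "plastic")
    prof$threshold_averages <- threshold_gradients(prof, att$strategy)
  prof
}

#' @export
print.selection_profile <- function(x, ...) {
  cat("Selection profile on the periodic attractor\n")
  cat(sprintf("  v.f conservation defect: %.3g (%d backward sweeps)\n",
              x$vf_defect, x$sweeps))
  cat("  period-averaged gradients:\n")
  print(x$averages)
  if (!is.null(x$threshold_averages)) {
    cat("  reaction-norm parameter gradients:\n")
    print(x$threshold_averages)
  }
  invisible(x)
}

# dH_k(A/thr - 1)/dA-threshold weight of the chain rule:
# -d/dthr H_k(A/thr - 1) = k A / (pi (thr^2 + k^2 (A - thr)^2))
threshold_weight <- function(A, thr, k) {
  k * A / (pi * (thr^2 + k^2 * (A - thr)^2))
}

#' Averaged selection gradients on reaction-norm parameters
#'
#' For a plastic strategy, computes by the chain rule the period-averaged
#' selection gradients on the arbitrium thresholds (`Aalpha`, `Aphi`,
#' `AalphaStar`, `AphiStar`) and on the maximal rates (`alphaMax`,
#' `phiMax`, `alphaMaxStar`, `phiMaxStar`), weighting the instantaneous
#' rate gradients by the sensitivity of the reaction norm to each
#' parameter along the resident arbitrium trajectory. Parameters whose
#' maximal rate is zero have an identically zero threshold gradient.
#'
#' @param profile A `selection_profile` from a plastic-resident attractor.
#' @param strategy The plastic `phage_strategy` (defaults to the
#'   attractor's resident strategy).
#' @return Named vector of averaged gradients on the eight reaction-norm
#'   parameters.
#' @export
threshold_gradients <- function(profile, strategy = NULL) {
  stopifnot(inherits(profile, "selection_profile"))
  att <- profile$attractor
  if (is.null(strategy)) strategy <- att$strategy
  if (strategy$kind != "plastic")
    stop("'strategy' must be plastic", call. = FALSE)
  s <- profile$series
  A <- att$states[, "A"]
  k <- att$params$k
  tt <- s$time
  hk_up <- function(thr) smooth_heaviside(A / thr - 1, k)
  avg <- function(x) averaged_gradient(x, tt)
  w <- function(thr) threshold_weight(A, thr, k)
  res <- c(Aalpha = 0, Aphi = 0, AalphaStar = 0, AphiStar = 0,
           alphaMax = avg(s$S_alpha * 1),
           phiMax = avg(s$S_phi * 1),
           alphaMaxStar = avg(s$S_alphaStar * 1),
           phiMaxStar = avg(s$S_phiStar * 1))
  if (strategy$alphaMax > 0) {
    res["Aalpha"] <- strategy$alphaMax * avg(s$S_alpha * w(strategy$Aalpha))
    res["alphaMax"] <- avg(s$S_alpha * (1 - hk_up(strategy$Aalpha)))
  }
  if (strategy$phiMax > 0) {
    res["Aphi"] <- -strategy$phiMax * avg(s$S_phi * w(strategy$Aphi))
    res["phiMax"] <- avg(s$S_phi * hk_up(strategy$Aphi))
  }
  if (strategy$alphaMaxStar > 0) {
    res["AalphaStar"] <- strategy$alphaMaxStar *
      avg(s$S_alphaStar * w(strategy$AalphaStar))
    res["alphaMaxStar"] <- avg(s$S_alphaStar *
                                 (1 - hk_up(strategy$AalphaStar)))
  }
  if (strategy$phiMaxStar > 0) {
    res["AphiStar"] <- -strategy$phiMaxStar *
      avg(s$S_phiStar * w(strategy$AphiStar))
    res["phiMaxStar"] <- avg(s$S_phiStar * hk_up(strategy$AphiStar))
  }
  res
}

#' Invasion (Floquet) growth exponent of a rare mutant
#'
#' Integrates the linearised dynamics of a rare mutant experiencing the
#' resident attractor over one period, builds the monodromy matrix from
#' three basis solutions, and returns the log of its dominant eigenvalue
#' modulus divided by the period. The exponent is zero (to numerical
#' tolerance) when the mutant equals the resident, and its sign for small
#' trait perturbations agrees with the sign of the corresponding averaged
#' selection gradient. Serves as an independent fitness measure to
#' cross-check gradients.
#'
#' @param att A converged `phage_attractor` of the resident.
#' @param mutant_strategy The mutant `phage_strategy`.
#' @return The Floquet exponent (h^-1).
#' @export
invasion_exponent <- function(att, mutant_strategy) {
  stopifnot(inherits(att, "phage_attractor"),
            inherits(mutant_strategy, "phage_strategy"))
  T <- max(att$times)
  fm <- fundamental_matrix(att, mutant_strategy, times = c(0, T))
  PhiT <- fm$Phi[, , dim(fm$Phi)[3L]]
  mu <- max(Mod(eigen(PhiT, only.values = TRUE)$values))
  if (!is.finite(mu) || mu <= 0)
    stop("non-finite monodromy spectrum", call. = FALSE)
  log(mu) / T
}

#' Export a selection profile to CSV
#'
#' Writes the per-time series (frequencies, reproductive values, growth
#' rate, instantaneous gradients) to a headered CSV, and the averaged
#' gradients to a JSON file `<file>.json` keyed by trait name.
#'
#' @param profile A `selection_profile`.
#' @param file Output CSV path.
#' @return Invisibly, the CSV path.
#' @export
export_profile_csv <- function(profile, file) {
  stopifnot(inherits(profile, "selection_profile"))
  df <- profile$series
  names(df)[1L] <- "t"
  utils::write.csv(df, file, row.names = FALSE)
  avg <- as.list(profile$averages)
  if (!is.null(profile$threshold_averages))
    avg <- c(avg, as.list(profile$threshold_averages))
  jsonlite::write_json(avg, paste0(file, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(file)
}
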