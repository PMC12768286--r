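p_def <- model_params()
fo_sq <- forcing_square()
st_ref <- strategy_fixed(phi = 0.325, alpha = 0.0197)

test_that("mutant projection matrix matches hand arithmetic", {
  # S=100, S*=10, L=40, L*=10 (N=160), V=1000, A=0; sigma=0.1, defaults;
  # mutant phi=0.3, phi*=0, alpha=0.02, alpha*=0.06
  p <- model_params(sigma = 0.1)
  mut <- strategy_fixed(phi = 0.3, phiStar = 0, alpha = 0.02,
                        alphaStar = 0.06)
  M <- mutant_matrix(c(S = 100, Sstar = 10, L = 40, Lstar = 10, V = 1000,
                       A = 0), p, mut)
  expect_equal(unname(M),
               matrix(c(0.62, 0.1, 0.003,
                        0.1, -0.26, 0,
                        0.2, 0.6, -0.036), 3, 3, byrow = TRUE),
               tolerance = 1e-12)
})

test_that("stressed-class couplings vanish without stressed cells", {
  M <- mutant_matrix(c(S = 100, Sstar = 0, L = 40, Lstar = 0, V = 1000,
                       A = 0), p_def, st_ref)
  expect_equal(M["L", "Lstar"], 0.1)        # recovery survives as a rate
  expect_equal(M["Lstar", "L"], 0)          # no stress flux (sigma = 0)
  expect_equal(M["Lstar", "V"], 0)          # no lysogenisation into L*
})

test_that("rw equals the per-capita growth of the resident viral classes", {
  att <- ref_attractor()
  fr <- class_frequencies(att)
  tot <- rowSums(att$states[, c("L", "Lstar", "V")])
  tt <- att$times
  # central-difference oracle on log total abundance
  i <- 2:(length(tt) - 1)
  rw_fd <- (log(tot[i + 1]) - log(tot[i - 1])) / (tt[i + 1] - tt[i - 1])
  # exclude the forcing discontinuity where the derivative jumps
  keep <- abs(tt[i] - 8) > 0.1
  expect_lt(max(abs(fr$rw[i][keep] - rw_fd[keep])), 1e-3)
})

test_that("class frequencies sum to one and track the virion peak", {
  att <- ref_attractor()
  fr <- class_frequencies(att)
  expect_lt(max(abs(rowSums(fr$f) - 1)), 1e-12)
  expect_true(all(fr$f[, c("fL", "fV")] > 0))
  expect_true(all(fr$f[, "fLstar"] == 0))  # sigma = 0
  t_fV <- att$times[which.max(fr$f[, "fV"])]
  t_V <- att$times[which.max(att$states[, "V"])]
  expect_lt(abs(t_fV - t_V), 5)
})

test_that("reproductive values are periodic, conserved and method-consistent", {
  att <- ref_attractor()
  fr <- class_frequencies(att)
  rv <- reproductive_values(att, fr)
  expect_lt(rv$vf_defect, 1e-6)
  expect_equal(rv$multiplier, 1, tolerance = 1e-4)
  # independent route: backward sweeps over interpolated forcings
  rv2 <- reproductive_values(att, fr, method = "sweep")
  # the sweep stalls at the interpolation noise floor of its forcing
  # tables (~1e-4 on v); the two routes must agree to that level
  expect_lt(max(abs(rv2$v - rv$v)), 5e-4)
  expect_gte(rv2$sweeps, 3)
})

test_that("a stressed host lowers the prophage's reproductive value", {
  # sigma > 0, no plasticity to stress (same traits in both states)
  p <- model_params(sigma = 0.1)
  st <- strategy_fixed(phi = 0.325, phiStar = 0.325, alpha = 0.0197,
                       alphaStar = 0.0197)
  att <- find_attractor(p, fo_sq, st)
  prof <- selection_profile(att)
  vL_bar <- averaged_gradient(prof$series$vL, prof$series$time)
  vLs_bar <- averaged_gradient(prof$series$vLstar, prof$series$time)
  expect_gt(vL_bar, vLs_bar)
})

test_that("instantaneous gradients have the analytic product structure", {
  prof <- ref_profile()
  s <- prof$series
  att <- ref_attractor()
  gap <- 10 * s$vV - s$vL
  expect_equal(s$S_alpha, gap * s$fL)
  expect_equal(s$S_phi, -gap * 1e-4 * att$states[, "S"] * s$fV)
  # reactivation and lysogenisation gradients oppose each other pointwise
  pos <- s$fL > 0 & s$fV > 0 & att$states[, "S"] > 0 & abs(gap) > 1e-10
  expect_true(all(sign(s$S_alpha[pos]) == -sign(s$S_phi[pos])))
  # the sign of selection alternates within a period
  expect_true(any(gap > 0) && any(gap < 0))
})

test_that("period averaging is exact for constants and zero-mean waves", {
  tt <- seq(0, 40, length.out = 4001)
  expect_equal(averaged_gradient(rep(3.7, length(tt)), tt), 3.7)
  expect_equal(averaged_gradient(sin(2 * pi * tt / 40), tt), 0,
               tolerance = 1e-8)
  expect_error(averaged_gradient(1:3, c(0, 1)), "equal-length")
})

test_that("threshold-gradient weights equal the norm's parameter derivative", {
  k <- 10
  thr <- 0.08
  A <- c(0.01, 0.05, 0.08, 0.1, 0.3)
  h <- 1e-7
  fd <- -(smooth_heaviside(A / (thr + h) - 1, k) -
            smooth_heaviside(A / (thr - h) - 1, k)) / (2 * h)
  expect_equal(lysogeny:::threshold_weight(A, thr, k), fd,
               tolerance = 1e-6)
})

test_that("threshold gradients vanish when the maximal rate is zero", {
  p <- model_params(sigma = 0.1)
  sp <- strategy_plastic(alphaMax = 0.02, Aalpha = 0.1, phiMax = 0.3,
                         Aphi = 0.06, alphaMaxStar = 0.06,
                         AalphaStar = 0.09, phiMaxStar = 0)
  att <- find_attractor(p, fo_sq, sp)
  prof <- selection_profile(att)
  expect_identical(unname(prof$threshold_averages["AphiStar"]), 0)
  expect_false(prof$threshold_averages["Aalpha"] == 0)
  sp0 <- strategy_plastic(alphaMax = 0, phiMax = 0.3, Aphi = 0.06)
  att0 <- find_attractor(p_def, fo_sq, sp0)
  prof0 <- selection_profile(att0)
  expect_identical(unname(prof0$threshold_averages["Aalpha"]), 0)
})

test_that("the resident is neutral in its own environment", {
  att <- ref_attractor()
  expect_lt(abs(invasion_exponent(att, st_ref)), 1e-7)
})

test_that("invasion exponents agree with averaged selection gradients", {
  # off-ESS resident so both gradients are appreciably nonzero
  st <- strategy_fixed(phi = 0.45, alpha = 0.03)
  att <- find_attractor(p_def, fo_sq, st)
  prof <- selection_profile(att)
  g <- prof$averages[c("S_alpha", "S_phi")]
  set.seed(7)
  for (i in 1:10) {
    dz <- c(runif(1, -1, 1) * 2e-3, runif(1, -1, 1) * 2e-2)
    pred <- sum(dz * g)
    if (abs(pred) < 1e-5) next
    mut <- strategy_fixed(phi = 0.45 + dz[2], alpha = 0.03 + dz[1])
    lam <- invasion_exponent(att, mut)
    expect_equal(sign(lam), sign(pred))
  }
  # the exponent's slope in a trait equals the averaged gradient
  eps <- 1e-4
  lam_p <- invasion_exponent(att, strategy_fixed(phi = 0.45,
                                                 alpha = 0.03 + eps))
  lam_m <- invasion_exponent(att, strategy_fixed(phi = 0.45,
                                                 alpha = 0.03 - eps))
  slope <- (lam_p - lam_m) / (2 * eps)
  expect_equal(slope, unname(g["S_alpha"]), tolerance = 0.05)
})

test_that("selection profiles export to CSV plus JSON averages", {
  tmp <- withr::local_tempdir()
  prof <- ref_profile()
  f <- file.path(tmp, "profile.csv")
  export_profile_csv(prof, f)
  df <- utils::read.csv(f)
  expect_true(all(c("t", "fL", "fV", "vL", "vV", "rw", "S_alpha",
                    "S_phi") %in% names(df)))
  avg <- jsonlite::read_json(paste0(f, ".json"))
  expect_equal(avg$S_alpha, unname(prof$averages["S_alpha"]),
               tolerance = 1e-12)
})
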