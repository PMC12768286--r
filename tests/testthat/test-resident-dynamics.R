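p_def <- model_params()
fo_sq <- forcing_square()
st_ref <- strategy_fixed(phi = 0.325, alpha = 0.0197)

test_that("resident derivatives match hand arithmetic", {
  # empty system: only the influx acts
  d0 <- resident_rhs(c(S = 0, Sstar = 0, L = 0, Lstar = 0, V = 0, A = 0),
                     0, p_def, forcing_constant(50), st_ref)
  expect_equal(unname(d0), c(50, 0, 0, 0, 0, 0))
  # frozen term-by-term arithmetic for a hand-picked interior state:
  # S=100, L=50, V=1000, A=0, defaults, phi=0.325, alpha=0.0197, theta=0
  # (N = 150, growth = 0.85; dS = 85 - (0.1 + 0.1)*100 = 65;
  #  dL = 42.5 + 3.25 - 5.985;  dV = 67.5 + 9.85 - 115;  dA = 10 + 50)
  d <- resident_rhs(c(S = 100, Sstar = 0, L = 50, Lstar = 0, V = 1000,
                      A = 0),
                    5, p_def, forcing_square(thetaMax = 0), st_ref)
  expect_equal(unname(d), c(65, 0, 39.765, 0, -37.65, 60),
               tolerance = 1e-12)
  expect_error(resident_rhs(c(S = -1, Sstar = 0, L = 0, Lstar = 0, V = 0,
                              A = 0), 0, p_def, fo_sq, st_ref),
               "non-negative")
})

test_that("compiled kernel agrees with the R reference right-hand side", {
  y0 <- c(S = 400, Sstar = 20, L = 80, Lstar = 5, V = 2000, A = 0.05)
  p <- model_params(sigma = 0.1)
  sp <- strategy_plastic(alphaMax = 0.02, Aalpha = 0.1, phiMax = 0.3,
                         Aphi = 0.06, alphaMaxStar = 0.06,
                         AalphaStar = 0.09)
  tr_c <- integrate_resident(y0, 0, 5, p, fo_sq, sp,
                             times = seq(0, 5, 1))
  rhs_wrap <- function(t, y, parms) {
    names(y) <- c("S", "Sstar", "L", "Lstar", "V", "A")
    list(resident_rhs(y, t, p, fo_sq, sp))
  }
  tr_r <- deSolve::lsoda(y0, seq(0, 5, 1), rhs_wrap, NULL,
                         rtol = 1e-10, atol = 1e-12)
  for (j in 1:6)
    expect_equal(tr_c[[j + 1]], unname(tr_r[, j + 1]), tolerance = 1e-6)
})

test_that("stressed classes stay empty without stress", {
  y0 <- c(S = 500, Sstar = 0, L = 1, Lstar = 0, V = 1, A = 0)
  d <- resident_rhs(y0, 0, p_def, fo_sq, st_ref)
  expect_equal(unname(d[c("Sstar", "Lstar")]), c(0, 0))
  att <- ref_attractor()
  expect_true(all(att$states[, "Sstar"] == 0))
  expect_true(all(att$states[, "Lstar"] == 0))
})

test_that("virus-free dynamics settle on the logistic-with-influx balance", {
  y0 <- c(S = 10, Sstar = 0, L = 0, Lstar = 0, V = 0, A = 0)
  tr <- integrate_resident(y0, 0, 400, p_def, forcing_constant(50),
                           strategy_fixed())
  # scalar-root oracle: theta0 + r*S*(1 - kappa*S) - dS*S = 0
  root <- uniroot(function(S) 50 + S * (1 - 1e-3 * S) - 0.1 * S,
                  c(100, 5000), tol = 1e-10)$root
  expect_equal(tr$S[nrow(tr)], root, tolerance = 1e-6)
})

test_that("arbitrium stays at zero without production", {
  p0 <- model_params(piV = 0, piL = 0)
  y0 <- c(S = 500, Sstar = 0, L = 10, Lstar = 0, V = 100, A = 0)
  tr <- integrate_resident(y0, 0, 80, p0, fo_sq, st_ref)
  expect_true(all(tr$A == 0))
})

test_that("the square-wave attractor is periodic, bounded and non-negative", {
  att <- ref_attractor()
  expect_true(att$converged)
  expect_equal(att$period, 40)
  expect_true(all(att$states >= 0))
  expect_true(all(is.finite(att$states)))
  # one virion peak per period
  v <- att$states[, "V"]
  peaks <- sum(diff(sign(diff(v))) == -2)
  expect_equal(peaks, 1L)
  # re-integration over one period returns to the starting state
  y_end <- integrate_resident(att$states[1L, ], 0, 40, p_def, fo_sq,
                              st_ref, times = c(0, 40))
  rel <- abs(unlist(y_end[2, 2:7]) - att$states[1L, ]) /
    pmax(att$states[1L, ], 1e-8)
  expect_lt(max(rel), 10 * 1e-6)
})

test_that("arbitrium production balances degradation on the attractor", {
  att <- ref_attractor()
  st <- att$states
  prod <- 1 * 1e-4 * st[, "V"] * (st[, "S"] + st[, "Sstar"]) +
    1 * (st[, "L"] + st[, "Lstar"])
  N <- rowSums(st[, c("S", "Sstar", "L", "Lstar")])
  degr <- (0 + 10 * N) * st[, "A"]
  mp <- averaged_gradient(prod, att$times)
  md <- averaged_gradient(degr, att$times)
  expect_lt(abs(mp - md) / mp, 0.01)
})

test_that("constant forcing yields a fixed point", {
  att <- find_attractor(p_def, forcing_constant(50), st_ref)
  expect_true(att$converged)
  expect_true(all(apply(att$states, 2, function(x) diff(range(x))) == 0))
})

test_that("the attractor is robust to the integrator tolerance", {
  att1 <- ref_attractor()
  att2 <- find_attractor(p_def, fo_sq, st_ref, rtol = 2e-8, atol = 2e-10)
  rel <- abs(att2$states - att1$states) / pmax(abs(att1$states), 1e-8)
  expect_lt(max(rel), max(att1$metric, att2$metric))
})

test_that("trajectories export to CSV with headers and a JSON sidecar", {
  tmp <- withr::local_tempdir()
  att <- ref_attractor()
  f <- file.path(tmp, "att.csv")
  export_csv(att, f)
  df <- utils::read.csv(f)
  expect_named(df, c("t", "S", "Sstar", "L", "Lstar", "V", "A", "theta"))
  meta <- jsonlite::read_json(paste0(f, ".json"))
  expect_equal(meta$period, 40)
  expect_true(meta$converged)
})
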