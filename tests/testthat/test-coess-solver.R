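test_that("scenarios validate their staging requirements", {
  scn <- scenario("fluctuating_fixed_no_stress")
  expect_equal(scn$sigma, 0)
  expect_setequal(scn$free, c("alpha", "phi"))
  expect_error(scenario("fluctuating_fixed_with_stress"), "staged")
  expect_error(scenario("fluctuating_plastic_no_stress"), "staged")
  scn4 <- scenario("fluctuating_plastic_with_stress",
                   fixed = list(alphaMax = 0.02, phiMax = 0.3,
                                alphaMaxStar = 0.06))
  expect_equal(scn4$sigma, 0.1)
  expect_equal(scn4$fixed$phiMaxStar, 0)
  expect_error(scenario("fluctuating_fixed_no_stress",
                        fixed = list(alpha = 0.1)),
               "disjoint")
  expect_error(scenario("fluctuating_fixed_no_stress",
                        fixed = list(Aalpha = 0.1)),
               "unknown fixed")
})

test_that("the box-constrained root finder handles interior and boundary roots", {
  # analytic toy gradient: root at x1 = 0.3; x2 pushed below its bound
  g <- function(x) c(a = -(x[["a"]] - 0.3), b = -(x[["b"]] + 0.2))
  fit <- lysogeny:::newton_box(g, c(a = 0.6, b = 0.5), lower = c(0, 0),
                               upper = c(1, 1), gtol = 1e-10)
  expect_true(fit$converged)
  expect_equal(fit$x[["a"]], 0.3, tolerance = 1e-8)
  expect_equal(fit$x[["b"]], 0)
  expect_true(fit$boundary[["b"]])
  expect_false(fit$boundary[["a"]])
  # interior 2-d root of a coupled system
  g2 <- function(x) c(a = x[["b"]] - x[["a"]]^2, b = 0.25 - x[["b"]])
  fit2 <- lysogeny:::newton_box(g2, c(a = 0.9, b = 0.9), c(0, 0), c(1, 1),
                                gtol = 1e-10)
  expect_equal(unname(fit2$x), c(0.5, 0.25), tolerance = 1e-6)
})

test_that("constant-environment equilibrium satisfies the influx identity", {
  st <- strategy_fixed(phi = 0.284, alpha = 0.02)
  eq <- equilibrium_constant(model_params(), 50, st)
  expect_lt(abs(eq$identity_lhs - eq$identity_rhs), 1e-6)
  expect_lt(abs(eq$rw), 1e-6)
  expect_equal(sum(eq$f), 1)
  expect_equal(sum(eq$v * eq$f), 1)
  # direction of selection on reactivation is set by theta0 - a*V*S
  for (al in c(0.005, 0.08)) {
    eqa <- equilibrium_constant(model_params(), 50,
                                strategy_fixed(phi = 0.284, alpha = al))
    expect_equal(sign(eqa$S_alpha), sign(eqa$selection_sign_driver))
  }
})

test_that("constant-environment singular strategies form a curve, not a point", {
  res <- solve_scenario(scenario("constant_no_stress"))
  expect_s3_class(res, "coess_result")
  expect_null(res$traits)
  cv <- res$curve
  ok <- !is.na(cv$phi)
  expect_gte(sum(ok), 3)
  expect_true(all(abs(cv$residual[ok]) < 1e-6))
  # reactivation and lysogenisation gradients are proportional with
  # opposite signs at any constant-environment equilibrium
  eq <- equilibrium_constant(model_params(), 50,
                             strategy_fixed(phi = 0.5, alpha = 0.02))
  expect_lt(eq$S_alpha * eq$S_phi, 0)
})

test_that("a degenerate sweep reproduces the base attractor", {
  st <- strategy_fixed(phi = 0.325, alpha = 0.0197)
  sw <- parameter_sweep(model_params(), forcing_square(), st, "B", 10,
                        n_points = 501)
  expect_equal(nrow(sw), 1L)
  att <- find_attractor(model_params(), forcing_square(), st,
                        n_points = 501)
  expect_true(sw$virus_persists)
  expect_equal(sw$V_min, min(att$states[, "V"]))
  expect_equal(sw$V_max, max(att$states[, "V"]))
  expect_equal(sw$A_mean, lysogeny:::trapezoid_mean(att$states[, "A"],
                                                    att$times))
})

test_that("the lysis-arbitrium anticorrelation persists across burst sizes", {
  st <- strategy_fixed(phi = 0.325, alpha = 0.0197)
  sw <- parameter_sweep(model_params(), forcing_square(), st, "B",
                        c(5, 10, 20), n_points = 501)
  expect_equal(sw$value, c(5, 10, 20))
  persists <- sw$virus_persists
  expect_true(all(sw$negative_covariance[persists]))
})
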