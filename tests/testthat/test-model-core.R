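test_that("parameter construction validates inputs", {
  p <- model_params()
  expect_s3_class(p, "phage_params")
  expect_equal(p$kappa, 1e-3)
  expect_equal(p$delta, 10)
  expect_error(model_params(r = -1), "non-negative")
  expect_error(model_params(B = 0.5), "'B'")
  expect_error(model_params(k = 0), "'k'")
  expect_error(forcing_square(g = 0), "'g'")
  expect_error(forcing_square(g = 1.2), "'g'")
})

test_that("square-wave influx follows the duty cycle and its period mean", {
  fo <- forcing_square(thetaMax = 250, g = 0.2, T = 40)
  expect_equal(influx(0, fo), 250)
  expect_equal(influx(7.999, fo), 250)
  expect_equal(influx(8, fo), 0)    # half-open [0, g) convention
  expect_equal(influx(20, fo), 0)
  expect_equal(influx(40, fo), 250) # periodic
  # quadrature over one period equals g * thetaMax * T
  int <- stats::integrate(function(t) influx(t, fo), 0, 40,
                          subdivisions = 2000L, stop.on.error = FALSE)
  expect_equal(int$value / 40, 50, tolerance = 1e-3)
  expect_error(influx(-1, fo), "non-negative")
  expect_equal(influx(123.4, forcing_constant(50)), 50)
})

test_that("forcing discontinuities are exposed for integrator restarts", {
  fo <- forcing_square()
  br <- forcing_breaks(fo, 0, 80)
  expect_equal(br, c(8, 40, 48))
  expect_length(forcing_breaks(forcing_constant(), 0, 100), 0)
})

test_that("smoothed Heaviside matches its closed form and limits", {
  expect_equal(smooth_heaviside(0, 10), 0.5)
  expect_equal(smooth_heaviside(-1, 10), 0.5 - atan(10) / pi)
  expect_equal(smooth_heaviside(1e9, 10), 1, tolerance = 1e-8)
  expect_equal(smooth_heaviside(-1e9, 10), 0, tolerance = 1e-8)
  x <- seq(-3, 3, length.out = 101)
  expect_true(all(diff(smooth_heaviside(x, 5)) > 0))
  # pointwise convergence to the step: k = 1000, |x| >= 1
  xx <- c(-5, -2, -1, 1, 2, 5)
  expect_true(all(abs(smooth_heaviside(xx, 1000) - (xx > 0)) < 0.01))
  expect_error(smooth_heaviside(1, k = -1), "positive")
})

test_that("fixed strategies ignore arbitrium; plastic norms respond to it", {
  sf <- strategy_fixed(phi = 0.325, alpha = 0.0197)
  for (A in c(0, 0.05, 10)) {
    tr <- evaluate_strategy(sf, A)
    expect_equal(tr$alpha, 0.0197)
    expect_equal(tr$phi, 0.325)
  }
  sp <- strategy_plastic(alphaMax = 0.02, Aalpha = 0.1,
                         phiMax = 0.3, Aphi = 0.06,
                         alphaMaxStar = 0.06, AalphaStar = 0.09)
  # half-maximum exactly at the threshold
  expect_equal(evaluate_strategy(sp, 0.1)$alpha, 0.01)
  expect_equal(evaluate_strategy(sp, 0.06)$phi, 0.15)
  expect_equal(evaluate_strategy(sp, 0.09)$alphaStar, 0.03)
  # limits: reactivation off, lysogenisation maximal at saturating signal
  hi <- evaluate_strategy(sp, 1e9)
  expect_equal(hi$alpha, 0, tolerance = 1e-7)
  expect_equal(hi$phi, 0.3, tolerance = 1e-6)
  # at A = 0 the norms sit at H_k(-1) of their range (k = 10 tails)
  lo <- evaluate_strategy(sp, 0)
  expect_equal(lo$alpha, 0.02 * (0.5 + atan(10) / pi))
  expect_equal(lo$phi, 0.3 * (0.5 - atan(10) / pi))
  expect_error(evaluate_strategy(sp, -0.1), "non-negative")
})

test_that("plastic rates stay inside [0, max] for arbitrary signal levels", {
  set.seed(42)
  sp <- strategy_plastic(alphaMax = 0.05, Aalpha = 0.08,
                         phiMax = 0.9, Aphi = 0.04)
  A <- c(0, stats::rexp(200, rate = 5))
  tr <- evaluate_strategy(sp, A)
  expect_true(all(tr$alpha >= 0 & tr$alpha <= 0.05))
  expect_true(all(tr$phi >= 0 & tr$phi <= 0.9))
  # monotone: reactivation decreases, lysogenisation increases in A
  As <- sort(A)
  trs <- evaluate_strategy(sp, As)
  expect_true(all(diff(trs$alpha) <= 0))
  expect_true(all(diff(trs$phi) >= 0))
})

test_that("strategy validation rejects ill-formed reaction norms", {
  expect_error(strategy_fixed(phi = 1.2), "probability")
  expect_error(strategy_fixed(alpha = -0.1), "non-negative")
  expect_error(strategy_plastic(alphaMax = 0.1), "Aalpha")
  expect_error(strategy_plastic(phiMax = 0.2, Aphi = 0), "Aphi")
  # zero maximal rate switches the trait off; threshold not needed
  sp <- strategy_plastic(alphaMax = 0.02, Aalpha = 0.1)
  expect_equal(evaluate_strategy(sp, 0.5)$phi, 0)
})
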