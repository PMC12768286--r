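# Shared fixtures, computed once per test session.
.cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.cache[[key]])) .cache[[key]] <- force(expr)
  .cache[[key]]
}

# Default-parameter attractor at the fixed-trait reference strategy.
ref_attractor <- function() memo("ref_att", {
  find_attractor(model_params(), forcing_square(),
                 strategy_fixed(phi = 0.325, alpha = 0.0197))
})

ref_profile <- function() memo("ref_prof", selection_profile(ref_attractor()))

# The staged coESS pipeline: fixed traits without stress, stressed-cell
# traits with the stage-1 solution fixed, then the arbitrium thresholds
# with the staged maximal rates fixed.
staged_solutions <- function() memo("stages", {
  s1 <- solve_scenario(scenario("fluctuating_fixed_no_stress"))
  s2 <- solve_scenario(scenario("fluctuating_fixed_with_stress",
                                fixed = as.list(s1$free)))
  s3 <- solve_threshold_scenario(scenario(
    "fluctuating_plastic_no_stress",
    fixed = list(alphaMax = s1$free[["alpha"]],
                 phiMax = s1$free[["phi"]])))
  s4 <- solve_threshold_scenario(scenario(
    "fluctuating_plastic_with_stress",
    fixed = list(alphaMax = s1$free[["alpha"]],
                 phiMax = s1$free[["phi"]],
                 alphaMaxStar = s2$free[["alphaStar"]])))
  list(s1 = s1, s2 = s2, s3 = s3, s4 = s4)
})
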