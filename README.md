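# lysogeny

Evolution of temperate-phage lysis–lysogeny decisions in fluctuating
environments.

Temperate phage face a recurring gamble: lyse the host now and release
`B` virions that must find new cells, or integrate as a prophage and
ride the host lineage. The best choice depends on the state of the
current host (a stressed, SOS-induced cell cannot divide) and on the
availability of susceptible hosts outside — which the phage reads
indirectly through the concentration of a secreted peptide signal
(arbitrium) that accumulates when infections have been frequent.
`lysogeny` is a toolkit for researchers in evolutionary epidemiology
and phage biology who want to compute, rather than intuit, how
selection shapes these decisions: it simulates the resident
host–phage–arbitrium system under constant or square-wave influx of
susceptible cells, performs the selection analysis on the periodic
attractor, and solves for (co)evolutionarily stable strategies of both
fixed traits and arbitrium-dependent reaction norms.

## The model in brief

The resident state is `(S, S*, L, L*, V, A)`: susceptible and
lysogenic cells in normal and stressed states, virions, and the
arbitrium concentration, with logistic cell growth `r(1 - κN)`,
adsorption `a`, burst size `B`, stress rate `σ`, recovery `γ`, and
arbitrium production/degradation `π_V, π_L, d_A + δN`. The traits
under selection are the lysogenisation probabilities `φ, φ*` and the
prophage reactivation rates `α, α*`; a plastic strategy replaces each
by a smoothed threshold function of the signal, e.g.
`α(A) = α_max (1 − H_k(A/A_α − 1))` with
`H_k(x) = 1/2 + arctan(kx)/π`.

Selection on a rare mutant is measured through the class-structured
machinery: class frequencies `f(t)`, reproductive values `v(t)`
(computed exactly via the monodromy matrix of the class dynamics), and
instantaneous gradients such as `S_α(t) = (B v_V − v_L) f_L`, averaged
over one forcing period. A coESS is a trait vector at which all free
averaged gradients vanish (or point outward at a boundary, as for
lysogenisation in stressed cells). Floquet invasion exponents provide
an independent check that these gradients are genuine derivatives of
invasion fitness. See the methods vignette
(`vignettes/lysogeny-methods.Rmd`) for the full model and the
numerical choices.

## Worked example

Resident dynamics at the reference fixed strategy, the selection
profile on the attractor, and the coESS of the no-stress fluctuating
scenario:

```r
library(lysogeny)

att <- find_attractor(model_params(), forcing_square(),
                      strategy_fixed(phi = 0.325, alpha = 0.0197))
att
#> Periodic attractor (square_wave forcing): period 40 h, 2001 grid points
#>   converged: TRUE after 6 periods (metric 2.83e-07)
#>   state ranges:
#>     S      [1.469, 612.1]
#>     Sstar  [0, 0]
#>     L      [425.4, 878.7]
#>     Lstar  [0, 0]
#>     V      [953.3, 5132]
#>     A      [0.05537, 0.09985]

selection_profile(att)
#> Selection profile on the periodic attractor
#>   v.f conservation defect: 4e-15 (0 backward sweeps)
#>   period-averaged gradients:
#>       S_alpha   S_alphaStar         S_phi     S_phiStar
#> -0.0269728505  0.0000000000  0.0005863819  0.0000000000

solve_scenario(scenario("fluctuating_fixed_no_stress"))
#> coESS solve: fluctuating_fixed_no_stress
#>   converged: TRUE in 7 iterations
#>   solved traits:
#>     alpha = 0.01904  [residual gradient 1.39e-10]
#>     phi = 0.3239  [residual gradient -1.4e-12]
```

Reading this: over one 40 h period the susceptible pool swings from
~1.5 to ~600 cells/ml as the influx pulses on and off, virions peak
once per period, and the arbitrium signal oscillates around 0.08
mol/ml. At the reference strategy the period-averaged gradient on
reactivation is slightly negative and on lysogenisation slightly
positive, so the joint root — the coESS — sits at a marginally lower
reactivation rate (`α ≈ 0.0190 h⁻¹`) and lysogenisation probability
`φ ≈ 0.324`. Staging this solution into the stressed-cell scenario
(`scenario("fluctuating_fixed_with_stress", fixed = as.list(s1$free))`)
yields a *higher* reactivation rate and a boundary optimum `φ* = 0` in
stressed cells; fixing the solved maxima and solving the plastic
scenarios yields the arbitrium thresholds of the reaction norms.

A thin command-line front end over the same functions lives in
`inst/scripts/lysogeny-cli.R` (subcommands `simulate`, `gradients`,
`coess`, `sweep`, each taking `--config`, `--out`, `--seed`).

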