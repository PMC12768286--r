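---
title: "Selection on lysis-lysogeny decisions in fluctuating environments: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selection on lysis-lysogeny decisions in fluctuating environments: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The biological problem

A temperate phage can transmit horizontally, by lysing its host and
releasing virions, or vertically, by integrating as a prophage and
replicating with the host lineage. Which route pays depends on two
things the phage cannot observe directly: the viability of its current
host, and the availability of susceptible hosts in the population. Real
phage have evolved sensors for both. The host's SOS (DNA-damage) response
reports the state of the current cell; a phage-encoded peptide signal
(arbitrium), secreted during infection and lysogeny and degraded by
cells, accumulates when infections have been frequent and susceptible
hosts are scarce, so its concentration carries indirect information
about the outside world.

`lysogeny` implements a deterministic evolutionary-epidemiology
framework for this situation: a resident host–phage–arbitrium system
driven to its periodic attractor, a selection analysis on that
attractor built from class frequencies and reproductive values, and
nested solvers that locate (co)evolutionarily stable strategies (coESS)
for fixed traits and for arbitrium-dependent reaction norms, in normal
and in stressed (SOS-induced) cells.

## The resident model

The state is $(S, S^*, L, L^*, V, A)$: susceptible and lysogenic cells
in normal and stressed (starred) physiological states, free virions,
and the arbitrium concentration. With total cell density
$N = S + S^* + L + L^*$:

$$
\begin{aligned}
\dot S   &= \theta(t) + r S (1-\kappa N) - (aV + d_S + \sigma) S + \gamma S^* \\
\dot S^* &= \sigma S - (aV + d_{S^*} + \gamma) S^* \\
\dot L   &= r L (1-\kappa N) + a \phi V S - (\alpha + d_L + \sigma) L + \gamma L^* \\
\dot L^* &= \sigma L + a \phi^* V S^* - (\alpha^* + d_{L^*} + \gamma) L^* \\
\dot V   &= a B V \big[(1-\phi) S + (1-\phi^*) S^*\big] + (\alpha L + \alpha^* L^*) B - (aN + d_V) V \\
\dot A   &= \pi_V\, a V (S + S^*) + \pi_L (L + L^*) - (d_A + \delta N) A .
\end{aligned}
$$

Stressed cells cannot divide, recover at rate $\gamma$, and are created
at rate $\sigma$. Adsorption of a virion to a susceptible cell
lysogenises it with probability $\phi$ (normal) or $\phi^*$ (stressed)
and otherwise triggers an immediate burst of $B$ virions; prophage
reactivate (and burst) at rates $\alpha$, $\alpha^*$. The arbitrium
equation is kept as a genuine ODE even though its relaxation is fast
($\delta N \sim 10^{3\text{--}4}\,h^{-1}$ at the defaults): treating it
quasi-statically would couple the trait evaluation to an algebraic
constraint for little gain, and the stiff integrator absorbs the fast
mode.

The influx of susceptible cells $\theta(t)$ is either constant
($\theta_0$) or a square wave: $\theta = \theta_{\max}$ while the
fractional phase $(t \bmod T)/T$ lies in $[0, g)$ and $0$ otherwise
(half-open convention, so period boundaries are unambiguous). Defaults
$\theta_{\max} = 250$, $g = 0.2$, $T = 40\,h$ give a period mean of 50
cells ml$^{-1}$ h$^{-1}$, matching the constant-influx reference. These
are the study conditions of the package's reference analyses; all other
defaults are in `?model_params`.

### Reaction norms

A plastic strategy expresses the traits as smoothed threshold functions
of the arbitrium concentration,

$$
\alpha(A) = \alpha_{\max}\big(1 - H_k(A/A_\alpha - 1)\big), \qquad
\phi(A) = \phi_{\max}\, H_k(A/A_\phi - 1),
$$

with $H_k(x) = 1/2 + \arctan(kx)/\pi$ and independent starred norms in
stressed cells. Reactivation is switched *off* and lysogenisation *on*
as the signal (scarcity of hosts) rises; at $A$ equal to a threshold
the rate is exactly half its maximum. The slope is fixed at $k = 10$
throughout the reference analyses; it is deliberately not solved for
(the smoothing exists to keep the selection gradients differentiable),
but it is exposed both as a parameter and as a sweep variable. Note
that $H_{10}$ has heavy arctan tails: at $A = 0$ a norm still sits at
$H_{10}(-1) \approx 0.032$ of its range, which is part of the model,
not an artefact.

## Selection analysis on the periodic attractor

A rare mutant experiences the resident environment. Its dynamics across
the three viral classes — prophage in a normal cell ($L$), prophage in
a stressed cell ($L^*$), free virion ($V$) — are linear,
$\dot n = M(t)\, n$, with

$$
M =
\begin{pmatrix}
r(1-\kappa N) - (\alpha_m + d_L + \sigma) & \gamma & a \phi_m S \\
\sigma & -(\alpha^*_m + d_{L^*} + \gamma) & a \phi^*_m S^* \\
\alpha_m B & \alpha^*_m B & a\big[(1-\phi_m)S + (1-\phi^*_m)S^*\big]B - (aN + d_V)
\end{pmatrix}
$$

evaluated along the resident attractor; the mutant's traits are
evaluated at the *resident* arbitrium concentration, because a rare
mutant does not perturb the signal field. The instantaneous selection
gradient on a trait $z$ is $S_z(t) = v(t) \cdot \partial_z M(t) \cdot
f(t)$, which for the four rates reduces to products of the *selection
balance* $B v_V - v_{L}$ (or $B v_V - v_{L^*}$) with class frequencies:

$$
S_\alpha = (B v_V - v_L) f_L, \quad
S_{\alpha^*} = (B v_V - v_{L^*}) f_{L^*}, \quad
S_\phi = -(B v_V - v_L)\, a S f_V, \quad
S_{\phi^*} = -(B v_V - v_{L^*})\, a S^* f_V .
$$

Selection favours lysis exactly when a burst of $B$ virions is worth
more than the prophage it destroys. The direction of long-term
evolution is the gradient averaged over one period of the attractor,
$\hat S_z = \frac1T \int_0^T S_z(t)\,dt$.

### Class frequencies

Because the resident's own class abundances $(L, L^*, V)$ solve
$\dot n = M n$ identically (this is an algebraic identity between the
resident equations and $M$), the class-frequency dynamics — the
sum-normalised linear system — are solved *exactly* by
$f(t) = n(t)/\mathbf 1^\top n(t)$, and the per-capita growth rate of
the resident viral population is
$r_w(t) = \mathbf 1^\top M n / \mathbf 1^\top n$, the unique
normalisation that conserves $\sum_i f_i = 1$. `class_frequencies()`
therefore normalises the attractor abundances instead of redundantly
re-integrating a frequency ODE; a finite-difference test verifies that
$r_w$ equals the growth of the summed abundances.

### Reproductive values

Reproductive values solve the adjoint system
$\dot v = r_w v - M^\top v$ with the periodicity condition
$v(0) = v(T)$ and normalisation $v \cdot f = 1$. Two routes are
implemented:

* **Monodromy (default).** The $3 \times 3$ fundamental matrix
  $\Phi(t)$ of $\dot x = M x$ is co-integrated with the resident state
  over one period, so $M$ is always evaluated exactly rather than
  interpolated. The exactly periodic boundary condition is the left
  eigenvector of $\Phi(T)$ for its dominant (unit) multiplier, and
  $v(t)$ is reconstructed pointwise from small linear solves. The
  conservation defect $\max_t |v \cdot f - 1|$ is typically
  $\sim 10^{-14}$.
* **Backward sweeps** (`method = "sweep"`). The adjoint is integrated
  backward over repeated periods; backward time contracts at the
  subdominant Floquet multiplier ($\sim 6\times10^{-3}$ per period at
  the defaults, so three sweeps suffice). The coefficients come from
  linearly interpolated tables of the resident densities, which sets a
  noise floor of order $10^{-4}$ on $v$; the sweep therefore stops at
  tolerance *or* at stagnation. This route is retained purely as an
  independent cross-check of the monodromy route, and the test suite
  holds the two to agreement at that floor.

The monodromy construction was preferred over iterated sweeps as the
default because it is exact on the grid, faster (one augmented
integration instead of several), and free of interpolation error —
the $v \cdot f = 1$ conservation then holds to machine precision
instead of the $\sim 10^{-5}$ achievable through interpolated
forcing tables.

An independent fitness measure, `invasion_exponent()`, integrates the
mutant monodromy matrix over one period and returns the dominant
Floquet exponent. At the resident it is zero; its derivative in any
trait equals the averaged gradient (the test suite checks the slope to
5%), and its sign agrees with first-order predictions for random small
perturbations. This is the package's oracle that the gradient pipeline
and the raw invasion dynamics describe the same selection.

### Reaction-norm parameters

For plastic strategies the chain rule converts the rate gradients into
gradients on the norm parameters, e.g.

$$
\hat S_{A_\alpha} = \alpha_{\max} \left\langle S_\alpha(t)\,
\frac{k A(t)}{\pi\big(A_\alpha^2 + k^2 (A(t) - A_\alpha)^2\big)}
\right\rangle ,
$$

where the weight is $-\partial_{A_\alpha} H_k(A/A_\alpha - 1)$
(verified against finite differences), and analogously for $A_\phi$
and the starred thresholds, and for the maximal rates with
$H_k$-weights. A zero maximal rate makes the corresponding threshold
gradient identically zero and removes that threshold from any solve.

## Locating the attractor

The resident system is integrated with `deSolve`'s stiff-capable
`lsoda` (compiled right-hand sides; `rtol = 1e-8`, `atol = 1e-10`),
*restarting at every forcing discontinuity* — phase $0$ and phase $g$
of each period — so no step straddles a jump. The rare `lsoda` failure
mode on the fast arbitrium relaxation (step-budget exhaustion during
mode switching) falls back to BDF with a tighter absolute tolerance.
The period map is iterated from an interior default start
($S = \langle\theta\rangle/d_S$, $L = V = 1$, $A = S^* = L^* = 0$)
until the boundary state changes by less than `tol = 1e-6` (relative),
with a cap of 200 periods; convergence takes 6–20 periods at the
defaults because the attractor is strongly contracting. The start is a
free choice that does not affect the attractor (checked by multi-start
in the solver). One period is then sampled on 2001 equally spaced
points (the forcing switch at $gT$ falls on the grid) and period
averages use trapezoid quadrature on that grid; gradients are
non-smooth at the forcing jumps, which trapezoid handles without
order loss. The reference coESS values move by less than $10^{-5}$
between 1001 and 8001 points per period, so 2001 is comfortable;
the test suite also runs a coarsened 501-point solve to document the
discretisation sensitivity.

Under constant forcing the attractor degenerates to a fixed point,
found by relaxation in 50 h chunks to the same tolerance, and the
selection analysis reduces to eigenvectors of the equilibrium matrix
$\hat M$: $f$ the right null vector, $v$ the left, $r_w = 0$.

## Solving for (co)ESS

The solver is *nested*: for every candidate trait vector the resident
attractor is recomputed (warm-started from the previous candidate),
frequencies, reproductive values and averaged gradients are rebuilt,
and a projected damped Newton iteration with a finite-difference
Jacobian drives the free averaged gradients to zero inside box bounds
(rates and probabilities in $[0,1]$, thresholds in $[10^{-3}, 1]$).
Bracketing-style damping (step halving on non-improvement) copes with
the mild quadrature-scale noise of the gradients. A trait pinned at a
bound with an outward-pointing gradient is frozen there and reported
as a *boundary optimum* — this is how the zero stressed-cell
lysogenisation probability is detected, rather than by forcing an
interior root. Optional multi-start (uniform draws in the viable lower
half of the boxes, seeded) probes uniqueness; in the fluctuating
scenarios all converged starts agree to well under 1%.

The five scenarios are staged the way the analysis is meant to be
read: (1) fixed traits, square-wave influx, no stress; (2) stressed
cell traits with the stage-1 normal traits held fixed and
$\sigma = 0.1$; (3) arbitrium thresholds with the maximal rates fixed
at the stage-1 solution, no stress; (4) the full model with all four
maxima fixed at the stage-1/2 solutions and three free thresholds.
Later stages take their fixed inputs *explicitly* from earlier
solutions (`scenario(..., fixed = )`); the package deliberately ships
no hard-wired staged constants, because the staging only makes sense
relative to the pipeline's own converged upstream values — feeding the
full model maxima that are not a coESS of the fixed-trait stages can
push the stressed-cell threshold to its bound (if the fixed
$\alpha^*_{\max}$ is below the stressed-cell optimum, selection keeps
reactivation on at every signal level and $A_{\alpha^*}$ has no
interior root).

In a **constant environment** the averaged gradients on reactivation
and lysogenisation are proportional with opposite signs — both are the
selection balance $B \hat v_V - \hat v_L$ times positive factors — so
no isolated ESS exists: the singular strategies form a one-dimensional
curve $\{(\alpha, \phi): \hat v_L = B \hat v_V\}$. `solve_scenario()`
returns that curve sampled over a reactivation grid (each point found
by 1-d root finding in $\phi$) instead of pretending to a point, and
`equilibrium_constant()` exposes the identity
$r(1-\kappa \hat N) - d_L = a\hat V - \theta_0/\hat S$ linking the
sign of selection on reactivation to
$\mathrm{sign}(\theta_0 - a \hat V \hat S)$: reactivation is favoured
whenever fresh susceptibles arrive faster than standing ones are
infected.

## What the model idealises

The framework is deterministic and well mixed: no demographic noise,
no spatial structure, no coinfection or polylysogeny, and mutants are
rare by construction (two genotypes never coexist at comparable
frequencies). Arbitrium sensing is noiseless and instantaneous, with a
single threshold per trait; real signal transduction is stochastic at
the single-cell level. The square wave is the simplest forcing with a
well-defined duty fraction; it makes the attractor's phase structure
(and hence the covariance between the selection balance and the
signal) easy to interpret, but quantitative trait values depend on the
forcing's period and amplitude. Consequently, agreement of the staged
solutions with reference values under these conditions demonstrates
the correctness of the selection machinery, not the realism of any
particular parameter.

Known numerical limitations: the stressed-cell stages are the most
delicate — their gradients involve the small stressed-class
frequencies, so their solved values are more sensitive than the
normal-cell ones to the exact composition of the virion-production
term in the class dynamics (the package uses the form consistent with
the resident equations and the mutant matrix throughout); thresholds
are only identified where the resident signal actually visits values
around them ($A(t)$ spans roughly 0.05–0.10 mol ml$^{-1}$ at the
defaults); and virus extinction at extreme trait values is reported
(sweeps) or handled by backtracking (solver), not integrated through.

## Problem sizes used by the tests

The test suite and the acceptance script run the full staged pipeline
at 2001 grid points per period with attractor tolerance $10^{-6}$
(plus one 501-point coarse solve), which completes in seconds; the
heavier consistency checks (invasion exponents for ten random
perturbations, dual-route reproductive values) reuse one cached
attractor per configuration.

```{r example}
library(lysogeny)

s1 <- solve_scenario(scenario("fluctuating_fixed_no_stress"))
s2 <- solve_scenario(scenario("fluctuating_fixed_with_stress",
                              fixed = as.list(s1$free)))
s3 <- solve_threshold_scenario(scenario(
  "fluctuating_plastic_no_stress",
  fixed = list(alphaMax = s1$free[["alpha"]], phiMax = s1$free[["phi"]])))
s4 <- solve_threshold_scenario(scenario(
  "fluctuating_plastic_with_stress",
  fixed = list(alphaMax = s1$free[["alpha"]], phiMax = s1$free[["phi"]],
               alphaMaxStar = s2$free[["alphaStar"]])))
s4
```
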