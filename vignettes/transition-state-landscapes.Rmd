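---
title: "Quantifying transition states on static and transitory landscapes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying transition states on static and transitory landscapes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

A differentiating cell can be pictured as a marble rolling on Waddington's
epigenetic landscape: valleys are stable phenotypes, and the ridge point
between two valleys — the **transition state** (TS) — is what every cell must
negotiate to change fate. This package makes that picture quantitative for
stochastic dynamical models

$$dX = f(X;\theta)\,dt + g(X;\eta)\,dW_t,$$

in two complementary senses:

* **Static landscapes.** With fixed parameters, the TS is an unstable fixed
  point (saddle) of the drift $f$. The landscape is quantified from the
  stationary distribution as $U = -\ln P_s(X)$, and the most probable
  transition routes are minimum action paths (MAPs) of the Freidlin–Wentzell
  functional.
* **Transitory landscapes.** When an external control deforms the landscape
  over time, the TS manifests instead as a *window of maximal cell-to-cell
  heterogeneity*: the ensemble variance of the switching variable rises to an
  interior peak while cells desynchronously hop basins.

Two fully specified models exercise both views.

## The two-dimensional bistable model

The toy system is defined by the potential

$$U(x_1, x_2) = \lambda(x_1^4 + x_2^4) - \alpha x_1^2 + \beta x_1$$

with drift $f = -\nabla U + f_U$, where the curl component

$$f_U = c\,\bigl(4\lambda x_2^3,\; 2\alpha x_1 - 4\lambda x_1^3 - \beta\bigr)$$

satisfies $\nabla U \cdot f_U = 0$ everywhere (`toy_decomposition()` asserts
this to $10^{-10}$ in the test-suite). Isotropic additive noise of amplitude
$\sigma$ completes the SDE.

Defaults: $[\alpha, \lambda, \beta, c, \sigma] = [0.5,\ 0.25,\ -0.05,\ 0.5,\ 0.4]$
(all dimensionless). What each controls:

* $\alpha$ — curvature scale; the saddle's positive eigenvalue is exactly
  $2\alpha$, so $\alpha$ sets how fast trajectories leave the TS.
* $\lambda$ — confining quartic; the wells sit near $x_1 \approx \pm 1$ when
  $2\alpha = 4\lambda$.
* $\beta$ — tilt; the system is bistable for $|\beta| < \beta_c \approx 0.385$
  at the defaults and monostable beyond.
* $c$ — curl magnitude. The stationary *distribution* is essentially blind to
  $c$ (the package's curl-indistinguishability criterion bounds the
  total-variation distance between matched histograms at $c = 0$ and
  $c = 0.5$ by 0.05), but transition *paths* are not: with curl, forward and
  reverse MAPs differ.
* $\sigma$ — noise amplitude; sets the basin-escape rate.

Two analytic facts anchor the MAP machinery. For a pure gradient system
($c = 0$) with isotropic noise, the minimized uphill action equals
$2\,\Delta U/\sigma^2$ — at $\beta = 0$ this is $2 \cdot 0.25 / 0.16 = 3.125$,
which `minimize_action()` must reproduce within 2%. With the orthogonal curl
component, the uphill MAP leg follows the flow $\dot X = \nabla U + f_U$;
`toy_uphill_reference_path()` constructs this heteroclinic independently of
the optimizer (see *Numerical choices*) and the optimized path must stay
within a 0.05-tube of it.

## The developmental network

The second model tracks molecule copy numbers of four regulators of early
stem-cell fate: Nanog ($N$), the Oct4–Sox2 complex ($O$), Fgf4 ($F$) and the
differentiation marker Gata6 ($G$), with the LIF concentration $L$ as an
external control ($L \in [0, 200]$ in all shipped experiments). Each species
has one effective birth reaction with a Hill-type propensity — the
quasi-equilibrium lumping of promoter binding, dimerization and complex
formation — and one first-order degradation with rate $k_d$:

* Nanog production ($a_1$) is activated by Oct4–Sox2, by Nanog itself
  (cooperatively, $k_2 N^2$) and by LIF ($k_3 L$), and repressed by Fgf4
  ($k_4 F^2$) and by Gata6 ($k_5 O G^2$).
* Oct4–Sox2 production ($a_2$) is self-sustaining and repressed by Gata6
  ($k_8 G^2$).
* Fgf4 production ($a_3$) is Oct4–Sox2-dependent.
* Gata6 production ($a_4$) is repressed by Nanog ($k_{13} N^2$) — the
  mutual-antagonism arm of the toggle — and activated by Gata6 itself and by
  Oct4–Sox2.

The stoichiometry matrix has one $+1$ (birth) and one $-1$ (death) per
species row; consequently the chemical-Langevin diffusion matrix
$S\,\mathrm{diag}(a)\,S^\top$ is **diagonal**, with entry
$a_i + a_{i+4}$ — a structure the action functional exploits.

High $N$ marks pluripotency, high $G$ differentiation; mutual inhibition
makes the both-high state inaccessible. $1/k_d$ sets the relaxation
timescale; time is in arbitrary units.

## Calibrating the developmental parameter set

The sixteen kinetic constants are published as an undelimited numeral string
whose unique 16-token parse is

```
k0=0.005 k1=0.01 k2=0.4 k3=1 k4=0.1 k5=0.00135 k6=0.01 k7=0.01
k8=1 k9=1 k10=0.01 k11=5 k12=1 k13=0.005 k14=1 kd=1
```

This literal set cannot reproduce the reported phenomenology, and the failure
is structural, not numerical:

1. Every birth propensity is bounded by a constant of order one, so with
   $k_d = 1$ all fixed-point copy numbers are $O(1)$ — incompatible with a
   stem state at $N \approx 60{-}100$.
2. Rescaling $k_d$ alone (any uniform value; we scanned $10^{-3}$ to $1$)
   never yields more than one fixed point. The reason is the Gata6
   propensity: its basal production $k_{11} = 5$ dominates the Nanog
   repression term $k_{13} N^2 \le 0.005 \cdot 150^2 \approx 113$ only
   marginally, and the resulting Gata6 influx collapses Oct4–Sox2 (via
   $k_8 G^2$) and hence Nanog everywhere: the high-Gata6 state is globally
   attracting.

The package therefore ships two config-selectable sets
(`dev_params(set = ...)`, `inst/extdata/params/`):

* **`paper-printed`** — the literal parse, for reference;
* **`calibrated`** (default) — the same constants with
  $k_d = 0.01$ (copy numbers $\sim 100$), the Gata6 arm rebalanced
  ($k_{11}: 5 \to 0.05$, $k_{14}: 1 \to 0.1$, $k_{13}: 0.005 \to 0.5$ —
  weaker basal/Oct4-driven Gata6 production, stronger Nanog repression), and
  slightly stronger Nanog autoactivation ($k_2: 0.4 \to 0.45$, which keeps
  the stem branch alive down to $L = 0$).

The arbiter is the **structural calibration gate**
(`dev_structure_gate()`): across $L \in [0, 200]$ the model must have three
branch-tracked fixed points — a stable stem-cell state ($N \gg G$), a stable
differentiated state ($G \gg N$) and a transition state with at least one
positive-real-part Jacobian eigenvalue. The calibrated set was selected by
this deterministic gate *before* any stochastic experiment was run; the gate
itself is part of the test-suite. At $L = 50$ the calibrated model places the
stem state at $(N, O, F, G) \approx (67, 9.9, 100, 0.05)$, the transition
state at $\approx (27, 7.7, 100, 0.2)$ and the differentiated state at
$\approx (0, 0, 100, 100)$.

Known costs of staying inside this propensity family:

* The transition state's *location* inherits an $L$-dependence through the
  Oct4-mediated Nanog production, moving by tens of copy numbers across the
  sweep; only the differentiated branch is (nearly exactly, $< 0.1$ copies)
  $L$-invariant. The qualitative claims that do transfer — stem-branch Nanog
  non-decreasing in $L$, transition branch unstable at every $L$ with its
  positive eigenvalue growing, differentiated branch unmoved — are asserted
  in the tests.
* From the high-$N$/high-$G$ plateau the calibrated model differentiates
  directly (high Gata6 shuts Nanog down through $k_5 O G^2$ before Nanog can
  suppress Gata6) instead of first converging to the stem valley.

## Simulation machinery

* **Exact SSA** (`ssa_gillespie()`): Gillespie's direct method in compiled
  code. A time-varying $L$ is frozen on a sub-grid of width 1% of the ramp
  duration: the sampled waiting time is discarded (memorylessness makes this
  unbiased) whenever it would cross a sub-grid boundary, and propensities are
  re-evaluated there. The residual bias from within-cell propensity drift is
  second order in the sub-grid width.
* **Chemical Langevin** (`cle_integrate()`): Euler–Maruyama with
  per-reaction noise amplitude $\sqrt{a_j}$. The $\sqrt{a}$ amplitude is the
  standard CLE convention and the only one whose one-step increment
  covariance $S\,\mathrm{diag}(a)\,S^\top dt$ matches the jump process (the
  test-suite verifies this against $2 \times 10^4$ seeded one-step samples
  within 5%). Coordinates are clamped at zero after each step — the simplest
  auditable negativity policy at copy numbers of order $10^2$ — and clamps
  are counted in `diagnostics$clamped`.
* **Euler–Maruyama** (`euler_maruyama()`): fixed step; $\sigma = 0$ reduces
  it to explicit Euler, cross-checked against an RK4 oracle. Default steps:
  $dt = 10^{-3}$ (toy), $dt = 10^{-2}/k_d \cdot k_d = 0.01$–$0.1$ time units
  (CLE), both configurable.
* **Reproducibility contract**: every simulator takes its seed from
  `sim_config()`; ensembles derive member $i$'s seed as
  `xor(base_seed, i)`, so members are order-independent and individually
  re-runnable. Identical seed and configuration give bit-identical output;
  the suite asserts this for all three simulators.

## Landscapes from samples

`histogram_density()` bins samples (default $60 \times 60$ over the 1st–99th
percentile range per axis; the published analyses never state a binning) and
`potential_from_density()` sets $U = -\ln(P + \epsilon)$ with the
Jeffreys-style pseudocount $\epsilon = 0.5/n$, so unexplored bins sit on a
finite plateau — the analogue of the white high-potential region around the
populated valleys. Potential *differences* between occupied bins are
independent of sample size; only the plateau height moves with $\epsilon$.

A bin is a **mode** if it holds at least 1% of the mass and exceeds all of
its 8-connected neighbours. One caveat discovered during validation: the toy
potential's transverse direction is purely quartic, so the stationary density
has a *flat top* in $x_2$; at fine binning, Monte Carlo noise on the plateau
fabricates spurious local maxima. Mode-location checks therefore use coarse,
odd-count transverse bins (so that $x_2 = 0$ is a bin center), which is
enough to resolve the genuine $\sim$12% density drop to the neighbouring bin
at $2 \times 10^5$ samples.

## Fixed points, classification, sweeps

`find_fixed_points()` runs a damped Newton iteration from 200
Latin-hypercube starts (box $[0,150]^4$ for the network, $[-2,2]^2$ for the
toy model), with three robustness devices:

* copy-number models are evaluated through an even reflection
  ($f(|x|)$), letting Newton cross zero while keeping propensities defined;
* near-singular Jacobians fall back to a pseudo-inverse step — necessary for
  the toy model, whose transverse eigenvalue is *exactly zero* on the
  $x_2 = 0$ axis (structural consequence of the quartic potential);
* converged roots are polished to residual $\sim 10^{-14}$ so that
  structurally-zero eigenvalues are numerically resolved, then deduplicated
  at radius $10^{-4}$ in box-scaled coordinates.

Classification follows the eigenvalue sign rule (stable: all
$\mathrm{Re} < -10^{-8}$; saddle: any $\mathrm{Re} > 10^{-8}$; marginal
otherwise), with marginal directions flagged separately — toy wells are
reported as `marginal` with one flagged direction, toy saddles as `saddle`
with one flagged direction. Where a clean minimum/saddle call on the
*potential* is needed (the toy acceptance structure), critical points are
classified by sampling $U$ on a small ring, which is robust to the vanishing
transverse curvature.

`sweep_parameter()` re-solves at each control value and matches fixed points
into branches by greedy nearest-neighbour assignment between consecutive
values; unmatched points open new branches and branch disappearance is
recorded, not fatal.

## Minimum action paths

The published analyses never print the action functional; this package
defines it as the standard Freidlin–Wentzell quadratic form

$$S[\varphi] = \tfrac12 \int_0^T
 (\dot\varphi - f(\varphi))^\top A(\varphi)^{-1} (\dot\varphi - f(\varphi))\,dt,
 \qquad A = \begin{cases}\sigma^2 I & \text{toy}\\
 S\,\mathrm{diag}(a)\,S^\top & \text{network}\end{cases}$$

discretized by the midpoint rule on a fixed-duration uniform grid with
pinned endpoints. Numerical choices:

* **Duration selection.** Infinite-time MAPs between hyperbolic points are
  approached as $T$ grows, while midpoint-rule error grows with $T/M$; the
  optimizer scans a logarithmic $T$-grid (default $\{5, 10, 20, 40, 80\}$
  for the toy model; $O(10^3)$ for the network, whose relaxation time is
  $1/k_d = 100$) and keeps the lowest action.
* **Optimizer.** L-BFGS-B on the stacked interior coordinates with an
  *analytic* gradient (drift and diffusion Jacobians are closed-form for
  both models; the gradient is verified against finite differences at
  $10^{-8}$ relative tolerance). Multi-start: straight line, a via-point
  detour through the transition state, optional user-supplied path
  (`init =`), plus seeded jitters. Convergence is declared at gradient norm
  $< 10^{-6}(1 + |S|)$ and reported honestly — accurate actions are often
  reached before that strict gradient criterion, so `converged = FALSE` with
  a correct action is a possible, documented outcome.
* **Regularization.** Where the diagonal diffusion is ill-conditioned
  (condition number $> 10^8$, e.g. near-extinct species), $\epsilon =
  10^{-6}\,\mathrm{tr}(A)/d$ is added and the number of regularized
  midpoints is reported in the result.
* **Reference heteroclinic.** Shooting $\dot X = \nabla U + f_U$ *forward*
  from a well cannot hit the saddle (its stable manifold has measure zero
  under that flow); the package integrates the *reversed* flow from a
  $10^{-4}$ offset off the saddle down into the well and reverses the
  result. The potential is non-decreasing along the resulting uphill leg by
  construction ($dU/dt = |\nabla U|^2$). Because the transverse relaxation
  is cubic, the tails approach the wells only algebraically; integration
  stops at radius 0.05 and the remaining straight crawl (along $x_2$ at
  fixed $x_1$) is appended geometrically to the uphill leg, while the
  downhill (free-fall) leg keeps its raw uniform time grid so that its
  action evaluates to $\sim 10^{-14}$.

For the developmental model at $L = 50$, the forward (differentiation) MAP
carries far less action than the reverse (reprogramming) MAP
($\approx 12$ vs $\approx 58$ at $M = 80$, $T \le 2400$) — the quantitative
face of irreversibility — and both directions pass within 25 copy numbers
(about 20% of the stem–differentiated separation; set a priori) of the
transition fixed point while remaining clearly distinct routes.

## Transitory landscapes

Two ramp experiments probe the heterogeneity definition of the TS:

* **Toy tilt ramp.** $\beta(t) = t - 0.5$ over one time unit, after
  equilibrating the ensemble at $\beta = -0.5$. At these parameters the
  ensemble does not begin hopping until *after* the ramp ends (measured:
  the ensemble mean is still $\approx +0.9$ at $t = 1$); the observation
  window therefore extends to $t = 12$ with $\beta$ held at $+0.5$, over
  which the variance of $x_1$ rises $\sim$12-fold to an interior peak near
  $t \approx 4.5$ and falls back, while the variance of $x_2$ stays flat
  (max/min ratio $< 3$). Truncating at the printed one-unit window shows no
  signature at all — a reading of the published time axis that
  implementation falsified.
* **LIF ramp.** $L(t) = 150\,(1 - t/T_{\text{ramp}})$ with
  $T_{\text{ramp}} = 2000 = 20/k_d$ (slow relative to relaxation, the
  criterion stated for choosing it), held at $L = 0$ until
  $t = 2.5\,T_{\text{ramp}}$ so that the laggards' switching completes and
  the end-of-window variance drops. At desk scale ($n = 1000$, three seeds)
  the Nanog and Gata6 variances rise from their initial-box values
  ($\approx 133$ and $\approx 23$) to interior peaks ($\approx 900$ and
  $\approx 2400$) and decay again.

## What the generator emulates — and what a green test establishes

The simulators *are* the data generators: there is no external data. They
emulate exact birth–death copy-number noise (SSA), its diffusion limit
(CLE), additive-noise landscape dynamics (toy SDE), parameter ramps and
boxed initial conditions. They do **not** emulate cell division or growth,
extrinsic noise, measurement noise of any assay, spatial structure, or the
real mouse-ESC gene network beyond four lumped regulators. A green
acceptance suite therefore establishes internal consistency of the method
stack — simulators match their analytic laws, landscapes match their
definitions, MAPs match closed forms where closed forms exist, and the
calibrated model reproduces the *structural* phenomenology (three states,
irreversibility, variance peak) — not agreement with any laboratory
measurement.

## Known limitations

* The calibrated parameter set is a package construction validated by the
  structural gate, not the (unrecoverable) original numbers; figure-level
  curves are reproduced qualitatively, not pointwise.
* The transition-state location varies with $L$ in this propensity family
  (only its existence, instability and the differentiated state's
  invariance are asserted).
* Plateau-region trajectories (high $N$ and $G$) differentiate directly
  rather than via the stem valley.
* CLE near extinction is clamp-biased; SSA under ramps is piecewise-frozen
  (both documented above, both second-order small in their control
  parameters).
* MAP durations are finite; actions carry an $O(1/T)$ surplus relative to
  the $T \to \infty$ quasipotential, visible as the $\sim$0.04% gap against
  the 3.125 oracle.
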