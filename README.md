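# epiland

Quantitative Waddington-landscape analysis for stochastic models of cell
differentiation: probabilistic landscapes, transition states, and minimum
action paths.

## What problem this solves, and for whom

Stem-cell differentiation is often drawn as a marble rolling through a
landscape of valleys (phenotypes) separated by ridges. For anyone building or
analysing dynamical models of fate decisions — systems biologists, modellers
of gene regulatory networks — this package turns that cartoon into computable
objects for stochastic models

$$dX = f(X;\theta)\,dt + g(X;\eta)\,dW_t$$

and answers four linked questions: what defines a transition state (TS); how
long a system lingers there (Jacobian eigenvalues); whether differentiation
and reprogramming take the same route (they don't, when the drift has a curl
component); and how the TS changes under an external signal.

Two fully specified models ship with the package:

* a **2D bistable SDE** with potential
  $U = \lambda(x_1^4 + x_2^4) - \alpha x_1^2 + \beta x_1$ and an orthogonal
  curl component $f_U$ (so $f = -\nabla U + f_U$, $\nabla U \cdot f_U = 0$);
* a **4-gene birth–death network** of Nanog, Oct4–Sox2, Fgf4 and Gata6 under
  external LIF control, simulated exactly (Gillespie) or as a chemical
  Langevin diffusion.

Core quantities:

* **Probabilistic landscape** $U = -\ln P_s(X)$ from binned simulation data;
* **Fixed points** of $f(X) = S\,a(X) = 0$ with eigenvalue classification and
  control-parameter sweeps (stem-cell / transition / differentiated branches);
* **Minimum action paths** minimizing the Freidlin–Wentzell functional
  $\tfrac12\int (\dot\varphi - f)^\top A^{-1} (\dot\varphi - f)\,dt$ with the
  model's diffusion metric $A$, in both the differentiation and the
  reprogramming direction;
* **Transitory-landscape signatures**: the interior peak of ensemble variance
  while a parameter ramp ($\beta(t)$ or $L(t) = 150(1 - t/T_{\mathrm{ramp}})$)
  deforms the landscape.

## Worked example

Locate and classify the developmental model's fixed points at LIF = 50:

```r
library(epiland)
fp <- find_fixed_points(dev_model(dev_params(L = 50)), seed = 1)
fp[, c("N", "O", "F", "G", "classification", "branch")]
#>         N      O   F        G classification         branch
#> 1  0.0025 0.0001 100  99.9905         stable differentiated
#> 2 66.9634 9.8929 100   0.0464         stable      stem-cell
#> 3 27.2805 7.6551 100   0.2326         saddle     transition
```

Three fixed points: a pluripotent attractor (Nanog-high, Gata6-low), a
differentiated attractor (Gata6-high), and between them the transition state
— a saddle whose leading Jacobian eigenvalue is positive
(`Re(ev1) ≈ +0.0027`), so cells are expelled from it along the fate axis.

Minimum action in a case with a known closed form (gradient system,
$c = 0$, $\beta = 0$: uphill action $= 2\Delta U/\sigma^2 = 3.125$):

```r
res <- minimize_action(toy_model(toy_params(beta = 0, c = 0)),
  from = c(1, 0), to = c(0, 0), M = 100, T_grid = c(10, 20, 40),
  n_starts = 2, seed = 1)
res$action
#> [1] 3.12632
```

The 0.04% surplus is the finite-duration correction (the exact value is the
$T \to \infty$ limit). Figure-level experiments are packaged as recipes:

```r
b <- run_recipe("fig8_dev_transitory", scale = "desk", seed = 1)
str(b$summary$variance$G)
#> List of 4
#>  $ start    : num 23.4
#>  $ peak     : num 2402
#>  $ peak_time: num 1400
#>  $ end      : num 466
```

Gata6 variance across 1000 cells rises ~100-fold to an interior peak midway
through the LIF withdrawal and collapses again — the ensemble-heterogeneity
fingerprint of a transitory-landscape transition state.

## Command line

```sh
Rscript -e 'quit(status = epiland::epiland_cli())' recipe fig7_L_sweep --scale desk --out out/
Rscript -e 'quit(status = epiland::epiland_cli())' map --model toy --from well+ --to well- --seed 1 --out out/
```

Subcommands: `simulate`, `landscape`, `fixedpoints`, `sweep`, `map`,
`recipe`, `fixtures`; see `--help`. Every recipe runs at a reduced `desk`
scale (default, seconds-to-minutes) and a `full` scale matching the published
ensemble sizes.

## Notes on the developmental parameter set

The published kinetic constants are printed as an undelimited string whose
literal parse is monostable at every LIF level (see the methods vignette,
`vignettes/transition-state-landscapes.Rmd`). The package ships that literal
set (`dev_params(set = "paper-printed")`) alongside a calibrated default
(`set = "calibrated"`) selected by a deterministic structural gate
(`dev_structure_gate()`): three branch-tracked fixed points with
stem/transition/differentiated character across LIF ∈ [0, 200].
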