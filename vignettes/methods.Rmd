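---
title: "Ramp and shape biases in viscoelastic shear identification: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ramp and shape biases in viscoelastic shear identification: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(viscofit)
```

## The constitutive model

`viscofit` models soft tissue in shear as isotropic linear viscoelasticity
with a three-term Prony series,

$$G(t) = G_\infty + \sum_{i=1}^{3} G_i e^{-\beta_i t},$$

where $G_\infty$ is the long-term shear modulus,
$G_0 = G_\infty + \sum_i G_i$ the instantaneous modulus, and the decay rates
are fixed at $\beta_i = 10^{i}\,\mathrm{s}^{-1}$, $i = 0,1,2$. The decades
1–100 s$^{-1}$ bracket the two time scales of the test protocol: a
$\sim$0.1 s strain ramp and a $\sim$4 s hold. Only the four moduli are
identified; fitting the decay rates as well is a famously ill-posed problem
and is deliberately out of scope.

The **reduced relaxation function** is defined here as
$G_r(t) = G(t)/G_\infty$, i.e. normalised by the *long-term* modulus, so
$G_r(0) = G_0/G_\infty \ge 1$. Note that much of the quasi-linear
viscoelasticity literature instead normalises by $G_0$; we keep the
long-term normalisation throughout so that all reduced curves produced by
the package are mutually comparable, and document the difference here to
avoid confusion when comparing with other sources.

For a perfect strain step of size $\varepsilon_0$ the shear stress is
$\sigma(t) = \varepsilon_0 G(t)$. For arbitrary strain histories the
Boltzmann superposition integral
$\sigma(t) = \int_0^t G(t-\tau)\,\dot\varepsilon(\tau)\,d\tau$
is evaluated by the standard per-term recursion (`stress_recursive()`):
strain is piecewise linear between samples, for which the within-step
integral has a closed form, giving an O(n) update that supports non-uniform
steps. The kernel of this hereditary integral is the *strain rate*
$\partial\varepsilon/\partial\tau$ — the only dimensionally consistent
reading, and the one that reduces to $\sigma = \varepsilon_0 G(t)$ in the
step limit. Because the update is exact for piecewise-linear strain, the
analytical fits evaluate the model on a compact grid (101 ramp knots plus
the log-time comparison points) rather than the full data sampling grid,
with no loss of accuracy.

`stress_quadrature()` is a deliberately independent cross-check: direct
trapezoidal quadrature of the same convolution, with $O(\Delta t^2)$
truncation error. On a grid of $5\times10^{-5}$ s the two agree to better
than $10^{-6}$ relative error, which is the package's oracle-equivalence
test.

## The specimen finite-element model

Cylindrical specimens (default 18 mm diameter, 12 mm height) are meshed with
a structured all-hex section: a rectangular core grid surrounded by ring
layers obtained by transfinite interpolation between the core boundary and
the circle, mapped by cumulative perimeter fraction so outer chords stay
uniform; boundary nodes lie exactly on the circle, and the small ($<1\%$ at
the default refinement, $<2\%$ for all built-in levels) faceting volume
deficit is accepted and tested. The default refinement (core $10\times4$,
4 ring layers, 10 extrusion layers) produces exactly 1,520 elements with all
edge lengths in 0.8–3 mm. The built-in convergence family spans 176 to
3,185 elements; the intermediate and finest levels are proportional
rescalings of the default topology so that discretisation error decreases
monotonically along the family. (A non-proportional intermediate level can
accidentally land closer to the finest trace than the default does — a
topology artefact we avoid by construction.) An extruded structured mesh
always has `layers x quads-per-layer` elements, so a 3,209-element level —
3,209 is prime — cannot be realised exactly; 3,185 is the closest
proportional level.

The solver (`solve_shear()`) is quasi-static and incremental: trilinear
hexahedra with $2\times2\times2$ Gauss quadrature, mean-dilatation (B-bar)
treatment of the volumetric term to avoid locking at
$K/G \approx 10^6$ ($K = 2.1$ GPa, water-like and rate-independent;
deviatoric response follows the same Prony recursion as the 1-D engine,
applied componentwise to the deviatoric strain at every Gauss point). The
bottom face is fully bonded, the top face is bonded in-plane with prescribed
x-displacement $\gamma(t)\,h$; the reported force is the x-resultant
transmitted to the bottom plate. Each increment solves one sparse SPD
system; within a step the effective shear modulus
$G_\mathrm{eff} = G_\infty + \sum_i G_i (1 - e^{-\beta_i \Delta t})/(\beta_i \Delta t)$
multiplies a unit-modulus deviatoric stiffness assembled once per mesh.

Two deliberate simplifications, both documented validity caveats rather than
claims of fidelity to any particular commercial solver:

* **quasi-static stepping** — the transducer ringing seen in real tests is
  inertial; the identification target is the inertia-free response, so no
  mass matrix is assembled and the ringing is instead *modelled* in the
  synthetic-data noise;
* **small-strain kinematics** — despite the 50 % nominal strain the
  constitutive model is linear, and all model-to-model comparisons in the
  package share the same kinematic treatment. Absolute strain-field details
  at 50 % strain (e.g. the exact census fractions below) are sensitive to
  this choice.

Time stepping uses 50 uniform steps over the ramp and ~150 steps over the
hold arranged in 12 geometric blocks (ratio 1.5) — log-like coverage
matching the fitting grid's density, while keeping the number of distinct
step sizes (hence sparse factorisations) at 13 per solve. A full
default-mesh solve takes ~25 s on one CPU; the coarse 176-element mesh
solves in ~2 s with the shortened 30 + 60 schedule used inside optimisation
loops and tests.

## Element strain census

At peak applied displacement the per-element engineering shear strain
($2\varepsilon_{xz}$ at the element centroid) quantifies how far the bonded
cylinder departs from the uniform-strain assumption. On the default mesh,
75.6 % of elements sit below the nominal 50 % strain — the qualitative
invariant the package asserts strictly. The finer breakdown we compute is
45.3 % of elements below 45 % strain and 30.3 % between 45 % and 50 %
(24.5 % above nominal, concentrated in the specimen core). These fractions
are *count* fractions and therefore depend on how the section topology
distributes element sizes between the low-strain rim and the above-nominal
core; without the original mesh topology they are reproducible only to
within several percentage points, and the acceptance checks treat the first
fraction with a 10-percentage-point band while the 45–50 % band fraction is
reported as-is (our finer-cored section places visibly more elements in the
above-nominal core than the published mesh did).

## Identification modes

* `fit_analytical(mode = "with_ramp")` — model stress from the recursion on
  the full sampled loading, SSE against the whole trace.
* `fit_analytical(mode = "no_ramp")` — time re-zeroed at ramp end,
  $\sigma(t') = \varepsilon_0 G(t')$ fitted to post-ramp data only. The
  re-zeroing (rather than keeping absolute times) is our reading of
  "neglecting the ramp": it is the idealisation that the step occurred at
  the moment the hold began.
* `fit_fe_srsm()` — force-space SSE between data and FE reaction force;
  successive response surfaces with a D-optimal design (greedy selection
  from a seeded uniform candidate pool of 500, 23 design points per
  iteration $\ge 1.5\times$ the 15 quadratic-basis terms), full quadratic
  surface by least squares, surface minimised in the trust region, and the
  region pans/contracts (per-dimension contraction
  $c + |d|(1-c)$ with $c = 0.65$, where $d$ is the normalised centre move —
  full shrink on no move, pure pan on a boundary move). Five iterations;
  the returned optimum is always the best *simulated* point. Initial region
  half-width is 40 % of the start values; bounds keep all moduli
  non-negative.

The SSE objective for both analytical modes uses stress units (the
uniform-strain conversion force/area), the FE mode force units, both on 200
points equidistant in log time from 1 ms ($t_{\min}$; a log grid cannot
contain $t = 0$) to the end of the record. Analytical fits use bounded
L-BFGS-B with five seeded starts (bounds $[0, 10^5]$ Pa); ties break toward
the lower SSE, then the lower $G_0$.

Self-recovery behaviour on noise-free synthetic data, at the package's
defaults: with-ramp analytical recovery within 0.1 %; FE-based SRSM
recovery within 0.1 % from a start perturbed ±30 % (coarse mesh,
~120 FE evaluations); no-ramp fits of ramped data recover the relaxation
tail but lose ~26 % of $G_0$ — the ramp-neglect bias the package exists to
quantify.

## Synthetic specimens

The generator (`generate_study_set()`) stands in for a seven-specimen
cadaveric series that was never deposited. Defaults: 7 cylinders, nominal
18 mm × 12 mm with 3 % lognormal jitter on height and diameter; ground-truth
moduli lognormally jittered with 20 % coefficient of variation around the
base material $G_\infty = 200$ Pa, $G_i = (500, 300, 200)$ Pa — soft-tissue
scale values consistent with the few-hundred-Pa-to-kPa range of published
brain moduli (the study's own moduli are published only as bar charts, so
the base values are a representative choice, fixed once). Sampling is 1 kHz
(a stated default; the real transducer characteristics are unknown). Noise
is additive white noise during the hold plus exponentially damped sinusoid
bursts (default 150 Hz, decay 50 s$^{-1}$) at the start and end of the ramp,
emulating inertial ringing; bursts are near zero-mean, so light noise
perturbs fitted moduli only weakly. Everything is seeded and exactly
reproducible; the ground truth travels in a JSON sidecar that fitting code
never reads.

What the generator does *not* emulate: glue-layer compliance, tissue
degradation, white/grey-matter composition, temperature, anisotropy, or
pre-compression. Passing recovery tests on these synthetic data therefore
demonstrates correctness of the identification machinery — not that real
brain tissue satisfies linear viscoelasticity.

## Study pipeline and experiment sizes

`run_mode_comparison()` fits all modes per specimen and re-simulates the
specimen model under each fitted material; peak-force errors are
$(\mathrm{model\ peak} - \mathrm{data\ peak})/\mathrm{data\ peak}$ and the
relaxation error is the hold-phase log-time SSE (same metric as the fitting
objective, for comparability). `run_convergence()` reports the max pointwise
force deviation against the finest family level. `run_sensitivity()` sweeps
height factors $\{1.0, 0.9, 0.8, 0.7\}$ (a four-level default; the published
sweep's increments are not stated) and cylinder/cube sections at matched
cross-sectional area, rescaling the prescribed displacement so the nominal
strain stays 50 %. "Data" in every error metric is the noise-free synthetic
trace; noisy variants are for illustration.

The default problem sizes are: 1,520-element specimen models (full-scale
runs, ~25 s each), the 176-element coarse model with a 30 + 60 step schedule
inside optimisation loops and the test suite, and 5 SRSM iterations of 24 FE
evaluations each. The acceptance script performs two full-scale solves
(default and 3,185-element meshes) plus the census; everything else it needs
is analytical.

## Numerical choices and degenerate inputs

* Sparse SPD systems are solved by CHOLMOD Cholesky with one symbolic
  analysis per mesh and one numeric factorisation per distinct step size.
* Element inversion (non-positive Jacobian) and non-increasing time grids
  are hard errors; failed FE evaluations inside SRSM are dropped with a
  warning, and a singular D-optimal information matrix triggers a larger
  candidate pool.
* Zero-amplitude noise models are exactly noise-free; `eps0 = 0` step
  responses and empty study reports are valid degenerate inputs.
* The no-ramp mode's comparison grid starts at $t_{\min}$ *after* ramp-end
  re-zeroing, so both modes fit 200 points of their respective clocks.

## Known limitations

* Small-strain kinematics at 50 % nominal strain (see above); no contact or
  adhesive modelling at the plates — the bond is ideal.
* The census fractions are mesh-topology-dependent count statistics; only
  their qualitative structure is robust.
* No identifiability or confidence-interval machinery: point estimates
  only, matching the procedures being compared.
* The FE-based identification inherits the FE model's discretisation error;
  on the coarse mesh this is ~1.4 % in force, which is below the biases
  being studied but not negligible for absolute moduli.
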