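---
title: "Quasi-steady-state reductions of enzyme kinetics in heterogeneous space"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quasi-steady-state reductions of enzyme kinetics in heterogeneous space}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spatialQSSA)
```

## The problem

The Michaelis–Menten (MM) rate law is the default description of an
enzyme-catalyzed reaction $S + E \rightleftharpoons C \to E + P$:

$$\frac{dP}{dt} = \frac{k_{cat} E_T S}{K_M + S}, \qquad
K_M = \frac{k_b + k_{cat}}{k_f}.$$

It is the *standard* quasi-steady-state approximation (sQSSA): the complex
$C$ is assumed to equilibrate instantly at fixed **free** substrate $S$,
giving $C(S) = E_T S/(K_M + S)$. The approximation is trustworthy when the
enzyme is scarce, $\varepsilon_{s} = E_T/(S_T + K_M) \ll 1$, and its error
is of order $\varepsilon_s$.

The *total* QSSA (tQSSA) instead takes the slow variable to be the total
substrate $\hat S = S + C$, whose only dynamics is the slow catalytic drain
$d\hat S/dt = -k_{cat} C$. Solving the quasi-equilibrium condition for $C$
at fixed $\hat S$ gives the smaller root of a quadratic,

$$C(\hat S) = \tfrac12\Big[b - \sqrt{b^2 - 4 E_T \hat S}\Big],
\qquad b = E_T + \hat S + K_M,$$

which this package evaluates as $2 E_T \hat S / (b + \sqrt{b^2 - 4E_T\hat
S})$ to avoid subtractive cancellation when $E_T \hat S \ll b^2$. The
corresponding validity factor,
$\varepsilon_{t} = \frac{K}{2 S_T}\left[\frac{b}{\sqrt{b^2 - 4E_T S_T}} -
1\right]$ with $K = k_{cat}/k_f$, is bounded by $1/4$ for every admissible
rate set (because $K \le K_M$), which is why the tQSSA is reliable across
essentially the whole parameter space. `validity_factors()` evaluates both,
plus the Eilertsen–Schnell factor $k_{cat}E_T/(k_f (K_M+E_T)^2)$ that
delimits the small remaining region where even the tQSSA degrades.

In a cell, enzymes are localized (ER, mitochondria, membranes), so the
well-mixed picture fails and the natural model is a reaction–diffusion PDE
on a no-flux domain. The question this package is built to explore: **when
do the sQSSA and tQSSA reductions of the PDE remain faithful to the full
mass-action PDE, given that only spatially averaged concentrations are
measurable?** The answer it reproduces: the sQSSA's validity cannot be
judged from spatial averages at all — it fails where substrate and enzyme
co-localize even though averages look "valid", and succeeds in segregated
geometries where averages look "invalid" — whereas the tQSSA tracks the
full model in every regime tested.

## Models

Three 1-D variants on $\Omega = (0, L)$ with zero-Neumann boundaries
(`simulate_rd()`):

* **full** — mass-action PDEs for $S, E, C, P$, each with its own
  diffusivity;
* **sqssa** — the MM reduction: transport of the primitive fields plus the
  catalytic drain $k_{cat} C(S)$ with the sQSS complex;
* **tqssa** — the same structure driven by the quadratic complex
  $C(\hat S)$.

A 2-D Goldbeter–Koshland (GK) cycle (`gk_simulate()`): one substrate
phosphorylated by a kinase $E$ and dephosphorylated by a phosphatase $D$,
six species, immobile enzymes, with sQSSA/tQSSA reductions applied per
arm. The headline observable is the phosphorylated fraction
$\hat S_p/S_T$; near-balanced, saturated arms give zero-order
ultrasensitivity.

## Numerics

**Splitting.** Each step is a Lie split: an implicit Euler diffusion
substep, then an explicit Euler reaction substep evaluated at the diffused
fields. No Strang correction is applied; first-order splitting is the
scheme the study conditions define, and the refinement test shows the
registered discretizations are converged to well under 1% in the final
averaged product.

**Spectral diffusion.** The endpoint-inclusive grid $x_j = jL/(N_x-1)$
carries a type-I cosine expansion, which diagonalizes the Neumann
Laplacian with continuum eigenvalues $\lambda_k = (k\pi/L)^2$. The
implicit substep is a per-mode damping $1/(1 + D\,\Delta t\,\lambda_k)$ —
unconditionally stable, mean-preserving, non-expansive. Transforms are
computed by FFT on the even extension; the 2-D version applies the
tensor-product eigenvalues to a 2-D transform (done in one pass; pairs of
fields sharing a diffusivity ride the real and imaginary parts of a
single complex FFT). `dct1()`/`idct1()` round-trip to machine precision.

**Quadrature.** Spatial averages use trapezoid weights, consistent with
the endpoint-inclusive grid. The alternative plain mean differs at
$O(1/N_x)$ and is immaterial at the registered resolutions; trapezoid was
chosen so that the $k=0$ cosine coefficient and the reported average are
the same object.

**Negative excursions.** The registered co-localized initial condition is a
tanh front of width 0.15 µm on a 0.3 µm grid; the cosine interpolant of
such an under-resolved front rings, undershooting to about $-0.055$ µM on
a 37 µM field. These excursions are a property of the spectral
discretization, not a bug: clamping them would inject mass and destroy
the $10^{-6}$-level conservation of spatial totals, and every reaction
formula in the package degrades gracefully for slightly negative
arguments. Policy: machine-scale negativity (within $-10^{-9}$ µM) is
zeroed after each reaction substep; ringing-scale negativity is carried;
negativity beyond 1% of the field's own scale aborts with a stability
error, since only an unstable explicit reaction step can produce it.

**Explicit-reaction stability.** The fast eigenvalue of the reaction
substep is $\approx k_f(S+E) + k_b + k_{cat}$. The registered 1-D
discretizations sit at $\Delta t\,\lambda \approx 1.1$ (stable, fast
transient crudely resolved, slow manifold accurate — the ODE-oracle tests
bound the pointwise error at 0.05%). The registered 2-D step scenario's
$\Delta t = 0.011$ s exceeds the full mass-action model's stability bound
by a factor of ~25 (the reduced models, whose stiff binding terms are
eliminated, are fine at that step); `gk_simulate()` therefore refuses it
with a stability error, and full-model runs of that scenario use an
overridden $N_t$ chosen the same way as the 1-D steps
($\Delta t\,\lambda \approx 1$, i.e. $\Delta t \approx 4\cdot10^{-4}$ s).

## The scenario generator

`make_scenario()` is the package's synthetic-data module: every study
condition is generated from its closed-form initial-condition family on
the registered grid, deterministically (regeneration is bit-identical).
The families: homogeneous levels; tanh fronts that co-localize or
segregate substrate and enzyme while (approximately) preserving spatial
averages; a Gaussian-localized enzyme of width $\sigma$ with the spatial
mean pinned at 5 µM for every $\sigma$ (the organelle-bound enzyme
family); and cosine stripes crossing substrate and enzyme gradients in a
2-D GK domain. Two generator choices deserve a note:

* the co-localized tanh pair's defining formula has spatial average
  1.8501 µM, 7.5% below its nominal homogeneous partner (2 µM); the
  formula, not the nominal average, is what the generator reproduces;
* the Gaussian family is normalized by its trapezoid *mean* on the finite
  domain, so the enzyme's spatial average is exactly the homogenized
  5 µM for every width — the only normalization consistent with its
  homogenized partner — and tails are truncated at the domain boundary.

The heterogeneity index `heterogeneity()` is the decibel-like scale
$10\log_{10}(\sigma_{max}/\sigma)$ with $\sigma_{max} = 25$ µm (the width
at which the profile is flat to a few percent); base 10 is assumed, as a
natural-log reading would only rescale the axis of the velocity sweep.

What the generator does **not** emulate: measurement noise, stochastic
reaction events, irregular organelle geometries, advective transport, or
3-D domains. Passing tests therefore certify the deterministic PDE
claims, not robustness of the conclusions to noise or geometry.

## Diagnostics and thresholds

* `pbar_series()` — trapezoid spatial average of product over time, the
  1-D headline summary; `initial_velocity()` is $\bar P(12\,s)/12\,s$,
  the drug-clearance-style initial rate.
* `validity_map()` — pointwise $E_T/(S_T+K_M)$ (or the phosphatase-arm
  ratio $D_T/(K_{MD}+S_T)$ for GK) from initial fields. "$\ll 1$" is
  operationalized as ratio $< 0.1$; this is a reporting convention only
  and never enters a solver.
* `compare_runs()` — sup-norm and time-integrated errors of a reduced
  model's summary against the full model, normalized by the maximum of
  the full model's summary (normalizing pointwise would divide by
  near-zero early values). "Accurate" in the package's tests means
  sup-error $< 0.1$, deliberately the same convention as the validity
  threshold: a reduction is doing its job when its error is at the scale
  of its validity factor, and the homogeneous-valid baseline scenario
  already has an sQSSA error of $\approx 0.08 = O(\varepsilon_s)$, so a
  tighter notion of "accurate" would reject the regime the reduction is
  *supposed* to cover.
* `steepness()` — max $|\partial_x(\hat S_p/S_T)|$ along a row: the
  ultrasensitivity measure. `anisotropy_index()` — variance of the
  fraction map's x-profile vs y-profile; the grid-pattern detector flags
  a variant when its x-variance exceeds 10× the full model's baseline.
  The striped GK scenario's y-dominated structure is a transient feature
  (the steady map is nearly flat at ~1/2), so y-dominance is asserted on
  a mid-transient frame and the grid flag on the final frame.

## Problem sizes used by the tests and the acceptance script

1-D scenarios run at their registered discretizations
($N_x = 100$, $N_t = 2730$ for the fast set; $N_x = 300$, $N_t = 11921$
for the localized-enzyme set). The heterogeneity sweep uses
$\sigma \in \{25, 2.5, 0.2\}$ µm, spanning the index range 0–21. The GK
step scenario is evaluated at the 37.5 s snapshot (its ultrasensitivity
pattern is established there; the full-model run uses the
stability-bounded $\Delta t \approx 4\cdot10^{-4}$ s). The striped GK
scenario runs to its final time 8.33 s at $\Delta t \approx 2\cdot10^{-4}$
s in the acceptance script ($\approx 2.5\cdot10^{-3}$ s in the test
suite); refinement checks showed the anisotropy diagnostics identical to
three digits across this range of steps, which is ~20× inside the
reaction stability bound.

## Worked example

```{r example, eval = FALSE}
sc <- make_scenario("fig2D")          # co-localized tanh fronts
runs <- lapply(c("full", "sqssa", "tqssa"),
               function(v) simulate_rd(sc, v))
names(runs) <- c("full", "sqssa", "tqssa")
compare_runs(runs$sqssa, runs$full)   # sup error ~0.22, overestimates
compare_runs(runs$tqssa, runs$full)   # sup error ~0.008
```

## Known limitations

* First-order splitting and explicit reactions: accuracy (and, for the
  full model, stability) is tied to the registered time steps; there is
  no adaptivity.
* Spectral ringing on under-resolved fronts is carried, not filtered; at
  the registered resolutions it stays at the $10^{-3}$ relative level.
* The GK module covers the two registered spatial scenarios;
  bistability and oscillatory regimes of the cycle are out of scope.
* All conclusions are deterministic-PDE statements; stochastic spatial
  kinetics can invalidate a reduction that is accurate deterministically.
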