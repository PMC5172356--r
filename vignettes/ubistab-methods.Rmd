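---
title: "Models and methods behind ubistab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ubistab}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ubistab)
```

`ubistab` measures how covalent ubiquitylation destabilizes a substrate
protein's fold, through three complementary experiments: tryptophan
fluorescence melting curves, differential scanning calorimetry (DSC), and
¹⁵N backbone relaxation. This vignette documents the models the package
fits, the parameters that matter (with units and defaults), what the
synthetic-data generator does and does not emulate, and the numerical
conventions adopted where more than one was defensible.

## Fluorescence melting analysis

### Model

A spectrum recorded at condition $x$ (temperature in K, or denaturant
concentration in mol/L) is reduced to its barycentric mean,
$\langle\lambda\rangle = \sum_i \lambda_i F(\lambda_i) / \sum_i
F(\lambda_i)$, over the recorded window (310–400 nm by default). The curve
of barycentric means versus condition is fit to the Boltzmann sigmoid

$$\lambda(x) = \lambda_N + \frac{\lambda_D - \lambda_N}
  {1 + \exp\!\big((x_{1/2} - x)/\textit{rate}\big)}$$

with $\lambda_N$, $\lambda_D$ the native and denatured baselines (nm),
$x_{1/2}$ the transition midpoint and *rate* the slope parameter (same
units as $x$). For a two-state transition the *rate* parameter maps onto
the van't Hoff enthalpy as $\textit{rate} = R\,T_{1/2}^2/\Delta H_{vH}$;
the package documents this mapping (and the simulator can be
parameterized either way) but does not enforce it, because midpoints — not
enthalpies — are the comparable quantity when unfolding is thermally
irreversible. For the same reason no $\Delta G$ extraction is attempted.

Replicate midpoints are summarized as mean ± SEM (sample SD / $\sqrt{n}$),
and constructs are compared with a two-tailed, pooled-variance Student's
$t$ test on the replicate midpoints (Welch's form is available via
`welch = TRUE`). Per-pair $p$ values are reported raw, with no
multiple-testing correction, matching how such transition tables are
conventionally reported. Baselines $\lambda_N$, $\lambda_D$ are never
shared between constructs: different conjugates place their tryptophans in
different environments.

### Numerical choices

* Fitting is Levenberg–Marquardt (`minpack.lm::nlsLM`); standard errors
  come from the estimated covariance of the fit.
* Starting values are data-derived: baselines from the barycentric means
  at the 10% lowest/highest conditions, midpoint from the steepest-slope
  condition, *rate* = 2 condition units. On sigmoid-shaped data this
  converges without user input.
* A failed optimization, or a fitted midpoint outside the data range
  (e.g. a flat curve with no transition in window), returns
  `converged = FALSE` rather than an error, so replicate batches survive
  one bad curve. Aggregation then warns and drops the non-converged fit.
* Degenerate comparisons follow fixed conventions: zero variance in both
  groups with equal means gives $p = 1$; zero variance with unequal means
  reports $p$ at the smallest positive double, with a warning.

## DSC analysis

The transition temperature is defined as the temperature of the transition
peak maximum on the measured grid — no model fitting and no interpolation,
so the resolution is the grid spacing (0.1 K in typical scans). Baseline
correction subtracts the straight line through the mean heat capacity of
two user-asserted transition-free windows (defaults: first and last 10% of
the grid); a warning fires if a clear peak's support reaches into a
window. Peak area is the trapezoidal integral over the contiguous support
where the corrected $C_p$ exceeds 5% of the peak height — a simple,
reproducible support definition. Reversibility is quantified per
transition as reheat area / first-heat area, with peaks matched by nearest
midpoint within 3 K (transitions of interest here are ≥ 10 K apart);
a first-heat peak with no reheat partner scores 0, the signature of
irreversible unfolding.

## ¹⁵N relaxation analysis

### Forward model

All relaxation quantities derive from the spectral density $J(\omega)$ of
the N–H bond vector through the standard dipolar + CSA expressions:

$$R_1 = \tfrac{d^2}{4}\big[J(\omega_H-\omega_N) + 3J(\omega_N) +
  6J(\omega_H+\omega_N)\big] + c^2 J(\omega_N)$$
$$R_2 = \tfrac{d^2}{8}\big[4J(0) + J(\omega_H-\omega_N) + 3J(\omega_N) +
  6J(\omega_H) + 6J(\omega_H+\omega_N)\big] +
  \tfrac{c^2}{6}\big[4J(0) + 3J(\omega_N)\big] + R_{ex}$$
$$\mathrm{NOE} = 1 + \tfrac{d^2}{4}\,\frac{\gamma_H}{\gamma_N}\,
  \frac{6J(\omega_H+\omega_N) - J(\omega_H-\omega_N)}{R_1}$$

with $d = \mu_0\hbar\gamma_H\gamma_N/(4\pi r_{NH}^3)$ and
$c = \omega_N\Delta\sigma/\sqrt{3}$. Defaults (config-overridable, echoed
into every result header): $\gamma_H = 2.6752\times10^8$,
$\gamma_N = -2.7116\times10^7$ rad s⁻¹ T⁻¹, $r_{NH} = 1.02$ Å,
$\Delta\sigma = -172$ ppm, field 600.13 MHz. Only the field is
instrument-specific; the rest follow common backbone-amide practice and
are stated rather than fit. When $R_1 = 0$ the NOE enhancement term is
$0/0$ and is defined as 1 (no enhancement).

A useful structural check: for a rigid dipolar-only spin pair in the
extreme narrowing limit the NOE approaches the closed form
$1 + \gamma_H/(2\gamma_N) \approx -3.93$. With the default ¹⁵N CSA
included the limit is less extreme (about $-3.4$); the package's tests pin
both, using the forward equations themselves as the oracle.

### Fitting and mapping

T₁/T₂ decays are fit as $I(t) = I_0 e^{-t/T_\alpha}$; errors are Monte
Carlo (default 500 refits of the fitted curve perturbed by Gaussian noise
at the residual RMS — a parametric bootstrap). The hnNOE is
$I_{sat}/I_{eq}$ averaged over (by convention two) independent
experiments, with the sample SD across replicates as its error; a single
replicate yields error 0 plus a warning rather than an imputed value.

Reduced spectral density mapping lumps the three high-frequency terms at
the single effective frequency $0.87\omega_H$ (the alternative multi-ε
conventions are not implemented) and inverts the forward equations in
closed form:

$$\sigma = R_1(\mathrm{NOE}-1)\gamma_N/\gamma_H,\qquad
  J(0.87\omega_H) = 4\sigma/(5d^2)$$
$$J(\omega_N) = \frac{R_1 - \tfrac{7d^2}{4}J(0.87\omega_H)}
  {\tfrac{3d^2}{4} + c^2},\qquad
  J(0) = \frac{R_2 - \tfrac{13d^2}{8}J(0.87\omega_H) -
  (\tfrac{3d^2}{8} + \tfrac{c^2}{2})J(\omega_N)}
  {\tfrac{d^2}{2} + \tfrac{2c^2}{3}}$$

Errors propagate to first order through these closed forms, treating
$R_1$, $R_2$, NOE as independent; the test suite holds the analytic errors
to within 15% of a Monte Carlo resampling oracle. For rigid isotropic
tumbling with $\tau_m$ in the 2–20 ns range at 600 MHz, mapping the full
five-frequency rates recovers $J(0) = \tfrac{2}{5}\tau_m$ to within 5%
(the cost of the lumping approximation).

Negative mapped values, which noise can produce, are **flagged** invalid
and excluded from group means, SDs and ratios — never clamped to zero,
because clamping would bias exactly the group SDs that the $J(0)$ profile
analysis reads out.

The isotropic $\tau_c$ estimator trims the most extreme $R_2/R_1$ ratios
symmetrically (`trim_fraction`, half per tail — exchange broadening pushes
ratios up, fast internal motion pushes them down) and solves the
rigid-rotor ratio equation by bracketed root finding on (0.1, 100] ns.
Full anisotropic diffusion-tensor analysis is out of scope; the estimate
serves as the isotropic reference point.

The chemical shift perturbation utility uses the conventional weighting
$\sqrt{\Delta\delta_H^2 + (0.14\,\Delta\delta_N)^2}$.

## The synthetic-data generator

The generator exists so the whole pipeline is testable against known
ground truth; its defaults define the simulated study conditions.

* **Melting spectra**: native and denatured Gaussian emission bands
  (centers 340 / 355 nm, SD 12 nm) mixed by the two-state logistic
  population, on a 310–400 nm grid at 1 nm steps, conditions 300–360 K at
  2 K steps, 3 replicates. Bands are normalized to equal integrated
  intensity on the recorded grid (equal apparent quantum yield), which
  makes the barycentric-mean curve exactly logistic with its midpoint at
  the thermodynamic midpoint — so zero-noise simulations invert exactly.
  Additive Gaussian noise, default SD 3% of the peak intensity: chosen
  once so that 3-replicate midpoint SEMs land in the 0.0–0.4 K range
  typical of reported transition tables (about 0.05–0.1 K), and not
  revisited. Real tryptophan bands are asymmetric and quantum yields
  change on unfolding; neither matters downstream because only the
  barycentric mean is consumed.
* **Relaxation data**: per-residue Lipari–Szabo model-free densities
  ($S^2$, $\tau_e$, $\tau_m$, optional $R_{ex}$) pushed through the full
  forward equations; decays sampled on the standard delay grids
  (10–1000 ms for T₁, 10–150 ms for T₂) with multiplicative Gaussian
  noise (default 2%); NOE pairs duplicated independently. The ground
  truth table (rates, times, NOE, model-free parameters) is always
  emitted. Lineshapes, peak overlap and CPMG-type dispersion are not
  simulated; exchange enters only as a scalar $R_{ex}$.
* **DSC**: each transition contributes a two-state van't Hoff excess heat
  capacity $C_p^{ex}(T) = \frac{\Delta H_{vH}^2}{RT^2}\frac{K}{(1+K)^2}$
  with $K = \exp[-\frac{\Delta H_{vH}}{R}(\frac1T - \frac1{T_m})]$, scaled
  by an amplitude; the reheat multiplies each component by its
  reversibility fraction. Default $\Delta H_{vH}$ = 500 kJ/mol: a typical
  single-domain cooperativity, sharp enough that the continuous peak
  maximum (which sits $\approx 4R^2T_m^3/\Delta H_{vH}^2 \approx 0.04$ K
  below $T_m$) rounds to the grid point at $T_m$ on a 0.1 K grid. DSC
  noise defaults to zero because the first-heat/reheat construction is
  usually the object of study; it is configurable.

All simulators draw from R's default Mersenne-Twister generator seeded
from their `seed` parameter, so a fixed seed reproduces a dataset
bit-identically across runs and platforms.

What passing tests on these simulations shows — and what it does not: the
pipeline recovers the parameters of data that obey its generative
assumptions (two-state transitions, mono-exponential decays, isotropic
tumbling) at realistic noise. It does not show robustness to baseline
curvature, aggregation exotherms, peak overlap, anisotropic diffusion or
non-two-state intermediates, which real data can exhibit.

## Problem sizes used by the test suite

The suite simulates its own data at sizes chosen to make the statistical
assertions stable: 100 three-replicate melting experiments for the
bias/coverage checks, 200 noisy decays (100 Monte Carlo refits each) for
the error-calibration checks, and 3000–4000 resampling draws for the
error-propagation oracle. The full suite runs in about a minute on one
core.

## Known limitations

* Midpoint comparison assumes all curves were acquired under the same
  protocol; midpoints of irreversible transitions are kinetic, not
  equilibrium, quantities, and are only comparable within a protocol.
* The reduced mapping's lumping error (≤ 5% on $J(0)$ for 2–20 ns at
  600 MHz) is inherited by the $J(0)$ ratios, though it largely cancels
  between numerator and denominator.
* The CSA value and N–H bond length are conventions; absolute $J$ values
  shift by a few percent under alternative choices, ratios much less.
* Interfaces are programmatic (functions plus `scripts/acceptance.R`);
  there is no shell CLI.
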