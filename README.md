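# ubistab

Quantitative analysis of protein fold destabilization by ubiquitylation.

Ubiquitin is a bulky post-translational modifier (8.6 kDa), and covalently
attaching it to a substrate protein does more than flag the protein for
signaling or degradation: it measurably loosens the substrate's fold.
`ubistab` implements the three biophysical readouts used to quantify this
effect on single-domain substrates such as FKBP12 and FABP4, together with a
synthetic-data generator so that every stage of the pipeline can be
exercised and validated without instrument data. It is aimed at protein
biophysicists and NMR spectroscopists who want a scripted, reproducible
version of analyses that are usually done in vendor software.

## What it computes

**1. Tryptophan fluorescence melting curves.** Each emission spectrum is
reduced to its barycentric mean wavelength
⟨λ⟩ = Σ λ·F(λ) / Σ F(λ), which red-shifts as buried tryptophans become
solvent-exposed. The series of barycentric means versus temperature (or
denaturant concentration) is fit to the Boltzmann sigmoid

λ(T) = λ_N + (λ_D − λ_N) / (1 + exp((T_half − T)/rate))

giving the transition midpoint T_half per replicate; replicate midpoints are
aggregated (mean ± SEM) and compared between constructs with a two-tailed
pooled Student's t test.

**2. DSC thermograms.** Baseline correction (linear, through two
transition-free windows), transition-peak detection with the transition
temperature defined as the temperature of the peak maximum, and a
reversibility index per transition — the ratio of reheat to first-heat peak
area, which is ~1 for reversible unfolding and ~0 when the endotherm
vanishes on reheating.

**3. ¹⁵N backbone relaxation.** Mono-exponential T₁/T₂ fits with Monte
Carlo errors, steady-state {¹H}-¹⁵N NOE (I_sat/I_eq, duplicate-based
errors), and reduced spectral density mapping of (R₁, R₂, NOE) to J(0),
J(ω_N) and J(0.87ω_H) with first-order error propagation. J(0) is sensitive
to slow (µs–ms) motions; per-residue J(0) ratios between the modified and
unmodified protein form a destabilization profile that can be written as a
structure-viewer attribute file. An isotropic rotational correlation time
estimator (trimmed R₂/R₁) is included.

The generator simulates all three experiments from their standard physical
models (two-state logistic populations with Gaussian emission bands,
van't Hoff excess heat capacity, Lipari–Szabo model-free spectral densities
pushed through the full five-frequency relaxation equations) and always
emits the ground truth next to the noisy data.

## Worked example: melting-curve comparison

```r
library(ubistab)

free <- melt_sim_params(t_half_true = 332.1, seed = 1)   # unmodified
conj <- melt_sim_params(t_half_true = 316.5, seed = 2)   # ubiquitylated
fits_free <- fit_melt_series(simulate_melt_series(free))
fits_conj <- fit_melt_series(simulate_melt_series(conj))

print(fits_free[["rep1"]])
#> melt_fit [rep1]: T_half/K = 332.17 +/- 0.10, rate = 2.00, lambda_N = 340.09, lambda_D = 354.98 nm

aggregate_replicates(fits_free)   # mean 332.1, SEM 0.1, n 3
aggregate_replicates(fits_conj)   # mean 316.5, SEM 0.1, n 3

compare_transitions(fits_conj, fits_free)
#> transition comparison (pooled t test): delta = 15.59, t = 162 (df 4), p = 8.65e-09
#>   group a: 316.49 +/- 0.08 (n=3); group b: 332.08 +/- 0.06 (n=3)
```

The fitted group means recover the generating midpoints to within their
SEMs; the ~15.6 K difference between the constructs is significant far below
the p < 0.001 tier.

## Worked example: J(0) destabilization profile

```r
sc <- spin_constants()                       # 600.13 MHz defaults
un <- model_free_params(1:20, s2 = 0.87, tau_m = 10, tau_e = 30)
mo <- model_free_params(1:20, s2 = 0.87, tau_m = 14, tau_e = 30,
                        rex = c(rep(0, 12), rep(6, 8)))
records <- function(mf, seed) {
  sim <- simulate_relaxation_dataset(relax_sim_params(mf, seed = seed))
  t1 <- lapply(sim$t1_curves, fit_exponential, mc_iterations = 100, seed = seed)
  t2 <- lapply(sim$t2_curves, fit_exponential, mc_iterations = 100, seed = seed + 1)
  relaxation_records(t1, t2, compute_hnnoe(sim$noe))
}
rec_un <- records(un, 11); rec_mo <- records(mo, 12)
prof <- jratio_profile(reduced_spectral_density(rec_mo, sc),
                       reduced_spectral_density(rec_un, sc))
print(prof)
#> J(0) ratio profile over 20 residues: mean 1.59, SD 0.25
#>   modified   J(0) = 5.5 +/- 0.8 ns (n=20)
#>   unmodified J(0) = 3.5 +/- 0.1 ns (n=20)

write_residue_attributes(
  data.frame(residue = prof$profile$residue, value = prof$profile$ratio),
  "j0_ratio.txt")   # two-column text for structure-viewer coloring
```

The exchange-broadened residues (Rex > 0) inflate J(0) in the modified form
only, raising both the mean and the spread of the ratio profile — the
signature of slow backbone fluctuations induced by the modification.

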