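# scmpop — spatial cumulant models for interacting cell populations

Solid tumours are not well-mixed: cells exchange diffusible growth factors
with their *neighbours*, so clustered populations grow differently from
uniform ones at the same density, and treatment doses calibrated on
densities alone under-dose clustered tumours. `scmpop` is for modellers in
mathematical oncology and spatial ecology who want three mutually
consistent views of the same individual-based system:

1. **STPP** — an exact stochastic spatio-temporal point process (Gillespie
   simulation) of two cell types on a periodic plane: producers (s1) divide
   autocrinely at rate *b₁* and by growth-factor facilitation at rate
   *b₁₁·Φ(x)*, non-producers (s2) at *b₁₂·Φ(x)*, where
   Φ(x) = Σ C(x − x₃) sums a Gaussian interaction kernel over the other
   producers; plus density-independent death and optional random jumps.
2. **MFPM** — the mean-field density ODEs
   q̇₁ = b₁q₁ + b₁₁c q₁² − δ₁q₁, q̇₂ = b₁₂c q₁q₂ − δ₂q₂.
3. **SCM** — the spatial cumulant model: closed equations for densities
   u⁽¹⁾ = q + ε²p and spatial covariances u⁽²⁾(t, r) = ε²g(t, εr), with the
   covariance spectra g̃ᵢⱼ(t, k) evolved in Hankel-transform space and the
   correction densities p sourced by the structure integrals
   W₁ⱼ = (b₁ⱼ/2π)∫ k g̃₁ⱼ(k) C̃(k) dk.

The package also estimates densities and radially binned covariances from
point patterns by FFT (exact pair counts on a periodic raster, self-pairs
removed), and derives treatment doses that zero the population growth at a
chosen time: mean-field doses δ₁ = b₁ + b₁₁c·û₁, δ₂ = b₁₂c·û₁, and
spatially informed doses δᵢ^SCM = δᵢ^MFPM + ε²Ŵ₁ᵢ/ûᵢ that anticipate the
extra facilitation inside clusters.

## Worked example

Generate a clustered-producer configuration, run the stochastic ensemble,
solve both deterministic models from the measured initial cumulants, and
check the envelope capture criterion:

```r
library(scmpop)
params <- model_params()
params
#> two-type growth-factor model
#>   b1 = 0.001, b11 = 0.025, b12 = 0.05 (sigma_B = 25)
#>   c = 100 (sigma_C = 100)
#>   m1 = 0, m2 = 0; delta1 = 0, delta2 = 0; ell = 1

res <- run_experiment(read_run_config(overrides = list(
  icc = list(kind = "icc2"))))
res
#> comparison experiment (icc2)
#>   statistic captured fraction_inside
#> 1   mfpm_u1    FALSE       0.5555556
#> 2   mfpm_u2     TRUE       1.0000000
#> 3    scm_u1     TRUE       1.0000000
#> 4    scm_u2     TRUE       1.0000000
```

With clustered producers, the mean-field producer density leaves the
30-replicate min–max band (captured only 5 of 9 recorded times), while the
spatial cumulant model — which tracks the covariance build-up — stays
inside it throughout. `plot_densities(res)` draws the bands and curves.

Deriving doses from one replicate's pattern at the treatment time t = 200:

```r
pat <- res$ensemble$trajectories[[1]]$final
u1 <- estimate_density(pat, 1); u2 <- estimate_density(pat, 2)
W <- w_hat_from_stats(pair_statistics(pat), params,
                      default_spectral_grid(params))
mfpm_dose(u1, params)
#>  delta1  delta2
#> 0.00178 0.00156
scm_dose(u1, u2, W["W11"], W["W12"], params)
#>  delta1  delta2
#> 0.00253 0.00177
```

The spatially informed producer dose is ~40% higher: the measured positive
covariance (Ŵ₁₁ = 2.3e−7) tells the model that producers sit in clusters
where facilitation exceeds its mean-field value, so stopping their growth
takes a larger death rate. `treat_and_continue()` applies per-replicate
doses and continues the simulation; with clustered producers, fewer
replicates keep growing under the spatially informed doses.

A command-line front end wrapping these functions (subcommands `simulate`,
`estimate`, `solve`, `treat`, `compare`, `demo-icc`) is installed at
`system.file("cli", "scmpop.R", package = "scmpop")`.

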