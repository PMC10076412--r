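---
title: "Spatial cumulant models for growth-factor-mediated cell populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatial cumulant models for growth-factor-mediated cell populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scmpop)
```

## The modelled system

`scmpop` studies a two-type cancer cell population in which cell--cell
interactions are mediated by a diffusible growth factor. Producer cells
($s_1$) secrete the factor and also internalise it; non-producers ($s_2$)
rely entirely on factor secreted by nearby producers. Four processes drive
the dynamics, each either a scalar rate or a radially symmetric interaction
kernel on a two-dimensional periodic domain:

* **Autocrine birth.** An $s_1$ cell divides at rate $b_1$, placing its
  daughter by the dispersal kernel $B_1$.
* **Facilitated birth.** An $s_1$ (resp. $s_2$) cell at $x$ divides at rate
  $b_{11}\Phi(x)$ (resp. $b_{12}\Phi(x)$), where
  $\Phi(x) = \sum_{x_3 \in s_1,\ x_3\neq x} C(x - x_3)$ sums the
  growth-factor kernel $C$ over all *other* producers. Self-facilitation is
  excluded because autocrine self-stimulation is already the separate
  $b_1$ process, and pair-based moment equations count distinct pairs.
* **Density-independent death** at rates $\delta_1,\delta_2$ (used to model
  drug exposure).
* **Random jumps** by movement kernels $M_1, M_2$ (optional).

Kernels are Gaussian, $a(r) = \tfrac{I}{2\pi\sigma^2}e^{-r^2/2\sigma^2}$,
or top-hat, $a(r) = \tfrac{I}{\pi r_0^2}\mathbf 1_{r \le r_0}$; $I$ is the
total integral (a rate) and $\sigma$ or $r_0$ the interaction scale. The
reference parameterisation, in dimensionless model units, is
$b_1 = 0.001 < b_{11} = 0.025 < b_{12} = 0.050$ with $\sigma_B = 25$,
$c = 100$ with $\sigma_C = 100$, and $\ell = 1$
(`model_params()` defaults). The ordering encodes the biology: receiving
growth factor from another cell is worth more than self-production, and
non-producers benefit most.

## Three model layers

**Stochastic point process.** `simulate_stpp()` runs the exact Gillespie
algorithm on the marked point configuration: exponential waiting times at
the global event rate, event selection proportional to per-cell rates,
daughters displaced by an isotropic Gaussian draw from the dispersal
kernel, periodic wrapping throughout. Facilitation sums are maintained
incrementally (a vectorised update over all cells per event) and refreshed
from scratch every few thousand events to bound floating-point drift; the
facilitation kernel is evaluated exactly, with no range cutoff, because at
$\sigma_C = 100$ on the default $1000^2$ domain any cutoff worth taking
would span most of the domain anyway.

**Mean-field model.** Assuming every cell interacts with every other
equally, densities $q_i(t)$ obey
$$\dot q_1 = b_1 q_1 + b_{11} c\, q_1^2 - \delta_1 q_1, \qquad
  \dot q_2 = b_{12} c\, q_1 q_2 - \delta_2 q_2,$$
solved by `mfpm_solve()`.

**Spatial cumulant model.** In the limit of long-ranged interactions
(scaling $\epsilon = 1/\ell$), densities and spatial covariances expand as
$$u^{(1)}_i(t) = q_i(t) + \epsilon^2 p_i(t) + o(\epsilon^2), \qquad
  u^{(2)}_{ij}(t, r) = \epsilon^2 g_{ij}(t, \epsilon r) + o(\epsilon^2),$$
with closed equations for the corrections $p_i$ and the covariance spectra
$\tilde g_{ij}(t,k)$ (order-0 Hankel transforms of $g_{ij}$). The spectra
evolve *locally in $k$* — e.g.
$$\partial_t \tilde g_{11} = 2\tilde B_1(q_1 + \tilde g_{11})
 + 2\tilde B_{11} q_1 (c + \tilde C)(q_1 + \tilde g_{11})
 - 2\delta_1 \tilde g_{11} + (2\tilde M_1 - 2m_1)\tilde g_{11},$$
so the whole system (4 scalar equations plus three spectra on the grid) is
integrated with a stiff-capable adaptive method (`deSolve::lsoda`,
`rtol = 1e-8`, `atol = 1e-10`) by `scm_solve()`. The corrections are
sourced by the spatial-structure integrals
$$W_{1j}(t) = b_{1j}\int u^{(2)}_{1j}(x)\, C(x)\, d^2x
  = \frac{b_{1j}}{2\pi}\int_0^\infty k\, \tilde g_{1j}(t,k)\, \tilde C(k)\, dk,$$
which quantify how much extra facilitation clustered cells experience over
the mean-field estimate. Note the prefactor: with the unnormalised
transform convention used throughout the package ($\tilde a(0)$ equals the
kernel's total integral, products of transforms correspond to real-space
convolutions — the convention in which the spectral covariance equations
above are exact), Parseval's identity fixes the $1/2\pi$. We verified this
both by deriving the correction equation directly from the moment hierarchy
and empirically: the alternative $2\pi$ prefactor sometimes quoted with a
differently normalised Hankel transform inflates $W$ by $(2\pi)^2$ and
makes the correction overshoot the stochastic ensemble roughly forty-fold.

Movement contributes $(\tilde M_i - m_i)$ relaxation terms to the spectra
only; it leaves $q$ and $p$ untouched, as jumps conserve cell numbers.

## Transform numerics

All forward transforms are direct Simpson quadrature of
$2\pi\int a(r) J_0(kr)\, r\,dr$ on a fine radial sample (4097 nodes to 12
Gaussian widths, or exactly to the top-hat edge). This is simple,
controllable, and accurate to about $10^{-7}$ relative where a Gaussian
spectrum exceeds $10^{-4}$ of its peak; no FFT-based Hankel machinery is
needed at these sizes. Measured covariances, which are radially binned
step functions, transform exactly bin-by-bin through the identity
$\int_{r_0}^{r_1} J_0(kr)\,r\,dr = [r J_1(kr)/k]_{r_0}^{r_1}$
(`covariance_spectrum()`). The spectral grid is uniform with trapezoidal
weights, 257 nodes on $[0, 10/\sigma_{\min}]$; Gaussian spectra decay as
$e^{-\sigma^2k^2/2}$, so every model kernel is fully resolved well before
the endpoint, and doubling the node count moves default-parameter densities
at $t = 200$ by under 0.5% (tested). Inverse transforms use the same grid
quadrature; a spectrum carrying over 1% of its mass in the last decade of
the grid triggers a coarseness warning rather than an error.

## Estimating cumulants from point patterns

Densities are exact counts over area. Second-order statistics rasterise
each type onto a $256^2$ periodic grid (pitch $\approx 3.9$, which resolves
both $\sigma_B = 25$ and $\sigma_C = 100$ structure) and compute all
ordered-pair correlations by FFT — exact integer pair counts on the raster,
with periodic wrap implementing the minimum-image convention. The $N_i$
self-pairs are removed from the zero lag before normalisation so pair
densities count distinct ordered pairs, mirroring the separate first-moment
term that handles self-pairs in the moment definitions. Raster
displacements are radially averaged into bins of width $\Delta h$ (default:
the raster pitch), and the covariance is the pair density minus the product
of densities. Cross-statistics are symmetrised, so
$\hat u^{(2)}_{12} \equiv \hat u^{(2)}_{21}$ exactly. The estimator is
validated against closed forms (Poisson: zero covariance; Thomas cluster
process: $\kappa\mu^2 e^{-r^2/4\sigma_c^2}/4\pi\sigma_c^2$) and against an
$O(N^2)$ brute-force pair count, which it matches bin-for-bin on the
quantised geometry.

## Initial configurations and what the generator emulates

`generate_icc()` builds the three canonical starting configurations:
uniform/uniform (`icc1`), clustered producers with uniform non-producers
(`icc2`), and clustered/clustered (`icc3`). Clustered types use a
fixed-count Thomas-like construction — parents uniform, offspring Gaussian
($\sigma$ = `cluster_sd`) around a uniformly chosen parent — so that all
three configurations hold exactly the same per-type counts and differ only
in second-order structure. Defaults: $1000\times1000$ domain, 200 cells per
type, 8 clusters of scatter 40 per clustered type. The cluster scale was
chosen once, on physical grounds: a cluster diameter ($\approx 4\,$sd
$= 160$) comparable to the growth-factor range $\sigma_C = 100$ puts the
system in the *moderately localised* regime where the mean-field model
fails visibly while the cumulant closure — derived for long-ranged
interactions — remains valid. (Much tighter clustering, e.g. scatter 20
with five clusters, drives facilitation to an order of magnitude above
mean field; there the closure itself underestimates late-time growth, a
known limitation discussed below.) The generator emulates idealised in
vitro seeding: it reproduces densities and short-range covariance structure
but none of the crowding, volume exclusion, nutrient gradients or boundary
effects of real cultures — so passing tests demonstrate fidelity to the
point-process model, not to any particular experiment.

## Initialisation, comparison, and the capture criterion

A comparison experiment (`run_experiment()`) measures $q_i(0)$ and
$\tilde g_{ij}(0,k)$ from the generated pattern (corrections start at
$p_i = 0$), runs an ensemble of stochastic replicates from that same
pattern, and solves both deterministic models from the measured initial
conditions. A deterministic curve *captures* the ensemble if it lies inside
the per-time min--max band of the replicates at every recorded time
(`envelope_capture()`, strict inequality-free comparison). With the default
30-replicate, $t\in[0,200]$ setup: both models are captured for the uniform
start; for clustered producers the mean-field densities leave the band
while the cumulant model stays inside — the package's central qualitative
result, reproduced in `tests/testthat/test-acceptance.R`.

## Treatment doses

Drugs are modelled implicitly as death rates switched on at a treatment
time $T$. Zeroing the mean-field growth at the measured density gives
$$\delta_1^{\mathrm{MFPM}} = b_1 + b_{11} c\,\hat u_1, \qquad
  \delta_2^{\mathrm{MFPM}} = b_{12} c\,\hat u_1,$$
while zeroing the corrected growth $H_q + \epsilon^2 H_p$ (corrections set
to zero at measurement) adds the measured structure integrals:
$$\delta_i^{\mathrm{SCM}} = \delta_i^{\mathrm{MFPM}}
  + \epsilon^2 \hat W_{1i}/\hat u_i .$$
The decomposition holds to machine precision by construction and is tested
as such. For clustered populations $\hat W > 0$, so spatially informed
doses are strictly larger — they anticipate the extra growth-factor supply
inside clusters. `treat_and_continue()` measures each stochastic
replicate's own $\hat u, \hat W$ at $T$, applies its individual doses, and
continues that replicate; with clustered producers, fewer replicates keep
growing under the spatially informed doses than under mean-field ones. A
noisy negative $\hat W$ (possible for uniform patterns) is *not* clipped
before the dose formula; only a net negative dose is floored at zero with a
warning, since death rates cannot be negative.

## Numerical and design choices

* **Exact event rates.** No kernel cutoff in the simulator; incremental
  cache with periodic from-scratch refresh (`refresh_every`, default 5000
  events; equality with a fresh recomputation after thousands of events is
  tested to $10^{-9}$ relative).
* **Shared initial pattern.** All replicates of an ensemble start from one
  realised configuration (per-replicate redraw available via
  `redraw_icc = TRUE`), matching the deterministic models' measured initial
  conditions.
* **Piecewise treatment.** Deterministic models handle the dose switch-on
  as a parameter discontinuity with an integrator restart at $T$; the
  simulator restarts from its state at $T$ with new death rates.
* **Degenerate inputs.** Zero-rate configurations return unchanged
  patterns; zero-horizon experiments reduce to the initial statistics; a
  population cap (default $10^6$) aborts with a flagged partial trajectory.
* **Negative densities.** The density equations preserve positivity from
  non-negative data; the solver does not clip but warns if $q$ falls below
  `-atol` (a diagnostic of integration failure).
* **Problem sizes.** Shipped tests use 30-replicate ensembles of ~400
  cells to $t = 200$ (treatment runs to $t = 300$), 200-replicate
  estimator/branching oracles, and spectral grids of 129–513 nodes — sizes
  at which every scientific claim in the test suite is decidable in a few
  minutes on one core.

## Known limitations

The closure is derived in the long-ranged-interaction limit. For strongly
localised interactions with tight clustering (facilitation an order of
magnitude above mean field), the cumulant model still outperforms the
mean-field model but systematically underestimates late-time growth; the
package reports this honestly via the capture report rather than hiding
it. Crowding, density-dependent death, mark conversion, continuous marks,
non-periodic or three-dimensional domains, and edge-corrected estimators
for non-periodic windows are out of scope. The scaling parameter $\ell$ is
a user choice (`ell` in `model_params()`); the package does not attempt to
select it automatically, and all reference experiments use $\ell = 1$.
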