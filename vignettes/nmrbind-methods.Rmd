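---
title: "Binding isotherms, stoichiometries and shift-perturbation epitopes: methods behind nmrbind"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Binding isotherms, stoichiometries and shift-perturbation epitopes: methods behind nmrbind}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nmrbind)
```

## The binding model and its assumptions

`nmrbind` treats a protein–oligonucleotide equilibrium as `N` independent,
identical protein-binding sites per oligonucleotide. For total protein
concentration $c_A$, total oligonucleotide concentration $c_B$, per-site
dissociation constant $K_D$, the probability that a protein molecule is
bound is the exact root of the mass-balance quadratic

$$P_{AB} = \frac{1}{2 c_A}\left(c_A + N c_B + K_D -
\sqrt{(c_A + N c_B + K_D)^2 - 4 N c_A c_B}\right),$$

which remains correct under ligand depletion — the regime of every
experiment this package targets, since nanomolar complexes are titrated at
protein concentrations between 5 nM (fluorescence) and 1 mM (NMR). In the
limit $K_D \to 0$ this collapses to the stoichiometric kink curve
$P_{AB} = \min(1, N c_B/c_A)$ with its breakpoint at the molar ratio
$1/N$.

Assumptions baked into the model, deliberately matching monophasic
titration behaviour:

* the `N` sites are independent and equal — no cooperativity, no Hill
  coefficient. Fitted `N` is allowed to be any positive real, because
  least-squares estimates of a physical integer stoichiometry land near
  but not on the integer;
* observation models are population-linear: fast-exchange shifts
  interpolate affinely between the free and bound endpoints, slow-exchange
  peak integrals are the populations themselves (differential relaxation
  between free and bound resonances is ignored, as it is when populations
  are quantified from integrals), and fluorescence follows
  $F = F_0 (1 - q\,P_{AB})$ with no floating baseline and no inner-filter
  correction;
* the protein concentration is constant through a titration. Dilution by
  ligand addition is not corrected; supplying per-point concentrations via
  the explicit `schedule`/table interfaces overrides this.

## Numerical choices

The quadratic root is evaluated in the rationalized form
$2 N c_B / (c_A + N c_B + K_D + \sqrt{\mathrm{disc}})$ with the
discriminant expanded as
$(c_A - N c_B)^2 + 2 K_D (c_A + N c_B) + K_D^2$ — a sum of nonnegative
terms. This matters: the interesting datasets have $K_D$ five to six
orders of magnitude below the concentrations, where the textbook
$b - \sqrt{b^2 - 4ac}$ form loses all significant digits. The test suite
pins the implementation against an independent bisection of the mass
balance to $10^{-10}$ relative over 1000 random parameter sets.

```{r isotherm}
# nM complex at mM concentrations: indistinguishable from tight binding
fraction_bound(c_A = 1e-3, c_B = 0.25e-3, N = 2, K_D = 4e-9)
fraction_bound_tight(c_A = 1e-3, c_B = 0.25e-3, N = 2)
```

`fit_kd_fluorescence()` minimizes squared intensity residuals over
$(K_D, F_0, q)$ with Levenberg–Marquardt (`minpack.lm`), parameterizing
$K_D$ as $\log_{10} K_D$ for conditioning and bounding it in
$[10^{-12}, 10^{-3}]$ M. Eight multi-starts log-spaced across that range
guard against the flat valleys that quench curves develop when the
titration barely resolves the affinity; the best converged start wins, and
non-convergence is reported as a flag, never an exception. Curvature-based
standard errors are mapped back to the $K_D$ scale by the delta method;
`bootstrap_uncertainty()` (case resampling, 1000 draws, default seed 1729)
provides the resampling alternative, since published ± values rarely state
their derivation.

`fit_stoichiometry_nmr()` exploits the structure of its model
$y = a \cdot P_{AB}(N)$: for fixed $N$ the amplitude is linear and is
profiled out analytically, reducing the fit to a 1-D minimization over
$N$ (coarse log-grid, then golden-section refinement). This is far more
robust than a joint 2-D descent at the tight-binding kink, where the
derivative with respect to $N$ is nearly discontinuous. Normalization
follows the experimental convention: shifts are divided by the change at
the final titration point, not by a fitted asymptote, so a saturated
titration has amplitude ≈ 1 and an unsaturated one shows up as
amplitude < 1 rather than as a biased $N$.

## Shift-perturbation mapping

Per residue, the combined perturbation is the weighted Euclidean norm
$\Delta\delta_{comb} = \sqrt{\sum_i (w_i \Delta\delta_i)^2}$ over whatever
atoms are observed in both endpoint spectra — backbone amides, tryptophan
indole Hε1/Nε1, glutamine side-chain NH₂ protons (kept as separate atom
records under one residue). Default weights are 1.0 for ¹H and 0.14 for
¹⁵N (backbone and side-chain alike); 0.14 is the conventional
amide-nitrogen scaling, and since atom-specific weight tables vary between
laboratories, every weight is overridable.

The classification threshold $\sigma_0$ is the plain population standard
deviation of $\Delta\delta_{comb}$ over *measured* residues only. Peaks
that vanish from the bound spectrum (intermediate exchange, or unassigned
bound resonances) are excluded from $\sigma_0$ first and imputed at
$2\sigma_0$ afterwards — computing the threshold from values defined by
the threshold would be circular. Classes: below $\sigma_0$ none, in
$[\sigma_0, 2\sigma_0)$ moderate, at or above $2\sigma_0$ high, vanished
peaks disappeared-high, prolines not-evaluable. The boundary value
$\Delta\delta_{comb} = 2\sigma_0$ counts as high. A residue joins the
cross-ligand consensus if it is high (or disappeared-high) for at least
one ligand and at least moderate for every other — a rule that is
symmetric in the ligands and yields a subset of the union of the high
sets.

Because $\sigma_0$ is a property of each dataset's perturbation
distribution, absolute thresholds from any particular published map are
not reproducible without that map's spectra and weight table; what the
package guarantees, and tests, is the procedure: scaling all shifts by a
constant scales $\Delta\delta_{comb}$ and $\sigma_0$ together and leaves
every class unchanged.

## What the generators emulate — and what they do not

The synthetic-data module reproduces the statistical structure the
analysis assumes, under the study conditions the package is built around:

* **HSQC titrations** (`simulate_hsqc_titration()`): 1 mM protein, five
  equal ligand increments to a molar ratio of 0.625, a 66-residue protein
  with a 19-residue epitope and a proline at position 57. Fast-exchange
  peaks move along the isotherm with Gaussian position noise (0.002 ppm
  ¹H, 0.02 ppm ¹⁵N, about the digital resolution); slow-exchange residues
  split into free/bound peaks with population integrals; designated
  intermediate-exchange residues vanish while $P_{AB} \in [0.2, 0.8]$ — a
  bookkeeping mimic of severe broadening, not lineshape physics.
* **Normalized shift series** (`simulate_shift_series()`): the
  residue-averaged observable directly, with Gaussian noise
  $\sigma = 0.03$ on the normalized shifts.
* **Fluorescence titrations** (`simulate_fluorescence_titration()`):
  12 log-spaced points from 5% to 99% saturation plus a zero-ligand
  reference, 1% multiplicative intensity noise; a warning fires when
  $c_A > 100 K_D$, where the curve degenerates to the stoichiometric
  limit and constrains only a bound on the affinity.
* **Epitope fixtures** (`simulate_epitope_profile()`): background
  perturbations drawn per atom as mean-zero Gaussians with 0.01 ppm
  weighted scale (their combined magnitudes are then half-normal-like,
  well below reported interface perturbations), epitope effects uniform
  at 3–8× background, a quarter of the epitope flagged to disappear.

Shift values are rounded to 4 decimal places end to end, so written
fixtures round-trip exactly.

What passing tests on these data do **not** show about real spectra: peak
tracking and assignment transfer are assumed solved (endpoint lists are
taken as given); exchange broadening is binary (present/vanished) rather
than continuous; noise is homoscedastic and uncorrelated across residues;
and real backgrounds contain weak secondary-site responses that the
mean-zero background model does not. Estimates of sensitivity and
false-positive rate from the fixtures are therefore upper bounds on
real-data performance.

## Problem sizes and reproducibility

The recovery studies shipped with the package use 200 replicate fits per
condition — enough to estimate a replicate mean to a few hundredths of a
site or a few percent of a $K_D$, while keeping a full run in seconds on
one core. All generators take explicit integer seeds and are
byte-deterministic given the seed; the command-line pipeline records the
seed and a configuration digest in a run manifest so any output is
reproducible from config + seed alone.

```{r recovery}
kd <- kd_value("dT7", 303)
set.seed(1729)
n_hat <- replicate(50, {
  s <- simulate_shift_series(c_A = 1e-3, N = 2, K_D = kd, noise_sd = 0.03)
  coef(fit_stoichiometry_nmr(s, K_D_fixed = kd))[["N"]]
})
round(c(mean = mean(n_hat), sd = sd(n_hat)), 3)
```

## Known limitations

* No Bloch–McConnell lineshape simulation, no exchange-rate ($k_{ex}$)
  estimation, and no quantitative treatment of intermediate-exchange
  broadening beyond disappeared-peak bookkeeping.
* No multi-temperature (van 't Hoff) global fit; dissociation constants
  are per temperature.
* The quench model floats its amplitude per titration; if an instrument
  provides an absolute quench calibration, fixing `q` would tighten the
  $K_D$ error, which the current interface does not expose.
* The tight-binding stoichiometry fit is insensitive to `K_D` over many
  orders of magnitude (that is the point of fixing it), so a wrong fixed
  `K_D` of the right order does not bias `N` — but a grossly wrong one
  (within a few fold of $c_A$) would.
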