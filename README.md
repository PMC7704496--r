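# nmrbind

Quantitative analysis of protein–oligonucleotide binding from NMR and
tryptophan-fluorescence titrations.

Cold shock proteins (CSPs) and other OB-fold proteins bind single-stranded
nucleic acids with affinities that range from micromolar to low nanomolar —
a regime in which the usual hyperbolic binding curve is wrong, because the
ligand is depleted by binding at the protein concentrations the experiments
require. `nmrbind` is for spectroscopists who titrate a protein with
oligonucleotides and need, from those titrations:

* a dissociation constant `K_D` from fluorescence quench curves,
* a binding stoichiometry `N` from NMR chemical-shift trajectories, and
* a residue-level binding epitope from chemical-shift perturbation maps.

## The model

A protein A binds an oligonucleotide B carrying `N` independent, identical
sites. With total concentrations `c_A` and `c_B`, the probability that a
protein molecule is bound is the exact root of the mass-balance quadratic:

    P_AB = (1 / 2 c_A) * ( c_A + N c_B + K_D
                           - sqrt( (c_A + N c_B + K_D)^2 - 4 N c_A c_B ) )

When `K_D` is negligible against the concentrations (nanomolar complexes
observed at millimolar NMR concentrations) this collapses to the
tight-binding kink curve `P_AB = min(1, N c_B / c_A)`, whose breakpoint at
the molar ratio `1/N` reveals the stoichiometry directly.

Observables hang off `P_AB`:

* **fast exchange** — resonances move continuously,
  `delta = P_AB * delta_bound + (1 - P_AB) * delta_free`, so the
  normalized shift change equals the bound fraction;
* **slow exchange** — two peaks per nucleus whose integrals trade off as
  `1 - P_AB` and `P_AB`;
* **fluorescence quenching** — `F = F0 * (1 - q * P_AB)`.

Epitope mapping uses the combined chemical-shift perturbation
`Δδ_comb = sqrt( Σ (w_i Δδ_i)^2 )` (weights 1 for ¹H, 0.14 for ¹⁵N by
convention) between the free and saturated endpoint spectra, classifies
residues against the perturbation standard deviation σ₀ (moderate ≥ σ₀,
high ≥ 2σ₀, disappeared peaks imputed at 2σ₀), and intersects maps from
several ligands into a consensus epitope.

## Worked example

Fit a nanomolar `K_D` from a simulated quench titration at 5 nM protein
(the regime where ligand depletion matters), then a stoichiometry from a
millimolar NMR titration:

```r
library(nmrbind)

sim <- simulate_fluorescence_titration(c_A = 5e-9, N = 2,
                                       K_D = kd_value("dT7", 303),
                                       F0 = 100, q = 0.8, noise_rel = 0.01,
                                       temperature_label = "303 K", seed = 11)
fit_kd_fluorescence(sim$curve, N_fixed = 2)
#> Titration fit: fluorescence_quench (13 points)
#>   fixed: N = 2
#>      estimate std_error
#> K_D 4.197e-09 1.361e-10
#> F0  9.922e+01 3.500e-01
#> q   8.015e-01 3.399e-03
#>   residual sum of squares: 3.696
```

The generating `K_D` was 4 nM; with 1% intensity noise the fit returns
4.20 ± 0.14 nM. The stoichiometry fit reads the kink position out of a
noisy normalized shift series (truth: two sites per heptanucleotide):

```r
s <- simulate_shift_series(c_A = 1e-3, N = 2, K_D = kd_value("dT7", 303),
                           noise_sd = 0.03, seed = 11)
fit_stoichiometry_nmr(s, K_D_fixed = kd_value("dT7", 303))
#> Titration fit: stoichiometry_nmr (6 points)
#>   fixed: K_D = 4e-09
#>           estimate std_error
#> N           1.9960   0.10300
#> amplitude   0.9851   0.03579
#>   residual sum of squares: 0.005328
```

Epitope mapping from free/bound endpoint peak lists, with a cross-ligand
consensus:

```r
ep1 <- simulate_epitope_profile(seed = 1)
ep2 <- simulate_epitope_profile(seed = 2)
m1 <- classify_residues(perturbation_profile(ep1$free, ep1$bound),
                        ligand_label = "dT7")
m2 <- classify_residues(perturbation_profile(ep2$free, ep2$bound),
                        ligand_label = "rU7")
m1
#> Epitope map [dT7]: sigma0 = 0.0291 ppm, 66 residues
#>
#>             none         moderate             high disappeared-high
#>               45                2               13                5
#>    not-evaluable
#>                1
#> high-probability residues: 7, 10, 12, 13, 14, 16, 28, 29, 30, 33, 37, ...

cons <- consensus_epitope(list(m1, m2))
sort(cons$residue_index[cons$in_consensus])
#>  [1]  7  9 10 12 13 14 16 28 29 30 33 37 38 39 41 53 55 63 65
```

The consensus recovers exactly the planted 19-residue epitope. The same
pipeline runs from the shell via `exec/nmrbind`
(`simulate`, `fit-kd`, `fit-stoichiometry`, `map-epitope`, `report`).

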