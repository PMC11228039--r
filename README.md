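# hemocoord

Coordination and disorder of hemoglobin-subunit expression along the
Visual–Hippocampal (V–H) brain pathway.

The V–H pathway carries visual information from the occipital visual cortex
to the hippocampus through five regions — OVC, MTG, ITG, PHG, HC — and its
energy supply depends on oxygen delivered by hemoglobin. `hemocoord` is for
researchers who want to quantify, from bulk expression data with per-sample
clinical annotation (disease stage, neurofibrillary-tangle burden), how the
three hemoglobin subunit genes **HBB, HBA1, HBA2** lose their level, their
mutual correlation, and their cross-region coordination as Alzheimer's
disease progresses.

## The statistics at its core

Each sample contributes a hemoglobin expression vector
**x** = (HBB, HBA1, HBA2). For two (adjacent) regions with vectors **x**,
**y**:

- **size correlation** |**x**| · |**y**| — the product of the two Euclidean
  lengths; small when either region is hemoglobin-poor;
- **proportion correlation** cos θ = **x**·**y** / (|**x**||**y**|) — 1 when
  both regions keep the same subunit proportions (ideally the molecular
  stoichiometry HBB : HBA1 : HBA2 = 2 : 1 : 1, i.e. vectors ∝ (2, 1, 1));
- **synthesized correlation** **x**·**y** = size × proportion — the inner
  product, weakened by either kind of discoordination.

Each statistic is paired with the geometric mean √(mn) of the two samples'
NFT burdens, giving the NFT-vs-coordination trends.

Disorder of the subunit system in a (region, stage) cell is measured by the
eigenvalue entropy of the 3×3 Pearson correlation matrix **C** of the
subunits: with eigenvalues λᵢ and mode probabilities pᵢ = λᵢ / Σλᵢ,

S = −Σ pᵢ log₂ pᵢ  (bits),  0 ≤ S ≤ log₂ 3,

0 at perfect correlation and log₂ 3 at independence. A 3×3 equicorrelation
matrix with off-diagonal ρ has the closed-form spectrum
(1 + 2ρ, 1 − ρ, 1 − ρ), used throughout the tests as an analytic oracle.
Via S_Gibbs = k ln 2 · S and the constant-enthalpy relation
d(ΔG) = −T d(ΔS), an entropy rise of 0.02 units costs the system 0.02 T of
free energy.

Around these sit a fold-change screen (keep FC > 1.5 or FC < 0.06), the
limma moderated-t screen (|log₂FC| ≥ 0.5, p ≤ 0.05) with screen
intersection, and a synthetic multi-region cohort generator
(equicorrelated trivariate normal subunits, per-subject latent factor for
cross-region coupling, gamma-distributed NFT burden) so the entire pipeline
runs and is testable without any download.

## Worked example

```r
library(hemocoord)

# the textbook vector pair: MTG (0.3, 0.2, 0.3) vs PHG (0.2, 0.4, 0.4)
synthesized_correlation(c(0.3, 0.2, 0.3), c(0.2, 0.4, 0.4))
#> [1] 0.26
proportion_correlation(c(0.3, 0.2, 0.3), c(0.2, 0.4, 0.4))
#> [1] 0.9238698
size_correlation(c(0.3, 0.2, 0.3), c(0.2, 0.4, 0.4))
#> [1] 0.2814249

# a full synthetic cohort with planted disease progression
report <- run_pipeline(ad_progression_config(n_subjects_per_stage = 40,
                                             seed = 7), n_bins = 8)
report
#> <hemo_report>
#>   samples: 800 over 5 regions x 4 stages
#>   DEG: 0 by fold change, 3 by moderated t, 0 in the intersection
#>   entropy (bits): 0.386 to 1.575 across the region x stage grid
#>   region-pair Pearson over 20 (edge, stage) cells
#>   size-correlation trend vs NFT: rho(mean) = -0.98, rho(variance) = 0.29

subset(report$entropy, region == "MTG",
       c(stage, n_samples, shannon_bits, delta_vs_baseline))
#>   stage        n_samples shannon_bits delta_vs_baseline
#> 1 Normal              40       0.5166            0.0000
#> 2 Possible AD         40       0.8486            0.3320
#> 3 Probable AD         40       1.3404            0.8238
#> 4 Definite AD         40       1.5752            1.0586
```

Reading the output: the synthesized correlation 0.26 of the damaged vector
pair is far below the perfect value obtained at the 2:1:1 stoichiometry
(cos θ = 1); in the simulated cohort the MTG subunit entropy climbs from
0.52 bits (Normal, subunits tightly correlated) toward the log₂ 3 ≈ 1.585
ceiling (Definite AD, subunits decorrelated) — a gain of ~1.06 bits over the
disease course, i.e. a free-energy loss of 1.06 · k ln 2 · T. The
moderated-t screen recovers exactly the three hemoglobin genes; the
fold-change screen at its published asymmetric cuts (1.5 / 0.06) does not
flag a 2^−1.6 fold change, which is why the printed intersection is empty at
these defaults. `autoplot()` works on every result object (entropy grid,
expression summary, NFT bins, DEG fit).

A command-line front end wrapping these functions is installed at
`inst/scripts/hemocoord` (subcommands `simulate`, `preprocess`, `deg`,
`entropy`, `coordinate`, `report`, `run-all`).

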