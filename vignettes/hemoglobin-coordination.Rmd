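---
title: "Measuring hemoglobin-subunit coordination and disorder along the Visual–Hippocampal pathway"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring hemoglobin-subunit coordination and disorder along the Visual–Hippocampal pathway}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hemocoord)
```

## The model

`hemocoord` treats the expression of the three hemoglobin subunit genes in
one brain sample as a vector $\vec{x} = (\mathrm{HBB}, \mathrm{HBA1},
\mathrm{HBA2})$ on the log2 scale, and asks two questions of a cohort
annotated with brain region, disease stage and neurofibrillary-tangle (NFT)
burden:

1. **Coordination.** How similar are the vectors of two adjacent regions of
   the Visual–Hippocampal pathway (edges OVC–MTG, OVC–ITG, MTG–PHG,
   ITG–PHG, PHG–HC)? Three statistics decompose similarity into amount and
   composition: the size correlation $|\vec{x}||\vec{y}|$, the proportion
   correlation $\cos\theta$, and their product, the synthesized correlation
   $\vec{x}\cdot\vec{y}$. Healthy tissue should sit near the molecular
   stoichiometry $\mathrm{HBB}:\mathrm{HBA1}:\mathrm{HBA2} = 2:1:1$, where
   every proportion correlation is exactly 1. Each pair of samples also
   carries the geometric mean $\sqrt{mn}$ of the two NFT burdens, so the
   statistics can be binned against tangle load (`summarize_vs_nft()`).
2. **Disorder.** Within one (region, stage) cell, how tightly do the three
   subunits co-vary? The 3×3 Pearson matrix $C$ is summarized by the
   Shannon entropy of its trace-normalized eigenvalue spectrum,
   $p_i = \lambda_i / \sum_j \lambda_j$, $S = -\sum_i p_i \log_2 p_i$.
   $S = 0$ for perfectly correlated subunits (rank-1 $C$) and
   $S = \log_2 3$ for independent ones. Because a correlation matrix has
   trace 3, normalizing by the eigenvalue sum and by 3 coincide for any
   valid input; we normalize by the sum so the probabilities remain proper
   after clipping round-off negatives. Gibbs entropy is the same quantity
   in natural units, $S_G = k \ln 2 \, S$, and with enthalpy held constant
   the free-energy differential is $d(\Delta G) = -T\, d(\Delta S)$
   (`free_energy_delta()`).

Assumptions worth keeping in mind: the vectors live on the log2 scale (the
pipeline's coordination stage deliberately uses log2, not z-scored, values,
because magnitudes carry the signal the size correlation needs); Pearson
correlation only captures linear dependence of the subunits; and entropy
estimated from a sample correlation matrix is biased slightly downward near
independence because sampled eigenvalues always spread.

## Conventions the data forced us to pick

Several choices were genuinely open; the package pins them as follows.

- **Worked-example discrepancy.** For the vector pair (0.3, 0.2, 0.3) and
  (0.2, 0.4, 0.4) the inner product is exactly 0.26 while the cosine is
  0.9239. Sources quoting "0.26" for this pair are reporting the inner
  product. The package computes both (`synthesized_correlation()`,
  `proportion_correlation()`) and never conflates them.
- **Region-pair Pearson (`region_pair_pearson()`).** The coefficient is
  computed over pooled component pairs (three per matched sample), after
  scaling each vector to unit length (default) *and centring each component
  across samples*. Without centring, the fixed subunit profile — identical
  in both regions — dominates the pooled series and reports $r \approx 0.8$
  even for completely uncoupled regions; after centring, $r$ measures how
  sample-to-sample deviations co-vary and vanishes when the coupling does.
  Matching is by subject when subject ids exist, else by stage-stratified
  order (with a message). Fewer than 3 matched pairs, or a zero-variance
  pooled series (all vectors proportional to (1, 1, 1) after unitizing),
  yield `NA` with a warning, never a silent `NaN`.
- **Fold-change screen.** The published cuts are kept verbatim — keep
  $FC > 1.5$ or $FC < 0.06$, both strict — although they are strikingly
  asymmetric (0.06 is far beyond $1/1.5$); both are arguments of
  `select_by_fc()`. Fold change is taken on anti-logged group means by
  default since inputs are stored as $\log_2(g + 1)$. The moderated-t
  screen uses *inclusive* boundaries ($|\log_2 FC| \ge 0.5$,
  $p \le 0.05$), matching how such screens are usually stated in results;
  no multiple-testing correction is applied by default (a BH option
  exists).
- **Standardization.** `standardize()` z-scores per gene with the sample
  (n−1) standard deviation, which makes the operation idempotent (to
  1e−12) and consistent with Pearson machinery; a population-SD variant is
  exposed because hand-worked three-point examples usually use it. The
  default grouping is global (all samples of a dataset) so that
  between-region level differences survive; a within-region mode exists.
  Zero-variance genes map to zero rows with a warning.
- **Numerical guards.** Eigenvalues in $[-10^{-10}, 0)$ are clipped to 0 as
  floating-point error; anything below $-10^{-6}$ raises an error rather
  than being silently repaired. `synthesized = size × proportion` holds to
  1e−9 by construction. Duplicate gene rows collapse to the per-sample
  median (even counts: mean of the central pair). Raw values are
  transformed as $\log_2(g+1)$, and a scale tag on every expression table
  prevents double-logging.

## The synthetic cohort generator

`synthetic_config()` / `generate_cohort()` emulate a multi-region
post-mortem cohort: per stage, each subject contributes one sample per
region; the subunit triple is drawn from an equicorrelated trivariate
normal with stage-specific mean shift; a per-subject latent factor with
loading $\sqrt{\rho_\text{cross}}$ couples a subject's values across
regions; background genes are independent noise; NFT burden is gamma
distributed (non-negative and right-skewed, like tangle densities, whose
true distribution is not published) with a stage-specific mean, drawn per
subject by default (per-sample mode exists, since it is not documented
which convention annotated cohorts use). All draws derive deterministically
from one seed via per-stage substreams.

Defaults, chosen once as a realistic disease trajectory (log2 units
throughout): baseline means (8, 7, 7) — HBB double the alphas on the raw
scale, i.e. the 2:1:1 stoichiometry; stage shifts (0, −0.5, −1, −1.5);
subunit equicorrelation (0.9, 0.7, 0.5, 0.3); cross-region coupling
(0.8, 0.6, 0.4, 0.2); residual SD 0.3; NFT means (1, 6, 15, 30) with gamma
shape 2; 30 subjects per stage (a scale comparable to a ~125-subject
four-stage cohort); 100 background genes. `ad_progression_config()` is a
steeper preset that drives the subunit correlation and the cross-region
coupling to exactly 0 and raises the noise SD with stage, so that all four
progression signatures — falling subunit means, rising entropy, collapsing
region-pair Pearson, falling/noisier size correlation vs NFT — are planted
by construction. The equicorrelation requirement $\rho > -1/2$ keeps the
3×3 matrix positive semi-definite; the latent-factor construction restricts
cross-region coupling to $[0, 1]$.

What the generator does **not** emulate: probe-level microarray artifacts,
batch effects, platform-specific probe–gene mapping, anatomies beyond the
five pathway regions, and any nonlinear or non-Gaussian dependence among
subunits. Tests passing on this generator therefore certify the
statistical machinery — recovery of planted means, correlations, entropy
and trends — not the biology of any real cohort.

## Analytic oracles and test scale

The equicorrelation spectrum $(1 + 2\rho, 1 - \rho, 1 - \rho)$ gives the
closed-form entropy `equicorrelation_entropy(rho)`, strictly decreasing on
$[0, 1)$; sampled cohorts are checked against it (within 0.02 bits at
5,000 samples, the scale at which sampling error of the entropy is a few
thousandths of a bit). The moderated-t screen is calibrated on a null
simulation of 5,000 genes at 10 vs 10 samples (type-I error within
0.05 ± 0.01). Planted-signal integration runs at 40 subjects per stage
across the five regions (800 samples), where every signature is several
standard errors deep; property tests of the generator use 300–2,000
subjects per cell depending on the precision the assertion needs. These
sizes keep the full suite to a few seconds to minutes while leaving each
assertion a wide margin.

## Known limitations

- The coordination statistics are descriptive; the package makes no causal
  claim linking them (or the free-energy bookkeeping) to symptoms.
- The entropy measure sees only the subunit *correlation* structure; two
  cells with equal correlation but very different expression levels have
  equal entropy.
- `read_cohort()`'s GEO series-matrix support covers the tab-separated
  table plus `Sample_characteristics` key–value lines; full GEO metadata
  parsing (platform annotation, probe mapping) is out of scope.
- The fold-change screen's verbatim asymmetric cuts mean that moderate
  down-regulation (e.g. $2^{-1.5}$) passes the moderated-t screen but not
  the fold-change screen; users studying such effects should set
  `select_by_fc(lower = )` to a cut matched to their effect size.
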