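---
title: "Modelling the DOM degradation cascade from FT-ICR mass spectra"
author: "domcascade"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the DOM degradation cascade from FT-ICR mass spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(domcascade)
```

## The scientific problem

Dissolved organic matter (DOM) in soils and headwaters is a mixture of
thousands of compounds. As microbial and photochemical reworking proceeds
along flowpaths — down a soil profile, down a hillslope, towards streams —
the easily degraded fraction is consumed and the mixture converges on a
shared pool of slowly cycling compounds. Compounds detected in *every*
sample of a study are called **universal** (or "core") compounds, and the
progressive convergence towards them is the **degradation cascade**.

Ultrahigh-resolution FT-ICR mass spectrometry resolves each sample into
thousands of exact masses, each attributable to a molecular formula
C~c~H~h~N~n~O~o~S~s~P~p~. `domcascade` implements the full analysis chain
from calibrated peak lists to cascade statistics and gradient inference,
together with a synthetic-data generator that provides ground truth for
every stage.

## Formula chemistry

A formula's descriptors are computed from its element counts:

* exact neutral monoisotopic mass, from a single constant table
  (`MONOISOTOPIC_MASS`; carbon-12 is exactly 12 Da, other elements to nine
  decimals);
* elemental ratios H/C, O/C, N/C;
* double-bond equivalents, DBE = 1 + C − H/2 + N/2 + P/2;
* the modified aromaticity index of Koch & Dittmar,
  AI~mod~ = (1 + C − O/2 − S − (N+P+H)/2) / (C − O/2 − S − N − P).
  When the denominator is non-positive or the quotient negative, AI~mod~
  is defined as 0, and it is clamped to at most 1. This prevents saturated
  formulas from being labelled condensed-aromatic.

Compound classes are assigned from a **first-match boundary table** over
H/C, O/C, AI~mod~ and nitrogen presence (`default_class_table()`).
Published van-Krevelen schemes differ in their exact cut points, so the
table is data the user can replace; the shipped default uses
AI~mod~ ≥ 0.67 for condensed aromatics, O/C > 0.67 splitting tannin-like
(H/C < 1.5) from carbohydrate-like (H/C ≥ 1.5), nitrogen-requiring
amino-sugar- and protein-like windows, lipid-like (O/C ≤ 0.3, H/C ≥ 1.5),
unsaturated hydrocarbons (O/C ≤ 0.1, 0.7 ≤ H/C < 1.5), lignin-like as the
broad interior window, and a terminal catch-all ("other") so every formula
receives exactly one label. Because the exact boundaries of published
schemes vary, absolute class shares (e.g. "79% lignin-like") depend on the
table; within-study contrasts along gradients are far less sensitive.

## Formula assignment

Peak lists are assumed calibrated (mass error well below the tolerance).
The assignment contract is:

1. **Replicate retention** — only signals detected in both duplicate
   measurements are kept. Peaks are matched greedily by nearest m/z within
   0.5 ppm, each peak used once; a matched pair becomes one peak with the
   intensity-weighted mean m/z and mean intensity.
2. **Analytical window** — 150–1000 m/z.
3. **Method detection limit** — peaks below `mdl_factor` (default 2) times
   a noise estimate are discarded. The default noise estimator is the
   median intensity of the lowest-intensity decile; it is pluggable
   because exported mass lists differ in how much sub-noise signal they
   contain. With fewer than 10 peaks the minimum intensity is used.
4. **Candidate enumeration** — all formulas within C 0–100, H 2–200,
   O 0–70, N 0–3, S 0–2, P 0–2 whose exact mass lies within 0.2 ppm of
   the neutralised mass, filtered to non-negative integer DBE. Ions are
   [M−H]⁻, singly charged; the neutral mass is m/z + 1.007276467 Da (the
   proton mass — at 0.2 ppm the electron mass is decisive). Candidates are
   ranked by |mass error|, then fewest heteroatoms (N+S+P), then canonical
   string; the first candidate wins. This deterministic tie-break replaces
   the homologous-series heuristics of interactive assignment tools.
5. **Normalisation** — intensities of peaks with an assigned formula are
   summed per formula and divided by their total, so each sample's
   intensities sum to 1.

The enumeration is tested for exact agreement with an independent
exhaustive element-grid oracle that never solves for hydrogen.

## Cascade statistics

* `universal_set()` — formulas with occupancy ≥ a threshold (default 1,
  i.e. present in every sample). The threshold is a parameter only to
  support sensitivity analyses.
* `universal_fractions()` — per sample, the percentage of detected
  formulas in the pool and the percentage of total normalised intensity
  carried by the pool. Because intensities are normalised per sample, the
  non-universal intensity share is exactly the complement.
* `class_profile()` — per-class shares under count weighting (shares of
  formulas, summing to 100%) or intensity weighting (sums of original
  normalised intensities — deliberately *not* renormalised after
  subsetting, so a subset's share is its share of total signal).
* `weighted_mass()` — the intensity-weighted mean mass
  m/z~wm~ = Σ m~i~ I~i~ / Σ I~i~ over a class and subset
  (all / universal / non-universal). Scale-invariant in the intensities;
  computed on neutral masses by default (the [M−H]⁻ m/z differs by a
  constant, so gradient shifts are identical).

## Rarefied similarity to a reference pool

To compare formula sharing across units with very different richness, the
unit's formula set is repeatedly subsampled without replacement to a fixed
depth (default 6000 formulas, 1000 draws) and the percentage of each draw
shared with a reference set is averaged. Draws are presence-based and
uniform — "a set of N compounds" semantics, as in richness rarefaction —
and units with fewer formulas than the depth are excluded rather than
up-sampled. The mean equals the hypergeometric expectation 100·k/n
regardless of depth; the standard deviation shrinks with depth, and
`rarefaction_profile()` exposes that series as the adequacy diagnostic.
The reference set is not rarefied by default. One master seed plus a
stable hash of the unit id gives per-unit substreams, so results do not
depend on processing order.

## Gradient inference

`fit_trend()` fits an additive GLM of a response on the focal gradient
factor (depth or hillslope position) plus the available covariates among
the other gradient, catchment and sample type. The interaction between
the two gradient factors is fitted first and dropped when its drop-test
p-value exceeds 0.05 (a fixed rule). Families: overdispersed binomial for
count proportions (quasi-likelihood dispersion scaling — a deterministic,
dependency-light alternative to an observation-level random effect; the
dispersion estimate is exposed so the two can be compared), and Gaussian
fits of logit-, log- or un-transformed responses. Marginal means average
model predictions with equal weights over non-focal factor levels and are
back-transformed; all pairwise contrasts of the focal factor are
Tukey-adjusted via emmeans' multivariate-t machinery (Holm fallback when
the contrast covariance is singular), and contrasts against the baseline
level (5 cm or shoulder) are extracted. Saturated or zero-variance fits
give 0/0 test statistics; a zero estimated difference with zero
uncertainty is reported as p = 1.

For multivariate composition, the package provides:

* `reduce_collinear()` — iterative removal at Pearson |r| > 0.80 of the
  member with the largest mean |r| (ties keep the earlier-listed column);
* `forward_select()` — permutation forward selection on the RDA pseudo-F
  with an add-then-drop loop at α = 0.10. The entry test permutes the
  *maximum* pseudo-F over the candidate set, not the best candidate's own
  null; without this, picking the best of p candidates inflates the entry
  rate and a pure-noise design would not stay empty at the nominal rate.
* `pcnm()` — principal coordinates of neighbour matrices (delegating to
  vegan): distances beyond the truncation (auto = longest
  minimum-spanning-tree edge) are replaced by 4× truncation, the matrix is
  Gower-centred and eigen-decomposed, eigenvectors with eigenvalue
  > 1e−10 are returned with a deterministic sign (first nonzero loading
  positive). Note that under auto truncation the leading eigenvector on
  an equally spaced transect is a full-period sine; the textbook monotone
  leading axis appears when the truncation spans the transect (the plain
  PCoA limit).
* `rda_adj_r2()` — multivariate least squares on column-centred matrices;
  R² as trace ratio, Ezekiel adjustment; errors on rank-deficient input.
  The partitioning routines use a rank-tolerant variant internally
  (effective p = rank) so duplicated predictor matrices behave like
  vegan's.
* `variance_partition()` — adjusted R² of every non-empty union of 2–3
  predictor matrices, Venn fractions by solving the inclusion–exclusion
  system exactly; raw fractions sum to the full-model adjusted R² to
  numerical precision, negatives are clamped only in the display column.
* `hierarchical_partition()` — each predictor's average incremental
  adjusted R² over all subsets, averaged within then across subset sizes;
  contributions sum exactly to the full-model adjusted R². Exact
  enumeration is limited to 15 predictors; larger sets must be grouped
  into matrices, as is standard for hierarchical partitioning across
  predictor matrices.

Predictors are standardised to zero mean and unit variance before
selection and partitioning.

## The synthetic study

`simulation_config()` defines the generator's study conditions: 4
catchments × (4 hillslope positions × 4 depths + 1 stream) = 68 samples; a
3000-formula library sampled inside the elemental bounds and the
150–1000 Da window with a realistic class mixture (lignin-like dominant at
45%); a 400-formula universal core whose composition is 79% lignin-like,
mirroring the dominance of aromatic, slowly cycling material in core DOM
pools. The cascade gradient is a single ordinal axis applied to both
factor sets: scaled positions g ∈ [0, 1] along depth and along hillslope,
additive across the two axes, with stream samples at the end of both.

Per sample:

* the core is always present; non-core members of the depleted classes are
  removed with probability `rate · g · (1 − z)^mass_bias`, where z is the
  within-class scaled mass. Tannin- and condensed-aromatic-like classes
  (plant-derived, photo/bio-labile in this context) use rate 0.5 with no
  mass preference; carbohydrate- and unsaturated-hydrocarbon-like classes
  use rate 1.0 with mass_bias 0.3, so their low-mass members are lost
  first and the class's intensity-weighted mass rises along the cascade.
  These defaults were calibrated so the synthetic carbohydrate-like
  weighted-mass increase from the shallowest to the deepest soil level
  (about 8–12% depending on the seed) falls within the 10–29% interval
  reported for such shifts in field data; the earlier exponential-decay
  preference could not reach that range because it concentrates removal
  on a thin low-mass tail.
* surviving non-core compounds are detected with probability 0.75;
  intensities are lognormal (meanlog 0, sdlog 1) — the standard
  heavy-tailed choice for MS signal, as no empirical intensity
  distribution is available;
* core intensities are rescaled so the universal intensity share follows
  base 0.50 plus 0.10 per gradient axis (i.e. +10 percentage points from
  the first to the last level of either axis), with logit-scale noise
  (sd 0.05).

`simulate_peaklist()` emulates duplicate measurements: each formula emits
its [M−H]⁻ m/z with independent 0.05 ppm Gaussian jitter per replicate
(the calibration-residual scale) and ±5% lognormal intensity variation;
spurious signals (10% of peaks) recur in both replicates at intensities
drawn from (0.15–0.25)× the weakest real peak, a band chosen so that
twice the median noise intensity — the detection limit at the default
factor — sits clearly above the largest noise peak. They therefore
survive replicate matching and are removed by the detection limit, which
is the failure mode the limit exists for.

What the generator does **not** emulate: chromatographic fractionation,
isotopologues, adducts beyond [M−H]⁻, instrument drift, ionisation
suppression, and formula-level phylogenetic structure in which compounds
co-occur. Passing tests therefore demonstrate that the statistics recover
known structure under realistic noise, not that field data meet the
generator's assumptions.

## Problem sizes and numerical choices

The shipped analyses and tests run the full 68-sample, 3000-formula study
for dataset-level statistics; peak-list emulation and reassignment use one
sample (~2400 peaks); seed-replication loops (weighted-mass detection,
selection behaviour) use 50–100 replicate seeds, with a 300-formula
library where library scale is not the point. Rarefaction in the shipped
analyses uses depth 1500 (samples hold ~2100–2600 formulas) with 200–500
draws. Tolerances: exact-mass assertions at 1e−8 Da scale, partitioning
identities at 1e−10, Monte-Carlo assertions at 3 standard errors.

## Known limitations

* Class shares depend on the boundary table; only the default table ships.
* The assignment tie-break is deterministic but simpler than
  homologous-series logic; at 0.2 ppm and ≤ 1000 Da the practical
  difference is small (candidate lists are nearly always singletons below
  ~500 Da).
* Quasi-likelihood overdispersion is not identical to an
  observation-level random effect; the dispersion estimate is exposed for
  comparison.
* `hierarchical_partition()` is exact and therefore exponential in the
  number of predictors.
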