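# domcascade

Analysis of the dissolved-organic-matter (DOM) **degradation cascade**
from ultrahigh-resolution FT-ICR mass spectra: as microbial reworking
proceeds down a soil profile and along a hillslope towards streams, DOM
converges on a *universal* pool of compounds detected in every sample.
`domcascade` implements the full chain for soil/stream biogeochemists:

* **Formula chemistry** — canonical CHNOSP formula parsing, exact
  monoisotopic masses, H/C, O/C, DBE, the modified aromaticity index
  AI_mod = (1 + C − O/2 − S − (N+P+H)/2)/(C − O/2 − S − N − P), and
  van-Krevelen compound classification via a user-replaceable first-match
  boundary table.
* **Formula assignment** — calibrated negative-mode ([M−H]⁻) peak lists
  to per-sample normalised formula tables: duplicate-measurement
  retention, 150–1000 m/z window, a method detection limit of 2 × noise,
  and exhaustive candidate enumeration within C 0–100, H 2–200, O 0–70,
  N 0–3, S 0–2, P 0–2 at 0.2 ppm.
* **Cascade statistics** — universal (core) pool detection by occupancy,
  per-sample universal richness/intensity fractions, class profiles, and
  intensity-weighted mean masses m/z_wm = Σ m_i·I_i / Σ I_i.
* **Rarefied similarity** — the percentage of a fixed-size random draw of
  a sample's formulas shared with a reference pool (mean ± sd over
  repeated draws), for fair comparison across unequally rich samples.
* **Gradient inference** — GLM trends with estimated marginal means and
  Tukey-adjusted contrasts (via emmeans); collinearity reduction at
  Pearson |r| > 0.8; permutation forward selection; PCNM spatial
  eigenvectors; variance partitioning across 2–3 predictor matrices with
  exact adjusted-R² Venn fractions; hierarchical partitioning.
* **Synthetic study generator** — gradient-structured datasets with known
  ground truth (universal core, class depletion, mass-biased removal,
  +10 pp universal-intensity slope) and jittered duplicate peak lists, so
  every stage is testable without field data.

## Worked example

```r
library(domcascade)

cfg <- simulation_config(seed = 1)       # 68 samples, 3000 formulas
sim <- simulate_dataset(cfg)
ds  <- sim$dataset

pool <- universal_set(ds)                # formulas present in all samples
length(pool$formulas)                    # 400
pool_class_composition(ds, pool$formulas)[1:2, ]
#>  compound_class   n pct
#>     lignin-like 316  79
#>     tannin-like  20   5

uf <- merge(universal_fractions(ds, pool), ds$samples, by = "sample_id")
soil <- uf[uf$sample_type == "soil", ]
soil$share <- soil$intensity_pct / 100
tr <- fit_trend(soil, "share", family = "gaussian-logit", focal = "depth")
tr$emmeans
#>  level  estimate     lower     upper
#>      5 0.5516174 0.5453948 0.5578238
#>     15 0.5823700 0.5762464 0.5884683
#>     30 0.6178612 0.6119112 0.6237761
#>     60 0.6532326 0.6475192 0.6589023
100 * trend_extreme_shift(tr)            # +10.16 pp, configured +10 pp
```

The marginal means are the universal intensity share at each depth,
averaged over hillslope positions and catchments and back-transformed from
the logit scale; the +10 percentage-point rise from 5 to 60 cm recovers
the effect the generator planted.

The numbered scripts under `analysis/` run the whole study —
`01_simulate.R` (dataset + ground truth), `02_assign.R` (peak-list
round-trip; 99.6% of planted formulas recovered at 0.05 ppm jitter),
`03_cascade_stats.R` (universal pool = 13.3% of the library, 79%
lignin-like), `04_similarity.R` (rarefied similarity rising 17.9% → 21.0%
along the cascade), `05_gradient.R` (trends, variance partitioning,
hierarchical partitioning) — writing tables under `results/`.

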