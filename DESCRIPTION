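Package: domcascade
Title: Degradation-Cascade Analysis of Dissolved Organic Matter from
    FT-ICR Mass Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to analyse the molecular degradation cascade of
    dissolved organic matter (DOM) characterised by ultrahigh-resolution
    FT-ICR mass spectrometry. Covers molecular-formula parsing, exact
    monoisotopic mass arithmetic, structural descriptors (double-bond
    equivalents, modified aromaticity index) and van-Krevelen compound
    classification; formula assignment of calibrated negative-mode peak
    lists under elemental bounds and ppm tolerance; assembly of
    formula-by-sample intensity datasets; universal (core) compound-pool
    statistics, compound-class profiles and intensity-weighted mean
    masses; rarefaction-based similarity to a reference formula pool;
    gradient trend models with marginal means and Tukey-adjusted
    contrasts; and environmental-versus-spatial variance partitioning
    with collinearity reduction, permutation forward selection, PCNM
    spatial eigenvectors and hierarchical partitioning. A synthetic-data
    generator with known ground truth makes every stage testable.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    emmeans,
    vegan
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
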