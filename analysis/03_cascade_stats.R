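#!/usr/bin/env Rscript
# Universal-pool statistics: detect the formulas present in every sample,
# compute per-sample universal richness and intensity fractions, the class
# composition of the universal pool, and per-class intensity-weighted
# masses of the non-universal pool.

suppressPackageStartupMessages(library(domcascade))

ds <- read_dataset("results/intensities.tsv", "results/metadata.tsv")
pool <- universal_set(ds)

uf <- merge(universal_fractions(ds, pool), ds$samples, by = "sample_id")
comp <- pool_class_composition(ds, pool$formulas)

groups <- c("all", "carbohydrate-like", "unsaturated-hydrocarbon-like",
            "tannin-like", "condensed-aromatic-like", "lignin-like")
wm <- do.call(rbind, lapply(groups, function(g)
  weighted_mass(ds, group = g, subset = "non-universal", pool = pool)))

dir.create("results", showWarnings = FALSE)
utils::write.table(uf, "results/universal_fractions.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
utils::write.table(comp, "results/universal_pool_classes.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
utils::write.table(wm, "results/weighted_mass.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

cat("Universal pool:", length(pool$formulas), "of", nrow(ds$intensity),
    sprintf("formulas (%.1f%% of the library)\n",
            100 * length(pool$formulas) / nrow(ds$intensity)))
cat(sprintf("Mean per-sample universal richness: %.1f%%; intensity: %.1f%%\n",
            mean(uf$richness_pct), mean(uf$intensity_pct)))
cat("Top classes of the universal pool:\n")
print(head(comp, 3), row.names = FALSE)
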