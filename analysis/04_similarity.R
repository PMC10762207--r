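#!/usr/bin/env Rscript
# Rarefaction-based similarity of every sample to a reference formula pool.
# The universal pool plays the role of the degradation end-member reference
# (in the field analysis this is a deep-sea DOM sample): samples further
# along the cascade share more of a fixed-size random draw of their
# formulas with the reference.

suppressPackageStartupMessages(library(domcascade))

seed <- 1
ds <- read_dataset("results/intensities.tsv", "results/metadata.tsv")
pool <- universal_set(ds)

res <- similarity_to_reference(ds, pool$formulas, depth = 1500,
                               iterations = 500, seed = seed)
res <- merge(res, ds$samples, by.x = "unit_id", by.y = "sample_id")

dir.create("results", showWarnings = FALSE)
utils::write.table(res, "results/similarity.tsv", sep = "\t", quote = FALSE,
                   row.names = FALSE)

soil <- res[res$sample_type == "soil", ]
agg <- aggregate(mean_shared_pct ~ depth_cm, soil, mean)
cat("Rarefied similarity to the reference pool (depth 1500, 500 draws):\n")
print(agg, row.names = FALSE)
cat(sprintf("Stream samples: %.1f%%\n",
            mean(res$mean_shared_pct[res$sample_type == "stream"])))
cat("Samples excluded (fewer formulas than the rarefaction depth):",
    sum(res$excluded), "\n")
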