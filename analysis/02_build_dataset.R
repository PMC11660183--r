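#!/usr/bin/env Rscript
# Step 2 — taxonomy mapping and leakage-controlled dataset construction.
#
# Maps the directory's surveyor tags through the shipped taxonomy config,
# checks recovery against ground truth, deduplicates to one example per
# normalized name with modal multi-labels, memorizes chains, and writes
# the 50/25/25 split manifest.

suppressPackageStartupMessages(library(foodenv))
seed <- 2024L

rec <- read_store_csv("results/data/directory.csv")
truth <- read_label_csv("results/data/directory_labels.csv")

tax <- load_taxonomy(default_taxonomy_path())
mapped <- map_records(rec, tax)
agree <- mean(apply(mapped == truth$labels, 1, all))
cat(sprintf("taxonomy recovery vs ground truth: %.1f%% of records exact\n",
            100 * agree))

ex <- deduplicate_modal(rec, truth$labels)
cat(sprintf("deduplicated %d records to %d unique names\n",
            nrow(rec), length(ex$names)))

split <- split_dataset(ex, location_counts(rec), seed = seed)
print(split)
stopifnot(length(intersect(split$train$names, split$test$names)) == 0)
write_split_manifest(split, "results/split_manifest.json")
cat("memorized chains:",
    paste(split$manifest$memorized_names, collapse = "; "), "\n")
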