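#!/usr/bin/env Rscript
# Step 3 — train the reference store-name classifier.
#
# Rebuilds the split (deterministic in the seed), fits the one-vs-rest
# n-gram model with validation-monitored early stopping, saves the model,
# and prints example predictions in the raw-score + boolean layout.

suppressPackageStartupMessages(library(foodenv))
seed <- 2024L

rec <- read_store_csv("results/data/directory.csv")
truth <- read_label_csv("results/data/directory_labels.csv")
ex <- deduplicate_modal(rec, truth$labels)
split <- split_dataset(ex, location_counts(rec), seed = seed)

cfg <- training_config(seed = seed)
model <- train_classifier(split$train, split$validation, cfg)
print(model)
save_model(model, "results/name_model.rds")

examples <- c("la vina bodega deli", "golden cocktail bar & steakhouse",
              "lucky hudson place")
sc <- predict_scores(model, examples)
write_predictions_csv(examples, sc, "results/example_predictions.csv")
for (i in seq_along(examples)) {
  held <- food_classes()[threshold_scores(sc[i, , drop = FALSE])[1, ]]
  cat(sprintf("  %-34s -> {%s}\n", examples[i],
              paste(held, collapse = ", ")))
}
write_manifest("results/train_manifest.json", seed,
               inputs = list(directory = "results/data/directory.csv"),
               extra = model$manifest[c("stopped_checkpoint",
                                        "best_validation_macro_f1")])
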