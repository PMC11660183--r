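#!/usr/bin/env Rscript
# Step 1 — simulate the three administrative data sources.
#
# Emits a labeled storefront directory (surveyor tags/flags + ground
# truth), a longitudinal inspection extract with closures and two planted
# churn signals, and a restaurant file with service/venue tags, all under
# results/data/.

suppressPackageStartupMessages(library(foodenv))
dir.create("results/data", recursive = TRUE, showWarnings = FALSE)
seed <- 2024L

dir_cfg <- synth_config(n_stores = 2000L, noise_rate = 0.10, seed = seed)
d <- generate_directory(dir_cfg)
write_store_csv(d$records, "results/data/directory.csv")
write_label_csv(d$labels, d$records$record_id,
                "results/data/directory_labels.csv")
cat(sprintf("directory: %d records (%d chain locations across %d chains)\n",
            nrow(d$records), sum(d$records$name %in% d$chain_names),
            length(d$chain_names)))
cat(sprintf("  labeled: %d; multi-label: %d (bodega-type: %d)\n",
            sum(rowSums(d$labels) > 0), sum(rowSums(d$labels) > 1),
            sum(d$labels[, "Convenience"] & d$labels[, "FastFood"])))

plants <- list(
  list(lon = -73.87, lat = 40.81, classes = c("Grocery", "SpecialtyFoods"),
       delta = -2),
  list(lon = -73.92, lat = 40.72, classes = "Convenience", delta = 3))
lon_cfg <- synth_config(n_stores = 1500L, closure_rate = 0.05,
                        year_range = c(2019L, 2021L),
                        planted_churn = plants, seed = seed + 1L)
g <- generate_longitudinal(lon_cfg)
write_store_csv(g$records, "results/data/longitudinal.csv")
write_label_csv(g$labels, g$records$record_id,
                "results/data/longitudinal_labels.csv")
closed <- sum(!is.na(g$records$out_of_business_date))
cat(sprintf("longitudinal: %d stores 2019-2021, %d recorded closures,\n",
            nrow(g$records), closed))
cat("  planted signals: grocery/specialty -2 per year; convenience +3 per year\n")

rest_cfg <- synth_config(n_stores = 3000L, fraction_other = 0.10,
                         service_vague_rate = 0.10, seed = seed + 2L)
r <- generate_restaurant_dataset(rest_cfg)
write_store_csv(r$records, "results/data/restaurants.csv")
write_label_csv(r$labels, r$records$record_id,
                "results/data/restaurant_labels.csv")
cat(sprintf("restaurants: %d records, %.1f%% venue tags masked as 'Other'\n",
            nrow(r$records), 100 * mean(r$records$venue_tag == "Other")))
write_manifest("results/data/manifest.json", seed,
               inputs = list(generator = "synth_config defaults"),
               extra = list(step = "simulate"))
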