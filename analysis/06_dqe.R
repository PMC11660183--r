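#!/usr/bin/env Rscript
# Step 6 — data quality enhancement on the tagged restaurant file.
#
# Cross-tabulates classifier labels against the service-description tags,
# ranks tag/label discrepancies, and breaks down what the classifier
# infers for records with the vague 'Other' venue tag.

suppressPackageStartupMessages(library(foodenv))

rec <- read_store_csv("results/data/restaurants.csv")
model <- load_model("results/name_model.rds")
labels <- threshold_scores(predict_scores(model, rec$name))

at <- agreement_table(rec, labels, tag_field = "service_description",
                      restrict_to = c("FastFood", "Restaurant"))
print(at)
write_agreement_csv(at, "results/service_agreement.csv")
cat(sprintf("restricted to FastFood/Restaurant: %.0f%% of records kept\n",
            100 * (1 - at$excluded_count / nrow(rec))))

alignment <- c("Fast Food" = "FastFood",
               "Takeout (To Go/Grab-And-Go only)" = "FastFood",
               "Quick Service" = "FastFood",
               "Fine Dining" = "Restaurant",
               "Family Style" = "Restaurant",
               "Casual Dining" = "Restaurant",
               "Table Service" = "Restaurant")
disc <- discrepancy_report(at, alignment)
write.csv(disc, "results/service_discrepancies.csv", row.names = FALSE)
cat(sprintf("tag/label discrepancies worth analyst review: %d cells, ",
            nrow(disc)))
cat(sprintf("top: %s\n", if (nrow(disc)) paste0(disc$class[1], " under '",
            disc$tag[1], "' (", disc$count[1], ")") else "none"))

oth <- rec$venue_tag == "Other"
ob <- impute_other(rec[oth, ], labels[oth, , drop = FALSE])
jsonlite::write_json(ob, "results/other_breakdown.json",
                     auto_unbox = TRUE, digits = NA)
cat(sprintf(paste0("venue 'Other' (%d records): %.0f%% restaurant no bar, ",
                   "%.0f%% with bar,\n  %.0f%% other classes, ",
                   "%.0f%% unlabeled\n"),
            ob$n, 100 * ob$fraction_restaurant_no_bar,
            100 * ob$fraction_restaurant_with_bar,
            100 * ob$fraction_other_classes, 100 * ob$fraction_unlabeled))
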