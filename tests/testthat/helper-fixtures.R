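# Small fixtures built in code for the unit and property tests.

default_tax <- local({
  tax <- NULL
  function() {
    if (is.null(tax)) tax <<- load_taxonomy(default_taxonomy_path())
    tax
  }
})

# one-row storefront data.frame
make_record <- function(record_id = "S000001", name = "store",
                        meta = "Food", tags = character(),
                        flags = character(),
                        survey_date = as.Date("2023-06-01"),
                        lon = -73.95, lat = 40.75) {
  rec <- data.frame(record_id = record_id, name = name,
                    meta_category = meta, survey_date = survey_date,
                    longitude = lon, latitude = lat,
                    out_of_business_date = as.Date(NA),
                    service_description = NA_character_,
                    venue_tag = NA_character_,
                    stringsAsFactors = FALSE)
  rec$tags <- list(tags)
  rec$flags <- list(flags)
  rec$inspection_dates <- list(as.Date(character()))
  rec
}

bind_records <- function(...) do.call(rbind, list(...))

# label matrix from a list of class-name vectors
lab <- function(...) as_label_matrix(list(...))

# small fast training config for classifier tests
fast_config <- function(seed = 1L) {
  training_config(max_epochs = 12L, patience = 3L, seed = seed)
}

# random label matrix
random_labels <- function(n, p = 0.2) {
  m <- matrix(runif(n * 10) < p, nrow = n)
  colnames(m) <- food_classes()
  as_label_matrix(m)
}
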