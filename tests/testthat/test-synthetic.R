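test_that("generator output is deterministic and internally consistent", {
  cfg <- synth_config(n_stores = 400, noise_rate = 0, seed = 99)
  a <- generate_directory(cfg)
  b <- generate_directory(cfg)
  expect_identical(a, b)
  # tags/flags recover the ground truth exactly at zero corruption
  expect_identical(map_records(a$records, default_tax()), a$labels)
  # record invariants
  expect_true(all(nzchar(a$records$name)))
  expect_true(all(a$records$longitude >= cfg$bbox[1] &
                  a$records$longitude <= cfg$bbox[3]))
  expect_true(all(a$records$latitude >= cfg$bbox[2] &
                  a$records$latitude <= cfg$bbox[4]))
  expect_false(anyDuplicated(a$records$record_id) > 0)
})

test_that("tag corruption breaks taxonomy recovery proportionally", {
  cfg <- synth_config(n_stores = 500, tag_corruption = 0.5, seed = 4)
  d <- generate_directory(cfg)
  mapped <- map_records(d$records, default_tax())
  agree <- foodenv:::label_key(mapped) == foodenv:::label_key(d$labels)
  # stores with no labels agree trivially; labeled ones break at ~50%
  labeled <- rowSums(d$labels) > 0
  expect_lt(mean(agree[labeled]), 0.75)
  expect_gt(mean(agree[labeled]), 0.25)
})

test_that("class prevalence matches the binomial sampling oracle", {
  cfg <- synth_config(n_stores = 10000, n_chains = 0, seed = 123)
  d <- generate_directory(cfg)
  p <- 0.10  # nominal Grocery prevalence
  se <- sqrt(p * (1 - p) / 10000)
  expect_lt(abs(mean(d$labels[, "Grocery"]) - p), 3 * se)
  # paired class marginal is preserved despite the cooccurrence plant
  pc <- 0.15  # Convenience
  se_c <- sqrt(pc * (1 - pc) / 10000)
  expect_lt(abs(mean(d$labels[, "Convenience"]) - pc), 3 * se_c)
  # joint at least the planted 0.05
  joint <- mean(d$labels[, "Convenience"] & d$labels[, "FastFood"])
  expect_gt(joint, 0.05 - 3 * sqrt(0.05 * 0.95 / 10000))
})

test_that("chains replicate one name at 11+ distinct locations", {
  cfg <- synth_config(n_stores = 300, n_chains = 5,
                      chain_size_range = c(11, 20), seed = 8)
  d <- generate_directory(cfg)
  expect_length(unique(d$chain_names), 5)
  tab <- table(d$records$name)
  for (nm in d$chain_names) expect_gte(tab[[nm]], 11)
  # chain locations are distinct points
  ch <- d$records[d$records$name == d$chain_names[1], ]
  expect_false(anyDuplicated(ch[, c("longitude", "latitude")]) > 0)
  expect_error(synth_config(chain_size_range = c(5, 9)), "at least 11")
})

test_that("longitudinal extract honors closures and inspection cadence", {
  cfg <- synth_config(n_stores = 200, closure_rate = 0,
                      year_range = c(2019, 2021), seed = 17)
  g <- generate_longitudinal(cfg)
  expect_identical(g, generate_longitudinal(cfg))
  # no closures: every store inspected in every window year
  yrs <- lapply(g$records$inspection_dates,
                function(d) unique(as.integer(format(d, "%Y"))))
  expect_true(all(vapply(yrs, function(y)
    all(2019:2021 %in% y), logical(1))))
  expect_true(all(is.na(g$records$out_of_business_date)))
  # sorted dates; closure dates after final inspection when present
  cfg2 <- synth_config(n_stores = 300, closure_rate = 0.3,
                       year_range = c(2019, 2021), seed = 18)
  g2 <- generate_longitudinal(cfg2)
  expect_true(all(vapply(g2$records$inspection_dates,
                         function(d) !is.unsorted(d), logical(1))))
  closed <- !is.na(g2$records$out_of_business_date)
  expect_gt(sum(closed), 0)
  last_insp <- as.Date(vapply(g2$records$inspection_dates[closed],
                              function(d) as.character(max(d)), ""))
  expect_true(all(g2$records$out_of_business_date[closed] >= last_insp))
})

test_that("planted churn budget is validated", {
  pl <- list(list(lon = -73.9, lat = 40.7, classes = "Grocery",
                  delta = -50))
  expect_error(generate_longitudinal(
    synth_config(n_stores = 100, planted_churn = pl,
                 year_range = c(2019, 2021))), "planted churn requires")
  expect_error(synth_config(planted_churn = list(
    list(lon = 0, lat = 0, classes = character(), delta = 1))),
    "planted_churn")
})

test_that("restaurant dataset carries consistent service and venue tags", {
  cfg <- synth_config(n_stores = 5000, fraction_other = 0.10, seed = 31)
  r <- generate_restaurant_dataset(cfg)
  # labels concentrate on the service classes
  off <- c("SpecialtyFoods", "Convenience", "Discount", "Grocery",
           "AlcoholStore")
  expect_equal(sum(r$labels[, off]), 0)
  expect_true(all(rowSums(r$labels) > 0))
  # observed 'Other' fraction within 3 binomial SEs of the nominal rate
  se <- sqrt(0.1 * 0.9 / 5000)
  expect_lt(abs(mean(r$records$venue_tag == "Other") - 0.10), 3 * se)
  # withheld truth is retained and differs from the masked tag
  oth <- r$records$venue_tag == "Other"
  expect_true(all(nzchar(r$records$venue_true[oth])))
  # fraction_other = 0 emits no masked venues
  r0 <- generate_restaurant_dataset(
    synth_config(n_stores = 300, fraction_other = 0, seed = 31))
  expect_false(any(r0$records$venue_tag == "Other" &
                   r0$records$venue_true != "Other"))
})

test_that("ambiguous-name rate degrades token separability monotonically", {
  # token-lookup classifier: name contains a class token iff class held
  vocab <- foodenv:::default_name_vocabulary()
  token_predict <- function(names) {
    m <- empty_labels(length(names))
    for (cl in food_classes())
      for (tok in vocab[[cl]])
        m[grepl(tok, names, fixed = TRUE), cl] <- TRUE
    m
  }
  f1_at <- function(noise, seed) {
    d <- generate_directory(synth_config(n_stores = 600, n_chains = 0,
                                         noise_rate = noise, seed = seed))
    suppressWarnings(
      evaluate_predictions(token_predict(normalize_name(d$records$name)),
                           d$labels)$macro_f1)
  }
  expect_equal(f1_at(0, 51), 1.0)
  lo <- mean(vapply(52:54, function(s) f1_at(0.3, s), 0))
  expect_lt(lo, 1.0)
})
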