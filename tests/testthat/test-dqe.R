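rest_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generate_restaurant_dataset(
        synth_config(n_stores = 2000, fraction_other = 0.12, seed = 57))
    cache
  }
})

test_that("agreement table matches a brute-force tally", {
  # degenerate: single class, single tag
  recs <- bind_records(make_record("S1", "a"), make_record("S2", "b"))
  recs$service_description <- "Takeout"
  at <- agreement_table(recs, lab("FastFood", "FastFood"))
  expect_equal(unname(at$counts["FastFood", "Takeout"]), 2)
  expect_equal(sum(at$counts), 2)
  expect_equal(at$excluded_count, 0)

  # multi-label records contribute once per held restricted row
  recs1 <- make_record("S1", "diner")
  recs1$service_description <- "Diner"
  at2 <- agreement_table(recs1, lab(c("FastFood", "Restaurant")))
  expect_equal(unname(at2$counts[, "Diner"]), c(1, 1))

  # synthetic dataset vs per-record loop
  fx <- rest_fixture()
  at3 <- agreement_table(fx$records, fx$labels)
  brute <- matrix(0L, 2, ncol(at3$counts),
                  dimnames = dimnames(at3$counts))
  excluded <- 0L
  for (i in seq_len(nrow(fx$records))) {
    held <- intersect(c("FastFood", "Restaurant"),
                      labels_to_list(fx$labels[i, , drop = FALSE])[[1]])
    if (!length(held)) { excluded <- excluded + 1L; next }
    tag <- fx$records$service_description[i]
    for (cl in held) brute[cl, tag] <- brute[cl, tag] + 1L
  }
  expect_identical(at3$counts, brute)
  expect_identical(at3$excluded_count, excluded)
  # column sums equal restricted per-tag counts times label multiplicity
  expect_equal(sum(at3$counts),
               sum(rowSums(fx$labels[, c("FastFood", "Restaurant")])[
                 rowSums(fx$labels[, c("FastFood", "Restaurant")]) > 0]))
})

test_that("missing tags are tallied under the reserved column", {
  recs <- make_record("S1", "x")
  recs$service_description <- NA_character_
  at <- agreement_table(recs, lab("Restaurant"))
  expect_equal(unname(at$counts["Restaurant", "(missing)"]), 1)
  expect_error(agreement_table(recs, lab("Restaurant"),
                               tag_field = "cuisine"), "tag_field")
  expect_error(agreement_table(recs, lab("Restaurant"),
                               restrict_to = character()), "restrict_to")
})

test_that("impute_other partitions 'Other' records into four shares", {
  labs <- lab("Restaurant", "Restaurant", "Restaurant")
  ob <- impute_other(data.frame(x = 1:3), labs)
  expect_equal(ob$fraction_restaurant_no_bar, 1)
  expect_equal(ob$fraction_restaurant_with_bar + ob$fraction_other_classes +
               ob$fraction_unlabeled, 0)

  ob0 <- impute_other(data.frame(x = 1:2), empty_labels(2))
  expect_equal(ob0$fraction_unlabeled, 1)

  mixed <- lab(c("FastFood", "AlcoholBar"), "JuiceCoffee", "Restaurant",
               character())
  obm <- impute_other(data.frame(x = 1:4), mixed)
  expect_equal(obm$fraction_restaurant_with_bar, 0.25)
  expect_equal(obm$fraction_other_classes, 0.25)
  expect_equal(obm$fraction_restaurant_no_bar, 0.25)
  expect_equal(obm$fraction_unlabeled, 0.25)
  expect_equal(with(obm, fraction_restaurant_no_bar +
                      fraction_restaurant_with_bar +
                      fraction_other_classes + fraction_unlabeled), 1,
               tolerance = 1e-9)
  expect_error(impute_other(data.frame(), empty_labels(0)), "at least one")
})

test_that("imputation recovers planted venue shares on noise-free names", {
  fx <- rest_fixture()
  oth <- fx$records$venue_tag == "Other"
  ob <- impute_other(fx$records[oth, ], fx$labels[oth, ])
  n <- sum(oth)
  truth <- fx$records$venue_true[oth]
  share_no_bar <- mean(truth == "Restaurant (no bar)")
  se <- sqrt(share_no_bar * (1 - share_no_bar) / n)
  expect_lt(abs(ob$fraction_restaurant_no_bar - share_no_bar), 3 * se)
  # the majority of masked venues is recovered as restaurant-no-bar
  expect_gt(ob$fraction_restaurant_no_bar,
            max(ob$fraction_restaurant_with_bar, ob$fraction_other_classes,
                ob$fraction_unlabeled))
  # fractions are order-invariant
  perm <- sample(which(oth))
  ob2 <- impute_other(fx$records[perm, ], fx$labels[perm, ])
  expect_equal(ob2[1:4], ob[1:4])
})

test_that("discrepancy report ranks contradicting cells", {
  counts <- matrix(c(3L, 10L, 0L, 7L), 2, 2,
                   dimnames = list(c("FastFood", "Restaurant"),
                                   c("fine dining", "fast food")))
  at <- structure(list(counts = counts, excluded_count = 0L,
                       tag_field = "service_description",
                       restrict_to = c("FastFood", "Restaurant")),
                  class = "agreement_table")
  rep <- discrepancy_report(at, c("fine dining" = "Restaurant",
                                  "fast food" = "FastFood"))
  expect_equal(rep$count, c(7L, 3L))
  expect_equal(rep$class[1], "Restaurant")
  expect_equal(rep$tag[1], "fast food")

  # full agreement: empty report
  agree <- at
  agree$counts["FastFood", "fine dining"] <- 0L
  agree$counts["Restaurant", "fast food"] <- 0L
  expect_equal(nrow(discrepancy_report(agree,
                                       c("fine dining" = "Restaurant",
                                         "fast food" = "FastFood"))), 0)
  # unaligned tags are skipped
  expect_equal(nrow(discrepancy_report(at, c(brunch = "Restaurant"))), 0)

  # random tables vs brute-force scan
  withr::local_seed(3)
  for (i in 1:10) {
    cn <- c("t1", "t2", "t3")
    m <- matrix(rpois(6, 3), 2, 3,
                dimnames = list(c("FastFood", "Restaurant"), cn))
    att <- structure(list(counts = m, excluded_count = 0L,
                          tag_field = "service_description",
                          restrict_to = rownames(m)),
                     class = "agreement_table")
    align <- c(t1 = "FastFood", t2 = "Restaurant")
    got <- discrepancy_report(att, align)
    brute <- 0L
    for (tg in names(align)) for (cl in rownames(m))
      if (cl != align[[tg]] && m[cl, tg] > 0) brute <- brute + 1L
    expect_equal(nrow(got), brute)
    if (nrow(got) > 1) expect_true(all(diff(got$count) <= 0))
  }
})
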