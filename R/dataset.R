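#' @title Leakage-controlled dataset construction
#' @description Turn a labeled storefront directory into train /
#'   validation / test sets: names are normalized, records are
#'   deduplicated to one example per distinct name with modal multi-label
#'   selection, high-frequency chain names (more than 10 locations) are
#'   set aside for memorization in the training set, and the remainder is
#'   split 50/25/25. Because deduplication is exact on the normalized
#'   name, no name can appear in two partitions.
#' @name dataset
NULL

#' Normalize a store name
#'
#' Lower-cases, collapses internal whitespace, trims, and applies Unicode
#' NFC normalization. Punctuation (apostrophes, ampersands) is kept:
#' store names carry meaningful punctuation. Idempotent.
#'
#' @param name Character vector of raw names.
#' @return Character vector of normalized names.
#' @export
#' @examples
#' normalize_name("La  Vina   Deli Grocery")
normalize_name <- function(name) {
  if (!is.character(name)) stop("name must be character", call. = FALSE)
  out <- stringi::stri_trans_nfc(name)
  out <- tolower(trimws(gsub("\\s+", " ", out)))
  if (any(!nzchar(out)))
    stop("empty or whitespace-only name at position(s): ",
         paste(which(!nzchar(out)), collapse = ", "), call. = FALSE)
  out
}

#' A set of labeled name examples
#'
#' Container pairing unique normalized names with their label matrix and
#' the record ids that contributed each example.
#'
#' @param names Character vector of unique normalized names.
#' @param labels Logical label matrix, rows aligned with `names`.
#' @param provenance Optional list of character vectors of record ids.
#' @return A `labeled_set` object.
#' @export
labeled_set <- function(names, labels, provenance = NULL) {
  labels <- as_label_matrix(labels)
  stopifnot(length(names) == nrow(labels))
  if (anyDuplicated(names))
    stop("normalized names must be unique within a labeled_set",
         call. = FALSE)
  structure(list(names = names, labels = labels,
                 provenance = provenance %||% as.list(names)),
            class = "labeled_set")
}

#' @export
print.labeled_set <- function(x, ...) {
  cat("<labeled_set> ", length(x$names), " examples, ",
      sum(rowSums(x$labels) > 0), " with at least one label\n", sep = "")
  invisible(x)
}

#' @export
length.labeled_set <- function(x) length(x$names)

subset_labeled <- function(x, idx) {
  labeled_set(x$names[idx], x$labels[idx, , drop = FALSE],
              x$provenance[idx])
}

#' Deduplicate records to one example per name with modal labels
#'
#' Groups records by normalized name and keeps, for each name, the most
#' frequent whole multi-label combination across that name's records.
#' Frequency ties are broken in favor of the combination carried by the
#' most recently surveyed record; any remaining tie is broken
#' deterministically by record id order.
#'
#' @param records Storefront data.frame with columns `record_id`, `name`,
#'   `survey_date` (Date).
#' @param labels Logical label matrix, rows aligned with `records`.
#' @return A `labeled_set` of unique normalized names.
#' @export
deduplicate_modal <- function(records, labels) {
  labels <- as_label_matrix(labels)
  stopifnot(nrow(records) == nrow(labels))
  nm <- normalize_name(records$name)
  keys <- label_key(labels)
  date_num <- as.numeric(as.Date(records$survey_date))
  groups <- split(seq_len(nrow(records)), nm)
  uniq <- names(groups)
  out_labels <- empty_labels(length(uniq))
  prov <- vector("list", length(uniq))
  for (g in seq_along(groups)) {
    idx <- groups[[g]]
    k <- keys[idx]
    tab <- table(k)
    winners <- names(tab)[tab == max(tab)]
    if (length(winners) > 1L) {
      # recency tie-break: candidate records holding a tied combination,
      # ordered by survey date (desc) then record_id (asc)
      cand <- idx[k %in% winners]
      ord <- order(-date_num[cand], records$record_id[cand])
      pick <- cand[ord[1L]]
    } else {
      pick <- idx[match(winners, k)]
    }
    out_labels[g, ] <- labels[pick, ]
    prov[[g]] <- records$record_id[idx]
  }
  labeled_set(uniq, out_labels, prov)
}

#' Count distinct locations per normalized name
#'
#' Used for chain detection ahead of the split: a name appearing at more
#' than `threshold` distinct locations is treated as a chain.
#'
#' @param records Storefront data.frame with a `name` column.
#' @return Named integer vector: records per normalized name.
#' @export
location_counts <- function(records) {
  tab <- table(normalize_name(records$name))
  stats::setNames(as.integer(tab), names(tab))
}

#' Split examples into train/validation/test with chain memorization
#'
#' Names backed by more than `chain_threshold` locations are set aside
#' from the split and added to the training set so the model memorizes
#' them; memorized names therefore never appear in validation or test, and
#' test scores are a lower bound on inference performance. The remaining
#' examples are shuffled with `seed` and partitioned 50/25/25
#' (train/validation/test); integer-division remainders go to train.
#'
#' @param examples A `labeled_set` (from [deduplicate_modal()]).
#' @param counts Named integer vector from [location_counts()]; must cover
#'   every example name.
#' @param seed Integer seed for the shuffle.
#' @param chain_threshold Locations above which a name is memorized
#'   (default 10).
#' @return A `dataset_split`: list with `labeled_set`s `train`,
#'   `validation`, `test`, `memorized` (subset of train) and a `manifest`
#'   (seed, sizes, memorized names).
#' @export
split_dataset <- function(examples, counts, seed, chain_threshold = 10L) {
  stopifnot(inherits(examples, "labeled_set"))
  missing <- setdiff(examples$names, names(counts))
  if (length(missing))
    stop("location counts missing for ", length(missing), " name(s), e.g. '",
         missing[1L], "'", call. = FALSE)
  mem_mask <- counts[examples$names] > chain_threshold
  pool <- which(!mem_mask)
  if (length(pool) < 4L)
    stop("need at least 4 non-memorized examples to form three non-empty ",
         "partitions", call. = FALSE)
  perm <- withr::with_seed(seed, sample(pool))
  n <- length(perm)
  n_val <- floor(n * 0.25)
  n_test <- floor(n * 0.25)
  n_train <- n - n_val - n_test
  train_idx <- perm[seq_len(n_train)]
  val_idx <- perm[n_train + seq_len(n_val)]
  test_idx <- perm[n_train + n_val + seq_len(n_test)]
  memorized <- subset_labeled(examples, which(mem_mask))
  train <- subset_labeled(examples, c(train_idx, which(mem_mask)))
  split <- structure(list(
    train = train,
    validation = subset_labeled(examples, val_idx),
    test = subset_labeled(examples, test_idx),
    memorized = memorized,
    manifest = list(seed = seed, chain_threshold = chain_threshold,
                    n_train = length(train$names),
                    n_validation = n_val, n_test = n_test,
                    n_memorized = length(memorized$names),
                    memorized_names = memorized$names)),
    class = "dataset_split")
  assert_no_leakage(split)
  split
}

assert_no_leakage <- function(split) {
  a <- split$train$names; b <- split$validation$names; c <- split$test$names
  if (length(intersect(a, b)) || length(intersect(a, c)) ||
      length(intersect(b, c)))
    stop("internal error: name leakage across partitions", call. = FALSE)
  if (length(setdiff(split$memorized$names, a)))
    stop("internal error: memorized example missing from train",
         call. = FALSE)
  invisible(split)
}

#' @export
print.dataset_split <- function(x, ...) {
  m <- x$manifest
  cat("<dataset_split> train ", m$n_train, " (incl. ", m$n_memorized,
      " memorized) / validation ", m$n_validation, " / test ", m$n_test,
      "  [seed ", m$seed, "]\n", sep = "")
  invisible(x)
}

#' Write a split manifest to JSON
#' @param split A `dataset_split`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_split_manifest <- function(split, path) {
  jsonlite::write_json(split$manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
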