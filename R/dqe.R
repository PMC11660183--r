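#' @title Data quality enhancement on externally tagged datasets
#' @description Uses classifier labels to audit an independent tag
#'   taxonomy on the same records: cross-tabulates labels against a tag
#'   field, breaks down what the classifier infers for vague `'Other'`
#'   venue tags, and ranks discrepancies between tags and labels. The
#'   module reports; it never rewrites source tags.
#' @name dqe
NULL

MISSING_TAG <- "(missing)"

#' Cross-tabulate classifier labels against a tag field
#'
#' Restricts to records whose label set intersects `restrict_to` (by
#' default the restaurant service classes FastFood and Restaurant —
#' records labeled only e.g. SweetsDesserts or JuiceCoffee are excluded
#' to avoid unwanted overlap) and counts one cell per (held restricted
#' class, tag value) pair. A record holding both restricted classes
#' contributes to both rows. Records without the tag are tallied under a
#' reserved `(missing)` column.
#'
#' @param records Data.frame with the tag field column.
#' @param labels Label matrix aligned with `records`.
#' @param tag_field `"service_description"` or `"venue_tag"`.
#' @param restrict_to Non-empty character vector of food classes.
#' @return An `agreement_table`: integer `counts` matrix (classes x
#'   tags), `excluded_count`, `tag_field`.
#' @export
agreement_table <- function(records, labels,
                            tag_field = "service_description",
                            restrict_to = c("FastFood", "Restaurant")) {
  if (!tag_field %in% c("service_description", "venue_tag"))
    stop("tag_field must be 'service_description' or 'venue_tag'",
         call. = FALSE)
  if (!length(restrict_to))
    stop("restrict_to must be non-empty", call. = FALSE)
  bad <- setdiff(restrict_to, food_classes())
  if (length(bad))
    stop("unknown food class name(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  labels <- as_label_matrix(labels)
  stopifnot(nrow(records) == nrow(labels))
  tags <- as.character(records[[tag_field]])
  tags[is.na(tags) | !nzchar(tags)] <- MISSING_TAG
  held <- labels[, restrict_to, drop = FALSE]
  keep <- rowSums(held) > 0
  cols <- sort(unique(tags[keep]))
  counts <- matrix(0L, nrow = length(restrict_to), ncol = length(cols),
                   dimnames = list(restrict_to, cols))
  for (cl in restrict_to) {
    tab <- table(tags[keep & held[, cl]])
    counts[cl, names(tab)] <- as.integer(tab)
  }
  structure(list(counts = counts, excluded_count = sum(!keep),
                 tag_field = tag_field, restrict_to = restrict_to),
            class = "agreement_table")
}

#' @export
print.agreement_table <- function(x, ...) {
  cat("<agreement_table> ", x$tag_field, ": ", sum(x$counts),
      " (class, tag) counts over ", ncol(x$counts), " tags; ",
      x$excluded_count, " records excluded by class restriction\n",
      sep = "")
  print(x$counts)
  invisible(x)
}

#' Write an agreement table to CSV
#' @param table An `agreement_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_agreement_csv <- function(table, path) {
  df <- as.data.frame(table$counts)
  df <- cbind(class = rownames(table$counts), df)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Breakdown of classifier inference for 'Other'-tagged records
#'
#' For records whose venue tag is `'Other'`, reports the shares the
#' classifier assigns to: restaurant without bar (`FastFood` or
#' `Restaurant`, no `AlcoholBar`), restaurant with bar (`FastFood` or
#' `Restaurant` plus `AlcoholBar`), some other class only, and no label
#' at all. The four fractions sum to 1.
#'
#' @param records Data.frame restricted to `venue_tag == 'Other'`
#'   records (enforced when the column is present).
#' @param labels Label matrix aligned with `records`.
#' @return List of the four fractions plus `n`.
#' @export
impute_other <- function(records, labels) {
  labels <- as_label_matrix(labels)
  if (!nrow(labels))
    stop("impute_other requires at least one record", call. = FALSE)
  if ("venue_tag" %in% names(records) &&
      !all(records$venue_tag == "Other"))
    stop("records must be restricted to venue_tag == 'Other'",
         call. = FALSE)
  rest <- labels[, "FastFood"] | labels[, "Restaurant"]
  bar <- labels[, "AlcoholBar"]
  any_label <- rowSums(labels) > 0
  n <- nrow(labels)
  list(
    fraction_restaurant_no_bar = sum(rest & !bar) / n,
    fraction_restaurant_with_bar = sum(rest & bar) / n,
    fraction_other_classes = sum(any_label & !rest) / n,
    fraction_unlabeled = sum(!any_label) / n,
    n = n)
}

#' Rank disagreements between tags and classifier labels
#'
#' Given an alignment mapping tag values to the class they are expected
#' to indicate (e.g. `'fine dining'` to Restaurant, `'fast food'` to
#' FastFood), returns the table cells where the held class contradicts
#' the expectation, sorted by count descending. Tags without an alignment
#' entry are skipped.
#'
#' @param table An `agreement_table`.
#' @param alignment Named character vector: `alignment[tag]` is the
#'   expected class.
#' @return Data.frame with columns `class`, `tag`, `count` (possibly
#'   zero-row).
#' @export
discrepancy_report <- function(table, alignment) {
  stopifnot(inherits(table, "agreement_table"))
  out <- data.frame(class = character(), tag = character(),
                    count = integer(), stringsAsFactors = FALSE)
  for (tag in intersect(names(alignment), colnames(table$counts))) {
    expected <- alignment[[tag]]
    for (cl in rownames(table$counts)) {
      cnt <- table$counts[cl, tag]
      if (cl != expected && cnt > 0)
        out <- rbind(out, data.frame(class = cl, tag = tag,
                                     count = as.integer(cnt),
                                     stringsAsFactors = FALSE))
    }
  }
  out[order(-out$count, out$class, out$tag), , drop = FALSE]
}
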