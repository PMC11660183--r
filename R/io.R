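#' @title Storefront file readers and writers
#' @description Plain-CSV interchange for storefront directories and
#'   ground-truth labels. Multi-valued fields (tags, flags, inspection
#'   dates) are semicolon-delimited within their column; dates are
#'   ISO-8601.
#' @name io
NULL

STORE_COLUMNS <- c("record_id", "name", "meta_category", "tags", "flags",
                   "survey_date", "longitude", "latitude",
                   "inspection_dates", "out_of_business_date",
                   "service_description", "venue_tag")

split_multi <- function(x) {
  lapply(strsplit(ifelse(is.na(x), "", x), ";", fixed = TRUE),
         function(v) trimws(v[nzchar(trimws(v))]))
}

join_multi <- function(x) {
  vapply(x, function(v) paste(as.character(v), collapse = ";"), "")
}

#' Read a storefront directory CSV
#'
#' Expects the documented columns (`record_id`, `name`, `meta_category`,
#' `tags`, `flags`, `survey_date`, `longitude`, `latitude`,
#' `inspection_dates`, `out_of_business_date`, `service_description`,
#' `venue_tag`); a missing required column is an error naming it.
#'
#' @param path CSV path.
#' @return Storefront data.frame with list columns for the multi-valued
#'   fields and Date columns for dates.
#' @export
read_store_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  missing <- setdiff(STORE_COLUMNS, names(df))
  if (length(missing))
    stop("store CSV ", path, " is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  out <- data.frame(record_id = df$record_id, name = df$name,
                    meta_category = df$meta_category,
                    survey_date = as.Date(df$survey_date),
                    longitude = as.numeric(df$longitude),
                    latitude = as.numeric(df$latitude),
                    out_of_business_date = as.Date(
                      ifelse(nzchar(df$out_of_business_date),
                             df$out_of_business_date, NA)),
                    service_description = ifelse(
                      nzchar(df$service_description),
                      df$service_description, NA),
                    venue_tag = ifelse(nzchar(df$venue_tag),
                                       df$venue_tag, NA),
                    stringsAsFactors = FALSE)
  out$tags <- split_multi(df$tags)
  out$flags <- split_multi(df$flags)
  out$inspection_dates <- lapply(split_multi(df$inspection_dates), as.Date)
  if ("venue_true" %in% names(df)) out$venue_true <- df$venue_true
  out
}

#' Write a storefront directory CSV
#'
#' @param records Storefront data.frame (as produced by the generators or
#'   [read_store_csv()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_store_csv <- function(records, path) {
  df <- data.frame(
    record_id = records$record_id, name = records$name,
    meta_category = records$meta_category,
    tags = join_multi(records$tags), flags = join_multi(records$flags),
    survey_date = as.character(records$survey_date),
    # full double precision so coordinates survive the round trip
    longitude = sprintf("%.17g", records$longitude),
    latitude = sprintf("%.17g", records$latitude),
    inspection_dates = join_multi(lapply(records$inspection_dates,
                                         as.character)),
    out_of_business_date = ifelse(is.na(records$out_of_business_date), "",
                                  as.character(records$out_of_business_date)),
    service_description = ifelse(is.na(records$service_description), "",
                                 records$service_description),
    venue_tag = ifelse(is.na(records$venue_tag), "", records$venue_tag),
    stringsAsFactors = FALSE)
  if ("venue_true" %in% names(records)) df$venue_true <- records$venue_true
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read / write ground-truth label CSVs
#'
#' Label CSVs carry `record_id` plus one indicator column per food class
#' in canonical order.
#'
#' @param labels Label matrix.
#' @param record_ids Character vector aligned with `labels`.
#' @param path CSV path.
#' @return `write_label_csv`: `path` invisibly; `read_label_csv`: list
#'   with `record_id` and `labels`.
#' @export
write_label_csv <- function(labels, record_ids, path) {
  labels <- as_label_matrix(labels)
  df <- data.frame(record_id = record_ids, stringsAsFactors = FALSE)
  for (cl in food_classes()) df[[cl]] <- as.integer(labels[, cl])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_label_csv
#' @export
read_label_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(c("record_id", food_classes()), names(df))
  if (length(missing))
    stop("label CSV ", path, " is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  m <- as.matrix(df[food_classes()]) > 0
  colnames(m) <- food_classes()
  list(record_id = df$record_id, labels = as_label_matrix(m))
}

#' Write a run manifest
#'
#' Small JSON sidecar recording the inputs, seed and package version of a
#' pipeline step.
#'
#' @param path Output path.
#' @param seed Integer seed used.
#' @param inputs Named list/character of input descriptions.
#' @param extra Optional named list of additional fields.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, seed, inputs = list(), extra = list()) {
  out <- c(list(seed = seed,
                package_version = as.character(
                  utils::packageVersion("foodenv")),
                inputs = inputs), extra)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
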