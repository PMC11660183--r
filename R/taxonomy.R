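#' @title Source-taxonomy to food-class mapping
#' @description Convert the tags and flags carried by an administrative
#'   storefront directory into the ten non-exclusive food retail classes.
#'   The mapping is a small, order-independent rule language: each rule
#'   matches a record on its meta-category, tags, and flags, and emits one
#'   or more classes; the final label set is the union of the emissions of
#'   all matching rules.
#' @name taxonomy
NULL

norm_token <- function(x) tolower(trimws(x))

# A single rule. All tag/flag matching is case-insensitive after trimming.
# Matching semantics:
#   - required_meta: if non-empty, the record's meta-category must be in it
#   - any_of_tags:   if non-empty, the record must carry at least one
#   - required_flags: every listed flag must be present on the record
#   - disqualify_if_only: if non-empty, the rule FAILS when the record's
#     full tag set is a subset of it (e.g. a record tagged only
#     'convenience store' never earns Grocery from a grocery rule)
new_taxonomy_rule <- function(rule_id, emit, required_meta = character(),
                              any_of_tags = character(),
                              disqualify_if_only = character(),
                              required_flags = character()) {
  if (!is.character(rule_id) || length(rule_id) != 1L || !nzchar(rule_id))
    stop("rule_id must be a non-empty string", call. = FALSE)
  emit <- as.character(emit)
  if (!length(emit))
    stop("rule '", rule_id, "': emit must be non-empty", call. = FALSE)
  bad <- setdiff(emit, food_classes())
  if (length(bad))
    stop("rule '", rule_id, "': unknown food class name(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  structure(list(
    rule_id = rule_id,
    required_meta = norm_token(as.character(required_meta)),
    any_of_tags = norm_token(as.character(any_of_tags)),
    disqualify_if_only = norm_token(as.character(disqualify_if_only)),
    required_flags = norm_token(as.character(required_flags)),
    emit = emit
  ), class = "taxonomy_rule")
}

new_taxonomy_map <- function(rules, meta_allowlist) {
  ids <- vapply(rules, `[[`, "", "rule_id")
  if (anyDuplicated(ids))
    stop("duplicate rule_id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  structure(list(rules = rules,
                 meta_allowlist = norm_token(as.character(meta_allowlist))),
            class = "taxonomy_map")
}

#' @export
print.taxonomy_map <- function(x, ...) {
  cat("<taxonomy_map> ", length(x$rules), " rules; meta allowlist: ",
      paste(x$meta_allowlist, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Load a taxonomy mapping from a YAML config file
#'
#' The config has a `meta_allowlist` (records whose meta-category falls
#' outside it receive no labels) and a list of `rules`, each with fields
#' `rule_id`, `emit`, and any of `required_meta`, `any_of_tags`,
#' `disqualify_if_only`, `required_flags`. The shipped default config is at
#' `system.file("extdata", "taxonomy_default.yaml", package = "foodenv")`;
#' it encodes the documented supermarket/convenience and dine-in/quick-bites
#' conventions plus extensible tag lists for the remaining classes.
#'
#' @param config_path Path to the YAML file.
#' @return A `taxonomy_map` object.
#' @export
#' @examples
#' tax <- load_taxonomy(default_taxonomy_path())
#' tax
load_taxonomy <- function(config_path) {
  if (!file.exists(config_path))
    stop("taxonomy config not found: ", config_path, call. = FALSE)
  raw <- yaml::read_yaml(config_path)
  if (!is.list(raw) || is.null(raw$rules))
    stop("taxonomy config must contain a 'rules' list", call. = FALSE)
  rules <- lapply(raw$rules, function(r) {
    if (is.null(r$rule_id))
      stop("taxonomy rule missing rule_id", call. = FALSE)
    tryCatch(
      new_taxonomy_rule(
        rule_id = r$rule_id, emit = r$emit,
        required_meta = r$required_meta %||% character(),
        any_of_tags = r$any_of_tags %||% character(),
        disqualify_if_only = r$disqualify_if_only %||% character(),
        required_flags = r$required_flags %||% character()),
      error = function(e) stop("in rule '", r$rule_id, "': ",
                               conditionMessage(e), call. = FALSE))
  })
  new_taxonomy_map(rules, raw$meta_allowlist %||%
                     c("Food", "Essentials", "Drink"))
}

#' Path to the shipped default taxonomy config
#' @return Path string.
#' @export
default_taxonomy_path <- function() {
  system.file("extdata", "taxonomy_default.yaml", package = "foodenv",
              mustWork = TRUE)
}

#' Save a taxonomy mapping back to YAML
#'
#' `load_taxonomy(save_taxonomy(tax, p))` reproduces `tax` exactly.
#'
#' @param tax A `taxonomy_map`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_taxonomy <- function(tax, path) {
  stopifnot(inherits(tax, "taxonomy_map"))
  out <- list(
    meta_allowlist = as.list(tax$meta_allowlist),
    rules = lapply(tax$rules, function(r) {
      keep <- r[vapply(r, length, 0L) > 0L]
      lapply(keep, as.list)
    }))
  yaml::write_yaml(out, path)
  invisible(path)
}

rule_matches <- function(rule, meta, tags, flags) {
  if (length(rule$required_meta) && !(meta %in% rule$required_meta))
    return(FALSE)
  if (length(rule$any_of_tags) && !any(tags %in% rule$any_of_tags))
    return(FALSE)
  if (length(rule$required_flags) && !all(rule$required_flags %in% flags))
    return(FALSE)
  # fails when the record's whole tag set (including the empty set) lies
  # inside the disqualifying set
  if (length(rule$disqualify_if_only) &&
      all(tags %in% rule$disqualify_if_only))
    return(FALSE)
  TRUE
}

#' Map storefront records to food-class label sets
#'
#' Applies every rule of a taxonomy map to each record and unions the
#' emitted classes. Records whose meta-category is outside the map's
#' allowlist get the empty label set. Unknown tags are ignored by
#' construction; the result does not depend on rule order.
#'
#' @param records A storefront data.frame with columns `meta_category`
#'   (character), `tags` and `flags` (list columns of character vectors);
#'   see [read_store_csv()].
#' @param tax A `taxonomy_map` from [load_taxonomy()].
#' @return Logical label matrix with one row per record.
#' @export
#' @examples
#' tax <- load_taxonomy(default_taxonomy_path())
#' rec <- data.frame(meta_category = "Food")
#' rec$tags <- list("supermarket"); rec$flags <- list(character())
#' labels_to_list(map_records(rec, tax))
map_records <- function(records, tax) {
  stopifnot(inherits(tax, "taxonomy_map"))
  n <- nrow(records)
  out <- empty_labels(n)
  meta <- norm_token(records$meta_category)
  for (i in seq_len(n)) {
    if (!(meta[i] %in% tax$meta_allowlist)) next
    tags <- norm_token(records$tags[[i]])
    flags <- norm_token(records$flags[[i]])
    for (rule in tax$rules) {
      if (rule_matches(rule, meta[i], tags, flags))
        out[i, rule$emit] <- TRUE
    }
  }
  out
}

#' Map a single record
#'
#' Convenience wrapper around [map_records()] for one storefront.
#'
#' @param tags,flags Character vectors (may be empty).
#' @param meta_category Meta-category string (default `"Food"`).
#' @param tax A `taxonomy_map`.
#' @return Character vector of assigned class identifiers.
#' @export
map_record <- function(tags, flags = character(), meta_category = "Food",
                       tax) {
  rec <- data.frame(meta_category = meta_category)
  rec$tags <- list(as.character(tags))
  rec$flags <- list(as.character(flags))
  labels_to_list(map_records(rec, tax))[[1L]]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
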