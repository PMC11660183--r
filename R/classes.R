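#' The ten food retail classes
#'
#' The package categorizes food retail locations into ten non-exclusive
#' classes developed from a public health perspective. The classes are
#' *not* mutually exclusive: a corner store with a deli counter (a bodega)
#' is simultaneously `Convenience` and `FastFood`. The order returned here
#' is fixed and defines the column order of every label matrix and score
#' matrix in the package.
#'
#' @return Character vector of the ten class identifiers, in canonical
#'   order.
#' @seealso [food_class_table()] for display names and descriptions.
#' @export
#' @examples
#' food_classes()
food_classes <- function() {
  c("SpecialtyFoods", "Convenience", "FastFood", "Discount", "Grocery",
    "Restaurant", "AlcoholStore", "AlcoholBar", "JuiceCoffee",
    "SweetsDesserts")
}

#' Display names and descriptions for the food retail classes
#'
#' @return A data.frame with columns `id`, `display`, `description`, one
#'   row per class in canonical order.
#' @export
food_class_table <- function() {
  data.frame(
    id = food_classes(),
    display = c("Specialty Foods Store", "Convenience Store", "Fast Food",
                "Discount Store", "Grocery Store", "Restaurant",
                "Alcohol Store", "Alcohol Bar", "Coffee/Juice Shop",
                "Sweets and Desserts"),
    description = c(
      "Goods stores predominantly selling a specific type of food (cheese, meat, fish, fruit), health food, or international market goods",
      "Smaller goods stores with beverage coolers, lotto/candy, and common pantry items",
      "Service of preparing standardized food items served or consumed quickly (chain fast food, deli counters)",
      "Stores selling items at a discount (e.g., 99 cents), generally without fresh food",
      "Goods stores offering a full range of groceries, from corner groceries to supermarkets",
      "Service of preparing food consumed on-premises, usually with table service",
      "Goods stores where alcohol is the primary offering",
      "Locations with bars dedicated to serving alcohol on premises",
      "Stores serving coffee, tea, smoothies, or juice",
      "Sweets and dessert stores, and bakeries that also sell desserts"),
    stringsAsFactors = FALSE
  )
}

#' Create an empty label matrix
#'
#' A label set is represented as a logical matrix with one row per record
#' and one column per food class (in [food_classes()] order). The empty
#' label set (no class assigned) is a legitimate outcome: a storefront may
#' be outside the food environment entirely.
#'
#' @param n Number of rows (records).
#' @return An `n` x 10 logical matrix of `FALSE`, with class identifiers as
#'   column names.
#' @export
empty_labels <- function(n) {
  matrix(FALSE, nrow = n, ncol = 10L,
         dimnames = list(NULL, food_classes()))
}

#' Coerce to a label matrix
#'
#' Accepts a logical matrix with the ten class columns (in any order), a
#' logical vector of length 10, or a list of character vectors of class
#' identifiers; returns a validated logical matrix in canonical column
#' order.
#'
#' @param x Object to coerce.
#' @return Logical label matrix.
#' @export
as_label_matrix <- function(x) {
  cls <- food_classes()
  if (is.matrix(x)) {
    if (ncol(x) != 10L || !all(cls %in% colnames(x)))
      stop("label matrix must have the 10 food class columns", call. = FALSE)
    m <- x[, cls, drop = FALSE]
    storage.mode(m) <- "logical"
    return(m)
  }
  if (is.logical(x) && length(x) == 10L) {
    m <- matrix(x, nrow = 1L, dimnames = list(NULL, cls))
    return(m)
  }
  if (is.list(x)) {
    bad <- setdiff(unlist(x), cls)
    if (length(bad))
      stop("unknown food class name(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    m <- empty_labels(length(x))
    for (i in seq_along(x)) m[i, x[[i]]] <- TRUE
    return(m)
  }
  stop("cannot coerce to a label matrix", call. = FALSE)
}

#' Label matrix to list of class-name vectors
#'
#' @param labels Logical label matrix.
#' @return List of character vectors, one per row; empty vector for rows
#'   with no label.
#' @export
labels_to_list <- function(labels) {
  labels <- as_label_matrix(labels)
  cls <- food_classes()
  lapply(seq_len(nrow(labels)), function(i) cls[labels[i, ]])
}

# Canonical string key for a whole label combination (multi-label), used
# by modal deduplication and tallies.
label_key <- function(labels) {
  labels <- as_label_matrix(labels)
  apply(labels, 1L, function(r) paste(as.integer(r), collapse = ""))
}
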