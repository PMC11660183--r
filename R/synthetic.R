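#' @title Synthetic storefront directory generator
#' @description Generates synthetic analogues of the three administrative
#'   data sources the pipeline consumes: a labeled storefront directory
#'   with surveyor tags and flags, a longitudinal inspection extract with
#'   inspection dates and closures, and a restaurant file with service
#'   description and venue tags. Store names are composed from
#'   class-conditional token grammars so that the name signals the class
#'   (the premise of name-based classification); `noise_rate` controls the
#'   fraction of ambiguous names. Tags and flags are emitted consistently
#'   with the ground-truth labels so the taxonomy mapping recovers them
#'   exactly when `tag_corruption` is 0. All generators are deterministic
#'   given the config seed.
#' @name synthetic
NULL

default_name_vocabulary <- function() {
  list(
    SpecialtyFoods = c("cheese shop", "butcher shop", "fish market",
                       "health foods", "international foods"),
    Convenience = c("convenience", "mini mart", "corner store", "bodega"),
    FastFood = c("deli", "pizzeria", "burger joint", "taqueria",
                 "fried chicken", "sandwich shop"),
    Discount = c("99 cents", "dollar store", "discount depot"),
    Grocery = c("grocery", "supermarket", "farm fresh grocery"),
    Restaurant = c("restaurant", "trattoria", "bistro", "steakhouse",
                   "diner"),
    AlcoholStore = c("liquors", "wine & spirits", "bottle shop"),
    # phrases chosen not to be substrings of any other class's tokens
    AlcoholBar = c("cocktail bar", "tavern", "pub", "taproom"),
    JuiceCoffee = c("coffee", "cafe", "juice bar", "smoothie"),
    SweetsDesserts = c("bakery", "desserts", "ice cream", "donut shop"))
}

# tag vocabulary aligned with the shipped default taxonomy config; the
# FastFood/Restaurant entry is the restaurant-subcategory list whose class
# is decided by the dine-in / quick-bites flags
default_tag_vocabulary <- function() {
  list(
    SpecialtyFoods = c("cheese shop", "butcher", "fish market",
                       "health food store", "international market"),
    Convenience = c("convenience store", "bodega", "mini market"),
    Discount = c("99 cents store", "dollar store", "discount store"),
    Grocery = c("supermarket", "grocery store"),
    AlcoholStore = c("liquor store", "wine store", "wine & spirits"),
    AlcoholBar = c("bar", "pub", "tavern"),
    JuiceCoffee = c("coffee shop", "cafe", "juice bar", "bubble tea"),
    SweetsDesserts = c("bakery", "dessert shop", "ice cream shop"),
    restaurant_subcategory = c("kosher delicatessen", "bagel shop",
                               "pizzeria", "taqueria", "french cafe",
                               "diner", "deli", "sandwich shop",
                               "burger joint", "gyro shop",
                               "fried chicken restaurant"))
}

proper_nouns <- function() {
  c("la vina", "tony's", "golden", "lucky", "broadway", "sunset", "royal",
    "empire", "atlantic", "bella", "green point", "star", "metro",
    "liberty", "hudson", "crown", "village", "john's", "paradise",
    "marina", "king's", "delancey", "flatbush", "astoria", "bowery",
    "riverside", "union", "majestic", "corona", "bayside")
}

name_suffixes <- function() {
  c("", "", "", "express", "plus", "deluxe", "& co", "of new york")
}

#' Configuration for the synthetic generators
#'
#' Defaults describe a mid-sized urban directory: 2,000 independent
#' storefronts plus 5 chains of 11-20 locations, class prevalences
#' dominated by restaurants and convenience stores, a planted
#' convenience/fast-food (bodega) co-occurrence, a 10% ambiguous-name
#' rate, a 3-year inspection window and a 5% annual closure rate.
#'
#' @param n_stores Number of independent (non-chain) storefronts.
#' @param class_prevalence Named numeric vector of marginal class
#'   probabilities (names = [food_classes()]).
#' @param cooccurrence_pairs List of `list(classes = c(a, b), joint = p)`:
#'   with probability `p` both classes are set jointly; marginals are
#'   preserved by residual adjustment (`joint` must not exceed either
#'   marginal; a class may appear in at most one pair).
#' @param n_chains Number of chain names.
#' @param chain_size_range Integer range of locations per chain; minimum
#'   must be at least 11 so chains qualify for memorization.
#' @param noise_rate Probability a name carries no class-indicative token.
#' @param tag_corruption Probability a record's tags and flags are dropped
#'   (taxonomy mapping then misses its labels).
#' @param vocabulary Per-class name token lists.
#' @param bbox Numeric vector `c(lon_min, lat_min, lon_max, lat_max)`.
#' @param year_range Inclusive integer year interval for the longitudinal
#'   extract.
#' @param closure_rate Per-year probability an operating store closes.
#' @param planted_churn List of `list(lon =, lat =, classes =, delta =)`
#'   entries: at the anchor point, per-year operating counts of stores in
#'   `classes` change by exactly `delta` per year across `year_range`
#'   (exact when `closure_rate` is 0).
#' @param fraction_other Fraction of restaurant-file venue tags replaced
#'   by `'Other'` (true venue retained in `venue_true`).
#' @param service_vague_rate Fraction of restaurant-file service tags
#'   replaced by a vague tag (`'Other'`, `'Not Applicable'`,
#'   `'Delivery only'`).
#' @param seed Integer RNG seed.
#' @return A validated `synth_config` list.
#' @export
synth_config <- function(n_stores = 2000L,
                         class_prevalence = c(
                           SpecialtyFoods = 0.06, Convenience = 0.15,
                           FastFood = 0.18, Discount = 0.05,
                           Grocery = 0.10, Restaurant = 0.22,
                           AlcoholStore = 0.05, AlcoholBar = 0.08,
                           JuiceCoffee = 0.08, SweetsDesserts = 0.08),
                         cooccurrence_pairs = list(
                           list(classes = c("Convenience", "FastFood"),
                                joint = 0.05)),
                         n_chains = 5L,
                         chain_size_range = c(11L, 20L),
                         noise_rate = 0.10,
                         tag_corruption = 0,
                         vocabulary = default_name_vocabulary(),
                         bbox = c(-74.05, 40.55, -73.70, 40.95),
                         year_range = c(2019L, 2021L),
                         closure_rate = 0.05,
                         planted_churn = list(),
                         fraction_other = 0.10,
                         service_vague_rate = 0.10,
                         seed = 1L) {
  cfg <- list(n_stores = as.integer(n_stores),
              class_prevalence = class_prevalence,
              cooccurrence_pairs = cooccurrence_pairs,
              n_chains = as.integer(n_chains),
              chain_size_range = as.integer(chain_size_range),
              noise_rate = noise_rate, tag_corruption = tag_corruption,
              vocabulary = vocabulary, bbox = as.numeric(bbox),
              year_range = as.integer(year_range),
              closure_rate = closure_rate, planted_churn = planted_churn,
              fraction_other = fraction_other,
              service_vague_rate = service_vague_rate,
              seed = as.integer(seed))
  validate_synth_config(cfg)
  structure(cfg, class = "synth_config")
}

validate_synth_config <- function(cfg) {
  cls <- food_classes()
  pv <- cfg$class_prevalence
  if (!all(cls %in% names(pv)))
    stop("class_prevalence must name all 10 food classes", call. = FALSE)
  probs <- c(pv, cfg$noise_rate, cfg$tag_corruption, cfg$closure_rate,
             cfg$fraction_other, cfg$service_vague_rate)
  if (any(probs < 0 | probs > 1))
    stop("all probabilities must lie in [0, 1]", call. = FALSE)
  if (cfg$n_stores < 1L) stop("n_stores must be positive", call. = FALSE)
  if (cfg$n_chains > 0L && cfg$chain_size_range[1L] < 11L)
    stop("chain_size_range minimum must be at least 11 (chains must ",
         "exceed the 10-location memorization threshold)", call. = FALSE)
  for (cl in cls[pv[cls] > 0])
    if (!length(cfg$vocabulary[[cl]]))
      stop("vocabulary empty for class with positive prevalence: ", cl,
           call. = FALSE)
  seen <- character()
  for (pair in cfg$cooccurrence_pairs) {
    ab <- pair$classes
    if (length(ab) != 2L || !all(ab %in% cls))
      stop("cooccurrence pair must name two food classes", call. = FALSE)
    if (any(ab %in% seen))
      stop("a class may appear in at most one cooccurrence pair",
           call. = FALSE)
    seen <- c(seen, ab)
    if (pair$joint > min(pv[ab]))
      stop("joint probability exceeds a marginal prevalence for pair ",
           paste(ab, collapse = "+"), call. = FALSE)
  }
  if (cfg$bbox[1L] >= cfg$bbox[3L] || cfg$bbox[2L] >= cfg$bbox[4L])
    stop("bbox must be c(lon_min, lat_min, lon_max, lat_max) with ",
         "positive extent", call. = FALSE)
  if (cfg$year_range[1L] > cfg$year_range[2L])
    stop("year_range must be increasing", call. = FALSE)
  for (p in cfg$planted_churn) {
    if (is.null(p$lon) || is.null(p$lat) || !length(p$classes) ||
        is.null(p$delta) || p$delta == 0)
      stop("planted_churn entries need lon, lat, non-empty classes, and ",
           "a non-zero delta", call. = FALSE)
    if (!all(p$classes %in% cls))
      stop("planted_churn classes must be food classes", call. = FALSE)
  }
  invisible(cfg)
}

# draw a label matrix honoring marginal prevalences and cooccurrence pairs
sample_labels <- function(n, prevalence, pairs) {
  cls <- food_classes()
  resid <- prevalence[cls]
  joint_draw <- matrix(FALSE, n, length(pairs))
  for (j in seq_along(pairs)) {
    pj <- pairs[[j]]$joint
    ab <- pairs[[j]]$classes
    joint_draw[, j] <- stats::runif(n) < pj
    # residual probability keeps the marginal at its nominal value
    resid[ab] <- (prevalence[ab] - pj) / (1 - pj)
  }
  labels <- empty_labels(n)
  for (cl in cls) labels[, cl] <- stats::runif(n) < resid[cl]
  for (j in seq_along(pairs))
    labels[joint_draw[, j], pairs[[j]]$classes] <- TRUE
  labels
}

compose_name <- function(held, vocab, noisy) {
  pn <- sample(proper_nouns(), 1L)
  if (noisy || !length(held)) {
    extra <- sample(c("place", "house", "shop", "spot", "corner"), 1L)
    return(paste(pn, sample(proper_nouns(), 1L), extra))
  }
  tokens <- vapply(held, function(cl) sample(vocab[[cl]], 1L), "")
  sfx <- sample(name_suffixes(), 1L)
  trimws(paste(pn, paste(tokens, collapse = " "), sfx))
}

# tags + flags consistent with a ground-truth label set, using the
# default taxonomy vocabulary
emit_tags <- function(held, tagvoc) {
  tags <- character(); flags <- character()
  ff <- "FastFood" %in% held; rs <- "Restaurant" %in% held
  if (ff || rs) {
    tags <- c(tags, sample(tagvoc$restaurant_subcategory, 1L))
    if (ff) flags <- c(flags, "quick-bites")
    if (rs) flags <- c(flags, "dine-in")
  }
  for (cl in setdiff(held, c("FastFood", "Restaurant")))
    tags <- c(tags, sample(tagvoc[[cl]], 1L))
  list(tags = tags, flags = flags)
}

build_records <- function(n, labels, cfg, id_prefix = "S") {
  vocab <- cfg$vocabulary
  tagvoc <- default_tag_vocabulary()
  held_list <- labels_to_list(labels)
  noisy <- stats::runif(n) < cfg$noise_rate
  corrupt <- stats::runif(n) < cfg$tag_corruption
  names_out <- character(n)
  tags <- vector("list", n); flags <- vector("list", n)
  for (i in seq_len(n)) {
    names_out[i] <- compose_name(held_list[[i]], vocab, noisy[i])
    tf <- if (corrupt[i]) list(tags = character(), flags = character())
          else emit_tags(held_list[[i]], tagvoc)
    tags[[i]] <- tf$tags; flags[[i]] <- tf$flags
  }
  y1 <- cfg$year_range[2L]
  rec <- data.frame(
    record_id = sprintf("%s%06d", id_prefix, seq_len(n)),
    name = names_out,
    meta_category = "Food",
    survey_date = as.Date(sprintf("%d-01-01", y1)) +
      sample.int(364L, n, replace = TRUE) - 1L,
    longitude = stats::runif(n, cfg$bbox[1L], cfg$bbox[3L]),
    latitude = stats::runif(n, cfg$bbox[2L], cfg$bbox[4L]),
    out_of_business_date = as.Date(NA),
    service_description = NA_character_,
    venue_tag = NA_character_,
    stringsAsFactors = FALSE)
  rec$tags <- tags
  rec$flags <- flags
  rec$inspection_dates <- rep(list(as.Date(character())), n)
  rec
}

#' Generate a labeled storefront directory
#'
#' Independent storefronts plus replicated chains. Each record carries a
#' name composed from class-conditional tokens (ambiguous with probability
#' `noise_rate`), a meta-category, and tags/flags from which
#' [map_records()] recovers the ground-truth labels exactly when
#' `tag_corruption` is 0.
#'
#' @param cfg A [synth_config()].
#' @return List with `records` (storefront data.frame), `labels`
#'   (ground-truth label matrix), and `chain_names` (character vector of
#'   the chain names generated).
#' @export
generate_directory <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  withr::with_seed(cfg$seed, {
    labels <- sample_labels(cfg$n_stores, cfg$class_prevalence,
                            cfg$cooccurrence_pairs)
    rec <- build_records(cfg$n_stores, labels, cfg)
    chain_names <- character(0)
    if (cfg$n_chains > 0L) {
      ch_labels <- sample_labels(cfg$n_chains, cfg$class_prevalence,
                                 cfg$cooccurrence_pairs)
      # a chain must be nameable: force at least one class
      for (i in seq_len(cfg$n_chains))
        if (!any(ch_labels[i, ]))
          ch_labels[i, sample(which(cfg$class_prevalence > 0), 1L)] <- TRUE
      sizes <- sample(seq(cfg$chain_size_range[1L],
                          cfg$chain_size_range[2L]), cfg$n_chains,
                      replace = TRUE)
      base <- build_records(cfg$n_chains, ch_labels, cfg, id_prefix = "C")
      # distinct chain names (regenerate on collision)
      while (anyDuplicated(base$name))
        base$name[duplicated(base$name)] <-
          vapply(labels_to_list(ch_labels)[duplicated(base$name)],
                 compose_name, "", vocab = cfg$vocabulary, noisy = FALSE)
      chain_names <- base$name
      idx <- rep(seq_len(cfg$n_chains), sizes)
      rep_rec <- base[idx, , drop = FALSE]
      n_rep <- nrow(rep_rec)
      rep_rec$record_id <- sprintf("C%06d", seq_len(n_rep))
      rep_rec$longitude <- stats::runif(n_rep, cfg$bbox[1L], cfg$bbox[3L])
      rep_rec$latitude <- stats::runif(n_rep, cfg$bbox[2L], cfg$bbox[4L])
      rownames(rep_rec) <- NULL
      rec <- rbind(rec, rep_rec)
      labels <- rbind(labels, ch_labels[idx, , drop = FALSE])
    }
    list(records = rec, labels = labels, chain_names = chain_names)
  })
}

year_date <- function(year, month, day) {
  as.Date(sprintf("%d-%02d-%02d", year, month, day))
}

# inspection dates for a store operating first_year..last_year; dates kept
# in Jan-Jun so an out-of-business date later that year stays after them
inspection_schedule <- function(first_year, last_year) {
  dates <- lapply(first_year:last_year, function(y)
    year_date(y, sample(1:6, 1L), sample(1:28, 1L)))
  sort(do.call(c, dates))
}

#' Generate a longitudinal inspection extract
#'
#' Every store receives at least one inspection date per operating year;
#' closures are sampled at `closure_rate` per year and recorded as an
#' out-of-business date. Planted churn anchors receive dedicated stores
#' whose openings/closings realize the requested per-year count deltas
#' exactly; planted stores are carved out of the `n_stores` budget.
#'
#' @param cfg A [synth_config()]; `year_range` must span at least 3
#'   years.
#' @return List with `records` and `labels` as in
#'   [generate_directory()].
#' @export
generate_longitudinal <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  y0 <- cfg$year_range[1L]; y1 <- cfg$year_range[2L]
  if (y1 - y0 + 1L < 3L)
    stop("year_range must span at least 3 years", call. = FALSE)
  span <- y1 - y0
  planted_n <- vapply(cfg$planted_churn, function(p)
    as.integer(abs(p$delta)) * (span + 1L), 0L)
  if (sum(planted_n) > cfg$n_stores)
    stop("planted churn requires ", sum(planted_n), " stores but only ",
         cfg$n_stores, " are available", call. = FALSE)
  withr::with_seed(cfg$seed + 1L, {
    n_bg <- cfg$n_stores - sum(planted_n)
    labels <- sample_labels(n_bg, cfg$class_prevalence,
                            cfg$cooccurrence_pairs)
    rec <- build_records(n_bg, labels, cfg, id_prefix = "L")
    # background dynamics: per-year closure hazard
    for (i in seq_len(n_bg)) {
      last <- y1
      if (cfg$closure_rate > 0) {
        for (y in y0:(y1 - 1L)) {
          if (stats::runif(1) < cfg$closure_rate) { last <- y; break }
        }
      }
      rec$inspection_dates[[i]] <- inspection_schedule(y0, last)
      if (last < y1)
        rec$out_of_business_date[i] <-
          year_date(last, sample(7:12, 1L), sample(1:28, 1L))
    }
    # planted churn: exact year-over-year deltas at each anchor
    plant_no <- 0L
    for (p in cfg$planted_churn) {
      plant_no <- plant_no + 1L
      d <- p$delta; k <- abs(d)
      n_p <- k * (span + 1L)
      lab_p <- empty_labels(n_p); lab_p[, p$classes] <- TRUE
      rp <- build_records(n_p, lab_p, cfg, id_prefix = "P")
      rp$record_id <- sprintf("P%02d_%06d", plant_no, seq_len(n_p))
      # all stores of one plant share the exact anchor point so they can
      # never straddle a cell boundary
      rp$longitude <- rep(p$lon, n_p)
      rp$latitude <- rep(p$lat, n_p)
      for (i in seq_len(n_p)) {
        g <- (i - 1L) %/% k  # 0 = always-on buffer, t>=1 = transition t
        if (d < 0) {
          last <- if (g == 0L) y1 else y0 + g - 1L
          rp$inspection_dates[[i]] <- inspection_schedule(y0, last)
          if (last < y1)
            rp$out_of_business_date[i] <- year_date(last, 12L, 15L)
        } else {
          first <- if (g == 0L) y0 else y0 + g
          rp$inspection_dates[[i]] <- inspection_schedule(first, y1)
        }
      }
      rec <- rbind(rec, rp)
      labels <- rbind(labels, lab_p)
    }
    rownames(rec) <- NULL
    list(records = rec, labels = labels, chain_names = character(0))
  })
}

restaurant_service_tags <- function() {
  list(fast = c("Fast Food", "Takeout (To Go/Grab-And-Go only)",
                "Quick Service"),
       sit = c("Fine Dining", "Family Style", "Casual Dining",
               "Table Service"),
       neither = c("Counter Service", "Caterer"),
       vague = c("Other", "Not Applicable", "Delivery only"))
}

true_venue_for <- function(held) {
  rest <- any(c("Restaurant", "FastFood") %in% held)
  bar <- "AlcoholBar" %in% held
  if (rest && bar) return("Restaurant (with Bar)")
  if (rest) return("Restaurant (no bar)")
  if (bar) return("Bar/Tavern/Lounge")
  if ("JuiceCoffee" %in% held) return("Coffee House")
  if ("SweetsDesserts" %in% held) return("Bakery/Dessert")
  "Other"
}

#' Generate a restaurant inspection dataset with service/venue tags
#'
#' Ground-truth labels concentrate on the service classes (Restaurant,
#' FastFood, AlcoholBar, JuiceCoffee, SweetsDesserts). Each record carries
#' one service description (vague with probability `service_vague_rate`)
#' and one venue tag; a `fraction_other` share of venue tags is replaced
#' with `'Other'`, the withheld true venue retained in `venue_true` for
#' recovery testing.
#'
#' @param cfg A [synth_config()].
#' @return List with `records` (including `service_description`,
#'   `venue_tag`, `venue_true` columns) and `labels`.
#' @export
generate_restaurant_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  withr::with_seed(cfg$seed + 2L, {
    n <- cfg$n_stores
    prev <- c(SpecialtyFoods = 0, Convenience = 0, FastFood = 0.35,
              Discount = 0, Grocery = 0, Restaurant = 0.50,
              AlcoholStore = 0, AlcoholBar = 0.12, JuiceCoffee = 0.10,
              SweetsDesserts = 0.08)
    pairs <- list(list(classes = c("Restaurant", "AlcoholBar"),
                       joint = 0.05))
    labels <- sample_labels(n, prev, pairs)
    unlabeled <- !rowSums(labels)
    labels[unlabeled, "Restaurant"] <- TRUE  # every record is a venue
    rec <- build_records(n, labels, cfg, id_prefix = "R")
    sv <- restaurant_service_tags()
    held_list <- labels_to_list(labels)
    service <- vapply(seq_len(n), function(i) {
      h <- held_list[[i]]
      ff <- "FastFood" %in% h; rs <- "Restaurant" %in% h
      pool <- if (ff && rs) c(sv$fast, sv$sit)
              else if (ff) sv$fast else if (rs) sv$sit else sv$neither
      sample(pool, 1L)
    }, "")
    vague <- stats::runif(n) < cfg$service_vague_rate
    service[vague] <- sample(sv$vague, sum(vague), replace = TRUE)
    venue_true <- vapply(held_list, true_venue_for, "")
    venue <- venue_true
    other <- stats::runif(n) < cfg$fraction_other
    venue[other] <- "Other"
    rec$service_description <- service
    rec$venue_tag <- venue
    rec$venue_true <- venue_true
    list(records = rec, labels = labels, chain_names = character(0))
  })
}
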