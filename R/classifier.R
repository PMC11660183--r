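#' @title Multi-label store-name classifier
#' @description One-vs-rest classification of store names into the ten
#'   food retail classes, producing independent per-class raw scores in
#'   \[0, 1\] that are thresholded (default 0.5) into non-exclusive
#'   labels. The shipped reference backend fits independent regularized
#'   log-linear scorers over word and character n-gram features of the
#'   normalized name, selecting the regularization-path checkpoint with
#'   the best validation macro-F1 (early stopping with patience). A
#'   `transformer` backend identifier is reserved for fine-tuned encoder
#'   models sharing the same train/predict contract on uncased text; such
#'   backends require external weights and GPU resources and are not
#'   shipped.
#' @name classifier
NULL

#' Training configuration
#'
#' The optimizer fields (`learning_rate`, `beta1`, `beta2`) document the
#' Adam settings of the transformer backend contract (learning rate 1e-6,
#' beta1 0.9, beta2 0.999); the reference backend is fit by coordinate
#' descent and maps "epochs" to checkpoints along a decreasing ridge
#' regularization path, keeping the checkpoint with the best validation
#' macro-F1.
#'
#' @param backend `'reference'` (shipped) or `'transformer'` (contract
#'   only).
#' @param learning_rate,beta1,beta2 Adam parameters for the transformer
#'   contract.
#' @param early_stopping_metric Metric monitored on the validation set;
#'   only `'macro_f1'` is implemented.
#' @param patience Checkpoints without improvement before stopping.
#' @param max_epochs Number of regularization-path checkpoints.
#' @param threshold Score threshold for label assignment, in (0, 1).
#' @param regularization_strength Scale of the ridge penalty path.
#' @param ngram_range Character n-gram span `c(min, max)`.
#' @param seed Integer seed recorded in the manifest.
#' @return A validated `training_config` list.
#' @export
training_config <- function(backend = "reference",
                            learning_rate = 1e-6,
                            beta1 = 0.9, beta2 = 0.999,
                            early_stopping_metric = "macro_f1",
                            patience = 5L, max_epochs = 25L,
                            threshold = 0.5,
                            regularization_strength = 1e-3,
                            ngram_range = c(3L, 5L),
                            seed = 1L) {
  if (!backend %in% c("reference", "transformer"))
    stop("backend must be 'reference' or 'transformer'", call. = FALSE)
  if (threshold <= 0 || threshold >= 1)
    stop("threshold must lie in (0, 1)", call. = FALSE)
  if (patience < 1L) stop("patience must be at least 1", call. = FALSE)
  if (early_stopping_metric != "macro_f1")
    stop("only 'macro_f1' early stopping is implemented", call. = FALSE)
  structure(list(backend = backend, learning_rate = learning_rate,
                 beta1 = beta1, beta2 = beta2,
                 early_stopping_metric = early_stopping_metric,
                 patience = as.integer(patience),
                 max_epochs = as.integer(max_epochs),
                 threshold = threshold,
                 regularization_strength = regularization_strength,
                 ngram_range = as.integer(ngram_range),
                 seed = as.integer(seed)),
            class = "training_config")
}

# word tokens plus boundary-padded character n-grams of the normalized name
extract_terms <- function(name, ngram_range) {
  words <- strsplit(name, " ", fixed = TRUE)[[1L]]
  padded <- paste0("^", gsub(" ", "_", name), "$")
  chars <- character(0)
  nc <- nchar(padded)
  for (k in ngram_range[1L]:ngram_range[2L]) {
    if (nc >= k)
      chars <- c(chars, substring(padded, 1:(nc - k + 1L), k:nc))
  }
  unique(c(paste0("w:", words), paste0("c:", chars)))
}

build_feature_space <- function(names, ngram_range) {
  terms <- lapply(names, extract_terms, ngram_range = ngram_range)
  vocab <- sort(unique(unlist(terms)))
  list(vocab = vocab, ngram_range = ngram_range, terms = terms)
}

featurize <- function(names, fe) {
  terms <- lapply(names, extract_terms, ngram_range = fe$ngram_range)
  idx <- lapply(terms, function(t) match(t, fe$vocab))
  idx <- lapply(idx, function(i) i[!is.na(i)])
  lens <- lengths(idx)
  Matrix::sparseMatrix(
    i = rep(seq_along(names), lens), j = unlist(idx), x = 1,
    dims = c(length(names), length(fe$vocab)))
}

# 32-bit FNV-1a over the concatenated names, for the training manifest
fnv1a <- function(strings) {
  h <- 2166136261
  for (b in utf8ToInt(paste(strings, collapse = "\x1f"))) {
    lo <- h %% 256
    h <- h - lo + bitwXor(lo, b %% 256)  # byte-wide xor keeps h < 2^32
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Train the reference store-name classifier
#'
#' Fits one ridge-penalized logistic scorer per class over word and
#' character n-gram features, sweeping a shared decreasing regularization
#' path. After each checkpoint the validation macro-F1 (at the configured
#' threshold) is computed; training keeps the best checkpoint and stops
#' after `patience` non-improving evaluations. A class with no positive
#' training examples degenerates to a constant-0 scorer with a warning.
#'
#' @param train,validation `labeled_set`s with disjoint names.
#' @param cfg A [training_config()].
#' @return A `name_model` with fitted per-class coefficients, the feature
#'   space, and a training manifest (config, data hash, stopped
#'   checkpoint, validation macro-F1).
#' @export
train_classifier <- function(train, validation, cfg = training_config()) {
  stopifnot(inherits(train, "labeled_set"),
            inherits(validation, "labeled_set"))
  if (!length(train$names) || !length(validation$names))
    stop("train and validation sets must be non-empty", call. = FALSE)
  if (length(intersect(train$names, validation$names)))
    stop("train and validation sets share names", call. = FALSE)
  if (cfg$backend != "reference")
    stop("the '", cfg$backend, "' backend is a contract only; train with ",
         "backend = 'reference'", call. = FALSE)
  fe <- build_feature_space(train$names, cfg$ngram_range)
  X <- featurize(train$names, fe)
  Xval <- featurize(validation$names, fe)
  lambda <- cfg$regularization_strength *
    10^seq(2, -4, length.out = cfg$max_epochs)
  cls <- food_classes()
  fits <- vector("list", length(cls)); names(fits) <- cls
  for (cl in cls) {
    y <- train$labels[, cl]
    if (sum(y) == 0L) {
      warning("class '", cl, "' has no positive training examples; ",
              "its scorer degenerates to constant 0", call. = FALSE)
      fits[[cl]] <- list(constant = 0)
    } else if (sum(y) == length(y)) {
      warning("class '", cl, "' has no negative training examples; ",
              "its scorer degenerates to constant 1", call. = FALSE)
      fits[[cl]] <- list(constant = 1)
    } else {
      fits[[cl]] <- glmnet::glmnet(X, factor(y, levels = c(FALSE, TRUE)),
                                   family = "binomial", alpha = 0,
                                   lambda = lambda, standardize = FALSE)
    }
  }
  score_at <- function(fit, M, t) {
    if (!is.null(fit$constant)) return(rep(fit$constant, nrow(M)))
    s <- stats::predict(fit, M, s = lambda[t], type = "response")
    as.numeric(s)
  }
  best_t <- 1L; best_f1 <- -Inf; stale <- 0L
  for (t in seq_along(lambda)) {
    sv <- vapply(cls, function(cl) score_at(fits[[cl]], Xval, t),
                 numeric(nrow(Xval)))
    if (is.null(dim(sv)))
      sv <- matrix(sv, nrow = 1L, dimnames = list(NULL, cls))
    pred <- sv >= cfg$threshold
    colnames(pred) <- cls
    mf1 <- summarize_macro_f1(pred, validation$labels)
    if (mf1 > best_f1 + 1e-12) {
      best_f1 <- mf1; best_t <- t; stale <- 0L
    } else {
      stale <- stale + 1L
      if (stale >= cfg$patience) break
    }
  }
  coefs <- lapply(cls, function(cl) {
    fit <- fits[[cl]]
    if (!is.null(fit$constant)) return(list(constant = fit$constant))
    cf <- stats::coef(fit, s = lambda[best_t])
    list(a0 = cf[1L], beta = Matrix::Matrix(cf[-1L, , drop = FALSE],
                                            sparse = TRUE))
  })
  names(coefs) <- cls
  structure(list(
    backend = "reference", fe = list(vocab = fe$vocab,
                                     ngram_range = fe$ngram_range),
    coefs = coefs, classes = cls, threshold = cfg$threshold,
    manifest = list(config = unclass(cfg),
                    n_train = length(train$names),
                    n_validation = length(validation$names),
                    train_hash = fnv1a(train$names),
                    stopped_checkpoint = best_t,
                    checkpoints_evaluated = min(t, length(lambda)),
                    best_validation_macro_f1 = best_f1)),
    class = "name_model")
}

summarize_macro_f1 <- function(predicted, actual) {
  suppressWarnings(
    summarize_metrics(confusion_counts(predicted, actual))$macro_f1)
}

#' @export
print.name_model <- function(x, ...) {
  cat("<name_model> backend ", x$backend, "; ", length(x$fe$vocab),
      " features; checkpoint ", x$manifest$stopped_checkpoint,
      "; validation macro-F1 ",
      round(x$manifest$best_validation_macro_f1, 3), "\n", sep = "")
  invisible(x)
}

#' Predict per-class raw scores for store names
#'
#' Names are normalized ([normalize_name()]) and scored; output rows
#' follow input order and every score lies in \[0, 1\]. Scores are
#' independent per class and need not sum to 1.
#'
#' @param model A fitted `name_model`.
#' @param names Character vector of raw store names (non-empty).
#' @return Numeric score matrix, one row per name, one column per class.
#' @export
predict_scores <- function(model, names) {
  stopifnot(inherits(model, "name_model"))
  if (!is.character(names) || !length(names))
    stop("names must be a non-empty character vector", call. = FALSE)
  bad <- which(is.na(names) | !nzchar(trimws(names)))
  if (length(bad))
    stop("empty name at position(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  nm <- normalize_name(names)
  X <- featurize(nm, model$fe)
  scores <- vapply(model$classes, function(cl) {
    cf <- model$coefs[[cl]]
    if (!is.null(cf$constant)) return(rep(cf$constant, nrow(X)))
    as.numeric(stats::plogis(cf$a0 + as.numeric(X %*% cf$beta)))
  }, numeric(nrow(X)))
  if (is.null(dim(scores)))
    scores <- matrix(scores, nrow = 1L,
                     dimnames = list(NULL, model$classes))
  rownames(scores) <- NULL
  scores
}

#' Threshold raw scores into a label set
#'
#' Class `c` is assigned iff its score is greater than or equal to the
#' threshold (inclusive boundary).
#'
#' @param scores Numeric score matrix (or vector of 10) in \[0, 1\].
#' @param threshold Threshold in (0, 1); default 0.5.
#' @return Logical label matrix.
#' @export
#' @examples
#' s <- matrix(c(0.688, 0.406, rep(0.1, 8)), nrow = 1,
#'             dimnames = list(NULL, food_classes()))
#' threshold_scores(s)
threshold_scores <- function(scores, threshold = 0.5) {
  if (threshold <= 0 || threshold >= 1)
    stop("threshold must lie in (0, 1)", call. = FALSE)
  if (is.null(dim(scores)))
    scores <- matrix(scores, nrow = 1L,
                     dimnames = list(NULL, food_classes()))
  if (any(!is.finite(scores)) || any(scores < 0) || any(scores > 1))
    stop("scores must lie in [0, 1]", call. = FALSE)
  out <- scores >= threshold
  colnames(out) <- colnames(scores)
  as_label_matrix(out)
}

#' Save / load a fitted model
#'
#' Single-file serialization with the training manifest embedded; a
#' reloaded model predicts bit-identically.
#'
#' @param model A `name_model`.
#' @param path File path.
#' @return `path` invisibly; `load_model` returns the model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "name_model"))
  saveRDS(model, path, version = 3)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "name_model"))
    stop("file does not contain a name_model: ", path, call. = FALSE)
  model
}

#' Write predictions in score + boolean layout
#'
#' One row per name with ten raw-score columns and ten boolean columns.
#'
#' @param names Character vector of input names.
#' @param scores Score matrix from [predict_scores()].
#' @param path Output CSV path.
#' @param threshold Threshold used for the boolean columns.
#' @return `path`, invisibly.
#' @export
write_predictions_csv <- function(names, scores, path, threshold = 0.5) {
  labels <- threshold_scores(scores, threshold)
  df <- data.frame(name = names, stringsAsFactors = FALSE)
  for (cl in food_classes()) df[[paste0("score_", cl)]] <- scores[, cl]
  for (cl in food_classes()) df[[paste0("label_", cl)]] <- labels[, cl]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
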