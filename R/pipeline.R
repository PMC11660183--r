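#' Run the classification pipeline end to end on synthetic data
#'
#' Generates a labeled directory, builds the deduplicated
#' leakage-controlled split, trains the reference classifier, and
#' evaluates on the held-out test set. Deterministic given the two
#' configs.
#'
#' @param cfg A [synth_config()].
#' @param tcfg A [training_config()].
#' @return List with `directory`, `split`, `model`, `scores` (test-set
#'   score matrix), and `metrics` (test-set `metrics_report`).
#' @export
#' @examples
#' \donttest{
#' out <- run_pipeline(synth_config(n_stores = 500, noise_rate = 0))
#' out$metrics$macro_f1
#' }
run_pipeline <- function(cfg = synth_config(),
                         tcfg = training_config(seed = cfg$seed)) {
  d <- generate_directory(cfg)
  ex <- deduplicate_modal(d$records, d$labels)
  split <- split_dataset(ex, location_counts(d$records), seed = cfg$seed)
  model <- train_classifier(split$train, split$validation, tcfg)
  scores <- predict_scores(model, split$test$names)
  metrics <- suppressWarnings(
    evaluate_predictions(threshold_scores(scores, tcfg$threshold),
                         split$test$labels))
  list(directory = d, split = split, model = model, scores = scores,
       metrics = metrics)
}
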