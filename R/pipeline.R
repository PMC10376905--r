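# End-to-end pipeline: simulate -> encode -> balance -> tune -> train ->
# evaluate -> tier. Thin orchestration over the module functions; the CLI
# script in inst/cli/ wraps these.

OPTIMIZERS <- c("de", "pso", "ga", "sa")

optimizer_function <- function(name) {
  switch(match.arg(name, OPTIMIZERS),
         de = de_optimize, pso = pso_optimize, ga = ga_optimize,
         sa = sa_optimize)
}

#' Default control settings for a named optimizer
#'
#' The tuning budgets used throughout: DE population 10 x 10 generations
#' (F 0.5, CR 0.9), PSO swarm 10 x 10 iterations (omega 0.5, c1 = c2 =
#' 2.05), GA population 10 x 10 generations (elitism 0.3, random selection
#' 0.1, mutation 0.5), SA 100 iterations (geometric cooling 0.95).
#'
#' @param name one of `"de"`, `"pso"`, `"ga"`, `"sa"`.
#' @param seed RNG seed threaded into the control object.
#' @return the optimizer's control list.
#' @export
default_optimizer_control <- function(name, seed = 1) {
  switch(match.arg(name, OPTIMIZERS),
         de = de_control(seed = seed),
         pso = pso_control(seed = seed),
         ga = ga_control(seed = seed),
         sa = sa_control(seed = seed))
}

#' Simulate a cohort and write it to TSV
#'
#' @param path output TSV path.
#' @param cfg a [cohort_config()].
#' @return the records, invisibly.
#' @export
simulate_cohort_tsv <- function(path, cfg = cohort_config()) {
  records <- generate_cohort(cfg)
  write_variants_tsv(records, path)
  invisible(records)
}

#' Tune learner hyperparameters with a metaheuristic
#'
#' Runs the chosen optimizer over the repeated-CV accuracy objective on a
#' labeled feature table (normally the oversampled training split). Returns
#' the tuned hyperparameters, the optimizer result with its convergence
#' trace, a one-row summary (method, CV accuracy and kappa, the seven
#' hyperparameters, runtime), and the trace as a data.frame ready for a
#' convergence plot.
#'
#' @param table labeled feature table.
#' @param optimizer one of `"de"`, `"pso"`, `"ga"`, `"sa"`.
#' @param space a [search_space()].
#' @param control optimizer control list (defaults per
#'   [default_optimizer_control()]).
#' @param cv a [cv_config()].
#' @param compute_kappa also estimate Cohen's kappa of the tuned candidate
#'   by one extra cross-validation pass with pooled predictions.
#' @return list with `hyperparameters`, `result`, `summary`, `trace`.
#' @export
tune_hyperparameters <- function(table, optimizer = "de",
                                 space = default_search_space(),
                                 control = NULL, cv = cv_config(),
                                 compute_kappa = TRUE) {
  check_labeled_table(table)
  optimizer <- match.arg(optimizer, OPTIMIZERS)
  if (is.null(control)) {
    control <- default_optimizer_control(optimizer)
  }
  objective <- fitness_function(table, space, cv)
  result <- optimizer_function(optimizer)(objective, space, control)
  hp <- decode_hyperparameters(result$best_position, space)
  kappa <- NA_real_
  if (compute_kappa) {
    kappa <- cv_kappa(result$best_position, space, table, cv)
  }
  summary <- data.frame(
    Method = toupper(optimizer),
    Accuracy = round(100 * result$best_fitness, 2),
    Kappa = if (is.na(kappa)) NA_real_ else round(100 * kappa, 2),
    Nrounds = hp$nrounds,
    `Eta (10^x)` = round(log10(hp$eta), 2),
    Md = hp$max_depth,
    Gamma = round(hp$gamma, 2),
    Cols = round(hp$colsample_bytree, 2),
    Mw = hp$min_child_weight,
    Sub = round(hp$subsample, 2),
    Runtime = sprintf("%.1f s", result$runtime),
    check.names = FALSE, stringsAsFactors = FALSE)
  trace <- data.frame(iteration = seq_along(result$trace) - 1L,
                      best_fitness = result$trace)
  list(hyperparameters = hp, result = result, summary = summary,
       trace = trace)
}

# pooled-prediction Cohen's kappa of a candidate under the CV partitions
cv_kappa <- function(position, space, table, cv) {
  hp <- decode_hyperparameters(position, space)
  ord <- do.call(order, unname(as.list(table)))
  table <- table[ord, , drop = FALSE]
  x <- feature_matrix(table)
  y <- table$isMut
  y_pred <- y_true <- numeric(0)
  for (r in seq_len(cv$repeats)) {
    set.seed(cv$seed + r - 1L)
    folds <- caret::createFolds(factor(y), k = cv$folds)
    for (fold in folds) {
      bst <- fit_booster(x[-fold, , drop = FALSE], y[-fold], hp, cv$seed)
      y_pred <- c(y_pred, as.numeric(predict(bst, x[fold, , drop = FALSE]) > 0.5))
      y_true <- c(y_true, y[fold])
    }
  }
  cohen_kappa(confusion_counts(y_true, y_pred))
}

#' Evaluate a trained model on a labeled test table
#'
#' Scores the test split, thresholds at 0.5, and reports the confusion
#' matrix (rows = predicted) together with every scalar metric and the
#' ROC/AUC.
#'
#' @param model a `variant_model`.
#' @param test labeled feature table.
#' @return list with `confusion`, `metrics`, `roc`, `row` (summary-table
#'   row).
#' @export
evaluate_model <- function(model, test) {
  check_labeled_table(test)
  scores <- predict_scores(model, test)
  cm <- confusion_counts(test$isMut, as.numeric(scores > 0.5))
  roc <- roc_curve(test$isMut, scores)
  metrics <- classification_metrics(cm, auc = roc$auc)
  list(confusion = cm, metrics = metrics, roc = roc,
       row = metrics_row(metrics, method = "model"))
}

#' Metrics from an externally reported confusion matrix
#'
#' Evaluates the full metric set for a confusion matrix given directly as
#' counts (rows = predicted), e.g. to reproduce a published results table.
#'
#' @inheritParams confusion_matrix
#' @return list with `confusion`, `metrics`, `row`.
#' @export
evaluate_confusion <- function(tp, tn, fp, fn) {
  cm <- confusion_matrix(tp, tn, fp, fn)
  metrics <- classification_metrics(cm)
  list(confusion = cm, metrics = metrics,
       row = metrics_row(metrics, method = "reported"))
}

#' Score and tier a batch of variant records
#'
#' Encodes raw records, applies the model, and appends the probability score
#' and its five-tier classification to each record.
#'
#' @param model a `variant_model`.
#' @param records data.frame of variant records (as from
#'   [load_annotation_table()] or [generate_toy_run()]).
#' @param dialect a [codec_dialect()].
#' @return `records` with `score` and `tier` columns appended.
#' @export
predict_variants <- function(model, records, dialect = codec_dialect()) {
  if (nrow(records) == 0L) {
    records$score <- numeric(0)
    records$tier <- character(0)
    return(records)
  }
  features <- build_feature_table(records, dialect)
  features$isMut <- NULL
  scores <- predict_scores(model, features)
  records$score <- scores
  records$tier <- as.character(assign_tier(scores))
  records
}

#' Run the whole tuning pipeline on a cohort
#'
#' Convenience wrapper for scripted use: encode a labeled cohort, split it
#' 70/30 stratified, balance the training split by smoothed-bootstrap
#' oversampling, tune with the chosen metaheuristic, train the final model
#' on the balanced training split, and evaluate on the untouched test split.
#'
#' @param records labeled variant records.
#' @param optimizer one of `"de"`, `"pso"`, `"ga"`, `"sa"`.
#' @param space a [search_space()].
#' @param control optimizer control list (`NULL` for the defaults).
#' @param cv a [cv_config()].
#' @param train_fraction stratified split fraction.
#' @param seed seed for split, oversampling and training.
#' @param dialect a [codec_dialect()].
#' @return list with `tuning`, `model`, `evaluation`, `split`.
#' @export
run_pipeline <- function(records, optimizer = "de",
                         space = default_search_space(), control = NULL,
                         cv = cv_config(), train_fraction = 0.7, seed = 1,
                         dialect = codec_dialect()) {
  features <- build_feature_table(records, dialect)
  split <- stratified_split(features, train_fraction, seed = seed)
  balanced <- oversample_minority(split$train, seed = seed)
  tuning <- tune_hyperparameters(balanced, optimizer, space, control, cv)
  model <- train_final_model(balanced, tuning$hyperparameters, seed = seed)
  evaluation <- evaluate_model(model, split$test)
  list(tuning = tuning, model = model, evaluation = evaluation,
       split = split)
}
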