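# The objective being optimized: decode a search-space position into
# gradient-boosted-tree hyperparameters and score mean accuracy under
# repeated stratified k-fold cross-validation; plus the surrounding model
# plumbing (split, minority oversampling, final fit, prediction, importance).

#' Default hyperparameter search space
#'
#' Seven tunable controls of the gradient-boosted tree learner with their box
#' bounds: boosting rounds \[100, 600\], log10 learning rate, maximum tree
#' depth \[2, 6\], minimum loss reduction gamma \[0, 1\], column subsampling
#' \[0.4, 1\], minimum child weight \[1, 3\], row subsampling \[0.5, 1\].
#' The learning rate is searched on a log10 scale; `eta_bounds` defaults to
#' \[-5, 0\], wide enough to contain the optima such searches typically
#' report (around 10^-1); pass `c(-5, -3)` for a deliberately slow-learning
#' configuration.
#'
#' @param eta_bounds bounds of the log10 learning-rate exponent.
#' @return a [search_space()] over the 7 dimensions.
#' @export
default_search_space <- function(eta_bounds = c(-5, 0)) {
  stopifnot(length(eta_bounds) == 2, eta_bounds[1] < eta_bounds[2])
  search_space(
    name = c("nrounds", "eta_exponent", "max_depth", "gamma",
             "colsample_bytree", "min_child_weight", "subsample"),
    lower = c(100, eta_bounds[1], 2, 0, 0.4, 1, 0.5),
    upper = c(600, eta_bounds[2], 6, 1, 1, 3, 1),
    integer = c(TRUE, FALSE, TRUE, FALSE, FALSE, TRUE, FALSE)
  )
}

#' Decode a search position into learner hyperparameters
#'
#' The search is continuous; at decode time integer-valued controls
#' (`nrounds`, `max_depth`, `min_child_weight`) are rounded to the nearest
#' integer and the learning rate becomes `10^eta_exponent`.
#'
#' @param position numeric vector over `space` (within bounds; projection is
#'   the optimizer's job).
#' @param space a [search_space()], normally [default_search_space()].
#' @return named list of learner hyperparameters.
#' @export
decode_hyperparameters <- function(position, space = default_search_space()) {
  if (length(position) != nrow(space)) {
    stop("position length does not match the search space", call. = FALSE)
  }
  eps <- 1e-9
  if (any(position < space$lower - eps) || any(position > space$upper + eps)) {
    stop("position is outside the search bounds", call. = FALSE)
  }
  val <- ifelse(space$integer, round(position), position)
  names(val) <- space$name
  hp <- as.list(val)
  if ("eta_exponent" %in% names(hp)) {
    hp$eta <- 10^hp$eta_exponent
    hp$eta_exponent <- NULL
  }
  hp
}

#' Stratified train/test split
#'
#' Splits a labeled feature table so that per-class proportions are preserved
#' within one record; partitions are disjoint and exhaustive.
#'
#' @param table data.frame with an `isMut` 0/1 column.
#' @param train_fraction fraction assigned to training, in (0,1).
#' @param seed RNG seed.
#' @return list with `train` and `test` data.frames.
#' @export
stratified_split <- function(table, train_fraction = 0.7, seed = 1) {
  check_labeled_table(table)
  stopifnot(train_fraction > 0, train_fraction < 1)
  set.seed(seed)
  idx_train <- integer()
  for (cls in c(0, 1)) {
    rows <- which(table$isMut == cls)
    n_train <- round(length(rows) * train_fraction)
    idx_train <- c(idx_train, sample(rows, n_train))
  }
  idx_train <- sort(idx_train)
  list(train = table[idx_train, , drop = FALSE],
       test = table[setdiff(seq_len(nrow(table)), idx_train), , drop = FALSE])
}

check_labeled_table <- function(table) {
  if (!is.data.frame(table) || !"isMut" %in% names(table)) {
    stop("expected a feature table with an 'isMut' label column",
         call. = FALSE)
  }
  if (length(unique(table$isMut)) < 2L) {
    stop("both classes must be present", call. = FALSE)
  }
  invisible(table)
}

# Continuous feature columns eligible for kernel smoothing during
# oversampling; all remaining columns are categorical codes and are copied.
SMOOTHABLE_FEATURES <- c("Freq", "MAFbin", "Coverage", "POS")

# empirical measurement quantum of a column: the smallest positive increment
# between observed values (synthetic rows are emitted on the same grid)
value_quantum <- function(x) {
  u <- sort(unique(x))
  if (length(u) < 2L) {
    return(1)
  }
  max(min(diff(u)), 1e-6)
}

#' Oversample the minority class by smoothed bootstrap
#'
#' Grows the minority class to approximately `target_ratio` times the
#' majority count by resampling minority rows with replacement and adding
#' zero-mean Gaussian noise to the continuous features (`Freq`, `MAFbin`
#' where present, `Coverage`, `POS`). The per-feature bandwidth is
#' Silverman's rule-of-thumb on the minority values times `jitter`;
#' `jitter = 0` degenerates to a plain bootstrap. Categorical codes are
#' copied unchanged, sentinel values (-1 codes) are never jittered, and
#' majority rows are untouched.
#'
#' @param train labeled feature table (`isMut` column).
#' @param target_ratio desired minority/majority ratio (default 1: balance).
#' @param jitter bandwidth multiplier for the Gaussian smoothing.
#' @param seed RNG seed.
#' @return the balanced table (majority rows first, then all minority rows).
#' @export
oversample_minority <- function(train, target_ratio = 1, jitter = 1,
                                seed = 1) {
  check_labeled_table(train)
  stopifnot(target_ratio > 0, jitter >= 0)
  set.seed(seed)
  counts <- table(factor(train$isMut, levels = c(0, 1)))
  minority <- as.numeric(names(which.min(counts)))
  n_min <- min(counts)
  n_maj <- max(counts)
  n_target <- round(target_ratio * n_maj)
  n_new <- max(0L, n_target - n_min)
  min_rows <- train[train$isMut == minority, , drop = FALSE]
  maj_rows <- train[train$isMut != minority, , drop = FALSE]
  if (n_new == 0L) {
    out <- rbind(maj_rows, min_rows)
    rownames(out) <- NULL
    return(out)
  }
  synth <- min_rows[sample.int(n_min, n_new, replace = TRUE), , drop = FALSE]
  if (jitter > 0) {
    for (col in intersect(SMOOTHABLE_FEATURES, names(synth))) {
      vals <- min_rows[[col]]
      real <- vals[vals != -1]          # sentinel -1 marks "not applicable"
      if (length(real) < 2L || stats::sd(real) == 0) next
      bw <- jitter * stats::bw.nrd0(real)
      q <- value_quantum(real)
      jit <- which(synth[[col]] != -1)
      synth[[col]][jit] <- synth[[col]][jit] + stats::rnorm(length(jit), 0, bw)
      # snap back to the source column's measurement quantum so synthetic
      # rows stay on the observed value grid
      synth[[col]][jit] <- round(synth[[col]][jit] / q) * q
      if (col %in% c("Freq", "MAFbin")) {
        lo <- if (col == "MAFbin") q else 0
        synth[[col]][jit] <- pmin(pmax(synth[[col]][jit], lo), 1)
      }
      if (col %in% c("Coverage", "POS")) {
        synth[[col]][jit] <- pmax(synth[[col]][jit], 0)
      }
    }
  }
  out <- rbind(maj_rows, min_rows, synth)
  rownames(out) <- NULL
  out
}

feature_matrix <- function(table) {
  feats <- table[, FEATURE_NAMES, drop = FALSE]
  as.matrix(feats)
}

fit_booster <- function(x, y, hp, seed) {
  params <- list(objective = "binary:logistic",
                 eta = hp$eta,
                 max_depth = as.integer(hp$max_depth),
                 gamma = hp$gamma,
                 colsample_bytree = hp$colsample_bytree,
                 min_child_weight = hp$min_child_weight,
                 subsample = hp$subsample,
                 nthread = 1,
                 seed = as.integer(seed))
  dtrain <- xgboost::xgb.DMatrix(x, label = y, nthread = 1)
  xgboost::xgb.train(params = params, data = dtrain,
                     nrounds = as.integer(hp$nrounds), verbose = 0)
}

#' Cross-validation configuration
#'
#' @param folds number of folds (>= 2), default 10.
#' @param repeats number of repetitions, default 3.
#' @param seed RNG seed for fold assignment and the learner.
#' @export
cv_config <- function(folds = 10, repeats = 3, seed = 1) {
  stopifnot(folds >= 2, repeats >= 1)
  list(folds = as.integer(folds), repeats = as.integer(repeats), seed = seed)
}

#' Mean cross-validated accuracy of a hyperparameter position
#'
#' The tuning objective. Decodes `position`, then for each of
#' `folds x repeats` stratified partitions fits the gradient-boosted learner
#' on the training folds and scores accuracy (threshold 0.5) on the held-out
#' fold; returns the mean. The table is sorted canonically before
#' partitioning, so the fitness is invariant to input row order; the result
#' is deterministic given (position, table, seed). The number of learner
#' fits performed is attached as attribute `n_models`.
#'
#' @param position numeric vector over `space`.
#' @param space a [search_space()].
#' @param table labeled feature table (typically the oversampled training
#'   split).
#' @param cv a [cv_config()].
#' @return mean accuracy in \[0,1\].
#' @export
cv_accuracy_fitness <- function(position, space = default_search_space(),
                                table, cv = cv_config()) {
  check_labeled_table(table)
  hp <- decode_hyperparameters(position, space)
  ord <- do.call(order, unname(as.list(table)))
  table <- table[ord, , drop = FALSE]
  x <- feature_matrix(table)
  y <- table$isMut
  accs <- numeric(0)
  n_models <- 0L
  for (r in seq_len(cv$repeats)) {
    set.seed(cv$seed + r - 1L)
    folds <- caret::createFolds(factor(y), k = cv$folds)
    for (fold in folds) {
      bst <- fit_booster(x[-fold, , drop = FALSE], y[-fold], hp, cv$seed)
      pred <- as.numeric(predict(bst, x[fold, , drop = FALSE]) > 0.5)
      accs <- c(accs, mean(pred == y[fold]))
      n_models <- n_models + 1L
    }
  }
  structure(mean(accs), n_models = n_models)
}

#' Build the tuning objective for a fixed table
#'
#' Convenience closure binding [cv_accuracy_fitness()] to a table, space and
#' CV configuration so it can be handed to any of the optimizers.
#'
#' @inheritParams cv_accuracy_fitness
#' @return function(position) -> mean CV accuracy.
#' @export
fitness_function <- function(table, space = default_search_space(),
                             cv = cv_config()) {
  check_labeled_table(table)
  force(space); force(cv)
  function(position) as.numeric(cv_accuracy_fitness(position, space, table, cv))
}

#' Train the final classifier
#'
#' Fits the gradient-boosted tree learner on a labeled feature table with
#' decoded hyperparameters. Single-threaded with a fixed seed, so refits are
#' reproducible.
#'
#' @param train labeled feature table.
#' @param hp hyperparameter list from [decode_hyperparameters()].
#' @param seed learner seed.
#' @return a `variant_model` handle (booster + metadata).
#' @export
train_final_model <- function(train, hp, seed = 1) {
  check_labeled_table(train)
  bst <- fit_booster(feature_matrix(train), train$isMut, hp, seed)
  structure(list(booster = bst, hyperparameters = hp,
                 feature_names = FEATURE_NAMES, seed = seed,
                 codec_version = "1"),
            class = "variant_model")
}

#' Predict pathogenicity probabilities
#'
#' @param model a `variant_model`.
#' @param features data.frame containing the 14 feature columns.
#' @return numeric vector of probabilities in \[0,1\], higher = more
#'   pathogenic.
#' @export
predict_scores <- function(model, features) {
  stopifnot(inherits(model, "variant_model"))
  missing_cols <- setdiff(model$feature_names, names(features))
  extra <- setdiff(names(features), c(model$feature_names, "isMut"))
  if (length(missing_cols) > 0L) {
    stop(sprintf("feature table is missing column(s): %s%s",
                 paste(missing_cols, collapse = ", "),
                 if (length(extra) > 0L)
                   paste0(" (unexpected: ", paste(extra, collapse = ", "), ")")
                 else ""),
         call. = FALSE)
  }
  if (nrow(features) == 0L) {
    return(numeric(0))
  }
  x <- as.matrix(features[, model$feature_names, drop = FALSE])
  if (any(!is.finite(x))) {
    stop("feature table contains non-finite values", call. = FALSE)
  }
  as.numeric(predict(model$booster, x))
}

#' Split-count feature importance
#'
#' Counts how many times each feature is used to split across all trees
#' ("weight" importance), normalized to sum to one; also rescaled so the top
#' feature reads 100. Features never used by the model report 0.
#'
#' @param model a `variant_model`.
#' @return data.frame with `feature`, `weight` (sums to 1) and `scaled`
#'   (0-100), sorted by decreasing weight.
#' @export
feature_importance <- function(model) {
  stopifnot(inherits(model, "variant_model"))
  imp <- xgboost::xgb.importance(model = model$booster)
  weight <- stats::setNames(rep(0, length(model$feature_names)),
                            model$feature_names)
  if (!is.null(imp) && nrow(imp) > 0L) {
    weight[imp$Feature] <- imp$Frequency
  }
  total <- sum(weight)
  if (total > 0) {
    weight <- weight / total
  }
  scaled <- if (max(weight) > 0) 100 * weight / max(weight) else weight
  out <- data.frame(feature = names(weight), weight = as.numeric(weight),
                    scaled = as.numeric(scaled), stringsAsFactors = FALSE)
  out[order(-out$weight), , drop = FALSE]
}

#' Persist a trained model
#'
#' Writes the learner's native binary model next to a JSON sidecar carrying
#' the hyperparameters, feature names and codec version.
#'
#' @param model a `variant_model`.
#' @param path file path for the model (sidecar gets `.json` appended).
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "variant_model"))
  raw <- xgboost::xgb.save.raw(model$booster)
  writeBin(raw, path)
  sidecar <- list(hyperparameters = model$hyperparameters,
                  feature_names = model$feature_names,
                  seed = model$seed,
                  codec_version = model$codec_version)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Load a persisted model
#'
#' @param path path previously given to [save_model()].
#' @return a `variant_model`.
#' @export
load_model <- function(path) {
  sidecar_path <- paste0(path, ".json")
  if (!file.exists(path) || !file.exists(sidecar_path)) {
    stop("model file or its .json sidecar not found", call. = FALSE)
  }
  raw <- readBin(path, "raw", n = file.size(path))
  sidecar <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  structure(list(booster = xgboost::xgb.load.raw(raw),
                 hyperparameters = as.list(sidecar$hyperparameters),
                 feature_names = sidecar$feature_names,
                 seed = sidecar$seed,
                 codec_version = sidecar$codec_version),
            class = "variant_model")
}
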