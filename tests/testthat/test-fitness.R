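test_that("positions decode to learner hyperparameters", {
  sp <- default_search_space()
  hp <- decode_hyperparameters(c(186, -1, 4.71, 0.25, 0.73, 1.49, 0.54), sp)
  expect_equal(hp$eta, 0.1)
  expect_equal(hp$max_depth, 5)       # 4.71 rounds to the integer the
  expect_equal(hp$nrounds, 186)       # learner requires
  expect_equal(hp$min_child_weight, 1)
  expect_equal(hp$subsample, 0.54)
  hp0 <- decode_hyperparameters(c(100, 0, 2, 0, 0.4, 1, 0.5), sp)
  expect_equal(hp0$eta, 1)
  expect_error(decode_hyperparameters(c(99, 0, 2, 0, 0.4, 1, 0.5), sp),
               "outside")
  # printed slow-learning bounds remain available
  slow <- default_search_space(eta_bounds = c(-5, -3))
  expect_equal(slow$upper[slow$name == "eta_exponent"], -3)
})

test_that("the stratified split preserves class proportions", {
  tab <- make_separable_table(100, seed = 2)
  tab$isMut <- rep(c(0, 1), times = c(90, 10))
  sp <- stratified_split(tab, 0.7, seed = 1)
  expect_equal(nrow(sp$train), 70)
  expect_equal(sum(sp$train$isMut == 0), 63)
  expect_equal(sum(sp$train$isMut == 1), 7)
  # disjoint and exhaustive
  combined <- rbind(sp$train, sp$test)
  expect_equal(nrow(combined), 100)
  expect_equal(sort(combined$POS), sort(tab$POS))
  # deterministic under the seed
  sp2 <- stratified_split(tab, 0.7, seed = 1)
  expect_identical(sp$train, sp2$train)
  expect_error(stratified_split(tab[tab$isMut == 0, ], 0.7), "both classes")
})

test_that("minority oversampling balances without touching the majority", {
  tab <- make_separable_table(1000, seed = 3)
  tab$isMut <- rep(c(0, 1), times = c(900, 100))
  tab$MAFbin <- ifelse(tab$isMut == 1, -1, tab$MAFbin)
  bal <- oversample_minority(tab, target_ratio = 1, jitter = 1, seed = 9)
  counts <- table(bal$isMut)
  expect_lt(abs(counts[["1"]] - counts[["0"]]) / counts[["0"]], 0.05)
  # majority rows are untouched
  expect_equal(bal[bal$isMut == 0, ], tab[tab$isMut == 0, ],
               ignore_attr = TRUE)
  # sentinels are never jittered and categorical codes stay in their sets
  expect_true(all(bal$MAFbin[bal$isMut == 1] == -1))
  expect_true(all(bal$TypeBin %in% 0:2))
  expect_true(all(bal$varEffectBin %in% c(-1, 0, 1, 2, 3)))

  # jitter 0 degenerates to a plain bootstrap: synthetic rows are copies
  bal0 <- oversample_minority(tab, jitter = 0, seed = 9)
  minority_keys <- unique(do.call(paste, tab[tab$isMut == 1, ]))
  synth_keys <- do.call(paste, bal0[bal0$isMut == 1, ])
  expect_true(all(synth_keys %in% minority_keys))
  expect_error(oversample_minority(tab[tab$isMut == 0, ]), "both classes")
})

test_that("cross-validated accuracy separates the separable and not the null", {
  tab <- make_separable_table(500, seed = 4)
  cv <- cv_config(folds = 5, repeats = 1, seed = 2)
  pos <- c(150, -1, 3, 0.1, 0.9, 1, 0.9)
  fit <- cv_accuracy_fitness(pos, table = tab, cv = cv)
  expect_gte(as.numeric(fit), 0.98)
  # an independent one-split stump confirms the separability of the fixture
  stump_acc <- max(mean((tab$MAFbin == -1) == (tab$isMut == 1)),
                   mean((tab$MAFbin != -1) == (tab$isMut == 1)))
  expect_gte(stump_acc, 0.98)

  # shuffled labels collapse to the majority-class rate: a slow learner
  # cannot beat chance
  null_tab <- tab
  set.seed(5)
  null_tab$isMut <- sample(rep(c(0, 1), times = c(300, 200)))
  null_fit <- cv_accuracy_fitness(c(100, -5, 2, 0.5, 0.8, 2, 0.8),
                                  table = null_tab, cv = cv)
  expect_lt(abs(as.numeric(null_fit) - 0.6), 0.05)

  # budget accounting: folds x repeats learner fits
  tiny <- make_separable_table(10, seed = 6)
  f2 <- cv_accuracy_fitness(pos, table = tiny,
                            cv = cv_config(folds = 2, repeats = 1, seed = 1))
  expect_identical(attr(f2, "n_models"), 2L)

  # row order does not change the fitness
  shuffled <- tab[sample.int(nrow(tab)), ]
  fit_shuffled <- cv_accuracy_fitness(pos, table = shuffled, cv = cv)
  expect_equal(as.numeric(fit_shuffled), as.numeric(fit))
})

test_that("final models train, persist, and score deterministically", {
  tab <- make_separable_table(300, seed = 7)
  hp <- decode_hyperparameters(c(120, -1, 3, 0.1, 0.9, 1, 0.9))
  model <- train_final_model(tab, hp, seed = 1)
  scores <- predict_scores(model, tab)
  expect_length(scores, 300)
  expect_true(all(scores >= 0 & scores <= 1))
  expect_gte(roc_curve(tab$isMut, scores)$auc, 0.999)

  path <- tempfile(fileext = ".bin")
  save_model(model, path)
  reloaded <- load_model(path)
  expect_equal(predict_scores(reloaded, tab), scores, tolerance = 1e-12)
  expect_equal(reloaded$hyperparameters$nrounds, hp$nrounds)

  # refit under the same seed is identical
  again <- train_final_model(tab, hp, seed = 1)
  expect_identical(predict_scores(again, tab), scores)

  one_class <- tab[tab$isMut == 0, ]
  expect_error(train_final_model(one_class, hp), "both classes")

  expect_length(predict_scores(model, tab[0, ]), 0)
  bad <- tab
  bad$Freq[1] <- NaN
  expect_error(predict_scores(model, bad), "non-finite")
  expect_error(predict_scores(model, tab[, -5]), "missing column")
})

test_that("split-count importance is normalized and finds the only signal", {
  tab <- make_separable_table(400, seed = 8)
  # flatten every column except the informative MAF sentinel
  for (col in setdiff(myelotune:::FEATURE_NAMES, "MAFbin")) {
    tab[[col]] <- 1
  }
  hp <- decode_hyperparameters(c(120, -1, 3, 0.1, 1, 1, 1))
  model <- train_final_model(tab, hp, seed = 1)
  imp <- feature_importance(model)
  expect_equal(sum(imp$weight), 1, tolerance = 1e-9)
  expect_equal(imp$feature[1], "MAFbin")
  expect_gte(imp$weight[1], 0.5)
  expect_equal(max(imp$scaled), 100)

  # a model with nothing to split on reports a defined all-zero table
  flat <- tab
  flat$MAFbin <- 1
  flat$isMut <- rep(c(0, 1), 200)
  degenerate <- train_final_model(flat, hp, seed = 1)
  imp0 <- feature_importance(degenerate)
  expect_true(all(imp0$weight == 0))
})

test_that("tuned hyperparameters beat the slowest corner of the space", {
  co <- generate_cohort(cohort_config(n_snv = 700, n_mnv = 5, n_indel = 95,
                                      n_benign = 740, n_pathogenic = 60,
                                      seed = 12))
  tab <- build_feature_table(co)
  bal <- oversample_minority(stratified_split(tab, 0.7, seed = 1)$train,
                             seed = 1)
  cv <- cv_config(folds = 3, repeats = 1, seed = 3)
  corner <- cv_accuracy_fitness(c(100, -5, 2, 0, 0.4, 1, 0.5),
                                table = bal, cv = cv)
  tuned <- tune_hyperparameters(bal, "de",
                                control = de_control(np = 4, generations = 2,
                                                     seed = 2),
                                cv = cv, compute_kappa = FALSE)
  expect_gte(tuned$result$best_fitness, as.numeric(corner))
  expect_true(all(diff(tuned$trace$best_fitness) >= 0))
  expect_named(tuned$summary,
               c("Method", "Accuracy", "Kappa", "Nrounds", "Eta (10^x)",
                 "Md", "Gamma", "Cols", "Mw", "Sub", "Runtime"))
})
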