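make_score_fixture <- function(n_proteins = 2, sources = c("a", "b"),
                               n_res = 12, include = "degree_gnm") {
  purrr::map(seq_len(n_proteins), function(i) {
    purrr::map(sources, function(src) {
      cm <- rand_map(n_res, seed = i * 10 + match(src, sources),
                     id = sprintf("p%d", i))
      cm$source_tag <- src
      score_protein(cm, include = include)
    }) |> purrr::list_rbind()
  }) |> purrr::list_rbind()
}

test_that("feature assembly produces one {source}:{score} column per combination", {
  scores <- make_score_fixture(n_proteins = 2, sources = c("a", "b", "c"))
  labels <- tibble::tibble(
    protein_id = rep(c("p1", "p2"), each = 4),
    residue = rep(c(2L, 5L, 7L, 11L), 2),
    label = rep(c(1L, 0L), 4)
  )
  tab <- assemble_feature_table(scores, labels)
  expect_equal(nrow(tab), 8)
  expect_equal(length(feature_names(tab)), 3 * 7) # 3 sources x 7 scores
  expect_true(all(grepl("^(a|b|c):", feature_names(tab))))

  # restrict sources and scores
  tab1 <- assemble_feature_table(scores, labels, sources = "a")
  expect_equal(length(feature_names(tab1)), 7)
  tab2 <- assemble_feature_table(scores, labels, score_set = c("W1", "MSF"))
  expect_equal(length(feature_names(tab2)), 6)

  # external columns ride along
  ext <- dplyr::mutate(labels[c("protein_id", "residue")],
                       esm1 = seq_len(8) / 10, esm2 = rev(seq_len(8)) / 10)
  tab3 <- assemble_feature_table(scores, labels, external = ext)
  expect_equal(length(feature_names(tab3)), 21 + 2)
})

test_that("feature assembly rejects out-of-range sites and missing sources", {
  scores <- make_score_fixture()
  labels <- tibble::tibble(protein_id = "p1", residue = 99L, label = 1L)
  expect_error(assemble_feature_table(scores, labels),
               "outside", class = "hotspotr_validation_error")
  labels2 <- tibble::tibble(protein_id = "nope", residue = 3L, label = 0L)
  expect_error(assemble_feature_table(scores, labels2),
               class = "hotspotr_validation_error")
  labels3 <- tibble::tibble(protein_id = "p1", residue = 3L, label = 1L)
  expect_error(assemble_feature_table(scores, labels3, sources = "zz"),
               class = "hotspotr_validation_error")
})

test_that("protein-grouped splits never leak and are seed-deterministic", {
  tab <- separable_table(n_per_protein = 6, n_proteins = 10)
  sp <- split_by_protein(tab, train_fraction = 0.7, seed = 5)
  expect_equal(length(unique(sp$train$protein_id)), 7)
  expect_equal(length(unique(sp$test$protein_id)), 3)
  expect_length(intersect(sp$train$protein_id, sp$test$protein_id), 0)
  sp2 <- split_by_protein(tab, train_fraction = 0.7, seed = 5)
  expect_identical(sp, sp2)
  sp3 <- split_by_protein(tab, train_fraction = 0.7, seed = 6)
  expect_false(identical(sp$train$protein_id, sp3$train$protein_id))

  expect_error(split_by_protein(tab, train_proteins = unique(tab$protein_id)),
               class = "hotspotr_validation_error")
  expect_error(split_by_protein(tab, train_proteins = "absent"),
               class = "hotspotr_validation_error")
  # explicit mode is deterministic and exact
  sp4 <- split_by_protein(tab, train_proteins = c("p1", "p2"))
  expect_setequal(unique(sp4$train$protein_id), c("p1", "p2"))
})

test_that("removing a training protein never changes test membership", {
  tab <- separable_table(n_per_protein = 4, n_proteins = 8)
  sp <- split_by_protein(tab, train_fraction = 0.75, seed = 9)
  test_prot <- sort(unique(sp$test$protein_id))
  for (drop in unique(sp$train$protein_id)) {
    sp2 <- split_by_protein(
      dplyr::filter(tab, .data$protein_id != drop),
      train_proteins = setdiff(unique(sp$train$protein_id), drop)
    )
    expect_identical(sort(unique(sp2$test$protein_id)), test_prot)
  }
})

test_that("each algorithm separates a separable table and is seed-reproducible", {
  tab <- separable_table()
  for (algo in c("rf", "gb", "xgb")) {
    b <- train_ensemble(tab, algo, tuning_trials = 3, seed = 7)
    p <- predict_scores(b, tab)
    expect_true(all(p >= 0 & p <= 1))
    expect_equal(roc_auc(p, tab$label)$auc, 1.0, tolerance = 1e-9)

    b2 <- train_ensemble(tab, algo, tuning_trials = 3, seed = 7)
    expect_identical(b$hyperparameters, b2$hyperparameters)
    expect_identical(predict_scores(b2, tab), p)
  }
})

test_that("permuted labels give chance-level grouped-CV AUC", {
  tab <- separable_table(n_per_protein = 20, n_proteins = 10) # 200 sites
  tab$label <- withr::with_seed(13, sample(tab$label))
  b <- train_ensemble(tab, "rf", tuning_trials = 2, seed = 3)
  expect_gt(max(b$tuning$cv_auc), 0.35)
  expect_lt(max(b$tuning$cv_auc), 0.65)
})

test_that("prediction aligns columns by name and rejects mismatches", {
  tab <- separable_table()
  b <- train_ensemble(tab, "xgb", tuning_trials = 2, seed = 1)
  p <- predict_scores(b, tab)
  shuffled <- tab[, c("protein_id", "residue", "label", "src:noise", "src:good")]
  expect_identical(predict_scores(b, shuffled), p)
  expect_identical(predict_scores(b, tab[3, ]), p[3])

  expect_error(predict_scores(b, dplyr::select(tab, -"src:good")),
               "Missing", class = "hotspotr_validation_error")
  expect_error(predict_scores(b, dplyr::mutate(tab, `src:extra` = 1)),
               "Extra", class = "hotspotr_validation_error")
})

test_that("single-class training data and invalid trial counts are rejected", {
  tab <- separable_table()
  tab$label <- 1L
  expect_error(train_ensemble(tab, "rf", tuning_trials = 2, seed = 1),
               class = "hotspotr_validation_error")
  expect_error(train_ensemble(separable_table(), "rf", tuning_trials = 0, seed = 1),
               class = "hotspotr_validation_error")
})

test_that("classifiers round-trip through files with identical predictions", {
  tab <- separable_table()
  for (algo in c("rf", "xgb")) {
    b <- train_ensemble(tab, algo, tuning_trials = 2, seed = 2)
    p <- predict_scores(b, tab)
    path <- withr::local_tempfile(fileext = ".rds")
    save_classifier(b, path)
    b2 <- load_classifier(path)
    expect_equal(predict_scores(b2, tab), p, tolerance = 1e-12)
    expect_identical(b2$hyperparameters, b$hyperparameters)
  }
})

test_that("ROC/AUC match the tie-corrected pairwise oracle and edge cases", {
  expect_equal(roc_auc(c(.9, .8, .2, .1), c(1, 1, 0, 0))$auc, 1.0)
  expect_equal(roc_auc(c(.9, .8, .2, .1), c(0, 0, 1, 1))$auc, 0.0)
  expect_equal(roc_auc(c(.5, .5), c(1, 0))$auc, 0.5)

  withr::with_seed(17, {
    for (i in 1:100) {
      n <- sample(10:60, 1)
      scores <- sample(seq(0, 1, by = 0.05), n, replace = TRUE) # many ties
      labels <- rbinom(n, 1, 0.4)
      if (length(unique(labels)) < 2) labels[1:2] <- c(0L, 1L)
      ev <- roc_auc(scores, labels)
      expect_equal(ev$auc, pairwise_auc(scores, labels), tolerance = 1e-12)
      # curve contract
      expect_true(all(diff(ev$roc$fpr) >= 0))
      expect_true(all(diff(ev$roc$tpr) >= 0))
      expect_equal(ev$roc$fpr[1], 0)
      expect_equal(ev$roc$tpr[nrow(ev$roc)], 1)
    }
  })
  expect_error(roc_auc(c(1, 2), c(1, 1)), class = "hotspotr_validation_error")
})

test_that("AUC is invariant under strictly monotone score transforms", {
  withr::with_seed(19, {
    scores <- rnorm(50)
    labels <- rbinom(50, 1, plogis(scores))
    if (length(unique(labels)) < 2) labels[1:2] <- c(0L, 1L)
    a0 <- roc_auc(scores, labels)$auc
    expect_equal(roc_auc(exp(scores), labels)$auc, a0)
    expect_equal(roc_auc(100 + 3 * scores, labels)$auc, a0)
  })
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(23, {
    scores <- runif(80)
    labels <- rbinom(80, 1, scores)
    if (length(unique(labels)) < 2) labels[1:2] <- c(0L, 1L)
    ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                          direction = "<")))
    expect_equal(roc_auc(scores, labels)$auc, ref, tolerance = 1e-12)
  })
})

test_that("the operating point maximizes Youden's J", {
  scores <- c(.9, .7, .6, .4, .3, .2)
  labels <- c(1, 1, 0, 1, 0, 0)
  ev <- roc_auc(scores, labels)
  j <- ev$roc$tpr - ev$roc$fpr
  expect_equal(ev$sensitivity - (1 - ev$specificity), max(j))

  g <- glance(ev)
  expect_equal(g$auc, ev$auc)
  expect_named(tidy(ev), c("threshold", "fpr", "tpr"))
})

test_that("single-score and combined evaluations share the same schema", {
  tab <- separable_table()
  singles <- evaluate_single_scores(tab)
  expect_named(singles, c("feature", "auc", "sensitivity", "specificity"))
  b <- train_ensemble(tab, "rf", tuning_trials = 2, seed = 4)
  combined <- glance(roc_auc(predict_scores(b, tab), tab$label))
  expect_true(all(c("auc", "sensitivity", "specificity") %in% names(combined)))
  expect_equal(singles$auc[singles$feature == "src:good"], 1.0)
})
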