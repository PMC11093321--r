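#' Train a tree-ensemble hotspot classifier with seeded random-search tuning
#'
#' Fits one of three tree ensembles on a site feature table: `"rf"` (random
#' forest via ranger), `"gb"` (plain gradient tree boosting: log-loss,
#' learning rate 0.1, no regularization terms), or `"xgb"` (regularized
#' extreme gradient boosting). Hyper-parameters are selected by seeded
#' random search, scoring each draw by the mean held-out AUC under
#' protein-grouped k-fold cross-validation (sites of one protein never
#' appear on both sides of a fold), then the winning configuration is refit
#' on all training rows. Fully reproducible given `seed`.
#'
#' Search spaces: `max_depth` in 2..16 and `n_estimators` in 50..800 for all
#' algorithms; `max_features` (fraction of features per split/tree) in
#' (0, 1] for `"rf"`/`"gb"`; `reg_alpha` and `reg_lambda` log-uniform in
#' `[1e-4, 10]` for `"xgb"`.
#'
#' @param train A feature table from [assemble_feature_table()] with both
#'   classes present.
#' @param algorithm `"rf"`, `"gb"`, or `"xgb"`.
#' @param tuning_trials Number of random-search draws (>= 1).
#' @param seed Integer seed controlling fold assignment, search draws, and
#'   model fitting.
#' @param cv_folds Grouped CV folds (capped at the number of proteins).
#' @param class_weight If `TRUE`, weight classes inversely to their
#'   frequency (off by default; the evaluation metric is AUC, which is
#'   prevalence-free).
#' @return An object of class `hotspot_classifier` with the fitted model,
#'   `algorithm`, `hyperparameters`, `feature_names`, `training_seed`, and
#'   the `tuning` results tibble.
#' @seealso [predict_scores()], [roc_auc()]
#' @export
train_ensemble <- function(train, algorithm = c("rf", "gb", "xgb"),
                           tuning_trials = 20L, seed = 1L, cv_folds = 5L,
                           class_weight = FALSE) {
  algorithm <- match.arg(algorithm)
  train <- as_tibble(train)
  if (tuning_trials < 1) {
    stop_hotspotr("`tuning_trials` must be >= 1.", "hotspotr_validation_error")
  }
  y <- train$label
  if (length(unique(y)) < 2L) {
    stop_hotspotr("Training data contains a single class.",
                  "hotspotr_validation_error")
  }
  feats <- feature_names(train)
  X <- as.matrix(train[feats])
  proteins <- unique(train$protein_id)
  k <- min(cv_folds, length(proteins))
  fold_of_protein <- with_seed(derive_seed(seed, 1L),
                               sample(rep_len(seq_len(k), length(proteins))))
  fold <- fold_of_protein[match(train$protein_id, proteins)]

  draws <- with_seed(derive_seed(seed, 2L),
                     purrr::map(seq_len(tuning_trials),
                                function(i) draw_hyperparameters(algorithm)))

  cv_auc <- vapply(seq_along(draws), function(t) {
    hp <- draws[[t]]
    aucs <- vapply(seq_len(k), function(f) {
      tr <- fold != f
      if (length(unique(y[!tr])) < 2L || length(unique(y[tr])) < 2L) {
        return(NA_real_)
      }
      fit <- fit_tree_model(algorithm, X[tr, , drop = FALSE], y[tr], hp,
                            seed = derive_seed(seed, t, f), class_weight = class_weight)
      roc_auc(predict_tree_model(fit, X[!tr, , drop = FALSE]), y[!tr])$auc
    }, numeric(1))
    mean(aucs, na.rm = TRUE)
  }, numeric(1))

  best <- which.max(cv_auc) # first maximum: deterministic tie-break
  if (length(best) == 0) {
    stop_hotspotr(
      "Every cross-validation fold was degenerate (single-class); use fewer folds or more proteins.",
      "hotspotr_validation_error"
    )
  }
  hp <- draws[[best]]
  model <- fit_tree_model(algorithm, X, y, hp,
                          seed = derive_seed(seed, 0L), class_weight = class_weight)
  structure(
    list(
      algorithm = algorithm,
      hyperparameters = hp,
      feature_names = feats,
      training_seed = as.integer(seed),
      class_weight = class_weight,
      cv_folds = k,
      model = model,
      tuning = tibble(
        trial = seq_along(draws),
        cv_auc = cv_auc,
        params = purrr::map_chr(draws, \(h) jsonlite::toJSON(h, auto_unbox = TRUE))
      )
    ),
    class = "hotspot_classifier"
  )
}

draw_hyperparameters <- function(algorithm) {
  hp <- list(
    max_depth = sample(2:16, 1L),
    n_estimators = sample(50:800, 1L)
  )
  if (algorithm %in% c("rf", "gb")) {
    hp$max_features <- runif(1, 0, 1)
    if (hp$max_features == 0) hp$max_features <- 1 # open interval (0, 1]
  } else {
    hp$reg_alpha <- 10^runif(1, -4, 1)
    hp$reg_lambda <- 10^runif(1, -4, 1)
  }
  hp
}

fit_tree_model <- function(algorithm, X, y, hp, seed, class_weight = FALSE) {
  if (algorithm == "rf") {
    cw <- if (class_weight) as.numeric(1 / table(y)[as.character(y)]) else NULL
    fit <- ranger::ranger(
      x = as.data.frame(X), y = factor(y, levels = c(0, 1)),
      probability = TRUE,
      num.trees = hp$n_estimators,
      max.depth = hp$max_depth,
      mtry = max(1L, round(hp$max_features * ncol(X))),
      case.weights = cw,
      seed = seed,
      num.threads = 1L,
      verbose = FALSE
    )
    return(structure(list(fit = fit), class = "hotspotr_rf"))
  }
  spw <- if (class_weight) sum(y == 0) / sum(y == 1) else 1
  params <- if (algorithm == "gb") {
    xgboost::xgb.params(
      objective = "binary:logistic",
      eta = 0.1,
      max_depth = hp$max_depth,
      colsample_bytree = hp$max_features,
      reg_lambda = 0, reg_alpha = 0,
      subsample = 1,
      tree_method = "exact",
      scale_pos_weight = spw,
      nthread = 1, seed = seed
    )
  } else {
    xgboost::xgb.params(
      objective = "binary:logistic",
      max_depth = hp$max_depth,
      reg_alpha = hp$reg_alpha,
      reg_lambda = hp$reg_lambda,
      scale_pos_weight = spw,
      nthread = 1, seed = seed
    )
  }
  fit <- xgboost::xgb.train(
    params = params,
    data = xgboost::xgb.DMatrix(X, label = y, nthread = 1),
    nrounds = hp$n_estimators,
    verbose = 0
  )
  structure(list(fit = fit), class = "hotspotr_xgb")
}

predict_tree_model <- function(model, X) {
  if (inherits(model, "hotspotr_rf")) {
    as.numeric(predict(model$fit, data = as.data.frame(X),
                       num.threads = 1L)$predictions[, "1"])
  } else {
    as.numeric(predict(model$fit, xgboost::xgb.DMatrix(X, nthread = 1)))
  }
}

#' @export
print.hotspot_classifier <- function(x, ...) {
  cat(sprintf("<hotspot_classifier> %s, %d features, seed %d\n",
              x$algorithm, length(x$feature_names), x$training_seed))
  cat("  tuned:", jsonlite::toJSON(x$hyperparameters, auto_unbox = TRUE, digits = 4), "\n")
  cat(sprintf("  best grouped-CV AUC: %.4f over %d trials\n",
              max(x$tuning$cv_auc, na.rm = TRUE), nrow(x$tuning)))
  invisible(x)
}

#' Predict deleterious-site probabilities for new sites
#'
#' Columns are aligned to the classifier's feature names by name; missing or
#' extra feature columns are an error.
#'
#' @param bundle A [train_ensemble()] classifier.
#' @param table A feature table with exactly the classifier's feature
#'   columns (plus the bookkeeping columns).
#' @return Numeric vector of probabilities in `[0, 1]`, one per row.
#' @export
predict_scores <- function(bundle, table) {
  stopifnot(inherits(bundle, "hotspot_classifier"))
  table <- as_tibble(table)
  feats <- feature_names(table)
  missing <- setdiff(bundle$feature_names, feats)
  extra <- setdiff(feats, bundle$feature_names)
  if (length(missing) > 0 || length(extra) > 0) {
    stop_hotspotr(
      sprintf("Feature columns do not match the classifier. Missing: %s. Extra: %s.",
              paste(missing, collapse = ", ") %||% "",
              paste(extra, collapse = ", ") %||% ""),
      "hotspotr_validation_error"
    )
  }
  X <- as.matrix(table[bundle$feature_names])
  predict_tree_model(bundle$model, X)
}

#' @describeIn train_ensemble Tidy the tuning trace: one row per random-search
#'   trial with its grouped-CV AUC and parameter JSON.
#' @param x A `hotspot_classifier`.
#' @param ... Unused.
#' @export
tidy.hotspot_classifier <- function(x, ...) x$tuning

#' @describeIn train_ensemble One-row summary: algorithm, number of
#'   features, folds, trials, best CV AUC.
#' @export
glance.hotspot_classifier <- function(x, ...) {
  tibble(
    algorithm = x$algorithm,
    n_features = length(x$feature_names),
    cv_folds = x$cv_folds,
    trials = nrow(x$tuning),
    best_cv_auc = max(x$tuning$cv_auc, na.rm = TRUE),
    training_seed = x$training_seed
  )
}

#' Persist a trained classifier to a file and restore it
#'
#' Uses R serialization (version 3). The restored bundle predicts
#' identically to the saved one.
#'
#' @param bundle A `hotspot_classifier`.
#' @param path File path.
#' @return `save_classifier()` returns the path invisibly;
#'   `load_classifier()` returns the bundle.
#' @export
save_classifier <- function(bundle, path) {
  stopifnot(inherits(bundle, "hotspot_classifier"))
  # xgboost handles are external pointers; serialize a raw snapshot instead
  if (inherits(bundle$model, "hotspotr_xgb")) {
    bundle$model_raw <- xgboost::xgb.save.raw(bundle$model$fit)
    bundle$model <- NULL
  }
  saveRDS(bundle, path, version = 3)
  invisible(path)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(path) {
  bundle <- readRDS(path)
  if (!is.null(bundle$model_raw)) {
    bundle$model <- structure(list(fit = xgboost::xgb.load.raw(bundle$model_raw)),
                              class = "hotspotr_xgb")
    bundle$model_raw <- NULL
  }
  stopifnot(inherits(bundle, "hotspot_classifier"))
  bundle
}
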