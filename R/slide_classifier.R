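#' Gradient-boosted slide classifier configuration
#'
#' Defaults follow the study setup: 60 boosting rounds, trees of depth
#' 3, and class weights of 1.0 for malignant and 0.1 for the other
#' categories (applied as per-sample weights), which tunes model
#' selection towards malignant sensitivity. The fit is repeated
#' `n_restarts` times with distinct seeds (row and column subsampling
#' make restarts genuinely different) and the restart with the highest
#' malignant sensitivity — ties broken by accuracy — on the validation
#' set is kept.
#'
#' @param n_estimators boosting rounds.
#' @param max_depth tree depth.
#' @param class_weights named weights per category.
#' @param n_restarts number of seeded restarts.
#' @param subsample,colsample_bytree stochastic-boosting fractions.
#' @param eta learning rate; the soft default of 0.1 yields shallower
#'   per-round corrections, which generalizes the learned thresholds
#'   better across staining labs than the backend default of 0.3.
#' @param min_child_weight minimum summed hessian per leaf. Defaults to
#'   0: with per-sample weights of 0.1 on a desk-scale cohort, the usual
#'   default of 1 exceeds whole-class hessian totals and silently blocks
#'   every split.
#' @param seed integer seed.
#' @return a `boost_config` list.
#' @export
boost_config <- function(n_estimators = 60L, max_depth = 3L,
                         class_weights = c(normal = 0.1, low_grade = 0.1,
                                           high_grade = 0.1,
                                           malignant = 1.0),
                         n_restarts = 20L, subsample = 0.8,
                         colsample_bytree = 0.8, eta = 0.1,
                         min_child_weight = 0, seed = 1L) {
  stopifnot(all(class_weights > 0))
  structure(list(n_estimators = n_estimators, max_depth = max_depth,
                 class_weights = class_weights, n_restarts = n_restarts,
                 subsample = subsample,
                 colsample_bytree = colsample_bytree, eta = eta,
                 min_child_weight = min_child_weight, seed = seed),
            class = "boost_config")
}

# per-sample weights from class weights
sample_weights <- function(labels, class_weights) {
  unname(class_weights[as.character(labels)])
}

#' Fit the boosted slide-level classifier
#'
#' @param features numeric matrix (slides x features).
#' @param labels category factor/character vector per slide.
#' @param valid_features,valid_labels validation split used to select
#'   the best restart.
#' @param cfg a [boost_config()].
#' @return a `slide_classifier` (list with the chosen booster, the
#'   restart's selection metrics, and the feature column order).
#' @export
fit_boosted <- function(features, labels, valid_features, valid_labels,
                        cfg = boost_config()) {
  features <- as.matrix(features)
  labels <- as_category_factor(labels)
  if (any(table(labels) == 0L)) {
    stop("class absent from training labels: ",
         paste(levels(labels)[table(labels) == 0L], collapse = ", "))
  }
  y <- as.integer(labels) - 1L
  w <- sample_weights(labels, cfg$class_weights)
  dtrain <- xgboost::xgb.DMatrix(features, label = y, weight = w)
  dvalid <- xgboost::xgb.DMatrix(as.matrix(valid_features))
  y_valid <- as_category_factor(valid_labels)

  best <- NULL
  for (r in seq_len(cfg$n_restarts)) {
    params <- list(objective = "multi:softprob", num_class = 4L,
                   max_depth = cfg$max_depth, eta = cfg$eta,
                   subsample = cfg$subsample,
                   colsample_bytree = cfg$colsample_bytree,
                   min_child_weight = cfg$min_child_weight,
                   seed = derive_seed(cfg$seed, r), nthread = 1L)
    booster <- xgboost::xgb.train(params = params, data = dtrain,
                                  nrounds = cfg$n_estimators, verbose = 0)
    pred <- predict_booster_category(booster, dvalid)
    cm <- confusion(y_valid, pred)
    score <- c(malignant_sensitivity(cm), cm$accuracy)
    if (is.null(best) || score[1] > best$score[1] ||
        (score[1] == best$score[1] && score[2] > best$score[2])) {
      best <- list(booster = booster, score = score, restart = r)
    }
  }
  structure(list(kind = "boosted", model = best$booster,
                 selection = c(malignant_sensitivity = best$score[1],
                               accuracy = best$score[2],
                               restart = best$restart),
                 feature_names = colnames(features)),
            class = "slide_classifier")
}

predict_booster_category <- function(booster, dmat) {
  probs <- predict(booster, dmat)
  probs <- matrix(probs, ncol = 4L, byrow = FALSE)
  # argmax with severity tie-break (last max wins in category order)
  idx <- apply(probs, 1, function(v) max(which(v == max(v))))
  factor(wsi_categories()[idx], levels = wsi_categories())
}

#' Random-forest hyperparameter search space
#'
#' The randomized-search grid for the forest slide classifier:
#' `n_estimators` in 100-1500 (step 10), `min_samples_split` in
#' \{2, 5, 10\}, `min_samples_leaf` in \{1, 2, 4\}, `max_features` in
#' \{auto, sqrt, log2\}, `max_depth` in 10-110 (step 10), `criterion`
#' in \{gini, entropy\}, `bootstrap` in \{TRUE, FALSE\};
#' `n_samples` settings are drawn and scored by `cv_folds`-fold
#' cross-validation.
#'
#' @param n_samples number of sampled settings.
#' @param cv_folds cross-validation folds.
#' @return a `forest_search_space` list.
#' @export
forest_search_space <- function(n_samples = 300L, cv_folds = 3L) {
  structure(list(
    n_estimators = seq(100L, 1500L, by = 10L),
    min_samples_split = c(2L, 5L, 10L),
    min_samples_leaf = c(1L, 2L, 4L),
    max_features = c("auto", "sqrt", "log2"),
    max_depth = seq(10L, 110L, by = 10L),
    criterion = c("gini", "entropy"),
    bootstrap = c(TRUE, FALSE),
    n_samples = n_samples, cv_folds = cv_folds
  ), class = "forest_search_space")
}

# fit one random forest with a sampled parameter setting
fit_forest_once <- function(features, labels, p, seed) {
  mtry <- switch(p$max_features,
                 auto = , sqrt = max(1L, floor(sqrt(ncol(features)))),
                 log2 = max(1L, floor(log2(ncol(features)))))
  ranger::ranger(
    x = features, y = labels,
    num.trees = p$n_estimators,
    mtry = min(mtry, ncol(features)),
    min.node.size = p$min_samples_split,
    min.bucket = p$min_samples_leaf,
    max.depth = p$max_depth,
    splitrule = "gini",  # backend supports Gini impurity for classification
    replace = p$bootstrap,
    sample.fraction = if (p$bootstrap) 1 else 0.8,
    seed = seed, num.threads = 1L
  )
}

#' Randomized-search random forest slide classifier
#'
#' Samples `n_samples` settings from the search grid, scores each by
#' stratified K-fold cross-validated accuracy, and refits the best
#' setting on all training data. Deterministic given `seed`.
#'
#' @param features numeric matrix (slides x features).
#' @param labels category labels.
#' @param space a [forest_search_space()].
#' @param seed integer seed.
#' @return a `slide_classifier` with `best_params` and `cv_accuracy`.
#' @export
fit_forest_with_search <- function(features, labels,
                                   space = forest_search_space(),
                                   seed = 1L) {
  features <- as.matrix(features)
  labels <- as_category_factor(labels)
  if (nrow(features) < space$cv_folds) {
    stop("fewer samples than cross-validation folds")
  }
  set.seed(seed)
  settings <- lapply(seq_len(space$n_samples), function(i) {
    list(n_estimators = sample_from(space$n_estimators),
         min_samples_split = sample_from(space$min_samples_split),
         min_samples_leaf = sample_from(space$min_samples_leaf),
         max_features = sample_from(space$max_features),
         max_depth = sample_from(space$max_depth),
         criterion = sample_from(space$criterion),
         bootstrap = sample_from(space$bootstrap))
  })
  folds <- stratified_folds(labels, space$cv_folds)
  scores <- vapply(seq_along(settings), function(i) {
    p <- settings[[i]]
    accs <- vapply(seq_len(space$cv_folds), function(k) {
      tr <- folds != k
      if (length(unique(labels[tr])) < 2L) return(NA_real_)
      fit <- fit_forest_once(features[tr, , drop = FALSE], labels[tr],
                             p, derive_seed(seed, i * 10L + k))
      pred <- predict(fit, data = features[!tr, , drop = FALSE])$predictions
      mean(pred == labels[!tr])
    }, numeric(1))
    mean(accs, na.rm = TRUE)
  }, numeric(1))
  best_i <- which.max(scores)
  best_params <- settings[[best_i]]
  final <- fit_forest_once(features, labels, best_params,
                           derive_seed(seed, 999L))
  structure(list(kind = "forest", model = final,
                 best_params = best_params,
                 cv_accuracy = scores[best_i],
                 feature_names = colnames(features)),
            class = "slide_classifier")
}

# fold id per sample, stratified by class
stratified_folds <- function(labels, k) {
  folds <- integer(length(labels))
  for (lv in levels(labels)) {
    idx <- which(labels == lv)
    folds[idx] <- sample(rep(seq_len(k), length.out = length(idx)))
  }
  folds
}

#' Predict slide categories
#'
#' @param model a `slide_classifier`.
#' @param features feature matrix with the training column order.
#' @return factor of predicted categories, one per slide (empty input
#'   gives an empty factor).
#' @export
predict_slides <- function(model, features) {
  features <- as.matrix(features)
  if (nrow(features) == 0L) {
    return(factor(character(0), levels = wsi_categories()))
  }
  if (!is.null(model$feature_names) &&
      ncol(features) != length(model$feature_names)) {
    stop("feature length mismatch: model expects ",
         length(model$feature_names), ", got ", ncol(features))
  }
  if (model$kind == "boosted") {
    predict_booster_category(model$model, xgboost::xgb.DMatrix(features))
  } else {
    pred <- predict(model$model, data = features)$predictions
    factor(as.character(pred), levels = wsi_categories())
  }
}
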