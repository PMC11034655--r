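#' End-to-end slide triage pipeline
#'
#' Runs the full pipeline on a cohort manifest: lab-held-out stratified
#' split, patch indexing (grid, tissue detection, max-severity
#' labelling), patch sampling and export, patch classifier training,
#' inference over all tissue patches of every slide, per-category
#' heatmaps, slide feature extraction, the boosted slide classifier
#' selected for malignant sensitivity, and test-set evaluation.
#'
#' @param manifest cohort manifest data.frame (paths must be readable).
#' @param work_dir working directory for exported patches.
#' @param grid a [grid_spec()]; the desk-scale default uses 64-pixel
#'   patches indexed on level-3 thumbnails.
#' @param mode patch sampling mode (`"imbalanced"` trains with focal
#'   loss, `"balanced"` with cross-entropy).
#' @param scheme slide feature scheme (`"boosted"` or `"forest90"`).
#' @param model_factory patch model factory.
#' @param n_members patch-classifier seed-ensemble size (see
#'   [train_patch_ensemble()]). The default of 1 trains a single
#'   classifier: across synthetic cohorts, probability averaging
#'   suppresses weak true-malignant heatmap regions, trading malignant
#'   sensitivity (the tuning objective) for accuracy.
#' @param max_per_category patch sampling cap.
#' @param n_heldout_labs labs fully held out for the test set.
#' @param seed master seed; every stochastic stage derives its own seed
#'   from it.
#' @return list with `split`, `patch_training` (history and best
#'   validation accuracy), `features`, `slide_model`, `predictions`,
#'   `test_confusion`, `test_accuracy`, `test_malignant_sensitivity`.
#' @export
run_triage_pipeline <- function(manifest, work_dir = tempfile("triage_"),
                                grid = grid_spec(64L, 3L),
                                mode = c("imbalanced", "balanced"),
                                scheme = c("boosted", "forest90"),
                                model_factory = mlp_patch_model(),
                                n_members = 1L,
                                max_per_category = Inf,
                                n_heldout_labs = 2L, seed = 1L) {
  mode <- match.arg(mode)
  scheme <- match.arg(scheme)
  dir.create(work_dir, recursive = TRUE, showWarnings = FALSE)

  split <- split_manifest(manifest, n_heldout_labs = n_heldout_labs,
                          seed = derive_seed(seed, 1L))
  splits <- setNames(split$assignment$split, split$assignment$slide_id)

  # index every slide once; keep only the patch tables in memory
  patch_tables <- vector("list", nrow(manifest))
  names(patch_tables) <- manifest$slide_id
  for (i in seq_len(nrow(manifest))) {
    slide <- open_slide(manifest$image_path[i])
    ann <- load_annotations(manifest$annotation_path[i])
    patch_tables[[i]] <- index_slide_patches(slide, ann, grid)
  }

  # pooled sampling + export for train and valid splits
  for (sp in c("train", "valid")) {
    ids <- names(splits)[splits == sp]
    pooled <- do.call(rbind, lapply(ids, function(id) {
      cbind(slide_id = id, patch_tables[[id]])
    }))
    sampled <- sample_patches(pooled, mode = mode,
                              max_per_category = max_per_category,
                              seed = derive_seed(seed, 2L + (sp == "valid")))
    for (id in unique(sampled$slide_id)) {
      slide <- open_slide(
        manifest$image_path[manifest$slide_id == id])
      export_patches(slide, sampled[sampled$slide_id == id, ], id, grid,
                     file.path(work_dir, "patches", sp))
    }
  }

  train_data <- load_patch_dataset(file.path(work_dir, "patches", "train"))
  valid_data <- load_patch_dataset(file.path(work_dir, "patches", "valid"))
  loss <- if (mode == "imbalanced") loss_config("focal") else
    loss_config("cross_entropy")
  training <- train_patch_ensemble(
    train_data, valid_data, n_members = n_members,
    model_factory = model_factory, loss = loss,
    cfg = training_config(seed = derive_seed(seed, 4L))
  )

  # heatmaps + features for every slide
  heatmaps <- vector("list", nrow(manifest))
  names(heatmaps) <- manifest$slide_id
  for (i in seq_len(nrow(manifest))) {
    slide <- open_slide(manifest$image_path[i])
    thumb_dims <- slide_dims(slide, grid$mag_level)
    n_cols <- thumb_dims[["width"]] %/% grid$cell
    n_rows <- thumb_dims[["height"]] %/% grid$cell
    probs <- infer_patches(training$model, slide,
                           patch_tables[[i]], grid)
    heatmaps[[i]] <- build_heatmaps(probs, n_rows, n_cols)
  }
  features <- slide_feature_table(heatmaps, scheme = scheme)
  feat_mat <- as.matrix(features[, -1, drop = FALSE])
  rownames(feat_mat) <- features$slide_id
  labels <- setNames(manifest$category, manifest$slide_id)

  tr_ids <- names(splits)[splits == "train"]
  va_ids <- names(splits)[splits == "valid"]
  te_ids <- names(splits)[splits == "test"]
  slide_model <- fit_boosted(
    feat_mat[tr_ids, , drop = FALSE], labels[tr_ids],
    feat_mat[va_ids, , drop = FALSE], labels[va_ids],
    cfg = boost_config(seed = derive_seed(seed, 5L))
  )
  pred_test <- predict_slides(slide_model, feat_mat[te_ids, , drop = FALSE])
  cm <- confusion(labels[te_ids], pred_test)

  list(split = split,
       patch_training = training,
       features = features,
       slide_model = slide_model,
       predictions = data.frame(slide_id = te_ids,
                                truth = unname(labels[te_ids]),
                                predicted = as.character(pred_test),
                                stringsAsFactors = FALSE),
       test_confusion = cm,
       test_accuracy = cm$accuracy,
       test_malignant_sensitivity = malignant_sensitivity(cm))
}
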