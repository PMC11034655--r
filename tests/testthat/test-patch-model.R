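test_that("normalization maps [0,1] inputs onto [-1,1] with 0.5 at zero", {
  img <- array(0.5, c(8, 8, 3))
  out <- wsitriage:::normalize_patch(img)
  expect_equal(max(abs(out)), 0)
  # identity jitter factors change nothing before normalization
  jit <- wsitriage:::apply_color_jitter(img, 1, 1, 1, 0)
  expect_equal(jit, img)

  set.seed(5)
  rnd <- array(stats::runif(8 * 8 * 3), c(8, 8, 3))
  for (i in 1:10) {
    a <- augment(rnd)
    expect_equal(dim(a), dim(rnd))
    expect_true(all(a >= -1 - 1e-12 & a <= 1 + 1e-12))
  }
})

test_that("90-degree rotation permutes pixels as transpose-and-flip", {
  img <- array(seq_len(2 * 3 * 3) / 18, c(2, 3, 3))
  r1 <- wsitriage:::rotate90(img, 1L)
  expect_equal(dim(r1), c(3L, 2L, 3L))
  for (ch in 1:3) {
    expect_equal(r1[, , ch], t(img[, , ch])[3:1, ])
  }
  expect_equal(wsitriage:::rotate90(img, 4L), img)
  # four quarter turns compose to the identity
  r <- img
  for (i in 1:4) r <- wsitriage:::rotate90(r, 1L)
  expect_equal(r, img)
})

test_that("focal loss reduces to cross-entropy at gamma 0 and hits hand values", {
  set.seed(8)
  for (i in 1:10) {
    z <- matrix(stats::rnorm(40), 10, 4)
    p <- exp(z) / rowSums(exp(z))
    truth <- sample(1:4, 10, replace = TRUE)
    ce <- -mean(log(p[cbind(1:10, truth)]))
    expect_equal(focal_loss(p, truth, gamma = 0, alpha = 1), ce,
                 tolerance = 1e-10)
  }
  # a perfectly predicted class contributes no loss
  expect_equal(focal_loss(matrix(c(1, 0, 0, 0), 1), 1L, gamma = 2), 0)
  # p_t = 0.5, gamma = 2: 0.25 * ln 2
  p <- matrix(c(0.5, 0.3, 0.1, 0.1), 1)
  expect_equal(focal_loss(p, 1L, gamma = 2, alpha = 1), 0.25 * log(2),
               tolerance = 1e-12)
})

test_that("the analytic focal-loss gradient matches numerical differentiation", {
  set.seed(9)
  for (gamma in c(0, 1, 2)) {
    z <- matrix(stats::rnorm(20), 5, 4)
    truth <- sample(1:4, 5, replace = TRUE)
    alpha <- c(1, 0.5, 2, 1)
    p <- exp(z - apply(z, 1, max))
    p <- p / rowSums(p)
    g_analytic <- wsitriage:::focal_loss_grad(p, truth, gamma, alpha)
    g_numeric <- wsitriage:::focal_loss_grad_numeric(z, truth, gamma, alpha)
    expect_equal(g_analytic, g_numeric, tolerance = 1e-6)
  }
})

test_that("the learning rate halves every two epochs", {
  cfg <- training_config()
  expect_equal(vapply(0:5, lr_at_epoch, numeric(1), cfg = cfg),
               c(0.001, 0.001, 0.0005, 0.0005, 0.00025, 0.00025))
})

test_that("temperature scaling preserves the argmax and sharpens towards truth", {
  set.seed(12)
  p <- matrix(stats::rexp(80), 20, 4)
  p <- p / rowSums(p)
  truth <- max.col(p)
  scaled <- scale_probs(p, 0.5)
  expect_equal(max.col(scaled), max.col(p))
  expect_equal(rowSums(scaled), rep(1, 20))
  expect_equal(scale_probs(p, 1), p)
  # an underconfident but correct classifier calibrates to T < 1
  expect_lt(fit_temperature(p, truth), 1)
})

# one shared training run over the separable textures backs several checks
texture_fit <- local({
  train <- make_texture_dataset(40L, seed = 41L)
  valid <- make_texture_dataset(15L, seed = 42L)
  list(train = train, valid = valid,
       fit = train_patch_classifier(train, valid,
                                    loss = loss_config("focal"),
                                    cfg = training_config(seed = 7L)))
})

test_that("training on separable textures reaches 95% validation accuracy", {
  expect_gte(texture_fit$fit$best_valid_accuracy, 0.95)
})

test_that("training history respects the epoch budget and early stopping", {
  fit <- texture_fit$fit
  cfg <- training_config()
  expect_lte(nrow(fit$history), cfg$max_epochs)
  expect_lte(nrow(fit$history), fit$best_epoch + cfg$patience + 1L)
  expect_equal(fit$history$lr,
               vapply(fit$history$epoch, lr_at_epoch, numeric(1),
                      cfg = cfg))
  # early stopping fires when validation accuracy plateaus immediately:
  # a factory whose forward pass ignores the input cannot improve
  constant_factory <- function(input_example, seed) {
    model <- mlp_patch_model(hidden = 4L)(input_example, seed)
    model$params <- lapply(model$params, function(p) p * 0)
    model$backward <- function(params, cache, dlogits) {
      lapply(params, function(p) p * 0)
    }
    model
  }
  flat <- train_patch_classifier(texture_fit$train, texture_fit$valid,
                                 model_factory = constant_factory,
                                 loss = loss_config("cross_entropy"),
                                 cfg = training_config(seed = 7L),
                                 calibrate = FALSE)
  expect_equal(nrow(flat$history), training_config()$patience + 1L)
})

test_that("empty training sets are rejected", {
  empty <- list(images = list(), labels = factor(character(0),
                                                 levels = wsi_categories()))
  expect_error(train_patch_classifier(empty, texture_fit$valid), "empty")
})

test_that("inference is deterministic, normalized and empty-safe", {
  td <- withr::local_tempdir()
  res <- make_test_slide(td, "inf", width = 128L, height = 128L,
                         lesion_categories = "malignant", seed = 6L)
  sl <- open_slide(res$slide_dir)
  g <- grid_spec(32L, 2L)
  recs <- index_slide_patches(sl, res$annotations, g)
  model <- texture_fit$fit$model
  pr1 <- infer_patches(model, sl, recs, g)
  pr2 <- infer_patches(model, sl, recs, g)
  expect_identical(pr1, pr2)
  expect_equal(nrow(pr1), sum(recs$is_tissue))
  sums <- unname(rowSums(pr1[, paste0("p_", wsi_categories())]))
  expect_equal(sums, rep(1, nrow(pr1)), tolerance = 1e-6)

  none <- recs; none$is_tissue <- FALSE
  expect_equal(nrow(infer_patches(model, sl, none, g)), 0L)
})

test_that("the trained texture classifier recognises pure lesion patches", {
  model <- texture_fit$fit$model
  probs <- predict_patch_probs(model, texture_fit$valid$images)
  pred <- wsi_categories()[max.col(probs)]
  expect_gte(mean(pred == as.character(texture_fit$valid$labels)), 0.95)
})
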