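test_that("a lesion-free spec yields a normal slide with no polygons", {
  td <- withr::local_tempdir()
  res <- make_test_slide(td, "n", lesion_categories = character(0))
  expect_equal(res$slide_label, "normal")
  expect_equal(length(res$annotations$polygons), 0L)
})

test_that("the same spec and seed produce byte-identical output", {
  td1 <- withr::local_tempdir(); td2 <- withr::local_tempdir()
  r1 <- make_test_slide(td1, "d", lesion_categories = "high_grade",
                        seed = 5L)
  r2 <- make_test_slide(td2, "d", lesion_categories = "high_grade",
                        seed = 5L)
  f1 <- list.files(r1$slide_dir, full.names = TRUE)
  f2 <- list.files(r2$slide_dir, full.names = TRUE)
  expect_equal(basename(f1), basename(f2))
  expect_equal(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  expect_identical(readLines(r1$annotation_path),
                   readLines(r2$annotation_path))
})

test_that("a single malignant lesion gives one malignant polygon", {
  td <- withr::local_tempdir()
  res <- make_test_slide(td, "m", lesion_categories = "malignant")
  expect_equal(length(res$annotations$polygons), 1L)
  expect_equal(res$annotations$polygons[[1]]$category, "malignant")
  expect_equal(res$slide_label, "malignant")
})

test_that("background is near-white and lesion pixels pass the tissue test", {
  td <- withr::local_tempdir()
  res <- make_test_slide(td, "bg", width = 256L, height = 256L,
                         lesion_categories = "malignant")
  sl <- open_slide(res$slide_dir)
  img <- read_region(sl, 0L, 0L, 0L, 256L, 256L)
  # corners are background on these fixtures
  expect_true(all(img[1:4, 1:4, ] >= 0.92))
  # pixels at the lesion centroid are stained tissue
  ctr <- round(colMeans(res$annotations$polygons[[1]]$vertices))
  block <- img[(ctr[2] - 1):(ctr[2] + 1), (ctr[1] - 1):(ctr[1] + 1), ]
  lum <- apply(block, c(1, 2), mean)
  expect_true(all(lum < 0.88))
})

test_that("explicit lesion polygons outside tissue are rejected", {
  td <- withr::local_tempdir()
  spec <- list(slide_id = "bad", width = 256L, height = 256L, seed = 1L,
               lab_id = 1L,
               lesions = list(list(category = "malignant",
                                   vertices = cbind(c(1, 20, 10),
                                                    c(1, 1, 20)))))
  expect_error(generate_slide(spec, td), "outside tissue")
})

test_that("slide label equals the max severity over painted lesions", {
  td <- withr::local_tempdir()
  res <- make_test_slide(td, "multi", width = 384L, height = 384L,
                         lesion_categories = c("low_grade", "high_grade"))
  expect_equal(res$slide_label, "high_grade")
  # where polygons overlap, the painted texture belongs to the most
  # severe category: the overlap pixels must be at least as dark as the
  # high-grade base colour allows (low grade is lighter)
  sl <- open_slide(res$slide_dir)
  g <- grid_spec(32L, 2L)
  pt <- index_slide_patches(sl, res$annotations, g, resolution = "level0")
  expect_equal(max_severity(pt$label[pt$is_tissue]), "high_grade")
})

test_that("cohort generation follows the category mix and lab rotation", {
  td <- withr::local_tempdir()
  man <- generate_cohort(file.path(td, "c"), n_slides = 12L,
                         category_mix = c(malignant = 1.0),
                         n_labs = 4L, seed = 3L,
                         size_range = c(128L, 192L))
  expect_equal(nrow(man), 12L)
  expect_true(all(man$category == "malignant"))
  expect_equal(man$lab_id, rep(1:4, 3))
  expect_true(all(file.exists(file.path(man$image_path, "slide.json"))))
  expect_true(all(file.exists(man$annotation_path)))
  expect_error(
    generate_cohort(file.path(td, "bad"), 4L,
                    c(malignant = 0.6, normal = 0.6), 4L, 1L),
    "sum to 1")
})

test_that("category counts at n = 400 fall inside exact binomial 99% bounds", {
  td <- withr::local_tempdir()
  mix <- c(normal = 0.25, low_grade = 0.25, high_grade = 0.25,
           malignant = 0.25)
  man <- generate_cohort(file.path(td, "big"), n_slides = 400L,
                         category_mix = mix, n_labs = 8L, seed = 17L,
                         size_range = c(128L, 128L))
  counts <- table(factor(man$category, levels = wsi_categories()))
  lo <- stats::qbinom(0.005, 400L, 0.25)
  hi <- stats::qbinom(0.995, 400L, 0.25)
  expect_true(all(counts >= lo & counts <= hi))
})

test_that("a depth-2 tree on simple colour/nuclei summaries separates the textures", {
  featurize <- function(img) {
    gray <- (img[, , 1] + img[, , 2] + img[, , 3]) / 3
    c(mr = mean(img[, , 1]), mg = mean(img[, , 2]), mb = mean(img[, , 3]),
      spots = sum(gray < 0.45) / 13)  # dark pixels per nucleus area
  }
  ds <- make_texture_dataset(60L, seed = 2L)
  X <- t(vapply(ds$images, featurize, numeric(4)))
  y <- as.character(ds$labels)
  idx <- rep(rep(c(TRUE, FALSE), c(40L, 20L)), 4L)  # 40 train / 20 test
  tree <- fit_depth2_tree(X[idx, ], y[idx])
  pred <- predict_depth2_tree(tree, X[!idx, , drop = FALSE])
  expect_gte(mean(pred == y[!idx]), 0.95)
})
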