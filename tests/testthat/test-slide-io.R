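test_that("pyramid geometry follows ceil(dims / 2^L) including odd sizes", {
  td <- withr::local_tempdir()
  img <- array(stats::runif(300 * 200 * 3), c(200, 300, 3))
  write_slide_pyramid(img, file.path(td, "odd"), n_levels = 5L)
  sl <- open_slide(file.path(td, "odd"))
  for (l in 0:4) {
    expect_equal(unname(slide_dims(sl, l)),
                 as.integer(ceiling(c(300, 200) / 2^l)))
  }

  res <- make_test_slide(td, "geo", width = 1024L, height = 1024L,
                         lesion_categories = character(0), n_levels = 6L)
  sl2 <- open_slide(res$slide_dir)
  expect_equal(sl2$n_levels, 6L)
  expect_equal(unname(slide_dims(sl2, 5L)), c(32L, 32L))
})

test_that("level-0 read of the full extent returns the stored base image", {
  td <- withr::local_tempdir()
  img <- round(array(stats::runif(64 * 48 * 3), c(48, 64, 3)) * 255) / 255
  write_slide_pyramid(img, file.path(td, "s"), n_levels = 3L)
  sl <- open_slide(file.path(td, "s"))
  expect_equal(read_region(sl, 0L, 0L, 0L, 64L, 48L), img,
               tolerance = 1e-12)
  # a sub-region matches the corresponding crop
  expect_equal(read_region(sl, 0L, 10L, 5L, 20L, 16L),
               img[6:21, 11:30, , drop = FALSE], tolerance = 1e-12)
})

test_that("unreadable and non-pyramidal inputs are errors", {
  td <- withr::local_tempdir()
  expect_error(open_slide(file.path(td, "missing")), "no such file")
  bad <- file.path(td, "bad.tiff")
  writeLines("not a tiff", bad)
  expect_error(open_slide(bad), "unreadable TIFF")
  # single-page TIFF is not a pyramid
  flat <- file.path(td, "flat.tiff")
  tiff::writeTIFF(array(0.5, c(16, 16, 3)), flat)
  expect_error(open_slide(flat), "non-pyramidal")
  # a directory without metadata is rejected
  dir.create(file.path(td, "plain"))
  expect_error(open_slide(file.path(td, "plain")), "slide.json")
})

test_that("multi-page TIFF slides open with consistent geometry", {
  td <- withr::local_tempdir()
  img <- round(array(stats::runif(128 * 128 * 3), c(128, 128, 3)) * 255) / 255
  path <- file.path(td, "pyr.tiff")
  write_slide_tiff(img, path, n_levels = 4L)
  sl <- open_slide(path)
  expect_equal(sl$n_levels, 4L)
  expect_equal(unname(slide_dims(sl, 3L)), c(16L, 16L))
  expect_equal(read_region(sl, 0L, 0L, 0L, 128L, 128L), img,
               tolerance = 1 / 254)
})

test_that("thumbnails have ceil(dims0 / 2^m) geometry and block-mean pixels", {
  td <- withr::local_tempdir()
  res <- make_test_slide(td, "t", width = 256L, height = 192L,
                         lesion_categories = "high_grade", n_levels = 4L)
  sl <- open_slide(res$slide_dir)
  base <- read_region(sl, 0L, 0L, 0L, 256L, 192L)
  expect_equal(dim(make_thumbnail(sl, 0L)), dim(base))  # identity at m = 0
  for (m in 1:3) {
    th <- make_thumbnail(sl, m)
    expect_equal(dim(th)[2:1], ceiling(c(256, 192) / 2^m))
    # pixel (i, j) summarizes the 2^m x 2^m level-0 block
    blk <- base[1:(2^m), 1:(2^m), , drop = FALSE]
    expect_equal(th[1, 1, ], apply(blk, 3, mean), tolerance = 2^m / 255)
  }
  expect_error(make_thumbnail(sl, 4L), "out of range")
  expect_error(read_region(sl, 0L, 250L, 0L, 10L, 10L), "outside")
})

test_that("annotation files round-trip and validate", {
  td <- withr::local_tempdir()
  ann <- make_annotations(list(
    square_polygon(10, 10, 50, "malignant"),
    square_polygon(80, 20, 30, "low_grade")
  ))
  p <- file.path(td, "a.json")
  write_annotations(ann, p)
  back <- load_annotations(p)
  expect_equal(back$slide_label, "malignant")
  expect_equal(length(back$polygons), 2L)
  expect_equal(back$polygons[[1]]$vertices, ann$polygons[[1]]$vertices)
  # write(load(p)) is content-identical
  p2 <- file.path(td, "b.json")
  write_annotations(back, p2)
  expect_identical(readLines(p), readLines(p2))
})

test_that("annotation categories normalize and malformed inputs error", {
  td <- withr::local_tempdir()
  # a CGIN polygon (upper-case, as annotation tools export it) is malignant
  jsonlite::write_json(list(
    slide_label = "Malignant", slide_sublabel = "CGIN",
    polygons = list(list(category = "Malignant", subcategory = "CGIN",
                         vertices = list(c(0, 0), c(10, 0), c(5, 10))))
  ), file.path(td, "cgin.json"), auto_unbox = TRUE)
  ann <- load_annotations(file.path(td, "cgin.json"))
  expect_equal(ann$slide_sublabel, "cgin")
  expect_equal(subcategory_parent("CGIN"), "malignant")

  # an empty polygon list is valid for a normal slide only
  jsonlite::write_json(list(slide_label = "normal",
                            slide_sublabel = "Normal/inflammation",
                            polygons = list()),
                       file.path(td, "n.json"), auto_unbox = TRUE)
  expect_equal(load_annotations(file.path(td, "n.json"))$slide_label,
               "normal")
  jsonlite::write_json(list(slide_label = "high grade",
                            slide_sublabel = "CIN 3", polygons = list()),
                       file.path(td, "hg.json"), auto_unbox = TRUE)
  expect_error(load_annotations(file.path(td, "hg.json")),
               "at least one polygon")

  # two-vertex polygons are malformed
  jsonlite::write_json(list(
    slide_label = "malignant", slide_sublabel = "cgin",
    polygons = list(list(category = "malignant", subcategory = "cgin",
                         vertices = list(c(0, 0), c(10, 10))))
  ), file.path(td, "2v.json"), auto_unbox = TRUE)
  expect_error(load_annotations(file.path(td, "2v.json")), "3 vertices")
})

test_that("manifests load, validate and normalize spellings", {
  td <- withr::local_tempdir()
  df <- data.frame(slide_id = c("a", "b", "c"), lab_id = c(1L, 5L, 8L),
                   category = c("Malignant", "High Grade",
                                "Normal/inflammation"),
                   subcategory = c("Squamous carcinoma", "CIN 2",
                                   "Normal/inflammation"),
                   image_path = "x", annotation_path = "y")
  p <- file.path(td, "m.csv")
  write_manifest(df, p)
  m <- load_manifest(p)
  expect_equal(nrow(m), 3L)
  expect_equal(m$subcategory[2], "cin2")
  expect_equal(m$category[2], "high_grade")

  dup <- rbind(df, df[1, ])
  expect_error(validate_manifest(dup), "duplicate slide_id")
  bad_lab <- df; bad_lab$lab_id[1] <- 9L
  expect_error(validate_manifest(bad_lab), "lab_id")
  mismatch <- df; mismatch$subcategory[1] <- "CIN 1"
  expect_error(validate_manifest(mismatch), "mismatch")
})
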