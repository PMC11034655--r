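test_that("grid cells map thumbnails to level-0 patch origins", {
  g <- grid_spec(256L, 5L)
  expect_equal(g$cell, 8L)  # 256-px patches are 8x8 thumbnail pixels

  # 16x16 thumbnail with 8-px cells: the 2x2 grid at origins {0, 256}^2
  p <- find_grid_patches(c(16L, 16L), g)
  expect_equal(nrow(p), 4L)
  expect_equal(p$x0, c(0L, 256L, 0L, 256L))
  expect_equal(p$y0, c(0L, 0L, 256L, 256L))
  # row-major from the top-left corner
  expect_equal(p$row, c(0L, 0L, 1L, 1L))

  # partial edge cells are dropped; sub-cell thumbnails give no patches
  expect_equal(nrow(find_grid_patches(c(7L, 7L), g)), 0L)
  expect_equal(nrow(find_grid_patches(c(23L, 16L), g)), 4L)

  expect_error(grid_spec(100L, 3L), "divisible")
})

test_that("grid coordinates round-trip between thumbnail and level 0", {
  set.seed(31)
  for (i in 1:20) {
    m <- sample(2:5, 1)
    P <- 2^m * sample(c(4L, 8L, 16L), 1)
    g <- grid_spec(P, m)
    dims <- sample(20:100, 2)
    p <- find_grid_patches(dims, g)
    if (nrow(p) == 0L) next
    expect_true(all(p$x0 %% P == 0L & p$y0 %% P == 0L))
    expect_equal(p$col, p$x0 %/% 2^m %/% g$cell)
    expect_equal(p$row, p$y0 %/% 2^m %/% g$cell)
  }
})

test_that("a patch is tissue iff at least one of its pixels is tissue", {
  g <- grid_spec(32L, 2L)  # 8x8 thumbnail cells
  thumb <- array(1, c(16, 16, 3))            # all white: two rows of cells
  thumb[3, 3, ] <- c(0.95, 0.55, 0.80)       # one pink pixel, cell (0, 0)
  thumb[, 9:16, 1] <- 0.7                    # right cells fully stained
  thumb[, 9:16, 2] <- 0.3
  thumb[, 9:16, 3] <- 0.6
  coords <- find_grid_patches(c(16L, 16L), g)
  flags <- detect_tissue(thumb, coords, g)
  # cell (0,0): single pink pixel -> tissue; (0,1)/(1,1): stained; (1,0): white
  expect_equal(flags, c(TRUE, TRUE, FALSE, TRUE))
})

test_that("patch labels take the most severe overlapping category", {
  g <- grid_spec(32L, 0L)  # level-0 grid so overlap geometry is exact
  coords <- find_grid_patches(c(64L, 64L), g)
  flags <- rep(TRUE, nrow(coords))

  # patch (0,0) fully high grade except one malignant pixel
  ann <- make_annotations(list(
    square_polygon(0, 0, 32, "high_grade"),
    square_polygon(10, 10, 1.5, "malignant"),
    # patch (0,1) overlaps both low and high grade polygons
    square_polygon(32, 0, 16, "low_grade"),
    square_polygon(50, 0, 10, "high_grade")
  ))
  recs <- label_patches(coords, flags, ann, g)
  lab <- matrix(recs$label, 2, 2, byrow = TRUE)
  expect_equal(lab[1, 1], "malignant")   # one malignant pixel dominates
  expect_equal(lab[1, 2], "high_grade")  # severity over low | high overlap
  expect_equal(lab[2, 1], "normal")      # tissue with no polygon overlap
  expect_equal(lab[2, 2], "normal")

  # non-tissue patches carry no label
  recs2 <- label_patches(coords, c(FALSE, TRUE, TRUE, TRUE), ann, g)
  expect_true(is.na(recs2$label[1]))
})

test_that("dilating a malignant polygon never lowers patch severity", {
  td <- withr::local_tempdir()
  res <- make_test_slide(td, "mono", width = 256L, height = 256L,
                         lesion_categories = c("malignant", "low_grade"),
                         seed = 13L)
  sl <- open_slide(res$slide_dir)
  g <- grid_spec(32L, 2L)
  base <- index_slide_patches(sl, res$annotations, g)
  dilated <- res$annotations
  for (i in seq_along(dilated$polygons)) {
    if (dilated$polygons[[i]]$category != "malignant") next
    v <- dilated$polygons[[i]]$vertices
    ctr <- colMeans(v)
    dilated$polygons[[i]]$vertices <-
      sweep(sweep(v, 2, ctr) * 1.3, 2, ctr, `+`)
  }
  after <- index_slide_patches(sl, dilated, g)
  tis <- base$is_tissue
  expect_true(all(category_severity(after$label[tis]) >=
                  category_severity(base$label[tis])))
})

test_that("thumbnail-grid labels agree with brute-force level-0 rasterization", {
  skip_if_not_installed("mgcv")
  td <- withr::local_tempdir()
  res <- make_test_slide(td, "oracle", width = 256L, height = 256L,
                         lesion_categories = c("malignant", "high_grade"),
                         seed = 23L)
  sl <- open_slide(res$slide_dir)
  g <- grid_spec(32L, 0L)
  thumb <- make_thumbnail(sl, 0L)
  coords <- find_grid_patches(c(dim(thumb)[2], dim(thumb)[1]), g)
  flags <- detect_tissue(thumb, coords, g)
  recs <- label_patches(coords, flags, res$annotations, g,
                        resolution = "level0")

  # oracle: per level-0 pixel point-in-polygon (independent implementation),
  # then max severity per patch
  sev_pix <- matrix(-1L, 256, 256)
  xs <- rep(seq_len(256) - 0.5, each = 256)
  ys <- rep(seq_len(256) - 0.5, times = 256)
  for (p in res$annotations$polygons) {
    bnd <- rbind(p$vertices, p$vertices[1, ])
    inside <- mgcv::in.out(bnd, cbind(xs, ys))
    s <- category_severity(p$category)
    m <- matrix(inside, 256, 256, byrow = TRUE)  # xs vary within a row block
    sev_pix[t(m)] <- pmax(sev_pix[t(m)], s)
  }
  for (i in seq_len(nrow(recs))) {
    if (!recs$is_tissue[i]) next
    rows <- (recs$y0[i] + 1):(recs$y0[i] + 32)
    cols <- (recs$x0[i] + 1):(recs$x0[i] + 32)
    m <- max(sev_pix[rows, cols])
    want <- if (m < 0L) "normal" else wsi_categories()[m + 1L]
    expect_equal(recs$label[i], want)
  }
})

test_that("patch sampling follows the balanced and imbalanced rules", {
  set.seed(2)
  tab <- data.frame(
    row = 0L, col = 0L, x0 = 0L, y0 = 0L, is_tissue = TRUE,
    label = rep(c("normal", "low_grade", "high_grade", "malignant"),
                c(100L, 10L, 20L, 50L))
  )
  bal <- sample_patches(tab, "balanced", seed = 1L)
  expect_equal(unname(table(bal$label)[wsi_categories()]),
               rep(10L, 4L), ignore_attr = TRUE)

  imb <- sample_patches(tab, "imbalanced", seed = 1L)
  counts <- table(factor(imb$label, levels = wsi_categories()))
  expect_equal(unname(c(counts)), c(50L, 10L, 20L, 50L))

  cap <- sample_patches(tab, "balanced", max_per_category = 5L, seed = 1L)
  expect_equal(unname(c(table(factor(cap$label,
                                     levels = wsi_categories())))),
               rep(5L, 4L))

  # deterministic given the seed
  expect_identical(sample_patches(tab, "imbalanced", seed = 7L),
                   sample_patches(tab, "imbalanced", seed = 7L))

  empty <- tab[tab$label != "low_grade", ]
  expect_error(sample_patches(empty, "balanced"), "empty")
})

test_that("patch export writes per-category folders idempotently", {
  td <- withr::local_tempdir()
  res <- make_test_slide(td, "exp", width = 128L, height = 128L,
                         lesion_categories = "malignant", seed = 3L)
  sl <- open_slide(res$slide_dir)
  g <- grid_spec(32L, 2L)
  recs <- index_slide_patches(sl, res$annotations, g)
  mal <- recs[recs$is_tissue & recs$label == "malignant", ][1:3, ]
  out <- file.path(td, "patches")
  paths <- export_patches(sl, mal, "exp", g, out)
  expect_equal(length(list.files(file.path(out, "malignant"))), 3L)
  md5_1 <- tools::md5sum(paths)
  paths2 <- export_patches(sl, mal, "exp", g, out)
  expect_identical(md5_1, tools::md5sum(paths2))

  oob <- mal[1, ]; oob$x0 <- 1000L
  expect_error(export_patches(sl, oob, "exp", g, out), "outside")

  ds <- load_patch_dataset(out)
  expect_equal(length(ds$images), 3L)
  expect_true(all(ds$labels == "malignant"))
  expect_equal(dim(ds$images[[1]]), c(32L, 32L, 3L))
})
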