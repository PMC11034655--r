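#' Assemble per-category probability heatmaps
#'
#' One grid per category on the patch grid: cell (r, c) of grid k holds
#' the probability of category k for the patch at grid position (r, c).
#' Non-tissue cells are zero in all four grids and excluded from the
#' tissue area.
#'
#' @param probs patch probabilities from [infer_patches()] (tissue
#'   patches only).
#' @param n_rows,n_cols patch grid dimensions.
#' @return a `category_heatmaps` object: list of four matrices (`normal`,
#'   `low_grade`, `high_grade`, `malignant`), a logical `tissue_mask`,
#'   and `tissue_area`.
#' @export
build_heatmaps <- function(probs, n_rows, n_cols) {
  idx <- probs$row * n_cols + probs$col
  if (anyDuplicated(idx)) stop("duplicate grid cell assignment")
  if (nrow(probs) &&
      (max(probs$row) >= n_rows || max(probs$col) >= n_cols)) {
    stop("patch outside the declared grid")
  }
  grids <- lapply(wsi_categories(), function(cat) {
    g <- matrix(0, n_rows, n_cols)
    g[cbind(probs$row + 1L, probs$col + 1L)] <- probs[[paste0("p_", cat)]]
    g
  })
  names(grids) <- wsi_categories()
  mask <- matrix(FALSE, n_rows, n_cols)
  mask[cbind(probs$row + 1L, probs$col + 1L)] <- TRUE
  structure(list(grids = grids, tissue_mask = mask,
                 tissue_area = sum(mask)),
            class = "category_heatmaps")
}

#' @export
print.category_heatmaps <- function(x, ...) {
  cat(sprintf("<category_heatmaps> %d x %d grid, tissue area %d\n",
              nrow(x$tissue_mask), ncol(x$tissue_mask), x$tissue_area))
  invisible(x)
}

#' Threshold a probability grid
#'
#' Cells with value `>= t` are set, matching the inclusive convention
#' used when rendering probability maps at 0.5.
#'
#' @param grid numeric probability matrix.
#' @param t threshold in (0, 1).
#' @return logical matrix.
#' @export
threshold_heatmap <- function(grid, t) {
  stopifnot(t > 0, t < 1)
  grid >= t
}

#' Per-cell category prediction map
#'
#' For every tissue cell: the argmax category if its probability reaches
#' `t`, otherwise unclassified; probability ties break towards the more
#' severe category. Rendered with a fixed palette (normal grey,
#' low grade green, high grade blue, malignant red, unclassified/
#' background white).
#'
#' @param h a `category_heatmaps`.
#' @param t classification threshold.
#' @return list with `categories` (character matrix, `NA` off tissue,
#'   `"unclassified"` below threshold) and `image` (H x W x 3 RGB
#'   array).
#' @export
prediction_map <- function(h, t = 0.5) {
  dims <- dim(h$tissue_mask)
  cats <- matrix(NA_character_, dims[1], dims[2])
  p <- vapply(h$grids, identity, h$grids[[1]])  # rows x cols x 4
  for (r in seq_len(dims[1])) {
    for (cc in seq_len(dims[2])) {
      if (!h$tissue_mask[r, cc]) next
      v <- p[r, cc, ]
      m <- max(v)
      if (m < t) { cats[r, cc] <- "unclassified"; next }
      # which.max on the reversed severity order keeps the most severe tie
      winners <- which(v == m)
      cats[r, cc] <- wsi_categories()[max(winners)]
    }
  }
  palette <- rbind(normal = c(0.6, 0.6, 0.6), low_grade = c(0, 0.7, 0),
                   high_grade = c(0, 0, 0.9), malignant = c(0.9, 0, 0),
                   unclassified = c(1, 1, 1))
  img <- array(1, c(dims, 3L))
  for (k in rownames(palette)) {
    sel <- which(cats == k)
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[sel] <- palette[k, ch]
      img[, , ch] <- plane
    }
  }
  list(categories = cats, image = img)
}

#' Export heatmaps as PNG images with a JSON sidecar
#'
#' Writes one greyscale PNG per category, the combined prediction map,
#' and a sidecar JSON recording grid dimensions, patch size and mag
#' level.
#'
#' @param h a `category_heatmaps`.
#' @param grid the [grid_spec()] the heatmaps were built on.
#' @param out_dir output directory.
#' @param prefix filename prefix (e.g. slide id).
#' @return invisibly, the sidecar path.
#' @export
export_heatmaps <- function(h, grid, out_dir, prefix) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (cat in wsi_categories()) {
    png::writePNG(h$grids[[cat]],
                  file.path(out_dir, sprintf("%s_%s.png", prefix, cat)))
  }
  pm <- prediction_map(h)
  png::writePNG(pm$image,
                file.path(out_dir, sprintf("%s_prediction.png", prefix)))
  sidecar <- file.path(out_dir, sprintf("%s_heatmaps.json", prefix))
  jsonlite::write_json(
    list(n_rows = nrow(h$tissue_mask), n_cols = ncol(h$tissue_mask),
         tissue_area = h$tissue_area, patch_size = grid$patch_size,
         mag_level = grid$mag_level),
    sidecar, auto_unbox = TRUE)
  invisible(sidecar)
}
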