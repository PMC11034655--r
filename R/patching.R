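#' Patch grid specification
#'
#' Patches are square level-0 tiles of side `patch_size` laid out on a
#' regular non-overlapping grid. The grid is found on the thumbnail at
#' `mag_level`: each grid cell is `cell = patch_size / 2^mag_level`
#' thumbnail pixels on a side (e.g. 256-pixel patches at mag level 5 give
#' 8x8-pixel thumbnail cells), and thumbnail coordinates are multiplied
#' by `2^mag_level` to map back to level 0.
#'
#' @param patch_size patch side length in level-0 pixels.
#' @param mag_level thumbnail pyramid level; must divide `patch_size` as
#'   a power of two.
#' @return a `grid_spec` list with `patch_size`, `mag_level`, `cell`.
#' @export
grid_spec <- function(patch_size = 256L, mag_level = 5L) {
  scale <- 2L^mag_level
  if (patch_size %% scale != 0L) {
    stop("patch_size must be divisible by 2^mag_level")
  }
  cell <- patch_size %/% scale
  if (cell < 1L) stop("cell size below 1 thumbnail pixel")
  structure(list(patch_size = as.integer(patch_size),
                 mag_level = as.integer(mag_level),
                 cell = as.integer(cell)),
            class = "grid_spec")
}

#' Find grid patches on a thumbnail
#'
#' Walks the thumbnail row-major from the top-left corner in
#' non-overlapping cells of `grid$cell` thumbnail pixels; partial cells
#' at the right/bottom edges are dropped. Level-0 origins are the
#' thumbnail cell origins multiplied by `2^mag_level`, i.e.
#' `x0 = col * patch_size`, `y0 = row * patch_size` (0-based rows/cols).
#'
#' @param thumbnail_dims integer `c(width, height)` of the thumbnail.
#' @param grid a [grid_spec()].
#' @return data.frame with columns `row`, `col` (0-based grid indices)
#'   and `x0`, `y0` (level-0 top-left corners); empty if the thumbnail is
#'   smaller than one cell.
#' @export
find_grid_patches <- function(thumbnail_dims, grid) {
  n_cols <- thumbnail_dims[1] %/% grid$cell
  n_rows <- thumbnail_dims[2] %/% grid$cell
  if (n_cols < 1L || n_rows < 1L) {
    return(data.frame(row = integer(0), col = integer(0),
                      x0 = integer(0), y0 = integer(0)))
  }
  g <- expand.grid(col = seq_len(n_cols) - 1L, row = seq_len(n_rows) - 1L)
  g <- g[order(g$row, g$col), ]  # row-major from (0, 0)
  data.frame(row = g$row, col = g$col,
             x0 = g$col * grid$patch_size, y0 = g$row * grid$patch_size)
}

#' Tissue detection parameters
#'
#' A thumbnail pixel counts as tissue when it is either darker than
#' `luminance_max` times full white (mean over RGB) or more saturated
#' than `saturation_min` (HSV saturation, `(max - min) / max`). H&E
#' background is near-white and unsaturated, stained tissue is pink to
#' purple; the defaults are conservative so faint tissue is kept.
#'
#' @param luminance_max luminance threshold as a fraction of white.
#' @param saturation_min minimum saturation counting as tissue.
#' @return a `tissue_params` list.
#' @export
tissue_params <- function(luminance_max = 0.88, saturation_min = 0.07) {
  stopifnot(luminance_max > 0, luminance_max < 1,
            saturation_min > 0, saturation_min < 1)
  structure(list(luminance_max = luminance_max,
                 saturation_min = saturation_min),
            class = "tissue_params")
}

# per-pixel tissue test on an H x W x 3 thumbnail -> logical matrix
tissue_pixel_mask <- function(thumbnail, params) {
  lum <- (thumbnail[, , 1] + thumbnail[, , 2] + thumbnail[, , 3]) / 3
  mx <- pmax(thumbnail[, , 1], thumbnail[, , 2], thumbnail[, , 3])
  mn <- pmin(thumbnail[, , 1], thumbnail[, , 2], thumbnail[, , 3])
  sat <- ifelse(mx > 0, (mx - mn) / mx, 0)
  lum < params$luminance_max | sat > params$saturation_min
}

#' Detect tissue patches on a thumbnail
#'
#' A patch is tissue if at least one of its thumbnail pixels passes the
#' tissue pixel test — deliberately conservative so patches containing
#' only a sliver of tissue are kept.
#'
#' @param thumbnail RGB thumbnail array.
#' @param coords patch coordinates from [find_grid_patches()] on this
#'   thumbnail.
#' @param grid the [grid_spec()] used.
#' @param params a [tissue_params()].
#' @return logical vector aligned with `coords` rows.
#' @export
detect_tissue <- function(thumbnail, coords, grid,
                          params = tissue_params()) {
  mask <- tissue_pixel_mask(thumbnail, params)
  c_sz <- grid$cell
  vapply(seq_len(nrow(coords)), function(i) {
    r0 <- coords$row[i] * c_sz
    c0 <- coords$col[i] * c_sz
    any(mask[(r0 + 1L):(r0 + c_sz), (c0 + 1L):(c0 + c_sz)])
  }, logical(1))
}

# category id (0..3 severity, -1 none) per thumbnail pixel of the grid
# area, from polygon annotations; `scale` maps thumbnail px -> level 0
rasterize_annotation_severity <- function(annotations, n_rows, n_cols,
                                          cell, scale) {
  sev <- matrix(-1L, n_rows * cell, n_cols * cell)
  if (length(annotations$polygons) == 0L) return(sev)
  h <- nrow(sev); w <- ncol(sev)
  xs <- (rep(seq_len(w), each = 1L) - 0.5) * scale
  ys <- (seq_len(h) - 0.5) * scale
  grid_x <- matrix(rep(xs, each = h), h, w)
  grid_y <- matrix(rep(ys, times = w), h, w)
  for (p in annotations$polygons) {
    s <- category_severity(p$category)
    # restrict the point-in-polygon test to the polygon bounding box
    bx <- range(p$vertices[, 1]); by <- range(p$vertices[, 2])
    sel <- which(grid_x >= bx[1] - scale & grid_x <= bx[2] + scale &
                 grid_y >= by[1] - scale & grid_y <= by[2] + scale)
    if (length(sel) == 0L) next
    inside <- points_in_polygon(grid_x[sel], grid_y[sel],
                                p$vertices[, 1], p$vertices[, 2])
    hit <- sel[inside]
    sev[hit] <- pmax(sev[hit], s)
  }
  sev
}

#' Label tissue patches by maximal annotation severity
#'
#' Each tissue patch receives the most severe category over all
#' annotation polygons that intersect it — one malignant pixel makes the
#' whole patch malignant. Patches touching no polygon are normal;
#' non-tissue patches carry `NA`.
#'
#' Overlap is evaluated at thumbnail resolution by default (`cell x
#' cell` sample points per patch, matching the granularity at which the
#' grid is defined); `resolution = "level0"` tests every level-0 pixel
#' center instead, which is exact but slower.
#'
#' @param coords patch coordinates from [find_grid_patches()].
#' @param tissue_flags logical vector from [detect_tissue()].
#' @param annotations an `annotation_set` with level-0 polygon
#'   coordinates.
#' @param grid the [grid_spec()] used.
#' @param resolution `"thumbnail"` (default) or `"level0"`.
#' @return data.frame of patch records: `row`, `col`, `x0`, `y0`,
#'   `is_tissue`, `label`.
#' @export
label_patches <- function(coords, tissue_flags, annotations, grid,
                          resolution = c("thumbnail", "level0")) {
  resolution <- match.arg(resolution)
  n_rows <- if (nrow(coords)) max(coords$row) + 1L else 0L
  n_cols <- if (nrow(coords)) max(coords$col) + 1L else 0L
  if (resolution == "thumbnail") {
    cell <- grid$cell; scale <- 2^grid$mag_level
  } else {
    cell <- grid$patch_size; scale <- 1
  }
  sev <- rasterize_annotation_severity(annotations, n_rows, n_cols,
                                       cell, scale)
  labels <- rep(NA_character_, nrow(coords))
  for (i in seq_len(nrow(coords))) {
    if (!tissue_flags[i]) next
    r0 <- coords$row[i] * cell
    c0 <- coords$col[i] * cell
    block <- sev[(r0 + 1L):(r0 + cell), (c0 + 1L):(c0 + cell)]
    m <- max(block)
    labels[i] <- if (m < 0L) "normal" else wsi_categories()[m + 1L]
  }
  data.frame(coords, is_tissue = tissue_flags, label = labels,
             stringsAsFactors = FALSE)
}

#' Index all patches of a slide
#'
#' Convenience wrapper running [find_grid_patches()], [detect_tissue()]
#' and [label_patches()] on one slide.
#'
#' @param slide a `slide_pyramid`.
#' @param annotations an `annotation_set` (or `NULL` for an unannotated
#'   slide: all tissue patches are labelled normal).
#' @param grid a [grid_spec()].
#' @param params a [tissue_params()].
#' @inheritParams label_patches
#' @return patch record data.frame as from [label_patches()].
#' @export
index_slide_patches <- function(slide, annotations, grid,
                                params = tissue_params(),
                                resolution = "thumbnail") {
  thumb <- make_thumbnail(slide, grid$mag_level)
  dims <- c(dim(thumb)[2], dim(thumb)[1])
  coords <- find_grid_patches(dims, grid)
  if (nrow(coords) == 0L) {
    return(data.frame(coords, is_tissue = logical(0),
                      label = character(0)))
  }
  flags <- detect_tissue(thumb, coords, grid, params)
  if (is.null(annotations)) {
    annotations <- structure(list(slide_label = "normal",
                                  slide_sublabel = "normal_inflammation",
                                  polygons = list()),
                             class = "annotation_set")
  }
  label_patches(coords, flags, annotations, grid, resolution)
}

#' Sample patches for training
#'
#' Operates on the pooled patch table of a whole split. Two modes:
#'
#' * `balanced`: equal counts per category, the minimum category count
#'   (capped at `max_per_category`); errors if a category is empty.
#' * `imbalanced`: keeps every malignant patch, randomly downsamples
#'   normal patches to the malignant count, and keeps all low-grade and
#'   high-grade patches — the sampling used to tune training towards
#'   malignant sensitivity.
#'
#' `max_per_category`, when finite, caps every category in both modes.
#' Sampling is deterministic given `seed`.
#'
#' @param patch_table pooled data.frame of tissue patch records with a
#'   `label` column.
#' @param mode `"balanced"` or `"imbalanced"`.
#' @param max_per_category cap per category (default unlimited).
#' @param seed integer seed.
#' @return sampled subset of `patch_table`.
#' @export
sample_patches <- function(patch_table, mode = c("balanced", "imbalanced"),
                           max_per_category = Inf, seed = 1L) {
  mode <- match.arg(mode)
  patch_table <- patch_table[patch_table$is_tissue, , drop = FALSE]
  counts <- table(factor(patch_table$label, levels = wsi_categories()))
  set.seed(seed)
  if (mode == "balanced") {
    if (any(counts == 0L)) {
      stop("balanced sampling requires patches in every category; empty: ",
           paste(names(counts)[counts == 0L], collapse = ", "))
    }
    target <- setNames(rep(min(min(counts), max_per_category), 4L),
                       wsi_categories())
  } else {
    n_mal <- counts[["malignant"]]
    target <- c(normal = min(counts[["normal"]], n_mal),
                low_grade = counts[["low_grade"]],
                high_grade = counts[["high_grade"]],
                malignant = n_mal)
    target <- pmin(target, max_per_category)
  }
  keep <- unlist(lapply(wsi_categories(), function(cat) {
    idx <- which(patch_table$label == cat)
    k <- min(length(idx), target[[cat]])
    if (k < length(idx)) sort(sample(idx, k)) else idx
  }))
  patch_table[sort(keep), , drop = FALSE]
}

#' Export sampled patches as PNG files
#'
#' Reads each sampled patch at level 0 and writes it under
#' `out_dir/<category>/`, the folder layout consumed by
#' [load_patch_dataset()]. Filenames encode slide id, level-0 origin and
#' patch size, so re-export overwrites byte-identical files.
#'
#' @param slide a `slide_pyramid`.
#' @param records patch records of this slide (tissue, labelled).
#' @param slide_id slide identifier used in filenames.
#' @param grid the [grid_spec()] used for indexing.
#' @param out_dir dataset root directory.
#' @return character vector of written paths, invisibly.
#' @export
export_patches <- function(slide, records, slide_id, grid, out_dir) {
  p_sz <- grid$patch_size
  paths <- character(nrow(records))
  for (i in seq_len(nrow(records))) {
    rec <- records[i, ]
    img <- read_region(slide, 0L, rec$x0, rec$y0, p_sz, p_sz)
    dir.create(file.path(out_dir, rec$label), recursive = TRUE,
               showWarnings = FALSE)
    paths[i] <- file.path(out_dir, rec$label,
                          sprintf("%s_x%d_y%d_p%d.png",
                                  slide_id, rec$x0, rec$y0, p_sz))
    png::writePNG(img, paths[i])
  }
  invisible(paths)
}
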