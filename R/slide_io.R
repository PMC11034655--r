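#' Open a pyramidal whole-slide image
#'
#' Whole-slide images are stored as multi-resolution pyramids: level 0 is
#' the full-resolution scan (0.25 microns/pixel by convention) and every
#' higher level halves both dimensions, so a pixel at level L covers a
#' \eqn{2^L \times 2^L} block of level-0 pixels. Two on-disk layouts are
#' supported:
#'
#' * a pyramidal (multi-page) TIFF whose pages are the levels, and
#' * a directory with one PNG per level plus a `slide.json` metadata file
#'   (the layout written by [generate_slide()]).
#'
#' @param path path to a `.tif`/`.tiff` file or a slide directory.
#' @return an object of class `slide_pyramid` with fields `level0_width`,
#'   `level0_height`, `n_levels`, `mpp_level0` and a per-level dimension
#'   table. Level images are read lazily and cached.
#' @seealso [read_region()], [make_thumbnail()]
#' @export
open_slide <- function(path) {
  if (dir.exists(path)) {
    meta_path <- file.path(path, "slide.json")
    if (!file.exists(meta_path)) {
      stop("not a slide directory (missing slide.json): ", path)
    }
    meta <- jsonlite::fromJSON(meta_path, simplifyVector = TRUE)
    level_files <- file.path(path, meta$levels$file)
    if (!all(file.exists(level_files))) {
      stop("slide directory is missing level images: ", path)
    }
    slide <- list(
      path = path, format = "directory",
      level0_width = as.integer(meta$width),
      level0_height = as.integer(meta$height),
      n_levels = as.integer(meta$n_levels),
      mpp_level0 = as.numeric(meta$mpp %||% 0.25),
      level_dims = cbind(width = as.integer(meta$levels$width),
                         height = as.integer(meta$levels$height)),
      level_files = level_files,
      cache = new.env(parent = emptyenv())
    )
  } else if (file.exists(path)) {
    if (!grepl("\\.tiff?$", path, ignore.case = TRUE)) {
      stop("unsupported slide format: ", path)
    }
    pages <- tryCatch(tiff::readTIFF(path, all = TRUE),
                      error = function(e) stop("unreadable TIFF: ", path,
                                               " (", conditionMessage(e), ")"))
    if (!is.list(pages)) pages <- list(pages)
    if (length(pages) < 2L) stop("non-pyramidal TIFF (single page): ", path)
    dims <- t(vapply(pages, function(p) dim(p)[2:1], integer(2)))
    colnames(dims) <- c("width", "height")
    slide <- list(
      path = path, format = "tiff",
      level0_width = dims[1L, "width"], level0_height = dims[1L, "height"],
      n_levels = length(pages), mpp_level0 = 0.25,
      level_dims = dims, level_files = NULL,
      cache = new.env(parent = emptyenv())
    )
    for (l in seq_along(pages)) {
      img <- pages[[l]]
      if (length(dim(img)) == 2L) img <- array(rep(img, 3), c(dim(img), 3))
      assign(sprintf("level_%d", l - 1L), img[, , 1:3, drop = FALSE],
             envir = slide$cache)
    }
  } else {
    stop("no such file or directory: ", path)
  }
  class(slide) <- "slide_pyramid"
  validate_slide_geometry(slide)
  slide
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# each level's dims must equal ceiling(level-0 dims / 2^L)
validate_slide_geometry <- function(slide) {
  lv <- seq_len(slide$n_levels) - 1L
  exp_w <- as.integer(ceiling(slide$level0_width / 2^lv))
  exp_h <- as.integer(ceiling(slide$level0_height / 2^lv))
  if (!all(slide$level_dims[, "width"] == exp_w) ||
      !all(slide$level_dims[, "height"] == exp_h)) {
    stop("inconsistent pyramid geometry in ", slide$path,
         ": level dims must be ceiling(level0 / 2^L)")
  }
  invisible(slide)
}

#' @export
print.slide_pyramid <- function(x, ...) {
  cat(sprintf("<slide_pyramid> %dx%d px, %d levels, %.2f mpp [%s]\n",
              x$level0_width, x$level0_height, x$n_levels, x$mpp_level0,
              x$format))
  invisible(x)
}

#' Slide level dimensions
#'
#' @param slide a `slide_pyramid`.
#' @param level pyramid level (0-based).
#' @return integer `c(width, height)` of the level image.
#' @export
slide_dims <- function(slide, level = 0L) {
  stopifnot(inherits(slide, "slide_pyramid"))
  if (level < 0L || level >= slide$n_levels) {
    stop("level ", level, " out of range [0, ", slide$n_levels - 1L, "]")
  }
  slide$level_dims[level + 1L, ]
}

# fetch a whole level image as H x W x 3 array in [0,1], cached
get_level_image <- function(slide, level) {
  key <- sprintf("level_%d", level)
  if (!exists(key, envir = slide$cache, inherits = FALSE)) {
    img <- png::readPNG(slide$level_files[level + 1L])
    if (length(dim(img)) == 2L) img <- array(rep(img, 3), c(dim(img), 3))
    assign(key, img[, , 1:3, drop = FALSE], envir = slide$cache)
  }
  get(key, envir = slide$cache, inherits = FALSE)
}

#' Read a rectangular region from a slide level
#'
#' Coordinates are 0-based with `x` = column and `y` = row, expressed in
#' the pixel grid of the requested level, and the region is the half-open
#' rectangle `[x, x+width) x [y, y+height)`. Reads that extend outside the
#' level bounds are errors.
#'
#' @param slide a `slide_pyramid`.
#' @param level pyramid level (0-based).
#' @param x,y top-left corner in level pixels.
#' @param width,height region size in level pixels.
#' @return `height x width x 3` RGB array with values in `[0, 1]`.
#' @export
read_region <- function(slide, level, x, y, width, height) {
  dims <- slide_dims(slide, level)
  if (width < 1L || height < 1L) stop("region size must be positive")
  if (x < 0L || y < 0L || x + width > dims["width"] ||
      y + height > dims["height"]) {
    stop(sprintf("region [%d,%d)+[%dx%d] outside level %d bounds %dx%d",
                 x, y, width, height, level, dims["width"], dims["height"]))
  }
  img <- get_level_image(slide, level)
  img[(y + 1L):(y + height), (x + 1L):(x + width), , drop = FALSE]
}

#' Thumbnail of a slide at a magnification level
#'
#' The thumbnail at `mag_level` m has dimensions `ceiling(dims0 / 2^m)`;
#' pixel (i, j) summarizes the \eqn{2^m \times 2^m} level-0 block with
#' top-left corner `(j * 2^m, i * 2^m)`. The stored pyramid level is
#' returned directly, which by construction holds the block means.
#'
#' @param slide a `slide_pyramid`.
#' @param mag_level pyramid level to read (must be `< n_levels`).
#' @return RGB array of the thumbnail.
#' @export
make_thumbnail <- function(slide, mag_level) {
  if (mag_level < 0L || mag_level >= slide$n_levels) {
    stop("mag_level ", mag_level, " out of range [0, ",
         slide$n_levels - 1L, "]")
  }
  get_level_image(slide, mag_level)
}

#' Write a slide pyramid to disk
#'
#' Builds all pyramid levels from a level-0 RGB image by successive 2x
#' mean-pooling (odd dimensions padded by edge replication, so level dims
#' are `ceiling(dims0 / 2^L)`) and writes the directory layout that
#' [open_slide()] reads: one PNG per level plus `slide.json`.
#'
#' @param base_image level-0 `H x W x 3` array in `[0, 1]`.
#' @param out_dir output directory (created if needed).
#' @param n_levels number of pyramid levels to write (including level 0).
#' @param mpp microns per pixel at level 0.
#' @return `out_dir`, invisibly.
#' @export
write_slide_pyramid <- function(base_image, out_dir, n_levels, mpp = 0.25) {
  stopifnot(length(dim(base_image)) == 3L, dim(base_image)[3] == 3L,
            n_levels >= 1L)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  levels <- vector("list", n_levels)
  img <- base_image
  for (l in seq_len(n_levels)) {
    file <- sprintf("level_%d.png", l - 1L)
    png::writePNG(img, file.path(out_dir, file))
    levels[[l]] <- list(level = l - 1L, width = dim(img)[2],
                        height = dim(img)[1], file = file)
    if (l < n_levels) img <- pool2(img)
  }
  meta <- list(
    width = dim(base_image)[2], height = dim(base_image)[1],
    n_levels = n_levels, mpp = mpp,
    levels = do.call(rbind, lapply(levels, as.data.frame))
  )
  jsonlite::write_json(meta, file.path(out_dir, "slide.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' @rdname write_slide_pyramid
#' @param path output `.tiff` path for the multi-page variant.
#' @export
write_slide_tiff <- function(base_image, path, n_levels) {
  pages <- vector("list", n_levels)
  img <- base_image
  for (l in seq_len(n_levels)) {
    pages[[l]] <- img
    if (l < n_levels) img <- pool2(img)
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  invisible(path)
}
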