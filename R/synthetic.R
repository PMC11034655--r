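#' Category texture models for synthetic slides
#'
#' Synthetic slides emulate the gross statistical structure of H&E
#' histology that the pipeline relies on: a near-white background,
#' textured tissue, and lesion regions whose colour and simulated nuclear
#' density differ by diagnostic category. Each category has a base RGB
#' colour, a density of dark "nuclei" spots (per squared pixel), a spot
#' radius and per-channel Gaussian noise. The four (base colour, spot
#' density) tuples are pairwise well separated — the green-channel means
#' are spaced by more than 0.1 — so a shallow classifier can separate
#' pure-texture patches and end-to-end tests probe the pipeline rather
#' than the texture model.
#'
#' @return named list of per-category texture parameter lists.
#' @export
texture_models <- function() {
  list(
    normal = list(base = c(0.91, 0.73, 0.85), spot_density = 0.002,
                  spot_radius = 2, noise_sd = 0.03),
    low_grade = list(base = c(0.82, 0.58, 0.78), spot_density = 0.004,
                     spot_radius = 2, noise_sd = 0.03),
    high_grade = list(base = c(0.70, 0.42, 0.68), spot_density = 0.008,
                      spot_radius = 2, noise_sd = 0.03),
    malignant = list(base = c(0.55, 0.28, 0.55), spot_density = 0.014,
                     spot_radius = 2, noise_sd = 0.03)
  )
}

# deterministic per-lab RGB stain offsets (emulates eight section
# thickness x staining protocol combinations); small so background and
# class separability are preserved
lab_stain_offsets <- function() {
  labs <- 1:8
  cbind(r = 0.015 * cos(labs * pi / 4),
        g = 0.010 * sin(labs * pi / 4),
        b = 0.015 * cos(labs * pi / 4 + pi / 3))
}

# paint texture onto img at the pixel indices in `idx` (single-channel
# linear indices into an h x w plane); draws from the current RNG stream
paint_texture <- function(img, idx, tex) {
  h <- dim(img)[1]; w <- dim(img)[2]
  n <- length(idx)
  if (n == 0L) return(img)
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[idx] <- clamp01(tex$base[ch] + stats::rnorm(n, 0, tex$noise_sd))
    img[, , ch] <- plane
  }
  # nuclei: dark spots at random positions inside the region
  n_spots <- stats::rpois(1, tex$spot_density * n)
  if (n_spots > 0L) {
    centers <- idx[sample.int(n, n_spots, replace = TRUE)]
    cy <- (centers - 1L) %% h + 1L
    cx <- (centers - 1L) %/% h + 1L
    r <- tex$spot_radius
    offs <- expand.grid(dy = -r:r, dx = -r:r)
    offs <- offs[offs$dy^2 + offs$dx^2 <= r^2, ]
    py <- rep(cy, each = nrow(offs)) + rep(offs$dy, n_spots)
    px <- rep(cx, each = nrow(offs)) + rep(offs$dx, n_spots)
    ok <- py >= 1L & py <= h & px >= 1L & px <= w
    spot_idx <- (px[ok] - 1L) * h + py[ok]
    dark <- tex$base * 0.45
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[spot_idx] <- dark[ch]
      img[, , ch] <- plane
    }
  }
  img
}

# star-shaped polygon around a center, vertex radii in [0.75, 1.2] * radius
random_lesion_polygon <- function(center, radius, n_vertices = 10L) {
  ang <- sort(stats::runif(n_vertices, 0, 2 * pi))
  rad <- radius * stats::runif(n_vertices, 0.75, 1.2)
  cbind(center[1] + rad * cos(ang), center[2] + rad * sin(ang))
}

# linear indices (h-major) of pixels whose centers fall inside the polygon
rasterize_polygon <- function(vertices, width, height) {
  xs <- floor(min(vertices[, 1])):ceiling(max(vertices[, 1]))
  ys <- floor(min(vertices[, 2])):ceiling(max(vertices[, 2]))
  xs <- xs[xs >= 0L & xs < width]
  ys <- ys[ys >= 0L & ys < height]
  if (length(xs) == 0L || length(ys) == 0L) return(integer(0))
  grid <- expand.grid(x = xs, y = ys)
  inside <- points_in_polygon(grid$x + 0.5, grid$y + 0.5,
                              vertices[, 1], vertices[, 2])
  (grid$x[inside]) * height + grid$y[inside] + 1L
}

#' Generate one synthetic slide with matching annotations
#'
#' Writes a full slide pyramid (directory-of-PNGs layout, readable by
#' [open_slide()]) and an annotation JSON. The slide has a near-white
#' background (all channels >= 0.92), tissue blobs painted with the
#' normal texture, and one polygonal lesion per entry of `lesions`,
#' painted with that category's texture. Annotation polygons are the
#' exact polygons that were rasterized, so labels are correct by
#' construction. The same `spec` and seed produce byte-identical files.
#'
#' @param spec list with fields `slide_id`, `width`, `height`, `seed`,
#'   `lab_id` (1..8), `lesions` (list of lists with `category`,
#'   optionally `subcategory`, and either `center`+`radius` or explicit
#'   `vertices`), and optionally `n_levels`, `subcategory` (slide
#'   sublabel), `annotation_jitter` (scale factor applied to polygon
#'   radii about their centroid, emulating imprecise manual annotation;
#'   default 1 = exact).
#' @param out_dir directory in which `slide_id/` and
#'   `slide_id_annotations.json` are written.
#' @return list with `slide_dir`, `annotation_path`, `slide_label`,
#'   `slide_sublabel` and the `annotation_set`.
#' @export
generate_slide <- function(spec, out_dir) {
  w <- as.integer(spec$width); h <- as.integer(spec$height)
  set.seed(spec$seed)
  n_levels <- spec$n_levels %||%
    (floor(log2(min(w, h) / 16)) + 1L)
  tex <- texture_models()

  # background: near-white with faint scanner noise
  img <- array(clamp01(0.97 + stats::rnorm(h * w * 3, 0, 0.008)), c(h, w, 3))
  img <- pmax(img, 0.94)

  # tissue support: one central blob plus satellites, plus a disc around
  # each lesion so lesions always lie inside tissue
  blob_centers <- list(c(w / 2 + stats::runif(1, -w / 12, w / 12),
                         h / 2 + stats::runif(1, -h / 12, h / 12)))
  blob_radii <- min(w, h) * 0.36
  for (k in 1:2) {
    blob_centers[[k + 1L]] <- c(stats::runif(1, w * 0.3, w * 0.7),
                                stats::runif(1, h * 0.3, h * 0.7))
    blob_radii <- c(blob_radii, min(w, h) * stats::runif(1, 0.12, 0.2))
  }
  lesions <- spec$lesions %||% list()
  lesion_polys <- vector("list", length(lesions))
  for (i in seq_along(lesions)) {
    les <- lesions[[i]]
    if (!is.null(les$vertices)) {
      # explicit polygons are taken as-is and validated against tissue below
      lesion_polys[[i]] <- les$vertices
    } else {
      rmax <- min(w, h) * 0.28
      radius <- min(les$radius, rmax)
      margin <- radius * 1.3
      center <- c(stats::runif(1, margin, w - margin),
                  stats::runif(1, margin, h - margin))
      lesion_polys[[i]] <- random_lesion_polygon(center, radius)
      # grow tissue under generated lesions so they lie inside it
      ctr <- colMeans(lesion_polys[[i]])
      rad <- max(sqrt(rowSums(sweep(lesion_polys[[i]], 2, ctr)^2)))
      blob_centers <- c(blob_centers, list(ctr))
      blob_radii <- c(blob_radii, rad * 1.15)
    }
  }

  tissue <- matrix(FALSE, h, w)
  xs <- matrix(rep(seq_len(w) - 0.5, each = h), h, w)
  ys <- matrix(rep(seq_len(h) - 0.5, times = w), h, w)
  for (k in seq_along(blob_centers)) {
    ctr <- blob_centers[[k]]
    tissue <- tissue |
      ((xs - ctr[1])^2 + (ys - ctr[2])^2 <= blob_radii[k]^2)
  }
  tissue_idx <- which(tissue)
  img <- paint_texture(img, tissue_idx, tex$normal)

  # lesions painted over the normal tissue, exactly on their polygons;
  # painting runs in ascending severity so that where polygons overlap
  # the most severe category owns the pixels, matching the max-severity
  # labelling rule
  categories <- vapply(lesions, function(l) normalize_category(l$category),
                       character(1))
  for (i in order(category_severity(categories))) {
    idx <- rasterize_polygon(lesion_polys[[i]], w, h)
    if (length(idx) == 0L || !all(tissue[idx])) {
      stop("lesion polygon outside tissue for slide ", spec$slide_id)
    }
    img <- paint_texture(img, idx, tex[[categories[i]]])
  }

  # per-lab stain shift on tissue pixels only (background stays white)
  if (!is.null(spec$lab_id)) {
    off <- lab_stain_offsets()[spec$lab_id, ]
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[tissue_idx] <- clamp01(plane[tissue_idx] + off[ch])
      img[, , ch] <- plane
    }
  }

  # quantize to 8-bit so in-memory pixels equal the PNG round-trip
  img <- round(img * 255) / 255

  slide_dir <- file.path(out_dir, spec$slide_id)
  write_slide_pyramid(img, slide_dir, n_levels = n_levels)

  jitter <- spec$annotation_jitter %||% 1
  ann_polys <- lapply(seq_along(lesions), function(i) {
    verts <- lesion_polys[[i]]
    if (jitter != 1) {
      ctr <- colMeans(verts)
      verts <- sweep(sweep(verts, 2, ctr) * jitter, 2, ctr, `+`)
      verts[, 1] <- pmin(pmax(verts[, 1], 0), w)
      verts[, 2] <- pmin(pmax(verts[, 2], 0), h)
    }
    sub <- lesions[[i]]$subcategory %||%
      default_subcategory(normalize_category(lesions[[i]]$category))
    list(category = normalize_category(lesions[[i]]$category),
         subcategory = sub, vertices = unname(verts))
  })
  slide_label <- max_severity(categories)
  slide_sublabel <- spec$subcategory %||%
    if (length(ann_polys)) {
      sev <- category_severity(vapply(ann_polys, `[[`, "", "category"))
      ann_polys[[which.max(sev)]]$subcategory
    } else "normal_inflammation"
  ann <- structure(list(slide_label = slide_label,
                        slide_sublabel = slide_sublabel,
                        polygons = ann_polys),
                   class = "annotation_set")
  ann_path <- file.path(out_dir, paste0(spec$slide_id, "_annotations.json"))
  write_annotations(ann, ann_path)
  list(slide_dir = slide_dir, annotation_path = ann_path,
       slide_label = slide_label, slide_sublabel = slide_sublabel,
       annotations = ann)
}

# canonical subcategory for a synthetic lesion of a category
default_subcategory <- function(category) {
  switch(category,
         malignant = "squamous_carcinoma",
         high_grade = "cin3",
         low_grade = "cin1",
         normal = "normal_inflammation")
}

#' Generate a synthetic cohort of slides
#'
#' Draws each slide's category from `category_mix`, assigns labs
#' round-robin, generates every slide with [generate_slide()] (slides of
#' a non-normal category get one or two lesions of that category, and
#' sometimes an additional lesion of lower severity, emulating multilabel
#' slides), and writes a cohort manifest CSV.
#'
#' @param out_dir cohort output directory.
#' @param n_slides number of slides.
#' @param category_mix named probability vector over the four categories
#'   (must sum to 1).
#' @param n_labs number of labs (1..8; at least 3 are needed if the
#'   lab-held-out split will be requested downstream).
#' @param seed integer seed; the whole cohort is deterministic in it.
#' @param size_range level-0 slide side lengths are drawn uniformly from
#'   multiples of 64 in this range.
#' @return the manifest data.frame (also written to
#'   `out_dir/manifest.csv`).
#' @export
generate_cohort <- function(out_dir, n_slides, category_mix, n_labs,
                            seed, size_range = c(512L, 1024L)) {
  stopifnot(n_labs >= 1L, n_labs <= 8L)
  if (abs(sum(category_mix) - 1) > 1e-8) {
    stop("category_mix must sum to 1")
  }
  if (n_labs < 3L) {
    warning("fewer than 3 labs: the lab-held-out split cannot hold out 2 labs")
  }
  names(category_mix) <- normalize_category(names(category_mix))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(seed)
  cats <- sample(names(category_mix), n_slides, replace = TRUE,
                 prob = category_mix)
  sizes_avail <- seq(size_range[1], size_range[2], by = 64L)
  sizes_w <- sample_from(sizes_avail, n_slides, replace = TRUE)
  sizes_h <- sample_from(sizes_avail, n_slides, replace = TRUE)
  labs <- rep(seq_len(n_labs), length.out = n_slides)
  slide_seeds <- sapply(seq_len(n_slides), function(i) derive_seed(seed, i))
  subs <- wsi_subcategories()

  rows <- vector("list", n_slides)
  for (i in seq_len(n_slides)) {
    slide_id <- sprintf("slide_%03d", i)
    cat_i <- cats[i]
    sub_i <- sample(subs$subcategory[subs$category == cat_i], 1L)
    lesions <- list()
    if (cat_i != "normal") {
      n_les <- sample(1:2, 1L)
      rad <- function() min(sizes_w[i], sizes_h[i]) *
        stats::runif(1, 0.18, 0.3)
      for (k in seq_len(n_les)) {
        lesions[[k]] <- list(category = cat_i, subcategory = sub_i,
                             radius = rad())
      }
      lower <- setdiff(wsi_categories()[seq_len(category_severity(cat_i))],
                       "normal")
      if (length(lower) && stats::runif(1) < 0.5) {
        lc <- sample(lower, 1L)
        lesions[[length(lesions) + 1L]] <-
          list(category = lc, subcategory = default_subcategory(lc),
               radius = rad())
      }
    }
    spec <- list(slide_id = slide_id, width = sizes_w[i],
                 height = sizes_h[i], lab_id = labs[i],
                 seed = slide_seeds[i], lesions = lesions,
                 subcategory = if (cat_i == "normal")
                   "normal_inflammation" else sub_i)
    res <- generate_slide(spec, out_dir)
    rows[[i]] <- data.frame(
      slide_id = slide_id, lab_id = labs[i], category = cat_i,
      subcategory = spec$subcategory,
      image_path = res$slide_dir, annotation_path = res$annotation_path,
      stringsAsFactors = FALSE
    )
  }
  manifest <- do.call(rbind, rows)
  write_manifest(manifest, file.path(out_dir, "manifest.csv"))
  manifest
}

#' Sample a pure-texture patch for one category
#'
#' Convenience generator for unit tests and separability checks: a
#' square patch painted entirely with one category's texture (no
#' background, no lesions). Draws from the current RNG stream.
#'
#' @param category diagnostic category.
#' @param size patch side length in pixels.
#' @return `size x size x 3` RGB array in `[0, 1]`.
#' @export
sample_texture_patch <- function(category, size = 64L) {
  tex <- texture_models()[[normalize_category(category)]]
  img <- array(0.5, c(size, size, 3))
  paint_texture(img, seq_len(size * size), tex)
}
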