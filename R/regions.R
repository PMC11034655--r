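#' Connected-component labelling of a binary grid
#'
#' Labels the foreground of a logical matrix under 8-connectivity
#' (diagonal neighbours touch) using a two-pass union-find algorithm.
#'
#' @param mask logical matrix.
#' @return integer matrix of component labels (0 = background), labelled
#'   in first-encounter (row-major) order.
#' @export
label_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  labels <- matrix(0L, nr, nc)
  parent <- integer(0)
  find_root <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  next_label <- 0L
  for (r in seq_len(nr)) {
    for (cc in seq_len(nc)) {
      if (!mask[r, cc]) next
      # previously-visited 8-neighbours: W, NW, N, NE
      neigh <- integer(0)
      if (cc > 1L && labels[r, cc - 1L] > 0L) {
        neigh <- c(neigh, labels[r, cc - 1L])
      }
      if (r > 1L) {
        for (dc in -1:1) {
          c2 <- cc + dc
          if (c2 >= 1L && c2 <= nc && labels[r - 1L, c2] > 0L) {
            neigh <- c(neigh, labels[r - 1L, c2])
          }
        }
      }
      if (length(neigh) == 0L) {
        next_label <- next_label + 1L
        parent[next_label] <- next_label
        labels[r, cc] <- next_label
      } else {
        roots <- unique(vapply(neigh, find_root, integer(1)))
        keep <- min(roots)
        labels[r, cc] <- keep
        for (other in setdiff(roots, keep)) parent[other] <- keep
      }
    }
  }
  if (next_label > 0L) {
    roots <- vapply(seq_len(next_label), find_root, integer(1))
    relabel <- integer(next_label)
    relabel[sort(unique(roots))] <- seq_along(unique(sort(roots)))
    nz <- labels > 0L
    labels[nz] <- relabel[roots[labels[nz]]]
  }
  labels
}

#' Extract the k largest regions of a thresholded heatmap
#'
#' Connected components (8-connectivity) of `mask`, sorted by pixel
#' count descending with ties broken by the row-major position of each
#' region's topmost-leftmost cell; at most `k` regions are returned.
#'
#' @param mask logical matrix.
#' @param intensity numeric matrix of the same shape (the source
#'   probability grid) supplying region intensities.
#' @param k maximum number of regions.
#' @return list of `region` objects (fields `cells` — an `n x 2` matrix
#'   of (row, col) 1-based indices — `pixel_count` and `intensities`);
#'   empty list for an empty mask.
#' @export
extract_regions <- function(mask, intensity, k = Inf) {
  stopifnot(all(dim(mask) == dim(intensity)))
  labels <- label_components(mask)
  n_reg <- max(labels)
  if (n_reg == 0L) return(list())
  regions <- lapply(seq_len(n_reg), function(l) {
    idx <- which(labels == l, arr.ind = TRUE)
    structure(list(cells = idx, pixel_count = nrow(idx),
                   intensities = intensity[labels == l]),
              class = "heatmap_region")
  })
  # row-major position of the topmost-leftmost cell, for tie-breaks
  anchor <- vapply(regions, function(rg) {
    min((rg$cells[, 1] - 1L) * ncol(mask) + rg$cells[, 2])
  }, numeric(1))
  ord <- order(-vapply(regions, `[[`, integer(1), "pixel_count"), anchor)
  regions <- regions[ord]
  regions[seq_len(min(k, length(regions)))]
}

# shoelace area of a polygon given vertex coordinates
polygon_area <- function(x, y) {
  n <- length(x)
  j <- c(n, seq_len(n - 1L))
  abs(sum(x[j] * y - x * y[j])) / 2
}

# flood fill (4-connectivity) of the background of a padded bbox patch;
# returns the hole mask and hole count
find_holes <- function(patch) {
  nr <- nrow(patch); nc <- ncol(patch)
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- patch
  outside <- matrix(FALSE, nr + 2L, nc + 2L)
  queue <- c(1L)  # linear index of (1,1), guaranteed background
  outside[1L] <- TRUE
  H <- nr + 2L
  while (length(queue)) {
    cur <- queue[length(queue)]
    queue <- queue[-length(queue)]
    r <- (cur - 1L) %% H + 1L
    cc <- (cur - 1L) %/% H + 1L
    for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
      r2 <- r + d[1]; c2 <- cc + d[2]
      if (r2 < 1L || r2 > H || c2 < 1L || c2 > nc + 2L) next
      i2 <- (c2 - 1L) * H + r2
      if (!outside[i2] && !pad[i2]) {
        outside[i2] <- TRUE
        queue <- c(queue, i2)
      }
    }
  }
  holes <- !pad & !outside
  holes_inner <- holes[2:(nr + 1L), 2:(nc + 1L), drop = FALSE]
  n_holes <- max(label_components_4(holes_inner))
  list(mask = holes_inner, n_holes = n_holes)
}

# 4-connectivity labelling (for counting holes in 8-connected objects)
label_components_4 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  labels <- matrix(0L, nr, nc)
  nxt <- 0L
  for (start in which(mask)) {
    if (labels[start] > 0L) next
    nxt <- nxt + 1L
    queue <- start
    labels[start] <- nxt
    while (length(queue)) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      r <- (cur - 1L) %% nr + 1L
      cc <- (cur - 1L) %/% nr + 1L
      for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
        r2 <- r + d[1]; c2 <- cc + d[2]
        if (r2 < 1L || r2 > nr || c2 < 1L || c2 > nc) next
        i2 <- (c2 - 1L) * nr + r2
        if (mask[i2] && labels[i2] == 0L) {
          labels[i2] <- nxt
          queue <- c(queue, i2)
        }
      }
    }
  }
  labels
}

#' Regional shape and intensity statistics
#'
#' Blob-analysis properties of one heatmap region, following the usual
#' regionprops conventions:
#'
#' * `area`: pixel count.
#' * `eccentricity`, `major_axis_length`, `minor_axis_length`: from the
#'   ellipse with the same second central moments as the pixel-center
#'   point set (axis lengths are `4 * sqrt(eigenvalue)`).
#' * `extent`: area / bounding-box area; `bbox_area`; `bbox_aspect`:
#'   bounding-box width / height.
#' * `max_intensity`, `mean_intensity`, `min_intensity` over the source
#'   probability grid.
#' * `convex_area`: geometric area of the convex hull of the region's
#'   unit pixel squares; `solidity` = area / convex_area.
#' * `filled_area`: area with interior holes filled (holes are
#'   4-connected background components not reachable from outside).
#' * `equivalent_diameter`: diameter of the circle with the region's
#'   area.
#' * `euler_number`: 1 minus the number of holes.
#' * `perimeter`: total length of the boundary between region pixels and
#'   non-region pixels, counted in unit pixel edges.
#'
#' @param region a `heatmap_region` from [extract_regions()].
#' @return named numeric vector of the statistics above.
#' @export
region_stats <- function(region) {
  cells <- region$cells
  n <- nrow(cells)
  r <- cells[, 1]; cc <- cells[, 2]
  rbar <- mean(r); cbar <- mean(cc)
  mu_rr <- mean((r - rbar)^2)
  mu_cc <- mean((cc - cbar)^2)
  mu_rc <- mean((r - rbar) * (cc - cbar))
  tr <- mu_rr + mu_cc
  det <- mu_rr * mu_cc - mu_rc^2
  disc <- sqrt(max(tr^2 / 4 - det, 0))
  l1 <- tr / 2 + disc; l2 <- max(tr / 2 - disc, 0)
  major <- 4 * sqrt(l1); minor <- 4 * sqrt(l2)
  ecc <- if (l1 > 0) sqrt(1 - l2 / l1) else 0

  bbox_h <- diff(range(r)) + 1L
  bbox_w <- diff(range(cc)) + 1L
  bbox_area <- bbox_h * bbox_w

  # convex hull over the 4 corners of each pixel square
  corners_x <- c(cc - 1, cc, cc - 1, cc)
  corners_y <- c(r - 1, r - 1, r, r)
  hull <- grDevices::chull(corners_x, corners_y)
  convex_area <- polygon_area(corners_x[hull], corners_y[hull])

  # holes: use the bbox-cropped mask
  patch <- matrix(FALSE, bbox_h, bbox_w)
  patch[cbind(r - min(r) + 1L, cc - min(cc) + 1L)] <- TRUE
  hl <- find_holes(patch)
  filled_area <- n + sum(hl$mask)

  # boundary edges: 4-neighbour non-region contacts (incl. outside)
  perim <- 0L
  for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
    r2 <- r - min(r) + 1L + d[1]
    c2 <- cc - min(cc) + 1L + d[2]
    inb <- r2 >= 1L & r2 <= bbox_h & c2 >= 1L & c2 <= bbox_w
    perim <- perim + sum(!inb) +
      sum(!patch[cbind(r2[inb], c2[inb])])
  }

  c(area = n,
    eccentricity = ecc,
    extent = n / bbox_area,
    bbox_area = bbox_area,
    major_axis_length = major,
    max_intensity = max(region$intensities),
    mean_intensity = mean(region$intensities),
    min_intensity = min(region$intensities),
    bbox_aspect = bbox_w / bbox_h,
    solidity = n / convex_area,
    convex_area = convex_area,
    filled_area = filled_area,
    minor_axis_length = minor,
    equivalent_diameter = sqrt(4 * n / pi),
    euler_number = 1 - hl$n_holes,
    perimeter = perim)
}
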