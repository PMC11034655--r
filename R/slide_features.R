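#' Global heatmap features
#'
#' For a probability grid and threshold t:
#' * `area_ratio`: number of cells with probability >= t, divided by the
#'   tissue area.
#' * `prob_area`: sum of the probabilities of those cells, divided by
#'   the tissue area.
#'
#' The forest scheme computes both at thresholds 0.5-0.9 (step 0.1) for
#' the malignant, high-grade and low-grade heatmaps: 30 global features,
#' ordered heatmap-major then threshold, with `(area_ratio, prob_area)`
#' pairs innermost.
#'
#' @param h a `category_heatmaps` with positive tissue area.
#' @return named numeric vector of length 30.
#' @export
global_features_forest <- function(h) {
  thresholds <- c(0.5, 0.6, 0.7, 0.8, 0.9)
  heatmap_global_features(h, c("malignant", "high_grade", "low_grade"),
                          thresholds, prob_area = TRUE)
}

#' @rdname global_features_forest
#' @details The boosted scheme keeps only `area_ratio`, at thresholds
#'   0.5, 0.7 and 0.9 on the malignant and high-grade heatmaps: 6 global
#'   features.
#' @return `global_features_boosted` returns a named vector of length 6.
#' @export
global_features_boosted <- function(h) {
  heatmap_global_features(h, c("malignant", "high_grade"),
                          c(0.5, 0.7, 0.9), prob_area = FALSE)
}

heatmap_global_features <- function(h, categories, thresholds, prob_area) {
  if (h$tissue_area == 0L) stop("tissue area is zero")
  out <- numeric(0)
  for (cat in categories) {
    g <- h$grids[[cat]]
    for (t in thresholds) {
      sel <- threshold_heatmap(g, t)
      vals <- c(area_ratio = sum(sel) / h$tissue_area)
      if (prob_area) {
        vals <- c(vals, prob_area = sum(g[sel]) / h$tissue_area)
      }
      names(vals) <- paste0(cat, "_t", t, "_", names(vals))
      out <- c(out, vals)
    }
  }
  out
}

# the 10 regional features of the forest scheme, in fixed order
forest_region_feature_names <- function() {
  c("area", "eccentricity", "extent", "bbox_area", "major_axis_length",
    "max_intensity", "mean_intensity", "min_intensity", "bbox_aspect",
    "solidity")
}

#' Regional features for the forest scheme
#'
#' @param region a `heatmap_region`.
#' @return the 10-vector (area, eccentricity, extent, bbox area, major
#'   axis length, max/mean/min intensity, bbox aspect ratio, solidity).
#' @export
region_features_forest <- function(region) {
  region_stats(region)[forest_region_feature_names()]
}

#' Assemble the 90-dimensional forest feature vector
#'
#' 30 global features plus, for each of the malignant, high-grade and
#' low-grade heatmaps thresholded at `region_threshold`, the 10 regional
#' features of the 2 largest connected regions (missing regions
#' contribute zeros): 30 + 3 x 2 x 10 = 90 values in a fixed, named
#' order. The vector depends only on the heatmap grids, not on patch
#' enumeration order.
#'
#' @param h a `category_heatmaps`.
#' @param region_threshold threshold defining the binary image whose
#'   components are analysed (default 0.5).
#' @return named numeric vector of length 90 with attribute `scheme =
#'   "forest90"`.
#' @export
assemble_forest_vector <- function(h, region_threshold = 0.5) {
  out <- global_features_forest(h)
  for (cat in c("malignant", "high_grade", "low_grade")) {
    g <- h$grids[[cat]]
    regions <- extract_regions(threshold_heatmap(g, region_threshold), g,
                               k = 2L)
    for (i in 1:2) {
      feats <- if (i <= length(regions)) {
        region_features_forest(regions[[i]])
      } else {
        setNames(rep(0, 10L), forest_region_feature_names())
      }
      names(feats) <- paste0(cat, "_r", i, "_", names(feats))
      out <- c(out, feats)
    }
  }
  structure(out, scheme = "forest90")
}

#' Feature mask of the boosted scheme
#'
#' Which of the 12 regional statistics are extracted per heatmap
#' category in the refined (gradient-boosting) scheme. The malignant
#' heatmap keeps all 12; high grade drops min intensity; low grade drops
#' area, equivalent diameter and perimeter; normal keeps only bounding
#' box area, major and minor axis lengths, mean intensity and filled
#' area.
#'
#' @return named list: per category, the character vector of enabled
#'   statistic names (in the fixed row order of the scheme).
#' @export
boosted_feature_masks <- function() {
  rows <- c("area", "bbox_area", "major_axis_length", "max_intensity",
            "mean_intensity", "min_intensity", "convex_area",
            "filled_area", "minor_axis_length", "equivalent_diameter",
            "euler_number", "perimeter")
  list(
    malignant = rows,
    high_grade = setdiff(rows, "min_intensity"),
    low_grade = setdiff(rows, c("area", "equivalent_diameter", "perimeter")),
    normal = c("bbox_area", "major_axis_length", "mean_intensity",
               "filled_area", "minor_axis_length")
  )
}

# regions analysed per category in the boosted scheme
boosted_region_counts <- function() {
  c(malignant = 7L, high_grade = 5L, low_grade = 3L, normal = 2L)
}

#' Assemble the boosted (refined) feature vector
#'
#' 6 global area ratios plus the masked regional statistics of the 7
#' largest malignant, 5 largest high-grade, 3 largest low-grade and 2
#' largest normal regions (missing regions contribute zeros):
#' 6 + 7x12 + 5x11 + 3x9 + 2x5 = 182 values in a fixed, named order.
#'
#' @inheritParams assemble_forest_vector
#' @return named numeric vector of length 182 with attribute `scheme =
#'   "boosted"`.
#' @export
assemble_boosted_vector <- function(h, region_threshold = 0.5) {
  out <- global_features_boosted(h)
  masks <- boosted_feature_masks()
  counts <- boosted_region_counts()
  for (cat in names(counts)) {
    g <- h$grids[[cat]]
    regions <- extract_regions(threshold_heatmap(g, region_threshold), g,
                               k = counts[[cat]])
    enabled <- masks[[cat]]
    for (i in seq_len(counts[[cat]])) {
      feats <- if (i <= length(regions)) {
        region_stats(regions[[i]])[enabled]
      } else {
        setNames(rep(0, length(enabled)), enabled)
      }
      names(feats) <- paste0(cat, "_r", i, "_", enabled)
      out <- c(out, feats)
    }
  }
  structure(out, scheme = "boosted")
}

#' Slide feature table for a cohort
#'
#' Applies one feature scheme to a list of per-slide heatmaps.
#'
#' @param heatmap_list named list of `category_heatmaps` (names = slide
#'   ids).
#' @param scheme `"forest90"` or `"boosted"`.
#' @return data.frame with `slide_id` and one column per feature, in the
#'   scheme's fixed column order.
#' @export
slide_feature_table <- function(heatmap_list,
                                scheme = c("forest90", "boosted")) {
  scheme <- match.arg(scheme)
  f <- if (scheme == "forest90") assemble_forest_vector else
    assemble_boosted_vector
  mat <- t(vapply(heatmap_list, function(h) as.numeric(f(h)),
                  numeric(length(f(heatmap_list[[1]])))))
  colnames(mat) <- names(f(heatmap_list[[1]]))
  cbind(data.frame(slide_id = names(heatmap_list),
                   stringsAsFactors = FALSE),
        as.data.frame(mat, row.names = NULL))
}
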