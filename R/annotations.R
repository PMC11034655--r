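#' Load polygon annotations for a slide
#'
#' The annotation file is JSON with a slide-level label and a list of
#' polygons, each carrying a diagnostic category and subcategory:
#'
#' ```
#' {"slide_label": "malignant", "slide_sublabel": "cgin",
#'  "polygons": [{"category": "malignant", "subcategory": "cgin",
#'                "vertices": [[x, y], ...]}]}
#' ```
#'
#' All vertex coordinates are level-0 pixels (0-based, x = column,
#' y = row). Category and subcategory spellings are normalized (e.g.
#' `"CGIN"` maps to the malignant parent category). A slide whose label is
#' not normal must carry at least one polygon; polygons need at least
#' three vertices.
#'
#' @param path path to the annotation JSON file.
#' @return an `annotation_set`: list with `slide_label`, `slide_sublabel`
#'   and `polygons` (each a list with `category`, `subcategory` and an
#'   `n x 2` `vertices` matrix).
#' @export
load_annotations <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  polygons <- lapply(raw$polygons, function(p) {
    verts <- do.call(rbind, lapply(p$vertices, function(v) {
      as.numeric(unlist(v))
    }))
    if (is.null(verts) || nrow(verts) < 3L) {
      stop("malformed polygon: fewer than 3 vertices in ", path)
    }
    sub <- normalize_subcategory(p$subcategory)
    list(category = normalize_category(p$category),
         subcategory = sub, vertices = unname(verts))
  })
  ann <- list(
    slide_label = normalize_category(raw$slide_label),
    slide_sublabel = normalize_subcategory(raw$slide_sublabel),
    polygons = polygons
  )
  class(ann) <- "annotation_set"
  validate_annotations(ann)
}

#' @rdname load_annotations
#' @param ann an `annotation_set`.
#' @param slide optional `slide_pyramid`; when given, vertices are checked
#'   against the slide bounds.
#' @export
validate_annotations <- function(ann, slide = NULL) {
  if (ann$slide_label != "normal" && length(ann$polygons) == 0L) {
    stop("non-normal slide label '", ann$slide_label,
         "' requires at least one polygon")
  }
  for (p in ann$polygons) {
    if (nrow(p$vertices) < 3L) stop("polygon with fewer than 3 vertices")
    if (!is.null(slide)) {
      if (any(p$vertices[, 1] < 0) || any(p$vertices[, 2] < 0) ||
          any(p$vertices[, 1] > slide$level0_width) ||
          any(p$vertices[, 2] > slide$level0_height)) {
        stop("polygon vertices outside slide bounds")
      }
    }
  }
  ann
}

#' @rdname load_annotations
#' @export
write_annotations <- function(ann, path) {
  stopifnot(inherits(ann, "annotation_set"))
  out <- list(
    slide_label = ann$slide_label,
    slide_sublabel = ann$slide_sublabel,
    polygons = lapply(ann$polygons, function(p) {
      list(category = p$category, subcategory = p$subcategory,
           vertices = lapply(seq_len(nrow(p$vertices)),
                             function(i) as.numeric(p$vertices[i, ])))
    })
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load and validate a cohort manifest
#'
#' The manifest is a CSV with columns `slide_id`, `lab_id`, `category`,
#' `subcategory`, `image_path`, `annotation_path`. Lab ids index the eight
#' section-thickness-by-staining-protocol combinations and must lie in
#' 1..8; slide ids must be unique; subcategory parents must match the
#' recorded category.
#'
#' @param path manifest CSV path.
#' @return data.frame of validated slide records.
#' @export
load_manifest <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("slide_id", "lab_id", "category", "subcategory",
                "image_path", "annotation_path")
  missing <- setdiff(required, names(m))
  if (length(missing)) {
    stop("manifest missing columns: ", paste(missing, collapse = ", "))
  }
  validate_manifest(m)
}

#' @rdname load_manifest
#' @param manifest a manifest data.frame.
#' @export
validate_manifest <- function(manifest) {
  if (anyDuplicated(manifest$slide_id)) {
    stop("duplicate slide_id in manifest: ",
         paste(unique(manifest$slide_id[duplicated(manifest$slide_id)]),
               collapse = ", "))
  }
  if (any(manifest$lab_id < 1L | manifest$lab_id > 8L)) {
    stop("lab_id outside 1..8")
  }
  manifest$category <- normalize_category(manifest$category)
  manifest$subcategory <- normalize_subcategory(manifest$subcategory)
  parent <- subcategory_parent(manifest$subcategory)
  bad <- manifest$category != parent
  if (any(bad)) {
    stop("subcategory/category mismatch for slide(s): ",
         paste(manifest$slide_id[bad], collapse = ", "))
  }
  manifest
}

#' @rdname load_manifest
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(manifest, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
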