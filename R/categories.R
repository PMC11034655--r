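#' Diagnostic categories and subcategories
#'
#' The pipeline stratifies cervical biopsies into four diagnostic
#' categories with a fixed severity order: normal/inflammation <
#' low grade (HPV change, CIN 1) < high grade (CIN 2/3) < malignant
#' (squamous carcinoma, adenocarcinoma, CGIN and other malignant tumours).
#' The severity order is the single source of truth for the "most severe
#' category" patch-labelling rule and for severity tie-breaks elsewhere.
#'
#' @format `wsi_categories()` returns a character vector of the four
#'   category names in increasing severity order.
#' @examples
#' wsi_categories()
#' category_severity("malignant")
#' @export
wsi_categories <- function() {
  c("normal", "low_grade", "high_grade", "malignant")
}

#' @rdname wsi_categories
#' @param category character vector of category names.
#' @return `category_severity` returns integer severity ranks (0 = normal,
#'   3 = malignant).
#' @export
category_severity <- function(category) {
  category <- normalize_category(category)
  match(category, wsi_categories()) - 1L
}

#' @rdname wsi_categories
#' @return `wsi_subcategories()` returns a data.frame mapping each
#'   subcategory to its parent category.
#' @export
wsi_subcategories <- function() {
  data.frame(
    subcategory = c("squamous_carcinoma", "adenocarcinoma", "cgin", "other",
                    "cin2", "cin3", "cin1", "hpv", "normal_inflammation"),
    category = c("malignant", "malignant", "malignant", "malignant",
                 "high_grade", "high_grade", "low_grade", "low_grade",
                 "normal"),
    stringsAsFactors = FALSE
  )
}

# squash to a canonical lookup key: lower-case alphanumerics only
.squash <- function(x) gsub("[^a-z0-9]", "", tolower(x))

#' Normalize category and subcategory spellings
#'
#' Annotation files and manifests in the wild spell labels in several ways
#' ("High Grade", "Normal/inflammation", "CIN 2"). These helpers map any
#' punctuation/case variant onto the canonical identifiers used throughout
#' the package.
#'
#' @param x character vector of labels.
#' @return canonical category (resp. subcategory) names.
#' @examples
#' normalize_category("Normal/inflammation")
#' normalize_subcategory("CIN 2")
#' @export
normalize_category <- function(x) {
  lut <- c(normal = "normal", normalinflammation = "normal",
           inflammation = "normal",
           lowgrade = "low_grade", highgrade = "high_grade",
           malignant = "malignant")
  out <- lut[.squash(x)]
  if (anyNA(out)) {
    stop("unknown category: ", paste(unique(x[is.na(out)]), collapse = ", "))
  }
  unname(out)
}

#' @rdname normalize_category
#' @export
normalize_subcategory <- function(x) {
  map <- wsi_subcategories()
  lut <- structure(map$subcategory, names = .squash(map$subcategory))
  out <- lut[.squash(x)]
  if (anyNA(out)) {
    stop("unknown subcategory: ",
         paste(unique(x[is.na(out)]), collapse = ", "))
  }
  unname(out)
}

#' @rdname normalize_category
#' @export
subcategory_parent <- function(x) {
  map <- wsi_subcategories()
  map$category[match(normalize_subcategory(x), map$subcategory)]
}

#' Most severe category of a set
#'
#' @param categories character vector (any normalizable spelling).
#' @return single category name with maximal severity; `"normal"` for an
#'   empty input.
#' @export
max_severity <- function(categories) {
  if (length(categories) == 0L) return("normal")
  wsi_categories()[max(category_severity(categories)) + 1L]
}

# internal: validate a category factor in canonical order
as_category_factor <- function(x) {
  factor(normalize_category(x), levels = wsi_categories())
}
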