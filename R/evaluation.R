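#' Confusion matrix with derived metrics
#'
#' Rows are truth, columns prediction. Derived quantities: the
#' row-percent matrix (each non-empty row sums to 100), overall
#' accuracy, and per-class sensitivity (diagonal over row total).
#'
#' @param truth,predicted equal-length label vectors (any normalizable
#'   category spelling), or factors sharing a level set.
#' @param levels label set; defaults to the four diagnostic categories.
#' @return a `confusion_matrix`: list with `counts`, `row_percent`,
#'   `accuracy`, `sensitivity`.
#' @export
confusion <- function(truth, predicted, levels = wsi_categories()) {
  if (length(truth) == 0L) stop("empty input")
  if (length(truth) != length(predicted)) {
    stop("truth and predicted differ in length")
  }
  truth <- factor(as.character(truth), levels = levels)
  predicted <- factor(as.character(predicted), levels = levels)
  if (anyNA(truth) || anyNA(predicted)) stop("unknown label")
  counts <- table(truth = truth, predicted = predicted)
  rs <- rowSums(counts)
  row_percent <- counts / ifelse(rs == 0, 1, rs) * 100
  sens <- ifelse(rs > 0, diag(counts) / rs, NA_real_)
  structure(list(counts = unclass(counts),
                 row_percent = unclass(row_percent),
                 accuracy = sum(diag(counts)) / sum(counts),
                 sensitivity = sens),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("<confusion_matrix> accuracy %.4f\n", x$accuracy))
  print(x$counts)
  invisible(x)
}

#' Malignant sensitivity
#'
#' Fraction of truly malignant slides (or patches) predicted malignant;
#' the headline triage metric.
#'
#' @param cm a `confusion_matrix`.
#' @return scalar in `[0, 1]`.
#' @export
malignant_sensitivity <- function(cm) {
  row <- cm$counts["malignant", ]
  if (sum(row) == 0L) stop("empty malignant row")
  unname(row["malignant"] / sum(row))
}

#' Cohen's kappa from a square agreement table
#'
#' Chance-corrected agreement between two labelings:
#' \eqn{\kappa = (p_o - p_e) / (1 - p_e)} with observed agreement
#' `p_o = trace / total` and chance agreement `p_e` from the marginal
#' products. Unweighted (nominal) kappa.
#'
#' @param table square count matrix (rows: labeling A, columns:
#'   labeling B, same category order).
#' @return an `agreement_stats` list with `table`, `p_o`, `p_e`,
#'   `kappa`.
#' @export
cohens_kappa <- function(table) {
  table <- as.matrix(table)
  if (nrow(table) != ncol(table)) stop("agreement table must be square")
  total <- sum(table)
  if (total == 0) stop("empty agreement table")
  p_o <- sum(diag(table)) / total
  p_e <- sum(rowSums(table) * colSums(table)) / total^2
  kappa <- if (p_e == 1) 1 else (p_o - p_e) / (1 - p_e)
  structure(list(table = table, p_o = p_o, p_e = p_e, kappa = kappa),
            class = "agreement_stats")
}

#' @export
print.agreement_stats <- function(x, ...) {
  cat(sprintf("<agreement_stats> p_o %.4f, p_e %.4f, kappa %.4f\n",
              x$p_o, x$p_e, x$kappa))
  invisible(x)
}

#' Cross-tabulate two labelings
#'
#' @param a,b equal-length label vectors.
#' @param levels shared level set.
#' @return square count matrix suitable for [cohens_kappa()].
#' @export
agreement_table <- function(a, b, levels = sort(unique(c(a, b)))) {
  unclass(table(factor(a, levels = levels), factor(b, levels = levels)))
}

#' Mean pairwise Cohen's kappa over several observers
#'
#' Computes kappa for every unordered pair of labelings and returns the
#' arithmetic mean — the summary used for multi-observer agreement.
#'
#' @param labelings list of >= 2 equal-length label vectors.
#' @param levels shared level set.
#' @return scalar mean kappa.
#' @export
mean_pairwise_kappa <- function(labelings,
                                levels = sort(unique(unlist(labelings)))) {
  if (length(labelings) < 2L) stop("need at least 2 labelings")
  lens <- lengths(labelings)
  if (length(unique(lens)) != 1L) stop("labelings differ in length")
  pairs <- utils::combn(length(labelings), 2L)
  kappas <- apply(pairs, 2L, function(p) {
    cohens_kappa(agreement_table(labelings[[p[1]]], labelings[[p[2]]],
                                 levels = levels))$kappa
  })
  mean(kappas)
}

#' Packaged inter-observer agreement data
#'
#' Loads the packaged counts from a 200-sample inter-observer study in
#' which three consultant pathologists independently re-annotated a
#' balanced subset of cervical biopsies (50 slides per category). The
#' category table cross-tabulates each observer's assigned category
#' against the original one.
#'
#' @param which `"categories"` for the per-observer category tables or
#'   `"subset"` for the subset composition.
#' @return data.frame in long format.
#' @export
interobserver_data <- function(which = c("categories", "subset")) {
  which <- match.arg(which)
  f <- system.file("extdata",
                   paste0("interobserver_", which, ".csv"),
                   package = "wsitriage", mustWork = TRUE)
  utils::read.csv(f, stringsAsFactors = FALSE)
}

#' @rdname interobserver_data
#' @param observer observer id (`"A"`, `"B"` or `"C"`).
#' @return `observer_category_table` returns the 4x4 count matrix of
#'   original (rows) vs observed (columns) categories for one observer.
#' @export
observer_category_table <- function(observer) {
  d <- interobserver_data("categories")
  d <- d[d$observer == observer, ]
  cats <- wsi_categories()
  m <- matrix(0L, 4L, 4L, dimnames = list(original = cats, observed = cats))
  for (i in seq_len(nrow(d))) {
    m[normalize_category(d$original_category[i]),
      normalize_category(d$observed_category[i])] <- d$count[i]
  }
  m
}
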