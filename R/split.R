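#' Lab-held-out stratified train/validation/test split
#'
#' Reproduces the cohort splitting protocol used for the cervical biopsy
#' study: all slides from `n_heldout_labs` randomly chosen labs, plus
#' `test_fraction` of the slides from every remaining lab (stratified by
#' category and subcategory), form the test set; the remaining slides are
#' divided into training and validation sets in the ratio
#' `train_fraction : 1 - train_fraction`, stratified by category,
#' subcategory and lab. Strata with fewer than 3 slides fall back to
#' category-level stratification (reported via a message). The assignment
#' is deterministic given `seed`.
#'
#' @param manifest manifest data.frame (see [load_manifest()]).
#' @param n_heldout_labs number of labs fully held out for testing.
#' @param test_fraction fraction of each remaining lab's slides added to
#'   the test set.
#' @param train_fraction fraction of the non-test slides used for
#'   training (the rest validate).
#' @param seed integer seed.
#' @param relabel optional data.frame with columns `slide_id`,
#'   `category`, `subcategory` overriding manifest labels before
#'   splitting (mirrors post-annotation label corrections).
#' @return a `split_assignment`: list with `assignment` (data.frame
#'   `slide_id`, `split`), `held_out_labs` and `seed`.
#' @export
split_manifest <- function(manifest, n_heldout_labs = 2L,
                           test_fraction = 0.10, train_fraction = 2 / 3,
                           seed = 1L, relabel = NULL) {
  manifest <- validate_manifest(manifest)
  if (!is.null(relabel)) {
    i <- match(relabel$slide_id, manifest$slide_id)
    if (anyNA(i)) stop("relabel refers to unknown slide_id")
    manifest$category[i] <- normalize_category(relabel$category)
    manifest$subcategory[i] <- normalize_subcategory(relabel$subcategory)
    manifest <- validate_manifest(manifest)
  }
  labs <- sort(unique(manifest$lab_id))
  if (length(labs) < n_heldout_labs + 1L) {
    stop("need at least ", n_heldout_labs + 1L, " labs, have ",
         length(labs))
  }
  set.seed(seed)
  held_out <- sort(sample(labs, n_heldout_labs))
  assign_vec <- setNames(rep(NA_character_, nrow(manifest)), manifest$slide_id)
  assign_vec[manifest$lab_id %in% held_out] <- "test"

  remaining <- which(is.na(assign_vec))
  # per-lab, stratified selection of the extra test slides
  strata <- stratum_keys(manifest[remaining, ],
                         c("lab_id", "category", "subcategory"),
                         min_size = 3L,
                         fallback = c("lab_id", "category"))
  for (s in split(remaining, factor(strata, levels = unique(strata)))) {
    k <- round(length(s) * test_fraction)
    if (k > 0L) {
      take <- s[sample.int(length(s), k)]
      assign_vec[take] <- "test"
    }
  }

  rest <- which(is.na(assign_vec))
  strata <- stratum_keys(manifest[rest, ],
                         c("category", "subcategory", "lab_id"),
                         min_size = 3L,
                         fallback = c("category", "lab_id"))
  for (s in split(rest, factor(strata, levels = unique(strata)))) {
    n_train <- round(length(s) * train_fraction)
    shuffled <- s[sample.int(length(s))]
    assign_vec[shuffled[seq_len(n_train)]] <- "train"
    if (n_train < length(s)) {
      assign_vec[shuffled[(n_train + 1L):length(s)]] <- "valid"
    }
  }

  out <- list(
    assignment = data.frame(slide_id = manifest$slide_id,
                            split = unname(assign_vec),
                            stringsAsFactors = FALSE),
    held_out_labs = held_out, seed = seed
  )
  class(out) <- "split_assignment"
  out
}

# stratum key per row; strata smaller than min_size are regrouped at the
# coarser fallback key
stratum_keys <- function(df, cols, min_size, fallback) {
  key <- do.call(paste, c(df[cols], sep = "|"))
  tab <- table(key)
  small <- names(tab)[tab < min_size]
  if (length(small)) {
    message(length(small),
            " small strata fell back to category-level stratification")
    coarse <- do.call(paste, c(df[fallback], sep = "|"))
    key[key %in% small] <- paste0("fb|", coarse[key %in% small])
  }
  key
}

#' @export
print.split_assignment <- function(x, ...) {
  cat("<split_assignment> held-out labs:",
      paste(x$held_out_labs, collapse = ", "), "\n")
  print(table(x$assignment$split))
  invisible(x)
}

#' Slides of one split
#'
#' @param manifest manifest data.frame.
#' @param assignment a `split_assignment`.
#' @param which one of `"train"`, `"valid"`, `"test"`.
#' @return the manifest rows assigned to that split.
#' @export
split_slides <- function(manifest, assignment, which) {
  ids <- assignment$assignment$slide_id[assignment$assignment$split == which]
  manifest[manifest$slide_id %in% ids, , drop = FALSE]
}
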