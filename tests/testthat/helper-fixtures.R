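# shared fixtures built in code at test time

# a small slide with one lesion per requested category, written under a
# fresh directory; returns generate_slide()'s result plus the manifest row
make_test_slide <- function(dir, slide_id = "s1", width = 256L,
                            height = 256L, lesion_categories = "malignant",
                            seed = 11L, lab_id = 1L, n_levels = NULL) {
  lesions <- lapply(lesion_categories, function(cat) {
    list(category = cat, radius = 0.22 * min(width, height))
  })
  spec <- list(slide_id = slide_id, width = width, height = height,
               seed = seed, lab_id = lab_id, lesions = lesions,
               n_levels = n_levels)
  generate_slide(spec, dir)
}

# an annotation_set built directly from polygons (no file round-trip)
make_annotations <- function(polygons, slide_label = NULL) {
  cats <- vapply(polygons, `[[`, "", "category")
  if (is.null(slide_label)) slide_label <- max_severity(cats)
  structure(list(slide_label = slide_label,
                 slide_sublabel = if (slide_label == "normal")
                   "normal_inflammation" else
                     switch(slide_label, malignant = "squamous_carcinoma",
                            high_grade = "cin3", low_grade = "cin1"),
                 polygons = polygons),
            class = "annotation_set")
}

square_polygon <- function(x0, y0, side, category) {
  list(category = category,
       subcategory = switch(category, malignant = "squamous_carcinoma",
                            high_grade = "cin3", low_grade = "cin1",
                            normal = "normal_inflammation"),
       vertices = cbind(c(x0, x0 + side, x0 + side, x0),
                        c(y0, y0, y0 + side, y0 + side)))
}

# category_heatmaps built from an explicit probability array
# probs: n_rows x n_cols x 4 (category order); mask: logical matrix
make_heatmaps <- function(probs, mask) {
  grids <- lapply(seq_len(4), function(k) {
    g <- probs[, , k]
    g[!mask] <- 0
    g
  })
  names(grids) <- wsi_categories()
  structure(list(grids = grids, tissue_mask = mask,
                 tissue_area = sum(mask)),
            class = "category_heatmaps")
}

# random heatmaps: dirichlet-ish rows on a random tissue mask
random_heatmaps <- function(n_rows = 10L, n_cols = 10L, seed = 1L) {
  set.seed(seed)
  mask <- matrix(stats::runif(n_rows * n_cols) < 0.7, n_rows, n_cols)
  raw <- array(stats::rexp(n_rows * n_cols * 4), c(n_rows, n_cols, 4))
  tot <- raw[, , 1] + raw[, , 2] + raw[, , 3] + raw[, , 4]
  for (k in 1:4) raw[, , k] <- raw[, , k] / tot
  make_heatmaps(raw, mask)
}

# pure-texture patch dataset for the four categories
make_texture_dataset <- function(n_per_class, size = 64L, seed = 1L) {
  set.seed(seed)
  imgs <- list(); labs <- character(0)
  for (cat in wsi_categories()) {
    for (i in seq_len(n_per_class)) {
      imgs[[length(imgs) + 1L]] <- sample_texture_patch(cat, size)
      labs <- c(labs, cat)
    }
  }
  list(images = imgs, labels = factor(labs, levels = wsi_categories()))
}

# manifest data.frame with uniform strata: n_per_lab slides per lab,
# evenly spread over 5 (category, subcategory) strata
make_uniform_manifest <- function(n_labs = 8L, n_per_lab = 100L) {
  strata <- data.frame(
    category = c("malignant", "high_grade", "high_grade", "low_grade",
                 "normal"),
    subcategory = c("squamous_carcinoma", "cin2", "cin3", "cin1",
                    "normal_inflammation")
  )
  rows <- do.call(rbind, lapply(seq_len(n_labs), function(lab) {
    k <- n_per_lab / nrow(strata)
    data.frame(
      slide_id = sprintf("l%d_s%03d", lab, seq_len(n_per_lab)),
      lab_id = lab,
      category = rep(strata$category, each = k),
      subcategory = rep(strata$subcategory, each = k),
      image_path = "none", annotation_path = "none",
      stringsAsFactors = FALSE
    )
  }))
  rows
}

# exhaustive best depth-2 axis-aligned decision tree (separability oracle):
# root split searched over quantile thresholds of every feature, each child
# given its own best single split with majority leaves
depth2_thresholds <- function(v) {
  unique(stats::quantile(v, probs = seq(0.05, 0.95, by = 0.05),
                         names = FALSE))
}
depth2_majority <- function(y) names(sort(table(y), decreasing = TRUE))[1]
depth2_best_split <- function(X, y) {
  best <- list(correct = max(table(y)), f = NA, t = NA,
               lab_l = depth2_majority(y), lab_r = depth2_majority(y))
  for (f in seq_len(ncol(X))) {
    for (t in depth2_thresholds(X[, f])) {
      l <- X[, f] < t
      if (!any(l) || all(l)) next
      ll <- depth2_majority(y[l]); lr <- depth2_majority(y[!l])
      corr <- sum(y[l] == ll) + sum(y[!l] == lr)
      if (corr > best$correct) {
        best <- list(correct = corr, f = f, t = t, lab_l = ll, lab_r = lr)
      }
    }
  }
  best
}
fit_depth2_tree <- function(X, y) {
  y <- as.character(y)
  best <- NULL
  for (f in seq_len(ncol(X))) {
    for (t in depth2_thresholds(X[, f])) {
      l <- X[, f] < t
      if (!any(l) || all(l)) next
      bl <- depth2_best_split(X[l, , drop = FALSE], y[l])
      br <- depth2_best_split(X[!l, , drop = FALSE], y[!l])
      if (is.null(best) || bl$correct + br$correct > best$correct) {
        best <- list(correct = bl$correct + br$correct, f = f, t = t,
                     left = bl, right = br)
      }
    }
  }
  best
}
predict_depth2_tree <- function(tree, X) {
  out <- character(nrow(X))
  l <- X[, tree$f] < tree$t
  pick <- function(node, Xs) {
    if (is.na(node$f)) return(rep(node$lab_l, nrow(Xs)))
    ifelse(Xs[, node$f] < node$t, node$lab_l, node$lab_r)
  }
  out[l] <- pick(tree$left, X[l, , drop = FALSE])
  out[!l] <- pick(tree$right, X[!l, , drop = FALSE])
  out
}

# independent 8-connectivity flood-fill labelling (test oracle)
flood_fill_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  for (start in which(mask)) {
    if (lab[start] > 0L) next
    cur <- cur + 1L
    stack <- start
    lab[start] <- cur
    while (length(stack)) {
      s <- stack[length(stack)]; stack <- stack[-length(stack)]
      r <- (s - 1L) %% nr + 1L; cc <- (s - 1L) %/% nr + 1L
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0L && dc == 0L) next
        r2 <- r + dr; c2 <- cc + dc
        if (r2 < 1L || r2 > nr || c2 < 1L || c2 > nc) next
        i2 <- (c2 - 1L) * nr + r2
        if (mask[i2] && lab[i2] == 0L) {
          lab[i2] <- cur
          stack <- c(stack, i2)
        }
      }
    }
  }
  lab
}

# canonicalize a labelling so partitions can be compared across algorithms
canonical_labels <- function(lab) {
  nz <- which(lab > 0L)
  first <- tapply(seq_along(lab)[nz], lab[nz], min)
  remap <- integer(max(lab))
  remap[as.integer(names(sort(first)))] <- seq_along(first)
  out <- lab
  out[nz] <- remap[lab[nz]]
  out
}
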