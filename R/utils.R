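# internal numeric helpers shared across modules

clamp01 <- function(x) pmin(pmax(x, 0), 1)

# 2x mean-pool an H x W x 3 array; odd dimensions are padded by edge
# replication so that dim(level L+1) == ceiling(dim(level L) / 2)
pool2 <- function(img) {
  h <- dim(img)[1]; w <- dim(img)[2]
  if (h %% 2L == 1L) img <- img[c(seq_len(h), h), , , drop = FALSE]
  if (w %% 2L == 1L) img <- img[, c(seq_len(w), w), , drop = FALSE]
  h2 <- dim(img)[1] %/% 2L; w2 <- dim(img)[2] %/% 2L
  out <- array(0, c(h2, w2, dim(img)[3]))
  for (ch in seq_len(dim(img)[3])) {
    m <- img[, , ch]
    out[, , ch] <- (m[seq(1, 2 * h2, 2), seq(1, 2 * w2, 2)] +
                    m[seq(2, 2 * h2, 2), seq(1, 2 * w2, 2)] +
                    m[seq(1, 2 * h2, 2), seq(2, 2 * w2, 2)] +
                    m[seq(2, 2 * h2, 2), seq(2, 2 * w2, 2)]) / 4
  }
  out
}

# mean-pool an H x W x 3 array down to (h/f) x (w/f) x 3; f must divide dims
pool_by <- function(img, f) {
  if (f == 1L) return(img)
  h <- dim(img)[1]; w <- dim(img)[2]
  stopifnot(h %% f == 0L, w %% f == 0L)
  h2 <- h %/% f; w2 <- w %/% f
  out <- array(0, c(h2, w2, dim(img)[3]))
  for (ch in seq_len(dim(img)[3])) {
    m <- img[, , ch]
    dim(m) <- c(f, h2, f, w2)
    out[, , ch] <- colMeans(aperm(m, c(1, 3, 2, 4)), dims = 2)
  }
  out
}

# sample from a vector, treating length-1 vectors as a single value
# (avoids base sample()'s expansion of a scalar n into 1:n)
sample_from <- function(v, n = 1L, replace = FALSE) {
  v[sample.int(length(v), n, replace = replace)]
}

# derive a child RNG seed from a base seed, kept inside 32-bit range
derive_seed <- function(seed, k) {
  (as.integer(seed) %% 1000003L) * 1009L %% 2147483647L + as.integer(k)
}

# even-odd rule point-in-polygon, vectorized over query points; points
# exactly on an edge may fall on either side (polygons here are closed
# regions whose boundary has measure zero on the sampling grids)
points_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- vx[i]; yi <- vy[i]; xj <- vx[j]; yj <- vy[j]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}
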