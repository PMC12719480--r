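# Independent brute-force oracles used to validate the fast implementations.
# These deliberately use naive loops / exhaustive enumeration and never call
# the package functions they check.

oracle_dice <- function(x, y) {
  inter <- 0; sx <- 0; sy <- 0
  for (i in seq_along(x)) {
    xi <- x[i] > 0; yi <- y[i] > 0
    inter <- inter + (xi && yi)
    sx <- sx + xi; sy <- sy + yi
  }
  if (sx + sy == 0) return(1)
  2 * inter / (sx + sy)
}

oracle_jaccard <- function(x, y) {
  inter <- 0; uni <- 0
  for (i in seq_along(x)) {
    xi <- x[i] > 0; yi <- y[i] > 0
    inter <- inter + (xi && yi)
    uni <- uni + (xi || yi)
  }
  if (uni == 0) return(1)
  inter / uni
}

# all-pairs counting: P(score+ > score-) + 0.5 P(tie)
oracle_auc <- function(scores, labels) {
  pos <- which(labels > 0); neg <- which(labels <= 0)
  tot <- 0
  for (i in pos) {
    for (j in neg) {
      tot <- tot + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
    }
  }
  tot / (length(pos) * length(neg))
}

# 4-neighborhood boundary, exhaustive distance matrix, type-7 percentile
oracle_boundary <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  pts <- NULL
  for (r in seq_len(H)) {
    for (c in seq_len(W)) {
      if (mask[r, c] > 0) {
        nb <- c(
          if (r > 1) mask[r - 1, c] else 0,
          if (r < H) mask[r + 1, c] else 0,
          if (c > 1) mask[r, c - 1] else 0,
          if (c < W) mask[r, c + 1] else 0
        )
        if (r == 1 || r == H || c == 1 || c == W || any(nb == 0)) {
          pts <- rbind(pts, c(r - 1, c - 1))
        }
      }
    }
  }
  pts
}

oracle_hd95 <- function(x, y, spacing = c(1, 1), q = 0.95) {
  bx <- oracle_boundary(x)
  by <- oracle_boundary(y)
  dmat <- matrix(0, nrow(bx), nrow(by))
  for (i in seq_len(nrow(bx))) {
    for (j in seq_len(nrow(by))) {
      dmat[i, j] <- sqrt(sum(((bx[i, ] - by[j, ]) * spacing)^2))
    }
  }
  dxy <- apply(dmat, 1, min)
  dyx <- apply(dmat, 2, min)
  max(quantile(dxy, q, names = FALSE, type = 7),
      quantile(dyx, q, names = FALSE, type = 7))
}

# exhaustive minimum within-cluster sum of squares over all 2-partitions
oracle_min_inertia_k2 <- function(X) {
  n <- nrow(X)
  best <- Inf
  for (code in 1:(2^(n - 1) - 1)) { # fix point 1 in cluster A; skip all-in-A
    members <- as.logical(bitwAnd(code, 2^(0:(n - 1))))
    a <- X[!members, , drop = FALSE]
    b <- X[members, , drop = FALSE]
    wss <- sum(sweep(a, 2, colMeans(a))^2) + sum(sweep(b, 2, colMeans(b))^2)
    if (wss < best) best <- wss
  }
  best
}

random_blob_mask <- function(size = 16L, p = 0.25) {
  m <- matrix(rbinom(size * size, 1, p), size, size)
  if (sum(m) == 0) m[sample.int(size * size, 1)] <- 1
  m
}

# a small normalized phantom bundle shared by slower tests
desk_phantoms <- function(n_subjects = 10L, slices = 3L, size = 32L, seed = 7L) {
  spec <- phantom_spec(image_size = size, n_subjects = n_subjects,
                       slices_per_subject = slices, seed = seed)
  ds <- generate_dataset(spec)
  ds$norm_images <- lapply(ds$samples, function(s) zscore_normalize(s$image)$image)
  ds$masks <- lapply(ds$samples, `[[`, "mask")
  ds$labels <- ds$manifest$label
  ds
}

# adjusted Rand index by pair counting (used for planted-cluster recovery)
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(tab))
  sum_a <- sum(ch2(rowSums(tab)))
  sum_b <- sum(ch2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / ch2(n)
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}
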