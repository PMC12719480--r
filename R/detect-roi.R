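#' k-means clustering of a latent feature map
#'
#' Lloyd's algorithm over the `h' * w'` latent positions (each a
#' d-dimensional feature vector) with k-means++-style seeding.  Fully
#' deterministic given `seed`: seeding, restarts, and every tie-break are
#' derived from it.  Equidistant points are assigned to the lowest cluster
#' index; a cluster that empties is re-seeded at the point farthest from its
#' assigned centroid.  `n_restarts` independent runs are performed and the
#' lowest-inertia solution kept (ties favouring the earliest restart).
#'
#' @param latent a `latent_map` from [encode_image()], or a plain numeric
#'   matrix of observations (rows) by features.
#' @param k number of clusters (>= 2); default 2 (tumor vs background).
#' @param seed integer RNG seed.
#' @param n_restarts independent k-means++ restarts.
#' @param max_iter Lloyd iteration cap per restart.
#' @return A `cluster_result`: `assignments` (per-position index in 1..k),
#'   `centroids` (k x d), `inertia`, `sizes`, `k`, `seed`, and (for latent
#'   input) the latent grid dimensions.
#' @export
kmeans_latent <- function(latent, k = 2L, seed = 42L,
                          n_restarts = 10L, max_iter = 100L) {
  grid_dim <- NULL
  if (inherits(latent, "latent_map")) {
    gd <- dim(latent$grid)
    grid_dim <- gd
    X <- matrix(latent$grid, gd[1L] * gd[2L], gd[3L])
  } else {
    X <- as.matrix(latent)
  }
  n <- nrow(X)
  check_that(k >= 2, "k must be >= 2")
  if (k > n) abort_arg("k exceeds the number of latent positions")

  best <- NULL
  for (r in seq_len(n_restarts)) {
    run <- with_seed(hash_seed(seed, 4242, r), kmeans_once(X, k, max_iter))
    if (is.null(best) || run$inertia < best$inertia - 1e-12) best <- run
  }
  structure(
    list(assignments = best$assign, centroids = best$centroids,
         inertia = best$inertia, sizes = tabulate(best$assign, k),
         k = as.integer(k), seed = as.integer(seed),
         iterations = best$iterations, inertia_trace = best$inertia_trace,
         grid_dim = grid_dim),
    class = "cluster_result"
  )
}

# squared distances from every row of X to every centroid
dist2_to_centroids <- function(X, C) {
  outer(rowSums(X^2), rep(1, nrow(C))) +
    outer(rep(1, nrow(X)), rowSums(C^2)) -
    2 * X %*% t(C)
}

kmeans_once <- function(X, k, max_iter) {
  n <- nrow(X)
  # k-means++ seeding
  centroids <- X[sample.int(n, 1L), , drop = FALSE]
  while (nrow(centroids) < k) {
    d2 <- pmax(apply(dist2_to_centroids(X, centroids), 1L, min), 0)
    if (sum(d2) <= 0) {
      cand <- sample.int(n, 1L) # all points coincide with a centroid
    } else {
      cand <- sample.int(n, 1L, prob = d2)
    }
    centroids <- rbind(centroids, X[cand, , drop = FALSE])
  }
  assign <- integer(n)
  iterations <- 0L
  inertia_trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    iterations <- it
    d2 <- dist2_to_centroids(X, centroids)
    new_assign <- max.col(-d2, ties.method = "first") # lowest index on ties
    # re-seed empty clusters at the point farthest from its centroid
    for (j in seq_len(k)) {
      if (!any(new_assign == j)) {
        far <- which.max(d2[cbind(seq_len(n), new_assign)])
        centroids[j, ] <- X[far, ]
        new_assign[far] <- j
      }
    }
    if (identical(new_assign, assign)) break
    assign <- new_assign
    for (j in seq_len(k)) {
      centroids[j, ] <- colMeans(X[assign == j, , drop = FALSE])
    }
    d2u <- dist2_to_centroids(X, centroids)
    inertia_trace <- c(inertia_trace,
                       sum(pmax(d2u[cbind(seq_len(n), assign)], 0)))
  }
  d2 <- dist2_to_centroids(X, centroids)
  inertia <- sum(pmax(d2[cbind(seq_len(n), assign)], 0))
  list(assign = assign, centroids = centroids, inertia = inertia,
       iterations = iterations, inertia_trace = inertia_trace)
}

#' Derive a coarse ROI mask from latent clusters
#'
#' Selects the tumor-like cluster — by default the minority cluster with the
#' highest mean feature-activation norm (tumors are small, high-salience
#' regions under attention-weighted features) — marks its latent positions,
#' dilates them by `dilate` cells, and upsamples to image resolution with
#' nearest-neighbor interpolation.  The ROI is a coarse proposal whose job
#' is to constrain the segmenter's search space without excluding tumor
#' tissue, so it carries a one-cell safety margin by default.
#' A degenerate single-cluster result yields an empty ROI with a warning.
#'
#' @param cluster a `cluster_result` computed from `latent`.
#' @param latent the `latent_map` the clustering was computed from.
#' @param selection `"minority_norm"` (default), `"norm"` (highest norm
#'   regardless of size), or `"minority"` (smallest cluster).
#' @param dilate 4-neighborhood dilation radius in latent cells applied to
#'   the selected cluster's support (0 disables).
#' @return An `roi_mask`: list with `mask` (binary matrix at image
#'   resolution), `latent_mask`, `cluster_index`, and `source`.
#' @export
roi_from_clusters <- function(cluster, latent,
                              selection = c("minority_norm", "norm", "minority"),
                              dilate = 1L) {
  selection <- match.arg(selection)
  check_that(inherits(latent, "latent_map"), "latent must be a latent_map")
  gd <- dim(latent$grid)
  check_that(!is.null(cluster$grid_dim) && all(cluster$grid_dim == gd),
             "cluster was not computed from this latent map")
  X <- matrix(latent$grid, gd[1L] * gd[2L], gd[3L])
  sizes <- cluster$sizes
  present <- which(sizes > 0)
  if (length(present) < 2L) {
    warning("degenerate single-cluster result; returning empty ROI")
    empty <- matrix(0, latent$source_shape[1L], latent$source_shape[2L])
    return(structure(list(mask = empty,
                          latent_mask = matrix(0, gd[1L], gd[2L]),
                          cluster_index = NA_integer_, source = "none"),
                     class = "roi_mask"))
  }
  norms <- vapply(present, function(j) {
    mean(sqrt(rowSums(X[cluster$assignments == j, , drop = FALSE]^2)))
  }, numeric(1))
  tumor_cluster <- switch(
    selection,
    minority_norm = {
      minority <- present[sizes[present] < max(sizes[present])]
      if (length(minority) == 0L) minority <- present
      minority[which.max(norms[match(minority, present)])]
    },
    norm = present[which.max(norms)],
    minority = present[which.min(sizes[present])]
  )
  latent_mask <- matrix(as.numeric(cluster$assignments == tumor_cluster),
                        gd[1L], gd[2L])
  if (dilate > 0L) latent_mask <- dilate_mask(latent_mask, as.integer(dilate))
  mask <- resize_image(latent_mask, latent$source_shape, method = "nearest")
  structure(
    list(mask = mask, latent_mask = latent_mask,
         cluster_index = as.integer(tumor_cluster), source = "latent_kmeans"),
    class = "roi_mask"
  )
}
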