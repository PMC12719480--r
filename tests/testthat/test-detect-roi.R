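test_that("classifier builds deterministically and yields finite 2-logits", {
  cfg <- classifier_config(base_channels = 4L, n_blocks = 2L, image_size = 16L)
  m1 <- build_classifier(cfg, init_seed = 5L)
  m2 <- build_classifier(cfg, init_seed = 5L)
  expect_identical(m1$params, m2$params)
  cp <- classify(m1, matrix(rnorm(256), 16, 16))
  expect_length(cp$logits, 2L)
  expect_true(all(is.finite(cp$logits)))
  expect_equal(sum(cp$probs), 1, tolerance = 1e-6)
})

test_that("zero-initialised residual blocks start as identity mappings", {
  cfg <- classifier_config(base_channels = 4L, n_blocks = 1L,
                           downsample = FALSE, zero_init_residual = TRUE,
                           image_size = 8L)
  m <- build_classifier(cfg, init_seed = 2L)
  x <- array(rnorm(8 * 8 * 1 * 2), c(8, 8, 1, 2))
  tp <- tumorseg:::nn_tape(m, training = FALSE)
  stem <- tumorseg:::f_relu(tp, "s_act",
    tumorseg:::f_bn(tp, "stem_bn", tumorseg:::f_conv(tp, "stem", x)))
  fw <- tumorseg:::classifier_forward(m, x, return_features = TRUE)
  expect_equal(fw$features, stem, tolerance = 1e-12)
})

test_that("softmax probabilities: symmetry, closed form, shift invariance", {
  expect_equal(tumorseg:::softmax_vec(c(3, 3)), c(0.5, 0.5))
  expect_equal(tumorseg:::softmax_vec(c(0, log(3))), c(0.25, 0.75), tolerance = 1e-12)
  set.seed(40)
  z <- rnorm(4)
  expect_equal(tumorseg:::softmax_vec(z + 100), tumorseg:::softmax_vec(z),
               tolerance = 1e-9)
})

test_that("classifier training separates easy phantoms and rejects one-class sets", {
  ds <- desk_phantoms(n_subjects = 12L, slices = 3L, size = 32L, seed = 23L)
  cfg <- classifier_config(base_channels = 6L, n_blocks = 2L, image_size = 32L)
  m <- build_classifier(cfg, init_seed = 42L)
  test_idx <- seq(3L, 36L, by = 3L) # last slice of every subject
  train_idx <- setdiff(1:36, test_idx)
  fit <- train_classifier(m, ds$norm_images[train_idx], ds$labels[train_idx],
                          train_config(max_epochs = 6L, seed = 42L))
  preds <- vapply(test_idx, function(i) classify(fit$model, ds$norm_images[[i]])$probs[2],
                  numeric(1))
  acc <- mean((preds >= 0.5) == (ds$labels[test_idx] == "tumor"))
  expect_gte(acc, 0.9)
  expect_error(
    train_classifier(m, ds$norm_images[1:3], rep("tumor", 3), train_config()),
    "single class")
  fit0 <- train_classifier(m, ds$norm_images[train_idx], ds$labels[train_idx],
                           train_config(max_epochs = 0L))
  expect_identical(fit0$model$params, m$params)
})

test_that("gate thresholds behave at the boundaries and are monotone", {
  cp <- structure(list(probs = c(0.4, 0.6)), class = "class_prob")
  expect_equal(gate(cp, tau = 0), "segment")
  expect_equal(gate(cp, tau = 1), "skip")
  expect_equal(gate(0.6, tau = 0.5), "segment")
  taus <- seq(0, 1, by = 0.05)
  decisions <- vapply(taus, function(t) gate(0.37, t), character(1))
  # increasing tau never converts a skip back into a segment
  expect_true(all(diff(decisions == "segment") <= 0))
  expect_error(gate(0.5, tau = 2), "tau")
})

test_that("k-means: exact two-point fit, tie-breaks, determinism", {
  X <- matrix(c(0, 0, 10, 10), 2, 2, byrow = TRUE)
  cl <- kmeans_latent(X, k = 2, seed = 1L)
  expect_equal(sort(cl$sizes), c(1L, 1L))
  expect_equal(cl$inertia, 0)
  cl2 <- kmeans_latent(X, k = 2, seed = 1L)
  expect_identical(cl[c("assignments", "centroids", "inertia")],
                   cl2[c("assignments", "centroids", "inertia")])
  expect_error(kmeans_latent(X, k = 3, seed = 1L), "exceeds")
  expect_error(kmeans_latent(X, k = 1, seed = 1L), "k must be")
})

test_that("k-means reaches the exhaustive-partition optimum on tiny sets", {
  set.seed(41)
  for (i in 1:50) {
    n <- sample(4:8, 1)
    X <- matrix(runif(n * 2, 0, 10), n, 2)
    cl <- kmeans_latent(X, k = 2, seed = i)
    expect_equal(cl$inertia, oracle_min_inertia_k2(X), tolerance = 1e-8)
    # converged assignments are nearest-centroid
    d2 <- tumorseg:::dist2_to_centroids(X, cl$centroids)
    expect_equal(cl$assignments, max.col(-d2, ties.method = "first"))
  }
})

test_that("k-means inertia is non-increasing across Lloyd iterations", {
  set.seed(42)
  for (i in 1:10) {
    X <- matrix(rnorm(60 * 3), 60, 3)
    cl <- kmeans_latent(X, k = 3, seed = i, n_restarts = 1L)
    tr <- cl$inertia_trace
    if (length(tr) > 1) expect_true(all(diff(tr) <= 1e-9))
  }
})

test_that("planted two-Gaussian clusters are recovered almost perfectly", {
  set.seed(43)
  truth <- rep(1:2, each = 100)
  X <- rbind(matrix(rnorm(100 * 2, mean = 0, sd = 1), 100, 2),
             matrix(rnorm(100 * 2, mean = 10, sd = 1), 100, 2))
  cl <- kmeans_latent(X, k = 2, seed = 9L)
  expect_gte(adjusted_rand(cl$assignments, truth), 0.95)
  # independent cross-check against the reference implementation
  km <- stats::kmeans(X, centers = 2, nstart = 10)
  expect_equal(cl$inertia, km$tot.withinss, tolerance = 1e-6)
})

test_that("ROI selection handles degenerate clusters and keeps image shape", {
  lat <- structure(
    list(grid = array(1, dim = c(4, 4, 3)), source_shape = c(32L, 32L),
         downsample_factor = 8L),
    class = "latent_map")
  cl <- list(assignments = rep(1L, 16), sizes = c(16L, 0L), k = 2L,
             grid_dim = c(4L, 4L, 3L))
  expect_warning(roi <- roi_from_clusters(cl, lat), "degenerate")
  expect_equal(dim(roi$mask), c(32L, 32L))
  expect_equal(sum(roi$mask), 0)
  expect_identical(roi$source, "none")
})

test_that("latent k-means ROI recalls the tumor on trained phantoms", {
  ds <- desk_phantoms(n_subjects = 10L, slices = 3L, size = 32L, seed = 29L)
  cfg <- gae_config(encoder_depth = 2L, base_channels = 6L,
                    latent_channels = 16L, attention_dim = 8L, image_size = 32L)
  m <- build_gae(cfg, init_seed = 42L)
  held_out <- seq(3L, 30L, by = 3L) # last slice of every subject
  fit <- pretrain_gae(m, ds$norm_images[-held_out],
                      train_config(learning_rate = 1e-3, max_epochs = 4L, seed = 42L))
  pos <- intersect(held_out, which(ds$labels == "tumor"))[1:4]
  recalls <- vapply(pos, function(i) {
    lat <- encode_image(fit$model, ds$norm_images[[i]])
    cl <- kmeans_latent(lat, k = 2, seed = 42L)
    roi <- roi_from_clusters(cl, lat)
    expect_equal(dim(roi$mask), dim(ds$masks[[i]]))
    lat_truth <- resize_image(ds$masks[[i]], dim(lat$grid)[1:2], "nearest")
    if (sum(lat_truth) == 0) return(NA_real_)
    sum(roi$latent_mask > 0 & lat_truth > 0) / sum(lat_truth)
  }, numeric(1))
  expect_gte(mean(recalls, na.rm = TRUE), 0.8)
})
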