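test_that("scaled dot-product attention: convexity, singleton, uniform cases", {
  set.seed(30)
  # hand-computed 2x2 example: softmax(1/1, 0/1) = (0.7311, 0.2689)
  out <- scaled_dot_attention(Q = matrix(c(1, 0), 1, 2),
                              K = matrix(c(1, 0, 0, 1), 2, 2, byrow = TRUE),
                              V = matrix(c(1, 0, 0, 1), 2, 2, byrow = TRUE),
                              d_k = 1)
  expect_equal(as.vector(out$output), c(0.7310586, 0.2689414), tolerance = 1e-6)
  # singleton key/value: output equals that value row for every query
  outs <- scaled_dot_attention(matrix(rnorm(6), 3, 2),
                               matrix(c(0.3, -1), 1, 2),
                               matrix(c(5, 7, 9), 1, 3))
  expect_equal(outs$output, matrix(rep(c(5, 7, 9), each = 3), 3, 3))
  # identical keys: uniform weights, output = column mean of V
  K <- matrix(rep(c(1, 2), 4), 4, 2, byrow = TRUE)
  V <- matrix(rnorm(8), 4, 2)
  outu <- scaled_dot_attention(matrix(rnorm(4), 2, 2), K, V)
  expect_equal(outu$output[1, ], colMeans(V), tolerance = 1e-12)
  expect_error(scaled_dot_attention(matrix(0, 2, 3), matrix(0, 2, 2), matrix(0, 2, 2)),
               "column dimension")
})

test_that("attention weight rows are simplex vectors on random inputs", {
  set.seed(31)
  for (i in 1:20) {
    nq <- sample(1:6, 1); nk <- sample(1:6, 1); dk <- sample(1:4, 1)
    out <- scaled_dot_attention(matrix(rnorm(nq * dk, sd = 3), nq, dk),
                                matrix(rnorm(nk * dk, sd = 3), nk, dk),
                                matrix(rnorm(nk * 2), nk, 2))
    expect_true(all(out$weights >= 0))
    expect_equal(rowSums(out$weights), rep(1, nq), tolerance = 1e-6)
  }
})

test_that("builder determinism, bottleneck geometry, and underflow errors", {
  cfg <- gae_config(encoder_depth = 4L, base_channels = 4L,
                    latent_channels = 8L, attention_dim = 4L, image_size = 64L)
  m1 <- build_gae(cfg, init_seed = 7L)
  m2 <- build_gae(cfg, init_seed = 7L)
  expect_identical(m1$params, m2$params)
  m3 <- build_gae(cfg, init_seed = 8L)
  expect_false(identical(m1$params, m3$params))
  lat <- encode_image(m1, matrix(rnorm(64 * 64), 64, 64))
  expect_equal(dim(lat$grid), c(4L, 4L, 8L))
  expect_equal(lat$downsample_factor, 16L)
  expect_error(gae_config(encoder_depth = 7L, image_size = 64L), "halved")
})

test_that("reconstruction restores the input shape and stays finite", {
  cfg <- gae_config(encoder_depth = 2L, base_channels = 4L,
                    latent_channels = 8L, attention_dim = 4L, image_size = 16L)
  for (seed in 1:5) {
    m <- build_gae(cfg, init_seed = seed)
    rec <- reconstruct_image(m, matrix(0, 16, 16))
    expect_equal(dim(rec), c(16L, 16L))
    expect_true(all(is.finite(rec)))
  }
})

test_that("zero-epoch pretraining is a no-op with empty history", {
  cfg <- gae_config(encoder_depth = 2L, base_channels = 4L,
                    latent_channels = 8L, attention_dim = 4L, image_size = 16L)
  m <- build_gae(cfg, init_seed = 1L)
  imgs <- replicate(4, matrix(rnorm(256), 16, 16), simplify = FALSE)
  fit <- pretrain_gae(m, imgs, train_config(max_epochs = 0L))
  expect_identical(fit$model$params, m$params)
  expect_equal(nrow(fit$history), 0L)
  expect_error(pretrain_gae(m, list(), train_config()), "at least one")
})

test_that("pretraining reduces reconstruction error deterministically", {
  ds <- desk_phantoms(n_subjects = 8L, slices = 3L, size = 32L, seed = 17L)
  cfg <- gae_config(encoder_depth = 3L, base_channels = 4L,
                    latent_channels = 16L, attention_dim = 8L, image_size = 32L)
  m <- build_gae(cfg, init_seed = 42L)
  tc <- train_config(learning_rate = 1e-3, max_epochs = 3L, seed = 42L)
  mse0 <- reconstruction_mse(m, ds$norm_images)
  f1 <- pretrain_gae(m, ds$norm_images, tc)
  f2 <- pretrain_gae(m, ds$norm_images, tc)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$model$params, f2$model$params)
  expect_lt(reconstruction_mse(f1$model, ds$norm_images), mse0)
  expect_equal(nrow(f1$history), 3L)
  # loss history non-increasing up to 10% transient upticks
  tl <- f1$history$train_loss
  if (length(tl) > 1) {
    expect_true(all(diff(tl) <= 0.1 * tl[-length(tl)]))
  }
})

test_that("trained latents separate tumor from background positions", {
  ds <- desk_phantoms(n_subjects = 10L, slices = 3L, size = 32L, seed = 19L)
  cfg <- gae_config(encoder_depth = 3L, base_channels = 6L,
                    latent_channels = 16L, attention_dim = 8L, image_size = 32L)
  m <- build_gae(cfg, init_seed = 42L)
  # hold out the last slice of every subject; train on the rest
  held_out <- seq(3L, 30L, by = 3L)
  fit <- pretrain_gae(m, ds$norm_images[-held_out],
                      train_config(learning_rate = 1e-3, max_epochs = 4L, seed = 42L))
  # held-out positive slices: latent norm inside tumor vs outside
  pos_idx <- intersect(held_out, which(ds$labels == "tumor"))[1:3]
  effects <- vapply(pos_idx, function(i) {
    lat <- encode_image(fit$model, ds$norm_images[[i]])
    lat_mask <- resize_image(ds$masks[[i]], dim(lat$grid)[1:2], "nearest")
    feats <- matrix(lat$grid, prod(dim(lat$grid)[1:2]), dim(lat$grid)[3])
    norms <- sqrt(rowSums(feats^2))
    inside <- norms[lat_mask > 0]
    outside <- norms[lat_mask == 0]
    abs(mean(inside) - mean(outside)) /
      sqrt((stats::var(inside) + stats::var(outside)) / 2)
  }, numeric(1))
  expect_gt(mean(effects), 0.5)
})
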