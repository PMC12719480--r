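test_that("attention U-Net: deterministic init, output shape and range", {
  cfg <- unet_config(depth = 2L, base_channels = 4L, image_size = 16L)
  m1 <- build_attention_unet(cfg, init_seed = 3L)
  m2 <- build_attention_unet(cfg, init_seed = 3L)
  expect_identical(m1$params, m2$params)
  x <- array(rnorm(16 * 16 * 1 * 2), c(16, 16, 1, 2))
  fw <- tumorseg:::unet_forward(m1, x)
  expect_equal(dim(fw$prob), c(16L, 16L, 1L, 2L))
  expect_true(all(fw$prob >= 0 & fw$prob <= 1))
  # minimal config: depth-1 net on an 8x8 input runs forward
  mini <- build_attention_unet(unet_config(depth = 1L, base_channels = 2L,
                                           image_size = 8L), init_seed = 1L)
  fmini <- tumorseg:::unet_forward(mini, array(rnorm(64), c(8, 8, 1, 1)))
  expect_equal(dim(fmini$prob), c(8L, 8L, 1L, 1L))
  expect_error(unet_config(depth = 5L, image_size = 16L), "too small")
})

test_that("attention gate limits: sigmoid(0) = 1/2, saturation, suppression", {
  set.seed(50)
  skip_feats <- array(rnorm(4 * 4 * 3 * 2), c(4, 4, 3, 2))
  gating <- array(rnorm(4 * 4 * 2 * 2), c(4, 4, 2, 2))
  zero_p <- list(Wx = matrix(0, 3, 4), Wg = matrix(0, 2, 4), b = rep(0, 4),
                 psi = matrix(0, 4, 1), b_psi = 0)
  out <- attention_gate(skip_feats, gating, zero_p)
  expect_equal(out$weights, array(0.5, c(4, 4, 1, 2)))
  expect_equal(out$output, skip_feats / 2, tolerance = 1e-12)
  # saturated gates: w -> 1 passes the skip unchanged, w -> 0 suppresses it
  sat1 <- zero_p; sat1$b_psi <- 50
  expect_equal(attention_gate(skip_feats, gating, sat1)$output, skip_feats,
               tolerance = 1e-12)
  sat0 <- zero_p; sat0$b_psi <- -50
  expect_equal(max(abs(attention_gate(skip_feats, gating, sat0)$output)), 0,
               tolerance = 1e-12)
  expect_error(attention_gate(skip_feats, gating, list(Wx = matrix(0, 2, 4),
                                                       Wg = matrix(0, 2, 4))),
               "channel")
})

test_that("soft voting: idempotence, means, degenerate weights, bounds", {
  a <- matrix(0.2, 4, 4)
  b <- matrix(0.8, 4, 4)
  cfg2 <- ensemble_config(members = c("a", "b"))
  expect_equal(soft_vote(list(a, a), cfg2), a)
  expect_equal(soft_vote(list(a, b), cfg2), matrix(0.5, 4, 4))
  w10 <- ensemble_config(members = c("a", "b"), weights = c(1, 0))
  expect_equal(soft_vote(list(a, b), w10), a)
  set.seed(51)
  maps <- replicate(3, matrix(runif(16), 4, 4), simplify = FALSE)
  cfg3 <- ensemble_config(members = letters[1:3], weights = runif(3) + 0.1)
  fused <- soft_vote(maps, cfg3)
  lo <- pmin(maps[[1]], maps[[2]], maps[[3]])
  hi <- pmax(maps[[1]], maps[[2]], maps[[3]])
  expect_true(all(fused >= lo - 1e-12 & fused <= hi + 1e-12))
  expect_error(soft_vote(list(a, matrix(0.1, 2, 2)), cfg2), "match")
})

test_that("early stopping halts after patience epochs without improvement", {
  # tiny net on noise: validation loss cannot improve for long
  set.seed(52)
  cfg <- unet_config(depth = 1L, base_channels = 2L, image_size = 8L)
  m <- build_attention_unet(cfg, init_seed = 4L)
  imgs <- replicate(8, matrix(rnorm(64), 8, 8), simplify = FALSE)
  msks <- replicate(8, matrix(rbinom(64, 1, 0.5), 8, 8), simplify = FALSE)
  val <- list(images = imgs[7:8], masks = msks[7:8])
  fit <- train_segmenter(m, imgs[1:6], msks[1:6],
                         train_config(max_epochs = 30L, patience = 2L,
                                      learning_rate = 1e-4, seed = 1L),
                         val = val)
  n <- nrow(fit$history)
  expect_lt(n, 30L)
  # the two final epochs did not improve on the best validation loss
  best <- min(fit$history$val_loss[seq_len(n - 2)])
  expect_true(all(fit$history$val_loss[(n - 1):n] >= best - 1e-9))
  expect_error(
    train_segmenter(m, imgs[1:6], msks[1:6], train_config(),
                    val = NULL, early_stopping = TRUE),
    "validation")
})

test_that("segmenter training is deterministic and a zero-epoch run is a no-op", {
  ds <- desk_phantoms(n_subjects = 6L, slices = 2L, size = 32L, seed = 31L)
  cfg <- unet_config(depth = 2L, base_channels = 4L, image_size = 32L)
  m <- build_attention_unet(cfg, init_seed = 42L)
  tc <- train_config(learning_rate = 1e-3, max_epochs = 2L, seed = 42L)
  f1 <- train_segmenter(m, ds$norm_images, ds$masks, tc)
  f2 <- train_segmenter(m, ds$norm_images, ds$masks, tc)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$model$params, f2$model$params)
  f0 <- train_segmenter(m, ds$norm_images, ds$masks,
                        train_config(max_epochs = 0L))
  expect_identical(f0$model$params, m$params)
})

test_that("a light U-Net reaches Dice >= 0.9 on easy phantoms", {
  spec <- phantom_spec(image_size = 32L, n_subjects = 25L,
                       slices_per_subject = 2L, tumor_prevalence = 1,
                       tumor_contrast = 0.8, noise_sigma = 0.03, seed = 33L)
  ds <- generate_dataset(spec)
  imgs <- lapply(ds$samples, function(s) zscore_normalize(s$image)$image)
  msks <- lapply(ds$samples, `[[`, "mask")
  cfg <- unet_config(depth = 2L, base_channels = 8L, image_size = 32L)
  m <- build_attention_unet(cfg, init_seed = 42L)
  fit <- train_segmenter(m, imgs, msks,
                         train_config(learning_rate = 2e-3, max_epochs = 10L,
                                      seed = 42L))
  pm <- predict_prob_maps(fit$model, imgs)
  dice <- mean(mapply(function(p, g) dice_coefficient(p >= 0.5, g), pm, msks))
  expect_gte(dice, 0.9)
})

test_that("residual U-Net trains and encoder transfer copies matching stages", {
  cfgU <- unet_config(depth = 2L, base_channels = 6L, image_size = 32L)
  ru <- build_residual_unet(cfgU, init_seed = 8L)
  expect_true(ru$config$residual_encoder)
  expect_false(ru$config$use_attention_gates)
  x <- array(rnorm(32 * 32), c(32, 32, 1, 1))
  expect_equal(dim(tumorseg:::unet_forward(ru, x)$prob), c(32L, 32L, 1L, 1L))

  gcfg <- gae_config(encoder_depth = 3L, base_channels = 6L,
                     latent_channels = 24L, attention_dim = 8L, image_size = 32L)
  g <- build_gae(gcfg, init_seed = 9L)
  un <- build_attention_unet(cfgU, init_seed = 10L)
  un2 <- transfer_encoder_weights(un, g)
  expect_identical(un2$params[["enc1.W"]], g$params[["enc1.W"]])
  expect_identical(un2$params[["enc2.W"]], g$params[["enc2.W"]])
  # ROI-channel variant: first input-channel slice transferred, extra kept
  cfg2 <- unet_config(depth = 2L, base_channels = 6L, in_channels = 2L,
                      image_size = 32L)
  un3 <- transfer_encoder_weights(build_attention_unet(cfg2, 11L), g)
  expect_identical(un3$params[["enc1.W"]][, , 1L, ], g$params[["enc1.W"]][, , 1L, ])
})
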