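#' Configuration of the generative autoencoder
#'
#' The encoder is a chain of `encoder_depth` conv(3x3, stride 2) + batch
#' norm + ReLU stages, each halving the spatial resolution; channel widths
#' double per stage from `base_channels`, with the final stage widened to
#' `latent_channels`.  A scaled dot-product self-attention block (with a
#' residual connection) acts on the flattened bottleneck positions through
#' learned linear Q/K/V projections.  The decoder mirrors the encoder with
#' nearest-neighbor upsampling + conv stages and a linear 1x1 output head
#' (reconstructions are real-valued, matching z-scored inputs).
#'
#' @param encoder_depth number of halving stages (>= 1).
#' @param base_channels channels of the first stage.
#' @param latent_channels bottleneck feature dimension d.
#' @param attention_dim key/query dimension d_k (<= latent_channels).
#' @param batch_norm use batch normalisation (default TRUE).
#' @param use_attention apply the bottleneck self-attention block.
#' @param in_channels input image channels.
#' @param image_size expected square input size; must be divisible by
#'   `2^encoder_depth`.
#' @export
gae_config <- function(encoder_depth = 4L,
                       base_channels = 16L,
                       latent_channels = 64L,
                       attention_dim = 32L,
                       batch_norm = TRUE,
                       use_attention = TRUE,
                       in_channels = 1L,
                       image_size = 64L) {
  check_that(encoder_depth >= 1, "encoder_depth must be >= 1")
  check_that(latent_channels >= attention_dim && attention_dim >= 1,
             "need latent_channels >= attention_dim >= 1")
  if (image_size %% 2^encoder_depth != 0 || image_size < 2^encoder_depth) {
    abort_arg(sprintf(
      "config error: image size %d cannot be halved %d times",
      image_size, encoder_depth))
  }
  structure(
    list(encoder_depth = as.integer(encoder_depth),
         base_channels = as.integer(base_channels),
         latent_channels = as.integer(latent_channels),
         attention_dim = as.integer(attention_dim),
         batch_norm = isTRUE(batch_norm),
         use_attention = isTRUE(use_attention),
         in_channels = as.integer(in_channels),
         image_size = as.integer(image_size)),
    class = "gae_config"
  )
}

gae_channels <- function(config) {
  d <- config$encoder_depth
  ch <- config$base_channels * 2^(seq_len(d) - 1L)
  ch[d] <- config$latent_channels
  c(config$in_channels, ch)
}

#' Build a generative autoencoder
#'
#' Parameters are He-normal initialised under `init_seed`; rebuilding with
#' the same `(config, init_seed)` reproduces identical tensors.
#'
#' @param config a [gae_config()].
#' @param init_seed integer seed for weight initialisation.
#' @return A model bundle (list with `config`, `init_seed`, `params`,
#'   `buffers`).
#' @export
build_gae <- function(config, init_seed = 42L) {
  ch <- gae_channels(config)
  d <- config$encoder_depth
  with_seed(init_seed, {
    b <- nn_builder()
    for (i in seq_len(d)) {
      init_conv(b, paste0("enc", i), 3L, ch[i], ch[i + 1L])
      if (config$batch_norm) init_bn(b, paste0("enc", i, "_bn"), ch[i + 1L])
    }
    if (config$use_attention) {
      init_attention(b, "attn", config$latent_channels, config$attention_dim)
    }
    for (i in rev(seq_len(d))) {
      init_conv(b, paste0("dec", i), 3L, ch[i + 1L], max(ch[i], config$base_channels))
      if (config$batch_norm) {
        init_bn(b, paste0("dec", i, "_bn"), max(ch[i], config$base_channels))
      }
    }
    init_conv(b, "head", 1L, max(ch[1L], config$base_channels), config$in_channels)
    structure(
      list(config = config, init_seed = as.integer(init_seed),
           params = b$params, buffers = b$buffers, kind = "gae"),
      class = "nn_model"
    )
  })
}

# forward through the encoder only; returns bottleneck tensor
gae_encode_fw <- function(tp, config, x) {
  d <- config$encoder_depth
  h <- x
  for (i in seq_len(d)) {
    h <- f_conv(tp, paste0("enc", i), h, stride = 2L)
    if (config$batch_norm) h <- f_bn(tp, paste0("enc", i, "_bn"), h)
    h <- f_relu(tp, paste0("enc", i, "_act"), h)
  }
  if (config$use_attention) h <- f_attention(tp, "attn", h)
  h
}

gae_decode_fw <- function(tp, config, z) {
  d <- config$encoder_depth
  h <- z
  for (i in rev(seq_len(d))) {
    h <- f_upsample2(tp, paste0("up", i), h)
    h <- f_conv(tp, paste0("dec", i), h, stride = 1L)
    if (config$batch_norm) h <- f_bn(tp, paste0("dec", i, "_bn"), h)
    h <- f_relu(tp, paste0("dec", i, "_act"), h)
  }
  f_conv(tp, "head", h, stride = 1L)
}

gae_forward <- function(model, x, training = FALSE) {
  check_that(dim(x)[1L] == model$config$image_size &&
               dim(x)[2L] == model$config$image_size,
             "input shape does not match the configured image size")
  tp <- nn_tape(model, training)
  z <- gae_encode_fw(tp, model$config, x)
  recon <- gae_decode_fw(tp, model$config, z)
  list(recon = recon, latent = z, tape = tp)
}

gae_backward <- function(tp, config, drecon) {
  d <- config$encoder_depth
  dh <- b_conv(tp, "head", drecon)
  for (i in seq_len(d)) {
    dh <- b_relu(tp, paste0("dec", i, "_act"), dh)
    if (config$batch_norm) dh <- b_bn(tp, paste0("dec", i, "_bn"), dh)
    dh <- b_conv(tp, paste0("dec", i), dh)
    dh <- b_upsample2(tp, paste0("up", i), dh)
  }
  if (config$use_attention) dh <- b_attention(tp, "attn", dh)
  for (i in rev(seq_len(d))) {
    dh <- b_relu(tp, paste0("enc", i, "_act"), dh)
    if (config$batch_norm) dh <- b_bn(tp, paste0("enc", i, "_bn"), dh)
    dh <- b_conv(tp, paste0("enc", i), dh)
  }
  dh
}

#' Encode an image to its latent feature map
#'
#' @param model a trained (or freshly built) GAE bundle.
#' @param image H x W matrix (or H x W x C array) matching the training
#'   shape.
#' @return A `latent_map`: list with `grid` (h' x w' x d array),
#'   `source_shape`, and `downsample_factor = 2^encoder_depth`.
#' @export
encode_image <- function(model, image) {
  x <- as_tensor(image)
  out <- gae_forward(model, x, training = FALSE)
  z <- out$latent
  structure(
    list(grid = array(z[, , , 1L], dim = dim(z)[1:3]),
         source_shape = dim(x)[1:2],
         downsample_factor = 2L^model$config$encoder_depth),
    class = "latent_map"
  )
}

#' Reconstruct an image through the full encode-decode round trip
#'
#' @inheritParams encode_image
#' @return Reconstructed image with the same spatial shape as the input.
#' @export
reconstruct_image <- function(model, image) {
  x <- as_tensor(image)
  out <- gae_forward(model, x, training = FALSE)
  matrix(out$recon[, , 1L, 1L], dim(x)[1L], dim(x)[2L])
}

#' Training hyperparameters
#'
#' Defaults follow the framework-wide settings: Adam, learning rate 3e-4,
#' batch size 8, up to 20 epochs, early stopping on validation loss.
#'
#' @param learning_rate Adam step size.
#' @param batch_size minibatch size.
#' @param max_epochs maximum epochs.
#' @param patience epochs without validation improvement before stopping;
#'   only active when a validation set is supplied.
#' @param seed seed controlling shuffling order.
#' @export
train_config <- function(learning_rate = 3e-4,
                         batch_size = 8L,
                         max_epochs = 20L,
                         patience = 5L,
                         seed = 42L) {
  check_that(learning_rate > 0, "learning_rate must be positive")
  check_that(batch_size >= 1, "batch_size must be >= 1")
  check_that(patience >= 1, "patience must be >= 1")
  structure(
    list(learning_rate = learning_rate, optimizer = "adam",
         batch_size = as.integer(batch_size),
         max_epochs = as.integer(max_epochs),
         patience = as.integer(patience), seed = as.integer(seed)),
    class = "train_config"
  )
}

epoch_batches <- function(n, batch_size, seed, epoch) {
  ord <- with_seed(hash_seed(seed, 7001, epoch), sample.int(n))
  split(ord, ceiling(seq_along(ord) / batch_size))
}

#' Pre-train the autoencoder by reconstruction
#'
#' Minimises mean-squared reconstruction error with Adam.  Shuffling is
#' deterministic given `train_config$seed`; two runs with identical inputs
#' produce identical loss histories.  When `val_images` is supplied,
#' training stops early after `patience` epochs without validation
#' improvement and the best-validation parameters are restored.
#'
#' @param model a GAE bundle from [build_gae()].
#' @param images list of preprocessed (z-scored) H x W images.
#' @param config a [train_config()].
#' @param val_images optional validation images for early stopping.
#' @return List with the trained `model` and `history` (data.frame with
#'   epoch, train_loss, val_loss).
#' @export
pretrain_gae <- function(model, images, config = train_config(),
                         val_images = NULL) {
  check_that(length(images) >= 1, "need at least one training image")
  x_all <- stack_images(images)
  x_val <- if (!is.null(val_images)) stack_images(val_images) else NULL
  n <- dim(x_all)[4L]
  opt <- adam_init(model$params)
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0))
  best_val <- Inf
  best_model <- model
  bad_epochs <- 0L
  if (config$max_epochs == 0L) {
    return(list(model = model, history = history))
  }
  for (epoch in seq_len(config$max_epochs)) {
    batches <- epoch_batches(n, config$batch_size, config$seed, epoch)
    ep_loss <- 0
    for (idx in batches) {
      xb <- x_all[, , , idx, drop = FALSE]
      fw <- gae_forward(model, xb, training = TRUE)
      resid <- fw$recon - xb
      loss <- mean(resid^2)
      ep_loss <- ep_loss + loss * length(idx)
      drecon <- 2 * resid / length(resid)
      gae_backward(fw$tape, model$config, drecon)
      upd <- adam_step(model$params, fw$tape$grads, opt, config$learning_rate)
      model$params <- upd$params
      opt <- upd$state
      model$buffers <- fw$tape$buffers
    }
    train_loss <- ep_loss / n
    val_loss <- NA_real_
    if (!is.null(x_val)) {
      vr <- gae_forward(model, x_val, training = FALSE)
      val_loss <- mean((vr$recon - x_val)^2)
      if (val_loss < best_val - 1e-9) {
        best_val <- val_loss
        best_model <- model
        bad_epochs <- 0L
      } else {
        bad_epochs <- bad_epochs + 1L
      }
    }
    history <- rbind(history, data.frame(epoch = epoch, train_loss = train_loss,
                                         val_loss = val_loss))
    if (!is.null(x_val) && bad_epochs >= config$patience) {
      model <- best_model
      break
    }
  }
  list(model = model, history = history)
}

#' Mean-squared reconstruction error of a GAE over a set of images
#' @param model a GAE bundle.
#' @param images list of images.
#' @export
reconstruction_mse <- function(model, images) {
  x <- stack_images(images)
  fw <- gae_forward(model, x, training = FALSE)
  mean((fw$recon - x)^2)
}
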