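#' Configuration of a segmentation U-Net
#'
#' Encoder: `depth` conv(3x3, stride 2) + BN + ReLU stages with channel
#' widths `base_channels * 2^(i-1)`; the full-resolution skip is the input
#' itself and deeper skips are the encoder stage outputs, so the encoder
#' topology matches the autoencoder's and pre-trained encoder weights can be
#' transferred.  Decoder: nearest-neighbor x2 upsampling, optional additive
#' attention gates on each skip connection, channel concatenation, and a
#' conv + BN + ReLU merge; a 1x1 conv + sigmoid head yields the per-pixel
#' tumor probability map.  `residual_encoder = TRUE` adds an identity
#' residual refinement block after each encoder stage (the second ensemble
#' member family).
#'
#' @param depth number of halving stages.
#' @param base_channels first-stage width.
#' @param in_channels input channels (2 when the ROI is concatenated as an
#'   extra input channel).
#' @param use_attention_gates gate each skip connection.
#' @param residual_encoder use residual encoder blocks (and no gates by
#'   default in that member).
#' @param image_size expected square input size, divisible by `2^depth`.
#' @export
unet_config <- function(depth = 2L,
                        base_channels = 8L,
                        in_channels = 1L,
                        use_attention_gates = TRUE,
                        residual_encoder = FALSE,
                        image_size = 64L) {
  check_that(depth >= 1, "depth must be >= 1")
  if (image_size %% 2^depth != 0 || image_size < 2^depth) {
    abort_arg(sprintf("config error: image size %d too small for depth %d",
                      image_size, depth))
  }
  structure(
    list(depth = as.integer(depth),
         base_channels = as.integer(base_channels),
         in_channels = as.integer(in_channels),
         use_attention_gates = isTRUE(use_attention_gates),
         residual_encoder = isTRUE(residual_encoder),
         image_size = as.integer(image_size)),
    class = "unet_config"
  )
}

unet_channels <- function(config) {
  c(config$in_channels, config$base_channels * 2^(seq_len(config$depth) - 1L))
}

#' Build an attention-gated U-Net
#'
#' @param config a [unet_config()].
#' @param init_seed He-normal initialisation seed.
#' @return A model bundle.
#' @export
build_attention_unet <- function(config, init_seed = 42L) {
  check_that(inherits(config, "unet_config"), "invalid config")
  ch <- unet_channels(config)
  D <- config$depth
  with_seed(init_seed, {
    b <- nn_builder()
    for (i in seq_len(D)) {
      init_conv(b, paste0("enc", i), 3L, ch[i], ch[i + 1L])
      init_bn(b, paste0("enc", i, "_bn"), ch[i + 1L])
      if (config$residual_encoder) {
        init_conv(b, paste0("encres", i, "_c1"), 3L, ch[i + 1L], ch[i + 1L])
        init_bn(b, paste0("encres", i, "_bn1"), ch[i + 1L])
        init_conv(b, paste0("encres", i, "_c2"), 3L, ch[i + 1L], ch[i + 1L])
        init_bn(b, paste0("encres", i, "_bn2"), ch[i + 1L])
      }
    }
    init_conv(b, "bott", 3L, ch[D + 1L], ch[D + 1L])
    init_bn(b, "bott_bn", ch[D + 1L])
    for (i in rev(seq_len(D))) {
      # decoder stage i: upsample from /2^i to /2^(i-1), merge with skip i-1
      c_skip <- ch[i]
      c_up <- ch[i + 1L]
      if (config$use_attention_gates) {
        init_gate(b, paste0("gate", i), c_skip, c_up,
                  max(c_skip %/% 2L, 4L))
      }
      init_conv(b, paste0("dec", i), 3L, c_skip + c_up, ch[max(i, 2L) - 0L])
      init_bn(b, paste0("dec", i, "_bn"), ch[max(i, 2L)])
    }
    init_conv(b, "head", 1L, ch[2L], 1L)
    structure(
      list(config = config, init_seed = as.integer(init_seed),
           params = b$params, buffers = b$buffers, kind = "unet"),
      class = "nn_model"
    )
  })
}

#' Build a residual-encoder U-Net (the second ensemble member)
#'
#' Same scaffold as [build_attention_unet()] but with residual encoder
#' blocks and plain (ungated) skip connections.
#'
#' @inheritParams build_attention_unet
#' @export
build_residual_unet <- function(config, init_seed = 42L) {
  config$residual_encoder <- TRUE
  config$use_attention_gates <- FALSE
  build_attention_unet(config, init_seed)
}

unet_forward <- function(model, x, training = FALSE) {
  config <- model$config
  check_that(dim(x)[1L] == config$image_size && dim(x)[3L] == config$in_channels,
             "input shape does not match the model configuration")
  D <- config$depth
  tp <- nn_tape(model, training)
  skips <- vector("list", D + 1L)
  skips[[1L]] <- x # full-resolution skip is the input itself
  h <- x
  for (i in seq_len(D)) {
    h <- f_conv(tp, paste0("enc", i), h, stride = 2L)
    h <- f_bn(tp, paste0("enc", i, "_bn"), h)
    h <- f_relu(tp, paste0("enc", i, "_act"), h)
    if (config$residual_encoder) {
      nm <- paste0("encres", i)
      r <- f_conv(tp, paste0(nm, "_c1"), h)
      r <- f_bn(tp, paste0(nm, "_bn1"), r)
      r <- f_relu(tp, paste0(nm, "_act1"), r)
      r <- f_conv(tp, paste0(nm, "_c2"), r)
      r <- f_bn(tp, paste0(nm, "_bn2"), r)
      h <- f_relu(tp, paste0(nm, "_act2"), h + r)
    }
    skips[[i + 1L]] <- h
  }
  h <- f_conv(tp, "bott", h)
  h <- f_bn(tp, "bott_bn", h)
  h <- f_relu(tp, "bott_act", h)
  for (i in rev(seq_len(D))) {
    up <- f_upsample2(tp, paste0("up", i), h)
    skip <- skips[[i]]
    if (config$use_attention_gates) {
      skip <- f_gate(tp, paste0("gate", i), skip, up)
    }
    h <- f_concat(tp, paste0("cat", i), skip, up)
    h <- f_conv(tp, paste0("dec", i), h)
    h <- f_bn(tp, paste0("dec", i, "_bn"), h)
    h <- f_relu(tp, paste0("dec", i, "_act"), h)
  }
  logits <- f_conv(tp, "head", h)
  prob <- f_sigmoid(tp, "out", logits)
  list(prob = prob, tape = tp)
}

unet_backward <- function(tp, config, dprob) {
  D <- config$depth
  dh <- b_sigmoid(tp, "out", dprob)
  dh <- b_conv(tp, "head", dh)
  dskips <- vector("list", D + 1L)
  for (i in seq_len(D)) {
    dh <- b_relu(tp, paste0("dec", i, "_act"), dh)
    dh <- b_bn(tp, paste0("dec", i, "_bn"), dh)
    dh <- b_conv(tp, paste0("dec", i), dh)
    parts <- b_concat(tp, paste0("cat", i), dh)
    dskip <- parts$da
    dup <- parts$db
    if (config$use_attention_gates) {
      gb <- b_gate(tp, paste0("gate", i), dskip)
      dskip <- gb$dx
      dup <- dup + gb$dg
    }
    dskips[[i]] <- dskip
    dh <- b_upsample2(tp, paste0("up", i), dup)
  }
  dh <- b_relu(tp, "bott_act", dh)
  dh <- b_bn(tp, "bott_bn", dh)
  dh <- b_conv(tp, "bott", dh)
  for (i in rev(seq_len(D))) {
    if (i < D) dh <- dh + dskips[[i + 1L]]
    if (config$residual_encoder) {
      nm <- paste0("encres", i)
      dsum <- b_relu(tp, paste0(nm, "_act2"), dh)
      dr <- b_bn(tp, paste0(nm, "_bn2"), dsum)
      dr <- b_conv(tp, paste0(nm, "_c2"), dr)
      dr <- b_relu(tp, paste0(nm, "_act1"), dr)
      dr <- b_bn(tp, paste0(nm, "_bn1"), dr)
      dr <- b_conv(tp, paste0(nm, "_c1"), dr)
      dh <- dsum + dr
    }
    dh <- b_relu(tp, paste0("enc", i, "_act"), dh)
    dh <- b_bn(tp, paste0("enc", i, "_bn"), dh)
    dh <- b_conv(tp, paste0("enc", i), dh)
  }
  dh + dskips[[1L]]
}

#' Transfer pre-trained autoencoder encoder weights into a U-Net
#'
#' Copies GAE encoder stage parameters (conv kernels, biases, batch-norm
#' statistics) into the matching U-Net encoder stages.  Stages are matched
#' by index; a stage is copied only where shapes agree.  When the U-Net has
#' extra input channels (e.g. a concatenated ROI channel), the first-stage
#' kernel is copied into the leading input-channel slice and the remaining
#' slices keep their fresh initialisation.
#'
#' @param unet a U-Net bundle.
#' @param gae a trained GAE bundle.
#' @return The U-Net with transferred encoder weights.
#' @export
transfer_encoder_weights <- function(unet, gae) {
  D <- min(unet$config$depth, gae$config$encoder_depth)
  for (i in seq_len(D)) {
    src_w <- gae$params[[paste0("enc", i, ".W")]]
    dst_w <- unet$params[[paste0("enc", i, ".W")]]
    if (is.null(src_w) || is.null(dst_w)) next
    ds <- dim(src_w)
    dd <- dim(dst_w)
    if (all(ds == dd)) {
      unet$params[[paste0("enc", i, ".W")]] <- src_w
    } else if (all(ds[c(1, 2, 4)] == dd[c(1, 2, 4)]) && ds[3] < dd[3]) {
      dst_w[, , seq_len(ds[3]), ] <- src_w
      unet$params[[paste0("enc", i, ".W")]] <- dst_w
    } else {
      next
    }
    unet$params[[paste0("enc", i, ".b")]] <- gae$params[[paste0("enc", i, ".b")]]
    for (suffix in c(".gamma", ".beta")) {
      src <- gae$params[[paste0("enc", i, "_bn", suffix)]]
      if (!is.null(src)) unet$params[[paste0("enc", i, "_bn", suffix)]] <- src
    }
    for (suffix in c(".mean", ".var")) {
      src <- gae$buffers[[paste0("enc", i, "_bn", suffix)]]
      if (!is.null(src)) unet$buffers[[paste0("enc", i, "_bn", suffix)]] <- src
    }
  }
  unet
}
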