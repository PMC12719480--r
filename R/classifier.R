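#' Configuration of the tumor-presence classifier
#'
#' A depth-scalable residual CNN: a conv stem followed by `n_blocks`
#' residual blocks (two 3x3 conv + BN layers with an identity or projected
#' shortcut), global average pooling, and a dense head producing 2-class
#' logits.  The desk-scale preset is a reduced residual stack in the
#' ResNet-18 family.  Input can be the preprocessed image (default) or the
#' autoencoder latent map.
#'
#' @param input `"image"` or `"latent"`.
#' @param in_channels input channel count (1 for grayscale images, the
#'   latent dimension d for latent input).
#' @param base_channels stem width.
#' @param n_blocks number of residual blocks.
#' @param downsample halve resolution (stride-2 first conv) in each block.
#' @param zero_init_residual initialise each block's residual scale at 0 so
#'   blocks start as identity mappings.
#' @param image_size expected square input size.
#' @param n_classes number of output classes.
#' @export
classifier_config <- function(input = c("image", "latent"),
                              in_channels = 1L,
                              base_channels = 8L,
                              n_blocks = 2L,
                              downsample = TRUE,
                              zero_init_residual = FALSE,
                              image_size = 64L,
                              n_classes = 2L) {
  input <- match.arg(input)
  check_that(n_blocks >= 1, "need at least one residual block")
  check_that(base_channels >= 1, "base_channels must be positive")
  if (downsample && image_size < 2^(n_blocks + 0L)) {
    abort_arg("config error: input too small for the requested block count")
  }
  structure(
    list(input = input, in_channels = as.integer(in_channels),
         base_channels = as.integer(base_channels),
         n_blocks = as.integer(n_blocks),
         downsample = isTRUE(downsample),
         zero_init_residual = isTRUE(zero_init_residual),
         image_size = as.integer(image_size),
         n_classes = as.integer(n_classes)),
    class = "classifier_config"
  )
}

cls_channels <- function(config) {
  if (config$downsample) {
    c(config$base_channels,
      config$base_channels * 2^seq_len(config$n_blocks))
  } else {
    rep(config$base_channels, config$n_blocks + 1L) # constant width, identity shortcuts
  }
}

#' Build the residual classifier
#'
#' @param config a [classifier_config()].
#' @param init_seed seed for He-normal initialisation.
#' @return A model bundle.
#' @export
build_classifier <- function(config, init_seed = 42L) {
  check_that(inherits(config, "classifier_config"), "invalid config")
  ch <- cls_channels(config)
  with_seed(init_seed, {
    b <- nn_builder()
    init_conv(b, "stem", 3L, config$in_channels, ch[1L])
    init_bn(b, "stem_bn", ch[1L])
    for (i in seq_len(config$n_blocks)) {
      cin <- ch[i]
      cout <- ch[i + 1L]
      init_conv(b, paste0("blk", i, "_c1"), 3L, cin, cout)
      init_bn(b, paste0("blk", i, "_bn1"), cout)
      init_conv(b, paste0("blk", i, "_c2"), 3L, cout, cout)
      init_bn(b, paste0("blk", i, "_bn2"), cout)
      if (cin != cout || config$downsample) {
        init_conv(b, paste0("blk", i, "_proj"), 1L, cin, cout)
      }
      init_scalar(b, paste0("blk", i, "_scale"),
                  if (config$zero_init_residual) 0 else 1)
    }
    init_dense(b, "fc", ch[config$n_blocks + 1L], config$n_classes)
    structure(
      list(config = config, init_seed = as.integer(init_seed),
           params = b$params, buffers = b$buffers, kind = "classifier"),
      class = "nn_model"
    )
  })
}

classifier_features_fw <- function(tp, config, x) {
  h <- f_conv(tp, "stem", x, stride = 1L)
  h <- f_bn(tp, "stem_bn", h)
  h <- f_relu(tp, "stem_act", h)
  stride <- if (config$downsample) 2L else 1L
  for (i in seq_len(config$n_blocks)) {
    nm <- paste0("blk", i)
    r <- f_conv(tp, paste0(nm, "_c1"), h, stride = stride)
    r <- f_bn(tp, paste0(nm, "_bn1"), r)
    r <- f_relu(tp, paste0(nm, "_act1"), r)
    r <- f_conv(tp, paste0(nm, "_c2"), r, stride = 1L)
    r <- f_bn(tp, paste0(nm, "_bn2"), r)
    short <- if (!is.null(tp$params[[paste0(nm, "_proj.W")]])) {
      f_conv(tp, paste0(nm, "_proj"), h, stride = stride)
    } else {
      h
    }
    tp$cache[[paste0(nm, "_resid")]] <- r
    h <- f_relu(tp, paste0(nm, "_act2"),
                short + tp$params[[paste0(nm, "_scale")]] * r)
  }
  h
}

classifier_forward <- function(model, x, training = FALSE,
                               return_features = FALSE) {
  tp <- nn_tape(model, training)
  feat <- classifier_features_fw(tp, model$config, x)
  pooled <- f_gap(tp, "gap", feat)
  logits <- f_dense(tp, "fc", pooled)
  if (return_features) {
    list(logits = logits, features = feat, tape = tp)
  } else {
    list(logits = logits, tape = tp)
  }
}

classifier_backward <- function(tp, config, dlogits) {
  dp <- b_dense(tp, "fc", dlogits)
  dh <- b_gap(tp, "gap", dp)
  stride <- if (config$downsample) 2L else 1L
  for (i in rev(seq_len(config$n_blocks))) {
    nm <- paste0("blk", i)
    dsum <- b_relu(tp, paste0(nm, "_act2"), dh)
    scale <- tp$params[[paste0(nm, "_scale")]]
    gacc(tp, paste0(nm, "_scale"), sum(dsum * tp$cache[[paste0(nm, "_resid")]]))
    dr <- scale * dsum
    dshort <- dsum
    dr <- b_bn(tp, paste0(nm, "_bn2"), dr)
    dr <- b_conv(tp, paste0(nm, "_c2"), dr)
    dr <- b_relu(tp, paste0(nm, "_act1"), dr)
    dr <- b_bn(tp, paste0(nm, "_bn1"), dr)
    dr <- b_conv(tp, paste0(nm, "_c1"), dr)
    if (!is.null(tp$params[[paste0(nm, "_proj.W")]])) {
      dshort <- b_conv(tp, paste0(nm, "_proj"), dshort)
    }
    dh <- dr + dshort
  }
  dh <- b_relu(tp, "stem_act", dh)
  dh <- b_bn(tp, "stem_bn", dh)
  b_conv(tp, "stem", dh)
}

#' Classify an image (or latent map)
#'
#' Softmax class probabilities `P(Y_i) = exp(x_i) / sum_j exp(x_j)` over the
#' network logits.  Class order is `(non_tumor, tumor)`.
#'
#' @param model a classifier bundle.
#' @param input H x W image matrix, H x W x C array, or a `latent_map`
#'   (when the model was configured with `input = "latent"`).
#' @return A `class_prob`: list with `probs`, `logits`, and
#'   `predicted` (`"tumor"` or `"non_tumor"`).
#' @export
classify <- function(model, input) {
  if (inherits(input, "latent_map")) input <- input$grid
  x <- as_tensor(input)
  out <- classifier_forward(model, x, training = FALSE)
  logits <- out$logits[1L, ]
  if (any(!is.finite(logits))) abort_arg("numeric error: non-finite logits")
  probs <- softmax_vec(logits)
  structure(
    list(probs = probs, logits = logits,
         predicted = c("non_tumor", "tumor")[which.max(probs)]),
    class = "class_prob"
  )
}

#' Gate the segmentation stage on the classifier output
#'
#' Segmentation runs only for tumor-positive cases: returns `"segment"` iff
#' the tumor-class probability is at least `tau`, else `"skip"` (which
#' yields an all-zero predicted mask downstream).
#'
#' @param class_prob a `class_prob` from [classify()], or a bare tumor
#'   probability.
#' @param tau decision threshold in `[0, 1]`.
#' @export
gate <- function(class_prob, tau = 0.5) {
  check_that(tau >= 0 && tau <= 1, "tau must lie in [0, 1]")
  p <- if (inherits(class_prob, "class_prob")) class_prob$probs[2L] else class_prob
  if (p >= tau) "segment" else "skip"
}

#' Train the tumor-presence classifier
#'
#' Minimises softmax cross-entropy with Adam; history records per-epoch
#' train/val loss and accuracy.  Early stopping on validation loss when a
#' validation set is supplied.
#'
#' @param model a classifier bundle.
#' @param inputs list of training inputs (images or latent grids).
#' @param labels character (`"tumor"`/`"non_tumor"`) or 0/1 labels.
#' @param config a [train_config()].
#' @param val_inputs,val_labels optional validation set.
#' @return List with trained `model` and `history`.
#' @export
train_classifier <- function(model, inputs, labels, config = train_config(),
                             val_inputs = NULL, val_labels = NULL) {
  y <- to_binary_labels(labels)
  check_that(length(inputs) == length(y), "inputs and labels must align")
  if (length(unique(y)) < 2L) {
    abort_arg("stratification error: training set contains a single class")
  }
  x_all <- stack_images(inputs)
  x_val <- if (!is.null(val_inputs)) stack_images(val_inputs) else NULL
  y_val <- if (!is.null(val_labels)) to_binary_labels(val_labels) else NULL
  n <- dim(x_all)[4L]
  opt <- adam_init(model$params)
  history <- data.frame()
  best_val <- Inf
  best_model <- model
  bad <- 0L
  if (config$max_epochs == 0L) {
    return(list(model = model, history = history))
  }
  for (epoch in seq_len(config$max_epochs)) {
    batches <- epoch_batches(n, config$batch_size, config$seed, epoch)
    ep_loss <- 0
    ep_correct <- 0
    for (idx in batches) {
      xb <- x_all[, , , idx, drop = FALSE]
      yb <- y[idx]
      fw <- classifier_forward(model, xb, training = TRUE)
      probs <- softmax_rows(fw$logits)
      onehot <- cbind(1 - yb, yb)
      loss <- -mean(log(pmax(probs[cbind(seq_along(yb), yb + 1L)], 1e-12)))
      ep_loss <- ep_loss + loss * length(idx)
      ep_correct <- ep_correct + sum(max.col(probs) == yb + 1L)
      dlogits <- (probs - onehot) / length(idx)
      classifier_backward(fw$tape, model$config, dlogits)
      upd <- adam_step(model$params, fw$tape$grads, opt, config$learning_rate)
      model$params <- upd$params
      opt <- upd$state
      model$buffers <- fw$tape$buffers
    }
    rec <- data.frame(epoch = epoch, train_loss = ep_loss / n,
                      train_acc = ep_correct / n,
                      val_loss = NA_real_, val_acc = NA_real_)
    if (!is.null(x_val)) {
      ev <- classifier_forward(model, x_val, training = FALSE)
      pv <- softmax_rows(ev$logits)
      rec$val_loss <- -mean(log(pmax(pv[cbind(seq_along(y_val), y_val + 1L)], 1e-12)))
      rec$val_acc <- mean(max.col(pv) == y_val + 1L)
      if (rec$val_loss < best_val - 1e-9) {
        best_val <- rec$val_loss
        best_model <- model
        bad <- 0L
      } else {
        bad <- bad + 1L
      }
    }
    history <- rbind(history, rec)
    if (!is.null(x_val) && bad >= config$patience) {
      model <- best_model
      break
    }
  }
  list(model = model, history = history)
}

to_binary_labels <- function(labels) {
  if (is.character(labels) || is.factor(labels)) {
    as.integer(as.character(labels) == "tumor")
  } else {
    as.integer(labels > 0)
  }
}
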