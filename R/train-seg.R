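#' Ensemble configuration
#'
#' Soft voting: the fused probability map is the weighted mean of member
#' probability maps; weights are normalised to sum to 1.
#'
#' @param members character identifiers of the member models.
#' @param weights non-negative vote weights (recycled to equal weights when
#'   `NULL`).
#' @param binarize_threshold probability cutoff for the final binary mask.
#' @export
ensemble_config <- function(members = c("attention_unet", "residual_unet"),
                            weights = NULL,
                            binarize_threshold = 0.5) {
  check_that(length(members) >= 1, "need at least one ensemble member")
  if (is.null(weights)) weights <- rep(1, length(members))
  check_that(length(weights) == length(members) && all(weights >= 0) &&
               sum(weights) > 0, "invalid vote weights")
  structure(
    list(members = members, weights = weights / sum(weights),
         binarize_threshold = binarize_threshold),
    class = "ensemble_config"
  )
}

#' Soft-vote fusion of probability maps
#'
#' @param maps list of probability maps (equal shapes, values in `[0, 1]`).
#' @param cfg an [ensemble_config()] whose weights align with `maps`.
#' @return The weighted-mean probability map (still in `[0, 1]`).
#' @export
soft_vote <- function(maps, cfg = ensemble_config(members = paste0("m", seq_along(maps)))) {
  check_that(length(maps) == length(cfg$weights),
             "number of maps must match the number of vote weights")
  d1 <- dim(maps[[1L]]) %||% length(maps[[1L]])
  out <- 0
  for (i in seq_along(maps)) {
    di <- dim(maps[[i]]) %||% length(maps[[i]])
    check_that(identical(d1, di), "probability map shapes must match")
    out <- out + cfg$weights[i] * maps[[i]]
  }
  out
}

seg_prepare_input <- function(image, roi = NULL) {
  x <- as_tensor(image)
  if (!is.null(roi)) {
    roi_m <- if (inherits(roi, "roi_mask")) roi$mask else roi
    d <- dim(x)
    out <- array(0, dim = c(d[1L], d[2L], d[3L] + 1L, 1L))
    out[, , seq_len(d[3L]), 1L] <- x[, , , 1L]
    out[, , d[3L] + 1L, 1L] <- roi_m
    x <- out
  }
  x
}

stack_seg_inputs <- function(images, rois = NULL) {
  xs <- lapply(seq_along(images), function(i) {
    seg_prepare_input(images[[i]], if (is.null(rois)) NULL else rois[[i]])
  })
  n <- length(xs)
  d <- dim(xs[[1L]])
  out <- array(0, dim = c(d[1L], d[2L], d[3L], n))
  for (i in seq_len(n)) out[, , , i] <- xs[[i]][, , , 1L]
  out
}

#' Train a segmentation network with the hybrid Dice + BCE loss
#'
#' Adam optimisation of `alpha * BCE + (1 - alpha) * Dice` over minibatches
#' with deterministic shuffling; early stopping restores the
#' best-validation-loss parameters after `patience` epochs without
#' improvement.  `roi_mode = "mask_input_channel"` concatenates the supplied
#' coarse ROI as an extra input channel (the model must be configured with
#' the matching `in_channels`); `"restrict_loss"` evaluates the loss only on
#' pixels inside a dilated ROI; `"off"` ignores ROIs.
#'
#' @param model a U-Net bundle.
#' @param images,masks training images and binary ground-truth masks.
#' @param train_cfg a [train_config()].
#' @param loss_cfg a [loss_config()].
#' @param roi_mode one of `"off"`, `"mask_input_channel"`, `"restrict_loss"`.
#' @param rois list of ROI masks (required when `roi_mode != "off"`).
#' @param val optional list with `images`, `masks`, and optionally `rois`;
#'   required when early stopping is wanted (`patience < max_epochs`).
#' @param early_stopping enable early stopping (requires `val`).
#' @return List with trained `model` and `history` (epoch, train_loss,
#'   val_loss, train_dice, val_dice).
#' @export
train_segmenter <- function(model, images, masks,
                            train_cfg = train_config(),
                            loss_cfg = loss_config(),
                            roi_mode = c("off", "mask_input_channel", "restrict_loss"),
                            rois = NULL, val = NULL,
                            early_stopping = !is.null(val)) {
  roi_mode <- match.arg(roi_mode)
  check_that(length(images) == length(masks), "images and masks must align")
  if (roi_mode != "off") {
    check_that(!is.null(rois) && length(rois) == length(images),
               "roi_mode requires one ROI per training image")
  }
  if (isTRUE(early_stopping) && is.null(val)) {
    abort_arg("config error: early stopping requires a validation set")
  }
  use_channel <- roi_mode == "mask_input_channel"
  x_all <- stack_seg_inputs(images, if (use_channel) rois else NULL)
  y_all <- stack_images(masks)
  loss_weight <- NULL
  if (roi_mode == "restrict_loss") {
    loss_weight <- stack_images(lapply(rois, function(r) {
      m <- if (inherits(r, "roi_mask")) r$mask else r
      dilate_mask(m, 3L)
    }))
  }
  x_val <- y_val <- NULL
  if (!is.null(val)) {
    x_val <- stack_seg_inputs(val$images, if (use_channel) val$rois else NULL)
    y_val <- stack_images(val$masks)
  }
  n <- dim(x_all)[4L]
  opt <- adam_init(model$params)
  history <- data.frame()
  best_val <- Inf
  best_model <- model
  bad <- 0L
  if (train_cfg$max_epochs == 0L) {
    return(list(model = model, history = history))
  }
  for (epoch in seq_len(train_cfg$max_epochs)) {
    batches <- epoch_batches(n, train_cfg$batch_size, train_cfg$seed, epoch)
    ep_loss <- 0
    ep_dice <- 0
    for (idx in batches) {
      xb <- x_all[, , , idx, drop = FALSE]
      yb <- y_all[, , , idx, drop = FALSE]
      fw <- unet_forward(model, xb, training = TRUE)
      p <- fw$prob
      if (!is.null(loss_weight)) {
        wb <- loss_weight[, , , idx, drop = FALSE]
        loss <- hybrid_loss(yb * wb, p * wb, loss_cfg)
        dp <- hybrid_loss_grad(yb * wb, p * wb, loss_cfg) * wb
      } else {
        loss <- hybrid_loss(yb, p, loss_cfg)
        dp <- hybrid_loss_grad(yb, p, loss_cfg)
      }
      ep_loss <- ep_loss + loss * length(idx)
      ep_dice <- ep_dice + batch_soft_dice(yb, p) * length(idx)
      unet_backward(fw$tape, model$config, dp)
      upd <- adam_step(model$params, fw$tape$grads, opt, train_cfg$learning_rate)
      model$params <- upd$params
      opt <- upd$state
      model$buffers <- fw$tape$buffers
    }
    rec <- data.frame(epoch = epoch, train_loss = ep_loss / n,
                      train_dice = ep_dice / n,
                      val_loss = NA_real_, val_dice = NA_real_)
    if (!is.null(x_val)) {
      ev <- unet_forward(model, x_val, training = FALSE)
      rec$val_loss <- hybrid_loss(y_val, ev$prob, loss_cfg)
      rec$val_dice <- batch_soft_dice(y_val, ev$prob)
      if (isTRUE(early_stopping)) {
        if (rec$val_loss < best_val - 1e-9) {
          best_val <- rec$val_loss
          best_model <- model
          bad <- 0L
        } else {
          bad <- bad + 1L
        }
      }
    }
    history <- rbind(history, rec)
    if (isTRUE(early_stopping) && bad >= train_cfg$patience) {
      model <- best_model
      break
    }
  }
  list(model = model, history = history)
}

batch_soft_dice <- function(y, p) {
  (2 * sum(y * p) + 1e-6) / (sum(y) + sum(p) + 1e-6)
}

dilate_mask <- function(mask, radius = 3L) {
  m <- mask > 0
  H <- nrow(m); W <- ncol(m)
  out <- m
  for (r in seq_len(radius)) {
    pad <- matrix(FALSE, H + 2L, W + 2L)
    pad[2:(H + 1L), 2:(W + 1L)] <- out
    out <- pad[1:H, 2:(W + 1L)] | pad[3:(H + 2L), 2:(W + 1L)] |
      pad[2:(H + 1L), 1:W] | pad[2:(H + 1L), 3:(W + 2L)] | out
  }
  out * 1.0
}

#' Predict probability maps for a batch of images with one segmenter
#' @param model a U-Net bundle.
#' @param images list of images.
#' @param rois optional list of ROI masks (for ROI-as-channel models).
#' @return List of H x W probability matrices.
#' @export
predict_prob_maps <- function(model, images, rois = NULL) {
  x <- stack_seg_inputs(images, rois)
  fw <- unet_forward(model, x, training = FALSE)
  lapply(seq_len(dim(x)[4L]), function(i) {
    matrix(fw$prob[, , 1L, i], dim(x)[1L], dim(x)[2L])
  })
}

#' Full single-image prediction through the staged pipeline
#'
#' Runs preprocess -> encode -> classify -> gate -> (if segmenting) latent
#' k-means ROI -> ensemble forward -> soft vote -> threshold.  A gate "skip"
#' decision short-circuits to an all-zero mask.
#'
#' @param models list with components `gae`, `classifier`, `segmenters`
#'   (list of U-Net bundles); any stage may be `NULL` if disabled in `cfg`.
#' @param image raw image matrix.
#' @param cfg list of pipeline options: `use_gate`, `use_kmeans_roi`,
#'   `roi_mode`, `gate_tau`, `kmeans_k`, `seed`, and `ensemble` (an
#'   [ensemble_config()]).
#' @return List with `mask` (binary), `prob` (fused probability map),
#'   `class_prob`, `roi`, and `decision`.
#' @export
predict_mask <- function(models, image, cfg) {
  norm <- zscore_normalize(image)
  img <- norm$image
  ens <- cfg$ensemble %||% ensemble_config(members = paste0("m", seq_along(models$segmenters)))
  cls <- NULL
  decision <- "segment"
  if (isTRUE(cfg$use_gate)) {
    if (is.null(models$classifier)) abort_arg("config error: gate enabled but no classifier model")
    cls <- classify(models$classifier, img)
    decision <- gate(cls, cfg$gate_tau %||% 0.5)
  }
  roi <- NULL
  if (decision == "skip") {
    zero <- matrix(0, nrow(img), ncol(img))
    return(list(mask = zero, prob = zero, class_prob = cls, roi = NULL,
                decision = "skip"))
  }
  if (isTRUE(cfg$use_kmeans_roi)) {
    if (is.null(models$gae)) abort_arg("config error: k-means ROI requires the autoencoder")
    lat <- encode_image(models$gae, img)
    cl <- kmeans_latent(lat, k = cfg$kmeans_k %||% 2L, seed = cfg$seed %||% 42L)
    roi <- suppressWarnings(roi_from_clusters(cl, lat))
  }
  if (length(models$segmenters) == 0L) abort_arg("config error: no segmentation model")
  use_channel <- isTRUE(cfg$use_kmeans_roi) &&
    (cfg$roi_mode %||% "mask_input_channel") == "mask_input_channel"
  maps <- lapply(models$segmenters, function(m) {
    predict_prob_maps(m, list(img), if (use_channel) list(roi) else NULL)[[1L]]
  })
  fused <- soft_vote(maps, ens)
  list(mask = (fused >= ens$binarize_threshold) * 1.0, prob = fused,
       class_prob = cls, roi = roi, decision = decision)
}
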