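#' Full pipeline configuration
#'
#' Bundles every stage configuration, the ablation toggles, and the global
#' seed.  The ablation flags reproduce the component ladder: a plain U-Net
#' baseline; + autoencoder pre-training (encoder weight transfer); +
#' attention (bottleneck self-attention and decoder skip gates); + latent
#' k-means ROI; and the full ensemble with classifier gating and soft
#' voting.
#'
#' The `scale = "desk"` preset (the default) runs the whole pipeline on a
#' CPU in minutes: 64 x 64 phantoms, 30 subjects x 10 slices, reduced
#' network widths.  `scale = "paper"` configures 224 x 224 inputs with
#' 4-stage encoders for use on real data; it is not sized for test suites.
#'
#' @param scale `"desk"` or `"paper"` preset.
#' @param phantom a [phantom_spec()].
#' @param split a [split_spec()].
#' @param gae a [gae_config()].
#' @param classifier a [classifier_config()].
#' @param unet a [unet_config()] shared by the ensemble members.
#' @param loss a [loss_config()].
#' @param train_gae,train_classifier,train_segmenter per-stage
#'   [train_config()]s.
#' @param ensemble an [ensemble_config()].
#' @param use_gae_pretrain,use_attention,use_kmeans_roi,use_gate,use_ensemble
#'   ablation toggles.
#' @param roi_mode how the ROI reaches the segmenter
#'   (`"mask_input_channel"`, `"restrict_loss"`, or `"off"`).
#' @param gate_tau classifier gating threshold.
#' @param kmeans_k number of latent clusters.
#' @param augment_copies augmented copies per training slice (0 disables
#'   augmentation).
#' @param augment an [augmentation_params()].
#' @param output_dir optional artifact directory.
#' @param global_seed master seed; all stage seeds derive from it.
#' @export
pipeline_config <- function(scale = c("desk", "paper"),
                            phantom = NULL, split = NULL, gae = NULL,
                            classifier = NULL, unet = NULL,
                            loss = loss_config(),
                            train_gae = NULL, train_classifier = NULL,
                            train_segmenter = NULL,
                            ensemble = ensemble_config(),
                            use_gae_pretrain = TRUE,
                            use_attention = TRUE,
                            use_kmeans_roi = TRUE,
                            use_gate = TRUE,
                            use_ensemble = TRUE,
                            roi_mode = "mask_input_channel",
                            gate_tau = 0.5,
                            kmeans_k = 2L,
                            augment_copies = 1L,
                            augment = NULL,
                            output_dir = NULL,
                            global_seed = 42L) {
  scale <- match.arg(scale)
  size <- if (scale == "desk") 64L else 224L
  phantom <- phantom %||% phantom_spec(
    image_size = size, n_subjects = 30L, slices_per_subject = 10L,
    tumor_prevalence = 0.5, seed = global_seed)
  split <- split %||% split_spec(seed = global_seed)
  gae <- gae %||% if (scale == "desk") {
    gae_config(encoder_depth = 3L, base_channels = 8L, latent_channels = 32L,
               attention_dim = 16L, image_size = size)
  } else {
    gae_config(image_size = size)
  }
  classifier <- classifier %||% classifier_config(
    base_channels = 8L, n_blocks = 2L, image_size = size)
  unet <- unet %||% unet_config(
    depth = 2L, base_channels = 8L, image_size = size)
  # desk-scale step sizes: the reconstruction and segmentation phases train
  # for far fewer iterations than a full 224x224 schedule, so they use a
  # larger Adam step (1e-3); the classifier keeps the framework default 3e-4
  train_gae <- train_gae %||% train_config(
    learning_rate = 1e-3, max_epochs = 5L, patience = 3L, seed = global_seed)
  train_classifier <- train_classifier %||% train_config(
    max_epochs = 8L, patience = 3L, seed = global_seed)
  train_segmenter <- train_segmenter %||% train_config(
    learning_rate = 1e-3, max_epochs = 8L, patience = 4L, seed = global_seed)
  augment <- augment %||% augmentation_params(seed = hash_seed(global_seed, 5000))
  structure(
    list(scale = scale, phantom = phantom, split = split, gae = gae,
         classifier = classifier, unet = unet, loss = loss,
         train_gae = train_gae, train_classifier = train_classifier,
         train_segmenter = train_segmenter, ensemble = ensemble,
         use_gae_pretrain = isTRUE(use_gae_pretrain),
         use_attention = isTRUE(use_attention),
         use_kmeans_roi = isTRUE(use_kmeans_roi),
         use_gate = isTRUE(use_gate),
         use_ensemble = isTRUE(use_ensemble),
         roi_mode = roi_mode, gate_tau = gate_tau,
         kmeans_k = as.integer(kmeans_k),
         augment_copies = as.integer(augment_copies),
         augment = augment,
         output_dir = output_dir,
         global_seed = as.integer(global_seed)),
    class = "pipeline_config"
  )
}

split_bundle <- function(samples, manifest) {
  idx <- manifest$idx
  list(
    images = lapply(samples[idx], `[[`, "image"),
    masks = lapply(samples[idx], `[[`, "mask"),
    labels = manifest$label,
    subject_ids = manifest$subject_id
  )
}

normalize_bundle <- function(bundle) {
  bundle$images <- lapply(bundle$images, function(im) zscore_normalize(im)$image)
  bundle
}

compute_rois <- function(gae_model, images, k, seed) {
  lapply(seq_along(images), function(i) {
    lat <- encode_image(gae_model, images[[i]])
    cl <- kmeans_latent(lat, k = k, seed = hash_seed(seed, 9000, i))
    suppressWarnings(roi_from_clusters(cl, lat))
  })
}

#' Run the full three-phase pipeline on synthetic phantoms
#'
#' Generates the phantom dataset, performs the stratified subject-wise
#' split, normalises intensities, optionally augments the training split,
#' pre-trains the autoencoder, trains the classifier and the segmentation
#' ensemble, predicts on the held-out test split (with classifier gating
#' and soft voting when enabled), and evaluates the full metric suite.
#' Disabled stages become documented pass-throughs (no gate = always
#' segment; no ensemble = single attention U-Net; no ROI = image-only
#' input).  Everything is deterministic given `config$global_seed`.
#'
#' @param config a [pipeline_config()].
#' @return A `run_report`: metrics report, per-stage histories, stage
#'   wall-times, seed record, and the config snapshot.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  check_that(inherits(config, "pipeline_config"), "invalid config")
  timings <- c()
  tic <- function() proc.time()[["elapsed"]]
  t_start <- tic()

  ds <- generate_dataset(config$phantom)
  man <- ds$manifest
  man$idx <- seq_len(nrow(man))
  split <- stratified_subject_split(man, config$split)
  bundles <- lapply(split[c("train", "val", "test")],
                    function(m) normalize_bundle(split_bundle(ds$samples, m)))
  train_b <- bundles$train
  val_b <- bundles$val
  test_b <- bundles$test
  timings["data"] <- tic() - t_start

  # training-split augmentation (after splitting, so no leakage)
  if (config$augment_copies > 0L) {
    n0 <- length(train_b$images)
    for (cp in seq_len(config$augment_copies)) {
      for (i in seq_len(n0)) {
        aug <- augment_pair(train_b$images[[i]], train_b$masks[[i]],
                            config$augment, draw_index = (cp - 1L) * n0 + i)
        train_b$images <- c(train_b$images, list(aug$image))
        train_b$masks <- c(train_b$masks, list(aug$mask))
        train_b$labels <- c(train_b$labels,
                            if (sum(aug$mask) > 0) "tumor" else "non_tumor")
      }
    }
  }

  models <- list(gae = NULL, classifier = NULL, segmenters = list())
  histories <- list()
  need_gae <- config$use_gae_pretrain || config$use_kmeans_roi
  if (need_gae) {
    t0 <- tic()
    gae_cfg <- config$gae
    gae_cfg$use_attention <- config$use_attention
    gae <- build_gae(gae_cfg, init_seed = hash_seed(config$global_seed, 101))
    fit <- pretrain_gae(gae, train_b$images, config$train_gae,
                        val_images = val_b$images)
    models$gae <- fit$model
    histories$gae <- fit$history
    timings["gae_pretrain"] <- tic() - t0
  }

  if (config$use_gate) {
    t0 <- tic()
    cls <- build_classifier(config$classifier,
                            init_seed = hash_seed(config$global_seed, 102))
    cls_inputs <- if (config$classifier$input == "latent") {
      lapply(train_b$images, function(im) encode_image(models$gae, im)$grid)
    } else {
      train_b$images
    }
    cls_val_inputs <- if (config$classifier$input == "latent") {
      lapply(val_b$images, function(im) encode_image(models$gae, im)$grid)
    } else {
      val_b$images
    }
    fit <- train_classifier(cls, cls_inputs, train_b$labels,
                            config$train_classifier,
                            val_inputs = cls_val_inputs,
                            val_labels = val_b$labels)
    models$classifier <- fit$model
    histories$classifier <- fit$history
    timings["classifier"] <- tic() - t0
  }

  rois <- list(train = NULL, val = NULL, test = NULL)
  if (config$use_kmeans_roi) {
    t0 <- tic()
    rois$train <- compute_rois(models$gae, train_b$images, config$kmeans_k,
                               config$global_seed)
    rois$val <- compute_rois(models$gae, val_b$images, config$kmeans_k,
                             config$global_seed)
    rois$test <- compute_rois(models$gae, test_b$images, config$kmeans_k,
                              config$global_seed)
    timings["kmeans_roi"] <- tic() - t0
  }

  roi_mode <- if (config$use_kmeans_roi) config$roi_mode else "off"
  in_ch <- if (roi_mode == "mask_input_channel") 2L else 1L
  seg_cfg <- config$unet
  seg_cfg$in_channels <- in_ch
  seg_cfg$use_attention_gates <- config$use_attention

  t0 <- tic()
  att_unet <- build_attention_unet(seg_cfg,
                                   init_seed = hash_seed(config$global_seed, 103))
  if (config$use_gae_pretrain) {
    att_unet <- transfer_encoder_weights(att_unet, models$gae)
  }
  val_list <- list(images = val_b$images, masks = val_b$masks, rois = rois$val)
  fit <- train_segmenter(att_unet, train_b$images, train_b$masks,
                         train_cfg = config$train_segmenter,
                         loss_cfg = config$loss,
                         roi_mode = roi_mode, rois = rois$train,
                         val = val_list)
  models$segmenters$attention_unet <- fit$model
  histories$attention_unet <- fit$history
  timings["attention_unet"] <- tic() - t0

  if (config$use_ensemble) {
    t0 <- tic()
    res_unet <- build_residual_unet(seg_cfg,
                                    init_seed = hash_seed(config$global_seed, 104))
    fit <- train_segmenter(res_unet, train_b$images, train_b$masks,
                           train_cfg = config$train_segmenter,
                           loss_cfg = config$loss,
                           roi_mode = roi_mode, rois = rois$train,
                           val = val_list)
    models$segmenters$residual_unet <- fit$model
    histories$residual_unet <- fit$history
    timings["residual_unet"] <- tic() - t0
  }

  ens <- config$ensemble
  if (length(ens$members) != length(models$segmenters)) {
    ens <- ensemble_config(members = names(models$segmenters),
                           binarize_threshold = ens$binarize_threshold)
  }

  t0 <- tic()
  pred <- predict_test_split(models, test_b, rois$test, roi_mode, ens, config)
  timings["predict"] <- tic() - t0

  report <- evaluate_dataset(
    pred$masks, test_b$masks,
    class_probs = pred$class_probs,
    class_labels = if (!is.null(pred$class_probs)) test_b$labels else NULL,
    gate_tau = config$gate_tau
  )
  timings["total"] <- tic() - t_start

  out <- structure(
    list(metrics = report, histories = histories, timings = timings,
         member_prob_maps = pred$member_maps,
         predictions = pred$masks,
         test_labels = test_b$labels,
         config = config,
         seed_record = list(global_seed = config$global_seed,
                            phantom = config$phantom$seed,
                            split = config$split$seed),
         models = models),
    class = "run_report"
  )
  if (!is.null(config$output_dir)) write_run_report(out, config$output_dir)
  out
}

predict_test_split <- function(models, test_b, test_rois, roi_mode, ens, config) {
  n <- length(test_b$images)
  use_channel <- roi_mode == "mask_input_channel"
  class_probs <- NULL
  segment_flags <- rep(TRUE, n)
  if (config$use_gate && !is.null(models$classifier)) {
    class_probs <- vapply(seq_len(n), function(i) {
      inp <- if (config$classifier$input == "latent") {
        encode_image(models$gae, test_b$images[[i]])$grid
      } else {
        test_b$images[[i]]
      }
      classify(models$classifier, inp)$probs[2L]
    }, numeric(1))
    segment_flags <- class_probs >= config$gate_tau
  }
  member_maps <- lapply(models$segmenters, function(m) {
    predict_prob_maps(m, test_b$images, if (use_channel) test_rois else NULL)
  })
  size <- dim(test_b$images[[1L]])
  masks <- vector("list", n)
  fused_maps <- vector("list", n)
  for (i in seq_len(n)) {
    if (!segment_flags[i]) {
      masks[[i]] <- matrix(0, size[1L], size[2L])
      fused_maps[[i]] <- matrix(0, size[1L], size[2L])
      next
    }
    fused <- soft_vote(lapply(member_maps, `[[`, i), ens)
    fused_maps[[i]] <- fused
    masks[[i]] <- (fused >= ens$binarize_threshold) * 1.0
  }
  list(masks = masks, prob_maps = fused_maps, member_maps = member_maps,
       class_probs = class_probs)
}

write_run_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_metrics_report(report$metrics,
                       path_json = file.path(dir, "metrics.json"),
                       path_csv = file.path(dir, "metrics.csv"))
  for (nm in names(report$histories)) {
    write_history(report$histories[[nm]],
                  file.path(dir, paste0("history_", nm, ".csv")))
  }
  cfg <- report$config
  cfg$output_dir <- NULL
  write_config(cfg, file.path(dir, "config.yaml"))
  invisible(dir)
}

#' @export
print.run_report <- function(x, ...) {
  cat("Pipeline run (seed", x$seed_record$global_seed, ")\n")
  flags <- x$config[c("use_gae_pretrain", "use_attention", "use_kmeans_roi",
                      "use_gate", "use_ensemble")]
  cat("  components:", paste(names(flags)[unlist(flags)], collapse = ", "), "\n")
  cat("  stage times (s):",
      paste(sprintf("%s=%.1f", names(x$timings), x$timings), collapse = " "), "\n")
  print(x$metrics)
  invisible(x)
}

ladder_rows <- function() {
  list(
    list(name = "unet_baseline",
         flags = c(FALSE, FALSE, FALSE, FALSE, FALSE)),
    list(name = "gae",
         flags = c(TRUE, FALSE, FALSE, FALSE, FALSE)),
    list(name = "gae_attention",
         flags = c(TRUE, TRUE, FALSE, FALSE, FALSE)),
    list(name = "gae_attention_kmeans_roi",
         flags = c(TRUE, TRUE, TRUE, FALSE, FALSE)),
    list(name = "full_ensemble",
         flags = c(TRUE, TRUE, TRUE, TRUE, TRUE))
  )
}

#' Ablation ladder: progressively enable pipeline components
#'
#' Runs the five ladder configurations (plain U-Net; + autoencoder
#' pre-training; + attention; + latent k-means ROI; full gated ensemble) on
#' identical data and seeds and tabulates Dice, Jaccard, sensitivity, and
#' HD95 per configuration.
#'
#' @param config a [pipeline_config()]; its ablation flags are overridden
#'   row by row.
#' @return List with `table` (one data.frame row per configuration) and
#'   `reports` (the five `run_report`s).  Written as `ablation.csv` when
#'   `config$output_dir` is set.
#' @export
ablation_ladder <- function(config = pipeline_config()) {
  rows <- ladder_rows()
  reports <- list()
  tab <- NULL
  out_dir <- config$output_dir
  config$output_dir <- NULL
  for (row in rows) {
    cfg <- config
    cfg$use_gae_pretrain <- row$flags[1L]
    cfg$use_attention <- row$flags[2L]
    cfg$use_kmeans_roi <- row$flags[3L]
    cfg$use_gate <- row$flags[4L]
    cfg$use_ensemble <- row$flags[5L]
    rep_i <- run_pipeline(cfg)
    reports[[row$name]] <- rep_i
    m <- rep_i$metrics
    tab <- rbind(tab, data.frame(
      configuration = row$name, dice = m$dice, jaccard = m$jaccard,
      sensitivity = m$sensitivity, hd95 = m$hd95))
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(tab, file.path(out_dir, "ablation.csv"), row.names = FALSE)
  }
  list(table = tab, reports = reports)
}

#' Build a pipeline configuration from a plain (YAML/JSON) list
#'
#' Inverse of [write_config()] for pipeline configurations: nested lists are
#' routed to the matching constructors, with package defaults for anything
#' omitted.
#'
#' @param lst a named list, e.g. from [read_config()].
#' @return A [pipeline_config()].
#' @export
pipeline_config_from_list <- function(lst) {
  lst <- lst %||% list()
  num <- function(x) if (is.null(x)) NULL else unlist(x)
  sub <- function(ctor, x, drop = character(0)) {
    if (is.null(x)) return(NULL)
    x <- x[setdiff(names(x), drop)]
    x <- lapply(x, unlist)
    do.call(ctor, x)
  }
  args <- list(
    phantom = sub(phantom_spec, lst$phantom),
    split = sub(split_spec, lst$split),
    gae = sub(gae_config, lst$gae),
    classifier = sub(classifier_config, lst$classifier),
    unet = sub(unet_config, lst$unet),
    train_gae = sub(train_config, lst$train_gae, drop = "optimizer"),
    train_classifier = sub(train_config, lst$train_classifier, drop = "optimizer"),
    train_segmenter = sub(train_config, lst$train_segmenter, drop = "optimizer"),
    augment = sub(augmentation_params, lst$augment)
  )
  if (!is.null(lst$loss)) args$loss <- sub(loss_config, lst$loss)
  if (!is.null(lst$ensemble)) args$ensemble <- sub(ensemble_config, lst$ensemble)
  for (nm in c("scale", "use_gae_pretrain", "use_attention", "use_kmeans_roi",
               "use_gate", "use_ensemble", "roi_mode", "gate_tau", "kmeans_k",
               "augment_copies", "output_dir", "global_seed")) {
    if (!is.null(lst[[nm]])) args[[nm]] <- lst[[nm]]
  }
  args <- args[!vapply(args, is.null, logical(1))]
  do.call(pipeline_config, args)
}
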