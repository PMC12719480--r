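#' Z-score intensity normalization
#'
#' Standardises an image to mean 0 and standard deviation 1:
#' `X_std = (X - mu) / sigma`.  The population standard deviation (no Bessel
#' correction) is used.  When `params` is supplied the stored `mu`/`sigma`
#' are applied instead (dataset-level normalization); otherwise they are
#' estimated from the image itself (per-image normalization, the default).
#'
#' @param image numeric matrix or array.
#' @param params optional list with `mu` and `sigma` to apply.
#' @return List with `image` (standardised) and `params` (`mu`, `sigma`).
#' @export
zscore_normalize <- function(image, params = NULL) {
  v <- as.vector(image)
  if (is.null(params)) {
    mu <- mean(v)
    sigma <- sqrt(mean((v - mu)^2))
    if (sigma <= 1e-12) {
      abort_arg("degenerate input: constant image has zero intensity variance")
    }
    params <- list(mu = mu, sigma = sigma)
  } else {
    check_that(params$sigma > 0, "sigma must be positive")
  }
  out <- (image - params$mu) / params$sigma
  list(image = out, params = params)
}

#' Resize an image by bilinear or nearest-neighbor interpolation
#'
#' Coordinate convention: row-major, 0-based, pixel centers at integer
#' coordinates.  An output pixel `i` samples the source at
#' `(i + 0.5) * H / H_target - 0.5`, clamped to the image; bilinear
#' interpolation is separable in rows and columns.  Use `"nearest"` for label
#' masks so binarity is preserved.
#'
#' @param image H x W matrix or H x W x C array.
#' @param target_size scalar or `c(height, width)`.
#' @param method `"bilinear"` (images) or `"nearest"` (masks).
#' @return Resized image of the same type.
#' @export
resize_image <- function(image, target_size, method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  if (length(target_size) == 1L) target_size <- c(target_size, target_size)
  check_that(all(target_size >= 1), "target size must be positive")
  nd <- length(dim(image))
  if (nd == 3L) {
    out <- array(0, dim = c(target_size, dim(image)[3L]))
    for (c_ in seq_len(dim(image)[3L])) {
      out[, , c_] <- resize_image(image[, , c_], target_size, method)
    }
    return(out)
  }
  check_that(nd == 2L || is.matrix(image), "image must be 2D or 2D x channels")
  H <- nrow(image)
  W <- ncol(image)
  Ht <- as.integer(target_size[1L])
  Wt <- as.integer(target_size[2L])
  if (Ht == H && Wt == W) return(image)

  src_r <- pmin(pmax((seq_len(Ht) - 0.5) * H / Ht - 0.5, 0), H - 1)
  src_c <- pmin(pmax((seq_len(Wt) - 0.5) * W / Wt - 0.5, 0), W - 1)

  if (method == "nearest") {
    ri <- pmin(floor(src_r + 0.5), H - 1) + 1L
    ci <- pmin(floor(src_c + 0.5), W - 1) + 1L
    return(image[ri, ci, drop = FALSE])
  }

  r0 <- floor(src_r); r1 <- pmin(r0 + 1, H - 1)
  c0 <- floor(src_c); c1 <- pmin(c0 + 1, W - 1)
  wr <- src_r - r0
  wc <- src_c - c0
  # interpolate rows, then columns
  top <- image[r0 + 1L, , drop = FALSE]
  bot <- image[r1 + 1L, , drop = FALSE]
  rows <- top * (1 - wr) + bot * wr
  left <- rows[, c0 + 1L, drop = FALSE]
  right <- rows[, c1 + 1L, drop = FALSE]
  sweep(left, 2L, 1 - wc, `*`) + sweep(right, 2L, wc, `*`)
}

#' Augmentation parameters
#'
#' Random rotations of up to +-`rotation_deg_max` degrees, integer
#' translations of up to +-`translate_px_max` pixels per axis, and optional
#' horizontal/vertical flips (each applied with probability 1/2 when
#' enabled).  Draws are deterministic functions of `(seed, draw_index)`.
#'
#' @param rotation_deg_max maximum absolute rotation in degrees.
#' @param translate_px_max maximum absolute translation in pixels.
#' @param hflip,vflip enable horizontal / vertical flips.
#' @param seed integer seed for the augmentation stream.
#' @export
augmentation_params <- function(rotation_deg_max = 10,
                                translate_px_max = 5,
                                hflip = TRUE,
                                vflip = TRUE,
                                seed = 42L) {
  check_that(rotation_deg_max >= 0, "rotation_deg_max must be >= 0")
  check_that(translate_px_max >= 0, "translate_px_max must be >= 0")
  structure(
    list(rotation_deg_max = rotation_deg_max,
         translate_px_max = as.integer(translate_px_max),
         hflip = isTRUE(hflip), vflip = isTRUE(vflip),
         seed = as.integer(seed)),
    class = "augmentation_params"
  )
}

# Inverse-map affine sampling shared by image (bilinear) and mask (nearest).
# Forward transform of 0-based pixel-center coordinates p = (row, col):
#   p1 = flip(p); p2 = R(p1 - ctr) + ctr; p3 = p2 + t
# Out-of-image samples are zero (no tissue invented by padding).
affine_sample <- function(image, angle_rad, tx, ty, hflip, vflip, method) {
  H <- nrow(image)
  W <- ncol(image)
  ctr_r <- (H - 1) / 2
  ctr_c <- (W - 1) / 2
  dst_r <- matrix(rep(0:(H - 1), W), H, W)
  dst_c <- matrix(rep(0:(W - 1), each = H), H, W)
  # invert: undo translation, rotation, then flips
  r2 <- dst_r - ty
  c2 <- dst_c - tx
  ca <- cos(angle_rad); sa <- sin(angle_rad)
  r1 <- ca * (r2 - ctr_r) + sa * (c2 - ctr_c) + ctr_r
  c1 <- -sa * (r2 - ctr_r) + ca * (c2 - ctr_c) + ctr_c
  if (hflip) c1 <- (W - 1) - c1
  if (vflip) r1 <- (H - 1) - r1

  if (method == "nearest") {
    ri <- floor(r1 + 0.5)
    ci <- floor(c1 + 0.5)
    inside <- ri >= 0 & ri <= H - 1 & ci >= 0 & ci <= W - 1
    out <- matrix(0, H, W)
    out[inside] <- image[cbind(ri[inside] + 1L, ci[inside] + 1L)]
    return(out)
  }
  r0 <- floor(r1); c0 <- floor(c1)
  fr <- r1 - r0; fc <- c1 - c0
  out <- matrix(0, H, W)
  for (dr in 0:1) {
    for (dc in 0:1) {
      rr <- r0 + dr
      cc <- c0 + dc
      wgt <- (if (dr == 0) 1 - fr else fr) * (if (dc == 0) 1 - fc else fc)
      inside <- rr >= 0 & rr <= H - 1 & cc >= 0 & cc <= W - 1 & wgt > 0
      if (any(inside)) {
        out[inside] <- out[inside] +
          wgt[inside] * image[cbind(rr[inside] + 1L, cc[inside] + 1L)]
      }
    }
  }
  out
}

#' Jointly augment an image and its mask
#'
#' Applies one identical geometric transform (rotation, integer translation,
#' optional flips) to both image and mask; the image is resampled bilinearly,
#' the mask with nearest-neighbor so it stays binary.  The transform is a
#' deterministic function of `(params$seed, draw_index)`.
#'
#' @param image H x W matrix.
#' @param mask H x W binary matrix of the same shape.
#' @param params an [augmentation_params()].
#' @param draw_index integer identifying the augmentation draw.
#' @return List with transformed `image`, `mask`, and the `draw` actually
#'   applied (angle, translation, flips).
#' @export
augment_pair <- function(image, mask, params, draw_index = 1L) {
  check_that(all(dim(image) == dim(mask)), "image and mask shapes must match")
  draw <- with_seed(hash_seed(params$seed, draw_index), {
    list(
      angle_deg = stats::runif(1, -params$rotation_deg_max, params$rotation_deg_max),
      tx = if (params$translate_px_max > 0)
        sample.int(2L * params$translate_px_max + 1L, 1L) - params$translate_px_max - 1L
      else 0L,
      ty = if (params$translate_px_max > 0)
        sample.int(2L * params$translate_px_max + 1L, 1L) - params$translate_px_max - 1L
      else 0L,
      hflip = params$hflip && stats::runif(1) < 0.5,
      vflip = params$vflip && stats::runif(1) < 0.5
    )
  })
  a <- draw$angle_deg * pi / 180
  img2 <- affine_sample(image, a, draw$tx, draw$ty, draw$hflip, draw$vflip, "bilinear")
  msk2 <- affine_sample(mask, a, draw$tx, draw$ty, draw$hflip, draw$vflip, "nearest")
  list(image = img2, mask = msk2, draw = draw)
}

#' Split specification
#'
#' @param fractions `c(train, val, test)`, each positive, summing to 1.
#' @param seed RNG seed used for the (stratified) subject shuffle.
#' @param stratify_on column used for stratification (the subject's label).
#' @export
split_spec <- function(fractions = c(0.622, 0.155, 0.223),
                       seed = 42L,
                       stratify_on = "label") {
  check_that(length(fractions) == 3 && all(fractions > 0),
             "fractions must be three positive numbers")
  check_that(abs(sum(fractions) - 1) < 1e-9, "fractions must sum to 1")
  structure(
    list(fractions = as.numeric(fractions), seed = as.integer(seed),
         stratify_on = stratify_on),
    class = "split_spec"
  )
}

# largest-remainder allocation of n items to 3 bins with every bin >= 1
allocate_counts <- function(n, fractions) {
  raw <- n * fractions
  cnt <- floor(raw)
  rem <- raw - cnt
  while (sum(cnt) < n) {
    i <- which.max(rem)
    cnt[i] <- cnt[i] + 1L
    rem[i] <- -1
  }
  # guarantee each split at least one subject per class
  for (i in seq_along(cnt)) {
    if (cnt[i] == 0L) {
      j <- which.max(cnt)
      cnt[j] <- cnt[j] - 1L
      cnt[i] <- cnt[i] + 1L
    }
  }
  as.integer(cnt)
}

#' Stratified subject-wise train/val/test split
#'
#' Subjects (never individual slices) are allocated to splits so that (i) the
#' three subject sets are pairwise disjoint and cover all subjects — no
#' subject's slices ever straddle two splits — and (ii) within each class the
#' subject counts follow `fractions` by largest-remainder rounding, so each
#' split's label proportions are within one subject of the stratified ideal.
#' The per-class subject order is shuffled deterministically from
#' `spec$seed`.
#'
#' @param manifest data.frame with at least `subject_id` and `label` columns;
#'   every subject must carry a single label, and every class at least 3
#'   subjects (one per split).
#' @param spec a [split_spec()].
#' @return List of class `subject_split` with `train`, `val`, `test`
#'   manifests.
#' @export
stratified_subject_split <- function(manifest, spec = split_spec()) {
  check_that(all(c("subject_id", "label") %in% names(manifest)),
             "manifest must have subject_id and label columns")
  subj_lab <- unique(manifest[, c("subject_id", "label")])
  if (anyDuplicated(subj_lab$subject_id)) {
    bad <- subj_lab$subject_id[duplicated(subj_lab$subject_id)][1L]
    abort_arg(sprintf("subject %s has mixed labels", bad))
  }
  classes <- sort(unique(subj_lab$label))
  assign_split <- character(0)
  assign_subj <- character(0)
  for (ci in seq_along(classes)) {
    subs <- sort(subj_lab$subject_id[subj_lab$label == classes[ci]])
    if (length(subs) < 3L) {
      abort_arg(sprintf(
        "stratification error: class '%s' has %d subjects (need >= 3, one per split)",
        classes[ci], length(subs)))
    }
    perm <- with_seed(hash_seed(spec$seed, ci), sample.int(length(subs)))
    subs <- subs[perm]
    cnt <- allocate_counts(length(subs), spec$fractions)
    assign_subj <- c(assign_subj, subs)
    assign_split <- c(assign_split,
                      rep(c("train", "val", "test"), times = cnt))
  }
  names(assign_split) <- assign_subj
  pick <- function(which_split) {
    keep <- assign_split[manifest$subject_id] == which_split
    out <- manifest[keep, , drop = FALSE]
    rownames(out) <- NULL
    out
  }
  structure(
    list(train = pick("train"), val = pick("val"), test = pick("test"),
         assignment = assign_split, spec = spec),
    class = "subject_split"
  )
}

#' Write a subject split as three CSV manifests
#' @param split a `subject_split`.
#' @param dir output directory; writes `train.csv`, `val.csv`, `test.csv`.
#' @export
write_split <- function(split, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in c("train", "val", "test")) {
    write_manifest(split[[nm]], file.path(dir, paste0(nm, ".csv")))
  }
  invisible(dir)
}
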