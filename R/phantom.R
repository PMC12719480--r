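#' Specification of a synthetic brain-slice phantom dataset
#'
#' Describes a subject-structured population of 2D grayscale slices: a smooth
#' low-frequency background field (soft-tissue stand-in), an elliptical bright
#' tumor in tumor-positive subjects, and additive Gaussian noise.  The phantom
#' exists so that every downstream stage (autoencoder, classifier, k-means
#' ROI, segmenters, metrics) is testable without any external MRI dataset; it
#' makes no claim of MRI physics realism (no bias fields, no multi-sequence
#' contrast, no 3D structure).
#'
#' @param image_size pixels per side of the square slice.
#' @param n_subjects number of subjects.
#' @param slices_per_subject slices generated per subject.
#' @param tumor_prevalence fraction of subjects (in `[0,1]`) that are
#'   tumor-positive.  The positive count is `round(prevalence * n_subjects)`.
#' @param tumor_radius_range `c(min, max)` ellipse semi-axis range in pixels;
#'   both semi-axes are drawn independently from this range, so a degenerate
#'   range `c(r, r)` yields exact circles of radius `r`.
#' @param tumor_contrast additive intensity offset of tumor over background
#'   (arbitrary intensity units; background sits near 0.35).
#' @param noise_sigma standard deviation of additive i.i.d. Gaussian noise.
#' @param background_texture_scale spatial correlation length (pixels) of the
#'   smooth background field.
#' @param texture_amplitude intensity amplitude of the background field.
#' @param seed integer RNG seed; all samples derive per-slice streams from it
#'   via [hash_seed()], so generation is order-independent.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(image_size = 64L,
                         n_subjects = 20L,
                         slices_per_subject = 5L,
                         tumor_prevalence = 0.5,
                         tumor_radius_range = c(6, 12),
                         tumor_contrast = 0.6,
                         noise_sigma = 0.05,
                         background_texture_scale = 8,
                         texture_amplitude = 0.06,
                         seed = 42L) {
  check_that(image_size >= 8, "image_size must be at least 8")
  check_that(n_subjects >= 1 && slices_per_subject >= 1,
             "n_subjects and slices_per_subject must be positive")
  check_that(tumor_prevalence >= 0 && tumor_prevalence <= 1,
             "tumor_prevalence must lie in [0, 1]")
  check_that(length(tumor_radius_range) == 2 &&
               tumor_radius_range[1] <= tumor_radius_range[2],
             "tumor_radius_range must be c(min, max) with min <= max")
  check_that(tumor_radius_range[2] < image_size / 2,
             "max tumor radius must be smaller than image_size / 2")
  check_that(noise_sigma >= 0, "noise_sigma must be non-negative")
  check_that(background_texture_scale >= 1, "background_texture_scale must be >= 1")
  structure(
    list(
      image_size = as.integer(image_size),
      n_subjects = as.integer(n_subjects),
      slices_per_subject = as.integer(slices_per_subject),
      tumor_prevalence = tumor_prevalence,
      tumor_radius_range = as.numeric(tumor_radius_range),
      tumor_contrast = tumor_contrast,
      noise_sigma = noise_sigma,
      background_texture_scale = background_texture_scale,
      texture_amplitude = texture_amplitude,
      seed = as.integer(seed)
    ),
    class = "phantom_spec"
  )
}

n_positive_subjects <- function(spec) {
  as.integer(round(spec$tumor_prevalence * spec$n_subjects))
}

subject_is_positive <- function(spec, subject_index) {
  subject_index <= n_positive_subjects(spec)
}

# Subject-level tumor geometry: drawn once per subject so all slices of a
# subject show the same lesion (jittered per slice).
subject_geometry <- function(spec, subject_index) {
  with_seed(hash_seed(spec$seed, subject_index, 0), {
    r <- spec$tumor_radius_range
    a <- stats::runif(1, r[1], r[2])
    b <- stats::runif(1, r[1], r[2])
    rmax <- max(a, b)
    lo <- rmax + 2
    hi <- spec$image_size - rmax - 3
    if (hi < lo) hi <- lo
    list(
      cx = stats::runif(1, lo, hi),
      cy = stats::runif(1, lo, hi),
      a = a, b = b,
      angle = stats::runif(1, 0, pi)
    )
  })
}

rasterize_ellipse <- function(size, cx, cy, a, b, angle) {
  # pixel centers at 0-based integer coordinates (row = y, col = x)
  y <- matrix(rep(0:(size - 1), size), size, size)
  x <- t(y)
  dx <- x - cx
  dy <- y - cy
  u <- dx * cos(angle) + dy * sin(angle)
  v <- -dx * sin(angle) + dy * cos(angle)
  mask <- (u / a)^2 + (v / b)^2 <= 1
  storage.mode(mask) <- "double"
  mask
}

# Smooth background: white noise on a coarse grid, bilinearly upsampled and
# standardised. Correlation length ~ background_texture_scale pixels.
smooth_background <- function(size, scale) {
  coarse <- max(2L, as.integer(ceiling(size / scale)) + 1L)
  field <- matrix(stats::rnorm(coarse * coarse), coarse, coarse)
  up <- resize_image(field, c(size, size), method = "bilinear")
  s <- stats::sd(as.vector(up))
  if (s < 1e-12) s <- 1
  (up - mean(up)) / s
}

#' Generate one phantom slice
#'
#' Deterministic function of `(spec$seed, subject_index, slice_index)`:
#' calling it twice yields bit-identical output, and the result does not
#' depend on which other samples were generated before it.
#'
#' @param spec a [phantom_spec()].
#' @param subject_index subject number in `1:n_subjects`.
#' @param slice_index slice number in `1:slices_per_subject`.
#' @return A `phantom_sample`: list with `image` (H x W matrix), `mask`
#'   (H x W binary matrix, 1 = tumor), `subject_id` (character), and `label`
#'   (`"tumor"` or `"non_tumor"`).  `label == "tumor"` iff the mask contains
#'   at least one positive pixel.
#' @export
generate_phantom <- function(spec, subject_index, slice_index) {
  check_that(inherits(spec, "phantom_spec"), "spec must be a phantom_spec")
  check_that(subject_index >= 1 && subject_index <= spec$n_subjects,
             "subject_index out of range")
  check_that(slice_index >= 1 && slice_index <= spec$slices_per_subject,
             "slice_index out of range")

  size <- spec$image_size
  positive <- subject_is_positive(spec, subject_index)
  geom <- subject_geometry(spec, subject_index)

  with_seed(hash_seed(spec$seed, subject_index, slice_index), {
    bg <- smooth_background(size, spec$background_texture_scale)
    img <- 0.35 + spec$texture_amplitude * bg
    if (positive) {
      # per-slice jitter: center +-2 px, angle +-10 deg, radii +-1%
      cx <- geom$cx + stats::runif(1, -2, 2)
      cy <- geom$cy + stats::runif(1, -2, 2)
      ang <- geom$angle + stats::runif(1, -pi / 18, pi / 18)
      a <- geom$a * stats::runif(1, 0.99, 1.01)
      b <- geom$b * stats::runif(1, 0.99, 1.01)
      mask <- rasterize_ellipse(size, cx, cy, a, b, ang)
      img <- img + spec$tumor_contrast * mask
    } else {
      mask <- matrix(0, size, size)
    }
    if (spec$noise_sigma > 0) {
      img <- img + matrix(stats::rnorm(size * size, 0, spec$noise_sigma), size, size)
    }
    structure(
      list(
        image = img,
        mask = mask,
        subject_id = sprintf("subj%03d", subject_index),
        label = if (sum(mask) > 0) "tumor" else "non_tumor"
      ),
      class = "phantom_sample"
    )
  })
}

#' Generate a full phantom dataset
#'
#' Produces `n_subjects * slices_per_subject` samples together with a manifest
#' (`path, mask_path, subject_id, label`).  When `output_dir` is given, images
#' and masks are written as 8-bit PNG (masks use values {0, 255}) and the
#' manifest as `manifest.csv`; paths in the manifest are relative to
#' `output_dir`.  Regeneration with the same spec reproduces the manifest
#' byte-for-byte.
#'
#' @param spec a [phantom_spec()].
#' @param output_dir optional directory to write images, masks, and manifest.
#' @return List with `samples` (list of `phantom_sample`) and `manifest`
#'   (data.frame).
#' @export
generate_dataset <- function(spec, output_dir = NULL) {
  check_that(inherits(spec, "phantom_spec"), "spec must be a phantom_spec")
  n <- spec$n_subjects * spec$slices_per_subject
  samples <- vector("list", n)
  path <- character(n)
  mask_path <- character(n)
  subject_id <- character(n)
  label <- character(n)
  idx <- 0L
  for (s in seq_len(spec$n_subjects)) {
    for (k in seq_len(spec$slices_per_subject)) {
      idx <- idx + 1L
      smp <- generate_phantom(spec, s, k)
      samples[[idx]] <- smp
      path[idx] <- sprintf("images/subj%03d_slice%02d.png", s, k)
      mask_path[idx] <- sprintf("masks/subj%03d_slice%02d.png", s, k)
      subject_id[idx] <- smp$subject_id
      label[idx] <- smp$label
    }
  }
  manifest <- data.frame(
    path = path, mask_path = mask_path,
    subject_id = subject_id, label = label,
    stringsAsFactors = FALSE
  )
  if (!is.null(output_dir)) {
    ok <- dir.exists(output_dir) || dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", output_dir)
    dir.create(file.path(output_dir, "images"), showWarnings = FALSE)
    dir.create(file.path(output_dir, "masks"), showWarnings = FALSE)
    for (i in seq_len(n)) {
      write_image_png(samples[[i]]$image, file.path(output_dir, manifest$path[i]))
      write_mask_png(samples[[i]]$mask, file.path(output_dir, manifest$mask_path[i]))
    }
    write_manifest(manifest, file.path(output_dir, "manifest.csv"))
  }
  list(samples = samples, manifest = manifest)
}
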