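#' Write a grayscale image as 8-bit PNG
#'
#' Intensities are clipped to `[0, 1]` before quantisation.
#' @param image H x W numeric matrix.
#' @param path output file.
#' @export
write_image_png <- function(image, path) {
  img <- pmin(pmax(image, 0), 1)
  png::writePNG(img, target = path)
  invisible(path)
}

#' Write a binary mask as 8-bit PNG with values {0, 255}
#' @param mask H x W binary matrix.
#' @param path output file.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG((mask > 0) * 1.0, target = path)
  invisible(path)
}

#' Read a PNG as a grayscale matrix
#'
#' Multi-channel PNGs are averaged over channels.
#' @param path input file.
#' @param binarize if `TRUE`, threshold at 0.5 and return a {0,1} mask.
#' @export
read_image_png <- function(path, binarize = FALSE) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 3L) {
    x <- apply(x[, , seq_len(min(3L, dim(x)[3L])), drop = FALSE], c(1L, 2L), mean)
  }
  if (binarize) x <- (x > 0.5) * 1.0
  x
}

#' Write/read the dataset manifest CSV (`path,mask_path,subject_id,label`)
#' @param manifest data.frame with the manifest columns.
#' @param path CSV file path.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(manifest, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Serialize a configuration object to YAML (or JSON) and back
#' @param x a list-like configuration.
#' @param path file ending in `.yaml`/`.yml` or `.json`.
#' @export
write_config <- function(x, path) {
  plain <- unclass_deep(x)
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(plain, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    yaml::write_yaml(plain, path)
  }
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
}

unclass_deep <- function(x) {
  if (is.list(x)) {
    lapply(unclass(x), unclass_deep)
  } else {
    x
  }
}

#' Save / load a model checkpoint (config + parameters + seed in one file)
#' @param model a model bundle as returned by the `build_*` functions.
#' @param path checkpoint file (RDS).
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  readRDS(path)
}

#' Write a training history as CSV
#' @param history data.frame of per-epoch records.
#' @param path CSV file path.
#' @export
write_history <- function(history, path) {
  utils::write.csv(history, path, row.names = FALSE)
  invisible(path)
}
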