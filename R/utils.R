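#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the RNG to a fixed state, evaluates `code`, and restores the previous
#' state so that library code never perturbs the caller's RNG stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  code
}

#' Derive a child seed from a base seed and integer coordinates
#'
#' Deterministic, order-sensitive integer hash into `[0, 2^31 - 2]`.  Used to
#' give every (subject, slice), every augmentation draw, every restart, and
#' every epoch its own independent RNG stream so that generation is
#' order-independent: sample (i, j) is identical whether generated alone or
#' as part of a full dataset.
#'
#' @param ... integers (seed first, then coordinates).
#' @return A single integer seed.
#' @export
hash_seed <- function(...) {
  xs <- as.numeric(c(...))
  stopifnot(all(is.finite(xs)))
  m <- 2147483647 # 2^31 - 1, keeps all intermediates exact in doubles
  h <- 113
  for (x in xs) {
    h <- (h * 31 + (abs(x) %% m) + 17) %% m
  }
  as.integer(h)
}

abort_arg <- function(msg) stop(msg, call. = FALSE)

check_that <- function(cond, msg) {
  if (!isTRUE(cond)) abort_arg(msg)
  invisible(TRUE)
}

#' @keywords internal
sigmoid <- function(x) 1 / (1 + exp(-x))

#' Row-wise softmax of a matrix (numerically stabilised)
#' @keywords internal
softmax_rows <- function(x) {
  x <- x - apply(x, 1L, max)
  e <- exp(x)
  e / rowSums(e)
}

#' @keywords internal
softmax_vec <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

# Coerce a 2D matrix or HxWxC array to the internal H x W x C x N layout.
as_tensor <- function(x) {
  if (is.matrix(x)) {
    array(x, dim = c(dim(x), 1L, 1L))
  } else if (length(dim(x)) == 3L) {
    array(x, dim = c(dim(x), 1L))
  } else if (length(dim(x)) == 4L) {
    x
  } else {
    abort_arg("expected a 2D matrix, 3D array, or 4D tensor")
  }
}

# Stack a list of H x W (or H x W x C) images into an H x W x C x N tensor.
stack_images <- function(imgs) {
  x1 <- as_tensor(imgs[[1L]])[, , , 1L, drop = FALSE]
  d <- dim(x1)
  out <- array(0, dim = c(d[1L], d[2L], d[3L], length(imgs)))
  for (i in seq_along(imgs)) {
    out[, , , i] <- as_tensor(imgs[[i]])[, , , 1L]
  }
  out
}
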