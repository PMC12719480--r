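# Minimal deterministic neural-network core.
#
# Tensors use the layout H x W x C x N (rows, cols, channels, batch).
# Convolutions are computed by im2col + BLAS matrix multiply; each
# architecture writes its forward and backward passes explicitly against a
# "tape" that caches per-layer intermediates and accumulates gradients by
# parameter name.  Weight initialisation is He-normal (sd = sqrt(2/fan_in))
# drawn from whatever RNG state is active, so builders run under a fixed
# seed for reproducible parameters.

nn_builder <- function() {
  b <- new.env(parent = emptyenv())
  b$params <- list()
  b$buffers <- list()
  b
}

init_conv <- function(b, name, k, c_in, c_out) {
  sd <- sqrt(2 / (k * k * c_in))
  b$params[[paste0(name, ".W")]] <-
    array(stats::rnorm(k * k * c_in * c_out, 0, sd), dim = c(k, k, c_in, c_out))
  b$params[[paste0(name, ".b")]] <- numeric(c_out)
  invisible(b)
}

init_bn <- function(b, name, c_out) {
  b$params[[paste0(name, ".gamma")]] <- rep(1, c_out)
  b$params[[paste0(name, ".beta")]] <- rep(0, c_out)
  b$buffers[[paste0(name, ".mean")]] <- rep(0, c_out)
  b$buffers[[paste0(name, ".var")]] <- rep(1, c_out)
  invisible(b)
}

init_dense <- function(b, name, f_in, f_out) {
  sd <- sqrt(2 / f_in)
  b$params[[paste0(name, ".W")]] <- matrix(stats::rnorm(f_in * f_out, 0, sd), f_in, f_out)
  b$params[[paste0(name, ".b")]] <- numeric(f_out)
  invisible(b)
}

init_attention <- function(b, name, c_in, d_k) {
  sd <- sqrt(2 / c_in)
  b$params[[paste0(name, ".Wq")]] <- matrix(stats::rnorm(c_in * d_k, 0, sd), c_in, d_k)
  b$params[[paste0(name, ".Wk")]] <- matrix(stats::rnorm(c_in * d_k, 0, sd), c_in, d_k)
  b$params[[paste0(name, ".Wv")]] <- matrix(stats::rnorm(c_in * c_in, 0, sd), c_in, c_in)
  invisible(b)
}

init_gate <- function(b, name, c_x, c_g, c_int) {
  sd_x <- sqrt(2 / c_x)
  sd_g <- sqrt(2 / c_g)
  sd_i <- sqrt(2 / c_int)
  b$params[[paste0(name, ".Wx")]] <- matrix(stats::rnorm(c_x * c_int, 0, sd_x), c_x, c_int)
  b$params[[paste0(name, ".Wg")]] <- matrix(stats::rnorm(c_g * c_int, 0, sd_g), c_g, c_int)
  b$params[[paste0(name, ".b")]] <- numeric(c_int)
  b$params[[paste0(name, ".psi")]] <- matrix(stats::rnorm(c_int, 0, sd_i), c_int, 1)
  b$params[[paste0(name, ".b_psi")]] <- 0
  invisible(b)
}

init_scalar <- function(b, name, value = 0) {
  b$params[[name]] <- value
  invisible(b)
}

# ---- tape ------------------------------------------------------------------

nn_tape <- function(model, training = FALSE) {
  tp <- new.env(parent = emptyenv())
  tp$params <- model$params
  tp$buffers <- model$buffers
  tp$training <- isTRUE(training)
  tp$cache <- list()
  tp$grads <- list()
  tp
}

gacc <- function(tp, name, g) {
  cur <- tp$grads[[name]]
  tp$grads[[name]] <- if (is.null(cur)) g else cur + g
  invisible(NULL)
}

# ---- channel helpers -------------------------------------------------------

# per-channel sum over (H, W, N) of an H x W x C x N tensor
channel_sum <- function(x) {
  d <- dim(x)
  m <- x
  dim(m) <- c(d[1L] * d[2L], d[3L] * d[4L])
  rowSums(matrix(colSums(m), d[3L], d[4L]))
}

# broadcast a length-C vector across an H x W x C x N tensor
channel_mul <- function(x, v) {
  d <- dim(x)
  x * rep(rep(v, each = d[1L] * d[2L]), times = d[4L])
}

channel_add <- function(x, v) {
  d <- dim(x)
  x + rep(rep(v, each = d[1L] * d[2L]), times = d[4L])
}

# 1x1 convolution as a channel-space matrix multiply: (H,W,Ci,N) -> (H,W,Co,N)
channel_matmul <- function(x, W) {
  d <- dim(x)
  m <- matrix(aperm(x, c(1L, 2L, 4L, 3L)), d[1L] * d[2L] * d[4L], d[3L])
  y <- m %*% W
  aperm(array(y, dim = c(d[1L], d[2L], d[4L], ncol(W))), c(1L, 2L, 4L, 3L))
}

# sum over the channel dimension -> (H, W, 1, N)
sum_channels <- function(x) {
  d <- dim(x)
  m <- matrix(aperm(x, c(1L, 2L, 4L, 3L)), d[1L] * d[2L] * d[4L], d[3L])
  array(aperm(array(rowSums(m), dim = c(d[1L], d[2L], d[4L], 1L)), c(1L, 2L, 4L, 3L)),
        dim = c(d[1L], d[2L], 1L, d[4L]))
}

# replicate a single-channel map across C channels
broadcast_channel <- function(w, C) {
  w[, , rep(1L, C), , drop = FALSE]
}

# ---- convolution -----------------------------------------------------------

conv_im2col <- function(x, k, stride, pad) {
  d <- dim(x)
  H <- d[1L]; W <- d[2L]; C <- d[3L]; N <- d[4L]
  Ho <- (H + 2L * pad - k) %/% stride + 1L
  Wo <- (W + 2L * pad - k) %/% stride + 1L
  if (pad > 0L) {
    xp <- array(0, dim = c(H + 2L * pad, W + 2L * pad, C, N))
    xp[pad + seq_len(H), pad + seq_len(W), , ] <- x
  } else {
    xp <- x
  }
  R <- Ho * Wo * N
  cols <- matrix(0, R, k * k * C)
  o <- 0L
  for (kw in seq_len(k)) {
    for (kh in seq_len(k)) {
      o <- o + 1L
      slab <- xp[seq.int(kh, by = stride, length.out = Ho),
                 seq.int(kw, by = stride, length.out = Wo), , , drop = FALSE]
      cols[, o + k * k * (seq_len(C) - 1L)] <-
        matrix(aperm(slab, c(1L, 2L, 4L, 3L)), R, C)
    }
  }
  list(cols = cols, Ho = Ho, Wo = Wo)
}

conv_col2im <- function(dcols, dimx, k, stride, pad, Ho, Wo) {
  H <- dimx[1L]; W <- dimx[2L]; C <- dimx[3L]; N <- dimx[4L]
  dxp <- array(0, dim = c(H + 2L * pad, W + 2L * pad, C, N))
  R <- Ho * Wo * N
  o <- 0L
  for (kw in seq_len(k)) {
    for (kh in seq_len(k)) {
      o <- o + 1L
      dslab <- aperm(array(dcols[, o + k * k * (seq_len(C) - 1L)],
                           dim = c(Ho, Wo, N, C)), c(1L, 2L, 4L, 3L))
      ri <- seq.int(kh, by = stride, length.out = Ho)
      ci <- seq.int(kw, by = stride, length.out = Wo)
      dxp[ri, ci, , ] <- dxp[ri, ci, , , drop = FALSE] + dslab
    }
  }
  if (pad > 0L) {
    dxp[pad + seq_len(H), pad + seq_len(W), , , drop = FALSE]
  } else {
    dxp
  }
}

f_conv <- function(tp, name, x, stride = 1L) {
  W <- tp$params[[paste0(name, ".W")]]
  b <- tp$params[[paste0(name, ".b")]]
  k <- dim(W)[1L]
  pad <- (k - 1L) %/% 2L
  ic <- conv_im2col(x, k, stride, pad)
  c_out <- dim(W)[4L]
  Wm <- matrix(W, k * k * dim(W)[3L], c_out)
  Ym <- ic$cols %*% Wm
  Ym <- Ym + rep(b, each = nrow(Ym))
  N <- dim(x)[4L]
  y <- aperm(array(Ym, dim = c(ic$Ho, ic$Wo, N, c_out)), c(1L, 2L, 4L, 3L))
  tp$cache[[name]] <- list(cols = ic$cols, dimx = dim(x), k = k,
                           stride = stride, pad = pad, Ho = ic$Ho, Wo = ic$Wo)
  y
}

b_conv <- function(tp, name, dy) {
  cc <- tp$cache[[name]]
  W <- tp$params[[paste0(name, ".W")]]
  c_out <- dim(W)[4L]
  R <- cc$Ho * cc$Wo * cc$dimx[4L]
  dym <- matrix(aperm(dy, c(1L, 2L, 4L, 3L)), R, c_out)
  Wm <- matrix(W, cc$k * cc$k * cc$dimx[3L], c_out)
  dW <- crossprod(cc$cols, dym)
  dim(dW) <- dim(W)
  gacc(tp, paste0(name, ".W"), dW)
  gacc(tp, paste0(name, ".b"), colSums(dym))
  dcols <- dym %*% t(Wm)
  conv_col2im(dcols, cc$dimx, cc$k, cc$stride, cc$pad, cc$Ho, cc$Wo)
}

# ---- batch normalisation ---------------------------------------------------

f_bn <- function(tp, name, x, momentum = 0.1, eps = 1e-5) {
  gamma <- tp$params[[paste0(name, ".gamma")]]
  beta <- tp$params[[paste0(name, ".beta")]]
  d <- dim(x)
  m <- d[1L] * d[2L] * d[4L]
  if (tp$training) {
    mu <- channel_sum(x) / m
    xc <- channel_add(x, -mu)
    varc <- channel_sum(xc * xc) / m
    tp$buffers[[paste0(name, ".mean")]] <-
      (1 - momentum) * tp$buffers[[paste0(name, ".mean")]] + momentum * mu
    tp$buffers[[paste0(name, ".var")]] <-
      (1 - momentum) * tp$buffers[[paste0(name, ".var")]] + momentum * varc
  } else {
    mu <- tp$buffers[[paste0(name, ".mean")]]
    varc <- tp$buffers[[paste0(name, ".var")]]
    xc <- channel_add(x, -mu)
  }
  ivar <- 1 / sqrt(varc + eps)
  xhat <- channel_mul(xc, ivar)
  y <- channel_add(channel_mul(xhat, gamma), beta)
  tp$cache[[name]] <- list(xhat = xhat, ivar = ivar, xc = xc, m = m)
  y
}

b_bn <- function(tp, name, dy) {
  cc <- tp$cache[[name]]
  gamma <- tp$params[[paste0(name, ".gamma")]]
  gacc(tp, paste0(name, ".gamma"), channel_sum(dy * cc$xhat))
  gacc(tp, paste0(name, ".beta"), channel_sum(dy))
  dxhat <- channel_mul(dy, gamma)
  m <- cc$m
  s1 <- channel_sum(dxhat)
  s2 <- channel_sum(dxhat * cc$xhat)
  channel_mul(dxhat - channel_add(channel_mul(cc$xhat, s2 / m), s1 / m), cc$ivar)
}

# ---- activations -----------------------------------------------------------

f_relu <- function(tp, name, x) {
  pos <- x > 0
  tp$cache[[name]] <- pos
  x * pos
}

b_relu <- function(tp, name, dy) {
  dy * tp$cache[[name]]
}

f_sigmoid <- function(tp, name, x) {
  y <- sigmoid(x)
  tp$cache[[name]] <- y
  y
}

b_sigmoid <- function(tp, name, dy) {
  y <- tp$cache[[name]]
  dy * y * (1 - y)
}

# ---- dense / pooling -------------------------------------------------------

f_dense <- function(tp, name, x) {
  W <- tp$params[[paste0(name, ".W")]]
  b <- tp$params[[paste0(name, ".b")]]
  tp$cache[[name]] <- x
  sweep(x %*% W, 2L, b, `+`)
}

b_dense <- function(tp, name, dy) {
  x <- tp$cache[[name]]
  W <- tp$params[[paste0(name, ".W")]]
  gacc(tp, paste0(name, ".W"), crossprod(x, dy))
  gacc(tp, paste0(name, ".b"), colSums(dy))
  dy %*% t(W)
}

# global average pool: (H,W,C,N) -> (N,C)
f_gap <- function(tp, name, x) {
  d <- dim(x)
  m <- x
  dim(m) <- c(d[1L] * d[2L], d[3L] * d[4L])
  tp$cache[[name]] <- d
  t(matrix(colSums(m) / (d[1L] * d[2L]), d[3L], d[4L]))
}

b_gap <- function(tp, name, dy) {
  d <- tp$cache[[name]]
  hw <- d[1L] * d[2L]
  v <- as.vector(t(dy)) / hw # channel fast, batch slow
  array(rep(v, each = hw), dim = d)
}

# ---- nearest-neighbor 2x up/down -------------------------------------------

f_upsample2 <- function(tp, name, x) {
  d <- dim(x)
  tp$cache[[name]] <- d
  x[rep(seq_len(d[1L]), each = 2L), rep(seq_len(d[2L]), each = 2L), , , drop = FALSE]
}

b_upsample2 <- function(tp, name, dy) {
  d <- tp$cache[[name]]
  a <- dy[seq.int(1L, 2L * d[1L], 2L), , , , drop = FALSE] +
    dy[seq.int(2L, 2L * d[1L], 2L), , , , drop = FALSE]
  a[, seq.int(1L, 2L * d[2L], 2L), , , drop = FALSE] +
    a[, seq.int(2L, 2L * d[2L], 2L), , , drop = FALSE]
}

# ---- channel concatenation -------------------------------------------------

f_concat <- function(tp, name, a, b) {
  da <- dim(a)
  db <- dim(b)
  out <- array(0, dim = c(da[1L], da[2L], da[3L] + db[3L], da[4L]))
  out[, , seq_len(da[3L]), ] <- a
  out[, , da[3L] + seq_len(db[3L]), ] <- b
  tp$cache[[name]] <- c(da[3L], db[3L])
  out
}

b_concat <- function(tp, name, dy) {
  cs <- tp$cache[[name]]
  list(da = dy[, , seq_len(cs[1L]), , drop = FALSE],
       db = dy[, , cs[1L] + seq_len(cs[2L]), , drop = FALSE])
}

# ---- scaled dot-product self-attention -------------------------------------

#' Scaled dot-product attention
#'
#' `Attention(Q, K, V) = SoftMax(Q K^T / sqrt(d_k)) V`.  Every output row is
#' a convex combination of the rows of `V`; each row of the returned
#' `weights` matrix is non-negative and sums to 1.
#'
#' @param Q query matrix (`n_q` x `d_k`).
#' @param K key matrix (`n_kv` x `d_k`).
#' @param V value matrix (`n_kv` x `d_v`).
#' @param d_k scaling dimension; defaults to `ncol(K)`.
#' @return List with `output` (`n_q` x `d_v`) and `weights` (`n_q` x `n_kv`).
#' @export
scaled_dot_attention <- function(Q, K, V, d_k = ncol(K)) {
  Q <- as.matrix(Q); K <- as.matrix(K); V <- as.matrix(V)
  check_that(ncol(Q) == ncol(K), "Q and K must have the same column dimension")
  check_that(nrow(K) == nrow(V), "K and V must have the same number of rows")
  check_that(d_k > 0, "d_k must be positive")
  A <- softmax_rows(Q %*% t(K) / sqrt(d_k))
  list(output = A %*% V, weights = A)
}

# bottleneck self-attention block with residual connection, batched over N
f_attention <- function(tp, name, x) {
  Wq <- tp$params[[paste0(name, ".Wq")]]
  Wk <- tp$params[[paste0(name, ".Wk")]]
  Wv <- tp$params[[paste0(name, ".Wv")]]
  d <- dim(x)
  P <- d[1L] * d[2L]
  dk <- ncol(Wq)
  y <- x
  caches <- vector("list", d[4L])
  for (n in seq_len(d[4L])) {
    Xs <- matrix(x[, , , n], P, d[3L])
    Qm <- Xs %*% Wq
    Km <- Xs %*% Wk
    Vm <- Xs %*% Wv
    A <- softmax_rows(Qm %*% t(Km) / sqrt(dk))
    O <- A %*% Vm
    y[, , , n] <- array(Xs + O, dim = c(d[1L], d[2L], d[3L]))
    caches[[n]] <- list(Xs = Xs, Q = Qm, K = Km, V = Vm, A = A)
  }
  tp$cache[[name]] <- list(d = d, caches = caches, dk = dk)
  y
}

b_attention <- function(tp, name, dy) {
  cc <- tp$cache[[name]]
  Wq <- tp$params[[paste0(name, ".Wq")]]
  Wk <- tp$params[[paste0(name, ".Wk")]]
  Wv <- tp$params[[paste0(name, ".Wv")]]
  d <- cc$d
  P <- d[1L] * d[2L]
  dWq <- 0; dWk <- 0; dWv <- 0
  dx <- dy
  for (n in seq_len(d[4L])) {
    ca <- cc$caches[[n]]
    dYs <- matrix(dy[, , , n], P, d[3L])
    dO <- dYs
    dA <- dO %*% t(ca$V)
    dV <- crossprod(ca$A, dO)
    dS <- ca$A * (dA - rowSums(dA * ca$A))
    dQ <- dS %*% ca$K / sqrt(cc$dk)
    dK <- crossprod(dS, ca$Q) / sqrt(cc$dk)
    dXs <- dYs + dQ %*% t(Wq) + dK %*% t(Wk) + dV %*% t(Wv)
    dWq <- dWq + crossprod(ca$Xs, dQ)
    dWk <- dWk + crossprod(ca$Xs, dK)
    dWv <- dWv + crossprod(ca$Xs, dV)
    dx[, , , n] <- array(dXs, dim = c(d[1L], d[2L], d[3L]))
  }
  gacc(tp, paste0(name, ".Wq"), dWq)
  gacc(tp, paste0(name, ".Wk"), dWk)
  gacc(tp, paste0(name, ".Wv"), dWv)
  dx
}

# ---- additive attention gate ------------------------------------------------

#' Additive attention gate
#'
#' Computes a per-position scalar weight `w = sigmoid(psi^T relu(Wx x + Wg g
#' + b) + b_psi)` in `[0, 1]` from the skip features `x` and the (spatially
#' aligned) gating signal `g`, and returns `w * x`.  This is the additive
#' gate used on U-Net skip connections — distinct from the transformer
#' self-attention at the autoencoder bottleneck.
#'
#' @param skip skip features, H x W x Cx x N tensor (2D/3D inputs are
#'   promoted).
#' @param gating gating signal, H x W x Cg x N tensor at the same spatial
#'   resolution.
#' @param params list with `Wx` (Cx x Ci), `Wg` (Cg x Ci), `b` (Ci),
#'   `psi` (Ci x 1), `b_psi` (scalar).
#' @return List with `output` (gated skip features) and `weights`
#'   (H x W x 1 x N attention map).
#' @export
attention_gate <- function(skip, gating, params) {
  x <- as_tensor(skip)
  g <- as_tensor(gating)
  check_that(all(dim(x)[c(1L, 2L, 4L)] == dim(g)[c(1L, 2L, 4L)]),
             "skip and gating signal must be spatially aligned")
  check_that(nrow(params$Wx) == dim(x)[3L] && nrow(params$Wg) == dim(g)[3L],
             "gate parameter channel dimensions do not match inputs")
  a <- channel_matmul(x, params$Wx) + channel_matmul(g, params$Wg)
  a <- channel_add(a, params$b)
  h <- a * (a > 0)
  s <- channel_matmul(h, params$psi) + params$b_psi
  w <- sigmoid(s)
  list(output = x * broadcast_channel(w, dim(x)[3L]), weights = w)
}

f_gate <- function(tp, name, x, g) {
  p <- function(suffix) tp$params[[paste0(name, ".", suffix)]]
  a <- channel_matmul(x, p("Wx")) + channel_matmul(g, p("Wg"))
  a <- channel_add(a, p("b"))
  pos <- a > 0
  h <- a * pos
  s <- channel_matmul(h, p("psi")) + p("b_psi")
  w <- sigmoid(s)
  wb <- broadcast_channel(w, dim(x)[3L])
  tp$cache[[name]] <- list(x = x, g = g, pos = pos, h = h, w = w, wb = wb)
  x * wb
}

b_gate <- function(tp, name, dy) {
  cc <- tp$cache[[name]]
  p <- function(suffix) tp$params[[paste0(name, ".", suffix)]]
  dx1 <- dy * cc$wb
  dw <- sum_channels(dy * cc$x)
  ds <- dw * cc$w * (1 - cc$w)
  gacc(tp, paste0(name, ".b_psi"), sum(ds))
  dh <- channel_matmul(ds, t(p("psi")))
  d <- dim(cc$h)
  hm <- matrix(aperm(cc$h, c(1L, 2L, 4L, 3L)), d[1L] * d[2L] * d[4L], d[3L])
  sm <- matrix(aperm(ds, c(1L, 2L, 4L, 3L)), d[1L] * d[2L] * d[4L], 1L)
  gacc(tp, paste0(name, ".psi"), crossprod(hm, sm))
  da <- dh * cc$pos
  gacc(tp, paste0(name, ".b"), channel_sum(da))
  dxm <- matrix(aperm(cc$x, c(1L, 2L, 4L, 3L)), , dim(cc$x)[3L])
  dgm <- matrix(aperm(cc$g, c(1L, 2L, 4L, 3L)), , dim(cc$g)[3L])
  dam <- matrix(aperm(da, c(1L, 2L, 4L, 3L)), , d[3L])
  gacc(tp, paste0(name, ".Wx"), crossprod(dxm, dam))
  gacc(tp, paste0(name, ".Wg"), crossprod(dgm, dam))
  list(dx = dx1 + channel_matmul(da, t(p("Wx"))),
       dg = channel_matmul(da, t(p("Wg"))))
}

# ---- Adam optimiser --------------------------------------------------------

adam_init <- function(params) {
  zeros <- lapply(params, function(p) p * 0)
  list(m = zeros, v = zeros, t = 0L)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}
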