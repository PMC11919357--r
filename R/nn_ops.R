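# Low-level neural-network primitives.
#
# Activations are dense arrays of dim (H, W, C, N).  Convolutions use TF-style
# "same" padding: for stride 1 the input is padded (k-1)/2 on each side; for
# stride 2 with even H the total padding is k - 2, applied at the bottom/right.
# Every forward function returns list(y, cache); the matching backward takes
# (dy, cache) and returns the input gradient plus per-parameter gradients.

nn_same_pad <- function(H, k, stride) {
  Ho <- as.integer(ceiling(H / stride))
  total <- max((Ho - 1L) * stride + k - H, 0L)
  list(out = Ho, beg = total %/% 2L)
}

# channel-first matrix view: (C x H*W*N), columns ordered (h, w, n)
nn_cf <- function(x) {
  d <- dim(x)
  matrix(aperm(x, c(3L, 1L, 2L, 4L)), d[3L], d[1L] * d[2L] * d[4L])
}

nn_uncf <- function(m, H, W, C, N) {
  aperm(array(m, c(C, H, W, N)), c(2L, 3L, 1L, 4L))
}

nn_bias_add <- function(y, b) {
  d <- dim(y)
  y + rep(b, each = d[1L] * d[2L])
}

# ---- standard convolution --------------------------------------------------

nn_conv_fwd <- function(x, W, b, stride = 1L, keep = TRUE) {
  d <- dim(x); k <- dim(W)[1L]; cin <- dim(W)[3L]; cout <- dim(W)[4L]
  ph <- nn_same_pad(d[1L], k, stride); pw <- nn_same_pad(d[2L], k, stride)
  cols <- .im2col(x, d[1L], d[2L], d[3L], d[4L], k, stride, ph$beg,
                  ph$out, pw$out)
  ym <- crossprod(matrix(W, k * k * cin, cout), cols) + b
  y <- nn_uncf(ym, ph$out, pw$out, cout, d[4L])
  cache <- if (keep) list(cols = cols, dims = d, k = k, stride = stride,
                          pad = ph$beg, Ho = ph$out, Wo = pw$out, W = W)
  list(y = y, cache = cache)
}

nn_conv_bwd <- function(dy, cache) {
  cc <- cache; d <- cc$dims; k <- cc$k
  cin <- dim(cc$W)[3L]; cout <- dim(cc$W)[4L]
  dym <- nn_cf(dy)
  cols <- cc$cols
  dW <- array(cols %*% t(dym), c(k, k, cin, cout))
  db <- rowSums(dym)
  dcols <- matrix(cc$W, k * k * cin, cout) %*% dym
  dx <- .col2im(dcols, d[1L], d[2L], d[3L], d[4L], k, cc$stride, cc$pad,
                cc$Ho, cc$Wo)
  list(dx = dx, dW = dW, db = db)
}

# ---- transposed convolution (stride-2 deconvolution) -----------------------
# Weights have dim (k, k, Cout, Cin); forward is the adjoint of a strided
# convolution mapping the (2H, 2W, Cout) output back to the input grid.

nn_deconv_fwd <- function(x, W, b, stride = 2L, keep = TRUE) {
  d <- dim(x); k <- dim(W)[1L]; cout <- dim(W)[3L]; cin <- dim(W)[4L]
  Hy <- d[1L] * stride; Wy <- d[2L] * stride
  ph <- nn_same_pad(Hy, k, stride)
  stopifnot(ph$out == d[1L])
  xm <- nn_cf(x)
  dcols <- matrix(W, k * k * cout, cin) %*% xm
  y <- .col2im(dcols, Hy, Wy, cout, d[4L], k, stride, ph$beg, d[1L], d[2L])
  y <- nn_bias_add(y, b)
  cache <- if (keep) list(xm = xm, dims = d, k = k, stride = stride,
                          pad = ph$beg, Hy = Hy, Wy = Wy, W = W)
  list(y = y, cache = cache)
}

nn_deconv_bwd <- function(dy, cache) {
  cc <- cache; d <- cc$dims; k <- cc$k
  cout <- dim(cc$W)[3L]; cin <- dim(cc$W)[4L]
  cols <- .im2col(dy, cc$Hy, cc$Wy, cout, d[4L], k, cc$stride, cc$pad,
                  d[1L], d[2L])
  dxm <- crossprod(matrix(cc$W, k * k * cout, cin), cols)
  dx <- nn_uncf(dxm, d[1L], d[2L], d[3L], d[4L])
  dW <- array(cols %*% t(cc$xm), c(k, k, cout, cin))
  db <- rowSums(nn_cf(dy))
  list(dx = dx, dW = dW, db = db)
}

# ---- depth-wise convolution ------------------------------------------------

nn_dwconv_fwd <- function(x, W, b, stride = 1L, keep = TRUE) {
  d <- dim(x); k <- dim(W)[1L]; C <- d[3L]
  ph <- nn_same_pad(d[1L], k, stride); pw <- nn_same_pad(d[2L], k, stride)
  cols <- .im2col(x, d[1L], d[2L], C, d[4L], k, stride, ph$beg, ph$out, pw$out)
  cw <- cols * as.vector(W)
  dim(cw) <- c(k * k, C * ncol(cols))
  ym <- matrix(colSums(cw), C, ncol(cols)) + b
  y <- nn_uncf(ym, ph$out, pw$out, C, d[4L])
  cache <- if (keep) list(cols = cols, dims = d, k = k, stride = stride,
                          pad = ph$beg, Ho = ph$out, Wo = pw$out, W = W)
  list(y = y, cache = cache)
}

nn_dwconv_bwd <- function(dy, cache) {
  cc <- cache; d <- cc$dims; k <- cc$k; C <- d[3L]
  dym <- nn_cf(dy)
  expand <- dym[rep(seq_len(C), each = k * k), , drop = FALSE]
  dcols <- expand * as.vector(cc$W)
  dx <- .col2im(dcols, d[1L], d[2L], C, d[4L], k, cc$stride, cc$pad,
                cc$Ho, cc$Wo)
  dW <- array(rowSums(cc$cols * expand), c(k, k, C))
  db <- rowSums(dym)
  list(dx = dx, dW = dW, db = db)
}

# ---- per-pixel dense (pointwise linear) ------------------------------------

nn_pw_fwd <- function(x, W, b, keep = TRUE) {
  d <- dim(x)
  xm <- nn_cf(x)
  ym <- crossprod(W, xm) + b
  y <- nn_uncf(ym, d[1L], d[2L], ncol(W), d[4L])
  cache <- if (keep) list(xm = xm, dims = d, W = W)
  list(y = y, cache = cache)
}

nn_pw_bwd <- function(dy, cache) {
  cc <- cache; d <- cc$dims
  dym <- nn_cf(dy)
  dW <- cc$xm %*% t(dym)
  db <- rowSums(dym)
  dx <- nn_uncf(cc$W %*% dym, d[1L], d[2L], d[3L], d[4L])
  list(dx = dx, dW = dW, db = db)
}

# ---- layer normalization over channels -------------------------------------

nn_ln_fwd <- function(x, gamma, beta, eps = 1e-5, keep = TRUE) {
  d <- dim(x); C <- d[3L]
  xm <- nn_cf(x)
  mu <- colMeans(xm)
  xc <- xm - rep(mu, each = C)
  v <- colMeans(xc * xc)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * rep(inv, each = C)
  ym <- xhat * gamma + beta
  y <- nn_uncf(ym, d[1L], d[2L], C, d[4L])
  cache <- if (keep) list(xhat = xhat, inv = inv, gamma = gamma, dims = d)
  list(y = y, cache = cache)
}

nn_ln_bwd <- function(dy, cache) {
  cc <- cache; d <- cc$dims; C <- d[3L]
  dym <- nn_cf(dy)
  dxhat <- dym * cc$gamma
  m1 <- colMeans(dxhat)
  m2 <- colMeans(dxhat * cc$xhat)
  dxm <- (dxhat - rep(m1, each = C) - cc$xhat * rep(m2, each = C)) *
    rep(cc$inv, each = C)
  list(dx = nn_uncf(dxm, d[1L], d[2L], C, d[4L]),
       dgamma = rowSums(dym * cc$xhat),
       dbeta = rowSums(dym))
}

# ---- activations -----------------------------------------------------------

# GeLU, tanh approximation: 0.5 x (1 + tanh(sqrt(2/pi) (x + 0.044715 x^3)))
nn_gelu_fwd <- function(x, keep = TRUE) {
  k0 <- sqrt(2 / pi)
  t <- tanh(k0 * (x + 0.044715 * x^3))
  list(y = 0.5 * x * (1 + t), cache = if (keep) list(x = x, t = t))
}

nn_gelu_bwd <- function(dy, cache) {
  x <- cache$x; t <- cache$t
  k0 <- sqrt(2 / pi)
  du <- k0 * (1 + 3 * 0.044715 * x^2)
  dy * (0.5 * (1 + t) + 0.5 * x * (1 - t^2) * du)
}

nn_sigmoid <- function(x) 1 / (1 + exp(-x))

nn_softmax_rows <- function(m) {
  e <- exp(m - apply(m, 1L, max))
  e / rowSums(e)
}

# ---- bilinear x2 upsampling (half-pixel alignment) -------------------------

nn_up2_matrix <- function(H) {
  A <- matrix(0, 2L * H, H)
  for (i in seq_len(2L * H) - 1L) {
    src <- (i + 0.5) / 2 - 0.5
    i0 <- floor(src)
    w1 <- src - i0
    lo <- min(max(i0, 0L), H - 1L)
    hi <- min(max(i0 + 1L, 0L), H - 1L)
    A[i + 1L, lo + 1L] <- A[i + 1L, lo + 1L] + (1 - w1)
    A[i + 1L, hi + 1L] <- A[i + 1L, hi + 1L] + w1
  }
  A
}

nn_resize_rowcol <- function(x, Ah, Aw) {
  d <- dim(x)
  y1 <- array(Ah %*% matrix(x, d[1L], d[2L] * d[3L] * d[4L]),
              c(nrow(Ah), d[2L], d[3L], d[4L]))
  xp <- aperm(y1, c(2L, 1L, 3L, 4L))
  y2 <- array(Aw %*% matrix(xp, d[2L], nrow(Ah) * d[3L] * d[4L]),
              c(nrow(Aw), nrow(Ah), d[3L], d[4L]))
  aperm(y2, c(2L, 1L, 3L, 4L))
}

nn_up2_fwd <- function(x, keep = TRUE) {
  d <- dim(x)
  Ah <- nn_up2_matrix(d[1L]); Aw <- nn_up2_matrix(d[2L])
  y <- nn_resize_rowcol(x, Ah, Aw)
  list(y = y, cache = if (keep) list(Ah = Ah, Aw = Aw))
}

nn_up2_bwd <- function(dy, cache) {
  nn_resize_rowcol(dy, t(cache$Ah), t(cache$Aw))
}

# ---- Glorot-uniform initializers -------------------------------------------

nn_init_conv <- function(k, cin, cout) {
  lim <- sqrt(6 / (k * k * cin + k * k * cout))
  list(W = array(runif(k * k * cin * cout, -lim, lim), c(k, k, cin, cout)),
       b = numeric(cout))
}

nn_init_deconv <- function(k, cout, cin) {
  lim <- sqrt(6 / (k * k * cin + k * k * cout))
  list(W = array(runif(k * k * cout * cin, -lim, lim), c(k, k, cout, cin)),
       b = numeric(cout))
}

nn_init_dw <- function(k, C) {
  lim <- sqrt(6 / (2 * k * k))
  list(W = array(runif(k * k * C, -lim, lim), c(k, k, C)), b = numeric(C))
}

nn_init_dense <- function(cin, cout) {
  lim <- sqrt(6 / (cin + cout))
  list(W = matrix(runif(cin * cout, -lim, lim), cin, cout), b = numeric(cout))
}

nn_init_ln <- function(C) list(gamma = rep(1, C), beta = numeric(C))
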