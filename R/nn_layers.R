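# Composite layers of the segmentation-denoising network: the separable
# convolutional transformer (SCT) attention, the depth-wise feed-forward
# network, the squeeze-and-excitation gate and the per-pixel linear decoder
# block.  Batched internals operate on (H, W, C, N) arrays; the exported
# single-image functions wrap them for a (H, W, C) input.

# Tokens are flattened row-major over (H, W): token t = (h-1)*W + w.
nn_tokens <- function(x, n) {
  d <- dim(x)
  matrix(aperm(x[, , , n, drop = FALSE], c(2L, 1L, 3L, 4L)),
         d[1L] * d[2L], d[3L])
}

nn_untokens <- function(m, H, W) {
  aperm(array(m, c(W, H, ncol(m))), c(2L, 1L, 3L))
}

# ---- multi-head self-attention over convolutional Q, K, V -----------------

nn_attn_fwd <- function(q, k, v, heads, keep = TRUE) {
  d <- dim(q); C <- d[3L]; N <- d[4L]; Tn <- d[1L] * d[2L]
  dh <- C %/% heads
  scl <- 1 / sqrt(dh)
  y <- array(0, d)
  cache <- if (keep) list(dims = d, heads = heads,
                          Q = vector("list", N), K = vector("list", N),
                          V = vector("list", N), A = vector("list", N))
  for (n in seq_len(N)) {
    Qm <- nn_tokens(q, n); Km <- nn_tokens(k, n); Vm <- nn_tokens(v, n)
    Om <- matrix(0, Tn, C)
    An <- if (keep) vector("list", heads)
    for (h in seq_len(heads)) {
      idx <- ((h - 1L) * dh + 1L):(h * dh)
      A <- nn_softmax_rows(tcrossprod(Qm[, idx, drop = FALSE],
                                      Km[, idx, drop = FALSE]) * scl)
      Om[, idx] <- A %*% Vm[, idx, drop = FALSE]
      if (keep) An[[h]] <- A
    }
    y[, , , n] <- nn_untokens(Om, d[1L], d[2L])
    if (keep) {
      cache$Q[[n]] <- Qm; cache$K[[n]] <- Km; cache$V[[n]] <- Vm
      cache$A[[n]] <- An
    }
  }
  list(y = y, cache = cache)
}

nn_attn_bwd <- function(dy, cache) {
  d <- cache$dims; C <- d[3L]; N <- d[4L]
  heads <- cache$heads; dh <- C %/% heads
  scl <- 1 / sqrt(dh)
  dq <- array(0, d); dk <- array(0, d); dv <- array(0, d)
  for (n in seq_len(N)) {
    dOm <- nn_tokens(dy, n)
    dQ <- matrix(0, nrow(dOm), C); dK <- dQ; dV <- dQ
    for (h in seq_len(heads)) {
      idx <- ((h - 1L) * dh + 1L):(h * dh)
      A <- cache$A[[n]][[h]]
      dOh <- dOm[, idx, drop = FALSE]
      Vh <- cache$V[[n]][, idx, drop = FALSE]
      dV[, idx] <- crossprod(A, dOh)
      dA <- tcrossprod(dOh, Vh)
      dS <- (dA - rowSums(dA * A)) * A
      dQ[, idx] <- dS %*% cache$K[[n]][, idx, drop = FALSE] * scl
      dK[, idx] <- crossprod(dS, cache$Q[[n]][, idx, drop = FALSE]) * scl
    }
    dq[, , , n] <- nn_untokens(dQ, d[1L], d[2L])
    dk[, , , n] <- nn_untokens(dK, d[1L], d[2L])
    dv[, , , n] <- nn_untokens(dV, d[1L], d[2L])
  }
  list(dq = dq, dk = dk, dv = dv)
}

# ---- squeeze-and-excitation ------------------------------------------------

nn_se_fwd <- function(x, W1, b1, W2, b2, keep = TRUE) {
  d <- dim(x); HW <- d[1L] * d[2L]
  g <- matrix(colMeans(matrix(x, HW, d[3L] * d[4L])), d[3L], d[4L])
  z <- crossprod(W1, g) + b1
  a <- z * pnorm(z)
  u <- crossprod(W2, a) + b2
  gate <- nn_sigmoid(u)
  y <- x * rep(as.vector(gate), each = HW)
  cache <- if (keep) list(x = x, g = g, z = z, a = a, gate = gate,
                          W1 = W1, W2 = W2, dims = d)
  list(y = y, gate = gate, cache = cache)
}

nn_se_bwd <- function(dy, cache) {
  cc <- cache; d <- cc$dims; HW <- d[1L] * d[2L]
  gatev <- rep(as.vector(cc$gate), each = HW)
  dx <- dy * gatev
  dgate <- matrix(colSums(matrix(dy * cc$x, HW, d[3L] * d[4L])),
                  d[3L], d[4L])
  du <- dgate * cc$gate * (1 - cc$gate)
  dW2 <- cc$a %*% t(du)
  db2 <- rowSums(du)
  da <- cc$W2 %*% du
  dz <- da * (pnorm(cc$z) + cc$z * dnorm(cc$z))
  dW1 <- cc$g %*% t(dz)
  db1 <- rowSums(dz)
  dg <- cc$W1 %*% dz
  dx <- dx + rep(as.vector(dg), each = HW) / HW
  list(dx = dx, dW1 = dW1, db1 = db1, dW2 = dW2, db2 = db2)
}

# ---- exported single-image operations --------------------------------------

as_hwcn <- function(x) {
  if (length(dim(x)) == 2L) dim(x) <- c(dim(x), 1L)
  stopifnot(length(dim(x)) == 3L)
  array(x, c(dim(x), 1L))
}

#' Parameters for a convolutional Q/K/V projection
#'
#' Builds randomly initialized weights for [sct_qkv_projection()]: for each of
#' the query, key and value branches a pointwise (1 x 1) convolution with `C`
#' filters followed by a 3 x 3 depth-wise convolution.
#'
#' @param C Number of channels of the feature map the projection acts on.
#' @param seed Optional integer seed for reproducible initialization.
#' @return A list with elements `q`, `k`, `v`, each holding `pw = list(W, b)`
#'   (a `C x C` matrix) and `dw = list(W, b)` (a `3 x 3 x C` array).
#' @export
sct_projection_params <- function(C, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  one <- function() list(pw = nn_init_dense(C, C), dw = nn_init_dw(3L, C))
  list(q = one(), k = one(), v = one())
}

#' Convolutional query/key/value projection of the SCT layer
#'
#' Projects a feature map into query, key and value token sequences through a
#' 1 x 1 convolution (spanning channels) followed by a 3 x 3 depth-wise
#' convolution (spanning space), one independent weight set per sequence.
#' The map is flattened row-major over (height, width), so token
#' `t = (h - 1) * W + w` corresponds to pixel `(h, w)`.
#'
#' @param x Feature map, an `H x W x C` array (a matrix is treated as C = 1).
#' @param proj Projection weights as built by [sct_projection_params()].
#' @return A list with matrices `Q`, `K`, `V`, each `H*W x C`.
#' @export
sct_qkv_projection <- function(x, proj) {
  xa <- as_hwcn(x)
  one <- function(p) {
    h1 <- nn_pw_fwd(xa, p$pw$W, p$pw$b, keep = FALSE)$y
    h2 <- nn_dwconv_fwd(h1, p$dw$W, p$dw$b, keep = FALSE)$y
    nn_tokens(h2, 1L)
  }
  list(Q = one(proj$q), K = one(proj$k), V = one(proj$v))
}

#' Multi-head self-attention over token sequences
#'
#' Splits the channel dimension across heads, applies scaled dot-product
#' attention `softmax(Q K' / sqrt(d)) V` per head, concatenates the heads and
#' optionally applies a final linear projection with `C` units.
#'
#' @param Q,K,V Token matrices of shape `T x C`.
#' @param heads Number of attention heads; `C` must be divisible by it.
#' @param d Scaling dimensionality; defaults to the per-head width `C / heads`.
#' @param proj Optional output projection `list(W, b)` with `W` a `C x C`
#'   matrix; `NULL` skips the projection.
#' @return A `T x C` matrix with attribute `"attention"`, a `T x T x heads`
#'   array of attention weights (each row non-negative, summing to 1).
#' @export
multi_head_self_attention <- function(Q, K, V, heads, d = NULL, proj = NULL) {
  C <- ncol(Q)
  if (C %% heads != 0L)
    stop("number of channels (", C, ") is not divisible by heads (",
         heads, ")")
  dh <- C %/% heads
  if (is.null(d)) d <- dh
  Tn <- nrow(Q)
  out <- matrix(0, Tn, C)
  att <- array(0, c(Tn, Tn, heads))
  for (h in seq_len(heads)) {
    idx <- ((h - 1L) * dh + 1L):(h * dh)
    A <- nn_softmax_rows(tcrossprod(Q[, idx, drop = FALSE],
                                    K[, idx, drop = FALSE]) / sqrt(d))
    out[, idx] <- A %*% V[, idx, drop = FALSE]
    att[, , h] <- A
  }
  if (!is.null(proj)) out <- out %*% proj$W + rep(proj$b, each = Tn)
  structure(out, attention = att)
}

#' Parameters for a depth-wise feed-forward network
#'
#' @param C Number of input/output channels; the hidden width is `4 * C`.
#' @param seed Optional integer seed.
#' @return A list with `pw1`, `dw`, `pw2` weight/bias pairs.
#' @export
dw_ffn_params <- function(C, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  list(pw1 = nn_init_dense(C, 4L * C), dw = nn_init_dw(3L, 4L * C),
       pw2 = nn_init_dense(4L * C, C))
}

#' Depth-wise feed-forward network
#'
#' The transformer feed-forward block with its linear layers replaced by
#' pointwise convolutions around a 3 x 3 depth-wise convolution:
#' `PW2(GeLU(DW(PW1(x))))`, where PW1 expands the channels to `4C` and PW2
#' reduces them back to `C`.  Output shape equals input shape.
#'
#' @param x Feature map, `H x W x C` array.
#' @param params Weights as built by [dw_ffn_params()].
#' @return An `H x W x C` array.
#' @export
dw_ffn <- function(x, params) {
  xa <- as_hwcn(x)
  h1 <- nn_pw_fwd(xa, params$pw1$W, params$pw1$b, keep = FALSE)$y
  h2 <- nn_dwconv_fwd(h1, params$dw$W, params$dw$b, keep = FALSE)$y
  h3 <- nn_gelu_fwd(h2, keep = FALSE)$y
  h4 <- nn_pw_fwd(h3, params$pw2$W, params$pw2$b, keep = FALSE)$y
  array(h4, dim(h4)[1:3])
}

#' Parameters for a squeeze-and-excitation block
#'
#' @param C Number of channels; must be at least `reduction`.
#' @param reduction Bottleneck reduction factor (default 8).
#' @param seed Optional integer seed.
#' @return A list with `W1`, `b1` (C to C/reduction) and `W2`, `b2` (back to C).
#' @export
se_block_params <- function(C, reduction = 8L, seed = NULL) {
  if (C < reduction)
    stop("squeeze-and-excitation needs C >= reduction (C = ", C, ")")
  if (!is.null(seed)) set.seed(seed)
  cr <- max(1L, C %/% reduction)
  p1 <- nn_init_dense(C, cr)
  p2 <- nn_init_dense(cr, C)
  list(W1 = p1$W, b1 = p1$b, W2 = p2$W, b2 = p2$b)
}

#' Squeeze-and-excitation channel gate
#'
#' Global average pooling followed by a two-layer bottleneck (C to C/8 to C)
#' and a sigmoid produces one gate per channel in (0, 1); the input is
#' rescaled channel-wise by the gate.
#'
#' @param x Feature map, `H x W x C` array.
#' @param params Weights as built by [se_block_params()].
#' @return An `H x W x C` array with attribute `"gate"` (length-C vector of
#'   gate values, all strictly inside (0, 1)).
#' @export
se_block <- function(x, params) {
  xa <- as_hwcn(x)
  r <- nn_se_fwd(xa, params$W1, params$b1, params$W2, params$b2, keep = FALSE)
  structure(array(r$y, dim(r$y)[1:3]), gate = as.vector(r$gate))
}

#' Parameters for a linear decoder block
#'
#' @param C Number of channels (must be even): the first projection maps to
#'   `C / 2` units, the second back to `C`.
#' @param seed Optional integer seed.
#' @return A list with `lp1`, `ln` (gamma/beta) and `lp2`.
#' @export
linear_decoder_params <- function(C, seed = NULL) {
  if (C %% 2L != 0L) stop("linear decoder block needs an even C (C = ", C, ")")
  if (!is.null(seed)) set.seed(seed)
  list(lp1 = nn_init_dense(C, C %/% 2L), ln = nn_init_ln(C %/% 2L),
       lp2 = nn_init_dense(C %/% 2L, C))
}

#' Linear decoder block
#'
#' The per-pixel projection block of the segmentation decoder:
#' `LP2(GeLU(LN(LP1(x))))` applied independently at every pixel, with LP1
#' mapping `C` to `C/2` units and LP2 back to `C`.
#'
#' @param x Feature map, `H x W x C` array with even `C`.
#' @param params Weights as built by [linear_decoder_params()].
#' @return An `H x W x C` array.
#' @export
linear_decoder_block <- function(x, params) {
  xa <- as_hwcn(x)
  if (dim(xa)[3L] %% 2L != 0L)
    stop("linear decoder block needs an even channel count")
  h1 <- nn_pw_fwd(xa, params$lp1$W, params$lp1$b, keep = FALSE)$y
  h2 <- nn_ln_fwd(h1, params$ln$gamma, params$ln$beta, keep = FALSE)$y
  h3 <- nn_gelu_fwd(h2, keep = FALSE)$y
  h4 <- nn_pw_fwd(h3, params$lp2$W, params$lp2$b, keep = FALSE)$y
  array(h4, dim(h4)[1:3])
}
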