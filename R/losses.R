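# The multi-task objective: denoising loss (pixel MSE plus feature-space
# content loss), soft-label cross-entropy segmentation loss, and their
# unweighted sum.  Following the calibrated alpha/beta balance the two
# denoising terms are plain sums over elements (not means); across a batch
# the per-sample sums are averaged.

#' Feature extractor for the content loss
#'
#' The content term compares images in the feature space of a convolutional
#' network.  Three modes: `"fixed-random-surrogate"` (default) is a small
#' two-stage convolutional net with frozen, seed-determined random weights --
#' deterministic, dependency-free and differentiable, in the spirit of
#' random-feature perceptual metrics; `"pretrained-perceptual"` delegates to
#' a user-supplied callable (for example a pretrained deep network) and is
#' usable for loss evaluation but not for training, since no gradient is
#' available through an opaque callable; `"off"` disables the content term.
#'
#' @param mode One of `"fixed-random-surrogate"`, `"pretrained-perceptual"`,
#'   `"off"`.
#' @param seed Seed fixing the surrogate weights.
#' @param channels Channel widths of the two surrogate stages.
#' @param fn Callable `function(image_array)` for the pretrained mode.
#' @return An object of class `feature_extractor`.
#' @export
feature_extractor <- function(mode = c("fixed-random-surrogate",
                                       "pretrained-perceptual", "off"),
                              seed = 7L, channels = c(8L, 16L), fn = NULL) {
  mode <- match.arg(mode)
  params <- NULL
  if (mode == "fixed-random-surrogate") {
    stopifnot(length(channels) == 2L, all(channels >= 1L))
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
    set.seed(as.integer(seed))
    params <- list(conv1 = nn_init_conv(3L, 1L, channels[1L]),
                   conv2 = nn_init_conv(3L, channels[1L], channels[2L]))
    if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  }
  if (mode == "pretrained-perceptual" && !is.function(fn))
    stop("pretrained-perceptual mode needs a callable `fn`")
  structure(list(mode = mode, seed = as.integer(seed), params = params,
                 fn = fn),
            class = "feature_extractor")
}

fe_forward <- function(fe, x, keep = FALSE) {
  if (fe$mode == "off") return(list(y = NULL, cache = NULL))
  if (fe$mode == "pretrained-perceptual") {
    ys <- lapply(seq_len(dim(x)[4L]), function(n)
      fe$fn(x[, , 1L, n, drop = TRUE]))
    return(list(y = simplify2array(ys), cache = NULL))
  }
  c1 <- nn_conv_fwd(x, fe$params$conv1$W, fe$params$conv1$b, 1L, keep)
  g1 <- nn_gelu_fwd(c1$y, keep)
  c2 <- nn_conv_fwd(g1$y, fe$params$conv2$W, fe$params$conv2$b, 2L, keep)
  g2 <- nn_gelu_fwd(c2$y, keep)
  list(y = g2$y, cache = if (keep) list(c1 = c1$cache, g1 = g1$cache,
                                        c2 = c2$cache, g2 = g2$cache))
}

fe_backward <- function(fe, dy, cache) {
  d <- nn_gelu_bwd(dy, cache$g2)
  d <- nn_conv_bwd(d, cache$c2)$dx
  d <- nn_gelu_bwd(d, cache$g1)
  nn_conv_bwd(d, cache$c1)$dx
}

#' Loss configuration
#'
#' @param alpha Weight of the pixel MSE term (default 1).
#' @param beta Weight of the content term (default 0.01); 0 disables it.
#' @param confidence Soft-label confidence used by the segmentation loss.
#' @param feature_extractor A [feature_extractor()].
#' @return An object of class `loss_config`.
#' @export
loss_config <- function(alpha = 1, beta = 0.01, confidence = 0.95,
                        feature_extractor = esdm::feature_extractor()) {
  stopifnot(alpha >= 0, beta >= 0, confidence > 0, confidence <= 1,
            inherits(feature_extractor, "feature_extractor"))
  structure(list(alpha = alpha, beta = beta, confidence = confidence,
                 feature_extractor = feature_extractor),
            class = "loss_config")
}

as_batch <- function(x) {
  if (is.matrix(x)) dim(x) <- c(dim(x), 1L, 1L)
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x)[1:2], 1L, dim(x)[3L])
  x
}

#' Denoising loss
#'
#' `alpha * sum((I - Ihat)^2) + beta * sum((phi(I) - phi(Ihat))^2)`, where
#' `phi` is the configured feature extractor and both sums run over all
#' elements of a sample (no 1/N normalization).  For a batch the per-sample
#' sums are averaged.
#'
#' @param target Ground-truth patch: matrix or `(H, W, 1, N)` array.
#' @param output Denoised patch of the same shape.
#' @param cfg A [loss_config()].
#' @return Non-negative scalar.
#' @export
denoise_loss <- function(target, output, cfg = loss_config()) {
  target <- as_batch(target); output <- as_batch(output)
  if (!all(dim(target) == dim(output)))
    stop("target and output shapes differ: ",
         paste(dim(target), collapse = "x"), " vs ",
         paste(dim(output), collapse = "x"))
  N <- dim(target)[4L]
  val <- cfg$alpha * sum((target - output)^2) / N
  if (cfg$beta > 0 && cfg$feature_extractor$mode != "off") {
    ft <- fe_forward(cfg$feature_extractor, target)$y
    fo <- fe_forward(cfg$feature_extractor, output)$y
    val <- val + cfg$beta * sum((ft - fo)^2) / N
  }
  val
}

# loss value plus gradient with respect to the output
denoise_loss_grad <- function(target, output, cfg) {
  N <- dim(target)[4L]
  diff <- output - target
  val <- cfg$alpha * sum(diff^2) / N
  dout <- cfg$alpha * 2 * diff / N
  if (cfg$beta > 0 && cfg$feature_extractor$mode == "fixed-random-surrogate") {
    ft <- fe_forward(cfg$feature_extractor, target, keep = FALSE)$y
    fo <- fe_forward(cfg$feature_extractor, output, keep = TRUE)
    fd <- fo$y - ft
    val <- val + cfg$beta * sum(fd^2) / N
    dout <- dout + cfg$beta *
      fe_backward(cfg$feature_extractor, 2 * fd / N, fo$cache)
  }
  list(value = val, dout = dout)
}

#' Soft-label cross-entropy segmentation loss
#'
#' `-(1/N) * sum over pixels and classes of soft_label * log(probability)`,
#' `N` the number of pixels; with confidence 0.95 and three classes this is
#' the soft-label cross entropy `-(1/N) sum(0.95 log p_true +
#' 0.025 sum_other log p)`.  Logs are clamped at 1e-12.
#'
#' @param probabilities `H x W x K` (or `H x W x K x N`) array of per-pixel
#'   class probabilities.
#' @param soft_labels Array of the same shape whose class vectors sum to 1.
#' @return Non-negative scalar (mean over pixels and batch).
#' @export
seg_loss <- function(probabilities, soft_labels) {
  if (length(dim(probabilities)) == 3L)
    dim(probabilities) <- c(dim(probabilities), 1L)
  if (length(dim(soft_labels)) == 3L)
    dim(soft_labels) <- c(dim(soft_labels), 1L)
  if (!all(dim(probabilities) == dim(soft_labels)))
    stop("probability and soft-label shapes differ")
  if (min(probabilities) < 0)
    stop("negative probabilities")
  d <- dim(probabilities)
  -sum(soft_labels * log(pmax(probabilities, 1e-12))) / (d[1L] * d[2L] * d[4L])
}

#' Combined multi-task loss
#'
#' The training objective is the plain sum of the denoising and segmentation
#' terms, with no extra weighting.
#'
#' @param denoise_term,seg_term Scalars as computed by [denoise_loss()] and
#'   [seg_loss()].
#' @return Their sum.
#' @export
combined_loss <- function(denoise_term, seg_term) denoise_term + seg_term

# softmax over the class axis of (H, W, K, N) logits
esdm_softmax_k <- function(logits) {
  d <- dim(logits)
  K <- d[3L]
  mm <- nn_cf(logits)                     # K x (H*W*N)
  mx <- mm[1L, ]
  if (K > 1L) for (k in 2:K) mx <- pmax(mx, mm[k, ])
  e <- exp(mm - rep(mx, each = K))
  p <- e / rep(colSums(e), each = K)
  nn_uncf(p, d[1L], d[2L], K, d[4L])
}
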