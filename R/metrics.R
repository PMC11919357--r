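# Image-quality metrics (PSNR, SSIM) and segmentation overlap metrics
# (mDice, mIoU) with per-image aggregation as mean +/- standard deviation.

#' Peak signal-to-noise ratio
#'
#' `10 log10(i_max^2 / MSE)`.  A zero MSE (identical images) is reported as
#' `Inf`.
#'
#' @param y Reference image (any numeric array).
#' @param yhat Test image of the same shape.
#' @param i_max Peak intensity of the dynamic range (1 for normalized
#'   images, 255 for 8-bit).
#' @return PSNR in dB.
#' @export
psnr <- function(y, yhat, i_max = 1) {
  if (length(y) == 0L) stop("empty images")
  stopifnot(length(y) == length(yhat), i_max > 0)
  mse <- mean((y - yhat)^2)
  if (mse == 0) return(Inf)
  10 * log10(i_max^2 / mse)
}

#' SSIM configuration
#'
#' @param dynamic_range Intensity range L of the images (1 for normalized).
#' @param k1,k2 Stabilizer coefficients; `C1 = (k1 L)^2`, `C2 = (k2 L)^2`.
#' @param window `"gaussian"` (11 x 11, sigma 1.5, the standard practice and
#'   the default) or `"global"` (whole-image statistics, the printed form of
#'   the index).
#' @param window_size,sigma Gaussian window parameters.
#' @return An object of class `ssim_config`.
#' @export
ssim_config <- function(dynamic_range = 1, k1 = 0.01, k2 = 0.03,
                        window = c("gaussian", "global"),
                        window_size = 11L, sigma = 1.5) {
  window <- match.arg(window)
  stopifnot(dynamic_range > 0, k1 > 0, k2 > 0, window_size >= 3L,
            window_size %% 2L == 1L, sigma > 0)
  structure(list(dynamic_range = dynamic_range, k1 = k1, k2 = k2,
                 window = window, window_size = as.integer(window_size),
                 sigma = sigma),
            class = "ssim_config")
}

# valid-mode separable filtering matrix ((H - w + 1) x H)
ssim_band <- function(H, k) {
  w <- length(k)
  n <- H - w + 1L
  A <- matrix(0, n, H)
  for (i in seq_len(n)) A[i, i:(i + w - 1L)] <- k
  A
}

#' Structural similarity index
#'
#' In windowed mode (the default) the SSIM map is computed from local
#' Gaussian-weighted means, variances and covariance over an 11 x 11 window
#' and averaged; in global mode the whole image contributes a single set of
#' (population) statistics.  Both modes agree when the window covers the
#' entire image with uniform weights.
#'
#' @param y,yhat Images of identical shape (matrices).
#' @param cfg An [ssim_config()].
#' @return SSIM value in `[-1, 1]`.
#' @export
ssim <- function(y, yhat, cfg = ssim_config()) {
  stopifnot(all(dim(y) == dim(yhat)))
  L <- cfg$dynamic_range
  C1 <- (cfg$k1 * L)^2
  C2 <- (cfg$k2 * L)^2
  if (cfg$window == "global") {
    mu1 <- mean(y); mu2 <- mean(yhat)
    v1 <- mean((y - mu1)^2); v2 <- mean((yhat - mu2)^2)
    cov <- mean((y - mu1) * (yhat - mu2))
    return(((2 * mu1 * mu2 + C1) * (2 * cov + C2)) /
             ((mu1^2 + mu2^2 + C1) * (v1 + v2 + C2)))
  }
  w <- cfg$window_size
  if (nrow(y) < w || ncol(y) < w)
    stop("image (", nrow(y), " x ", ncol(y),
         ") is smaller than the ", w, " x ", w, " SSIM window")
  half <- (w - 1L) %/% 2L
  k <- dnorm(seq(-half, half), sd = cfg$sigma)
  k <- k / sum(k)
  Ah <- ssim_band(nrow(y), k); Aw <- ssim_band(ncol(y), k)
  f <- function(img) Ah %*% img %*% t(Aw)
  mu1 <- f(y); mu2 <- f(yhat)
  s11 <- f(y * y) - mu1^2
  s22 <- f(yhat * yhat) - mu2^2
  s12 <- f(y * yhat) - mu1 * mu2
  map <- ((2 * mu1 * mu2 + C1) * (2 * s12 + C2)) /
    ((mu1^2 + mu2^2 + C1) * (s11 + s22 + C2))
  mean(map)
}

#' Per-class confusion counts of a mask pair
#'
#' @param pred,ref Integer masks of identical shape with labels in `0:(K-1)`.
#' @param K Number of classes.
#' @return An object of class `confusion_counts` with integer vectors `TP`,
#'   `FP`, `FN` (one entry per class).
#' @export
confusion <- function(pred, ref, K = 3L) {
  stopifnot(length(pred) == length(ref))
  if (any(pred < 0L | pred >= K) || any(ref < 0L | ref >= K))
    stop("labels out of range [0, ", K, ")")
  tab <- table(factor(as.vector(pred), levels = 0:(K - 1L)),
               factor(as.vector(ref), levels = 0:(K - 1L)))
  TP <- diag(tab)
  FP <- rowSums(tab) - TP
  FN <- colSums(tab) - TP
  structure(list(TP = as.integer(TP), FP = as.integer(FP),
                 FN = as.integer(FN), K = as.integer(K)),
            class = "confusion_counts")
}

#' Mean Dice similarity coefficient
#'
#' Class-wise `2 TP / (2 TP + FP + FN)` averaged over the K classes; a class
#' absent from both masks contributes 1 (perfect-agreement convention).
#'
#' @param counts A [confusion()] object.
#' @return Value in `[0, 1]`.
#' @export
mdice <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  den <- 2 * counts$TP + counts$FP + counts$FN
  mean(ifelse(den == 0, 1, 2 * counts$TP / den))
}

#' Mean intersection over union
#'
#' Class-wise `TP / (TP + FP + FN)` averaged over the K classes, with the
#' same absent-class convention as [mdice()].
#'
#' @param counts A [confusion()] object.
#' @return Value in `[0, 1]`.
#' @export
miou <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  den <- counts$TP + counts$FP + counts$FN
  mean(ifelse(den == 0, 1, counts$TP / den))
}

#' Evaluate a collection of model outputs
#'
#' Computes the per-image quality metrics (PSNR/SSIM of the denoised output
#' against the frame-averaged target) and segmentation metrics (mDice/mIoU of
#' the predicted mask against the reference label) and aggregates each as
#' mean +/- sample standard deviation over images (std 0 for a single image).
#'
#' @param pairs List of data pairs (each with `target` and `label`, see
#'   [make_dataset()]).
#' @param outputs List of model outputs aligned with `pairs`, each a list
#'   with `denoised` and/or `mask`.
#' @param ssim_cfg An [ssim_config()].
#' @param K Number of segmentation classes.
#' @return A data frame of class `metric_report` with columns `metric`,
#'   `mean`, `sd`, `n`.
#' @export
evaluate_dataset <- function(pairs, outputs, ssim_cfg = ssim_config(),
                             K = 3L) {
  if (length(pairs) == 0L) stop("empty collection")
  stopifnot(length(pairs) == length(outputs))
  per <- list(PSNR = c(), SSIM = c(), mDice = c(), mIoU = c())
  for (i in seq_along(pairs)) {
    p <- pairs[[i]]; o <- outputs[[i]]
    if (!is.null(o$denoised)) {
      per$PSNR <- c(per$PSNR, psnr(p$target, o$denoised))
      per$SSIM <- c(per$SSIM, ssim(p$target, o$denoised, ssim_cfg))
    }
    if (!is.null(o$mask)) {
      cm <- confusion(o$mask, p$label, K)
      per$mDice <- c(per$mDice, mdice(cm))
      per$mIoU <- c(per$mIoU, miou(cm))
    }
  }
  per <- per[vapply(per, length, integer(1L)) > 0L]
  rep_df <- data.frame(
    metric = names(per),
    mean = vapply(per, mean, numeric(1L)),
    sd = vapply(per, function(v) if (length(v) > 1L) sd(v) else 0,
                numeric(1L)),
    n = vapply(per, length, integer(1L)),
    row.names = NULL)
  class(rep_df) <- c("metric_report", "data.frame")
  attr(rep_df, "per_image") <- per
  rep_df
}

#' @export
print.metric_report <- function(x, ...) {
  cat("Per-image metrics (mean +/- sd over n images)\n")
  for (i in seq_len(nrow(x)))
    cat(sprintf("  %-6s %8.4f +/- %.4f  (n = %d)\n",
                x$metric[i], x$mean[i], x$sd[i], x$n[i]))
  invisible(x)
}

#' Write a metric report to CSV and JSON
#'
#' @param report A [evaluate_dataset()] result.
#' @param path Output path without extension; `.csv` and `.json` are added.
#' @return The two paths, invisibly.
#' @export
write_metric_report <- function(report, path) {
  csv <- paste0(path, ".csv"); js <- paste0(path, ".json")
  utils::write.csv(as.data.frame(unclass(report))[, c("metric", "mean",
                                                      "sd", "n")],
                   csv, row.names = FALSE)
  jsonlite::write_json(
    lapply(seq_len(nrow(report)), function(i)
      list(metric = report$metric[i], mean = report$mean[i],
           sd = report$sd[i], n = report$n[i])),
    js, auto_unbox = TRUE, digits = NA)
  invisible(c(csv, js))
}
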