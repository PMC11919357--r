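# Epithelium-thickness quantification from segmentation masks.  The pixel
# count between the segmented epithelium boundaries is converted to
# micrometres with the system's axial coefficient corrected by the tissue
# refractive index.

#' Thickness measurement configuration
#'
#' @param axial_coeff_air Axial conversion coefficient in air, um/pixel
#'   (default 8.74, the swept-source system value).
#' @param refractive_index Average refractive index of oral tissue
#'   (default 1.395).
#' @param min_run Minimum epithelium run length in pixels for an A-line to
#'   be accepted (shorter runs are marked missing).
#' @return An object of class `thickness_config`.
#' @export
thickness_config <- function(axial_coeff_air = 8.74,
                             refractive_index = 1.395,
                             min_run = 1L) {
  stopifnot(axial_coeff_air > 0, refractive_index >= 1, min_run >= 1L)
  structure(list(axial_coeff_air = axial_coeff_air,
                 refractive_index = refractive_index,
                 min_run = as.integer(min_run)),
            class = "thickness_config")
}

#' Axial conversion coefficient in tissue
#'
#' Divides the in-air axial pixel pitch by the tissue refractive index:
#' 8.74 / 1.395 gives approximately 6.27 um/pixel in oral tissue.
#'
#' @param cfg A [thickness_config()].
#' @return um per pixel inside tissue.
#' @export
tissue_coefficient <- function(cfg = thickness_config()) {
  stopifnot(inherits(cfg, "thickness_config"))
  cfg$axial_coeff_air / cfg$refractive_index
}

#' Measure the epithelium thickness of one mask frame
#'
#' For every A-line the number of epithelium pixels is taken as the length of
#' the longest contiguous run of label 1 -- robust to isolated flipped pixels
#' in pseudo or predicted masks -- and converted to micrometres with
#' [tissue_coefficient()].  A-lines with fewer than `min_run` epithelium
#' pixels are marked missing and excluded from the frame statistics; a frame
#' with no accepted A-line has mean `NA`.
#'
#' @param mask `depth x width` integer matrix with values 0/1/2.
#' @param cfg A [thickness_config()].
#' @return An object of class `thickness_profile`: list with `n_pixels`,
#'   `thickness_um` (per A-line, `NA` where missing), `mean`, `sd`,
#'   `n_alines` and `coefficient`.
#' @export
measure_thickness <- function(mask, cfg = thickness_config()) {
  stopifnot(is.matrix(mask), all(mask %in% 0:2),
            inherits(cfg, "thickness_config"))
  coeff <- tissue_coefficient(cfg)
  npix <- apply(mask == 1L, 2L, function(col) {
    r <- rle(col)
    runs <- r$lengths[r$values]
    if (length(runs)) max(runs) else 0L
  })
  ok <- npix >= cfg$min_run
  th <- ifelse(ok, npix * coeff, NA_real_)
  structure(list(n_pixels = ifelse(ok, npix, NA_integer_),
                 thickness_um = th,
                 mean = if (any(ok)) mean(th[ok]) else NA_real_,
                 sd = if (sum(ok) > 1L) sd(th[ok]) else 0,
                 n_alines = sum(ok),
                 coefficient = coeff),
            class = "thickness_profile")
}

#' @export
print.thickness_profile <- function(x, ...) {
  if (is.na(x$mean))
    cat("Thickness profile: frame missing (no accepted A-line)\n")
  else
    cat(sprintf("Thickness profile: %.2f +/- %.2f um over %d A-lines (%.3f um/px)\n",
                x$mean, x$sd, x$n_alines, x$coefficient))
  invisible(x)
}

#' Mean absolute error between thickness measurements
#'
#' Compares frame-mean thicknesses of predicted and reference masks:
#' per frame `|mean(predicted) - mean(reference)|` in micrometres, aggregated
#' as mean +/- sample standard deviation over frames.  Frames missing on
#' either side are excluded.
#'
#' @param predicted,reference Lists of [measure_thickness()] profiles for
#'   aligned frames (single profiles are accepted).
#' @return An object of class `thickness_mae`: list with `per_frame`, `mean`,
#'   `sd`, `n`.
#' @export
thickness_mae <- function(predicted, reference) {
  if (inherits(predicted, "thickness_profile")) predicted <- list(predicted)
  if (inherits(reference, "thickness_profile")) reference <- list(reference)
  stopifnot(length(predicted) == length(reference))
  pm <- vapply(predicted, function(p) p$mean, numeric(1L))
  rm_ <- vapply(reference, function(p) p$mean, numeric(1L))
  ok <- is.finite(pm) & is.finite(rm_)
  if (!any(ok)) stop("no overlapping frames with accepted A-lines")
  err <- abs(pm[ok] - rm_[ok])
  structure(list(per_frame = err, mean = mean(err),
                 sd = if (length(err) > 1L) sd(err) else 0,
                 n = length(err)),
            class = "thickness_mae")
}

#' @export
print.thickness_mae <- function(x, ...) {
  cat(sprintf("Thickness MAE: %.2f +/- %.2f um over %d frame(s)\n",
              x$mean, x$sd, x$n))
  invisible(x)
}

#' Write thickness measurements to CSV
#'
#' @param profiles List of [measure_thickness()] profiles.
#' @param path CSV output path.
#' @param volume,region Optional identifier columns.
#' @param mae Optional [thickness_mae()] against a reference.
#' @return The path, invisibly.
#' @export
write_thickness_csv <- function(profiles, path, volume = "volume1",
                                region = "lip", mae = NULL) {
  df <- data.frame(
    volume = volume, frame = seq_along(profiles), region = region,
    mean_thickness_um = vapply(profiles, function(p) p$mean, numeric(1L)),
    sd = vapply(profiles, function(p) p$sd, numeric(1L)),
    n_alines = vapply(profiles, function(p) p$n_alines, numeric(1L)))
  if (!is.null(mae)) df$mae_vs_reference <- c(mae$per_frame,
                                              rep(NA, nrow(df) -
                                                    length(mae$per_frame)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
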