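# Synthetic layered-speckle phantoms: two-layer oral-mucosa geometry (air /
# epithelium / stroma) with smooth boundaries, per-class reflectivity and
# exponential depth attenuation, imaged with N independent unit-mean
# multiplicative speckle realizations per B-frame.

#' Phantom configuration
#'
#' Describes a synthetic oral-OCT acquisition: image geometry, layer
#' boundaries (smooth seeded curves), optical properties per tissue class and
#' the speckle model.  Intensities are normalized to `[0, 1]`.
#'
#' @param width Transverse size in pixels (A-lines per B-frame).
#' @param depth Axial size in pixels.
#' @param n_frames Number of B-frames in the volume.
#' @param n_repetitions Repeated acquisitions per B-frame location (NR).
#' @param surface_depth_mean Mean depth of the air/epithelium surface, pixels.
#' @param epithelium_thickness_mean Mean epithelium thickness, pixels.
#' @param boundary_amplitude Standard deviation of the boundary undulation,
#'   pixels; 0 gives perfectly flat layers.
#' @param boundary_smoothness Transverse correlation length of the boundary
#'   curves, pixels.
#' @param layer_reflectivity Mean backscatter per class (background,
#'   epithelium, stroma), each in (0, 1].
#' @param attenuation Exponential intensity decay per pixel of depth for each
#'   class, all >= 0.
#' @param speckle_shape Gamma shape parameter of the unit-mean multiplicative
#'   speckle field; variance is `1 / speckle_shape`, and `Inf` disables the
#'   noise entirely.
#' @param noise_floor Additive background level in `[0, 1)`.
#' @param lens_tag Which sample lens the phantom emulates, `"intraoral"` or
#'   `"LSM03"` (controls the default cropping protocol downstream).
#' @param axial_coeff_air Axial conversion coefficient in air, um/pixel.
#' @param seed Integer seed; identical seeds give bit-identical phantoms.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(width = 256L, depth = 256L, n_frames = 4L,
                           n_repetitions = 4L,
                           surface_depth_mean = 40,
                           epithelium_thickness_mean = 60,
                           boundary_amplitude = 6,
                           boundary_smoothness = 25,
                           layer_reflectivity = c(background = 0.04,
                                                  epithelium = 0.32,
                                                  stroma = 0.55),
                           attenuation = c(background = 0,
                                           epithelium = 0.002,
                                           stroma = 0.004),
                           speckle_shape = 4,
                           noise_floor = 0.03,
                           lens_tag = c("intraoral", "LSM03"),
                           axial_coeff_air = 8.74,
                           seed = 1L) {
  lens_tag <- match.arg(lens_tag)
  stopifnot(width >= 4L, depth >= 4L, n_frames >= 1L, n_repetitions >= 1L,
            surface_depth_mean + epithelium_thickness_mean < depth,
            boundary_amplitude >= 0, boundary_smoothness > 0,
            length(layer_reflectivity) == 3L,
            all(layer_reflectivity > 0), all(layer_reflectivity <= 1),
            length(attenuation) == 3L, all(attenuation >= 0),
            speckle_shape > 0, noise_floor >= 0, noise_floor < 1,
            axial_coeff_air > 0)
  structure(list(width = as.integer(width), depth = as.integer(depth),
                 n_frames = as.integer(n_frames),
                 n_repetitions = as.integer(n_repetitions),
                 surface_depth_mean = surface_depth_mean,
                 epithelium_thickness_mean = epithelium_thickness_mean,
                 boundary_amplitude = boundary_amplitude,
                 boundary_smoothness = boundary_smoothness,
                 layer_reflectivity = layer_reflectivity,
                 attenuation = attenuation,
                 speckle_shape = speckle_shape,
                 noise_floor = noise_floor,
                 lens_tag = lens_tag,
                 axial_coeff_air = axial_coeff_air,
                 seed = as.integer(seed)),
            class = "phantom_config")
}

#' Repetition-resolved OCT volume
#'
#' @param data Array of dim `(n_frames, n_repetitions, depth, width)` with
#'   finite values in `[0, 1]`.
#' @param lens_tag `"intraoral"` or `"LSM03"`.
#' @param axial_coeff_air Axial conversion coefficient in air, um/pixel.
#' @return An object of class `oct_volume`.
#' @export
oct_volume <- function(data, lens_tag = "intraoral", axial_coeff_air = 8.74) {
  stopifnot(length(dim(data)) == 4L, all(is.finite(data)),
            min(data) >= 0, max(data) <= 1, axial_coeff_air > 0)
  lens_tag <- match.arg(lens_tag, c("intraoral", "LSM03"))
  structure(list(data = data, lens_tag = lens_tag,
                 axial_coeff_air = axial_coeff_air),
            class = "oct_volume")
}

#' @export
print.oct_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(paste0("OCT volume: %d frame(s) x %d repetition(s), ",
                     "%d (z) x %d (x) pixels; %s lens, %.2f um/px in air\n"),
              d[1L], d[2L], d[3L], d[4L], x$lens_tag, x$axial_coeff_air))
  invisible(x)
}

#' Per-pixel layer labels aligned to an OCT volume
#'
#' Labels are 0 (background, above the tissue surface), 1 (epithelium) and
#' 2 (stroma); along every A-line the three runs are contiguous and ordered
#' top to bottom.  `boundary_curves` stores, per frame, the depth (in pixels)
#' of the last background pixel (`surface`) and the last epithelium pixel
#' (`interface`) of each A-line.
#'
#' @param labels Integer array of dim `(n_frames, depth, width)`.
#' @param boundary_curves List (one element per frame) of
#'   `list(surface, interface)` integer vectors of length `width`; may be
#'   `NULL` when unknown.
#' @return An object of class `layer_mask_volume`.
#' @export
layer_mask_volume <- function(labels, boundary_curves = NULL) {
  stopifnot(length(dim(labels)) == 3L, all(labels %in% 0:2))
  Z <- dim(labels)[2L]
  if (Z > 1L) {
    mono <- labels[, -1L, , drop = FALSE] - labels[, -Z, , drop = FALSE]
    if (min(mono) < 0)
      stop("labels must be ordered background/epithelium/stroma along every A-line")
  }
  if (!is.null(boundary_curves))
    stopifnot(length(boundary_curves) == dim(labels)[1L])
  structure(list(labels = labels, boundary_curves = boundary_curves),
            class = "layer_mask_volume")
}

#' @export
print.layer_mask_volume <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("Layer mask volume: %d frame(s), %d (z) x %d (x) pixels\n",
              d[1L], d[2L], d[3L]))
  frac <- tabulate(x$labels + 1L, 3L) / length(x$labels)
  cat(sprintf("  background %.1f%% | epithelium %.1f%% | stroma %.1f%%\n",
              100 * frac[1L], 100 * frac[2L], 100 * frac[3L]))
  invisible(x)
}

# unit-variance smooth noise field (n x m), correlation length `len` along
# rows and `flen` along columns
smooth_noise_field <- function(n, m, len, flen = max(1, m / 4)) {
  gsmooth <- function(M, s, along) {
    half <- max(1L, ceiling(3 * s))
    k <- dnorm(seq(-half, half), sd = s)
    if (along == 2L) M <- t(M)
    padded <- rbind(M[rep(1L, half), , drop = FALSE], M,
                    M[rep(nrow(M), half), , drop = FALSE])
    out <- matrix(0, nrow(M), ncol(M))
    for (j in seq_along(k))
      out <- out + k[j] * padded[j:(j + nrow(M) - 1L), , drop = FALSE]
    if (along == 2L) t(out) else out
  }
  z <- matrix(rnorm(n * m), n, m)
  z <- gsmooth(z, len, 1L)
  if (m > 1L) z <- gsmooth(z, flen, 2L)
  s <- sd(as.vector(z))
  if (s > 0) z / s else z
}

#' Generate a synthetic layered-speckle phantom
#'
#' Draws smooth surface and epithelium/stroma boundary curves (low-pass
#' filtered seeded noise, slowly varying across frames), computes the
#' noise-free image as per-class reflectivity attenuated exponentially with
#' cumulative depth plus the noise floor, and multiplies each repetition by
#' an independent unit-mean gamma speckle field, clipping to `[0, 1]`.
#' The label masks are derived from the same boundary curves, so mask
#' transitions coincide with the reflectivity transitions exactly.
#'
#' @param config A [phantom_config()].
#' @return A list with `volume` (an [oct_volume()]), `masks` (a
#'   [layer_mask_volume()]) and `noise_free` (array `(n_frames, depth,
#'   width)`).
#' @export
generate_phantom <- function(config = phantom_config()) {
  stopifnot(inherits(config, "phantom_config"))
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(config$seed)
  X <- config$width; Z <- config$depth
  Fn <- config$n_frames; NR <- config$n_repetitions
  amp <- config$boundary_amplitude
  surf_field <- smooth_noise_field(X, Fn, config$boundary_smoothness)
  thick_field <- smooth_noise_field(X, Fn, config$boundary_smoothness)
  surface <- round(config$surface_depth_mean + amp * surf_field)
  n_epi <- round(config$epithelium_thickness_mean + amp * thick_field)
  interface <- surface + n_epi
  if (min(surface) < 1L || max(interface) > Z - 1L || min(n_epi) < 1L)
    stop("layer boundaries leave the image; reduce boundary_amplitude or ",
         "the mean depths")
  refl <- as.numeric(config$layer_reflectivity)
  attn <- as.numeric(config$attenuation)
  labels <- array(0L, c(Fn, Z, X))
  noise_free <- array(0, c(Fn, Z, X))
  z <- seq_len(Z)
  for (f in seq_len(Fn)) {
    lab <- outer(z, surface[, f], ">") + outer(z, interface[, f], ">")
    att <- matrix(attn[lab + 1L], Z, X)
    img <- matrix(refl[lab + 1L], Z, X) * exp(-apply(att, 2L, cumsum)) +
      config$noise_floor
    labels[f, , ] <- lab
    noise_free[f, , ] <- img
  }
  data <- array(0, c(Fn, NR, Z, X))
  for (f in seq_len(Fn)) for (r in seq_len(NR)) {
    speckle <- if (is.finite(config$speckle_shape))
      matrix(rgamma(Z * X, shape = config$speckle_shape,
                    rate = config$speckle_shape), Z, X)
    else 1
    data[f, r, , ] <- pmin(pmax(noise_free[f, , ] * speckle, 0), 1)
  }
  curves <- lapply(seq_len(Fn), function(f)
    list(surface = as.integer(surface[, f]),
         interface = as.integer(interface[, f])))
  list(volume = oct_volume(data, config$lens_tag, config$axial_coeff_air),
       masks = layer_mask_volume(labels, curves),
       noise_free = noise_free)
}

#' True per-A-line epithelium thickness of a mask volume
#'
#' Counts the epithelium-labelled pixels of every A-line.  Because phantom
#' masks are contiguous by construction this equals the run length between
#' the two boundaries.  A-lines without any epithelium are reported as `NA`
#' (missing) so they drop out of any mean.
#'
#' @param masks A [layer_mask_volume()].
#' @return An `n_frames x width` matrix of thicknesses in pixels, `NA` where
#'   an A-line holds no epithelium.
#' @export
true_thickness_profile <- function(masks) {
  stopifnot(inherits(masks, "layer_mask_volume"))
  d <- dim(masks$labels)
  out <- matrix(NA_real_, d[1L], d[3L])
  for (f in seq_len(d[1L])) {
    cnt <- colSums(masks$labels[f, , , drop = TRUE] == 1L)
    out[f, ] <- ifelse(cnt > 0L, cnt, NA_real_)
  }
  out
}
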