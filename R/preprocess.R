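# Training-pair construction: frame averaging, patch cropping, pseudo-label
# generation through a teacher interface, soft-label encoding and the
# volume-level train/validation/test split.

#' Frame averaging
#'
#' Collapses the repetition axis of a volume by the arithmetic per-frame mean
#' over its NR repeated acquisitions, the standard speckle-reduction
#' ground-truth used to supervise denoising.  With a single repetition the
#' output equals the input.
#'
#' @param volume An [oct_volume()].
#' @return An array of dim `(n_frames, depth, width)` with values in `[0, 1]`.
#' @export
frame_average <- function(volume) {
  stopifnot(inherits(volume, "oct_volume"))
  d <- dim(volume$data)
  out <- colMeans(aperm(volume$data, c(2L, 1L, 3L, 4L)))
  array(out, d[-2L])
}

#' Patch cropping specification
#'
#' Fixed-size crop boxes: one axial window anchored at `axial_start` and one
#' transverse window per entry of `transverse_starts`.  Coordinates are
#' 0-based and windows are half-open, so the printed range `[0, 256]` of the
#' acquisition protocol denotes columns 0..255 and has width exactly 256.
#'
#' @param patch_height Axial (z) patch size in pixels.
#' @param patch_width Transverse (x) patch size in pixels.
#' @param transverse_starts Integer vector of 0-based window start offsets.
#' @param axial_start 0-based axial start offset.
#' @return An object of class `crop_spec`.
#' @export
crop_spec <- function(patch_height = 256L, patch_width = 256L,
                      transverse_starts = 0L, axial_start = 0L) {
  stopifnot(patch_height >= 1L, patch_width >= 1L,
            length(transverse_starts) >= 1L, all(transverse_starts >= 0L),
            axial_start >= 0L)
  structure(list(patch_height = as.integer(patch_height),
                 patch_width = as.integer(patch_width),
                 transverse_starts = as.integer(sort(transverse_starts)),
                 axial_start = as.integer(axial_start)),
            class = "crop_spec")
}

#' Default cropping protocol per sample lens
#'
#' The acquisition protocol crops 256 x 256 boxes whose transverse ranges
#' depend on the lens: `[0, 256)` and `[144, 400)` for the 400-pixel-wide
#' intraoral frames; `[0, 256)`, `[256, 512)` and `[344, 600)` for the
#' 600-pixel-wide LSM03 frames.
#'
#' @param lens `"intraoral"` or `"LSM03"`.
#' @param patch_height,patch_width Patch size (default 256 x 256).
#' @param axial_start 0-based axial offset (default 0, the image top).
#' @return A [crop_spec()].
#' @export
default_crop_spec <- function(lens = c("intraoral", "LSM03"),
                              patch_height = 256L, patch_width = 256L,
                              axial_start = 0L) {
  lens <- match.arg(lens)
  starts <- if (lens == "intraoral") c(0L, 144L) else c(0L, 256L, 344L)
  crop_spec(patch_height, patch_width, starts, axial_start)
}

#' Extract patches from a B-frame
#'
#' @param frame A `depth x width` matrix.
#' @param spec A [crop_spec()]; every transverse window and the axial window
#'   must fit inside the frame.
#' @return A list of `patch_height x patch_width` matrices; each carries the
#'   attribute `window` (`c(start, axial_start)`, 0-based).
#' @export
extract_patches <- function(frame, spec) {
  stopifnot(is.matrix(frame), inherits(spec, "crop_spec"))
  Z <- nrow(frame); X <- ncol(frame)
  if (spec$axial_start + spec$patch_height > Z)
    stop("axial window [", spec$axial_start, ", ",
         spec$axial_start + spec$patch_height, ") exceeds the frame depth ", Z)
  lapply(spec$transverse_starts, function(s) {
    if (s + spec$patch_width > X)
      stop("transverse window [", s, ", ", s + spec$patch_width,
           ") exceeds the frame width ", X)
    p <- frame[spec$axial_start + seq_len(spec$patch_height),
               s + seq_len(spec$patch_width), drop = FALSE]
    attr(p, "window") <- c(start = s, axial_start = spec$axial_start)
    p
  })
}

#' Stitch patches back onto a frame canvas
#'
#' Places each patch at its recorded window and averages wherever windows
#' overlap.  Pixels covered by no window are `NA`.
#'
#' @param patches List of matrices carrying a `window` attribute (as returned
#'   by [extract_patches()] or produced by the model on such patches).
#' @param depth,width Size of the output canvas.
#' @return A `depth x width` matrix.
#' @export
stitch_patches <- function(patches, depth, width) {
  acc <- matrix(0, depth, width)
  cnt <- matrix(0, depth, width)
  for (p in patches) {
    w <- attr(p, "window")
    if (is.null(w)) stop("every patch needs a 'window' attribute")
    rows <- w[["axial_start"]] + seq_len(nrow(p))
    cols <- w[["start"]] + seq_len(ncol(p))
    acc[rows, cols] <- acc[rows, cols] + p
    cnt[rows, cols] <- cnt[rows, cols] + 1
  }
  out <- acc / cnt
  out[cnt == 0] <- NA_real_
  out
}

#' Teacher interface for pseudo-label generation
#'
#' Pseudo labels stand in for manual annotation on all but the first frame of
#' each training volume.  Two modes are supported: `"external-model"`
#' delegates to a user-supplied segmentation callable (for example a
#' pre-trained network) and validates its output; `"corrupting-oracle"`
#' derives labels from the true mask but degrades them deliberately --
#' boundaries displaced by smooth seeded noise of scale `jitter` and pixels
#' resampled uniformly over the classes with probability `flip_rate` -- so
#' the pipeline can be exercised with a controllable label-noise level.
#'
#' @param mode `"corrupting-oracle"` or `"external-model"`.
#' @param jitter Boundary displacement scale in pixels (corrupting mode).
#' @param flip_rate Per-pixel probability of resampling the label uniformly
#'   over the classes (corrupting mode).
#' @param smoothness Transverse correlation length of the displacement.
#' @param seed Integer seed for the corruption draws.
#' @param model Callable `function(frame)` returning an integer mask
#'   (external mode).
#' @return An object of class `teacher_oracle`.
#' @export
teacher_oracle <- function(mode = c("corrupting-oracle", "external-model"),
                           jitter = 2, flip_rate = 0.02, smoothness = 20,
                           seed = 1L, model = NULL) {
  mode <- match.arg(mode)
  stopifnot(jitter >= 0, flip_rate >= 0, flip_rate <= 1, smoothness > 0)
  if (mode == "external-model" && !is.function(model))
    stop("external-model mode needs a callable `model`")
  structure(list(mode = mode, jitter = jitter, flip_rate = flip_rate,
                 smoothness = smoothness, seed = as.integer(seed),
                 model = model),
            class = "teacher_oracle")
}

#' Generate a pseudo label for one frame
#'
#' @param teacher A [teacher_oracle()].
#' @param true_mask_frame `depth x width` integer matrix with values 0/1/2
#'   (used by the corrupting oracle).
#' @param averaged_frame Optional `depth x width` intensity matrix handed to
#'   an external model.
#' @param frame_index Frame number, mixed into the corruption seed so
#'   different frames receive independent corruptions.
#' @param K Number of classes (default 3).
#' @return A `depth x width` integer mask with values in `0:(K-1)`.
#' @export
pseudo_label <- function(teacher, true_mask_frame, averaged_frame = NULL,
                         frame_index = 1L, K = 3L) {
  stopifnot(inherits(teacher, "teacher_oracle"))
  if (teacher$mode == "external-model") {
    lab <- teacher$model(averaged_frame)
    if (!all(dim(lab) == dim(averaged_frame)) ||
        !all(lab %in% 0:(K - 1L)))
      stop("external teacher returned labels outside {0..", K - 1L,
           "} or of the wrong shape")
    return(matrix(as.integer(lab), nrow(lab), ncol(lab)))
  }
  stopifnot(is.matrix(true_mask_frame), all(true_mask_frame %in% 0:2))
  Z <- nrow(true_mask_frame); X <- ncol(true_mask_frame)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(teacher$seed + 7919L * as.integer(frame_index))
  surface <- colSums(true_mask_frame == 0L)
  interface <- surface + colSums(true_mask_frame == 1L)
  if (teacher$jitter > 0) {
    surface <- surface +
      round(teacher$jitter * smooth_noise_field(X, 1L, teacher$smoothness))
    interface <- interface +
      round(teacher$jitter * smooth_noise_field(X, 1L, teacher$smoothness))
    surface <- pmin(pmax(surface, 0L), Z)
    interface <- pmin(pmax(interface, surface), Z)
  }
  z <- seq_len(Z)
  lab <- outer(z, as.vector(surface), ">") + outer(z, as.vector(interface), ">")
  if (teacher$flip_rate > 0) {
    hit <- runif(Z * X) < teacher$flip_rate
    lab[hit] <- sample(0:(K - 1L), sum(hit), replace = TRUE)
  }
  matrix(as.integer(lab), Z, X)
}

#' Soft-label encoding
#'
#' Expands an integer mask into a per-pixel class distribution: the annotated
#' class receives `confidence`, every other class `(1 - confidence)/(K - 1)`.
#' Spreading 5% of the mass over the other classes makes the cross-entropy
#' tolerant of pseudo-label errors.
#'
#' @param mask `H x W` integer matrix with values in `0:(K-1)`.
#' @param confidence Probability assigned to the annotated class, in (0, 1].
#' @param K Number of classes (>= 2).
#' @return An `H x W x K` array whose class vectors sum to 1.
#' @export
encode_soft_labels <- function(mask, confidence = 0.95, K = 3L) {
  stopifnot(is.matrix(mask), confidence > 0, confidence <= 1, K >= 2L)
  if (any(mask < 0L) || any(mask >= K))
    stop("mask labels must lie in [0, ", K, ")")
  H <- nrow(mask); W <- ncol(mask)
  soft <- array((1 - confidence) / (K - 1L), c(H, W, K))
  idx <- cbind(rep(seq_len(H), W), rep(seq_len(W), each = H),
               as.vector(mask) + 1L)
  soft[idx] <- confidence
  soft
}

#' Assemble training/validation/test data pairs
#'
#' Enumerates every (frame, window) crop of every volume into a data pair of
#' noisy input (repetition 1), frame-averaged target, label mask and its
#' soft-label encoding.  The first frame of each volume uses the manual
#' (uncorrupted) mask; all other frames use the pseudo labels.  The split is
#' drawn by volume -- never by patch -- so no volume contributes to more than
#' one role.
#'
#' @param volumes List of entries, each a list with `noisy` (an
#'   [oct_volume()]), `averaged` (array `(F, Z, X)`, see [frame_average()]),
#'   `pseudo_masks` (integer array `(F, Z, X)`), `manual_mask` (matrix
#'   `(Z, X)` for frame 1; when `NULL` the pseudo mask of frame 1 is used)
#'   and optionally `id`.
#' @param spec A [crop_spec()].
#' @param split Named or positional fractions `c(train, val, test)`; their
#'   sum must not exceed 1.
#' @param seed Integer seed for the volume assignment.
#' @param confidence Soft-label confidence (default 0.95).
#' @return A list with elements `train`, `val`, `test`, each a list of data
#'   pairs `list(noisy, target, label, soft_label, provenance)`.
#' @export
make_dataset <- function(volumes, spec, split = c(0.8, 0.2, 0), seed = 1L,
                         confidence = 0.95) {
  stopifnot(length(volumes) >= 1L, inherits(spec, "crop_spec"),
            length(split) == 3L, all(split >= 0))
  if (sum(split) > 1 + 1e-9)
    stop("split fractions sum to ", sum(split), " > 1")
  V <- length(volumes)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(as.integer(seed))
  perm <- sample.int(V)
  n_tr <- round(split[1L] * V)
  n_va <- min(round(split[2L] * V), V - n_tr)
  n_te <- min(round(split[3L] * V), V - n_tr - n_va)
  roles <- rep(NA_character_, V)
  roles[perm[seq_len(n_tr)]] <- "train"
  if (n_va > 0) roles[perm[n_tr + seq_len(n_va)]] <- "val"
  if (n_te > 0) roles[perm[n_tr + n_va + seq_len(n_te)]] <- "test"
  out <- list(train = list(), val = list(), test = list())
  for (v in seq_len(V)) {
    if (is.na(roles[v])) next
    entry <- volumes[[v]]
    id <- entry$id
    if (is.null(id)) id <- paste0("volume", v)
    Fn <- dim(entry$noisy$data)[1L]
    for (f in seq_len(Fn)) {
      noisy_f <- entry$noisy$data[f, 1L, , , drop = TRUE]
      target_f <- entry$averaged[f, , , drop = TRUE]
      label_f <- if (f == 1L && !is.null(entry$manual_mask))
        entry$manual_mask
      else entry$pseudo_masks[f, , , drop = TRUE]
      np <- extract_patches(noisy_f, spec)
      tp <- extract_patches(target_f, spec)
      lp <- extract_patches(matrix(as.integer(label_f), nrow(noisy_f)), spec)
      for (w in seq_along(np)) {
        pair <- list(noisy = np[[w]], target = tp[[w]],
                     label = lp[[w]],
                     soft_label = encode_soft_labels(lp[[w]], confidence),
                     provenance = list(volume = id, frame = f,
                                       window = attr(np[[w]], "window")))
        out[[roles[v]]] <- c(out[[roles[v]]], list(pair))
      }
    }
  }
  structure(out, class = "esdm_dataset",
            split = split, seed = as.integer(seed), roles = roles)
}

#' @export
print.esdm_dataset <- function(x, ...) {
  cat(sprintf("Data pairs: %d train / %d val / %d test\n",
              length(x$train), length(x$val), length(x$test)))
  invisible(x)
}
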