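# On-disk formats: multi-page TIFF for repetition-resolved volumes (with a
# JSON sidecar manifest documenting the page ordering), one 8-bit PNG per
# frame for label masks, YAML/JSON for configurations.

#' Quantize a normalized image to 8 bit
#'
#' Rounds half up: `floor(x * 255 + 0.5)`.
#'
#' @param x Numeric array in `[0, 1]`.
#' @return Integer array in `0:255`.
#' @export
quantize8 <- function(x) {
  out <- as.integer(floor(pmin(pmax(x, 0), 1) * 255 + 0.5))
  if (!is.null(dim(x))) dim(out) <- dim(x)
  out
}

#' Write / read an OCT volume as multi-page TIFF
#'
#' Pages are ordered frame-major -- page `(f - 1) * NR + r` holds frame `f`,
#' repetition `r` -- and stored as 32-bit float in `[0, 1]`.  A JSON sidecar
#' `<name>.json` records the dimensions, the page ordering, the lens tag and
#' the axial coefficient, so the stack is self-describing.
#'
#' @param volume An [oct_volume()].
#' @param dir Output directory (created if needed).
#' @param name Base name of the TIFF/JSON pair.
#' @return `write_oct_volume` returns the TIFF path invisibly;
#'   `read_oct_volume` the reconstructed [oct_volume()].
#' @export
write_oct_volume <- function(volume, dir, name = "volume") {
  stopifnot(inherits(volume, "oct_volume"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- dim(volume$data)
  pages <- vector("list", d[1L] * d[2L])
  for (f in seq_len(d[1L])) for (r in seq_len(d[2L]))
    pages[[(f - 1L) * d[2L] + r]] <- volume$data[f, r, , , drop = TRUE]
  path <- file.path(dir, paste0(name, ".tiff"))
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  jsonlite::write_json(
    list(n_frames = d[1L], n_repetitions = d[2L], depth = d[3L],
         width = d[4L],
         page_order = "frame-major: page = (frame - 1) * NR + repetition",
         lens_tag = volume$lens_tag,
         axial_coeff_air = volume$axial_coeff_air),
    file.path(dir, paste0(name, ".json")), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_oct_volume
#' @export
read_oct_volume <- function(dir, name = "volume") {
  meta <- jsonlite::read_json(file.path(dir, paste0(name, ".json")),
                              simplifyVector = TRUE)
  pages <- tiff::readTIFF(file.path(dir, paste0(name, ".tiff")), all = TRUE)
  data <- array(0, c(meta$n_frames, meta$n_repetitions, meta$depth,
                     meta$width))
  for (f in seq_len(meta$n_frames)) for (r in seq_len(meta$n_repetitions))
    data[f, r, , ] <- pages[[(f - 1L) * meta$n_repetitions + r]]
  oct_volume(data, meta$lens_tag, meta$axial_coeff_air)
}

#' Write / read a label mask volume as per-frame PNG
#'
#' Each frame is an 8-bit grayscale PNG holding the raw class indices
#' (pixel values 0, 1, 2); boundary curves, when present, go to a JSON
#' sidecar.
#'
#' @param masks A [layer_mask_volume()], or a plain integer array
#'   `(n_frames, depth, width)` for masks (e.g. predictions) that need not
#'   satisfy the layer-ordering invariant.
#' @param dir Output directory.
#' @param name Base name; frames become `<name>_fNNN.png`.
#' @return `write_mask_volume` returns `dir` invisibly; `read_mask_volume`
#'   the reconstructed [layer_mask_volume()].
#' @export
write_mask_volume <- function(masks, dir, name = "mask") {
  if (!inherits(masks, "layer_mask_volume")) {
    stopifnot(length(dim(masks)) == 3L, all(masks %in% 0:255))
    masks <- structure(list(labels = masks, boundary_curves = NULL),
                       class = "layer_mask_volume")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- dim(masks$labels)
  for (f in seq_len(d[1L]))
    png::writePNG(masks$labels[f, , , drop = TRUE] / 255,
                  file.path(dir, sprintf("%s_f%03d.png", name, f)))
  jsonlite::write_json(
    list(n_frames = d[1L], depth = d[2L], width = d[3L],
         boundary_curves = masks$boundary_curves),
    file.path(dir, paste0(name, ".json")), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_mask_volume
#' @export
read_mask_volume <- function(dir, name = "mask") {
  meta <- jsonlite::read_json(file.path(dir, paste0(name, ".json")))
  labels <- array(0L, c(meta$n_frames, meta$depth, meta$width))
  for (f in seq_len(meta$n_frames)) {
    img <- png::readPNG(file.path(dir, sprintf("%s_f%03d.png", name, f)))
    labels[f, , ] <- as.integer(round(img * 255))
  }
  curves <- NULL
  if (!is.null(meta$boundary_curves) && length(meta$boundary_curves))
    curves <- lapply(meta$boundary_curves, function(cv)
      list(surface = as.integer(unlist(cv$surface)),
           interface = as.integer(unlist(cv$interface))))
  layer_mask_volume(labels, curves)
}

#' Write / read a configuration as YAML or JSON
#'
#' The format follows the file extension (`.yaml`/`.yml` or `.json`).
#'
#' @param config Any configuration list (e.g. [phantom_config()],
#'   [esdm_config()]).
#' @param path Output path.
#' @return `write_config` returns `path` invisibly; `read_config` a plain
#'   list.
#' @export
write_config <- function(config, path) {
  x <- unclass(config)
  if (grepl("\\.ya?ml$", path)) yaml::write_yaml(x, path)
  else jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Write data pairs as paired TIFF/PNG trees with a CSV index
#'
#' Each pair's noisy and target patches go to one two-page TIFF, its label
#' patch to a PNG; `index.csv` records volume, frame, window and role.
#'
#' @param dataset A [make_dataset()] result.
#' @param dir Output directory.
#' @return The index path, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  i <- 0L
  for (role in c("train", "val", "test")) for (p in dataset[[role]]) {
    i <- i + 1L
    base <- sprintf("pair%05d", i)
    tiff::writeTIFF(list(p$noisy, p$target),
                    file.path(dir, paste0(base, ".tiff")),
                    bits.per.sample = 32L)
    png::writePNG(p$label / 255, file.path(dir, paste0(base, ".png")))
    rows[[i]] <- data.frame(file = base, volume = p$provenance$volume,
                            frame = p$provenance$frame,
                            window = p$provenance$window[["start"]],
                            role = role)
  }
  idx <- file.path(dir, "index.csv")
  utils::write.csv(do.call(rbind, rows), idx, row.names = FALSE)
  invisible(idx)
}
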