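# Disk layout: one directory per sequence with 8-bit gray PNG frames
# (frame_0000.png, ...) or a single multi-page TIFF, a ground_truth.csv with
# columns frame_index,diameter,imt, and a params.json; a dataset-level
# manifest.json records config and per-sequence seeds.

#' Save a sequence to a directory
#'
#' Writes frames as 8-bit gray PNGs (or one multi-page TIFF), the
#' ground-truth trace as CSV and the generation parameters as JSON.
#' Round trip: [load_sequence()] reproduces the diameters exactly and the
#' frames to 8-bit quantization (error at most 1/510 per pixel).
#'
#' @param seq A `vt_sequence`.
#' @param dir Output directory (created if needed).
#' @param format `"png"` (one file per frame) or `"tiff"` (one stack).
#' @return The directory path, invisibly usable in manifests.
#' @export
save_sequence <- function(seq, dir, format = c("png", "tiff")) {
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  k <- dim(seq$frames)[3]
  q <- round(seq$frames * 255) / 255   # explicit 8-bit quantization
  if (format == "png") {
    for (t in seq_len(k)) {
      png::writePNG(q[, , t],
                    file.path(dir, sprintf("frame_%04d.png", t - 1)))
    }
  } else {
    if (!requireNamespace("tiff", quietly = TRUE))
      abort("the tiff package is needed for format = 'tiff'")
    tiff::writeTIFF(lapply(seq_len(k), function(t) q[, , t]),
                    file.path(dir, "frames.tif"), bits.per.sample = 8)
  }
  # 17 significant digits guarantee an exact double round trip through text
  gt <- tibble(frame_index = seq_len(k) - 1L,
               diameter = sprintf("%.17g", seq$diameters),
               imt = if (is.null(seq$imt)) NA else sprintf("%.17g", seq$imt))
  readr::write_csv(gt, file.path(dir, "ground_truth.csv"))
  jsonlite::write_json(
    list(units = seq$units, pixel_spacing = seq$pixel_spacing,
         seed = seq$seed,
         params = if (is.null(seq$params)) NULL else as.list(seq$params)),
    file.path(dir, "params.json"), auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Load a sequence from a directory
#'
#' Reads PNG frames (or a `frames.tif` stack) and the ground-truth CSV.
#' Frames are converted to gray scale in `[0, 1]`; when `target_size` is
#' given and differs from the stored size, each frame is center-cropped to a
#' square and resized with bilinear interpolation (the preprocessing applied
#' to real scanner frames, e.g. 720x960 -> 720x720 -> 128x128). Diameter
#' annotations are physical measurements and are never rescaled by resizing.
#'
#' @param dir Sequence directory.
#' @param units Unit tag to attach (`"pixel"` or `"mm"`); default from
#'   `params.json` when present.
#' @param target_size Optional `c(height, width)` to crop/resize to.
#' @param crop_offset Vertical/horizontal center-crop offset override
#'   (`c(row, col)`, default centered).
#' @return A `vt_sequence`.
#' @export
load_sequence <- function(dir, units = NULL, target_size = NULL,
                          crop_offset = NULL) {
  meta <- list()
  pj <- file.path(dir, "params.json")
  if (file.exists(pj)) meta <- jsonlite::read_json(pj)
  tifp <- file.path(dir, "frames.tif")
  if (file.exists(tifp)) {
    if (!requireNamespace("tiff", quietly = TRUE))
      abort("the tiff package is needed to read TIFF stacks")
    fl <- tiff::readTIFF(tifp, all = TRUE)
    frames <- lapply(fl, as_gray)
  } else {
    files <- sort(list.files(dir, pattern = "^frame_\\d+\\.png$",
                             full.names = TRUE))
    if (length(files) == 0)
      abort(sprintf("no frames found in %s", dir), class = "vt_io_error")
    frames <- lapply(files, function(f) as_gray(png::readPNG(f)))
  }
  if (!is.null(target_size))
    frames <- lapply(frames, preprocess_frame, target_size = target_size,
                     crop_offset = crop_offset)
  # base read.csv parses doubles with correctly rounded strtod, preserving
  # the exact values written by save_sequence()
  gt <- utils::read.csv(file.path(dir, "ground_truth.csv"))
  if (nrow(gt) != length(frames))
    abort(sprintf("annotation rows (%d) != frame count (%d) in %s",
                  nrow(gt), length(frames), dir), class = "vt_io_error")
  arr <- array(0, c(dim(frames[[1]]), length(frames)))
  for (t in seq_along(frames)) arr[, , t] <- frames[[t]]
  new_vt_sequence(arr, gt$diameter,
                  imt = if (all(is.na(gt$imt))) NULL else gt$imt,
                  params = if (!is.null(meta$params)) as_tibble(meta$params) else NULL,
                  units = units %||% meta$units %||% "pixel",
                  pixel_spacing = meta$pixel_spacing %||% "pixel-native",
                  seed = meta$seed)
}

as_gray <- function(img) {
  if (length(dim(img)) == 3) img <- apply(img[, , 1:min(3, dim(img)[3]), drop = FALSE],
                                          c(1, 2), mean)
  img
}

#' Crop to a square and resize a frame
#'
#' Center-crops to the smaller dimension (square aspect ratio), then resizes
#' with bilinear interpolation to `target_size`. Pass-through when the frame
#' is already the target size.
#'
#' @param frame `H x W` matrix.
#' @param target_size `c(height, width)`.
#' @param crop_offset Optional `c(row, col)` top-left crop origin override.
#' @return Matrix of size `target_size`.
#' @export
preprocess_frame <- function(frame, target_size = c(128L, 128L),
                             crop_offset = NULL) {
  h <- nrow(frame); w <- ncol(frame)
  if (h == target_size[1] && w == target_size[2]) return(frame)
  side <- min(h, w)
  off <- crop_offset %||% c(floor((h - side) / 2) + 1, floor((w - side) / 2) + 1)
  sq <- frame[off[1]:(off[1] + side - 1), off[2]:(off[2] + side - 1), drop = FALSE]
  if (all(dim(sq) == target_size)) return(sq)
  if (!requireNamespace("EBImage", quietly = TRUE))
    abort("the EBImage package is needed for resizing")
  as.matrix(EBImage::resize(EBImage::Image(sq), w = target_size[1],
                            h = target_size[2]))
}

write_manifest <- function(manifest, config, seed, dir) {
  jsonlite::write_json(
    list(kind = "synthetic", master_seed = seed,
         config = unclass(config), sequences = manifest),
    file.path(dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "rows", null = "null")
  invisible(file.path(dir, "manifest.json"))
}

#' Read a dataset manifest
#'
#' @param dir Dataset directory containing `manifest.json`.
#' @return List with `kind`, `master_seed`, `config`, and `sequences`
#'   (tibble).
#' @export
read_manifest <- function(dir) {
  m <- jsonlite::read_json(file.path(dir, "manifest.json"),
                           simplifyVector = TRUE)
  m$sequences <- as_tibble(m$sequences)
  m
}

#' Load every sequence of a dataset directory
#'
#' @param dir Dataset directory written by [generate_dataset()].
#' @param ... Passed to [load_sequence()].
#' @return Named list of `vt_sequence`.
#' @export
load_dataset <- function(dir, ...) {
  m <- read_manifest(dir)
  seqs <- lapply(m$sequences$path, load_sequence, ...)
  names(seqs) <- m$sequences$sequence_id
  seqs
}

#' Save / load a trained model
#'
#' Checkpoints are RDS files holding the flat weight vector, the model
#' configuration, the normalization constants and training metadata
#' (format version 1).
#'
#' @param model A `vt_model` or `vt_fit`.
#' @param path Checkpoint path.
#' @return `save_model()` the path; `load_model()` the restored object.
#' @export
save_model <- function(model, path) {
  obj <- list(format = "vesseltrace-checkpoint", version = 1L, object = model)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "vesseltrace-checkpoint"))
    abort("not a vesseltrace checkpoint", class = "vt_io_error")
  obj$object
}
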