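# Sequence container and readers/writers.
#
# Raw-array layout (documented contract): 64-bit IEEE floats, little
# endian, frame-major — frame 0 first, rows top to bottom within a frame,
# columns left to right within a row (row-major).  Dimensions travel in a
# plain-text sidecar "<file>.dims" holding "T H W" (or "2 H W" for flow
# planes u then v).

#' Construct an image sequence
#'
#' The package's core container: an ordered stack of T single-channel
#' frames with identical height and width, stored as an H x W x T numeric
#' array.  Intensities are promoted to double; at least two frames are
#' required (the temporal derivative needs a pair).
#'
#' @param frames H x W x T numeric array, or a list of equally sized
#'   matrices (stacked in list order).
#' @param spacing_hint Optional pixel size in mm/pixel (metadata only).
#' @param frame_interval Optional seconds between frames (metadata only).
#' @param source Format tag recording where the data came from.
#' @return An object of class `"image_sequence"`.
#' @examples
#' s <- image_sequence(array(runif(8 * 8 * 3), c(8, 8, 3)))
#' dim(s)
#' @export
image_sequence <- function(frames, spacing_hint = NULL, frame_interval = NULL,
                           source = "array") {
  if (is.list(frames)) {
    shapes <- unique(lapply(frames, dim))
    if (length(shapes) != 1L || length(shapes[[1L]]) != 2L)
      .shape_error("all frames must be matrices of identical dimensions")
    frames <- array(unlist(frames, use.names = FALSE),
                    c(shapes[[1L]], length(frames)))
  }
  if (!is.array(frames) || length(dim(frames)) != 3L)
    .shape_error("'frames' must be an H x W x T array or a list of matrices")
  storage.mode(frames) <- "double"
  if (dim(frames)[3L] < 2L)
    .flowseg_error("flowseg_sequence_error",
                   "an image sequence needs at least 2 frames")
  if (!all(is.finite(frames)))
    .input_error("frames contain non-finite intensities")
  structure(
    list(frames = frames, spacing_hint = spacing_hint,
         frame_interval = frame_interval, source = source),
    class = "image_sequence"
  )
}

#' @export
dim.image_sequence <- function(x) dim(x$frames)

#' @export
print.image_sequence <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("image_sequence: %d frames of %d x %d (source: %s)\n",
              d[3L], d[1L], d[2L], x$source))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(x$frames), max(x$frames)))
  invisible(x)
}

# Collapse an H x W x C raster to luminance by channel average.
.to_gray <- function(img, what) {
  if (length(dim(img)) == 3L) {
    nc <- dim(img)[3L]
    if (nc > 1L)
      warning(sprintf("%s has %d channels; converted to single channel by luminance average",
                      what, nc))
    img <- apply(img[, , seq_len(min(nc, 3L)), drop = FALSE], c(1L, 2L), mean)
  }
  img
}

#' Load an image sequence from disk
#'
#' Reads a temporally ordered grayscale stack from a directory of PNG
#' files, a multi-page TIFF, a raw float array (see the layout note in
#' [write_sequence_raw()]), or a DICOM series (requires the optional
#' \pkg{oro.dicom} package).  Multi-channel frames are collapsed to a
#' single channel by luminance average, with a warning.
#'
#' @param path File (tiff/raw) or directory (png/dicom).
#' @param format One of `"png-dir"`, `"tiff-stack"`, `"raw-array"`,
#'   `"dicom-series"`.
#' @param order Filename sort rule for directory formats:
#'   `"lexicographic"` (default, locale-independent) or `"natural"`
#'   (numeric-aware).
#' @param dims Integer `c(T, H, W)` for `"raw-array"` when no
#'   `"<path>.dims"` sidecar exists.
#' @return An [image_sequence()].
#' @export
load_sequence <- function(path,
                          format = c("png-dir", "tiff-stack", "raw-array",
                                     "dicom-series"),
                          order = c("lexicographic", "natural"),
                          dims = NULL) {
  format <- match.arg(format)
  order <- match.arg(order)
  if (!file.exists(path))
    .input_error(sprintf("path does not exist: %s", path))

  frames <- switch(format,
    "png-dir" = {
      files <- list.files(path, pattern = "\\.png$", ignore.case = TRUE,
                          full.names = TRUE)
      if (length(files) == 0L) .input_error("no .png files found in directory")
      files <- .sort_files(files, order)
      lapply(files, function(f) .to_gray(png::readPNG(f), basename(f)))
    },
    "tiff-stack" = {
      pages <- tiff::readTIFF(path, all = TRUE)
      if (!is.list(pages)) pages <- list(pages)
      lapply(seq_along(pages), function(i)
        .to_gray(pages[[i]], sprintf("page %d", i)))
    },
    "raw-array" = {
      if (is.null(dims)) dims <- .read_dims_sidecar(path, 3L)
      n <- prod(dims)
      x <- readBin(path, what = "double", n = n, size = 8L,
                   endian = "little")
      if (length(x) != n)
        .io_error("raw array shorter than the declared dimensions")
      # file order: frame-major, row-major within frame -> [W, H, T] col-fastest
      a <- aperm(array(x, c(dims[3L], dims[2L], dims[1L])), c(2L, 1L, 3L))
      lapply(seq_len(dims[1L]), function(t) a[, , t])
    },
    "dicom-series" = {
      if (!requireNamespace("oro.dicom", quietly = TRUE))
        .input_error(paste("DICOM reading requires the 'oro.dicom' package,",
                           "which is not installed; convert the series to",
                           "TIFF/PNG/raw instead"))
      series <- oro.dicom::readDICOM(path)
      lapply(series$img, function(m) .to_gray(m, "dicom frame"))
    }
  )

  shapes <- unique(lapply(frames, dim))
  if (length(shapes) != 1L)
    .shape_error("frames have inconsistent dimensions")
  if (length(frames) < 2L)
    .flowseg_error("flowseg_sequence_error",
                   "an image sequence needs at least 2 frames")
  image_sequence(frames, source = format)
}

.sort_files <- function(files, order) {
  base <- basename(files)
  if (order == "lexicographic") {
    files[order(base, method = "radix")]
  } else {
    num <- suppressWarnings(as.numeric(gsub("\\D", "", base)))
    files[order(num, base, method = "radix")]
  }
}

.read_dims_sidecar <- function(path, expected_len) {
  sidecar <- paste0(path, ".dims")
  if (!file.exists(sidecar))
    .input_error(sprintf("no 'dims' given and no sidecar %s", sidecar))
  dims <- as.integer(scan(sidecar, what = integer(), quiet = TRUE))
  if (length(dims) != expected_len || any(is.na(dims)) || any(dims < 1L))
    .io_error(sprintf("malformed dims sidecar %s", sidecar))
  dims
}

.write_dims_sidecar <- function(path, dims) {
  writeLines(paste(dims, collapse = " "), paste0(path, ".dims"))
}

#' Write an image sequence as a raw float array
#'
#' Serialises the frames as 64-bit little-endian IEEE floats, frame-major
#' with row-major frames, and writes a `"<path>.dims"` sidecar holding
#' `T H W`.  [load_sequence()] with `format = "raw-array"` reads the pair
#' back bit-identically.
#'
#' @param seq An [image_sequence()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sequence_raw <- function(seq, path) {
  stopifnot(inherits(seq, "image_sequence"))
  d <- dim(seq$frames)
  # [H, W, T] -> file order t, row, col (col fastest)
  x <- as.vector(aperm(seq$frames, c(2L, 1L, 3L)))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(x, con, size = 8L, endian = "little")
  .write_dims_sidecar(path, c(d[3L], d[1L], d[2L]))
  invisible(path)
}

#' Write a flow field as a two-plane raw array
#'
#' Plane u then plane v, 64-bit little-endian floats, row-major planes,
#' with a `"<path>.dims"` sidecar holding `2 H W`.
#'
#' @param flow A `flow_field` (see [optical_flow()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_flow_raw <- function(flow, path) {
  stopifnot(inherits(flow, "flow_field"))
  d <- dim(flow$u)
  x <- c(as.vector(t(flow$u)), as.vector(t(flow$v)))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(x, con, size = 8L, endian = "little")
  .write_dims_sidecar(path, c(2L, d[1L], d[2L]))
  invisible(path)
}

#' Read back a two-plane raw flow array
#'
#' @param path File written by [write_flow_raw()].
#' @param dims Integer `c(2, H, W)`; read from the sidecar when omitted.
#' @return List with numeric matrices `u` and `v`.
#' @export
read_flow_raw <- function(path, dims = NULL) {
  if (!file.exists(path)) .input_error(sprintf("path does not exist: %s", path))
  if (is.null(dims)) dims <- .read_dims_sidecar(path, 3L)
  n <- prod(dims)
  x <- readBin(path, what = "double", n = n, size = 8L, endian = "little")
  if (length(x) != n) .io_error("raw flow array shorter than declared dims")
  H <- dims[2L]; W <- dims[3L]
  list(u = t(matrix(x[1:(H * W)], W, H)),
       v = t(matrix(x[(H * W + 1):(2 * H * W)], W, H)))
}

#' Write segmentation and flow outputs to a directory
#'
#' Writes the binary motion mask as an 8-bit PNG (0/255), each flow field
#' as a two-plane raw array (optionally with a rendered vector-map PNG),
#' the colour overlay when a reference frame is available, and a
#' tab-separated manifest listing every file with its role.
#'
#' @param result A `motion_segmentation` from [segment_motion()].
#' @param flow A `flow_field` or list of flow fields; defaults to the
#'   fields stored in `result`.
#' @param out_dir Output directory (created if needed).
#' @param formats Subset of `c("png", "raw", "quiver")`.
#' @param prefix Filename prefix.
#' @return Data frame manifest (`file`, `role`), invisibly; also written
#'   as `manifest.txt`.
#' @export
save_outputs <- function(result, flow = NULL, out_dir,
                         formats = c("png", "raw", "quiver"),
                         prefix = "flowseg") {
  stopifnot(inherits(result, "motion_segmentation"))
  formats <- match.arg(formats, several.ok = TRUE)
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) .io_error(sprintf("cannot create output directory %s", out_dir))
  }
  if (file.access(out_dir, 2L) != 0L)
    .io_error(sprintf("output directory not writable: %s", out_dir))
  if (is.null(flow)) flow <- result$flows
  if (inherits(flow, "flow_field")) flow <- list(flow)

  manifest <- data.frame(file = character(), role = character(),
                         stringsAsFactors = FALSE)
  add <- function(file, role)
    manifest <<- rbind(manifest, data.frame(file = file, role = role,
                                            stringsAsFactors = FALSE))

  if ("png" %in% formats) {
    f <- file.path(out_dir, paste0(prefix, "_mask.png"))
    png::writePNG(result$mask * 1.0, f)   # logical -> 0/1 -> 0/255 in 8 bit
    add(f, "mask")
    if (!is.null(result$reference_frame)) {
      f <- file.path(out_dir, paste0(prefix, "_overlay.png"))
      png::writePNG(render_overlay(result$reference_frame, result$mask,
                                   palette = result$params$palette), f)
      add(f, "overlay")
    }
  }
  for (i in seq_along(flow)) {
    fl <- flow[[i]]
    if ("raw" %in% formats) {
      f <- file.path(out_dir, sprintf("%s_flow_%02d.raw", prefix, i))
      write_flow_raw(fl, f)
      add(f, "flow-raw")
      add(paste0(f, ".dims"), "flow-dims")
    }
    if ("quiver" %in% formats) {
      f <- file.path(out_dir, sprintf("%s_quiver_%02d.png", prefix, i))
      png::writePNG(render_vector_map(fl), f)
      add(f, "flow-quiver")
    }
  }
  mf <- file.path(out_dir, "manifest.txt")
  utils::write.table(manifest, mf, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(manifest)
}
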