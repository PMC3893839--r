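# Raster rendering of masks and flow fields.

# Colour name -> RGB triple in [0, 1].
.palette_rgb <- function(palette) {
  as.vector(grDevices::col2rgb(palette)) / 255
}

# Normalise a frame to [0, 1] for display; frames already inside [0, 1]
# are passed through unchanged so overlays are exact for standard inputs.
.display_gray <- function(frame) {
  lo <- min(frame); hi <- max(frame)
  if (lo >= 0 && hi <= 1) return(frame)
  if (hi > lo) (frame - lo) / (hi - lo) else matrix(0.5, nrow(frame), ncol(frame))
}

#' Render a colour overlay of a motion mask
#'
#' Background pixels are shown in grayscale; mask pixels are tinted with
#' the palette colour at the given opacity (high-motion zones rendered
#' clear red by default, with white available as an alternative style).
#'
#' @param frame H x W intensity image.
#' @param mask Logical H x W motion mask.
#' @param palette Tint colour (default `"red"`; any R colour name works).
#' @param opacity Tint opacity in \[0, 1\]; 1 replaces masked pixels by
#'   the palette colour outright.
#' @return H x W x 3 RGB array in \[0, 1\].
#' @export
render_overlay <- function(frame, mask, palette = "red", opacity = 0.6) {
  if (!is.matrix(frame) || !identical(dim(frame), dim(mask)))
    .shape_error("'frame' and 'mask' must be matrices of identical shape")
  if (opacity < 0 || opacity > 1)
    .parameter_error("'opacity' must lie in [0, 1]")
  gray <- .display_gray(frame)
  col <- .palette_rgb(palette)
  out <- array(gray, c(dim(frame), 3L))
  for (ch in 1:3) {
    plane <- out[, , ch]
    plane[mask] <- (1 - opacity) * plane[mask] + opacity * col[ch]
    out[, , ch] <- plane
  }
  out
}

# Rasterise a line segment into a set of (row, col) pixels (simple DDA).
.segment_pixels <- function(r0, c0, r1, c1) {
  n <- max(2L, ceiling(max(abs(r1 - r0), abs(c1 - c0))) + 1L)
  t <- seq(0, 1, length.out = n)
  cbind(round(r0 + t * (r1 - r0)), round(c0 + t * (c1 - c0)))
}

#' Render a flow-vector map as a raster image
#'
#' Draws a vector at every stride-th valid pixel on a black canvas:
#' direction (u, v), length proportional to the flow magnitude times
#' `scale`.  Invalid (aperture-degenerate) pixels draw nothing.  The
#' drawn vectors are attached as the `"arrows"` attribute (a data frame
#' with row, col, u, v).
#'
#' @param flow A `flow_field`.
#' @param stride Lattice spacing in pixels (>= 1).
#' @param scale Display gain on the vector lengths.
#' @param color Vector colour (default green).
#' @return H x W x 3 RGB array in \[0, 1\] with attribute `"arrows"`.
#' @export
render_vector_map <- function(flow, stride = 8L, scale = 4, color = "green") {
  stopifnot(inherits(flow, "flow_field"))
  stride <- as.integer(stride)
  if (is.na(stride) || stride < 1L)
    .parameter_error("'stride' must be an integer >= 1")
  d <- dim(flow$u)
  H <- d[1L]; W <- d[2L]
  canvas <- array(0, c(H, W, 3L))
  col <- .palette_rgb(color)

  rows <- seq(1L, H, by = stride)
  cols <- seq(1L, W, by = stride)
  grid <- expand.grid(row = rows, col = cols)
  keep <- flow$valid[cbind(grid$row, grid$col)]
  grid <- grid[keep, , drop = FALSE]

  if (nrow(grid) > 0L) {
    for (i in seq_len(nrow(grid))) {
      r <- grid$row[i]; c0 <- grid$col[i]
      u <- flow$u[r, c0]; v <- flow$v[r, c0]
      px <- .segment_pixels(r, c0, r + v * scale, c0 + u * scale)
      px <- px[px[, 1L] >= 1 & px[, 1L] <= H & px[, 2L] >= 1 & px[, 2L] <= W,
               , drop = FALSE]
      for (ch in 1:3) {
        plane <- canvas[, , ch]
        plane[px] <- col[ch]
        canvas[, , ch] <- plane
      }
    }
  }
  arrows <- data.frame(row = grid$row, col = grid$col,
                       u = flow$u[cbind(grid$row, grid$col)],
                       v = flow$v[cbind(grid$row, grid$col)])
  attr(canvas, "arrows") <- arrows
  canvas
}
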