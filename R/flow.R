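# Windowed least-squares (Lucas-Kanade) dense optical flow.
#
# At each pixel the brightness-constancy constraint Ix*u + Iy*v + It = 0
# is solved in the least-squares sense over an odd-sided square vicinity
# V, giving the 2x2 normal equations A [u v]' = B with
#   A = [ S Ix^2   S IxIy ;  S IxIy   S Iy^2 ],
#   B = [ -S IxIt ;  -S IyIt ],
# the sums running over V.  Where the smallest eigenvalue of A falls at or
# below a threshold tau the system is aperture-degenerate (the window sees
# effectively one-dimensional structure) and the pixel is flagged invalid.

#' Accumulate per-pixel Lucas-Kanade normal equations
#'
#' Box-window sums of the derivative products over the vicinity centred at
#' each pixel, using the same border padding rule as the derivative
#' filters.  `weighting = "gaussian"` replaces the plain box sum by a
#' Gaussian-weighted sum (sigma = window/4); the unweighted sum is the
#' default.
#'
#' @param derivs A `derivative_volumes` from [compute_derivatives()].
#' @param frame_index Temporal sample (1-based) the equations describe.
#' @param window Odd side length (>= 3) of the vicinity in pixels.
#' @param weighting `"uniform"` (default) or `"gaussian"`.
#' @return Object of class `"normal_equations"`: matrices `Sxx`, `Sxy`,
#'   `Syy`, `Bx`, `By` plus bookkeeping fields.
#' @export
accumulate_normal_equations <- function(derivs, frame_index, window = 7L,
                                        weighting = c("uniform", "gaussian")) {
  stopifnot(inherits(derivs, "derivative_volumes"))
  weighting <- match.arg(weighting)
  window <- as.integer(window)
  if (is.na(window) || window < 3L || !.is_odd(window))
    .parameter_error("'window' must be an odd integer >= 3")
  T_ <- derivs$params$dim[3L]
  if (frame_index < 1L || frame_index > T_)
    .parameter_error("'frame_index' outside the temporal support")

  r <- (window - 1L) %/% 2L
  taps <- if (weighting == "uniform") rep(1, window)
          else gaussian_kernel(window / 4, 0L, r)$taps * window  # keep box scale
  border <- derivs$params$border

  wsum <- function(m) {
    a <- array(m, c(dim(m), 1L))
    .corr_along(.corr_along(a, taps, 1L, border), taps, 2L, border)[, , 1L]
  }

  Ix <- derivs$Ix[, , frame_index]
  Iy <- derivs$Iy[, , frame_index]
  It <- derivs$It[, , frame_index]

  structure(
    list(
      Sxx = wsum(Ix * Ix), Sxy = wsum(Ix * Iy), Syy = wsum(Iy * Iy),
      Bx = -wsum(Ix * It), By = -wsum(Iy * It),
      window = window, weighting = weighting, frame_index = frame_index,
      border = border,
      intensity_range = derivs$params$intensity_range,
      border_mask = derivs$border_mask
    ),
    class = "normal_equations"
  )
}

#' Default aperture-degeneracy threshold
#'
#' The eigenvalue guard scales with the window area and the squared
#' intensity range so the same relative gradient structure is accepted
#' regardless of image scaling: `1e-5 * window^2 * range^2`.  The
#' coefficient is set so that band-limited texture with gradients a few
#' percent of the intensity range stays valid (dense flow), while exactly
#' one-dimensional structure — whose smallest eigenvalue is zero up to
#' float error — is always flagged.
#'
#' @param window Odd vicinity side length.
#' @param intensity_range Max minus min intensity of the source sequence.
#' @return Numeric threshold for the smallest eigenvalue of A.
#' @export
default_tau <- function(window, intensity_range) {
  1e-5 * window^2 * intensity_range^2
}

#' Solve the per-pixel 2x2 flow systems
#'
#' Closed-form inversion of the normal equations wherever the smallest
#' eigenvalue of A exceeds `tau`; elsewhere the pixel is marked invalid
#' and carries (0, 0) — degeneracy (the aperture problem) is a mask state,
#' not an error.  The computation is a pure per-pixel map, so results are
#' bit-identical regardless of traversal order.
#'
#' @param ne A `normal_equations` object.
#' @param tau Eigenvalue threshold (>= 0); defaults to
#'   [default_tau()] of the window and source intensity range.
#' @return Object of class `"flow_field"`: matrices `u`, `v` (pixels per
#'   frame; x and y components), logical `valid`, `lambda_min`
#'   conditioning diagnostic, and the originating `frame_index`.
#' @export
solve_flow <- function(ne, tau = NULL) {
  stopifnot(inherits(ne, "normal_equations"))
  if (is.null(tau)) tau <- default_tau(ne$window, ne$intensity_range)
  if (!is.numeric(tau) || length(tau) != 1L || tau < 0)
    .parameter_error("'tau' must be a single number >= 0")

  tr <- ne$Sxx + ne$Syy
  disc <- sqrt((ne$Sxx - ne$Syy)^2 + 4 * ne$Sxy^2)
  lambda_min <- (tr - disc) / 2

  det <- ne$Sxx * ne$Syy - ne$Sxy^2
  valid <- lambda_min > tau & det > 0
  u <- matrix(0, nrow(ne$Sxx), ncol(ne$Sxx))
  v <- u
  u[valid] <- (ne$Syy[valid] * ne$Bx[valid] - ne$Sxy[valid] * ne$By[valid]) / det[valid]
  v[valid] <- (ne$Sxx[valid] * ne$By[valid] - ne$Sxy[valid] * ne$Bx[valid]) / det[valid]

  structure(
    list(u = u, v = v, valid = valid, lambda_min = lambda_min,
         frame_index = ne$frame_index, window = ne$window, tau = tau,
         border_mask = ne$border_mask),
    class = "flow_field"
  )
}

#' Dense optical flow of one temporal sample
#'
#' Convenience wrapper chaining [compute_derivatives()],
#' [accumulate_normal_equations()] and [solve_flow()] for a single frame
#' index.
#'
#' @param seq An [image_sequence()].
#' @param frame_index Temporal sample to analyse (default 2, the first
#'   sample with a central temporal difference in short sequences).
#' @param window Odd vicinity side length (default 7).
#' @param sigma_s,sigma_t,border Passed to [compute_derivatives()].
#' @param tau Degeneracy threshold; `NULL` for [default_tau()].
#' @param weighting Window weighting, see [accumulate_normal_equations()].
#' @return A `flow_field`.
#' @examples
#' ph <- phantom_sequence("translating-texture", shape = c(32, 32),
#'                        frames = 3, velocity = c(1, 0), seed = 7)
#' fl <- optical_flow(ph$sequence)
#' summary(fl)
#' @export
optical_flow <- function(seq, frame_index = 2L, window = 7L,
                         sigma_s = 1.5, sigma_t = 1, border = "reflect",
                         tau = NULL, weighting = "uniform") {
  derivs <- compute_derivatives(seq, sigma_s = sigma_s, sigma_t = sigma_t,
                                border = border)
  ne <- accumulate_normal_equations(derivs, frame_index, window, weighting)
  solve_flow(ne, tau)
}

#' Flow magnitude map
#'
#' @param flow A `flow_field`.
#' @return H x W matrix `sqrt(u^2 + v^2)` in pixels/frame; 0 at invalid
#'   pixels (which carry u = v = 0 by construction).
#' @export
flow_magnitude <- function(flow) {
  stopifnot(inherits(flow, "flow_field"))
  sqrt(flow$u^2 + flow$v^2)
}

#' @export
print.flow_field <- function(x, ...) {
  d <- dim(x$u)
  cat(sprintf("flow_field: %d x %d, frame %d, window %d\n",
              d[1L], d[2L], x$frame_index, x$window))
  cat(sprintf("  valid pixels: %d / %d (%.1f%%)\n",
              sum(x$valid), length(x$valid), 100 * mean(x$valid)))
  if (any(x$valid)) {
    m <- flow_magnitude(x)[x$valid]
    cat(sprintf("  |flow| over valid pixels: median %.3f, max %.3f px/frame\n",
                stats::median(m), max(m)))
  }
  invisible(x)
}

#' @export
summary.flow_field <- function(object, ...) {
  m <- flow_magnitude(object)
  out <- list(
    dim = dim(object$u),
    frame_index = object$frame_index,
    window = object$window,
    tau = object$tau,
    valid_fraction = mean(object$valid),
    u = summary(object$u[object$valid]),
    v = summary(object$v[object$valid]),
    magnitude = summary(m[object$valid])
  )
  class(out) <- "summary.flow_field"
  out
}

#' @export
print.summary.flow_field <- function(x, ...) {
  cat(sprintf("Dense optical flow, %d x %d (frame %d)\n",
              x$dim[1L], x$dim[2L], x$frame_index))
  cat(sprintf("window %d, tau %.4g, valid fraction %.3f\n",
              x$window, x$tau, x$valid_fraction))
  cat("u (px/frame):\n"); print(x$u)
  cat("v (px/frame):\n"); print(x$v)
  invisible(x)
}

#' Quiver plot of a flow field
#'
#' Draws the valid flow vectors on a stride lattice with
#' [graphics::arrows()], y axis oriented like the image (row 1 on top).
#'
#' @param x A `flow_field`.
#' @param stride Lattice spacing in pixels.
#' @param scale Display gain applied to the arrow lengths.
#' @param ... Passed to [graphics::arrows()].
#' @export
plot.flow_field <- function(x, stride = 8L, scale = 1, ...) {
  d <- dim(x$u)
  rows <- seq(1L, d[1L], by = stride)
  cols <- seq(1L, d[2L], by = stride)
  sel <- expand.grid(row = rows, col = cols)
  keep <- x$valid[cbind(sel$row, sel$col)]
  sel <- sel[keep, , drop = FALSE]
  graphics::plot(NA, xlim = c(1, d[2L]), ylim = c(d[1L], 1),
                 xlab = "x (col)", ylab = "y (row)", asp = 1,
                 main = sprintf("flow field, frame %d", x$frame_index))
  if (nrow(sel) > 0L) {
    u <- x$u[cbind(sel$row, sel$col)] * scale
    v <- x$v[cbind(sel$row, sel$col)] * scale
    nz <- (u != 0 | v != 0)
    if (any(nz))
      graphics::arrows(sel$col[nz], sel$row[nz],
                       sel$col[nz] + u[nz], sel$row[nz] + v[nz],
                       length = 0.04, ...)
  }
  invisible(x)
}
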