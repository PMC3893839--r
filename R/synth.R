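# Synthetic phantoms with exact ground-truth motion.
#
# Textures are periodic (wrap-around) band-limited noise, and motion is
# realised by sub-pixel bilinear sampling of the periodic texture, so the
# displacement is exact at every pixel — no border information is created
# or destroyed.  A single seeded generator drives all randomness; the
# caller's RNG state is untouched.

# Bilinear sample of a periodic image at (row - dy, col - dx); content
# therefore appears shifted by (+dx, +dy) (x = col, y = row).
.shift_bilinear_wrap <- function(img, dx, dy) {
  H <- nrow(img); W <- ncol(img)
  r0 <- (seq_len(H) - 1) - dy
  c0 <- (seq_len(W) - 1) - dx
  ri <- floor(r0); rf <- r0 - ri
  ci <- floor(c0); cf <- c0 - ci
  riw  <- (ri %% H) + 1L
  riw1 <- ((ri + 1) %% H) + 1L
  ciw  <- (ci %% W) + 1L
  ciw1 <- ((ci + 1) %% W) + 1L
  (1 - rf) * ((img[riw,  ciw,  drop = FALSE] * rep(1 - cf, each = H)) +
              (img[riw,  ciw1, drop = FALSE] * rep(cf,     each = H))) +
       rf  * ((img[riw1, ciw,  drop = FALSE] * rep(1 - cf, each = H)) +
              (img[riw1, ciw1, drop = FALSE] * rep(cf,     each = H)))
}

# Band-limited periodic texture: white noise smoothed with a wrap-around
# Gaussian (sigma = bandwidth), standardised to mean 0.5, sd 0.1.
.texture <- function(H, W, bandwidth = 2) {
  tex <- matrix(stats::rnorm(H * W), H, W)
  g <- gaussian_kernel(bandwidth, 0L)$taps
  tex <- .corr_matrix(.corr_matrix(tex, g, 1L, "wrap"), g, 2L, "wrap")
  0.5 + 0.1 * (tex - mean(tex)) / stats::sd(tex)
}

#' Generate a synthetic image sequence with known motion
#'
#' Phantoms for validating every pipeline stage without external data:
#' \describe{
#'   \item{`"translating-texture"`}{a periodic band-limited random texture
#'     translating globally at `velocity` px/frame (sub-pixel shifts via
#'     bilinear interpolation; exact shift identity at integer velocity).}
#'   \item{`"moving-blob"`}{a static textured background plus an additive
#'     Gaussian-profile blob (the "lesion") whose centre translates at
#'     `velocity`; the ground-truth moving region is the union over frames
#'     of the disc of radius `blob$radius` around the centre path.}
#'   \item{`"grating"`}{a 1-D sinusoid translating along its normal — the
#'     classic aperture-problem stimulus; the least-squares flow matrix is
#'     singular everywhere.}
#'   \item{`"static"`}{a texture repeated unchanged.}
#' }
#' Additive Gaussian noise of standard deviation `noise_sigma` (intensity
#' units; textures have mean 0.5, sd 0.1) is applied last.  Identical
#' seeds give bit-identical output.
#'
#' @param kind Phantom type, see above.
#' @param shape Integer `c(H, W)` frame shape (default `c(256, 256)`, the
#'   breast-MRI geometry; use `c(95, 69)` for the fMRI-slide geometry).
#' @param frames Number of frames T (default 6, a dynamic-study protocol
#'   of six measurements).
#' @param velocity `c(u, v)` in px/frame, each component in \[-2, 2\] (the
#'   range over which a single-scale gradient estimator is meaningful).
#'   For `"grating"`, the velocity is projected onto the grating normal.
#' @param blob List with `center` (`c(row, col)`, default frame centre),
#'   `radius` (px, default 10) and `contrast` (intensity units, default
#'   0.4); the Gaussian profile has sigma = radius/2 and the centre path
#'   is centred on `center`.
#' @param grating List with `orientation` (radians; angle of the normal,
#'   default 0 = intensity varies along x, i.e. vertical stripes) and
#'   `wavelength` (px, default 16).
#' @param noise_sigma Additive Gaussian noise sd (default 0: exact ground
#'   truth).
#' @param seed Integer seed; fully determines the output.
#' @return Object of class `"phantom"`: `sequence` (an
#'   [image_sequence()]), `truth` (list with `velocity`, per-pair constant
#'   ground-truth flow and the logical `moving_mask`), and `spec` (the
#'   arguments).
#' @examples
#' ph <- phantom_sequence("moving-blob", shape = c(64, 64), frames = 4,
#'                        velocity = c(1, 0), seed = 1)
#' ph$sequence
#' @export
phantom_sequence <- function(kind = c("translating-texture", "moving-blob",
                                      "grating", "static"),
                             shape = c(256L, 256L), frames = 6L,
                             velocity = c(0, 0),
                             blob = list(), grating = list(),
                             noise_sigma = 0, seed = 1L) {
  kind <- match.arg(kind)
  H <- as.integer(shape[1L]); W <- as.integer(shape[2L])
  T_ <- as.integer(frames)
  if (is.na(H) || is.na(W) || H < 4L || W < 4L)
    .parameter_error("'shape' must be at least 4 x 4")
  if (is.na(T_) || T_ < 2L)
    .parameter_error("'frames' must be >= 2")
  velocity <- as.numeric(velocity)
  if (length(velocity) != 2L || any(!is.finite(velocity)) ||
      any(abs(velocity) > 2))
    .parameter_error("'velocity' components must be finite and within [-2, 2] px/frame")
  if (!is.numeric(noise_sigma) || noise_sigma < 0)
    .parameter_error("'noise_sigma' must be >= 0")

  u <- velocity[1L]; v <- velocity[2L]

  out <- .with_seed(as.integer(seed), {
    fr <- array(0, c(H, W, T_))
    moving_mask <- matrix(FALSE, H, W)

    if (kind %in% c("translating-texture", "static")) {
      tex <- .texture(H, W)
      if (kind == "static") { u <- 0; v <- 0 }
      for (t in seq_len(T_))
        fr[, , t] <- if (u == 0 && v == 0) tex
                     else .shift_bilinear_wrap(tex, (t - 1) * u, (t - 1) * v)
      moving_mask[] <- (u != 0 || v != 0)
    } else if (kind == "moving-blob") {
      b <- utils::modifyList(
        list(center = c(H, W) / 2, radius = 10, contrast = 0.4), blob)
      bg <- .texture(H, W)
      sigma_b <- b$radius / 2
      rowg <- matrix(seq_len(H), H, W)
      colg <- matrix(seq_len(W), H, W, byrow = TRUE)
      for (t in seq_len(T_)) {
        ct <- b$center + (t - 1 - (T_ - 1) / 2) * c(v, u)  # (row, col) path
        d2 <- (rowg - ct[1L])^2 + (colg - ct[2L])^2
        fr[, , t] <- bg + b$contrast * exp(-d2 / (2 * sigma_b^2))
        moving_mask <- moving_mask | (d2 <= b$radius^2)
      }
    } else if (kind == "grating") {
      g <- utils::modifyList(list(orientation = 0, wavelength = 16), grating)
      speed <- u * cos(g$orientation) + v * sin(g$orientation)  # along normal
      rowg <- matrix(seq_len(H) - 1, H, W)
      colg <- matrix(seq_len(W) - 1, H, W, byrow = TRUE)
      phase <- colg * cos(g$orientation) + rowg * sin(g$orientation)
      for (t in seq_len(T_))
        fr[, , t] <- 0.5 + 0.4 * sin(2 * pi * (phase - (t - 1) * speed) /
                                       g$wavelength)
      moving_mask[] <- (speed != 0)
      u <- speed * cos(g$orientation); v <- speed * sin(g$orientation)
    }

    if (noise_sigma > 0)
      fr <- fr + array(stats::rnorm(length(fr), sd = noise_sigma), dim(fr))
    list(frames = fr, moving_mask = moving_mask, u = u, v = v)
  })

  flow_pairs <- lapply(seq_len(T_ - 1L), function(t) {
    uu <- matrix(0, H, W); vv <- matrix(0, H, W)
    uu[out$moving_mask] <- out$u
    vv[out$moving_mask] <- out$v
    list(u = uu, v = vv)
  })

  structure(
    list(
      sequence = image_sequence(out$frames, source = "synthetic"),
      truth = list(velocity = c(u = out$u, v = out$v),
                   flow = flow_pairs, moving_mask = out$moving_mask),
      spec = list(kind = kind, shape = c(H, W), frames = T_,
                  velocity = c(u = out$u, v = out$v), blob = blob,
                  grating = grating, noise_sigma = noise_sigma, seed = seed)
    ),
    class = "phantom"
  )
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("phantom: %s, %d x %d x %d frames, velocity (%.2f, %.2f) px/frame, noise sd %.3g, seed %d\n",
              x$spec$kind, x$spec$shape[1L], x$spec$shape[2L],
              x$spec$frames, x$truth$velocity[1L], x$truth$velocity[2L],
              x$spec$noise_sigma, x$spec$seed))
  invisible(x)
}
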