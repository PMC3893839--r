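# Separable Gaussian smoothing / derivative filtering.
#
# Coordinate convention (used package-wide): frames are matrices indexed
# (row, col) with row 1 at the top; x is the column direction (increasing
# rightward), y the row direction (increasing downward).  u denotes the x
# component of flow, v the y component.  Derivative kernels are oriented so
# that correlation with an increasing ramp gives a positive response, i.e.
# Ix approximates +dI/dx.

# Map possibly out-of-range positions onto 1..n by mirror reflection
# without repeating the edge sample (…, 3, 2, 1 | 2, 3, …).
.mirror_positions <- function(pos, n) {
  if (n == 1L) return(rep(1L, length(pos)))
  period <- 2L * (n - 1L)
  q <- (pos - 1L) %% period
  ifelse(q < n, q + 1L, 2L * n - 1L - q)
}

# Source indices for a padded axis of length n + 2r; NA marks zero padding.
.pad_indices <- function(n, r, border) {
  pos <- (1L - r):(n + r)
  switch(border,
    reflect  = .mirror_positions(pos, n),
    nearest  = pmin(pmax(pos, 1L), n),
    wrap     = ((pos - 1L) %% n) + 1L,
    constant = ifelse(pos < 1L | pos > n, NA_integer_, pos),
    .parameter_error(sprintf("unknown border rule '%s'", border))
  )
}

# Correlate a 3-D array [H, W, T] with a 1-D tap vector along one axis.
# Correlation orientation: out[i] = sum_m taps[m + r + 1] * in[i + m].
.corr_along <- function(arr, taps, along, border = "reflect") {
  d <- dim(arr)
  n <- d[along]
  len <- length(taps)
  r <- (len - 1L) %/% 2L
  if (r == 0L) return(arr * taps)
  idx <- .pad_indices(n, r, border)
  zero <- is.na(idx)
  idx[zero] <- 1L
  padded <- switch(along,
    arr[idx, , , drop = FALSE],
    arr[, idx, , drop = FALSE],
    arr[, , idx, drop = FALSE]
  )
  if (any(zero)) {
    w <- as.numeric(!zero)
    padded <- switch(along,
      padded * w,
      aperm(aperm(padded, c(2L, 1L, 3L)) * w, c(2L, 1L, 3L)),
      aperm(aperm(padded, c(3L, 2L, 1L)) * w, c(3L, 2L, 1L))
    )
  }
  out <- array(0, d)
  for (k in seq_len(len)) {
    if (taps[k] == 0) next
    sl <- switch(along,
      padded[k:(k + n - 1L), , , drop = FALSE],
      padded[, k:(k + n - 1L), , drop = FALSE],
      padded[, , k:(k + n - 1L), drop = FALSE]
    )
    out <- out + taps[k] * sl
  }
  out
}

# Matrix front-end to .corr_along.
.corr_matrix <- function(m, taps, along, border = "reflect") {
  a <- array(m, c(dim(m), 1L))
  .corr_along(a, taps, along, border)[, , 1L]
}

#' Sampled Gaussian smoothing or first-derivative kernel
#'
#' Builds an odd-length separable filter tap vector: either a sampled
#' Gaussian renormalised to unit DC gain (`order = 0`) or a sampled
#' Gaussian first derivative (`order = 1`), antisymmetric about the centre
#' and DC-corrected to sum exactly to zero.  Derivative taps are oriented
#' so that correlating an increasing linear ramp yields approximately +1
#' per sample at interior positions.
#'
#' @param sigma Scale of the Gaussian, in samples (pixels for spatial use,
#'   frames for temporal use). Must be positive.
#' @param order 0 for smoothing, 1 for the first derivative.
#' @param radius Half-length of the kernel in samples; the tap vector has
#'   length `2 * radius + 1`. Defaults to `ceiling(3 * sigma)`; a warning
#'   is issued below that support.
#' @return An object of class `"kernel_1d"` with elements `taps`, `order`,
#'   `sigma` and `radius`.
#' @examples
#' k <- gaussian_kernel(1.5, order = 0)
#' sum(k$taps)          # 1 (unit DC gain)
#' d <- gaussian_kernel(1.5, order = 1)
#' sum(d$taps)          # 0 (no DC response)
#' @export
gaussian_kernel <- function(sigma, order = 0L, radius = ceiling(3 * sigma)) {
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) || sigma <= 0)
    .parameter_error("'sigma' must be a single positive number")
  if (!order %in% c(0L, 1L))
    .parameter_error("'order' must be 0 (smoothing) or 1 (first derivative)")
  radius <- as.integer(radius)
  if (is.na(radius) || radius < 1L)
    .parameter_error("'radius' must be an integer >= 1")
  if (radius < ceiling(3 * sigma))
    warning(sprintf("radius %d is below the recommended ceiling(3*sigma) = %d; kernel is truncated",
                    radius, as.integer(ceiling(3 * sigma))))
  m <- (-radius):radius
  g <- exp(-(m^2) / (2 * sigma^2))
  g <- g / sum(g)
  taps <- if (order == 0L) g else {
    t1 <- (m / sigma^2) * g       # response ~ d/dx; antisymmetric by construction
    t1 - mean(t1)                 # exact zero DC
  }
  structure(
    list(taps = taps, order = as.integer(order), sigma = sigma, radius = radius),
    class = "kernel_1d"
  )
}

#' Spatiotemporal derivative volumes of an image sequence
#'
#' Computes the spatial derivatives Ix, Iy and the temporal derivative It
#' of every frame by separable filtering: the derivative axis is filtered
#' with a Gaussian first-derivative kernel and the remaining axes with
#' Gaussian smoothing kernels.  These are the inputs to the brightness-
#' constancy motion constraint `Ix * u + Iy * v + It = 0` solved by
#' [optical_flow()].
#'
#' For short sequences (fewer frames than the temporal Gaussian support
#' `2 * ceiling(3 * sigma_t) + 1`), the temporal scheme falls back to
#' finite differences — forward at the first and last frame, central
#' inside — and no temporal smoothing is applied to Ix/Iy; the fallback is
#' recorded in `params$temporal_scheme`.
#'
#' @param seq An [image_sequence()].
#' @param sigma_s Spatial Gaussian scale in pixels (default 1.5).
#' @param sigma_t Temporal Gaussian scale in frames (default 1).
#' @param border Border rule for spatial filtering: `"reflect"` (mirror
#'   without repeating the edge sample, the default), `"nearest"` or
#'   `"constant"` (zero padding).
#' @param radius_s,radius_t Optional kernel half-length overrides.
#' @return An object of class `"derivative_volumes"`: list with `Ix`,
#'   `Iy`, `It` (arrays of the same H x W x T shape as the input),
#'   `border_mask` (TRUE within one spatial kernel radius of the frame
#'   border) and `params`.
#' @export
compute_derivatives <- function(seq, sigma_s = 1.5, sigma_t = 1,
                                border = c("reflect", "nearest", "constant"),
                                radius_s = NULL, radius_t = NULL) {
  stopifnot(inherits(seq, "image_sequence"))
  border <- match.arg(border)
  frames <- seq$frames
  d <- dim(frames)
  H <- d[1L]; W <- d[2L]; T_ <- d[3L]

  rs <- if (is.null(radius_s)) ceiling(3 * sigma_s) else as.integer(radius_s)
  gs <- gaussian_kernel(sigma_s, 0L, rs)
  gd <- gaussian_kernel(sigma_s, 1L, rs)

  rt <- if (is.null(radius_t)) ceiling(3 * sigma_t) else as.integer(radius_t)
  use_gaussian_t <- T_ >= 2L * rt + 1L
  temporal_scheme <- if (use_gaussian_t) "gaussian" else "finite-difference"

  # x = columns (axis 2), y = rows (axis 1), t = axis 3
  Ix <- .corr_along(.corr_along(frames, gd$taps, 2L, border), gs$taps, 1L, border)
  Iy <- .corr_along(.corr_along(frames, gd$taps, 1L, border), gs$taps, 2L, border)
  Sp <- .corr_along(.corr_along(frames, gs$taps, 1L, border), gs$taps, 2L, border)

  if (use_gaussian_t) {
    gt0 <- gaussian_kernel(sigma_t, 0L, rt)
    gt1 <- gaussian_kernel(sigma_t, 1L, rt)
    Ix <- .corr_along(Ix, gt0$taps, 3L, "reflect")
    Iy <- .corr_along(Iy, gt0$taps, 3L, "reflect")
    It <- .corr_along(Sp, gt1$taps, 3L, "reflect")
  } else {
    It <- array(0, d)
    It[, , 1L] <- Sp[, , 2L] - Sp[, , 1L]
    if (T_ > 2L)
      for (t in 2L:(T_ - 1L))
        It[, , t] <- (Sp[, , t + 1L] - Sp[, , t - 1L]) / 2
    It[, , T_] <- Sp[, , T_] - Sp[, , T_ - 1L]
  }

  if (!all(is.finite(Ix)) || !all(is.finite(Iy)) || !all(is.finite(It)))
    .numeric_error("non-finite values in derivative volumes")

  border_mask <- matrix(TRUE, H, W)
  if (H > 2L * rs && W > 2L * rs)
    border_mask[(rs + 1L):(H - rs), (rs + 1L):(W - rs)] <- FALSE

  structure(
    list(
      Ix = Ix, Iy = Iy, It = It,
      border_mask = border_mask,
      params = list(
        sigma_s = sigma_s, sigma_t = sigma_t,
        radius_s = rs, radius_t = rt,
        border = border, temporal_scheme = temporal_scheme,
        intensity_range = diff(range(frames)),
        dim = d
      )
    ),
    class = "derivative_volumes"
  )
}
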