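# End-to-end motion segmentation: derivatives -> Lucas-Kanade flow ->
# magnitude -> attention-windowed Otsu threshold -> density summary.

#' Rectangular motion-attention window
#'
#' The adjustable zone within which flow magnitudes are histogrammed and
#' segmented, matched to the diagnostic target.  Called with no arguments
#' it denotes the full frame.
#'
#' @param row0,col0 Top-left corner (1-based pixel indices).
#' @param height,width Rectangle size in pixels.
#' @return Object of class `"attention_window"`.
#' @export
attention_window <- function(row0 = NULL, col0 = NULL,
                             height = NULL, width = NULL) {
  if (is.null(row0) && is.null(col0) && is.null(height) && is.null(width))
    return(structure(list(full = TRUE), class = "attention_window"))
  vals <- c(row0, col0, height, width)
  if (length(vals) != 4L || any(!is.finite(vals)) || any(vals < 1))
    .parameter_error("attention window needs positive row0, col0, height, width")
  structure(list(full = FALSE, row0 = as.integer(row0),
                 col0 = as.integer(col0), height = as.integer(height),
                 width = as.integer(width)),
            class = "attention_window")
}

# Resolve a window against frame dims; validate geometry.
.resolve_attention <- function(aw, H, W, flow_window) {
  if (aw$full)
    aw <- attention_window(1L, 1L, H, W)
  if (aw$row0 + aw$height - 1L > H || aw$col0 + aw$width - 1L > W)
    .parameter_error("attention window extends outside the frame")
  if (aw$height < flow_window || aw$width < flow_window)
    .parameter_error(sprintf(
      "attention window must be at least the flow window (%d px) on each side",
      flow_window))
  aw
}

.attention_mask <- function(aw, H, W) {
  m <- matrix(FALSE, H, W)
  m[aw$row0:(aw$row0 + aw$height - 1L),
    aw$col0:(aw$col0 + aw$width - 1L)] <- TRUE
  m
}

#' Pipeline configuration
#'
#' Collects every tunable of the segmentation pipeline with the package
#' defaults.
#'
#' @param window Odd Lucas-Kanade vicinity side length (default 7;
#'   typical sweep 5/7/9).
#' @param sigma_s Spatial Gaussian scale, pixels (default 1.5).
#' @param sigma_t Temporal Gaussian scale, frames (default 1; short
#'   sequences fall back to finite differences, see
#'   [compute_derivatives()]).
#' @param tau Aperture-degeneracy eigenvalue threshold; `NULL` for
#'   [default_tau()].
#' @param levels Histogram level count L (default 256).
#' @param border Spatial border rule (default `"reflect"`).
#' @param aggregate `"max"` (default): per-pixel maximum of the per-pair
#'   magnitude maps is segmented once; `"per-pair"`: each frame pair is
#'   segmented separately and the reported mask is their union.
#' @param weighting Vicinity weighting, `"uniform"` (default) or
#'   `"gaussian"`.
#' @param palette Overlay tint, `"red"` (default) or `"white"` (or any R
#'   colour).
#' @param opacity Overlay tint opacity in \[0, 1\] (default 0.6).
#' @return A list of class `"motion_config"`.
#' @export
motion_config <- function(window = 7L, sigma_s = 1.5, sigma_t = 1,
                          tau = NULL, levels = 256L,
                          border = c("reflect", "nearest", "constant"),
                          aggregate = c("max", "per-pair"),
                          weighting = c("uniform", "gaussian"),
                          palette = "red", opacity = 0.6) {
  window <- as.integer(window)
  if (is.na(window) || window < 3L || !.is_odd(window))
    .parameter_error("'window' must be an odd integer >= 3")
  structure(
    list(window = window, sigma_s = sigma_s, sigma_t = sigma_t, tau = tau,
         levels = as.integer(levels), border = match.arg(border),
         aggregate = match.arg(aggregate), weighting = match.arg(weighting),
         palette = palette, opacity = opacity),
    class = "motion_config"
  )
}

#' Motion segmentation of an image sequence
#'
#' The package's main entry point.  For every consecutive frame pair,
#' dense Lucas-Kanade flow is estimated and reduced to a magnitude map;
#' the magnitudes inside the attention window (aggregated by per-pixel
#' maximum by default) are quantised, histogrammed and split by Otsu's
#' between-class-variance threshold.  The high class C1 is reported as
#' the moving region, together with its density — the fraction of
#' attention-window pixels in C1.
#'
#' A sequence with no magnitude contrast inside the window (e.g. a static
#' scene, where the flow is exactly zero) yields an empty mask and
#' density 0 with a logged notice rather than an error.
#'
#' @param seq An [image_sequence()].
#' @param config A [motion_config()].
#' @param attention An [attention_window()]; default full frame.
#' @return Object of class `"motion_segmentation"`: logical `mask` (FALSE
#'   outside the attention window), `k_star`, `density`, `coverage`
#'   (fraction of the attention window processed, always 1 here),
#'   `histogram`, `threshold`, aggregated `magnitude`, `flows` (list of
#'   `flow_field`s, one per frame pair), `per_frame` (per-pair densities
#'   and, under `aggregate = "per-pair"`, masks), `attention` (resolved
#'   rectangle), `reference_frame` (first frame, for overlays) and
#'   `params`.
#' @examples
#' ph <- phantom_sequence("moving-blob", shape = c(64, 64), frames = 4,
#'                        velocity = c(1, 0), seed = 2)
#' seg <- segment_motion(ph$sequence, motion_config(window = 5))
#' seg
#' @export
segment_motion <- function(seq, config = motion_config(),
                           attention = attention_window()) {
  stopifnot(inherits(seq, "image_sequence"),
            inherits(config, "motion_config"),
            inherits(attention, "attention_window"))
  d <- dim(seq$frames)
  H <- d[1L]; W <- d[2L]; T_ <- d[3L]
  aw <- .resolve_attention(attention, H, W, config$window)
  aw_mask <- .attention_mask(aw, H, W)

  derivs <- compute_derivatives(seq, sigma_s = config$sigma_s,
                                sigma_t = config$sigma_t,
                                border = config$border)
  pair_idx <- seq_len(T_ - 1L)
  flows <- lapply(pair_idx, function(t) {
    ne <- accumulate_normal_equations(derivs, t, config$window,
                                      config$weighting)
    solve_flow(ne, config$tau)
  })
  mags <- lapply(flows, flow_magnitude)

  segment_one <- function(mag) {
    h <- build_histogram(mag, mask = aw_mask, levels = config$levels)
    th <- tryCatch(otsu_threshold(h), flowseg_no_threshold_error = function(e) NULL)
    if (is.null(th)) {
      list(mask = matrix(FALSE, H, W), k_star = NA_integer_,
           histogram = h, threshold = NULL, notice = "no motion detected")
    } else {
      list(mask = apply_threshold(mag, h, th$k_star), k_star = th$k_star,
           histogram = h, threshold = th, notice = NULL)
    }
  }

  aw_area <- sum(aw_mask)
  if (config$aggregate == "max") {
    agg <- Reduce(pmax, mags)
    s <- segment_one(agg)
    per_frame <- lapply(pair_idx, function(t) {
      pm <- if (is.null(s$threshold)) matrix(FALSE, H, W)
            else apply_threshold(mags[[t]], s$histogram, s$k_star)
      list(pair = c(t, t + 1L), density = sum(pm & aw_mask) / aw_area)
    })
    mask <- s$mask
  } else {
    per <- lapply(mags, segment_one)
    agg <- Reduce(pmax, mags)
    mask <- Reduce(`|`, lapply(per, `[[`, "mask"))
    per_frame <- lapply(pair_idx, function(t)
      list(pair = c(t, t + 1L), mask = per[[t]]$mask,
           k_star = per[[t]]$k_star,
           density = sum(per[[t]]$mask) / aw_area))
    s <- segment_one(agg)   # aggregate histogram/threshold for reporting
    s$mask <- mask
  }
  density <- sum(s$mask & aw_mask) / aw_area
  if (!is.null(s$notice)) message("flowseg: ", s$notice)

  structure(
    list(mask = s$mask, k_star = s$k_star, density = density,
         coverage = 1,
         histogram = s$histogram, threshold = s$threshold,
         magnitude = agg, flows = flows, per_frame = per_frame,
         attention = aw, reference_frame = seq$frames[, , 1L],
         notice = s$notice,
         params = list(config = config,
                       tau = flows[[1L]]$tau,
                       temporal_scheme = derivs$params$temporal_scheme,
                       dim = d)),
    class = "motion_segmentation"
  )
}

#' Motion density inside an attention window
#'
#' The fraction of attention-window pixels assigned to the moving class.
#'
#' @param mask Logical H x W motion mask.
#' @param aw An [attention_window()] lying inside the mask's frame.
#' @return A fraction in \[0, 1\].
#' @export
compute_density <- function(mask, aw) {
  stopifnot(is.matrix(mask), inherits(aw, "attention_window"))
  H <- nrow(mask); W <- ncol(mask)
  if (aw$full) aw <- attention_window(1L, 1L, H, W)
  if (aw$height < 1L || aw$width < 1L)
    .parameter_error("attention window has zero area")
  if (aw$row0 + aw$height - 1L > H || aw$col0 + aw$width - 1L > W)
    .parameter_error("attention window extends outside the frame")
  m <- .attention_mask(aw, H, W)
  sum(mask & m) / sum(m)
}

#' @export
print.motion_segmentation <- function(x, ...) {
  d <- x$params$dim
  cat(sprintf("motion_segmentation: %d x %d, %d frame pairs (window %d, L = %d)\n",
              d[1L], d[2L], length(x$flows), x$params$config$window,
              x$params$config$levels))
  aw <- x$attention
  cat(sprintf("  attention window: rows %d..%d, cols %d..%d\n",
              aw$row0, aw$row0 + aw$height - 1L,
              aw$col0, aw$col0 + aw$width - 1L))
  if (is.na(x$k_star)) {
    cat("  no motion detected (single-level magnitude histogram)\n")
  } else {
    cat(sprintf("  Otsu threshold k* = %d; motion density %.4f\n",
                x$k_star, x$density))
  }
  invisible(x)
}

#' @export
summary.motion_segmentation <- function(object, ...) {
  out <- list(
    dim = object$params$dim,
    window = object$params$config$window,
    tau = object$params$tau,
    temporal_scheme = object$params$temporal_scheme,
    k_star = object$k_star,
    density = object$density,
    per_pair_density = vapply(object$per_frame, `[[`, numeric(1), "density"),
    valid_fraction = mean(vapply(object$flows, function(f) mean(f$valid),
                                 numeric(1)))
  )
  class(out) <- "summary.motion_segmentation"
  out
}

#' @export
print.summary.motion_segmentation <- function(x, ...) {
  cat(sprintf("Motion segmentation of a %d x %d x %d sequence\n",
              x$dim[1L], x$dim[2L], x$dim[3L]))
  cat(sprintf("LK window %d, tau %.4g, temporal scheme: %s\n",
              x$window, x$tau, x$temporal_scheme))
  cat(sprintf("mean valid-flow fraction: %.3f\n", x$valid_fraction))
  if (is.na(x$k_star)) cat("no motion detected\n")
  else cat(sprintf("k* = %d; motion density %.4f\n", x$k_star, x$density))
  invisible(x)
}

#' Overlay plot of a segmentation result
#'
#' Renders the first frame in grayscale with the motion mask tinted and
#' the attention window outlined.
#'
#' @param x A `motion_segmentation`.
#' @param ... Unused.
#' @export
plot.motion_segmentation <- function(x, ...) {
  img <- render_overlay(x$reference_frame, x$mask,
                        palette = x$params$config$palette,
                        opacity = x$params$config$opacity)
  d <- dim(img)
  graphics::plot(NA, xlim = c(0, d[2L]), ylim = c(d[1L], 0), asp = 1,
                 xlab = "", ylab = "", axes = FALSE,
                 main = sprintf("motion density %.3f", x$density))
  graphics::rasterImage(img, 0, d[1L], d[2L], 0)
  aw <- x$attention
  graphics::rect(aw$col0 - 1, aw$row0 + aw$height - 1,
                 aw$col0 + aw$width - 1, aw$row0 - 1,
                 border = "yellow", lwd = 1.5)
  invisible(x)
}

#' Sweep the Lucas-Kanade window size
#'
#' Runs [segment_motion()] once per window size and returns the results
#' with a density summary — the configurability study mode (window sizes
#' 5, 7, 9 by default).
#'
#' @param seq An [image_sequence()].
#' @param windows Integer vector of odd window sizes.
#' @param config Base [motion_config()]; its window is replaced per run.
#' @param attention An [attention_window()].
#' @return Object of class `"window_sweep"`: list of results indexed by
#'   window size plus a `summary` data frame (window, k_star, density).
#' @export
sweep_windows <- function(seq, windows = c(5L, 7L, 9L),
                          config = motion_config(),
                          attention = attention_window()) {
  results <- lapply(windows, function(w) {
    cfg <- config
    cfg$window <- as.integer(w)
    segment_motion(seq, cfg, attention)
  })
  names(results) <- as.character(windows)
  structure(
    list(results = results,
         summary = data.frame(
           window = as.integer(windows),
           k_star = vapply(results, function(r)
             ifelse(is.na(r$k_star), NA_integer_, as.integer(r$k_star)),
             integer(1)),
           density = vapply(results, `[[`, numeric(1), "density")
         )),
    class = "window_sweep"
  )
}

#' @export
print.window_sweep <- function(x, ...) {
  cat("window_sweep:\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}
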