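# Otsu's automatic histogram threshold.
#
# Levels are 0-based (0 .. L-1) internally; with p_i the normalised
# histogram, cumulative weight w(k) = sum_{i<=k} p_i and cumulative first
# moment mu(k) = sum_{i<=k} i*p_i, the between-class variance at split k
# (class C0 = levels <= k, C1 = levels > k) is
#   sigma_B^2(k) = (mu_T * w(k) - mu(k))^2 / (w(k) * (1 - w(k))),
# algebraically identical to w0*w1*(mu0 - mu1)^2.  The optimal threshold
# maximises sigma_B^2 over the valid set {k : w(k)*(1 - w(k)) > 0}; ties
# break to the smallest k (an ascending sequential scan finds it first).

#' Build a normalised histogram model
#'
#' Quantises a continuous scalar map to `levels` equal-width bins over the
#' min-max range of the masked pixels (top edge inclusive) and normalises
#' the counts to a probability distribution.  A constant input maps all
#' mass to level 0.
#'
#' @param values H x W numeric map (e.g. a flow-magnitude map).
#' @param mask Logical H x W selection; `NULL` selects every pixel.
#' @param levels Number of gray levels L (default 256).
#' @return Object of class `"flow_histogram"`: `counts` (n_i), `probs`
#'   (p_i, summing to 1), `L`, `N`, `bin_edges` (range and width used for
#'   quantisation) and the `mask`.
#' @export
build_histogram <- function(values, mask = NULL, levels = 256L) {
  if (!is.matrix(values)) .shape_error("'values' must be a matrix")
  L <- as.integer(levels)
  if (is.na(L) || L < 2L) .parameter_error("'levels' must be an integer >= 2")
  if (is.null(mask)) mask <- matrix(TRUE, nrow(values), ncol(values))
  if (!identical(dim(mask), dim(values)))
    .shape_error("'mask' must match the shape of 'values'")
  v <- values[mask]
  if (length(v) == 0L)
    .flowseg_error("flowseg_empty_selection_error",
                   "mask selects no pixels")
  if (!all(is.finite(v))) .input_error("masked values contain non-finite entries")

  lo <- min(v); hi <- max(v)
  lev <- .quantize(v, lo, hi, L)
  counts <- tabulate(lev + 1L, nbins = L)
  structure(
    list(counts = counts, probs = counts / length(v), L = L, N = length(v),
         bin_edges = list(min = lo, max = hi, L = L), mask = mask),
    class = "flow_histogram"
  )
}

# min-max scaling to integer levels 0..L-1, top edge inclusive
.quantize <- function(v, lo, hi, L) {
  if (hi <= lo) return(integer(length(v)))
  lev <- floor((v - lo) / (hi - lo) * L)
  lev[lev >= L] <- L - 1L
  lev[lev < 0L] <- 0L
  as.integer(lev)
}

#' Class occurrence probabilities and mean levels at a split
#'
#' For the split `C0 = {levels <= k}`, `C1 = {levels > k}` returns
#' `w0 = sum_{i<=k} p_i`, `w1 = 1 - w0`, and the class mean levels
#' `mu0`, `mu1`.  A class with zero probability has its mean flagged as
#' `NA` (never NaN).
#'
#' @param h A `flow_histogram`.
#' @param k Split level, 0-based, in `0 .. L-2`.
#' @return List `w0`, `w1`, `mu0`, `mu1`.
#' @export
class_statistics <- function(h, k) {
  stopifnot(inherits(h, "flow_histogram"))
  k <- as.integer(k)
  if (is.na(k) || k < 0L || k > h$L - 2L)
    .parameter_error("'k' must lie in 0 .. L-2")
  i <- 0:(h$L - 1L)
  lower <- i <= k
  w0 <- sum(h$probs[lower])
  w1 <- sum(h$probs[!lower])
  mu0 <- if (w0 > 0) sum(i[lower] * h$probs[lower]) / w0 else NA_real_
  mu1 <- if (w1 > 0) sum(i[!lower] * h$probs[!lower]) / w1 else NA_real_
  list(w0 = w0, w1 = w1, mu0 = mu0, mu1 = mu1)
}

#' Between-class variance at a split
#'
#' Computed from cumulative moments as
#' `(mu_T * w(k) - mu(k))^2 / (w(k) * (1 - w(k)))`; only defined on the
#' valid set `w(k) * (1 - w(k)) > 0`.
#'
#' @param h A `flow_histogram`.
#' @param k Split level, 0-based.
#' @return The between-class variance (squared levels).
#' @export
between_class_variance <- function(h, k) {
  stopifnot(inherits(h, "flow_histogram"))
  k <- as.integer(k)
  if (is.na(k) || k < 0L || k > h$L - 1L)
    .parameter_error("'k' must lie in 0 .. L-1")
  i <- 0:(h$L - 1L)
  w <- sum(h$probs[i <= k])
  mu <- sum(i[i <= k] * h$probs[i <= k])
  muT <- sum(i * h$probs)
  if (w * (1 - w) <= 0)
    .flowseg_error("flowseg_undefined_variance_error",
                   sprintf("split k = %d is outside the valid set", k))
  (muT * w - mu)^2 / (w * (1 - w))
}

#' Otsu threshold by sequential search over cumulative moments
#'
#' Builds the cumulative zeroth and first moments in a single pass and
#' scans k ascending for the maximiser of the between-class variance,
#' which for tied maxima yields the smallest k.  Identical by construction
#' to exhaustive per-k recomputation.
#'
#' @param h A `flow_histogram`.
#' @return Object of class `"otsu_threshold"`: `k_star` (0-based level),
#'   `sigma_b2_curve` (length L; `NA` outside the valid set), `valid_set`,
#'   and `w0`, `w1`, `mu0`, `mu1` at the chosen split.
#' @section Degenerate input: a histogram with a single occupied level has
#'   an empty valid set and raises a `flowseg_no_threshold_error`; the
#'   pipeline maps this to "no motion detected" (empty mask).
#' @export
otsu_threshold <- function(h) {
  stopifnot(inherits(h, "flow_histogram"))
  i <- 0:(h$L - 1L)
  w <- cumsum(h$probs)          # w(k), k = 0 .. L-1
  mu <- cumsum(i * h$probs)     # mu(k)
  muT <- mu[h$L]
  denom <- w * (1 - w)
  valid <- denom > 0
  if (!any(valid))
    .flowseg_error("flowseg_no_threshold_error",
                   "histogram occupies a single level; no threshold exists")
  sigma <- rep(NA_real_, h$L)
  sigma[valid] <- (muT * w[valid] - mu[valid])^2 / denom[valid]
  k_star <- i[valid][which.max(sigma[valid])]   # ascending scan: smallest k on ties
  cs <- class_statistics(h, k_star)
  structure(
    list(k_star = k_star, sigma_b2_curve = sigma, valid_set = i[valid],
         w0 = cs$w0, w1 = cs$w1, mu0 = cs$mu0, mu1 = cs$mu1,
         L = h$L),
    class = "otsu_threshold"
  )
}

#' @export
print.otsu_threshold <- function(x, ...) {
  cat(sprintf("otsu_threshold: k* = %d of L = %d levels\n", x$k_star, x$L))
  cat(sprintf("  sigma_B^2(k*) = %.4g; w0 = %.3f, w1 = %.3f\n",
              x$sigma_b2_curve[x$k_star + 1L], x$w0, x$w1))
  invisible(x)
}

#' Apply a threshold level to a scalar map
#'
#' Quantises `values` with the histogram's bin edges and returns the
#' moving-object class C1: TRUE exactly where the level exceeds `k_star`.
#' Pixels outside the histogram's mask are FALSE.
#'
#' @param values H x W numeric map (same scale as the histogram source).
#' @param h The `flow_histogram` defining the quantisation.
#' @param k_star Threshold level (0-based), e.g. from [otsu_threshold()].
#' @return Logical H x W mask.
#' @export
apply_threshold <- function(values, h, k_star) {
  stopifnot(inherits(h, "flow_histogram"))
  if (!identical(dim(values), dim(h$mask)))
    .shape_error("'values' must match the histogram's mask shape")
  lev <- matrix(.quantize(as.vector(values), h$bin_edges$min,
                          h$bin_edges$max, h$L),
                nrow(values), ncol(values))
  (lev > k_star) & h$mask
}
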