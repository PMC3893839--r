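# Histogram model and Otsu threshold selection.

test_that("histogram counts match a direct tally and probabilities sum to 1", {
  set.seed(31)
  v <- matrix(runif(128 * 128), 128, 128)
  h <- build_histogram(v, levels = 256)
  expect_identical(sum(h$counts), length(v))
  expect_equal(sum(h$probs), 1, tolerance = 1e-12)
  # direct per-pixel tally oracle of the min-max scaled-floor binning
  lo <- min(v); hi <- max(v)
  tally <- integer(256)
  for (x in as.vector(v)) {
    b <- min(floor((x - lo) / (hi - lo) * 256), 255)
    tally[b + 1L] <- tally[b + 1L] + 1L
  }
  expect_identical(h$counts, tally)
})

test_that("degenerate and masked histograms behave as specified", {
  const <- matrix(2.5, 10, 10)
  h <- build_histogram(const, levels = 16)
  expect_identical(h$counts[1L], 100L)
  expect_true(all(h$counts[-1L] == 0L))
  expect_equal(h$probs[1L], 1)
  expect_error(build_histogram(const, mask = matrix(FALSE, 10, 10)),
               class = "flowseg_empty_selection_error")
  expect_error(build_histogram(const, levels = 1),
               class = "flowseg_parameter_error")
  # the mask defines the quantisation range
  v <- matrix(c(rep(0, 50), rep(100, 25), rep(1, 25)), 10, 10)
  m <- v < 50
  h2 <- build_histogram(v, mask = m, levels = 4)
  expect_identical(h2$N, sum(m))
  expect_identical(h2$bin_edges$max, 1)
})

test_that("class statistics match the hand-computed four-level case", {
  h <- hist_from_counts(c(25, 25, 25, 25))
  cs <- class_statistics(h, 1L)
  expect_equal(cs$w0, 0.5)
  expect_equal(cs$w1, 0.5)
  expect_equal(cs$mu0, 0.5)
  expect_equal(cs$mu1, 2.5)
  # all mass at level 0, split at 0: empty C1 flagged, not NaN
  h0 <- hist_from_counts(c(100, 0, 0, 0))
  cs0 <- class_statistics(h0, 0L)
  expect_equal(cs0$w0, 1)
  expect_equal(cs0$w1, 0)
  expect_true(is.na(cs0$mu1) && !is.nan(cs0$mu1))
})

test_that("w0 + w1 = 1 and the total mean decomposes at every split", {
  set.seed(32)
  for (rep in 1:20) {
    p <- random_probs(16)
    h <- hist_from_counts(as.integer(round(p * 1000)) + 1L)
    muT <- sum((0:15) * h$probs)
    for (k in 0:14) {
      cs <- class_statistics(h, k)
      expect_equal(cs$w0 + cs$w1, 1, tolerance = 1e-12)
      if (cs$w0 > 0 && cs$w1 > 0)
        expect_equal(cs$w0 * cs$mu0 + cs$w1 * cs$mu1, muT, tolerance = 1e-10)
    }
  }
})

test_that("both algebraic forms of the between-class variance agree", {
  # two-point histogram: half the mass at a, half at b
  h <- hist_from_counts(c(0, 0, 50, 0, 0, 0, 50, 0))  # a = 2, b = 6
  for (k in 2:5)
    expect_equal(between_class_variance(h, k), 0.25 * (6 - 2)^2,
                 tolerance = 1e-12)
  set.seed(33)
  for (rep in 1:10) {
    h2 <- hist_from_counts(as.integer(round(random_probs(16) * 500)) + 1L)
    for (k in 0:14)
      expect_equal(between_class_variance(h2, k),
                   sigma_b2_class_form(h2$probs, k), tolerance = 1e-10)
  }
  # single occupied level: every split is outside the valid set
  h1 <- hist_from_counts(c(0, 80, 0, 0))
  expect_error(between_class_variance(h1, 1L),
               class = "flowseg_undefined_variance_error")
})

test_that("sequential search equals exhaustive recomputation", {
  # bimodal with a plateau of tied maxima: tie broken to the smallest k
  counts <- integer(16); counts[3L] <- 50L; counts[13L] <- 50L  # levels 2, 12
  h <- hist_from_counts(counts)
  th <- otsu_threshold(h)
  expect_identical(th$k_star, 2L)
  br <- otsu_brute(h$probs)
  expect_identical(th$k_star, br$k_star)
  expect_equal(th$sigma_b2_curve, br$curve, tolerance = 1e-14)
  expect_equal(th$sigma_b2_curve[th$k_star + 1L],
               max(th$sigma_b2_curve, na.rm = TRUE))
  expect_equal(th$w0 + th$w1, 1, tolerance = 1e-12)

  set.seed(34)
  for (rep in 1:50) {
    L <- sample(c(16L, 256L), 1L)
    hh <- hist_from_counts(as.integer(round(random_probs(L) * 5000)))
    res <- tryCatch(otsu_threshold(hh),
                    flowseg_no_threshold_error = function(e) NULL)
    bb <- otsu_brute(hh$probs)
    if (is.null(res)) {
      expect_true(is.na(bb$k_star) || sum(hh$probs > 0) <= 1L)
    } else {
      expect_identical(res$k_star, bb$k_star)
      expect_equal(res$sigma_b2_curve, bb$curve, tolerance = 1e-12)
    }
  }
})

test_that("two well-separated clusters are split between their supports", {
  set.seed(35)
  lev <- c(sample(0:40, 500, replace = TRUE), sample(200:255, 500, replace = TRUE))
  counts <- tabulate(lev + 1L, nbins = 256L)
  h <- hist_from_counts(counts)
  th <- otsu_threshold(h)
  expect_gte(th$k_star, 40L)
  expect_lt(th$k_star, 200L)
  expect_identical(th$k_star, otsu_brute(h$probs)$k_star)
})

test_that("constant input raises a no-threshold error", {
  h <- build_histogram(matrix(1, 8, 8), levels = 256)
  expect_error(otsu_threshold(h), class = "flowseg_no_threshold_error")
})

test_that("shifting the histogram support shifts k* and preserves the maximum", {
  set.seed(36)
  base <- as.integer(round(random_probs(16) * 800))
  h <- hist_from_counts(c(base, integer(16)))        # support 0..15 in L = 32
  hs <- hist_from_counts(c(integer(8), base, integer(8)))  # shifted by 8
  t0 <- otsu_threshold(h); t8 <- otsu_threshold(hs)
  expect_identical(t8$k_star, t0$k_star + 8L)
  expect_equal(max(t8$sigma_b2_curve, na.rm = TRUE),
               max(t0$sigma_b2_curve, na.rm = TRUE), tolerance = 1e-10)
})

test_that("applying a threshold reproduces the counting identity", {
  set.seed(37)
  v <- matrix(runif(32 * 32), 32, 32)
  h <- build_histogram(v, levels = 16)
  th <- otsu_threshold(h)
  mask <- apply_threshold(v, h, th$k_star)
  expect_identical(sum(mask), sum(h$counts[(th$k_star + 2L):16L]))
  # all levels <= k* -> empty mask
  expect_true(all(!apply_threshold(v, h, 15L)))
  # bimodal toy: mask is exactly the high cluster
  vv <- matrix(c(rep(0.1, 50), rep(0.9, 50)), 10, 10)
  hh <- build_histogram(vv, levels = 16)
  tt <- otsu_threshold(hh)
  expect_identical(unname(apply_threshold(vv, hh, tt$k_star)), vv == 0.9)
})
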