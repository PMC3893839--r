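# Lucas-Kanade normal equations and the per-pixel 2x2 solve.

test_that("normal-equation entries match brute-force window sums", {
  ph <- phantom_sequence("translating-texture", shape = c(64, 64),
                         frames = 3, velocity = c(0.5, -0.5), seed = 5)
  d <- compute_derivatives(ph$sequence)
  ne <- accumulate_normal_equations(d, 2L, window = 5L)
  Ix <- d$Ix[, , 2L]; Iy <- d$Iy[, , 2L]; It <- d$It[, , 2L]
  set.seed(6)
  pts <- cbind(sample(64, 10), sample(64, 10))
  for (p in seq_len(nrow(pts))) {
    i <- pts[p, 1L]; j <- pts[p, 2L]
    expect_equal(ne$Sxx[i, j], brute_window_sum(Ix * Ix, i, j, 5L),
                 tolerance = 1e-10)
    expect_equal(ne$Sxy[i, j], brute_window_sum(Ix * Iy, i, j, 5L),
                 tolerance = 1e-10)
    expect_equal(ne$Bx[i, j], -brute_window_sum(Ix * It, i, j, 5L),
                 tolerance = 1e-10)
    expect_equal(ne$By[i, j], -brute_window_sum(Iy * It, i, j, 5L),
                 tolerance = 1e-10)
  }
  expect_error(accumulate_normal_equations(d, 2L, window = 4L),
               class = "flowseg_parameter_error")
})

test_that("structural zeros and positive semidefiniteness hold", {
  # zero derivatives -> all entries zero
  zd <- structure(list(
    Ix = array(0, c(8, 8, 2)), Iy = array(0, c(8, 8, 2)),
    It = array(0, c(8, 8, 2)),
    border_mask = matrix(FALSE, 8, 8),
    params = list(border = "reflect", dim = c(8L, 8L, 2L),
                  intensity_range = 1)), class = "derivative_volumes")
  ne0 <- accumulate_normal_equations(zd, 1L, 3L)
  expect_true(all(ne0$Sxx == 0) && all(ne0$Bx == 0) && all(ne0$By == 0))

  # Iy == 0 -> Sxy = Syy = By = 0
  set.seed(7)
  zd$Ix <- array(rnorm(128), c(8, 8, 2))
  ne1 <- accumulate_normal_equations(zd, 1L, 3L)
  expect_true(all(ne1$Sxy == 0) && all(ne1$Syy == 0) && all(ne1$By == 0))

  # PSD on a real phantom
  ph <- phantom_sequence("moving-blob", shape = c(48, 48), frames = 3,
                         velocity = c(1, 0), seed = 8)
  ne <- accumulate_normal_equations(compute_derivatives(ph$sequence), 2L, 7L)
  expect_true(all(ne$Sxx >= 0))
  expect_true(all(ne$Syy >= 0))
  expect_true(all(ne$Sxx * ne$Syy - ne$Sxy^2 >= -1e-10))
})

test_that("identity normal equations return the right-hand side", {
  one <- matrix(1, 4, 4); zero <- matrix(0, 4, 4)
  ne <- structure(list(
    Sxx = one, Sxy = zero, Syy = one,
    Bx = matrix(0.3, 4, 4), By = matrix(-0.2, 4, 4),
    window = 3L, frame_index = 1L, intensity_range = 1,
    border_mask = matrix(FALSE, 4, 4)), class = "normal_equations")
  fl <- solve_flow(ne, tau = 1e-3)
  expect_true(all(fl$valid))
  expect_equal(fl$u, matrix(0.3, 4, 4))
  expect_equal(fl$v, matrix(-0.2, 4, 4))
})

test_that("closed-form 2x2 solve agrees with a general linear solver", {
  ph <- phantom_sequence("translating-texture", shape = c(32, 32),
                         frames = 3, velocity = c(0.8, 0.4), seed = 9)
  ne <- accumulate_normal_equations(compute_derivatives(ph$sequence), 2L, 5L)
  fl <- solve_flow(ne)
  idx <- which(fl$valid)[seq(1, sum(fl$valid), length.out = 25)]
  for (p in idx) {
    A <- matrix(c(ne$Sxx[p], ne$Sxy[p], ne$Sxy[p], ne$Syy[p]), 2, 2)
    uv <- solve(A, c(ne$Bx[p], ne$By[p]))
    expect_equal(c(fl$u[p], fl$v[p]), uv, tolerance = 1e-12)
  }
  expect_true(all(fl$lambda_min >= -1e-10))
  expect_true(all(fl$u[!fl$valid] == 0) && all(fl$v[!fl$valid] == 0))
})

test_that("a static sequence yields exactly zero flow at valid pixels", {
  ph <- phantom_sequence("static", shape = c(32, 32), frames = 4, seed = 10)
  fl <- optical_flow(ph$sequence)
  expect_gt(mean(fl$valid), 0.5)       # texture keeps the system conditioned
  expect_identical(max(abs(fl$u)), 0)  # B == 0 => exact zero everywhere
  expect_identical(max(abs(fl$v)), 0)
})

test_that("sub-pixel global translations are recovered to < 0.1 px/frame", {
  cases <- list(c(0.5, -0.25), c(-0.75, 0.3), c(0.25, 0.9))
  for (vel in cases) {
    ph <- phantom_sequence("translating-texture", shape = c(64, 64),
                           frames = 3, velocity = vel, seed = 21)
    fl <- optical_flow(ph$sequence, frame_index = 2L, window = 7L)
    sel <- fl$valid & !fl$border_mask
    expect_gt(sum(sel), 1000)
    expect_lt(median(abs(fl$u[sel] - vel[1L])), 0.1)
    expect_lt(median(abs(fl$v[sel] - vel[2L])), 0.1)
  }
})

test_that("rotating the frames rotates the recovered flow", {
  ph <- phantom_sequence("translating-texture", shape = c(48, 48),
                         frames = 3, velocity = c(0.6, 0.2), seed = 22)
  fl <- optical_flow(ph$sequence, 2L, 7L)
  rot_frames <- array(0, dim(ph$sequence$frames)[c(2, 1, 3)])
  for (t in 1:3) rot_frames[, , t] <- rot_cw(ph$sequence$frames[, , t])
  fl_rot <- optical_flow(image_sequence(rot_frames), 2L, 7L)
  # clockwise rotation maps (u, v) -> (-v, u)
  sel <- fl$valid & !fl$border_mask
  sel_rot <- rot_cw(sel)
  expect_equal(median(fl_rot$u[sel_rot]), median(-fl$v[sel]), tolerance = 0.02)
  expect_equal(median(fl_rot$v[sel_rot]), median(fl$u[sel]), tolerance = 0.02)
})

test_that("a translating grating is flagged aperture-degenerate", {
  ph <- phantom_sequence("grating", shape = c(64, 64), frames = 3,
                         velocity = c(1, 0), seed = 23)
  fl <- optical_flow(ph$sequence)
  interior <- !fl$border_mask
  expect_gte(mean(!fl$valid[interior]), 0.95)
  mag <- flow_magnitude(fl)
  expect_true(all(mag[fl$valid] < 2.5))  # no spurious large flows
})

test_that("flow magnitude matches the element-wise definition", {
  fl <- structure(list(u = matrix(3, 2, 2), v = matrix(-4, 2, 2),
                       valid = matrix(TRUE, 2, 2)), class = "flow_field")
  expect_equal(flow_magnitude(fl), matrix(5, 2, 2))
  set.seed(24)
  u <- matrix(rnorm(30), 5, 6); v <- matrix(rnorm(30), 5, 6)
  fl2 <- structure(list(u = u, v = v, valid = matrix(TRUE, 5, 6)),
                   class = "flow_field")
  oracle <- matrix(0, 5, 6)
  for (i in 1:5) for (j in 1:6) oracle[i, j] <- sqrt(u[i, j]^2 + v[i, j]^2)
  expect_equal(flow_magnitude(fl2), oracle)
  # invalid pixels carry zero flow, hence zero magnitude
  ph <- phantom_sequence("grating", shape = c(32, 32), frames = 2,
                         velocity = c(1, 0), seed = 25)
  fl3 <- optical_flow(ph$sequence, frame_index = 1L)
  expect_true(all(flow_magnitude(fl3)[!fl3$valid] == 0))
})

test_that("solving is deterministic", {
  ph <- phantom_sequence("moving-blob", shape = c(48, 48), frames = 3,
                         velocity = c(1, 1), seed = 26)
  f1 <- optical_flow(ph$sequence)
  f2 <- optical_flow(ph$sequence)
  expect_identical(f1$u, f2$u)
  expect_identical(f1$v, f2$v)
  expect_identical(f1$valid, f2$valid)
})
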