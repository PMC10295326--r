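test_that("IsoData matches its closed forms and the brute-force fixed point", {
  # equal mass at 0 and 255 only: symmetric fixed point
  x <- array(rep(c(0, 255), each = 10), c(20, 1, 1))
  expect_equal(isodata_threshold(x), 127.5)
  # mass at {50, 200} with 3:1 ratio
  x2 <- c(rep(50, 30), rep(200, 10))
  fp <- oracle_isodata_fixed_points(x2)
  expect_true(isodata_threshold(array(x2, c(40, 1, 1))) %in% fp)
  expect_error(isodata_threshold(array(7, c(5, 1, 1))), "degenerate")
})

test_that("IsoData equals a brute-force intermeans fixed point on random histograms", {
  set.seed(11)
  for (rep in 1:25) {
    n <- sample(50:400, 1)
    v <- round(pmin(pmax(c(rnorm(n, 60, 25), rnorm(n, 190, 30)), 0), 255))
    if (min(v) == max(v)) next
    t_impl <- isodata_threshold(array(v, c(length(v), 1, 1)))
    fps <- oracle_isodata_fixed_points(v)
    expect_gt(length(fps), 0)
    expect_true(min(abs(t_impl - fps)) < 1e-9)
  }
})

test_that("VOI rasterization matches geometry", {
  grid <- voxel_volume(array(0, c(40, 100, 100)), c(0.05, 0.05, 0.05))
  ctr <- dim(grid$data) * grid$voxel_size / 2
  # cylinder larger than the grid covers every voxel
  big <- cylindrical_voi(ctr, diameter_mm = 50, height_mm = 50)
  expect_true(all(voxelize_voi(big, grid)))
  # count within 1% of pi r^2 h / voxel volume
  voi <- cylindrical_voi(ctr, diameter_mm = 4, height_mm = 1.5)
  n <- sum(voxelize_voi(voi, grid))
  analytic <- pi * 2^2 * 1.5 / prod(grid$voxel_size)
  expect_lt(abs(n - analytic) / analytic, 0.01)
  # hand enumeration: 2 mm x 2 mm cylinder on a 1 mm grid -> 8 voxels
  g1 <- voxel_volume(array(0, c(4, 4, 4)), c(1, 1, 1))
  v1 <- cylindrical_voi(c(2, 2, 2), diameter_mm = 2, height_mm = 2)
  expect_equal(sum(voxelize_voi(v1, g1)), 8)
  far <- cylindrical_voi(c(100, 100, 100), 2, 2)
  expect_error(voxelize_voi(far, g1), "intersect")
})

test_that("VOI placement follows the anterior-tangent construction", {
  # circular body mask, radius 30 mm, centred; 0.5 mm pixels
  n <- 140L
  vs <- 0.5
  ys <- (seq_len(n) - 0.5) * vs
  circ <- outer((ys - 35)^2, (ys - 35)^2, `+`) <= 30^2
  body <- voxel_volume(array(rep(as.numeric(circ), each = 36),
                             c(36, n, n)), c(vs, vs, vs), binary = TRUE)
  vois <- position_voi_from_body_mask(body)
  # anterior pole at y = 5; tangent point P at 10; centre 7.5 further in
  expect_equal(vois$superior$center[2], 17.5, tolerance = vs)
  expect_equal(vois$superior$center[3], 35, tolerance = vs)
  zmid <- 36 * vs / 2
  expect_equal(vois$superior$center[1], zmid + 5, tolerance = 1e-6)
  expect_equal(vois$inferior$center[1], zmid - 5, tolerance = 1e-6)
  expect_false(vois$superior$clipped)

  # ellipse with semi-axes (25, 32): same analytic construction
  ell <- outer(((ys - 35) / 25)^2, ((ys - 35) / 32)^2, `+`) <= 1
  bodye <- voxel_volume(array(rep(as.numeric(ell), each = 36),
                              c(36, n, n)), c(vs, vs, vs), binary = TRUE)
  ve <- position_voi_from_body_mask(bodye)
  expect_equal(ve$superior$center[2], (35 - 25) + 5 + 7.5, tolerance = vs)

  # mask smaller than the VOI: clipped flag raised
  small <- outer((ys - 35)^2, (ys - 35)^2, `+`) <= 6^2
  bodys <- voxel_volume(array(rep(as.numeric(small), each = 36),
                              c(36, n, n)), c(vs, vs, vs), binary = TRUE)
  ws <- capture_warnings(vs2 <- position_voi_from_body_mask(bodys))
  expect_match(ws, "clipped", all = FALSE)
  expect_true(vs2$superior$clipped)
})

test_that("BV/TV is exact voxel counting, invariant to monotone remaps", {
  b <- array(0, c(4, 4, 4))
  b[, 1:2, ] <- 1
  expect_equal(bvtv(b), 0.5)
  expect_equal(bvtv(array(1, c(3, 3, 3))), 1)
  expect_equal(bvtv(array(0, c(3, 3, 3))), 0)
  # monotone intensity remap preserving threshold sides leaves BV/TV fixed
  img <- array(c(40, 60, 190, 210), c(4, 1, 1))
  t1 <- isodata_threshold(img)
  remap <- img^1.3 / 255^0.3
  expect_equal(sum(img > t1), sum(remap > isodata_threshold(remap)))
})

test_that("measure_stack composes thresholding, counting and thickness", {
  sp <- tiny_spec(seed = 21)
  sp$noise_sd[["micro"]] <- 0
  gt <- generate_trabecular_volume(sp)
  mic <- render_micro_ct(gt, sp)
  ctr <- dim(mic$data) * mic$voxel_size / 2
  voi <- cylindrical_voi(ctr, diameter_mm = 4, height_mm = 1.6)
  res <- measure_stack(mic, voi)
  expect_s3_class(res, "morphometry_result")
  expect_equal(res$bvtv, res$n_foreground / res$n_total)
  expect_gt(res$tbth_mm, 0)
  expect_gt(res$tbsp_mm, 0)
  expect_true(res$threshold_used > 50 && res$threshold_used < 200)
  # a fixed numeric threshold is honoured
  res2 <- measure_stack(mic, voi, threshold = res$threshold_used)
  expect_equal(res2$bvtv, res$bvtv)
})
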