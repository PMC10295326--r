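test_that("quantile thresholding pins BV/TV exactly, even for an iid field", {
  sp <- tiny_spec(seed = 4, structured = FALSE, target_bvtv = 0.5)
  gt <- generate_trabecular_volume(sp)
  n_canc <- sum(gt$cancellous_mask$data)
  expect_lte(abs(gt$bvtv_true - 0.5), 1 / n_canc)
  # structured field too
  sp2 <- tiny_spec(seed = 4)
  gt2 <- generate_trabecular_volume(sp2)
  expect_lte(abs(gt2$bvtv_true - sp2$target_bvtv),
             1 / sum(gt2$cancellous_mask$data))
})

test_that("identical seed and spec give bit-identical phantoms", {
  sp <- tiny_spec(seed = 8)
  g1 <- generate_trabecular_volume(sp)
  g2 <- generate_trabecular_volume(sp)
  expect_identical(g1$binary$data, g2$binary$data)
  expect_identical(render_micro_ct(g1, sp)$data, render_micro_ct(g2, sp)$data)
  g3 <- generate_trabecular_volume(tiny_spec(seed = 9))
  expect_false(identical(g1$binary$data, g3$binary$data))
})

test_that("thickness calibration realises the Tb.Th target on the 52 um grid", {
  sp <- phantom_spec(extent_mm = c(3, 6, 6), seed = 2)  # default 52 um voxels
  gt <- generate_trabecular_volume(sp)
  expect_lt(abs(gt$tbth_true_mm / sp$target_tbth_mm - 1), 0.2)
  expect_equal(gt$computed_by, "oracle")
})

test_that("infeasible Tb.Th below the two-voxel limit is refused by name", {
  expect_error(phantom_spec(voxel_mm = 0.2, target_tbth_mm = 0.218),
               "resolution limit")
})

test_that("noise-free, PSF-free rendering is a two-level relabeling", {
  sp <- tiny_spec(seed = 6, noise_sd = c(micro = 0, mdct = 0),
                  psf_micro_vox = 0)
  gt <- generate_trabecular_volume(sp)
  mic <- render_micro_ct(gt, sp)
  iv <- sp$intensities
  inside <- gt$body_mask$data > 0
  expect_true(all(mic$data[inside] %in% c(iv[["marrow"]], iv[["bone"]])))
  # IsoData re-binarization recovers the ground truth exactly inside the body
  thr <- isodata_threshold(mic$data, inside)
  expect_identical(array(as.numeric(mic$data > thr), dim = dim(mic$data))[inside],
                   gt$binary$data[inside])
})

test_that("noisy rendering still recovers BV/TV within 2% absolute", {
  sp <- tiny_spec(seed = 13, noise_sd = c(micro = 10, mdct = 4))
  gt <- generate_trabecular_volume(sp)
  mic <- render_micro_ct(gt, sp)
  canc <- gt$cancellous_mask$data > 0
  thr <- isodata_threshold(mic$data, canc)
  bv <- bvtv(array(as.numeric(mic$data > thr), dim = dim(mic$data)), canc)
  expect_lt(abs(bv - gt$bvtv_true), 0.02)
})

test_that("MDCT rendering halves the slice count and preserves body mean", {
  sp <- tiny_spec(seed = 3)
  gt <- generate_trabecular_volume(sp)
  mic <- render_micro_ct(gt, sp)
  md <- render_mdct(gt, sp)
  expect_equal(dim(md$data)[1], ceiling(dim(mic$data)[1] / 2))
  expect_error(render_mdct(gt, {
    s <- sp
    s$mdct_pixel_mm <- 0.01
    s
  }), "finer")
  # blurring conserves the mean intensity away from boundaries: average over
  # the body interior eroded beyond the PSF's reach
  img <- trabeculagen:::.intensity_field(gt, sp)
  sig <- c(0.6, 0.4, 0.4) / (2 * sqrt(2 * log(2))) / gt$binary$voxel_size
  blur <- trabeculagen:::gaussian_blur_vox(img, sig)
  b <- gt$body_mask$data > 0
  d2 <- trabeculagen:::.edt3d_sq(as.numeric(b), dim(b),
                                 gt$body_mask$voxel_size)
  inner <- b & sqrt(array(d2, dim(b))) > sp$cortical_thickness_mm + 0.8
  m0 <- mean(img[inner])
  m1 <- mean(blur[inner])
  expect_lt(abs(m1 - m0) / m0, 0.01)
})

test_that("study sets are deterministic, jittered and correctly sized", {
  st <- make_study_set(3, tiny_spec(), seed = 5)
  expect_length(st, 3)
  expect_equal(dim(st[[1]]$micro$data)[1], 24)          # as configured
  expect_equal(dim(st[[1]]$mdct$data)[1], 12)           # 2:1 slice ratio
  st2 <- make_study_set(3, tiny_spec(), seed = 5)
  expect_identical(st[[2]]$gt$binary$data, st2[[2]]$gt$binary$data)
  st3 <- make_study_set(3, tiny_spec(), seed = 6)
  expect_false(identical(st[[1]]$gt$binary$data, st3[[1]]$gt$binary$data))
  # distinct vertebrae differ
  expect_false(identical(st[[1]]$gt$binary$data, st[[2]]$gt$binary$data))
  # targets jittered around the template
  bvs <- vapply(st, function(r) r$spec$target_bvtv, numeric(1))
  expect_gt(stats::sd(bvs), 0)
})

test_that("phantom sidecars carry spec, seed and ground truth", {
  st <- make_study_set(1, tiny_spec(), seed = 2)
  d <- file.path(tempdir(), "phantom_out")
  p <- write_phantom(st[[1]], d)
  side <- jsonlite::read_json(p)
  expect_equal(side$ground_truth$bvtv_true, st[[1]]$gt$bvtv_true)
  expect_equal(side$spec$seed, st[[1]]$spec$seed)
  expect_true(file.exists(file.path(d, "vertebra_001_micro.tif")))
  unlink(d, recursive = TRUE)
})
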