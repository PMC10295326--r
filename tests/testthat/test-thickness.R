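# Local thickness against the exhaustive largest-inscribed-sphere oracle.

test_that("slab thickness equals the slab width at interior voxels", {
  b <- make_slab(c(14, 20, 14), axis = 2L, from = 9L, to = 11L)
  th <- local_thickness_map(voxel_volume(b, c(1, 1, 1), binary = TRUE))
  # interior: away from the open ends of the slab
  expect_equal(unique(as.numeric(th$data[5:10, 9:11, 5:10])), 3)
})

test_that("an isolated voxel has one-voxel thickness", {
  b <- array(0, c(5, 5, 5))
  b[3, 3, 3] <- 1
  th <- local_thickness_map(voxel_volume(b, c(1, 1, 1), binary = TRUE))
  expect_equal(th$data[3, 3, 3], 1)
  expect_equal(sum(th$data), 1)
})

test_that("thickness map matches the brute-force sphere oracle on fixtures", {
  fixtures <- list(
    slab = make_slab(c(12, 18, 12), axis = 2L, from = 8L, to = 10L),
    ball = make_ball(14L, 4.5),
    two_slab = {
      b <- make_slab(c(12, 20, 12), axis = 2L, from = 4L, to = 6L)
      b[, 12:16, ] <- 1
      b
    }
  )
  for (nm in names(fixtures)) {
    b <- fixtures[[nm]]
    th <- local_thickness_map(voxel_volume(b, c(1, 1, 1), binary = TRUE))
    oracle <- oracle_local_thickness(b)
    err <- abs(th$data - oracle)[b != 0]
    expect_lt(mean(err), 1, label = paste("mean |impl - oracle| for", nm))
    # and the maxima agree closely
    expect_equal(max(th$data), max(oracle), tolerance = 1e-8)
  }
})

test_that("squared EDT equals brute force on random binary volumes", {
  set.seed(5)
  for (rep in 1:3) {
    b <- array(rbinom(10 * 9 * 8, 1, 0.6), c(10, 9, 8))
    b[1, 1, 1] <- 0  # guarantee background
    d2 <- trabeculagen:::.edt3d_sq(as.numeric(b), dim(b), c(1, 1, 1))
    bg <- which(b == 0, arr.ind = TRUE)
    fg_idx <- which(b != 0)
    fg <- which(b != 0, arr.ind = TRUE)
    brute <- vapply(seq_len(nrow(fg)), function(i) {
      min(rowSums(sweep(bg, 2L, fg[i, ])^2))
    }, numeric(1))
    expect_equal(as.numeric(d2[fg_idx]), brute, tolerance = 1e-9)
  }
})

test_that("Tb.Th / Tb.Sp respect slab geometry and complement duality", {
  # alternating slabs: bone 3 voxels, gap 5 voxels, interior region only
  b <- array(0, c(16, 24, 16))
  for (y in 1:24) if (((y - 1) %% 8) < 3) b[, y, ] <- 1
  mask <- array(FALSE, c(16, 24, 16))
  mask[5:12, 9:16, 5:12] <- TRUE  # one full interior period
  v <- voxel_volume(b, c(1, 1, 1), binary = TRUE)
  tt <- tbth_tbsp(v, mask)
  expect_equal(tt$tbth_mm, 3, tolerance = 1e-8)
  expect_equal(tt$tbsp_mm, 5, tolerance = 1e-8)
  # complement duality on the same mask
  inv <- voxel_volume(1 - b, c(1, 1, 1), binary = TRUE)
  td <- tbth_tbsp(inv, mask)
  expect_equal(td$tbth_mm, tt$tbsp_mm)
  expect_equal(td$tbsp_mm, tt$tbth_mm)
})

test_that("anisotropic grids are refused with a resampling hint", {
  b <- array(1, c(4, 4, 4))
  b[1, 1, 1] <- 0
  v <- voxel_volume(b, c(0.6, 0.2, 0.2), binary = TRUE)
  expect_error(local_thickness_map(v), "isotropic")
})
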