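test_that("SSIM identities, symmetry and the constant-image closed form", {
  set.seed(2)
  a <- matrix(runif(24 * 24, 0, 255), 24, 24)
  b <- matrix(runif(24 * 24, 0, 255), 24, 24)
  expect_equal(ssim(a, a), 1)
  expect_equal(ssim(a, b), ssim(b, a))
  # constant images: structure and contrast terms are exactly 1
  ca <- matrix(100, 16, 16)
  cb <- matrix(180, 16, 16)
  C1 <- (0.01 * 255)^2
  expect_equal(ssim(ca, cb),
               (2 * 100 * 180 + C1) / (100^2 + 180^2 + C1), tolerance = 1e-12)
  expect_error(ssim(a, matrix(0, 10, 10)), "shape")
})

test_that("SSIM equals a direct windowed recomputation on a 16x16 pair", {
  set.seed(8)
  a <- matrix(runif(256, 0, 255), 16, 16)
  b <- a + matrix(rnorm(256, 0, 20), 16, 16)
  expect_equal(ssim(a, b), oracle_ssim(a, b), tolerance = 1e-12)
})

test_that("the feature embedder is deterministic and separates classes", {
  set.seed(4)
  sharp <- lapply(1:8, function(i) matrix(sample(c(30, 220), 1024,
                                                 replace = TRUE), 32, 32))
  smooth <- lapply(1:8, function(i) {
    trabeculagen:::blur2d(matrix(runif(1024, 0, 255), 32, 32), 3)
  })
  e1 <- embed_images(sharp)
  e2 <- embed_images(sharp)
  expect_identical(e1, e2)
  expect_identical(e1[1, ], e1[1, ])
  # identical images map to identical vectors
  ei <- embed_images(list(sharp[[1]], sharp[[1]]))
  expect_equal(ei[1, ], ei[2, ])
  # silhouette of the two texture classes is positive
  all_f <- rbind(embed_images(sharp), embed_images(smooth))
  lab <- rep(1:2, each = 8)
  dmat <- as.matrix(dist(all_f))
  sil <- vapply(seq_len(16), function(i) {
    a <- mean(dmat[i, lab == lab[i]][-which(which(lab == lab[i]) == i)])
    b <- mean(dmat[i, lab != lab[i]])
    (b - a) / max(a, b)
  }, numeric(1))
  expect_gt(mean(sil), 0)
})

test_that("Frechet feature distance identities and closed form", {
  set.seed(6)
  fa <- matrix(rnorm(40 * 6), 40, 6)
  expect_lt(fid(fa, fa), 1e-6)
  fb <- matrix(rnorm(40 * 6, 1), 40, 6)
  expect_lt(abs(fid(fa, fb) - fid(fb, fa)), 1e-8)
  expect_gte(fid(fa, fb), 0)
  # 1-D sets with sample moments (0,1) and (1,1): distance exactly 1
  s <- sqrt(0.5)
  one_a <- matrix(c(-s, s), 2, 1)
  one_b <- one_a + 1
  expect_equal(fid(one_a, one_b), 1, tolerance = 1e-9)
  # matches an independent eigendecomposition recomputation
  expect_equal(fid(fa, fb), oracle_fid(fa, fb), tolerance = 1e-8)
  expect_error(fid(fa, matrix(rnorm(10), 5, 2)), "dimensions")
})

test_that("cancellous cropping erodes exactly by the requested radius", {
  sp <- tiny_spec(seed = 2)
  gt <- generate_trabecular_volume(sp)
  mic <- render_micro_ct(gt, sp)
  cr <- cancellous_crop(mic, gt$body_mask, sp$cortical_thickness_mm, 0)
  expect_true(all(dim(cr$volume$data) <= dim(mic$data)))
  expect_true(any(cr$mask))
  # erosion by r removes exactly the voxels within r of the boundary
  b <- gt$body_mask$data > 0
  d2 <- trabeculagen:::.edt3d_sq(as.numeric(b), dim(b),
                                 gt$body_mask$voxel_size)
  expect_identical(sum(cr$mask),
                   sum(b & sqrt(d2) > sp$cortical_thickness_mm))
  # idempotence at the same margin
  body2 <- voxel_volume(array(as.numeric(cr$mask), dim = dim(cr$mask)),
                        mic$voxel_size, binary = TRUE)
  cr2 <- cancellous_crop(cr$volume, body2, 0, 0)
  expect_equal(dim(cr2$volume$data), dim(cr$volume$data))
  expect_error(cancellous_crop(mic, gt$body_mask, 50, 0), "empty")
})

test_that("method comparison reproduces hand-computed rank statistics", {
  # identical groups: Friedman statistic is 0
  g <- list(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4), c = c(1, 2, 3, 4))
  rep0 <- compare_methods(g)
  expect_equal(rep0$statistic[rep0$test == "friedman"], 0)
  # two disjoint-support groups, n = 3 vs 3: U = 0
  rep2 <- compare_methods(list(lo = c(1, 2, 3), hi = c(10, 11, 12)),
                          paired = FALSE)
  expect_equal(rep2$statistic[rep2$test == "mann_whitney_u"], 0)
  # fixed 4-row, 3-method table: Friedman from hand-computed ranks
  tab <- list(m1 = c(1, 2, 1, 3), m2 = c(5, 6, 7, 4), m3 = c(9, 8, 9, 9))
  # within-row ranks are always (1, 2, 3): chi2 = 12n/(k(k+1)) * sum(Rbar - (k+1)/2)^2
  hand <- 12 * 4 / (3 * 4) * sum((c(1, 2, 3) - 2)^2)
  rep3 <- compare_methods(tab)
  expect_equal(unname(rep3$statistic[rep3$test == "friedman"]), hand)
  # paired t on two groups appears with its stats::t.test value
  repp <- compare_methods(list(a = c(1, 2, 3, 4, 6), b = c(2, 2, 4, 5, 6)))
  tt <- t.test(c(1, 2, 3, 4, 6), c(2, 2, 4, 5, 6), paired = TRUE)
  expect_equal(unname(repp$statistic[repp$test == "paired_t"]),
               unname(tt$statistic))
})

test_that("OLS metrics regression matches the normal equations", {
  x <- c(0, 1, 2, 3)
  y <- c(1, 3, 4, 8)
  r <- regress_metrics(x, y)
  # hand-computed normal equations
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  r2 <- sxy^2 / (sxx * sum((y - mean(y))^2))
  expect_equal(r$slope, slope)
  expect_equal(r$intercept, intercept)
  expect_equal(r$r_squared, r2)
  expect_equal(r$f_value, r2 * 2 / (1 - r2))
  # y = x exactly
  rp <- regress_metrics(1:5, 1:5)
  expect_equal(rp$slope, 1)
  expect_equal(rp$r_squared, 1)
  # orthogonal noise: R^2 near zero
  set.seed(3)
  rn <- regress_metrics(1:200, rnorm(200))
  expect_lt(rn$r_squared, 0.05)
  expect_error(regress_metrics(rep(1, 5), 1:5), "variance")
})

test_that("Fisher z comparison of correlations is exact and antisymmetric", {
  r0 <- compare_correlations(0.6, 30, 0.6, 40)
  expect_equal(r0$z, 0)
  expect_equal(r0$p_value, 1)
  # plug-in arithmetic for r1=0.8 (n=50) vs r2=0.5 (n=50)
  zhand <- (atanh(0.8) - atanh(0.5)) / sqrt(1 / 47 + 1 / 47)
  r1 <- compare_correlations(0.8, 50, 0.5, 50)
  expect_equal(r1$z, zhand)
  expect_equal(r1$p_value, 2 * pnorm(-abs(zhand)))
  r2 <- compare_correlations(0.5, 50, 0.8, 50)
  expect_equal(r2$z, -r1$z)
  expect_error(compare_correlations(1, 10, 0.5, 10), "< 1")
})

test_that("ICC(2,1) matches ANOVA variance components and its identities", {
  m <- cbind(c(9, 6, 8, 7, 10, 6), c(2, 1, 4, 1, 5, 2))
  r <- icc(m)
  # independent route: mean squares from aov()
  df <- data.frame(y = c(m), subj = factor(rep(1:6, 2)),
                   rater = factor(rep(1:2, each = 6)))
  ms <- summary(stats::aov(y ~ subj + rater, df))[[1]][["Mean Sq"]]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  k <- 2; n <- 6
  hand <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
  expect_equal(r$icc, hand, tolerance = 1e-12)
  expect_true(r$lower <= r$icc && r$icc <= r$upper)
  # identical columns: perfect agreement
  ri <- icc(cbind(1:8, 1:8))
  expect_equal(ri$icc, 1)
  # independent noise: near zero at n = 100
  set.seed(12)
  rn <- icc(cbind(rnorm(100), rnorm(100)))
  expect_lt(abs(rn$icc), 0.2)
  expect_error(icc(cbind(rep(3, 6), rep(3, 6))), "variance")
  expect_error(icc(cbind(1:3, 3:1)), "at least 5")
})

test_that("full_report writes metrics, stats and a labelled summary", {
  d <- file.path(tempdir(), "report_test")
  set.seed(9)
  out <- full_report(
    ssim_by_method = list(gen = runif(6, 0.5, 0.9), up = runif(6, 0.2, 0.5)),
    fid_by_method = c(gen = 1.2, up = 4.5),
    morphometry = data.frame(id = 1:2, method = "gen",
                             bvtv = c(0.18, 0.19), tbth_mm = c(0.2, 0.21),
                             tbsp_mm = c(0.9, 0.8)),
    out_dir = d, scope = "overall")
  expect_true(all(file.exists(unlist(out))))
  expect_match(paste(readLines(out$summary), collapse = " "),
               "seed-frozen random convolutional")
  expect_error(full_report(list(), c(), NULL, d), "empty")
  unlink(d, recursive = TRUE)
})
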