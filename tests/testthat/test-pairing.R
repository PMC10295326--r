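test_that("an image matched against itself has zero keypoint distance", {
  img <- make_texture(96)[17:80, 17:80]
  m <- detect_and_match(img, img)
  expect_gt(m$n_matches, 3)
  expect_false(m$unmatched)
  expect_equal(m$a_coords, m$b_coords)
  expect_equal(image_distance(img, img), 0)
})

test_that("a pure translation is recovered by the matched keypoints", {
  big <- make_texture(160)
  a <- big[17:144, 17:144]
  b <- big[17:144, 12:139]  # content shifted 5 px in x
  m <- detect_and_match(a, b)
  expect_gt(m$n_matches, 10)
  off <- m$b_coords - m$a_coords
  expect_equal(as.numeric(apply(off, 2, stats::median)), c(0, 5))
  d <- image_distance(a, b)
  expect_lt(abs(d - 5), 1)
  # near-symmetry of the distance under argument swap
  expect_lt(abs(d - image_distance(b, a)), 1)
})

test_that("featureless noise yields the unmatched sentinel", {
  set.seed(3)
  a <- make_texture(96)[17:80, 17:80]
  noise <- matrix(runif(64 * 64, 0, 255), 64, 64)
  expect_true(is.na(image_distance(a, noise)))
  dm <- build_distance_matrix(list(a, a), list(a, noise))
  expect_equal(dim(dm), c(2L, 2L))
  expect_equal(dm[1, 1], 0)
  # sentinel = max finite + 1
  expect_equal(dm[1, 2], max(dm[, 1]) + 1)
})

test_that("DTW equals exhaustive path enumeration on random small matrices", {
  set.seed(42)
  for (rep in 1:200) {
    n <- sample(2:6, 1)
    k <- sample(2:6, 1)
    m <- matrix(runif(n * k), n, k)
    al <- dtw_align(m)
    expect_equal(al$cost, oracle_dtw_cost(m), tolerance = 1e-12)
    # path invariants: boundaries and monotone steps
    expect_equal(al$path[1, ], c(1, 1))
    expect_equal(al$path[nrow(al$path), ], c(n, k))
    steps <- diff(al$path)
    expect_true(all(steps >= 0 & steps <= 1))
    expect_true(all(rowSums(steps) >= 1))
  }
})

test_that("DTW handles the worked 2x3 example and zero-diagonal identity", {
  m <- matrix(c(0, 1, 9, 9, 1, 0), 2, 3, byrow = TRUE)
  al <- dtw_align(m)
  expect_equal(al$cost, oracle_dtw_cost(m))
  expect_equal(al$cost, 1)
  z <- matrix(1, 5, 5) - diag(5)
  alz <- dtw_align(z)
  expect_equal(alz$cost, 0)
  expect_equal(alz$path, cbind(1:5, 1:5), ignore_attr = TRUE)
})

test_that("replication pairs every micro slice once, honouring 2:1", {
  dm <- abs(outer(seq_len(250) * 2, seq_len(500), `-`))
  al <- dtw_align(dm)
  pairs <- replicate_and_pair(al$path, 250, 500)
  expect_equal(nrow(pairs), 500)
  expect_equal(pairs$micro_index, 1:500)
  expect_true(all(table(pairs$mdct_index) <= 3))
  # square zero-diagonal matrix -> identity pairing
  z <- matrix(1, 6, 6) - diag(6)
  pz <- replicate_and_pair(dtw_align(z)$path, 6, 6)
  expect_equal(pz$mdct_index, 1:6)
})

test_that("phantom stacks are paired within one slice of ground truth", {
  sp <- tiny_spec(seed = 5)
  gt <- generate_trabecular_volume(sp)
  mic <- render_micro_ct(gt, sp)
  md <- render_mdct(gt, sp)
  pr <- pair_stacks(md, mic)
  expect_s3_class(pr, "pairing_result")
  expect_equal(nrow(pr$pairs), dim(mic$data)[1])
  true_mdct <- ceiling(pr$pairs$micro_index / 2)
  expect_gte(mean(abs(pr$pairs$mdct_index - true_mdct) <= 1), 0.9)
})
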