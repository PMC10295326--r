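# Independent brute-force oracles and small fixture builders used across the
# suite. Oracles share only the *definitions* with the implementation, never
# its algorithms (no distance transform, no dynamic program, no histogram
# recursion).

# Local thickness by exhaustive sphere search: for every candidate centre c
# (a foreground voxel), the sphere radius is the distance to the nearest
# background voxel centre minus half a voxel; a voxel v is covered when
# |v - c| < r(c); the map records the largest covering sphere's diameter.
oracle_local_thickness <- function(b) {
  d <- dim(b)
  fg <- which(b != 0, arr.ind = TRUE)
  bg <- which(b == 0, arr.ind = TRUE)
  stopifnot(nrow(fg) > 0, nrow(bg) > 0)
  out <- array(0, dim = d)
  lin <- fg[, 1] + (fg[, 2] - 1L) * d[1] + (fg[, 3] - 1L) * d[1] * d[2]
  r <- vapply(seq_len(nrow(fg)), function(i) {
    sqrt(min(rowSums(sweep(bg, 2L, fg[i, ])^2))) - 0.5
  }, numeric(1))
  for (i in seq_len(nrow(fg))) {
    cov <- rowSums(sweep(fg, 2L, fg[i, ])^2) < r[i]^2
    cov[i] <- TRUE
    idx <- lin[cov]
    out[idx] <- pmax(out[idx], 2 * r[i])
  }
  out
}

# DTW oracle: explicit enumeration of every monotone boundary-to-boundary
# path (steps right / down / diagonal), returning the minimal total cost.
oracle_dtw_cost <- function(m) {
  n <- nrow(m)
  k <- ncol(m)
  best <- Inf
  walk <- function(i, j, acc) {
    acc <- acc + m[i, j]
    if (acc >= best) return(invisible())
    if (i == n && j == k) {
      best <<- acc
      return(invisible())
    }
    if (i < n && j < k) walk(i + 1L, j + 1L, acc)
    if (j < k) walk(i, j + 1L, acc)
    if (i < n) walk(i + 1L, j, acc)
    invisible()
  }
  walk(1L, 1L, 0)
  best
}

# all fixed points of the intermeans map over integer histogram cuts
oracle_isodata_fixed_points <- function(values) {
  v <- round(values)
  res <- numeric(0)
  for (cut in 0:254) {
    lo <- v[v <= cut]
    hi <- v[v > cut]
    if (length(lo) == 0L || length(hi) == 0L) next
    t <- (mean(lo) + mean(hi)) / 2
    if (t >= cut && t < cut + 1) res <- c(res, t)
  }
  res
}

# direct windowed SSIM recomputation (explicit patch loop)
oracle_ssim <- function(a, b, L = 255) {
  g <- exp(-0.5 * ((-5:5) / 1.5)^2)
  w <- outer(g, g)
  w <- w / sum(w)
  C1 <- (0.01 * L)^2
  C2 <- (0.03 * L)^2
  vals <- c()
  for (i in 1:(nrow(a) - 10)) {
    for (j in 1:(ncol(a) - 10)) {
      pa <- a[i:(i + 10), j:(j + 10)]
      pb <- b[i:(i + 10), j:(j + 10)]
      mua <- sum(w * pa)
      mub <- sum(w * pb)
      va <- sum(w * pa^2) - mua^2
      vb <- sum(w * pb^2) - mub^2
      cab <- sum(w * pa * pb) - mua * mub
      vals <- c(vals, ((2 * mua * mub + C1) * (2 * cab + C2)) /
                  ((mua^2 + mub^2 + C1) * (va + vb + C2)))
    }
  }
  mean(vals)
}

# Frechet distance recomputed through the eigendecomposition of the
# (non-symmetric) covariance product
oracle_fid <- function(fa, fb) {
  mu1 <- colMeans(fa)
  mu2 <- colMeans(fb)
  S1 <- cov(fa)
  S2 <- cov(fb)
  ev <- eigen(S1 %*% S2)$values
  sum((mu1 - mu2)^2) + sum(diag(S1)) + sum(diag(S2)) -
    2 * sum(sqrt(pmax(Re(ev), 0)))
}

# fixtures ------------------------------------------------------------------

make_slab <- function(dims = c(14, 20, 14), axis = 2L, from = 9L, to = 11L) {
  b <- array(0, dim = dims)
  idx <- list(seq_len(dims[1]), seq_len(dims[2]), seq_len(dims[3]))
  idx[[axis]] <- from:to
  b[idx[[1]], idx[[2]], idx[[3]]] <- 1
  b
}

make_ball <- function(n = 16L, radius = 5) {
  b <- array(0, dim = c(n, n, n))
  cc <- (n + 1) / 2
  for (z in 1:n) for (y in 1:n) for (x in 1:n) {
    if ((z - cc)^2 + (y - cc)^2 + (x - cc)^2 <= radius^2) b[z, y, x] <- 1
  }
  b
}

# smooth textured image for keypoint tests
make_texture <- function(n = 160L, sigma = 2, seed = 2L) {
  set.seed(seed)
  base <- matrix(rnorm(n * n), n, n)
  img <- trabeculagen:::gaussian_blur_vox(array(base, c(n, n, 1)),
                                          c(sigma, sigma, 0))[, , 1]
  (img - min(img)) / diff(range(img)) * 255
}

# small fast phantom spec for integration tests
tiny_spec <- function(seed = 1L, ...) {
  phantom_spec(extent_mm = c(2.4, 6.4, 6.4), voxel_mm = 0.1, seed = seed, ...)
}
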