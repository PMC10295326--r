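# Slice correspondence between MDCT and micro-CT stacks: scale-space keypoint
# matching gives a per-slice-pair distance, dynamic time warping aligns the
# stacks, and the alignment is replicated into one-to-one image pairs.

# 2-D Gaussian blur of a matrix (reflect padding)
blur2d <- function(img, sigma) {
  if (sigma <= 0) return(img)
  k <- .gauss_kernel(sigma)
  d <- c(dim(img), 1L)
  out <- .convolve_axis(as.numeric(img), d, k, 1L)
  out <- .convolve_axis(out, d, k, 2L)
  matrix(out, nrow(img), ncol(img))
}

#' Detect scale-space keypoints and descriptors
#'
#' Difference-of-Gaussian extrema over a single-octave scale pyramid, with
#' SIFT-style descriptors: 4 x 4 spatial cells of 8-bin gradient-orientation
#' histograms over a 16 x 16 patch at the keypoint's pyramid level,
#' Gaussian-weighted, normalized and clipped at 0.2.
#'
#' @param img numeric matrix (y, x), intensities in `[0, 255]`.
#' @param n_scales number of pyramid levels (>= 4).
#' @param sigma0 base blur of the pyramid.
#' @param contrast_thresh DoG magnitude threshold on `[0, 1]`-scaled images.
#' @return list with `coords` (n x 2 matrix of (y, x)), `descriptors`
#'   (n x 128), `scales`.
#' @export
sift_keypoints <- function(img, n_scales = 6L, sigma0 = 1.6,
                           contrast_thresh = 0.015) {
  im <- img / 255
  h <- nrow(im); w <- ncol(im)
  sig <- sigma0 * 2^((seq_len(n_scales) - 1) / 3)
  pyr <- lapply(sig, function(s) blur2d(im, s))
  dog <- array(0, dim = c(h, w, n_scales - 1L))
  for (l in seq_len(n_scales - 1L)) dog[, , l] <- pyr[[l + 1L]] - pyr[[l]]
  border <- 9L
  if (h <= 2 * border + 2 || w <= 2 * border + 2) {
    return(list(coords = matrix(0, 0, 2), descriptors = matrix(0, 0, 128),
                scales = numeric(0)))
  }
  kp <- .dog_extrema(as.numeric(dog), dim(dog), contrast_thresh, border)
  if (nrow(kp) == 0L) {
    return(list(coords = matrix(0, 0, 2), descriptors = matrix(0, 0, 128),
                scales = numeric(0)))
  }
  # descriptor geometry: 16x16 patch, 4x4 cells, 8 orientation bins
  off <- -8:7
  cell <- pmin(3L, (off + 8L) %/% 4L)  # 0..3
  gw <- exp(-0.5 * ((off + 0.5) / 8)^2)
  wpatch <- outer(gw, gw)
  cell_idx <- outer(cell, cell * 4L, `+`)  # 0..15
  desc <- matrix(0, nrow(kp), 128L)
  coords <- matrix(0, nrow(kp), 2L)
  for (t in seq_len(nrow(kp))) {
    i <- kp[t, 1L]; j <- kp[t, 2L]; l <- kp[t, 3L]
    g <- pyr[[l + 1L]]
    rows <- (i + off); cols <- (j + off)
    # clamp for gradient neighbours
    rm1 <- pmax(rows - 1L, 1L); rp1 <- pmin(rows + 1L, h)
    cm1 <- pmax(cols - 1L, 1L); cp1 <- pmin(cols + 1L, w)
    gy <- (g[rp1, cols, drop = FALSE] - g[rm1, cols, drop = FALSE]) / 2
    gx <- (g[rows, cp1, drop = FALSE] - g[rows, cm1, drop = FALSE]) / 2
    mag <- sqrt(gy^2 + gx^2) * wpatch
    ori <- atan2(gy, gx)                      # (-pi, pi]
    bin <- floor((ori + pi) / (2 * pi) * 8)
    bin[bin > 7] <- 7L
    idx <- cell_idx * 8L + bin + 1L           # 1..128
    v <- as.numeric(rowsum(as.numeric(mag), as.integer(idx)))
    dd <- numeric(128L)
    dd[sort(unique(as.integer(idx)))] <- v
    nrm <- sqrt(sum(dd^2))
    if (nrm > 0) dd <- dd / nrm
    dd <- pmin(dd, 0.2)
    nrm <- sqrt(sum(dd^2))
    if (nrm > 0) dd <- dd / nrm
    desc[t, ] <- dd
    coords[t, ] <- c(i, j)
  }
  list(coords = coords, descriptors = desc, scales = sig[kp[, 3L] + 1L])
}

# nearest-neighbour descriptor matching with Lowe ratio test and mutual-NN
match_descriptors <- function(ka, kb, ratio = 0.75) {
  na <- nrow(ka$descriptors); nb <- nrow(kb$descriptors)
  if (na == 0L || nb == 0L) return(matrix(0L, 0, 2))
  d2 <- outer(rowSums(ka$descriptors^2), rowSums(kb$descriptors^2), `+`) -
    2 * tcrossprod(ka$descriptors, kb$descriptors)
  d2[d2 < 0] <- 0
  nn_ab <- apply(d2, 1L, which.min)
  nn_ba <- apply(d2, 2L, which.min)
  keep <- logical(na)
  for (i in seq_len(na)) {
    j <- nn_ab[i]
    if (nn_ba[j] != i) next                    # mutual nearest neighbour
    if (nb >= 2L) {
      ds <- sort(d2[i, ], partial = 2)[1:2]
      if (!(sqrt(ds[1]) < ratio * sqrt(ds[2]) || ds[2] == 0)) next
    }
    keep[i] <- TRUE
  }
  cbind(which(keep), nn_ab[keep])
}

#' Detect and match keypoints between two images
#'
#' Both images must already live on a common pixel grid (upsample the MDCT
#' slice to the micro-CT in-plane grid first; see [pair_stacks()]).
#'
#' @param a,b numeric matrices on the same grid.
#' @param ratio Lowe ratio threshold.
#' @param min_matches below this count the pair is reported unmatched.
#' @return list with `a_coords`, `b_coords` (m x 2 each), `n_matches`,
#'   `unmatched` flag.
#' @export
detect_and_match <- function(a, b, ratio = 0.75, min_matches = 3L) {
  ka <- sift_keypoints(a)
  kb <- sift_keypoints(b)
  m <- match_descriptors(ka, kb, ratio)
  list(a_coords = ka$coords[m[, 1L], , drop = FALSE],
       b_coords = kb$coords[m[, 2L], , drop = FALSE],
       n_matches = nrow(m), unmatched = nrow(m) < min_matches)
}

#' Keypoint distance between two images
#'
#' Mean Euclidean distance between matched keypoint coordinates; `NA` when
#' fewer than `min_matches` keypoints match (the distance-matrix builder
#' substitutes the unmatched sentinel).
#'
#' @inheritParams detect_and_match
#' @return nonnegative scalar or `NA`.
#' @export
image_distance <- function(a, b, ratio = 0.75, min_matches = 3L) {
  m <- detect_and_match(a, b, ratio, min_matches)
  if (m$unmatched) return(NA_real_)
  mean(sqrt(rowSums((m$a_coords - m$b_coords)^2)))
}

#' Build the all-pairs slice distance matrix
#'
#' Descriptors are computed once per slice; unmatched pairs receive the
#' sentinel `max(finite distances) + 1` so the warping stays total.
#'
#' @param mdct_slices,micro_slices lists of matrices on a common pixel grid.
#' @param ratio Lowe ratio threshold.
#' @param min_matches unmatched threshold.
#' @return numeric matrix `(n_mdct x n_micro)`.
#' @export
build_distance_matrix <- function(mdct_slices, micro_slices, ratio = 0.75,
                                  min_matches = 3L) {
  ka <- lapply(mdct_slices, sift_keypoints)
  kb <- lapply(micro_slices, sift_keypoints)
  n <- length(ka); m <- length(kb)
  out <- matrix(NA_real_, n, m)
  for (i in seq_len(n))
    for (j in seq_len(m)) {
      mt <- match_descriptors(ka[[i]], kb[[j]], ratio)
      if (nrow(mt) >= min_matches) {
        pa <- ka[[i]]$coords[mt[, 1L], , drop = FALSE]
        pb <- kb[[j]]$coords[mt[, 2L], , drop = FALSE]
        out[i, j] <- mean(sqrt(rowSums((pa - pb)^2)))
      }
    }
  if (anyNA(out)) {
    mx <- suppressWarnings(max(out, na.rm = TRUE))
    if (!is.finite(mx)) mx <- 0
    out[is.na(out)] <- mx + 1
  }
  out
}

#' Dynamic time warping alignment
#'
#' Standard DTW dynamic program over a nonnegative cost matrix with steps
#' `{(1,0), (0,1), (1,1)}`; backtracking ties prefer `(1,1)`, then `(0,1)`,
#' then `(1,0)`. The path runs from `(1,1)` to `(n, m)` (1-based).
#'
#' @param matrix numeric cost matrix (rows: MDCT, cols: micro-CT).
#' @return list with `path` (L x 2 integer matrix) and `cost`.
#' @export
dtw_align <- function(matrix) {
  if (any(!is.finite(matrix)) || any(matrix < 0)) {
    stop("cost matrix must be finite and nonnegative")
  }
  .dtw_core(matrix)
}

#' Replicate MDCT slices along the warping path into one-to-one pairs
#'
#' Every micro-CT index appears exactly once, partnered with the MDCT index
#' the path assigns it (the first when the path visits several); MDCT slices
#' may repeat. For 250 MDCT and 500 micro-CT slices this yields 500 pairs.
#'
#' @param path L x 2 matrix from [dtw_align()] (1-based).
#' @param n_mdct,n_micro stack sizes.
#' @return data.frame with columns `mdct_index`, `micro_index`.
#' @export
replicate_and_pair <- function(path, n_mdct, n_micro) {
  stopifnot(path[1, 1] == 1L, path[1, 2] == 1L,
            path[nrow(path), 1] == n_mdct, path[nrow(path), 2] == n_micro)
  first <- !duplicated(path[, 2])
  mdct_of_micro <- path[first, 1][order(path[first, 2])]
  data.frame(mdct_index = as.integer(mdct_of_micro),
             micro_index = seq_len(n_micro))
}

#' Pair an MDCT stack with a micro-CT stack
#'
#' End-to-end pairing: MDCT slices are upsampled (bicubic) to the micro-CT
#' in-plane grid, the keypoint distance matrix is built, DTW aligns the two
#' stacks and MDCT slices are replicated into one-to-one pairs.
#'
#' @param mdct,micro [voxel_volume()] stacks of the same specimen.
#' @param distance_matrix optional precomputed matrix (skips the keypoint
#'   stage).
#' @param ratio,min_matches matching parameters.
#' @return object of class `pairing_result`: `distance_matrix`, `path`,
#'   `cost`, `pairs`, `replication_factor`.
#' @export
pair_stacks <- function(mdct, micro, distance_matrix = NULL, ratio = 0.75,
                        min_matches = 3L) {
  n_mdct <- dim(mdct$data)[1]
  n_micro <- dim(micro$data)[1]
  if (is.null(distance_matrix)) {
    hy <- dim(micro$data)[2]; hx <- dim(micro$data)[3]
    ms <- lapply(seq_len(n_mdct), function(k) {
      .bicubic_resize(mdct$data[k, , ], hy, hx)
    })
    us <- lapply(seq_len(n_micro), function(k) micro$data[k, , ])
    distance_matrix <- build_distance_matrix(ms, us, ratio, min_matches)
  }
  al <- dtw_align(distance_matrix)
  pairs <- replicate_and_pair(al$path, n_mdct, n_micro)
  structure(list(distance_matrix = distance_matrix, path = al$path,
                 cost = al$cost, pairs = pairs,
                 replication_factor = round(n_micro / n_mdct)),
            class = "pairing_result")
}

#' @export
print.pairing_result <- function(x, ...) {
  cat(sprintf(
    "<pairing_result> %d MDCT x %d micro-CT slices -> %d pairs (cost %.3f)\n",
    nrow(x$distance_matrix), ncol(x$distance_matrix), nrow(x$pairs), x$cost))
  invisible(x)
}
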