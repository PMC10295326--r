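#' IsoData global threshold
#'
#' Iterative intermeans thresholding on the 8-bit histogram: starting from the
#' mean of the masked region, the threshold is repeatedly replaced by the
#' midpoint of the mean intensity below and the mean intensity above it until
#' a fixed point is reached. Voxels strictly above the returned threshold are
#' classified as bone.
#'
#' @param volume a [voxel_volume()] or numeric array of intensities in
#'   `[0, 255]`.
#' @param mask optional logical/0-1 array of the same shape restricting the
#'   histogram.
#' @param max_iter iteration cap (convergence is typically < 20 steps).
#' @return the converged threshold (numeric scalar, possibly fractional).
#' @export
isodata_threshold <- function(volume, mask = NULL, max_iter = 200L) {
  x <- if (inherits(volume, "voxel_volume")) volume$data else volume
  v <- as.numeric(x)
  if (!is.null(mask)) {
    m <- if (inherits(mask, "voxel_volume")) mask$data else mask
    v <- v[as.logical(m)]
  }
  if (length(v) == 0L) stop("masked region is empty")
  v <- round(pmin(pmax(v, 0), 255))
  if (min(v) == max(v)) stop("degenerate histogram: masked region is constant")
  # histogram once; iterate on cumulative sums
  h <- tabulate(v + 1L, nbins = 256L)
  lev <- 0:255
  csum_n <- cumsum(h)
  csum_s <- cumsum(h * lev)
  n_tot <- csum_n[256L]
  s_tot <- csum_s[256L]
  t_cur <- s_tot / n_tot
  for (it in seq_len(max_iter)) {
    cut <- min(254L, max(0L, floor(t_cur)))  # partition: <= cut vs > cut
    n_lo <- csum_n[cut + 1L]
    if (n_lo == 0L || n_lo == n_tot) {
      # pathological start; nudge toward interior
      cut <- if (n_lo == 0L) min(which(h > 0)) - 1L else max(which(h > 0)) - 2L
      n_lo <- csum_n[cut + 1L]
    }
    m_lo <- csum_s[cut + 1L] / n_lo
    m_hi <- (s_tot - csum_s[cut + 1L]) / (n_tot - n_lo)
    t_new <- (m_lo + m_hi) / 2
    if (abs(t_new - t_cur) < 1e-9) return(t_new)
    t_cur <- t_new
  }
  t_cur
}

#' Cylindrical volume of interest
#'
#' Default geometry follows standard centrum sampling: a cylinder of 15 mm
#' diameter and 5 mm height with its axis along the slice normal (z).
#'
#' @param center `(z, y, x)` centre in mm.
#' @param diameter_mm,height_mm cylinder dimensions in mm.
#' @param axis unit axis vector `(z, y, x)`; default slice-normal.
#' @return an object of class `cylindrical_voi`.
#' @export
cylindrical_voi <- function(center, diameter_mm = 15, height_mm = 5,
                            axis = c(1, 0, 0)) {
  stopifnot(diameter_mm > 0, height_mm > 0)
  axis <- as.numeric(axis)
  nrm <- sqrt(sum(axis^2))
  if (abs(nrm - 1) > 1e-6) stop("`axis` must have unit norm")
  structure(list(center = as.numeric(center), diameter_mm = diameter_mm,
                 height_mm = height_mm, axis = axis, clipped = FALSE),
            class = "cylindrical_voi")
}

#' @export
print.cylindrical_voi <- function(x, ...) {
  cat(sprintf(
    "<cylindrical_voi> %.3g mm diameter x %.3g mm height at (%.2f, %.2f, %.2f) mm%s\n",
    x$diameter_mm, x$height_mm, x$center[1], x$center[2], x$center[3],
    if (isTRUE(x$clipped)) " [clipped]" else ""))
  invisible(x)
}

#' Rasterize a cylindrical VOI onto a voxel grid
#'
#' A voxel belongs to the VOI when its centre lies strictly inside the
#' cylinder (strict radial and axial inequalities).
#'
#' @param voi a [cylindrical_voi()].
#' @param grid a [voxel_volume()] defining the grid.
#' @return logical array of the grid's dimensions.
#' @export
voxelize_voi <- function(voi, grid) {
  d <- dim(grid$data)
  cz <- axis_centers(grid, 1) - voi$center[1]
  cy <- axis_centers(grid, 2) - voi$center[2]
  cx <- axis_centers(grid, 3) - voi$center[3]
  a <- voi$axis
  r <- voi$diameter_mm / 2
  hh <- voi$height_mm / 2
  # pairwise terms via outer sums; axial coordinate t = p . a
  tz <- array(cz * a[1], dim = d)
  ty <- aperm(array(cy * a[2], dim = d[c(2, 1, 3)]), c(2, 1, 3))
  tx <- aperm(array(cx * a[3], dim = d[c(3, 2, 1)]), c(3, 2, 1))
  tt <- tz + ty + tx
  p2 <- outer(cz^2, outer(cy^2, cx^2, `+`), `+`)
  rad2 <- p2 - tt^2
  mask <- (abs(tt) < hh) & (rad2 < r^2)
  if (!any(mask)) stop("VOI does not intersect the grid")
  mask
}

#' Place the two centrum VOIs from a vertebral body mask
#'
#' Reproduces the standard axial construction: the sagittal midline of the
#' axial body mask (the centreline of its short, anterior-posterior axis) is
#' intersected with the anterior edge of the body; the tangent point sits 5 mm
#' interior to that intersection, and a 15 mm cylinder is placed tangent to it,
#' extending posteriorly. The two VOIs are centred 5 mm above and 5 mm below
#' the mid-transverse plane of the stack.
#'
#' @param body_mask a binary [voxel_volume()] of the vertebral body.
#' @param diameter_mm,height_mm VOI geometry (defaults 15 and 5 mm).
#' @param setback_mm interior offset of the tangent point from the anterior
#'   edge (default 5 mm).
#' @param z_offset_mm axial offset of each VOI centre from the mid-plane
#'   (default 5 mm; shrunk with a warning when the stack is too short).
#' @return list of two [cylindrical_voi()]; each carries a `clipped` flag set
#'   when the cylinder does not fit inside the mask.
#' @export
position_voi_from_body_mask <- function(body_mask, diameter_mm = 15,
                                        height_mm = 5, setback_mm = 5,
                                        z_offset_mm = 5) {
  d <- dim(body_mask$data)
  if (!any(body_mask$data > 0)) stop("body mask is empty")
  kmid <- max(1L, as.integer(round(d[1] / 2)))
  sl <- body_mask$data[kmid, , ] > 0
  if (!any(sl)) stop("mid-stack body mask slice is empty")
  ys <- axis_centers(body_mask, 2)
  xs <- axis_centers(body_mask, 3)
  idx <- which(sl, arr.ind = TRUE)
  x_c <- mean(xs[idx[, 2]])
  # line A: anterior-posterior line at the mask centroid's x
  jx <- which.min(abs(xs - x_c))
  col_on <- which(sl[, jx])
  if (length(col_on) == 0L) stop("sagittal midline misses the body mask")
  y_ant <- ys[min(col_on)]              # anterior = smallest y
  y_tan <- y_ant + setback_mm           # tangent point P on line A
  y_cen <- y_tan + diameter_mm / 2      # cylinder tangent at P, posterior
  zs <- axis_centers(body_mask, 1)
  z_mid <- mean(range(zs))
  z_extent <- diff(range(zs)) + body_mask$voxel_size[1]
  zo <- z_offset_mm
  if (z_extent < 2 * z_offset_mm + height_mm) {
    zo <- max(0, (z_extent - height_mm) / 2)
    warning("stack too short for the requested axial offsets; VOIs moved in")
  }
  mk <- function(zc) {
    voi <- cylindrical_voi(c(zc, y_cen, x_c), diameter_mm, height_mm)
    # clipped when part of the cylinder leaves the body mask
    msk <- tryCatch(voxelize_voi(voi, body_mask), error = function(e) NULL)
    clip <- is.null(msk) || any(msk & !(body_mask$data > 0))
    if (clip) warning("VOI extends outside the body mask; flagged as clipped")
    voi$clipped <- clip
    voi
  }
  list(superior = mk(z_mid + zo), inferior = mk(z_mid - zo))
}

#' Bone volume fraction by voxel counting
#'
#' @param binary a binary [voxel_volume()] or 0/1 array (bone = 1).
#' @param mask optional logical array restricting the count.
#' @return foreground voxels / total voxels in the mask, an exact ratio of
#'   integer counts.
#' @export
bvtv <- function(binary, mask = NULL) {
  b <- if (inherits(binary, "voxel_volume")) binary$data else binary
  if (is.null(mask)) mask <- array(TRUE, dim = dim(b))
  m <- as.logical(mask)
  n_tot <- sum(m)
  if (n_tot == 0L) stop("mask is empty")
  sum(b[m] != 0) / n_tot
}

#' Local thickness map
#'
#' For each foreground voxel, the diameter of the largest sphere that lies
#' entirely within the foreground and contains the voxel (the model-free
#' direct thickness definition). Computed via the exact Euclidean distance
#' transform, a distance-ridge reduction (ties kept) and sphere painting.
#'
#' @param binary a binary [voxel_volume()] on an isotropic grid.
#' @return a [voxel_volume()] whose data holds thickness in mm (0 outside the
#'   foreground).
#' @export
local_thickness_map <- function(binary) {
  vs <- binary$voxel_size
  if (max(abs(vs - vs[1])) > 1e-6 * vs[1]) {
    stop("local thickness requires isotropic voxels; resample first ",
         "(see resample_isotropic())")
  }
  b <- binary$data
  if (!any(b != 0)) stop("no foreground voxels")
  th <- .local_thickness_vox(as.numeric(b != 0), dim(b))
  voxel_volume(array(th * vs[1], dim = dim(b)), vs, binary$origin)
}

#' Trabecular thickness and separation
#'
#' Tb.Th is the mean local thickness of the bone phase over foreground voxels
#' in the mask; Tb.Sp applies the same measurement to the background (marrow)
#' phase. Standard deviations are over voxels.
#'
#' @param binary a binary [voxel_volume()] (bone = 1) on an isotropic grid.
#' @param mask optional logical array restricting the averaging region (the
#'   thickness maps themselves are computed on the full array).
#' @return list with `tbth_mm`, `tbth_sd_mm`, `tbsp_mm`, `tbsp_sd_mm`.
#' @export
tbth_tbsp <- function(binary, mask = NULL) {
  b <- binary$data != 0
  if (is.null(mask)) mask <- array(TRUE, dim = dim(b))
  m <- as.logical(mask)
  if (!any(b & m)) stop("no foreground voxels in mask")
  if (!any(!b & m)) stop("no background voxels in mask")
  fg <- local_thickness_map(binary)
  inv <- voxel_volume(array(as.numeric(!b), dim = dim(b)),
                      binary$voxel_size, binary$origin, binary = TRUE)
  bg <- local_thickness_map(inv)
  vth <- fg$data[b & m]
  vsp <- bg$data[(!b) & m]
  list(tbth_mm = mean(vth), tbth_sd_mm = if (length(vth) > 1) sd(vth) else 0,
       tbsp_mm = mean(vsp), tbsp_sd_mm = if (length(vsp) > 1) sd(vsp) else 0)
}

#' Measure bone structure metrics in a cylindrical VOI
#'
#' Composes the morphometry chain: one global IsoData threshold over the VOI,
#' binarization (bone strictly above threshold), BV/TV by voxel counting, and
#' model-free Tb.Th / Tb.Sp from local-thickness maps. Anisotropic stacks are
#' resampled to isotropic voxels first; thickness maps are computed on the
#' VOI's bounding box.
#'
#' @param volume a grayscale [voxel_volume()] (8-bit range).
#' @param voi a [cylindrical_voi()].
#' @param threshold `"global"` (default: one IsoData threshold for the VOI),
#'   `"per-slice"` (independent IsoData per axial slice), or a fixed numeric
#'   threshold.
#' @param precomputed_binary optional binary [voxel_volume()] to measure
#'   directly, skipping thresholding (used for ground-truth oracles).
#' @return an object of class `morphometry_result` with fields `bvtv`,
#'   `tbth_mm`, `tbth_sd_mm`, `tbsp_mm`, `tbsp_sd_mm`, `threshold_used`,
#'   `voi`, `n_foreground`, `n_total`, `scope_3d`.
#' @export
measure_stack <- function(volume, voi, threshold = "global",
                          precomputed_binary = NULL) {
  if (!is.null(precomputed_binary)) {
    vol_iso <- resample_isotropic(precomputed_binary)
    vol_iso$data <- as.numeric(vol_iso$data > 0.5) * 255
    thr_used <- 127.5
  } else {
    vol_iso <- resample_isotropic(volume)
    thr_used <- NA_real_
  }
  mask <- voxelize_voi(voi, vol_iso)
  if (is.null(precomputed_binary)) {
    if (is.numeric(threshold)) {
      thr_used <- threshold
    } else if (identical(threshold, "global")) {
      thr_used <- isodata_threshold(vol_iso$data, mask)
    } else if (identical(threshold, "per-slice")) {
      thr_used <- NA_real_  # per-slice thresholds recorded as their mean
    } else {
      stop("unknown threshold policy")
    }
  }
  bin <- array(0, dim = dim(vol_iso$data))
  if (identical(threshold, "per-slice") && is.null(precomputed_binary)) {
    ts <- c()
    for (k in seq_len(dim(vol_iso$data)[1])) {
      mk <- mask[k, , ]
      if (!any(mk)) next
      tk <- isodata_threshold(vol_iso$data[k, , ], mk)
      bin[k, , ] <- as.numeric(vol_iso$data[k, , ] > tk)
      ts <- c(ts, tk)
    }
    thr_used <- mean(ts)
  } else {
    bin <- array(as.numeric(vol_iso$data > thr_used), dim = dim(vol_iso$data))
  }
  n_tot <- sum(mask)
  n_fg <- sum(bin[mask] != 0)

  # thickness on the VOI bounding box (with a small pad) to bound cost
  ix <- which(mask, arr.ind = TRUE)
  pad <- 2L
  rg <- lapply(1:3, function(a) {
    max(1L, min(ix[, a]) - pad):min(dim(bin)[a], max(ix[, a]) + pad)
  })
  sub <- voxel_volume(bin[rg[[1]], rg[[2]], rg[[3]], drop = FALSE],
                      vol_iso$voxel_size, binary = TRUE)
  subm <- mask[rg[[1]], rg[[2]], rg[[3]], drop = FALSE]
  th <- tbth_tbsp(sub, subm)

  structure(
    list(bvtv = n_fg / n_tot, tbth_mm = th$tbth_mm, tbth_sd_mm = th$tbth_sd_mm,
         tbsp_mm = th$tbsp_mm, tbsp_sd_mm = th$tbsp_sd_mm,
         threshold_used = thr_used, voi = voi,
         n_foreground = n_fg, n_total = n_tot, scope_3d = TRUE),
    class = "morphometry_result"
  )
}

#' @export
print.morphometry_result <- function(x, ...) {
  cat("<morphometry_result> (3-D over VOI)\n")
  cat(sprintf("  BV/TV : %.4f  (%d / %d voxels)\n",
              x$bvtv, x$n_foreground, x$n_total))
  cat(sprintf("  Tb.Th : %.4f +/- %.4f mm\n", x$tbth_mm, x$tbth_sd_mm))
  cat(sprintf("  Tb.Sp : %.4f +/- %.4f mm\n", x$tbsp_mm, x$tbsp_sd_mm))
  cat(sprintf("  IsoData threshold: %.2f\n", x$threshold_used))
  invisible(x)
}
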