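#' Voxel volume container
#'
#' A `voxel_volume` is the package's universal 3-D image container: a numeric
#' array in `(z, y, x)` index order together with the physical voxel size and
#' origin. Voxel centres sit at `origin + (index - 1 + 0.5) * voxel_size`
#' (0-based index plus half a voxel), so slice `k` of a stack is
#' `vol$data[k, , ]`.
#'
#' @param data numeric 3-D array, dimensions `(nz, ny, nx)`. Intensity volumes
#'   are expected in `[0, 255]`; binary volumes contain only `{0, 1}`.
#' @param voxel_size numeric length-3, `(dz, dy, dx)` in mm; all `> 0`.
#' @param origin numeric length-3, `(z0, y0, x0)` in mm.
#' @param binary logical; declare (and check) that `data` is a binary mask.
#' @return an object of class `voxel_volume`.
#' @export
voxel_volume <- function(data, voxel_size, origin = c(0, 0, 0),
                         binary = FALSE) {
  if (length(dim(data)) != 3L) {
    stop("`data` must be a 3-D array in (z, y, x) order")
  }
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) ||
      any(voxel_size <= 0)) {
    stop("`voxel_size` must be three positive values (dz, dy, dx) in mm")
  }
  if (any(dim(data) < 1L)) stop("every axis must have at least one voxel")
  if (binary && !all(data %in% c(0, 1))) {
    stop("binary volume contains values other than {0, 1}")
  }
  structure(
    list(data = data, voxel_size = voxel_size,
         origin = as.numeric(origin), binary = binary),
    class = "voxel_volume"
  )
}

#' @export
print.voxel_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<voxel_volume> %d x %d x %d voxels (z,y,x), %.4g x %.4g x %.4g mm/voxel%s\n",
    d[1], d[2], d[3], x$voxel_size[1], x$voxel_size[2], x$voxel_size[3],
    if (isTRUE(x$binary)) ", binary" else ""
  ))
  cat(sprintf("  extent: %.2f x %.2f x %.2f mm; intensity range [%.3g, %.3g]\n",
              d[1] * x$voxel_size[1], d[2] * x$voxel_size[2],
              d[3] * x$voxel_size[3], min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.voxel_volume <- function(x) dim(x$data)

# physical centre coordinates of voxel indices along one axis (1-based)
axis_centers <- function(vol, axis) {
  n <- dim(vol$data)[axis]
  vol$origin[axis] + (seq_len(n) - 0.5) * vol$voxel_size[axis]
}

#' Resample a volume onto a new grid by trilinear interpolation
#'
#' @param vol a [voxel_volume()].
#' @param voxel_size target voxel size `(dz, dy, dx)` in mm.
#' @param dims optional target dimensions; by default chosen to cover the
#'   source extent.
#' @param origin target origin; defaults to the source origin.
#' @return a [voxel_volume()] on the new grid.
#' @export
resample_volume <- function(vol, voxel_size, dims = NULL,
                            origin = vol$origin) {
  voxel_size <- rep_len(as.numeric(voxel_size), 3L)
  if (is.null(dims)) {
    extent <- dim(vol$data) * vol$voxel_size
    dims <- pmax(1L, as.integer(round(extent / voxel_size)))
  }
  q <- lapply(1:3, function(a) {
    origin[a] + (seq_len(dims[a]) - 0.5) * voxel_size[a]
  })
  out <- .trilinear_sample(as.numeric(vol$data), dim(vol$data),
                           vol$voxel_size, vol$origin,
                           q[[1]], q[[2]], q[[3]])
  voxel_volume(array(out, dim = dims), voxel_size, origin)
}

#' Resample a volume to isotropic voxels
#'
#' Local-thickness measurement is defined on isotropic grids; anisotropic
#' stacks (e.g. MDCT) are passed through this first.
#'
#' @param vol a [voxel_volume()].
#' @param voxel_mm target isotropic voxel size; default the smallest axis.
#' @return a [voxel_volume()] with equal voxel sizes.
#' @export
resample_isotropic <- function(vol, voxel_mm = min(vol$voxel_size)) {
  if (max(abs(vol$voxel_size - vol$voxel_size[1])) < 1e-9 &&
      abs(vol$voxel_size[1] - voxel_mm) < 1e-9) {
    return(vol)
  }
  resample_volume(vol, rep(voxel_mm, 3))
}

# separable Gaussian blur of a volume, sigma per axis in voxels
gaussian_blur_vox <- function(arr, sigma_vox) {
  out <- as.numeric(arr)
  d <- dim(arr)
  for (a in 1:3) {
    s <- sigma_vox[a]
    if (s <= 0) next
    half <- max(1L, as.integer(ceiling(3 * s)))
    k <- exp(-0.5 * ((-half:half) / s)^2)
    k <- k / sum(k)
    out <- .convolve_axis(out, d, k, a)
  }
  array(out, dim = d)
}

#' Write an image stack as a multi-page TIFF
#'
#' Intensities are rescaled from `[0, 255]` to `[0, 1]` for storage.
#'
#' @param vol a [voxel_volume()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_stack_tiff <- function(vol, path) {
  pages <- lapply(seq_len(dim(vol$data)[1]), function(k) {
    m <- vol$data[k, , ]
    pmin(pmax(m / 255, 0), 1)
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  invisible(path)
}

#' Read a multi-page TIFF as an image stack
#'
#' @param path TIFF file path.
#' @param voxel_size voxel size `(dz, dy, dx)` in mm to attach (TIFF carries
#'   no reliable 3-D calibration).
#' @return a [voxel_volume()] with intensities in `[0, 255]`.
#' @export
read_stack_tiff <- function(path, voxel_size = c(1, 1, 1)) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  d <- dim(pages[[1]])
  arr <- array(0, dim = c(length(pages), d[1], d[2]))
  for (k in seq_along(pages)) {
    p <- pages[[k]]
    if (length(dim(p)) == 3L) p <- p[, , 1]
    arr[k, , ] <- p * 255
  }
  voxel_volume(arr, voxel_size)
}
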