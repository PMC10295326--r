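# Synthetic vertebral phantoms: ground-truth trabecular microstructure with
# prescribed morphometry, rendered as paired micro-CT-like and MDCT-like
# stacks.

# run code with a temporary RNG state seeded from `seed`
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Phantom specification
#'
#' Parameters of a synthetic vertebral trabecular phantom. Morphometric
#' targets default to reference micro-CT values for lumbar cancellous bone
#' (BV/TV 0.180, Tb.Th 0.218 mm, Tb.Sp 0.934 mm) on a 52 um isotropic grid.
#'
#' @param extent_mm physical size `(z, y, x)` in mm.
#' @param voxel_mm isotropic generation/micro-CT voxel size in mm (52 um
#'   default, the micro-CT effective pixel size).
#' @param target_bvtv bone volume fraction in (0, 1).
#' @param target_tbth_mm target mean trabecular thickness (mm).
#' @param target_tbsp_mm nominal trabecular separation (mm); recorded for
#'   reference, the realised value follows from the random-field geometry.
#' @param anisotropy per-axis `(z, y, x)` correlation-length weights; > 1 on
#'   z elongates trabeculae axially (primary compressive orientation).
#' @param cortical_thickness_mm thickness of the cortical shell added on the
#'   body boundary.
#' @param body_semiaxes_mm ellipse semi-axes `(y, x)` of the vertebral body
#'   cross-section; `NULL` fills 92% of the field of view.
#' @param canal_radius_mm radius of the posterior canal notch carved out of
#'   the body ellipse (0 disables).
#' @param intensities named 8-bit intensity levels `bone`, `marrow`, `soft`.
#' @param noise_sd additive Gaussian noise sd per modality,
#'   `c(micro = ..., mdct = ...)`.
#' @param psf_micro_vox sub-voxel Gaussian PSF sigma of the micro-CT
#'   rendering, in voxels.
#' @param mdct_fwhm_mm MDCT PSF FWHM `c(axial = 0.6, inplane = 0.4)` mm.
#' @param mdct_pixel_mm MDCT in-plane pixel size (0.195 mm: a 512 matrix over
#'   a 100 mm field of view).
#' @param structured logical; `FALSE` replaces the band-pass random field by
#'   a pure iid field (useful for exactness checks only).
#' @param seed RNG seed; the same seed and spec give bit-identical phantoms.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(extent_mm = c(6, 12, 13),
                         voxel_mm = 0.052,
                         target_bvtv = 0.180,
                         target_tbth_mm = 0.218,
                         target_tbsp_mm = 0.934,
                         anisotropy = c(1.3, 1, 1),
                         cortical_thickness_mm = 0.4,
                         body_semiaxes_mm = NULL,
                         canal_radius_mm = 0,
                         intensities = c(bone = 200, marrow = 50, soft = 80),
                         noise_sd = c(micro = 8, mdct = 4),
                         psf_micro_vox = 0.3,
                         mdct_fwhm_mm = c(axial = 0.6, inplane = 0.4),
                         mdct_pixel_mm = 0.195,
                         structured = TRUE,
                         seed = 1L) {
  spec <- list(extent_mm = as.numeric(extent_mm), voxel_mm = voxel_mm,
               target_bvtv = target_bvtv, target_tbth_mm = target_tbth_mm,
               target_tbsp_mm = target_tbsp_mm,
               anisotropy = as.numeric(anisotropy),
               cortical_thickness_mm = cortical_thickness_mm,
               body_semiaxes_mm = body_semiaxes_mm,
               canal_radius_mm = canal_radius_mm,
               intensities = intensities, noise_sd = noise_sd,
               psf_micro_vox = psf_micro_vox, mdct_fwhm_mm = mdct_fwhm_mm,
               mdct_pixel_mm = mdct_pixel_mm, structured = structured,
               seed = as.integer(seed))
  class(spec) <- "phantom_spec"
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  stopifnot(spec$target_bvtv > 0, spec$target_bvtv < 1,
            spec$target_tbth_mm > 0, spec$target_tbsp_mm > 0,
            spec$voxel_mm > 0, all(spec$extent_mm > 0),
            all(spec$anisotropy > 0))
  if (spec$structured && spec$target_tbth_mm < 2 * spec$voxel_mm) {
    stop(sprintf(
      "infeasible spec: target Tb.Th %.3f mm is below the resolution limit of 2 voxels (%.3f mm at %.3f mm voxels)",
      spec$target_tbth_mm, 2 * spec$voxel_mm, spec$voxel_mm))
  }
  invisible(spec)
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf(
    "<phantom_spec> %.1f x %.1f x %.1f mm at %.3f mm voxels (seed %d)\n",
    x$extent_mm[1], x$extent_mm[2], x$extent_mm[3], x$voxel_mm, x$seed))
  cat(sprintf("  targets: BV/TV %.3f, Tb.Th %.3f mm, Tb.Sp %.3f mm\n",
              x$target_bvtv, x$target_tbth_mm, x$target_tbsp_mm))
  invisible(x)
}

# 2-D body cross-section mask (ny x nx): ellipse minus posterior canal notch
body_cross_section <- function(spec, ny, nx) {
  ys <- (seq_len(ny) - 0.5) * spec$voxel_mm
  xs <- (seq_len(nx) - 0.5) * spec$voxel_mm
  cy <- mean(range(ys)); cx <- mean(range(xs))
  semi <- spec$body_semiaxes_mm
  if (is.null(semi)) {
    semi <- 0.46 * c(ny, nx) * spec$voxel_mm
  }
  e <- outer(((ys - cy) / semi[1])^2, ((xs - cx) / semi[2])^2, `+`) <= 1
  if (spec$canal_radius_mm > 0) {
    # canal carved at the posterior pole (largest y)
    ccy <- cy + semi[1]
    canal <- outer((ys - ccy)^2, (xs - cx)^2, `+`) <=
      spec$canal_radius_mm^2
    e <- e & !canal
  }
  e
}

# gaussian kernel helper (voxel units)
.gauss_kernel <- function(sigma) {
  half <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- exp(-0.5 * ((-half:half) / sigma)^2)
  k / sum(k)
}

# band-pass anisotropic Gaussian random field on an arbitrary grid
.grf_field <- function(dims, sigma_vox, anisotropy, structured) {
  f <- array(rnorm(prod(dims)), dim = dims)
  if (!structured) return(f)
  s <- sigma_vox * anisotropy
  lo <- gaussian_blur_vox(f, s)
  hi <- gaussian_blur_vox(f, 2 * s)
  g <- lo - hi
  (g - mean(g)) / sd(g)
}

# measured Tb.Th of a thresholded calibration field (cube, voxel units)
.calib_measure <- function(sigma_vox, spec, n = 56L) {
  f <- .grf_field(c(n, n, n), sigma_vox, spec$anisotropy, TRUE)
  n_fg <- round(spec$target_bvtv * length(f))
  thr <- sort(as.numeric(f), decreasing = TRUE)[n_fg]
  b <- voxel_volume(array(as.numeric(f >= thr), dim = dim(f)), rep(1, 3),
                    binary = TRUE)
  th <- local_thickness_map(b)
  mean(th$data[b$data != 0])
}

.calib_cache <- new.env(parent = emptyenv())

# filter scale (voxels) that realises the target Tb.Th; cached per condition
.calibrate_scale <- function(spec) {
  tb_vox <- spec$target_tbth_mm / spec$voxel_mm
  key <- paste(signif(tb_vox, 6), spec$target_bvtv,
               paste(spec$anisotropy, collapse = ","), sep = "|")
  hit <- .calib_cache[[key]]
  if (!is.null(hit)) return(hit)
  sigma <- tb_vox  # initial guess: thickness of the minority phase ~ sigma
  with_seed(99991L, {
    for (i in 1:3) {
      m <- .calib_measure(sigma, spec)
      sigma <- sigma * tb_vox / m
    }
  })
  .calib_cache[[key]] <- sigma
  sigma
}

#' Generate a ground-truth trabecular microstructure
#'
#' Builds a binary trabecular network inside a vertebral body cross-section
#' by thresholding an anisotropic band-pass-filtered Gaussian random field at
#' the quantile that realises the target BV/TV exactly (up to one voxel)
#' inside the cancellous region, and adds a cortical shell on the body
#' boundary. Ground-truth Tb.Th/Tb.Sp are measured with the local-thickness
#' oracle on a central cancellous block and stored.
#'
#' @param spec a [phantom_spec()].
#' @return an object of class `phantom_ground_truth` with fields `binary`
#'   (bone = 1), `body_mask`, `cancellous_mask`, `bvtv_true`, `tbth_true_mm`,
#'   `tbsp_true_mm`, `computed_by`, `spec`.
#' @export
generate_trabecular_volume <- function(spec) {
  validate_phantom_spec(spec)
  dims <- pmax(2L, as.integer(round(spec$extent_mm / spec$voxel_mm)))
  vs <- rep(spec$voxel_mm, 3)

  bc <- body_cross_section(spec, dims[2], dims[3])
  body <- aperm(array(bc, dim = c(dims[2], dims[3], dims[1])), c(3, 1, 2))

  # cortical shell: body voxels within cortical_thickness of the boundary
  # (2-D in-plane distance; the body is prismatic along z)
  d2 <- .edt3d_sq(as.numeric(bc), c(dims[2], dims[3], 1L),
                  c(spec$voxel_mm, spec$voxel_mm, 1))
  shell2d <- bc & (sqrt(matrix(d2, dims[2], dims[3])) <=
                     spec$cortical_thickness_mm)
  canc2d <- bc & !shell2d
  shell <- aperm(array(shell2d, dim = c(dims[2], dims[3], dims[1])),
                 c(3, 1, 2))
  canc <- aperm(array(canc2d, dim = c(dims[2], dims[3], dims[1])),
                c(3, 1, 2))

  sigma <- if (spec$structured) .calibrate_scale(spec) else 1
  f <- with_seed(spec$seed,
                 .grf_field(dims, sigma, spec$anisotropy, spec$structured))

  n_canc <- sum(canc)
  if (n_canc < 100L) stop("cancellous region too small; enlarge the phantom")
  n_fg <- round(spec$target_bvtv * n_canc)
  vals <- f[canc]
  thr <- sort(vals, decreasing = TRUE)[n_fg]
  trab <- canc & (f >= thr)
  binary <- array(as.numeric(trab | shell), dim = dims)
  bvtv_true <- sum(trab) / n_canc

  # ground-truth thickness oracle on a central cancellous block
  side <- pmin(dims, 72L)
  lo <- pmax(1L, as.integer(floor((dims - side) / 2)) + 1L)
  rg <- lapply(1:3, function(a) lo[a]:(lo[a] + side[a] - 1L))
  sub <- binary[rg[[1]], rg[[2]], rg[[3]], drop = FALSE]
  subm <- canc[rg[[1]], rg[[2]], rg[[3]], drop = FALSE]
  subv <- voxel_volume(sub, vs, binary = TRUE)
  th <- tbth_tbsp(subv, subm)

  structure(
    list(binary = voxel_volume(binary, vs, binary = TRUE),
         body_mask = voxel_volume(array(as.numeric(body), dim = dims), vs,
                                  binary = TRUE),
         cancellous_mask = voxel_volume(array(as.numeric(canc), dim = dims),
                                        vs, binary = TRUE),
         bvtv_true = bvtv_true,
         tbth_true_mm = th$tbth_mm, tbsp_true_mm = th$tbsp_mm,
         computed_by = "oracle", spec = spec),
    class = "phantom_ground_truth"
  )
}

#' @export
print.phantom_ground_truth <- function(x, ...) {
  cat("<phantom_ground_truth>\n")
  print(x$binary)
  cat(sprintf("  BV/TV %.4f | Tb.Th %.3f mm | Tb.Sp %.3f mm (%s)\n",
              x$bvtv_true, x$tbth_true_mm, x$tbsp_true_mm, x$computed_by))
  invisible(x)
}

# continuous two-level intensity field from the ground truth
.intensity_field <- function(gt, spec) {
  iv <- spec$intensities
  out <- array(iv[["soft"]], dim = dim(gt$binary$data))
  body <- gt$body_mask$data > 0
  out[body] <- iv[["marrow"]]
  out[gt$binary$data > 0] <- iv[["bone"]]
  out
}

#' Render the micro-CT-like stack of a phantom
#'
#' 8-bit volume on the generation grid (52 um default): bone bright, marrow
#' and soft tissue dark, with a mild sub-voxel Gaussian PSF and additive
#' Gaussian noise.
#'
#' @param gt a `phantom_ground_truth`.
#' @param spec its [phantom_spec()] (noise and PSF settings are read here).
#' @return a grayscale [voxel_volume()].
#' @export
render_micro_ct <- function(gt, spec = gt$spec) {
  img <- .intensity_field(gt, spec)
  if (spec$psf_micro_vox > 0) {
    img <- gaussian_blur_vox(img, rep(spec$psf_micro_vox, 3))
  }
  ns <- spec$noise_sd[["micro"]]
  if (ns > 0) {
    img <- img + with_seed(spec$seed + 1L,
                           array(rnorm(length(img), sd = ns), dim = dim(img)))
  }
  voxel_volume(array(pmin(pmax(round(img), 0), 255), dim = dim(img)),
               gt$binary$voxel_size, gt$binary$origin)
}

#' Render the MDCT-like stack of a phantom
#'
#' Applies an anisotropic Gaussian PSF (FWHM ~ in-plane resolution laterally,
#' ~ slice thickness axially) to the continuous intensity field, resamples to
#' the MDCT grid (0.195 mm in-plane by default; half the micro-CT slice count
#' over the same extent), adds noise and quantizes to 8 bits.
#'
#' @param gt a `phantom_ground_truth`.
#' @param spec its [phantom_spec()].
#' @return a grayscale [voxel_volume()] on the MDCT grid.
#' @export
render_mdct <- function(gt, spec = gt$spec) {
  vs <- gt$binary$voxel_size
  if (spec$mdct_pixel_mm < vs[2] - 1e-12) {
    stop("requested MDCT grid is finer than the source grid")
  }
  img <- .intensity_field(gt, spec)
  sig_mm <- c(spec$mdct_fwhm_mm[["axial"]], spec$mdct_fwhm_mm[["inplane"]],
              spec$mdct_fwhm_mm[["inplane"]]) / (2 * sqrt(2 * log(2)))
  sig_vox <- sig_mm / vs
  if (any(sig_vox > 0)) img <- gaussian_blur_vox(img, sig_vox)

  dims <- dim(img)
  n_micro <- dims[1]
  n_mdct <- as.integer(ceiling(n_micro / 2))
  extent <- dims * vs
  dz <- extent[1] / n_mdct
  nyx <- pmax(1L, as.integer(round(extent[2:3] / spec$mdct_pixel_mm)))
  src <- voxel_volume(img, vs, gt$binary$origin)
  out <- resample_volume(src, c(dz, spec$mdct_pixel_mm, spec$mdct_pixel_mm),
                         dims = c(n_mdct, nyx[1], nyx[2]))
  ns <- spec$noise_sd[["mdct"]]
  if (ns > 0) {
    out$data <- out$data + with_seed(spec$seed + 2L,
      array(rnorm(length(out$data), sd = ns), dim = dim(out$data)))
  }
  out$data <- array(pmin(pmax(round(out$data), 0), 255), dim = dim(out$data))
  out
}

#' Generate a cohort of phantoms with paired renderings
#'
#' Per-vertebra specs are jittered around the template (BV/TV sd 0.016,
#' Tb.Th sd 0.015 mm, matching the spread of reference micro-CT morphometry)
#' and all randomness derives from the single master seed.
#'
#' @param n_vertebrae number of phantoms.
#' @param template a [phantom_spec()] template.
#' @param seed master seed.
#' @param jitter_sd named jitter standard deviations (`bvtv`, `tbth_mm`).
#' @return list of records `list(id, spec, gt, micro, mdct)`.
#' @export
make_study_set <- function(n_vertebrae, template = phantom_spec(),
                           seed = 1L,
                           jitter_sd = c(bvtv = 0.016, tbth_mm = 0.015)) {
  jit <- with_seed(seed, list(
    bvtv = rnorm(n_vertebrae, 0, jitter_sd[["bvtv"]]),
    tbth = rnorm(n_vertebrae, 0, jitter_sd[["tbth_mm"]])
  ))
  lapply(seq_len(n_vertebrae), function(i) {
    sp <- template
    sp$target_bvtv <- min(0.9, max(0.02, template$target_bvtv + jit$bvtv[i]))
    sp$target_tbth_mm <- max(2 * sp$voxel_mm,
                             template$target_tbth_mm + jit$tbth[i])
    sp$seed <- as.integer(seed + 1000L * i)
    gt <- generate_trabecular_volume(sp)
    list(id = i, spec = sp, gt = gt,
         micro = render_micro_ct(gt, sp), mdct = render_mdct(gt, sp))
  })
}

#' Write a phantom record to disk
#'
#' Writes one multi-page TIFF per modality plus a JSON sidecar holding the
#' spec, seed and ground-truth morphometry.
#'
#' @param record an element of [make_study_set()]'s result.
#' @param dir output directory (created if missing).
#' @return the sidecar path, invisibly.
#' @export
write_phantom <- function(record, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  base <- file.path(dir, sprintf("vertebra_%03d", record$id))
  write_stack_tiff(record$micro, paste0(base, "_micro.tif"))
  write_stack_tiff(record$mdct, paste0(base, "_mdct.tif"))
  side <- list(
    id = record$id,
    spec = record$spec[setdiff(names(record$spec), "intensities")],
    intensities = as.list(record$spec$intensities),
    ground_truth = list(bvtv_true = record$gt$bvtv_true,
                        tbth_true_mm = record$gt$tbth_true_mm,
                        tbsp_true_mm = record$gt$tbsp_true_mm,
                        computed_by = record$gt$computed_by),
    voxel_size_micro = record$micro$voxel_size,
    voxel_size_mdct = record$mdct$voxel_size)
  jsonlite::write_json(side, paste0(base, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paste0(base, ".json"))
}
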