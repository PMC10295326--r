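# Similarity metrics (SSIM, Frechet distance on feature embeddings) and the
# statistical battery used to compare generated and reference image sets.

#' Structural similarity index
#'
#' Standard windowed SSIM: per-window luminance/contrast/structure product
#' with an 11 x 11 Gaussian window (sigma 1.5), `C1 = (0.01 L)^2`,
#' `C2 = (0.03 L)^2`, averaged over all fully contained windows.
#'
#' @param a,b numeric matrices of identical shape.
#' @param L dynamic range (255 for 8-bit images).
#' @return scalar in `[-1, 1]`.
#' @export
ssim <- function(a, b, L = 255) {
  if (!all(dim(a) == dim(b))) stop("images must have the same shape")
  win <- 11L
  if (any(dim(a) < win)) stop("images smaller than the 11 x 11 SSIM window")
  g <- exp(-0.5 * ((-5:5) / 1.5)^2)
  w <- outer(g, g)
  w <- w / sum(w)
  C1 <- (0.01 * L)^2
  C2 <- (0.03 * L)^2
  mu_a <- .filter2_valid(a, w)
  mu_b <- .filter2_valid(b, w)
  s_aa <- .filter2_valid(a * a, w) - mu_a^2
  s_bb <- .filter2_valid(b * b, w) - mu_b^2
  s_ab <- .filter2_valid(a * b, w) - mu_a * mu_b
  num <- (2 * mu_a * mu_b + C1) * (2 * s_ab + C2)
  den <- (mu_a^2 + mu_b^2 + C1) * (s_aa + s_bb + C2)
  mean(num / den)
}

.embed_cache <- new.env(parent = emptyenv())

# seed-frozen random convolutional projector weights
.embed_weights <- function(seed, width = 4L) {
  key <- paste(seed, width, sep = "|")
  hit <- .embed_cache[[key]]
  if (!is.null(hit)) return(hit)
  w <- with_seed(seed, list(
    W1 = .he_init(3L, 1L, width), b1 = numeric(width),
    W2 = .he_init(3L, width, 2L * width), b2 = numeric(2L * width)))
  .embed_cache[[key]] <- w
  w
}

#' Embed images as fixed-length feature vectors
#'
#' Default extractor: a weight-frozen random convolutional projector (two
#' strided conv + ReLU stages, per-channel spatial mean and standard
#' deviation pooling), fully determined by `seed`. Feature distances are
#' therefore comparable only within one run configuration. A user-supplied
#' `extractor` function (image -> numeric vector) can replace it, e.g. a
#' pretrained network.
#'
#' @param images list of matrices with intensities in `[0, 255]`.
#' @param seed seed freezing the projector weights.
#' @param extractor optional function overriding the default projector.
#' @return matrix (n_images x feature_dim).
#' @export
embed_images <- function(images, seed = 7L, extractor = NULL) {
  if (is.null(extractor)) {
    wts <- .embed_weights(seed)
    extractor <- function(img) {
      x <- .as_tensor(img / 255)
      h1 <- conv_prim_fwd(wts$W1, wts$b1, x, 2L, 1L)$y
      h1 <- pmax(h1, 0)
      h2 <- conv_prim_fwd(wts$W2, wts$b2, h1, 2L, 1L)$y
      h2 <- pmax(h2, 0)
      m <- matrix(h2, prod(dim(h2)[1:2]), dim(h2)[3])
      c(colMeans(m), apply(m, 2L, stats::sd))
    }
  }
  t(vapply(images, extractor, numeric(length(extractor(images[[1]])))))
}

#' Frechet distance between Gaussian fits of two feature sets
#'
#' `||mu1 - mu2||^2 + Tr(S1 + S2 - 2 (S1 S2)^{1/2})`, with the symmetric
#' matrix square root computed by eigendecomposition; eigenvalues below
#' -1e-8 are an error of conditioning, small negatives are clipped to zero.
#' Singular covariances are regularized by a ridge `epsilon I` (messaged).
#'
#' @param features_a,features_b matrices (observations x features), at least
#'   two rows each.
#' @param ridge ridge added when a covariance is numerically singular.
#' @return nonnegative scalar.
#' @export
fid <- function(features_a, features_b, ridge = 1e-10) {
  if (ncol(features_a) != ncol(features_b)) stop("feature dimensions differ")
  if (nrow(features_a) < 2L || nrow(features_b) < 2L) {
    stop("need at least two feature vectors per set")
  }
  mu1 <- colMeans(features_a)
  mu2 <- colMeans(features_b)
  S1 <- stats::cov(features_a)
  S2 <- stats::cov(features_b)
  fix <- function(S) {
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < max(abs(ev)) * 1e-12) {
      message("singular covariance: ridge ", ridge, " added")
      S <- S + diag(ridge, ncol(S))
    }
    S
  }
  S1 <- fix(S1)
  S2 <- fix(S2)
  e1 <- eigen(S1, symmetric = TRUE)
  v1 <- pmax(e1$values, 0)
  S1h <- e1$vectors %*% (sqrt(v1) * t(e1$vectors))
  M <- S1h %*% S2 %*% S1h
  M <- (M + t(M)) / 2
  ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) stop("matrix square root failed: eigenvalue ", min(ev))
  ev <- pmax(ev, 0)
  val <- sum((mu1 - mu2)^2) + sum(diag(S1)) + sum(diag(S2)) - 2 * sum(sqrt(ev))
  max(val, 0)
}

#' Crop a volume to the cancellous interior
#'
#' Erodes the body mask by the cortical thickness plus a margin (exact
#' Euclidean distance to the exterior) and crops to the bounding box of what
#' remains, isolating the cancellous compartment.
#'
#' @param volume a [voxel_volume()] (grayscale or binary).
#' @param body_mask a binary [voxel_volume()] of the body region.
#' @param cortical_thickness_mm shell thickness to strip.
#' @param margin_mm extra erosion margin.
#' @return list with `volume` (cropped), `mask` (cropped eroded mask) and
#'   `bbox` (index ranges in the source grid).
#' @export
cancellous_crop <- function(volume, body_mask, cortical_thickness_mm = 0.4,
                            margin_mm = 0) {
  r <- cortical_thickness_mm + margin_mm
  b <- body_mask$data > 0
  d2 <- .edt3d_sq(as.numeric(b), dim(b), body_mask$voxel_size)
  inner <- b & (array(sqrt(d2), dim = dim(b)) > r)
  if (!any(inner)) stop("empty region after erosion; reduce the margin")
  ix <- which(inner, arr.ind = TRUE)
  bbox <- lapply(1:3, function(a) min(ix[, a]):max(ix[, a]))
  sub <- volume$data[bbox[[1]], bbox[[2]], bbox[[3]], drop = FALSE]
  list(volume = voxel_volume(sub, volume$voxel_size, binary = volume$binary),
       mask = inner[bbox[[1]], bbox[[2]], bbox[[3]], drop = FALSE],
       bbox = bbox)
}

#' Compare metric distributions across methods
#'
#' Runs the standard battery on per-subject metric values: Kolmogorov-
#' Smirnov normality and Levene homogeneity pre-checks, then a Friedman test
#' across three or more related groups, a Mann-Whitney U test for two
#' independent groups, and a paired t-test for two paired groups. Two-sided
#' p-values, alpha 0.05.
#'
#' @param groups named list of numeric vectors (equal lengths for paired
#'   tests; rows are subjects).
#' @param paired logical; whether two groups are paired observations.
#' @return data.frame of class `stats_report` with columns `test`,
#'   `statistic`, `p_value`, `groups`.
#' @export
compare_methods <- function(groups, paired = TRUE) {
  if (length(groups) < 2L) stop("need at least two groups")
  nm <- names(groups)
  if (is.null(nm)) nm <- paste0("g", seq_along(groups))
  rows <- list()
  add <- function(test, stat, p, g) {
    rows[[length(rows) + 1L]] <<- data.frame(
      test = test, statistic = as.numeric(stat), p_value = as.numeric(p),
      groups = g, stringsAsFactors = FALSE)
  }
  for (i in seq_along(groups)) {
    x <- groups[[i]]
    if (stats::sd(x) > 0) {
      ks <- suppressWarnings(ks.test(scale(x), "pnorm"))
      add("kolmogorov_smirnov_normality", ks$statistic, ks$p.value, nm[i])
    }
  }
  stacked <- data.frame(
    value = unlist(groups, use.names = FALSE),
    group = factor(rep(nm, lengths(groups))))
  lev <- car::leveneTest(value ~ group, data = stacked)
  add("levene_homogeneity", lev$`F value`[1], lev$`Pr(>F)`[1],
      paste(nm, collapse = ","))
  if (length(groups) >= 3L) {
    if (length(unique(lengths(groups))) != 1L) {
      stop("Friedman test needs equal-length (related) groups")
    }
    mat <- do.call(cbind, groups)
    if (all(apply(mat, 1L, function(r) max(r) == min(r)))) {
      # fully tied rows: no rank differences, chi-squared statistic is 0
      add("friedman", 0, 1, paste(nm, collapse = ","))
    } else {
      fr <- friedman.test(mat)
      add("friedman", fr$statistic, fr$p.value, paste(nm, collapse = ","))
    }
  } else {
    if (paired) {
      tt <- t.test(groups[[1]], groups[[2]], paired = TRUE)
      add("paired_t", tt$statistic, tt$p.value, paste(nm, collapse = ","))
    }
    mw <- suppressWarnings(wilcox.test(groups[[1]], groups[[2]],
                                       exact = FALSE))
    add("mann_whitney_u", mw$statistic, mw$p.value,
        paste(nm, collapse = ","))
  }
  out <- do.call(rbind, rows)
  class(out) <- c("stats_report", "data.frame")
  out
}

#' Linear regression between reference and generated metrics
#'
#' Ordinary least squares of `y` on `x` with `R^2` and the overall
#' `F = R^2 (n - 2) / (1 - R^2)`.
#'
#' @param x reference metric values.
#' @param y generated metric values.
#' @return list with `slope`, `intercept`, `r_squared`, `f_value`, `p_value`,
#'   `n`.
#' @export
regress_metrics <- function(x, y) {
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 paired observations")
  if (stats::sd(x) == 0) stop("zero variance in x")
  fit <- lm(y ~ x)
  r2 <- 1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
  fv <- r2 * (n - 2) / (1 - r2)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = r2, f_value = fv,
       p_value = pf(fv, 1, n - 2, lower.tail = FALSE), n = n)
}

#' Compare two correlation coefficients (Fisher z-test)
#'
#' `z = (z1 - z2) / sqrt(1/(n1-3) + 1/(n2-3))` with `zi = atanh(ri)`;
#' two-sided normal p-value.
#'
#' @param r1,r2 correlation coefficients, `|r| < 1`.
#' @param n1,n2 sample sizes (>= 4).
#' @return list with `z`, `p_value`.
#' @export
compare_correlations <- function(r1, n1, r2, n2) {
  if (abs(r1) >= 1 || abs(r2) >= 1) stop("|r| must be < 1")
  if (n1 < 4 || n2 < 4) stop("need n >= 4 in both samples")
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  list(z = z, p_value = 2 * pnorm(-abs(z)))
}

#' Intraclass correlation coefficient ICC(2,1)
#'
#' Two-way random-effects model, absolute agreement, single measures, with a
#' 95% confidence interval from F-distribution bounds.
#'
#' @param pairs numeric matrix or data.frame with two columns (the two
#'   measurement methods) and one row per subject (n >= 5).
#' @param conf confidence level.
#' @return list with `icc`, `lower`, `upper`, `n`.
#' @export
icc <- function(pairs, conf = 0.95) {
  m <- as.matrix(pairs)
  m <- m[complete.cases(m), , drop = FALSE]
  n <- nrow(m)
  k <- ncol(m)
  if (n < 5L) stop("need at least 5 paired measurements")
  if (k != 2L) stop("expected exactly two measurement columns")
  grand <- mean(m)
  if (sum((m - grand)^2) == 0) stop("zero total variance")
  ri <- rowMeans(m)
  cj <- colMeans(m)
  ssr <- k * sum((ri - grand)^2)
  ssc <- n * sum((cj - grand)^2)
  sst <- sum((m - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  val <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
  # McGraw & Wong CI for ICC(A,1)
  alpha <- 1 - conf
  if (mse == 0 && msc == 0) {
    lo <- up <- 1
  } else {
    a <- (k * val) / (n * (1 - val))
    b <- 1 + (k * val * (n - 1)) / (n * (1 - val))
    v <- (a * msc + b * mse)^2 /
      ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
    fl <- qf(1 - alpha / 2, n - 1, v)
    fu <- qf(1 - alpha / 2, v, n - 1)
    lo <- n * (msr - fl * mse) /
      (fl * (k * msc + (k * n - k - n) * mse) + n * msr)
    up <- n * (fu * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * fu * msr)
  }
  list(icc = val, lower = lo, upper = up, n = n)
}

#' Assemble a full evaluation report
#'
#' Writes `metrics.csv` (per-subject similarity metrics), `stats.csv` (the
#' statistical battery) and a human-readable `summary.txt` for one scope
#' (overall or cancellous).
#'
#' @param ssim_by_method named list: per-method numeric vectors of per-pair
#'   SSIM values against the reference.
#' @param fid_by_method named numeric vector of set-level Frechet feature
#'   distances per method.
#' @param morphometry optional data.frame of per-subject bone structure
#'   metrics (columns `id`, `method`, `bvtv`, `tbth_mm`, `tbsp_mm`).
#' @param out_dir output directory.
#' @param scope `"overall"` or `"cancellous"`.
#' @return list with the file paths, invisibly.
#' @export
full_report <- function(ssim_by_method, fid_by_method, morphometry = NULL,
                        out_dir, scope = "overall") {
  if (length(ssim_by_method) == 0L) stop("empty method set")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  metrics <- do.call(rbind, lapply(names(ssim_by_method), function(m) {
    data.frame(method = m, pair = seq_along(ssim_by_method[[m]]),
               ssim = ssim_by_method[[m]])
  }))
  mp <- file.path(out_dir, "metrics.csv")
  write.csv(metrics, mp, row.names = FALSE)

  stats_rep <- if (length(ssim_by_method) >= 2L) {
    compare_methods(ssim_by_method)
  } else {
    data.frame(test = character(), statistic = numeric(),
               p_value = numeric(), groups = character())
  }
  sp <- file.path(out_dir, "stats.csv")
  write.csv(stats_rep, sp, row.names = FALSE)

  up <- file.path(out_dir, "summary.txt")
  con <- file(up, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("Evaluation summary (scope: %s)", scope),
    paste("NOTE: feature distances use a seed-frozen random convolutional",
          "projector, not a pretrained network; values are comparable only",
          "within one run configuration."),
    ""), con)
  for (m in names(ssim_by_method)) {
    v <- ssim_by_method[[m]]
    writeLines(sprintf("  %-18s SSIM %.4f +/- %.4f (n=%d)   FID %.4f",
                       m, mean(v), if (length(v) > 1) sd(v) else 0,
                       length(v),
                       if (m %in% names(fid_by_method))
                         fid_by_method[[m]] else NA_real_), con)
  }
  if (!is.null(morphometry) && nrow(morphometry) > 0) {
    writeLines(c("", "Bone structure metrics (mean +/- sd by method):"), con)
    for (m in unique(morphometry$method)) {
      sub <- morphometry[morphometry$method == m, ]
      writeLines(sprintf(
        "  %-18s BV/TV %.4f+/-%.4f  Tb.Th %.4f+/-%.4f  Tb.Sp %.4f+/-%.4f",
        m, mean(sub$bvtv), sd(sub$bvtv), mean(sub$tbth_mm), sd(sub$tbth_mm),
        mean(sub$tbsp_mm), sd(sub$tbsp_mm)), con)
    }
    write.csv(morphometry, file.path(out_dir, "morphometry.csv"),
              row.names = FALSE)
  }
  if (nrow(stats_rep) > 0) {
    writeLines(c("", "Statistical tests:"), con)
    writeLines(sprintf("  %-32s stat %10.4f  p %.4g  [%s]",
                       stats_rep$test, stats_rep$statistic,
                       stats_rep$p_value, stats_rep$groups), con)
  }
  invisible(list(metrics = mp, stats = sp, summary = up))
}
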