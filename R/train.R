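# Adversarial training loop: D ascends the GAN objective while G descends
# the GAN term plus weighted reconstruction and feature-matching losses.
# Each iteration draws one image from each of two distinct classes (the
# direction alternates randomly), so the discriminator sees both classes as
# real and as fake across iterations.

.gen_group_names <- c("ex", "ey", "fx", "mlp")

.flat_gen_params <- function(params) unlist(params[.gen_group_names], use.names = FALSE)

# relist a flat numeric vector into the nested array structure of `skeleton`
# (utils::relist drops array dims, so do it by hand)
.relist_like <- function(flat, skeleton) {
  pos <- 0L
  walk <- function(sk) {
    if (is.list(sk)) return(lapply(sk, walk))
    n <- length(sk)
    v <- flat[pos + seq_len(n)]
    pos <<- pos + n
    if (!is.null(dim(sk))) dim(v) <- dim(sk)
    v
  }
  out <- walk(skeleton)
  stopifnot(pos == length(flat))
  out
}

.set_gen_params <- function(model, flat) {
  model$params[.gen_group_names] <-
    .relist_like(flat, model$params[.gen_group_names])
  model
}

.add_grads <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  if (is.list(a)) return(mapply(.add_grads, a, b, SIMPLIFY = FALSE))
  a + b
}

# generator loss + gradients on one (x, y) draw; cy is y's class channel
.g_pass <- function(model, x3, y3, cy) {
  cfg <- model$config
  prm <- model$params
  arch <- model$arch
  w4 <- model$widths[4]

  ex_f <- net_fwd(arch$ex, prm$ex, x3)
  zx <- ex_f$out
  ey_f <- net_fwd(arch$ey, prm$ey, y3)
  zy <- ey_f$out
  mf <- .mlp_fwd(prm$mlp, zy, w4)
  fx_f <- net_fwd(arch$fx, prm$fx, zx, adain = mf$adain)
  xbar <- fx_f$out

  # adversarial + feature-matching through D (D params frozen here)
  nl <- length(arch$d)
  dfw <- net_fwd(arch$d, prm$d, xbar, keep_out = nl - 1L)
  feat_y <- net_fwd(arch$d[-nl], prm$d[-nl], y3)$out
  sc <- dfw$out
  p <- .clamp_prob(stats::plogis(sc[, , cy]), cfg$eps)
  np <- length(p)
  dscore <- array(0, dim = dim(sc))
  if (cfg$gan_form == "literal") {
    l_adv <- mean(log(1 - p))
    dscore[, , cy] <- -p / np
  } else {
    l_adv <- -mean(log(p))
    dscore[, , cy] <- (p - 1) / np
  }
  l_f <- mean(abs(dfw$kept - feat_y))
  dfeat <- cfg$lambda_f * sign(dfw$kept - feat_y) / length(feat_y)
  inj <- stats::setNames(list(dfeat), as.character(nl - 1L))
  dbk <- net_bwd(arch$d, prm$d, dfw$caches, dscore, inject = inj,
                 need_dx = TRUE)
  dxbar <- dbk$dx

  # reconstruction pass G(x, x): shares the content code zx
  ey_fr <- net_fwd(arch$ey, prm$ey, x3)
  mfr <- .mlp_fwd(prm$mlp, ey_fr$out, w4)
  fx_fr <- net_fwd(arch$fx, prm$fx, zx, adain = mfr$adain)
  xr <- fx_fr$out
  l_r <- mean(abs(x3 - xr))
  dxr <- cfg$lambda_r * sign(xr - x3) / length(xr)

  # backward: decoder (both passes), MLP, class encoder, content encoder
  fx_b1 <- net_bwd(arch$fx, prm$fx, fx_f$caches, dxbar, need_dx = TRUE)
  fx_b2 <- net_bwd(arch$fx, prm$fx, fx_fr$caches, dxr, need_dx = TRUE)
  m_b1 <- .mlp_bwd(prm$mlp, zy, mf$pre_s, fx_b1$dadain, w4)
  m_b2 <- .mlp_bwd(prm$mlp, ey_fr$out, mfr$pre_s, fx_b2$dadain, w4)
  ey_b1 <- net_bwd(arch$ey, prm$ey, ey_f$caches, m_b1$dzy, need_dx = FALSE)
  ey_b2 <- net_bwd(arch$ey, prm$ey, ey_fr$caches, m_b2$dzy, need_dx = FALSE)
  ex_b <- net_bwd(arch$ex, prm$ex, ex_f$caches, fx_b1$dx + fx_b2$dx,
                  need_dx = FALSE)

  grads <- list(ex = ex_b$grads,
                ey = .add_grads(ey_b1$grads, ey_b2$grads),
                fx = .add_grads(fx_b1$grads, fx_b2$grads),
                mlp = .add_grads(m_b1$grads, m_b2$grads))
  list(grads_flat = unlist(grads, use.names = FALSE), xbar = xbar,
       losses = c(adv = l_adv, l_r = l_r, l_f = l_f))
}

# discriminator loss + gradients: real image of class cx, fake of class cy
.d_pass <- function(model, x3, xbar, cx, cy) {
  cfg <- model$config
  arch <- model$arch
  prm <- model$params
  fr <- net_fwd(arch$d, prm$d, x3)
  ff <- net_fwd(arch$d, prm$d, xbar)
  p_r <- .clamp_prob(stats::plogis(fr$out[, , cx]), cfg$eps)
  p_f <- .clamp_prob(stats::plogis(ff$out[, , cy]), cfg$eps)
  d_obj <- mean(log(p_r)) + mean(log(1 - p_f))
  ds_r <- array(0, dim = dim(fr$out))
  ds_f <- array(0, dim = dim(ff$out))
  ds_r[, , cx] <- (p_r - 1) / length(p_r)  # d of -log(p) wrt score
  ds_f[, , cy] <- p_f / length(p_f)        # d of -log(1-p) wrt score
  b_r <- net_bwd(arch$d, prm$d, fr$caches, ds_r, need_dx = FALSE)
  b_f <- net_bwd(arch$d, prm$d, ff$caches, ds_f, need_dx = FALSE)
  list(grads_flat = unlist(.add_grads(b_r$grads, b_f$grads), use.names = FALSE), d_obj = d_obj)
}

.rmsprop <- function(theta, g, cache, lr, decay) {
  cache <- decay * cache + (1 - decay) * g^2
  list(theta = theta - lr * g / sqrt(cache + 1e-8), cache = cache)
}

#' Train the translation model
#'
#' Alternating min-max optimization: each iteration draws two images of
#' distinct classes, updates the discriminator on the saturating GAN
#' objective and then the generator on its adversarial term plus
#' `lambda_r` x reconstruction and `lambda_f` x feature-matching losses.
#' All randomness (weight init, batch sampling) flows from the config seed.
#'
#' @param mdct_images,micro_images lists of same-sized square matrices with
#'   intensities in `[0, 255]` (class 1 = MDCT, class 2 = micro-CT).
#' @param iterations number of optimization iterations.
#' @param config a [translator_config()].
#' @param model optionally continue training an existing `trab_translator`.
#' @param log_every record losses every this many iterations.
#' @param verbose print progress.
#' @return a `trab_translator` with updated parameters, optimizer state,
#'   iteration counter and a `loss_history` data frame. If a loss becomes
#'   non-finite, training aborts at that iteration and the returned model
#'   carries `diverged = TRUE`.
#' @export
train_translator <- function(mdct_images, micro_images, iterations = 2000L,
                             config = translator_config(), model = NULL,
                             log_every = 25L, verbose = FALSE) {
  if (is.null(model)) model <- init_translator(config)
  cfg <- model$config
  classes <- list(mdct_images, micro_images)
  stopifnot(length(classes[[1]]) > 0, length(classes[[2]]) > 0)
  scale01 <- function(m) m / 127.5 - 1

  pg <- .flat_gen_params(model$params)
  pd <- unlist(model$params$d, use.names = FALSE)
  if (is.null(model$opt)) {
    model$opt <- list(g = numeric(length(pg)), d = numeric(length(pd)))
  }
  hist <- model$loss_history
  set.seed(cfg$seed + model$iter + 1L)

  for (it in seq_len(iterations)) {
    cx <- sample(1:2, 1L)
    cy <- 3L - cx
    x <- .as_tensor(scale01(classes[[cx]][[sample(length(classes[[cx]]), 1L)]]))
    y <- .as_tensor(scale01(classes[[cy]][[sample(length(classes[[cy]]), 1L)]]))

    gp <- .g_pass(model, x, y, cy)
    dp <- .d_pass(model, x, gp$xbar, cx, cy)

    if (!all(is.finite(c(gp$losses, dp$d_obj)))) {
      warning(sprintf("non-finite loss at iteration %d; training aborted",
                      model$iter + it))
      model$diverged <- TRUE
      break
    }
    up_d <- .rmsprop(pd, dp$grads_flat, model$opt$d, cfg$lr, cfg$rmsprop_decay)
    pd <- up_d$theta
    model$opt$d <- up_d$cache
    model$params$d <- .relist_like(pd, model$params$d)

    up_g <- .rmsprop(pg, gp$grads_flat, model$opt$g, cfg$lr, cfg$rmsprop_decay)
    pg <- up_g$theta
    model$opt$g <- up_g$cache
    model <- .set_gen_params(model, pg)

    if (it %% log_every == 0L || it == iterations) {
      hist <- rbind(hist, data.frame(
        iter = model$iter + it, d_objective = dp$d_obj,
        g_adv = gp$losses[["adv"]], l_r = gp$losses[["l_r"]],
        l_f = gp$losses[["l_f"]]))
      if (verbose) {
        cat(sprintf("iter %5d  D %8.4f  G_adv %8.4f  L_R %7.4f  L_F %7.4f\n",
                    model$iter + it, dp$d_obj, gp$losses[["adv"]],
                    gp$losses[["l_r"]], gp$losses[["l_f"]]))
      }
    }
  }
  model$iter <- model$iter + iterations
  model$loss_history <- hist
  model
}

#' @export
print.trab_translator <- function(x, ...) {
  np <- length(.flat_gen_params(x$params))
  nd <- length(unlist(x$params$d))
  cat(sprintf(
    "<trab_translator> %d x %d images, %d generator + %d discriminator parameters\n",
    x$config$img_size, x$config$img_size, np, nd))
  cat(sprintf("  trained %d iterations (lambda_R = %.3g, lambda_F = %.3g)%s\n",
              x$iter, x$config$lambda_r, x$config$lambda_f,
              if (isTRUE(x$diverged)) " [diverged]" else ""))
  invisible(x)
}

#' @export
summary.trab_translator <- function(object, ...) {
  print(object)
  if (nrow(object$loss_history) > 0) {
    cat("last logged losses:\n")
    print(utils::tail(object$loss_history, 3L), row.names = FALSE)
  }
  invisible(object)
}

#' @export
plot.trab_translator <- function(x, ...) {
  h <- x$loss_history
  if (nrow(h) == 0) {
    warning("no loss history to plot")
    return(invisible(x))
  }
  graphics::matplot(h$iter, cbind(h$d_objective, h$g_adv, h$l_r, h$l_f),
                    type = "l", lty = 1, xlab = "iteration", ylab = "loss",
                    ...)
  graphics::legend("topright", c("D objective", "G adversarial",
                                 "reconstruction", "feature matching"),
                   col = 1:4, lty = 1, cex = 0.8)
  invisible(x)
}

#' Translate an image with a trained model
#'
#' @param object a `trab_translator`.
#' @param x source image matrix in `[0, 255]` (resized to the model's input
#'   size if needed).
#' @param ys target-class reference image(s) in `[0, 255]`.
#' @param ... unused.
#' @return translated image matrix in `[0, 255]` at the model's input size.
#' @export
predict.trab_translator <- function(object, x, ys, ...) {
  sz <- object$config$img_size
  fit <- function(m) {
    if (!all(dim(m) == c(sz, sz))) m <- .bicubic_resize(m, sz, sz)
    m / 127.5 - 1
  }
  if (!is.list(ys)) ys <- list(ys)
  out <- generate(object, fit(x), lapply(ys, fit))
  (out + 1) * 127.5
}

#' Translate a whole MDCT stack into a micro-CT-like stack
#'
#' Slice-wise generation: each MDCT slice is upsampled to the model's input
#' grid and translated under a class code averaged over the reference
#' micro-CT slices. The output stack keeps the source's physical extent on
#' the finer in-plane grid.
#'
#' @param model a trained `trab_translator`.
#' @param mdct_stack a [voxel_volume()].
#' @param ref_micro a [voxel_volume()] or list of micro-CT reference slices.
#' @param n_ref number of reference slices used for the class code.
#' @return a [voxel_volume()] with the same slice count as the input.
#' @export
translate_stack <- function(model, mdct_stack, ref_micro, n_ref = 4L) {
  refs <- if (inherits(ref_micro, "voxel_volume")) {
    ks <- unique(round(seq(1, dim(ref_micro$data)[1],
                           length.out = min(n_ref, dim(ref_micro$data)[1]))))
    lapply(ks, function(k) ref_micro$data[k, , ])
  } else {
    utils::head(ref_micro, n_ref)
  }
  sz <- model$config$img_size
  nz <- dim(mdct_stack$data)[1]
  out <- array(0, dim = c(nz, sz, sz))
  for (k in seq_len(nz)) {
    out[k, , ] <- pmin(pmax(
      predict(model, mdct_stack$data[k, , ], refs), 0), 255)
  }
  ext <- dim(mdct_stack$data)[2:3] * mdct_stack$voxel_size[2:3]
  voxel_volume(out, c(mdct_stack$voxel_size[1], ext[1] / sz, ext[2] / sz),
               mdct_stack$origin)
}

#' Save / load a translation model checkpoint
#'
#' The checkpoint is a single self-describing file (config embedded);
#' reloading reproduces the forward pass bit-identically.
#'
#' @param model a `trab_translator`.
#' @param path file path.
#' @return `path` (save) or the model (load).
#' @export
save_translator <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_translator
#' @export
load_translator <- function(path) readRDS(path)
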