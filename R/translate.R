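# Unpaired image-to-image translation model: content encoder Ex, class
# encoder Ey, AdaIN-conditioned decoder Fx, and a multi-class patch
# discriminator D, trained with an adversarial loss, an L1 reconstruction
# loss and a discriminator-feature matching loss.

.content_arch <- function(w) {
  list(ly_conv(1L, w[1], 3L, 1L, 1L, "in", "relu"),
       ly_conv(w[1], w[2], 4L, 2L, 1L, "in", "relu"),
       ly_conv(w[2], w[3], 4L, 2L, 1L, "in", "relu"),
       ly_conv(w[3], w[4], 4L, 2L, 1L, "in", "relu"),
       ly_res_in(w[4]), ly_res_in(w[4]))
}

.class_arch <- function(w, code_dim) {
  list(ly_conv(1L, w[1], 3L, 1L, 1L, "none", "relu"),
       ly_conv(w[1], w[2], 4L, 2L, 1L, "none", "relu"),
       ly_conv(w[2], w[3], 4L, 2L, 1L, "none", "relu"),
       ly_conv(w[3], w[3], 4L, 2L, 1L, "none", "relu"),
       ly_gap(),
       ly_fc(w[3], code_dim, "none"))
}

.decoder_arch <- function(w) {
  list(ly_res_adain(w[4], 1L), ly_res_adain(w[4], 2L),
       ly_up(), ly_conv(w[4], w[3], 3L, 1L, 1L, "in", "relu"),
       ly_up(), ly_conv(w[3], w[2], 3L, 1L, 1L, "in", "relu"),
       ly_up(), ly_conv(w[2], w[1], 3L, 1L, 1L, "in", "relu"),
       ly_conv(w[1], 1L, 3L, 1L, 1L, "none", "tanh"))
}

# Conv -> 10 residual blocks without normalization (Leaky ReLU) with four
# 2x2 average-pool halvings -> final conv with one score channel per class.
.disc_arch <- function(dw, n_class = 2L) {
  list(ly_conv(1L, dw, 3L, 1L, 1L, "none", "none"),
       ly_res_plain(dw, 2L * dw), ly_res_plain(2L * dw, 2L * dw), ly_pool(),
       ly_res_plain(2L * dw, 4L * dw), ly_res_plain(4L * dw, 4L * dw),
       ly_pool(),
       ly_res_plain(4L * dw, 8L * dw), ly_res_plain(8L * dw, 8L * dw),
       ly_pool(),
       ly_res_plain(8L * dw, 8L * dw), ly_res_plain(8L * dw, 8L * dw),
       ly_pool(),
       ly_res_plain(8L * dw, 8L * dw), ly_res_plain(8L * dw, 8L * dw),
       ly_conv(8L * dw, n_class, 1L, 1L, 0L, "none", "none"))
}

#' Translation model configuration
#'
#' Defaults are desk scale: 64 x 64 single-channel slices and thin channel
#' widths so a smoke training run fits on one CPU. Full-scale widths are
#' reachable through `base_width` / `d_width`.
#'
#' @param img_size input side length (must be divisible by 16).
#' @param base_width generator stem width; encoder widths are
#'   `base_width * c(1, 2, 4, 8)`.
#' @param d_width discriminator stem width.
#' @param class_code_dim length of the class latent code.
#' @param lambda_r,lambda_f reconstruction / feature-matching loss weights.
#' @param lr RMSProp learning rate.
#' @param rmsprop_decay second-moment decay.
#' @param gan_form `"nonsaturating"` (default) or `"literal"` generator
#'   adversarial term; the saturating log form is always used for D.
#' @param eps probability clamp inside logs.
#' @param seed master seed for weight init and batch sampling.
#' @return a list of class `translator_config`.
#' @export
translator_config <- function(img_size = 64L, base_width = 4L, d_width = 4L,
                              class_code_dim = 8L, lambda_r = 0.1,
                              lambda_f = 1.0, lr = 1e-4,
                              rmsprop_decay = 0.99,
                              gan_form = c("nonsaturating", "literal"),
                              eps = 1e-7, seed = 1L) {
  structure(list(img_size = as.integer(img_size),
                 base_width = as.integer(base_width),
                 d_width = as.integer(d_width),
                 class_code_dim = as.integer(class_code_dim),
                 lambda_r = lambda_r, lambda_f = lambda_f, lr = lr,
                 rmsprop_decay = rmsprop_decay,
                 gan_form = match.arg(gan_form), eps = eps,
                 seed = as.integer(seed), n_class = 2L),
            class = "translator_config")
}

#' Initialize an untrained translation model
#'
#' @param config a [translator_config()].
#' @return an object of class `trab_translator` holding all learnable
#'   parameters of the generator (Ex, Ey, Fx, AdaIN MLPs) and the
#'   discriminator, plus optimizer state and the iteration counter.
#' @export
init_translator <- function(config = translator_config()) {
  w <- config$base_width * c(1L, 2L, 4L, 8L)
  arch <- list(ex = .content_arch(w), ey = .class_arch(w, config$class_code_dim),
               fx = .decoder_arch(w), d = .disc_arch(config$d_width,
                                                     config$n_class))
  cd <- config$class_code_dim
  nada <- 2L * w[4]  # two AdaIN residual blocks, one (g, b) pair each
  params <- with_seed(config$seed, list(
    ex = net_init(arch$ex), ey = net_init(arch$ey), fx = net_init(arch$fx),
    mlp = list(
      Wm = matrix(rnorm(nada * cd, sd = sqrt(1 / cd)), nada, cd),
      bm = numeric(nada),
      Ws = matrix(rnorm(nada * cd, sd = sqrt(1 / cd)), nada, cd),
      # softplus(0.55) ~ 1: start AdaIN scales near identity
      bs = rep(0.55, nada)),
    d = net_init(arch$d)))
  structure(list(params = params, arch = arch, config = config,
                 widths = w, opt = NULL, iter = 0L,
                 loss_history = data.frame()),
            class = "trab_translator")
}

.softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))

# AdaIN parameters (per-block scale/bias) from a class code
.mlp_fwd <- function(mlp, zy, w4) {
  pre_m <- as.numeric(mlp$Wm %*% zy + mlp$bm)
  pre_s <- as.numeric(mlp$Ws %*% zy + mlp$bs)
  sig <- .softplus(pre_s)
  adain <- list(list(g = sig[1:w4], b = pre_m[1:w4]),
                list(g = sig[w4 + 1:w4], b = pre_m[w4 + 1:w4]))
  list(adain = adain, pre_s = pre_s)
}

.mlp_bwd <- function(mlp, zy, pre_s, dadain, w4) {
  dm <- numeric(2L * w4)
  ds <- numeric(2L * w4)
  for (bidx in names(dadain)) {
    b <- as.integer(bidx)
    sl <- (b - 1L) * w4 + 1:w4
    dm[sl] <- dm[sl] + dadain[[bidx]]$db
    ds[sl] <- ds[sl] + dadain[[bidx]]$dg
  }
  dpre_s <- ds * (1 / (1 + exp(-pre_s)))  # softplus'
  list(grads = list(Wm = matrix(dm, ncol = 1) %*% matrix(zy, nrow = 1),
                    bm = dm,
                    Ws = matrix(dpre_s, ncol = 1) %*% matrix(zy, nrow = 1),
                    bs = dpre_s),
       dzy = as.numeric(crossprod(mlp$Wm, dm) + crossprod(mlp$Ws, dpre_s)))
}

.as_tensor <- function(x) {
  if (length(dim(x)) == 2L) array(x, dim = c(dim(x), 1L)) else x
}

#' Encode image content
#'
#' Maps an input image to a spatial content code through a convolution stack
#' with instance normalization, three stride-2 downsamplings and residual
#' blocks. Output spatial dimensions are the input's divided by 8.
#'
#' @param model a `trab_translator`.
#' @param x image matrix or `(h, w, 1)` array, values in `[-1, 1]`.
#' @return content code array `(h/8, w/8, channels)`.
#' @export
content_encode <- function(model, x) {
  x <- .as_tensor(x)
  if (any(dim(x)[1:2] %% 8L != 0L)) {
    stop("content encoder input dimensions must be divisible by 8")
  }
  net_fwd(model$arch$ex, model$params$ex, x)$out
}

#' Encode a class latent code from one or more class images
#'
#' Each image is embedded by a convolutional network; the codes are averaged
#' along the sampling axis.
#'
#' @param model a `trab_translator`.
#' @param ys a single image or a list of images of the target class.
#' @return class code vector.
#' @export
class_encode <- function(model, ys) {
  if (!is.list(ys)) ys <- list(ys)
  if (length(ys) == 0L) stop("class_encode needs at least one image (K >= 1)")
  codes <- lapply(ys, function(y) {
    net_fwd(model$arch$ey, model$params$ey, .as_tensor(y))$out
  })
  Reduce(`+`, codes) / length(codes)
}

#' Decode a content code under a class code
#'
#' The class code is injected through AdaIN residual blocks (one scale/bias
#' pair per block from two fully connected networks, applied uniformly at
#' every spatial location), followed by nearest-neighbour x2 upsampling
#' stages back to the input resolution.
#'
#' @param model a `trab_translator`.
#' @param zx content code from [content_encode()].
#' @param zy class code from [class_encode()].
#' @return decoded image matrix in `[-1, 1]`.
#' @export
decode <- function(model, zx, zy) {
  mf <- .mlp_fwd(model$params$mlp, zy, model$widths[4])
  out <- net_fwd(model$arch$fx, model$params$fx, zx, adain = mf$adain)$out
  out[, , 1]
}

#' Generate a translated image
#'
#' `decode(content_encode(x), class_encode(y))`: the translation
#' `x-bar = G(x, y1..yK)` with K mapping targets (K = 1 in this study:
#' micro-CT is the only target class).
#'
#' @param model a `trab_translator`.
#' @param x source-class image in `[-1, 1]`.
#' @param ys target-class image(s).
#' @return translated image matrix.
#' @export
generate <- function(model, x, ys) {
  decode(model, content_encode(model, x), class_encode(model, ys))
}

#' Patch discriminator scores
#'
#' @param model a `trab_translator`.
#' @param img image in `[-1, 1]`.
#' @param class 1 (source/MDCT) or 2 (target/micro-CT).
#' @return per-patch raw score matrix for the requested class channel.
#' @export
discriminate <- function(model, img, class = 2L) {
  img <- .as_tensor(img)
  if (any(dim(img)[1:2] < 16L) || any(dim(img)[1:2] %% 16L != 0L)) {
    stop("discriminator input must be at least 16 x 16 and divisible by 16")
  }
  out <- net_fwd(model$arch$d, model$params$d, img)$out
  out[, , class]
}

.clamp_prob <- function(p, eps) pmin(pmax(p, eps), 1 - eps)

#' Adversarial loss values
#'
#' Evaluates the two sides of the saturating GAN objective
#' `E[log D^cx(x)] + E[log(1 - D^cy(x-bar))]` on one batch. Scores are mapped
#' to probabilities with the logistic function and clamped away from {0, 1}.
#' The returned `g` term is the generator's loss: by default the
#' non-saturating surrogate `-E[log D^cy(x-bar)]`, or the literal
#' `E[log(1 - D^cy(x-bar))]` when the model's config says so.
#'
#' @param model a `trab_translator`.
#' @param x real image of class `cx`.
#' @param y real image of class `cy` (the mapping target).
#' @param cx,cy class labels (1 = MDCT, 2 = micro-CT).
#' @return list with `d` (the objective D maximizes), `d_loss` (`-d`), and
#'   `g` (the generator's adversarial loss).
#' @export
gan_loss <- function(model, x, y, cx = 1L, cy = 2L) {
  eps <- model$config$eps
  xbar <- generate(model, x, list(y))
  p_real <- .clamp_prob(stats::plogis(discriminate(model, x, cx)), eps)
  p_fake <- .clamp_prob(stats::plogis(discriminate(model, xbar, cy)), eps)
  d_obj <- mean(log(p_real)) + mean(log(1 - p_fake))
  g <- if (model$config$gan_form == "literal") {
    mean(log(1 - p_fake))
  } else {
    -mean(log(p_fake))
  }
  list(d = d_obj, d_loss = -d_obj, g = g)
}

#' Reconstruction loss
#'
#' Mean absolute error between an image and its self-translation
#' `G(x, x)` (the same image as input and as the single mapping target),
#' which pushes the generator toward the identity within a class.
#'
#' @param G either a `trab_translator` or a function `G(x, y)`.
#' @param x input image.
#' @return nonnegative scalar (mean over pixels).
#' @export
reconstruction_loss <- function(G, x) {
  out <- if (inherits(G, "trab_translator")) generate(G, x, list(x)) else G(x, x)
  mean(abs(x - out))
}

#' Feature matching loss
#'
#' L1 distance between discriminator features (the discriminator minus its
#' final layer, `Df`) of the translated image and the mean features of the K
#' target-class images.
#'
#' @param Df either a `trab_translator` (its discriminator's feature
#'   extractor is used) or a function mapping an image to features.
#' @param xbar translated image.
#' @param ys list of target-class images (K >= 1).
#' @return nonnegative scalar (mean over feature elements).
#' @export
feature_matching_loss <- function(Df, xbar, ys) {
  if (!is.list(ys)) ys <- list(ys)
  fe <- if (inherits(Df, "trab_translator")) {
    function(img) .disc_features(Df, .as_tensor(img))$feat
  } else {
    Df
  }
  fx <- fe(xbar)
  fy <- Reduce(`+`, lapply(ys, fe)) / length(ys)
  mean(abs(fx - fy))
}

# discriminator forward returning both the score map and the feature node
# (the output feeding the final conv layer, i.e. Df)
.disc_features <- function(model, img) {
  nl <- length(model$arch$d)
  fw <- net_fwd(model$arch$d, model$params$d, img, keep_out = nl - 1L)
  list(scores = fw$out, feat = fw$kept, caches = fw$caches)
}
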