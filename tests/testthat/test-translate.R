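# Architecture traces, loss identities and gradient correctness of the
# translation model.

tiny_cfg <- function(seed = 5L) {
  translator_config(img_size = 16L, base_width = 2L, d_width = 2L,
                    class_code_dim = 4L, seed = seed)
}

test_that("encoders, decoder and discriminator trace the printed geometry", {
  m <- init_translator(translator_config(seed = 3))
  x <- matrix(runif(64 * 64, -1, 1), 64, 64)
  zx <- content_encode(m, x)
  expect_equal(dim(zx)[1:2], c(8L, 8L))       # 3 stride-2 stages: 64 / 8
  expect_length(class_encode(m, x), m$config$class_code_dim)
  out <- decode(m, zx, class_encode(m, x))
  expect_equal(dim(out), c(64L, 64L))          # back to input resolution
  sc0 <- net_fwd(m$arch$d, m$params$d, trabeculagen:::.as_tensor(x))$out
  expect_equal(dim(sc0), c(4L, 4L, 2L))        # 4 avg-pool halvings, S = 2
  expect_error(content_encode(m, matrix(0, 63, 63)), "divisible")
  expect_error(discriminate(m, matrix(0, 8, 8)), "16")
})

test_that("structural encoder properties hold", {
  m <- init_translator(tiny_cfg())
  x <- matrix(runif(256, -1, 1), 16, 16)
  # zero weights and biases produce a zero content code
  mz <- m
  mz$params$ex <- rapply(mz$params$ex, function(a) a * 0, how = "replace")
  expect_equal(max(abs(content_encode(mz, x))), 0)
  # instance normalization makes the content code scale-invariant at init
  # (all conv biases start at zero; exact up to the normalizer's epsilon)
  expect_equal(content_encode(m, x), content_encode(m, 3 * x),
               tolerance = 1e-5)
  # class code: K identical images equal K = 1; order does not matter
  y1 <- matrix(runif(256, -1, 1), 16, 16)
  y2 <- matrix(runif(256, -1, 1), 16, 16)
  expect_equal(class_encode(m, list(y1, y1, y1)), class_encode(m, y1))
  expect_equal(class_encode(m, list(y1, y2)), class_encode(m, list(y2, y1)))
  expect_error(class_encode(m, list()), "K >= 1")
})

test_that("decoding is deterministic and propagates uniform content", {
  m <- init_translator(translator_config(seed = 11))
  zy <- class_encode(m, matrix(runif(64 * 64, -1, 1), 64, 64))
  zx <- array(0.37, dim = c(16, 16, m$widths[4]))  # spatially uniform code
  out1 <- decode(m, zx, zy)
  out2 <- decode(m, zx, zy)
  expect_identical(out1, out2)
  # centre of the output (outside every boundary receptive field) is uniform
  ctr <- out1[63:66, 63:66]
  expect_lt(max(abs(ctr - mean(ctr))), 1e-8)
})

test_that("adversarial loss matches its plug-in values", {
  m <- init_translator(tiny_cfg())
  nl <- length(m$arch$d)
  x <- matrix(runif(256, -1, 1), 16, 16)
  y <- matrix(runif(256, -1, 1), 16, 16)
  # zeroed final layer -> D outputs probability 0.5 everywhere
  m0 <- m
  m0$params$d[[nl]]$W[] <- 0
  m0$params$d[[nl]]$b[] <- 0
  gl <- gan_loss(m0, x, y)
  expect_equal(gl$d, 2 * log(0.5), tolerance = 1e-12)
  # near-perfect D: objective approaches 0 from below
  mp <- m0
  mp$params$d[[nl]]$b <- c(40, -40)
  glp <- gan_loss(mp, x, y, cx = 1L, cy = 2L)
  expect_lte(glp$d, 0)
  expect_gt(glp$d, -1e-5)
})

test_that("reconstruction and feature-matching losses hit their identities", {
  x <- matrix(runif(400, 0, 1), 20, 20)
  expect_equal(reconstruction_loss(function(a, b) a, x), 0)
  expect_equal(reconstruction_loss(function(a, b) a + 1, x), 1)
  g <- function(a, b) a + matrix(seq(-1, 1, length.out = 400), 20, 20)
  expect_equal(reconstruction_loss(g, x), mean(abs(x - g(x, x))))
  f <- function(img) img[1:4, 1:4] * 2
  expect_equal(feature_matching_loss(f, x, list(x)), 0)
  y <- x + 0.3
  expect_equal(feature_matching_loss(f, x, list(y, y)),
               feature_matching_loss(f, x, list(y)))
  # against direct elementwise computation
  z <- matrix(runif(400), 20, 20)
  expect_equal(feature_matching_loss(f, x, list(z)), mean(abs(f(x) - f(z))))
  # losses on a real model are nonnegative and zero on identity cases
  m <- init_translator(tiny_cfg())
  x16 <- matrix(runif(256, -1, 1), 16, 16)
  expect_gte(reconstruction_loss(m, x16), 0)
  expect_equal(feature_matching_loss(m, x16, list(x16)), 0)
})

test_that("analytic gradients agree with central finite differences", {
  set.seed(9)
  model <- init_translator(tiny_cfg(seed = 5L))
  x <- trabeculagen:::.as_tensor(matrix(runif(256, -0.9, 0.9), 16, 16))
  y <- trabeculagen:::.as_tensor(matrix(runif(256, -0.9, 0.9), 16, 16))
  h <- 1e-6
  reltol <- 1e-4

  g_loss_val <- function(m) {
    gp <- trabeculagen:::.g_pass(m, x, y, 2L)
    l <- gp$losses
    l[["adv"]] + m$config$lambda_f * l[["l_f"]] +
      m$config$lambda_r * l[["l_r"]]
  }
  gp <- trabeculagen:::.g_pass(model, x, y, 2L)
  pg <- trabeculagen:::.flat_gen_params(model$params)
  set.seed(42)
  for (i in sample(length(pg), 20)) {
    pp <- pg
    pp[i] <- pg[i] + h
    lp <- g_loss_val(trabeculagen:::.set_gen_params(model, pp))
    pp[i] <- pg[i] - h
    lm <- g_loss_val(trabeculagen:::.set_gen_params(model, pp))
    fd <- (lp - lm) / (2 * h)
    an <- gp$grads_flat[i]
    expect_lt(abs(fd - an) / max(abs(fd), abs(an), 1e-6), reltol)
  }

  dp <- trabeculagen:::.d_pass(model, x, gp$xbar, 1L, 2L)
  pd <- unlist(model$params$d, use.names = FALSE)
  d_loss_val <- function(m) -trabeculagen:::.d_pass(m, x, gp$xbar, 1L, 2L)$d_obj
  set.seed(43)
  for (i in sample(length(pd), 20)) {
    pp <- pd
    pp[i] <- pd[i] + h
    mp <- model
    mp$params$d <- trabeculagen:::.relist_like(pp, model$params$d)
    lp <- d_loss_val(mp)
    pp[i] <- pd[i] - h
    mp$params$d <- trabeculagen:::.relist_like(pp, model$params$d)
    lm <- d_loss_val(mp)
    fd <- (lp - lm) / (2 * h)
    an <- dp$grads_flat[i]
    expect_lt(abs(fd - an) / max(abs(fd), abs(an), 1e-6), reltol)
  }
})

test_that("training is seeded, resumable and respects zero iterations", {
  set.seed(1)
  xs <- lapply(1:2, function(i) matrix(runif(256, 0, 255), 16, 16))
  ys <- lapply(1:2, function(i) matrix(runif(256, 0, 255), 16, 16))
  m0 <- init_translator(tiny_cfg(seed = 2L))
  mz <- train_translator(xs, ys, iterations = 0L, model = m0)
  expect_identical(mz$params, m0$params)
  m1 <- train_translator(xs, ys, iterations = 5L, config = tiny_cfg(seed = 2L))
  m2 <- train_translator(xs, ys, iterations = 5L, config = tiny_cfg(seed = 2L))
  expect_identical(m1$params, m2$params)
  expect_equal(m1$iter, 5L)
})

test_that("a dominant reconstruction weight drives L_R down", {
  set.seed(7)
  base <- make_texture(40, sigma = 1.5, seed = 4)[5:36, 5:36]
  xs <- lapply(1:3, function(i) pmin(pmax(base + matrix(rnorm(1024, 0, 10),
                                                        32, 32), 0), 255))
  cfg <- translator_config(img_size = 32L, base_width = 2L, d_width = 2L,
                           class_code_dim = 4L, lambda_r = 50, seed = 3L)
  m <- init_translator(cfg)
  l0 <- mean(vapply(xs, function(x) {
    reconstruction_loss(m, x / 127.5 - 1)
  }, numeric(1)))
  mt <- train_translator(xs, xs, iterations = 150L, model = m)
  l1 <- mean(vapply(xs, function(x) {
    reconstruction_loss(mt, x / 127.5 - 1)
  }, numeric(1)))
  expect_lt(l1, l0)
})

test_that("stack translation preserves slice count and is deterministic", {
  sp <- tiny_spec(seed = 17)
  gt <- generate_trabecular_volume(sp)
  mic <- render_micro_ct(gt, sp)
  md <- render_mdct(gt, sp)
  m <- init_translator(translator_config(seed = 4))
  tv1 <- translate_stack(m, md, mic)
  tv2 <- translate_stack(m, md, mic)
  expect_equal(dim(tv1$data)[1], dim(md$data)[1])
  expect_equal(dim(tv1$data)[2:3], c(64L, 64L))
  expect_identical(tv1$data, tv2$data)
  expect_true(all(tv1$data >= 0 & tv1$data <= 255))
  # checkpoints reload to a bit-identical forward pass
  p <- tempfile(fileext = ".rds")
  save_translator(m, p)
  m2 <- load_translator(p)
  expect_identical(translate_stack(m2, md, mic)$data, tv1$data)
  unlink(p)
})
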