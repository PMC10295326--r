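# Minimal dense-tensor neural network layers with manual backpropagation.
# Tensors are (h, w, c) arrays; convolution is GEMM over im2col patches.
# Double precision throughout so analytic gradients can be checked against
# central finite differences.

.he_init <- function(k, cin, cout) {
  array(rnorm(k * k * cin * cout, sd = sqrt(2 / (k * k * cin))),
        dim = c(k, k, cin, cout))
}

conv_prim_fwd <- function(W, b, x, s, pad) {
  d <- dim(x)
  k <- dim(W)[1]
  cols <- .im2col(as.numeric(x), d[1], d[2], d[3], k, s, pad)
  Wm <- matrix(W, k * k * d[3], dim(W)[4])
  y <- cols %*% Wm
  y <- y + matrix(b, nrow(y), length(b), byrow = TRUE)
  oh <- (d[1] + 2 * pad - k) %/% s + 1
  ow <- (d[2] + 2 * pad - k) %/% s + 1
  list(y = array(y, dim = c(oh, ow, dim(W)[4])), cols = cols, xdim = d)
}

conv_prim_bwd <- function(W, cache, dy, s, pad, need_dx = TRUE) {
  d <- cache$xdim
  k <- dim(W)[1]
  dym <- matrix(dy, prod(dim(dy)[1:2]), dim(dy)[3])
  dW <- array(crossprod(cache$cols, dym), dim = dim(W))
  db <- colSums(dym)
  dx <- NULL
  if (need_dx) {
    Wm <- matrix(W, k * k * d[3], dim(W)[4])
    dcols <- tcrossprod(dym, Wm)
    dx <- array(.col2im(dcols, d[1], d[2], d[3], k, s, pad), dim = d)
  }
  list(dx = dx, dW = dW, db = db)
}

in_prim_fwd <- function(x, eps = 1e-5) {
  d <- dim(x)
  xm <- matrix(x, d[1] * d[2], d[3])
  mu <- colMeans(xm)
  xc <- sweep(xm, 2L, mu)
  sinv <- 1 / sqrt(colMeans(xc^2) + eps)
  xhat <- sweep(xc, 2L, sinv, `*`)
  list(y = array(xhat, dim = d), xhat = xhat, sinv = sinv, d = d)
}

in_prim_bwd <- function(cache, dxhat) {
  d <- cache$d
  dm <- matrix(dxhat, d[1] * d[2], d[3])
  m1 <- colMeans(dm)
  m2 <- colMeans(dm * cache$xhat)
  dx <- sweep(dm, 2L, m1) - sweep(cache$xhat, 2L, m2, `*`)
  array(sweep(dx, 2L, cache$sinv, `*`), dim = d)
}

act_fwd <- function(x, type) {
  switch(type,
         none = list(y = x, cache = NULL),
         relu = {
           pos <- x > 0
           list(y = x * pos, cache = pos)
         },
         lrelu = {
           pos <- x > 0
           list(y = x * (0.2 + 0.8 * pos), cache = pos)
         },
         tanh = { y <- tanh(x); list(y = y, cache = y) },
         stop("unknown activation"))
}

act_bwd <- function(dy, cache, type) {
  switch(type,
         none = dy,
         relu = dy * cache,
         lrelu = dy * (0.2 + 0.8 * cache),
         tanh = dy * (1 - cache^2))
}

adain_prim_fwd <- function(x, g, b) {
  inn <- in_prim_fwd(x)
  d <- inn$d
  ym <- sweep(sweep(inn$xhat, 2L, g, `*`), 2L, b, `+`)
  list(y = array(ym, dim = d), inn = inn)
}

adain_prim_bwd <- function(cache, g, dy) {
  d <- cache$inn$d
  dm <- matrix(dy, d[1] * d[2], d[3])
  dg <- colSums(dm * cache$inn$xhat)
  db <- colSums(dm)
  dxhat <- sweep(dm, 2L, g, `*`)
  list(dx = in_prim_bwd(cache$inn, array(dxhat, dim = d)), dg = dg, db = db)
}

avgpool2_fwd <- function(x) {
  d <- dim(x)
  o1 <- seq(1L, d[1], 2L); o2 <- seq(1L, d[2], 2L)
  y <- (x[o1, o2, , drop = FALSE] + x[o1 + 1L, o2, , drop = FALSE] +
        x[o1, o2 + 1L, , drop = FALSE] + x[o1 + 1L, o2 + 1L, , drop = FALSE]) / 4
  list(y = y, xdim = d)
}

avgpool2_bwd <- function(dy, xdim) {
  dx <- array(0, dim = xdim)
  o1 <- seq(1L, xdim[1], 2L); o2 <- seq(1L, xdim[2], 2L)
  q <- dy / 4
  dx[o1, o2, ] <- q
  dx[o1 + 1L, o2, ] <- q
  dx[o1, o2 + 1L, ] <- q
  dx[o1 + 1L, o2 + 1L, ] <- q
  dx
}

upsample2_fwd <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2L), rep(seq_len(d[2]), each = 2L), ,
    drop = FALSE]
}

upsample2_bwd <- function(dy, xdim) {
  o1 <- seq(1L, 2L * xdim[1], 2L); o2 <- seq(1L, 2L * xdim[2], 2L)
  dy[o1, o2, , drop = FALSE] + dy[o1 + 1L, o2, , drop = FALSE] +
    dy[o1, o2 + 1L, , drop = FALSE] + dy[o1 + 1L, o2 + 1L, , drop = FALSE]
}

# ---------------------------------------------------------------------------
# sequential networks: layer spec constructors

ly_conv <- function(cin, cout, k = 3L, s = 1L, pad = 1L, norm = "none",
                    act = "relu") {
  list(type = "conv", cin = cin, cout = cout, k = k, s = s, pad = pad,
       norm = norm, act = act)
}
ly_res_in <- function(c) list(type = "res_in", c = c)
ly_res_adain <- function(c, block) list(type = "res_adain", c = c,
                                        block = block)
ly_res_plain <- function(cin, cout) list(type = "res_plain", cin = cin,
                                         cout = cout)
ly_pool <- function() list(type = "pool")
ly_up <- function() list(type = "up")
ly_gap <- function() list(type = "gap")
ly_fc <- function(cin, cout, act = "none") list(type = "fc", cin = cin,
                                                cout = cout, act = act)

net_init <- function(arch) {
  lapply(arch, function(l) {
    switch(l$type,
      conv = list(W = .he_init(l$k, l$cin, l$cout), b = numeric(l$cout)),
      res_in = list(W1 = .he_init(3L, l$c, l$c), b1 = numeric(l$c),
                    W2 = .he_init(3L, l$c, l$c), b2 = numeric(l$c)),
      res_adain = list(W1 = .he_init(3L, l$c, l$c), b1 = numeric(l$c),
                       W2 = .he_init(3L, l$c, l$c), b2 = numeric(l$c)),
      res_plain = {
        p <- list(W1 = .he_init(3L, l$cin, l$cout), b1 = numeric(l$cout),
                  W2 = .he_init(3L, l$cout, l$cout), b2 = numeric(l$cout))
        if (l$cin != l$cout) {
          p$Ws <- .he_init(1L, l$cin, l$cout)
          p$bs <- numeric(l$cout)
        }
        p
      },
      fc = list(W = matrix(rnorm(l$cout * l$cin, sd = sqrt(1 / l$cin)),
                           l$cout, l$cin),
                b = numeric(l$cout)),
      list()  # pool / up / gap carry no parameters
    )
  })
}

# zero-filled gradient skeleton matching `params`
net_zero_grads <- function(params) {
  lapply(params, function(p) lapply(p, function(a) array(0, dim = dim(a) %||%
                                                           length(a))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# forward pass; `adain` is a list indexed by block id with elements g, b.
# `keep_out` stores the output of the named layer index (feature tap).
net_fwd <- function(arch, params, x, adain = NULL, keep_out = NULL) {
  caches <- vector("list", length(arch))
  kept <- NULL
  for (i in seq_along(arch)) {
    l <- arch[[i]]
    p <- params[[i]]
    cc <- list()
    if (l$type == "conv") {
      cv <- conv_prim_fwd(p$W, p$b, x, l$s, l$pad)
      h <- cv$y
      cc$cv <- cv[c("cols", "xdim")]
      if (l$norm == "in") {
        inn <- in_prim_fwd(h)
        h <- inn$y
        cc$inn <- inn[c("xhat", "sinv", "d")]
      }
      av <- act_fwd(h, l$act)
      cc$act <- av$cache
      x <- av$y
    } else if (l$type == "res_in") {
      c1 <- conv_prim_fwd(p$W1, p$b1, x, 1L, 1L)
      i1 <- in_prim_fwd(c1$y)
      a1 <- act_fwd(i1$y, "relu")
      c2 <- conv_prim_fwd(p$W2, p$b2, a1$y, 1L, 1L)
      i2 <- in_prim_fwd(c2$y)
      cc <- list(c1 = c1[c("cols", "xdim")], i1 = i1[c("xhat", "sinv", "d")],
                 a1 = a1$cache, c2 = c2[c("cols", "xdim")],
                 i2 = i2[c("xhat", "sinv", "d")])
      x <- x + i2$y
    } else if (l$type == "res_adain") {
      g <- adain[[l$block]]$g
      bb <- adain[[l$block]]$b
      c1 <- conv_prim_fwd(p$W1, p$b1, x, 1L, 1L)
      a1f <- adain_prim_fwd(c1$y, g, bb)
      r1 <- act_fwd(a1f$y, "relu")
      c2 <- conv_prim_fwd(p$W2, p$b2, r1$y, 1L, 1L)
      a2f <- adain_prim_fwd(c2$y, g, bb)
      cc <- list(c1 = c1[c("cols", "xdim")], a1 = a1f, r1 = r1$cache,
                 c2 = c2[c("cols", "xdim")], a2 = a2f, block = l$block,
                 g = g)
      x <- x + a2f$y
    } else if (l$type == "res_plain") {
      p1 <- act_fwd(x, "lrelu")
      c1 <- conv_prim_fwd(p$W1, p$b1, p1$y, 1L, 1L)
      p2 <- act_fwd(c1$y, "lrelu")
      c2 <- conv_prim_fwd(p$W2, p$b2, p2$y, 1L, 1L)
      if (is.null(p$Ws)) {
        sc <- x
        cc$cs <- NULL
      } else {
        cs <- conv_prim_fwd(p$Ws, p$bs, x, 1L, 0L)
        sc <- cs$y
        cc$cs <- cs[c("cols", "xdim")]
      }
      cc$p1 <- p1$cache; cc$c1 <- c1[c("cols", "xdim")]
      cc$p2 <- p2$cache; cc$c2 <- c2[c("cols", "xdim")]
      x <- sc + c2$y
    } else if (l$type == "pool") {
      pv <- avgpool2_fwd(x)
      cc$xdim <- pv$xdim
      x <- pv$y
    } else if (l$type == "up") {
      cc$xdim <- dim(x)
      x <- upsample2_fwd(x)
    } else if (l$type == "gap") {
      cc$xdim <- dim(x)
      x <- colMeans(matrix(x, prod(dim(x)[1:2]), dim(x)[3]))
    } else if (l$type == "fc") {
      cc$x <- x
      h <- as.numeric(p$W %*% x + p$b)
      av <- act_fwd(h, l$act)
      cc$act <- av$cache
      x <- av$y
    }
    caches[[i]] <- cc
    if (!is.null(keep_out) && i == keep_out) kept <- x
  }
  list(out = x, caches = caches, kept = kept)
}

# backward pass. `inject` maps layer index -> gradient added at that layer's
# output (used to tap the discriminator's feature node). Returns dx, grads
# and accumulated AdaIN style gradients (per block: dg, db).
net_bwd <- function(arch, params, caches, dout, inject = NULL,
                    need_dx = TRUE) {
  grads <- vector("list", length(arch))
  dadain <- list()
  dx <- dout
  for (i in rev(seq_along(arch))) {
    l <- arch[[i]]
    p <- params[[i]]
    cc <- caches[[i]]
    if (!is.null(inject) && !is.null(inject[[as.character(i)]])) {
      dx <- dx + inject[[as.character(i)]]
    }
    need_in <- need_dx || i > 1L
    if (l$type == "conv") {
      dh <- act_bwd(dx, cc$act, l$act)
      if (l$norm == "in") dh <- in_prim_bwd(cc$inn, dh)
      bk <- conv_prim_bwd(p$W, cc$cv, dh, l$s, l$pad, need_in)
      grads[[i]] <- list(W = bk$dW, b = bk$db)
      dx <- bk$dx
    } else if (l$type == "res_in") {
      dh <- in_prim_bwd(cc$i2, dx)
      b2 <- conv_prim_bwd(p$W2, cc$c2, dh, 1L, 1L, TRUE)
      da <- act_bwd(b2$dx, cc$a1, "relu")
      da <- in_prim_bwd(cc$i1, da)
      b1 <- conv_prim_bwd(p$W1, cc$c1, da, 1L, 1L, need_in)
      grads[[i]] <- list(W1 = b1$dW, b1 = b1$db, W2 = b2$dW, b2 = b2$db)
      dx <- if (need_in) dx + b1$dx else NULL
    } else if (l$type == "res_adain") {
      a2b <- adain_prim_bwd(cc$a2, cc$g, dx)
      b2 <- conv_prim_bwd(p$W2, cc$c2, a2b$dx, 1L, 1L, TRUE)
      dr <- act_bwd(b2$dx, cc$r1, "relu")
      a1b <- adain_prim_bwd(cc$a1, cc$g, dr)
      b1 <- conv_prim_bwd(p$W1, cc$c1, a1b$dx, 1L, 1L, need_in)
      grads[[i]] <- list(W1 = b1$dW, b1 = b1$db, W2 = b2$dW, b2 = b2$db)
      blk <- as.character(cc$block)
      if (is.null(dadain[[blk]])) {
        dadain[[blk]] <- list(dg = 0, db = 0)
      }
      dadain[[blk]]$dg <- dadain[[blk]]$dg + a1b$dg + a2b$dg
      dadain[[blk]]$db <- dadain[[blk]]$db + a1b$db + a2b$db
      dx <- if (need_in) dx + b1$dx else NULL
    } else if (l$type == "res_plain") {
      b2 <- conv_prim_bwd(p$W2, cc$c2, dx, 1L, 1L, TRUE)
      da2 <- act_bwd(b2$dx, cc$p2, "lrelu")
      b1 <- conv_prim_bwd(p$W1, cc$c1, da2, 1L, 1L, TRUE)
      da1 <- act_bwd(b1$dx, cc$p1, "lrelu")
      gr <- list(W1 = b1$dW, b1 = b1$db, W2 = b2$dW, b2 = b2$db)
      if (is.null(p$Ws)) {
        dsc <- dx
      } else {
        bs <- conv_prim_bwd(p$Ws, cc$cs, dx, 1L, 0L, TRUE)
        gr$Ws <- bs$dW
        gr$bs <- bs$db
        dsc <- bs$dx
      }
      grads[[i]] <- gr
      dx <- if (need_in) dsc + da1 else NULL
    } else if (l$type == "pool") {
      grads[[i]] <- list()
      dx <- avgpool2_bwd(dx, cc$xdim)
    } else if (l$type == "up") {
      grads[[i]] <- list()
      dx <- upsample2_bwd(dx, cc$xdim)
    } else if (l$type == "gap") {
      grads[[i]] <- list()
      d <- cc$xdim
      dx <- array(rep(dx / (d[1] * d[2]), each = d[1] * d[2]), dim = d)
    } else if (l$type == "fc") {
      dh <- act_bwd(dx, cc$act, l$act)
      grads[[i]] <- list(W = matrix(dh, ncol = 1) %*% matrix(cc$x, nrow = 1),
                         b = dh)
      dx <- as.numeric(crossprod(p$W, dh))
    }
  }
  list(dx = dx, grads = grads, dadain = dadain)
}
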