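# Primitive differentiable layers. Every forward returns list(out, cache) and
# every backward consumes (dout, cache) and returns the input gradient plus a
# `grads` list mirroring the layer's parameter list. Feature tensors are
# column-major arrays in (H, W, C, B) layout.

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

## ---- convolution ----------------------------------------------------------

init_conv2d <- function(cin, cout, k, bias = FALSE, gain = 2) {
  sd <- sqrt(gain / (k * k * cin))
  p <- list(w = array(rnorm(k * k * cin * cout, sd = sd), dim = c(k, k, cin, cout)))
  if (bias) p$b <- numeric(cout)
  p
}

conv2d_fwd <- function(params, x, stride = 1L, pad = NULL, keep = TRUE) {
  k <- dim(params$w)[1]
  if (is.null(pad)) pad <- k %/% 2L
  r <- cpp_conv_forward(x, dim(x), params$w, dim(params$w),
                        params$b %||% numeric(0), stride, pad, keep)
  list(out = r$out,
       cache = list(cols = r$cols, xdim = dim(x), odim = dim(r$out),
                    stride = stride, pad = pad))
}

conv2d_bwd <- function(params, cache, dout, need_dx = TRUE) {
  r <- cpp_conv_backward(dout, cache$odim, cache$cols, params$w, dim(params$w),
                         cache$xdim, cache$stride, cache$pad, need_dx)
  g <- list(w = r$dw)
  if (!is.null(params$b)) g$b <- r$db
  list(dx = if (need_dx) r$dx else NULL, grads = g)
}

## ---- batch normalization --------------------------------------------------

# reshape (H,W,C,B) -> (H*W*B, C) sample-by-channel matrix and back
.x_to_nc <- function(x) {
  d <- dim(x)
  m <- aperm(x, c(1, 2, 4, 3))
  dim(m) <- c(d[1] * d[2] * d[4], d[3])
  m
}
.nc_to_x <- function(m, d) {
  dim(m) <- c(d[1], d[2], d[4], d[3])
  aperm(m, c(1, 2, 4, 3))
}

init_bn <- function(c) {
  list(gamma = rep(1, c), beta = numeric(c))
}
init_bn_buffers <- function(c) {
  list(rmean = numeric(c), rvar = rep(1, c))
}

# xm: (N, C) matrix of samples; returns list(out, cache, buffers)
bn_fwd_mat <- function(params, buffers, xm, training) {
  n <- nrow(xm)
  if (training && n > 1L) {
    mu <- colMeans(xm)
    xc <- sweep(xm, 2L, mu)
    v <- colMeans(xc^2)
    invsd <- 1 / sqrt(v + BN_EPS)
    xhat <- sweep(xc, 2L, invsd, `*`)
    buffers$rmean <- (1 - BN_MOMENTUM) * buffers$rmean + BN_MOMENTUM * mu
    buffers$rvar <- (1 - BN_MOMENTUM) * buffers$rvar +
      BN_MOMENTUM * v * n / max(n - 1, 1)
    cache <- list(xhat = xhat, invsd = invsd, train = TRUE)
  } else {
    invsd <- 1 / sqrt(buffers$rvar + BN_EPS)
    xhat <- sweep(sweep(xm, 2L, buffers$rmean), 2L, invsd, `*`)
    cache <- list(xhat = xhat, invsd = invsd, train = FALSE)
  }
  out <- sweep(sweep(xhat, 2L, params$gamma, `*`), 2L, params$beta, `+`)
  list(out = out, cache = cache, buffers = buffers)
}

bn_bwd_mat <- function(params, cache, dout) {
  n <- nrow(dout)
  dgamma <- colSums(dout * cache$xhat)
  dbeta <- colSums(dout)
  dxhat <- sweep(dout, 2L, params$gamma, `*`)
  if (cache$train) {
    t1 <- sweep(dxhat, 2L, colSums(dxhat) / n)
    t2 <- sweep(cache$xhat, 2L, colSums(dxhat * cache$xhat) / n, `*`)
    dx <- sweep(t1 - t2, 2L, cache$invsd, `*`)
  } else {
    dx <- sweep(dxhat, 2L, cache$invsd, `*`)
  }
  list(dx = dx, grads = list(gamma = dgamma, beta = dbeta))
}

bn2d_fwd <- function(params, buffers, x, training) {
  d <- dim(x)
  r <- bn_fwd_mat(params, buffers, .x_to_nc(x), training)
  list(out = .nc_to_x(r$out, d), cache = c(r$cache, list(d = d)),
       buffers = r$buffers)
}

bn2d_bwd <- function(params, cache, dout) {
  r <- bn_bwd_mat(params, cache, .x_to_nc(dout))
  list(dx = .nc_to_x(r$dx, cache$d), grads = r$grads)
}

## ---- activations ----------------------------------------------------------

silu_fwd <- function(x) {
  s <- sigmoid(x)
  list(out = x * s, cache = list(x = x, s = s))
}
silu_bwd <- function(cache, dout) {
  dout * (cache$s * (1 + cache$x * (1 - cache$s)))
}

relu_fwd <- function(x) list(out = pmax(x, 0), cache = list(mask = x > 0))
relu_bwd <- function(cache, dout) dout * cache$mask

## ---- conv + BN + SiLU unit ------------------------------------------------

init_convunit <- function(cin, cout, k, stride = 1L) {
  list(type = "convunit", cin = cin, cout = cout, k = k, stride = stride,
       params = list(conv = init_conv2d(cin, cout, k), bn = init_bn(cout)),
       buffers = init_bn_buffers(cout))
}

convunit_fwd <- function(u, x, training, keep = TRUE) {
  c1 <- conv2d_fwd(u$params$conv, x, stride = u$stride, keep = keep)
  b1 <- bn2d_fwd(u$params$bn, u$buffers, c1$out, training)
  a1 <- silu_fwd(b1$out)
  list(out = a1$out, buffers = b1$buffers,
       cache = list(conv = c1$cache, bn = b1$cache, act = a1$cache))
}

convunit_bwd <- function(u, cache, dout, need_dx = TRUE) {
  da <- silu_bwd(cache$act, dout)
  b <- bn2d_bwd(u$params$bn, cache$bn, da)
  cv <- conv2d_bwd(u$params$conv, cache$conv, b$dx, need_dx)
  list(dx = cv$dx, grads = list(conv = cv$grads, bn = b$grads))
}

## ---- fully connected ------------------------------------------------------

init_fc <- function(cin, cout) {
  list(w = matrix(rnorm(cin * cout, sd = sqrt(2 / cin)), cin, cout),
       b = numeric(cout))
}
fc_fwd <- function(params, x) { # x: (B, Cin)
  list(out = sweep(x %*% params$w, 2L, params$b, `+`), cache = list(x = x))
}
fc_bwd <- function(params, cache, dout) {
  list(dx = dout %*% t(params$w),
       grads = list(w = crossprod(cache$x, dout), b = colSums(dout)))
}

## ---- pooling / resampling -------------------------------------------------

maxpool_fwd <- function(x, k, stride = 1L, pad = NULL) {
  if (is.null(pad)) pad <- k %/% 2L
  r <- cpp_maxpool_forward(x, dim(x), k, stride, pad)
  list(out = r$out, cache = list(idx = r$idx, xdim = dim(x)))
}
maxpool_bwd <- function(cache, dout) {
  cpp_maxpool_backward(dout, cache$idx, cache$xdim)
}

upsample2_fwd <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2L), rep(seq_len(d[2]), each = 2L), , , drop = FALSE]
}
upsample2_bwd <- function(dout) {
  d <- dim(dout)
  o <- seq(1L, d[1], by = 2L); p <- seq(1L, d[2], by = 2L)
  dout[o, p, , , drop = FALSE] + dout[o + 1L, p, , , drop = FALSE] +
    dout[o, p + 1L, , , drop = FALSE] + dout[o + 1L, p + 1L, , , drop = FALSE]
}

concat_fwd <- function(xs) {
  d1 <- dim(xs[[1]])
  chans <- vapply(xs, function(x) dim(x)[3], integer(1))
  out <- array(0, dim = c(d1[1], d1[2], sum(chans), d1[4]))
  at <- 0L
  for (x in xs) {
    cc <- dim(x)[3]
    out[, , (at + 1L):(at + cc), ] <- x
    at <- at + cc
  }
  list(out = out, cache = list(chans = chans))
}
concat_bwd <- function(cache, dout) {
  at <- 0L
  lapply(cache$chans, function(cc) {
    sl <- dout[, , (at + 1L):(at + cc), , drop = FALSE]
    at <<- at + cc
    sl
  })
}
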