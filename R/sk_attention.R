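# Modified selective-kernel (SK) channel attention.
#
# The block has three stages. Split: the input map X is convolved with a 3x3
# and a 5x5 kernel, giving branch maps U1 and U2 whose sum is U. Fuse: U is
# globally average-pooled to a channel descriptor s, passed through a
# bottleneck FC -> batch-norm -> ReLU -> FC, and squashed by a sigmoid into a
# channel weight vector a in (0,1)^C. Scale: both branch maps are reweighted
# by the same vector, V = U1 (.) a + U2 (.) a, which is identical to
# (U1 + U2) (.) a. Unlike the original selective-kernel design there is a
# single shared weight vector rather than a per-branch softmax pair; the
# classic softmax variant is available via `mode = "softmax"` for comparison.

#' Create parameters for a selective-kernel attention block
#'
#' @param channels Number of input (= output) channels C.
#' @param reduction Bottleneck reduction ratio r; the hidden width is
#'   `max(floor(C / r), 8)`.
#' @param mode `"single"` (default) applies one sigmoid channel-weight vector
#'   to both branches; `"softmax"` is the classic per-branch softmax pair.
#' @return An `sk_params` list holding the 3x3/5x5 branch kernels, the two
#'   fully connected layers and batch-norm state.
#' @export
sk_params <- function(channels, reduction = 16, mode = c("single", "softmax")) {
  mode <- match.arg(mode)
  d <- max(channels %/% reduction, 8L)
  p <- list(
    channels = channels, hidden = d, mode = mode,
    params = list(
      w3 = init_conv2d(channels, channels, 3L),
      w5 = init_conv2d(channels, channels, 5L),
      fc1 = init_fc(channels, d),
      bn = init_bn(d),
      fc2 = init_fc(d, channels)
    ),
    buffers = init_bn_buffers(d)
  )
  if (mode == "softmax") p$params$fc2b <- init_fc(d, channels)
  class(p) <- "sk_params"
  p
}

.sk_check_x <- function(x, channels) {
  b <- as_batched(x)
  stop_if_not(dim(b$x)[3] == channels,
              "input has %d channels but the SK block expects %d",
              dim(b$x)[3], channels)
  stop_if_not(all(is.finite(b$x)), "non-finite values in SK input")
  b
}

#' Split stage: two-kernel branch convolutions
#'
#' Convolves the input with the 3x3 and the 5x5 branch kernel (stride 1,
#' same padding, no bias) and returns both branch maps.
#'
#' @param x Feature map, an H x W x C (or H x W x C x B) array.
#' @param sk An [sk_params()] object.
#' @return `list(u1, u2)` of maps with the input's shape.
#' @export
sk_split <- function(x, sk) {
  b <- .sk_check_x(x, sk$channels)
  u1 <- conv2d_fwd(sk$params$w3, b$x, keep = FALSE)$out
  u2 <- conv2d_fwd(sk$params$w5, b$x, keep = FALSE)$out
  if (!b$batched) { dim(u1) <- dim(u1)[1:3]; dim(u2) <- dim(u2)[1:3] }
  list(u1 = u1, u2 = u2)
}

#' Global average pooling to a channel descriptor
#'
#' @param u Feature map, H x W x C (or H x W x C x B).
#' @return A length-C vector (or B x C matrix): the spatial mean per channel.
#' @export
global_average_pool <- function(u) {
  b <- as_batched(u)
  d <- dim(b$x)
  stop_if_not(d[1] >= 1 && d[2] >= 1 && length(b$x) > 0, "empty feature map")
  m <- b$x
  dim(m) <- c(d[1] * d[2], d[3] * d[4])
  s <- matrix(colMeans(m), nrow = d[3], ncol = d[4]) # C x B
  if (b$batched) t(s) else drop(s)
}

#' Fuse stage: channel weights from the descriptor
#'
#' Computes `a = sigmoid(FC2(ReLU(BN(FC1(s)))))`, the channel attention
#' weights; every component lies strictly in (0, 1).
#'
#' @param s Channel descriptor: length-C vector or B x C matrix.
#' @param sk An [sk_params()] object.
#' @param training Use batch statistics (TRUE) or running statistics in the
#'   batch-norm step.
#' @return Channel weights with the shape of `s`.
#' @export
fuse_fc <- function(s, sk, training = FALSE) {
  vec <- is.null(dim(s))
  if (vec) s <- matrix(s, nrow = 1)
  stop_if_not(ncol(s) == sk$channels, "descriptor length must equal C")
  stop_if_not(all(is.finite(s)), "non-finite values in channel descriptor")
  f1 <- fc_fwd(sk$params$fc1, s)
  bn <- bn_fwd_mat(sk$params$bn, sk$buffers, f1$out, training)
  z <- relu_fwd(bn$out)
  a <- sigmoid(fc_fwd(sk$params$fc2, z$out)$out)
  if (vec) drop(a) else a
}

#' Full selective-kernel attention forward pass
#'
#' Split, fuse and scale: `V = U1 (.) a + U2 (.) a` with one shared channel
#' weight vector (mode `"single"`), or the classic per-branch softmax
#' weighting (mode `"softmax"`).
#'
#' @inheritParams sk_split
#' @return Feature map with the input's shape.
#' @export
sk_forward <- function(x, sk) {
  b <- .sk_check_x(x, sk$channels)
  r <- .sk_fwd(sk, b$x, training = FALSE)
  if (!b$batched) dim(r$out) <- dim(r$out)[1:3]
  r$out
}

# broadcast a (B x C) row-per-sample matrix over an (H,W,C,B) map
.bc_chan <- function(a, d) {
  array(rep(as.vector(t(a)), each = d[1] * d[2]), dim = d)
}

# internal batched forward with caches (training path)
.sk_fwd <- function(sk, x, training) {
  p <- sk$params
  c3 <- conv2d_fwd(p$w3, x, keep = training)
  c5 <- conv2d_fwd(p$w5, x, keep = training)
  u <- c3$out + c5$out
  d <- dim(u)
  s <- global_average_pool(u)
  if (is.null(dim(s))) s <- matrix(s, nrow = 1)
  f1 <- fc_fwd(p$fc1, s)
  bn <- bn_fwd_mat(p$bn, sk$buffers, f1$out, training)
  z <- relu_fwd(bn$out)
  f2 <- fc_fwd(p$fc2, z$out)
  if (sk$mode == "softmax") {
    f2b <- fc_fwd(p$fc2b, z$out)
    e1 <- exp(f2$out - pmax(f2$out, f2b$out))
    e2 <- exp(f2b$out - pmax(f2$out, f2b$out))
    a1 <- e1 / (e1 + e2); a2 <- e2 / (e1 + e2)
    out <- c3$out * .bc_chan(a1, d) + c5$out * .bc_chan(a2, d)
    cache <- NULL # softmax mode is inference-only
  } else {
    a <- sigmoid(f2$out)
    av <- .bc_chan(a, d)
    out <- u * av
    cache <- list(c3 = c3$cache, c5 = c5$cache, u = u, a = a, av = av,
                  f1 = f1$cache, bn = bn$cache, z = z$cache, f2 = f2$cache,
                  d = d)
  }
  list(out = out, cache = cache, buffers = bn$buffers)
}

.sk_bwd <- function(sk, cache, dv) {
  p <- sk$params
  d <- cache$d
  hw <- d[1] * d[2]
  du <- dv * cache$av
  m <- dv * cache$u
  dim(m) <- c(hw, d[3] * d[4])
  da <- t(matrix(colSums(m), nrow = d[3])) # B x C
  df2 <- da * cache$a * (1 - cache$a)
  g2 <- fc_bwd(p$fc2, cache$f2, df2)
  dz <- relu_bwd(cache$z, g2$dx)
  gb <- bn_bwd_mat(p$bn, cache$bn, dz)
  g1 <- fc_bwd(p$fc1, cache$f1, gb$dx)
  du <- du + .bc_chan(g1$dx / hw, d)
  b3 <- conv2d_bwd(p$w3, cache$c3, du)
  b5 <- conv2d_bwd(p$w5, cache$c5, du)
  list(dx = b3$dx + b5$dx,
       grads = list(w3 = b3$grads, w5 = b5$grads, fc1 = g1$grads,
                    bn = gb$grads, fc2 = g2$grads))
}
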