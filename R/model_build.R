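# Model construction and graph execution. A built model is the spec plus one
# initialized node per graph row; forward execution walks the rows, backward
# replays them in reverse accumulating gradients into a tree that mirrors the
# parameter tree (see node_param_tree), which is what the SGD step consumes.

#' Lossless 2x2 space-to-depth (focus) transform
#'
#' Rearranges each 2x2 pixel block into four channel groups, halving the
#' spatial size and quadrupling the channel count (3 -> 12 for RGB). A pure
#' permutation of the input values; [focus_inverse()] undoes it exactly.
#'
#' @param x H x W x C (or H x W x C x B) array with even H and W.
#' @return (H/2) x (W/2) x 4C array (batch dim preserved).
#' @export
focus_transform <- function(x) {
  b <- as_batched(x)
  d <- dim(b$x)
  stop_if_not(d[1] %% 2L == 0L && d[2] %% 2L == 0L,
              "spatial dimensions must be even")
  o <- seq(1L, d[1], by = 2L); p <- seq(1L, d[2], by = 2L)
  phases <- list(b$x[o, p, , , drop = FALSE], b$x[o + 1L, p, , , drop = FALSE],
                 b$x[o, p + 1L, , , drop = FALSE], b$x[o + 1L, p + 1L, , , drop = FALSE])
  out <- array(0, dim = c(d[1] / 2L, d[2] / 2L, 4L * d[3], d[4]))
  for (i in seq_along(phases))
    out[, , ((i - 1L) * d[3] + 1L):(i * d[3]), ] <- phases[[i]]
  if (!b$batched) dim(out) <- dim(out)[1:3]
  out
}

#' Inverse of the focus transform
#' @param y Output of [focus_transform()].
#' @return The original array.
#' @export
focus_inverse <- function(y) {
  b <- as_batched(y)
  d <- dim(b$x)
  cc <- d[3] %/% 4L
  out <- array(0, dim = c(d[1] * 2L, d[2] * 2L, cc, d[4]))
  o <- seq(1L, 2L * d[1], by = 2L); p <- seq(1L, 2L * d[2], by = 2L)
  out[o, p, , ] <- b$x[, , 1:cc, , drop = FALSE]
  out[o + 1L, p, , ] <- b$x[, , (cc + 1L):(2L * cc), , drop = FALSE]
  out[o, p + 1L, , ] <- b$x[, , (2L * cc + 1L):(3L * cc), , drop = FALSE]
  out[o + 1L, p + 1L, , ] <- b$x[, , (3L * cc + 1L):(4L * cc), , drop = FALSE]
  if (!b$batched) dim(out) <- dim(out)[1:3]
  out
}

focus_bwd <- function(dout) focus_inverse(dout)

## ---- node construction ----------------------------------------------------

init_csp <- function(cin, cout, n, sk, shortcut, reduction) {
  ch <- cout %/% 2L
  node <- list(type = "csp", n = n, shortcut = shortcut,
               cv1 = init_convunit(cin, ch, 1L),
               cv2 = init_convunit(cin, ch, 1L),
               cv3 = init_convunit(2L * ch, cout, 1L),
               m = lapply(seq_len(n), function(i)
                 list(cv1 = init_convunit(ch, ch, 1L),
                      cv2 = init_convunit(ch, ch, 3L))))
  if (sk) node$sk <- sk_params(ch, reduction)
  node
}

init_spp <- function(cin, cout) {
  ch <- cin %/% 2L
  list(type = "spp", ks = c(5L, 9L, 13L),
       cv1 = init_convunit(cin, ch, 1L),
       cv2 = init_convunit(4L * ch, cout, 1L))
}

init_head <- function(cin, num_classes, stride, input_size) {
  p <- init_conv2d(cin, 3L * (5L + num_classes), 1L, bias = TRUE, gain = 1)
  # prior-aware bias: rare objectness, near-uniform classes
  nc <- 5L + num_classes
  grid_cells <- (input_size / stride)^2
  for (a in 0:2) {
    p$b[a * nc + 5L] <- log(8 / grid_cells)
    p$b[a * nc + 5L + seq_len(num_classes)] <- log(0.6 / (num_classes - 0.99))
  }
  list(type = "head", conv = p)
}

#' Build a pest detector network
#'
#' Initializes every layer of the architecture described by a
#' [model_spec()]: focus stem, (extended) CSP backbone with optional
#' selective-kernel attention, SPP, PANet neck and the per-scale detection
#' heads. Weights use Kaiming-style initialization; head biases encode a
#' low objectness prior.
#'
#' @param spec A `pest_model_spec`.
#' @param seed Optional integer seed for reproducible initialization.
#' @return A `pest_model` object.
#' @export
build_model <- function(spec, seed = NULL) {
  stop_if_not(inherits(spec, "pest_model_spec"), "spec must be a pest_model_spec")
  if (!is.null(seed)) set.seed(seed)
  nodes <- lapply(spec$layers, function(r) {
    switch(r$module,
      focus = list(type = "focus", unit = init_convunit(r$cin, r$cout, r$k)),
      conv = list(type = "conv",
                  unit = init_convunit(r$cin, r$cout, r$k, r$stride)),
      csp = init_csp(r$cin, r$cout, r$n, r$sk, r$shortcut, spec$reduction),
      spp = init_spp(r$cin, r$cout),
      upsample = list(type = "upsample"),
      concat = list(type = "concat"),
      head = NULL # initialized below, needs its scale's stride
    )
  })
  hi <- 0L
  for (i in seq_along(spec$layers)) {
    if (spec$layers[[i]]$module == "head") {
      hi <- hi + 1L
      nodes[[i]] <- init_head(spec$layers[[i]]$cin, spec$num_classes,
                              spec$strides[hi], spec$input_size)
    }
  }
  model <- list(spec = spec, nodes = nodes)
  class(model) <- "pest_model"
  model
}

#' @export
print.pest_model <- function(x, ...) {
  print(x$spec)
  cat(sprintf("  parameters: %s\n",
              format(model_num_params(x), big.mark = ",")))
  invisible(x)
}

#' Total number of learnable parameters in a built model
#' @param model A `pest_model`.
#' @return Integer parameter count (conv kernels, biases, BN affine, FC).
#' @export
model_num_params <- function(model) {
  n <- 0L
  walk <- function(t) {
    if (is.numeric(t)) n <<- n + length(t)
    else if (is.list(t)) for (e in t) if (!is.null(e)) walk(e)
  }
  for (i in seq_along(model$nodes)) walk(node_param_tree(model$nodes[[i]]))
  n
}

## ---- parameter trees ------------------------------------------------------

unit_tree <- function(u) u$params
sk_tree <- function(sk) sk$params[c("w3", "w5", "fc1", "bn", "fc2")]

node_param_tree <- function(node) {
  switch(node$type,
    focus = , conv = list(unit = unit_tree(node$unit)),
    csp = {
      t <- list(cv1 = unit_tree(node$cv1), cv2 = unit_tree(node$cv2),
                cv3 = unit_tree(node$cv3),
                m = lapply(node$m, function(b)
                  list(cv1 = unit_tree(b$cv1), cv2 = unit_tree(b$cv2))))
      if (!is.null(node$sk)) t$sk <- sk_tree(node$sk)
      t
    },
    spp = list(cv1 = unit_tree(node$cv1), cv2 = unit_tree(node$cv2)),
    head = list(conv = node$conv),
    NULL)
}

node_set_param_tree <- function(node, tree) {
  switch(node$type,
    focus = , conv = { node$unit$params <- tree$unit },
    csp = {
      node$cv1$params <- tree$cv1; node$cv2$params <- tree$cv2
      node$cv3$params <- tree$cv3
      for (i in seq_along(node$m)) {
        node$m[[i]]$cv1$params <- tree$m[[i]]$cv1
        node$m[[i]]$cv2$params <- tree$m[[i]]$cv2
      }
      if (!is.null(node$sk)) node$sk$params[names(tree$sk)] <- tree$sk
    },
    spp = { node$cv1$params <- tree$cv1; node$cv2$params <- tree$cv2 },
    head = { node$conv <- tree$conv },
    NULL)
  node
}

## ---- node forward / backward ----------------------------------------------

csp_fwd <- function(node, x, training) {
  c1 <- convunit_fwd(node$cv1, x, training)
  c2 <- convunit_fwd(node$cv2, x, training)
  node$cv1$buffers <- c1$buffers; node$cv2$buffers <- c2$buffers
  y <- c1$out
  mcaches <- vector("list", length(node$m))
  for (i in seq_along(node$m)) {
    b <- node$m[[i]]
    b1 <- convunit_fwd(b$cv1, y, training)
    b2 <- convunit_fwd(b$cv2, b1$out, training)
    node$m[[i]]$cv1$buffers <- b1$buffers
    node$m[[i]]$cv2$buffers <- b2$buffers
    mcaches[[i]] <- list(cv1 = b1$cache, cv2 = b2$cache)
    y <- if (node$shortcut) y + b2$out else b2$out
  }
  skcache <- NULL
  if (!is.null(node$sk)) {
    s <- .sk_fwd(node$sk, y, training)
    node$sk$buffers <- s$buffers
    skcache <- s$cache
    y <- s$out
  }
  cc <- concat_fwd(list(y, c2$out))
  c3 <- convunit_fwd(node$cv3, cc$out, training)
  node$cv3$buffers <- c3$buffers
  list(out = c3$out, node = node,
       cache = list(cv1 = c1$cache, cv2 = c2$cache, cv3 = c3$cache,
                    m = mcaches, sk = skcache, cc = cc$cache))
}

csp_bwd <- function(node, cache, dout) {
  g3 <- convunit_bwd(node$cv3, cache$cv3, dout)
  dparts <- concat_bwd(cache$cc, g3$dx)
  dy <- dparts[[1]]
  g2 <- convunit_bwd(node$cv2, cache$cv2, dparts[[2]])
  gsk <- NULL
  if (!is.null(node$sk)) {
    s <- .sk_bwd(node$sk, cache$sk, dy)
    gsk <- s$grads
    dy <- s$dx
  }
  gm <- vector("list", length(node$m))
  for (i in rev(seq_along(node$m))) {
    b <- node$m[[i]]
    b2 <- convunit_bwd(b$cv2, cache$m[[i]]$cv2, dy)
    b1 <- convunit_bwd(b$cv1, cache$m[[i]]$cv1, b2$dx)
    gm[[i]] <- list(cv1 = b1$grads, cv2 = b2$grads)
    dy <- if (node$shortcut) dy + b1$dx else b1$dx
  }
  g1 <- convunit_bwd(node$cv1, cache$cv1, dy)
  grads <- list(cv1 = g1$grads, cv2 = g2$grads, cv3 = g3$grads, m = gm)
  if (!is.null(gsk)) grads$sk <- gsk
  list(dx = g1$dx + g2$dx, grads = grads)
}

spp_fwd <- function(node, x, training) {
  c1 <- convunit_fwd(node$cv1, x, training)
  node$cv1$buffers <- c1$buffers
  pools <- lapply(node$ks, function(k) maxpool_fwd(c1$out, k))
  cc <- concat_fwd(c(list(c1$out), lapply(pools, `[[`, "out")))
  c2 <- convunit_fwd(node$cv2, cc$out, training)
  node$cv2$buffers <- c2$buffers
  list(out = c2$out, node = node,
       cache = list(cv1 = c1$cache, cv2 = c2$cache, cc = cc$cache,
                    pools = lapply(pools, `[[`, "cache")))
}

spp_bwd <- function(node, cache, dout) {
  g2 <- convunit_bwd(node$cv2, cache$cv2, dout)
  dparts <- concat_bwd(cache$cc, g2$dx)
  dy <- dparts[[1]]
  for (i in seq_along(cache$pools))
    dy <- dy + maxpool_bwd(cache$pools[[i]], dparts[[i + 1L]])
  g1 <- convunit_bwd(node$cv1, cache$cv1, dy)
  list(dx = g1$dx, grads = list(cv1 = g1$grads, cv2 = g2$grads))
}

node_forward <- function(node, inputs, training) {
  switch(node$type,
    focus = {
      z <- focus_transform(inputs[[1]])
      r <- convunit_fwd(node$unit, z, training)
      node$unit$buffers <- r$buffers
      list(out = r$out, node = node, cache = r$cache)
    },
    conv = {
      r <- convunit_fwd(node$unit, inputs[[1]], training)
      node$unit$buffers <- r$buffers
      list(out = r$out, node = node, cache = r$cache)
    },
    csp = csp_fwd(node, inputs[[1]], training),
    spp = spp_fwd(node, inputs[[1]], training),
    upsample = list(out = upsample2_fwd(inputs[[1]]), node = node, cache = NULL),
    concat = {
      r <- concat_fwd(inputs)
      list(out = r$out, node = node, cache = r$cache)
    },
    head = {
      r <- conv2d_fwd(node$conv, inputs[[1]], keep = training)
      list(out = r$out, node = node, cache = r$cache)
    })
}

node_backward <- function(node, cache, dout) {
  switch(node$type,
    focus = {
      r <- convunit_bwd(node$unit, cache, dout)
      list(dins = list(focus_bwd(r$dx)), grads = list(unit = r$grads))
    },
    conv = {
      r <- convunit_bwd(node$unit, cache, dout)
      list(dins = list(r$dx), grads = list(unit = r$grads))
    },
    csp = {
      r <- csp_bwd(node, cache, dout)
      list(dins = list(r$dx), grads = r$grads)
    },
    spp = {
      r <- spp_bwd(node, cache, dout)
      list(dins = list(r$dx), grads = r$grads)
    },
    upsample = list(dins = list(upsample2_bwd(dout)), grads = NULL),
    concat = list(dins = concat_bwd(cache, dout), grads = NULL),
    head = {
      r <- conv2d_bwd(node$conv, cache, dout)
      list(dins = list(r$dx), grads = list(conv = r$grads))
    })
}

## ---- full-graph execution -------------------------------------------------

#' Run the detector forward
#'
#' @param model A `pest_model`.
#' @param x Input batch: H x W x 3 (single image) or H x W x 3 x B array with
#'   H = W divisible by 32, values in `[0, 1]`.
#' @param training Logical; training mode uses batch statistics in the
#'   batch-norm layers and retains the caches needed for the backward pass.
#' @return `list(preds, model)` where `preds` is the list of raw per-scale
#'   head outputs (H_s x W_s x 3(5+K) x B arrays, finest scale first);
#'   with `training = TRUE` also `outs` and `caches` for [model_backward()].
#' @export
model_forward <- function(model, x, training = FALSE) {
  b <- as_batched(x)
  stop_if_not(dim(b$x)[3] == 3L, "input must have 3 channels")
  stop_if_not(dim(b$x)[1] %% 32L == 0L && dim(b$x)[2] %% 32L == 0L,
              "input side must be divisible by 32")
  nr <- length(model$nodes)
  outs <- vector("list", nr)
  caches <- if (training) vector("list", nr) else NULL
  # last row index that still needs each output (to free memory in eval mode)
  for (i in seq_len(nr)) {
    r <- model$spec$layers[[i]]
    ins <- lapply(r$from, function(f) if (f == 0L) b$x else outs[[f]])
    fw <- node_forward(model$nodes[[i]], ins, training)
    model$nodes[[i]] <- fw$node
    outs[[i]] <- fw$out
    if (training) caches[[i]] <- fw$cache
  }
  head_idx <- which(vapply(model$spec$layers, function(r) r$module == "head",
                           logical(1)))
  preds <- outs[head_idx]
  res <- list(preds = preds, model = model)
  if (training) { res$outs <- outs; res$caches <- caches }
  res
}

#' Backward pass through the detector graph
#'
#' @param model A `pest_model`.
#' @param fw The value returned by `model_forward(..., training = TRUE)`.
#' @param dpreds Gradients of the loss with respect to each raw head output
#'   (same shapes as `fw$preds`).
#' @return A gradient tree: one entry per graph row, mirroring
#'   `node_param_tree()` of that row's node.
#' @export
model_backward <- function(model, fw, dpreds) {
  nr <- length(model$nodes)
  douts <- vector("list", nr)
  head_idx <- which(vapply(model$spec$layers, function(r) r$module == "head",
                           logical(1)))
  for (k in seq_along(head_idx)) douts[[head_idx[k]]] <- dpreds[[k]]
  grads <- vector("list", nr)
  for (i in rev(seq_len(nr))) {
    if (is.null(douts[[i]])) next
    r <- model$spec$layers[[i]]
    bw <- node_backward(model$nodes[[i]], fw$caches[[i]], douts[[i]])
    grads[i] <- list(bw$grads) # plain [[<- would shrink the list on NULL
    for (k in seq_along(r$from)) {
      f <- r$from[k]
      if (f == 0L) next
      douts[[f]] <- if (is.null(douts[[f]])) bw$dins[[k]] else
        douts[[f]] + bw$dins[[k]]
    }
    douts[i] <- list(NULL) # free, preserving list length
  }
  grads
}
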