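test_that("global average pooling equals brute-force channel means", {
  set.seed(1)
  u <- array(rnorm(3 * 3 * 4), c(3, 3, 4))
  s <- global_average_pool(u)
  for (c in 1:4) {
    m <- 0
    for (i in 1:3) for (j in 1:3) m <- m + u[i, j, c]
    expect_lt(abs(s[c] - m / 9), 1e-7)
  }
  const <- array(3.5, c(5, 7, 2))
  expect_equal(global_average_pool(const), c(3.5, 3.5))
  expect_equal(global_average_pool(array(0, c(2, 2, 3))), c(0, 0, 0))
  expect_error(global_average_pool(array(0, c(0, 2, 3))), "empty")
})

test_that("branch convolutions: identity 3x3 kernel reproduces the input", {
  set.seed(2)
  C <- 4
  sk <- sk_params(C)
  # identity-initialized 3x3 branch, zero 5x5 branch
  sk$params$w3$w[] <- 0
  for (c in 1:C) sk$params$w3$w[2, 2, c, c] <- 1
  sk$params$w5$w[] <- 0
  x <- array(rnorm(6 * 6 * C), c(6, 6, C))
  sp <- sk_split(x, sk)
  expect_equal(sp$u1, x, tolerance = 1e-12)
  expect_equal(sp$u2, array(0, dim(x)))
  # zero input -> zero branch outputs (bias-free convolutions)
  z <- sk_split(array(0, c(4, 4, C)), sk)
  expect_true(all(z$u1 == 0) && all(z$u2 == 0))
})

test_that("branch convolution matches a brute-force nested-loop oracle", {
  set.seed(3)
  C <- 8
  sk <- sk_params(C)
  x <- array(rnorm(5 * 5 * C), c(5, 5, C))
  sp <- sk_split(x, sk)
  w <- sk$params$w3$w
  brute <- array(0, c(5, 5, C))
  for (co in 1:C) for (i in 1:5) for (j in 1:5) {
    acc <- 0
    for (ci in 1:C) for (kh in 1:3) for (kw in 1:3) {
      ii <- i + kh - 2; jj <- j + kw - 2
      if (ii >= 1 && ii <= 5 && jj >= 1 && jj <= 5)
        acc <- acc + x[ii, jj, ci] * w[kh, kw, ci, co]
    }
    brute[i, j, co] <- acc
  }
  expect_lt(max(abs(sp$u1 - brute)), 1e-10)
})

test_that("fuse weights are strictly inside (0, 1)", {
  set.seed(4)
  for (i in 1:5) {
    C <- sample(c(4, 8, 16), 1)
    sk <- sk_params(C)
    s <- rnorm(C, sd = 2) # moderate scale: sigmoid saturates to 1.0 in
    a <- fuse_fc(s, sk)   # double precision beyond |logit| ~ 37
    expect_true(all(a > 0 & a < 1))
  }
  # zero FC weights and biases -> sigmoid(0) = 0.5 everywhere
  sk0 <- sk_params(4)
  sk0$params$fc1$w[] <- 0; sk0$params$fc1$b[] <- 0
  sk0$params$fc2$w[] <- 0; sk0$params$fc2$b[] <- 0
  expect_equal(fuse_fc(rnorm(4), sk0), rep(0.5, 4))
  expect_error(fuse_fc(c(1, NA, 3, 4), sk_params(4)), "finite")
})

test_that("hidden width respects the reduction-ratio floor", {
  expect_equal(sk_params(256)$hidden, 16L)
  expect_equal(sk_params(64)$hidden, 8L)   # floored at 8
  expect_equal(sk_params(8)$hidden, 8L)
})

test_that("sk_forward equals the composed sub-operations and the shared-weight identity", {
  set.seed(5)
  for (i in 1:100) {
    C <- sample(c(4, 8), 1)
    H <- sample(3:6, 1); W <- sample(3:6, 1)
    sk <- sk_params(C)
    x <- array(rnorm(H * W * C), c(H, W, C))
    v <- sk_forward(x, sk)
    sp <- sk_split(x, sk)
    u <- sp$u1 + sp$u2
    a <- fuse_fc(global_average_pool(u), sk)
    manual <- sp$u1 * rep(a, each = H * W) + sp$u2 * rep(a, each = H * W)
    expect_lt(max(abs(v - manual)), 1e-10)
    # the single shared weight vector makes V == (U1 + U2) (.) a exactly
    expect_lt(max(abs(v - u * rep(a, each = H * W))), 1e-10)
    expect_true(all(is.finite(v)))
    expect_equal(dim(v), dim(x))
  }
})

test_that("all-ones channel weights reduce the scale stage to U1 + U2", {
  set.seed(6)
  C <- 4
  sk <- sk_params(C)
  # saturate the second FC bias so a -> 1 numerically
  sk$params$fc2$w[] <- 0
  sk$params$fc2$b[] <- 40
  x <- array(rnorm(5 * 5 * C), c(5, 5, C))
  sp <- sk_split(x, sk)
  expect_equal(sk_forward(x, sk), sp$u1 + sp$u2, tolerance = 1e-10)
})

test_that("channel mismatch and batched inputs are handled", {
  sk <- sk_params(4)
  expect_error(sk_split(array(0, c(4, 4, 3)), sk), "channels")
  xb <- array(rnorm(4 * 4 * 4 * 2), c(4, 4, 4, 2))
  vb <- sk_forward(xb, sk)
  expect_equal(dim(vb), dim(xb))
  # batch consistency with per-sample evaluation
  v1 <- sk_forward(xb[, , , 1], sk)
  expect_lt(max(abs(vb[, , , 1] - v1)), 1e-10)
})

test_that("softmax mode reweights branches with weights summing to one", {
  set.seed(7)
  sk <- sk_params(4, mode = "softmax")
  x <- array(rnorm(5 * 5 * 4), c(5, 5, 4))
  v <- sk_forward(x, sk)
  expect_true(all(is.finite(v)))
  expect_equal(dim(v), dim(x))
})
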