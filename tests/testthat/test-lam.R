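test_that("channel importance pooling matches a double-loop reference", {
  f <- array(0, c(2, 2, 1)); f[, , 1] <- matrix(c(1, 3, 2, 4), 2, 2)
  expect_equal(importance_vector(f, "average"), 2.5)
  const <- array(7, c(5, 3, 4))
  expect_equal(importance_vector(const, "average"), rep(7, 4))
  expect_equal(importance_vector(const, "max"), rep(7, 4))
  withr::with_seed(2, {
    g <- array(rnorm(7 * 5 * 3), c(7, 5, 3))
    ref_avg <- ref_max <- numeric(3)
    for (c in 1:3) {
      s <- 0; m <- -Inf
      for (a in 1:7) for (b in 1:5) {
        s <- s + g[a, b, c]
        if (g[a, b, c] > m) m <- g[a, b, c]
      }
      ref_avg[c] <- s / 35; ref_max[c] <- m
    }
    expect_equal(importance_vector(g, "average"), ref_avg)
    expect_equal(importance_vector(g, "max"), ref_max)
  })
})

test_that("adaptive kernel size is the nearest odd integer, ties downward", {
  cfg <- lam_config(gamma = 2, b = 1)
  expect_equal(lam_kernel_size(2, cfg), 1L)    # |0.5 + 0.5|_odd
  expect_equal(lam_kernel_size(64, cfg), 3L)   # 3.5 ties to the smaller odd
  expect_equal(lam_kernel_size(256, cfg), 5L)  # nearest odd to 4.5
  ks <- lam_kernel_size(1:4096, cfg)
  expect_true(all(ks %% 2 == 1))
  expect_true(all(ks >= 1))
})

test_that("softmax channel weights are a proper order-preserving simplex map", {
  expect_equal(channel_weights(c(0, log(3))), c(0.25, 0.75))
  expect_equal(channel_weights(rep(1.7, 8)), rep(1 / 8, 8))
  withr::with_seed(3, {
    k <- rnorm(100, sd = 4)
    w <- channel_weights(k)
    expect_equal(w, exp(k) / sum(exp(k)), tolerance = 1e-12)
    expect_equal(order(k), order(w))
  })
  expect_error(channel_weights(c(1, NA)), "finite")
})

test_that("weighted fusion rescales channels and is identity under uniform weights", {
  withr::with_seed(4, {
    f <- array(rnorm(6 * 5 * 4), c(6, 5, 4))
    expect_equal(weighted_fuse(f, rep(1 / 4, 4)), f)
    w <- channel_weights(rnorm(4))
    out <- weighted_fuse(f, w)
    for (c in 1:4) expect_equal(out[, , c], 4 * w[c] * f[, , c])
    w0 <- c(0, 0.5, 0.5, 0)
    expect_true(all(weighted_fuse(f, w0)[, , 1] == 0))
    expect_error(weighted_fuse(f, rep(0.5, 2)), "mismatch")
  })
})

test_that("the two-FC weight path has the declared shape and gradients", {
  withr::with_seed(5, {
    z <- rnorm(8)
    k <- weight_logits(z, lam_config(reduction = 2))
    expect_length(k, 8)
    for (C in c(8, 64, 256))
      expect_length(weight_logits(rnorm(C), lam_config(reduction = 4)), C)
    # finite-difference check of d(sum k^2)/d(FC1 W) through the layer
    ns <- asNamespace("fishdeblur")
    l <- lam_new(6, lam_config(reduction = 2))
    f <- array(rnorm(4 * 4 * 6), c(4, 4, 6))
    ns$nn_zero_grads(ns$lam_layers(l))
    y <- lam_forward(l, f, training = TRUE)
    ns$lam_backward(l, y)   # L = sum(y^2)/2
    eps <- 1e-5
    for (i in sample(length(l$fc1$params$W), 5)) {
      v0 <- l$fc1$params$W[i]
      l$fc1$params$W[i] <- v0 + eps
      lp <- sum(lam_forward(l, f, training = TRUE)^2) / 2
      l$fc1$params$W[i] <- v0 - eps
      lm <- sum(lam_forward(l, f, training = TRUE)^2) / 2
      l$fc1$params$W[i] <- v0
      expect_equal(l$fc1$grads$W[i], (lp - lm) / (2 * eps), tolerance = 1e-4)
    }
  })
})

test_that("LAM forward is shape-preserving, normalised and identity-configurable", {
  withr::with_seed(6, {
    l <- lam_new(5, lam_config(reduction = 1))
    f <- array(rnorm(8 * 8 * 5), c(8, 8, 5))
    y <- lam_forward(l, f)
    expect_identical(dim(y), dim(f))
    # zeroing the second FC makes the logits zero -> uniform weights -> identity
    l$fc2$params$W[] <- 0; l$fc2$params$b[] <- 0
    expect_equal(lam_forward(l, f), f)
  })
})

test_that("LAM weights form a simplex on many random feature maps", {
  withr::with_seed(8, {
    for (i in 1:50) {
      C <- sample(2:32, 1)
      f <- array(rnorm(3 * 4 * C, sd = runif(1, 0.1, 5)), c(3, 4, C))
      k <- weight_logits(importance_vector(f), lam_config(reduction = 1))
      w <- channel_weights(k)
      expect_equal(sum(w), 1, tolerance = 1e-6)
      expect_true(all(w >= 0 & w <= 1))
    }
  })
})

test_that("identity-FC LAM is equivariant under channel permutations", {
  ns <- asNamespace("fishdeblur")
  withr::with_seed(9, {
    l <- lam_new(4, lam_config(reduction = 1))
    l$fc1$params$W <- diag(4); l$fc1$params$b[] <- 0
    l$fc2$params$W <- diag(4); l$fc2$params$b[] <- 0
    f <- array(abs(rnorm(5 * 5 * 4)), c(5, 5, 4))  # positive: ReLU transparent
    perm <- c(3, 1, 4, 2)
    y1 <- lam_forward(l, f)[, , perm]
    y2 <- lam_forward(l, f[, , perm])
    expect_equal(y1, y2, tolerance = 1e-12)
  })
})
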