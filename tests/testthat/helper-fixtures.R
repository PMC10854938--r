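# shared fixtures: random images and brute-force reference implementations

rand_img <- function(h, w, seed = NULL) {
  draw <- function() image_grid(array(runif(h * w * 3, 0, 255), c(h, w, 3)))
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

# per-pixel reference of the ripple warp (direct loop over the displacement,
# assignment and overlay equations)
ripple_oracle <- function(img, frequency, amplitude, blend = "replace") {
  a <- unclass(as_image_grid(img))
  h <- dim(a)[1L]; w <- dim(a)[2L]
  out <- array(0, dim(a))
  for (y in 0:(h - 1)) for (x in 0:(w - 1)) {
    ox <- round(amplitude * sin(2 * pi * y * frequency))
    oy <- round(amplitude * cos(2 * pi * x * frequency))
    sx <- (x + ox) %% w
    sy <- (y + oy) %% h
    out[y + 1, x + 1, ] <- a[sy + 1, sx + 1, ]
  }
  if (blend == "mean") out <- (a + out) / 2
  image_grid(out)
}

# sort-free reference for top-k accuracy: explicit count of better-scoring
# classes, ties resolved toward lower class index
topk_oracle <- function(scores, labels, k) {
  hits <- 0L
  for (i in seq_len(nrow(scores))) {
    s <- scores[i, ]; l <- labels[i]
    rank <- sum(s > s[l]) + sum(s == s[l] & seq_along(s) < l) + 1L
    if (rank <= k) hits <- hits + 1L
  }
  hits / nrow(scores) * 100
}

# finite-difference gradient check of a layer stack under L = sum(y^2)/2;
# returns the worst relative error over sampled parameters and inputs
fd_gradcheck <- function(layers, xdim, n_probe = 4, eps = 1e-5) {
  x <- array(rnorm(prod(xdim)), xdim)
  loss <- function() sum(fishdeblur:::seq_fwd(layers, x, training = TRUE)^2) / 2
  fishdeblur:::nn_zero_grads(layers)
  y <- fishdeblur:::seq_fwd(layers, x, training = TRUE)
  dx <- fishdeblur:::seq_bwd(layers, y)
  errs <- c()
  for (l in layers) for (p in names(l$params)) {
    for (i in sample(length(l$params[[p]]), min(n_probe, length(l$params[[p]])))) {
      v0 <- l$params[[p]][i]
      l$params[[p]][i] <- v0 + eps; lp <- loss()
      l$params[[p]][i] <- v0 - eps; lm <- loss()
      l$params[[p]][i] <- v0
      num <- (lp - lm) / (2 * eps)
      errs <- c(errs, abs(num - l$grads[[p]][i]) /
                  max(1e-4, abs(num) + abs(l$grads[[p]][i])))
    }
  }
  for (i in sample(length(x), n_probe)) {
    v0 <- x[i]
    x[i] <- v0 + eps; lp <- loss()
    x[i] <- v0 - eps; lm <- loss()
    x[i] <- v0
    num <- (lp - lm) / (2 * eps)
    errs <- c(errs, abs(num - dx[i]) / max(1e-4, abs(num) + abs(dx[i])))
  }
  max(errs)
}
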