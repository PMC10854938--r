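# Minimal CPU neural-network substrate.
#
# Feature maps are H x W x C double arrays. Layers are environments holding
# `params` / `grads` (gradients accumulate across a mini-batch; the optimiser
# zeroes them after each step). Convolutions are lowered to BLAS matrix
# products through im2col; the patch-index matrix is cached per input shape.
# All randomness (init, dropout) draws from the session RNG so seeded runs
# are bit-reproducible.

nn_env <- function(type, params = list()) {
  l <- new.env(parent = emptyenv())
  l$type <- type
  l$params <- params
  l$grads <- lapply(params, function(p) {
    if (is.matrix(p)) matrix(0, nrow(p), ncol(p)) else numeric(length(p))
  })
  l
}

# He-scaled Gaussian init
he_init <- function(n_out_rows, n_cols, fan_in) {
  matrix(stats::rnorm(n_out_rows * n_cols, sd = sqrt(2 / fan_in)), n_out_rows, n_cols)
}

conv2d_new <- function(in_ch, out_ch, k, stride = 1L, pad = NULL, dilation = 1L) {
  if (is.null(pad)) pad <- ((k - 1L) * dilation) %/% 2L
  l <- nn_env("conv2d", list(
    W = he_init(k * k * in_ch, out_ch, fan_in = k * k * in_ch),
    b = numeric(out_ch)))
  l$k <- as.integer(k); l$stride <- as.integer(stride)
  l$pad <- as.integer(pad); l$dil <- as.integer(dilation)
  l$in_ch <- as.integer(in_ch); l$out_ch <- as.integer(out_ch)
  l
}

# patch-index matrix (Ho*Wo) x (k*k*C) into the zero-padded input
conv_idx <- function(l, H, W, C) {
  key <- paste(H, W, C, sep = "x")
  if (identical(l$idx_key, key)) return(invisible(NULL))
  p <- l$pad; k <- l$k; s <- l$stride; dl <- l$dil
  Hp <- H + 2L * p; Wp <- W + 2L * p
  span <- (k - 1L) * dl + 1L
  Ho <- (Hp - span) %/% s + 1L; Wo <- (Wp - span) %/% s + 1L
  if (Ho < 1L || Wo < 1L) stop("input too small for this convolution")
  base <- as.vector(outer(seq.int(0L, by = s, length.out = Ho),
                          seq.int(0L, by = s, length.out = Wo) * Hp, "+"))
  off_sp <- as.vector(outer((0:(k - 1L)) * dl, (0:(k - 1L)) * dl * Hp, "+"))
  off <- as.vector(outer(off_sp, (0:(C - 1L)) * Hp * Wp, "+"))
  idx <- outer(base, off, "+") + 1
  storage.mode(idx) <- "integer"
  l$idx <- idx; l$idx_key <- key
  l$Ho <- Ho; l$Wo <- Wo; l$Hp <- Hp; l$Wp <- Wp
  # scatter-add structure for the backward pass (segment sums over sorted idx)
  idxv <- as.vector(idx)
  perm <- order(idxv)
  sorted <- idxv[perm]
  ends <- c(which(diff(sorted) != 0L), length(sorted))
  l$sc_perm <- perm; l$sc_ends <- ends; l$sc_uidx <- sorted[ends]
  invisible(NULL)
}

# dxp[uidx] <- per-group sums of v over the cached index layout
scatter_add <- function(l, v, n_out) {
  cs <- cumsum(v[l$sc_perm])
  ends <- l$sc_ends
  sums <- cs[ends] - c(0, cs[ends[-length(ends)]])
  out <- numeric(n_out)
  out[l$sc_uidx] <- sums
  out
}

conv2d_fwd <- function(l, x, training = FALSE) {
  d <- dim(x)
  if (d[3L] != l$in_ch) stop("channel mismatch in conv2d")
  conv_idx(l, d[1L], d[2L], d[3L])
  xp <- array(0, c(l$Hp, l$Wp, d[3L]))
  xp[l$pad + seq_len(d[1L]), l$pad + seq_len(d[2L]), ] <- x
  xc <- matrix(xp[l$idx], nrow(l$idx), ncol(l$idx))
  y <- xc %*% l$params$W
  y <- y + rep(l$params$b, each = nrow(y))
  if (training) l$cache <- list(xc = xc, xdim = d)
  array(y, c(l$Ho, l$Wo, l$out_ch))
}

conv2d_bwd <- function(l, dy) {
  cc <- l$cache; d <- cc$xdim
  dym <- matrix(dy, l$Ho * l$Wo, l$out_ch)
  l$grads$W <- l$grads$W + crossprod(cc$xc, dym)
  l$grads$b <- l$grads$b + colSums(dym)
  dxc <- tcrossprod(dym, l$params$W)
  dxp <- array(scatter_add(l, as.vector(dxc), l$Hp * l$Wp * d[3L]),
               c(l$Hp, l$Wp, d[3L]))
  l$cache <- NULL
  dxp[l$pad + seq_len(d[1L]), l$pad + seq_len(d[2L]), , drop = FALSE]
}

dense_new <- function(n_in, n_out) {
  l <- nn_env("dense", list(W = he_init(n_in, n_out, fan_in = n_in),
                            b = numeric(n_out)))
  l$n_in <- n_in; l$n_out <- n_out
  l
}

dense_fwd <- function(l, x, training = FALSE) {
  x <- as.vector(x)
  if (training) l$cache <- x
  as.vector(x %*% l$params$W) + l$params$b
}

dense_bwd <- function(l, dy) {
  x <- l$cache
  l$grads$W <- l$grads$W + outer(x, dy)
  l$grads$b <- l$grads$b + dy
  l$cache <- NULL
  as.vector(l$params$W %*% dy)
}

batchnorm_new <- function(C, momentum = 0.1, eps = 1e-5) {
  l <- nn_env("batchnorm", list(gamma = rep(1, C), beta = numeric(C)))
  l$C <- C; l$momentum <- momentum; l$eps <- eps
  l$run_mean <- numeric(C); l$run_var <- rep(1, C)
  l
}

batchnorm_fwd <- function(l, x, training = FALSE) {
  d <- dim(x); n <- d[1L] * d[2L]
  xm <- matrix(x, n, d[3L])
  if (training) {
    mu <- colMeans(xm)
    v <- colMeans(xm * xm) - mu^2
    v[v < 0] <- 0
    inv <- 1 / sqrt(v + l$eps)
    xh <- (xm - rep(mu, each = n)) * rep(inv, each = n)
    l$run_mean <- (1 - l$momentum) * l$run_mean + l$momentum * mu
    l$run_var <- (1 - l$momentum) * l$run_var + l$momentum * v
    l$cache <- list(xh = xh, inv = inv, d = d)
  } else {
    inv <- 1 / sqrt(l$run_var + l$eps)
    xh <- (xm - rep(l$run_mean, each = n)) * rep(inv, each = n)
  }
  y <- xh * rep(l$params$gamma, each = n) + rep(l$params$beta, each = n)
  array(y, d)
}

batchnorm_bwd <- function(l, dy) {
  cc <- l$cache; d <- cc$d; n <- d[1L] * d[2L]
  dym <- matrix(dy, n, d[3L])
  l$grads$gamma <- l$grads$gamma + colSums(dym * cc$xh)
  l$grads$beta <- l$grads$beta + colSums(dym)
  dxh <- dym * rep(l$params$gamma, each = n)
  s1 <- colSums(dxh); s2 <- colSums(dxh * cc$xh)
  dx <- (dxh - rep(s1 / n, each = n) - cc$xh * rep(s2 / n, each = n)) *
    rep(cc$inv, each = n)
  l$cache <- NULL
  array(dx, d)
}

relu_new <- function() nn_env("relu")
relu_fwd <- function(l, x, training = FALSE) {
  y <- x; y[y < 0] <- 0
  if (training) l$cache <- x > 0
  y
}
relu_bwd <- function(l, dy) {
  dx <- dy * l$cache
  l$cache <- NULL
  dx
}

elu_new <- function(alpha = 1) { l <- nn_env("elu"); l$alpha <- alpha; l }
elu_fwd <- function(l, x, training = FALSE) {
  neg <- x < 0
  y <- x
  y[neg] <- l$alpha * (exp(x[neg]) - 1)
  if (training) l$cache <- list(neg = neg, yneg = y[neg])
  y
}
elu_bwd <- function(l, dy) {
  dx <- dy
  dx[l$cache$neg] <- dy[l$cache$neg] * (l$cache$yneg + l$alpha)
  l$cache <- NULL
  dx
}

dropout_new <- function(p = 0.1) { l <- nn_env("dropout"); l$p <- p; l }
dropout_fwd <- function(l, x, training = FALSE) {
  if (!training || l$p <= 0) return(x)
  mask <- array((stats::runif(length(x)) > l$p) / (1 - l$p), dim(x))
  l$cache <- mask
  x * mask
}
dropout_bwd <- function(l, dy) {
  if (is.null(l$cache)) return(dy)
  dx <- dy * l$cache
  l$cache <- NULL
  dx
}

maxpool_new <- function(k = 2L, stride = k, pad = 0L) {
  l <- nn_env("maxpool")
  l$k <- as.integer(k); l$stride <- as.integer(stride)
  l$pad <- as.integer(pad); l$dil <- 1L
  l
}

maxpool_fwd <- function(l, x, training = FALSE) {
  d <- dim(x)
  conv_idx(l, d[1L], d[2L], 1L)   # single-channel patch index
  kk <- l$k * l$k
  y <- array(0, c(l$Ho, l$Wo, d[3L]))
  am <- if (training) matrix(0L, l$Ho * l$Wo, d[3L])
  xp <- matrix(-Inf, l$Hp, l$Wp)
  for (c in seq_len(d[3L])) {
    xp[l$pad + seq_len(d[1L]), l$pad + seq_len(d[2L])] <- x[, , c]
    xc <- matrix(xp[l$idx], nrow(l$idx), kk)
    m <- xc[, 1L]; a <- rep(1L, length(m))
    for (j in seq_len(kk)[-1L]) {
      sel <- xc[, j] > m
      m[sel] <- xc[sel, j]; a[sel] <- j
    }
    y[, , c] <- m
    if (training) am[, c] <- a
  }
  if (training) l$cache <- list(am = am, xdim = d)
  y
}

maxpool_bwd <- function(l, dy) {
  cc <- l$cache; d <- cc$xdim
  dx <- array(0, d)
  rows <- seq_len(nrow(l$idx))
  for (c in seq_len(d[3L])) {
    dxp <- numeric(l$Hp * l$Wp)
    win <- l$idx[cbind(rows, cc$am[, c])]
    dyv <- as.vector(dy[, , c])
    o <- order(win); w_s <- win[o]; v_s <- dyv[o]
    ends <- c(which(diff(w_s) != 0L), length(w_s))
    cs <- cumsum(v_s)
    dxp[w_s[ends]] <- cs[ends] - c(0, cs[ends[-length(ends)]])
    dx[, , c] <- matrix(dxp, l$Hp, l$Wp)[l$pad + seq_len(d[1L]),
                                         l$pad + seq_len(d[2L])]
  }
  l$cache <- NULL
  dx
}

upsample2_new <- function() nn_env("upsample2")
upsample2_fwd <- function(l, x, training = FALSE) {
  d <- dim(x)
  if (training) l$cache <- d
  x[rep(seq_len(d[1L]), each = 2L), rep(seq_len(d[2L]), each = 2L), , drop = FALSE]
}
upsample2_bwd <- function(l, dy) {
  d <- l$cache
  o <- seq.int(1L, 2L * d[1L], 2L); p <- seq.int(1L, 2L * d[2L], 2L)
  dx <- dy[o, p, , drop = FALSE] + dy[o + 1L, p, , drop = FALSE] +
    dy[o, p + 1L, , drop = FALSE] + dy[o + 1L, p + 1L, , drop = FALSE]
  l$cache <- NULL
  dx
}

# per-pixel softmax over the channel dimension
softmaxc_new <- function() nn_env("softmaxc")
softmaxc_fwd <- function(l, x, training = FALSE) {
  d <- dim(x)
  xm <- matrix(x, d[1L] * d[2L], d[3L])
  mx <- as.vector(do.call(pmax, lapply(asplit(xm, 2L), as.vector)))
  e <- exp(xm - mx)
  y <- e / rowSums(e)
  y <- array(y, d)
  if (training) l$cache <- y
  y
}
softmaxc_bwd <- function(l, dy) {
  y <- l$cache; d <- dim(y)
  ym <- matrix(y, d[1L] * d[2L], d[3L])
  dym <- matrix(dy, d[1L] * d[2L], d[3L])
  s <- rowSums(dym * ym)
  dx <- ym * (dym - s)
  l$cache <- NULL
  array(dx, d)
}

nn_forward <- function(l, x, training = FALSE) {
  switch(l$type,
         conv2d = conv2d_fwd(l, x, training),
         dense = dense_fwd(l, x, training),
         batchnorm = batchnorm_fwd(l, x, training),
         relu = relu_fwd(l, x, training),
         elu = elu_fwd(l, x, training),
         dropout = dropout_fwd(l, x, training),
         maxpool = maxpool_fwd(l, x, training),
         upsample2 = upsample2_fwd(l, x, training),
         softmaxc = softmaxc_fwd(l, x, training),
         lam = lam_forward(l, x, training),
         identity = x,
         stop("unknown layer type ", l$type))
}

nn_backward <- function(l, dy) {
  switch(l$type,
         conv2d = conv2d_bwd(l, dy),
         dense = dense_bwd(l, dy),
         batchnorm = batchnorm_bwd(l, dy),
         relu = relu_bwd(l, dy),
         elu = elu_bwd(l, dy),
         dropout = dropout_bwd(l, dy),
         maxpool = maxpool_bwd(l, dy),
         upsample2 = upsample2_bwd(l, dy),
         softmaxc = softmaxc_bwd(l, dy),
         lam = lam_backward(l, dy),
         identity = dy,
         stop("unknown layer type ", l$type))
}

identity_new <- function() nn_env("identity")

# flatten composite layers (LAM) into their parameter-bearing pieces
flatten_layers <- function(layers) {
  out <- list()
  for (l in layers) {
    if (l$type == "lam") out <- c(out, lam_layers(l)) else out <- c(out, list(l))
  }
  out
}

seq_fwd <- function(layers, x, training = FALSE) {
  for (l in layers) x <- nn_forward(l, x, training)
  x
}
seq_bwd <- function(layers, dy) {
  for (l in rev(layers)) dy <- nn_backward(l, dy)
  dy
}

#' Count trainable parameters
#' @param layers a flat list of internal layer objects (as stored in the
#'   `$layers` field of the package's models).
#' @return integer total parameter count.
#' @export
count_params <- function(layers) {
  sum(vapply(layers, function(l) sum(vapply(l$params, length, 1L)), 1L))
}

nn_zero_grads <- function(layers) {
  for (l in layers)
    l$grads <- lapply(l$grads, function(g) { g[] <- 0; g })
  invisible(NULL)
}

# Adam over a flat layer list; moment state lives inside each layer env
adam_new <- function(layers, lr = 2e-3, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  opt <- new.env(parent = emptyenv())
  opt$layers <- layers; opt$lr <- lr
  opt$beta1 <- beta1; opt$beta2 <- beta2; opt$eps <- eps; opt$t <- 0L
  opt
}

adam_step <- function(opt) {
  opt$t <- opt$t + 1L
  b1 <- opt$beta1; b2 <- opt$beta2
  c1 <- 1 - b1^opt$t; c2 <- 1 - b2^opt$t
  for (l in opt$layers) {
    if (length(l$params) == 0L) next
    if (is.null(l$opt_m)) {
      l$opt_m <- lapply(l$grads, function(g) { g[] <- 0; g })
      l$opt_v <- l$opt_m
    }
    for (p in names(l$params)) {
      g <- l$grads[[p]]
      l$opt_m[[p]] <- b1 * l$opt_m[[p]] + (1 - b1) * g
      l$opt_v[[p]] <- b2 * l$opt_v[[p]] + (1 - b2) * g * g
      l$params[[p]] <- l$params[[p]] -
        opt$lr * (l$opt_m[[p]] / c1) / (sqrt(l$opt_v[[p]] / c2) + opt$eps)
      l$grads[[p]][] <- 0
    }
  }
  invisible(NULL)
}
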