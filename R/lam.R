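#' Configuration of the learnable attention module (LAM)
#'
#' LAM reweights the channels of a feature map in three steps: channel
#' importance by global pooling, weight learning through a two-layer fully
#' connected bottleneck with ReLU, and softmax-normalised weighted fusion.
#' `gamma` and `b` parameterise the adaptive kernel-size diagnostic
#' [lam_kernel_size()]; `reduction` sets the FC bottleneck ratio.
#'
#' @param gamma positive integer scale of the kernel-size formula (default 2).
#' @param b integer offset of the kernel-size formula (default 1).
#' @param pooling `"average"` or `"max"` global pooling.
#' @param reduction positive integer bottleneck divisor for the two FC layers
#'   (default 4).
#' @return a `lam_config` list.
#' @export
lam_config <- function(gamma = 2L, b = 1L, pooling = c("average", "max"),
                       reduction = 4L) {
  pooling <- match.arg(pooling)
  if (gamma < 1) stop("`gamma` must be >= 1")
  if (reduction < 1) stop("`reduction` must be >= 1")
  structure(list(gamma = as.integer(gamma), b = as.integer(b),
                 pooling = pooling, reduction = as.integer(reduction)),
            class = "lam_config")
}

#' Channel importance by global pooling
#'
#' `Z_c = mean_{a,b} x_c(a, b)` for average pooling (or the spatial maximum
#' for max pooling), one value per channel.
#'
#' @param f feature map, `H x W x C` array.
#' @param pooling `"average"` or `"max"`.
#' @return numeric vector of length `C`.
#' @export
importance_vector <- function(f, pooling = c("average", "max")) {
  pooling <- match.arg(pooling)
  d <- dim(f)
  if (is.null(d) || length(d) != 3L) stop("`f` must be an H x W x C array")
  if (d[1L] < 1L || d[2L] < 1L) stop("zero-sized spatial dimensions")
  m <- matrix(f, d[1L] * d[2L], d[3L])
  if (pooling == "average") colMeans(m)
  else apply(m, 2L, max)
}

#' Adaptive kernel size
#'
#' `phi(C) = | log2(C) / gamma + b / gamma |_odd`, the nearest odd integer
#' (ties broken toward the smaller odd number), floored at 1. Used as a
#' channel-coverage diagnostic for the attention module.
#'
#' @param C channel count, `>= 1` (vectorised).
#' @param config a [lam_config()].
#' @return odd integer(s) `>= 1`.
#' @examples
#' lam_kernel_size(c(2, 64, 256), lam_config())  # 1, 3, 5
#' @export
lam_kernel_size <- function(C, config = lam_config()) {
  if (any(C < 1)) stop("`C` must be >= 1")
  v <- log2(C) / config$gamma + config$b / config$gamma
  lo <- 2 * floor((v - 1) / 2) + 1   # greatest odd <= v
  res <- ifelse(v - lo <= (lo + 2) - v, lo, lo + 2)  # ties -> smaller odd
  as.integer(pmax(res, 1))
}

# the two-FC weight-learning path as a param-bearing unit
lam_fc_new <- function(C, reduction) {
  cr <- max(1L, C %/% reduction)
  if (reduction > C) stop("`reduction` larger than channel count")
  list(fc1 = dense_new(C, cr), fc2 = dense_new(cr, C))
}

#' Channel weight logits from the importance vector
#'
#' `k = FC2(ReLU(FC1(Z)))` with `FC1: C -> C/reduction` and
#' `FC2: C/reduction -> C`.
#'
#' @param z importance vector of length `C` (see [importance_vector()]).
#' @param config a [lam_config()].
#' @param params the FC parameters of a LAM layer (from [lam_new()]); fresh
#'   randomly initialised layers are created when omitted.
#' @return numeric vector of length `C`.
#' @export
weight_logits <- function(z, config = lam_config(), params = NULL) {
  C <- length(z)
  if (is.null(params)) params <- lam_fc_new(C, config$reduction)
  h <- dense_fwd(params$fc1, z)
  h[h < 0] <- 0
  dense_fwd(params$fc2, h)
}

#' Softmax channel weights
#'
#' Maps the logit vector `k` to weights in `[0, 1]` summing to 1,
#' `w_c = exp(k_c) / sum_j exp(k_j)`, preserving the order of `k`.
#'
#' @param k numeric logit vector.
#' @return numeric weight vector of the same length.
#' @export
channel_weights <- function(k) {
  if (any(!is.finite(k))) stop("logits must be finite")
  e <- exp(k - max(k))
  e / sum(e)
}

#' Weighted channel fusion
#'
#' Rescales channel `c` by `C * w_c`, so that the uninformative uniform
#' weight vector (`w_c = 1/C`) is the identity transform while weights near
#' zero suppress their channel.
#'
#' @param f feature map, `H x W x C`.
#' @param w channel weights of length `C` (see [channel_weights()]).
#' @return feature map of the same shape.
#' @export
weighted_fuse <- function(f, w) {
  d <- dim(f)
  if (length(w) != d[3L]) stop("channel-count mismatch between `f` and `w`")
  sweep(f, 3L, d[3L] * w, "*")
}

#' LAM layer
#'
#' Creates a learnable attention layer for feature maps with `C` channels.
#' [lam_forward()] applies the full composition
#' `importance_vector -> weight_logits -> channel_weights -> weighted_fuse`;
#' the layer is differentiable end to end (used inside the package's
#' classifiers).
#'
#' @param C channel count.
#' @param config a [lam_config()].
#' @return a LAM layer object.
#' @export
lam_new <- function(C, config = lam_config()) {
  l <- nn_env("lam")
  fcs <- lam_fc_new(C, config$reduction)
  l$fc1 <- fcs$fc1; l$fc2 <- fcs$fc2
  l$C <- as.integer(C); l$config <- config
  l
}

#' @rdname lam_new
#' @param l a LAM layer.
#' @param f feature map, `H x W x C`.
#' @param training logical; retain caches for backpropagation.
#' @export
lam_forward <- function(l, f, training = FALSE) {
  d <- dim(f)
  if (d[3L] != l$C) stop("channel mismatch in LAM")
  z <- importance_vector(f, l$config$pooling)
  h <- dense_fwd(l$fc1, z, training)
  hr <- h; hr[hr < 0] <- 0
  k <- dense_fwd(l$fc2, hr, training)
  w <- channel_weights(k)
  y <- weighted_fuse(f, w)
  if (training) l$cache <- list(f = f, w = w, hmask = h > 0, d = d)
  y
}

lam_backward <- function(l, dy) {
  cc <- l$cache; d <- cc$d; C <- l$C
  w <- cc$w
  # y_c = C * w_c * f_c
  dym <- matrix(dy, d[1L] * d[2L], C)
  fm <- matrix(cc$f, d[1L] * d[2L], C)
  dw <- C * colSums(dym * fm)
  df_direct <- sweep(dy, 3L, C * w, "*")
  # softmax backward
  dk <- w * (dw - sum(dw * w))
  dhr <- dense_bwd(l$fc2, dk)
  dh <- dhr * cc$hmask
  dz <- dense_bwd(l$fc1, dh)
  # z_c = mean of f_c (average pooling path); max pooling is not trained
  if (l$config$pooling == "average") {
    df_pool <- sweep(array(1, d), 3L, dz / (d[1L] * d[2L]), "*")
  } else {
    df_pool <- array(0, d)
  }
  l$cache <- NULL
  df_direct + df_pool
}

# parameter-bearing sublayers of a LAM (for optimiser collection)
lam_layers <- function(l) list(l$fc1, l$fc2)
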