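# Two-stage diffusion deblurrer: a U-Net predictive stage emitting per-pixel
# class-probability maps, then a reconstructive stage of four
# (residual block -> upsampling) modules operating on the channel
# concatenation of the probability map and the degraded input.

cat3 <- function(a, b) {
  da <- dim(a); db <- dim(b)
  array(c(a, b), c(da[1L], da[2L], da[3L] + db[3L]))
}

unet_new <- function(n_classes, base = 8L, in_ch = 3L) {
  u <- new.env(parent = emptyenv())
  ch <- base * c(1L, 2L, 4L, 8L)
  ins <- c(in_ch, ch[1:3])
  u$enc <- lapply(1:4, function(i)
    list(conv2d_new(ins[i], ch[i], 3L), batchnorm_new(ch[i]), relu_new()))
  u$pool <- lapply(1:4, function(i) maxpool_new(2L))
  # decoder level i consumes the upsampled deeper feature + skip f_i
  dec_in <- c(2L * ch[1L], 2L * ch[2L], 2L * ch[3L], 2L * ch[4L])
  dec_out <- c(ch[1L], ch[1L], ch[2L], ch[3L])
  u$up <- lapply(1:4, function(i) upsample2_new())
  u$dec <- lapply(1:4, function(i)
    list(conv2d_new(dec_in[i], dec_out[i], 3L), batchnorm_new(dec_out[i]), relu_new()))
  u$out_conv <- conv2d_new(dec_out[1L], n_classes, 1L)
  u$softmax <- softmaxc_new()
  u$ch <- ch; u$n_classes <- as.integer(n_classes)
  u$layers <- c(unlist(u$enc, recursive = FALSE), u$pool,
                unlist(u$dec, recursive = FALSE), u$up,
                list(u$out_conv, u$softmax))
  u
}

unet_fwd <- function(u, x, training = FALSE) {
  d <- dim(x)
  if (d[1L] %% 16L != 0L || d[2L] %% 16L != 0L)
    stop("input dims must be divisible by 16 (four 2x poolings); pad the image")
  f <- vector("list", 4L)
  h <- x
  for (i in 1:4) {
    f[[i]] <- seq_fwd(u$enc[[i]], h, training)
    h <- maxpool_fwd(u$pool[[i]], f[[i]], training)
  }
  skip_ch <- integer(4L)
  for (i in 4:1) {
    hu <- upsample2_fwd(u$up[[i]], h, training)
    skip_ch[i] <- dim(hu)[3L]
    h <- seq_fwd(u$dec[[i]], cat3(hu, f[[i]]), training)
  }
  logits <- conv2d_fwd(u$out_conv, h, training)
  if (training) u$skip_ch <- skip_ch
  softmaxc_fwd(u$softmax, logits, training)
}

unet_bwd <- function(u, dy) {
  d <- softmaxc_bwd(u$softmax, dy)
  dh <- conv2d_bwd(u$out_conv, d)
  dpool <- NULL
  dskip <- vector("list", 4L)
  for (i in 1:4) {
    dcat <- seq_bwd(u$dec[[i]], dh)
    ca <- u$skip_ch[i]
    dup <- dcat[, , seq_len(ca), drop = FALSE]
    dskip[[i]] <- dcat[, , -seq_len(ca), drop = FALSE]
    dh <- upsample2_bwd(u$up[[i]], dup)
  }
  # dh is now the gradient at the deepest pooled feature; walk back up
  for (i in 4:1) {
    df <- maxpool_bwd(u$pool[[i]], dh) + dskip[[i]]
    dh <- seq_bwd(u$enc[[i]], df)
  }
  dh
}

res_block_new <- function(ch, dilation = 1L, dropout = 0.1) {
  b <- new.env(parent = emptyenv())
  b$main <- list(conv2d_new(ch, ch, 3L, dilation = dilation), batchnorm_new(ch),
                 elu_new(), dropout_new(dropout),
                 conv2d_new(ch, ch, 3L, dilation = dilation), batchnorm_new(ch))
  b
}
res_block_fwd <- function(b, x, training = FALSE) x + seq_fwd(b$main, x, training)
res_block_bwd <- function(b, dy) dy + seq_bwd(b$main, dy)

recon_new <- function(n_classes, base = 8L, dilation = 1L, dropout = 0.1) {
  r <- new.env(parent = emptyenv())
  ch <- base * c(1L, 2L, 4L, 8L)
  in_ch <- n_classes + 3L
  ins <- c(in_ch, ch[1:3])
  # x16 contraction so that the four 2x upsamplings restore the input size
  r$down <- lapply(1:4, function(i)
    list(conv2d_new(ins[i], ch[i], 3L, stride = 2L), batchnorm_new(ch[i]), elu_new()))
  mods <- vector("list", 4L)
  mch <- rev(ch)                     # 8b -> 4b -> 2b -> b
  for (i in 1:4) {
    out_ch <- if (i < 4L) mch[i + 1L] else mch[4L]
    mods[[i]] <- list(res = res_block_new(mch[i], dilation, dropout),
                      up = upsample2_new(),
                      conv = conv2d_new(mch[i], out_ch, 3L),
                      bn = batchnorm_new(out_ch), act = elu_new())
  }
  r$mods <- mods
  r$out_conv <- conv2d_new(ch[1L], 3L, 3L)
  r$n_classes <- as.integer(n_classes)
  r$layers <- c(unlist(r$down, recursive = FALSE),
                unlist(lapply(mods, function(m)
                  c(m$res$main, list(m$up, m$conv, m$bn, m$act))),
                  recursive = FALSE),
                list(r$out_conv))
  r
}

recon_fwd <- function(r, x, training = FALSE) {
  h <- x
  for (dn in r$down) h <- seq_fwd(dn, h, training)
  for (m in r$mods) {
    h <- res_block_fwd(m$res, h, training)
    h <- upsample2_fwd(m$up, h, training)
    h <- conv2d_fwd(m$conv, h, training)
    h <- batchnorm_fwd(m$bn, h, training)
    h <- elu_fwd(m$act, h, training)
  }
  conv2d_fwd(r$out_conv, h, training)
}

recon_bwd <- function(r, dy) {
  dh <- conv2d_bwd(r$out_conv, dy)
  for (m in rev(r$mods)) {
    dh <- elu_bwd(m$act, dh)
    dh <- batchnorm_bwd(m$bn, dh)
    dh <- conv2d_bwd(m$conv, dh)
    dh <- upsample2_bwd(m$up, dh)
    dh <- res_block_bwd(m$res, dh)
  }
  for (dn in rev(r$down)) dh <- seq_bwd(dn, dh)
  dh
}

#' Create a two-stage diffusion deblurring model
#'
#' The predictive stage is a four-level U-Net producing a per-pixel softmax
#' probability map over `n_classes`; the reconstructive stage contracts the
#' channel-concatenated (probability map, degraded image) sixteen-fold through
#' strided convolutions and restores resolution through four modules of
#' (residual block, 2x nearest-neighbour upsampling, convolution). A
#' diffusion schedule (see [make_schedule()]) drives the noise-injection
#' augmentation during training.
#'
#' @param n_classes number of classes of the per-pixel probability map.
#' @param base_unet,base_recon channel widths of the two stages.
#' @param schedule a [make_schedule()] object.
#' @param dilation dilation of the residual-block convolutions.
#' @param dropout dropout rate inside the residual blocks.
#' @return a TSD model object.
#' @export
tsd_new <- function(n_classes, base_unet = 8L, base_recon = 8L,
                    schedule = make_schedule(100L), dilation = 1L,
                    dropout = 0.1) {
  m <- new.env(parent = emptyenv())
  m$unet <- unet_new(n_classes, base_unet)
  m$recon <- recon_new(n_classes, base_recon, dilation, dropout)
  m$schedule <- schedule
  m$n_classes <- as.integer(n_classes)
  m$layers <- c(m$unet$layers, m$recon$layers)
  class(m) <- "fishdeblur_tsd"
  m
}

#' Per-pixel class-probability map
#'
#' Runs the predictive U-Net stage. The output has the spatial dimensions of
#' the input and `n_classes` channels; each pixel's channel vector sums to 1.
#'
#' @param img an [image_grid()] with height and width divisible by 16.
#' @param net a TSD model (or its U-Net stage).
#' @return `H x W x K` array of class probabilities.
#' @export
predict_prob_map <- function(img, net) {
  u <- if (inherits(net, "fishdeblur_tsd")) net$unet else net
  img <- as_image_grid(img)
  unet_fwd(u, ig_to_float(img), training = FALSE)
}

#' Reconstruct a clean image from a probability map and the degraded input
#'
#' @param prob_map `H x W x K` probability map (see [predict_prob_map()]).
#' @param img the degraded [image_grid()], spatially matching `prob_map`.
#' @param recon a TSD model (or its reconstructive stage).
#' @return an [image_grid()] of the input's dimensions (values clamped to
#'   `[0, 255]`).
#' @export
reconstruct <- function(prob_map, img, recon) {
  r <- if (inherits(recon, "fishdeblur_tsd")) recon$recon else recon
  img <- as_image_grid(img)
  if (!all(dim(prob_map)[1:2] == dim(img)[1:2]))
    stop("probability map and image are not spatially compatible")
  out <- recon_fwd(r, cat3(prob_map, ig_to_float(img)), training = FALSE)
  float_to_ig(out)
}

#' Deblur an image
#'
#' Deterministic inference composition of the two stages:
#' `predict_prob_map()` then [reconstruct()].
#'
#' @param img an [image_grid()] (dims divisible by 16).
#' @param model a TSD model from [tsd_new()] / [train_tsd()].
#' @return an [image_grid()] of the same dimensions.
#' @export
deblur <- function(img, model) {
  stopifnot(inherits(model, "fishdeblur_tsd"))
  reconstruct(predict_prob_map(img, model), img, model)
}

#' Train the two-stage diffusion deblurrer
#'
#' Minimises the pixel-wise mean squared error between `deblur(degraded)` and
#' the clean counterpart with Adam. As augmentation, each presentation of a
#' pair injects closed-form diffusion noise (see [forward_diffuse()]) into
#' the degraded input at a timestep sampled uniformly from the lowest
#' `noise_frac` portion of the schedule, with probability `noise_prob`.
#' Batch normalisation and dropout are active in training mode only.
#'
#' @param pairs list of `list(degraded = , clean = )` [image_grid()] pairs.
#' @param schedule a [make_schedule()] object.
#' @param model an existing TSD model to continue training, or `NULL`.
#' @param n_classes probability-map classes when building a fresh model.
#' @param epochs,lr,batch_size optimisation settings.
#' @param noise_frac,noise_prob noise-injection augmentation controls.
#' @param base_unet,base_recon widths of a freshly built model.
#' @param seed optional integer; when set, the run (init, shuffling, noise,
#'   dropout) is reproducible.
#' @param verbose print per-epoch loss.
#' @return list with `model` and `history` (per-epoch mean training loss, one
#'   entry per epoch).
#' @export
train_tsd <- function(pairs, schedule = make_schedule(100L), model = NULL,
                      n_classes = 5L, epochs = 20L, lr = 2e-3, batch_size = 4L,
                      noise_frac = 0.1, noise_prob = 0.5,
                      base_unet = 8L, base_recon = 8L, seed = NULL,
                      verbose = FALSE) {
  if (length(pairs) < 1L) stop("need at least one training pair")
  with_seed_if(seed, {
    if (is.null(model))
      model <- tsd_new(n_classes, base_unet, base_recon, schedule)
    opt <- adam_new(model$layers, lr = lr)
    t_max <- max(1L, round(noise_frac * schedule$T))
    history <- numeric(epochs)
    for (ep in seq_len(epochs)) {
      ord <- sample(length(pairs))
      losses <- numeric(length(pairs))
      done <- 0L
      for (i in ord) {
        deg <- ig_to_float(pairs[[i]]$degraded)
        cln <- ig_to_float(pairs[[i]]$clean)
        if (stats::runif(1) < noise_prob) {
          t <- sample.int(t_max, 1L)
          deg <- forward_diffuse(deg, t, schedule)
        }
        pm <- unet_fwd(model$unet, deg, training = TRUE)
        out <- recon_fwd(model$recon, cat3(pm, deg), training = TRUE)
        err <- out - cln
        losses[i] <- mean(err^2)
        dcat <- recon_bwd(model$recon, 2 * err / length(err))
        dpm <- dcat[, , seq_len(model$n_classes), drop = FALSE]
        unet_bwd(model$unet, dpm)
        done <- done + 1L
        if (done %% batch_size == 0L || done == length(pairs)) adam_step(opt)
      }
      history[ep] <- mean(losses)
      if (verbose) message(sprintf("epoch %d: mse %.5f", ep, history[ep]))
    }
    list(model = model, history = history)
  })
}

#' Mean squared error between two images
#'
#' Computed on the `[0, 1]` intensity scale.
#'
#' @param a,b [image_grid()] objects of identical dimensions.
#' @return scalar MSE.
#' @export
image_mse <- function(a, b) {
  mean((ig_to_float(as_image_grid(a)) - ig_to_float(as_image_grid(b)))^2)
}
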