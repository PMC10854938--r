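# ResNet bottleneck classifier with LAM insertion between stages.

bottleneck_new <- function(in_ch, mid_ch, out_ch, stride = 1L, dropout = 0) {
  b <- new.env(parent = emptyenv())
  b$main <- list(conv2d_new(in_ch, mid_ch, 1L), batchnorm_new(mid_ch), relu_new(),
                 conv2d_new(mid_ch, mid_ch, 3L, stride = stride),
                 batchnorm_new(mid_ch), relu_new(),
                 conv2d_new(mid_ch, out_ch, 1L), batchnorm_new(out_ch))
  b$proj <- if (in_ch != out_ch || stride != 1L)
    list(conv2d_new(in_ch, out_ch, 1L, stride = stride), batchnorm_new(out_ch))
  b$r_out <- relu_new()
  b
}

bottleneck_fwd <- function(b, x, training = FALSE) {
  m <- seq_fwd(b$main, x, training)
  sk <- if (is.null(b$proj)) x else seq_fwd(b$proj, x, training)
  relu_fwd(b$r_out, m + sk, training)
}

bottleneck_bwd <- function(b, dy) {
  d <- relu_bwd(b$r_out, dy)
  dm <- seq_bwd(b$main, d)
  dsk <- if (is.null(b$proj)) d else seq_bwd(b$proj, d)
  dm + dsk
}

bottleneck_layers <- function(b) c(b$main, b$proj %||% list(), list(b$r_out))

#' Build a ResNet-style classifier with learnable channel attention
#'
#' Constructs the standard four-stage bottleneck ResNet layout (ResNet50 with
#' the defaults `blocks = c(3, 4, 6, 3)`, `base = 64`) with a LAM layer
#' inserted at each of the three junctions between adjacent stages, sized to
#' the incoming channel count (256, 512, 1024 at full width). The stem is a
#' 7x7 stride-2 convolution followed by 3x3 stride-2 max pooling; the head is
#' global average pooling into a softmax classifier over `n_classes`.
#'
#' Reduced-width instances for CPU-scale experiments come from shrinking
#' `base` and `blocks` (see [build_tiny_classifier()]); the layout is
#' unchanged.
#'
#' @param n_classes number of output classes, `>= 2`.
#' @param config a [lam_config()].
#' @param attention `"lam"` for attention layers, `"none"` for the plain
#'   backbone (ablation).
#' @param base stem channel width (64 for the full network).
#' @param blocks integer vector of length 4, bottlenecks per stage.
#' @param input_size expected square input side in pixels (must be divisible
#'   by 32).
#' @param post_stage_lam also insert a fourth LAM after the final stage.
#' @return a classifier model object.
#' @examples
#' m <- build_tiny_classifier(5, input_size = 32)
#' length(classify(image_grid(array(100, c(32, 32, 3))), m))
#' @export
build_modified_resnet50 <- function(n_classes, config = lam_config(),
                                    attention = c("lam", "none"),
                                    base = 64L, blocks = c(3L, 4L, 6L, 3L),
                                    input_size = 224L, post_stage_lam = FALSE) {
  attention <- match.arg(attention)
  if (n_classes < 2) stop("`n_classes` must be >= 2")
  if (length(blocks) != 4L) stop("`blocks` must have length 4")
  if (input_size %% 32L != 0L || input_size < 64L)
    stop("`input_size` must be a multiple of 32 and at least 64 ",
         "(the final stage needs more than one spatial position ",
         "for its normalisation statistics)")
  m <- new.env(parent = emptyenv())
  m$stem <- list(conv2d_new(3L, base, 7L, stride = 2L, pad = 3L),
                 batchnorm_new(base), relu_new(),
                 maxpool_new(3L, 2L, 1L))
  widths <- base * c(1L, 2L, 4L, 8L)
  m$stages <- vector("list", 4L)
  in_ch <- base
  for (s in 1:4) {
    mid <- widths[s]; out <- 4L * mid
    stride <- if (s == 1L) 1L else 2L
    blks <- vector("list", blocks[s])
    for (j in seq_len(blocks[s])) {
      blks[[j]] <- bottleneck_new(in_ch, mid, out,
                                  stride = if (j == 1L) stride else 1L)
      in_ch <- out
    }
    m$stages[[s]] <- blks
  }
  n_lam <- if (post_stage_lam) 4L else 3L
  m$lams <- lapply(seq_len(n_lam), function(s) {
    if (attention == "lam") lam_new(4L * widths[s], config) else identity_new()
  })
  m$head <- dense_new(4L * widths[4L], n_classes)
  m$n_classes <- as.integer(n_classes)
  m$input_size <- as.integer(input_size)
  m$attention <- attention
  m$post_stage_lam <- post_stage_lam
  m$layers <- flatten_layers(c(
    m$stem,
    unlist(lapply(m$stages, function(st) unlist(lapply(st, bottleneck_layers),
                                                recursive = FALSE)),
           recursive = FALSE),
    m$lams, list(m$head)))
  class(m) <- "fishdeblur_classifier"
  m
}

#' @rdname build_modified_resnet50
#' @export
build_tiny_classifier <- function(n_classes, config = lam_config(reduction = 2L),
                                  attention = "lam", input_size = 64L) {
  build_modified_resnet50(n_classes, config = config, attention = attention,
                          base = 8L, blocks = c(1L, 1L, 1L, 1L),
                          input_size = input_size)
}

# logits (pre-softmax); caches pooled feature size for backward
classifier_fwd <- function(m, x, training = FALSE) {
  h <- seq_fwd(m$stem, x, training)
  for (s in 1:4) {
    for (b in m$stages[[s]]) h <- bottleneck_fwd(b, h, training)
    if (s <= length(m$lams)) h <- nn_forward(m$lams[[s]], h, training)
  }
  m$pool_dim <- dim(h)
  z <- importance_vector(h, "average")
  dense_fwd(m$head, z, training)
}

classifier_bwd <- function(m, dlogits) {
  dz <- dense_bwd(m$head, dlogits)
  d <- m$pool_dim
  dh <- sweep(array(1, d), 3L, dz / (d[1L] * d[2L]), "*")
  for (s in 4:1) {
    if (s <= length(m$lams)) dh <- nn_backward(m$lams[[s]], dh)
    for (b in rev(m$stages[[s]])) dh <- bottleneck_bwd(b, dh)
  }
  seq_bwd(m$stem, dh)
}

#' Classify an image
#'
#' Runs the classifier on a standardized image and returns the softmax
#' class-probability vector (non-negative, summing to 1). Inference is
#' deterministic: batch-normalisation uses running statistics and dropout is
#' inactive.
#'
#' @param img an [image_grid()] whose side length equals the model's
#'   `input_size`.
#' @param model a classifier from [build_modified_resnet50()].
#' @return numeric probability vector of length `n_classes`.
#' @export
classify <- function(img, model) {
  img <- as_image_grid(img)
  if (ig_height(img) != model$input_size || ig_width(img) != model$input_size)
    stop("input must be ", model$input_size, " x ", model$input_size,
         "; run standardize() first")
  logits <- classifier_fwd(model, ig_to_float(img), training = FALSE)
  channel_weights(logits)   # softmax
}
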