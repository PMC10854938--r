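#' Training configuration
#'
#' Defaults follow the study's tuned hyperparameters: 224 x 224 inputs,
#' learning rate 0.002, ReLU activations, batch size 32, softmax classifier,
#' Adam, 100 epochs. Reduced `epochs`/`input_size` suit CPU-scale runs.
#'
#' @param input_size square input side in pixels.
#' @param lr Adam learning rate (`> 0`).
#' @param batch_size mini-batch size (`>= 1`).
#' @param epochs training epochs (`>= 1`).
#' @param seed optional integer for a reproducible run.
#' @return a `train_config` list (also records `activation = "ReLU"`,
#'   `classifier = "Softmax"`, `optimizer = "Adam"`).
#' @export
train_config <- function(input_size = 224L, lr = 0.002, batch_size = 32L,
                         epochs = 100L, seed = NULL) {
  if (lr <= 0) stop("`lr` must be > 0")
  if (batch_size < 1) stop("`batch_size` must be >= 1")
  if (epochs < 1) stop("`epochs` must be >= 1")
  structure(list(input_size = as.integer(input_size), lr = lr,
                 activation = "ReLU", batch_size = as.integer(batch_size),
                 classifier = "Softmax", optimizer = "Adam",
                 epochs = as.integer(epochs), seed = seed),
            class = "train_config")
}

load_split_images <- function(manifest, split) {
  rows <- manifest[manifest$split == split, , drop = FALSE]
  list(images = lapply(rows$path, read_image), labels = rows$label)
}

#' Train a softmax image classifier
#'
#' Cross-entropy training with Adam under the supplied [train_config()].
#' Images pass through the network one at a time; gradients accumulate over
#' each mini-batch before the optimiser steps. The history records per-epoch
#' training accuracy (over the predictions made during that epoch) and, when
#' a validation split exists, validation top-1 accuracy.
#'
#' @param manifest data frame with `path`, `label`, `split`; images of the
#'   `"train"` split are used (and `"val"` for validation accuracy).
#' @param model a classifier from [build_modified_resnet50()]; its class
#'   ordering is `sort(unique(manifest$label))`.
#' @param config a [train_config()].
#' @param validate logical; compute per-epoch validation top-1.
#' @param verbose print per-epoch progress.
#' @return list with `model`, `history` (data frame: `epoch`, `train_acc`,
#'   `val_top1`), `classes` and `best_epoch` (highest validation top-1, or
#'   highest training accuracy without validation).
#' @export
train_classifier <- function(manifest, model, config = train_config(),
                             validate = TRUE, verbose = FALSE) {
  classes <- sort(unique(manifest$label))
  if (length(classes) != model$n_classes)
    stop("label set size (", length(classes),
         ") does not match the model head (", model$n_classes, ")")
  tr <- load_split_images(manifest, "train")
  if (length(tr$images) == 0L) stop("empty train split")
  has_val <- validate && any(manifest$split == "val")
  va <- if (has_val) load_split_images(manifest, "val")
  y <- match(tr$labels, classes)
  with_seed_if(config$seed, {
    opt <- adam_new(model$layers, lr = config$lr)
    hist <- data.frame(epoch = seq_len(config$epochs), train_acc = NA_real_,
                       val_top1 = NA_real_)
    for (ep in seq_len(config$epochs)) {
      ord <- sample(length(tr$images))
      correct <- 0L; done <- 0L
      for (i in ord) {
        x <- ig_to_float(tr$images[[i]])
        logits <- classifier_fwd(model, x, training = TRUE)
        p <- channel_weights(logits)
        if (which.max(p) == y[i]) correct <- correct + 1L
        dlogits <- p
        dlogits[y[i]] <- dlogits[y[i]] - 1   # d(CE)/d(logits)
        classifier_bwd(model, dlogits)
        done <- done + 1L
        if (done %% config$batch_size == 0L || done == length(ord))
          adam_step(opt)
      }
      hist$train_acc[ep] <- correct / length(ord) * 100
      if (has_val) {
        sc <- t(vapply(va$images, function(im)
          classify(im, model), numeric(model$n_classes)))
        hist$val_top1[ep] <- topk_accuracy(sc, match(va$labels, classes), 1L)
      }
      if (verbose)
        message(sprintf("epoch %d: train %.1f%% val %.1f%%", ep,
                        hist$train_acc[ep], hist$val_top1[ep]))
    }
    best <- if (has_val) which.max(hist$val_top1) else which.max(hist$train_acc)
    list(model = model, history = hist, classes = classes, best_epoch = best)
  })
}

pipeline_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the end-to-end pipeline from a config file
#'
#' Orchestrates: synthetic data generation -> dataset construction (split +
#' augmentation) -> noise injection -> optional deblurrer training and
#' deblurring of the degraded evaluation images -> classifier training ->
#' evaluation. Writes manifests, a metrics CSV (columns `model_tag`,
#' `dataset_tag`, `training_acc`, `top1`, `top5`) and a run log recording the
#' seed and the config hash.
#'
#' @param config path to a YAML file or an equivalent named list. Recognised
#'   keys (all optional): `seed`; `out_dir`; `synthetic: {classes, per_class,
#'   size}`; `noise: {mode, frequency, amplitude, diameter_cm,
#'   intensity_lux}`; `deblur: {enabled, epochs}`; `classifier: {epochs,
#'   batch_size, lr, attention}`; `augment`.
#' @return list with `metrics` (data frame), `manifest`, and file paths.
#' @export
run_pipeline <- function(config) {
  cfg_text <- NULL
  if (is.character(config)) {
    cfg_text <- paste(readLines(config), collapse = "\n")
    config <- yaml::read_yaml(config)
  }
  g <- function(path, default) {
    v <- config
    for (p in path) {
      v <- v[[p]]
      if (is.null(v)) return(default)
    }
    v
  }
  seed <- g("seed", 1L)
  out_dir <- g("out_dir", tempfile("fishdeblur_run_"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  size <- g(c("synthetic", "size"), 64L)

  spec <- synthetic_spec(n_classes = g(c("synthetic", "classes"), 5L),
                         per_class = g(c("synthetic", "per_class"), 12L),
                         size = size, seed = seed)
  raw_dir <- file.path(out_dir, "raw")
  pipeline_stage("gen-synthetic", gen_toy_dataset(spec, raw_dir))

  manifest <- pipeline_stage("build-data", build_dataset(
    raw_dir, file.path(out_dir, "data"), size = size, seed = seed,
    augment = isTRUE(g("augment", FALSE))))

  noise_mode <- g(c("noise", "mode"), "ripple")
  np <- if (noise_mode == "ripple")
    ripple_params(g(c("noise", "frequency"), 0.06), g(c("noise", "amplitude"), 6))
  else
    reflection_params(g(c("noise", "diameter_cm"), 0.8),
                      g(c("noise", "intensity_lux"), 250),
                      px_per_cm = size / 4.5, seed = seed)
  noisy <- pipeline_stage("add-noise", build_noise_variants(
    manifest, ripple_grid = if (noise_mode == "ripple") list(np) else list(),
    reflection_grid = if (noise_mode == "ripple") list() else list(np),
    out_dir = file.path(out_dir, "noisy")))

  deblur_on <- isTRUE(g(c("deblur", "enabled"), FALSE))
  model_tag <- if (deblur_on) "tsd+lam" else "lam_only"
  eval_manifest <- noisy
  if (deblur_on) {
    pair_spec <- synthetic_spec(n_classes = spec$n_classes,
                                per_class = g(c("deblur", "pairs_per_class"), 4L),
                                size = size, seed = seed + 1L)
    pairs <- pipeline_stage("gen-pairs", gen_deblur_pairs(pair_spec, np))$pairs
    fit <- pipeline_stage("train-tsd", train_tsd(
      pairs, epochs = g(c("deblur", "epochs"), 10L),
      n_classes = spec$n_classes, seed = seed))
    deb_dir <- file.path(out_dir, "deblurred")
    for (i in seq_len(nrow(eval_manifest))) {
      out <- deblur(read_image(eval_manifest$path[i]), fit$model)
      newp <- file.path(deb_dir, eval_manifest$label[i],
                        basename(eval_manifest$path[i]))
      write_image(out, newp)
      eval_manifest$path[i] <- newp
    }
  }

  cls <- pipeline_stage("train-cls", {
    model <- with_seed_if(seed, build_tiny_classifier(
      spec$n_classes,
      attention = g(c("classifier", "attention"), "lam"),
      input_size = size))
    train_classifier(eval_manifest, model, train_config(
      input_size = size,
      lr = g(c("classifier", "lr"), 0.002),
      batch_size = g(c("classifier", "batch_size"), 32L),
      epochs = g(c("classifier", "epochs"), 5L),
      seed = seed))
  })
  rep <- pipeline_stage("evaluate",
                        evaluate(cls$model, eval_manifest, split = "test"))

  metrics <- data.frame(
    model_tag = model_tag,
    dataset_tag = variant_tag(np),
    training_acc = cls$history$train_acc[nrow(cls$history)],
    top1 = rep$top1, top5 = rep$top5)
  metrics_path <- file.path(out_dir, "metrics.csv")
  utils::write.csv(metrics, metrics_path, row.names = FALSE)
  write_manifest(eval_manifest, file.path(out_dir, "eval_manifest.csv"))
  cfg_hash <- if (!is.null(cfg_text)) {
    tf <- tempfile(); writeLines(cfg_text, tf)
    unname(tools::md5sum(tf))
  } else NA_character_
  writeLines(c(sprintf("seed: %d", seed),
               sprintf("config_md5: %s", cfg_hash),
               sprintf("model_tag: %s", model_tag)),
             file.path(out_dir, "run.log"))
  list(metrics = metrics, manifest = eval_manifest,
       metrics_path = metrics_path, out_dir = out_dir)
}
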