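# Dataset construction: standardisation, stratified 8:1:1 leave-out
# splitting with round-half-even shares, 13-fold augmentation, manifests.

#' Standardize an image
#'
#' Resizes to `size x size` RGB with bilinear interpolation (greyscale inputs
#' are replicated to three channels). Images already at the target size pass
#' through unchanged.
#'
#' @param img an [image_grid()] (or `H x W` matrix / `H x W x 3` array).
#' @param size target side in pixels (default 224).
#' @return a `size x size x 3` [image_grid()].
#' @export
standardize <- function(img, size = 224L) {
  img <- as_image_grid(img)
  if (ig_height(img) == size && ig_width(img) == size) return(img)
  e <- EBImage::Image(aperm(ig_to_float(img), c(2L, 1L, 3L)),
                      colormode = "Color")
  r <- EBImage::resize(e, w = size, h = size)     # bilinear
  image_grid(aperm(EBImage::imageData(r), c(2L, 1L, 3L)) * 255)
}

#' Per-class 8:1:1 leave-out shares
#'
#' The validation and test shares are the 10% share rounded half-to-even
#' (banker's rounding, R's `round()`); training takes the remainder, so the
#' three shares always sum to the class total.
#'
#' @param n class size (vectorised).
#' @return for scalar `n` a named vector `c(train, val, test)`; for vector
#'   `n` a data frame with one row per class.
#' @examples
#' split_counts(115)   # 91, 12, 12
#' split_counts(1365)  # 1093, 136, 136 (136.5 rounds half-even to 136)
#' @export
split_counts <- function(n) {
  v <- round(n / 10)
  out <- data.frame(train = n - 2 * v, val = v, test = v)
  if (length(n) == 1L) c(train = out$train, val = out$val, test = out$test)
  else out
}

#' Stratified leave-out split of a manifest
#'
#' Assigns each record a `split` in `{train, val, test}`, per class, with the
#' 8:1:1 round-half-even shares of [split_counts()]; assignment within a
#' class is seeded-random.
#'
#' @param manifest data frame with columns `path`, `label`.
#' @param seed integer seed.
#' @param min_class_size smallest admissible class.
#' @return the manifest with its `split` column filled in.
#' @export
split_manifest <- function(manifest, seed = 1L, min_class_size = 3L) {
  counts <- table(manifest$label)
  if (any(counts < min_class_size))
    stop("class too small to split: ",
         paste(names(counts)[counts < min_class_size], collapse = ", "))
  manifest$split <- NA_character_
  with_seed_if(seed, {
    for (lb in names(counts)) {
      ix <- which(manifest$label == lb)
      n <- length(ix)
      sc <- split_counts(n)
      lab <- c(rep("train", sc["train"]), rep("val", sc["val"]),
               rep("test", sc["test"]))
      manifest$split[ix] <- lab[sample.int(n)]
    }
  })
  manifest
}

#' Augmentation plan
#'
#' The default plan applies six operation families to each image: 2 pans,
#' 2 crops (with resize back), 3 rotations, 1 horizontal mirror, 1 vertical
#' flip and 3 brightness scalings — 12 variants, so each source image yields
#' 13 records (itself plus the variants).
#'
#' @param plan named integer vector over the operations
#'   `pan`, `crop`, `rotate`, `mirror`, `flip`, `brightness`.
#' @param seed optional seed making a single [augment()] call reproducible.
#' @return an `augmentation_spec` with `variants_per_image = sum(plan)`.
#' @export
augmentation_spec <- function(plan = c(pan = 2L, crop = 2L, rotate = 3L,
                                       mirror = 1L, flip = 1L, brightness = 3L),
                              seed = NULL) {
  ops <- c("pan", "crop", "rotate", "mirror", "flip", "brightness")
  if (!all(names(plan) %in% ops)) stop("unknown augmentation operation")
  if (any(plan < 0)) stop("operation counts must be >= 0")
  if (sum(plan) > 0 && length(plan) == 0) stop("empty operation list")
  structure(list(plan = plan, variants_per_image = sum(plan), seed = seed),
            class = "augmentation_spec")
}

aug_pan <- function(img, dx, dy) {
  a <- unclass(img); d <- dim(a)
  out <- array(0L, d)
  sr <- seq_len(d[1L]) - dy; sc <- seq_len(d[2L]) - dx
  ok_r <- sr >= 1 & sr <= d[1L]; ok_c <- sc >= 1 & sc <= d[2L]
  out[which(ok_r), which(ok_c), ] <- a[sr[ok_r], sc[ok_c], , drop = FALSE]
  image_grid(out)
}

aug_crop <- function(img, scale, fx, fy) {
  d <- dim(img)
  ch <- max(1L, round(d[1L] * scale)); cw <- max(1L, round(d[2L] * scale))
  r0 <- 1L + round(fy * (d[1L] - ch)); c0 <- 1L + round(fx * (d[2L] - cw))
  standardize(image_grid(unclass(img)[r0:(r0 + ch - 1L),
                                      c0:(c0 + cw - 1L), , drop = FALSE]),
              size = d[1L])
}

aug_rotate <- function(img, angle) {
  e <- EBImage::Image(aperm(ig_to_float(img), c(2L, 1L, 3L)), colormode = "Color")
  r <- EBImage::rotate(e, angle, output.dim = dim(e)[1:2], bg.col = "black")
  image_grid(aperm(EBImage::imageData(r), c(2L, 1L, 3L)) * 255)
}

aug_mirror <- function(img) image_grid(unclass(img)[, rev(seq_len(dim(img)[2L])), , drop = FALSE])
aug_flip <- function(img) image_grid(unclass(img)[rev(seq_len(dim(img)[1L])), , , drop = FALSE])
aug_brightness <- function(img, factor) image_grid(unclass(img) * factor)

#' Augment one image
#'
#' Produces exactly `spec$variants_per_image` images, each from one seeded
#' parameter draw of its operation family; all outputs keep the input's
#' dimensions.
#'
#' @param img a standardized [image_grid()].
#' @param spec an [augmentation_spec()].
#' @return list of [image_grid()] variants (possibly empty).
#' @export
augment <- function(img, spec = augmentation_spec()) {
  img <- as_image_grid(img)
  if (spec$variants_per_image == 0L) return(list())
  d <- dim(img)
  with_seed_if(spec$seed, {
    out <- list()
    for (op in names(spec$plan)) {
      for (i in seq_len(spec$plan[[op]])) {
        out[[length(out) + 1L]] <- switch(
          op,
          pan = aug_pan(img, sample(seq(-(d[2L] %/% 8L), d[2L] %/% 8L), 1L),
                        sample(seq(-(d[1L] %/% 8L), d[1L] %/% 8L), 1L)),
          crop = aug_crop(img, stats::runif(1, 0.7, 0.92),
                          stats::runif(1), stats::runif(1)),
          rotate = aug_rotate(img, stats::runif(1, -25, 25)),
          mirror = aug_mirror(img),
          flip = aug_flip(img),
          brightness = aug_brightness(img, stats::runif(1, 0.65, 1.35)))
      }
    }
    out
  })
}

#' Read/write a dataset manifest CSV
#'
#' Columns: `path`, `label`, `split`, `variant_tag`.
#'
#' @param manifest data frame.
#' @param path CSV path.
#' @export
write_manifest <- function(manifest, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Build a labelled dataset from a class-subfolder image tree
#'
#' Runs the full construction protocol: cleaning (unreadable files and exact
#' content duplicates dropped), standardisation to `size x size` RGB,
#' stratified 8:1:1 leave-out splitting, per-split augmentation (so augmented
#' variants never cross split boundaries), and PASCAL VOC annotation. Writes
#' standardized images, XMLs and `manifest.csv` under `out_dir`.
#'
#' @param raw_dir directory laid out as `<raw_dir>/<class>/<image>`.
#' @param out_dir output directory.
#' @param size standardized image side (default 224).
#' @param seed integer seed for splitting and augmentation draws.
#' @param augment logical; apply the augmentation plan.
#' @param aug_spec an [augmentation_spec()].
#' @param augment_splits which splits to expand (default all three).
#' @return the manifest data frame.
#' @export
build_dataset <- function(raw_dir, out_dir, size = 224L, seed = 1L,
                          augment = TRUE, aug_spec = augmentation_spec(),
                          augment_splits = c("train", "val", "test")) {
  classes <- list.dirs(raw_dir, recursive = FALSE)
  if (length(classes) == 0L) stop("no class subfolders under ", raw_dir)
  recs <- list()
  for (cd in classes) {
    lb <- basename(cd)
    files <- list.files(cd, pattern = "\\.(png|jpg|jpeg)$", ignore.case = TRUE,
                        full.names = TRUE)
    if (length(files) == 0L) {
      warning("empty class skipped: ", lb)
      next
    }
    hashes <- tools::md5sum(files)
    files <- files[!duplicated(hashes)]
    for (f in files) {
      img <- tryCatch(read_image(f), error = function(e) NULL)
      if (is.null(img)) next
      recs[[length(recs) + 1L]] <-
        list(label = lb, img = standardize(img, size),
             stem = tools::file_path_sans_ext(basename(f)))
    }
  }
  if (length(recs) == 0L) stop("no readable images under ", raw_dir)
  manifest <- data.frame(
    path = vapply(recs, function(r) file.path(out_dir, r$label,
                                              paste0(r$stem, ".png")), ""),
    label = vapply(recs, function(r) r$label, ""),
    stringsAsFactors = FALSE)
  manifest <- split_manifest(manifest, seed = seed)
  manifest$variant_tag <- "clean"
  out <- list()
  with_seed_if(seed + 1L, {
    for (i in seq_along(recs)) {
      r <- recs[[i]]
      write_image(r$img, manifest$path[i])
      write_voc_xml(voc_annotation(basename(manifest$path[i]), r$label,
                                   size, size, folder = r$label),
                    sub("\\.png$", ".xml", manifest$path[i]))
      out[[length(out) + 1L]] <- manifest[i, ]
      if (augment && manifest$split[i] %in% augment_splits) {
        vars <- augment(r$img, aug_spec)
        for (j in seq_along(vars)) {
          vp <- file.path(out_dir, r$label,
                          sprintf("%s_aug%02d.png", r$stem, j))
          write_image(vars[[j]], vp)
          write_voc_xml(voc_annotation(basename(vp), r$label, size, size,
                                       folder = r$label),
                        sub("\\.png$", ".xml", vp))
          out[[length(out) + 1L]] <-
            data.frame(path = vp, label = r$label, split = manifest$split[i],
                       variant_tag = sprintf("aug%02d", j),
                       stringsAsFactors = FALSE)
        }
      }
    }
  })
  manifest <- do.call(rbind, out)
  rownames(manifest) <- NULL
  write_manifest(manifest, file.path(out_dir, "manifest.csv"))
  manifest
}
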