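#' Synthetic toy-fish dataset specification
#'
#' Defines a deterministic generator of labelled fish-like images: each class
#' is a distinct tuple of (body aspect ratio, stripe frequency, fin count,
#' base hue), rendered as a parametric ellipse body with triangular tail and
#' fins over a textured water background. The generator stands in for field
#' image collection so that every pipeline stage is testable offline.
#'
#' @param n_classes number of classes `K >= 2`.
#' @param per_class images per class.
#' @param size square image side in pixels (use multiples of 16 for the
#'   deblurrer). The CPU-scale default profile is 5 classes, 40 per class,
#'   64 px.
#' @param seed integer seed; the dataset is bit-identical under a fixed seed.
#' @param clutter background clutter level in `[0, 1]`.
#' @return a `synthetic_spec` list, including the per-class parameter table.
#' @export
synthetic_spec <- function(n_classes = 5L, per_class = 40L, size = 64L,
                           seed = 1L, clutter = 0.3) {
  if (n_classes < 2) stop("`n_classes` must be >= 2")
  if (per_class < 1) stop("`per_class` must be >= 1")
  k <- as.integer(n_classes)
  classes <- data.frame(
    label = sprintf("species_%02d", seq_len(k)),
    aspect = seq(0.3, 0.62, length.out = k),          # body ry / rx
    stripe_freq = seq(0, 7, length.out = k),          # cycles along the body
    fin_count = 1L + (seq_len(k) - 1L) %% 3L,
    hue = (seq_len(k) - 1L) / k,
    stringsAsFactors = FALSE)
  structure(list(n_classes = k, per_class = as.integer(per_class),
                 size = as.integer(size), seed = as.integer(seed),
                 clutter = clutter, classes = classes),
            class = "synthetic_spec")
}

# renders one fish; consumes the current RNG stream for pose/background draws
render_toy_fish <- function(cls, size, clutter) {
  s <- size
  base_rgb <- grDevices::col2rgb(grDevices::hsv(cls$hue, 0.75, 0.95)) / 255
  # water background: bluish gradient + low-frequency clutter + grain
  gx <- matrix(rep(seq(0, 1, length.out = s), each = s), s, s)
  gy <- matrix(rep(seq(0, 1, length.out = s), times = s), s, s)
  ph <- stats::runif(4, 0, 2 * pi)
  tex <- sin(2 * pi * (1.5 * gx + ph[1])) * cos(2 * pi * (2.5 * gy + ph[2])) +
    0.6 * sin(2 * pi * (4 * gx + 3 * gy + ph[3]) + ph[4])
  bg_col <- c(0.13, 0.32, 0.45)
  img <- array(0, c(s, s, 3))
  grain <- matrix(stats::rnorm(s * s, 0, 0.02), s, s)
  for (c in 1:3)
    img[, , c] <- bg_col[c] * (0.8 + 0.4 * gy) + clutter * 0.12 * tex + grain
  # pose
  cx <- stats::runif(1, -0.12, 0.12); cy <- stats::runif(1, -0.12, 0.12)
  ang <- stats::runif(1, -pi / 9, pi / 9)
  scale <- stats::runif(1, 0.8, 1.05)
  xg <- matrix(rep(seq(-1, 1, length.out = s), each = s), s, s) - cx
  yg <- matrix(rep(seq(-1, 1, length.out = s), times = s), s, s) - cy
  xr <- (cos(ang) * xg + sin(ang) * yg) / scale
  yr <- (-sin(ang) * xg + cos(ang) * yg) / scale
  rx <- 0.52; ry <- rx * cls$aspect
  body <- (xr / rx)^2 + (yr / ry)^2 <= 1
  # stripes across the body
  stripe <- 0.5 + 0.5 * sin(pi * cls$stripe_freq * xr / rx)
  shade <- ifelse(stripe > 0.5, 1, 0.45)
  # tail: triangle trailing the body
  tail <- xr > rx * 0.85 & xr < rx * 1.45 &
    abs(yr) < (xr - rx * 0.85) * 0.8
  # dorsal fins: small triangles on top of the body
  fins <- array(FALSE, dim(body))
  fx <- seq(-0.5, 0.5, length.out = cls$fin_count + 2L)[-c(1L, cls$fin_count + 2L)]
  for (f in fx) {
    fins <- fins | (abs(xr - f * rx) < 0.08 & yr < -ry * 0.75 &
                      yr > -ry * 0.75 - (0.1 - abs(xr - f * rx)))
  }
  eye <- (xr + rx * 0.62)^2 + yr^2 <= 0.003
  for (c in 1:3) {
    ch <- img[, , c]
    ch[body] <- base_rgb[c] * shade[body]
    ch[tail | fins] <- base_rgb[c] * 0.6
    ch[eye] <- 0.05
    img[, , c] <- ch
  }
  fish <- body | tail | fins
  cols <- which(apply(fish, 2, any)); rows <- which(apply(fish, 1, any))
  image_grid(img * 255) -> g
  attr(g, "bbox") <- c(xmin = min(cols), ymin = min(rows),
                       xmax = max(cols), ymax = max(rows))
  g
}

#' Generate a labelled toy-fish image collection
#'
#' Renders `K * n` images into `<out_dir>/<class>/<image>.png`, each with a
#' PASCAL VOC XML annotation alongside, and returns the manifest. Output is
#' bit-identical for a fixed `spec$seed`.
#'
#' @param spec a [synthetic_spec()].
#' @param out_dir output directory.
#' @return manifest data frame with columns `path`, `label`, `split`
#'   (all `"unsplit"`), `variant_tag` (`"clean"`).
#' @export
gen_toy_dataset <- function(spec, out_dir) {
  stopifnot(inherits(spec, "synthetic_spec"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  recs <- vector("list", spec$n_classes * spec$per_class)
  with_seed_if(spec$seed, {
    k <- 0L
    for (i in seq_len(spec$n_classes)) {
      cls <- spec$classes[i, ]
      for (j in seq_len(spec$per_class)) {
        g <- render_toy_fish(cls, spec$size, spec$clutter)
        stem <- sprintf("%s_%03d", cls$label, j)
        path <- file.path(out_dir, cls$label, paste0(stem, ".png"))
        write_image(g, path)
        bb <- attr(g, "bbox")
        ann <- voc_annotation(filename = basename(path), label = cls$label,
                              width = spec$size, height = spec$size,
                              bndbox = bb, folder = cls$label)
        write_voc_xml(ann, file.path(out_dir, cls$label, paste0(stem, ".xml")))
        k <- k + 1L
        recs[[k]] <- data.frame(path = path, label = cls$label,
                                split = "unsplit", variant_tag = "clean",
                                stringsAsFactors = FALSE)
      }
    }
  })
  do.call(rbind, recs)
}

#' Generate matched clean/degraded image pairs for deblurrer training
#'
#' Renders clean toy-fish images and degrades each with the supplied noise
#' configuration(s), writing `clean/` and `degraded/` subdirectories plus a
#' pairing manifest.
#'
#' @param spec a [synthetic_spec()].
#' @param noise_params a [ripple_params()]/[reflection_params()] or a list of
#'   them (each clean image is degraded by every configuration).
#' @param out_dir output directory, or `NULL` to keep the pairs in memory.
#' @return list with `pairs` (list of `list(degraded, clean, label, tag)`
#'   image pairs) and `manifest` (data frame; paths empty when
#'   `out_dir = NULL`).
#' @export
gen_deblur_pairs <- function(spec, noise_params, out_dir = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (inherits(noise_params, "ripple_params") ||
      inherits(noise_params, "reflection_params"))
    noise_params <- list(noise_params)
  pairs <- list()
  recs <- list()
  with_seed_if(spec$seed, {
    for (i in seq_len(spec$n_classes)) {
      cls <- spec$classes[i, ]
      for (j in seq_len(spec$per_class)) {
        g <- render_toy_fish(cls, spec$size, spec$clutter)
        attr(g, "bbox") <- NULL
        for (np in noise_params) {
          deg <- if (inherits(np, "ripple_params")) apply_water_ripple(g, np)
          else apply_light_reflection(g, np)
          tag <- variant_tag(np)
          cp <- dp <- ""
          if (!is.null(out_dir)) {
            stem <- sprintf("%s_%03d", cls$label, j)
            cp <- file.path(out_dir, "clean", paste0(stem, ".png"))
            dp <- file.path(out_dir, "degraded", tag, paste0(stem, ".png"))
            write_image(g, cp)
            write_image(deg, dp)
          }
          pairs[[length(pairs) + 1L]] <-
            list(degraded = deg, clean = g, label = cls$label, tag = tag)
          recs[[length(recs) + 1L]] <-
            data.frame(clean = cp, degraded = dp, label = cls$label,
                       variant_tag = tag, stringsAsFactors = FALSE)
        }
      }
    }
  })
  manifest <- do.call(rbind, recs)
  if (!is.null(out_dir))
    utils::write.csv(manifest, file.path(out_dir, "pairs.csv"),
                     row.names = FALSE)
  list(pairs = pairs, manifest = manifest)
}
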