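#' Water-ripple parameters
#'
#' Parameters of the sinusoidal water-ripple warp. The per-pixel displacement
#' is `offset_x = A * sin(2 * pi * y * F)` and `offset_y = A * cos(2 * pi * x * F)`
#' with `F` the ripple frequency (cycles per pixel index) and `A` the
#' amplitude in pixels.
#'
#' @param frequency ripple frequency `F`, cycles per pixel index; `>= 0`.
#' @param amplitude ripple amplitude `A` in pixels; `>= 0`.
#' @param blend_mode `"replace"` overlays the warped field alone;
#'   `"mean"` averages warped and original.
#' @param seed reserved (the warp itself is deterministic).
#' @return a `ripple_params` list.
#' @export
ripple_params <- function(frequency, amplitude, blend_mode = c("replace", "mean"),
                          seed = NULL) {
  blend_mode <- match.arg(blend_mode)
  if (!is.finite(frequency) || frequency < 0) stop("`frequency` must be >= 0")
  if (!is.finite(amplitude) || amplitude < 0) stop("`amplitude` must be >= 0")
  structure(list(frequency = frequency, amplitude = amplitude,
                 blend_mode = blend_mode, seed = seed),
            class = "ripple_params")
}

#' Light-reflection parameters
#'
#' Specular light-spot degradation: `n_spots` bright discs of physical
#' diameter `diameter_cm` (converted to pixels through `px_per_cm`) are placed
#' at seeded-random centres; inside each disc the intensity is raised
#' additively by `intensity_lux * lux_to_delta` grey levels with a Gaussian
#' radial falloff (`sigma = radius / 2`).
#'
#' @param diameter_cm spot diameter in centimetres; `> 0`.
#' @param intensity_lux light intensity in Lux; `>= 0`.
#' @param px_per_cm pixel pitch, pixels per centimetre; `> 0`.
#' @param n_spots number of spots; `>= 1`.
#' @param lux_to_delta additive grey levels per Lux at the spot centre.
#' @param seed integer seed controlling spot placement.
#' @return a `reflection_params` list.
#' @export
reflection_params <- function(diameter_cm, intensity_lux, px_per_cm = 50,
                              n_spots = 1L, lux_to_delta = 0.3, seed = NULL) {
  if (!is.finite(diameter_cm) || diameter_cm <= 0) stop("`diameter_cm` must be > 0")
  if (!is.finite(intensity_lux) || intensity_lux < 0) stop("`intensity_lux` must be >= 0")
  if (!is.finite(px_per_cm) || px_per_cm <= 0) stop("`px_per_cm` must be > 0")
  if (n_spots < 1) stop("`n_spots` must be >= 1")
  structure(list(diameter_cm = diameter_cm, intensity_lux = intensity_lux,
                 px_per_cm = px_per_cm, n_spots = as.integer(n_spots),
                 lux_to_delta = lux_to_delta, seed = seed),
            class = "reflection_params")
}

#' Ripple displacement at a pixel
#'
#' @param x,y 0-based pixel coordinates (x = column, y = row); vectorised.
#' @param params a [ripple_params()].
#' @return list with `offset_x = A * sin(2*pi*y*F)` and
#'   `offset_y = A * cos(2*pi*x*F)`, both bounded by `A` in absolute value.
#' @examples
#' ripple_offsets(0, 0, ripple_params(0.04, 2))
#' @export
ripple_offsets <- function(x, y, params) {
  stopifnot(inherits(params, "ripple_params"))
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("coordinates must be finite")
  list(offset_x = params$amplitude * sin(2 * pi * y * params$frequency),
       offset_y = params$amplitude * cos(2 * pi * x * params$frequency))
}

#' Apply the water-ripple warp to an image
#'
#' Each destination pixel `(x, y)` takes the value of the source pixel at
#' `((x + round(offset_x)) %% width, (y + round(offset_y)) %% height)`; the
#' warped field is then composited with the original according to
#' `blend_mode`.
#'
#' @param img an [image_grid()].
#' @param params a [ripple_params()].
#' @return an [image_grid()] of identical dimensions.
#' @export
apply_water_ripple <- function(img, params) {
  img <- as_image_grid(img)
  stopifnot(inherits(params, "ripple_params"))
  h <- ig_height(img); w <- ig_width(img)
  xs <- 0:(w - 1L); ys <- 0:(h - 1L)
  # offset_x depends only on y; offset_y only on x
  off_x <- round(params$amplitude * sin(2 * pi * ys * params$frequency))
  off_y <- round(params$amplitude * cos(2 * pi * xs * params$frequency))
  src_x <- outer(ys * 0L, (xs), "+")            # h x w matrix of x coords
  src_x <- sweep(src_x, 1L, off_x, "+") %% w    # (x + off_x(y)) mod w
  src_y <- outer(ys, xs * 0L, "+")
  src_y <- sweep(src_y, 2L, off_y, "+") %% h    # (y + off_y(x)) mod h
  lin <- as.vector(src_y + 1L + src_x * h)      # column-major within a channel
  a <- unclass(img)
  warped <- array(0L, dim(a))
  for (c in 1:3) {
    ch <- a[, , c]
    warped[, , c] <- array(ch[lin], c(h, w))
  }
  out <- switch(params$blend_mode,
                replace = warped,
                mean    = (a + warped) / 2)
  image_grid(out)
}

#' Add light-reflection spots to an image
#'
#' @param img an [image_grid()].
#' @param params a [reflection_params()].
#' @return an [image_grid()] with the spots composited in (clamped at 255).
#' @export
apply_light_reflection <- function(img, params) {
  img <- as_image_grid(img)
  stopifnot(inherits(params, "reflection_params"))
  h <- ig_height(img); w <- ig_width(img)
  radius <- params$diameter_cm * params$px_per_cm / 2
  if (radius > min(h, w)) stop("spot radius exceeds image size")
  centres <- with_seed_if(params$seed, {
    cbind(x = stats::runif(params$n_spots, 0, w - 1),
          y = stats::runif(params$n_spots, 0, h - 1))
  })
  delta <- matrix(0, h, w)
  if (params$intensity_lux > 0) {
    sigma <- radius / 2
    xs <- 0:(w - 1L); ys <- 0:(h - 1L)
    for (i in seq_len(nrow(centres))) {
      dx2 <- (xs - centres[i, "x"])^2
      dy2 <- (ys - centres[i, "y"])^2
      r2 <- outer(dy2, dx2, "+")
      spot <- params$intensity_lux * params$lux_to_delta * exp(-r2 / (2 * sigma^2))
      spot[r2 > radius^2] <- 0
      delta <- delta + spot
    }
  }
  a <- unclass(img) + array(rep(delta, 3L), c(h, w, 3L))
  image_grid(a)
}

#' Variant tag for a noise configuration
#'
#' Reflection configurations are tagged `D_<diameter>_E_<intensity>`, ripple
#' configurations `F_<frequency>_A_<amplitude>`, matching the naming used for
#' the degraded dataset grids.
#'
#' @param params a [ripple_params()] or [reflection_params()].
#' @return character tag.
#' @export
variant_tag <- function(params) {
  if (inherits(params, "ripple_params"))
    sprintf("F_%g_A_%g", params$frequency, params$amplitude)
  else if (inherits(params, "reflection_params"))
    sprintf("D_%g_E_%g", params$diameter_cm, params$intensity_lux)
  else stop("unknown noise parameter object")
}

#' Expand a manifest over a grid of noise configurations
#'
#' Replicates every record of `manifest` once per noise configuration and tags
#' the copies with the configuration's [variant_tag()]. With `out_dir` set
#' (and source images on disk) the degraded images are rendered under
#' `<out_dir>/<variant_tag>/<label>/<image>`; with `out_dir = NULL` only the
#' expanded manifest is produced (count reconciliation).
#'
#' @param manifest data frame with columns `path`, `label` (and optionally
#'   `split`, `variant_tag`).
#' @param ripple_grid list of [ripple_params()].
#' @param reflection_grid list of [reflection_params()].
#' @param out_dir output directory, or `NULL` for manifest-only expansion.
#' @return the expanded manifest: `nrow(manifest) * (length(ripple_grid) +
#'   length(reflection_grid))` records.
#' @examples
#' m <- data.frame(path = c("a.png", "b.png"), label = "fish", split = "train")
#' g <- ripple_noise_grid()
#' nrow(build_noise_variants(m, ripple_grid = g))  # 2 * 3
#' @export
build_noise_variants <- function(manifest, ripple_grid = list(),
                                 reflection_grid = list(), out_dir = NULL) {
  if (nrow(manifest) == 0L) stop("`manifest` must be non-empty")
  if (!"split" %in% names(manifest)) manifest$split <- "train"
  grids <- c(reflection_grid, ripple_grid)
  tags <- vapply(grids, variant_tag, character(1))
  if (anyDuplicated(tags)) stop("variant tag collision: ", tags[duplicated(tags)][1])
  out <- vector("list", length(grids))
  for (i in seq_along(grids)) {
    m <- manifest
    m$variant_tag <- tags[i]
    if (!is.null(out_dir)) {
      new_paths <- file.path(out_dir, tags[i], m$label, basename(m$path))
      for (j in seq_len(nrow(m))) {
        img <- read_image(m$path[j])
        deg <- if (inherits(grids[[i]], "ripple_params"))
          apply_water_ripple(img, grids[[i]])
        else apply_light_reflection(img, grids[[i]])
        write_image(deg, new_paths[j])
      }
      m$path <- new_paths
    }
    out[[i]] <- m
  }
  do.call(rbind, out)
}

#' The standard degradation grids
#'
#' `reflection_noise_grid()` returns the nine light-reflection configurations
#' (diameters 0.6/0.8/1.0 cm crossed with intensities 100/250/400 Lux);
#' `ripple_noise_grid()` the three water-ripple configurations
#' (F, A) in {(0.04, 2), (0.06, 6), (0.08, 10)}.
#'
#' @param px_per_cm,lux_to_delta,n_spots,seed passed to [reflection_params()].
#' @return a list of parameter objects.
#' @export
reflection_noise_grid <- function(px_per_cm = 50, lux_to_delta = 0.3,
                                  n_spots = 1L, seed = 1L) {
  grid <- expand.grid(D = c(0.6, 0.8, 1.0), E = c(100, 250, 400))
  grid <- grid[order(grid$D, grid$E), ]
  lapply(seq_len(nrow(grid)), function(i)
    reflection_params(grid$D[i], grid$E[i], px_per_cm = px_per_cm,
                      n_spots = n_spots, lux_to_delta = lux_to_delta,
                      seed = seed + i))
}

#' @rdname reflection_noise_grid
#' @param blend_mode passed to [ripple_params()].
#' @export
ripple_noise_grid <- function(blend_mode = "replace") {
  list(ripple_params(0.04, 2,  blend_mode = blend_mode),
       ripple_params(0.06, 6,  blend_mode = blend_mode),
       ripple_params(0.08, 10, blend_mode = blend_mode))
}
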