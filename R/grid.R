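#' Image grid container
#'
#' The universal image carrier of the package: an `H x W x 3` integer array of
#' 8-bit pixel intensities in `[0, 255]`, row index = y (top to bottom),
#' column index = x (left to right). Pixel coordinates used by the noise
#' operators are 0-based, `(x = column, y = row)`.
#'
#' @param pixels numeric array, `H x W x 3` (a greyscale `H x W` matrix is
#'   replicated to three channels). Values are rounded and clamped to
#'   `[0, 255]`.
#' @return an object of class `image_grid`: the integer array with the same
#'   dimensions.
#' @examples
#' g <- image_grid(array(128, c(4, 4, 3)))
#' ig_width(g); ig_height(g)
#' @export
image_grid <- function(pixels) {
  if (is.matrix(pixels)) pixels <- array(rep(pixels, 3L), c(dim(pixels), 3L))
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3L] != 3L)
    stop("`pixels` must be an H x W x 3 array (or an H x W matrix)")
  d <- dim(pixels)
  if (d[1L] < 1L || d[2L] < 1L) stop("image must have height >= 1 and width >= 1")
  px <- round(pixels)
  px[px < 0] <- 0
  px[px > 255] <- 255
  storage.mode(px) <- "integer"
  structure(px, class = "image_grid")
}

#' @rdname image_grid
#' @param x object to coerce / query.
#' @export
as_image_grid <- function(x) {
  if (inherits(x, "image_grid")) x else image_grid(x)
}

#' @rdname image_grid
#' @export
ig_width <- function(x) dim(x)[2L]

#' @rdname image_grid
#' @export
ig_height <- function(x) dim(x)[1L]

#' @export
print.image_grid <- function(x, ...) {
  cat(sprintf("<image_grid %d x %d, mean intensity %.1f>\n",
              ig_height(x), ig_width(x), mean(x)))
  invisible(x)
}

# float [0,1] array <-> grid; the network side works in [0,1]
ig_to_float <- function(g) {
  a <- unclass(g) / 255
  storage.mode(a) <- "double"
  a
}

float_to_ig <- function(a) image_grid(a * 255)

#' Read and write images
#'
#' PNG files are handled with the `png` package; JPEG (and any other format
#' EBImage understands) through [EBImage::readImage()]. Writing always emits
#' PNG.
#'
#' @param path file path.
#' @return `read_image()` returns an [image_grid()].
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("no such image: ", path)
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    a <- png::readPNG(path)
    if (length(dim(a)) == 2L) a <- array(rep(a, 3L), c(dim(a), 3L))
    if (dim(a)[3L] >= 4L) a <- a[, , 1:3, drop = FALSE]  # drop alpha
    return(image_grid(a[, , 1:3, drop = FALSE] * 255))
  }
  e <- EBImage::imageData(EBImage::readImage(path))  # x, y[, c] order
  if (length(dim(e)) == 2L) e <- array(rep(e, 3L), c(dim(e), 3L))
  if (dim(e)[3L] >= 4L) e <- e[, , 1:3, drop = FALSE]
  image_grid(aperm(e, c(2L, 1L, 3L)) * 255)
}

#' @rdname read_image
#' @param img an [image_grid()] (or coercible array).
#' @export
write_image <- function(img, path) {
  img <- as_image_grid(img)
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  png::writePNG(unclass(img) / 255, target = path)
  invisible(path)
}

# run `expr` under a fixed RNG seed without touching the caller's RNG state
with_seed_if <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}
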