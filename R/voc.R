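#' PASCAL VOC annotation
#'
#' In-memory representation of a single-object PASCAL VOC XML annotation:
#' image filename, folder, pixel size, species label and an optional bounding
#' box. Unknown top-level nodes encountered by [read_voc_xml()] are preserved
#' opaquely (as XML text in `extras`) and written back verbatim.
#'
#' @param filename image file name.
#' @param label species label (non-empty).
#' @param width,height image dimensions in pixels (positive).
#' @param depth channel count.
#' @param bndbox optional numeric `c(xmin, ymin, xmax, ymax)`.
#' @param folder folder name.
#' @param extras character vector of verbatim XML fragments.
#' @return a `voc_annotation` list.
#' @export
voc_annotation <- function(filename, label, width, height, depth = 3L,
                           bndbox = NULL, folder = "", extras = character()) {
  if (!nzchar(label)) stop("`label` must be non-empty")
  if (width <= 0 || height <= 0) stop("image dimensions must be positive")
  if (!is.null(bndbox)) {
    bndbox <- as.integer(round(bndbox))
    names(bndbox) <- c("xmin", "ymin", "xmax", "ymax")
  }
  structure(list(filename = filename, label = label,
                 width = as.integer(width), height = as.integer(height),
                 depth = as.integer(depth), bndbox = bndbox,
                 folder = folder, extras = extras),
            class = "voc_annotation")
}

#' Read and write PASCAL VOC XML files
#'
#' `write_voc_xml()` followed by `read_voc_xml()` is the identity on all
#' annotation fields.
#'
#' @param path XML file path.
#' @return `read_voc_xml()` returns a [voc_annotation()].
#' @export
read_voc_xml <- function(path) {
  doc <- xml2::read_xml(path)
  if (xml2::xml_name(doc) != "annotation") stop("not a VOC annotation: ", path)
  get1 <- function(xp) {
    n <- xml2::xml_find_first(doc, xp)
    if (inherits(n, "xml_missing")) NA_character_ else xml2::xml_text(n)
  }
  filename <- get1("./filename")
  if (is.na(filename)) stop("missing <filename> in ", path)
  w <- get1("./size/width"); h <- get1("./size/height")
  if (is.na(w) || is.na(h)) stop("missing <size> in ", path)
  d <- get1("./size/depth")
  label <- get1("./object/name")
  if (is.na(label)) stop("missing <object><name> in ", path)
  bb <- NULL
  bbn <- xml2::xml_find_first(doc, "./object/bndbox")
  if (!inherits(bbn, "xml_missing")) {
    bb <- as.numeric(c(get1("./object/bndbox/xmin"), get1("./object/bndbox/ymin"),
                       get1("./object/bndbox/xmax"), get1("./object/bndbox/ymax")))
  }
  known <- c("folder", "filename", "size", "object")
  kids <- xml2::xml_children(doc)
  extras <- vapply(kids[!xml2::xml_name(kids) %in% known], as.character,
                   character(1))
  voc_annotation(filename = filename, label = label,
                 width = as.integer(w), height = as.integer(h),
                 depth = if (is.na(d)) 3L else as.integer(d),
                 bndbox = bb,
                 folder = if (is.na(get1("./folder"))) "" else get1("./folder"),
                 extras = extras)
}

#' @rdname read_voc_xml
#' @param ann a [voc_annotation()].
#' @export
write_voc_xml <- function(ann, path) {
  stopifnot(inherits(ann, "voc_annotation"))
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  esc <- function(x) xml2::xml_text(xml2::xml_new_root("x", x))  # not needed for our names
  bb <- if (!is.null(ann$bndbox)) sprintf(
    "  <object>\n    <name>%s</name>\n    <bndbox>\n      <xmin>%d</xmin>\n      <ymin>%d</ymin>\n      <xmax>%d</xmax>\n      <ymax>%d</ymax>\n    </bndbox>\n  </object>",
    ann$label, ann$bndbox["xmin"], ann$bndbox["ymin"],
    ann$bndbox["xmax"], ann$bndbox["ymax"])
  else sprintf("  <object>\n    <name>%s</name>\n  </object>", ann$label)
  xml <- paste0(
    "<annotation>\n",
    sprintf("  <folder>%s</folder>\n", ann$folder),
    sprintf("  <filename>%s</filename>\n", ann$filename),
    sprintf("  <size>\n    <width>%d</width>\n    <height>%d</height>\n    <depth>%d</depth>\n  </size>\n",
            ann$width, ann$height, ann$depth),
    bb, "\n",
    if (length(ann$extras)) paste0("  ", ann$extras, "\n", collapse = "") else "",
    "</annotation>\n")
  writeLines(xml, path)
  invisible(path)
}
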