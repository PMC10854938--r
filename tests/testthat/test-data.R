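test_that("VOC XML round-trips all annotation fields", {
  ann <- voc_annotation("fish_001.png", "Dascyllus reticulatus", 224, 224,
                        bndbox = c(10, 20, 200, 180), folder = "Dascyllus reticulatus")
  p <- tempfile(fileext = ".xml")
  write_voc_xml(ann, p)
  back <- read_voc_xml(p)
  expect_equal(back, ann)
  # without a bounding box
  ann2 <- voc_annotation("a.png", "x", 32, 48)
  p2 <- tempfile(fileext = ".xml")
  write_voc_xml(ann2, p2)
  expect_equal(read_voc_xml(p2), ann2)
})

test_that("unknown XML nodes are preserved opaquely across a round-trip", {
  p <- tempfile(fileext = ".xml")
  writeLines(paste0(
    "<annotation><filename>z.png</filename>",
    "<size><width>10</width><height>12</height><depth>3</depth></size>",
    "<object><name>sp</name></object>",
    "<segmented>0</segmented><pose>Left</pose></annotation>"), p)
  ann <- read_voc_xml(p)
  expect_equal(ann$width, 10L)
  expect_length(ann$extras, 2L)
  expect_match(ann$extras[1], "segmented")
  p2 <- tempfile(fileext = ".xml")
  write_voc_xml(ann, p2)
  expect_equal(read_voc_xml(p2), ann)
})

test_that("malformed VOC files are rejected with the missing node named", {
  p <- tempfile(fileext = ".xml")
  writeLines("<annotation><size><width>5</width><height>5</height></size></annotation>", p)
  expect_error(read_voc_xml(p), "filename")
  writeLines("<annotation><filename>a</filename><object><name>b</name></object></annotation>", p)
  expect_error(read_voc_xml(p), "size")
})

test_that("standardize resizes to 224 RGB and passes same-size images through", {
  img <- rand_img(448, 448, seed = 21)
  out <- standardize(img)
  expect_identical(dim(out), c(224L, 224L, 3L))
  expect_identical(unclass(standardize(out)), unclass(out))
  const <- image_grid(array(99, c(100, 60, 3)))
  sc <- standardize(const, 50)
  expect_true(all(unclass(sc) == 99L))
  grey <- matrix(runif(64 * 64, 0, 255), 64, 64)
  expect_identical(dim(standardize(image_grid(grey), 32)), c(32L, 32L, 3L))
})

test_that("split shares reproduce the published per-class rows exactly", {
  # pre-augmentation census rows (25 classes)
  totals <- blurryfish_counts()$total
  train1 <- c(91, 84, 85, 88, 94, 85, 84, 83, 86, 92, 82, 85, 95, 85, 89,
              92, 92, 84, 91, 95, 90, 87, 82, 89, 92)
  val1 <- c(12, 11, 10, 11, 12, 11, 10, 10, 11, 11, 10, 11, 12, 10, 11,
            11, 12, 11, 12, 12, 11, 11, 10, 11, 12)
  s1 <- split_counts(totals)
  expect_equal(s1$train, train1)
  expect_equal(s1$val, val1)
  expect_equal(s1$test, val1)
  # post-augmentation rows are the same rule applied to the 13x totals
  train13 <- c(1195, 1102, 1093, 1144, 1228, 1113, 1082, 1071, 1124, 1186,
               1060, 1113, 1237, 1093, 1155, 1186, 1206, 1102, 1195, 1237,
               1164, 1133, 1060, 1155, 1206)
  val13 <- c(150, 138, 136, 143, 153, 139, 135, 134, 140, 148, 133, 139,
             155, 136, 144, 148, 151, 138, 150, 155, 146, 142, 133, 144, 151)
  s13 <- split_counts(13 * totals)
  expect_equal(s13$train, train13)
  expect_equal(s13$val, val13)
  expect_equal(s13$test, val13)
  # shares always conserve the class total
  expect_true(all(rowSums(s13) == 13 * totals))
})

test_that("manifest splitting is stratified, seeded and conserving", {
  m <- data.frame(path = sprintf("p%03d", 1:230),
                  label = rep(c("a", "b"), c(115, 115)),
                  stringsAsFactors = FALSE)
  s1 <- split_manifest(m, seed = 4)
  s2 <- split_manifest(m, seed = 4)
  expect_identical(s1, s2)
  tab <- table(s1$label, s1$split)
  expect_equal(unname(tab["a", c("train", "val", "test")]), c(91, 12, 12),
               ignore_attr = TRUE)
  expect_error(split_manifest(data.frame(path = "x", label = "only")),
               "too small")
})

test_that("augmentation produces the planned 12 variants with involutive mirror", {
  img <- rand_img(64, 64, seed = 22)
  expect_length(augment(img, augmentation_spec(plan = c(pan = 0L))), 0)
  vars <- augment(img, augmentation_spec(seed = 1))
  expect_length(vars, 12)
  expect_true(all(vapply(vars, function(v) all(dim(v) == c(64, 64, 3)), TRUE)))
  ns <- asNamespace("fishdeblur")
  expect_identical(unclass(ns$aug_mirror(ns$aug_mirror(img))), unclass(img))
  expect_identical(unclass(ns$aug_flip(ns$aug_flip(img))), unclass(img))
  expect_error(augmentation_spec(plan = c(warp = 1L)), "unknown")
})

test_that("build_dataset cleans, splits, 13-fold expands and never leaks", {
  raw <- tempfile("raw_")
  spec <- synthetic_spec(n_classes = 3, per_class = 10, size = 32, seed = 31)
  gen_toy_dataset(spec, raw)
  # inject an exact duplicate: it must be dropped by content hash
  f <- list.files(file.path(raw, "species_01"), pattern = "png$",
                  full.names = TRUE)[1]
  file.copy(f, file.path(dirname(f), "duplicate_copy.png"))
  out <- tempfile("data_")
  man <- build_dataset(raw, out, size = 32, seed = 5)
  expect_equal(nrow(man), 3 * 10 * 13)
  tab <- table(man$label)
  expect_true(all(tab == 130))
  # augmented variants stay in their source image's split
  for (lb in unique(man$label)) {
    per_split <- table(man$split[man$label == lb],
                       man$variant_tag[man$label == lb] == "clean")
    counts <- split_counts(10)
    expect_equal(unname(per_split[c("train", "val", "test"), "TRUE"]),
                 unname(counts), ignore_attr = TRUE)
    expect_equal(unname(per_split[c("train", "val", "test"), "FALSE"]),
                 unname(counts) * 12, ignore_attr = TRUE)
  }
  # every record has an annotation and files exist
  expect_true(all(file.exists(man$path)))
  expect_true(all(file.exists(sub("\\.png$", ".xml", man$path))))
  expect_true(file.exists(file.path(out, "manifest.csv")))
  expect_identical(read_manifest(file.path(out, "manifest.csv"))$path, man$path)
})

test_that("a 25-class folder tree yields 25 distinct recovered labels", {
  raw <- tempfile("raw25_")
  gen_toy_dataset(synthetic_spec(n_classes = 25, per_class = 1, size = 32,
                                 seed = 33), raw)
  xmls <- list.files(raw, pattern = "\\.xml$", recursive = TRUE,
                     full.names = TRUE)
  labels <- vapply(xmls, function(p) read_voc_xml(p)$label, "")
  expect_length(unique(labels), 25)
})
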