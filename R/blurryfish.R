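#' Per-class census of the BlurryFish image collection
#'
#' The 25 fish species of the BlurryFish dataset (built from Fish4Knowledge
#' and field imagery) with the number of source images per species — 2754
#' images in total before augmentation. These counts drive the count
#' reconciliation of the dataset-construction pipeline: applying
#' [split_counts()] to each class total gives the published per-class
#' train/val/test rows, applying it to 13x the totals gives the
#' post-augmentation rows, and expanding over the standard noise grids (see
#' [reflection_noise_grid()], [ripple_noise_grid()]) gives the degraded
#' dataset volumes.
#'
#' @return data frame with columns `species` and `total`.
#' @examples
#' sum(blurryfish_counts()$total)  # 2754
#' @export
blurryfish_counts <- function() {
  utils::read.csv(system.file("extdata", "blurryfish_class_counts.csv",
                              package = "fishdeblur"),
                  stringsAsFactors = FALSE)
}
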