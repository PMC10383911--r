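# Fixed vocabularies of the LUCAS crop-photo setting: the 12 land-cover
# classes, the cereal group, the six unfavorable-condition labels, and the
# published per-country tallies shipped as plain-text data.

#' The 12 LUCAS LC1 crop classes
#'
#' Common wheat (B11), durum wheat (B12), barley (B13), rye (B14), oats
#' (B15), maize (B16), potatoes (B21), sugar beet (B22), sunflower (B31),
#' rape and turnip rape (B32), soya (B33) and temporary grassland (B55),
#' in canonical order.
#'
#' @return character vector of length 12.
#' @export
lc1Classes <- function() {
  c("B11", "B12", "B13", "B14", "B15", "B16",
    "B21", "B22", "B31", "B32", "B33", "B55")
}

#' Cereal LC1 classes (B11--B15)
#'
#' @return character vector of the five cereal codes.
#' @export
cerealClasses <- function() c("B11", "B12", "B13", "B14", "B15")

#' The six unfavorable photo-condition labels
#'
#' @return character vector: Blurry, Close, Early, Landscape, Object,
#'   Post-harvest.
#' @export
conditionLabels <- function() {
  c("Blurry", "Close", "Early", "Landscape", "Object", "Post-harvest")
}

#' Published per-country, per-class photo tallies
#'
#' The visually validated clean-photo counts per country and crop class,
#' together with the per-country and per-class totals of the larger
#' mature-crop (MMEC) photo stack, shipped as a plain CSV.  The clean
#' counts sum to 15,876 and the MMEC marginals to 169,460.
#'
#' @return data frame with columns `country`, one column per LC1 class,
#'   and `mmec_total` (per-country mature-stack total); the attribute
#'   `mmec_by_class` holds the per-class MMEC totals.
#' @export
lucasTable1 <- function() {
  path <- system.file("extdata", "lucas_photo_counts.csv",
                      package = "cropvision", mustWork = TRUE)
  tab <- read.csv(path, check.names = FALSE)
  mmec <- read.csv(system.file("extdata", "lucas_mmec_class_totals.csv",
                               package = "cropvision", mustWork = TRUE))
  attr(tab, "mmec_by_class") <- setNames(mmec$count, mmec$class)
  tab
}

#' Published unfavorable-condition classification counts
#'
#' True/false classification counts of the best model over the 354-photo
#' unfavorable-condition inference set (59 photos per condition).
#'
#' @return data frame with columns `condition`, `false`, `true`.
#' @export
lucasConditionCounts <- function() {
  data.frame(
    condition = conditionLabels(),
    false = c(27L, 27L, 41L, 35L, 37L, 47L),
    true  = c(32L, 32L, 18L, 24L, 22L, 12L),
    stringsAsFactors = FALSE
  )
}

# Round half away from zero (printed tables round 12/59 to 0.20).
roundHalfUp <- function(x, digits = 2L) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}
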