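#' Color spaces used for seed coat descriptors
#'
#' The coat color of a seed is summarized in four color spaces: RGB, HSV,
#' CIE Lab and YCrCb (ITU-R BT.601). All descriptors are reported on a single
#' 8-bit scale so that values are comparable across spaces:
#'
#' * RGB: channels as-is, 0-255.
#' * HSV: hue mapped from 0-360 degrees to 0-255; saturation and value from
#'   0-1 to 0-255.
#' * Lab: D65 white point, sRGB gamma; L mapped from 0-100 to 0-255; a and b
#'   offset by +128.
#' * YCrCb: BT.601 full-range; Cr and Cb offset by +128.
#'
#' @name seed-color-spaces
#' @keywords internal
NULL

COLOR_SPACES <- c("RGB", "HSV", "Lab", "YCrCb")

#' Channel letters of a color space, in reporting order
#' @param space one of "RGB", "HSV", "Lab", "YCrCb"
#' @return character vector of three channel designations
#' @keywords internal
space_channels <- function(space) {
  switch(space,
    RGB   = c("R", "G", "B"),
    HSV   = c("H", "S", "V"),
    Lab   = c("L", "a", "b"),
    YCrCb = c("Y", "Cr", "Cb"),
    stop("unknown color space: ", space)
  )
}

# index of the channel used as "lightness" when breaking cluster-rank ties
space_lightness_channel <- function(space) {
  switch(space, RGB = NA_integer_, HSV = 3L, Lab = 1L, YCrCb = 1L)
}

#' Convert 8-bit sRGB pixels to a target color space on the 8-bit scale
#'
#' @param rgb numeric matrix (n x 3) of sRGB values in 0-255
#' @param space target space, one of `COLOR_SPACES`
#' @return numeric matrix (n x 3), columns named per [space_channels()],
#'   values on the 8-bit scale described in [seed-color-spaces]
#' @export
convert_pixels <- function(rgb, space = COLOR_SPACES) {
  space <- match.arg(space)
  rgb <- matrix(as.numeric(rgb), ncol = 3)
  out <- switch(space,
    RGB = rgb,
    HSV = {
      h <- grDevices::rgb2hsv(t(rgb), maxColorValue = 255)
      t(h) * 255
    },
    Lab = {
      lab <- grDevices::convertColor(rgb / 255, from = "sRGB", to = "Lab")
      cbind(lab[, 1] * 255 / 100, lab[, 2] + 128, lab[, 3] + 128)
    },
    YCrCb = {
      y <- 0.299 * rgb[, 1] + 0.587 * rgb[, 2] + 0.114 * rgb[, 3]
      cr <- (rgb[, 1] - y) * 0.713 + 128
      cb <- (rgb[, 3] - y) * 0.564 + 128
      cbind(y, cr, cb)
    }
  )
  out <- pmin(pmax(out, 0), 255)
  colnames(out) <- space_channels(space)
  out
}

# sRGB electro-optical transfer (gamma) and its inverse, on [0, 1]
srgb_to_linear <- function(x) {
  ifelse(x <= 0.04045, x / 12.92, ((x + 0.055) / 1.055)^2.4)
}

linear_to_srgb <- function(x) {
  x <- pmin(pmax(x, 0), 1)
  ifelse(x <= 0.0031308, x * 12.92, 1.055 * x^(1 / 2.4) - 0.055)
}

#' Names of the 55 seed descriptors, in canonical order
#'
#' Three size traits (sL, sW, sA), four shape traits (sCi, sRo, sRg, sSo) and,
#' for each of the four color spaces, three mean descriptors (`<S>_m<j>`) and
#' nine dominant-color descriptors (`<S>_dC<j>_<i>`, component j, dominant
#' cluster rank i = 1..3).
#'
#' @return character vector of length 55
#' @export
trait_names <- function() {
  nm <- c("sL", "sW", "sA", "sCi", "sRo", "sRg", "sSo")
  for (sp in COLOR_SPACES) {
    ch <- space_channels(sp)
    nm <- c(nm, paste0(sp, "_m", ch))
    for (i in 1:3) nm <- c(nm, paste0(sp, "_dC", ch, "_", i))
  }
  nm
}

SIZE_SHAPE_TRAITS <- c("sL", "sW", "sA", "sCi", "sRo", "sRg", "sSo")

#' Classify a trait as size/shape or color
#'
#' Used by the gene-prioritization stage: the seed-expression filter applies
#' to color-trait QTLs only. `sRu` is accepted as an alias of `sRg` (rugosity).
#'
#' @param trait character vector of trait names
#' @return character vector, "size_shape" or "color"
#' @export
trait_class <- function(trait) {
  ifelse(trait %in% c(SIZE_SHAPE_TRAITS, "sRu"), "size_shape", "color")
}
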