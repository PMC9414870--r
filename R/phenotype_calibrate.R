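#' Detect the calibration card and fit a color correction
#'
#' Locates the 24-patch calibration card (the single largest dark connected
#' component in the image; the card is assumed axis-aligned), derives the
#' mm-per-pixel scale from its known physical width, samples the central
#' region of every patch, and fits a linear color-correction map (3 x 3 matrix
#' plus offset, acting in linearized RGB) taking measured patch colors to
#' their nominal values by least squares.
#'
#' @param image array width x height x 3, sRGB in `[0, 1]`
#' @param card the [card_layout()] present in the image
#' @param dark_max upper lightness bound for "dark" pixels used to find the
#'   card body
#' @return object of class `color_calibration`: `scale` (mm/px), `card_bbox`
#'   (x0, y0, x1, y1 in px), per-patch measured and nominal sRGB, the fitted
#'   `matrix` and `offset`, and `residual` (mean per-patch RMS error on the
#'   8-bit scale after correction)
#' @export
detect_card_and_calibrate <- function(image, card = card_layout(),
                                      dark_max = 0.35) {
  stopifnot(length(dim(image)) == 3, dim(image)[3] == 3)
  lum <- 0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
  dark <- EBImage::Image(lum < dark_max)
  lab <- EBImage::bwlabel(dark)
  areas <- tabulate(as.integer(EBImage::imageData(lab)))
  if (length(areas) == 0 || max(areas) < 500)
    stop("card-not-found: no sufficiently large dark component")
  ord <- order(areas, decreasing = TRUE)
  if (length(areas) > 1 && areas[ord[2]] > 0.5 * areas[ord[1]])
    stop("ambiguous-card: multiple card-sized dark components")
  id <- ord[1]
  idx <- which(EBImage::imageData(lab) == id, arr.ind = TRUE)
  bbox <- c(min(idx[, 1]), min(idx[, 2]), max(idx[, 1]), max(idx[, 2]))
  width_px <- bbox[3] - bbox[1] + 1
  height_px <- bbox[4] - bbox[2] + 1
  scale <- card$width_mm / width_px

  # sample patches: central 40% of each patch rectangle
  rects <- card_patch_rects(card)
  sx <- width_px / card$width_mm   # px per mm, x
  sy <- height_px / card$height_mm
  measured <- matrix(NA_real_, nrow(rects), 3)
  for (i in seq_len(nrow(rects))) {
    cxm <- (rects[i, 1] + rects[i, 3]) / 2
    cym <- (rects[i, 2] + rects[i, 4]) / 2
    hw <- (rects[i, 3] - rects[i, 1]) * 0.2
    hh <- (rects[i, 4] - rects[i, 2]) * 0.2
    xs <- (bbox[1] + floor((cxm - hw) * sx)):(bbox[1] + ceiling((cxm + hw) * sx))
    ys <- (bbox[2] + floor((cym - hh) * sy)):(bbox[2] + ceiling((cym + hh) * sy))
    xs <- xs[xs >= 1 & xs <= dim(image)[1]]
    ys <- ys[ys >= 1 & ys <= dim(image)[2]]
    for (k in 1:3) measured[i, k] <- mean(image[xs, ys, k])
  }

  nominal <- card$patches / 255
  mlin <- srgb_to_linear(measured)
  nlin <- srgb_to_linear(nominal)
  # nlin ~ A mlin + b, columnwise least squares on the 24 patches
  X <- cbind(mlin, 1)
  fit <- qr.solve(X, nlin)          # 4 x 3
  A <- t(fit[1:3, ])
  b <- fit[4, ]

  corr <- linear_to_srgb(sweep(mlin %*% t(A), 2, b, "+"))
  residual <- mean(sqrt(rowSums((corr - nominal)^2) / 3)) * 255

  structure(list(
    scale = scale, card_bbox = bbox,
    measured = measured * 255, nominal = card$patches,
    matrix = A, offset = b, residual = residual, card = card
  ), class = "color_calibration")
}

#' Apply a fitted color correction to an image
#'
#' The correction acts in linearized RGB: `out = A x + b`, clipped to gamut
#' and returned through the sRGB gamma.
#'
#' @param image array width x height x 3, sRGB in `[0, 1]`
#' @param calibration a `color_calibration`
#' @return corrected image, same shape
#' @export
apply_calibration <- function(image, calibration) {
  stopifnot(inherits(calibration, "color_calibration"))
  lin <- matrix(srgb_to_linear(image), ncol = 3)
  out <- sweep(lin %*% t(calibration$matrix), 2, calibration$offset, "+")
  array(linear_to_srgb(out), dim = dim(image))
}
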