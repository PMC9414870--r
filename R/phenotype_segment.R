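#' Segment seeds from a calibrated image
#'
#' Seeds photographed on a white background are segmented by thresholding the
#' lightness channel with Otsu's method (the calibration-card region is
#' excluded first), followed by a 3 x 3 morphological opening, connected-
#' component labelling and a minimum-area filter. Touching-seed splitting is
#' not attempted: the imaging protocol scatters seeds so that they do not
#' touch.
#'
#' @param image array width x height x 3, sRGB in `[0, 1]` (color-corrected
#'   or raw; segmentation uses lightness only)
#' @param calibration a `color_calibration` from [detect_card_and_calibrate()]
#' @param min_area_mm2 components smaller than this are discarded
#' @return list of `seed_contour` objects (possibly empty); each carries the
#'   pixel mask, traced contour, smoothed-contour perimeter, convex-hull
#'   perimeter and area, and the minimum-area rotated bounding rectangle
#' @export
segment_seeds <- function(image, calibration, min_area_mm2 = 2) {
  stopifnot(inherits(calibration, "color_calibration"))
  lum <- 0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
  bb <- calibration$card_bbox
  xs <- max(1, bb[1] - 2):min(nrow(lum), bb[3] + 2)
  ys <- max(1, bb[2] - 2):min(ncol(lum), bb[4] + 2)
  lum[xs, ys] <- 1  # card joins the background peak
  thr <- EBImage::otsu(EBImage::Image(lum), range = c(0, 1))
  # a threshold inside the white background peak means there is nothing to
  # segment (blank scene): Otsu always splits, even pure noise
  if (!is.finite(thr) || thr > 0.9) return(list())
  mask <- EBImage::Image(lum < thr)
  mask <- EBImage::opening(mask, EBImage::makeBrush(3, shape = "box"))
  lab <- EBImage::bwlabel(mask)
  labm <- EBImage::imageData(lab)
  areas <- tabulate(as.integer(labm))
  min_px <- min_area_mm2 / calibration$scale^2
  keep <- which(areas >= min_px)
  contours <- ebi_contours(lab)
  out <- list()
  for (id in keep) {
    ct <- contours[[id]]
    if (is.null(ct) || nrow(ct) < 3) next
    out[[length(out) + 1]] <- seed_contour(labm == id, ct, area_px = areas[id])
  }
  out
}

# object contours from a labelled image, 1-based pixel coordinates
ebi_contours <- function(lab) {
  ct <- EBImage::ocontour(lab)
  lapply(ct, function(m) m + 1)
}

#' Build a seed contour object from a mask and traced boundary
#'
#' Perimeters are measured on a closed moving-average-smoothed version of the
#' pixel contour (window 5), which removes the systematic overestimation of a
#' raw 8-connected chain. The convex-hull perimeter uses the hull of the same
#' smoothed points (so rugosity >= 1 exactly). The convex-hull area is
#' measured on the pixel grid itself — the count of pixel centers inside the
#' convex hull of the boundary pixel centers — so that solidity compares a
#' pixel count with a pixel count and is <= 1 exactly.
#'
#' @param mask logical matrix (full image frame) marking the seed's pixels
#' @param contour integer matrix of boundary pixel coordinates (x, y), ordered
#' @param area_px pixel count of the mask (computed if missing)
#' @return object of class `seed_contour`
#' @export
seed_contour <- function(mask, contour, area_px = NULL) {
  if (is.null(area_px)) area_px <- sum(mask)
  if (nrow(contour) < 3) stop("degenerate contour: fewer than 3 points")
  sm <- smooth_closed(contour, k = 5)
  per <- poly_length(sm)
  hull_pts <- sm[rev(grDevices::chull(sm)), , drop = FALSE]
  hull_per <- poly_length(hull_pts)
  hull_raw <- contour[rev(grDevices::chull(contour)), , drop = FALSE]
  hull_area <- rasterized_hull_area(hull_raw, contour)
  rect <- min_area_rect(hull_pts)
  structure(list(
    contour = contour, smoothed = sm, area_px = area_px,
    perimeter_px = per, hull_perimeter_px = hull_per,
    hull_area_px = hull_area, rect = rect,
    pixels = which(mask, arr.ind = TRUE)
  ), class = "seed_contour")
}

# circular moving average of a closed polygon's vertices
smooth_closed <- function(pts, k = 5) {
  n <- nrow(pts)
  if (n <= k) return(pts)
  half <- (k - 1) / 2
  pad <- rbind(pts[(n - half + 1):n, , drop = FALSE], pts,
               pts[1:half, , drop = FALSE])
  xs <- stats::filter(pad[, 1], rep(1 / k, k))
  ys <- stats::filter(pad[, 2], rep(1 / k, k))
  cbind(as.numeric(xs[(half + 1):(half + n)]),
        as.numeric(ys[(half + 1):(half + n)]))
}

poly_length <- function(pts) {
  n <- nrow(pts)
  d <- pts - pts[c(2:n, 1), , drop = FALSE]
  sum(sqrt(rowSums(d^2)))
}

poly_area <- function(pts) {
  n <- nrow(pts)
  x <- pts[, 1]; y <- pts[, 2]
  xn <- x[c(2:n, 1)]; yn <- y[c(2:n, 1)]
  abs(sum(x * yn - xn * y)) / 2
}

# pixel-center count inside a convex hull polygon (vertices are pixel centers
# of the contour, so every mask pixel center lies inside: solidity <= 1)
rasterized_hull_area <- function(hull, contour) {
  xs <- floor(min(contour[, 1])):ceiling(max(contour[, 1]))
  ys <- floor(min(contour[, 2])):ceiling(max(contour[, 2]))
  px <- as.vector(outer(xs, ys * 0, "+"))
  py <- as.vector(outer(xs * 0, ys, "+"))
  n <- nrow(hull)
  # orient so the interior gives non-negative cross products
  sgn <- sign(sum(hull[, 1] * hull[c(2:n, 1), 2] -
                    hull[c(2:n, 1), 1] * hull[, 2]))
  if (sgn == 0) sgn <- 1
  inside <- rep(TRUE, length(px))
  for (i in seq_len(n)) {
    j <- i %% n + 1
    ex <- hull[j, 1] - hull[i, 1]; ey <- hull[j, 2] - hull[i, 2]
    cr <- sgn * (ex * (py - hull[i, 2]) - ey * (px - hull[i, 1]))
    inside <- inside & cr >= -1e-9
    if (!any(inside)) break
  }
  sum(inside)
}

# minimum-area rotated bounding rectangle by rotating calipers over hull edges
min_area_rect <- function(hull) {
  n <- nrow(hull)
  best <- list(area = Inf)
  for (i in seq_len(n)) {
    e <- hull[i %% n + 1, ] - hull[i, ]
    len <- sqrt(sum(e^2))
    if (len < 1e-9) next
    ux <- e / len
    uy <- c(-ux[2], ux[1])
    p1 <- hull %*% ux
    p2 <- hull %*% uy
    s1 <- max(p1) - min(p1)
    s2 <- max(p2) - min(p2)
    if (s1 * s2 < best$area) {
      ctr <- ((max(p1) + min(p1)) / 2) * ux + ((max(p2) + min(p2)) / 2) * uy
      best <- list(
        area = s1 * s2,
        sides = sort(c(s1, s2), decreasing = TRUE),
        angle = atan2(ux[2], ux[1]) * 180 / pi,
        center = ctr
      )
    }
  }
  if (!is.finite(best$area)) stop("degenerate hull")
  best
}
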