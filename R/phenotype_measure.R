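#' Seed size from a contour
#'
#' Length and width are the sides of the minimum-area rotated bounding
#' rectangle of the (smoothed) contour, enlarged by one pixel to account for
#' the half-pixel footprint on each side; projected area is the pixel count.
#' All converted to mm via the calibration scale.
#'
#' @param contour a `seed_contour`
#' @param calibration a `color_calibration` (provides mm/px)
#' @return named numeric: `sL`, `sW` (mm), `sA` (mm^2)
#' @export
measure_size <- function(contour, calibration) {
  stopifnot(inherits(contour, "seed_contour"))
  s <- calibration$scale
  c(sL = (contour$rect$sides[1] + 1) * s,
    sW = (contour$rect$sides[2] + 1) * s,
    sA = contour$area_px * s^2)
}

#' Seed shape indices from a contour
#'
#' * circularity `sCi = 4*pi*A / P^2` (1 for a circle),
#' * roundness `sRo = 4*A / (pi * L^2)` with L the bounding-rectangle long
#'   side; normalized so a circle gives 1 and any other shape less than 1,
#' * rugosity `sRg = P / P_convex` (>= 1; 1 for convex outlines),
#' * solidity `sSo = A / A_convex` (<= 1; 1 for convex outlines).
#'
#' All quantities are in pixel units and the indices are dimensionless, so no
#' calibration is needed.
#'
#' @param contour a `seed_contour`
#' @return named numeric: `sCi`, `sRo`, `sRg`, `sSo`
#' @export
measure_shape <- function(contour) {
  stopifnot(inherits(contour, "seed_contour"))
  A <- contour$area_px
  P <- contour$perimeter_px
  if (A <= 0 || P <= 0) stop("degenerate contour: zero area or perimeter")
  L <- contour$rect$sides[1] + 1
  c(sCi = 4 * pi * A / P^2,
    sRo = 4 * A / (pi * L^2),
    sRg = P / contour$hull_perimeter_px,
    sSo = A / contour$hull_area_px)
}

#' The 48 color descriptors of one seed
#'
#' For each color space (RGB, HSV, Lab, YCrCb, 8-bit scale):
#' * 3 mean descriptors `<S>_m<j>`: per channel, pixels deviating from the
#'   channel mean by more than `sd_mult` standard deviations are excluded in a
#'   single pass (independently per channel) and the mean of the survivors is
#'   reported;
#' * 9 dominant-color descriptors `<S>_dC<j>_<i>`: the seed's pixels are
#'   clustered into `k = 3` groups by k-means in the space's 3-D coordinates,
#'   clusters are ranked by pixel count (ties broken by descending centroid
#'   lightness) and each ranked centroid's components are reported.
#'
#' A one-pixel boundary ring is eroded from the mask before sampling to avoid
#' background bleed at the seed edge. K-means uses deterministic initial
#' centers: the pixels at the 10th/50th/90th percentile positions along the
#' first principal axis of the pixel cloud. If the seed has fewer than three
#' distinct colors, the missing cluster slots repeat the lowest-ranked
#' centroid.
#'
#' @param image color-corrected image array (width x height x 3, `[0, 1]`)
#' @param contour a `seed_contour`
#' @param calibration a `color_calibration` (unused directly; kept so all
#'   measurement functions share one signature)
#' @param k number of dominant-color clusters
#' @param sd_mult outlier exclusion multiplier for mean descriptors
#' @param erode_boundary drop the 1-px boundary ring before sampling
#' @return named numeric vector of the 48 color descriptors
#' @export
measure_color <- function(image, contour, calibration = NULL, k = 3,
                          sd_mult = 3, erode_boundary = TRUE) {
  stopifnot(inherits(contour, "seed_contour"))
  pix_idx <- contour$pixels
  if (erode_boundary) {
    er <- erode_mask_pixels(pix_idx, dim(image)[1:2])
    if (nrow(er) > 0) pix_idx <- er
  }
  if (nrow(pix_idx) == 0) stop("empty mask")
  rgb <- cbind(image[cbind(pix_idx, 1)],
               image[cbind(pix_idx, 2)],
               image[cbind(pix_idx, 3)]) * 255
  out <- numeric(0)
  for (sp in COLOR_SPACES) {
    px <- convert_pixels(rgb, sp)
    ch <- space_channels(sp)
    means <- vapply(1:3, function(j) trimmed_channel_mean(px[, j], sd_mult),
                    numeric(1))
    names(means) <- paste0(sp, "_m", ch)
    dom <- dominant_colors(px, k = k, space = sp)
    dn <- as.vector(vapply(1:k, function(i) paste0(sp, "_dC", ch, "_", i),
                           character(3)))
    dv <- as.vector(t(dom))
    names(dv) <- dn
    out <- c(out, means, dv)
  }
  out
}

# single-pass 3-sigma-trimmed mean of one channel
trimmed_channel_mean <- function(x, sd_mult = 3) {
  m <- mean(x); s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(m)
  mean(x[abs(x - m) <= sd_mult * s])
}

# k dominant colors: rows = cluster ranks 1..k, cols = space components
dominant_colors <- function(px, k = 3, space = "RGB") {
  uniq <- unique(px)
  if (nrow(uniq) < k) {
    key <- apply(px, 1, paste, collapse = "\r")
    cnt <- table(key)
    ukey <- apply(uniq, 1, paste, collapse = "\r")
    sizes <- as.integer(cnt[ukey])
    centers <- uniq
  } else {
    init <- pca_percentile_centers(px, uniq, k)
    km <- tryCatch(
      stats::kmeans(px, centers = init, iter.max = 100),
      error = function(e) lloyd_fallback(px, init)
    )
    centers <- km$centers
    sizes <- as.integer(km$size)
  }
  ord <- order(-sizes, -centroid_lightness(centers, space))
  centers <- centers[ord, , drop = FALSE]
  sizes <- sizes[ord]
  keep <- sizes > 0
  centers <- centers[keep, , drop = FALSE]
  while (nrow(centers) < k)
    centers <- rbind(centers, centers[nrow(centers), ])
  unname(centers[1:k, , drop = FALSE])
}

pca_percentile_centers <- function(px, uniq, k) {
  ctr <- colMeans(px)
  sc <- sweep(px, 2, ctr)
  v <- svd(sc, nu = 0, nv = 1)$v[, 1]
  su <- sweep(uniq, 2, ctr) %*% v
  ord <- order(su, uniq[, 1], uniq[, 2], uniq[, 3])
  n <- nrow(uniq)
  qs <- pmax(1, ceiling(c(0.10, 0.50, 0.90) * n))
  qs <- unique(qs)
  while (length(qs) < k) qs <- unique(c(qs, pmin(n, max(qs) + 1), max(1, min(qs) - 1)))
  uniq[ord[qs[1:k]], , drop = FALSE]
}

centroid_lightness <- function(centers, space) {
  j <- space_lightness_channel(space)
  if (is.na(j)) rowMeans(centers) else centers[, j]
}

# plain Lloyd iterations; tolerates clusters that empty out
lloyd_fallback <- function(px, centers, iter.max = 100) {
  k <- nrow(centers)
  assign <- rep(1L, nrow(px))
  for (it in seq_len(iter.max)) {
    d <- vapply(seq_len(k), function(j)
      rowSums(sweep(px, 2, centers[j, ])^2), numeric(nrow(px)))
    new_assign <- max.col(-d, ties.method = "first")
    if (all(new_assign == assign) && it > 1) break
    assign <- new_assign
    for (j in seq_len(k)) {
      sel <- assign == j
      if (any(sel)) centers[j, ] <- colMeans(px[sel, , drop = FALSE])
    }
  }
  list(centers = centers, size = tabulate(assign, k))
}

# 4-neighbour erosion of a pixel set given as (x, y) index rows
erode_mask_pixels <- function(idx, dims) {
  m <- matrix(FALSE, dims[1], dims[2])
  m[idx] <- TRUE
  er <- EBImage::erode(EBImage::Image(m), EBImage::makeBrush(3, "box"))
  which(EBImage::imageData(er) > 0.5, arr.ind = TRUE)
}
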