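#' Phenotype all seeds in one image
#'
#' Runs the full per-image chain: card detection and color calibration,
#' color correction, seed segmentation, and measurement of the 55 descriptors
#' for every detected seed.
#'
#' @param image array width x height x 3 in `[0, 1]`, or a PNG/JPEG path
#' @param card the [card_layout()] present in the image
#' @param min_area_mm2 segmentation minimum component area
#' @param k dominant-color cluster count
#' @param sd_mult outlier exclusion multiplier for mean color descriptors
#' @return list with `seeds` (data.frame, one row per seed, 55 descriptor
#'   columns in [trait_names()] order plus `seed`), `calibration`, and
#'   `contours`
#' @export
phenotype_image <- function(image, card = card_layout(), min_area_mm2 = 2,
                            k = 3, sd_mult = 3) {
  if (is.character(image)) image <- read_scene_png(image)
  calib <- detect_card_and_calibrate(image, card = card)
  corrected <- apply_calibration(image, calib)
  contours <- segment_seeds(corrected, calib, min_area_mm2 = min_area_mm2)
  rows <- lapply(contours, function(ct) {
    c(measure_size(ct, calib), measure_shape(ct),
      measure_color(corrected, ct, calib, k = k, sd_mult = sd_mult))
  })
  seeds <- if (length(rows)) {
    df <- as.data.frame(do.call(rbind, rows))
    df <- df[, trait_names()]
    cbind(seed = seq_len(nrow(df)), df)
  } else {
    df <- as.data.frame(matrix(numeric(0), 0, 55,
                               dimnames = list(NULL, trait_names())))
    cbind(seed = integer(0), df)
  }
  list(seeds = seeds, calibration = calib, contours = contours)
}

#' Per-genotype trait vector from one or more seed images
#'
#' Seeds detected across all images of a genotype are pooled and each of the
#' 55 descriptors is averaged with equal weight per seed (the protocol uses
#' two images, of 15 and 5 seeds, per genotype).
#'
#' @param images list of image arrays or file paths
#' @param ... passed to [phenotype_image()]
#' @return list with `genotype` (named numeric vector of 55 trait means) and
#'   `seeds` (pooled per-seed table with an `image` column)
#' @export
phenotype_genotype <- function(images, ...) {
  if (!is.list(images)) images <- list(images)
  tabs <- lapply(seq_along(images), function(i) {
    ph <- phenotype_image(images[[i]], ...)
    if (nrow(ph$seeds)) cbind(image = i, ph$seeds) else NULL
  })
  tabs <- Filter(Negate(is.null), tabs)
  if (!length(tabs)) stop("no-seeds-detected: no seed found in any image")
  seeds <- do.call(rbind, tabs)
  genotype <- colMeans(seeds[, trait_names(), drop = FALSE])
  list(genotype = genotype, seeds = seeds)
}

#' Phenotype a set of genotypes and write a trait table
#'
#' @param image_sets named list: genotype -> list of images/paths
#' @param ... passed to [phenotype_image()]
#' @return data.frame with `genotype` and the 55 trait columns
#' @export
phenotype_population <- function(image_sets, ...) {
  stopifnot(length(names(image_sets)) == length(image_sets))
  rows <- lapply(image_sets, function(im) phenotype_genotype(im, ...)$genotype)
  df <- as.data.frame(do.call(rbind, rows))
  cbind(genotype = names(image_sets), df, row.names = NULL)
}
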