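# Card calibration, segmentation, and the 55 descriptors.

test_that("identity scenes calibrate to an identity correction", {
  sc <- render_seed_image(scene_spec(n_seeds = 3, seed = 1))
  cal <- detect_card_and_calibrate(sc$image)
  expect_lt(max(abs(cal$matrix - diag(3))), 0.01)
  expect_lt(max(abs(cal$offset)), 1 / 255)
  expect_lt(cal$residual, 0.5)
  # scale recovered from the known card width
  expect_equal(cal$scale, sc$spec$scale, tolerance = 0.01)
})

test_that("a planted linear cast is inverted by calibration", {
  M <- matrix(c(1.10, 0.03, 0.00,
                0.02, 0.95, 0.01,
                0.00, 0.02, 1.05), 3, 3, byrow = TRUE)
  sc <- render_seed_image(scene_spec(n_seeds = 3, seed = 2, cast = M))
  cal <- detect_card_and_calibrate(sc$image)
  expect_lt(max(abs(cal$matrix - solve(M))), 0.01)
  # corrected patches match nominal within 2/255
  corr <- apply_calibration(sc$image, cal)
  cal2 <- detect_card_and_calibrate(corr)
  expect_lt(max(abs(cal2$measured - cal2$nominal)), 2)
})

test_that("card detection errors are informative", {
  img <- array(1, dim = c(120, 100, 3))  # blank white frame
  expect_error(detect_card_and_calibrate(img), "card-not-found")
})

test_that("segmentation finds each rendered seed and nothing else", {
  sc <- render_seed_image(scene_spec(n_seeds = 15, seed = 3, noise_sd = 2))
  cal <- detect_card_and_calibrate(sc$image)
  cts <- segment_seeds(apply_calibration(sc$image, cal), cal)
  expect_length(cts, 15)
  # each contour matches one ground-truth mask with IoU > 0.95
  for (ct in cts) {
    ids <- sc$labels[ct$pixels]
    id <- as.integer(names(which.max(table(ids[ids > 0]))))
    truth_px <- which(sc$labels == id, arr.ind = TRUE)
    inter <- sum(ids == id)
    union <- nrow(truth_px) + nrow(ct$pixels) - inter
    expect_gt(inter / union, 0.95)
  }
  # blank scene: nothing to segment
  sc0 <- render_seed_image(scene_spec(n_seeds = 0, seed = 4))
  cal0 <- detect_card_and_calibrate(sc0$image)
  expect_length(segment_seeds(sc0$image, cal0), 0)
})

test_that("size measurements recover circle and ellipse geometry", {
  cal <- fake_calibration(scale = 0.05)          # 20 px per mm
  circ <- shape_contour(a_px = 40)               # radius 2 mm
  sz <- measure_size(circ, cal)
  expect_equal(unname(sz["sL"]), 4, tolerance = 0.05 / 4 * 2)
  expect_equal(unname(sz["sW"]), 4, tolerance = 0.05 / 4 * 2)
  expect_equal(unname(sz["sA"]), pi * 4, tolerance = 0.02 * pi * 4)
  ell <- shape_contour(a_px = 70, b_px = 32)     # 3.5 x 1.6 mm
  sz2 <- measure_size(ell, cal)
  expect_equal(unname(sz2["sL"]), 7.0, tolerance = 0.1)
  expect_equal(unname(sz2["sW"]), 3.2, tolerance = 0.1)
  expect_equal(unname(sz2["sA"]), pi * 3.5 * 1.6, tolerance = 0.35)
})

test_that("size is invariant to image resolution", {
  lo <- measure_size(shape_contour(a_px = 60, b_px = 30),
                     fake_calibration(scale = 1 / 20))
  hi <- measure_size(shape_contour(a_px = 120, b_px = 60),
                     fake_calibration(scale = 1 / 40))
  expect_equal(unname(lo), unname(hi), tolerance = 0.02)
})

test_that("shape indices behave on circles, ellipses and rough outlines", {
  circ <- measure_shape(shape_contour(a_px = 110))
  expect_true(all(circ[c("sCi", "sRo", "sSo")] > 0.97 &
                    circ[c("sCi", "sRo", "sSo")] < 1.03))
  expect_true(circ["sRg"] >= 1 && circ["sRg"] < 1.05)
  # 2:1 ellipse: roundness is the axis ratio, strictly below 1
  ell <- measure_shape(shape_contour(a_px = 160, b_px = 80))
  expect_equal(unname(ell["sRo"]), 0.5, tolerance = 0.02)
  expect_lt(ell["sRo"], 1)
  expect_equal(unname(ell["sSo"]), 1, tolerance = 0.01)
  expect_equal(unname(ell["sRg"]), 1, tolerance = 0.02)
  # radial perturbation raises rugosity and lowers solidity
  rough <- measure_shape(shape_contour(a_px = 120, b_px = 70, rough = 0.1))
  expect_gt(rough["sRg"], 1.01)
  expect_lt(rough["sSo"], 0.99)
})

test_that("shape indices are invariant to rotation and translation", {
  base <- measure_shape(shape_contour(a_px = 120, b_px = 60))
  for (ang in c(20, 45, 77)) {
    rot <- measure_shape(shape_contour(a_px = 120, b_px = 60,
                                       angle_deg = ang))
    expect_equal(unname(rot), unname(base), tolerance = 0.02)
  }
})

test_that("solidity and rugosity bounds hold across random shapes", {
  set.seed(1)
  for (i in 1:8) {
    a <- sample(60:120, 1); b <- sample(30:60, 1)
    rough <- sample(c(0, 0.05, 0.12), 1)
    sh <- measure_shape(shape_contour(a_px = a, b_px = b, rough = rough,
                                      phase = runif(1, 0, 2 * pi)))
    expect_lte(sh["sSo"], 1)
    expect_gte(sh["sRg"], 1)
  }
})

test_that("uniform seeds report their base color in all four spaces", {
  base <- c(150, 110, 70)
  sc <- render_seed_image(scene_spec(n_seeds = 2, base_rgb = base,
                                     seed = 5))
  ph <- phenotype_image(sc$image)
  expected <- unlist(lapply(c("RGB", "HSV", "Lab", "YCrCb"), function(sp)
    as.vector(convert_pixels(matrix(base, 1), sp))))
  for (s in seq_len(nrow(ph$seeds))) {
    for (sp in c("RGB", "HSV", "Lab", "YCrCb")) {
      mcols <- grep(paste0("^", sp, "_m"), names(ph$seeds), value = TRUE)
      got <- unlist(ph$seeds[s, mcols])
      want <- as.vector(convert_pixels(matrix(base, 1), sp))
      expect_equal(unname(got), want, tolerance = 1)
      # all three dominant centroids collapse onto the same color
      for (i in 1:3) {
        dcols <- grep(paste0("^", sp, "_dC.*_", i, "$"), names(ph$seeds),
                      value = TRUE)
        expect_equal(unname(unlist(ph$seeds[s, dcols])), want,
                     tolerance = 1)
      }
    }
  }
})

test_that("3-sigma exclusion protects the mean descriptors from outliers", {
  set.seed(10)
  base <- c(140, 100, 60)
  w <- 60
  img <- array(0, dim = c(w, w, 3))
  n <- w * w
  n_out <- round(0.01 * n)
  for (k in 1:3) {
    ch <- rep(base[k], n) + rnorm(n, 0, 2)
    ch[sample(n, n_out)] <- base[k] + 50   # impulse outliers, > 3 sd away
    img[, , k] <- matrix(ch, w, w) / 255
  }
  mask <- matrix(FALSE, w, w); mask[5:56, 5:56] <- TRUE
  ct <- seed_contour(mask, EBImage::ocontour(EBImage::Image(mask))[[1]] + 1)
  v <- measure_color(img, ct, erode_boundary = FALSE)
  naive <- mean(img[, , 1][mask]) * 255
  expect_gt(abs(naive - base[1]), 0.3)     # untrimmed mean is pulled away
  expect_lt(abs(v["RGB_mR"] - base[1]), 0.5)
  expect_lt(abs(v["RGB_mG"] - base[2]), 0.5)
  expect_lt(abs(v["RGB_mB"] - base[3]), 0.5)
})

test_that("dominant colors split a planted two-color mixture by frequency", {
  w <- 50
  maj <- c(170, 120, 60); minr <- c(60, 90, 160)
  img <- array(0, dim = c(w, w, 3))
  cut <- round(0.7 * w)
  for (k in 1:3) {
    m <- matrix(minr[k] / 255, w, w)
    m[, 1:cut] <- maj[k] / 255
    img[, , k] <- m
  }
  mask <- matrix(TRUE, w, w)
  ct <- seed_contour(mask, EBImage::ocontour(EBImage::Image(mask))[[1]] + 1)
  v <- measure_color(img, ct, erode_boundary = FALSE)
  expect_equal(unname(v[c("RGB_dCR_1", "RGB_dCG_1", "RGB_dCB_1")]),
               maj, tolerance = 2)
  expect_equal(unname(v[c("RGB_dCR_2", "RGB_dCG_2", "RGB_dCB_2")]),
               minr, tolerance = 2)
})

test_that("per-genotype aggregation pools seeds across images", {
  im1 <- render_seed_image(scene_spec(n_seeds = 1, a_mm = 3, b_mm = 1.5,
                                      seed = 6))$image
  im2 <- render_seed_image(scene_spec(n_seeds = 1, a_mm = 4, b_mm = 2,
                                      seed = 7))$image
  g <- phenotype_genotype(list(im1, im2))
  expect_equal(nrow(g$seeds), 2)
  expect_equal(unname(g$genotype["sL"]), 7, tolerance = 0.1)
  expect_equal(unname(g$genotype["sL"]), mean(g$seeds$sL))
  # image order cannot matter
  g2 <- phenotype_genotype(list(im2, im1))
  expect_equal(g2$genotype, g$genotype)
  # no seeds anywhere is an error
  blank <- render_seed_image(scene_spec(n_seeds = 0, seed = 8))$image
  expect_error(phenotype_genotype(list(blank)), "no-seeds-detected")
})

test_that("every seed record carries exactly the 55 named descriptors", {
  sc <- render_seed_image(scene_spec(n_seeds = 4, seed = 9, noise_sd = 1))
  ph <- phenotype_image(sc$image)
  nm <- trait_names()
  expect_length(nm, 55)
  expect_identical(setdiff(names(ph$seeds), "seed"), nm)
  expect_length(grep("^s[LWA]$", nm), 3)
  expect_length(grep("^s(Ci|Ro|Rg|So)$", nm), 4)
  expect_length(grep("_m", nm), 12)
  expect_length(grep("_dC", nm), 36)
})

test_that("dominant clusters are ranked by pixel count", {
  # three well-separated colors at 60/30/10%: ranks must follow frequency
  w <- 60
  cols <- rbind(c(180, 130, 70), c(70, 100, 170), c(30, 200, 90))
  img <- array(0, dim = c(w, w, 3))
  b1 <- round(0.6 * w); b2 <- round(0.9 * w)
  for (k in 1:3) {
    m <- matrix(cols[3, k] / 255, w, w)
    m[, 1:b1] <- cols[1, k] / 255
    m[, (b1 + 1):b2] <- cols[2, k] / 255
    img[, , k] <- m
  }
  mask <- matrix(TRUE, w, w)
  ct <- seed_contour(mask, EBImage::ocontour(EBImage::Image(mask))[[1]] + 1)
  v <- measure_color(img, ct, erode_boundary = FALSE)
  for (i in 1:3) {
    got <- unname(v[paste0("RGB_dC", c("R", "G", "B"), "_", i)])
    expect_equal(got, cols[i, ], tolerance = 2)
  }
})
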