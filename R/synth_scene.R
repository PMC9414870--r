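#' Layout of the 24-patch color calibration card
#'
#' The synthetic scenes emulate an imaging protocol in which seeds are
#' scattered on white paper next to a 24-patch ColorChecker-style calibration
#' card used for color correction and for recovering the mm-per-pixel scale.
#' The layout is a dark card body carrying a 6 x 4 grid of patches with the
#' classic nominal sRGB values.
#'
#' @param width_mm,height_mm physical card size in mm
#' @param border_mm width of the dark border around the patch grid
#' @param gutter_mm gap between patches
#' @return object of class `card_layout`: card geometry, patch grid and the
#'   24 nominal sRGB patch colors (rows, 0-255)
#' @export
card_layout <- function(width_mm = 108, height_mm = 63.5, border_mm = 6,
                        gutter_mm = 2) {
  patches <- matrix(c(
    115, 82, 68,   194, 150, 130,  98, 122, 157,   87, 108, 67,
    133, 128, 177, 103, 189, 170,  214, 126, 44,   80, 91, 166,
    193, 90, 99,   94, 60, 108,    157, 188, 64,   224, 163, 46,
    56, 61, 150,   70, 148, 73,    175, 54, 60,    231, 199, 31,
    187, 86, 149,  8, 133, 161,    243, 243, 242,  200, 200, 200,
    160, 160, 160, 122, 122, 121,  85, 85, 85,     52, 52, 52
  ), ncol = 3, byrow = TRUE)
  colnames(patches) <- c("R", "G", "B")
  structure(list(
    width_mm = width_mm, height_mm = height_mm,
    border_mm = border_mm, gutter_mm = gutter_mm,
    ncol = 6L, nrow = 4L, patches = patches,
    body_rgb = c(40, 40, 40)
  ), class = "card_layout")
}

# patch rectangles in mm relative to the card's top-left corner
# rows: patch 1..24 (row-major over the 6 x 4 grid); cols: x0, y0, x1, y1
card_patch_rects <- function(card) {
  pw <- (card$width_mm - 2 * card$border_mm -
           (card$ncol - 1) * card$gutter_mm) / card$ncol
  ph <- (card$height_mm - 2 * card$border_mm -
           (card$nrow - 1) * card$gutter_mm) / card$nrow
  out <- matrix(NA_real_, card$ncol * card$nrow, 4)
  k <- 1
  for (r in seq_len(card$nrow)) {
    for (cc in seq_len(card$ncol)) {
      x0 <- card$border_mm + (cc - 1) * (pw + card$gutter_mm)
      y0 <- card$border_mm + (r - 1) * (ph + card$gutter_mm)
      out[k, ] <- c(x0, y0, x0 + pw, y0 + ph)
      k <- k + 1
    }
  }
  out
}

#' Specify a synthetic seed scene
#'
#' Describes a photograph-like scene: up to `n_seeds` non-overlapping
#' elliptical seeds (optionally with a low-order radial cosine boundary
#' perturbation controlling rugosity) scattered on a near-white background
#' next to the calibration card. Per-seed geometry and coat colors may be
#' given explicitly or are drawn reproducibly from `seed`.
#'
#' @param n_seeds number of seeds (0 allowed)
#' @param scale mm per pixel (> 0)
#' @param canvas_mm canvas width and height in mm
#' @param a_mm,b_mm semi-axis ranges (mm) seeds are drawn from, or vectors of
#'   length `n_seeds` for explicit geometry; `a >= b > 0` is enforced
#' @param angle_deg optional per-seed orientations (degrees)
#' @param roughness radial cosine perturbation amplitude in `[0, 0.2]`
#' @param rough_order integer order of the cosine perturbation
#' @param base_rgb a single base coat color (length 3, 0-255) or an
#'   `n_seeds` x 3 matrix; default draws wheat-like reddish-brown coats
#' @param color_jitter per-seed uniform jitter (8-bit units) applied to the
#'   default base colors
#' @param background background sRGB color (near-white, 0-255)
#' @param noise_sd Gaussian pixel noise sd per channel, 8-bit units
#' @param cast optional 3 x 3 linear color-cast matrix applied to the whole
#'   image in linearized RGB (exercises the calibration stage)
#' @param cast_offset optional length-3 offset added with `cast`
#' @param card a [card_layout()]
#' @param card_origin_mm top-left corner of the card on the canvas
#' @param seed integer RNG seed; all randomness in rendering flows from it
#' @return object of class `scene_spec`
#' @export
scene_spec <- function(n_seeds = 15, scale = 0.1, canvas_mm = c(190, 120),
                       a_mm = c(2.8, 3.8), b_mm = c(1.4, 2.0),
                       angle_deg = NULL, roughness = 0, rough_order = 7L,
                       base_rgb = NULL, color_jitter = 12,
                       background = c(250, 250, 250), noise_sd = 0,
                       cast = NULL, cast_offset = c(0, 0, 0),
                       card = card_layout(), card_origin_mm = c(4, 4),
                       seed = 1L) {
  stopifnot(n_seeds >= 0, scale > 0, length(canvas_mm) == 2,
            roughness >= 0, roughness <= 0.2)
  if (!is.null(cast)) stopifnot(is.matrix(cast), all(dim(cast) == c(3, 3)))
  spec <- structure(list(
    n_seeds = as.integer(n_seeds), scale = scale, canvas_mm = canvas_mm,
    a_mm = a_mm, b_mm = b_mm, angle_deg = angle_deg,
    roughness = roughness, rough_order = as.integer(rough_order),
    base_rgb = base_rgb, color_jitter = color_jitter,
    background = background, noise_sd = noise_sd,
    cast = cast, cast_offset = cast_offset,
    card = card, card_origin_mm = card_origin_mm, seed = as.integer(seed)
  ), class = "scene_spec")
  spec
}

# evaluate with a local RNG state so callers' streams are untouched
with_local_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Render a synthetic seed scene with exact ground truth
#'
#' Produces an 8-bit RGB raster of the scene plus a ground-truth table with
#' one row per seed (true length `2a`, width `2b`, projected area
#' `pi*a*b*(1 + roughness^2/2)`, and the base coat color) and a label image
#' assigning every seed pixel to its seed id. Seeds are placed by rejection
#' sampling; placement failing after bounded retries is an error.
#'
#' @param spec a [scene_spec()]
#' @return list with `image` (array width x height x 3, values in `[0, 1]`),
#'   `truth` (data.frame), `labels` (integer matrix width x height) and `spec`
#' @export
render_seed_image <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  with_local_seed(spec$seed, render_scene_impl(spec))
}

render_scene_impl <- function(spec) {
  w <- as.integer(round(spec$canvas_mm[1] / spec$scale))
  h <- as.integer(round(spec$canvas_mm[2] / spec$scale))
  img <- array(rep(spec$background / 255, each = w * h), dim = c(w, h, 3))
  labels <- matrix(0L, w, h)

  # --- card ---
  card <- spec$card
  co <- spec$card_origin_mm
  px <- function(mm) as.integer(round(mm / spec$scale))
  fill_rect <- function(x0, y0, x1, y1, rgb) {
    xs <- max(1L, px(x0) + 1L):min(w, px(x1))
    ys <- max(1L, px(y0) + 1L):min(h, px(y1))
    for (k in 1:3) img[xs, ys, k] <<- rgb[k] / 255
  }
  fill_rect(co[1], co[2], co[1] + card$width_mm, co[2] + card$height_mm,
            card$body_rgb)
  rects <- card_patch_rects(card)
  for (i in seq_len(nrow(rects))) {
    fill_rect(co[1] + rects[i, 1], co[2] + rects[i, 2],
              co[1] + rects[i, 3], co[2] + rects[i, 4], card$patches[i, ])
  }

  # --- per-seed geometry ---
  n <- spec$n_seeds
  truth <- data.frame()
  if (n > 0) {
    a <- if (length(spec$a_mm) == n && n != 2) spec$a_mm
         else if (length(spec$a_mm) == 1) rep(spec$a_mm, n)
         else stats::runif(n, spec$a_mm[1], spec$a_mm[2])
    b <- if (length(spec$b_mm) == n && n != 2) spec$b_mm
         else if (length(spec$b_mm) == 1) rep(spec$b_mm, n)
         else stats::runif(n, spec$b_mm[1], spec$b_mm[2])
    bad <- b > a
    if (any(bad)) { tmp <- a[bad]; a[bad] <- b[bad]; b[bad] <- tmp }
    stopifnot(all(b > 0))
    ang <- if (is.null(spec$angle_deg)) stats::runif(n, 0, 180)
           else rep_len(spec$angle_deg, n)
    phase <- stats::runif(n, 0, 2 * pi)
    cols <- seed_base_colors(spec, n)

    # --- placement: rejection sampling outside the card, non-overlapping ---
    rad <- a * (1 + spec$roughness) + 0.6
    margin <- 2
    card_x <- co[1] + c(-margin, card$width_mm + margin)
    card_y <- co[2] + c(-margin, card$height_mm + margin)
    cx <- numeric(n); cy <- numeric(n)
    for (i in seq_len(n)) {
      ok <- FALSE
      for (try in 1:400) {
        x <- stats::runif(1, rad[i] + 1, spec$canvas_mm[1] - rad[i] - 1)
        y <- stats::runif(1, rad[i] + 1, spec$canvas_mm[2] - rad[i] - 1)
        in_card <- x + rad[i] > card_x[1] && x - rad[i] < card_x[2] &&
                   y + rad[i] > card_y[1] && y - rad[i] < card_y[2]
        if (in_card) next
        if (i > 1) {
          d <- sqrt((x - cx[seq_len(i - 1)])^2 + (y - cy[seq_len(i - 1)])^2)
          if (any(d < rad[i] + rad[seq_len(i - 1)])) next
        }
        cx[i] <- x; cy[i] <- y; ok <- TRUE; break
      }
      if (!ok) stop("could not place seed ", i,
                    " without overlap; reduce n_seeds or seed size")
    }

    # --- rasterize seeds ---
    amp <- spec$roughness; ko <- spec$rough_order
    for (i in seq_len(n)) {
      th <- ang[i] * pi / 180
      x0 <- max(1L, px(cx[i] - rad[i])); x1 <- min(w, px(cx[i] + rad[i]) + 1L)
      y0 <- max(1L, px(cy[i] - rad[i])); y1 <- min(h, px(cy[i] + rad[i]) + 1L)
      xs <- x0:x1; ys <- y0:y1
      # pixel-center mm coordinates
      xm <- (xs - 0.5) * spec$scale - cx[i]
      ym <- (ys - 0.5) * spec$scale - cy[i]
      U <- outer(xm,  ym * 0, "+") ; V <- outer(xm * 0, ym, "+")
      u <-  U * cos(th) + V * sin(th)
      v <- -U * sin(th) + V * cos(th)
      rho <- sqrt((u / a[i])^2 + (v / b[i])^2)
      inside <- if (amp > 0) {
        t <- atan2(v / b[i], u / a[i])
        rho <= 1 + amp * cos(ko * t + phase[i])
      } else rho <= 1
      sel <- which(inside, arr.ind = TRUE)
      if (nrow(sel) == 0) next
      ix <- xs[sel[, 1]]; iy <- ys[sel[, 2]]
      idx <- cbind(ix, iy)
      labels[idx] <- i
      for (k in 1:3) {
        pl <- img[, , k]
        pl[idx] <- cols[i, k] / 255
        img[, , k] <- pl
      }
    }

    truth <- data.frame(
      seed_id = seq_len(n), center_x_mm = cx, center_y_mm = cy,
      a_mm = a, b_mm = b, angle_deg = ang, roughness = amp,
      sL = 2 * a, sW = 2 * b, sA = pi * a * b * (1 + amp^2 / 2),
      base_R = cols[, 1], base_G = cols[, 2], base_B = cols[, 3]
    )
  }

  # --- global color cast in linearized RGB ---
  if (!is.null(spec$cast)) {
    lin <- srgb_to_linear(img)
    m <- matrix(lin, ncol = 3)
    m <- m %*% t(spec$cast)
    m <- sweep(m, 2, spec$cast_offset, "+")
    img <- array(linear_to_srgb(m), dim = dim(img))
  }

  # --- sensor noise ---
  if (spec$noise_sd > 0) {
    img <- img + array(stats::rnorm(length(img), 0, spec$noise_sd / 255),
                       dim = dim(img))
    img <- pmin(pmax(img, 0), 1)
  }

  list(image = img, truth = truth, labels = labels, spec = spec)
}

# default coat colors: wheat-like reddish brown with per-seed jitter
seed_base_colors <- function(spec, n) {
  if (!is.null(spec$base_rgb)) {
    m <- if (is.matrix(spec$base_rgb)) spec$base_rgb
         else matrix(spec$base_rgb, n, 3, byrow = TRUE)
    stopifnot(nrow(m) == n)
    return(m)
  }
  base <- c(156, 116, 74)
  j <- matrix(stats::runif(n * 3, -spec$color_jitter, spec$color_jitter), n, 3)
  round(pmin(pmax(sweep(j, 2, base, "+"), 0), 255))
}

#' Write a rendered scene to a PNG file
#'
#' @param scene result of [render_seed_image()]
#' @param path output PNG path
#' @return `path`, invisibly
#' @export
write_scene_png <- function(scene, path) {
  im <- EBImage::Image(scene$image, colormode = "Color")
  EBImage::writeImage(im, path, type = "png", bits.per.sample = 8L)
  invisible(path)
}

#' Read a scene image from PNG
#'
#' @param path PNG path
#' @return array width x height x 3 in `[0, 1]`
#' @export
read_scene_png <- function(path) {
  im <- EBImage::readImage(path)
  a <- EBImage::imageData(im)
  if (length(dim(a)) == 2) a <- array(rep(a, 3), dim = c(dim(a), 3))
  a[, , 1:3, drop = FALSE][, , 1:3]
}
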