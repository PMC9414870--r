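# Independent oracles and small fixture builders used across the suite.

# Ochiai index by explicit element-wise set arithmetic
brute_ochiai <- function(a, b) {
  a <- unique(a); b <- unique(b)
  if (length(a) == 0 || length(b) == 0) return(0)
  inter <- 0
  for (x in a) if (any(b == x)) inter <- inter + 1
  inter / sqrt(length(a) * length(b))
}

# single-marker LOD through R's likelihood machinery (independent of the
# scan's RSS-ratio code path)
lod_single_marker <- function(y, x) {
  keep <- !is.na(x) & !is.na(y)
  f1 <- stats::lm(y[keep] ~ x[keep])
  f0 <- stats::lm(y[keep] ~ 1)
  as.numeric(stats::logLik(f1) - stats::logLik(f0)) / log(10)
}

# brute-force prioritization cascade: explicit gene x QTL x filter loops
brute_candidates <- function(qtl, fx, tpm_min = 1) {
  rows <- list()
  for (i in seq_len(nrow(qtl))) {
    q <- qtl[i, ]
    if (q$lod <= 3) next
    ml <- fx$marker_coords[fx$marker_coords$marker == q$marker_left, ]
    mr <- fx$marker_coords[fx$marker_coords$marker == q$marker_right, ]
    if (!nrow(ml) || !nrow(mr)) next
    if (any(c(ml$chrom, mr$chrom) != q$chrom)) next
    s <- min(ml$start, mr$start); e <- max(ml$end, mr$end)
    cls <- seedqtl::trait_class(q$trait)
    tset <- if (cls == "color") fx$ko_color else fx$ko_size
    for (j in seq_len(nrow(fx$genes))) {
      g <- fx$genes[j, ]
      if (g$chrom != q$chrom) next
      if (g$end < s || g$start > e) next
      if (g$confidence != "high") next
      if (cls == "color") {
        tpm <- fx$expression$tpm[fx$expression$gene == g$gene_id &
                                   fx$expression$tissue == "seed"]
        if (!length(tpm) || max(tpm) < tpm_min) next
      }
      kos <- unique(fx$gene2ko$ko[fx$gene2ko$gene == g$gene_id])
      for (ko in kos[kos %in% tset$ko]) {
        rows[[length(rows) + 1]] <- paste(q$name, g$gene_id, ko)
      }
    }
  }
  sort(unique(unlist(rows)))
}

# rasterize a disk/ellipse mask and trace its contour into a seed_contour
shape_contour <- function(a_px, b_px = a_px, angle_deg = 0, pad = 10,
                          rough = 0, rough_order = 7, phase = 0.3) {
  r <- a_px * (1 + rough)
  w <- as.integer(2 * r + 2 * pad + 1)
  cx <- (w + 1) / 2
  xs <- seq_len(w) - cx
  th <- angle_deg * pi / 180
  U <- outer(xs, rep(1, w)) ; V <- outer(rep(1, w), xs)
  u <- U * cos(th) + V * sin(th)
  v <- -U * sin(th) + V * cos(th)
  rho <- sqrt((u / a_px)^2 + (v / b_px)^2)
  inside <- if (rough > 0) {
    t <- atan2(v / b_px, u / a_px)
    rho <= 1 + rough * cos(rough_order * t + phase)
  } else rho <= 1
  mask <- matrix(FALSE, w, w); mask[inside] <- TRUE
  ct <- EBImage::ocontour(EBImage::Image(mask))[[1]] + 1
  seedqtl::seed_contour(mask, ct)
}

# calibration object with unit scale for shape/size tests on raw masks
fake_calibration <- function(scale = 1) {
  structure(list(scale = scale, matrix = diag(3), offset = rep(0, 3),
                 card_bbox = c(1, 1, 2, 2), residual = 0),
            class = "color_calibration")
}

# a small QTL table suitable for prioritization fixtures
toy_qtl_table <- function() {
  data.frame(
    name = c("Q.sA-3A", "Q.Lab_mb-3B", "Q.sW-2D"),
    trait = c("sA", "Lab_mb", "sW"),
    chrom = c("3A", "3B", "2D"),
    pos = c(155, 299.179, 74),
    lod = c(5.1, 7.3, 4.2),
    marker_left = c("mkA_L", "mkB_L", "mkD_L"),
    marker_right = c("mkA_R", "mkB_R", "mkD_R"))
}
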