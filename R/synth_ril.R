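#' Haldane map distance to RIL recombination frequency
#'
#' Haldane's map function (no interference) gives the per-meiosis
#' recombination fraction `r = (1 - exp(-2 d / 100)) / 2` for a distance `d`
#' in cM; repeated selfing to fixation inflates observed recombination
#' between RIL genotypes to `R = 2 r / (1 + 2 r)`.
#'
#' @param d map distance in cM (vectorized)
#' @return observed RIL recombination frequency in `[0, 0.5)`
#' @export
ril_recomb <- function(d) {
  r <- (1 - exp(-2 * d / 100)) / 2
  2 * r / (1 + 2 * r)
}

#' Build a genetic map
#'
#' Default layout mimics a hexaploid wheat map: 21 chromosomes (1A..7D) with
#' evenly spaced markers. Chromosome lengths are spread over `length_range`
#' deterministically (they are a study condition, not a random draw).
#'
#' @param n_chrom number of chromosomes
#' @param spacing marker spacing in cM
#' @param length_range range of chromosome lengths in cM
#' @param chrom_names optional chromosome names
#' @return data.frame with `chrom`, `marker`, `pos` (cM), class `genetic_map`
#' @export
make_genetic_map <- function(n_chrom = 21, spacing = 5,
                             length_range = c(100, 300),
                             chrom_names = NULL) {
  if (is.null(chrom_names)) {
    wheat <- paste0(rep(1:7, each = 3), c("A", "B", "D"))
    chrom_names <- if (n_chrom <= 21) wheat[seq_len(n_chrom)]
    else paste0("chr", seq_len(n_chrom))
  }
  lens <- seq(length_range[1], length_range[2], length.out = n_chrom)
  lens <- round(lens / spacing) * spacing
  maps <- lapply(seq_len(n_chrom), function(i) {
    pos <- seq(0, lens[i], by = spacing)
    data.frame(chrom = chrom_names[i],
               marker = sprintf("m%s_%04d", chrom_names[i], pos),
               pos = pos)
  })
  out <- do.call(rbind, maps)
  class(out) <- c("genetic_map", "data.frame")
  out
}

#' Specify a RIL population simulation
#'
#' @param map a [make_genetic_map()]-style data.frame (`chrom`, `marker`,
#'   `pos`), positions strictly increasing within chromosome
#' @param n_lines number of recombinant inbred lines (>= 2)
#' @param qtl data.frame of planted additive QTLs: `chrom`, `pos`, `effect`
#'   (phenotype units for the +1 allele)
#' @param epi data.frame of planted epistatic pairs: `chrom1`, `pos1`,
#'   `chrom2`, `pos2`, `effect`
#' @param resid_sd residual standard deviation (>= 0)
#' @param missing_rate genotype missing rate in `[0, 1)`
#' @param seed integer RNG seed
#' @return object of class `ril_sim_spec`
#' @export
ril_sim_spec <- function(map = make_genetic_map(), n_lines = 114,
                         qtl = NULL, epi = NULL, resid_sd = 1,
                         missing_rate = 0, seed = 1L) {
  stopifnot(n_lines >= 2, resid_sd >= 0,
            missing_rate >= 0, missing_rate < 1)
  for (ch in unique(map$chrom)) {
    p <- map$pos[map$chrom == ch]
    if (any(diff(p) <= 0) && length(p) > 1)
      stop("marker positions must be strictly increasing on chromosome ", ch)
  }
  structure(list(map = map, n_lines = as.integer(n_lines), qtl = qtl,
                 epi = epi, resid_sd = resid_sd,
                 missing_rate = missing_rate, seed = as.integer(seed)),
            class = "ril_sim_spec")
}

#' Simulate selfed-RIL genotypes along a genetic map
#'
#' Each line is an independent realization of a two-state Markov chain per
#' chromosome: the first marker is +1/-1 with probability 1/2, and adjacent
#' markers at distance `d` cM disagree with probability [ril_recomb()]`(d)`.
#' Missing genotypes are masked completely at random at `missing_rate`; the
#' complete matrix is kept in the `"complete"` attribute for use as
#' simulation ground truth.
#'
#' @param spec a [ril_sim_spec()]
#' @return integer matrix lines x markers with entries +1/-1/NA, marker
#'   columns named as in the map, attribute `complete` holding the unmasked
#'   matrix
#' @export
simulate_ril_genotypes <- function(spec) {
  stopifnot(inherits(spec, "ril_sim_spec"))
  with_local_seed(spec$seed, {
    map <- spec$map
    n <- spec$n_lines
    geno <- matrix(NA_integer_, n, nrow(map),
                   dimnames = list(sprintf("RIL%03d", seq_len(n)),
                                   map$marker))
    for (ch in unique(map$chrom)) {
      j <- which(map$chrom == ch)
      g <- matrix(0L, n, length(j))
      g[, 1] <- sample(c(-1L, 1L), n, replace = TRUE)
      if (length(j) > 1) {
        R <- ril_recomb(diff(map$pos[j]))
        for (k in 2:length(j)) {
          flip <- stats::runif(n) < R[k - 1]
          g[, k] <- ifelse(flip, -g[, k - 1], g[, k - 1])
        }
      }
      geno[, j] <- g
    }
    complete <- geno
    if (spec$missing_rate > 0) {
      miss <- stats::runif(length(geno)) < spec$missing_rate
      geno[miss] <- NA_integer_
    }
    attr(geno, "complete") <- complete
    geno
  })
}

#' Simulate a phenotype with planted additive and epistatic QTLs
#'
#' `y = sum(a_q * x_q) + sum(e_p * x_p1 * x_p2) + N(0, resid_sd^2)` with
#' genotypes coded +1/-1. Each planted locus is snapped to the nearest marker
#' on its chromosome; a locus outside the chromosome's map extent is an
#' error. Missing genotypes at a QTL marker contribute 0 (the population
#' mean). The realized per-QTL percentage of variance explained is attached
#' as attribute `"pve"`.
#'
#' @param genotypes matrix from [simulate_ril_genotypes()] (the complete
#'   attribute is used if present)
#' @param spec the [ril_sim_spec()] holding `qtl`, `epi` and `resid_sd`
#' @param trait name for the simulated trait
#' @return data.frame `line`, `<trait>`; attributes `pve` (per planted term)
#' @export
simulate_phenotypes <- function(genotypes, spec, trait = "y") {
  stopifnot(inherits(spec, "ril_sim_spec"))
  g <- attr(genotypes, "complete")
  if (is.null(g)) g <- genotypes
  map <- spec$map
  n <- nrow(g)
  qtl_marker <- function(chrom, pos) {
    j <- which(map$chrom == chrom)
    if (!length(j)) stop("QTL chromosome not on map: ", chrom)
    p <- map$pos[j]
    if (pos < min(p) || pos > max(p))
      stop("QTL at ", chrom, ":", pos, " lies outside the map extent")
    j[which.min(abs(p - pos))]
  }
  with_local_seed(spec$seed + 1L, {
    genetic <- numeric(n)
    terms <- list()
    if (!is.null(spec$qtl) && nrow(spec$qtl)) {
      for (i in seq_len(nrow(spec$qtl))) {
        x <- g[, qtl_marker(spec$qtl$chrom[i], spec$qtl$pos[i])]
        x[is.na(x)] <- 0
        v <- spec$qtl$effect[i] * x
        genetic <- genetic + v
        terms[[paste0("qtl_", i)]] <- v
      }
    }
    if (!is.null(spec$epi) && nrow(spec$epi)) {
      for (i in seq_len(nrow(spec$epi))) {
        x1 <- g[, qtl_marker(spec$epi$chrom1[i], spec$epi$pos1[i])]
        x2 <- g[, qtl_marker(spec$epi$chrom2[i], spec$epi$pos2[i])]
        x1[is.na(x1)] <- 0; x2[is.na(x2)] <- 0
        v <- spec$epi$effect[i] * x1 * x2
        genetic <- genetic + v
        terms[[paste0("epi_", i)]] <- v
      }
    }
    y <- genetic + stats::rnorm(n, 0, spec$resid_sd)
    out <- data.frame(line = rownames(g), y = y)
    names(out)[2] <- trait
    vy <- stats::var(y)
    attr(out, "pve") <- vapply(terms, function(v)
      100 * stats::var(v) / vy, numeric(1))
    out
  })
}

#' Bundle map, genotypes and phenotypes into a RIL dataset
#'
#' @param map genetic map data.frame (`chrom`, `marker`, `pos`)
#' @param geno matrix lines x markers coded +1 (first parent) / -1 (second
#'   parent) / NA
#' @param pheno data.frame with `line` plus one numeric column per trait
#' @return object of class `ril_dataset`
#' @export
ril_dataset <- function(map, geno, pheno) {
  stopifnot(all(c("chrom", "marker", "pos") %in% names(map)),
            is.matrix(geno), "line" %in% names(pheno))
  if (!all(colnames(geno) == map$marker))
    stop("genotype columns must match map markers, in order")
  if (!all(pheno$line %in% rownames(geno)))
    stop("phenotype lines missing from genotype matrix")
  bad <- !(geno %in% c(-1L, 1L) | is.na(geno))
  if (any(bad)) stop("genotypes must be coded +1/-1/NA")
  structure(list(map = map, geno = geno, pheno = pheno),
            class = "ril_dataset")
}

#' Simulate a complete RIL dataset for one or more traits
#'
#' Convenience wrapper: simulates genotypes once and one phenotype per
#' element of `traits`, where each element is a list with optional `qtl`,
#' `epi` and `resid_sd` overriding the spec.
#'
#' @param spec a [ril_sim_spec()]
#' @param traits named list of per-trait specs (see details); default is a
#'   single trait from `spec` itself
#' @return a [ril_dataset()]; per-trait realized PVE in attribute `pve`
#' @export
simulate_ril_dataset <- function(spec, traits = NULL) {
  geno <- simulate_ril_genotypes(spec)
  if (is.null(traits)) traits <- list(y = list(qtl = spec$qtl,
                                               epi = spec$epi))
  pheno <- NULL
  pves <- list()
  for (i in seq_along(traits)) {
    tr <- names(traits)[i]
    sp <- spec
    sp$qtl <- traits[[i]]$qtl
    sp$epi <- traits[[i]]$epi
    if (!is.null(traits[[i]]$resid_sd)) sp$resid_sd <- traits[[i]]$resid_sd
    sp$seed <- spec$seed + i
    ph <- simulate_phenotypes(geno, sp, trait = tr)
    pves[[tr]] <- attr(ph, "pve")
    pheno <- if (is.null(pheno)) ph else merge(pheno, ph, by = "line")
  }
  ds <- ril_dataset(spec$map, geno, pheno)
  attr(ds, "pve") <- pves
  ds
}
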