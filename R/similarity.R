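#' Per-trait QTL locus sets
#'
#' Collapses a pooled QTL table into one set of locus keys per trait. Peak
#' positions are rounded to `digits` decimals; peaks on the same chromosome
#' whose rounded positions lie within `tolerance` cM of each other (chained
#' across traits) are unified to a single canonical key, so that traits
#' mapping to the same locus share a key.
#'
#' @param qtl_results data.frame with `trait`, `chrom`, `pos` (peak cM)
#' @param tolerance unification tolerance in cM (default 0: only identical
#'   rounded positions share a key)
#' @param digits rounding applied to positions before comparison
#' @param traits optional full trait list; traits without QTLs get empty sets
#' @return named list: trait -> character vector of canonical `chrom:pos`
#'   keys
#' @export
build_locus_sets <- function(qtl_results, tolerance = 0, digits = 3,
                             traits = NULL) {
  if (is.null(traits)) traits <- unique(qtl_results$trait)
  pos <- round(qtl_results$pos, digits)
  key <- rep(NA_character_, nrow(qtl_results))
  for (ch in unique(qtl_results$chrom)) {
    i <- which(qtl_results$chrom == ch)
    p <- sort(unique(pos[i]))
    # chain positions whose consecutive gaps are within tolerance
    grp <- cumsum(c(1, diff(p) > tolerance + 1e-12))
    canon <- stats::ave(p, grp, FUN = min)
    lab <- paste0(ch, ":", format(canon, trim = TRUE, scientific = FALSE))
    key[i] <- lab[match(pos[i], p)]
  }
  out <- lapply(traits, function(tr)
    sort(unique(key[qtl_results$trait == tr])))
  names(out) <- traits
  out
}

#' Ochiai index of two locus sets
#'
#' `|A intersect B| / sqrt(|A| |B|)`: 1 when the sets are identical, 0 when
#' they do not overlap; defined as 0 when either set is empty.
#'
#' @param a,b character vectors (sets; duplicates ignored)
#' @return index in `[0, 1]`
#' @export
ochiai <- function(a, b) {
  a <- unique(a); b <- unique(b)
  if (!length(a) || !length(b)) return(0)
  length(intersect(a, b)) / sqrt(length(a) * length(b))
}

#' Pairwise Ochiai similarity matrix over traits
#'
#' @param locus_sets named list from [build_locus_sets()]
#' @return symmetric numeric matrix with trait dimnames; the diagonal is 1
#'   for traits with at least one locus and 0 for empty sets
#' @export
trait_similarity <- function(locus_sets) {
  n <- length(locus_sets)
  nm <- names(locus_sets)
  m <- matrix(0, n, n, dimnames = list(nm, nm))
  for (i in seq_len(n)) for (j in i:n) {
    v <- ochiai(locus_sets[[i]], locus_sets[[j]])
    m[i, j] <- v; m[j, i] <- v
  }
  m
}

#' Cluster traits by QTL-location similarity
#'
#' Agglomerative clustering on distance `1 - Ochiai` with UPGMA (average)
#' linkage. Traits are ordered lexicographically before clustering so ties
#' are broken deterministically; traits with empty locus sets sit at
#' distance 1 from everything and attach last.
#'
#' @param similarity matrix from [trait_similarity()]
#' @param method linkage passed to [stats::hclust()]
#' @return list: `hclust`, `tree` (an ape phylo), `newick` (string with
#'   branch lengths), `leaf_order`
#' @export
cluster_traits <- function(similarity, method = "average") {
  ord <- order(rownames(similarity))
  sim <- similarity[ord, ord]
  d <- stats::as.dist(1 - sim)
  hc <- stats::hclust(d, method = method)
  tree <- ape::as.phylo(hc)
  list(hclust = hc, tree = tree,
       newick = ape::write.tree(tree),
       leaf_order = hc$labels[hc$order])
}
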