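#' Physical intervals for highly significant QTLs
#'
#' Converts QTLs with LOD above 3 to physical intervals using a marker
#' coordinate table (marker, chrom, start, end in bp, 1-based inclusive):
#' the interval spans from the smaller flanking-marker start to the larger
#' flanking-marker end. QTLs whose flanking markers are missing from the
#' table, or whose marker coordinates name a different chromosome than the
#' QTL (the alignment-went-elsewhere case), are skipped with a logged reason.
#'
#' @param qtl data.frame of QTL rows (`name`, `trait`, `chrom`, `pos`,
#'   `lod`, `marker_left`, `marker_right`)
#' @param marker_coords data.frame `marker`, `chrom`, `start`, `end`
#' @return data.frame of intervals (`qtl`, `trait`, `chrom`, `start`, `end`,
#'   flanking markers); skipped QTLs in attribute `"skipped"` with reasons
#' @export
qtl_to_interval <- function(qtl, marker_coords) {
  out <- list(); skipped <- list()
  log_skip <- function(name, reason)
    skipped[[length(skipped) + 1]] <<- data.frame(qtl = name,
                                                  reason = reason)
  for (i in seq_len(nrow(qtl))) {
    q <- qtl[i, ]
    if (q$lod <= 3) { log_skip(q$name, "LOD <= 3"); next }
    ml <- marker_coords[marker_coords$marker == q$marker_left, ]
    mr <- marker_coords[marker_coords$marker == q$marker_right, ]
    if (!nrow(ml) || !nrow(mr)) {
      log_skip(q$name, "flanking marker without physical coordinates"); next
    }
    if (any(c(ml$chrom, mr$chrom) != q$chrom)) {
      log_skip(q$name,
               "marker aligned to a different chromosome than the QTL"); next
    }
    out[[length(out) + 1]] <- data.frame(
      qtl = q$name, trait = q$trait, chrom = q$chrom,
      start = min(ml$start, mr$start), end = max(ml$end, mr$end),
      marker_left = q$marker_left, marker_right = q$marker_right)
  }
  res <- if (length(out)) do.call(rbind, c(out, make.row.names = FALSE))
  else data.frame(qtl = character(0), trait = character(0),
                  chrom = character(0), start = numeric(0), end = numeric(0),
                  marker_left = character(0), marker_right = character(0))
  attr(res, "skipped") <- if (length(skipped))
    do.call(rbind, c(skipped, make.row.names = FALSE))
  else data.frame(qtl = character(0), reason = character(0))
  res
}

#' High-confidence genes overlapping a physical interval
#'
#' Any overlap of at least 1 bp counts (1-based inclusive coordinates); only
#' genes whose `confidence` attribute equals `"high"` are returned.
#'
#' @param annotation a `GRanges` of genes (e.g. from [read_annotation()])
#'   with metadata columns `gene_id` and `confidence`
#' @param interval one-row data.frame with `chrom`, `start`, `end`
#' @return character vector of gene ids (empty, with a warning, for a
#'   chromosome absent from the annotation)
#' @export
genes_in_interval <- function(annotation, interval) {
  if (!interval$chrom %in% as.character(S4Vectors::runValue(
        GenomicRanges::seqnames(annotation)))) {
    warning("chromosome not in annotation: ", interval$chrom)
    return(character(0))
  }
  q <- GenomicRanges::GRanges(interval$chrom,
                              IRanges::IRanges(interval$start, interval$end))
  hits <- GenomicRanges::findOverlaps(annotation, q, minoverlap = 1L)
  g <- annotation[S4Vectors::queryHits(hits)]
  unique(g$gene_id[g$confidence == "high"])
}

#' Seed-expression filter
#'
#' Keeps genes whose TPM in at least one sample labelled with the seed
#' tissue reaches `tpm_min` (aggregation over seed samples is the maximum).
#' Genes absent from the expression table are treated as not expressed.
#' In the prioritization cascade this filter applies to color-trait QTLs
#' only.
#'
#' @param genes character vector of gene ids
#' @param expression data.frame `gene`, `sample`, `tissue`, `tpm`
#' @param tissue_label label marking seed samples
#' @param tpm_min minimum TPM
#' @return the subset of `genes` passing the filter
#' @export
filter_by_expression <- function(genes, expression, tissue_label = "seed",
                                 tpm_min = 1) {
  ex <- expression[expression$tissue == tissue_label &
                     expression$gene %in% genes, ]
  if (!nrow(ex)) return(character(0))
  mx <- tapply(ex$tpm, ex$gene, max)
  genes[genes %in% names(mx)[mx >= tpm_min]]
}

#' Match genes against target KEGG orthogroup sets
#'
#' A gene is a candidate if at least one of its KOs (a gene may carry several,
#' from different assignment sources) lies in the target set for the QTL's
#' trait class. Rows carry the KO annotation (description, EC, pathway) from
#' the target table.
#'
#' @param genes character vector of gene ids
#' @param gene2ko data.frame `gene`, `ko`
#' @param targets data.frame of target KOs for the relevant trait class:
#'   `ko`, `description`, `ec`, and for color sets `pathway_id`,
#'   `pathway_desc`
#' @return data.frame `gene`, `ko` plus annotation columns (zero rows if no
#'   match)
#' @export
match_orthogroups <- function(genes, gene2ko, targets) {
  g2k <- unique(gene2ko[gene2ko$gene %in% genes, c("gene", "ko")])
  m <- merge(g2k, targets, by = "ko")
  m <- m[order(m$gene, m$ko), c("gene", setdiff(names(m), "gene"))]
  rownames(m) <- NULL
  m
}

#' Full candidate-gene prioritization cascade
#'
#' For every QTL with LOD above 3: convert to a physical interval, list
#' high-confidence genes overlapping it, for color-trait QTLs keep only
#' genes expressed in seed tissue (TPM >= `tpm_min`), and keep genes whose
#' KEGG orthogroup is in the target set of the QTL's trait class.
#'
#' @param qtl pooled QTL table (as from [scan_traits()], with `name`)
#' @param marker_coords marker physical coordinate table
#' @param annotation gene `GRanges` (see [read_annotation()])
#' @param expression expression table (`gene`, `sample`, `tissue`, `tpm`)
#' @param gene2ko gene-to-KO table
#' @param ko_size,ko_color target KO tables for size/shape and color traits
#' @param tpm_min seed-expression threshold
#' @param tissue_label tissue label marking seed samples
#' @param expression_classes trait classes the expression filter applies to
#' @return `candidate_gene_table`: one row per (QTL, gene, KO) with
#'   annotation columns; skipped QTLs in attribute `"skipped"`
#' @export
prioritize_candidates <- function(qtl, marker_coords, annotation, expression,
                                  gene2ko, ko_size, ko_color, tpm_min = 1,
                                  tissue_label = "seed",
                                  expression_classes = "color") {
  iv <- qtl_to_interval(qtl, marker_coords)
  rows <- list()
  for (i in seq_len(nrow(iv))) {
    cls <- trait_class(iv$trait[i])
    genes <- genes_in_interval(annotation, iv[i, ])
    if (cls %in% expression_classes)
      genes <- filter_by_expression(genes, expression,
                                    tissue_label = tissue_label,
                                    tpm_min = tpm_min)
    targets <- if (cls == "color") ko_color else ko_size
    m <- match_orthogroups(genes, gene2ko, targets)
    for (col in c("description", "ec", "pathway_id", "pathway_desc"))
      if (!col %in% names(m)) m[[col]] <- rep(NA_character_, nrow(m))
    m <- m[, c("gene", "ko", "description", "ec", "pathway_id",
               "pathway_desc")]
    if (nrow(m)) {
      rows[[length(rows) + 1]] <- cbind(
        qtl = iv$qtl[i], trait = iv$trait[i], trait_class = cls,
        chrom = iv$chrom[i], start = iv$start[i], end = iv$end[i], m)
    }
  }
  out <- if (length(rows)) do.call(rbind, c(rows, make.row.names = FALSE))
  else data.frame(qtl = character(0), trait = character(0),
                  trait_class = character(0), chrom = character(0),
                  start = numeric(0), end = numeric(0), gene = character(0),
                  ko = character(0))
  attr(out, "skipped") <- attr(iv, "skipped")
  class(out) <- c("candidate_gene_table", "data.frame")
  out
}
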