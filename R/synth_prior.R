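#' Target KEGG orthogroup tables bundled with the synthetic fixtures
#'
#' Two small curated tables: orthogroups from the eight pigment-biosynthesis
#' pathways (tryptophan metabolism through flavone and flavonol biosynthesis)
#' for seed coat color, and orthogroups of seed-development regulators
#' (transcription factors, ubiquitination enzymes, translation initiation
#' factors, chitinases, ...) for seed size/shape.
#'
#' @return list with data.frames `size` (`ko`, `description`, `ec`) and
#'   `color` (`ko`, `description`, `ec`, `pathway_id`, `pathway_desc`)
#' @export
target_ko_sets <- function() {
  size <- data.frame(
    ko = c("K09286", "K09338", "K09422", "K11593", "K19045", "K09602",
           "K20547", "K00279", "K08869"),
    description = c(
      "EREBP; EREBP-like factor",
      "HD-ZIP; homeobox-leucine zipper protein",
      "MYBP; transcription factor MYB, plant",
      "ELF2C, AGO; eukaryotic translation initiation factor 2C",
      "BB; E3 ubiquitin-protein ligase BIG BROTHER and related proteins",
      "OTUB1; ubiquitin thioesterase protein OTUB1",
      "CHIB; basic endochitinase B",
      "CKX; cytokinin dehydrogenase",
      "ADCK, ABC1; aarF domain-containing kinase"),
    ec = c("-", "-", "-", "-", "EC:2.3.2.27", "EC:3.4.19.12",
           "EC:3.2.1.14", "EC:1.5.99.12", "-"))
  pathways <- data.frame(
    pathway_id = c("map00380", "map00900", "map00906", "map00940",
                   "map00941", "map00942", "map00943", "map00944"),
    pathway_desc = c("Tryptophan metabolism",
                     "Terpenoid backbone biosynthesis",
                     "Carotenoid biosynthesis",
                     "Phenylpropanoid biosynthesis",
                     "Flavonoid biosynthesis",
                     "Anthocyanin biosynthesis",
                     "Isoflavonoid biosynthesis",
                     "Flavone and flavonol biosynthesis"))
  color <- data.frame(
    ko = c("K13066", "K00021", "K09840", "K09843", "K01904", "K12355",
           "K00430", "K13065", "K90942", "K90943", "K22772"),
    description = c(
      "COMT; caffeic acid 3-O-methyltransferase",
      "HMGCR; hydroxymethylglutaryl-CoA reductase (NADPH)",
      "NCED; 9-cis-epoxycarotenoid dioxygenase",
      "CYP707A; (+)-abscisic acid 8'-hydroxylase",
      "4CL; 4-coumarate--CoA ligase",
      "REF1; coniferyl-aldehyde dehydrogenase",
      "peroxidase",
      "HCT; shikimate O-hydroxycinnamoyltransferase",
      "synthetic anthocyanin-pathway orthogroup",
      "synthetic isoflavonoid-pathway orthogroup",
      "FG2; flavonol-3-O-glucoside L-rhamnosyltransferase"),
    ec = c("EC:2.1.1.68", "EC:1.1.1.34", "EC:1.13.11.51", "EC:1.14.14.137",
           "EC:6.2.1.12", "EC:1.2.1.68", "EC:1.11.1.7", "EC:2.3.1.133",
           "-", "-", "EC:2.4.1.159"),
    pathway_id = c("map00380", "map00900", "map00906", "map00906",
                   "map00940", "map00940", "map00940", "map00941",
                   "map00942", "map00943", "map00944"))
  color <- merge(color, pathways, by = "pathway_id")
  color <- color[, c("ko", "description", "ec", "pathway_id", "pathway_desc")]
  color <- color[order(color$ko), ]
  rownames(color) <- NULL
  list(size = size, color = color)
}

#' Generate a synthetic gene-prioritization fixture
#'
#' Builds, for a table of (highly significant) QTLs, a complete set of
#' prioritization inputs with known answers: marker physical coordinates
#' defining one disjoint ~2 Mb interval per QTL, a GFF3 gene annotation, a
#' seed/leaf expression table, a gene-to-KO table and the target KO sets.
#' Each QTL receives `n_planted` candidate genes that pass every filter, and
#' one decoy per failure mode, each failing exactly one filter: outside the
#' interval, low annotation confidence, seed TPM below 1 (color QTLs only),
#' or a KO absent from both target sets. All content is synthetic and
#' deterministic given `seed`.
#'
#' @param qtl QTL table (`name`, `trait`, `chrom`, `pos`, `lod`,
#'   `marker_left`, `marker_right`); only rows with LOD > 3 are used
#' @param dir output directory; created. Set NULL to skip writing files.
#' @param n_planted planted candidates per QTL (0 allowed)
#' @param seed RNG seed for coordinate jitter
#' @return list with all tables (`marker_coords`, `annotation` as GRanges,
#'   `expression`, `gene2ko`, `ko_size`, `ko_color`), the `planted` and
#'   `decoys` manifests, and `paths` when files were written
#' @export
make_prior_fixture <- function(qtl, dir = NULL, n_planted = 1, seed = 1L) {
  q <- qtl[qtl$lod > 3, , drop = FALSE]
  targets <- target_ko_sets()
  with_local_seed(seed, {
    mc <- list(); genes <- list(); g2k <- list(); expr <- list()
    planted <- list(); decoys <- list()
    add_gene <- function(id, chrom, start, width, conf, ko, seed_tpm) {
      genes[[length(genes) + 1]] <<- data.frame(
        gene_id = id, chrom = chrom, start = start,
        end = start + width - 1, confidence = conf)
      if (!is.na(ko))
        g2k[[length(g2k) + 1]] <<- data.frame(gene = id, ko = ko)
      expr[[length(expr) + 1]] <<- data.frame(
        gene = id,
        sample = c("seed_rep1", "seed_rep2", "leaf_rep1"),
        tissue = c("seed", "seed", "leaf"),
        tpm = c(seed_tpm, round(seed_tpm * 0.8, 3), 0.2))
    }
    rank_on_chrom <- stats::ave(seq_len(nrow(q)), q$chrom,
                                FUN = seq_along)
    for (i in seq_len(nrow(q))) {
      cls <- trait_class(q$trait[i])
      tset <- if (cls == "color") targets$color else targets$size
      s <- 1e6 + (rank_on_chrom[i] - 1) * 5e6
      e <- s + 2e6
      mc[[length(mc) + 1]] <- data.frame(
        marker = c(q$marker_left[i], q$marker_right[i]),
        chrom = q$chrom[i],
        start = c(s, e - 5e4), end = c(s + 5e4, e))
      gid <- function(k) sprintf("SYNG_%s_%02d_%02d", q$chrom[i], i, k)
      if (n_planted > 0) {
        for (k in seq_len(n_planted)) {
          ko <- tset$ko[(i + k - 2) %% nrow(tset) + 1]
          pos <- s + 2e5 + (k - 1) * 5e4 + sample.int(1e4, 1)
          add_gene(gid(k), q$chrom[i], pos, 3000, "high", ko, 5.2)
          planted[[length(planted) + 1]] <- data.frame(
            qtl = q$name[i], gene = gid(k), ko = ko, trait_class = cls)
        }
      }
      ko1 <- tset$ko[(i - 1) %% nrow(tset) + 1]
      dec <- function(id, reason) decoys[[length(decoys) + 1]] <<-
        data.frame(qtl = q$name[i], gene = id, reason = reason)
      add_gene(gid(90), q$chrom[i], s - 4e5, 3000, "high", ko1, 5.2)
      dec(gid(90), "outside interval")
      add_gene(gid(91), q$chrom[i], s + 8e5, 3000, "low", ko1, 5.2)
      dec(gid(91), "low confidence")
      if (cls == "color") {
        add_gene(gid(92), q$chrom[i], s + 9e5, 3000, "high", ko1, 0.5)
        dec(gid(92), "seed TPM below threshold")
      }
      add_gene(gid(93), q$chrom[i], s + 1e6, 3000, "high", "K99999", 5.2)
      dec(gid(93), "KO not in target sets")
    }
    gene_df <- do.call(rbind, genes)
    annotation <- GenomicRanges::GRanges(
      gene_df$chrom,
      IRanges::IRanges(gene_df$start, gene_df$end),
      type = "gene", ID = gene_df$gene_id,
      gene_id = gene_df$gene_id, confidence = gene_df$confidence)
    mcdf <- do.call(rbind, c(mc, make.row.names = FALSE))
    mcdf <- mcdf[!duplicated(mcdf$marker), ]
    out <- list(
      marker_coords = mcdf,
      annotation = annotation,
      genes = gene_df,
      expression = do.call(rbind, c(expr, make.row.names = FALSE)),
      gene2ko = do.call(rbind, c(g2k, make.row.names = FALSE)),
      ko_size = targets$size, ko_color = targets$color,
      planted = if (length(planted))
        do.call(rbind, c(planted, make.row.names = FALSE))
      else data.frame(qtl = character(0), gene = character(0),
                      ko = character(0), trait_class = character(0)),
      decoys = do.call(rbind, c(decoys, make.row.names = FALSE)))
    if (!is.null(dir)) {
      dir.create(dir, showWarnings = FALSE, recursive = TRUE)
      paths <- c(
        marker_coords = file.path(dir, "marker_coords.tsv"),
        annotation = file.path(dir, "annotation.gff3"),
        expression = file.path(dir, "expression.tsv"),
        gene2ko = file.path(dir, "gene2ko.tsv"),
        ko_size = file.path(dir, "ko_targets_size.tsv"),
        ko_color = file.path(dir, "ko_targets_color.tsv"),
        manifest = file.path(dir, "manifest.json"))
      write_tsv(out$marker_coords, paths["marker_coords"])
      export_gene_gff3(gene_df, paths["annotation"])
      write_tsv(out$expression, paths["expression"])
      write_tsv(out$gene2ko, paths["gene2ko"])
      write_tsv(out$ko_size, paths["ko_size"])
      write_tsv(out$ko_color, paths["ko_color"])
      jsonlite::write_json(list(planted = out$planted,
                                decoys = out$decoys),
                           paths["manifest"], pretty = TRUE)
      out$paths <- paths
    }
    out
  })
}

# write a minimal valid GFF3 (1-based inclusive) for synthetic genes
export_gene_gff3 <- function(gene_df, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  writeLines(sprintf(
    "%s\tsynthetic\tgene\t%d\t%d\t.\t+\t.\tID=%s;confidence=%s",
    gene_df$chrom, as.integer(gene_df$start), as.integer(gene_df$end),
    gene_df$gene_id, gene_df$confidence), con)
  invisible(path)
}
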