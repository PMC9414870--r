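#' Tab-separated I/O helpers
#'
#' Plain TSV with a header, no quoting and no row names; used for all tabular
#' artifacts (maps, genotypes, phenotypes, traits, scan results, fixtures) so
#' that reruns are byte-identical.
#'
#' @param x data.frame
#' @param path file path
#' @return `path` invisibly
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Read a RIL dataset from TSV files
#'
#' The genotype file has one row per line (first column `line`) and one
#' column per marker, coded `A` (first parent), `B` (second parent) or `NA`;
#' internally A/B become +1/-1.
#'
#' @param map_path TSV `chrom`, `marker`, `pos`
#' @param geno_path genotype TSV as described
#' @param pheno_path TSV `line` plus one column per trait
#' @return a [ril_dataset()]
#' @export
read_ril_dataset <- function(map_path, geno_path, pheno_path) {
  map <- read_tsv(map_path)
  g <- read_tsv(geno_path)
  lines <- g$line
  gm <- as.matrix(g[, -1, drop = FALSE])
  geno <- matrix(NA_integer_, nrow(gm), ncol(gm),
                 dimnames = list(lines, colnames(gm)))
  geno[gm == "A"] <- 1L
  geno[gm == "B"] <- -1L
  bad <- !(gm %in% c("A", "B")) & !is.na(gm) & gm != "NA"
  if (any(bad)) stop("invalid genotype codes: ",
                     paste(unique(gm[bad]), collapse = ", "))
  ril_dataset(map, geno, read_tsv(pheno_path))
}

#' Write a RIL dataset to TSV files
#'
#' @param dataset a [ril_dataset()]
#' @param dir output directory (created if needed)
#' @return named vector of paths
#' @export
write_ril_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- c(map = file.path(dir, "map.tsv"),
         geno = file.path(dir, "genotypes.tsv"),
         pheno = file.path(dir, "phenotypes.tsv"))
  write_tsv(dataset$map, p["map"])
  g <- dataset$geno
  codes <- matrix("NA", nrow(g), ncol(g), dimnames = dimnames(g))
  codes[!is.na(g) & g == 1] <- "A"
  codes[!is.na(g) & g == -1] <- "B"
  write_tsv(data.frame(line = rownames(g), codes, check.names = FALSE),
            p["geno"])
  write_tsv(dataset$pheno, p["pheno"])
  p
}

#' Read a gene annotation GFF3 into a gene GRanges
#'
#' Keeps `gene` features; `gene_id` is taken from the `ID` attribute and the
#' `confidence` attribute ("high"/"low") is preserved.
#'
#' @param path GFF3 path (1-based inclusive coordinates)
#' @return `GRanges` with metadata columns `gene_id`, `confidence`
#' @export
read_annotation <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type == "gene"]
  mc <- S4Vectors::mcols(gr)
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    gene_id = as.character(mc$ID),
    confidence = as.character(mc$confidence))
  gr
}
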