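#' Default pipeline configuration
#'
#' All analysis thresholds default to the published protocol values: 1 cM
#' additive walking speed, LOD > 2 / > 3 significance classes, 5 cM epistasis
#' grid with LOD >= 5 and PVE >= 5% report filters, 3-sigma outlier exclusion
#' and k = 3 dominant-color clusters, TPM >= 1 seed-expression threshold,
#' 2 mm^2 segmentation minimum area, and exact-position locus unification.
#' The synthetic study sizes (114 lines, 21 chromosomes, two images of 15
#' and 5 seeds) mirror the emulated experiment; the demo defaults are scaled
#' down where noted in the configuration itself.
#'
#' @return nested named list; serialize with [yaml::write_yaml()]
#' @export
default_config <- function() {
  list(
    seed = 1L,
    stages = list(simulate = TRUE, phenotype = TRUE, scan = TRUE,
                  similarity = TRUE, prioritize = TRUE),
    images = list(n_genotypes = 2L, seeds_per_image = c(15L, 5L),
                  scale = 0.1, noise_sd = 2),
    ril = list(n_lines = 114L, n_chrom = 21L, spacing = 5,
               length_range = c(100, 300), missing_rate = 0.02,
               resid_sd = 1),
    planted = list(
      qtl = list(trait = "sim_add", chrom = "3B", pos = 40, pve = 20),
      epi = list(trait = "sim_epi", chrom1 = "3A", pos1 = 40,
                 chrom2 = "3D", pos2 = 60, pve = 15)),
    scan = list(step = 1, lod_sig = 2, lod_high = 3, merge_cM = 10,
                p_entry = 0.001, p_exit = 0.002,
                epi_step = 5, epi_lod_min = 5, epi_pve_min = 5,
                epi_min_gap = 20),
    phenotyping = list(min_area_mm2 = 2, k_clusters = 3L, sd_mult = 3),
    similarity = list(tolerance = 0, digits = 3, linkage = "average"),
    prioritize = list(tpm_min = 1, tissue_label = "seed",
                      n_planted = 1L, expression_classes = "color")
  )
}

#' Run the full synthetic-study pipeline
#'
#' Orchestrates the five stages on synthetic data: (1) render seed images
#' and simulate a RIL population with one planted additive QTL, one planted
#' epistatic pair and one pure-noise trait; (2) phenotype the rendered
#' images; (3) additive and epistasis QTL scans; (4) trait clustering by
#' QTL-location overlap; (5) candidate-gene prioritization against a planted
#' fixture. Every output is written to `out_dir` as TSV/Newick/JSON, and a
#' manifest with MD5 checksums of all outputs is written last. Outputs are
#' deterministic given the config seed.
#'
#' @param config a [default_config()]-style list, or a YAML file path
#' @param out_dir run directory (created)
#' @return invisibly, a list with the main in-memory results and the
#'   manifest
#' @export
run_pipeline <- function(config = default_config(), out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(default_config(), config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  logf <- function(...) cat(sprintf(...), "\n", sep = "",
                            file = log_path, append = TRUE)
  cat("", file = log_path)
  yaml::write_yaml(cfg, file.path(out_dir, "config.yaml"))
  outputs <- character(0)
  note <- function(p) outputs <<- c(outputs, p)
  res <- list(config = cfg)

  stage <- function(name, expr) {
    logf("[%s] start", name)
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  # ---- stage 1+2: images and phenotyping ----
  if (cfg$stages$phenotype) {
    traits_tab <- stage("phenotype", {
      sets <- list()
      for (g in seq_len(cfg$images$n_genotypes)) {
        imgs <- lapply(seq_along(cfg$images$seeds_per_image), function(k)
          render_seed_image(scene_spec(
            n_seeds = cfg$images$seeds_per_image[k],
            scale = cfg$images$scale, noise_sd = cfg$images$noise_sd,
            seed = cfg$seed + 1000L * g + k))$image)
        sets[[sprintf("GT%02d", g)]] <- imgs
      }
      phenotype_population(sets,
                           min_area_mm2 = cfg$phenotyping$min_area_mm2,
                           k = cfg$phenotyping$k_clusters,
                           sd_mult = cfg$phenotyping$sd_mult)
    })
    note(write_tsv(round_df(traits_tab, 4),
                   file.path(out_dir, "traits.tsv")))
    res$traits <- traits_tab
    logf("[phenotype] %d genotypes, 55 descriptors", nrow(traits_tab))
  }

  # ---- stage 1+3: RIL simulation and scans ----
  if (cfg$stages$scan) {
    map <- make_genetic_map(cfg$ril$n_chrom, cfg$ril$spacing,
                            cfg$ril$length_range)
    a_eff <- pve_to_effect(cfg$planted$qtl$pve, cfg$ril$resid_sd)
    e_eff <- pve_to_effect(cfg$planted$epi$pve, cfg$ril$resid_sd)
    spec <- ril_sim_spec(map, n_lines = cfg$ril$n_lines,
                         resid_sd = cfg$ril$resid_sd,
                         missing_rate = cfg$ril$missing_rate,
                         seed = cfg$seed)
    traits <- list()
    traits[[cfg$planted$qtl$trait]] <- list(
      qtl = data.frame(chrom = cfg$planted$qtl$chrom,
                       pos = cfg$planted$qtl$pos, effect = a_eff))
    traits[[cfg$planted$epi$trait]] <- list(
      epi = data.frame(chrom1 = cfg$planted$epi$chrom1,
                       pos1 = cfg$planted$epi$pos1,
                       chrom2 = cfg$planted$epi$chrom2,
                       pos2 = cfg$planted$epi$pos2, effect = e_eff))
    traits[["sim_noise"]] <- list()
    ds <- stage("simulate", simulate_ril_dataset(spec, traits))
    note(write_ril_dataset(ds, file.path(out_dir, "ril")))
    qtl <- stage("scan", scan_traits(
      ds, step = cfg$scan$step, lod_sig = cfg$scan$lod_sig,
      lod_high = cfg$scan$lod_high, merge_cM = cfg$scan$merge_cM,
      p_entry = cfg$scan$p_entry, p_exit = cfg$scan$p_exit))
    epi <- stage("scan", epistasis_scan(
      ds, cfg$planted$epi$trait, step = cfg$scan$epi_step,
      lod_min = cfg$scan$epi_lod_min, pve_min = cfg$scan$epi_pve_min,
      min_gap_cM = cfg$scan$epi_min_gap,
      p_entry = cfg$scan$p_entry, p_exit = cfg$scan$p_exit))
    note(write_tsv(round_df(qtl, 4), file.path(out_dir, "qtl.tsv")))
    note(write_tsv(round_df(epi, 4), file.path(out_dir, "epistasis.tsv")))
    res$dataset <- ds; res$qtl <- qtl; res$epi <- epi
    logf("[scan] %d additive QTLs, %d epistatic pairs",
         nrow(qtl), nrow(epi))
  }

  # ---- stage 4: similarity ----
  if (cfg$stages$similarity && !is.null(res$qtl) && nrow(res$qtl)) {
    sim <- stage("similarity", {
      ls <- build_locus_sets(res$qtl, tolerance = cfg$similarity$tolerance,
                             digits = cfg$similarity$digits,
                             traits = setdiff(names(res$dataset$pheno),
                                              "line"))
      list(sets = ls, matrix = trait_similarity(ls),
           clust = cluster_traits(trait_similarity(ls),
                                  method = cfg$similarity$linkage))
    })
    note(write_tsv(cbind(trait = rownames(sim$matrix),
                         round_df(as.data.frame(sim$matrix), 6)),
                   file.path(out_dir, "ochiai.tsv")))
    writeLines(sim$clust$newick, file.path(out_dir, "tree.nwk"))
    note(file.path(out_dir, "tree.nwk"))
    res$similarity <- sim
    logf("[similarity] %d traits clustered", nrow(sim$matrix))
  }

  # ---- stage 5: prioritization ----
  if (cfg$stages$prioritize && !is.null(res$qtl)) {
    hs <- res$qtl[res$qtl$lod > 3, , drop = FALSE]
    cand <- stage("prioritize", {
      if (!nrow(hs)) {
        empty <- data.frame()
        attr(empty, "planted") <- data.frame()
        empty
      } else {
        fx <- make_prior_fixture(hs, dir = file.path(out_dir, "fixture"),
                                 n_planted = cfg$prioritize$n_planted,
                                 seed = cfg$seed + 7L)
        cc <- prioritize_candidates(
          hs, fx$marker_coords, fx$annotation, fx$expression, fx$gene2ko,
          fx$ko_size, fx$ko_color, tpm_min = cfg$prioritize$tpm_min,
          tissue_label = cfg$prioritize$tissue_label,
          expression_classes = cfg$prioritize$expression_classes)
        attr(cc, "planted") <- fx$planted
        cc
      }
    })
    note(write_tsv(as.data.frame(cand), file.path(out_dir,
                                                  "candidates.tsv")))
    res$candidates <- cand
    logf("[prioritize] %d candidate rows", nrow(cand))
  }

  manifest <- list(
    config = cfg,
    outputs = lapply(stats::setNames(outputs, basename(outputs)),
                     function(p) unname(tools::md5sum(p))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       pretty = TRUE, auto_unbox = TRUE)
  res$manifest <- manifest
  logf("done")
  invisible(res)
}

# additive/interaction effect giving a requested PVE (%), coded +1/-1
# genotypes: PVE = a^2 / (a^2 + sd^2)
pve_to_effect <- function(pve, resid_sd) {
  f <- pve / 100
  resid_sd * sqrt(f / (1 - f))
}

round_df <- function(df, digits) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round, digits)
  df
}

#' Validate pipeline input files
#'
#' Schema checks that never mutate anything: RIL genotype codes must be
#' A/B/NA, map positions must be strictly increasing within chromosome,
#' phenotypes numeric, GFF3 lines well-formed with start <= end. Violations
#' are reported with file and line numbers; clean inputs give a zero-row
#' report.
#'
#' @param paths named list/vector with any of `map`, `geno`, `pheno`, `gff3`
#' @return data.frame `file`, `line`, `problem`
#' @export
validate_inputs <- function(paths) {
  rep <- list()
  add <- function(file, line, problem)
    rep[[length(rep) + 1]] <<- data.frame(file = file, line = line,
                                          problem = problem)
  if (!is.null(paths$map)) {
    map <- read_tsv(paths$map)
    if (!all(c("chrom", "marker", "pos") %in% names(map))) {
      add(paths$map, 1, "map needs columns chrom, marker, pos")
    } else {
      for (ch in unique(map$chrom)) {
        i <- which(map$chrom == ch)
        bad <- which(diff(map$pos[i]) <= 0)
        for (b in bad)
          add(paths$map, i[b + 1] + 1,
              sprintf("cM not strictly increasing on chromosome %s", ch))
      }
    }
  }
  if (!is.null(paths$geno)) {
    g <- utils::read.delim(paths$geno, colClasses = "character",
                           check.names = FALSE)
    gm <- as.matrix(g[, -1, drop = FALSE])
    bad <- which(!(gm %in% c("A", "B", "NA", "")) & !is.na(gm))
    for (b in unique((bad - 1) %% nrow(gm) + 1))
      add(paths$geno, b + 1,
          sprintf("invalid genotype code(s): RIL matrix admits only A/B/NA"))
  }
  if (!is.null(paths$pheno)) {
    ph <- read_tsv(paths$pheno)
    for (cn in setdiff(names(ph), "line"))
      if (!is.numeric(ph[[cn]]))
        add(paths$pheno, 1, sprintf("phenotype column '%s' not numeric", cn))
  }
  if (!is.null(paths$gff3)) {
    ln <- readLines(paths$gff3)
    for (i in seq_along(ln)) {
      if (startsWith(ln[i], "#") || !nzchar(ln[i])) next
      f <- strsplit(ln[i], "\t", fixed = TRUE)[[1]]
      if (length(f) != 9) { add(paths$gff3, i, "GFF3 line not 9 fields"); next }
      s <- suppressWarnings(as.numeric(f[4])); e <- suppressWarnings(as.numeric(f[5]))
      if (is.na(s) || is.na(e) || s > e)
        add(paths$gff3, i, "GFF3 start/end invalid")
    }
  }
  if (length(rep)) do.call(rbind, c(rep, make.row.names = FALSE))
  else data.frame(file = character(0), line = integer(0),
                  problem = character(0))
}
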