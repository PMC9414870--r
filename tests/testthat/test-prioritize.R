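# QTL physical intervals, gene filters, and the full prioritization cascade.

test_that("intervals span the outer bounds of the flanking markers", {
  qtl <- data.frame(name = "Q.sA-3D", trait = "sA", chrom = "3D",
                    pos = 100, lod = 4,
                    marker_left = "mL", marker_right = "mR")
  mc <- data.frame(marker = c("mL", "mR"), chrom = "3D",
                   start = c(1.0e6, 2.5e6), end = c(1.2e6, 2.6e6))
  iv <- qtl_to_interval(qtl, mc)
  expect_equal(iv$start, 1.0e6)
  expect_equal(iv$end, 2.6e6)
  expect_equal(iv$chrom, "3D")
})

test_that("wrong-chromosome alignments and weak QTLs are skipped with reasons", {
  qtl <- data.frame(
    name = c("Q.a-3D", "Q.b-3D", "Q.c-3D"),
    trait = c("sA", "sA", "sA"), chrom = "3D", pos = c(10, 20, 30),
    lod = c(4, 4, 2.8),
    marker_left = c("w1", "m1", "m1"), marker_right = c("w2", "m2", "m2"))
  mc <- data.frame(marker = c("w1", "w2", "m1", "m2"),
                   chrom = c("5A", "3D", "3D", "3D"),
                   start = c(1e6, 2e6, 1e6, 2e6),
                   end = c(1.1e6, 2.1e6, 1.1e6, 2.1e6))
  iv <- qtl_to_interval(qtl, mc)
  expect_equal(iv$qtl, "Q.b-3D")
  sk <- attr(iv, "skipped")
  expect_match(sk$reason[sk$qtl == "Q.a-3D"], "different chromosome")
  expect_match(sk$reason[sk$qtl == "Q.c-3D"], "LOD")
})

test_that("gene-interval overlap is any-overlap and confidence-filtered", {
  ann <- GenomicRanges::GRanges(
    "3D", IRanges::IRanges(c(1500, 900, 2000, 5000), width = c(200, 101, 300, 10)),
    gene_id = c("inside", "edge", "lowconf", "outside"),
    confidence = c("high", "high", "low", "high"))
  iv <- data.frame(chrom = "3D", start = 1000, end = 3000)
  got <- genes_in_interval(ann, iv)
  expect_setequal(got, c("inside", "edge"))  # edge overlaps by exactly 1 bp
  expect_warning(g2 <- genes_in_interval(ann, data.frame(chrom = "9Z",
                                                         start = 1,
                                                         end = 10)),
                 "not in annotation")
  expect_length(g2, 0)
})

test_that("the seed expression filter keeps TPM >= 1 in seed tissue only", {
  expr <- data.frame(
    gene = c("g1", "g1", "g2", "g2", "g3"),
    sample = c("s1", "leaf1", "s1", "s2", "leaf1"),
    tissue = c("seed", "leaf", "seed", "seed", "leaf"),
    tpm = c(5.2, 100, 0.5, 0.9, 50))
  expect_equal(filter_by_expression(c("g1", "g2", "g3", "g4"), expr), "g1")
  # exactly at the threshold passes
  expr$tpm[3] <- 1
  expect_setequal(filter_by_expression(c("g1", "g2"), expr), c("g1", "g2"))
})

test_that("orthogroup matching keeps only target KOs", {
  g2k <- data.frame(gene = c("g1", "g2", "g2", "g3"),
                    ko = c("K01904", "K99999", "K09286", "K77777"))
  targets <- target_ko_sets()
  m <- match_orthogroups(c("g1", "g2", "g3"), g2k, targets$color)
  expect_equal(m$gene, "g1")
  expect_equal(m$pathway_id, "map00940")
  m2 <- match_orthogroups(c("g1", "g2", "g3"), g2k, targets$size)
  expect_equal(m2$gene, "g2")  # second KO source carries the match
})

test_that("cascade equals the brute-force oracle and recovers planted genes", {
  qtl <- toy_qtl_table()
  for (sd in c(1, 2)) {
    fx <- make_prior_fixture(qtl, dir = NULL, n_planted = 2, seed = sd)
    cand <- prioritize_candidates(qtl, fx$marker_coords, fx$annotation,
                                  fx$expression, fx$gene2ko,
                                  fx$ko_size, fx$ko_color)
    got <- sort(unique(paste(cand$qtl, cand$gene, cand$ko)))
    expect_identical(got, brute_candidates(qtl, fx))
    expect_setequal(paste(cand$qtl, cand$gene),
                    paste(fx$planted$qtl, fx$planted$gene))
    # no decoy sneaks in
    expect_false(any(cand$gene %in% fx$decoys$gene))
  }
})

test_that("size/shape QTLs bypass the expression filter", {
  qtl <- toy_qtl_table()
  fx <- make_prior_fixture(qtl, dir = NULL, n_planted = 1, seed = 3)
  # force all planted genes below the expression threshold
  fx$expression$tpm[fx$expression$gene %in% fx$planted$gene] <- 0.4
  cand <- prioritize_candidates(qtl, fx$marker_coords, fx$annotation,
                                fx$expression, fx$gene2ko,
                                fx$ko_size, fx$ko_color)
  cls <- trait_class(cand$trait)
  expect_true(all(cls == "size_shape"))
  expect_true(any(cand$qtl == "Q.sA-3A"))     # size candidates survive
  expect_false(any(cand$qtl == "Q.Lab_mb-3B"))  # color ones are dropped
})

test_that("filters are monotone: wider intervals and lower TPM keep more", {
  qtl <- toy_qtl_table()
  fx <- make_prior_fixture(qtl, dir = NULL, n_planted = 2, seed = 5)
  base <- prioritize_candidates(qtl, fx$marker_coords, fx$annotation,
                                fx$expression, fx$gene2ko,
                                fx$ko_size, fx$ko_color)
  # enlarge every interval by widening marker coordinates
  mc2 <- fx$marker_coords
  mc2$start <- pmax(1, mc2$start - 6e5)
  mc2$end <- mc2$end + 6e5
  wide <- prioritize_candidates(qtl, mc2, fx$annotation, fx$expression,
                                fx$gene2ko, fx$ko_size, fx$ko_color)
  expect_true(all(paste(base$qtl, base$gene) %in%
                    paste(wide$qtl, wide$gene)))
  # raising tpm_min never adds candidates
  strict <- prioritize_candidates(qtl, fx$marker_coords, fx$annotation,
                                  fx$expression, fx$gene2ko,
                                  fx$ko_size, fx$ko_color, tpm_min = 10)
  expect_true(all(paste(strict$qtl, strict$gene) %in%
                    paste(base$qtl, base$gene)))
})

test_that("prioritization is deterministic on identical inputs", {
  qtl <- toy_qtl_table()
  fx <- make_prior_fixture(qtl, dir = NULL, n_planted = 1, seed = 6)
  a <- prioritize_candidates(qtl, fx$marker_coords, fx$annotation,
                             fx$expression, fx$gene2ko,
                             fx$ko_size, fx$ko_color)
  b <- prioritize_candidates(qtl, fx$marker_coords, fx$annotation,
                             fx$expression, fx$gene2ko,
                             fx$ko_size, fx$ko_color)
  expect_identical(as.data.frame(a), as.data.frame(b))
})

test_that("fixture files round-trip through the standard readers", {
  qtl <- toy_qtl_table()
  dir <- withr::local_tempdir()
  fx <- make_prior_fixture(qtl, dir = dir, n_planted = 1, seed = 7)
  ann <- read_annotation(fx$paths[["annotation"]])
  cand <- prioritize_candidates(qtl, read_tsv(fx$paths[["marker_coords"]]),
                                ann, read_tsv(fx$paths[["expression"]]),
                                read_tsv(fx$paths[["gene2ko"]]),
                                read_tsv(fx$paths[["ko_size"]]),
                                read_tsv(fx$paths[["ko_color"]]))
  expect_setequal(paste(cand$qtl, cand$gene),
                  paste(fx$planted$qtl, fx$planted$gene))
  # the color KO table matches the eight pigment pathways
  kc <- read_tsv(fx$paths[["ko_color"]])
  expect_setequal(unique(kc$pathway_id),
                  c("map00380", "map00900", "map00906", "map00940",
                    "map00941", "map00942", "map00943", "map00944"))
})
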