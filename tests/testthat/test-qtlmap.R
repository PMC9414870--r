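# Cofactor selection, additive scan, significance classes, epistasis, naming.

small_map <- function(n_chrom = 3, spacing = 5, len = c(100, 150)) {
  make_genetic_map(n_chrom = n_chrom, spacing = spacing, length_range = len)
}

test_that("constant phenotypes select no cofactors and yield a flat profile", {
  map <- small_map()
  ds <- simulate_ril_dataset(ril_sim_spec(map, n_lines = 60, seed = 1))
  ds$pheno$y <- 5
  expect_equal(nrow(select_cofactors(ds, "y")), 0)
  sc <- additive_scan(ds, "y")
  expect_true(all(sc$profile$lod == 0))
  expect_equal(nrow(sc$qtl), 0)
  expect_equal(nrow(epistasis_scan(ds, "y")), 0)
})

test_that("scan LOD at markers equals the single-marker likelihood oracle", {
  map <- small_map()
  ds <- simulate_ril_dataset(ril_sim_spec(map, n_lines = 80, seed = 2))
  no_cof <- data.frame(marker = character(0), chrom = character(0),
                       pos = numeric(0), coef = numeric(0))
  sc <- additive_scan(ds, "y", cofactors = no_cof)
  for (mk in sample(map$marker, 12)) {
    i <- match(mk, map$marker)
    row <- sc$profile[sc$profile$chrom == map$chrom[i] &
                        abs(sc$profile$pos - map$pos[i]) < 1e-9, ]
    oracle <- lod_single_marker(ds$pheno$y, ds$geno[, mk])
    expect_equal(row$lod, oracle, tolerance = 1e-9)
  }
})

test_that("LOD profiles are invariant to affine phenotype transforms", {
  map <- small_map()
  spec <- ril_sim_spec(map, n_lines = 120, resid_sd = 2, seed = 3,
                       qtl = data.frame(chrom = "1B", pos = 40, effect = 1))
  ds <- simulate_ril_dataset(spec)
  sc1 <- additive_scan(ds, "y")
  ds2 <- ds
  ds2$pheno$y <- -3.5 * ds$pheno$y + 11
  sc2 <- additive_scan(ds2, "y")
  expect_equal(sc2$profile$lod, sc1$profile$lod, tolerance = 1e-8)
})

test_that("stepwise selection finds a strong planted marker QTL", {
  map <- small_map(5, 5, c(100, 200))   # ~780 markers over 5 chromosomes
  hits <- 0
  reps <- 20
  for (i in seq_len(reps)) {
    spec <- ril_sim_spec(map, n_lines = 200, resid_sd = 2, seed = 100 + i,
                         qtl = data.frame(chrom = "1D", pos = 50,
                                          effect = 1))
    ds <- simulate_ril_dataset(spec)
    cof <- select_cofactors(ds, "y")
    ok <- any(cof$chrom == "1D" & abs(cof$pos - 50) <= 5)
    hits <- hits + ok
  }
  expect_gte(hits / reps, 0.95)
})

test_that("false cofactors on pure noise stay near the multiplicity rate", {
  # ~1000 markers at entry p = 0.001: about one false positive per trait
  map <- small_map(10, 10, c(480, 520))
  counts <- integer(8)
  for (i in seq_along(counts)) {
    ds <- simulate_ril_dataset(ril_sim_spec(map, n_lines = 200,
                                            seed = 300 + i))
    counts[i] <- nrow(select_cofactors(ds, "y"))
  }
  expect_lte(mean(counts), 2.5)
})

test_that("a planted QTL is localized with support interval and effect", {
  map <- small_map()
  spec <- ril_sim_spec(map, n_lines = 200, resid_sd = 2, seed = 5,
                       qtl = data.frame(chrom = "1A", pos = 42, effect = 1))
  ds <- simulate_ril_dataset(spec)
  sc <- additive_scan(ds, "y")
  q <- sc$qtl[which.max(sc$qtl$lod), ]
  expect_equal(q$chrom, "1A")
  expect_lte(abs(q$pos - 42), 5)
  expect_gt(q$lod, 3)
  expect_equal(q$class, "highly_significant")
  expect_true(q$ci_lo <= q$pos && q$pos <= q$ci_hi)
  expect_equal(q$effect, 1, tolerance = 0.35)
  expect_true(q$marker_left %in% map$marker && q$marker_right %in% map$marker)
})

test_that("power rises with planted PVE", {
  map <- small_map()
  mean_lod <- vapply(c(5, 10, 20), function(pve) {
    lods <- vapply(1:5, function(i) {
      a <- 2 * sqrt(pve / 100 / (1 - pve / 100))
      spec <- ril_sim_spec(map, n_lines = 150, resid_sd = 2,
                           seed = 700 + i,
                           qtl = data.frame(chrom = "1B", pos = 60,
                                            effect = a))
      ds <- simulate_ril_dataset(spec)
      pr <- additive_scan(ds, "y")$profile
      max(pr$lod[pr$chrom == "1B" & abs(pr$pos - 60) <= 10])
    }, numeric(1))
    mean(lods)
  }, numeric(1))
  expect_true(all(diff(mean_lod) > 0))
})

test_that("significance classes follow the LOD thresholds", {
  expect_equal(classify_significance(c(2.5, 3.2, 2.0, 0, 3.0)),
               c("significant", "highly_significant", "none", "none",
                 "significant"))
  expect_error(classify_significance(-0.1), "negative")
})

test_that("QTL names follow the catalog convention", {
  expect_equal(name_qtl("sA", "3A", 155), "Q.sA-3A")
  nm <- name_qtl(c("sA", "sA"), c("2B", "2B"), c(208, 129))
  expect_equal(nm, c("Q.sA-2B.2", "Q.sA-2B.1"))
  expect_equal(name_qtl(c("sA", "sA"), c("2B", "3B"), c(10, 10)),
               c("Q.sA-2B", "Q.sA-3B"))
})

test_that("missing flanking genotypes drop lines pointwise", {
  map <- data.frame(chrom = "1A", marker = c("m1", "m2", "m3"),
                    pos = c(0, 10, 20))
  spec <- ril_sim_spec(map, n_lines = 60, seed = 8)
  ds <- simulate_ril_dataset(spec)
  ds$geno[1:10, "m1"] <- NA
  sc <- additive_scan(ds, "y", cofactors = data.frame(
    marker = character(0), chrom = character(0), pos = numeric(0),
    coef = numeric(0)))
  n_at <- function(p) sc$profile$n[abs(sc$profile$pos - p) < 1e-9]
  expect_equal(n_at(0), 50)   # marker with masked lines
  expect_equal(n_at(5), 50)   # interval needing that flank
  expect_equal(n_at(15), 60)  # unaffected interval
})

test_that("epistasis scan recovers a planted interaction and reports PVE", {
  map <- small_map()
  spec <- ril_sim_spec(map, n_lines = 300, resid_sd = 2, seed = 9,
                       epi = data.frame(chrom1 = "1A", pos1 = 40,
                                        chrom2 = "1B", pos2 = 60,
                                        effect = 0.9))
  ds <- simulate_ril_dataset(spec)
  ep <- epistasis_scan(ds, "y")
  expect_gt(nrow(ep), 0)
  top <- ep[1, ]
  expect_equal(top$chrom1, "1A"); expect_lte(abs(top$pos1 - 40), 5)
  expect_equal(top$chrom2, "1B"); expect_lte(abs(top$pos2 - 60), 5)
  expect_gte(top$lod, 5)
  expect_gte(top$pve, 5)
  expect_equal(top$effect_int, 0.9, tolerance = 0.3)
})
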