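---
title: "seedqtl: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{seedqtl: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the models implemented in `seedqtl`, the numerical
choices that matter for reproducing its outputs, and what the synthetic-data
validation does and does not establish.

## The measurement model

Seeds are photographed on a white background next to a 24-patch color
calibration card of known geometry and patch colors. The package assumes:

* exactly one card per image, axis-aligned, fully visible;
* seeds do not touch each other or the card (the scattering protocol);
* near-uniform illumination, so a single global linear correction suffices.

**Calibration.** The card body is found as the largest dark connected
component; the mm-per-pixel scale is the known card width divided by its
measured pixel width. Patch colors are sampled from the central 40% of each
patch and a linear map (3×3 matrix plus offset) is fitted by least squares
*in linearized RGB* — gamma-encoded sRGB is not closed under linear casts,
so a cast planted in linear RGB is exactly invertible there and only there.
The per-patch RMS residual is reported; calibration quality should always be
checked before trusting color descriptors.

**Segmentation.** Lightness is thresholded with Otsu's method after masking
the card region to white. Otsu always splits a histogram, including pure
background noise, so a threshold falling inside the white background peak
(> 0.9) is interpreted as "nothing to segment". A 3×3 morphological opening
removes speckle; components smaller than 2 mm² (default, configurable) are
discarded. Touching-seed splitting is deliberately not attempted.

## The 55 descriptors

Size (`sL`, `sW` from the minimum-area rotated bounding rectangle, `sA` from
the pixel count) and four shape indices:

* circularity `sCi = 4πA/P²`,
* roundness `sRo = 4A/(πL²)`, normalized so a circle scores 1; the
  unnormalized area-over-squared-major-axis form would never reach 1, while
  the definitional intent (values below 1 for non-circles, 1 in the circle
  limit) requires the `4/π` factor,
* rugosity `sRg = P/P_convex` (written `sRu` in some trait lists; the two
  names are treated as aliases),
* solidity `sSo = A/A_convex`.

**Perimeter estimation.** A raw 8-connected chain with √2-weighted diagonal
steps overestimates the perimeter of a digitized disk by about 5%, which
alone would push `sCi` of a circle down to ≈ 0.90. Perimeters are therefore
measured on a closed moving-average smoothing of the contour (window 5
vertices), which is within 0.3% of the analytic circumference at radius
100 px. The convex perimeter uses the convex hull *of the same smoothed
points*, so `sRg ≥ 1` holds exactly (a closed polygon is at least as long
as its hull). The convex-hull area is the count of pixel centers inside the
hull of the boundary pixel centers — a pixel count compared with a pixel
count — so `sSo ≤ 1` holds exactly and convex shapes score ≈ 1 at moderate
resolution. Bounding-rectangle sides are enlarged by one pixel for the
half-pixel footprint on each side. These estimators are accurate to ≈ 1–2%
for seeds at least ~50 px long; descriptors from smaller components should
not be trusted.

**Color.** Seed pixels (after a 1-px boundary erosion to avoid background
bleed at the contour) are expressed in four spaces on a single 8-bit scale:
RGB as-is; HSV with hue mapped 0–360° → 0–255 and S, V scaled to 0–255;
CIE Lab (D65, sRGB gamma) with L mapped 0–100 → 0–255 and a, b offset by
+128; YCrCb per BT.601 with Cr, Cb offset by +128. Two descriptor families:

* *means*: per channel, one pass of 3σ exclusion (pixels deviating more
  than three standard deviations from the channel mean are dropped,
  independently per channel — a pixel can be excluded for R and kept for
  G), then the mean of the survivors;
* *dominant colors*: k-means with k = 3 on the space's 3-D pixel
  coordinates, run independently per space (clustering once in one space
  and converting centroids is a defensible alternative; per-space was
  chosen so each space's descriptors are self-contained, and the choice is
  isolated in one function). Initial centers are the pixels at the
  10th/50th/90th percentile positions along the first principal axis of
  the pixel cloud, which makes the clustering deterministic. Clusters are
  ranked by pixel count, ties broken by descending centroid lightness
  (V, L, or Y depending on the space; channel mean for RGB). If a seed has
  fewer than three distinct colors, the lowest-ranked centroid is repeated
  into the empty slots, so the descriptor vector always has 55 entries.

Per-genotype values are unweighted means over all seeds pooled across the
genotype's images (the emulated protocol uses two images, of 15 and 5
seeds).

## QTL mapping

The population model is a selfed biparental RIL panel: fully homozygous
lines, genotypes coded ±1, no dominance. Map distances convert to
recombination fractions with Haldane's function (no interference),
`r = (1 − e^{−2d/100})/2`, inflated for repeated selfing to
`R = 2r/(1+2r)`; the same two formulas drive the simulator and the scan, so
simulator-vs-scan agreement tests the implementation, not the model choice.

**Cofactors.** Stepwise forward–backward regression on marker codes with
entry/exit p-values 0.001/0.002 (the scan tool family's documented
defaults; the exact tuning used in any given study is rarely printed, so
both are configurable). Missing genotypes are mean-imputed in this phase
only; at ~0.1% entry across ~10³ markers the expected false-cofactor count
per trait is of order one, which the backward step and the scan's
flank-exclusion rule tolerate.

**Additive scan.** At each 1-cM position the phenotype is adjusted by
subtracting the joint-fit contributions of all cofactors *except* those at
the current interval's flanking markers, then regressed on the expected
QTL code `E[x | flanking genotypes]` from the RIL Markov chain
(Haley–Knott-style regression; at marker positions this is algebraically a
single-marker regression, which the tests exploit as an oracle). Lines
missing a needed flanking genotype are dropped at that position only.
`LOD = (n/2)log₁₀(RSS₀/RSS₁)`; peaks above LOD 2 are reported with PVE
(relative to the adjusted phenotype variance), additive effect, and a
LOD−1 support interval; peaks within 10 cM merge, keeping the higher —
conservative, since genuinely distinct nearby loci are reported separately
in the emulated study, and configurable down to 0.

**Epistasis.** All position pairs on a 5-cM grid, excluding same-chromosome
pairs closer than 20 cM (linkage between `E[x₁]` and `E[x₂]` otherwise
produces interaction-like artifacts). The interaction LOD compares the
additive two-locus model with the model adding `E[x₁]E[x₂]`; pairs need
LOD ≥ 5 *and* interaction PVE ≥ 5% to be reported. The source protocol's
phrase "LOD was kept at 5.0 cM" conflates two settings; it is read here as
a 5-cM grid step *and* a LOD ≥ 5 filter, both of which are stated
separately elsewhere in that protocol. Overlapping reported pairs merge to
the locally strongest pair (both loci within 10 cM).

QTL names follow the catalog convention `Q.<trait>-<chrom>`, with `.1`,
`.2` suffixes in peak-position order when one trait has several QTLs on a
chromosome.

## Trait similarity

Each trait's QTL peaks, rounded to 3 decimals, become a locus set; peaks on
one chromosome within a configurable tolerance (default 0 cM — observed
cross-trait overlaps in this kind of data are exact-position, and whether
near-adjacent peaks 1–2 cM apart should unify is a judgment call left to
the user) are unified by chaining. The Ochiai index
`|A∩B|/√(|A||B|)` is 0 when either set is empty — a convention that also
places zero-QTL traits at maximal distance in the tree rather than dropping
them. Clustering is UPGMA on `1 − Ochiai` with leaves pre-sorted
lexicographically so ties resolve deterministically; single and complete
linkage are available.

## Gene prioritization

Only highly significant QTLs (LOD > 3) are considered. Marker physical
coordinates are consumed from a table rather than produced by sequence
alignment — the provenance expected of that table is a BLASTn of marker
sequences against a reference genome, but running it is out of scope and
the logic under test is the filtering cascade. A QTL whose marker
coordinates land on a different chromosome than the genetic assignment is
skipped with a logged reason. Genes qualify by: any-overlap (≥ 1 bp,
1-based inclusive, the inclusive reading of "genes in marker-limited
sites") with the interval; `confidence = high` annotation; for color-trait
QTLs only, TPM ≥ 1 in at least one seed-tissue sample (aggregation is the
maximum over seed samples; size/shape QTLs bypass this filter, matching
the protocol's wording, with the filtered classes configurable); and at
least one KEGG orthogroup in the target set for the trait class. A gene
with several KO assignments (multiple services) is matched through any of
them.

## The synthetic-data module

The generators define the validation conditions:

* **Scenes**: elliptical seeds (semi-axes ~2.8–3.8 × 1.4–2.0 mm,
  wheat-like reddish-brown coats) with an optional low-order radial cosine
  boundary perturbation (amplitude ≤ 0.2) — chosen because area and axes
  stay closed-form for oracles; a 24-patch card; optional global linear
  cast and Gaussian pixel noise. Default canvas 190 × 120 mm at
  0.1 mm/px.
* **Populations**: 114 lines over 21 chromosomes named 1A–7D with 5-cM
  marker spacing and lengths spread 100–300 cM (the emulated map's true
  density is not published; these are configurable defaults, chosen as
  typical for dense hexaploid wheat maps, not inferred). Planted QTLs are
  snapped to the nearest marker; requested PVE converts to an effect via
  `PVE = a²/(a² + σ²)` with Var(x) = 1.
* **Prioritization fixtures**: one disjoint ~2-Mb interval per QTL, planted
  candidates passing every filter, and one decoy per failure mode (outside
  the interval, low confidence, seed TPM 0.5, non-target KO), each failing
  exactly one filter.

Validation problem sizes were fixed in advance of any tuning: shape
analytics on radius ≥ 100 px rasterizations; recovery of a PVE-20% QTL in
200 lines over a 3-chromosome genome across 20 seeded replicates; false
positive behavior of noise traits on the full 21-chromosome genome at
n = 114, 20 replicates; epistasis recovery (PVE 15%, n = 300) and
additive-only null scans, 20 replicates each; 1000 random set pairs for
the Ochiai brute-force equivalence.

What passing these tests shows: the estimators are unbiased and accurate on
geometry and populations that satisfy the model assumptions, and the
filtering cascade is exact. What they do not show: robustness to real-image
nuisances — shadows, specular highlights, seed texture, lens distortion,
touching seeds, card rotation — none of which the renderer emulates, nor
segregation distortion or genotyping error in real populations.

## Known limitations

* The scan uses regression (Haley–Knott) likelihoods throughout; a full EM
  mixture model would differ slightly between widely spaced markers.
* Genome-wide significance is by fixed LOD thresholds, not permutation.
* Dominance is not modeled (RILs are homozygous).
* Scan positions are treated as opaque cM coordinates; no assumptions are
  made about map offset conventions in external result tables.
* The color-correction model is global and linear; spatially varying
  illumination requires flat-fielding before input.
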