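#' Stepwise cofactor selection for inclusive composite interval mapping
#'
#' Forward-backward stepwise linear regression of one trait on marker codes.
#' A marker enters while its partial-regression p-value is below `p_entry`
#' and is removed when its p-value in the joint model rises above `p_exit`.
#' Missing genotypes are mean-imputed for this phase; collinear markers
#' (no residual variance given the current model) are skipped.
#'
#' @param dataset a [ril_dataset()]
#' @param trait name of a phenotype column
#' @param p_entry,p_exit stepwise entry/exit p-value thresholds
#' @param max_cofactors hard cap on the number of selected markers
#' @return data.frame `marker`, `chrom`, `pos`, `coef` (joint-fit
#'   coefficients); zero rows if nothing is selected
#' @export
select_cofactors <- function(dataset, trait, p_entry = 0.001,
                             p_exit = 0.002, max_cofactors = 30) {
  d <- scan_data(dataset, trait)
  if (length(d$y) < 10) stop("need >= 10 non-missing lines")
  X <- d$X_imp
  y <- d$y
  n <- length(y)
  usable <- which(apply(X, 2, stats::var) > 1e-12)
  sel <- integer(0)
  repeat {
    changed <- FALSE
    # forward step
    if (length(sel) < max_cofactors) {
      Q <- qr.Q(qr(cbind(1, X[, sel, drop = FALSE])))
      ry <- y - Q %*% crossprod(Q, y)
      cand <- setdiff(usable, sel)
      RX <- X[, cand, drop = FALSE]
      RX <- RX - Q %*% crossprod(Q, RX)
      ssx <- colSums(RX^2)
      ok <- ssx > 1e-8
      df <- n - length(sel) - 2
      if (any(ok) && df > 0 && sum(ry^2) > 0) {
        r <- as.vector(crossprod(RX[, ok, drop = FALSE], ry)) /
          sqrt(ssx[ok] * sum(ry^2))
        r2 <- pmin(r^2, 1 - 1e-12)
        tt <- abs(r) * sqrt(df / (1 - r2))
        p <- 2 * stats::pt(-tt, df)
        if (min(p) < p_entry) {
          sel <- c(sel, cand[ok][which.min(p)])
          changed <- TRUE
        }
      }
    }
    # backward step
    while (length(sel) > 0) {
      fit <- stats::lm.fit(cbind(1, X[, sel, drop = FALSE]), y)
      rss <- sum(fit$residuals^2)
      dfr <- n - length(sel) - 1
      se2 <- rss / dfr
      XtX <- crossprod(cbind(1, X[, sel, drop = FALSE]))
      vc <- tryCatch(diag(solve(XtX)) * se2, error = function(e) NULL)
      if (is.null(vc)) { sel <- sel[-length(sel)]; changed <- TRUE; next }
      tt <- fit$coefficients[-1] / sqrt(vc[-1])
      p <- 2 * stats::pt(-abs(tt), dfr)
      if (max(p) > p_exit) {
        sel <- sel[-which.max(p)]
        changed <- TRUE
      } else break
    }
    if (!changed) break
  }
  if (!length(sel)) {
    return(data.frame(marker = character(0), chrom = character(0),
                      pos = numeric(0), coef = numeric(0)))
  }
  fit <- stats::lm.fit(cbind(1, X[, sel, drop = FALSE]), y)
  data.frame(marker = colnames(X)[sel],
             chrom = d$map$chrom[sel],
             pos = d$map$pos[sel],
             coef = unname(fit$coefficients[-1]))
}

# aligned phenotype/genotype view used by all scans
scan_data <- function(dataset, trait) {
  stopifnot(inherits(dataset, "ril_dataset"))
  if (!trait %in% names(dataset$pheno)) stop("unknown trait: ", trait)
  ph <- dataset$pheno[!is.na(dataset$pheno[[trait]]), ]
  g <- dataset$geno[match(ph$line, rownames(dataset$geno)), , drop = FALSE]
  X_imp <- apply(g, 2, function(col) {
    m <- mean(col, na.rm = TRUE)
    if (!is.finite(m)) m <- 0
    col[is.na(col)] <- m
    col
  })
  list(y = ph[[trait]], G = g, X_imp = X_imp, map = dataset$map)
}

# expected +1/-1 QTL code at position p from flanking marker genotypes
# (selfed-RIL Markov chain, Haldane distances); returns NA where a needed
# flank is missing
expected_code <- function(gL, gR, dL, dR) {
  tL <- ril_recomb(dL); tR <- ril_recomb(dR)
  # transition prob of agreeing with each flank
  pLsame <- ifelse(gL == 1, 1 - tL, tL)      # P(x = +1 | gL)
  pRsame <- ifelse(gR == 1, 1 - tR, tR)      # P(gR | x = +1) up to symmetry
  pp <- pLsame * pRsame
  pm <- (1 - pLsame) * (1 - pRsame)
  (pp - pm) / (pp + pm)
}

#' Additive QTL scan (inclusive composite interval mapping style)
#'
#' Walks every chromosome at `step` cM. At each position the phenotype is
#' adjusted by subtracting the joint-fit effects of all selected cofactors
#' except those flanking the current marker interval; the expected QTL
#' genotype given the flanking markers (selfed-RIL conditional probabilities,
#' Haldane distances) is regressed on the adjusted phenotype, and
#' `LOD = (n/2) log10(RSS0 / RSS1)`. Lines missing a needed flanking
#' genotype are dropped at that position. Peaks above `lod_sig` are reported
#' with PVE, additive effect, a LOD-1 support interval, flanking markers and
#' a significance class; peaks within `merge_cM` on a chromosome are merged
#' keeping the higher.
#'
#' @param dataset a [ril_dataset()]
#' @param trait phenotype column to scan
#' @param step walking speed in cM
#' @param cofactors optional precomputed [select_cofactors()] table
#' @param lod_sig LOD above which a peak is reported (exclusive)
#' @param lod_high LOD above which a peak is highly significant (exclusive)
#' @param merge_cM peak merging radius
#' @param ... passed to [select_cofactors()] when `cofactors` is NULL
#' @return list of class `qtl_scan`: `profile` (chrom, pos, lod, n) and
#'   `qtl` (one row per reported QTL)
#' @export
additive_scan <- function(dataset, trait, step = 1, cofactors = NULL,
                          lod_sig = 2, lod_high = 3, merge_cM = 10, ...) {
  d <- scan_data(dataset, trait)
  if (is.null(cofactors)) cofactors <- select_cofactors(dataset, trait, ...)
  adj <- adjusted_phenotype(d, cofactors)
  map <- d$map
  prof <- list()
  for (ch in unique(map$chrom)) {
    j <- which(map$chrom == ch)
    mpos <- map$pos[j]
    grid <- unique(c(seq(min(mpos), max(mpos), by = step), max(mpos)))
    res <- vapply(grid, function(p) {
      scan_position(d, adj, ch, p, j, mpos)
    }, numeric(4))
    prof[[ch]] <- data.frame(chrom = ch, pos = grid,
                             lod = res[1, ], n = res[2, ],
                             pve = res[3, ], effect = res[4, ])
  }
  profile <- do.call(rbind, c(prof, make.row.names = FALSE))
  qtl <- find_peaks(profile, map, trait, lod_sig, lod_high, merge_cM)
  structure(list(profile = profile[, c("chrom", "pos", "lod", "n")],
                 qtl = qtl, trait = trait, cofactors = cofactors),
            class = "qtl_scan")
}

# per-line cofactor contributions and fully adjusted phenotype
adjusted_phenotype <- function(d, cofactors) {
  if (nrow(cofactors)) {
    ci <- match(cofactors$marker, colnames(d$X_imp))
    contrib <- sweep(d$X_imp[, ci, drop = FALSE], 2, cofactors$coef, "*")
    list(y_all = d$y - rowSums(contrib), contrib = contrib,
         chrom = cofactors$chrom, pos = cofactors$pos)
  } else {
    list(y_all = d$y, contrib = NULL, chrom = character(0), pos = numeric(0))
  }
}

# LOD, n, PVE, effect at one scan position
scan_position <- function(d, adj, ch, p, j, mpos) {
  k <- length(j)
  jm <- if (k == 1) 1 else min(max(findInterval(p, mpos), 1), k - 1)
  # cofactors flanking the current interval are excluded from adjustment
  excl <- which(adj$chrom == ch &
                  (abs(adj$pos - mpos[jm]) < 1e-9 |
                     (k > 1 & abs(adj$pos - mpos[min(jm + 1, k)]) < 1e-9)))
  y <- adj$y_all
  if (length(excl)) y <- y + rowSums(adj$contrib[, excl, drop = FALSE])
  at <- which(abs(mpos - p) < 1e-6)
  if (length(at)) {
    x <- d$G[, j[at[1]]]
  } else {
    gL <- d$G[, j[jm]]; gR <- d$G[, j[jm + 1]]
    x <- expected_code(gL, gR, p - mpos[jm], mpos[jm + 1] - p)
  }
  keep <- !is.na(x)
  x <- x[keep]; yk <- y[keep]
  nn <- length(yk)
  if (nn < 5) return(c(0, nn, 0, 0))
  xc <- x - mean(x); yc <- yk - mean(yk)
  sxx <- sum(xc^2); rss0 <- sum(yc^2)
  if (sxx < 1e-10 || rss0 < 1e-12) return(c(0, nn, 0, 0))
  b <- sum(xc * yc) / sxx
  rss1 <- rss0 - b^2 * sxx
  rss1 <- max(rss1, 1e-12)
  lod <- (nn / 2) * log10(rss0 / rss1)
  c(lod, nn, 100 * (1 - rss1 / rss0), b)
}

# local maxima above threshold, merged, with LOD-1 support intervals
find_peaks <- function(profile, map, trait, lod_sig, lod_high, merge_cM) {
  out <- list()
  for (ch in unique(profile$chrom)) {
    pr <- profile[profile$chrom == ch, ]
    lod <- pr$lod
    m <- length(lod)
    if (m == 0) next
    left <- c(-Inf, lod[-m]); right <- c(lod[-1], -Inf)
    peaks <- which(lod > lod_sig & lod >= left & lod > right)
    if (!length(peaks)) next
    # merge nearby peaks, keep the higher
    peaks <- peaks[order(-lod[peaks])]
    kept <- integer(0)
    for (pk in peaks) {
      if (!length(kept) || all(abs(pr$pos[kept] - pr$pos[pk]) > merge_cM))
        kept <- c(kept, pk)
    }
    kept <- sort(kept)
    mpos <- map$pos[map$chrom == ch]
    mnames <- map$marker[map$chrom == ch]
    for (pk in kept) {
      lo <- pk; while (lo > 1 && lod[lo - 1] > lod[pk] - 1) lo <- lo - 1
      hi <- pk; while (hi < m && lod[hi + 1] > lod[pk] - 1) hi <- hi + 1
      ml <- max(which(mpos <= pr$pos[lo] + 1e-9))
      mr <- min(which(mpos >= pr$pos[hi] - 1e-9))
      out[[length(out) + 1]] <- data.frame(
        trait = trait, chrom = ch, pos = pr$pos[pk], lod = lod[pk],
        pve = pr$pve[pk], effect = pr$effect[pk],
        ci_lo = pr$pos[lo], ci_hi = pr$pos[hi],
        marker_left = mnames[ml], marker_right = mnames[mr],
        class = classify_significance(lod[pk])
      )
    }
  }
  if (!length(out)) {
    return(data.frame(trait = character(0), chrom = character(0),
                      pos = numeric(0), lod = numeric(0), pve = numeric(0),
                      effect = numeric(0), ci_lo = numeric(0),
                      ci_hi = numeric(0), marker_left = character(0),
                      marker_right = character(0), class = character(0),
                      name = character(0)))
  }
  qtl <- do.call(rbind, c(out, make.row.names = FALSE))
  qtl$name <- name_qtl(qtl$trait, qtl$chrom, qtl$pos)
  qtl
}

#' Significance class of a LOD score
#'
#' LOD in (2, 3] is `significant`, above 3 `highly_significant`, at or below
#' 2 `none` (both thresholds exclusive at the lower bound).
#'
#' @param lod numeric vector of non-negative LOD scores
#' @return character vector of classes
#' @export
classify_significance <- function(lod) {
  if (any(lod < 0)) stop("negative LOD rejected")
  ifelse(lod > 3, "highly_significant",
         ifelse(lod > 2, "significant", "none"))
}

#' Assign QTL names
#'
#' `Q.<trait>-<chrom>`; when a trait has several QTLs on one chromosome they
#' are suffixed `.1`, `.2`, ... in peak-position order.
#'
#' @param trait,chrom,pos parallel vectors describing the QTLs
#' @return character vector of names
#' @export
name_qtl <- function(trait, chrom, pos) {
  base <- paste0("Q.", trait, "-", chrom)
  nm <- base
  for (b in unique(base)) {
    i <- which(base == b)
    if (length(i) > 1) nm[i[order(pos[i])]] <- paste0(b, ".", seq_along(i))
  }
  nm
}

#' Scan several traits and pool the QTL table
#'
#' @param dataset a [ril_dataset()]
#' @param traits trait names (default: all phenotype columns)
#' @param ... passed to [additive_scan()]
#' @return data.frame of pooled QTL rows (see [additive_scan()])
#' @export
scan_traits <- function(dataset, traits = NULL, ...) {
  if (is.null(traits)) traits <- setdiff(names(dataset$pheno), "line")
  res <- lapply(traits, function(tr) additive_scan(dataset, tr, ...)$qtl)
  do.call(rbind, c(res, make.row.names = FALSE))
}

#' Digenic epistasis scan
#'
#' Over all ordered pairs of positions on a `step`-cM genome grid (pairs on
#' the same chromosome closer than `min_gap_cM` are excluded as linkage
#' artifacts), fits the cofactor-adjusted phenotype on
#' `{E[x1], E[x2], E[x1] E[x2]}` and computes the interaction LOD
#' `(n/2) log10(RSS_additive / RSS_full)` and interaction PVE relative to the
#' adjusted phenotypic variance. Pairs with `LOD >= lod_min` and
#' `PVE >= pve_min` are reported after merging overlapping pairs to their
#' local two-dimensional maximum.
#'
#' @param dataset a [ril_dataset()]
#' @param trait phenotype column
#' @param step grid step in cM
#' @param lod_min,pve_min report filters
#' @param min_gap_cM minimum same-chromosome separation
#' @param merge_cM per-locus merging radius
#' @param cofactors optional precomputed cofactor table
#' @param ... passed to [select_cofactors()]
#' @return data.frame, one row per reported pair: loci, interaction LOD and
#'   PVE, and effect estimates from the full model
#' @export
epistasis_scan <- function(dataset, trait, step = 5, lod_min = 5,
                           pve_min = 5, min_gap_cM = 20, merge_cM = 10,
                           cofactors = NULL, ...) {
  d <- scan_data(dataset, trait)
  if (is.null(cofactors)) cofactors <- select_cofactors(dataset, trait, ...)
  adj <- adjusted_phenotype(d, cofactors)
  map <- d$map
  # genome grid with expected codes and per-position excluded cofactors
  grid <- list()
  for (ch in unique(map$chrom)) {
    j <- which(map$chrom == ch)
    mpos <- map$pos[j]
    pos <- unique(c(seq(min(mpos), max(mpos), by = step), max(mpos)))
    for (p in pos) {
      k <- length(j)
      jm <- if (k == 1) 1 else min(max(findInterval(p, mpos), 1), k - 1)
      at <- which(abs(mpos - p) < 1e-6)
      x <- if (length(at)) d$G[, j[at[1]]]
      else expected_code(d$G[, j[jm]], d$G[, j[jm + 1]],
                         p - mpos[jm], mpos[jm + 1] - p)
      excl <- which(adj$chrom == ch &
                      (abs(adj$pos - mpos[jm]) < 1e-9 |
                         (k > 1 & abs(adj$pos - mpos[min(jm + 1, k)]) < 1e-9)))
      grid[[length(grid) + 1]] <- list(chrom = ch, pos = p, x = x,
                                       excl = excl)
    }
  }
  P <- length(grid)
  hits <- list()
  for (i in seq_len(P - 1)) {
    gi <- grid[[i]]
    for (jj in (i + 1):P) {
      gj <- grid[[jj]]
      if (gi$chrom == gj$chrom && abs(gi$pos - gj$pos) < min_gap_cM) next
      keep <- !is.na(gi$x) & !is.na(gj$x)
      nn <- sum(keep)
      if (nn < 10) next
      y <- adj$y_all[keep]
      excl <- union(gi$excl, gj$excl)
      if (length(excl))
        y <- y + rowSums(adj$contrib[keep, excl, drop = FALSE])
      x1 <- gi$x[keep]; x2 <- gj$x[keep]
      w <- x1 * x2
      X <- cbind(1, x1, x2, w)
      XtX <- crossprod(X)
      Xty <- crossprod(X, y)
      yty <- sum(y * y)
      cf <- tryCatch(solve(XtX, Xty), error = function(e) NULL)
      if (is.null(cf)) next
      ba <- tryCatch(solve(XtX[1:3, 1:3], Xty[1:3]),
                     error = function(e) NULL)
      if (is.null(ba)) next
      rss_f <- max(yty - sum(cf * Xty), 1e-12)
      rss_a <- max(yty - sum(ba * Xty[1:3]), rss_f)
      lod <- (nn / 2) * log10(rss_a / rss_f)
      rss0 <- yty - sum(y)^2 / nn
      pve <- 100 * (rss_a - rss_f) / rss0
      if (lod >= lod_min && pve >= pve_min) {
        hits[[length(hits) + 1]] <- data.frame(
          trait = trait, chrom1 = gi$chrom, pos1 = gi$pos,
          chrom2 = gj$chrom, pos2 = gj$pos, lod = lod, pve = pve,
          effect1 = cf[2], effect2 = cf[3], effect_int = cf[4], n = nn)
      }
    }
  }
  if (!length(hits)) {
    return(data.frame(trait = character(0), chrom1 = character(0),
                      pos1 = numeric(0), chrom2 = character(0),
                      pos2 = numeric(0), lod = numeric(0), pve = numeric(0),
                      effect1 = numeric(0), effect2 = numeric(0),
                      effect_int = numeric(0), n = integer(0)))
  }
  hits <- do.call(rbind, c(hits, make.row.names = FALSE))
  # merge overlapping pairs to the local 2-D maximum
  hits <- hits[order(-hits$lod), ]
  kept <- integer(0)
  for (i in seq_len(nrow(hits))) {
    dup <- FALSE
    for (k in kept) {
      if (hits$chrom1[i] == hits$chrom1[k] &&
          hits$chrom2[i] == hits$chrom2[k] &&
          abs(hits$pos1[i] - hits$pos1[k]) <= merge_cM &&
          abs(hits$pos2[i] - hits$pos2[k]) <= merge_cM) { dup <- TRUE; break }
    }
    if (!dup) kept <- c(kept, i)
  }
  out <- hits[kept, ]
  rownames(out) <- NULL
  out
}
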