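# Hierarchical screen model
#
# Element c pairing guides a (gene g) and b (gene h) has expected LFC
#   inter-gene:    mu = x_a y_g + x_b y_h + x_a x_b s_gh
#   targeting+NT:  mu = x_t y_g
#   intra-gene:    mu = (1 - (1 - x_a)(1 - x_b)) y_g   (probabilistic union)
#   NT + NT:       mu = 0
# with guide efficacies x in [0,1] (0 for NT), gene effects y and pair
# interactions s on the T14 LFC scale. The fit minimizes
#   sum_{c,r} (LFC_cr - mu_c)^2 + ridge (sum y^2 + sum s^2)
# by alternating conditional updates that are each exactly solvable.

# mu for a set of elements given parameters; sLookup named by pairKey
muForElements <- function(info, x, y, sLookup = NULL) {
  mu <- numeric(nrow(info))
  cls <- info$pair_class
  tnt <- cls == "targeting_nt"
  if (any(tnt)) {
    tg <- ifelse(info$gene_a[tnt] == NT_GENE, info$guide_b[tnt],
                 info$guide_a[tnt])
    gn <- ifelse(info$gene_a[tnt] == NT_GENE, info$gene_b[tnt],
                 info$gene_a[tnt])
    mu[tnt] <- x[tg] * y[gn]
  }
  intra <- cls == "intra_gene"
  if (any(intra)) {
    xa <- x[info$guide_a[intra]]
    xb <- x[info$guide_b[intra]]
    mu[intra] <- (xa + xb - xa * xb) * y[info$gene_a[intra]]
  }
  inter <- cls == "inter_gene"
  if (any(inter)) {
    xa <- x[info$guide_a[inter]]
    xb <- x[info$guide_b[inter]]
    sv <- if (is.null(sLookup)) 0 else {
      v <- sLookup[pairKey(info$gene_a[inter], info$gene_b[inter])]
      v[is.na(v)] <- 0
      v
    }
    mu[inter] <- xa * y[info$gene_a[inter]] + xb * y[info$gene_b[inter]] +
      xa * xb * sv
  }
  unname(mu)
}

#' Fit the hierarchical interaction model to LFCs
#'
#' Fits per-guide efficacies `x` in \[0,1\], per-gene effects `y` and
#' per-gene-pair interaction effects `s` to the per-replicate LFC table by
#' penalized least squares (ridge `1e-3` on `y` and `s`), using alternating
#' conditional updates: closed-form updates for `y` (per gene) and `s` (per
#' pair) given `x`, exact clamped updates for each `x` given the rest, and a
#' per-gene rescaling after each sweep that anchors the largest guide
#' efficacy of every gene owning a full-activity (perfect) guide at 1.
#' Replicates enter as independent observations of the same element mean.
#'
#' When the LFC table carries its normalized counts (the output of
#' [computeLfc()] does), the fit is performed on the de-saturated
#' half-count-corrected log-ratio `log2((n_T14 + 0.5)/(n_T0 + 0.5))` with
#' inverse-variance weights `1/(1/(n_T14 + 0.5) + 1/(n_T0 + 0.5))`: the
#' pseudo-counted LFC cannot fall below `log2(p/(n_T0 + p))`, and fitting it
#' directly biases strongly depleted pairs toward apparent positive
#' epistasis, while near-zero T14 counts carry little information and get
#' correspondingly little weight here. Set `useCounts = FALSE` (or fit a
#' table without count matrices) to minimize the plain unweighted LFC
#' objective.
#'
#' Mismatch-variant guides whose gene has no perfect guide left in the data
#' (the situation after [substituteMismatchVariants()]) are not separately
#' identifiable from their gene effect; their efficacy is pinned to the
#' guide's recorded empirical (else predicted) activity, which the library
#' design measured precisely for this purpose, and `y` is estimated on the
#' true single-knockdown scale.
#'
#' @param lfc an \linkS4class{LfcTable}
#' @param design the matching \linkS4class{PairedGuideLibrary}
#' @param seed integer recorded in the fit (the default fit is
#'   deterministic; no stochastic restarts).
#' @param tol convergence tolerance on the largest absolute parameter change
#'   (default 1e-4).
#' @param maxIter maximum update sweeps (default 500).
#' @param ridge ridge penalty on `y` and `s` (default 1e-3).
#' @param useCounts use count-weighted de-saturated observations when the
#'   table provides counts (default TRUE; see Details).
#' @return a \linkS4class{ModelFit}
#' @export
fitInteractionModel <- function(lfc, design, seed = 1L, tol = 1e-4,
                                maxIter = 500L, ridge = 1e-3,
                                useCounts = TRUE) {
  info <- lfc@elementInfo
  checkColumns(info, c("guide_a", "guide_b", "gene_a", "gene_b", "pair_class"),
               "elementInfo")
  L <- lfc@lfc
  if (any(!is.finite(L))) stop("non-finite LFC values")
  g <- design@guides

  # Observations: when the table carries its normalized counts, fit the
  # de-saturated half-count-corrected log-ratio with inverse-variance
  # (count-information) weights -- the pseudo-counted LFC flattens out at
  # log2(p / (n0 + p)), and fitting it directly reads depletion beyond that
  # floor as positive epistasis. Tables built from LFC values alone are fit
  # unweighted on the LFC itself.
  useCounts <- isTRUE(useCounts) && nrow(lfc@n0) == nrow(L)
  if (useCounts) {
    v <- log2((lfc@n1 + 0.5) / (lfc@n0 + 0.5))
    wMat <- 1 / (1 / (lfc@n1 + 0.5) + 1 / (lfc@n0 + 0.5))
    wMat <- wMat / mean(wMat)
  } else {
    v <- L
    wMat <- matrix(1, nrow(L), ncol(L))
  }

  # collapse replicates: per-element weighted mean and total weight
  w <- rowSums(wMat)
  m <- rowSums(wMat * v) / w
  ssWithin <- sum(wMat * (v - m)^2)
  nObs <- length(v)

  cls <- info$pair_class
  genes <- sort(unique(c(info$gene_a, info$gene_b)))
  genes <- genes[genes != NT_GENE]
  tntRows <- which(cls == "targeting_nt")
  tntGuide <- ifelse(info$gene_a[tntRows] == NT_GENE,
                     info$guide_b[tntRows], info$guide_a[tntRows])
  tntGene <- ifelse(info$gene_a[tntRows] == NT_GENE,
                    info$gene_b[tntRows], info$gene_a[tntRows])
  noNT <- setdiff(genes, unique(tntGene))
  if (length(noNT)) {
    stop("gene(s) without NT-paired measurements: ",
         paste(head(noNT, 5L), collapse = ", "))
  }
  interRows <- which(cls == "inter_gene")
  intraRows <- which(cls == "intra_gene")
  ntntRows <- which(cls == "nt_nt")

  modeledGuides <- sort(unique(c(info$guide_a, info$guide_b)))
  gtype <- g$guide_type[match(modeledGuides, g$guide_id)]
  targetGuides <- modeledGuides[gtype != "non_targeting"]
  guideGene <- setNames(g$gene[match(modeledGuides, g$guide_id)],
                        modeledGuides)

  # initialization
  act <- g$empirical_activity[match(modeledGuides, g$guide_id)]
  act <- ifelse(is.na(act), g$predicted_activity[match(modeledGuides, g$guide_id)],
                act)
  x <- setNames(ifelse(gtype == "non_targeting", 0,
                ifelse(gtype == "mismatch",
                       ifelse(is.na(act), 0.5, clamp01(act)), 1)),
                modeledGuides)
  hasPerfect <- vapply(genes, function(gn) {
    any(gtype == "perfect" & guideGene[modeledGuides] == gn)
  }, logical(1))
  names(hasPerfect) <- genes
  pinned <- targetGuides[gtype[match(targetGuides, modeledGuides)] == "mismatch" &
                         !hasPerfect[guideGene[targetGuides]]]
  freeGuides <- setdiff(targetGuides, pinned)

  y <- vapply(genes, function(gn) {
    rows <- tntRows[tntGene == gn]
    sum(w[rows] * m[rows] * x[tntGuide[tntGene == gn]]) /
      (sum(w[rows] * x[tntGuide[tntGene == gn]]^2) + ridge)
  }, numeric(1))
  names(y) <- genes

  pkeys <- pairKey(info$gene_a[interRows], info$gene_b[interRows])
  upairs <- sort(unique(pkeys))
  s <- setNames(numeric(length(upairs)), upairs)
  pidx <- match(pkeys, upairs)
  usplit <- strsplit(upairs, "\r", fixed = TRUE)
  upairA <- vapply(usplit, `[`, "", 1L)
  upairB <- vapply(usplit, `[`, "", 2L)

  # prebuilt index lists -----------------------------------------------------
  geneIdx <- lapply(genes, function(gn) {
    list(tnt = tntRows[tntGene == gn],
         tntG = tntGuide[tntGene == gn],
         intra = intraRows[info$gene_a[intraRows] == gn],
         interA = interRows[info$gene_a[interRows] == gn],
         interB = interRows[info$gene_b[interRows] == gn])
  })
  names(geneIdx) <- genes
  guideIdx <- lapply(freeGuides, function(gu) {
    list(tnt = tntRows[tntGuide == gu],
         interA = interRows[info$guide_a[interRows] == gu],
         interB = interRows[info$guide_b[interRows] == gu],
         intraA = intraRows[info$guide_a[intraRows] == gu],
         intraB = intraRows[info$guide_b[intraRows] == gu])
  })
  names(guideIdx) <- freeGuides

  pairOfInter <- setNames(pidx, NULL)  # inter row -> pair index
  sAt <- function(rows) s[pairOfInter[match(rows, interRows)]]

  converged <- FALSE
  iter <- 0L
  while (iter < maxIter) {
    iter <- iter + 1L
    xOld <- x; yOld <- y; sOld <- s

    # y updates (Gauss-Seidel over genes)
    for (gn in genes) {
      ix <- geneIdx[[gn]]
      num <- 0; den <- ridge
      if (length(ix$tnt)) {
        a <- x[ix$tntG]
        num <- num + sum(w[ix$tnt] * a * m[ix$tnt])
        den <- den + sum(w[ix$tnt] * a^2)
      }
      if (length(ix$intra)) {
        xa <- x[info$guide_a[ix$intra]]; xb <- x[info$guide_b[ix$intra]]
        a <- xa + xb - xa * xb
        num <- num + sum(w[ix$intra] * a * m[ix$intra])
        den <- den + sum(w[ix$intra] * a^2)
      }
      if (length(ix$interA)) {
        xa <- x[info$guide_a[ix$interA]]; xb <- x[info$guide_b[ix$interA]]
        o <- xb * y[info$gene_b[ix$interA]] + xa * xb * sAt(ix$interA)
        num <- num + sum(w[ix$interA] * xa * (m[ix$interA] - o))
        den <- den + sum(w[ix$interA] * xa^2)
      }
      if (length(ix$interB)) {
        xa <- x[info$guide_a[ix$interB]]; xb <- x[info$guide_b[ix$interB]]
        o <- xa * y[info$gene_a[ix$interB]] + xa * xb * sAt(ix$interB)
        num <- num + sum(w[ix$interB] * xb * (m[ix$interB] - o))
        den <- den + sum(w[ix$interB] * xb^2)
      }
      y[gn] <- num / den
    }

    # s updates (closed form per pair, vectorized)
    if (length(interRows)) {
      xa <- x[info$guide_a[interRows]]; xb <- x[info$guide_b[interRows]]
      r <- m[interRows] - xa * y[info$gene_a[interRows]] -
        xb * y[info$gene_b[interRows]]
      q <- xa * xb
      num <- rowsum(w[interRows] * q * r, pidx)
      den <- rowsum(w[interRows] * q^2, pidx) + ridge
      s[] <- (num / den)[match(seq_along(upairs), as.integer(rownames(num)))]
    }

    # x updates (projected closed form per free guide)
    for (gu in freeGuides) {
      ix <- guideIdx[[gu]]
      num <- 0; den <- 0
      if (length(ix$tnt)) {
        gn <- guideGene[gu]
        q <- rep(y[gn], length(ix$tnt))
        num <- num + sum(w[ix$tnt] * q * m[ix$tnt])
        den <- den + sum(w[ix$tnt] * q^2)
      }
      if (length(ix$interA)) {
        xb <- x[info$guide_b[ix$interA]]
        q <- y[info$gene_a[ix$interA]] + xb * sAt(ix$interA)
        o <- xb * y[info$gene_b[ix$interA]]
        num <- num + sum(w[ix$interA] * q * (m[ix$interA] - o))
        den <- den + sum(w[ix$interA] * q^2)
      }
      if (length(ix$interB)) {
        xa <- x[info$guide_a[ix$interB]]
        q <- y[info$gene_b[ix$interB]] + xa * sAt(ix$interB)
        o <- xa * y[info$gene_a[ix$interB]]
        num <- num + sum(w[ix$interB] * q * (m[ix$interB] - o))
        den <- den + sum(w[ix$interB] * q^2)
      }
      if (length(ix$intraA)) {
        gn <- guideGene[gu]
        xs <- x[info$guide_b[ix$intraA]]
        q <- y[gn] * (1 - xs); o <- y[gn] * xs
        num <- num + sum(w[ix$intraA] * q * (m[ix$intraA] - o))
        den <- den + sum(w[ix$intraA] * q^2)
      }
      if (length(ix$intraB)) {
        gn <- guideGene[gu]
        xs <- x[info$guide_a[ix$intraB]]
        q <- y[gn] * (1 - xs); o <- y[gn] * xs
        num <- num + sum(w[ix$intraB] * q * (m[ix$intraB] - o))
        den <- den + sum(w[ix$intraB] * q^2)
      }
      if (den > 1e-12) x[gu] <- min(max(num / den, 0), 1)
    }

    # per-gene anchor: max efficacy of genes with a perfect guide is 1
    for (gn in genes[hasPerfect]) {
      ids <- targetGuides[guideGene[targetGuides] == gn]
      mx <- max(x[ids])
      if (mx > 1e-8 && abs(mx - 1) > 1e-12) {
        x[ids] <- x[ids] / mx
        y[gn] <- y[gn] * mx
        hit <- upairA == gn | upairB == gn
        s[hit] <- s[hit] * mx
      }
    }

    delta <- max(abs(x - xOld), abs(y - yOld),
                 if (length(s)) abs(s - sOld) else 0)
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }

  mu <- muForElements(info, x, y, s)
  sigma2 <- (sum(w * (m - mu)^2) + ssWithin) / nObs
  sdf <- data.frame(gene_a = upairA, gene_b = upairB,
                    s = unname(s), stringsAsFactors = FALSE)
  if (!converged) {
    warning(sprintf("model did not converge in %d iterations (last delta above %g)",
                    maxIter, tol))
  }
  new("ModelFit", x = x, y = y, s = sdf,
      sigma = max(sqrt(sigma2), 1e-12),
      converged = converged, nIter = iter, seed = as.integer(seed),
      pinned = pinned)
}

#' Predict element LFCs from a model fit
#'
#' Evaluates the generative model mean for every element of the design that
#' the fit covers; when an LFC table is supplied the residual RMSE is
#' attached as attribute `rmse`.
#'
#' @param fit a \linkS4class{ModelFit}
#' @param design a \linkS4class{PairedGuideLibrary}
#' @param lfc optional \linkS4class{LfcTable} for the residual summary.
#' @return data.frame with `element_id`, `pair_class` and predicted `mu`
#'   (NA for elements whose parameters are not in the fit).
#' @export
predictLfc <- function(fit, design, lfc = NULL) {
  info <- design@elements
  sLookup <- setNames(fit@s$s, pairKey(fit@s$gene_a, fit@s$gene_b))
  known <- function(gid) gid %in% names(fit@x)
  x <- fit@x
  y <- fit@y
  covered <- (known(info$guide_a) & known(info$guide_b)) &
    (info$gene_a == NT_GENE | info$gene_a %in% names(y)) &
    (info$gene_b == NT_GENE | info$gene_b %in% names(y))
  mu <- rep(NA_real_, nrow(info))
  if (any(covered)) {
    mu[covered] <- muForElements(info[covered, , drop = FALSE], x, y, sLookup)
  }
  if (any(!covered)) {
    warning(sprintf("%d element(s) not covered by the fit", sum(!covered)))
  }
  out <- data.frame(element_id = info$element_id,
                    pair_class = info$pair_class, mu = mu,
                    stringsAsFactors = FALSE)
  if (!is.null(lfc)) {
    shared <- intersect(rownames(lfc@lfc), info$element_id)
    pm <- mu[match(shared, info$element_id)]
    resid <- lfc@lfc[shared, , drop = FALSE] - pm
    attr(out, "rmse") <- sqrt(mean(resid^2, na.rm = TRUE))
  }
  out
}
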