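#' Configure a simulated dual-guide screen
#'
#' Builds a validated \linkS4class{SimConfig}. The defaults encode the
#' screen conditions the package models: 15 non-targeting guides, about 18%
#' strongly essential genes (effects uniform on \[-5, -3\], each represented
#' by a top perfect guide plus a partial-activity mismatch variant), neutral
#' effects centered on 0, interaction effects uniform on \[-3, -1\] for 10%
#' of gene pairs, perfect-guide efficacies uniform on \[0.7, 1\] with each
#' gene's best guide anchored at 1, mismatch efficacies uniform on
#' \[0.3, 0.7\], ten population doublings over the 14-day screen, a mean T0
#' coverage of 500 reads per element with lognormal abundance skew, Poisson
#' count noise, and a 0.1% per-base sequencing error rate.
#'
#' @param nGenes,guidesPerGene,nNT library dimensions.
#' @param fracEssential fraction of genes with a strong negative effect.
#' @param fracInteracting fraction of gene pairs with a negative interaction.
#' @param yEssentialRange,yNeutralSd,sRange effect distributions (T14 LFC
#'   scale).
#' @param xPerfectRange,xMismatchRange guide efficacy distributions.
#' @param mismatchForEssential give essential genes a mismatch variant of
#'   their top guide (default TRUE).
#' @param activityNoiseSd measurement noise on the recorded empirical
#'   activity of mismatch guides.
#' @param doublings population doublings across the screen (default 10).
#' @param depthPerElement mean T0 reads per element (default 500).
#' @param abundanceSkew lognormal sdlog of T0 abundances.
#' @param seqErrorRate per-base substitution probability in FASTQ output.
#' @param dispersion negative-binomial dispersion; 0 (default) gives Poisson
#'   counts.
#' @param nReplicates biological replicates (default 2).
#' @param readLength simulated read length (>= 22).
#' @param seed master seed; all generator stages derive from it.
#' @return a \linkS4class{SimConfig}
#' @export
simConfig <- function(nGenes = 60L, guidesPerGene = 2L, nNT = 15L,
                      fracEssential = 0.18, fracInteracting = 0.10,
                      yEssentialRange = c(-5, -3), yNeutralSd = 0.2,
                      sRange = c(-3, -1), xPerfectRange = c(0.7, 1),
                      xMismatchRange = c(0.3, 0.7),
                      mismatchForEssential = TRUE, activityNoiseSd = 0.05,
                      doublings = 10, depthPerElement = 500,
                      abundanceSkew = 0.5, seqErrorRate = 0.001,
                      dispersion = 0, nReplicates = 2L, readLength = 22L,
                      seed = 1L) {
  new("SimConfig", nGenes = as.integer(nGenes),
      guidesPerGene = as.integer(guidesPerGene), nNT = as.integer(nNT),
      fracEssential = fracEssential, fracInteracting = fracInteracting,
      yEssentialRange = yEssentialRange, yNeutralSd = yNeutralSd,
      sRange = sRange, xPerfectRange = xPerfectRange,
      xMismatchRange = xMismatchRange,
      mismatchForEssential = mismatchForEssential,
      activityNoiseSd = activityNoiseSd, doublings = doublings,
      depthPerElement = depthPerElement, abundanceSkew = abundanceSkew,
      seqErrorRate = seqErrorRate, dispersion = dispersion,
      nReplicates = as.integer(nReplicates),
      readLength = as.integer(readLength), seed = as.integer(seed))
}

#' Simulate the ground truth of a dual-guide screen
#'
#' Draws gene effects, guide efficacies and pair interactions from the
#' configured distributions (with each gene's best perfect guide anchored at
#' efficacy 1), builds the combinatorial library with [buildPairSet()], and
#' evaluates the expected T14-scale phenotype of every element under the
#' interaction model. Fully deterministic given the config seed.
#'
#' @param config a \linkS4class{SimConfig}
#' @return a \linkS4class{SimTruth}
#' @export
simulateTruth <- function(config) {
  validObject(config)
  withLocalSeed(config@seed, {
    nG <- config@nGenes
    genes <- sprintf("G%04d", seq_len(nG))
    nEss <- round(config@fracEssential * nG)
    essential <- sort(sample(genes, nEss))
    y <- setNames(rnorm(nG, 0, config@yNeutralSd), genes)
    y[essential] <- runif(nEss, config@yEssentialRange[1],
                          config@yEssentialRange[2])

    gpg <- config@guidesPerGene
    rows <- vector("list", nG)
    for (i in seq_len(nG)) {
      gn <- genes[i]
      mm <- config@mismatchForEssential && gn %in% essential
      nPerf <- if (mm) gpg - 1L else gpg
      xp <- runif(nPerf, config@xPerfectRange[1], config@xPerfectRange[2])
      xp <- xp / max(xp)                       # per-gene anchor in the truth
      ids <- sprintf("%s_g%d", gn, seq_len(nPerf))
      df <- data.frame(guide_id = ids, gene = gn, tss_id = "T1",
                       guide_type = "perfect", parent_guide_id = "",
                       empirical_activity = NA_real_,
                       predicted_activity = NA_real_,
                       specificity_score = 1, rank_score = unname(y[gn]),
                       x_true = xp, stringsAsFactors = FALSE)
      if (mm) {
        xm <- runif(1, config@xMismatchRange[1], config@xMismatchRange[2])
        df <- rbind(df, data.frame(
          guide_id = paste0(gn, "_g1m"), gene = gn, tss_id = "T1",
          guide_type = "mismatch", parent_guide_id = ids[1],
          empirical_activity = pmin(pmax(
            xm + rnorm(1, 0, config@activityNoiseSd), 0.02), 0.98),
          predicted_activity = pmin(pmax(xm + rnorm(1, 0, 0.1), 0.02), 0.98),
          specificity_score = 1, rank_score = unname(y[gn]), x_true = xm,
          stringsAsFactors = FALSE))
      }
      rows[[i]] <- df
    }
    guideTable <- do.call(rbind, rows)
    ntTable <- data.frame(guide_id = sprintf("NT_g%02d", seq_len(config@nNT)),
                          gene = NT_GENE, tss_id = "T1",
                          guide_type = "non_targeting", parent_guide_id = "",
                          empirical_activity = NA_real_,
                          predicted_activity = NA_real_,
                          specificity_score = 1, rank_score = NA_real_,
                          stringsAsFactors = FALSE)
    nGuides <- nrow(guideTable) + nrow(ntTable)
    protos <- randomDnaStrings(nGuides, 20L)
    while (anyDuplicated(protos)) {
      dup <- duplicated(protos)
      protos[dup] <- randomDnaStrings(sum(dup), 20L)
    }
    guideTable$protospacer <- protos[seq_len(nrow(guideTable))]
    ntTable$protospacer <- protos[nrow(guideTable) + seq_len(nrow(ntTable))]

    x <- setNames(c(guideTable$x_true, rep(0, nrow(ntTable))),
                  c(guideTable$guide_id, ntTable$guide_id))
    guideTable$x_true <- NULL

    cp <- combn(genes, 2L)
    nPairs <- ncol(cp)
    sVal <- numeric(nPairs)
    nInt <- round(config@fracInteracting * nPairs)
    if (nInt > 0L) {
      hit <- sample(nPairs, nInt)
      sVal[hit] <- runif(nInt, config@sRange[1], config@sRange[2])
    }
    sdf <- data.frame(gene_a = cp[1L, ], gene_b = cp[2L, ], s = sVal,
                      stringsAsFactors = FALSE)

    lib <- buildPairSet(guideTable, ntTable,
                        orientationSeed = config@seed,
                        expectedNT = config@nNT)
    sLookup <- setNames(sdf$s, pairKey(sdf$gene_a, sdf$gene_b))
    phi <- setNames(muForElements(lib@elements, x, y, sLookup),
                    lib@elements$element_id)
    new("SimTruth", library = lib, x = x, y = y, s = sdf, phi = phi,
        config = config)
  })
}

#' Simulate screen count matrices from a ground truth
#'
#' T0 abundances per element are lognormal around the configured mean depth;
#' the expected T14 abundance multiplies in the exponential growth factor
#' `2^(phi * doublings / 10)` (phi is parameterized on the 14-day/10-doubling
#' LFC scale) and each T14 sample is renormalized to the same mean
#' sequencing depth, as a sequencer fixes total reads. Counts are Poisson
#' (or negative binomial when `dispersion > 0`) around these means,
#' independently per replicate and timepoint.
#'
#' @param truth a \linkS4class{SimTruth}
#' @param seed RNG seed (default: config seed + 1000).
#' @return a \linkS4class{ScreenCounts} with samples
#'   `R<rep>_T0`, `R<rep>_T14`.
#' @export
simulateScreenCounts <- function(truth, seed = NULL) {
  config <- truth@config
  if (is.null(seed)) seed <- config@seed + 1000L
  withLocalSeed(seed, {
    el <- truth@library@elements
    nEl <- nrow(el)
    depth <- config@depthPerElement
    sk <- config@abundanceSkew
    a <- depth * rlnorm(nEl, meanlog = -sk^2 / 2, sdlog = sk)
    growth <- 2^(truth@phi * config@doublings / 10)
    w <- a * growth
    t14mean <- depth * w / mean(w)
    draw <- function(mu) {
      if (config@dispersion > 0) {
        rnbinom(length(mu), size = 1 / config@dispersion, mu = mu)
      } else {
        rpois(length(mu), mu)
      }
    }
    reps <- seq_len(config@nReplicates)
    counts <- matrix(0L, nEl, 2L * length(reps))
    cn <- character(2L * length(reps))
    replicate <- character(2L * length(reps))
    timepoint <- character(2L * length(reps))
    for (r in reps) {
      counts[, 2L * r - 1L] <- draw(a)
      counts[, 2L * r] <- draw(t14mean)
      cn[2L * r - 1L] <- sprintf("R%d_T0", r)
      cn[2L * r] <- sprintf("R%d_T14", r)
      replicate[(2L * r - 1L):(2L * r)] <- sprintf("R%d", r)
      timepoint[(2L * r - 1L):(2L * r)] <- c("T0", "T14")
    }
    dimnames(counts) <- list(el$element_id, cn)
    ScreenCounts(counts, replicate, timepoint,
                 rowData = el[, setdiff(ELEMENT_COLS, "element_id")])
  })
}

# substitute random bases at the given per-base rate (vectorized by position)
mutateReads <- function(reads, rate) {
  if (rate <= 0 || length(reads) == 0L) return(reads)
  len <- nchar(reads[1L])
  bases <- c("A", "C", "G", "T")
  for (p in seq_len(len)) {
    i <- which(runif(length(reads)) < rate)
    if (length(i)) {
      cur <- substr(reads[i], p, p)
      repl <- bases[(match(cur, bases) + sample(1:3, length(i),
                                                replace = TRUE) - 1L) %% 4L + 1L]
      substr(reads[i], p, p) <- repl
    }
  }
  reads
}

#' Write simulated paired FASTQ files for a count matrix
#'
#' Emits one read pair per count unit: read 1 carries the element's
#' position-a protospacer at offset 0 followed by random filler, read 2 the
#' position-b protospacer likewise. Filler is rejection-sampled so that no
#' scanned 20-mer window accidentally equals a library protospacer,
#' substitution errors are applied at the configured per-base rate, and the
#' read order is shuffled deterministically per seed.
#'
#' @param counts a \linkS4class{ScreenCounts}
#' @param truth the generating \linkS4class{SimTruth}
#' @param dir output directory (created if needed).
#' @param seed RNG seed (default: config seed + 2000).
#' @param gzip write gzip-compressed FASTQ (default FALSE).
#' @return sample sheet data.frame (`sample_id`, `fastq_r1`, `fastq_r2`,
#'   `replicate`, `timepoint`) ready for [countScreen()].
#' @export
simulateFastq <- function(counts, truth, dir, seed = NULL, gzip = FALSE) {
  config <- truth@config
  if (is.null(seed)) seed <- config@seed + 2000L
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  g <- truth@library@guides
  el <- truth@library@elements
  stopifnot(identical(rownames(counts), el$element_id))
  protoA <- g$protospacer[match(el$guide_a, g$guide_id)]
  protoB <- g$protospacer[match(el$guide_b, g$guide_id)]
  allProtos <- unique(g$protospacer)
  fillerLen <- config@readLength - 20L
  ext <- if (gzip) ".fastq.gz" else ".fastq"
  m <- assay(counts, "counts")
  cd <- colData(counts)
  sheet <- data.frame(sample_id = colnames(m),
                      fastq_r1 = file.path(dir, paste0(colnames(m), "_R1", ext)),
                      fastq_r2 = file.path(dir, paste0(colnames(m), "_R2", ext)),
                      replicate = cd$replicate, timepoint = cd$timepoint,
                      stringsAsFactors = FALSE)
  makeReads <- function(proto) {
    reads <- paste0(proto, randomDnaStrings(length(proto), fillerLen))
    # avoid spurious protospacer hits at scan offsets 1 and 2
    for (try in 1:10) {
      bad <- substr(reads, 2L, 21L) %in% allProtos |
        substr(reads, 3L, 22L) %in% allProtos
      if (!any(bad)) break
      reads[bad] <- paste0(proto[bad],
                           randomDnaStrings(sum(bad), fillerLen))
    }
    mutateReads(reads, config@seqErrorRate)
  }
  withLocalSeed(seed, {
    for (j in seq_len(ncol(m))) {
      idx <- rep.int(seq_len(nrow(m)), m[, j])
      ord <- if (length(idx)) sample(length(idx)) else integer(0)
      idx <- idx[ord]
      r1 <- makeReads(protoA[idx])
      r2 <- makeReads(protoB[idx])
      nm <- sprintf("read%07d", seq_along(idx))
      writeXStringSet(DNAStringSet(setNames(r1, nm)), sheet$fastq_r1[j],
                      format = "fastq", compress = gzip)
      writeXStringSet(DNAStringSet(setNames(r2, nm)), sheet$fastq_r2[j],
                      format = "fastq", compress = gzip)
    }
  })
  sheet
}

#' Simulate a complete screen (truth + counts)
#'
#' @param config a \linkS4class{SimConfig}
#' @return list with elements `truth` and `counts`.
#' @export
simulateScreen <- function(config) {
  truth <- simulateTruth(config)
  list(truth = truth, counts = simulateScreenCounts(truth))
}

#' Run the standard analysis pipeline on a counted screen
#'
#' Convenience wrapper chaining the T0 filter, NT-anchored median-ratio size
#' factors, pseudo-counted LFCs, essential-guide calling, mismatch-variant
#' substitution, the interaction model fit and gene-pair scoring.
#'
#' @param counts a \linkS4class{ScreenCounts}
#' @param design the matching \linkS4class{PairedGuideLibrary}
#' @param minReads T0 filter threshold (default 50).
#' @param pseudo,nominalCoverage see [computeLfc()].
#' @param reference see [estimateSizeFactors()].
#' @param essentialThreshold see [callEssentialGuides()].
#' @param substitute apply [substituteMismatchVariants()] (default TRUE).
#' @param lambda,cutoff see [scoreGenePairs()].
#' @param seed recorded in the model fit.
#' @param ... passed to [fitInteractionModel()].
#' @return list with `sizeFactors`, `lfc`, `essential`, `fit`, `scores`.
#' @export
analyzeScreen <- function(counts, design, minReads = 50L, pseudo = 10,
                          nominalCoverage = 500, reference = "nt_nt",
                          essentialThreshold = -3, substitute = TRUE,
                          lambda = 1, cutoff = -1, seed = 1L, ...) {
  sf <- estimateSizeFactors(counts, reference = reference)
  filtered <- filterMinT0(counts, minReads = minReads)
  lfc <- computeLfc(filtered, sf, pseudo = pseudo,
                    nominalCoverage = nominalCoverage)
  ess <- callEssentialGuides(lfc, design, threshold = essentialThreshold)
  if (substitute) {
    lfc <- substituteMismatchVariants(lfc, ess, design)
  }
  fit <- fitInteractionModel(lfc, design, seed = seed, ...)
  scores <- scoreGenePairs(fit, lambda = lambda, cutoff = cutoff)
  list(sizeFactors = sf, lfc = lfc, essential = ess, fit = fit,
       scores = scores)
}

#' Parameter-recovery metrics against a simulation truth
#'
#' Compares a fitted model and its scores with the generating truth:
#' Pearson correlation of true and fitted gene effects, correlation of true
#' and fitted interaction effects restricted to truly interacting pairs
#' (`s_true < 0`), precision and recall of synthetic-lethal calls at the
#' cutoff (truth positive: `s_true <= cutoff`), and the false-positive call
#' rate among truly non-interacting pairs.
#'
#' @param fit a \linkS4class{ModelFit}
#' @param scores the matching \linkS4class{InteractionScores}
#' @param truth the generating \linkS4class{SimTruth}
#' @param cutoff synthetic-lethal cutoff (default -1).
#' @return list of metrics (`r_y`, `r_s_interacting`, `precision`, `recall`,
#'   `fpr`, counts).
#' @export
recoveryReport <- function(fit, scores, truth, cutoff = -1) {
  genes <- names(fit@y)
  if (!all(genes %in% names(truth@y))) {
    stop("gene universes of fit and truth do not match")
  }
  tKey <- pairKey(truth@s$gene_a, truth@s$gene_b)
  sTrueAll <- setNames(truth@s$s, tKey)
  fKey <- pairKey(fit@s$gene_a, fit@s$gene_b)
  if (!all(fKey %in% tKey)) {
    stop("gene-pair universes of fit and truth do not match")
  }
  yTrue <- truth@y[genes]
  rY <- if (length(genes) >= 3L) cor(yTrue, fit@y[genes]) else NA_real_
  sTrue <- sTrueAll[fKey]
  int <- sTrue < 0
  rS <- if (sum(int) >= 3L) cor(sTrue[int], fit@s$s[int]) else NA_real_
  st <- scoreTable(scores)
  sKey <- pairKey(st$gene_a, st$gene_b)
  sTrueScored <- sTrueAll[sKey]
  called <- st$sensitive_score <= cutoff
  truthPos <- sTrueScored <= cutoff
  tp <- sum(called & truthPos)
  precision <- if (sum(called)) tp / sum(called) else NA_real_
  recall <- if (sum(truthPos)) tp / sum(truthPos) else NA_real_
  null <- sTrueScored == 0
  fpr <- if (sum(null)) mean(called[null]) else NA_real_
  list(r_y = unname(rY), r_s_interacting = unname(rS),
       precision = precision, recall = recall, fpr = fpr,
       n_pairs_scored = nrow(st), n_true_interacting = sum(int),
       n_called = sum(called))
}
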