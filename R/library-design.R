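#' Assign genes to ranking tiers
#'
#' Genes essential for growth in K562 cells form tier 1; remaining genes
#' that scored as significant hits in at least four CRISPRi screens form
#' tier 2; everything else is tier 3. Tiers determine which score is used to
#' rank a gene's candidate guides (see [rankGuides()]).
#'
#' @param geneTable data.frame with columns `gene`, `essential_in_K562`
#'   (logical) and `n_screens_hit` (integer).
#' @return the input with an integer `tier` column added.
#' @examples
#' assignTiers(data.frame(gene = c("A", "B", "C"),
#'                        essential_in_K562 = c(TRUE, FALSE, FALSE),
#'                        n_screens_hit = c(9L, 4L, 0L)))$tier
#' @export
assignTiers <- function(geneTable) {
  checkColumns(geneTable, c("gene", "essential_in_K562", "n_screens_hit"),
               "gene table")
  bad <- is.na(geneTable$essential_in_K562) | is.na(geneTable$n_screens_hit)
  if (any(bad)) {
    stop("missing tier flags for gene(s): ",
         paste(geneTable$gene[bad], collapse = ", "))
  }
  geneTable$tier <- ifelse(geneTable$essential_in_K562, 1L,
                    ifelse(geneTable$n_screens_hit >= 4L, 2L, 3L))
  geneTable
}

#' Rank candidate guides within a tier
#'
#' Orders one gene's candidate guides by their tier-specific `rank_score`,
#' strongest first. For tiers 1 and 2 the score is a growth phenotype
#' (log2 depletion; more negative is stronger), so ranking is ascending.
#' For tier 3 the score is an activity-prediction regression score (higher
#' is better), so ranking is descending. Ties break lexicographically on
#' `guide_id` for full determinism.
#'
#' @param candidates data.frame of guides for one gene with `guide_id`,
#'   `gene` and `rank_score` columns.
#' @param tier 1, 2 or 3.
#' @return `candidates` reordered, strongest guide first.
#' @export
rankGuides <- function(candidates, tier) {
  if (!tier %in% 1:3) stop("tier must be 1, 2 or 3")
  if (is.null(nrow(candidates)) || nrow(candidates) == 0L) {
    stop("empty candidate list")
  }
  checkColumns(candidates, c("guide_id", "gene", "rank_score"), "candidates")
  if (length(unique(candidates$gene)) != 1L) {
    stop("all candidates must target the same gene")
  }
  if (any(is.na(candidates$rank_score))) {
    stop("rank_score missing for guide(s): ",
         paste(candidates$guide_id[is.na(candidates$rank_score)],
               collapse = ", "))
  }
  key <- if (tier == 3L) -candidates$rank_score else candidates$rank_score
  candidates[order(key, candidates$guide_id), , drop = FALSE]
}

#' Select the mismatch variant of a guide
#'
#' Among singly mismatched variants of `parent`, drops variants with an
#' on-target specificity score below 0.15, then picks the variant with
#' empirically measured relative activity inside the 0.47 +/- 0.15 window
#' that lies closest to 0.47; if no variant has a measured activity in that
#' window, picks the surviving variant whose predicted activity is closest
#' to 0.5. Ties break lexicographically on `guide_id`.
#'
#' @param parent single-row data.frame, the perfect guide.
#' @param variants data.frame of candidate mismatch variants of `parent`.
#' @param activityCenter,activityHalfWidth the empirical-activity selection
#'   window (defaults 0.47 and 0.15).
#' @param minSpecificity minimum specificity score (default 0.15).
#' @return the selected variant row, or `NULL` (with a warning of class
#'   `dualscreen_no_variant`) when no admissible variant exists.
#' @export
selectMismatchVariant <- function(parent, variants,
                                  activityCenter = 0.47,
                                  activityHalfWidth = 0.15,
                                  minSpecificity = 0.15) {
  if (is.null(variants) || nrow(variants) == 0L) {
    warning(warningCondition(
      sprintf("no admissible mismatch variant for guide %s", parent$guide_id),
      class = "dualscreen_no_variant"))
    return(NULL)
  }
  checkColumns(variants, c("guide_id", "parent_guide_id",
                           "empirical_activity", "predicted_activity",
                           "specificity_score"), "variants")
  if (!all(variants$parent_guide_id == parent$guide_id)) {
    stop("variants must all derive from the given parent guide")
  }
  keep <- !is.na(variants$specificity_score) &
    variants$specificity_score >= minSpecificity
  surv <- variants[keep, , drop = FALSE]
  if (nrow(surv) == 0L) {
    warning(warningCondition(
      sprintf("no admissible mismatch variant for guide %s", parent$guide_id),
      class = "dualscreen_no_variant"))
    return(NULL)
  }
  lo <- activityCenter - activityHalfWidth
  hi <- activityCenter + activityHalfWidth
  inWin <- !is.na(surv$empirical_activity) &
    surv$empirical_activity >= lo & surv$empirical_activity <= hi
  if (any(inWin)) {
    cand <- surv[inWin, , drop = FALSE]
    d <- abs(cand$empirical_activity - activityCenter)
  } else {
    cand <- surv[!is.na(surv$predicted_activity), , drop = FALSE]
    if (nrow(cand) == 0L) {
      warning(warningCondition(
        sprintf("no admissible mismatch variant for guide %s", parent$guide_id),
        class = "dualscreen_no_variant"))
      return(NULL)
    }
    d <- abs(cand$predicted_activity - 0.5)
  }
  cand[order(d, cand$guide_id), , drop = FALSE][1L, , drop = FALSE]
}

#' Select the guides representing one gene
#'
#' For a gene with a strong knockout growth phenotype, each transcription
#' start site contributes its top-ranked guide plus that guide's selected
#' mismatch variant (to blunt the essential phenotype); otherwise each TSS
#' contributes its top two perfect guides. When a strong-phenotype TSS has
#' no admissible mismatch variant, the top two perfect guides are used as a
#' fallback and a warning is emitted.
#'
#' @param meta single-row data.frame with `gene` and `strong_ko_phenotype`.
#' @param ranked named list (one entry per TSS) of guide data.frames already
#'   ordered strongest-first (see [rankGuides()]).
#' @param variants data.frame pool of mismatch variants (any parent).
#' @return data.frame of selected guides for the gene.
#' @export
selectGeneGuides <- function(meta, ranked, variants = NULL) {
  stopifnot(length(ranked) >= 1L)
  out <- vector("list", length(ranked))
  for (i in seq_along(ranked)) {
    r <- ranked[[i]]
    if (is.null(r) || nrow(r) == 0L) {
      stop(sprintf("no candidates for TSS '%s' of gene %s",
                   names(ranked)[i], meta$gene))
    }
    if (isTRUE(meta$strong_ko_phenotype)) {
      top <- r[1L, , drop = FALSE]
      pool <- if (is.null(variants)) NULL else
        variants[variants$parent_guide_id == top$guide_id, , drop = FALSE]
      var <- selectMismatchVariant(top, pool)
      if (is.null(var)) {
        if (nrow(r) < 2L) {
          stop(sprintf("TSS '%s' of gene %s has no mismatch variant and <2 perfect guides",
                       names(ranked)[i], meta$gene))
        }
        warning(sprintf("gene %s TSS '%s': falling back to top-2 perfect guides",
                        meta$gene, names(ranked)[i]))
        out[[i]] <- r[1:2, , drop = FALSE]
      } else {
        out[[i]] <- rbind(top[, intersect(names(top), names(var)), drop = FALSE],
                          var[, intersect(names(top), names(var)), drop = FALSE])
      }
    } else {
      if (nrow(r) < 2L) {
        stop(sprintf("TSS '%s' of gene %s has fewer than 2 candidates",
                     names(ranked)[i], meta$gene))
      }
      out[[i]] <- r[1:2, , drop = FALSE]
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Build the combinatorial dual-guide pair set
#'
#' Realizes the full pairing scheme of a combinatorial dual-guide library:
#' \itemize{
#'   \item every unordered pair of targeted genes is randomly assigned one
#'     orientation ("ab" or "ba"; seeded RNG over lexicographically sorted
#'     gene pairs) and all guide cross-products are realized in that
#'     orientation (`inter_gene`);
#'   \item distinct guides of the same gene are paired once, in canonical
#'     guide_id-sorted orientation (`intra_gene`);
#'   \item every targeting guide is paired with every non-targeting guide in
#'     both orientations (`targeting_nt`; 30 elements per guide with the
#'     standard 15 NT controls);
#'   \item all ordered combinations of the non-targeting guides are included
#'     as negative controls (`nt_nt`; 225 elements with 15 NT guides).
#' }
#'
#' @param guideTable data.frame of targeting guides (columns of
#'   `GUIDE_COLS`; missing annotation columns are filled with `NA`).
#' @param ntGuides data.frame of non-targeting guides (gene must be
#'   `NT_GENE`).
#' @param orientationSeed integer seed for the ab/ba orientation draw.
#' @param expectedNT required number of NT guides (default 15; the build is
#'   rejected when `ntGuides` differs).
#' @return a \linkS4class{PairedGuideLibrary}
#' @examples
#' # a toy 2-gene design (real designs use genome-derived protospacers)
#' proto <- apply(matrix(sample(c("A", "C", "G", "T"), 19 * 20,
#'                              replace = TRUE), nrow = 19), 1,
#'                paste, collapse = "")
#' g <- data.frame(guide_id = c("A_g1", "A_g2", "B_g1", "B_g2"),
#'                 gene = rep(c("A", "B"), each = 2),
#'                 protospacer = proto[1:4])
#' nt <- data.frame(guide_id = sprintf("NT_%02d", 1:15), gene = "NT",
#'                  protospacer = proto[5:19])
#' design <- buildPairSet(g, nt, orientationSeed = 1)
#' libraryStats(design)$by_class
#' @export
buildPairSet <- function(guideTable, ntGuides, orientationSeed = 1L,
                         expectedNT = 15L) {
  guideTable <- completeGuideColumns(guideTable, default_type = "perfect")
  ntGuides <- completeGuideColumns(ntGuides, default_type = "non_targeting")
  ntGuides$gene <- NT_GENE
  ntGuides$guide_type <- "non_targeting"
  if (nrow(ntGuides) != expectedNT) {
    stop(sprintf("expected exactly %d non-targeting guides, got %d",
                 expectedNT, nrow(ntGuides)))
  }
  g <- rbind(guideTable, ntGuides)
  if (anyDuplicated(g$guide_id)) {
    stop("duplicate guide_ids: ",
         paste(unique(g$guide_id[duplicated(g$guide_id)]), collapse = ", "))
  }
  ok <- validGuides(g)
  if (!isTRUE(ok)) stop(ok)
  genes <- sort(unique(guideTable$gene))
  byGene <- split(guideTable$guide_id, guideTable$gene)
  byGene <- lapply(byGene, sort)
  nPerGene <- lengths(byGene)
  if (any(nPerGene < 2L)) {
    stop("every gene needs at least 2 guides; offending: ",
         paste(names(nPerGene)[nPerGene < 2L], collapse = ", "))
  }

  # --- inter-gene elements -------------------------------------------------
  inter <- NULL
  if (length(genes) >= 2L) {
    cp <- combn(genes, 2L)                   # columns sorted lexicographically
    nPair <- ncol(cp)
    flip <- withLocalSeed(orientationSeed,
                          sample(c(FALSE, TRUE), nPair, replace = TRUE))
    geneA <- ifelse(flip, cp[2L, ], cp[1L, ])
    geneB <- ifelse(flip, cp[1L, ], cp[2L, ])
    nA <- nPerGene[geneA]
    nB <- nPerGene[geneB]
    m <- nA * nB
    pairIdx <- rep.int(seq_len(nPair), m)
    local0 <- sequence(m) - 1L
    nAe <- nA[pairIdx]
    aLoc <- local0 %% nAe
    bLoc <- local0 %/% nAe
    # guide ids ordered by gene, with per-gene offsets
    allGuides <- unlist(byGene, use.names = FALSE)
    off <- setNames(cumsum(c(0L, nPerGene[-length(nPerGene)])),
                    names(nPerGene))
    ga <- allGuides[off[geneA[pairIdx]] + aLoc + 1L]
    gb <- allGuides[off[geneB[pairIdx]] + bLoc + 1L]
    inter <- data.frame(guide_a = ga, guide_b = gb,
                        gene_a = geneA[pairIdx], gene_b = geneB[pairIdx],
                        pair_class = "inter_gene", stringsAsFactors = FALSE)
  }

  # --- intra-gene elements (unordered distinct pairs, canonical order) -----
  intra <- NULL
  if (any(nPerGene >= 2L)) {
    intraList <- lapply(genes, function(gn) {
      ids <- byGene[[gn]]
      cp <- combn(ids, 2L)
      data.frame(guide_a = cp[1L, ], guide_b = cp[2L, ],
                 gene_a = gn, gene_b = gn, pair_class = "intra_gene",
                 stringsAsFactors = FALSE)
    })
    intra <- do.call(rbind, intraList)
  }

  # --- targeting x NT, both orientations -----------------------------------
  tg <- guideTable$guide_id
  tgGene <- guideTable$gene
  ntIds <- sort(ntGuides$guide_id)
  tnt <- data.frame(
    guide_a = c(rep(tg, each = length(ntIds)),
                rep(ntIds, times = length(tg))),
    guide_b = c(rep(ntIds, times = length(tg)),
                rep(tg, each = length(ntIds))),
    gene_a = c(rep(tgGene, each = length(ntIds)),
               rep(NT_GENE, length(ntIds) * length(tg))),
    gene_b = c(rep(NT_GENE, length(ntIds) * length(tg)),
               rep(tgGene, each = length(ntIds))),
    pair_class = "targeting_nt", stringsAsFactors = FALSE)

  # --- NT x NT negative controls (all ordered combinations) ----------------
  ntnt <- data.frame(
    guide_a = rep(ntIds, each = length(ntIds)),
    guide_b = rep(ntIds, times = length(ntIds)),
    gene_a = NT_GENE, gene_b = NT_GENE,
    pair_class = "nt_nt", stringsAsFactors = FALSE)

  e <- rbind(inter, intra, tnt, ntnt)
  e <- data.frame(element_id = makeElementId(e$guide_a, e$guide_b), e,
                  stringsAsFactors = FALSE)
  if (anyDuplicated(e$element_id)) {
    stop("internal error: duplicate element ids generated")
  }
  rownames(e) <- NULL
  design <- new("PairedGuideLibrary", guides = g, elements = e,
                orientationSeed = as.integer(orientationSeed),
                stats = list())
  design@stats <- libraryStats(design)
  design
}

# fill optional guide annotation columns with NA so rbind is well-defined
completeGuideColumns <- function(g, default_type) {
  checkColumns(g, c("guide_id", "gene", "protospacer"), "guide table")
  if (is.null(g$tss_id)) g$tss_id <- "T1"
  if (is.null(g$guide_type)) g$guide_type <- default_type
  if (is.null(g$parent_guide_id)) g$parent_guide_id <- ""
  g$parent_guide_id[is.na(g$parent_guide_id)] <- ""
  for (col in c("empirical_activity", "predicted_activity",
                "specificity_score", "rank_score")) {
    if (is.null(g[[col]])) g[[col]] <- NA_real_
  }
  g[, GUIDE_COLS]
}

#' Library design statistics
#'
#' Recomputes the design summary from the element table: element counts per
#' pair class, the number of targeted genes `G`, the number of gene-level
#' interactions queried (`choose(G, 2)`), and the number of guide-level
#' interactions (elements whose two positions both carry targeting guides).
#'
#' @param design a \linkS4class{PairedGuideLibrary}
#' @return list with `n_genes`, `gene_level_interactions`,
#'   `guide_level_interactions`, `by_class`, `n_elements`.
#' @export
libraryStats <- function(design) {
  e <- design@elements
  byClass <- table(factor(e$pair_class, levels = PAIR_CLASSES))
  byClass <- setNames(as.integer(byClass), names(byClass))
  genes <- unique(c(e$gene_a, e$gene_b))
  genes <- genes[genes != NT_GENE]
  G <- length(genes)
  list(n_genes = G,
       gene_level_interactions = as.integer(choose(G, 2)),
       guide_level_interactions =
         as.integer(byClass[["inter_gene"]] + byClass[["intra_gene"]]),
       by_class = byClass,
       n_elements = nrow(e))
}
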