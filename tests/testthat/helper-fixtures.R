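# shared fixtures, all generated in code

# deterministic unique 20-mers
makeProtos <- function(n, seed = 99) {
  set.seed(seed)
  p <- dualscreen:::randomDnaStrings(n, 20L)
  while (anyDuplicated(p)) {
    dup <- duplicated(p)
    p[dup] <- dualscreen:::randomDnaStrings(sum(dup), 20L)
  }
  p
}

mkGuideTable <- function(nGenes = 3L, perGene = 2L, seed = 99,
                         genes = sprintf("GEN%02d", seq_len(nGenes))) {
  ids <- unlist(lapply(genes, function(g) sprintf("%s_g%d", g, seq_len(perGene))))
  data.frame(guide_id = ids,
             gene = rep(genes, each = perGene),
             protospacer = makeProtos(length(ids), seed = seed),
             stringsAsFactors = FALSE)
}

mkNtTable <- function(n = 15L, seed = 77) {
  data.frame(guide_id = sprintf("NT_g%02d", seq_len(n)),
             gene = "NT",
             protospacer = makeProtos(n, seed = seed),
             stringsAsFactors = FALSE)
}

toyDesign <- function(nGenes = 3L, perGene = 2L, seed = 1L, ntSeed = 77) {
  buildPairSet(mkGuideTable(nGenes, perGene), mkNtTable(seed = ntSeed),
               orientationSeed = seed)
}

# LfcTable built directly from values (no count matrices)
mkLfc <- function(values, info, reps = 2L) {
  m <- matrix(rep(values, reps), ncol = reps,
              dimnames = list(info$element_id, paste0("R", seq_len(reps))))
  new("LfcTable", lfc = m, pseudocount = 10, effectivePseudo = 10,
      elementInfo = info)
}

# minimal ScreenCounts from a matrix with samples R*_T0 / R*_T14
mkCounts <- function(m, rowData = NULL) {
  parts <- strsplit(colnames(m), "_", fixed = TRUE)
  ScreenCounts(m,
               replicate = vapply(parts, `[`, "", 1L),
               timepoint = vapply(parts, `[`, "", 2L),
               rowData = rowData)
}

# minimal ModelFit for scoring tests
mkFit <- function(y, s, x = NULL, converged = TRUE) {
  if (is.null(x)) {
    x <- stats::setNames(rep(1, length(y)), paste0(names(y), "_g1"))
  }
  new("ModelFit", x = x, y = y, s = s, sigma = 0.1,
      converged = converged, nIter = 1L, seed = 1L, pinned = character())
}

# canonical-pair score table
mkScoreTable <- function(gene_a, gene_b, sensitive, strong = sensitive,
                         cutoff = -1) {
  a <- pmin(gene_a, gene_b)
  b <- pmax(gene_a, gene_b)
  data.frame(gene_a = a, gene_b = b,
             raw_sensitive = sensitive, raw_strong = strong,
             sensitive_score = pmin(sensitive, 0),
             strong_score = pmin(strong, 0),
             is_synthetic_lethal = pmin(sensitive, 0) <= cutoff,
             stringsAsFactors = FALSE)
}
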