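#' Call synthetic-lethal gene pairs
#'
#' Flags pairs whose sensitive score is at or below the cutoff (default -1),
#' sorted ascending (strongest interaction first).
#'
#' @param scores an \linkS4class{InteractionScores} or its score table.
#' @param cutoff inclusive score cutoff (default -1).
#' @return data.frame of flagged pairs sorted by sensitive score.
#' @export
callSyntheticLethal <- function(scores, cutoff = -1) {
  tab <- if (is(scores, "InteractionScores")) scoreTable(scores) else scores
  checkColumns(tab, c("gene_a", "gene_b", "sensitive_score"), "score table")
  hit <- tab[tab$sensitive_score <= cutoff, , drop = FALSE]
  hit <- hit[order(hit$sensitive_score, hit$gene_a, hit$gene_b), , drop = FALSE]
  rownames(hit) <- NULL
  hit
}

#' Build the annotated synthetic-lethal network
#'
#' Nodes are genes incident to at least one flagged pair; edge weight is the
#' absolute sensitive score. Node flags `cancer_gene` and `druggable` are set
#' by membership in the user-supplied annotation sets (e.g. COSMIC tier 1/2
#' genes and DGIdb targets; this package does not bundle external
#' databases). An edge is `actionable` when one endpoint is cancer-flagged
#' and the other drug-flagged.
#'
#' @param pairs flagged pair data.frame from [callSyntheticLethal()].
#' @param cancerGenes,drugTargets character vectors of gene symbols.
#' @return an [igraph::igraph] with the attributes above.
#' @seealso [writeNetworkGraphML()]
#' @export
buildNetwork <- function(pairs, cancerGenes = character(),
                         drugTargets = character()) {
  checkColumns(pairs, c("gene_a", "gene_b", "sensitive_score"), "pairs")
  edges <- data.frame(from = pairs$gene_a, to = pairs$gene_b,
                      weight = abs(pairs$sensitive_score),
                      stringsAsFactors = FALSE)
  nodes <- sort(unique(c(edges$from, edges$to)))
  vdf <- data.frame(name = nodes,
                    cancer_gene = nodes %in% cancerGenes,
                    druggable = nodes %in% drugTargets,
                    stringsAsFactors = FALSE)
  g <- graph_from_data_frame(edges, directed = FALSE, vertices = vdf)
  if (ecount(g)) {
    ca <- V(g)$cancer_gene
    dr <- V(g)$druggable
    el <- igraph::ends(g, E(g), names = FALSE)
    E(g)$actionable <- (ca[el[, 1]] & dr[el[, 2]]) |
      (ca[el[, 2]] & dr[el[, 1]])
  }
  g
}

#' Export a network as GraphML
#'
#' @param graph an igraph network (see [buildNetwork()]).
#' @param file output path.
#' @export
writeNetworkGraphML <- function(graph, file) {
  write_graph(graph, file, format = "graphml")
  invisible(file)
}

# symmetric gene x gene score matrix; unqueried pairs stay at 0, the
# non-interacting value under the clipping convention
symmetricScoreMatrix <- function(tab, value = "sensitive_score",
                                 genes = NULL) {
  if (is.null(genes)) genes <- sort(unique(c(tab$gene_a, tab$gene_b)))
  m <- matrix(0, length(genes), length(genes),
              dimnames = list(genes, genes))
  ia <- match(tab$gene_a, genes)
  ib <- match(tab$gene_b, genes)
  keep <- !is.na(ia) & !is.na(ib)
  m[cbind(ia[keep], ib[keep])] <- tab[[value]][keep]
  m[cbind(ib[keep], ia[keep])] <- tab[[value]][keep]
  m
}

#' Cluster genetic-interaction profiles
#'
#' Computes the mean `m` and standard deviation `sd` of all non-zero
#' sensitive scores, retains genes with at least one partner scoring 2 s.d.
#' or more away from that mean (two-sided on `|score - m|` by default; with
#' all scores <= 0 this selects the strong interactors), builds the
#' symmetric sensitive-score matrix over the retained genes (0 for
#' unqueried pairs), and clusters rows by Ward variance-minimizing
#' agglomerative clustering on Euclidean distances. Genes are processed in
#' alphabetical order so the output does not depend on input order.
#'
#' @param scores an \linkS4class{InteractionScores} or score table.
#' @param k number of clusters to cut the dendrogram into (default 20,
#'   capped at the number of retained genes).
#' @param nSd deviation threshold in standard deviations (default 2).
#' @param twoSided retain on `|score - m| >= nSd * sd` (default) or
#'   one-sided on `score <= m - nSd * sd`.
#' @return list with `genes`, the score `matrix` used, the `hclust` tree,
#'   integer cluster `labels`, and the filter statistics (`mean`, `sd`,
#'   `n_retained`, `n_total`).
#' @export
clusterProfiles <- function(scores, k = 20L, nSd = 2, twoSided = TRUE) {
  tab <- if (is(scores, "InteractionScores")) scoreTable(scores) else scores
  checkColumns(tab, c("gene_a", "gene_b", "sensitive_score"), "score table")
  nz <- tab$sensitive_score[tab$sensitive_score != 0]
  if (length(nz) == 0L) stop("all sensitive scores are zero; nothing to cluster")
  mNz <- mean(nz)
  sdNz <- if (length(nz) > 1L) sd(nz) else 0
  dev <- if (twoSided) abs(tab$sensitive_score - mNz) >= nSd * sdNz
         else tab$sensitive_score <= mNz - nSd * sdNz
  retained <- sort(unique(c(tab$gene_a[dev], tab$gene_b[dev])))
  total <- sort(unique(c(tab$gene_a, tab$gene_b)))
  if (length(retained) < 2L) {
    stop(sprintf("only %d of %d genes survive the %g-s.d. filter; need >= 2",
                 length(retained), length(total), nSd))
  }
  m <- symmetricScoreMatrix(tab, "sensitive_score", genes = retained)
  hc <- hclust(dist(m), method = "ward.D2")
  kUse <- min(as.integer(k), length(retained))
  labels <- cutree(hc, k = kUse)
  list(genes = retained, matrix = m, hclust = hc, labels = labels,
       mean = mNz, sd = sdNz, n_retained = length(retained),
       n_total = length(total), k = kUse)
}

#' Embed interaction profiles in 2-D
#'
#' Builds the symmetric strong-score matrix across the entire score table
#' (no prior dimension or variance reduction) and maps each gene to 2-D
#' coordinates with a pluggable embedder. The default embedder is classical
#' multidimensional scaling of Euclidean row distances, which is
#' deterministic; stochastic embedders (e.g. a UMAP implementation) receive
#' a fixed RNG seed so repeated runs reproduce.
#'
#' @param scores an \linkS4class{InteractionScores} or score table.
#' @param embedder `function(matrix) -> n x 2 coordinates`; default
#'   classical MDS.
#' @param value which score to embed (default `"strong_score"`).
#' @param seed RNG seed applied around the embedder call.
#' @return numeric matrix (genes x 2) with rownames.
#' @export
embedProfiles <- function(scores, embedder = NULL, value = "strong_score",
                          seed = 1L) {
  tab <- if (is(scores, "InteractionScores")) scoreTable(scores) else scores
  checkColumns(tab, c("gene_a", "gene_b", value), "score table")
  m <- symmetricScoreMatrix(tab, value)
  if (nrow(m) < 3L) stop("need at least 3 genes to embed")
  if (is.null(embedder)) {
    embedder <- function(mat) cmdscale(dist(mat), k = 2)
  }
  coords <- withLocalSeed(seed, embedder(m))
  coords <- as.matrix(coords)
  if (ncol(coords) < 2L) {   # degenerate input (e.g. identical profiles)
    coords <- cbind(coords, matrix(0, nrow(coords), 2L - ncol(coords)))
  }
  rownames(coords) <- rownames(m)
  colnames(coords) <- c("dim1", "dim2")
  coords
}

#' Compare synthetic-lethal calls across cell lines
#'
#' Restricts all score tables to their shared gene-pair universe, flags
#' pairs per line at the per-line cutoffs (e.g. -1 for K562 and -0.5 for
#' HeLa S3), and reports the full Venn partition of the flagged sets plus
#' each line's overlap with the reference line.
#'
#' @param tables named list of \linkS4class{InteractionScores} or score
#'   tables (>= 2).
#' @param cutoffs named numeric vector of per-line cutoffs (names matching
#'   `tables`).
#' @param reference name of the reference line (default: first table).
#' @return list with `universe_size`, per-line `n_flagged`, the Venn
#'   `partition` (one row per membership pattern with its count), and
#'   `fraction_of_reference` (share of the reference line's calls also
#'   flagged in each other line, and in any other line).
#' @export
crossLineOverlap <- function(tables, cutoffs, reference = names(tables)[1]) {
  stopifnot(length(tables) >= 2L, !is.null(names(tables)))
  if (!all(names(tables) %in% names(cutoffs))) {
    stop("cutoffs must be named for every table")
  }
  stopifnot(reference %in% names(tables))
  keyed <- lapply(tables, function(t) {
    tab <- if (is(t, "InteractionScores")) scoreTable(t) else t
    checkColumns(tab, c("gene_a", "gene_b", "sensitive_score"), "score table")
    setNames(tab$sensitive_score, pairKey(tab$gene_a, tab$gene_b))
  })
  universe <- Reduce(intersect, lapply(keyed, names))
  if (length(universe) == 0L) stop("score tables share no gene pairs")
  flagged <- lapply(names(keyed), function(l) {
    v <- keyed[[l]][universe]
    universe[v <= cutoffs[[l]]]
  })
  names(flagged) <- names(keyed)
  un <- unique(unlist(flagged, use.names = FALSE))
  membership <- vapply(flagged, function(f) un %in% f,
                       logical(length(un)))
  membership <- matrix(membership, nrow = length(un),
                       dimnames = list(NULL, names(flagged)))
  mdf <- as.data.frame(membership)
  pat <- do.call(paste, c(mdf, sep = "|"))
  keep <- !duplicated(pat)
  partition <- mdf[keep, , drop = FALSE]
  partition$n <- as.integer(table(pat)[pat[keep]])
  partition <- partition[order(pat[keep]), , drop = FALSE]
  rownames(partition) <- NULL
  refSet <- flagged[[reference]]
  others <- setdiff(names(flagged), reference)
  fracRef <- vapply(others, function(l) {
    if (length(refSet) == 0L) NA_real_
    else length(intersect(refSet, flagged[[l]])) / length(refSet)
  }, numeric(1))
  anyOther <- if (length(refSet) == 0L) NA_real_ else {
    length(intersect(refSet,
                     unique(unlist(flagged[others], use.names = FALSE)))) /
      length(refSet)
  }
  allLines <- if (length(refSet) == 0L) NA_real_ else {
    length(Reduce(intersect, flagged)) / length(refSet)
  }
  list(universe_size = length(universe),
       n_flagged = vapply(flagged, length, integer(1)),
       flagged = flagged,
       partition = partition,
       fraction_of_reference = c(fracRef,
                                 any_other = anyOther,
                                 all_lines = allLines),
       reference = reference)
}

#' Additive double-knockdown expectation
#'
#' The expected double-perturbation phenotype under no interaction: the sum
#' of the two single-perturbation log2 fold changes.
#'
#' @param phenotypeA,phenotypeB numeric log2 fold changes (vectorized).
#' @return their sum.
#' @examples
#' additiveExpectation(-1.2, -0.8)  # -2
#' @export
additiveExpectation <- function(phenotypeA, phenotypeB) {
  stopifnot(is.numeric(phenotypeA), is.numeric(phenotypeB))
  phenotypeA + phenotypeB
}
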