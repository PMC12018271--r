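#' Median-ratio size factors anchored on non-targeting constructs
#'
#' Estimates per-sample size factors by the median-of-ratios method
#' restricted to a designated reference element set: for sample j, the
#' factor is the median over reference elements i of
#' `count[i, j] / geomean_i`, where `geomean_i` is element i's geometric
#' mean across samples, computed over reference elements with all-positive
#' counts (delegated to [DESeq2::estimateSizeFactorsForMatrix()]). The
#' default reference is the non-targeting-only (`nt_nt`) constructs, the
#' purest null set; `reference = "any_nt"` uses every NT-containing element
#' instead, and an explicit character vector of element ids is also
#' accepted.
#'
#' The geometric mean of the usable reference elements' `geomean_i` values
#' is retained as the `referenceScale` (the data's own per-element reference
#' coverage, in raw-count units); [computeLfc()] uses it to anchor the
#' pseudo-count so that log fold changes do not depend on total sequencing
#' depth.
#'
#' @param object a \linkS4class{ScreenCounts} whose `rowData` carries
#'   `pair_class` (as produced by [countScreen()] or
#'   [simulateScreenCounts()]).
#' @param reference `"nt_nt"` (default), `"any_nt"`, or element ids.
#' @param ... ignored.
#' @return a \linkS4class{SizeFactors}
#' @export
setMethod("estimateSizeFactors", "ScreenCounts",
          function(object, reference = c("nt_nt", "any_nt"), ...) {
  m <- assay(object, "counts")
  if (is.character(reference) && all(reference %in% c("nt_nt", "any_nt"))) {
    reference <- match.arg(reference)
    pc <- rowData(object)$pair_class
    if (is.null(pc)) stop("rowData lacks pair_class; pass explicit reference ids")
    ref <- if (reference == "nt_nt") rownames(m)[pc == "nt_nt"]
           else rownames(m)[pc %in% c("nt_nt", "targeting_nt")]
  } else {
    ref <- reference
    bad <- setdiff(ref, rownames(m))
    if (length(bad)) {
      stop("reference element(s) absent from counts: ",
           paste(head(bad, 5L), collapse = ", "))
    }
  }
  if (length(ref) == 0L) stop("empty reference element set")
  rm <- m[ref, , drop = FALSE]
  usable <- rowSums(rm > 0) == ncol(rm)
  if (!any(usable)) {
    stop("no reference element has positive counts in every sample; ",
         "size factors cannot be estimated")
  }
  f <- DESeq2::estimateSizeFactorsForMatrix(rm)
  geo <- exp(rowMeans(log(rm[usable, , drop = FALSE])))
  new("SizeFactors", factors = f,
      referenceScale = exp(mean(log(geo))),
      reference = ref)
})

#' Filter elements on minimum T0 representation
#'
#' Retains elements whose raw count is at least `minReads` in the T0 sample
#' of every replicate; the number of removed elements is recorded in
#' `metadata(x)$t0_filter`. Idempotent.
#'
#' @param counts a \linkS4class{ScreenCounts}
#' @param minReads minimum raw T0 count (default 50).
#' @return the filtered \linkS4class{ScreenCounts}
#' @export
filterMinT0 <- function(counts, minReads = 50L) {
  cd <- colData(counts)
  reps <- unique(cd$replicate)
  t0 <- vapply(reps, function(r) {
    j <- which(cd$replicate == r & cd$timepoint == "T0")
    if (length(j) == 0L) stop(sprintf("replicate %s has no T0 sample", r))
    j[1L]
  }, integer(1))
  m <- assay(counts, "counts")
  keep <- rowSums(m[, t0, drop = FALSE] >= minReads) == length(t0)
  out <- counts[keep, ]
  metadata(out)$t0_filter <- list(min_reads = minReads,
                                  n_removed = sum(!keep),
                                  n_retained = sum(keep))
  message(sprintf("filterMinT0: removed %d of %d elements (T0 < %d in some replicate)",
                  sum(!keep), length(keep), minReads))
  out
}

#' Per-replicate log fold changes with an anchored pseudo-count
#'
#' For every element and replicate,
#' `LFC = log2((n_T14 + p) / (n_T0 + p))` where `n = count / size factor`
#' are the median-ratio-normalized counts and `p` is the pseudo-count.
#' Normalization is applied exactly once, here: raw (filtered) counts in,
#' size factors divided in at this step only.
#'
#' The pseudo-count is specified in reads at a nominal per-element coverage
#' (default 500, the coverage a screen of this design maintains) and is
#' anchored to the dataset's own reference coverage:
#' `p = pseudo * referenceScale(factors) / nominalCoverage`. At nominal
#' coverage this is exactly `pseudo`; at any other total depth the anchored
#' pseudo-count keeps every LFC identical to what the same screen sequenced
#' at nominal depth would give (global rescaling invariance). Set
#' `nominalCoverage = NULL` to add the literal `pseudo` instead.
#'
#' @param counts a filtered \linkS4class{ScreenCounts} (see [filterMinT0()]).
#' @param factors a \linkS4class{SizeFactors} covering every sample.
#' @param pseudo pseudo-count (default 10).
#' @param nominalCoverage nominal reads-per-element scale (default 500), or
#'   `NULL` for a fixed pseudo-count.
#' @return an \linkS4class{LfcTable} (elements x replicates)
#' @export
computeLfc <- function(counts, factors, pseudo = 10, nominalCoverage = 500) {
  stopifnot(is(counts, "ScreenCounts"), is(factors, "SizeFactors"))
  f <- sizeFactors(factors)
  missing <- setdiff(colnames(counts), names(f))
  if (length(missing)) {
    stop("no size factor for sample(s): ", paste(missing, collapse = ", "))
  }
  pEff <- if (is.null(nominalCoverage) || is.na(nominalCoverage)) pseudo
          else pseudo * referenceScale(factors) / nominalCoverage
  cd <- colData(counts)
  reps <- unique(cd$replicate)
  m <- assay(counts, "counts")
  lfc <- matrix(NA_real_, nrow = nrow(m), ncol = length(reps),
                dimnames = list(rownames(m), reps))
  n0m <- lfc
  n1m <- lfc
  for (k in seq_along(reps)) {
    j0 <- which(cd$replicate == reps[k] & cd$timepoint == "T0")
    j1 <- which(cd$replicate == reps[k] & cd$timepoint == "T14")
    if (length(j0) != 1L || length(j1) != 1L) {
      stop(sprintf("replicate %s must have exactly one T0 and one T14 sample",
                   reps[k]))
    }
    n0 <- m[, j0] / f[colnames(m)[j0]]
    n1 <- m[, j1] / f[colnames(m)[j1]]
    lfc[, k] <- log2((n1 + pEff) / (n0 + pEff))
    n0m[, k] <- n0
    n1m[, k] <- n1
  }
  info <- as.data.frame(rowData(counts))
  info <- if (nrow(info)) cbind(element_id = rownames(m), info)
          else data.frame(element_id = rownames(m))
  new("LfcTable", lfc = lfc, pseudocount = pseudo, effectivePseudo = pEff,
      elementInfo = info, n0 = n0m, n1 = n1m)
}

#' Call essential guides from non-targeting-partner LFCs
#'
#' A targeting guide is called essential when its mean LFC across all its
#' NT-partner elements and replicates is strictly below the threshold
#' (default -3). Guides with no surviving NT-partner element are excluded
#' from the calls with a warning.
#'
#' @param lfc an \linkS4class{LfcTable} whose `elementInfo` carries guides,
#'   genes and pair classes.
#' @param design the \linkS4class{PairedGuideLibrary}.
#' @param threshold strict essentiality cutoff on the mean LFC (default -3).
#' @return data.frame with `guide_id`, `gene`, `mean_nt_lfc`, `essential`.
#' @export
callEssentialGuides <- function(lfc, design, threshold = -3) {
  info <- lfc@elementInfo
  checkColumns(info, c("guide_a", "guide_b", "gene_a", "gene_b", "pair_class"),
               "elementInfo")
  tnt <- info$pair_class == "targeting_nt"
  g <- design@guides
  targeting <- g$guide_id[g$guide_type != "non_targeting"]
  tguide <- ifelse(info$gene_a == NT_GENE, info$guide_b, info$guide_a)
  vals <- lfc@lfc[tnt, , drop = FALSE]
  grp <- tguide[tnt]
  means <- tapply(as.vector(vals), rep(grp, times = ncol(vals)), mean)
  uncovered <- setdiff(targeting, names(means))
  if (length(uncovered)) {
    warning(sprintf("%d guide(s) have no surviving NT-partner element and are excluded: %s",
                    length(uncovered),
                    paste(head(uncovered, 5L), collapse = ", ")))
  }
  called <- intersect(targeting, names(means))
  data.frame(guide_id = called,
             gene = g$gene[match(called, g$guide_id)],
             mean_nt_lfc = as.numeric(means[called]),
             essential = as.numeric(means[called]) < threshold,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Substitute mismatch variants for essential perfect guides
#'
#' For every perfect guide called essential that has a mismatch variant in
#' the design, drops all LFC rows whose elements contain the perfect guide;
#' the variant's elements are retained so the gene stays queryable through
#' its blunted guide. Essential guides without a variant are retained with a
#' warning; non-essential guides are untouched.
#'
#' @param lfc an \linkS4class{LfcTable}
#' @param calls output of [callEssentialGuides()].
#' @param design the \linkS4class{PairedGuideLibrary}.
#' @return the filtered \linkS4class{LfcTable}
#' @export
substituteMismatchVariants <- function(lfc, calls, design) {
  g <- design@guides
  ess <- calls$guide_id[calls$essential]
  essPerfect <- ess[g$guide_type[match(ess, g$guide_id)] == "perfect"]
  hasVariant <- essPerfect %in% g$parent_guide_id[g$guide_type == "mismatch"]
  orphans <- essPerfect[!hasVariant]
  if (length(orphans)) {
    warning(sprintf("essential guide(s) without mismatch variant retained: %s",
                    paste(head(orphans, 5L), collapse = ", ")))
  }
  drop <- essPerfect[hasVariant]
  info <- lfc@elementInfo
  keep <- !(info$guide_a %in% drop | info$guide_b %in% drop)
  message(sprintf("substituteMismatchVariants: dropped %d elements containing %d essential perfect guide(s)",
                  sum(!keep), length(drop)))
  subMat <- function(m) if (nrow(m)) m[keep, , drop = FALSE] else m
  new("LfcTable", lfc = lfc@lfc[keep, , drop = FALSE],
      pseudocount = lfc@pseudocount, effectivePseudo = lfc@effectivePseudo,
      elementInfo = info[keep, , drop = FALSE],
      n0 = subMat(lfc@n0), n1 = subMat(lfc@n1))
}
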