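#' @include dualscreen-package.R utils.R
NULL

GUIDE_COLS <- c("guide_id", "gene", "tss_id", "protospacer", "guide_type",
                "parent_guide_id", "empirical_activity", "predicted_activity",
                "specificity_score", "rank_score")
ELEMENT_COLS <- c("element_id", "guide_a", "guide_b", "gene_a", "gene_b",
                  "pair_class")
GUIDE_TYPES <- c("perfect", "mismatch", "non_targeting")
PAIR_CLASSES <- c("inter_gene", "intra_gene", "targeting_nt", "nt_nt")

validGuides <- function(g) {
  miss <- setdiff(GUIDE_COLS, names(g))
  if (length(miss)) {
    return(sprintf("guides lacks column(s): %s", paste(miss, collapse = ", ")))
  }
  if (anyDuplicated(g$guide_id)) return("duplicate guide_id in guides")
  if (any(nchar(g$protospacer) != 20L)) {
    return("all protospacers must be exactly 20 nt")
  }
  if (any(grepl("[^ACGT]", g$protospacer))) {
    return("protospacers must contain only A, C, G, T")
  }
  if (!all(g$guide_type %in% GUIDE_TYPES)) {
    return(sprintf("guide_type must be one of %s",
                   paste(GUIDE_TYPES, collapse = ", ")))
  }
  mm <- g$guide_type == "mismatch"
  if (any(mm & (is.na(g$parent_guide_id) | g$parent_guide_id == ""))) {
    return("mismatch guides must carry a parent_guide_id")
  }
  nt <- g$guide_type == "non_targeting"
  if (any(nt & g$gene != NT_GENE)) {
    return(sprintf("non-targeting guides must have gene '%s'", NT_GENE))
  }
  if (any(!nt & g$gene == NT_GENE)) {
    return(sprintf("targeting guides must not use the '%s' sentinel", NT_GENE))
  }
  TRUE
}

#' Dual-guide library design
#'
#' Container for a combinatorial dual-guide library: the guide table
#' (one row per sgRNA with gene, protospacer, type and activity annotations),
#' the element table (one row per ordered dual-guide construct with its
#' pair class), the orientation seed used for the random ab/ba assignment,
#' and the summary statistics computed at build time.
#'
#' @slot guides data.frame of guides (see [buildPairSet()] for columns).
#' @slot elements data.frame of library elements.
#' @slot orientationSeed integer seed used for gene-pair orientation.
#' @slot stats list of design statistics (see [libraryStats()]).
#'
#' @seealso [buildPairSet()], [libraryStats()], [emitOligoPool()]
#' @export
setClass("PairedGuideLibrary",
  slots = c(guides = "data.frame", elements = "data.frame",
            orientationSeed = "integer", stats = "list"))

setValidity("PairedGuideLibrary", function(object) {
  g <- object@guides
  e <- object@elements
  ok <- validGuides(g)
  if (!isTRUE(ok)) return(ok)
  miss <- setdiff(ELEMENT_COLS, names(e))
  if (length(miss)) {
    return(sprintf("elements lacks column(s): %s", paste(miss, collapse = ", ")))
  }
  if (anyDuplicated(e$element_id)) return("element_id values must be unique")
  if (!all(e$pair_class %in% PAIR_CLASSES)) {
    return(sprintf("pair_class must be one of %s",
                   paste(PAIR_CLASSES, collapse = ", ")))
  }
  if (!all(c(e$guide_a, e$guide_b) %in% g$guide_id)) {
    return("elements reference guide_ids absent from the guide table")
  }
  # pair_class must be consistent with the two guides' genes/types
  ga <- g$gene[match(e$guide_a, g$guide_id)]
  gb <- g$gene[match(e$guide_b, g$guide_id)]
  expected <- ifelse(ga == NT_GENE & gb == NT_GENE, "nt_nt",
              ifelse(ga == NT_GENE | gb == NT_GENE, "targeting_nt",
              ifelse(ga == gb, "intra_gene", "inter_gene")))
  if (!identical(expected, e$pair_class)) {
    return("pair_class inconsistent with the guides' genes/types")
  }
  TRUE
})

setMethod("show", "PairedGuideLibrary", function(object) {
  st <- object@stats
  cat("PairedGuideLibrary\n")
  cat(sprintf("  %d guides (%d targeting, %d non-targeting), %d genes\n",
              nrow(object@guides),
              sum(object@guides$guide_type != "non_targeting"),
              sum(object@guides$guide_type == "non_targeting"),
              st$n_genes))
  cat(sprintf("  %d elements:", nrow(object@elements)))
  bc <- st$by_class
  cat(paste0(" ", names(bc), "=", bc, collapse = ","), "\n")
  cat(sprintf("  gene-level interactions: %d; guide-level interactions: %d\n",
              st$gene_level_interactions, st$guide_level_interactions))
  cat(sprintf("  orientation seed: %d\n", object@orientationSeed))
})

#' @describeIn PairedGuideLibrary guide table accessor
#' @param x,object a `PairedGuideLibrary`
#' @export
guides <- function(x) {
  stopifnot(is(x, "PairedGuideLibrary"))
  x@guides
}

#' @describeIn PairedGuideLibrary element table accessor
#' @export
elements <- function(x) {
  stopifnot(is(x, "PairedGuideLibrary"))
  x@elements
}

#' Paired-read assignment index
#'
#' Lookup structure mapping 20-mer protospacers to guides per cassette
#' position and valid guide pairs to library element ids, used by
#' [assignReadPair()] and [countScreen()].
#'
#' @slot aMap,bMap named character vectors (20-mer -> guide_id) for
#'   positions a and b.
#' @slot pairs named character vector (guide-pair key -> element_id).
#' @slot elements the element table of the indexed design.
#' @seealso [buildPairIndex()]
#' @export
setClass("PairIndex",
  slots = c(aMap = "character", bMap = "character", pairs = "character",
            elements = "data.frame"))

setValidity("PairIndex", function(object) {
  if (anyDuplicated(names(object@aMap))) return("position-a map not injective")
  if (anyDuplicated(names(object@bMap))) return("position-b map not injective")
  TRUE
})

setMethod("show", "PairIndex", function(object) {
  cat("PairIndex\n")
  cat(sprintf("  position a: %d protospacers; position b: %d protospacers\n",
              length(object@aMap), length(object@bMap)))
  cat(sprintf("  valid pairs: %d elements\n", length(object@pairs)))
})

#' Element-by-sample screen count matrix
#'
#' A \linkS4class{SummarizedExperiment} with a single integer `counts` assay
#' whose rows are library elements (all elements of the design, including
#' never-observed ones) and whose columns are screen samples with `replicate`
#' and `timepoint` (`"T0"` or `"T14"`) column data.
#'
#' @seealso [ScreenCounts()], [countScreen()], [simulateScreenCounts()]
#' @export
setClass("ScreenCounts", contains = "SummarizedExperiment")

setValidity("ScreenCounts", function(object) {
  if (!"counts" %in% SummarizedExperiment::assayNames(object)) {
    return("assay 'counts' is required")
  }
  m <- assay(object, "counts")
  if (any(m < 0) || any(m != round(m))) {
    return("counts must be non-negative integers")
  }
  cd <- colData(object)
  if (!all(c("replicate", "timepoint") %in% names(cd))) {
    return("colData must contain 'replicate' and 'timepoint'")
  }
  if (!all(cd$timepoint %in% c("T0", "T14"))) {
    return("timepoint must be 'T0' or 'T14'")
  }
  TRUE
})

#' Construct a ScreenCounts object
#'
#' @param counts integer matrix, elements x samples, with dimnames.
#' @param replicate,timepoint per-sample metadata vectors (timepoint in
#'   `"T0"`/`"T14"`).
#' @param rowData optional per-element annotation (e.g. guide/gene columns
#'   copied from the library design).
#' @return a \linkS4class{ScreenCounts}
#' @export
ScreenCounts <- function(counts, replicate, timepoint, rowData = NULL) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  cd <- DataFrame(replicate = as.character(replicate),
                  timepoint = as.character(timepoint),
                  row.names = colnames(counts))
  se <- SummarizedExperiment(assays = list(counts = counts), colData = cd)
  if (!is.null(rowData)) rowData(se) <- rowData
  new("ScreenCounts", se)
}

#' Median-ratio size factors
#'
#' Per-sample size factors estimated by the median-of-ratios method on a
#' designated reference element set (non-targeting-only constructs by
#' default), plus the geometric-mean reference coverage used to anchor the
#' pseudo-count in [computeLfc()].
#'
#' @slot factors named positive numeric vector, one per sample.
#' @slot referenceScale geometric mean of the reference elements'
#'   cross-sample geometric-mean counts (raw-count units).
#' @slot reference element ids of the reference set actually used.
#' @seealso [estimateSizeFactors()], [computeLfc()]
#' @export
setClass("SizeFactors",
  slots = c(factors = "numeric", referenceScale = "numeric",
            reference = "character"))

setValidity("SizeFactors", function(object) {
  f <- object@factors
  if (is.null(names(f))) return("factors must be named by sample")
  if (any(!is.finite(f)) || any(f <= 0)) return("factors must be positive")
  if (length(object@referenceScale) != 1L || object@referenceScale <= 0) {
    return("referenceScale must be a single positive number")
  }
  TRUE
})

setMethod("show", "SizeFactors", function(object) {
  cat("SizeFactors over", length(object@reference), "reference elements\n")
  print(round(object@factors, 4))
  cat(sprintf("  reference coverage scale: %.1f\n", object@referenceScale))
})

#' @describeIn SizeFactors numeric factor accessor
#' @param x,object a `SizeFactors`
#' @export
sizeFactors <- function(x) {
  stopifnot(is(x, "SizeFactors"))
  x@factors
}

#' @describeIn SizeFactors reference coverage scale accessor
#' @export
referenceScale <- function(x) {
  stopifnot(is(x, "SizeFactors"))
  x@referenceScale
}

#' Per-replicate log fold change table
#'
#' Log2 fold changes of normalized element abundance at T14 versus the
#' matched T0, one column per replicate, with the pseudo-count provenance.
#'
#' @slot lfc numeric matrix (elements x replicates).
#' @slot pseudocount the nominal pseudo-count requested.
#' @slot effectivePseudo the coverage-anchored pseudo-count actually added.
#' @slot elementInfo per-element annotation (guides, genes, pair class).
#' @slot n0,n1 normalized T0 and T14 count matrices (same shape as `lfc`;
#'   empty when the table was built from LFC values alone). They let
#'   [fitInteractionModel()] weight observations by their count information
#'   and see past the pseudo-count floor.
#' @seealso [computeLfc()]
#' @export
setClass("LfcTable",
  slots = c(lfc = "matrix", pseudocount = "numeric",
            effectivePseudo = "numeric", elementInfo = "data.frame",
            n0 = "matrix", n1 = "matrix"),
  prototype = list(n0 = matrix(numeric(0), 0, 0),
                   n1 = matrix(numeric(0), 0, 0)))

setValidity("LfcTable", function(object) {
  if (is.null(rownames(object@lfc))) return("lfc matrix must have rownames")
  if (any(!is.finite(object@lfc))) return("LFC values must be finite")
  TRUE
})

setMethod("show", "LfcTable", function(object) {
  cat(sprintf("LfcTable: %d elements x %d replicates (pseudo-count %g, effective %.3g)\n",
              nrow(object@lfc), ncol(object@lfc), object@pseudocount,
              object@effectivePseudo))
})

#' @describeIn LfcTable LFC matrix accessor
#' @param x,object an `LfcTable`
#' @export
lfcMatrix <- function(x) {
  stopifnot(is(x, "LfcTable"))
  x@lfc
}

#' Fitted interaction model
#'
#' Point estimates of the hierarchical screen model: per-guide efficacies
#' `x` in \[0,1\] (0 for non-targeting guides), per-gene single-knockdown
#' effects `y` on the T14 LFC scale, per-gene-pair interaction effects `s`,
#' and the residual noise scale.
#'
#' @slot x named numeric, guide efficacies.
#' @slot y named numeric, gene effects.
#' @slot s data.frame with `gene_a`, `gene_b` (canonical order) and `s`.
#' @slot sigma residual standard deviation.
#' @slot converged logical convergence flag.
#' @slot nIter iterations used.
#' @slot seed integer seed recorded for provenance.
#' @slot pinned guide_ids whose efficacy was fixed at the recorded activity
#'   (partial-activity guides of genes with no full-activity guide left).
#' @seealso [fitInteractionModel()], [scoreGenePairs()], [predictLfc()]
#' @export
setClass("ModelFit",
  slots = c(x = "numeric", y = "numeric", s = "data.frame", sigma = "numeric",
            converged = "logical", nIter = "integer", seed = "integer",
            pinned = "character"))

setValidity("ModelFit", function(object) {
  if (any(object@x < -1e-9 | object@x > 1 + 1e-9)) {
    return("guide efficacies must lie in [0, 1]")
  }
  if (length(object@sigma) != 1L || object@sigma <= 0) {
    return("sigma must be a single positive number")
  }
  if (!all(c("gene_a", "gene_b", "s") %in% names(object@s))) {
    return("s must have columns gene_a, gene_b, s")
  }
  if (any(object@s$gene_a >= object@s$gene_b)) {
    return("pair table must be in canonical gene order (gene_a < gene_b)")
  }
  TRUE
})

setMethod("show", "ModelFit", function(object) {
  cat(sprintf("ModelFit: %d guides, %d genes, %d gene pairs\n",
              length(object@x), length(object@y), nrow(object@s)))
  cat(sprintf("  sigma = %.4g; %s after %d iterations\n", object@sigma,
              if (object@converged) "converged" else "NOT converged",
              object@nIter))
  if (length(object@pinned)) {
    cat(sprintf("  %d guide efficacies pinned to recorded activity\n",
                length(object@pinned)))
  }
})

#' @describeIn ModelFit guide efficacy accessor
#' @param x,object a `ModelFit`
#' @export
guideEfficacies <- function(x) {
  stopifnot(is(x, "ModelFit"))
  x@x
}

#' @describeIn ModelFit gene effect accessor
#' @export
geneEffects <- function(x) {
  stopifnot(is(x, "ModelFit"))
  x@y
}

#' @describeIn ModelFit pair interaction accessor
#' @export
pairInteractions <- function(x) {
  stopifnot(is(x, "ModelFit"))
  x@s
}

#' Gene-pair interaction scores
#'
#' Sensitive and strong interaction scores per unordered gene pair after the
#' clip-at-zero / negative-sign convention (all reported scores are <= 0;
#' more negative means stronger synthetic lethality), with the raw additive
#' deviations retained.
#'
#' @slot table data.frame with columns `gene_a`, `gene_b`, `raw_sensitive`,
#'   `raw_strong`, `sensitive_score`, `strong_score`, `is_synthetic_lethal`.
#' @slot lambda scaling factor applied to the additive expectation.
#' @slot cutoff synthetic-lethal call cutoff on the sensitive score.
#' @seealso [scoreGenePairs()], [callSyntheticLethal()]
#' @export
setClass("InteractionScores",
  slots = c(table = "data.frame", lambda = "numeric", cutoff = "numeric"))

setValidity("InteractionScores", function(object) {
  t <- object@table
  need <- c("gene_a", "gene_b", "raw_sensitive", "raw_strong",
            "sensitive_score", "strong_score", "is_synthetic_lethal")
  miss <- setdiff(need, names(t))
  if (length(miss)) {
    return(sprintf("score table lacks column(s): %s",
                   paste(miss, collapse = ", ")))
  }
  if (any(t$sensitive_score > 0) || any(t$strong_score > 0)) {
    return("reported scores must be <= 0")
  }
  if (!identical(t$is_synthetic_lethal, t$sensitive_score <= object@cutoff)) {
    return("is_synthetic_lethal inconsistent with cutoff")
  }
  if (any(t$gene_a >= t$gene_b)) {
    return("pairs must be in canonical gene order (gene_a < gene_b)")
  }
  TRUE
})

setMethod("show", "InteractionScores", function(object) {
  cat(sprintf("InteractionScores: %d gene pairs (lambda = %g)\n",
              nrow(object@table), object@lambda))
  cat(sprintf("  %d synthetic-lethal pairs at sensitive score <= %g\n",
              sum(object@table$is_synthetic_lethal), object@cutoff))
})

#' @describeIn InteractionScores score table accessor
#' @param x,object an `InteractionScores`
#' @export
scoreTable <- function(x) {
  stopifnot(is(x, "InteractionScores"))
  x@table
}

#' Simulated screen configuration
#'
#' All knobs of the synthetic dual-guide screen generator. Defaults encode
#' the conditions of the screen the package models: ~18% strongly essential
#' genes blunted by mismatch-variant guides, interaction effects uniform on
#' \[-3, -1\] for 10% of pairs, 15 non-targeting guides, ~500 reads per
#' element, ten population doublings over the 14-day screen, Poisson count
#' noise on a lognormally skewed T0 abundance distribution.
#'
#' @seealso [simConfig()], [simulateTruth()]
#' @export
setClass("SimConfig",
  slots = c(nGenes = "integer", guidesPerGene = "integer", nNT = "integer",
            fracEssential = "numeric", fracInteracting = "numeric",
            yEssentialRange = "numeric", yNeutralSd = "numeric",
            sRange = "numeric", xPerfectRange = "numeric",
            xMismatchRange = "numeric", mismatchForEssential = "logical",
            activityNoiseSd = "numeric", doublings = "numeric",
            depthPerElement = "numeric", abundanceSkew = "numeric",
            seqErrorRate = "numeric", dispersion = "numeric",
            nReplicates = "integer", readLength = "integer",
            seed = "integer"))

setValidity("SimConfig", function(object) {
  fr <- c(object@fracEssential, object@fracInteracting)
  if (any(fr < 0 | fr > 1)) return("fractions must lie in [0, 1]")
  if (object@depthPerElement <= 0) return("depthPerElement must be > 0")
  if (object@nGenes < 2L) return("need at least two genes")
  if (object@guidesPerGene < 2L) return("need at least two guides per gene")
  if (object@seqErrorRate < 0 || object@seqErrorRate > 1) {
    return("seqErrorRate must lie in [0, 1]")
  }
  if (object@readLength < 22L) return("readLength must be at least 22")
  if (object@nReplicates < 1L) return("need at least one replicate")
  if (abs(object@seed) >= 2^31 - 10) return("seed must fit a 32-bit integer")
  TRUE
})

setMethod("show", "SimConfig", function(object) {
  cat(sprintf(paste0("SimConfig: %d genes x %d guides, %d NT guides, ",
                     "%.0f%% essential, %.0f%% interacting pairs\n"),
              object@nGenes, object@guidesPerGene, object@nNT,
              100 * object@fracEssential, 100 * object@fracInteracting))
  cat(sprintf("  depth %g reads/element, %g doublings, %d replicate(s), seed %d\n",
              object@depthPerElement, object@doublings, object@nReplicates,
              object@seed))
})

#' Ground truth of a simulated screen
#'
#' The library design plus the generating parameters (guide efficacies,
#' gene effects, pair interactions) and the per-element expected T14-scale
#' phenotype implied by the interaction model.
#'
#' @slot library the simulated \linkS4class{PairedGuideLibrary}.
#' @slot x,y named numeric truth parameters.
#' @slot s data.frame of all gene pairs with the true interaction effect.
#' @slot phi named numeric expected phenotype per element.
#' @slot config the \linkS4class{SimConfig} used.
#' @seealso [simulateTruth()], [recoveryReport()]
#' @export
setClass("SimTruth",
  slots = c(library = "PairedGuideLibrary", x = "numeric", y = "numeric",
            s = "data.frame", phi = "numeric", config = "SimConfig"))

setMethod("show", "SimTruth", function(object) {
  cat("SimTruth\n")
  show(object@config)
  cat(sprintf("  %d elements, %d interacting gene pairs (s < 0)\n",
              length(object@phi), sum(object@s$s < 0)))
})
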