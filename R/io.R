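#' Read a guide candidate table
#'
#' Reads a TSV of guide records (columns `guide_id`, `gene`, `protospacer`,
#' and optionally `tss_id`, `guide_type`, `parent_guide_id`,
#' `empirical_activity`, `predicted_activity`, `specificity_score`,
#' `rank_score`; missing annotation columns are filled).
#'
#' @param file TSV path.
#' @param default_type guide type assumed when the column is absent.
#' @return data.frame of guides.
#' @export
readGuideTable <- function(file, default_type = "perfect") {
  g <- read.delim(file, stringsAsFactors = FALSE)
  completeGuideColumns(g, default_type = default_type)
}

#' Read a gene metadata table
#'
#' TSV with columns `gene`, `essential_in_K562`, `n_screens_hit` and
#' optionally `strong_ko_phenotype` and `tss_ids`.
#'
#' @param file TSV path.
#' @return data.frame.
#' @export
readGeneTable <- function(file) {
  g <- read.delim(file, stringsAsFactors = FALSE)
  checkColumns(g, c("gene", "essential_in_K562", "n_screens_hit"),
               "gene table")
  g
}

#' Write the library element table
#'
#' One row per element with the guide ids, genes, pair class, both
#' protospacers and (optionally) the full synthesis oligo.
#'
#' @param design a \linkS4class{PairedGuideLibrary}
#' @param file output TSV path.
#' @param withOligo include the 148-nt oligo column (default TRUE).
#' @export
writeLibraryTable <- function(design, file, withOligo = TRUE) {
  g <- design@guides
  e <- design@elements
  out <- data.frame(e,
                    protospacer_a = g$protospacer[match(e$guide_a, g$guide_id)],
                    protospacer_b = g$protospacer[match(e$guide_b, g$guide_id)],
                    stringsAsFactors = FALSE)
  if (withOligo) out$oligo <- emitOligoPool(design)$oligo
  write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Write the guide table of a design
#'
#' @param design a \linkS4class{PairedGuideLibrary}
#' @param file output TSV path.
#' @export
writeGuideTable <- function(design, file) {
  write.table(design@guides, file, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(file)
}

#' Rebuild a library design from its exported tables
#'
#' @param libraryFile TSV written by [writeLibraryTable()].
#' @param guidesFile TSV written by [writeGuideTable()].
#' @return a \linkS4class{PairedGuideLibrary} (the orientation seed is not
#'   recoverable from the tables and is recorded as NA).
#' @export
readPairedGuideLibrary <- function(libraryFile, guidesFile) {
  e <- read.delim(libraryFile, stringsAsFactors = FALSE)
  g <- read.delim(guidesFile, stringsAsFactors = FALSE)
  checkColumns(e, ELEMENT_COLS, "library table")
  g$parent_guide_id[is.na(g$parent_guide_id)] <- ""
  design <- new("PairedGuideLibrary", guides = g[, GUIDE_COLS],
                elements = e[, ELEMENT_COLS],
                orientationSeed = NA_integer_, stats = list())
  design@stats <- libraryStats(design)
  design
}

#' Write the oligo pool as FASTA
#'
#' One record per element, named by element id; letter case of the constant
#' regions is preserved.
#'
#' @param design a \linkS4class{PairedGuideLibrary}
#' @param file output FASTA path.
#' @export
writeOligoFasta <- function(design, file) {
  pool <- emitOligoPool(design)
  writeXStringSet(BStringSet(setNames(pool$oligo, pool$element_id)), file)
  invisible(file)
}

#' Write counts and sample metadata
#'
#' @param counts a \linkS4class{ScreenCounts}
#' @param countsFile output TSV (element_id + one column per sample).
#' @param samplesFile output CSV (sample_id, replicate, timepoint).
#' @export
writeCountsTable <- function(counts, countsFile, samplesFile) {
  m <- assay(counts, "counts")
  out <- data.frame(element_id = rownames(m), m, check.names = FALSE,
                    stringsAsFactors = FALSE)
  write.table(out, countsFile, sep = "\t", quote = FALSE, row.names = FALSE)
  cd <- colData(counts)
  write.table(data.frame(sample_id = rownames(cd),
                         replicate = cd$replicate,
                         timepoint = cd$timepoint),
              samplesFile, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(countsFile)
}

#' Read counts and sample metadata back into a ScreenCounts
#'
#' @param countsFile TSV written by [writeCountsTable()].
#' @param samplesFile CSV written by [writeCountsTable()].
#' @param design optional \linkS4class{PairedGuideLibrary} used to restore
#'   per-element annotation.
#' @return a \linkS4class{ScreenCounts}
#' @export
readScreenCounts <- function(countsFile, samplesFile, design = NULL) {
  tab <- read.delim(countsFile, check.names = FALSE, stringsAsFactors = FALSE)
  ss <- read.csv(samplesFile, stringsAsFactors = FALSE)
  m <- as.matrix(tab[, ss$sample_id, drop = FALSE])
  rownames(m) <- tab$element_id
  rd <- NULL
  if (!is.null(design)) {
    e <- design@elements
    rd <- e[match(tab$element_id, e$element_id),
            setdiff(ELEMENT_COLS, "element_id")]
  }
  ScreenCounts(m, ss$replicate, ss$timepoint, rowData = rd)
}

#' Write an interaction score table
#'
#' @param scores an \linkS4class{InteractionScores}
#' @param file output TSV path.
#' @export
writeScoresTable <- function(scores, file) {
  write.table(scoreTable(scores), file, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(file)
}

#' Serialize a model fit to JSON
#'
#' @param fit a \linkS4class{ModelFit}
#' @param file output JSON path.
#' @export
writeModelFit <- function(fit, file) {
  write_json(list(x = as.list(fit@x), y = as.list(fit@y), s = fit@s,
                  sigma = fit@sigma, converged = fit@converged,
                  n_iter = fit@nIter, seed = fit@seed,
                  pinned = fit@pinned),
             file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' Read a model fit from JSON
#'
#' @param file JSON written by [writeModelFit()].
#' @return a \linkS4class{ModelFit}
#' @export
readModelFit <- function(file) {
  j <- read_json(file, simplifyVector = TRUE)
  s <- as.data.frame(j$s, stringsAsFactors = FALSE)
  if (!nrow(s)) {
    s <- data.frame(gene_a = character(), gene_b = character(),
                    s = numeric(), stringsAsFactors = FALSE)
  }
  new("ModelFit", x = unlist(j$x), y = unlist(j$y),
      s = s,
      sigma = j$sigma, converged = j$converged,
      nIter = as.integer(j$n_iter), seed = as.integer(j$seed),
      pinned = as.character(unlist(j$pinned)))
}

#' Serialize size factors to JSON
#'
#' @param factors a \linkS4class{SizeFactors}
#' @param file output JSON path.
#' @export
writeSizeFactors <- function(factors, file) {
  write_json(list(factors = as.list(sizeFactors(factors)),
                  reference_scale = referenceScale(factors),
                  n_reference = length(factors@reference)),
             file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}
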