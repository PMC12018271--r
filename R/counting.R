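#' Build the read-assignment index for a library design
#'
#' Maps each 20-mer protospacer occurring in cassette position a (read 1) or
#' position b (read 2) to its guide, and each valid ordered guide pair to
#' its element id. Assignment requires an exact (hamming distance 0) 20-mer
#' match, so a protospacer occurring twice within one position is rejected.
#'
#' @param design a \linkS4class{PairedGuideLibrary}
#' @return a \linkS4class{PairIndex}
#' @export
buildPairIndex <- function(design) {
  g <- design@guides
  e <- design@elements
  mkMap <- function(ids, position) {
    ids <- unique(ids)
    protos <- g$protospacer[match(ids, g$guide_id)]
    dup <- duplicated(protos) | duplicated(protos, fromLast = TRUE)
    if (any(dup)) {
      stop(sprintf("protospacer collision in position %s: %s shared by %s",
                   position, protos[dup][1L],
                   paste(ids[protos == protos[dup][1L]], collapse = ", ")))
    }
    setNames(ids, protos)
  }
  aMap <- mkMap(e$guide_a, "a")
  bMap <- mkMap(e$guide_b, "b")
  pairs <- setNames(e$element_id, elementKey(e$guide_a, e$guide_b))
  new("PairIndex", aMap = aMap, bMap = bMap, pairs = pairs, elements = e)
}

# vectorized 20-mer lookup in the first 22 bp (offsets 0, 1, 2)
# returns list(guide = character (NA if none), ambiguous = logical)
matchWindow <- function(reads, map) {
  protos <- names(map)
  gids <- unname(map)
  i1 <- match(substr(reads, 1L, 20L), protos)
  i2 <- match(substr(reads, 2L, 21L), protos)
  i3 <- match(substr(reads, 3L, 22L), protos)
  first <- ifelse(!is.na(i1), i1, ifelse(!is.na(i2), i2, i3))
  amb <- (!is.na(i1) & !is.na(first) & i1 != first) |
         (!is.na(i2) & !is.na(first) & i2 != first) |
         (!is.na(i3) & !is.na(first) & i3 != first)
  list(guide = ifelse(is.na(first), NA_character_, gids[first]),
       ambiguous = amb)
}

UNASSIGNED_REASONS <- c("too_short", "bad_bases", "ambiguous",
                        "no_match_a", "no_match_b", "invalid_pair")

#' Assign paired reads to library elements
#'
#' Scans the first 22 bp of each read (20-mer start offsets 0, 1 and 2) for
#' an exact protospacer match: read 1 against position-a protospacers,
#' read 2 against position-b protospacers. A pair is assigned when both
#' reads resolve to guides and the ordered guide pair is a library element;
#' otherwise the reason is one of `too_short`, `bad_bases` (non-ACGTN in the
#' scanned window), `ambiguous` (two different protospacers match one read),
#' `no_match_a`, `no_match_b`, `invalid_pair` (both guides found but the
#' pair is not in the library).
#'
#' @param read1,read2 character vectors of read sequences (same length).
#' @param index a \linkS4class{PairIndex}
#' @param rcRead2 reverse-complement read 2 before matching (for chemistries
#'   that sequence the b cassette on the opposite strand; the simulator
#'   writes both reads protospacer-forward, the default).
#' @return data.frame with `element_id` (NA when unassigned) and `reason`
#'   (NA when assigned).
#' @export
assignReadPairs <- function(read1, read2, index, rcRead2 = FALSE) {
  stopifnot(length(read1) == length(read2))
  n <- length(read1)
  element <- rep(NA_character_, n)
  reason <- rep(NA_character_, n)
  if (n == 0L) return(data.frame(element_id = element, reason = reason))
  if (rcRead2) {
    read2 <- as.character(reverseComplement(DNAStringSet(read2)))
  }
  tooShort <- nchar(read1) < 22L | nchar(read2) < 22L
  w1 <- substr(read1, 1L, 22L)
  w2 <- substr(read2, 1L, 22L)
  badBases <- grepl("[^ACGTN]", w1) | grepl("[^ACGTN]", w2)
  reason[badBases] <- "bad_bases"
  reason[tooShort] <- "too_short"
  todo <- !tooShort & !badBases
  if (any(todo)) {
    ma <- matchWindow(w1[todo], index@aMap)
    mb <- matchWindow(w2[todo], index@bMap)
    r <- rep(NA_character_, sum(todo))
    r[is.na(mb$guide)] <- "no_match_b"
    r[is.na(ma$guide)] <- "no_match_a"
    r[ma$ambiguous | mb$ambiguous] <- "ambiguous"
    open <- is.na(r)
    eid <- rep(NA_character_, sum(todo))
    if (any(open)) {
      hit <- index@pairs[elementKey(ma$guide[open], mb$guide[open])]
      eid[open] <- unname(hit)
      r[open][is.na(hit)] <- "invalid_pair"
    }
    element[todo] <- eid
    reason[todo] <- r
  }
  data.frame(element_id = element, reason = reason, stringsAsFactors = FALSE)
}

#' @describeIn assignReadPairs single read pair; returns
#'   `list(element_id, reason)`.
#' @export
assignReadPair <- function(read1, read2, index, rcRead2 = FALSE) {
  res <- assignReadPairs(read1, read2, index, rcRead2 = rcRead2)
  list(element_id = res$element_id[1L], reason = res$reason[1L])
}

#' Count a screen from paired FASTQ files
#'
#' Reads each sample's R1/R2 FASTQ files (plain or gzip), assigns read pairs
#' to library elements by exact protospacer matching ([assignReadPairs()]),
#' and tallies an element-by-sample count matrix covering every library
#' element (zeros included). The per-sample assignment log (total reads,
#' assigned, unassigned by reason) is stored in `metadata(result)$assignment_log`
#' and satisfies assigned + unassigned = total.
#'
#' @param sampleSheet data.frame with columns `sample_id`, `fastq_r1`,
#'   `fastq_r2`, `replicate`, `timepoint`.
#' @param index a \linkS4class{PairIndex}
#' @param rcRead2 see [assignReadPairs()].
#' @return a \linkS4class{ScreenCounts}
#' @export
countScreen <- function(sampleSheet, index, rcRead2 = FALSE) {
  checkColumns(sampleSheet,
               c("sample_id", "fastq_r1", "fastq_r2", "replicate", "timepoint"),
               "sample sheet")
  if (anyDuplicated(sampleSheet$sample_id)) {
    stop("duplicate sample_id in sample sheet")
  }
  els <- index@elements$element_id
  counts <- matrix(0L, nrow = length(els), ncol = nrow(sampleSheet),
                   dimnames = list(els, sampleSheet$sample_id))
  log <- vector("list", nrow(sampleSheet))
  names(log) <- sampleSheet$sample_id
  for (i in seq_len(nrow(sampleSheet))) {
    r1 <- as.character(readDNAStringSet(sampleSheet$fastq_r1[i],
                                        format = "fastq"))
    r2 <- as.character(readDNAStringSet(sampleSheet$fastq_r2[i],
                                        format = "fastq"))
    if (length(r1) != length(r2)) {
      stop(sprintf("sample %s: R1 has %d reads but R2 has %d",
                   sampleSheet$sample_id[i], length(r1), length(r2)))
    }
    asg <- assignReadPairs(unname(r1), unname(r2), index, rcRead2 = rcRead2)
    tab <- table(factor(asg$element_id, levels = els))
    counts[, i] <- as.integer(tab)
    byReason <- table(factor(asg$reason, levels = UNASSIGNED_REASONS))
    log[[i]] <- list(total = length(r1),
                     assigned = sum(!is.na(asg$element_id)),
                     unassigned = as.list(setNames(as.integer(byReason),
                                                   names(byReason))))
  }
  sc <- ScreenCounts(counts, sampleSheet$replicate, sampleSheet$timepoint,
                     rowData = index@elements[, setdiff(ELEMENT_COLS,
                                                        "element_id")])
  metadata(sc)$assignment_log <- log
  sc
}

#' Per-sample coverage quality control
#'
#' @param counts a \linkS4class{ScreenCounts}
#' @return data.frame per sample with total reads, mean and median reads per
#'   element, the fraction of elements with zero counts, and a flag for
#'   all-zero samples.
#' @export
coverageQC <- function(counts) {
  m <- assay(counts, "counts")
  data.frame(sample_id = colnames(m),
             replicate = colData(counts)$replicate,
             timepoint = colData(counts)$timepoint,
             total_reads = colSums(m),
             mean_coverage = colMeans(m),
             median_coverage = apply(m, 2, median),
             zero_fraction = colMeans(m == 0),
             all_zero = colSums(m) == 0,
             row.names = NULL, stringsAsFactors = FALSE)
}
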