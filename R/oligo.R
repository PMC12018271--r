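#' Constant cassette regions of the dual-guide expression vector
#'
#' The synthesized oligo of every library element is
#' `upstream + protospacer_a + middle + protospacer_b + downstream`
#' (148 nt in total: 29 + 20 + 44 + 20 + 35). Case is preserved exactly as
#' synthesized (the middle scaffold/linker region is lowercase).
#'
#' @format named character vector with entries `upstream`, `middle`,
#'   `downstream`.
#' @export
OLIGO_CONSTANTS <- c(
  upstream   = "AACTGCGATCGCTAATGTCCACCTTGTTG",
  middle     = "gtttcagagcgagacgtgcctgcaggatacgtctcagaaacatg",
  downstream = "GTTTAAGAGCTAAGCTGGTTCTCCAGTGCCTTATT"
)

#' Emit the oligo pool of a library design
#'
#' Assembles the 148-nt synthesis oligo for every element (constant regions
#' plus the two protospacers, position a before position b).
#'
#' @param design a \linkS4class{PairedGuideLibrary}
#' @return data.frame with `element_id` and `oligo` columns.
#' @seealso [parseOligo()] for the inverse operation,
#'   [writeOligoFasta()] to export the pool.
#' @export
emitOligoPool <- function(design) {
  g <- design@guides
  e <- design@elements
  pa <- g$protospacer[match(e$guide_a, g$guide_id)]
  pb <- g$protospacer[match(e$guide_b, g$guide_id)]
  if (any(grepl("[^ACGT]", c(pa, pb)))) {
    stop("protospacers must contain only A, C, G, T")
  }
  data.frame(element_id = e$element_id,
             oligo = paste0(OLIGO_CONSTANTS[["upstream"]], pa,
                            OLIGO_CONSTANTS[["middle"]], pb,
                            OLIGO_CONSTANTS[["downstream"]]),
             stringsAsFactors = FALSE)
}

#' Parse oligos back into protospacers
#'
#' Splits synthesis oligos on the three constant regions and recovers both
#' protospacers, the round-trip inverse of [emitOligoPool()].
#'
#' @param oligo character vector of 148-nt oligos.
#' @return data.frame with `protospacer_a` and `protospacer_b`.
#' @export
parseOligo <- function(oligo) {
  up <- OLIGO_CONSTANTS[["upstream"]]
  mid <- OLIGO_CONSTANTS[["middle"]]
  down <- OLIGO_CONSTANTS[["downstream"]]
  ok <- startsWith(oligo, up) & endsWith(oligo, down) &
    nchar(oligo) == nchar(up) + nchar(mid) + nchar(down) + 40L &
    substr(oligo, nchar(up) + 21L, nchar(up) + 20L + nchar(mid)) == mid
  if (!all(ok)) {
    stop("malformed oligo(s) at position(s): ",
         paste(head(which(!ok), 5L), collapse = ", "))
  }
  data.frame(
    protospacer_a = substr(oligo, nchar(up) + 1L, nchar(up) + 20L),
    protospacer_b = substr(oligo, nchar(up) + 20L + nchar(mid) + 1L,
                           nchar(up) + 40L + nchar(mid)),
    stringsAsFactors = FALSE)
}
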