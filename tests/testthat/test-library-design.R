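test_that("tier assignment follows the essential / multi-screen-hit rules", {
  tab <- assignTiers(data.frame(
    gene = c("A", "B", "C", "D"),
    essential_in_K562 = c(TRUE, FALSE, FALSE, TRUE),
    n_screens_hit = c(9L, 4L, 0L, 0L)))
  expect_identical(tab$tier, c(1L, 2L, 3L, 1L))
  # tiers exhaustive and mutually exclusive over a grid of flag combinations
  grid <- expand.grid(essential_in_K562 = c(TRUE, FALSE),
                      n_screens_hit = 0:6)
  grid$gene <- sprintf("G%02d", seq_len(nrow(grid)))
  tiers <- assignTiers(grid)$tier
  expect_true(all(tiers %in% 1:3))
  expect_identical(tiers == 1L, grid$essential_in_K562)
  expect_identical(tiers == 2L, !grid$essential_in_K562 & grid$n_screens_hit >= 4)
  expect_error(assignTiers(data.frame(gene = "A", essential_in_K562 = NA,
                                      n_screens_hit = 1L)), "A")
})

test_that("guide ranking is strongest-first with lexicographic tie-break", {
  cand <- data.frame(guide_id = c("g1", "g2", "g3"), gene = "A",
                     rank_score = c(-4.1, -2.0, -3.3))
  expect_identical(rankGuides(cand, 1)$rank_score, c(-4.1, -3.3, -2.0))
  expect_identical(rankGuides(cand[2, ], 2)$guide_id, "g2")
  tie <- data.frame(guide_id = c("gB", "gA"), gene = "A",
                    rank_score = c(-1, -1))
  expect_identical(rankGuides(tie, 1)$guide_id, c("gA", "gB"))
  # tier 3 scores are regression scores: higher is better
  expect_identical(rankGuides(cand, 3)$rank_score, c(-2.0, -3.3, -4.1))
  expect_error(rankGuides(cand[0, ], 1), "empty")
  expect_error(rankGuides(transform(cand, gene = c("A", "A", "B")), 1),
               "same gene")
})

test_that("mismatch variant selection uses the activity window and specificity floor", {
  parent <- data.frame(guide_id = "p1")
  vt <- function(id, emp = NA, pred = NA, spec = 1) {
    data.frame(guide_id = id, parent_guide_id = "p1",
               empirical_activity = emp, predicted_activity = pred,
               specificity_score = spec, stringsAsFactors = FALSE)
  }
  # empirical activity closest to 0.47 wins within the window
  v <- rbind(vt("m1", emp = 0.47), vt("m2", emp = 0.60))
  expect_identical(selectMismatchVariant(parent, v)$guide_id, "m1")
  # window is the closed interval [0.32, 0.62]
  v <- rbind(vt("m1", emp = 0.32), vt("m2", emp = 0.63, pred = 0.5))
  expect_identical(selectMismatchVariant(parent, v)$guide_id, "m1")
  # specificity below 0.15 is inadmissible
  expect_warning(
    out <- selectMismatchVariant(parent, vt("m1", emp = 0.47, spec = 0.10)),
    class = "dualscreen_no_variant")
  expect_null(out)
  # no empirical value in window: predicted activity closest to 0.5
  v <- rbind(vt("m1", pred = 0.30), vt("m2", pred = 0.55), vt("m3", pred = 0.80))
  expect_identical(selectMismatchVariant(parent, v)$guide_id, "m2")
  # tie on distance breaks lexicographically (0.25/0.75 tie exactly)
  v <- rbind(vt("mB", pred = 0.25), vt("mA", pred = 0.75))
  expect_identical(selectMismatchVariant(parent, v)$guide_id, "mA")
})

test_that("per-gene guide selection follows the strong-phenotype rules", {
  ranked1 <- data.frame(guide_id = c("g1", "g2", "g3"), gene = "A",
                        rank_score = c(-3, -2, -1), stringsAsFactors = FALSE)
  variants <- data.frame(guide_id = "g1m", parent_guide_id = "g1",
                         empirical_activity = 0.5, predicted_activity = 0.5,
                         specificity_score = 1, stringsAsFactors = FALSE)
  strong <- data.frame(gene = "A", strong_ko_phenotype = TRUE)
  weak <- data.frame(gene = "A", strong_ko_phenotype = FALSE)
  expect_setequal(
    selectGeneGuides(strong, list(T1 = ranked1), variants)$guide_id,
    c("g1", "g1m"))
  expect_setequal(
    selectGeneGuides(weak, list(T1 = ranked1))$guide_id, c("g1", "g2"))
  # two TSSs give two guides each
  two <- selectGeneGuides(strong, list(T1 = ranked1, T2 = ranked1), variants)
  expect_identical(nrow(two), 4L)
  # strong gene without an admissible variant falls back to top-2 perfect
  expect_warning(
    expect_warning(
      fb <- selectGeneGuides(strong, list(T1 = ranked1),
                             transform(variants, specificity_score = 0.1)),
      "falling back"),
    class = "dualscreen_no_variant")
  expect_setequal(fb$guide_id, c("g1", "g2"))
  expect_error(selectGeneGuides(weak, list(T1 = ranked1[1, ])), "fewer than 2")
})

test_that("pair set realizes the full combinatorial scheme", {
  d <- toyDesign(nGenes = 2, perGene = 2)
  e <- elements(d)
  expect_identical(sum(e$pair_class == "inter_gene"), 4L)
  expect_identical(sum(e$pair_class == "intra_gene"), 2L)
  expect_identical(sum(e$pair_class == "nt_nt"), 225L)
  # every targeting guide appears in exactly 30 NT-containing elements
  tnt <- e[e$pair_class == "targeting_nt", ]
  tg <- guides(d)$guide_id[guides(d)$gene != "NT"]
  perGuide <- table(c(tnt$guide_a[tnt$gene_a != "NT"],
                      tnt$guide_b[tnt$gene_b != "NT"]))
  expect_true(all(perGuide[tg] == 30L))
  expect_false(anyDuplicated(e$element_id) > 0)
  # intra-gene pairs are canonical (guide_id-sorted) and unordered-unique
  intra <- e[e$pair_class == "intra_gene", ]
  expect_true(all(intra$guide_a < intra$guide_b))
})

test_that("orientation assignment is seeded, exclusive and deterministic", {
  d1 <- toyDesign(nGenes = 6, seed = 11)
  d2 <- toyDesign(nGenes = 6, seed = 11)
  expect_identical(elements(d1), elements(d2))
  e <- elements(d1)
  inter <- e[e$pair_class == "inter_gene", ]
  # exactly one orientation realized per unordered gene pair
  oriented <- unique(paste(inter$gene_a, inter$gene_b))
  unord <- unique(paste(pmin(inter$gene_a, inter$gene_b),
                        pmax(inter$gene_a, inter$gene_b)))
  expect_identical(length(oriented), length(unord))
  expect_identical(length(unord), as.integer(choose(6, 2)))
  # and both orientations occur somewhere across seeds (sanity of the draw)
  expect_true(any(inter$gene_a > inter$gene_b) || {
    e3 <- elements(toyDesign(nGenes = 6, seed = 12))
    i3 <- e3[e3$pair_class == "inter_gene", ]
    any(i3$gene_a > i3$gene_b)
  })
})

test_that("pair set rejects malformed inputs", {
  g <- mkGuideTable(2)
  nt <- mkNtTable()
  expect_error(buildPairSet(g, nt[1:14, ]), "exactly 15")
  gdup <- rbind(g, g[1, ])
  expect_error(buildPairSet(gdup, nt), "duplicate guide_id")
  g1 <- mkGuideTable(2, perGene = 1)
  expect_error(buildPairSet(g1, nt), "at least 2 guides")
})

test_that("library stats are recomputable and match closed forms", {
  d <- toyDesign(nGenes = 5, perGene = 2)
  st <- libraryStats(d)
  expect_identical(st, d@stats)
  expect_identical(st$gene_level_interactions, as.integer(choose(5, 2)))
  expect_identical(st$n_elements, nrow(elements(d)))
  # inter-gene guide-level count alone: 3 genes x 2 guides -> 12
  d3 <- toyDesign(nGenes = 3, perGene = 2)
  keep <- elements(d3)$pair_class == "inter_gene"
  d3@elements <- elements(d3)[keep, ]
  expect_identical(libraryStats(d3)$guide_level_interactions, 12L)
  # single gene: no gene-level interactions
  dG1 <- buildPairSet(mkGuideTable(1), mkNtTable())
  expect_identical(libraryStats(dG1)$gene_level_interactions, 0L)
})

test_that("oligos assemble from the printed constant regions and round-trip", {
  expect_identical(nchar(unname(OLIGO_CONSTANTS)), c(29L, 44L, 35L))
  d <- toyDesign(nGenes = 2)
  pool <- emitOligoPool(d)
  expect_true(all(nchar(pool$oligo) == 148L))
  expect_true(all(startsWith(pool$oligo, OLIGO_CONSTANTS[["upstream"]])))
  # elements sharing guide_a share the first 29 + 20 = 49 characters
  e <- elements(d)
  shared <- which(e$guide_a == e$guide_a[1])
  expect_identical(length(unique(substr(pool$oligo[shared], 1, 49))), 1L)
  # round trip: splitting on the constants recovers both protospacers
  parsed <- parseOligo(pool$oligo)
  g <- guides(d)
  expect_identical(parsed$protospacer_a,
                   g$protospacer[match(e$guide_a, g$guide_id)])
  expect_identical(parsed$protospacer_b,
                   g$protospacer[match(e$guide_b, g$guide_id)])
  # non-ACGT protospacers are rejected
  bad <- d
  gg <- bad@guides
  gg$protospacer[1] <- paste0("N", substr(gg$protospacer[1], 2, 20))
  slot(bad, "guides", check = FALSE) <- gg
  expect_error(emitOligoPool(bad), "A, C, G, T")
})

test_that("library tables and oligo FASTA round-trip through files", {
  d <- toyDesign(nGenes = 2)
  libF <- tempfile(fileext = ".tsv")
  gF <- tempfile(fileext = ".tsv")
  writeLibraryTable(d, libF)
  writeGuideTable(d, gF)
  d2 <- readPairedGuideLibrary(libF, gF)
  expect_identical(elements(d2), elements(d))
  expect_identical(guides(d2)$protospacer, guides(d)$protospacer)
  expect_identical(libraryStats(d2)$by_class, libraryStats(d)$by_class)
  fa <- tempfile(fileext = ".fa")
  writeOligoFasta(d, fa)
  seqs <- Biostrings::readBStringSet(fa)
  expect_identical(length(seqs), nrow(elements(d)))
  expect_identical(as.character(seqs[[1]]), emitOligoPool(d)$oligo[1])
})
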