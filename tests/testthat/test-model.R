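# noiseless LFC table straight from a simulation truth
truthLfc <- function(tr, reps = 2L) {
  mkLfc(unname(tr@phi), tr@library@elements, reps = reps)
}

test_that("noiseless screens return the generating parameters", {
  cfg <- simConfig(nGenes = 8, seed = 31)
  tr <- simulateTruth(cfg)
  fit <- fitInteractionModel(truthLfc(tr), tr@library, tol = 1e-9,
                             maxIter = 2000L)
  expect_true(fit@converged)
  expect_lt(max(abs(fit@y - tr@y[names(fit@y)])), 1e-3)
  expect_lt(max(abs(fit@x - tr@x[names(fit@x)])), 1e-3)
  sTrue <- setNames(tr@s$s, paste(tr@s$gene_a, tr@s$gene_b))
  expect_lt(max(abs(fit@s$s - sTrue[paste(fit@s$gene_a, fit@s$gene_b)])),
            1e-3)
  expect_lt(fit@sigma, 1e-4)
  # predicted LFCs reproduce the input residual-free (negligible ridge so
  # shrinkage does not set the residual floor)
  fit0 <- fitInteractionModel(truthLfc(tr), tr@library, tol = 1e-11,
                              maxIter = 5000L, ridge = 1e-9)
  pred <- predictLfc(fit0, tr@library, lfc = truthLfc(tr))
  expect_lt(attr(pred, "rmse"), 1e-6)
  expect_true(all(pred$mu[pred$pair_class == "nt_nt"] == 0))
})

test_that("degenerate inputs solve in closed form", {
  d <- toyDesign(nGenes = 3)
  zero <- mkLfc(rep(0, nrow(elements(d))), elements(d))
  fit <- fitInteractionModel(zero, d)
  expect_true(all(abs(fit@y) < 1e-12))
  expect_true(all(abs(fit@s$s) < 1e-12))
  # single gene with NT-pair LFCs of -2 from full-efficacy guides
  d1 <- buildPairSet(mkGuideTable(1), mkNtTable())
  e1 <- elements(d1)
  vals <- ifelse(e1$pair_class == "nt_nt", 0, -2)
  fit1 <- fitInteractionModel(mkLfc(vals, e1), d1, tol = 1e-9)
  expect_lt(abs(fit1@y[["GEN01"]] + 2), 0.01)
  expect_equal(unname(fit1@x[c("GEN01_g1", "GEN01_g2")]), c(1, 1),
               tolerance = 1e-6)
})

test_that("the fit validates its inputs", {
  d <- toyDesign(nGenes = 2)
  e <- elements(d)
  onlyInter <- e[e$pair_class == "inter_gene", ]
  expect_error(
    fitInteractionModel(mkLfc(rep(-1, nrow(onlyInter)), onlyInter), d),
    "without NT-paired")
  lfc <- mkLfc(rep(0, nrow(e)), e)
  lfc@lfc[1, 1] <- NaN
  expect_error(fitInteractionModel(lfc, d), "non-finite")
  set.seed(4)
  short <- mkLfc(rnorm(nrow(e)), e)
  expect_warning(fitInteractionModel(short, d, maxIter = 1L),
                 "did not converge")
})

test_that("alternating updates match an independent box-constrained optimizer", {
  # 3 genes x 2 guides, inter-gene + NT elements only, plain LFC objective
  d <- toyDesign(nGenes = 3, perGene = 2, seed = 5)
  e <- elements(d)[elements(d)$pair_class != "intra_gene", ]
  gid <- guides(d)$guide_id
  tgt <- gid[guides(d)$gene != "NT"]
  genes <- sort(unique(guides(d)$gene[guides(d)$gene != "NT"]))
  pairs <- t(combn(genes, 2))
  xT <- setNames(c(1, 0.8, 0.9, 1, 1, 0.7, rep(0, 15)),
                 c(tgt, gid[guides(d)$gene == "NT"]))
  yT <- setNames(c(-2, -0.3, -1), genes)
  sT <- setNames(c(-1.5, 0, -0.5), paste(pairs[, 1], pairs[, 2]))
  # independent mean computation: explicit formulas over precomputed indices
  allG <- c(tgt, gid[guides(d)$gene == "NT"])
  ia <- match(e$guide_a, allG)
  ib <- match(e$guide_b, allG)
  gaIdx <- match(e$gene_a, genes)           # NA for NT
  gbIdx <- match(e$gene_b, genes)
  pKey <- paste(pmin(e$gene_a, e$gene_b), pmax(e$gene_a, e$gene_b))
  pIdx <- match(pKey, paste(pairs[, 1], pairs[, 2]))
  muOracle <- function(x, y, s, info = NULL) {
    ya <- ifelse(is.na(gaIdx), 0, y[gaIdx] * x[ia])
    yb <- ifelse(is.na(gbIdx), 0, y[gbIdx] * x[ib])
    si <- ifelse(is.na(pIdx) | is.na(gaIdx) | is.na(gbIdx), 0,
                 x[ia] * x[ib] * s[ifelse(is.na(pIdx), 1L, pIdx)])
    ya + yb + si
  }
  set.seed(8)
  reps <- 2L
  muT <- muOracle(xT, yT, sT, e)
  L <- matrix(rep(muT, reps) + rnorm(nrow(e) * reps, 0, 0.1), ncol = reps,
              dimnames = list(e$element_id, paste0("R", 1:reps)))
  lfc <- new("LfcTable", lfc = L, pseudocount = 10, effectivePseudo = 10,
             elementInfo = e)
  ridge <- 1e-3
  fit <- fitInteractionModel(lfc, d, tol = 1e-10, maxIter = 5000L,
                             ridge = ridge)
  objective <- function(x, y, s) {
    mu <- muOracle(x[allG], y[genes], s[paste(pairs[, 1], pairs[, 2])])
    sum((L - mu)^2) + ridge * (sum(y^2) + sum(s^2))
  }
  # canonicalize a parameter vector to the per-gene max-efficacy-1 gauge
  canon <- function(x, y, s) {
    for (gn in genes) {
      ids <- tgt[startsWith(tgt, gn)]
      mx <- max(x[ids])
      x[ids] <- x[ids] / mx
      y[gn] <- y[gn] * mx
      hit <- pairs[, 1] == gn | pairs[, 2] == gn
      s[hit] <- s[hit] * mx
    }
    list(x = x, y = y, s = s)
  }
  # independent minimizer: multi-start box-constrained quasi-Newton
  par0 <- function() c(runif(6, 0.3, 1), rnorm(3, -1, 1), rnorm(3, 0, 1))
  obj <- function(p) {
    x <- setNames(c(p[1:6], rep(0, 15)), names(xT))
    objective(x, setNames(p[7:9], genes), setNames(p[10:12], names(sT)))
  }
  best <- NULL
  set.seed(99)
  starts <- c(list(c(unname(xT[1:6]), unname(yT), unname(sT))),
              lapply(1:6, function(i) par0()))
  for (p0 in starts) {
    o <- optim(p0, obj, method = "L-BFGS-B",
               lower = c(rep(0, 6), rep(-Inf, 6)),
               upper = c(rep(1, 6), rep(Inf, 6)),
               control = list(maxit = 2000, factr = 1e4))
    if (is.null(best) || o$value < best$value) best <- o
  }
  co <- canon(setNames(c(best$par[1:6], rep(0, 15)), names(xT)),
              setNames(best$par[7:9], genes),
              setNames(best$par[10:12], names(sT)))
  cf <- canon(fit@x, fit@y, setNames(fit@s$s, paste(fit@s$gene_a,
                                                    fit@s$gene_b)))
  expect_lt(abs(objective(cf$x, cf$y, cf$s) -
                  objective(co$x, co$y, co$s)), 1e-2)
  expect_lt(max(abs(cf$x[tgt] - co$x[tgt])), 1e-2)
  expect_lt(max(abs(cf$y - co$y)), 1e-2)
  expect_lt(max(abs(cf$s - co$s)), 1e-2)
})

test_that("interaction scores follow the lambda / clipping / sign conventions", {
  fit <- mkFit(y = c(A = -0.5, B = -0.4),
               s = data.frame(gene_a = "A", gene_b = "B", s = -2.1))
  st <- scoreTable(scoreGenePairs(fit, lambda = 1))
  expect_equal(st$sensitive_score, -2.1)
  expect_equal(st$strong_score, (-0.5 - 0.4 - 2.1) - min(-0.5, -0.4))
  expect_equal(st$strong_score, -2.5)
  expect_true(st$is_synthetic_lethal)
  # buffering (positive deviation) clips to 0
  fitPos <- mkFit(y = c(A = -0.5, B = -0.4),
                  s = data.frame(gene_a = "A", gene_b = "B", s = 0.1))
  stPos <- scoreTable(scoreGenePairs(fitPos))
  expect_identical(stPos$sensitive_score, 0)
  expect_equal(stPos$raw_sensitive, 0.1)        # raw deviation retained
  expect_false(stPos$is_synthetic_lethal)
  # no interaction with a neutral partner scores exactly 0 for both
  fit0 <- mkFit(y = c(A = -0.5, B = 0.1),
                s = data.frame(gene_a = "A", gene_b = "B", s = 0))
  st0 <- scoreTable(scoreGenePairs(fit0))
  expect_identical(st0$sensitive_score, 0)
  expect_identical(st0$strong_score, 0)
  # with two depleting genes the strong deviation is max(y) + s
  fitD <- mkFit(y = c(A = -0.5, B = -0.4),
                s = data.frame(gene_a = "A", gene_b = "B", s = 0))
  expect_equal(scoreTable(scoreGenePairs(fitD))$strong_score, -0.4)
  # lambda scales the additive expectation
  st2 <- scoreTable(scoreGenePairs(fit, lambda = 0.5))
  expect_equal(st2$raw_sensitive, (-0.5 - 0.4 - 2.1) - 0.5 * (-0.9))
  expect_warning(scoreGenePairs(mkFit(y = c(A = -1, B = 0),
                                      s = data.frame(gene_a = "A",
                                                     gene_b = "B", s = 0),
                                      converged = FALSE)),
                 "did not converge")
})

test_that("scores are gene-order symmetric and monotone in the interaction", {
  # same pair under two labelings that flip the canonical order
  f1 <- mkFit(y = c(ALPHA = -0.5, BETA = -0.4),
              s = data.frame(gene_a = "ALPHA", gene_b = "BETA", s = -1.2))
  f2 <- mkFit(y = c(ZETA = -0.5, BETA = -0.4),
              s = data.frame(gene_a = "BETA", gene_b = "ZETA", s = -1.2))
  s1 <- scoreTable(scoreGenePairs(f1))
  s2 <- scoreTable(scoreGenePairs(f2))
  expect_equal(s1$sensitive_score, s2$sensitive_score)
  expect_equal(s1$strong_score, s2$strong_score)
  # holding y fixed, more negative s never increases either score
  sGrid <- seq(0.5, -3, by = -0.25)
  tabs <- lapply(sGrid, function(sv) {
    scoreTable(scoreGenePairs(mkFit(
      y = c(A = -0.7, B = -0.2),
      s = data.frame(gene_a = "A", gene_b = "B", s = sv))))
  })
  sens <- vapply(tabs, function(t) t$sensitive_score, numeric(1))
  strong <- vapply(tabs, function(t) t$strong_score, numeric(1))
  expect_true(all(diff(sens) <= 1e-12))
  expect_true(all(diff(strong) <= 1e-12))
  expect_true(all(sens <= 0) && all(strong <= 0))
})

test_that("predictions follow the generative means", {
  fit <- mkFit(y = c(A = -2, B = 0),
               s = data.frame(gene_a = "A", gene_b = "B", s = 0),
               x = c(A_g1 = 1, A_g2 = 0.5, B_g1 = 1, B_g2 = 1,
                     setNames(rep(0, 15), sprintf("NT_g%02d", 1:15))))
  gt <- mkGuideTable(2, genes = c("A", "B"))
  d <- buildPairSet(gt, mkNtTable())
  pred <- predictLfc(fit, d)
  e <- elements(d)
  expect_true(all(pred$mu[e$pair_class == "nt_nt"] == 0))
  ntA1 <- pred$mu[(e$guide_a == "A_g1" & e$gene_b == "NT") |
                    (e$guide_b == "A_g1" & e$gene_a == "NT")]
  expect_true(all(ntA1 == -2))
  ntA2 <- pred$mu[(e$guide_a == "A_g2" & e$gene_b == "NT") |
                    (e$guide_b == "A_g2" & e$gene_a == "NT")]
  expect_true(all(ntA2 == -1))
  # intra-gene union efficacy: 1 - (1 - 1)(1 - 0.5) = 1
  intraA <- pred$mu[e$guide_a == "A_g1" & e$guide_b == "A_g2"]
  expect_equal(intraA, -2)
})

test_that("model fits serialize to JSON and back", {
  cfg <- simConfig(nGenes = 4, seed = 61)
  tr <- simulateTruth(cfg)
  fit <- fitInteractionModel(truthLfc(tr), tr@library)
  f <- tempfile(fileext = ".json")
  writeModelFit(fit, f)
  fit2 <- readModelFit(f)
  expect_equal(fit2@x, fit@x)
  expect_equal(fit2@y, fit@y)
  expect_equal(fit2@s, fit@s)
  expect_identical(fit2@converged, fit@converged)
})
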