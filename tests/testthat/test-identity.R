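test_that("wilcoxonDE exact p matches rank-permutation enumeration (5v5)", {
  m <- makeLogMatrix(0, 3, 10)
  m[1, ] <- c(1.2, 0.7, 2.5, 1.9, 0.3, 0.1, 0.5, 0.2, 0.45, 0.05)
  m[2, ] <- c(10, 9, 8, 7, 6, 5, 4, 3, 2, 1)      # extreme separation
  m[3, ] <- c(1, 3, 5, 7, 9, 2, 4, 6, 8, 10)      # interleaved
  de <- wilcoxonDE(m, colnames(m)[1:5], colnames(m)[6:10], minCells = 3)
  for (i in 1:3) {
    oracle <- wilcoxEnumOracle(m[i, 1:5], m[i, 6:10])
    expect_equal(de$p[i], oracle, tolerance = 1e-9,
                 label = sprintf("gene %d", i))
  }
  ## cross-check the tie-free exact path against stats::wilcox.test
  ref <- wilcox.test(m[1, 1:5], m[1, 6:10], exact = TRUE)$p.value
  expect_equal(de$p[1], ref, tolerance = 1e-12)
})

test_that("wilcoxonDE large-sample path agrees with wilcox.test and flags planted effects", {
  ## null data: identical group distributions give a flat DE table
  set.seed(3)
  null <- makeLogMatrix(rexp(50 * 60), 50, 60)
  deN <- wilcoxonDE(null, colnames(null)[1:30], colnames(null)[31:60])
  expect_gt(min(deN$fdr), 0.2)

  ## agreement with the uncorrected normal approximation of wilcox.test
  refP <- apply(null[1:10, ], 1, function(v)
    wilcox.test(v[1:30], v[31:60], exact = FALSE, correct = FALSE)$p.value)
  expect_equal(deN$p[1:10], unname(refP), tolerance = 1e-9)

  ## planted 4-fold shift in one gene among 200v200 NB cells
  set.seed(3)
  counts <- matrix(rnbinom(200 * 400, mu = 2, size = 2), nrow = 200)
  counts[7, 1:200] <- rnbinom(200, mu = 8, size = 2)
  dimnames(counts) <- list(sprintf("g%03d", 1:200), sprintf("c%03d", 1:400))
  ln <- logNormalizeCounts(counts)
  de <- wilcoxonDE(ln, colnames(ln)[1:200], colnames(ln)[201:400])
  expect_lt(de$fdr[7], 0.05)
  expect_identical(de$direction[7], "up_in_A")
  ## an all-zero gene would be p = 1, fc = 0
  counts0 <- counts; counts0[1, ] <- 0
  de0 <- wilcoxonDE(logNormalizeCounts(counts0), colnames(ln)[1:200],
                    colnames(ln)[201:400])
  expect_equal(de0$p[1], 1)
  expect_equal(de0$log2_fc[1], 0)

  expect_error(wilcoxonDE(ln, colnames(ln)[1:5], colnames(ln)[5:10]),
               "disjoint")
  expect_error(wilcoxonDE(ln, colnames(ln)[1:2], colnames(ln)[3:10]),
               "at least")
})

test_that("BH adjustment agrees with an independent step-up implementation", {
  set.seed(11)
  for (i in 1:20) {
    p <- runif(50)^sample(1:3, 1)
    expect_equal(p.adjust(p, "BH"), bhOracle(p), tolerance = 1e-12)
  }
})

test_that("deriveIdentitySignature selects top genes and enforces minimums", {
  de <- data.frame(
    gene = sprintf("g%03d", 1:200),
    log2_fc = c(seq(0.3, 2, length.out = 100), seq(-0.3, -2, length.out = 100)),
    p = rep(1e-6, 200), fdr = rep(1e-5, 200),
    direction = rep(c("up_in_A", "up_in_B"), each = 100),
    stringsAsFactors = FALSE)
  sig <- deriveIdentitySignature(de, nTop = 50)
  expect_length(medGenes(sig), 50)
  expect_length(extramedGenes(sig), 50)
  ## ranked by |lfc|: the strongest genes must be present
  expect_true("g100" %in% medGenes(sig))
  expect_true("g200" %in% extramedGenes(sig))
  expect_length(intersect(medGenes(sig), extramedGenes(sig)), 0)

  deNull <- de; deNull$fdr <- 1
  expect_error(deriveIdentitySignature(deNull), "lowering")

  ## planted-program recovery: >= 80% of the 50 planted genes per direction
  bench <- identityBenchmark(trainSeed = 41, medSeed = 42, exSeed = 43,
                             nTrain = 300, nTest = 60, nGenes = 1000)
  medTruth <- sprintf("G%05d", 101:150)
  exTruth <- sprintf("G%05d", 151:200)
  expect_gte(mean(medGenes(bench$signature) %in% medTruth), 0.8)
  expect_gte(mean(extramedGenes(bench$signature) %in% exTruth), 0.8)
})

test_that("identity ratio: symmetric case gives R = 1 and swapping halves inverts R", {
  set.seed(6)
  m <- makeLogMatrix(rexp(3000), 100, 30)
  sig <- new("IdentitySignature", medGenes = rownames(m)[1:10],
             extramedGenes = rownames(m)[11:20], params = list())
  ## identical per-cell scores for both halves -> all ratios exactly 1
  mSame <- m
  mSame[11:20, ] <- mSame[1:10, ]
  resSame <- computeIdentityRatio(mSame, sig, nBins = 1, nCtrl = 90,
                                  seed = 2, nBoot = 50)
  expect_equal(cellRatios(resSame)$ratio, rep(1, 30))

  res <- computeIdentityRatio(m, sig, nBins = 1, nCtrl = 90, seed = 2,
                              nBoot = 50)
  swapped <- new("IdentitySignature", medGenes = extramedGenes(sig),
                 extramedGenes = medGenes(sig), params = list())
  ## swap the control seeds too: MED/EXTRAMED labels drive seed derivation,
  ## so compare the rank structure, which is seed-free with one bin and an
  ## exhausted control pool
  resSw <- computeIdentityRatio(m, swapped, nBins = 1, nCtrl = 90, seed = 2,
                                nBoot = 50)
  rk <- cellRatios(res); rkSw <- cellRatios(resSw)
  expect_equal(rkSw$rank_med, rk$rank_extramed)
  expect_equal(rkSw$ratio, 1 / rk$ratio, tolerance = 1e-9)
})

test_that("classifyIdentity applies the threshold-plus-CI rule", {
  mk <- function(n, med, lo, hi)
    new("IdentityResult",
        cells = data.frame(cell_id = sprintf("c%d", 1:n), sample = "s",
                           score_med = 0, score_extramed = 0,
                           rank_med = 0.5, rank_extramed = 0.5, ratio = 1),
        samples = data.frame(sample = "s", n = n, median_ratio = med,
                             ci_lo = lo, ci_hi = hi),
        params = list())
  expect_identical(classifyIdentity(mk(100, 1.4, 1.2, 1.6))$classification,
                   "medullary")
  expect_identical(classifyIdentity(mk(100, 0.7, 0.5, 1.1))$classification,
                   "indeterminate")
  expect_identical(classifyIdentity(mk(100, 0.7, 0.5, 0.9))$classification,
                   "extramedullary")
  expect_identical(classifyIdentity(mk(100, 1.0, 0.9, 1.1))$classification,
                   "indeterminate")
  few <- classifyIdentity(mk(5, 1.4, 1.2, 1.6))
  expect_identical(few$classification, "indeterminate")
  expect_identical(few$flag, "too_few_cells")
})

test_that("end-to-end identity recovery across seeds", {
  ## train on simulated poles, classify held-out med/extramed samples
  ok <- vapply(1:10, function(s) {
    b <- identityBenchmark(trainSeed = 100 + s, medSeed = 200 + s,
                           exSeed = 300 + s, nTrain = 200, nTest = 150,
                           nGenes = 1000, scoreSeed = s)
    cls <- classifyIdentity(b$result)
    isTRUE(cls$classification[cls$sample == "med"] == "medullary") &&
      isTRUE(cls$classification[cls$sample == "ex"] == "extramedullary")
  }, logical(1))
  expect_true(all(ok))
})
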