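test_that("simulateDataset respects compositions, phases and determinism", {
  ## degenerate cycling fraction: every cell in G1
  cfg0 <- simConfig(nGenes = 500, clusters = list(clusterSpec("A")),
                    tissues = list(tissueSpec("BM", 100, c(A = 1))),
                    seed = 3)
  sce0 <- simulateDataset(cfg0)
  expect_true(all(sce0$phase == "G1"))
  expect_identical(ncol(sce0), 100L)

  ## two tissues with mirrored compositions: empirical fractions within
  ## 3 binomial SEs of truth
  cfg <- simConfig(
    nGenes = 500,
    clusters = list(clusterSpec("A"), clusterSpec("B")),
    tissues = list(tissueSpec("T1", 20000, c(A = 0.8, B = 0.2)),
                   tissueSpec("T2", 20000, c(A = 0.2, B = 0.8))),
    libMeanlog = log(500), seed = 11)
  sce <- simulateDataset(cfg)
  fr <- function(tis) mean(sce$cluster[sce$tissue == tis] == "A")
  se <- sqrt(0.8 * 0.2 / 20000)
  expect_lt(abs(fr("T1") - 0.8), 3 * se)
  expect_lt(abs(fr("T2") - 0.2), 3 * se)

  ## same config and seed -> bit-identical counts and labels
  sceA <- simulateDataset(cfg0)
  sceB <- simulateDataset(cfg0)
  expect_identical(as.matrix(assay(sceA, "counts")),
                   as.matrix(assay(sceB, "counts")))
  expect_identical(colData(sceA), colData(sceB))

  ## library_size equals the column sums of the counts
  expect_identical(sce0$library_size,
                   as.integer(Matrix::colSums(assay(sce0, "counts"))))
})

test_that("per-cluster cycling converges to f and S/G2M split is even", {
  cfg <- simConfig(nGenes = 500,
                   clusters = list(clusterSpec("A", cyclingFraction = 0.4)),
                   tissues = list(tissueSpec("BM", 20000, c(A = 1))),
                   libMeanlog = log(300), seed = 5)
  sce <- simulateDataset(cfg)
  fcyc <- mean(sce$phase %in% c("S", "G2M"))
  expect_lt(abs(fcyc - 0.4), 3 * sqrt(0.4 * 0.6 / 20000))
  nS <- sum(sce$phase == "S"); nG <- sum(sce$phase == "G2M")
  expect_lt(abs(nS / (nS + nG) - 0.5), 3 * sqrt(0.25 / (nS + nG)))
})

test_that("invalid configurations are rejected with informative messages", {
  expect_error(simConfig(nGenes = 100, clusters = list(clusterSpec("A")),
                         tissues = list(tissueSpec("BM", 10, c(A = 0.5)))),
               "sum to 1")
  expect_error(simConfig(nGenes = 100,
                         clusters = list(clusterSpec("A", programGenes = 200)),
                         tissues = list(tissueSpec("BM", 10, c(A = 1)))),
               "gene indices")
  expect_error(simConfig(nGenes = 100,
                         clusters = list(clusterSpec("A", fold = -1)),
                         tissues = list(tissueSpec("BM", 10, c(A = 1)))),
               "fold")
})

test_that("program-bearing cells score above baseline cells (score separation)", {
  ## med-program vs extramed-program cells at fold 2, 50 genes, n = 500
  sce <- logNormalizeCounts(simulateDataset(
    identityPoleConfig(250, 250, seed = 21, nGenes = 1000)))
  sets <- truthGeneSets(metadata(sce)$simConfig)
  sc <- scoreSignature(sce, sets$MED, seed = 2, name = "MED")
  med <- sc[sce$tissue == "BM"]; other <- sc[sce$tissue == "SPL"]
  ## probability that a random med cell outscores a random extramed cell
  auc <- mean(outer(med, other, ">"))
  expect_gt(auc, 0.95)
})

test_that("simulateBranchCounts: exact mode, sampling bounds, determinism", {
  bm <- simulateBranchCounts(c(1000, 2000), c(0.5, 0.5), nSample = 0)
  d <- branchData(bm)
  expect_equal(d$n_cells, c(1000, 2000))
  expect_equal(d$f_sg2m, c(0.5, 0.5))

  obs <- simulateBranchCounts(c(1000, 2000, 4000, 8000), rep(0.5, 4),
                              nSample = 10000, seed = 31)
  props <- branchData(obs)$n_cells / 10000
  truth <- c(1, 2, 4, 8) / 15
  se <- sqrt(truth * (1 - truth) / 10000)
  expect_true(all(abs(props - truth) < 3 * se))

  again <- simulateBranchCounts(c(1000, 2000, 4000, 8000), rep(0.5, 4),
                                nSample = 10000, seed = 31)
  expect_identical(branchData(obs), branchData(again))

  expect_error(simulateBranchCounts(c(-1, 5), c(0.5, 0.5)), "nonnegative")
  expect_error(simulateBranchCounts(c(10, 5), c(0.5)), "equal length")
})

test_that("simulateLDA follows the single-hit response law", {
  expect_true(all(simulateLDA(0, c(100, 1000), c(50, 50))$n_positive == 0))

  tab <- simulateLDA(0.01, 1000, 10000, seed = 13)
  pTrue <- 1 - exp(-10)
  se <- sqrt(pTrue * (1 - pTrue) / 10000)
  expect_lt(abs(tab$n_positive / 10000 - pTrue), 3 * se + 1e-12)

  expect_identical(simulateLDA(0.003, c(100, 500), c(20, 20), seed = 2),
                   simulateLDA(0.003, c(100, 500), c(20, 20), seed = 2))
  expect_error(simulateLDA(0.01, c(100, 500), c(20)), "equal length")
})
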