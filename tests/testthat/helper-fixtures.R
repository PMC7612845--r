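## shared fixture builders; everything is generated in code

## dense normalized matrix with controllable values
makeLogMatrix <- function(values, nGenes, nCells,
                          genes = sprintf("G%05d", seq_len(nGenes)),
                          cells = sprintf("c%03d", seq_len(nCells))) {
  m <- matrix(values, nrow = nGenes, ncol = nCells,
              dimnames = list(genes, cells))
  m
}

## tiny raw count SCE written by hand
makeCountSCE <- function(counts, donor = "D1", tissue = "BM",
                         cluster = "A") {
  m <- Matrix::Matrix(counts, sparse = TRUE)
  if (is.null(rownames(m))) rownames(m) <- sprintf("g%d", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("c%d", seq_len(ncol(m)))
  n <- ncol(m)
  SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = m),
    colData = S4Vectors::DataFrame(
      cell_id = colnames(m), donor = rep_len(donor, n),
      tissue = rep_len(tissue, n), cluster = rep_len(cluster, n),
      row.names = colnames(m)))
}

## independent oracle: two-sided exact binomial p by full enumeration of
## outcome probabilities no larger than the observed one ("minlike")
binomMinlikeOracle <- function(x, n, p0) {
  probs <- dbinom(0:n, n, p0)
  sum(probs[probs <= probs[x + 1] * (1 + 1e-7)])
}

## independent oracle: GSEA running sum built step by step from the
## definition (hit: |metric|^p over hit total; miss: 1/(N - Nh))
esOracle <- function(stats, geneSet, p = 1) {
  N <- length(stats)
  hit <- names(stats) %in% geneSet
  w <- abs(stats)^p
  tot <- sum(w[hit])
  running <- numeric(N)
  cur <- 0
  for (i in seq_len(N)) {
    cur <- if (hit[i]) {
      cur + (if (tot > 0) w[i] / tot else 1 / sum(hit))
    } else {
      cur - 1 / (N - sum(hit))
    }
    running[i] <- cur
  }
  maxDev <- max(running); minDev <- min(running)
  if (maxDev > -minDev) maxDev else minDev   # ties resolve negative
}

## independent oracle: exact two-sided rank-sum p by enumerating every
## assignment of the pooled observations to group A
wilcoxEnumOracle <- function(va, vb) {
  n1 <- length(va); n2 <- length(vb)
  pooled <- c(va, vb)
  rk <- rank(pooled)
  uObs <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  center <- n1 * n2 / 2
  combos <- utils::combn(n1 + n2, n1)
  us <- apply(combos, 2, function(idx) sum(rk[idx]) - n1 * (n1 + 1) / 2)
  mean(abs(us - center) >= abs(uObs - center) - 1e-9)
}

## independent oracle: reference step-up BH implementation
bhOracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(1, adj)
  out
}

## shared protocol for the identity benchmark: train a signature on a
## two-pole simulation, score held-out single-pole samples in one cohort
identityBenchmark <- function(trainSeed, medSeed, exSeed, nTrain = 400L,
                              nTest = 500L, nGenes = 2000L, scoreSeed = 1L) {
  train <- logNormalizeCounts(simulateDataset(
    identityPoleConfig(nTrain, nTrain, seed = trainSeed, nGenes = nGenes)))
  cd <- SummarizedExperiment::colData(train)
  de <- wilcoxonDE(train, cd$cell_id[cd$tissue == "BM"],
                   cd$cell_id[cd$tissue == "SPL"])
  sig <- deriveIdentitySignature(de, nTop = 50L, fdrCut = 0.05, lfcCut = 0.2)
  med <- simulateDataset(identityPoleConfig(nTest, 0L, seed = medSeed,
                                            nGenes = nGenes))
  ex <- simulateDataset(identityPoleConfig(0L, nTest, seed = exSeed,
                                           nGenes = nGenes))
  counts <- cbind(SummarizedExperiment::assay(med, "counts"),
                  SummarizedExperiment::assay(ex, "counts"))
  lab <- c(rep("med", ncol(med)), rep("ex", ncol(ex)))
  res <- computeIdentityRatio(logNormalizeCounts(counts), sig, sample = lab,
                              seed = scoreSeed)
  s <- sampleSummary(res)
  list(signature = sig, result = res,
       medMedian = s$median_ratio[s$sample == "med"],
       exMedian = s$median_ratio[s$sample == "ex"])
}
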