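#' Wilcoxon rank-sum differential expression between two cell groups
#'
#' Per gene, a two-sided Wilcoxon rank-sum (Mann-Whitney) test of group A
#' versus group B on normalized expression. For group sizes up to
#' `exactMax` with no tied values the exact null distribution is used;
#' otherwise the normal approximation with tie correction (no continuity
#' correction, the convention of single-cell DE). Log fold changes are
#' `log2((mean(expm1(A)) + 1) / (mean(expm1(B)) + 1))` and p-values are
#' Benjamini-Hochberg adjusted across all tested genes.
#'
#' @param x A `SingleCellExperiment` with a `logcounts` assay, or a
#'   normalized genes-x-cells matrix.
#' @param cellsA,cellsB Disjoint character vectors of cell ids (or
#'   column indices) of the two groups.
#' @param minCells Minimum cells per group (default 3).
#' @param exactMax Largest group size for which the exact (tie-free) null is
#'   used (default 20).
#' @return data.frame with one row per gene: `gene`, `log2_fc`, `p`, `fdr`,
#'   `direction` (`"up_in_A"` / `"up_in_B"`). All-zero genes get `p = 1`,
#'   `log2_fc = 0`.
#' @export
wilcoxonDE <- function(x, cellsA, cellsB, minCells = 3L, exactMax = 20L) {
  m <- .logMatrix(x)
  if (is.character(cellsA)) cellsA <- match(cellsA, colnames(m))
  if (is.character(cellsB)) cellsB <- match(cellsB, colnames(m))
  if (any(is.na(cellsA)) || any(is.na(cellsB)))
    .stopf("some cells not found in the matrix")
  if (length(intersect(cellsA, cellsB)))
    .stopf("cell groups must be disjoint")
  n1 <- length(cellsA); n2 <- length(cellsB)
  if (n1 < minCells || n2 < minCells)
    .stopf("each group needs at least %d cells (got %d and %d)",
           minCells, n1, n2)
  a <- as.matrix(m[, cellsA, drop = FALSE])
  b <- as.matrix(m[, cellsB, drop = FALSE])
  n <- n1 + n2
  useExact <- max(n1, n2) <= exactMax
  G <- nrow(m)
  p <- numeric(G); lfc <- numeric(G)
  for (i in seq_len(G)) {
    va <- a[i, ]; vb <- b[i, ]
    ma <- mean(expm1(va)); mb <- mean(expm1(vb))
    if (ma == 0 && mb == 0 && all(va == 0) && all(vb == 0)) {
      p[i] <- 1; lfc[i] <- 0
      next
    }
    lfc[i] <- log2((ma + 1) / (mb + 1))
    v <- c(va, vb)
    rk <- rank(v)
    U <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
    nties <- table(v)
    hasTies <- any(nties > 1L)
    if (useExact && !hasTies) {
      p[i] <- if (U > n1 * n2 / 2)
        min(1, 2 * (1 - pwilcox(U - 1, n1, n2)))
      else
        min(1, 2 * pwilcox(U, n1, n2))
    } else {
      sg <- sqrt(n1 * n2 / 12 * ((n + 1) - sum(nties^3 - nties) / (n * (n - 1))))
      p[i] <- if (sg == 0) 1 else 2 * pnorm(-abs((U - n1 * n2 / 2) / sg))
    }
  }
  data.frame(gene = rownames(m), log2_fc = lfc, p = p,
             fdr = p.adjust(p, method = "BH"),
             direction = ifelse(lfc >= 0, "up_in_A", "up_in_B"),
             stringsAsFactors = FALSE)
}

#' Derive the two-pole identity signature from a DE table
#'
#' Keeps genes with `fdr < fdrCut` and `|log2_fc| > lfcCut`, ranks each
#' direction by `|log2_fc|` and takes the top `nTop` per direction. Genes up
#' in group A become the medullary half (group A is the medullary pole by
#' convention), genes up in B the extramedullary half.
#'
#' @param de DE table from [wilcoxonDE()] comparing the medullary (A) and
#'   extramedullary (B) reference poles.
#' @param nTop Genes kept per direction (default 50).
#' @param fdrCut,lfcCut Significance and fold-change cutoffs (defaults 0.05
#'   and 0.2).
#' @return An [IdentitySignature-class].
#' @export
deriveIdentitySignature <- function(de, nTop = 50L, fdrCut = 0.05,
                                    lfcCut = 0.2) {
  pass <- de[de$fdr < fdrCut & abs(de$log2_fc) > lfcCut, , drop = FALSE]
  up <- pass[pass$direction == "up_in_A", , drop = FALSE]
  dn <- pass[pass$direction == "up_in_B", , drop = FALSE]
  if (nrow(up) < 5L || nrow(dn) < 5L)
    .stopf(paste("fewer than 5 genes pass in %s direction(s);",
                 "consider lowering fdrCut/lfcCut"),
           paste(c("medullary", "extramedullary")[c(nrow(up) < 5L,
                                                    nrow(dn) < 5L)],
                 collapse = " and "))
  top <- function(d) d$gene[order(-abs(d$log2_fc))][seq_len(min(nTop, nrow(d)))]
  new("IdentitySignature", medGenes = top(up), extramedGenes = top(dn),
      params = list(n_top = nTop, fdr_cut = fdrCut, lfc_cut = lfcCut))
}

#' Per-cell medullary/extramedullary identity ratio
#'
#' Scores each cell against the two signature halves with
#' [scoreSignature()], converts each score to its fractional rank over the
#' scored cohort (`rank / n`, in `(0, 1]`, ties averaged) and forms the
#' per-cell ratio `R = rank_med / rank_extramed`. `R > 1` indicates
#' medullary (BM-type) standing, `R < 1` extramedullary. Per sample, the
#' median ratio and a seeded bootstrap confidence interval of the median are
#' reported. Rank normalization guarantees positivity and makes `R = 1`
#' mean "equal standing in the cohort"; set `rawRatio = TRUE` for a
#' min-shifted raw-score ratio instead.
#'
#' @param x A `SingleCellExperiment` with a `logcounts` assay, or a
#'   normalized genes-x-cells matrix.
#' @param signature An [IdentitySignature-class].
#' @param sample Optional per-cell sample labels (single sample by default).
#' @param nBins,nCtrl Control-gene parameters passed to [scoreSignature()].
#' @param seed Integer seed (control draws and bootstrap).
#' @param nBoot Bootstrap replicates for the median CI (default 1000).
#' @param confLevel CI level (default 0.95).
#' @param rawRatio Use min-shifted raw scores instead of fractional ranks.
#' @return An [IdentityResult-class].
#' @export
computeIdentityRatio <- function(x, signature, sample = NULL, nBins = 25L,
                                 nCtrl = 50L, seed = 1L, nBoot = 1000L,
                                 confLevel = 0.95, rawRatio = FALSE) {
  stopifnot(is(signature, "IdentitySignature"))
  m <- .logMatrix(x)
  sm <- scoreSignature(m, medGenes(signature), nBins, nCtrl,
                       seed = deriveSeed(seed, "score", "MED"), name = "MED")
  se <- scoreSignature(m, extramedGenes(signature), nBins, nCtrl,
                       seed = deriveSeed(seed, "score", "EXTRAMED"),
                       name = "EXTRAMED")
  ncells <- ncol(m)
  if (is.null(sample)) sample <- rep("sample1", ncells)
  if (length(sample) != ncells)
    .stopf("sample labels must match the number of cells")
  if (rawRatio) {
    shift <- min(c(sm, se))
    rm <- sm - shift + 1
    re <- se - shift + 1
  } else {
    rm <- rank(sm, ties.method = "average") / ncells
    re <- rank(se, ties.method = "average") / ncells
  }
  ratio <- rm / re
  cellsDf <- data.frame(cell_id = colnames(m), sample = as.character(sample),
                        score_med = as.numeric(sm), score_extramed = as.numeric(se),
                        rank_med = rm, rank_extramed = re, ratio = ratio,
                        stringsAsFactors = FALSE)
  alpha <- (1 - confLevel) / 2
  bySample <- split(ratio, cellsDf$sample)
  samples <- do.call(rbind, lapply(names(bySample), function(nm) {
    r <- bySample[[nm]]
    boots <- .withSeed(deriveSeed(seed, "boot", nm), {
      vapply(seq_len(nBoot), function(i)
        median(r[sample.int(length(r), replace = TRUE)]), numeric(1))
    })
    data.frame(sample = nm, n = length(r), median_ratio = median(r),
               ci_lo = as.numeric(quantile(boots, alpha)),
               ci_hi = as.numeric(quantile(boots, 1 - alpha)),
               stringsAsFactors = FALSE)
  }))
  rownames(samples) <- NULL
  new("IdentityResult", cells = cellsDf, samples = samples,
      params = list(n_bins = nBins, n_ctrl = nCtrl, seed = seed,
                    n_boot = nBoot, conf_level = confLevel,
                    raw_ratio = rawRatio))
}

#' Classify samples as medullary, extramedullary or indeterminate
#'
#' A sample is `medullary` when its median identity ratio exceeds 1 and the
#' bootstrap CI excludes 1, `extramedullary` when below 1 with the CI
#' excluding 1, otherwise `indeterminate`. Samples with fewer than
#' `minCells` cells are `indeterminate` and flagged.
#'
#' @param result An [IdentityResult-class].
#' @param minCells Minimum cells per sample (default 20).
#' @return data.frame: per-sample summary plus `classification` and `flag`.
#' @export
classifyIdentity <- function(result, minCells = 20L) {
  stopifnot(is(result, "IdentityResult"))
  s <- sampleSummary(result)
  cls <- character(nrow(s)); flag <- character(nrow(s))
  for (i in seq_len(nrow(s))) {
    if (s$n[i] < minCells) {
      cls[i] <- "indeterminate"; flag[i] <- "too_few_cells"
    } else if (s$median_ratio[i] > 1 && s$ci_lo[i] > 1) {
      cls[i] <- "medullary"; flag[i] <- ""
    } else if (s$median_ratio[i] < 1 && s$ci_hi[i] < 1) {
      cls[i] <- "extramedullary"; flag[i] <- ""
    } else {
      cls[i] <- "indeterminate"; flag[i] <- ""
    }
  }
  data.frame(s, classification = cls, flag = flag, stringsAsFactors = FALSE)
}
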