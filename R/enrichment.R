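## validate a ranked list: named, unique, finite, descending metric
.checkRanked <- function(stats) {
  if (is.null(names(stats)) || anyDuplicated(names(stats)))
    .stopf("ranked list must have unique gene names")
  if (any(!is.finite(stats))) .stopf("ranking metrics must be finite")
  if (is.unsorted(rev(stats)) && any(diff(stats) > 0))
    .stopf("ranked list must be in descending metric order")
  stats
}

## ES from hit positions only (O(k)); w = |metric|^p over the whole list
.esFromPositions <- function(pos, w, N) {
  k <- length(pos)
  pos <- sort(pos)
  cw <- cumsum(w[pos])
  tot <- cw[k]
  cwn <- if (tot > 0) cw / tot else seq_len(k) / k
  if (N == k) return(list(es = 1, peak = pos[k]))  # set covers the list
  md <- 1 / (N - k)
  miss <- (pos - seq_len(k)) * md
  top <- cwn - miss
  bot <- c(0, cwn[-k]) - miss
  iTop <- which.max(top); iBot <- which.min(bot)
  ## tie on |deviation| resolves to the negative excursion (the usual
  ## convention of preranked implementations)
  if (top[iTop] > -bot[iBot])
    list(es = as.numeric(top[iTop]), peak = pos[iTop])
  else
    list(es = as.numeric(bot[iBot]), peak = pos[iBot] - 1L)
}

#' Weighted running-sum enrichment score of one gene set
#'
#' Walks the ranked list from top to bottom; a hit increments the running
#' sum by `|metric|^weight` (normalized over hits), a miss decrements it by
#' `1/(N - N_hits)`. The enrichment score ES is the signed maximum deviation
#' from zero; an exact tie between the positive and negative excursions
#' resolves to the negative one.
#'
#' @param stats Named numeric vector: ranking metric per gene, sorted
#'   descending.
#' @param geneSet Character vector of genes (at least one present in the
#'   list; a set covering the whole list saturates at ES = 1).
#' @param weight Exponent on the metric (default 1, classical; 0 for the
#'   unweighted statistic).
#' @return List with `es`, the full `running` sum (length of the list), and
#'   `leadingEdge` (set genes at or before the ES extremum for positive ES,
#'   after it for negative).
#' @export
enrichmentScore <- function(stats, geneSet, weight = 1) {
  stats <- .checkRanked(stats)
  N <- length(stats)
  hits <- names(stats) %in% geneSet
  k <- sum(hits)
  if (k == 0L) .stopf("gene set has no overlap with the ranked list")
  w <- abs(stats)^weight
  totHit <- sum(w[hits])
  inc <- numeric(N)
  inc[hits] <- if (totHit > 0) w[hits] / totHit else 1 / k
  dec <- numeric(N)
  if (N > k) dec[!hits] <- 1 / (N - k)
  running <- cumsum(inc - dec)
  es <- .esFromPositions(which(hits), w, N)
  le <- if (es$es >= 0) names(stats)[hits & seq_len(N) <= es$peak]
        else names(stats)[hits & seq_len(N) > es$peak]
  list(es = es$es, running = running, leadingEdge = le)
}

#' Pre-ranked gene-set enrichment with a gene-label permutation null
#'
#' For each set, computes the observed enrichment score, then builds a null
#' by reassigning set membership uniformly at random over the list
#' (`nPerm` seeded draws of the same set size). The permutation p-value is
#' `(1 + #{null ES of the same sign with |ES_null| >= |ES|}) / (nPerm + 1)`;
#' NES is the ES divided by the mean `|ES_null|` of matching sign; FDR is
#' the standard NES-based ratio of null to observed tail fractions, clipped
#' to `[0, 1]`.
#'
#' @param stats Named numeric metric vector, descending (e.g. signed
#'   `-log10(p) * sign(log2_fc)` from [wilcoxonDE()]; see [rankMetric()]).
#' @param geneSets Named list of gene vectors.
#' @param nPerm Number of permutations (>= 100).
#' @param seed Integer seed.
#' @param weight Metric exponent (default 1).
#' @return data.frame with one row per scored set: `set`, `size`, `es`,
#'   `nes`, `p_perm`, `fdr`, `leading_edge` (comma-separated). Sets with no
#'   overlap are skipped with a warning.
#' @export
prerankedGSEA <- function(stats, geneSets, nPerm = 1000L, seed = 1L,
                          weight = 1) {
  stats <- .checkRanked(stats)
  if (nPerm < 100L) .stopf("nPerm must be >= 100")
  N <- length(stats)
  w <- abs(stats)^weight
  rows <- list()
  nullNES <- list()
  for (nm in names(geneSets)) {
    k <- sum(names(stats) %in% geneSets[[nm]])
    if (k == 0L || k >= N) {
      .warnf("set '%s' skipped (overlap %d of %d)", nm, k, N)
      next
    }
    obs <- enrichmentScore(stats, geneSets[[nm]], weight)
    nulls <- .withSeed(deriveSeed(seed, "gsea", nm), {
      vapply(seq_len(nPerm), function(b)
        .esFromPositions(sample.int(N, k), w, N)$es, numeric(1))
    })
    same <- if (obs$es >= 0) nulls[nulls >= 0] else nulls[nulls < 0]
    pPerm <- (1 + sum(abs(same) >= abs(obs$es))) / (nPerm + 1)
    denom <- if (length(same)) mean(abs(same)) else mean(abs(nulls))
    nes <- if (denom > 0) obs$es / denom else NA_real_
    posDen <- mean(abs(nulls[nulls >= 0]))
    negDen <- mean(abs(nulls[nulls < 0]))
    nullNES[[nm]] <- c(if (is.finite(posDen) && posDen > 0)
                         nulls[nulls >= 0] / posDen,
                       if (is.finite(negDen) && negDen > 0)
                         nulls[nulls < 0] / negDen)
    rows[[nm]] <- data.frame(
      set = nm, size = k, es = obs$es, nes = nes, p_perm = pPerm,
      fdr = NA_real_, leading_edge = paste(obs$leadingEdge, collapse = ","),
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) .stopf("no gene set overlaps the ranked list")
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  pooled <- unlist(nullNES, use.names = FALSE)
  obsNES <- res$nes
  for (i in seq_len(nrow(res))) {
    s <- obsNES[i]
    if (!is.finite(s)) next
    if (s >= 0) {
      num <- mean(pooled[pooled >= 0] >= s)
      den <- mean(obsNES[obsNES >= 0] >= s)
    } else {
      num <- mean(pooled[pooled < 0] <= s)
      den <- mean(obsNES[obsNES < 0] <= s)
    }
    res$fdr[i] <- min(1, max(0, if (den > 0) num / den else 1))
  }
  res
}

#' Signed ranking metric from a DE table
#'
#' The default two-group ranking metric for [prerankedGSEA()]:
#' `-log10(p) * sign(log2_fc)`, returned as a named vector sorted
#' descending. Zero p-values are clamped to the smallest representable
#' positive double.
#'
#' @param de DE table from [wilcoxonDE()].
#' @return Named numeric vector, descending.
#' @export
rankMetric <- function(de) {
  p <- pmax(de$p, .Machine$double.xmin)
  metric <- -log10(p) * sign(de$log2_fc)
  sort(setNames(metric, de$gene), decreasing = TRUE)
}
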