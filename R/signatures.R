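## helper: extract the log-normalized matrix from whatever the user passed
.logMatrix <- function(x) {
  if (is(x, "SummarizedExperiment")) {
    if (!"logcounts" %in% SummarizedExperiment::assayNames(x))
      .stopf("no 'logcounts' assay; run logNormalizeCounts() first")
    return(SummarizedExperiment::assay(x, "logcounts"))
  }
  x
}

#' Score one gene signature per cell
#'
#' Bin-matched control-subtracted signature score: the per-cell mean
#' expression of the signature genes minus the mean over control genes,
#' where each signature gene contributes `nCtrl` controls sampled without
#' replacement (seeded) from its average-expression bin (`nBins` bins by
#' rank of the gene's mean expression over all cells, signature genes
#' themselves excluded from the control pool). Signature genes absent from
#' the matrix are dropped with a warning.
#'
#' @param x A `SingleCellExperiment` with a `logcounts` assay, or a
#'   normalized genes-x-cells matrix with dimnames.
#' @param genes Character vector of signature gene ids.
#' @param nBins Number of average-expression bins (default 25).
#' @param nCtrl Controls sampled per signature gene (default 50).
#' @param seed Integer seed for the control draw.
#' @param name Signature name used in messages.
#' @return Named numeric vector of per-cell scores.
#' @export
scoreSignature <- function(x, genes, nBins = 25L, nCtrl = 50L, seed = 1L,
                           name = "signature") {
  m <- .logMatrix(x)
  if (nBins < 1L || nCtrl < 1L) .stopf("nBins and nCtrl must be >= 1")
  present <- intersect(genes, rownames(m))
  if (!length(present))
    .stopf("signature '%s': no genes found in the matrix", name)
  if (length(present) < length(genes))
    .warnf("signature '%s': %d gene(s) absent from the matrix dropped",
           name, length(genes) - length(present))
  G <- nrow(m)
  means <- Matrix::rowMeans(m)
  bin <- ceiling(nBins * rank(means, ties.method = "first") / G)
  setIdx <- match(present, rownames(m))
  inSet <- logical(G)
  inSet[setIdx] <- TRUE
  ctrlIdx <- .withSeed(seed, {
    unlist(lapply(setIdx, function(i) {
      pool <- which(bin == bin[i] & !inSet)
      if (!length(pool)) return(integer(0))
      if (length(pool) <= nCtrl) pool else sample(pool, nCtrl)
    }), use.names = FALSE)
  })
  setMean <- Matrix::colMeans(m[setIdx, , drop = FALSE])
  ctrlMean <- if (length(ctrlIdx))
    Matrix::colMeans(m[ctrlIdx, , drop = FALSE]) else 0
  score <- setMean - ctrlMean
  if (!length(ctrlIdx))
    .warnf("signature '%s': empty control pool, no control subtraction", name)
  setNames(as.numeric(score), colnames(m))
}

#' Score a collection of gene signatures
#'
#' Applies [scoreSignature()] to every set of a collection, deriving the
#' per-signature control-sampling seed from the top-level seed and the
#' signature name (so identical sets under different names give identical
#' columns). A set that fails (e.g. no overlap with the matrix) is skipped
#' with a warning; scoring continues.
#'
#' @inheritParams scoreSignature
#' @param geneSets Named list of gene vectors (e.g. from [readGMT()]).
#' @return data.frame with `cell_id` and one numeric column per scored
#'   signature, columns in collection order.
#' @export
scoreSignatures <- function(x, geneSets, nBins = 25L, nCtrl = 50L, seed = 1L) {
  m <- .logMatrix(x)
  out <- data.frame(cell_id = colnames(m), stringsAsFactors = FALSE)
  for (nm in names(geneSets)) {
    sc <- tryCatch(
      scoreSignature(m, geneSets[[nm]], nBins = nBins, nCtrl = nCtrl,
                     seed = deriveSeed(seed, "score", nm), name = nm),
      error = function(e) {
        .warnf("signature '%s' skipped: %s", nm, conditionMessage(e))
        NULL
      })
    if (!is.null(sc)) out[[nm]] <- sc
  }
  out
}

#' Assign a transcriptional cell-cycle phase from S and G2M scores
#'
#' A cell is `G1` when both scores are negative; otherwise the phase of the
#' larger score, with ties broken towards `S`.
#'
#' @param sScore,g2mScore Numeric vectors of per-cell S-phase and G2M-phase
#'   signature scores (recycled to common length).
#' @return Character vector of phases in `{"G1", "S", "G2M"}`.
#' @export
assignCyclePhase <- function(sScore, g2mScore) {
  if (any(!is.finite(sScore)) || any(!is.finite(g2mScore)))
    .stopf("scores must be finite")
  ifelse(pmax(sScore, g2mScore) < 0, "G1",
         ifelse(sScore >= g2mScore, "S", "G2M"))
}

#' Score S and G2M signatures and assign phases
#'
#' Convenience wrapper: scores the two cell-cycle signatures with
#' [scoreSignature()] and applies [assignCyclePhase()].
#'
#' @inheritParams scoreSignature
#' @param sGenes,g2mGenes Gene vectors of the S and G2M signatures.
#' @return data.frame with `cell_id`, `s_score`, `g2m_score`, `phase`.
#' @export
cellCyclePhases <- function(x, sGenes, g2mGenes, nBins = 25L, nCtrl = 50L,
                            seed = 1L) {
  m <- .logMatrix(x)
  s <- scoreSignature(m, sGenes, nBins, nCtrl,
                      seed = deriveSeed(seed, "score", "S_PHASE"), name = "S")
  g <- scoreSignature(m, g2mGenes, nBins, nCtrl,
                      seed = deriveSeed(seed, "score", "G2M_PHASE"), name = "G2M")
  data.frame(cell_id = colnames(m), s_score = as.numeric(s),
             g2m_score = as.numeric(g), phase = assignCyclePhase(s, g),
             stringsAsFactors = FALSE)
}
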