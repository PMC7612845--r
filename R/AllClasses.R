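## S4 classes for the bespoke model objects. Count data itself lives in a
## SingleCellExperiment (counts assay + per-cell colData), the standard
## container for this kind of data.

#' BranchModel: ordered differentiation stages with abundances and cycling
#'
#' Holds, for one differentiation branch (e.g. the megakaryocyte/erythroid/
#' eosinophil/mast/basophil "MEMB" branch or the neutrophil/monocyte "My"
#' branch), the ordered stages with per-(donor, tissue, stage) cell counts
#' and S-G2-M ("active") fractions. This is the input of
#' [estimateExpansion()].
#'
#' @slot branchName Single character branch label.
#' @slot stages Character vector of stage names in differentiation order
#'   (length >= 2).
#' @slot data data.frame with columns `donor`, `tissue`, `stage`, `n_cells`,
#'   `f_sg2m`, `empty` (logical flag for stages observed with zero cells).
#'   `n_cells` may be real-valued: the expansion model depends only on
#'   abundance ratios, so relative abundances are legitimate inputs.
#' @slot cyclingSource Character label recording where the cycling fractions
#'   came from (`"transcriptional"`, `"supplied"`, ...).
#' @export
setClass("BranchModel",
  representation(branchName = "character", stages = "character",
                 data = "data.frame", cyclingSource = "character"))

setValidity("BranchModel", function(object) {
  msg <- character(0)
  if (length(object@stages) < 2L)
    msg <- c(msg, "a branch needs at least 2 ordered stages")
  need <- c("donor", "tissue", "stage", "n_cells", "f_sg2m", "empty")
  if (!all(need %in% names(object@data)))
    msg <- c(msg, paste("data must have columns:", paste(need, collapse = ", ")))
  else {
    d <- object@data
    if (!all(d$stage %in% object@stages))
      msg <- c(msg, "data contains stages not in the stage order")
    if (any(d$n_cells < 0))
      msg <- c(msg, "n_cells must be nonnegative")
    if (any(d$f_sg2m < 0 | d$f_sg2m > 1))
      msg <- c(msg, "f_sg2m must lie in [0, 1]")
  }
  if (length(msg)) msg else TRUE
})

#' ExpansionResult: per-transition amplification and divisions
#'
#' Output of [estimateExpansion()]: for each (donor, tissue) series, the
#' lower-bound amplification `a_s` and symmetric differentiating divisions
#' `d_s = log2(a_s)` per stage transition, the cumulative output `O_s`
#' (`O_1 = 1`), and the total divisions `D = sum(d_s)`.
#'
#' @slot branchName Branch label, carried over from the input model.
#' @slot stages Stage order, carried over.
#' @slot transitions data.frame: `donor`, `tissue`, `from`, `to`,
#'   `amplification`, `divisions`, `flagged` (TRUE when a floor was applied
#'   or a stage was empty).
#' @slot output data.frame: `donor`, `tissue`, `stage`, `cum_output`.
#' @slot totals data.frame: `donor`, `tissue`, `total_divisions`.
#' @export
setClass("ExpansionResult",
  representation(branchName = "character", stages = "character",
                 transitions = "data.frame", output = "data.frame",
                 totals = "data.frame"))

setValidity("ExpansionResult", function(object) {
  t <- object@transitions
  if (nrow(t) && any(t$amplification < 1)) return("amplification must be >= 1 (floored)")
  if (nrow(t) && any(t$divisions < 0)) return("divisions must be >= 0")
  if (nrow(object@totals) && any(object@totals$total_divisions < 0))
    return("total divisions must be >= 0")
  TRUE
})

#' IdentitySignature: paired medullary / extramedullary gene lists
#'
#' The two halves of the two-pole HSC/MPP identity signature: genes up in the
#' medullary (bone-marrow-type) pole and genes up in the extramedullary
#' (spleen-type) pole, as derived by [deriveIdentitySignature()].
#'
#' @slot medGenes Character vector of medullary-pole genes.
#' @slot extramedGenes Character vector of extramedullary-pole genes.
#' @slot params Named list recording the derivation parameters
#'   (`n_top`, `fdr_cut`, `lfc_cut`).
#' @export
setClass("IdentitySignature",
  representation(medGenes = "character", extramedGenes = "character",
                 params = "list"))

setValidity("IdentitySignature", function(object) {
  msg <- character(0)
  if (length(object@medGenes) == 0L || length(object@extramedGenes) == 0L)
    msg <- c(msg, "both signature halves must be nonempty")
  if (length(intersect(object@medGenes, object@extramedGenes)))
    msg <- c(msg, "medullary and extramedullary gene lists must be disjoint")
  if (anyDuplicated(object@medGenes) || anyDuplicated(object@extramedGenes))
    msg <- c(msg, "gene lists must not contain duplicates")
  if (length(msg)) msg else TRUE
})

#' IdentityResult: per-cell identity ratios and per-sample summaries
#'
#' Output of [computeIdentityRatio()]: per-cell medullary and extramedullary
#' signature scores, their fractional ranks over the scored cohort, the
#' per-cell ratio `R = rank_med / rank_extramed`, and per-sample median
#' ratios with bootstrap confidence intervals.
#'
#' @slot cells data.frame: `cell_id`, `sample`, `score_med`,
#'   `score_extramed`, `rank_med`, `rank_extramed`, `ratio`.
#' @slot samples data.frame: `sample`, `n`, `median_ratio`, `ci_lo`, `ci_hi`.
#' @slot params Named list (scoring and bootstrap parameters incl. seed).
#' @export
setClass("IdentityResult",
  representation(cells = "data.frame", samples = "data.frame", params = "list"))

setValidity("IdentityResult", function(object) {
  c <- object@cells
  if (nrow(c) && any(!is.finite(c$ratio) | c$ratio <= 0))
    return("identity ratios must be finite and positive")
  if (nrow(c) && (any(c$rank_med <= 0 | c$rank_med > 1) ||
                  any(c$rank_extramed <= 0 | c$rank_extramed > 1)))
    return("fractional ranks must lie in (0, 1]")
  TRUE
})

#' LdaResult: limiting-dilution frequency estimate
#'
#' Output of [ldaFrequency()]: the single-hit Poisson maximum-likelihood
#' frequency of responding cells, with a confidence interval, the customary
#' "1 in N" rendering, and flags for boundary situations.
#'
#' @slot frequency Estimated frequency per cell (>= 0; `Inf` when every
#'   animal responded).
#' @slot ciLow,ciHigh Confidence bounds on the frequency.
#' @slot confLevel Confidence level used.
#' @slot flags Character vector of condition flags (e.g. `"all_negative"`,
#'   `"all_positive"`, `"profile_ci"`).
#' @slot table The input dose table (`dose`, `n_tested`, `n_positive`).
#' @export
setClass("LdaResult",
  representation(frequency = "numeric", ciLow = "numeric", ciHigh = "numeric",
                 confLevel = "numeric", flags = "character", table = "data.frame"))

setValidity("LdaResult", function(object) {
  if (object@frequency < 0) return("frequency must be >= 0")
  if (!(object@ciLow <= object@frequency || is.infinite(object@frequency)))
    return("ciLow must not exceed the estimate")
  if (object@ciHigh < object@frequency && is.finite(object@frequency))
    return("ciHigh must not be below the estimate")
  TRUE
})

#' SimConfig: ground-truth configuration for the synthetic-data generator
#'
#' Describes a synthetic HSPC scRNA-seq experiment: tissues with cluster
#' compositions, clusters with gene programs and cycling fractions,
#' tissue-level medullary/extramedullary identity programs, cell-cycle (S and
#' G2M) programs, the negative-binomial count model, and the seed. Build one
#' with [simConfig()] or [defaultSimConfig()].
#'
#' @slot nGenes Number of genes.
#' @slot tissues List of tissue specs from [tissueSpec()].
#' @slot clusters List of cluster specs from [clusterSpec()].
#' @slot baselineMeanlog,baselineSdlog Lognormal parameters of baseline gene
#'   means.
#' @slot dispersion Shared negative-binomial inverse-dispersion (size) > 0.
#' @slot libMeanlog,libSdlog Lognormal parameters of cell library sizes.
#' @slot identityPrograms List with `med` and `extramed` elements, each
#'   `list(genes = <integer indices>, fold = <numeric > 0>)`.
#' @slot ccPrograms List with `s` and `g2m` elements of the same shape.
#' @slot seed Integer seed; identical config + seed gives bit-identical data.
#' @export
setClass("SimConfig",
  representation(nGenes = "integer", tissues = "list", clusters = "list",
                 baselineMeanlog = "numeric", baselineSdlog = "numeric",
                 dispersion = "numeric", libMeanlog = "numeric",
                 libSdlog = "numeric", identityPrograms = "list",
                 ccPrograms = "list", seed = "integer"))

.checkProgram <- function(p, nGenes, label) {
  msg <- character(0)
  if (!is.list(p) || !all(c("genes", "fold") %in% names(p)))
    return(sprintf("%s: a program needs 'genes' and 'fold'", label))
  if (length(p$genes) && (any(p$genes < 1) || any(p$genes > nGenes)))
    msg <- c(msg, sprintf("%s: program gene indices must lie in [1, nGenes]", label))
  if (any(p$fold <= 0))
    msg <- c(msg, sprintf("%s: fold-effects must be > 0", label))
  msg
}

setValidity("SimConfig", function(object) {
  msg <- character(0)
  if (object@nGenes < 1L) msg <- c(msg, "nGenes must be >= 1")
  if (object@dispersion <= 0) msg <- c(msg, "dispersion must be > 0")
  clNames <- vapply(object@clusters, `[[`, character(1), "name")
  if (anyDuplicated(clNames)) msg <- c(msg, "duplicate cluster names")
  for (cl in object@clusters) {
    if (cl$cycling_fraction < 0 || cl$cycling_fraction > 1)
      msg <- c(msg, sprintf("cluster %s: cycling_fraction outside [0, 1]", cl$name))
    msg <- c(msg, .checkProgram(cl$program, object@nGenes,
                                sprintf("cluster %s", cl$name)))
  }
  for (ts in object@tissues) {
    comp <- ts$composition
    if (abs(sum(comp) - 1) > 1e-9)
      msg <- c(msg, sprintf("tissue %s: composition must sum to 1", ts$name))
    if (any(comp < 0))
      msg <- c(msg, sprintf("tissue %s: composition must be nonnegative", ts$name))
    if (!all(names(comp) %in% clNames))
      msg <- c(msg, sprintf("tissue %s: composition names unknown clusters", ts$name))
    if (!ts$identity %in% c("med", "extramed", "none"))
      msg <- c(msg, sprintf("tissue %s: identity must be med/extramed/none", ts$name))
    if (!is.null(ts$cycling)) {
      if (any(ts$cycling < 0 | ts$cycling > 1) || is.null(names(ts$cycling)) ||
          !all(names(ts$cycling) %in% clNames))
        msg <- c(msg, sprintf("tissue %s: cycling override must be named by known clusters with values in [0, 1]",
                              ts$name))
    }
    if (ts$n_cells < 0) msg <- c(msg, sprintf("tissue %s: n_cells < 0", ts$name))
  }
  for (nm in c("med", "extramed"))
    msg <- c(msg, .checkProgram(object@identityPrograms[[nm]], object@nGenes,
                                paste0("identity ", nm)))
  for (nm in c("s", "g2m"))
    msg <- c(msg, .checkProgram(object@ccPrograms[[nm]], object@nGenes,
                                paste0("cell cycle ", nm)))
  if (length(msg)) msg else TRUE
})

setMethod("show", "BranchModel", function(object) {
  cat(sprintf("BranchModel '%s': %d stages (%s), %d (donor,tissue) series\n",
              object@branchName, length(object@stages),
              paste(object@stages, collapse = " -> "),
              nrow(unique(object@data[, c("donor", "tissue")]))))
  cat(sprintf("  cycling fractions: %s\n", object@cyclingSource))
})

setMethod("show", "ExpansionResult", function(object) {
  cat(sprintf("ExpansionResult '%s' (%d transitions/series)\n",
              object@branchName, length(object@stages) - 1L))
  for (i in seq_len(nrow(object@totals))) {
    t <- object@totals[i, ]
    cat(sprintf("  %s/%s: total divisions D = %.3g\n", t$donor, t$tissue,
                t$total_divisions))
  }
})

setMethod("show", "IdentitySignature", function(object) {
  cat(sprintf("IdentitySignature: %d medullary + %d extramedullary genes\n",
              length(object@medGenes), length(object@extramedGenes)))
})

setMethod("show", "IdentityResult", function(object) {
  cat(sprintf("IdentityResult: %d cells, %d samples\n",
              nrow(object@cells), nrow(object@samples)))
  if (nrow(object@samples)) print(object@samples, row.names = FALSE)
})

setMethod("show", "LdaResult", function(object) {
  f <- object@frequency
  lab <- if (is.finite(f) && f > 0) sprintf("1 in %d", oneIn(object)) else
    if (f == 0) "0 (no responders)" else "all responders"
  cat(sprintf("LdaResult: frequency %.4g (%s), %.0f%% CI [%.4g, %.4g]\n",
              f, lab, 100 * object@confLevel, object@ciLow, object@ciHigh))
  if (length(object@flags)) cat("  flags:", paste(object@flags, collapse = ", "), "\n")
})

setMethod("show", "SimConfig", function(object) {
  cat(sprintf("SimConfig: %d genes, %d tissues (%s), %d clusters, seed %d\n",
              object@nGenes, length(object@tissues),
              paste(vapply(object@tissues, `[[`, character(1), "name"),
                    collapse = ", "),
              length(object@clusters), object@seed))
})
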