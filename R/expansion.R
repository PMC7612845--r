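#' Construct a BranchModel directly from stage counts and cycling fractions
#'
#' For fixtures and externally measured inputs (e.g. Ki-67-based cycling
#' fractions). Builds a single-(donor, tissue) series; use
#' [buildBranchModel()] to derive one from annotated cells.
#'
#' @param stages Character stage names in differentiation order (>= 2).
#' @param nCells Cell counts per stage.
#' @param cycling S-G2-M fraction per stage.
#' @param branchName Branch label.
#' @param donor,tissue Series labels.
#' @param cyclingSource Provenance label for the cycling fractions
#'   (`"supplied"`, `"transcriptional"`, ...).
#' @return A [BranchModel-class].
#' @export
BranchModel <- function(stages, nCells, cycling, branchName = "branch",
                        donor = "pooled", tissue = "all",
                        cyclingSource = "supplied") {
  if (length(stages) != length(nCells) || length(stages) != length(cycling))
    .stopf("stages, nCells and cycling must have equal length")
  d <- data.frame(donor = donor, tissue = tissue, stage = stages,
                  n_cells = as.numeric(nCells), f_sg2m = as.numeric(cycling),
                  empty = nCells == 0, stringsAsFactors = FALSE)
  new("BranchModel", branchName = branchName, stages = as.character(stages),
      data = d, cyclingSource = cyclingSource)
}

#' Build a BranchModel from annotated cells
#'
#' Counts cells and S-G2-M fractions per ordered stage, per (donor, tissue),
#' for a branch defined as an ordered mapping of stages to disjoint cluster
#' sets.
#'
#' @param cells A `SingleCellExperiment` or data.frame with columns `donor`,
#'   `tissue`, `cluster`, `phase`.
#' @param branchSpec Named list, in differentiation order: stage name ->
#'   character vector of member clusters (disjoint across stages).
#' @param branchName Branch label.
#' @return A [BranchModel-class]; stages observed with zero cells are kept
#'   with `n_cells = 0` and flagged.
#' @export
buildBranchModel <- function(cells, branchSpec, branchName = "branch") {
  cells <- .cellTable(cells, c("donor", "tissue", "cluster", "phase"))
  stages <- names(branchSpec)
  if (length(stages) < 2L) .stopf("a branch needs at least 2 stages")
  allCl <- unlist(branchSpec, use.names = FALSE)
  if (anyDuplicated(allCl))
    .stopf("cluster(s) assigned to more than one stage: %s",
           paste(unique(allCl[duplicated(allCl)]), collapse = ", "))
  inBranch <- cells$cluster %in% allCl
  cells <- cells[inBranch, , drop = FALSE]
  if (!nrow(cells)) .stopf("no cells fall in any branch stage")
  bad <- is.na(cells$phase)
  if (any(bad)) .stopf("%d branch cell(s) lack a phase assignment", sum(bad))
  stageOf <- setNames(rep(stages, lengths(branchSpec)), allCl)
  cells$stage <- unname(stageOf[as.character(cells$cluster)])
  key <- interaction(cells$donor, cells$tissue, drop = TRUE, sep = "\r")
  d <- do.call(rbind, lapply(split(cells, key), function(g) {
    st <- factor(g$stage, levels = stages)
    n <- as.integer(table(st))
    x <- as.integer(table(st[g$phase %in% c("S", "G2M")]))
    data.frame(donor = as.character(g$donor[1L]),
               tissue = as.character(g$tissue[1L]), stage = stages,
               n_cells = n, f_sg2m = ifelse(n > 0, x / n, 0),
               empty = n == 0L, stringsAsFactors = FALSE)
  }))
  rownames(d) <- NULL
  new("BranchModel", branchName = branchName, stages = stages, data = d,
      cyclingSource = "transcriptional")
}

#' Lower-bound branch expansion: amplification and differentiating divisions
#'
#' The expansion model: only cells in S-G2-M are taken to be active, and
#' every division is assumed symmetric and differentiating, so the number of
#' active cells `A_s = N_s * f_s` at stage `s` bounds from below the
#' amplification into the next stage,
#' `a_s = max(1, N_(s+1) / max(A_s, 1))`, contributing
#' `d_s = log2(a_s)` divisions. The `max(A_s, 1)` floor encodes "at least
#' one active cell" and the `a_s >= 1` floor makes shrinking stages
#' contribute zero divisions, keeping the estimate a lower bound. Total
#' divisions `D = sum(d_s)`; cumulative output `O_1 = 1`,
#' `O_(s+1) = O_s * a_s`. Depends only on ratios of stage abundances, so
#' relative (composition) counts can be used.
#'
#' @param model A [BranchModel-class].
#' @return An [ExpansionResult-class], one series per (donor, tissue) of the
#'   input. Transitions where a floor engaged or a stage was empty carry
#'   `flagged = TRUE`.
#' @export
estimateExpansion <- function(model) {
  stopifnot(is(model, "BranchModel"))
  stages <- model@stages
  S <- length(stages)
  key <- interaction(model@data$donor, model@data$tissue, drop = TRUE,
                     sep = "\r")
  trans <- list(); outp <- list(); tot <- list()
  for (g in split(model@data, key)) {
    g <- g[match(stages, g$stage), , drop = FALSE]
    if (any(is.na(g$n_cells)))
      .stopf("series %s/%s misses stage rows", g$donor[1L], g$tissue[1L])
    N <- g$n_cells
    A <- N * g$f_sg2m
    nxt <- N[-1L]
    denom <- pmax(A[-S], 1)
    a <- pmax(1, nxt / denom)
    flagged <- (A[-S] < 1) | (nxt <= A[-S]) | (N[-S] == 0) | (nxt == 0)
    d <- log2(a)
    O <- c(1, cumprod(a))
    id <- list(donor = g$donor[1L], tissue = g$tissue[1L])
    trans[[length(trans) + 1L]] <- data.frame(
      donor = id$donor, tissue = id$tissue, from = stages[-S], to = stages[-1L],
      amplification = a, divisions = d, flagged = flagged,
      stringsAsFactors = FALSE)
    outp[[length(outp) + 1L]] <- data.frame(
      donor = id$donor, tissue = id$tissue, stage = stages, cum_output = O,
      stringsAsFactors = FALSE)
    tot[[length(tot) + 1L]] <- data.frame(
      donor = id$donor, tissue = id$tissue, total_divisions = sum(d),
      stringsAsFactors = FALSE)
  }
  new("ExpansionResult", branchName = model@branchName, stages = stages,
      transitions = do.call(rbind, trans), output = do.call(rbind, outp),
      totals = do.call(rbind, tot))
}

#' Normalize cumulative outputs across conditions against a reference
#'
#' Aligns the cumulative output curves of several conditions (each an
#' [ExpansionResult-class] over the same stage order) and reports them next
#' to the reference condition's theoretical exponential line
#' `2^(sum of reference divisions up to each stage)`. Within each condition,
#' per-stage outputs are averaged over its (donor, tissue) series on the
#' divisions (log2) scale.
#'
#' @param results Named list of [ExpansionResult-class] objects (the
#'   conditions).
#' @param reference Name of the reference condition (default: first).
#' @return data.frame with `condition`, `stage`, `output`, `ref_output`.
#' @export
normalizeOutput <- function(results, reference = names(results)[1L]) {
  if (is.null(names(results)) || any(!nzchar(names(results))))
    .stopf("results must be a named list of conditions")
  if (!reference %in% names(results))
    .stopf("reference condition '%s' not among results", reference)
  stages <- results[[1L]]@stages
  for (r in results)
    if (!identical(r@stages, stages))
      .stopf("all conditions must share the same ordered stage list")
  curve <- function(res) {
    key <- interaction(res@output$donor, res@output$tissue, drop = TRUE)
    logs <- vapply(split(res@output, key), function(o)
      log2(o$cum_output[match(stages, o$stage)]), numeric(length(stages)))
    2^rowMeans(matrix(logs, nrow = length(stages)))
  }
  ref <- curve(results[[reference]])
  out <- do.call(rbind, lapply(names(results), function(nm)
    data.frame(condition = nm, stage = stages, output = curve(results[[nm]]),
               ref_output = ref, stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out
}
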