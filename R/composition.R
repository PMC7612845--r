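## helper: per-cell annotation data.frame from SCE or data.frame input
.cellTable <- function(cells, need) {
  if (is(cells, "SummarizedExperiment"))
    cells <- as.data.frame(SummarizedExperiment::colData(cells))
  missing <- setdiff(need, names(cells))
  if (length(missing))
    .stopf("cell table lacks column(s): %s", paste(missing, collapse = ", "))
  cells
}

#' Per-(donor, tissue) cluster or group composition
#'
#' Fractions of cells per cluster within each donor and tissue; with a
#' `groupMap`, clusters are first aggregated into HSPC groups.
#'
#' @param cells A `SingleCellExperiment` or data.frame with columns `donor`,
#'   `tissue`, `cluster`.
#' @param groupMap Optional named character vector `cluster -> group`; must
#'   cover every cluster present.
#' @return data.frame with columns `donor`, `tissue`, `group`, `n_cells`,
#'   `fraction`; within each (donor, tissue), fractions sum to 1.
#' @export
clusterFractions <- function(cells, groupMap = NULL) {
  cells <- .cellTable(cells, c("donor", "tissue", "cluster"))
  grp <- as.character(cells$cluster)
  if (!is.null(groupMap)) {
    unmapped <- setdiff(unique(grp), names(groupMap))
    if (length(unmapped))
      .stopf("groupMap does not cover cluster(s): %s",
             paste(unmapped, collapse = ", "))
    grp <- unname(groupMap[grp])
  }
  key <- interaction(cells$donor, cells$tissue, drop = TRUE, sep = "\r")
  res <- lapply(split(grp, key), function(g) {
    tab <- table(g)
    data.frame(group = names(tab), n_cells = as.integer(tab),
               fraction = as.numeric(tab) / length(g),
               stringsAsFactors = FALSE)
  })
  ids <- do.call(rbind, strsplit(names(res), "\r", fixed = TRUE))
  out <- do.call(rbind, lapply(seq_along(res), function(i)
    data.frame(donor = ids[i, 1L], tissue = ids[i, 2L], res[[i]],
               stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out
}

#' Ratio of summed group fractions per (donor, tissue)
#'
#' E.g. the ratio of early-to-late progenitors of a branch: the summed
#' fractions of the numerator groups over the summed fractions of the
#' denominator groups, per donor and tissue. A zero denominator with a
#' positive numerator yields `Inf` with `degenerate = TRUE`.
#'
#' @param composition Output of [clusterFractions()].
#' @param numeratorGroups,denominatorGroups Disjoint character vectors of
#'   group names.
#' @return data.frame with `donor`, `tissue`, `numerator`, `denominator`,
#'   `ratio`, `degenerate`.
#' @export
groupRatio <- function(composition, numeratorGroups, denominatorGroups) {
  if (length(intersect(numeratorGroups, denominatorGroups)))
    .stopf("numerator and denominator groups must be disjoint")
  key <- interaction(composition$donor, composition$tissue, drop = TRUE,
                     sep = "\r")
  out <- do.call(rbind, lapply(split(composition, key), function(d) {
    num <- sum(d$fraction[d$group %in% numeratorGroups])
    den <- sum(d$fraction[d$group %in% denominatorGroups])
    ratio <- if (den > 0) num / den else if (num > 0) Inf else NaN
    data.frame(donor = d$donor[1L], tissue = d$tissue[1L], numerator = num,
               denominator = den, ratio = ratio, degenerate = den == 0,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Per-(donor, tissue, cluster) S-G2-M cycling fractions
#'
#' @param cells A `SingleCellExperiment` or data.frame with columns `donor`,
#'   `tissue`, `cluster`, `phase` (every cell must have a phase in
#'   `{"G1", "S", "G2M"}`; missing phases are an error listing the cells).
#' @return data.frame with `donor`, `tissue`, `cluster`, `n_total`,
#'   `n_sg2m`, `fraction_sg2m`, `empty` (flag for zero-cell groups).
#' @export
cyclingFractions <- function(cells) {
  cells <- .cellTable(cells, c("donor", "tissue", "cluster", "phase"))
  bad <- is.na(cells$phase) | !(cells$phase %in% c("G1", "S", "G2M"))
  if (any(bad)) {
    ids <- if ("cell_id" %in% names(cells)) cells$cell_id[bad] else which(bad)
    .stopf("cells without a valid phase: %s",
           paste(utils::head(ids, 5L), collapse = ", "))
  }
  clLevels <- if (is.factor(cells$cluster)) levels(cells$cluster) else
    sort(unique(as.character(cells$cluster)))
  key <- interaction(cells$donor, cells$tissue, drop = TRUE, sep = "\r")
  out <- do.call(rbind, lapply(split(cells, key), function(d) {
    cl <- factor(as.character(d$cluster), levels = clLevels)
    n <- as.integer(table(cl))
    x <- as.integer(table(cl[d$phase %in% c("S", "G2M")]))
    data.frame(donor = as.character(d$donor[1L]),
               tissue = as.character(d$tissue[1L]), cluster = clLevels,
               n_total = n, n_sg2m = x,
               fraction_sg2m = ifelse(n > 0, x / n, 0), empty = n == 0L,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Two-sided exact binomial comparison of cycling fractions
#'
#' Tests the cycling count of tissue B against the pooled cycling fraction
#' of reference tissue A: an exact binomial test of `xB` successes in `nB`
#' trials against `p0 = xA / nA`, two-sided by summing the probabilities of
#' all outcomes no more likely than the observed one (the "minlike" rule).
#'
#' @param xA,nA Cycling and total cell counts in the reference tissue
#'   (`nA > 0`).
#' @param xB,nB Cycling and total cell counts in the compared tissue.
#' @return The exact two-sided p-value in `(0, 1]` (degenerate reference
#'   fractions 0 or 1 give exactly 0 or 1).
#' @export
compareCyclingBinomial <- function(xA, nA, xB, nB) {
  xA <- .checkScalarCount(xA, "xA"); nA <- .checkScalarCount(nA, "nA")
  xB <- .checkScalarCount(xB, "xB"); nB <- .checkScalarCount(nB, "nB")
  if (nA == 0L) .stopf("nA must be > 0")
  if (xA > nA || xB > nB) .stopf("x must not exceed n")
  p0 <- xA / nA
  if (p0 == 0) return(if (xB == 0L) 1 else 0)
  if (p0 == 1) return(if (xB == nB) 1 else 0)
  binom.test(xB, nB, p = p0, alternative = "two.sided")$p.value
}
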