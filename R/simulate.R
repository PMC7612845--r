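#' Specify a synthetic tissue
#'
#' @param name Tissue name (e.g. `"BM"`, `"SPL"`, `"PB"`).
#' @param nCells Number of cells to draw for this tissue.
#' @param composition Named probability vector over cluster names (sums to
#'   1); cells are assigned to clusters by multinomial sampling.
#' @param identity Which tissue-level identity program the cells carry:
#'   `"med"` (medullary/bone-marrow-type), `"extramed"` or `"none"`.
#' @param donors Number of donors; cells are assigned round-robin to donors
#'   `D1..Dk`, so the same donor ids recur across tissues (matched design).
#' @param cycling Optional named vector overriding cluster cycling fractions
#'   within this tissue (how tissue-specific proliferation is encoded).
#' @return A list understood by [simConfig()].
#' @export
tissueSpec <- function(name, nCells, composition, identity = "none",
                       donors = 1L, cycling = NULL) {
  list(name = name, n_cells = as.integer(nCells), composition = composition,
       identity = identity, donors = as.integer(donors), cycling = cycling)
}

#' Specify a synthetic cluster
#'
#' @param name Cluster name.
#' @param stage Optional stage label, format `"branch:order"` (e.g.
#'   `"MEMB:1"`), used to build branch models from the truth; `NA` for
#'   clusters outside any branch.
#' @param programGenes Integer gene indices upregulated in this cluster.
#' @param fold Fold-effect (> 0) applied to the program genes.
#' @param cyclingFraction Fraction of cells of this cluster in S-G2-M.
#' @return A list understood by [simConfig()].
#' @export
clusterSpec <- function(name, stage = NA_character_, programGenes = integer(0),
                        fold = 2, cyclingFraction = 0) {
  list(name = name, stage = as.character(stage),
       program = list(genes = as.integer(programGenes), fold = fold),
       cycling_fraction = cyclingFraction)
}

#' Build a synthetic-data configuration
#'
#' See [SimConfig-class] for the meaning of each component and
#' [defaultSimConfig()] for the stock multi-tissue configuration.
#'
#' @param nGenes Number of genes.
#' @param tissues List of [tissueSpec()] entries.
#' @param clusters List of [clusterSpec()] entries.
#' @param baselineMeanlog,baselineSdlog Lognormal parameters for baseline
#'   gene means.
#' @param dispersion Negative-binomial inverse-dispersion (size) shared by
#'   all genes.
#' @param libMeanlog,libSdlog Lognormal parameters for cell library sizes.
#' @param identityPrograms List with `med` and `extramed` programs
#'   (`list(genes =, fold =)`).
#' @param ccPrograms List with `s` and `g2m` programs.
#' @param seed Integer seed.
#' @return A validated [SimConfig-class] object.
#' @export
simConfig <- function(nGenes, tissues, clusters,
                      baselineMeanlog = 0, baselineSdlog = 1,
                      dispersion = 2,
                      libMeanlog = log(5000), libSdlog = 0.3,
                      identityPrograms = list(med = list(genes = integer(0), fold = 2),
                                              extramed = list(genes = integer(0), fold = 2)),
                      ccPrograms = list(s = list(genes = integer(0), fold = 2),
                                        g2m = list(genes = integer(0), fold = 2)),
                      seed = 1L) {
  obj <- new("SimConfig", nGenes = as.integer(nGenes), tissues = tissues,
             clusters = clusters, baselineMeanlog = baselineMeanlog,
             baselineSdlog = baselineSdlog, dispersion = dispersion,
             libMeanlog = libMeanlog, libSdlog = libSdlog,
             identityPrograms = identityPrograms, ccPrograms = ccPrograms,
             seed = as.integer(seed))
  ok <- validObject(obj, test = TRUE)
  if (!isTRUE(ok))
    .stopf("invalid SimConfig: %s", paste(ok, collapse = "; "))
  obj
}

#' Stock synthetic multi-tissue HSPC configuration
#'
#' Emulates the statistical structure of a multi-tissue HSPC scRNA-seq
#' experiment: a bone-marrow tissue with abundant late progenitors and
#' actively cycling progenitor stages, and spleen / peripheral-blood tissues
#' skewed towards HSC/MPPs and early progenitors with near-quiescent
#' progenitor compartments. Clusters form two ordered branches (MEMB and My,
#' early -> late). BM cells carry the medullary identity program, SPL and PB
#' cells the extramedullary one. Gene programs occupy disjoint 50-gene
#' blocks with fold-effect 2.
#'
#' @param seed Integer seed.
#' @param nGenes Number of genes (>= 500 so all program blocks fit).
#' @param cellsPerTissue Cells per tissue.
#' @param donors Donors per tissue.
#' @param dispersion Negative-binomial size parameter.
#' @param fold Fold-effect shared by the cluster and identity programs.
#' @param ccFold Fold-effect of the S and G2M programs. Cell-cycle genes are
#'   induced much more strongly than lineage programs in real data, hence
#'   the larger default.
#' @return A [SimConfig-class].
#' @export
defaultSimConfig <- function(seed = 1L, nGenes = 2000L, cellsPerTissue = 1000L,
                             donors = 2L, dispersion = 2, fold = 2,
                             ccFold = 6) {
  if (nGenes < 500L) .stopf("nGenes must be >= 500 to fit the program blocks")
  blk <- function(i) ((i - 1L) * 50L + 1L):(i * 50L)
  clusters <- list(
    clusterSpec("HSC/MPP", NA, blk(1), fold, 0.05),
    clusterSpec("MEMB_early", "MEMB:1", blk(2), fold, 0.05),
    clusterSpec("MEMB_late", "MEMB:2", blk(3), fold, 0.05),
    clusterSpec("My_early", "My:1", blk(4), fold, 0.05),
    clusterSpec("My_late", "My:2", blk(5), fold, 0.05))
  ## cluster defaults encode the quiescent extramedullary regime; the BM
  ## tissue overrides them with actively cycling progenitor stages
  bmCycling <- c("HSC/MPP" = 0.05, "MEMB_early" = 0.30, "MEMB_late" = 0.50,
                 "My_early" = 0.30, "My_late" = 0.50)
  tissues <- list(
    tissueSpec("BM", cellsPerTissue,
               c("HSC/MPP" = 0.30, "MEMB_early" = 0.10, "MEMB_late" = 0.25,
                 "My_early" = 0.10, "My_late" = 0.25),
               identity = "med", donors = donors, cycling = bmCycling),
    tissueSpec("SPL", cellsPerTissue,
               c("HSC/MPP" = 0.40, "MEMB_early" = 0.25, "MEMB_late" = 0.10,
                 "My_early" = 0.20, "My_late" = 0.05),
               identity = "extramed", donors = donors),
    tissueSpec("PB", cellsPerTissue,
               c("HSC/MPP" = 0.35, "MEMB_early" = 0.35, "MEMB_late" = 0.05,
                 "My_early" = 0.20, "My_late" = 0.05),
               identity = "extramed", donors = donors))
  simConfig(nGenes = nGenes, tissues = tissues, clusters = clusters,
            dispersion = dispersion,
            identityPrograms = list(med = list(genes = blk(7), fold = fold),
                                    extramed = list(genes = blk(8), fold = fold)),
            ccPrograms = list(s = list(genes = blk(9), fold = ccFold),
                              g2m = list(genes = blk(10), fold = ccFold)),
            seed = seed)
}

#' Single-cluster two-pole configuration for identity benchmarking
#'
#' Builds the canonical training/test configuration for the identity-ratio
#' classifier: one HSC/MPP-like cluster, a medullary tissue pole (`"BM"`)
#' and/or an extramedullary pole (`"SPL"`), each carrying its identity gene
#' program (disjoint `programSize`-gene blocks, fold-effect `fold`). Set one
#' pole's cell count to 0 to generate a single-pole (held-out test) sample.
#'
#' @param nMed,nExtramed Cells carrying the medullary / extramedullary
#'   program.
#' @param seed Integer seed.
#' @param nGenes Number of genes (>= 100 + 2 * programSize).
#' @param dispersion Negative-binomial size parameter.
#' @param fold Identity-program fold-effect.
#' @param programSize Genes per identity program.
#' @return A [SimConfig-class].
#' @export
identityPoleConfig <- function(nMed = 400L, nExtramed = 400L, seed = 1L,
                               nGenes = 2000L, dispersion = 2, fold = 2,
                               programSize = 50L) {
  if (nGenes < 100L + 2L * programSize)
    .stopf("nGenes too small for the identity program blocks")
  medBlk <- seq(101L, length.out = programSize)
  exBlk <- seq(101L + programSize, length.out = programSize)
  tissues <- list()
  if (nMed > 0)
    tissues <- c(tissues, list(tissueSpec("BM", nMed, c("HSC/MPP" = 1),
                                          identity = "med")))
  if (nExtramed > 0)
    tissues <- c(tissues, list(tissueSpec("SPL", nExtramed, c("HSC/MPP" = 1),
                                          identity = "extramed")))
  if (!length(tissues)) .stopf("at least one pole must have cells")
  simConfig(nGenes = nGenes, tissues = tissues,
            clusters = list(clusterSpec("HSC/MPP")), dispersion = dispersion,
            identityPrograms = list(med = list(genes = medBlk, fold = fold),
                                    extramed = list(genes = exBlk, fold = fold)),
            seed = seed)
}

#' Ground-truth gene sets of a configuration
#'
#' Returns the cluster, identity and cell-cycle programs of a [SimConfig-class]
#' as named gene-id lists (GMT-style), for scoring the simulated data against
#' its own truth.
#'
#' @param config A [SimConfig-class].
#' @return Named list of character gene vectors.
#' @export
truthGeneSets <- function(config) {
  ids <- .geneIds(config@nGenes)
  sets <- list()
  for (cl in config@clusters)
    if (length(cl$program$genes))
      sets[[cl$name]] <- ids[cl$program$genes]
  for (nm in c("med", "extramed"))
    if (length(config@identityPrograms[[nm]]$genes))
      sets[[toupper(nm)]] <- ids[config@identityPrograms[[nm]]$genes]
  if (length(config@ccPrograms$s$genes))
    sets[["S_PHASE"]] <- ids[config@ccPrograms$s$genes]
  if (length(config@ccPrograms$g2m$genes))
    sets[["G2M_PHASE"]] <- ids[config@ccPrograms$g2m$genes]
  sets
}

.geneIds <- function(n) sprintf("G%05d", seq_len(n))

#' Simulate a ground-truth-labelled HSPC scRNA-seq dataset
#'
#' Draws, per tissue, cell cluster memberships by multinomial sampling from
#' the tissue composition; per cell a cycling indicator Bernoulli(f) with
#' cycling cells split S vs G2M 50/50; then negative-binomial counts with
#' mean `baseline * cluster fold * identity fold * phase fold`, rescaled per
#' cell so that expected totals match the drawn library size. Identical
#' config and seed give bit-identical output.
#'
#' @param config A [SimConfig-class].
#' @return A `SingleCellExperiment` with a sparse `counts` assay; `colData`
#'   columns `cell_id`, `donor`, `tissue`, `cluster`, `stage`, `phase`,
#'   `library_size` (realized column sums); the config is kept in
#'   `metadata(x)$simConfig`.
#' @export
simulateDataset <- function(config) {
  stopifnot(is(config, "SimConfig"))
  ok <- validObject(config, test = TRUE)
  if (!isTRUE(ok)) .stopf("invalid SimConfig: %s", paste(ok, collapse = "; "))
  G <- config@nGenes
  clNames <- vapply(config@clusters, `[[`, character(1), "name")
  clByName <- setNames(config@clusters, clNames)
  .withSeed(config@seed, {
    base <- rlnorm(G, config@baselineMeanlog, config@baselineSdlog)
    cellRows <- list()
    for (ts in config@tissues) {
      n <- ts$n_cells
      if (n == 0L) next
      comp <- ts$composition
      cl <- sample(names(comp), n, replace = TRUE, prob = comp)
      phase <- rep("G1", n)
      f <- vapply(clByName[cl], `[[`, numeric(1), "cycling_fraction")
      if (!is.null(ts$cycling)) {
        ov <- !is.na(match(cl, names(ts$cycling)))
        f[ov] <- ts$cycling[cl[ov]]
      }
      cyc <- runif(n) < f
      if (any(cyc))
        phase[cyc] <- ifelse(runif(sum(cyc)) < 0.5, "S", "G2M")
      lib <- rlnorm(n, config@libMeanlog, config@libSdlog)
      cellRows[[ts$name]] <- data.frame(
        tissue = ts$name,
        donor = paste0("D", 1L + (seq_len(n) - 1L) %% ts$donors),
        cluster = cl, phase = phase, lib = lib,
        identity = ts$identity, stringsAsFactors = FALSE)
    }
    cells <- do.call(rbind, cellRows)
    rownames(cells) <- NULL
    nCells <- nrow(cells)
    ## group cells sharing an expression profile (tissue-identity, cluster,
    ## phase) and draw their counts in one vectorized NB call
    grp <- interaction(cells$identity, cells$cluster, cells$phase, drop = TRUE)
    counts <- matrix(0, nrow = G, ncol = nCells)
    for (g in levels(grp)) {
      idx <- which(grp == g)
      first <- cells[idx[1L], ]
      mu <- base
      pr <- clByName[[first$cluster]]$program
      if (length(pr$genes)) mu[pr$genes] <- mu[pr$genes] * pr$fold
      if (first$identity != "none") {
        ip <- config@identityPrograms[[first$identity]]
        if (length(ip$genes)) mu[ip$genes] <- mu[ip$genes] * ip$fold
      }
      if (first$phase != "G1") {
        cp <- config@ccPrograms[[tolower(first$phase)]]
        if (length(cp$genes)) mu[cp$genes] <- mu[cp$genes] * cp$fold
      }
      muMat <- outer(mu / sum(mu), cells$lib[idx])
      counts[, idx] <- rnbinom(G * length(idx), mu = muMat,
                               size = config@dispersion)
    }
    m <- .asSparse(counts)
    dimnames(m) <- list(.geneIds(G),
                        sprintf("%s_%s_c%05d", cells$tissue, cells$donor,
                                seq_len(nCells)))
    stage <- vapply(clByName[cells$cluster], `[[`, character(1), "stage")
    cd <- S4Vectors::DataFrame(
      cell_id = colnames(m), donor = cells$donor, tissue = cells$tissue,
      cluster = cells$cluster, stage = stage, phase = cells$phase,
      library_size = as.integer(Matrix::colSums(m)), row.names = colnames(m))
    SingleCellExperiment(assays = list(counts = m), colData = cd,
                         metadata = list(simConfig = config))
  })
}

#' Simulate observed stage abundances and cycling fractions along a branch
#'
#' Fixture generator for the branch-expansion estimator: a multinomial
#' sample of `nSample` cells over the stages (proportional to
#' `stageCounts`), with per-stage cycling counts Binomial(N_s, f_s).
#' `nSample = 0` is exact mode: the supplied counts and fractions are
#' returned untouched.
#'
#' @param stageCounts Integer true cell counts per ordered stage (>= 2
#'   stages).
#' @param cyclingFractions True S-G2-M fraction per stage.
#' @param nSample Number of cells to sample (0 = exact mode).
#' @param seed Integer seed.
#' @param branchName,donor,tissue Labels for the returned model.
#' @return A [BranchModel-class] with observed `N_s` and `f_hat_s`.
#' @export
simulateBranchCounts <- function(stageCounts, cyclingFractions, nSample = 0L,
                                 seed = 1L, branchName = "branch",
                                 donor = "sim", tissue = "sim") {
  if (length(stageCounts) != length(cyclingFractions))
    .stopf("stageCounts and cyclingFractions must have equal length")
  if (length(stageCounts) < 2L) .stopf("need at least 2 stages")
  if (any(stageCounts < 0)) .stopf("stage counts must be nonnegative")
  if (any(cyclingFractions < 0 | cyclingFractions > 1))
    .stopf("cycling fractions must lie in [0, 1]")
  nSample <- .checkScalarCount(nSample, "nSample")
  stages <- paste0("stage", seq_along(stageCounts))
  if (nSample == 0L) {
    N <- as.numeric(stageCounts)
    fhat <- cyclingFractions
    src <- "supplied"
  } else {
    .withSeed(seed, {
      N <- as.numeric(rmultinom(1L, nSample, prob = stageCounts))
      x <- rbinom(length(N), N, cyclingFractions)
    })
    fhat <- ifelse(N > 0, x / N, 0)
    src <- "sampled"
  }
  BranchModel(stages = stages, nCells = N, cycling = fhat,
              branchName = branchName, donor = donor, tissue = tissue,
              cyclingSource = src)
}

#' Simulate a limiting-dilution dose table
#'
#' Under the single-hit Poisson model each animal receiving `dose` cells
#' responds with probability `1 - exp(-f * dose)`.
#'
#' @param trueFrequency True frequency of responding cells per cell (>= 0).
#' @param doses Integer cell doses (> 0), one per row.
#' @param nPerDose Animals tested per dose.
#' @param seed Integer seed.
#' @return data.frame with columns `dose`, `n_tested`, `n_positive`.
#' @export
simulateLDA <- function(trueFrequency, doses, nPerDose, seed = 1L) {
  if (trueFrequency < 0) .stopf("trueFrequency must be >= 0")
  if (length(doses) != length(nPerDose))
    .stopf("doses and nPerDose must have equal length")
  if (any(doses <= 0)) .stopf("doses must be positive")
  p <- 1 - exp(-trueFrequency * doses)
  pos <- .withSeed(seed, rbinom(length(doses), nPerDose, p))
  data.frame(dose = as.integer(doses), n_tested = as.integer(nPerDose),
             n_positive = as.integer(pos))
}
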