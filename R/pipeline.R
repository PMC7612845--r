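.defaultStages <- c("simulate", "score", "composition", "expansion",
                    "identity", "gsea", "lda")

## fill a config list with defaults and validate stage dependencies upfront
.resolveConfig <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  if (!is.list(config)) .stopf("config must be a list or a YAML file path")
  if (is.null(config$seed)) config$seed <- 1L
  if (is.null(config$out_dir)) .stopf("config must set out_dir")
  stages <- setNames(rep(TRUE, length(.defaultStages)), .defaultStages)
  for (nm in names(config$stages)) {
    if (!nm %in% .defaultStages) .stopf("unknown stage '%s'", nm)
    stages[nm] <- isTRUE(config$stages[[nm]])
  }
  config$stages <- as.list(stages)
  sim <- config$simulate
  config$simulate <- list(
    n_genes = sim$n_genes %||% 1500L,
    cells_per_tissue = sim$cells_per_tissue %||% 600L,
    donors = sim$donors %||% 2L,
    dispersion = sim$dispersion %||% 2,
    fold = sim$fold %||% 2)
  sc <- config$score
  config$score <- list(n_bins = sc$n_bins %||% 25L, n_ctrl = sc$n_ctrl %||% 50L)
  id <- config$identity
  config$identity <- list(
    pole_a = id$pole_a, pole_b = id$pole_b,
    n_top = id$n_top %||% 50L, fdr_cut = id$fdr_cut %||% 0.05,
    lfc_cut = id$lfc_cut %||% 0.2)
  gs <- config$gsea
  config$gsea <- list(n_perm = gs$n_perm %||% 200L)
  ld <- config$lda
  config$lda <- list(
    true_frequency = ld$true_frequency %||% 0.002,
    doses = ld$doses %||% c(250L, 500L, 1000L),
    n_per_dose = ld$n_per_dose %||% c(6L, 6L, 6L),
    conf_level = ld$conf_level %||% 0.95)
  ## upfront dependency validation: nothing runs if this fails
  on <- function(s) isTRUE(config$stages[[s]])
  for (s in setdiff(.defaultStages, c("simulate", "lda")))
    if (on(s) && !on("simulate"))
      .stopf("stage '%s' requires the simulate stage", s)
  for (s in c("composition", "expansion"))
    if (on(s) && !on("score"))
      .stopf("stage '%s' requires the score stage (phase assignment)", s)
  if (on("identity")) {
    for (p in c("pole_a", "pole_b")) {
      pole <- config$identity[[p]]
      if (is.null(pole) || is.null(pole$tissue) || is.null(pole$cluster))
        .stopf("identity stage enabled but %s lacks tissue/cluster labels", p)
    }
  }
  if (on("gsea") && !on("identity"))
    .stopf("gsea stage requires the identity stage (its DE ranking)")
  config
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full synthetic-data analysis pipeline
#'
#' Executes the enabled stages in dependency order on one synthetic dataset:
#' simulate, signature scoring + phase assignment, composition statistics,
#' branch expansion, identity training + classification, pre-ranked GSEA and
#' limiting-dilution estimation. Every stage draws its seed from the
#' top-level seed via [deriveSeed()], so disabling a downstream stage never
#' changes upstream outputs and identical config + seed give identical
#' output hashes. A JSON manifest (config, per-stage seeds, output MD5
#' hashes) is written last.
#'
#' @param config A list or path to a YAML file. Recognized fields: `seed`,
#'   `out_dir`, `stages` (named logical toggles), and per-stage parameter
#'   blocks `simulate`, `score`, `identity` (requires `pole_a`/`pole_b`,
#'   each `list(tissue =, cluster =)`), `gsea`, `lda`. Unset parameters take
#'   package defaults.
#' @return Invisibly, the manifest list.
#' @export
runPipeline <- function(config) {
  cfg <- .resolveConfig(config)
  outDir <- cfg$out_dir
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  on <- function(s) isTRUE(cfg$stages[[s]])
  seeds <- setNames(lapply(.defaultStages, function(s)
    deriveSeed(cfg$seed, "stage", s)), .defaultStages)
  outputs <- character(0)
  emit <- function(df, name) {
    path <- file.path(outDir, name)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    outputs <<- c(outputs, path)
    path
  }
  message("pipeline: out_dir=", outDir, " seed=", cfg$seed)

  sce <- NULL; phases <- NULL; simCfg <- NULL
  if (on("simulate")) {
    message("stage simulate")
    simCfg <- defaultSimConfig(seed = seeds$simulate,
                               nGenes = cfg$simulate$n_genes,
                               cellsPerTissue = cfg$simulate$cells_per_tissue,
                               donors = cfg$simulate$donors,
                               dispersion = cfg$simulate$dispersion,
                               fold = cfg$simulate$fold)
    sce <- simulateDataset(simCfg)
    countDir <- file.path(outDir, "counts")
    outputs <- c(outputs, writeCounts(sce, countDir))
    sets <- truthGeneSets(simCfg)
    gmtPath <- file.path(outDir, "truth_sets.gmt")
    writeGMT(sets, gmtPath)
    outputs <- c(outputs, gmtPath)
    sce <- logNormalizeCounts(sce)
  }

  if (on("score")) {
    message("stage score")
    sets <- truthGeneSets(simCfg)
    lineage <- sets[setdiff(names(sets), c("S_PHASE", "G2M_PHASE"))]
    scores <- scoreSignatures(sce, lineage, nBins = cfg$score$n_bins,
                              nCtrl = cfg$score$n_ctrl, seed = seeds$score)
    emit(scores, "scores.tsv")
    phases <- cellCyclePhases(sce, sets$S_PHASE, sets$G2M_PHASE,
                              nBins = cfg$score$n_bins,
                              nCtrl = cfg$score$n_ctrl, seed = seeds$score)
    emit(phases, "phases.tsv")
  }

  cells <- if (!is.null(sce)) {
    ct <- as.data.frame(SummarizedExperiment::colData(sce))
    if (!is.null(phases))
      ct$phase_assigned <- phases$phase[match(ct$cell_id, phases$cell_id)]
    ct
  } else NULL

  if (on("composition")) {
    message("stage composition")
    comp <- clusterFractions(cells)
    emit(comp, "composition.tsv")
    ratios <- groupRatio(comp, "MEMB_early", "MEMB_late")
    emit(ratios, "ratio_memb_early_late.tsv")
    cellsT <- cells; cellsT$phase <- cellsT$phase_assigned
    cyc <- cyclingFractions(cellsT)
    emit(cyc, "cycling.tsv")
    ## BM (reference) vs each other tissue, pooled over donors, per cluster
    tests <- list()
    for (cl in unique(cyc$cluster)) {
      ref <- cyc[cyc$cluster == cl & cyc$tissue == "BM", ]
      for (tis in setdiff(unique(cyc$tissue), "BM")) {
        cmp <- cyc[cyc$cluster == cl & cyc$tissue == tis, ]
        if (!sum(ref$n_total) || !sum(cmp$n_total)) next
        pv <- compareCyclingBinomial(sum(ref$n_sg2m), sum(ref$n_total),
                                     sum(cmp$n_sg2m), sum(cmp$n_total))
        tests[[length(tests) + 1L]] <- data.frame(
          cluster = cl, tissue = tis,
          f_ref = sum(ref$n_sg2m) / sum(ref$n_total),
          f_cmp = sum(cmp$n_sg2m) / sum(cmp$n_total), p_value = pv,
          stringsAsFactors = FALSE)
      }
    }
    emit(do.call(rbind, tests), "cycling_tests.tsv")
  }

  if (on("expansion")) {
    message("stage expansion")
    cellsT <- cells; cellsT$phase <- cellsT$phase_assigned
    rows <- list()
    for (br in c("MEMB", "My")) {
      spec <- .branchSpecFromStages(simCfg, br)
      bm <- buildBranchModel(cellsT, spec, branchName = br)
      res <- estimateExpansion(bm)
      tr <- transitions(res); tr$branch <- br
      rows[[br]] <- tr
    }
    emit(do.call(rbind, rows), "expansion.tsv")
  }

  if (on("identity")) {
    message("stage identity")
    pa <- cfg$identity$pole_a; pb <- cfg$identity$pole_b
    idxA <- cells$cell_id[cells$tissue == pa$tissue & cells$cluster == pa$cluster]
    idxB <- cells$cell_id[cells$tissue == pb$tissue & cells$cluster == pb$cluster]
    de <- wilcoxonDE(sce, idxA, idxB)
    emit(de, "identity_de.tsv")
    sig <- deriveIdentitySignature(de, nTop = cfg$identity$n_top,
                                   fdrCut = cfg$identity$fdr_cut,
                                   lfcCut = cfg$identity$lfc_cut)
    gmtPath <- file.path(outDir, "identity_signature.gmt")
    writeGMT(list(MED = medGenes(sig), EXTRAMED = extramedGenes(sig)), gmtPath)
    outputs <- c(outputs, gmtPath)
    hsc <- cells$cluster == pa$cluster
    res <- computeIdentityRatio(
      sce[, hsc], sig, sample = paste(cells$tissue, cells$donor,
                                      sep = "_")[hsc],
      seed = seeds$identity)
    emit(classifyIdentity(res), "identity.tsv")
  }

  if (on("gsea")) {
    message("stage gsea")
    de <- read.delim(file.path(outDir, "identity_de.tsv"))
    sets <- truthGeneSets(simCfg)
    gsea <- prerankedGSEA(rankMetric(de), sets, nPerm = cfg$gsea$n_perm,
                          seed = seeds$gsea)
    emit(gsea, "gsea.tsv")
  }

  if (on("lda")) {
    message("stage lda")
    tab <- simulateLDA(cfg$lda$true_frequency, cfg$lda$doses,
                       cfg$lda$n_per_dose, seed = seeds$lda)
    emit(tab, "lda_table.tsv")
    res <- ldaFrequency(tab, confLevel = cfg$lda$conf_level)
    ldaPath <- file.path(outDir, "lda_result.json")
    jsonlite::write_json(
      list(frequency = ldaEstimate(res), ci = as.list(ldaConfint(res)),
           one_in = oneIn(res), flags = ldaFlags(res)),
      ldaPath, auto_unbox = TRUE, digits = NA)
    outputs <- c(outputs, ldaPath)
  }

  manifest <- list(
    package_version = as.character(packageVersion("emhscope")),
    seed = cfg$seed, stage_seeds = seeds,
    parameters = cfg[c("simulate", "score", "identity", "gsea", "lda")],
    stages_run = names(Filter(isTRUE, cfg$stages)),
    outputs = as.list(setNames(unname(tools::md5sum(outputs)),
                               basename(outputs))))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

## ordered stage -> cluster mapping for one branch, read off the truth
## stage labels of the config ("branch:order")
.branchSpecFromStages <- function(config, branch) {
  st <- vapply(config@clusters, `[[`, character(1), "stage")
  nm <- vapply(config@clusters, `[[`, character(1), "name")
  keep <- !is.na(st) & startsWith(st, paste0(branch, ":"))
  ord <- order(as.integer(sub(".*:", "", st[keep])))
  spec <- as.list(nm[keep][ord])
  names(spec) <- paste0(branch, "_stage", seq_along(spec))
  spec
}
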