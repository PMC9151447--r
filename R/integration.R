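#' Correlate regulator expression with immune population scores
#'
#' For every (regulator, immune population, ancestry group) tuple, the
#' Pearson correlation between the regulator's log-transformed normalized
#' expression and the population's score across the group's samples, with
#' the two-sided correlation-test p and BH q across all tuples.
#'
#' @param expression genes x samples normalized (log-scale) expression
#'   matrix.
#' @param immuneScores populations x samples matrix from [mcpScores()].
#' @param regulators regulator gene names; absent ones are dropped with a
#'   message.
#' @param metadata per-sample metadata with \code{sample_id},
#'   \code{ancestry}.
#' @param populations immune populations to use (default: all rows).
#' @return data.frame: regulator, population, group, n, r, p, q.
#' @export
correlateRegulatorsWithImmune <- function(expression, immuneScores,
                                          regulators, metadata,
                                          populations =
                                            rownames(immuneScores)) {
  present <- intersect(regulators, rownames(expression))
  if (length(present) < length(regulators))
    message("dropping ", length(regulators) - length(present),
            " regulator(s) absent from the expression matrix")
  shared <- intersect(colnames(expression), colnames(immuneScores))
  md <- metadata[match(shared, metadata$sample_id), , drop = FALSE]
  groups <- sort(unique(md$ancestry))
  rows <- list()
  for (reg in present) for (popName in populations) for (grp in groups) {
    ids <- shared[md$ancestry == grp]
    if (length(ids) < 3L) next
    e <- expression[reg, ids]
    s <- immuneScores[popName, ids]
    if (stats::sd(e) == 0) {
      warning("zero-variance regulator ", reg, " in group ", grp,
              ": skipped", call. = FALSE)
      next
    }
    ct <- stats::cor.test(e, s)
    rows[[length(rows) + 1L]] <-
      data.frame(regulator = reg, population = popName, group = grp,
                 n = length(ids), r = unname(ct$estimate), p = ct$p.value,
                 stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(regulator = character(), population = character(),
                      group = character(), n = integer(), r = numeric(),
                      p = numeric(), q = numeric()))
  out$q <- bhAdjust(out$p)
  out
}

#' Run the full pipeline on a simulated cohort
#'
#' Executes the stages in dependency order — simulate, ancestry, cohort
#' statistics, differential expression, immune deconvolution, regulatory
#' network (motif enrichment, composite module, master regulators with
#' feedback flags), methylation (tumor-specific DMPs, feature mapping,
#' methylation-sensitive genes) and regulator-immune integration — and
#' writes every stage's tables under \code{outDir}. Somatic-mutation
#' consolidation runs only when MAF inputs are supplied via
#' \code{mafsByCaller}. Deterministic under \code{config$seed}.
#'
#' @param config a [simConfig()] or a path to a YAML file of its arguments.
#' @param outDir output directory; NULL skips writing.
#' @param stages subset of stages to run (dependencies are run as needed).
#' @param mafsByCaller optional named list of MAF data.frames for the
#'   somatic stage.
#' @param gaParams named list of overrides for [cmaSearch()] (e.g.
#'   \code{list(generations = 30)}).
#' @return named list of stage results, invisibly when \code{outDir} is
#'   set.
#' @export
runPipeline <- function(config, outDir = NULL,
                        stages = c("ancestry", "cohort", "de", "immune",
                                   "regulatory", "methylation",
                                   "integration"),
                        mafsByCaller = NULL, gaParams = list()) {
  if (is.character(config))
    config <- do.call(simConfig, yaml::read_yaml(config))
  sim <- simulateAll(config)
  out <- list(sim = sim)
  writeIf <- function(x, file) {
    if (!is.null(outDir)) {
      dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
      .writeTsv(x, file.path(outDir, file))
    }
  }
  if (!is.null(outDir)) writeSimulation(sim, file.path(outDir, "sim"))

  if ("ancestry" %in% stages) {
    labels <- sim$genotypes$labels
    # first half of each population serves as the labeled reference panel
    ref <- unlist(lapply(split(names(labels), labels), function(ids)
      ids[seq_len(length(ids) %/% 2)]))
    anc <- inferAncestry(sim$genotypes$dosages, labels[ref])
    anc$calls$truth <- labels[anc$calls$sample_id]
    out$ancestry <- anc$calls
    out$ancestryRecovery <- mean(anc$calls$predicted == anc$calls$truth)
    writeIf(anc$calls, "ancestry_calls.tsv")
  }
  if ("cohort" %in% stages) {
    out$cohort <- cohortAssociationTests(
      sim$metadata[sim$metadata$tissue == "tumor", ])
    writeIf(out$cohort, "cohort_stats.tsv")
  }
  if (!is.null(mafsByCaller)) {
    merged <- mergeCallerMafs(mafsByCaller)
    out$somatic <- list(merged = merged, tmb = computeTmb(merged))
    writeIf(merged, "merged_maf.tsv")
    writeIf(out$somatic$tmb, "tmb.tsv")
  }
  needDe <- any(c("de", "regulatory", "methylation", "integration") %in%
                  stages)
  if (needDe) {
    counts <- filterZeroExpression(sim$expression$counts)
    out$de <- differentialExpression(counts, sim$metadata)
    writeIf(out$de, "de_results.tsv")
  }
  needImmune <- any(c("immune", "integration") %in% stages)
  if (needImmune) {
    norm <- vstLikeTransform(sim$expression$counts)
    scores <- mcpScores(norm, sim$expression$markerSets)
    grouping <- stats::setNames(
      sim$metadata$ancestry[match(colnames(scores),
                                  sim$metadata$sample_id)],
      colnames(scores))
    out$immune <- list(scores = scores,
                       comparison = rankSumCompare(scores, grouping))
    writeIf(out$immune$comparison, "immune_comparison.tsv")
    if (!is.null(outDir))
      .writeMatrixTsv(scores, file.path(outDir, "immune_scores.tsv"),
                      "population")
  }
  if ("regulatory" %in% stages) {
    enr <- tfbsEnrichment(sim$promoters$yes, sim$promoters$no,
                          sim$pwmLibrary)
    module <- do.call(cmaSearch, c(
      list(yesRegions = sim$promoters$yes, noRegions = sim$promoters$no,
           pwms = sim$pwmLibrary, seed = config$seed), gaParams))
    mtr <- findMasterRegulators(sim$network$network, sim$network$tfs)
    mtr$feedback <- vapply(mtr$node, function(v)
      flagFeedbackLoops(sim$network$network, v, sim$network$tfs,
                        sim$network$degGenes, sim$network$geneProduct,
                        sim$network$tfTargets)$feedback, logical(1))
    out$regulatory <- list(enrichment = enr, module = module, mtr = mtr)
    writeIf(enr, "tfbs_enrichment.tsv")
    writeIf(mtr, "mtr_ranking.tsv")
    writeIf(data.frame(member = moduleMembers(module),
                       fitness = moduleFitness(module)),
            "composite_module.tsv")
  }
  if ("methylation" %in% stages) {
    betas <- cbind(sim$methylation$betaTumor, sim$methylation$betaNormal)
    filt <- filterProbes(betas, sim$methylation$annotation)
    ts <- tumorSpecificDmps(filt$betas, sim$metadata)
    mapping <- mapCpgToFeatures(
      sim$methylation$annotation[sim$methylation$annotation$cpg %in%
                                   rownames(filt$betas), ],
      sim$methylation$geneModels)
    assoc <- mapping[!is.na(mapping$gene), c("cpg", "gene")]
    allDmps <- testDmps(sim$methylation$betaTumor[
      rownames(filt$betas)[rownames(filt$betas) %in%
                             rownames(sim$methylation$betaTumor)], ,
      drop = FALSE], sim$metadata)
    norm <- vstLikeTransform(sim$expression$counts)
    ms <- methylationSensitiveGenes(out$de, allDmps, assoc,
                                    sim$methylation$betaTumor, norm,
                                    sim$metadata)
    out$methylation <- list(tumorSpecific = ts, mapping = mapping,
                            dmps = allDmps, msGenes = ms)
    writeIf(ts$dmps, "tumor_specific_dmps.tsv")
    writeIf(mapping, "cpg_feature_mapping.tsv")
    writeIf(ms, "methylation_sensitive_genes.tsv")
  }
  if ("integration" %in% stages) {
    norm <- vstLikeTransform(sim$expression$counts)
    regulators <- utils::head(out$de$gene[order(out$de$q)], 5L)
    out$integration <- correlateRegulatorsWithImmune(
      norm, out$immune$scores, regulators, sim$metadata,
      populations = c("cytotoxic_lymphocytes", "neutrophils"))
    writeIf(out$integration, "regulator_immune_correlation.tsv")
  }
  if (is.null(outDir)) out else invisible(out)
}
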