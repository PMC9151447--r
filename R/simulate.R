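#' Simulation configuration
#'
#' Builds and validates the configuration shared by all synthetic-data
#' generators. Defaults emulate the structure of a two-ancestry
#' microsatellite-stable colorectal tumor cohort: cohort sizes mirror the
#' 55/456 AFR/EUR multi-omics cohort, covariate imbalance (age, tumor site,
#' stage) follows the printed demographic table, the between-population
#' divergence is a typical continental Fst of 0.1, and the immune effects
#' lower cytotoxic lymphocyte and neutrophil fractions in the AFR group.
#'
#' @param seed integer seed; every generator derives its randomness from it.
#' @param nAfr,nEur tumor sample counts per ancestry.
#' @param nSnps number of simulated variants.
#' @param fst Balding-Nichols divergence in [0, 1).
#' @param nGenes number of genes.
#' @param plantedDe data.frame(gene, log2fc): ancestry effects planted into
#'   expression. Default: 50 genes at +1.5, 50 at -1.5.
#' @param nbDispersion negative-binomial dispersion (0 gives Poisson counts).
#' @param immuneEffects named list: population label -> named numeric vector
#'   of latent immune-fraction shifts per cell type.
#' @param markerGain log2-expression units added per unit of latent immune
#'   fraction to that population's marker genes.
#' @param covariateEffectSd SD of the log2 age/location effects given to a
#'   random 10% of genes (0 disables covariate effects).
#' @param nMarkersPerPop marker genes assigned per immune population.
#' @param nCpgs number of CpG probes.
#' @param plantedDmps data.frame(cpg, deltaBeta, direction): ancestry
#'   methylation effects (direction "hyper"/"hypo" for AFR relative to EUR)
#'   planted into tumor samples; the same CpGs also receive a tumor-vs-normal
#'   effect so that they are tumor specific.
#' @param plantedMsGenes data.frame(gene, cpg, targetR): methylation-sensitive
#'   couplings; the CpG's beta is generated with the stated-sign correlation
#'   to the gene's simulated expression.
#' @param betaSigma logit-scale noise SD for methylation.
#' @param promoterLength promoter length in bp (>= 1100 so the
#'   -1000/+100 window fits).
#' @param plantedModule character vector of PWM names forming the planted
#'   composite module (may be empty).
#' @param moduleWindow width in bp of the shared window the planted sites are
#'   clustered into.
#' @param nYesPromoters,nNoPromoters promoter set sizes.
#' @param networkSize number of network nodes (including TFs and MTRs).
#' @param nTfs number of designated transcription-factor nodes.
#' @param plantedMtrs names of planted master-regulator nodes.
#' @param plantedFeedbackMtrs subset of \code{plantedMtrs} wired with a
#'   positive-feedback chain (TF regulates the gene encoding the MTR, and
#'   that gene is differentially expressed).
#' @param normalFraction fraction of tumor samples with a paired normal.
#'
#' @return a validated list of class \code{SimConfig}.
#' @export
simConfig <- function(seed = 1L,
                      nAfr = 55L, nEur = 456L,
                      nSnps = 500L, fst = 0.1,
                      nGenes = 2000L,
                      plantedDe = NULL,
                      nbDispersion = 0.1,
                      immuneEffects = list(
                        AFR = c(cytotoxic_lymphocytes = -0.3,
                                neutrophils = -0.3)),
                      markerGain = 4,
                      covariateEffectSd = 0.5,
                      nMarkersPerPop = 5L,
                      nCpgs = 2000L,
                      plantedDmps = NULL,
                      plantedMsGenes = NULL,
                      betaSigma = 0.5,
                      promoterLength = 1100L,
                      plantedModule = character(),
                      moduleWindow = 150L,
                      nYesPromoters = 60L, nNoPromoters = 60L,
                      networkSize = 200L, nTfs = 10L,
                      plantedMtrs = c("MTR1", "MTR2"),
                      plantedFeedbackMtrs = "MTR1",
                      normalFraction = 0.3) {
  geneIds <- sprintf("G%05d", seq_len(nGenes))
  cpgIds <- sprintf("cg%06d", seq_len(nCpgs))
  if (is.null(plantedDe)) {
    nDe <- min(100L, nGenes %/% 4L)
    plantedDe <- data.frame(
      gene = geneIds[seq_len(nDe)],
      log2fc = rep(c(1.5, -1.5), length.out = nDe),
      stringsAsFactors = FALSE)
  }
  if (is.null(plantedDmps)) {
    nDmp <- min(100L, nCpgs %/% 4L)
    plantedDmps <- data.frame(
      cpg = cpgIds[seq_len(nDmp)],
      deltaBeta = rep(0.25, nDmp),
      direction = rep(c("hyper", "hypo"), length.out = nDmp),
      stringsAsFactors = FALSE)
  }
  if (is.null(plantedMsGenes)) {
    n <- min(10L, nrow(plantedDe))
    # couple to planted DE genes, using CpGs outside the planted-DMP block
    freeCpgs <- setdiff(cpgIds, plantedDmps$cpg)
    plantedMsGenes <- data.frame(
      gene = plantedDe$gene[seq_len(n)],
      cpg = freeCpgs[seq_len(n)],
      targetR = rep(-0.7, n),
      stringsAsFactors = FALSE)
  }
  cfg <- list(seed = as.integer(seed), nAfr = as.integer(nAfr),
              nEur = as.integer(nEur), nSnps = as.integer(nSnps), fst = fst,
              nGenes = as.integer(nGenes), geneIds = geneIds,
              plantedDe = plantedDe, nbDispersion = nbDispersion,
              immuneEffects = immuneEffects, markerGain = markerGain,
              covariateEffectSd = covariateEffectSd,
              nMarkersPerPop = as.integer(nMarkersPerPop),
              nCpgs = as.integer(nCpgs), cpgIds = cpgIds,
              plantedDmps = plantedDmps, plantedMsGenes = plantedMsGenes,
              betaSigma = betaSigma,
              promoterLength = as.integer(promoterLength),
              plantedModule = plantedModule,
              moduleWindow = as.integer(moduleWindow),
              nYesPromoters = as.integer(nYesPromoters),
              nNoPromoters = as.integer(nNoPromoters),
              networkSize = as.integer(networkSize), nTfs = as.integer(nTfs),
              plantedMtrs = plantedMtrs,
              plantedFeedbackMtrs = plantedFeedbackMtrs,
              normalFraction = normalFraction)
  class(cfg) <- "SimConfig"
  validateSimConfig(cfg)
  cfg
}

#' Validate a simulation configuration
#'
#' @param cfg a \code{SimConfig}.
#' @return the config, invisibly; errors on violated invariants.
#' @export
validateSimConfig <- function(cfg) {
  if (cfg$fst < 0 || cfg$fst >= 1)
    stop("fst must lie in [0, 1)", call. = FALSE)
  counts <- c(cfg$nAfr, cfg$nEur, cfg$nSnps, cfg$nGenes, cfg$nCpgs,
              cfg$promoterLength, cfg$networkSize, cfg$nTfs,
              cfg$nYesPromoters, cfg$nNoPromoters)
  if (any(counts <= 0)) stop("all counts must be > 0", call. = FALSE)
  if (!all(cfg$plantedDe$gene %in% cfg$geneIds))
    stop("plantedDe references unknown genes", call. = FALSE)
  if (!all(cfg$plantedDmps$cpg %in% cfg$cpgIds))
    stop("plantedDmps references unknown CpGs", call. = FALSE)
  if (!all(cfg$plantedMsGenes$gene %in% cfg$geneIds) ||
      !all(cfg$plantedMsGenes$cpg %in% cfg$cpgIds))
    stop("plantedMsGenes references unknown genes or CpGs", call. = FALSE)
  # planted baselines leave at most ~0.35 beta of headroom after the
  # tumor shift, so larger deltas cannot be realized inside [0, 1]
  if (nrow(cfg$plantedDmps) &&
      any(cfg$plantedDmps$deltaBeta <= 0 | cfg$plantedDmps$deltaBeta > 0.35))
    stop("planted delta-beta would push betas outside [0, 1]", call. = FALSE)
  if (!all(cfg$plantedDmps$direction %in% c("hyper", "hypo")))
    stop("DMP direction must be 'hyper' or 'hypo'", call. = FALSE)
  if (!all(cfg$plantedFeedbackMtrs %in% cfg$plantedMtrs))
    stop("plantedFeedbackMtrs must be a subset of plantedMtrs", call. = FALSE)
  invisible(cfg)
}

#' Names of the simulated immune cell populations
#' @return character vector of 10 population labels.
#' @export
immunePopulations <- function() {
  c("t_cells", "cd8_t_cells", "cytotoxic_lymphocytes", "b_lineage",
    "nk_cells", "monocytic_lineage", "myeloid_dendritic_cells",
    "neutrophils", "endothelial_cells", "fibroblasts")
}

#' Simulate cohort metadata
#'
#' Draws per-patient clinical labels with the ancestry imbalances seen in
#' observational colorectal cohorts: AFR patients are more often diagnosed
#' young (<50 y) and with right-sided tumors, so the covariate-adjustment
#' code downstream is genuinely exercised. A subset of patients also receives
#' a paired normal-tissue sample.
#'
#' @param cfg a [simConfig()].
#' @return data.frame with columns sample_id, patient_id, ancestry,
#'   age_group, tumor_location, stage, msi_status, tissue.
#' @export
simulateMetadata <- function(cfg) {
  withr::with_seed(cfg$seed + 2L, {
    n <- cfg$nAfr + cfg$nEur
    ancestry <- c(rep("AFR", cfg$nAfr), rep("EUR", cfg$nEur))
    patient <- sprintf("P%04d", seq_len(n))
    pYoung <- ifelse(ancestry == "AFR", 0.20, 0.11)
    age <- ifelse(stats::runif(n) < pYoung, "young", "old")
    pRight <- ifelse(ancestry == "AFR", 0.52, 0.33)
    loc <- ifelse(stats::runif(n) < pRight, "right", "left")
    stageP <- list(AFR = c(9, 20, 22, 13) / 64,
                   EUR = c(96, 195, 154, 77) / 522)
    stage <- vapply(ancestry, function(a)
      sample(c("I", "II", "III", "IV"), 1L, prob = stageP[[a]]),
      character(1))
    msi <- sample(c("MSS", "MSI-L", "MSI-H"), n, replace = TRUE,
                  prob = c(0.70, 0.16, 0.14))
    tumor <- data.frame(sample_id = paste0(patient, "_T"),
                        patient_id = patient, ancestry = ancestry,
                        age_group = age, tumor_location = loc, stage = stage,
                        msi_status = msi, tissue = "tumor",
                        stringsAsFactors = FALSE)
    hasNormal <- stats::runif(n) < cfg$normalFraction
    normal <- tumor[hasNormal, , drop = FALSE]
    normal$sample_id <- paste0(normal$patient_id, "_N")
    normal$tissue <- "normal"
    md <- rbind(tumor, normal)
    rownames(md) <- NULL
    md
  })
}

#' Simulate diverged-population genotypes (Balding-Nichols)
#'
#' Per variant an ancestral allele frequency is drawn from Uniform(0.05,
#' 0.95); each population's frequency is then drawn from
#' Beta(p(1-F)/F, (1-p)(1-F)/F) with divergence F, and dosages are
#' Binomial(2, p). F = 0 collapses to identical frequencies.
#'
#' @param cfg a [simConfig()].
#' @param pops named integer vector of per-population sample counts; default
#'   \code{c(AFR = cfg$nAfr, EUR = cfg$nEur)}.
#' @return list with \code{dosages} (samples x variants, values 0/1/2) and
#'   \code{labels} (true population per sample).
#' @export
simulateGenotypes <- function(cfg, pops = NULL) {
  if (is.null(pops)) pops <- c(AFR = cfg$nAfr, EUR = cfg$nEur)
  if (cfg$fst < 0 || cfg$fst >= 1)
    stop("fst must lie in [0, 1)", call. = FALSE)
  withr::with_seed(cfg$seed + 1L, {
    m <- cfg$nSnps
    pAnc <- stats::runif(m, 0.05, 0.95)
    labels <- rep(names(pops), pops)
    n <- length(labels)
    dos <- matrix(0L, n, m,
                  dimnames = list(sprintf("S%04d", seq_len(n)),
                                  sprintf("rs%05d", seq_len(m))))
    for (k in names(pops)) {
      if (cfg$fst == 0) pk <- pAnc
      else {
        a <- pAnc * (1 - cfg$fst) / cfg$fst
        b <- (1 - pAnc) * (1 - cfg$fst) / cfg$fst
        pk <- stats::rbeta(m, a, b)
      }
      idx <- which(labels == k)
      dos[idx, ] <- matrix(
        stats::rbinom(length(idx) * m, 2L, rep(pk, each = length(idx))),
        length(idx), m)
    }
    list(dosages = dos, labels = stats::setNames(labels, rownames(dos)),
         popFrequencies = pAnc)
  })
}

#' Simulate RNA-seq counts with planted ancestry and immune effects
#'
#' Counts are negative binomial with mean
#' \eqn{baseline \cdot 2^{X\beta}}: planted genes carry the configured
#' ancestry log2 effect, a random 10% of genes carry mild age/location
#' effects, and each immune population's marker genes gain
#' \code{markerGain} log2 units per unit of that sample's latent fraction.
#' Latent fractions are independent Beta(2, 2) draws, shifted per
#' \code{immuneEffects} for the affected ancestry and clipped to
#' [0.01, 0.99].
#'
#' @param cfg a [simConfig()].
#' @param metadata output of [simulateMetadata()]; only tumor samples
#'   receive counts.
#' @return list with \code{counts} (genes x samples), \code{fractions}
#'   (populations x samples), \code{markerSets} (named list) and
#'   \code{plantedDe}.
#' @export
simulateExpression <- function(cfg, metadata) {
  md <- metadata[metadata$tissue == "tumor", , drop = FALSE]
  withr::with_seed(cfg$seed + 3L, {
    nS <- nrow(md); nG <- cfg$nGenes
    pops <- immunePopulations()
    # marker genes always come from the tail of the gene list, so marker
    # identity does not move when planted-DE lists change
    markerSets <- stats::setNames(
      split(utils::head(rev(cfg$geneIds),
                        cfg$nMarkersPerPop * length(pops)),
            rep(seq_along(pops), each = cfg$nMarkersPerPop)), pops)
    # conflicting-sign check: a marker of a shifted population must not be
    # planted with an opposite ancestry effect
    for (anc in names(cfg$immuneEffects)) {
      eff <- cfg$immuneEffects[[anc]]
      for (popName in names(eff)) {
        overlap <- intersect(markerSets[[popName]], cfg$plantedDe$gene)
        if (length(overlap)) {
          sgn <- sign(cfg$plantedDe$log2fc[match(overlap,
                                                 cfg$plantedDe$gene)])
          if (any(sgn * sign(eff[popName]) < 0))
            stop("marker gene planted as DE with conflicting sign: ",
                 paste(overlap, collapse = ", "), call. = FALSE)
        }
      }
    }
    fractions <- matrix(stats::rbeta(length(pops) * nS, 2, 2),
                        length(pops), nS,
                        dimnames = list(pops, md$sample_id))
    for (anc in names(cfg$immuneEffects)) {
      eff <- cfg$immuneEffects[[anc]]
      idx <- which(md$ancestry == anc)
      for (popName in names(eff))
        fractions[popName, idx] <- pmin(pmax(
          fractions[popName, idx] + eff[[popName]], 0.01), 0.99)
    }
    baseLog2 <- stats::rnorm(nG, mean = 7, sd = 1.5)
    beta <- stats::setNames(rep(0, nG), cfg$geneIds)
    beta[cfg$plantedDe$gene] <- cfg$plantedDe$log2fc
    covGenes <- sample(cfg$geneIds, max(1L, nG %/% 10L))
    alphaAge <- alphaLoc <- stats::setNames(rep(0, nG), cfg$geneIds)
    alphaAge[covGenes] <- stats::rnorm(length(covGenes), 0,
                                       cfg$covariateEffectSd)
    alphaLoc[covGenes] <- stats::rnorm(length(covGenes), 0,
                                       cfg$covariateEffectSd)
    isAfr <- as.numeric(md$ancestry == "AFR")
    isYoung <- as.numeric(md$age_group == "young")
    isRight <- as.numeric(md$tumor_location == "right")
    log2mu <- outer(baseLog2, rep(1, nS)) +
      outer(beta, isAfr) + outer(alphaAge, isYoung) +
      outer(alphaLoc, isRight)
    for (popName in pops) {
      g <- markerSets[[popName]]
      log2mu[g, ] <- log2mu[g, , drop = FALSE] +
        matrix(cfg$markerGain * fractions[popName, ],
               length(g), nS, byrow = TRUE)
    }
    mu <- 2^log2mu
    counts <- if (cfg$nbDispersion <= 0)
      matrix(stats::rpois(nG * nS, mu), nG, nS)
    else
      matrix(stats::rnbinom(nG * nS, mu = mu, size = 1 / cfg$nbDispersion),
             nG, nS)
    if (max(counts) < .Machine$integer.max)
      storage.mode(counts) <- "integer"
    dimnames(counts) <- list(cfg$geneIds, md$sample_id)
    list(counts = counts, fractions = fractions, markerSets = markerSets,
         plantedDe = cfg$plantedDe)
  })
}

#' Simulate 450K-style beta values with planted tumor-specific DMPs
#'
#' Betas are inverse-logit of Normal(logit(base) + effects, sigma), so every
#' emitted value lies in (0, 1) by construction. Planted DMPs receive a
#' tumor-vs-normal shift in both ancestries (making them tumor specific)
#' plus the configured AFR-vs-EUR shift in tumors. Planted
#' methylation-sensitive CpGs are generated with the stated-sign coupling to
#' the standardized log2 expression of their gene.
#'
#' @param cfg a [simConfig()].
#' @param metadata output of [simulateMetadata()].
#' @param expression optional counts matrix (genes x tumor samples) used for
#'   the methylation-expression couplings; required when
#'   \code{cfg$plantedMsGenes} is non-empty.
#' @return list with \code{betaTumor}, \code{betaNormal} (CpGs x samples),
#'   \code{annotation} (CpG positions and probe flags),
#'   \code{geneModels} (synthetic gene coordinates), \code{plantedDmps} and
#'   \code{plantedMsGenes}.
#' @export
simulateMethylation <- function(cfg, metadata, expression = NULL) {
  msg <- cfg$plantedMsGenes
  if (nrow(msg) > 0 && is.null(expression))
    stop("expression matrix required for methylation-sensitive couplings",
         call. = FALSE)
  mdT <- metadata[metadata$tissue == "tumor", , drop = FALSE]
  mdN <- metadata[metadata$tissue == "normal", , drop = FALSE]
  withr::with_seed(cfg$seed + 4L, {
    nC <- cfg$nCpgs
    base <- stats::runif(nC, 0.1, 0.9)
    names(base) <- cfg$cpgIds
    # planted DMPs get direction-dependent baselines so that both the
    # tumor shift and the ancestry delta stay inside (0, 1)
    dHyper <- ifelse(cfg$plantedDmps$direction == "hyper", 1, -1)
    base[cfg$plantedDmps$cpg] <- ifelse(
      dHyper > 0, stats::runif(nrow(cfg$plantedDmps), 0.25, 0.45),
      stats::runif(nrow(cfg$plantedDmps), 0.55, 0.75))
    clamp <- function(x) pmin(pmax(x, 0.02), 0.98)
    tumorLogit <- stats::setNames(rep(0, nC), cfg$cpgIds)
    ancLogit <- stats::setNames(rep(0, nC), cfg$cpgIds)
    # a fixed logit shift makes the CpG tumor specific in both ancestries;
    # the ancestry delta is then laid on top of the tumor baseline so the
    # realized AFR-vs-EUR tumor difference matches deltaBeta
    tumorLogit[cfg$plantedDmps$cpg] <- 0.8 * dHyper
    baseTumor <- stats::plogis(stats::qlogis(base[cfg$plantedDmps$cpg]) +
                                 0.8 * dHyper)
    ancLogit[cfg$plantedDmps$cpg] <-
      stats::qlogis(clamp(baseTumor + dHyper * cfg$plantedDmps$deltaBeta)) -
      stats::qlogis(baseTumor)
    simBeta <- function(md, isTumor) {
      nS <- nrow(md)
      eta <- outer(stats::qlogis(base), rep(1, nS))
      if (isTumor) {
        eta <- eta + outer(tumorLogit, rep(1, nS)) +
          outer(ancLogit, as.numeric(md$ancestry == "AFR"))
      }
      eta <- eta + matrix(stats::rnorm(nC * nS, 0, cfg$betaSigma), nC, nS)
      b <- stats::plogis(eta)
      dimnames(b) <- list(cfg$cpgIds, md$sample_id)
      b
    }
    betaTumor <- simBeta(mdT, TRUE)
    betaNormal <- simBeta(mdN, FALSE)
    # overwrite planted methylation-sensitive CpGs in tumors with the
    # expression-coupled draw
    if (nrow(msg) > 0) {
      expr <- log2(expression[, mdT$sample_id, drop = FALSE] + 1)
      for (i in seq_len(nrow(msg))) {
        z <- as.numeric(scale(expr[msg$gene[i], ]))
        r <- msg$targetR[i]
        eps <- stats::rnorm(ncol(expr))
        eta <- stats::qlogis(base[msg$cpg[i]]) +
          0.8 * (r * z + sqrt(1 - r^2) * eps)
        betaTumor[msg$cpg[i], ] <- stats::plogis(eta)
      }
    }
    # synthetic coordinates: gene g sits at TSS = 10000 * g on chr1 (plus
    # strand); planted MS CpGs are placed in their gene's promoter, the rest
    # at random offsets
    geneIdx <- seq_len(cfg$nGenes)
    geneModels <- data.frame(
      gene = cfg$geneIds, chrom = "chr1", strand = "+",
      tss = 10000L * geneIdx, tx_start = 10000L * geneIdx,
      tx_end = 10000L * geneIdx + 3000L,
      utr5_start = 10000L * geneIdx, utr5_end = 10000L * geneIdx + 200L,
      utr3_start = 10000L * geneIdx + 2800L,
      utr3_end = 10000L * geneIdx + 3000L,
      stringsAsFactors = FALSE)
    pos <- sample(5000L:(10000L * cfg$nGenes + 5000L), nC)
    names(pos) <- cfg$cpgIds
    pos[msg$cpg] <- geneModels$tss[match(msg$gene, geneModels$gene)] - 500L
    # planted DMPs are placed in promoters of genes, favoring planted DE
    # genes so the integration stage has signal to find; genes carrying a
    # methylation-sensitive coupling keep their promoter free so the
    # lowest-q CpG selected for them is the coupled one
    dePool <- setdiff(cfg$plantedDe$gene, msg$gene)
    dmpGenes <- dePool[seq_len(min(nrow(cfg$plantedDmps),
                                   length(dePool)))]
    if (length(dmpGenes) < nrow(cfg$plantedDmps))
      dmpGenes <- c(dmpGenes,
                    sample(setdiff(cfg$geneIds, msg$gene),
                           nrow(cfg$plantedDmps) - length(dmpGenes),
                           replace = TRUE))
    keep <- !cfg$plantedDmps$cpg %in% msg$cpg
    pos[cfg$plantedDmps$cpg[keep]] <-
      geneModels$tss[match(dmpGenes[keep], geneModels$gene)] - 600L
    annotation <- data.frame(
      cpg = cfg$cpgIds, chrom = "chr1", pos = as.integer(pos),
      cross_reactive = FALSE, snp_related = FALSE, multi_hit = FALSE,
      non_cpg = FALSE, sex_chromosome = FALSE,
      design_type = sample(c("I", "II"), nC, replace = TRUE,
                           prob = c(0.3, 0.7)),
      stringsAsFactors = FALSE)
    list(betaTumor = betaTumor, betaNormal = betaNormal,
         annotation = annotation, geneModels = geneModels,
         plantedDmps = cfg$plantedDmps, plantedMsGenes = msg)
  })
}

#' Simulate promoter sets with a planted composite module
#'
#' Background sequences are i.i.d. uniform nucleotides. Every "yes" promoter
#' receives one site sampled from each planted-module PWM, all placed
#' without overlap inside a shared window of \code{cfg$moduleWindow} bp at a
#' random location; "no" promoters carry no planted sites.
#'
#' @param cfg a [simConfig()].
#' @param pwmLibrary named list of [PWMotif-class]; must contain
#'   \code{cfg$plantedModule}.
#' @return list with \code{yes}, \code{no} (named character vectors),
#'   \code{tssIndex} (TSS position within each sequence) and \code{truth}
#'   (data.frame promoter, pwm, start, site).
#' @export
simulatePromoters <- function(cfg, pwmLibrary) {
  mod <- cfg$plantedModule
  if (!all(mod %in% names(pwmLibrary)))
    stop("plantedModule PWMs missing from library: ",
         paste(setdiff(mod, names(pwmLibrary)), collapse = ", "),
         call. = FALSE)
  if (cfg$promoterLength < 1100L)
    stop("promoterLength must be >= 1100 to cover -1000/+100", call. = FALSE)
  lens <- vapply(pwmLibrary[mod], pwmLength, integer(1))
  if (length(mod) && cfg$moduleWindow < sum(lens))
    stop("module window smaller than summed motif lengths", call. = FALSE)
  withr::with_seed(cfg$seed + 5L, {
    L <- cfg$promoterLength
    randSeq <- function(n) vapply(seq_len(n), function(i)
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
            collapse = ""), character(1))
    yes <- randSeq(cfg$nYesPromoters)
    no <- randSeq(cfg$nNoPromoters)
    names(yes) <- sprintf("yes_%03d", seq_along(yes))
    names(no) <- sprintf("no_%03d", seq_along(no))
    truth <- NULL
    if (length(mod)) {
      for (i in seq_along(yes)) {
        w0 <- sample.int(L - cfg$moduleWindow + 1L, 1L)
        ord <- sample(seq_along(mod))    # shuffle motif order per promoter
        lensOrd <- lens[ord]
        free <- cfg$moduleWindow - sum(lens)
        # non-overlapping placement: distribute the free bp into gaps
        cuts <- sort(sample.int(free + length(mod), length(mod))) -
          seq_along(mod)
        gaps <- diff(c(0L, cuts))
        starts <- w0 + cumsum(gaps) + c(0L, cumsum(lensOrd))[seq_along(mod)]
        s <- strsplit(yes[i], "")[[1]]
        for (j in seq_along(mod)) {
          p <- pwmLibrary[[mod[ord[j]]]]
          site <- vapply(seq_len(pwmLength(p)), function(k)
            sample(c("A", "C", "G", "T"), 1L, prob = pwmMatrix(p)[, k]),
            character(1))
          st <- starts[j]
          s[st:(st + pwmLength(p) - 1L)] <- site
          truth <- rbind(truth, data.frame(
            promoter = names(yes)[i], pwm = pwmName(p), start = st,
            site = paste(site, collapse = ""), stringsAsFactors = FALSE))
        }
        yes[i] <- paste(s, collapse = "")
      }
    }
    list(yes = yes, no = no, tssIndex = L - 100L, truth = truth)
  })
}

#' Simulate a signaling network with planted master regulators
#'
#' Builds a sparse random directed graph over \code{networkSize} nodes
#' (including \code{nTfs} transcription-factor nodes and the planted MTR
#' nodes), then wires each planted MTR to at least 80% of the TFs within at
#' most 2 steps (60% direct, 30% through one intermediate). Feedback-flagged
#' MTRs additionally get a TF-to-encoding-gene regulation whose gene is in
#' the differential-expression set.
#'
#' @param cfg a [simConfig()].
#' @return list with \code{network} ([SignalNetwork-class]), \code{tfs},
#'   \code{tfTargets} (data.frame tf, gene), \code{geneProduct} (named
#'   vector gene -> node), \code{degGenes}, and \code{truth} (planted MTRs
#'   with feedback flags).
#' @export
simulateNetwork <- function(cfg) {
  nTf <- cfg$nTfs
  mtrs <- cfg$plantedMtrs
  nOther <- cfg$networkSize - nTf - length(mtrs)
  if (nOther < 1)
    stop("networkSize too small for the planted wiring", call. = FALSE)
  withr::with_seed(cfg$seed + 6L, {
    tfs <- sprintf("TF%02d", seq_len(nTf))
    others <- sprintf("N%03d", seq_len(nOther))
    nodes <- c(mtrs, tfs, others)
    edges <- NULL
    # sparse random background among non-TF-targets
    for (v in others) {
      tgt <- sample(setdiff(nodes, v), 2L)
      edges <- rbind(edges, data.frame(source = v, type = "unspecified",
                                       target = tgt,
                                       stringsAsFactors = FALSE))
    }
    for (m in mtrs) {
      direct <- sample(tfs, max(1L, ceiling(0.6 * nTf)))
      onehop <- sample(setdiff(tfs, direct),
                       min(ceiling(0.3 * nTf), nTf - length(direct)))
      edges <- rbind(edges,
                     data.frame(source = m, type = "activation",
                                target = direct, stringsAsFactors = FALSE))
      for (t in onehop) {
        mid <- sample(others, 1L)
        edges <- rbind(edges,
                       data.frame(source = c(m, mid), type = "activation",
                                  target = c(mid, t),
                                  stringsAsFactors = FALSE))
      }
    }
    # keep one edge per node pair, preferring the planted activation wiring
    edges <- edges[order(edges$type != "activation"), , drop = FALSE]
    edges <- edges[!duplicated(edges[, c("source", "target")]), ,
                   drop = FALSE]
    net <- signalNetwork(edges)
    genes <- stats::setNames(paste0("g_", mtrs), mtrs)
    geneProduct <- stats::setNames(mtrs, genes)
    tfTargets <- NULL
    degGenes <- character()
    truth <- data.frame(mtr = mtrs,
                        feedback = mtrs %in% cfg$plantedFeedbackMtrs,
                        stringsAsFactors = FALSE)
    for (m in cfg$plantedFeedbackMtrs) {
      # a TF the MTR reaches regulates the gene encoding the MTR
      reached <- intersect(
        networkEdges(net)$target[networkEdges(net)$source == m], tfs)
      if (!length(reached)) reached <- tfs[1]
      tfTargets <- rbind(tfTargets, data.frame(
        tf = reached[1], gene = genes[[m]], stringsAsFactors = FALSE))
      degGenes <- c(degGenes, genes[[m]])
    }
    list(network = net, tfs = tfs, tfTargets = tfTargets,
         geneProduct = geneProduct, degGenes = degGenes, truth = truth)
  })
}

#' Run every generator and bundle the results
#'
#' @param cfg a [simConfig()].
#' @param pwmLibrary PWM library for [simulatePromoters()]; when NULL and
#'   \code{cfg$plantedModule} is empty a small synthetic library is built.
#' @return list of all generator outputs plus \code{metadata}.
#' @export
simulateAll <- function(cfg, pwmLibrary = NULL) {
  metadata <- simulateMetadata(cfg)
  genotypes <- simulateGenotypes(cfg)
  expression <- simulateExpression(cfg, metadata)
  methylation <- simulateMethylation(cfg, metadata, expression$counts)
  if (is.null(pwmLibrary)) pwmLibrary <- syntheticPwmLibrary(cfg$seed)
  if (!length(cfg$plantedModule)) cfg$plantedModule <- names(pwmLibrary)[1:3]
  promoters <- simulatePromoters(cfg, pwmLibrary)
  network <- simulateNetwork(cfg)
  list(config = cfg, metadata = metadata, genotypes = genotypes,
       expression = expression, methylation = methylation,
       promoters = promoters, network = network, pwmLibrary = pwmLibrary)
}

#' Build a synthetic PWM library
#'
#' Generates sharply peaked random motifs (one dominant base per position),
#' useful as a scanning/search library in tests and simulations.
#'
#' @param seed integer seed.
#' @param n number of motifs.
#' @param length motif length in bp.
#' @param weight count weight of the dominant base (out of
#'   \code{weight + 3}).
#' @return named list of [PWMotif-class] objects (\code{PWM01}, ...).
#' @export
syntheticPwmLibrary <- function(seed = 1L, n = 20L, length = 10L,
                                weight = 20) {
  withr::with_seed(seed + 7L, {
    pwms <- lapply(seq_len(n), function(i) {
      counts <- matrix(1, 4, length, dimnames = list(c("A", "C", "G", "T"),
                                                     NULL))
      dom <- sample.int(4L, length, replace = TRUE)
      counts[cbind(dom, seq_len(length))] <- weight
      pwMotif(sprintf("PWM%02d", i), counts)
    })
    stats::setNames(pwms, vapply(pwms, pwmName, character(1)))
  })
}

#' Write a simulation bundle and its ground truth to disk
#'
#' Writes genotypes.tsv, counts.tsv, betas_tumor.tsv, betas_normal.tsv,
#' metadata.tsv, cpg_annotation.tsv, gene_models.tsv, promoters_yes.fasta,
#' promoters_no.fasta, network.sif and a \code{truth/} directory of
#' machine-readable TSVs (one schema: columns \code{category}, \code{id},
#' \code{key}, \code{value}).
#'
#' @param sim output of [simulateAll()].
#' @param dir output directory (created if absent).
#' @return the directory, invisibly.
#' @export
writeSimulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "truth"), showWarnings = FALSE)
  .writeMatrixTsv(sim$genotypes$dosages, file.path(dir, "genotypes.tsv"),
                  "sample")
  .writeMatrixTsv(sim$expression$counts, file.path(dir, "counts.tsv"),
                  "gene")
  .writeMatrixTsv(sim$methylation$betaTumor,
                  file.path(dir, "betas_tumor.tsv"), "cpg")
  .writeMatrixTsv(sim$methylation$betaNormal,
                  file.path(dir, "betas_normal.tsv"), "cpg")
  .writeTsv(sim$metadata, file.path(dir, "metadata.tsv"))
  .writeTsv(sim$methylation$annotation, file.path(dir, "cpg_annotation.tsv"))
  .writeTsv(sim$methylation$geneModels, file.path(dir, "gene_models.tsv"))
  writeFastaSequences(sim$promoters$yes,
                      file.path(dir, "promoters_yes.fasta"))
  writeFastaSequences(sim$promoters$no, file.path(dir, "promoters_no.fasta"))
  writeNetwork(sim$network$network, file.path(dir, "network.sif"))
  long <- function(category, df, idCol) {
    do.call(rbind, lapply(setdiff(names(df), idCol), function(k)
      data.frame(category = category, id = df[[idCol]], key = k,
                 value = as.character(df[[k]]), stringsAsFactors = FALSE)))
  }
  truth <- rbind(
    long("planted_de", sim$expression$plantedDe, "gene"),
    long("planted_dmp", sim$methylation$plantedDmps, "cpg"),
    long("planted_ms", sim$methylation$plantedMsGenes, "gene"),
    long("planted_mtr", sim$network$truth, "mtr"),
    data.frame(category = "true_population",
               id = names(sim$genotypes$labels), key = "population",
               value = unname(sim$genotypes$labels),
               stringsAsFactors = FALSE))
  if (!is.null(sim$promoters$truth))
    truth <- rbind(truth, long("planted_site", sim$promoters$truth,
                               "promoter"))
  .writeTsv(truth, file.path(dir, "truth", "planted.tsv"))
  invisible(dir)
}
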