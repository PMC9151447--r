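#' Filter 450K-style probes
#'
#' Removes probes that are unannotated, carry any missing value, or have a
#' quality flag set. Rules are applied in a documented order and each probe
#' is tallied under the first rule that removes it: unannotated, missing
#' value, cross-reactive, sex chromosome, non-CpG, SNP-related, multi-hit.
#'
#' @param betas CpGs x samples beta matrix.
#' @param annotation data.frame with columns \code{cpg} and logical flags
#'   \code{cross_reactive}, \code{sex_chromosome} (or chrom in chrX/chrY),
#'   \code{non_cpg}, \code{snp_related}, \code{multi_hit}.
#' @return list with \code{betas} (filtered) and \code{tally} (named
#'   integer vector of removals per rule).
#' @export
filterProbes <- function(betas, annotation) {
  ann <- annotation[match(rownames(betas), annotation$cpg), , drop = FALSE]
  flag <- function(col) {
    v <- ann[[col]]
    if (is.null(v)) rep(FALSE, nrow(betas)) else !is.na(v) & v
  }
  sexChrom <- flag("sex_chromosome")
  if ("chrom" %in% names(ann))
    sexChrom <- sexChrom | (!is.na(ann$chrom) &
                              ann$chrom %in% c("chrX", "chrY", "X", "Y"))
  rules <- list(
    unannotated = is.na(ann$cpg),
    missing_value = apply(betas, 1, anyNA),
    cross_reactive = flag("cross_reactive"),
    sex_chromosome = sexChrom,
    non_cpg = flag("non_cpg"),
    snp_related = flag("snp_related"),
    multi_hit = flag("multi_hit"))
  removed <- rep(FALSE, nrow(betas))
  tally <- integer(length(rules))
  names(tally) <- names(rules)
  for (r in names(rules)) {
    hit <- rules[[r]] & !removed
    tally[r] <- sum(hit)
    removed <- removed | rules[[r]]
  }
  if (all(removed)) stop("all probes removed", call. = FALSE)
  list(betas = betas[!removed, , drop = FALSE], tally = tally)
}

#' Quantile normalization of type-II probes onto the type-I distribution
#'
#' Within each sample, the type-II beta distribution is quantile-mapped
#' onto that sample's type-I distribution (rank -> interpolated type-I
#' quantile), preserving rank order within type II and keeping all output
#' in [0, 1]. Samples with fewer than 10 type-I probes are left untouched
#' with a warning.
#'
#' @param betas CpGs x samples beta matrix.
#' @param designType named character vector (cpg -> "I"/"II") or an
#'   annotation data.frame with \code{cpg} and \code{design_type} columns.
#' @return normalized beta matrix of the same shape.
#' @export
normalizeBetas <- function(betas, designType) {
  if (is.data.frame(designType))
    designType <- stats::setNames(designType$design_type, designType$cpg)
  dt <- designType[rownames(betas)]
  if (anyNA(dt)) {
    warning("probes without a design type are left unnormalized",
            call. = FALSE)
  }
  i1 <- which(!is.na(dt) & dt == "I")
  i2 <- which(!is.na(dt) & dt == "II")
  out <- betas
  if (length(i1) < 10L) {
    warning("fewer than 10 type-I probes: normalization skipped",
            call. = FALSE)
    return(out)
  }
  for (s in seq_len(ncol(betas))) {
    x1 <- betas[i1, s]
    x2 <- betas[i2, s]
    n2 <- length(x2)
    if (n2 < 2L) next
    pr <- (rank(x2, ties.method = "average") - 1) / (n2 - 1)
    out[i2, s] <- as.numeric(stats::quantile(x1, probs = pr, type = 7,
                                             names = FALSE))
  }
  out
}

#' Beta to M-value transform
#'
#' \code{M = log2(beta / (1 - beta))} after clipping beta to
#' \code{[eps, 1 - eps]}.
#'
#' @param beta numeric vector or matrix of betas.
#' @param eps clipping bound (default 1e-6).
#' @return M-values of the same shape.
#' @export
betaToM <- function(beta, eps = 1e-6) {
  b <- pmin(pmax(beta, eps), 1 - eps)
  log2(b / (1 - b))
}

#' Covariate-adjusted differential methylation
#'
#' Per CpG, an ordinary linear model on M-values with the contrast variable
#' plus covariates; the p-value comes from the t-test on the contrast
#' coefficient and the effect is reported on the beta scale as the group
#' mean difference. Direction is "hyper" when the first contrast level has
#' the higher mean beta.
#'
#' @param betas CpGs x samples beta matrix.
#' @param metadata per-sample metadata with \code{sample_id}.
#' @param contrastVar metadata column defining the two compared groups.
#' @param contrast length-2 vector (numerator, reference).
#' @param covariates covariate columns (set to \code{character()} for an
#'   unadjusted test).
#' @return data.frame: cpg, delta_beta, p, q, direction.
#' @export
testDmps <- function(betas, metadata, contrastVar = "ancestry",
                     contrast = c("AFR", "EUR"),
                     covariates = c("age_group", "tumor_location")) {
  md <- metadata[match(colnames(betas), metadata$sample_id), , drop = FALSE]
  grp <- factor(md[[contrastVar]], levels = rev(contrast))
  if (any(table(grp) < 3L))
    stop("need at least 3 samples per contrast group", call. = FALSE)
  m <- betaToM(betas)
  df <- data.frame(.grp = grp)
  for (cv in covariates) {
    f <- factor(md[[cv]])
    if (nlevels(f) < 2L) {
      message("covariate '", cv, "' is constant in this subset: dropped")
      next
    }
    df[[cv]] <- f
  }
  design <- stats::model.matrix(~ ., df)
  fit <- .rowwiseOls(m, design, paste0(".grp", contrast[1]))
  isNum <- md[[contrastVar]] == contrast[1]
  delta <- rowMeans(betas[, isNum, drop = FALSE]) -
    rowMeans(betas[, !isNum, drop = FALSE])
  out <- data.frame(cpg = fit$feature, delta_beta = as.numeric(delta),
                    p = fit$p, stringsAsFactors = FALSE)
  out$q <- bhAdjust(out$p)
  out$direction <- ifelse(out$delta_beta >= 0, "hyper", "hypo")
  out
}

#' Tumor-specific differentially methylated positions
#'
#' First pass: tumor-vs-normal DMPs (q < \code{candidateQ}) within each
#' ancestry; the candidate set is their union. Second pass: the
#' covariate-adjusted AFR-vs-EUR tumor test restricted to the candidates,
#' with BH over candidates only.
#'
#' @param betas CpGs x samples beta matrix covering tumor and normal
#'   samples of both ancestries.
#' @param metadata per-sample metadata with \code{sample_id},
#'   \code{ancestry}, \code{tissue}.
#' @param covariates covariates for the second-pass ancestry test.
#' @param candidateQ q threshold of the first pass.
#' @param contrast ancestry contrast of the second pass.
#' @return list with \code{candidates} (CpG ids) and \code{dmps}
#'   (second-pass data.frame; empty with a warning when no candidate).
#' @export
tumorSpecificDmps <- function(betas, metadata,
                              covariates = c("age_group",
                                             "tumor_location"),
                              candidateQ = 0.05,
                              contrast = c("AFR", "EUR")) {
  candidates <- character()
  for (anc in contrast) {
    ids <- metadata$sample_id[metadata$ancestry == anc]
    sub <- betas[, intersect(colnames(betas), ids), drop = FALSE]
    mdSub <- metadata[metadata$sample_id %in% colnames(sub), , drop = FALSE]
    if (!all(c("tumor", "normal") %in% mdSub$tissue))
      stop("ancestry ", anc, " lacks tumor or normal samples",
           call. = FALSE)
    res <- testDmps(sub, mdSub, contrastVar = "tissue",
                    contrast = c("tumor", "normal"),
                    covariates = character())
    candidates <- union(candidates, res$cpg[res$q < candidateQ])
  }
  if (!length(candidates)) {
    warning("no tumor-specific candidate DMP", call. = FALSE)
    return(list(candidates = character(),
                dmps = data.frame(cpg = character(), delta_beta = numeric(),
                                  p = numeric(), q = numeric(),
                                  direction = character())))
  }
  tumorIds <- metadata$sample_id[metadata$tissue == "tumor"]
  sub <- betas[candidates, intersect(colnames(betas), tumorIds),
               drop = FALSE]
  mdT <- metadata[metadata$sample_id %in% colnames(sub), , drop = FALSE]
  dmps <- testDmps(sub, mdT, contrastVar = "ancestry", contrast = contrast,
                   covariates = covariates)
  list(candidates = candidates, dmps = dmps)
}

#' Map CpGs to genomic features of nearby genes
#'
#' A CpG is assigned to a gene's promoter when its strand-aware TSS-relative
#' offset lies in the closed window [-1200, +200]; otherwise to the 5'/3'
#' UTR, then the gene body, then (when inside a supplied enhancer region)
#' an intergenic enhancer, else intergenic. Precedence per gene:
#' promoter > UTR > body; all matching genes are reported.
#'
#' @param cpgs data.frame with \code{cpg}, \code{chrom}, \code{pos}.
#' @param geneModels data.frame with \code{gene}, \code{chrom},
#'   \code{strand}, \code{tss}, \code{tx_start}, \code{tx_end} and optional
#'   \code{utr5_start}, \code{utr5_end}, \code{utr3_start},
#'   \code{utr3_end}.
#' @param enhancers optional data.frame with \code{chrom}, \code{start},
#'   \code{end} (1-based inclusive).
#' @param promoterWindow TSS-relative window, closed at both ends.
#' @return data.frame: cpg, feature, gene (NA for intergenic/enhancer).
#' @export
mapCpgToFeatures <- function(cpgs, geneModels, enhancers = NULL,
                             promoterWindow = c(-1200L, 200L)) {
  knownChrom <- unique(geneModels$chrom)
  rows <- lapply(seq_len(nrow(cpgs)), function(i) {
    chrom <- cpgs$chrom[i]; pos <- cpgs$pos[i]
    if (!chrom %in% knownChrom) {
      warning("unannotated chromosome ", chrom, " for ", cpgs$cpg[i],
              call. = FALSE)
      return(data.frame(cpg = cpgs$cpg[i], feature = "intergenic",
                        gene = NA_character_, stringsAsFactors = FALSE))
    }
    gm <- geneModels[geneModels$chrom == chrom, , drop = FALSE]
    offset <- ifelse(gm$strand == "-", gm$tss - pos, pos - gm$tss)
    inPromoter <- offset >= promoterWindow[1] & offset <= promoterWindow[2]
    inSpan <- function(st, en) !is.na(st) & !is.na(en) & pos >= st &
      pos <= en
    inUtr <- inSpan(gm$utr5_start %||na% NA, gm$utr5_end %||na% NA) |
      inSpan(gm$utr3_start %||na% NA, gm$utr3_end %||na% NA)
    inBody <- inSpan(gm$tx_start, gm$tx_end)
    feature <- rep(NA_character_, nrow(gm))
    feature[inBody] <- "body"
    feature[inUtr] <- "utr"
    feature[inPromoter] <- "promoter"
    hit <- which(!is.na(feature))
    if (length(hit))
      return(data.frame(cpg = cpgs$cpg[i], feature = feature[hit],
                        gene = gm$gene[hit], stringsAsFactors = FALSE))
    if (!is.null(enhancers)) {
      enh <- enhancers[enhancers$chrom == chrom & pos >= enhancers$start &
                         pos <= enhancers$end, , drop = FALSE]
      if (nrow(enh))
        return(data.frame(cpg = cpgs$cpg[i], feature = "enhancer",
                          gene = NA_character_, stringsAsFactors = FALSE))
    }
    data.frame(cpg = cpgs$cpg[i], feature = "intergenic",
               gene = NA_character_, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

`%||na%` <- function(a, b) if (is.null(a)) rep(b, 1) else a

#' Screen for methylation-sensitive genes
#'
#' For each differentially expressed gene with at least one associated CpG,
#' the CpG with the lowest DMP q is selected and the Pearson correlation
#' between its beta values and the gene's normalized expression is computed
#' across shared samples (pooled, plus per ancestry group). The gene is
#' included when the pooled correlation is negative with a two-sided
#' correlation-test p below \code{pMax}; BH q over the included tests is
#' reported.
#'
#' @param degs data.frame from [differentialExpression()]; only genes with
#'   q < 0.05 are screened.
#' @param dmps data.frame from [testDmps()] (or the second pass of
#'   [tumorSpecificDmps()]).
#' @param associations data.frame with \code{cpg}, \code{gene} linking CpGs
#'   to genes (e.g. the promoter rows of [mapCpgToFeatures()]).
#' @param betas CpGs x samples beta matrix.
#' @param expression genes x samples normalized expression matrix.
#' @param metadata per-sample metadata (for the per-ancestry correlations).
#' @param pMax inclusion threshold on the pooled correlation p.
#' @return data.frame: gene, cpg, r (pooled), p, q, r_AFR, r_EUR,
#'   included.
#' @export
methylationSensitiveGenes <- function(degs, dmps, associations, betas,
                                      expression, metadata, pMax = 0.05) {
  sig <- degs$gene[degs$q < 0.05]
  shared <- intersect(colnames(betas), colnames(expression))
  md <- metadata[match(shared, metadata$sample_id), , drop = FALSE]
  rows <- lapply(sig, function(g) {
    cands <- associations$cpg[associations$gene %in% g]
    cands <- intersect(cands, dmps$cpg)
    cands <- intersect(cands, rownames(betas))
    if (!length(cands)) return(NULL)
    qv <- dmps$q[match(cands, dmps$cpg)]
    cpg <- cands[which.min(qv)]
    if (length(shared) < 3L) {
      warning("fewer than 3 paired samples for ", g, ": skipped",
              call. = FALSE)
      return(NULL)
    }
    b <- betas[cpg, shared]
    e <- expression[g, shared]
    if (stats::sd(b) == 0 || stats::sd(e) == 0) return(NULL)
    ct <- stats::cor.test(b, e)
    perGroup <- vapply(c("AFR", "EUR"), function(a) {
      idx <- which(md$ancestry == a)
      if (length(idx) < 3L) return(NA_real_)
      stats::cor(b[idx], e[idx])
    }, numeric(1))
    data.frame(gene = g, cpg = cpg, r = unname(ct$estimate),
               p = ct$p.value, r_AFR = perGroup[["AFR"]],
               r_EUR = perGroup[["EUR"]], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(gene = character(), cpg = character(), r = numeric(),
                      p = numeric(), q = numeric(), r_AFR = numeric(),
                      r_EUR = numeric(), included = logical()))
  out$q <- bhAdjust(out$p)
  out$included <- out$r < 0 & out$p < pMax
  rownames(out) <- NULL
  out
}

#' Partition TFs by the methylation state near their binding sites
#'
#' A TF enters the hyper list when at least one of its binding-site hits
#' lies within \code{window} bp of a hypermethylated DMP associated with a
#' downregulated gene, and the hypo list analogously for hypomethylated
#' DMPs near upregulated genes. The result splits assigned TFs into
#' disjoint hyper-only / hypo-only / shared sets.
#'
#' @param hits data.frame with \code{pwm}, \code{chrom}, \code{pos}
#'   (genomic coordinate of each binding-site hit).
#' @param dmps data.frame with \code{cpg}, \code{direction} plus genomic
#'   \code{chrom}, \code{pos} and the associated \code{gene}.
#' @param degClasses named vector gene -> class ("up"/"down"/"none").
#' @param window distance window in bp (default 1000).
#' @return list with \code{hyperOnly}, \code{hypoOnly}, \code{shared}.
#' @export
tfbsMethylationPartition <- function(hits, dmps, degClasses,
                                     window = 1000L) {
  if (!all(c("chrom", "pos") %in% names(hits)))
    stop("hits must carry genomic chrom/pos coordinates", call. = FALSE)
  geneClass <- degClasses[dmps$gene]
  hyperDmps <- dmps[dmps$direction == "hyper" &
                      !is.na(geneClass) & geneClass == "down", ,
                    drop = FALSE]
  hypoDmps <- dmps[dmps$direction == "hypo" &
                     !is.na(geneClass) & geneClass == "up", , drop = FALSE]
  near <- function(dmpSet) {
    vapply(unique(hits$pwm), function(tf) {
      h <- hits[hits$pwm == tf, , drop = FALSE]
      any(vapply(seq_len(nrow(h)), function(i)
        any(dmpSet$chrom == h$chrom[i] &
              abs(dmpSet$pos - h$pos[i]) <= window), logical(1)))
    }, logical(1))
  }
  inHyper <- near(hyperDmps)
  inHypo <- near(hypoDmps)
  tfs <- unique(hits$pwm)
  list(hyperOnly = tfs[inHyper & !inHypo],
       hypoOnly = tfs[inHypo & !inHyper],
       shared = tfs[inHyper & inHypo])
}
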