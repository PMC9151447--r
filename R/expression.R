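#' Remove genes with effective zero expression
#'
#' A gene is removed when every sample value is missing, 0 or 1; a single
#' count of 2 anywhere retains it.
#'
#' @param counts genes x samples count matrix.
#' @return filtered matrix; a message reports the removal count.
#' @export
filterZeroExpression <- function(counts) {
  zero <- apply(counts, 1, function(x) all(is.na(x) | x <= 1))
  if (all(zero)) stop("all genes removed by the zero-expression filter",
                      call. = FALSE)
  if (any(zero))
    message("removed ", sum(zero), " gene(s) with effective zero expression")
  counts[!zero, , drop = FALSE]
}

#' Median-of-ratios size factors
#'
#' For each sample, the factor is the median over all-positive genes of the
#' ratio of its count to the gene's geometric mean across samples.
#'
#' @param counts genes x samples count matrix.
#' @return named positive numeric vector of per-sample factors.
#' @export
sizeFactorsMedianOfRatios <- function(counts) {
  pos <- apply(counts, 1, function(x) all(!is.na(x) & x > 0))
  if (!any(pos))
    stop("no gene with all-positive counts; cannot form a reference",
         call. = FALSE)
  lc <- log(counts[pos, , drop = FALSE])
  geo <- rowMeans(lc)
  sf <- apply(lc, 2, function(x) exp(stats::median(x - geo)))
  sf
}

#' Log2 transform of size-factor-normalized counts
#'
#' \code{log2(count / sizeFactor + 1)}: the variance-stabilizing surrogate
#' used throughout the pipeline for scoring and testing.
#'
#' @param counts genes x samples count matrix.
#' @param sizeFactors per-sample positive factors; computed by
#'   [sizeFactorsMedianOfRatios()] when NULL.
#' @return transformed matrix of the same shape.
#' @export
vstLikeTransform <- function(counts, sizeFactors = NULL) {
  if (is.null(sizeFactors)) sizeFactors <- sizeFactorsMedianOfRatios(counts)
  if (any(sizeFactors <= 0)) stop("size factors must be positive",
                                  call. = FALSE)
  log2(sweep(counts, 2, sizeFactors, "/") + 1)
}

#' Covariate-adjusted differential expression
#'
#' Per gene, an ordinary linear model on \code{log2(count/sizeFactor + 1)}
#' with design \code{~ ancestry + age_group + tumor_location}; the reported
#' log2 fold change is the AFR-vs-EUR ancestry coefficient, the p-value the
#' two-sided t-test on that coefficient, and q the BH adjustment over all
#' tested genes.
#'
#' @param counts genes x samples count matrix (tumor samples).
#' @param metadata per-sample metadata with \code{sample_id},
#'   \code{ancestry} and the covariate columns.
#' @param covariates covariate columns to adjust for.
#' @param contrast length-2 vector: (numerator, reference) ancestry levels.
#' @return data.frame: gene, log2fc, p, q, class (via [classifyDegs()]).
#' @export
differentialExpression <- function(counts, metadata,
                                   covariates = c("age_group",
                                                  "tumor_location"),
                                   contrast = c("AFR", "EUR")) {
  md <- metadata[match(colnames(counts), metadata$sample_id), ,
                 drop = FALSE]
  if (any(is.na(md$sample_id)))
    stop("metadata is missing some count-matrix samples", call. = FALSE)
  anc <- factor(md$ancestry, levels = rev(contrast))
  if (any(table(anc) < 3L))
    stop("need at least 3 samples per ancestry group", call. = FALSE)
  y <- vstLikeTransform(counts)
  df <- data.frame(.anc = anc)
  for (cv in covariates) df[[cv]] <- factor(md[[cv]])
  design <- stats::model.matrix(~ ., df)
  coefName <- paste0(".anc", contrast[1])
  fit <- .rowwiseOls(y, design, coefName)
  res <- data.frame(gene = fit$feature, log2fc = fit$estimate, p = fit$p,
                    stringsAsFactors = FALSE)
  res$q <- bhAdjust(res$p)
  res$class <- classifyDegs(res)$class
  res
}

#' Classify differential-expression results
#'
#' up when fold-change > \code{upFc} and q < \code{qMax}; down when
#' fold-change < \code{downFc} and q < \code{qMax}; otherwise none
#' (fold-change = \code{2^log2fc}).
#'
#' @param results data.frame with \code{log2fc} and \code{q}.
#' @param upFc,downFc,qMax classification thresholds.
#' @return the input with a \code{class} column.
#' @export
classifyDegs <- function(results, upFc = 1.5, downFc = 0.5, qMax = 0.05) {
  if (upFc <= downFc) stop("upFc must exceed downFc", call. = FALSE)
  fc <- 2^results$log2fc
  cls <- rep("none", nrow(results))
  cls[fc > upFc & results$q < qMax] <- "up"
  cls[fc < downFc & results$q < qMax] <- "down"
  results$class <- cls
  results
}

#' Hypergeometric over-representation test
#'
#' Upper-tail probability of observing at least the seen overlap between a
#' query gene list and a gene set, both drawn from a common universe.
#'
#' @param query character vector of query genes (subset of universe).
#' @param geneSet character vector (subset of universe).
#' @param universe character vector of all testable genes.
#' @return list with \code{p}, \code{overlap}, \code{overlapGenes}.
#' @export
oraEnrichment <- function(query, geneSet, universe) {
  if (!length(universe)) stop("empty universe", call. = FALSE)
  universe <- unique(universe)
  query <- intersect(unique(query), universe)
  geneSet <- intersect(unique(geneSet), universe)
  ov <- intersect(query, geneSet)
  p <- stats::phyper(length(ov) - 1, length(geneSet),
                     length(universe) - length(geneSet), length(query),
                     lower.tail = FALSE)
  list(p = p, overlap = length(ov), overlapGenes = ov)
}

#' Over-representation tests across a gene-set collection
#'
#' @param query query genes.
#' @param geneSets named list of gene sets (e.g. from [readGmt()]).
#' @param universe universe genes.
#' @return data.frame: set, size, overlap, p, q (BH across sets).
#' @export
oraEnrichmentTable <- function(query, geneSets, universe) {
  rows <- lapply(names(geneSets), function(nm) {
    r <- oraEnrichment(query, geneSets[[nm]], universe)
    data.frame(set = nm,
               size = length(intersect(unique(geneSets[[nm]]),
                                       unique(universe))),
               overlap = r$overlap, p = r$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bhAdjust(out$p)
  out
}
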