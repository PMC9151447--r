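#' Merge MAF tables from several variant callers
#'
#' Takes the union of variants over the key (sample, chromosome, position,
#' ref, alt); each merged record carries the set of callers that reported
#' it. Conflicting reference alleles at the same genomic site are an error.
#'
#' @param mafsByCaller named list of MAF data.frames (see [readMaf()]); the
#'   list names are used as caller tags when a table lacks a \code{caller}
#'   column.
#' @return data.frame of unique variants with a \code{callers} column
#'   (comma-separated, sorted).
#' @export
mergeCallerMafs <- function(mafsByCaller) {
  if (!length(mafsByCaller)) stop("need at least one caller list",
                                  call. = FALSE)
  if (is.data.frame(mafsByCaller)) mafsByCaller <- list(mafsByCaller)
  tagged <- lapply(seq_along(mafsByCaller), function(i) {
    df <- mafsByCaller[[i]]
    if (!"caller" %in% names(df))
      df$caller <- names(mafsByCaller)[i] %||% "other"
    df
  })
  common <- Reduce(intersect, lapply(tagged, names))
  all <- do.call(rbind, lapply(tagged, function(d) d[, common,
                                                     drop = FALSE]))
  key <- with(all, paste(Tumor_Sample_Barcode, Chromosome, Start_Position,
                         Reference_Allele, Tumor_Seq_Allele2, sep = "\r"))
  site <- with(all, paste(Tumor_Sample_Barcode, Chromosome, Start_Position,
                          sep = "\r"))
  refsPerSite <- tapply(all$Reference_Allele, site,
                        function(x) length(unique(x)))
  if (any(refsPerSite > 1)) {
    bad <- names(refsPerSite)[refsPerSite > 1][1]
    stop("conflicting reference alleles at ",
         gsub("\r", ":", bad), call. = FALSE)
  }
  callers <- vapply(split(all$caller, key), function(x)
    paste(sort(unique(x)), collapse = ","), character(1))
  merged <- all[!duplicated(key), , drop = FALSE]
  merged$caller <- NULL
  merged$callers <- unname(callers[unique(key)])
  rownames(merged) <- NULL
  merged
}

`%||%` <- function(a, b)
  if (is.null(a) || !length(a) || is.na(a) || !nzchar(a)) b else a

#' Tumor mutation burden
#'
#' Counts every merged variant of a sample; all variant classifications
#' count.
#'
#' @param merged output of [mergeCallerMafs()].
#' @param sample single sample barcode, or NULL for a per-sample table.
#' @return integer count, or a data.frame (sample, tmb) when
#'   \code{sample} is NULL.
#' @export
computeTmb <- function(merged, sample = NULL) {
  if (is.null(sample)) {
    tab <- table(merged$Tumor_Sample_Barcode)
    return(data.frame(sample = names(tab), tmb = as.integer(tab),
                      stringsAsFactors = FALSE))
  }
  sum(merged$Tumor_Sample_Barcode == sample)
}

#' Hotspot concentration score for a gene's mutations
#'
#' Clusters are maximal runs of mutated positions where adjacent positions
#' are at most \code{gapMax} bp apart; the score is the Simpson
#' concentration \eqn{\sum_c f_c^2} over cluster mutation fractions. The
#' score is 1 exactly when a single hotspot holds all mutations, and 1/m
#' when m mutations fall into m singleton clusters.
#'
#' @param positions integer vector of mutation positions (with
#'   multiplicity).
#' @param gapMax maximum within-cluster gap in bp (default 5).
#' @return score in (0, 1].
#' @export
hotspotClusterScore <- function(positions, gapMax = 5) {
  if (gapMax < 0) stop("gapMax must be >= 0", call. = FALSE)
  if (!length(positions)) stop("need at least one mutation", call. = FALSE)
  p <- sort(positions)
  breaks <- c(0, which(diff(p) > gapMax), length(p))
  sizes <- diff(breaks)
  f <- sizes / length(p)
  sum(f^2)
}

#' Flag samples carrying a mutation in a given gene
#'
#' Convenience metadata filter, e.g. to drop POLE-mutated samples before
#' burden comparisons.
#'
#' @param merged output of [mergeCallerMafs()].
#' @param gene gene symbol (default "POLE").
#' @return character vector of sample barcodes carrying the mutation.
#' @export
mutatedSamples <- function(merged, gene = "POLE") {
  unique(merged$Tumor_Sample_Barcode[merged$Hugo_Symbol == gene])
}
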