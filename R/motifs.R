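#' Extract a promoter window around the TSS
#'
#' Clips a sequence to the regulatory window \code{[-upstream, +downstream]}
#' relative to the TSS (default -1000/+100).
#'
#' @param sequence full promoter sequence.
#' @param tssIndex 1-based position of the TSS within \code{sequence}.
#' @param upstream,downstream window extent in bp.
#' @return the window subsequence.
#' @export
extractRegulatoryRegion <- function(sequence, tssIndex, upstream = 1000L,
                                    downstream = 100L) {
  from <- tssIndex - upstream
  to <- tssIndex + downstream
  if (from < 1L || to > nchar(sequence))
    stop("window [-", upstream, ", +", downstream,
         "] falls outside the sequence", call. = FALSE)
  substr(sequence, from, to)
}

# Log-odds score matrix (4 x L) of a PWMotif: log2(p / background).
.pwmLogOdds <- function(pwm) {
  log2(pwm@matrix / pwm@background)
}

#' Maximum attainable log-odds score of a motif
#'
#' @param pwm a [PWMotif-class].
#' @return sum over positions of the best per-base log-odds.
#' @export
pwmMaxScore <- function(pwm) {
  sum(apply(.pwmLogOdds(pwm), 2, max))
}

# Score every start position of one strand; returns numeric vector of
# length nchar - L + 1 (positions with N score -Inf).
.scanStrand <- function(codes, lodds) {
  L <- ncol(lodds)
  n <- length(codes) - L + 1L
  if (n < 1L) return(numeric(0))
  s <- numeric(n)
  for (j in seq_len(L))
    s <- s + lodds[cbind(codes[j:(j + n - 1L)], j)]
  s[is.na(s)] <- -Inf
  s
}

#' Scan a sequence with a PWM on both strands
#'
#' Positions are scored as \eqn{\sum_j \log_2(p_{b_j,j} / bg_{b_j})};
#' hits are positions reaching \code{threshold}. Reverse-strand hits are
#' reported by the forward-strand start of the site (leftmost base).
#'
#' @param sequence ACGTN string (a regulatory window).
#' @param pwm a [PWMotif-class].
#' @param threshold log-odds threshold; default 60% of the motif's maximum
#'   attainable score.
#' @return data.frame: pwm, start, strand ("+"/"-"), score. Empty (with a
#'   warning) when the motif is longer than the sequence.
#' @export
scanPwm <- function(sequence, pwm, threshold = NULL) {
  if (is.null(threshold)) threshold <- 0.6 * pwmMaxScore(pwm)
  L <- pwmLength(pwm)
  n <- nchar(sequence)
  empty <- data.frame(pwm = character(), start = integer(),
                      strand = character(), score = numeric(),
                      stringsAsFactors = FALSE)
  if (L > n) {
    warning("motif ", pwmName(pwm), " longer than the sequence",
            call. = FALSE)
    return(empty)
  }
  lodds <- .pwmLogOdds(pwm)
  fwd <- .scanStrand(.encodeDna(sequence), lodds)
  rev <- .scanStrand(.encodeDna(.revcompDna(sequence)), lodds)
  hitsF <- which(fwd >= threshold)
  hitsR <- which(rev >= threshold)
  out <- rbind(
    if (length(hitsF)) data.frame(pwm = pwmName(pwm), start = hitsF,
                                  strand = "+", score = fwd[hitsF],
                                  stringsAsFactors = FALSE),
    if (length(hitsR)) data.frame(pwm = pwmName(pwm),
                                  start = n - (hitsR + L - 1L) + 1L,
                                  strand = "-", score = rev[hitsR],
                                  stringsAsFactors = FALSE))
  if (is.null(out)) empty else out[order(out$start), , drop = FALSE]
}

#' Scan many regions with a PWM library
#'
#' @param regions named character vector of sequences.
#' @param pwms named list of [PWMotif-class].
#' @param threshold shared log-odds threshold, a named per-PWM vector, or
#'   NULL for the 60%-of-maximum default per motif.
#' @return data.frame of hits with a \code{region} column.
#' @export
scanRegions <- function(regions, pwms, threshold = NULL) {
  rows <- lapply(names(pwms), function(pn) {
    th <- if (is.null(threshold)) NULL
          else if (length(threshold) > 1) threshold[[pn]] else threshold
    do.call(rbind, lapply(names(regions), function(rn) {
      h <- scanPwm(regions[[rn]], pwms[[pn]], th)
      if (nrow(h)) cbind(region = rn, h, stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(region = character(), pwm = character(),
                      start = integer(), strand = character(),
                      score = numeric(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Binding-site enrichment of motifs in a yes-set versus a no-set
#'
#' Per motif, regions are dichotomized by presence of at least one hit and
#' the resulting 2x2 table is tested: Pearson chi-squared without
#' correction, switching to the two-sided Fisher exact test when any
#' expected cell is below 5. q is BH across the library; a motif is called
#' enriched at q < 0.05 with a higher hit proportion in the yes-set.
#'
#' @param yesRegions,noRegions named character vectors of sequences.
#' @param pwms named list of [PWMotif-class].
#' @param threshold see [scanRegions()].
#' @param qMax enrichment threshold.
#' @return data.frame: pwm, yes_hits, no_hits, yes_n, no_n, test, p, q,
#'   enriched.
#' @export
tfbsEnrichment <- function(yesRegions, noRegions, pwms, threshold = NULL,
                           qMax = 0.05) {
  if (!length(pwms)) stop("empty PWM library", call. = FALSE)
  if (!length(yesRegions) || !length(noRegions))
    stop("both region sets must be non-empty", call. = FALSE)
  rows <- lapply(names(pwms), function(pn) {
    th <- if (is.null(threshold)) NULL
          else if (length(threshold) > 1) threshold[[pn]] else threshold
    hitYes <- sum(vapply(yesRegions, function(s)
      nrow(scanPwm(s, pwms[[pn]], th)) > 0, logical(1)))
    hitNo <- sum(vapply(noRegions, function(s)
      nrow(scanPwm(s, pwms[[pn]], th)) > 0, logical(1)))
    tab <- rbind(c(hitYes, length(yesRegions) - hitYes),
                 c(hitNo, length(noRegions) - hitNo))
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (any(expected < 5)) {
      p <- stats::fisher.test(tab)$p.value
      test <- "fisher"
    } else {
      p <- suppressWarnings(stats::chisq.test(tab,
                                              correct = FALSE))$p.value
      test <- "chisq"
    }
    if (is.nan(p)) p <- 1
    data.frame(pwm = pn, yes_hits = hitYes, no_hits = hitNo,
               yes_n = length(yesRegions), no_n = length(noRegions),
               test = test, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bhAdjust(out$p)
  out$enriched <- out$q < qMax &
    out$yes_hits / out$yes_n > out$no_hits / out$no_n
  out
}
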