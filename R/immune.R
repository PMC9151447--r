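#' Marker-mean immune population scores
#'
#' The score of a population in a sample is the arithmetic mean of the
#' transformed expression of that population's marker genes — the
#' MCP-counter contract: scores are comparable across samples within a
#' population but not across populations. Markers absent from the matrix
#' are dropped with a warning; a population left with no marker is an
#' error. Overlapping marker sets are allowed but warned about.
#'
#' @param transformed genes x samples matrix (see [vstLikeTransform()]).
#' @param markerSets named list: population -> marker gene vector.
#' @return populations x samples score matrix.
#' @export
mcpScores <- function(transformed, markerSets) {
  allMk <- unlist(markerSets)
  if (anyDuplicated(allMk))
    warning("marker sets overlap: ",
            paste(unique(allMk[duplicated(allMk)]), collapse = ", "),
            call. = FALSE)
  out <- t(vapply(names(markerSets), function(popName) {
    mk <- markerSets[[popName]]
    present <- intersect(mk, rownames(transformed))
    if (!length(present))
      stop("population '", popName, "' has no marker in the matrix",
           call. = FALSE)
    if (length(present) < length(mk))
      warning("dropping ", length(mk) - length(present),
              " absent marker(s) for ", popName, call. = FALSE)
    colMeans(transformed[present, , drop = FALSE])
  }, numeric(ncol(transformed))))
  colnames(out) <- colnames(transformed)
  out
}

# Exact two-sided rank-sum p by full enumeration of group assignments,
# valid with ties (uses midranks). Used when both groups have <= 8 samples.
.exactRankSumP <- function(x, y) {
  vals <- c(x, y)
  r <- rank(vals)
  n1 <- length(x)
  obs <- sum(r[seq_len(n1)])
  ew <- n1 * (length(vals) + 1) / 2
  combos <- utils::combn(length(vals), n1)
  ws <- colSums(matrix(r[combos], nrow = n1))
  mean(abs(ws - ew) >= abs(obs - ew) - 1e-9)
}

#' Rank-sum comparison of immune scores between two groups
#'
#' Two-sided Wilcoxon rank-sum (Mann-Whitney) per population. Both groups
#' of size at most 8 trigger exact enumeration over all group assignments
#' (valid under ties); larger groups use the normal approximation with tie
#' correction and no continuity correction.
#'
#' @param scores populations x samples matrix from [mcpScores()].
#' @param grouping named vector (sample -> group) or a vector aligned with
#'   the score columns; exactly 2 groups required.
#' @return data.frame: population, n per group, statistic (rank-sum of the
#'   first group), p.
#' @export
rankSumCompare <- function(scores, grouping) {
  if (!is.null(names(grouping)))
    grouping <- grouping[colnames(scores)]
  g <- factor(grouping)
  if (nlevels(g) != 2L) stop("grouping must have exactly 2 levels",
                             call. = FALSE)
  if (any(table(g) < 1L)) stop("a group is empty", call. = FALSE)
  rows <- lapply(rownames(scores), function(popName) {
    x <- scores[popName, g == levels(g)[1]]
    y <- scores[popName, g == levels(g)[2]]
    if (length(x) <= 8L && length(y) <= 8L) {
      p <- .exactRankSumP(x, y)
    } else {
      p <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                               correct = FALSE))$p.value
      if (is.nan(p)) p <- 1  # all values tied
    }
    data.frame(population = popName, n1 = length(x), n2 = length(y),
               statistic = sum(rank(c(x, y))[seq_along(x)]), p = p,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Two-way ANOVA of one population's immune scores
#'
#' Fits \code{score ~ ancestry * factor2} and reports Type II F-tests for
#' the two main effects and the interaction. When some ancestry-by-factor2
#' cell is empty the interaction is dropped with a warning.
#'
#' @param scores numeric vector of one population's scores, named by sample
#'   or aligned with \code{metadata}.
#' @param metadata per-sample metadata with \code{ancestry} and
#'   \code{factor2}.
#' @param factor2 second factor column: one of age_group, stage,
#'   tumor_location (any categorical column works).
#' @return data.frame: term, sum_sq, df, F, p.
#' @export
twoWayAnova <- function(scores, metadata, factor2) {
  if (!is.null(names(scores)))
    metadata <- metadata[match(names(scores), metadata$sample_id), ,
                         drop = FALSE]
  d <- data.frame(score = as.numeric(scores),
                  ancestry = factor(metadata$ancestry),
                  f2 = factor(metadata[[factor2]]))
  if (nlevels(d$ancestry) < 2L || nlevels(d$f2) < 2L)
    stop("both factors need at least 2 levels", call. = FALSE)
  cells <- table(d$ancestry, d$f2)
  form <- score ~ ancestry * f2
  if (any(cells == 0L)) {
    warning("empty design cell(s): interaction dropped", call. = FALSE)
    form <- score ~ ancestry + f2
  }
  fit <- stats::lm(form, data = d)
  a <- car::Anova(fit, type = 2)
  out <- data.frame(term = rownames(a), sum_sq = a[["Sum Sq"]],
                    df = a[["Df"]], F = a[["F value"]], p = a[["Pr(>F)"]],
                    stringsAsFactors = FALSE)
  out$term <- sub("^f2", factor2, sub(":f2", paste0(":", factor2),
                                      out$term))
  rownames(out) <- NULL
  out
}
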