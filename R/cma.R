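# Composite-module discovery by genetic algorithm.
#
# The module score of a region under a motif subset is the maximum over
# sliding windows of width W of the sum, across members, of the best hit
# log-odds inside the window (0 for a member without a hit there). Fitness
# is the rank AUC separating yes-set from no-set module scores, minus a
# size penalty lambda * |members|.

# Per (pwm, region): vector over window starts s of the best hit score with
# start in [s, s + W - 1], 0 when none; padded with -Inf up to maxW.
.windowBestVector <- function(hits, seqLen, W, maxW) {
  nW <- max(1L, seqLen - W + 1L)
  v <- numeric(nW)
  if (nrow(hits)) {
    for (i in seq_len(nrow(hits))) {
      lo <- max(1L, hits$start[i] - W + 1L)
      hi <- min(nW, hits$start[i])
      if (lo <= hi) v[lo:hi] <- pmax(v[lo:hi], hits$score[i])
    }
  }
  if (nW < maxW) v <- c(v, rep(-Inf, maxW - nW))
  v
}

# Precompute, for every pwm, a (maxW x nRegions) matrix of window-best
# scores over the concatenated yes and no sets.
.cmaPrecompute <- function(yes, no, pwms, windowWidth, threshold) {
  regions <- c(yes, no)
  lens <- nchar(regions)
  maxW <- max(1L, max(lens) - windowWidth + 1L)
  mats <- lapply(names(pwms), function(pn) {
    th <- if (is.null(threshold)) NULL
          else if (length(threshold) > 1) threshold[[pn]] else threshold
    cols <- vapply(seq_along(regions), function(r) {
      h <- scanPwm(regions[[r]], pwms[[pn]], th)
      .windowBestVector(h, lens[r], windowWidth, maxW)
    }, numeric(maxW))
    matrix(cols, nrow = maxW)
  })
  names(mats) <- names(pwms)
  list(mats = mats, nYes = length(yes), nNo = length(no),
       regionNames = names(regions))
}

# Module scores of every region for a member subset (indices into mats).
.cmaModuleScores <- function(precomp, members) {
  M <- precomp$mats[[members[1]]]
  if (length(members) > 1)
    for (m in members[-1]) M <- M + precomp$mats[[m]]
  apply(M, 2, max)
}

.cmaFitness <- function(precomp, members, lambda) {
  s <- .cmaModuleScores(precomp, members)
  yes <- s[seq_len(precomp$nYes)]
  no <- s[precomp$nYes + seq_len(precomp$nNo)]
  .rankAuc(yes, no) - lambda * length(members)
}

#' Composite-module search by genetic algorithm
#'
#' Evolves motif subsets (at most \code{maxMembers} members) to maximize
#' the separation of yes-set from no-set module scores. Individuals are
#' selected by tournament, the best \code{elitism} survive unchanged, and
#' offspring mutate by adding, removing or swapping one member with
#' probability \code{mutationP}. The best individual ever seen is
#' returned. Deterministic under \code{seed}.
#'
#' @param yesRegions,noRegions named character vectors of sequences.
#' @param pwms named list of [PWMotif-class] (at least 2).
#' @param windowWidth sliding-window width in bp (default 200).
#' @param threshold scan threshold (see [scanRegions()]).
#' @param popSize,generations GA population size and generation count.
#' @param maxMembers maximum module size K.
#' @param elitism elite count carried over unchanged.
#' @param mutationP per-offspring mutation probability.
#' @param tournamentSize tournament size for parent selection.
#' @param lambda fitness penalty per member.
#' @param seed integer seed.
#' @return a [CompositeModule-class].
#' @export
cmaSearch <- function(yesRegions, noRegions, pwms, windowWidth = 200L,
                      threshold = NULL, popSize = 50L, generations = 100L,
                      maxMembers = 10L, elitism = 2L, mutationP = 0.3,
                      tournamentSize = 3L, lambda = 0.01, seed = 1L) {
  if (maxMembers < 1L) stop("maxMembers must be >= 1", call. = FALSE)
  if (length(pwms) < 2L) stop("library must hold at least 2 PWMs",
                              call. = FALSE)
  if (!length(yesRegions) || !length(noRegions))
    stop("both region sets must be non-empty", call. = FALSE)
  precomp <- .cmaPrecompute(yesRegions, noRegions, pwms, windowWidth,
                            threshold)
  nP <- length(pwms)
  K <- min(maxMembers, nP)
  memo <- new.env(parent = emptyenv())
  fitnessOf <- function(ind) {
    key <- paste(ind, collapse = ",")
    f <- memo[[key]]
    if (is.null(f)) {
      f <- .cmaFitness(precomp, names(pwms)[ind], lambda)
      memo[[key]] <- f
    }
    f
  }
  withr::with_seed(seed, {
    pop <- lapply(seq_len(popSize), function(i)
      sort(sample.int(nP, sample.int(K, 1L))))
    fits <- vapply(pop, fitnessOf, numeric(1))
    bestInd <- pop[[which.max(fits)]]
    bestFit <- max(fits)
    mutate <- function(ind) {
      ops <- c(if (length(ind) < K && length(ind) < nP) "add",
               if (length(ind) > 1L) "remove",
               if (length(ind) < nP) "swap")
      op <- if (length(ops) == 1L) ops else sample(ops, 1L)
      pool <- setdiff(seq_len(nP), ind)
      switch(op,
        add = sort(c(ind, pool[sample.int(length(pool), 1L)])),
        remove = sort(ind[-sample.int(length(ind), 1L)]),
        swap = sort(c(ind[-sample.int(length(ind), 1L)],
                      pool[sample.int(length(pool), 1L)])))
    }
    for (gen in seq_len(generations)) {
      ord <- order(fits, decreasing = TRUE)
      newPop <- pop[ord[seq_len(elitism)]]
      while (length(newPop) < popSize) {
        contenders <- sample.int(popSize, tournamentSize)
        parent <- pop[[contenders[which.max(fits[contenders])]]]
        child <- if (stats::runif(1) < mutationP) mutate(parent) else parent
        newPop[[length(newPop) + 1L]] <- child
      }
      pop <- newPop
      fits <- vapply(pop, fitnessOf, numeric(1))
      if (max(fits) > bestFit) {
        bestFit <- max(fits)
        bestInd <- pop[[which.max(fits)]]
      }
    }
    members <- names(pwms)[bestInd]
    s <- .cmaModuleScores(precomp, members)
    methods::new("CompositeModule", members = members,
                 windowWidth = as.numeric(windowWidth), fitness = bestFit,
                 scores = list(
                   yes = stats::setNames(s[seq_len(precomp$nYes)],
                                         names(yesRegions)),
                   no = stats::setNames(
                     s[precomp$nYes + seq_len(precomp$nNo)],
                     names(noRegions))))
  })
}

#' Score a fixed motif subset as a composite module
#'
#' Computes the per-sequence module scores and the AUC-based fitness of a
#' given member set without any search; useful for exhaustive enumeration
#' on small libraries.
#'
#' @inheritParams cmaSearch
#' @param members character vector of motif names (subset of
#'   \code{names(pwms)}).
#' @return a [CompositeModule-class].
#' @export
compositeModuleScore <- function(yesRegions, noRegions, pwms, members,
                                 windowWidth = 200L, threshold = NULL,
                                 lambda = 0.01) {
  stopifnot(all(members %in% names(pwms)))
  precomp <- .cmaPrecompute(yesRegions, noRegions, pwms, windowWidth,
                            threshold)
  s <- .cmaModuleScores(precomp, members)
  methods::new("CompositeModule", members = members,
               windowWidth = as.numeric(windowWidth),
               fitness = .cmaFitness(precomp, members, lambda),
               scores = list(
                 yes = stats::setNames(s[seq_len(precomp$nYes)],
                                       names(yesRegions)),
                 no = stats::setNames(s[precomp$nYes +
                                          seq_len(precomp$nNo)],
                                      names(noRegions))))
}
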