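# Master-regulator search over a directed signaling network.

.networkIgraph <- function(network) {
  e <- networkEdges(network)
  igraph::graph_from_data_frame(e[, c("source", "target")], directed = TRUE,
                                vertices = networkNodes(network))
}

#' Rank candidate master regulators upstream of enriched TFs
#'
#' For every non-TF node v, the enriched TFs reachable from v along directed
#' edges within \code{radius} steps are collected with their BFS distances
#' d; the node is scored as
#' \deqn{score(v) = \Big(\sum_{t} 1/d(v,t)\Big) \times |T_v| / |T|,}
#' rewarding both proximity and coverage of the TF set. Ties are broken by
#' smaller mean distance, then lexicographic node name.
#'
#' @param network a [SignalNetwork-class].
#' @param tfs enriched TF node names; unmapped names are dropped with a
#'   message.
#' @param radius maximum BFS distance (default 10).
#' @return data.frame ranked by score: node, score, n_reached, mean_dist,
#'   reached (comma-separated TFs).
#' @export
findMasterRegulators <- function(network, tfs, radius = 10L) {
  nodes <- networkNodes(network)
  mapped <- intersect(tfs, nodes)
  if (length(mapped) < length(tfs))
    message("dropping ", length(tfs) - length(mapped),
            " TF(s) not present in the network")
  if (!length(mapped)) stop("no TF maps to the network", call. = FALSE)
  g <- .networkIgraph(network)
  candidates <- setdiff(nodes, mapped)
  d <- igraph::distances(g, v = candidates, to = mapped, mode = "out")
  reached <- is.finite(d) & d >= 1 & d <= radius
  score <- rowSums(ifelse(reached, 1 / d, 0)) *
    rowSums(reached) / length(mapped)
  meanDist <- ifelse(rowSums(reached) > 0,
                     rowSums(ifelse(reached, d, 0)) / rowSums(reached),
                     Inf)
  out <- data.frame(node = candidates, score = as.numeric(score),
                    n_reached = as.integer(rowSums(reached)),
                    mean_dist = as.numeric(meanDist),
                    reached = vapply(seq_along(candidates), function(i)
                      paste(mapped[reached[i, ]], collapse = ","),
                      character(1)),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$score, out$mean_dist, out$node), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Detect a positive feedback loop through a differentially expressed gene
#'
#' A candidate master regulator closes a feedback loop when some TF it
#' reaches regulates a differentially expressed gene whose product is the
#' candidate itself.
#'
#' @param network a [SignalNetwork-class].
#' @param candidate node name of the candidate regulator.
#' @param tfs enriched TF node names.
#' @param degGenes character vector of differentially expressed genes.
#' @param geneProduct named vector: gene -> network node it encodes.
#' @param tfTargets data.frame with columns \code{tf}, \code{gene}: the
#'   TF-to-target regulation map.
#' @param radius BFS radius used to define the TFs the candidate reaches.
#' @return list with \code{feedback} (logical), and when TRUE
#'   \code{witness} (tf, gene) and \code{path} (candidate -> tf node
#'   sequence).
#' @export
flagFeedbackLoops <- function(network, candidate, tfs, degGenes,
                              geneProduct, tfTargets, radius = 10L) {
  if (is.null(geneProduct) || !length(geneProduct))
    stop("gene-to-product map is required", call. = FALSE)
  nodes <- networkNodes(network)
  if (!candidate %in% nodes)
    stop("candidate '", candidate, "' not in the network", call. = FALSE)
  g <- .networkIgraph(network)
  mapped <- intersect(tfs, nodes)
  d <- igraph::distances(g, v = candidate, to = mapped, mode = "out")[1, ]
  reachedTfs <- mapped[is.finite(d) & d >= 1 & d <= radius]
  encoding <- names(geneProduct)[geneProduct == candidate]
  hits <- tfTargets[tfTargets$tf %in% reachedTfs &
                      tfTargets$gene %in% intersect(encoding, degGenes), ,
                    drop = FALSE]
  if (!nrow(hits)) return(list(feedback = FALSE))
  t0 <- hits$tf[1]
  path <- igraph::shortest_paths(g, from = candidate, to = t0,
                                 mode = "out")$vpath[[1]]
  list(feedback = TRUE,
       witness = c(tf = t0, gene = hits$gene[1]),
       path = names(path))
}
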