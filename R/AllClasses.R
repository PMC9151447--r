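#' @import methods
NULL

#' Position weight matrix for a transcription factor binding motif
#'
#' Holds a pseudocount-regularized probability matrix (rows A, C, G, T; one
#' column per motif position) together with the background nucleotide
#' distribution used for log-odds scoring.
#'
#' @slot name motif name or accession.
#' @slot matrix 4 x L numeric matrix of per-position nucleotide probabilities;
#'   every column sums to 1.
#' @slot background length-4 numeric vector of background probabilities
#'   (default uniform 0.25).
#'
#' @seealso [readTransfacPwms()], [scanPwm()]
#' @export
setClass("PWMotif",
  representation(name = "character", matrix = "matrix",
                 background = "numeric"),
  prototype(background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)))

setValidity("PWMotif", function(object) {
  msg <- character()
  m <- object@matrix
  if (!identical(rownames(m), c("A", "C", "G", "T")))
    msg <- c(msg, "matrix rows must be A, C, G, T")
  if (ncol(m) < 4L)
    msg <- c(msg, "motif length must be >= 4")
  if (any(abs(colSums(m) - 1) > 1e-9))
    msg <- c(msg, "probability columns must sum to 1")
  if (length(object@background) != 4L ||
      abs(sum(object@background) - 1) > 1e-9)
    msg <- c(msg, "background must be 4 probabilities summing to 1")
  if (length(object@name) != 1L || !nzchar(object@name))
    msg <- c(msg, "name must be a non-empty string")
  if (length(msg)) msg else TRUE
})

#' Directed signaling network
#'
#' An edge list of typed, directed molecular interactions (SIF-like:
#' source, interaction type, target). Interaction types are one of
#' \code{activation}, \code{inhibition}, \code{unspecified}.
#'
#' @slot edges data.frame with columns \code{source}, \code{type},
#'   \code{target}; duplicate (source, type, target) triples are collapsed.
#'
#' @seealso [readNetwork()], [findMasterRegulators()]
#' @export
setClass("SignalNetwork", representation(edges = "data.frame"))

setValidity("SignalNetwork", function(object) {
  e <- object@edges
  msg <- character()
  if (!all(c("source", "type", "target") %in% names(e)))
    msg <- c(msg, "edges must have columns source, type, target")
  else {
    if (any(!nzchar(e$source)) || any(!nzchar(e$target)))
      msg <- c(msg, "node names must be non-empty")
    if (!all(e$type %in% c("activation", "inhibition", "unspecified")))
      msg <- c(msg, "interaction types must be activation/inhibition/unspecified")
  }
  if (length(msg)) msg else TRUE
})

#' Principal-component model of a genotype matrix
#'
#' Result of [computePrincipalComponents()]: sample scores, variant loadings
#' and eigenvalues of the normalized genotype matrix, plus the per-variant
#' centering/scaling needed to reproduce the projection.
#'
#' @slot scores n x k matrix of sample scores (rownames = sample ids).
#' @slot loadings m x k matrix of variant loadings (rownames = variant ids).
#' @slot eigenvalues non-increasing vector of length k.
#' @slot center,scale per-variant centering and scaling applied before
#'   decomposition (named by variant id).
#'
#' @seealso [assignAncestry()]
#' @export
setClass("AncestryPCA",
  representation(scores = "matrix", loadings = "matrix",
                 eigenvalues = "numeric", center = "numeric",
                 scale = "numeric"))

setValidity("AncestryPCA", function(object) {
  msg <- character()
  k <- ncol(object@scores)
  if (ncol(object@loadings) != k || length(object@eigenvalues) != k)
    msg <- c(msg, "scores, loadings and eigenvalues must agree on k")
  if (k > 1 && any(diff(object@eigenvalues) > 1e-8))
    msg <- c(msg, "eigenvalues must be non-increasing")
  if (is.null(rownames(object@scores)))
    msg <- c(msg, "scores must carry sample ids as rownames")
  if (length(msg)) msg else TRUE
})

#' Composite cis-regulatory module
#'
#' A set of motifs whose binding sites co-occur within a confined window of a
#' regulatory region, together with the fitness reached by the genetic
#' algorithm and the per-sequence module scores it induces.
#'
#' @slot members motif names in the module (at most \code{maxMembers}).
#' @slot windowWidth width in bp of the sliding co-occurrence window.
#' @slot fitness AUC-based fitness (separation of yes vs no sets minus a
#'   size penalty).
#' @slot scores list with numeric vectors \code{yes} and \code{no} of
#'   per-sequence module scores.
#'
#' @seealso [cmaSearch()]
#' @export
setClass("CompositeModule",
  representation(members = "character", windowWidth = "numeric",
                 fitness = "numeric", scores = "list"))

setValidity("CompositeModule", function(object) {
  msg <- character()
  if (length(object@members) < 1L)
    msg <- c(msg, "a module must have at least one member")
  if (!is.finite(object@fitness))
    msg <- c(msg, "fitness must be finite")
  if (!all(c("yes", "no") %in% names(object@scores)))
    msg <- c(msg, "scores must hold 'yes' and 'no' vectors")
  if (length(msg)) msg else TRUE
})

# ---- accessors ----

#' @describeIn PWMotif-class motif name
#' @param object a \code{PWMotif}
#' @export
setGeneric("pwmName", function(object) standardGeneric("pwmName"))

#' @export
setMethod("pwmName", "PWMotif", function(object) object@name)

#' @describeIn PWMotif-class 4 x L probability matrix
#' @export
setGeneric("pwmMatrix", function(object) standardGeneric("pwmMatrix"))

#' @export
setMethod("pwmMatrix", "PWMotif", function(object) object@matrix)

#' @describeIn PWMotif-class motif length in bp
#' @export
setGeneric("pwmLength", function(object) standardGeneric("pwmLength"))

#' @export
setMethod("pwmLength", "PWMotif", function(object) ncol(object@matrix))

#' @describeIn SignalNetwork-class edge table (source, type, target)
#' @param object a \code{SignalNetwork}
#' @export
setGeneric("networkEdges", function(object) standardGeneric("networkEdges"))

#' @export
setMethod("networkEdges", "SignalNetwork", function(object) object@edges)

#' @describeIn SignalNetwork-class all node names (sorted, unique)
#' @export
setGeneric("networkNodes", function(object) standardGeneric("networkNodes"))

#' @export
setMethod("networkNodes", "SignalNetwork", function(object)
  sort(unique(c(object@edges$source, object@edges$target))))

#' @describeIn AncestryPCA-class sample score matrix
#' @param object an \code{AncestryPCA}
#' @export
setGeneric("pcaScores", function(object) standardGeneric("pcaScores"))

#' @export
setMethod("pcaScores", "AncestryPCA", function(object) object@scores)

#' @describeIn AncestryPCA-class eigenvalues (non-increasing)
#' @export
setGeneric("pcaEigenvalues", function(object) standardGeneric("pcaEigenvalues"))

#' @export
setMethod("pcaEigenvalues", "AncestryPCA", function(object) object@eigenvalues)

#' @describeIn AncestryPCA-class variant loading matrix
#' @export
setGeneric("pcaLoadings", function(object) standardGeneric("pcaLoadings"))

#' @export
setMethod("pcaLoadings", "AncestryPCA", function(object) object@loadings)

#' @describeIn CompositeModule-class member motif names
#' @param object a \code{CompositeModule}
#' @export
setGeneric("moduleMembers", function(object) standardGeneric("moduleMembers"))

#' @export
setMethod("moduleMembers", "CompositeModule", function(object) object@members)

#' @describeIn CompositeModule-class fitness of the module
#' @export
setGeneric("moduleFitness", function(object) standardGeneric("moduleFitness"))

#' @export
setMethod("moduleFitness", "CompositeModule", function(object) object@fitness)

#' @describeIn CompositeModule-class per-sequence module scores
#' @export
setGeneric("moduleScores", function(object) standardGeneric("moduleScores"))

#' @export
setMethod("moduleScores", "CompositeModule", function(object) object@scores)

# ---- show methods ----

setMethod("show", "PWMotif", function(object) {
  cat("PWMotif", object@name, "(", ncol(object@matrix), "bp )\n")
  cat("  consensus:", pwmConsensus(object), "\n")
})

setMethod("show", "SignalNetwork", function(object) {
  cat("SignalNetwork with", nrow(object@edges), "edges over",
      length(networkNodes(object)), "nodes\n")
})

setMethod("show", "AncestryPCA", function(object) {
  cat("AncestryPCA:", nrow(object@scores), "samples,",
      ncol(object@scores), "components\n")
  ev <- object@eigenvalues
  cat("  leading eigenvalues:",
      paste(signif(utils::head(ev, 3), 4), collapse = ", "), "\n")
})

setMethod("show", "CompositeModule", function(object) {
  cat("CompositeModule of", length(object@members), "motifs",
      "(window", object@windowWidth, "bp, fitness",
      signif(object@fitness, 4), ")\n")
  cat("  members:", paste(object@members, collapse = ", "), "\n")
})
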