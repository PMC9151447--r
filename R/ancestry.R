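#' EIGENSTRAT-style genotype normalization
#'
#' Per variant j: missing dosages are mean-imputed, the column mean
#' \eqn{\mu_j} is subtracted, and values are divided by
#' \eqn{\sqrt{p_j(1-p_j)}} with the smoothed allele frequency
#' \eqn{p_j = (1 + \sum_i g_{ij}) / (2 + 2n)}. Zero-variance columns are
#' dropped with a message.
#'
#' @param dosages samples x variants matrix with values 0/1/2 (NA allowed).
#' @return list with \code{matrix} (normalized), \code{dropped} (variant ids
#'   removed), \code{center} and \code{scale} (per retained variant).
#' @export
eigenstratNormalize <- function(dosages) {
  if (nrow(dosages) < 2L || ncol(dosages) < 2L)
    stop("need at least 2 samples and 2 variants", call. = FALSE)
  bad <- !(dosages %in% c(0, 1, 2) | is.na(dosages))
  if (any(bad)) stop("dosages must be 0, 1, 2 or missing", call. = FALSE)
  g <- dosages
  for (j in seq_len(ncol(g))) {
    miss <- is.na(g[, j])
    if (any(miss)) g[miss, j] <- mean(g[!miss, j])
  }
  n <- nrow(g)
  keep <- apply(g, 2, stats::var) > 0
  dropped <- colnames(g)[!keep]
  if (length(dropped))
    message("dropping ", length(dropped), " zero-variance variant(s)")
  g <- g[, keep, drop = FALSE]
  if (ncol(g) == 0L) stop("all variants dropped", call. = FALSE)
  mu <- colMeans(g)
  p <- (1 + colSums(g)) / (2 + 2 * n)
  sc <- sqrt(p * (1 - p))
  norm <- sweep(sweep(g, 2, mu), 2, sc, "/")
  list(matrix = norm, dropped = dropped, center = mu, scale = sc)
}

#' Principal components of a normalized genotype matrix
#'
#' Top-k components by eigenvalue of the sample covariance of the normalized
#' matrix, computed by singular value decomposition. Sign convention: within
#' each component the largest-magnitude loading is positive.
#'
#' @param normalized samples x variants normalized matrix (output
#'   \code{matrix} of [eigenstratNormalize()]).
#' @param k number of components (default 10, capped at the matrix rank
#'   bound).
#' @param center,scale optional per-variant centering/scaling to store for
#'   later projection.
#' @return an [AncestryPCA-class].
#' @export
computePrincipalComponents <- function(normalized, k = 10L,
                                       center = NULL, scale = NULL) {
  if (k < 1L) stop("k must be >= 1", call. = FALSE)
  k <- min(k, nrow(normalized), ncol(normalized))
  sv <- svd(normalized, nu = k, nv = k)
  # fix signs: largest-magnitude loading positive
  for (j in seq_len(k)) {
    i <- which.max(abs(sv$v[, j]))
    if (sv$v[i, j] < 0) {
      sv$v[, j] <- -sv$v[, j]
      sv$u[, j] <- -sv$u[, j]
    }
  }
  scores <- sv$u %*% diag(sv$d[seq_len(k)], k, k)
  dimnames(scores) <- list(rownames(normalized), paste0("PC", seq_len(k)))
  loadings <- sv$v
  dimnames(loadings) <- list(colnames(normalized), paste0("PC", seq_len(k)))
  ev <- sv$d[seq_len(k)]^2 / (nrow(normalized) - 1)
  if (is.null(center)) center <- stats::setNames(rep(0, ncol(normalized)),
                                                 colnames(normalized))
  if (is.null(scale)) scale <- stats::setNames(rep(1, ncol(normalized)),
                                               colnames(normalized))
  methods::new("AncestryPCA", scores = scores, loadings = loadings,
               eigenvalues = ev, center = center, scale = scale)
}

#' Assign ancestry by nearest reference centroid on PC1-PC3
#'
#' Reference samples (those named in \code{referenceLabels}) define one
#' centroid per label as the mean of their scores on the first three
#' principal components; every remaining sample in the model is assigned to
#' the label of the nearest centroid by Euclidean distance on PC1-PC3.
#' Reference and query samples must have been co-embedded in the same PCA.
#' Exact ties are broken lexicographically and flagged.
#'
#' @param model an [AncestryPCA-class] embedding reference and query samples.
#' @param referenceLabels named character vector: sample id -> ancestry
#'   label.
#' @return data.frame with sample_id, predicted, tie flag, and one
#'   \code{dist_<label>} column per reference label.
#' @export
assignAncestry <- function(model, referenceLabels) {
  sc <- pcaScores(model)
  if (ncol(sc) < 3L) stop("model must hold at least 3 components",
                          call. = FALSE)
  sc3 <- sc[, 1:3, drop = FALSE]
  refIds <- intersect(names(referenceLabels), rownames(sc3))
  labels <- sort(unique(referenceLabels[refIds]))
  if (!length(refIds)) stop("no reference sample found in the model",
                            call. = FALSE)
  centroids <- t(vapply(labels, function(l) {
    ids <- refIds[referenceLabels[refIds] == l]
    if (!length(ids)) stop("label '", l, "' has no reference samples",
                           call. = FALSE)
    colMeans(sc3[ids, , drop = FALSE])
  }, numeric(3)))
  queries <- setdiff(rownames(sc3), refIds)
  d <- vapply(labels, function(l)
    sqrt(rowSums(sweep(sc3[queries, , drop = FALSE], 2,
                       centroids[l, ])^2)),
    numeric(length(queries)))
  d <- matrix(d, nrow = length(queries),
              dimnames = list(queries, labels))
  best <- apply(d, 1, function(x) which(x == min(x)))
  predicted <- labels[vapply(best, `[`, 1L, 1L)]   # lexicographic tie-break
  tie <- lengths(best) > 1L
  out <- data.frame(sample_id = queries, predicted = predicted, tie = tie,
                    stringsAsFactors = FALSE)
  dd <- as.data.frame(d)
  names(dd) <- paste0("dist_", labels)
  cbind(out, dd, row.names = NULL)
}

#' Concordance between predicted and self-reported ancestry
#'
#' @param calls output of [assignAncestry()].
#' @param selfReported named character vector: sample id -> self-reported
#'   label; samples without a self-report are ignored.
#' @return fraction of compared samples whose prediction matches.
#' @export
concordanceRate <- function(calls, selfReported) {
  ids <- intersect(calls$sample_id, names(selfReported))
  ids <- ids[!is.na(selfReported[ids])]
  if (!length(ids)) stop("no overlapping sample with a self-report",
                         call. = FALSE)
  pred <- calls$predicted[match(ids, calls$sample_id)]
  mean(pred == selfReported[ids])
}

#' One-call ancestry pipeline
#'
#' Normalizes a combined reference+query dosage matrix, computes principal
#' components, and assigns every unlabeled sample to the nearest reference
#' centroid.
#'
#' @param dosages samples x variants dosage matrix holding reference and
#'   query samples.
#' @param referenceLabels named character vector over the reference samples.
#' @param k components to compute (distance always uses PC1-PC3).
#' @return list with \code{calls} (see [assignAncestry()]) and \code{model}.
#' @export
inferAncestry <- function(dosages, referenceLabels, k = 10L) {
  norm <- eigenstratNormalize(dosages)
  model <- computePrincipalComponents(norm$matrix, k = max(k, 3L),
                                      center = norm$center,
                                      scale = norm$scale)
  list(calls = assignAncestry(model, referenceLabels), model = model)
}
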