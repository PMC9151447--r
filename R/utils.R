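# Internal helpers shared across modules.

# Encode an ACGTN string as integer codes 1..4 (NA for N).
.encodeDna <- function(seq) {
  codes <- match(strsplit(toupper(seq), "")[[1]], c("A", "C", "G", "T"))
  codes
}

.revcompDna <- function(seq) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(toupper(seq), "")[[1]]),
                                 collapse = ""))
}

# Consensus (argmax base per position) of a PWMotif.
pwmConsensus <- function(pwm) {
  m <- pwm@matrix
  paste(rownames(m)[apply(m, 2, which.max)], collapse = "")
}

.assertProb <- function(p, what = "p") {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop(what, " values must lie in [0, 1]", call. = FALSE)
  invisible(p)
}

# Per-feature ordinary least squares across many response rows sharing one
# design matrix. Returns coefficient, se, t and p for a single named
# coefficient. Errors on a rank-deficient design, naming aliased columns.
.rowwiseOls <- function(Y, design, coefName) {
  stopifnot(is.matrix(Y), nrow(design) == ncol(Y))
  qrX <- qr(design)
  if (qrX$rank < ncol(design)) {
    aliased <- colnames(design)[qrX$pivot[-seq_len(qrX$rank)]]
    stop("design is rank deficient; aliased columns: ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }
  n <- nrow(design); p <- ncol(design)
  B <- qr.coef(qrX, t(Y))                       # p x features
  fitted <- design %*% B
  res <- t(Y) - fitted
  df <- n - p
  if (df < 1) stop("not enough residual degrees of freedom", call. = FALSE)
  sigma2 <- colSums(res^2) / df
  XtXinv <- chol2inv(qr.R(qrX))
  dimnames(XtXinv) <- list(colnames(design), colnames(design))
  j <- match(coefName, colnames(design))
  if (is.na(j)) stop("coefficient '", coefName, "' not in design",
                     call. = FALSE)
  beta <- B[j, ]
  se <- sqrt(sigma2 * XtXinv[j, j])
  tstat <- beta / se
  pval <- 2 * stats::pt(-abs(tstat), df)
  data.frame(feature = rownames(Y), estimate = as.numeric(beta),
             se = as.numeric(se), t = as.numeric(tstat),
             p = as.numeric(pval), row.names = NULL,
             stringsAsFactors = FALSE)
}

# Rank-based AUC of scores in `pos` versus `neg` (probability that a random
# positive outranks a random negative, ties counted half).
.rankAuc <- function(pos, neg) {
  r <- rank(c(pos, neg))
  nP <- length(pos); nN <- length(neg)
  (sum(r[seq_len(nP)]) - nP * (nP + 1) / 2) / (nP * nN)
}

.writeTsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.writeMatrixTsv <- function(m, path, idCol = "id") {
  df <- data.frame(id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- idCol
  .writeTsv(df, path)
}

.readMatrixTsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
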