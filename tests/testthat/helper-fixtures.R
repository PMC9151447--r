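# Programmatic fixtures shared across test files.

makeToyMaf <- function(sample, chrom, pos, ref, alt,
                       gene = "GENE1", class = "Missense_Mutation") {
  n <- max(length(sample), length(pos))
  data.frame(Hugo_Symbol = rep_len(gene, n),
             Tumor_Sample_Barcode = rep_len(sample, n),
             Chromosome = rep_len(chrom, n),
             Start_Position = rep_len(pos, n),
             Reference_Allele = rep_len(ref, n),
             Tumor_Seq_Allele2 = rep_len(alt, n),
             Variant_Classification = rep_len(class, n),
             stringsAsFactors = FALSE)
}

writeMafFixture <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# Sharp motif from a consensus string: dominant base gets `weight` counts,
# the rest 1 each.
consensusPwm <- function(name, consensus, weight = 50) {
  bases <- strsplit(consensus, "")[[1]]
  counts <- matrix(1, 4, length(bases),
                   dimnames = list(c("A", "C", "G", "T"), NULL))
  counts[cbind(match(bases, c("A", "C", "G", "T")),
               seq_along(bases))] <- weight
  pwMotif(name, counts)
}

# Naive per-position log-odds scores of both strands: the brute-force
# oracle against which the vectorized scanner is checked.
bruteForceScan <- function(sequence, pwm, threshold) {
  m <- pwmMatrix(pwm)
  bg <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
  L <- ncol(m)
  scoreAt <- function(seq, i) {
    s <- 0
    for (j in seq_len(L)) {
      b <- substr(seq, i + j - 1, i + j - 1)
      if (!b %in% names(bg)) return(-Inf)
      s <- s + log2(m[b, j] / bg[b])
    }
    s
  }
  rc <- chartr("ACGT", "TGCA",
               paste(rev(strsplit(sequence, "")[[1]]), collapse = ""))
  n <- nchar(sequence)
  hits <- NULL
  for (i in seq_len(n - L + 1)) {
    sF <- scoreAt(sequence, i)
    if (sF >= threshold)
      hits <- rbind(hits, data.frame(start = i, strand = "+", score = sF))
    sR <- scoreAt(rc, i)
    if (sR >= threshold)
      hits <- rbind(hits, data.frame(start = n - (i + L - 1) + 1,
                                     strand = "-", score = sR))
  }
  hits
}

# Breadth-first distances from one node over a directed edge list: the
# independent oracle for the igraph-backed master-regulator search.
bfsDistances <- function(edges, from, nodes) {
  adj <- split(edges$target, edges$source)
  d <- setNames(rep(Inf, length(nodes)), nodes)
  d[from] <- 0
  queue <- from
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    for (w in adj[[v]]) {
      if (d[w] == Inf) {
        d[w] <- d[v] + 1
        queue <- c(queue, w)
      }
    }
  }
  d
}

# Step-up BH from first principles (sorted thresholds), for small m.
bruteForceBH <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    rankI <- which(ord == i)
    cand <- vapply(rankI:m, function(k) min(1, m * p[ord[k]] / k),
                   numeric(1))
    q[i] <- min(cand)
  }
  q
}
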