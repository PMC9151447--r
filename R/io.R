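#' Read a mutation annotation format (MAF) table
#'
#' Parses a tab-separated MAF file. Column order does not matter; columns
#' beyond the mandatory set are preserved untouched. Positions are 1-based
#' inclusive.
#'
#' @param path path to a tab-separated file whose header contains at least
#'   \code{Hugo_Symbol}, \code{Tumor_Sample_Barcode}, \code{Chromosome},
#'   \code{Start_Position}, \code{Reference_Allele},
#'   \code{Tumor_Seq_Allele2}, \code{Variant_Classification}.
#' @param caller caller tag to attach to every record; one of
#'   \code{"MuSe"}, \code{"MuTect2"}, \code{"SomaticSniper"},
#'   \code{"VarScan2"}, \code{"other"}. When the file itself carries a
#'   \code{caller} column it takes precedence.
#'
#' @return data.frame of MAF records with a \code{caller} column; extra input
#'   columns are retained.
#' @export
readMaf <- function(path, caller = "other") {
  mandatory <- c("Hugo_Symbol", "Tumor_Sample_Barcode", "Chromosome",
                 "Start_Position", "Reference_Allele", "Tumor_Seq_Allele2",
                 "Variant_Classification")
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE,
                          colClasses = "character", comment.char = "#")
  missing <- setdiff(mandatory, names(df))
  if (length(missing))
    stop("MAF file ", path, " lacks mandatory column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  pos <- suppressWarnings(as.numeric(df$Start_Position))
  bad <- which(is.na(pos) | pos < 1 | pos != round(pos))
  if (length(bad))
    stop("unparsable Start_Position at data line ", bad[1],
         " of ", path, call. = FALSE)
  df$Start_Position <- as.integer(pos)
  if (any(df$Reference_Allele == df$Tumor_Seq_Allele2))
    stop("MAF record with identical ref and alt allele in ", path,
         call. = FALSE)
  if (!"caller" %in% names(df)) df$caller <- caller
  df
}

#' Write a MAF table
#'
#' @param maf data.frame as returned by [readMaf()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeMaf <- function(maf, path) {
  .writeTsv(maf, path)
  invisible(path)
}

#' Read TRANSFAC-format position weight matrices
#'
#' Parses TRANSFAC-style blocks: an \code{ID} (or \code{NA}) line naming the
#' motif, a \code{P0 A C G T} header, numbered count rows, and a terminating
#' \code{//}. Counts are converted to probabilities with a pseudocount of
#' 0.01 added to every cell.
#'
#' @param path path to the matrix file.
#' @param pseudocount per-cell pseudocount (default 0.01).
#' @param background background nucleotide distribution for scoring
#'   (default uniform).
#' @return list of [PWMotif-class] objects in file order, named by motif.
#' @export
readTransfacPwms <- function(path, pseudocount = 0.01,
                             background = rep(0.25, 4)) {
  lines <- readLines(path)
  pwms <- list()
  name <- NULL
  counts <- NULL
  for (ln in lines) {
    ln <- trimws(ln)
    if (!nzchar(ln)) next
    tag <- sub("^(\\S+).*$", "\\1", ln)
    if (tag %in% c("ID", "NA") && is.null(counts)) {
      name <- trimws(sub("^\\S+\\s*", "", ln))
    } else if (tag == "P0" || tag == "PO") {
      counts <- list()
    } else if (grepl("^[0-9]+$", tag) && !is.null(counts)) {
      fields <- strsplit(ln, "\\s+")[[1]]
      vals <- suppressWarnings(as.numeric(fields[2:5]))
      if (any(is.na(vals)))
        stop("unparsable count row '", ln, "' in ", path, call. = FALSE)
      counts[[length(counts) + 1L]] <- vals
    } else if (tag == "//") {
      if (!is.null(counts)) {
        pwms[[length(pwms) + 1L]] <-
          .countsToPwm(name, counts, pseudocount, background)
        name <- NULL; counts <- NULL
      }
    }
  }
  if (!is.null(counts))
    pwms[[length(pwms) + 1L]] <-
      .countsToPwm(name, counts, pseudocount, background)
  names(pwms) <- vapply(pwms, pwmName, character(1))
  pwms
}

.countsToPwm <- function(name, countRows, pseudocount, background) {
  if (is.null(name) || !nzchar(name)) name <- "unnamed"
  m <- do.call(cbind, lapply(seq_along(countRows), function(i) {
    cts <- countRows[[i]]
    tot <- sum(cts)
    if (!is.finite(tot) || tot + 4 * pseudocount <= 0)
      stop("matrix column ", i, " of motif ", name,
           " does not sum to a positive total", call. = FALSE)
    (cts + pseudocount) / (tot + 4 * pseudocount)
  }))
  rownames(m) <- c("A", "C", "G", "T")
  bg <- background / sum(background)
  names(bg) <- c("A", "C", "G", "T")
  methods::new("PWMotif", name = name, matrix = m, background = bg)
}

#' Construct a PWMotif from a count or probability matrix
#'
#' @param name motif name.
#' @param counts 4 x L matrix (rows A, C, G, T) of counts or probabilities.
#' @param pseudocount per-cell pseudocount applied before normalization.
#' @param background background distribution.
#' @return a [PWMotif-class].
#' @export
pwMotif <- function(name, counts, pseudocount = 0.01,
                    background = rep(0.25, 4)) {
  .countsToPwm(name, lapply(seq_len(ncol(counts)), function(j) counts[, j]),
               pseudocount, background)
}

#' Read promoter sequences from FASTA
#'
#' Sequences are uppercased and must use the alphabet ACGTN only.
#'
#' @param path FASTA file.
#' @return named character vector of sequences, in file order.
#' @export
readFastaSequences <- function(path) {
  set <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(set))
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad))
    stop("non-nucleotide character in FASTA record '",
         names(seqs)[which(bad)[1]], "'", call. = FALSE)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeFastaSequences <- function(seqs, path) {
  set <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read a directed signaling network from a SIF-like edge list
#'
#' Each line is \code{source <tab> type <tab> target}. Duplicate edges with
#' the same type are collapsed; an edge pair with conflicting types is
#' retained with a warning.
#'
#' @param path edge-list file.
#' @return a [SignalNetwork-class].
#' @export
readNetwork <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t")
  bad <- which(lengths(parts) != 3L)
  if (length(bad))
    stop("network line ", bad[1], " does not have 3 tab-separated fields",
         call. = FALSE)
  e <- data.frame(source = vapply(parts, `[`, "", 1L),
                  type = vapply(parts, `[`, "", 2L),
                  target = vapply(parts, `[`, "", 3L),
                  stringsAsFactors = FALSE)
  signalNetwork(e)
}

#' Construct a SignalNetwork from an edge table
#'
#' @param edges data.frame with columns \code{source}, \code{type},
#'   \code{target}.
#' @return a [SignalNetwork-class]; exact duplicate edges are collapsed, and
#'   a warning reports node pairs connected by conflicting interaction types.
#' @export
signalNetwork <- function(edges) {
  edges$type[!edges$type %in% c("activation", "inhibition", "unspecified")] <-
    "unspecified"
  dup <- duplicated(edges[, c("source", "type", "target")])
  edges <- edges[!dup, , drop = FALSE]
  key <- paste(edges$source, edges$target)
  conf <- unique(key[duplicated(key)])
  if (length(conf))
    warning("conflicting interaction types retained for: ",
            paste(conf, collapse = "; "), call. = FALSE)
  rownames(edges) <- NULL
  methods::new("SignalNetwork", edges = edges)
}

#' Write a SignalNetwork as a SIF-like edge list
#'
#' @param network a [SignalNetwork-class].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeNetwork <- function(network, path) {
  e <- networkEdges(network)
  writeLines(paste(e$source, e$type, e$target, sep = "\t"), path)
  invisible(path)
}

#' Read GMT-like gene sets
#'
#' Each line: set name, description, then member genes, tab-separated.
#'
#' @param path GMT file.
#' @return named list of character vectors.
#' @export
readGmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t")
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[`, "", 1L)
  sets
}

#' Write GMT-like gene sets
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @param description description field (recycled).
#' @return the path, invisibly.
#' @export
writeGmt <- function(sets, path, description = "na") {
  writeLines(vapply(names(sets), function(nm)
    paste(c(nm, description, sets[[nm]]), collapse = "\t"), character(1)),
    path)
  invisible(path)
}

#' Read / write a numeric matrix with row ids in the first column
#'
#' @param path TSV path.
#' @return matrix with rownames from the first column.
#' @export
readTsvMatrix <- function(path) .readMatrixTsv(path)

#' @rdname readTsvMatrix
#' @param m numeric matrix with rownames.
#' @param idCol header for the id column.
#' @export
writeTsvMatrix <- function(m, path, idCol = "id") .writeMatrixTsv(m, path, idCol)

#' Convert BED-like (0-based half-open) to 1-based inclusive coordinates
#'
#' @param start,end BED start/end vectors.
#' @return data.frame with 1-based inclusive \code{start}, \code{end}.
#' @export
bedToOneBased <- function(start, end) {
  data.frame(start = start + 1L, end = end)
}

#' @rdname bedToOneBased
#' @export
oneBasedToBed <- function(start, end) {
  data.frame(start = start - 1L, end = end)
}
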