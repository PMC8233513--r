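# Alignments and site-pattern compression.
#
# An alignment is a plain character matrix (taxa x columns, uppercase) with
# an `alphabet` attribute, "nucleotide" or "codon".  Codon alignments keep
# the nucleotide matrix; codon columns are triplets.

NUC <- c("A", "C", "G", "T")

# IUPAC ambiguity codes -> partial-likelihood rows over (A, C, G, T).
# Gaps and '?' are treated as fully missing by default.
IUPAC_PARTIALS <- local({
  m <- rbind(
    A = c(1, 0, 0, 0), C = c(0, 1, 0, 0), G = c(0, 0, 1, 0), T = c(0, 0, 0, 1),
    U = c(0, 0, 0, 1),
    R = c(1, 0, 1, 0), Y = c(0, 1, 0, 1), S = c(0, 1, 1, 0), W = c(1, 0, 0, 1),
    K = c(0, 0, 1, 1), M = c(1, 1, 0, 0),
    B = c(0, 1, 1, 1), D = c(1, 0, 1, 1), H = c(1, 1, 0, 1), V = c(1, 1, 1, 0),
    N = c(1, 1, 1, 1), `-` = c(1, 1, 1, 1), `?` = c(1, 1, 1, 1),
    X = c(1, 1, 1, 1))
  colnames(m) <- NUC
  m
})

new_alignment <- function(mat, alphabet = c("nucleotide", "codon")) {
  alphabet <- match.arg(alphabet)
  stopifnot(is.matrix(mat), !is.null(rownames(mat)))
  mat[] <- toupper(mat)
  if (alphabet == "codon" && ncol(mat) %% 3 != 0)
    stop(sprintf("codon alignment length %d is not divisible by 3", ncol(mat)))
  structure(mat, alphabet = alphabet, class = c("seq_alignment", "matrix"))
}

#' @export
print.seq_alignment <- function(x, ...) {
  cat(sprintf("<seq_alignment> %d taxa x %d columns (%s)\n",
              nrow(x), ncol(x), attr(x, "alphabet")))
  invisible(x)
}

aln_alphabet <- function(aln) attr(aln, "alphabet")

#' Number of alignment units (nucleotide columns or codons)
#' @export
n_units <- function(aln) {
  if (aln_alphabet(aln) == "codon") ncol(aln) %/% 3L else ncol(aln)
}

#' Read a multiple sequence alignment
#'
#' Reads FASTA (via \pkg{Biostrings}, which preserves arbitrary characters)
#' or relaxed sequential PHYLIP.  Characters are upper-cased; anything
#' outside the IUPAC nucleotide set becomes fully ambiguous (`N`).  In codon
#' mode the length must be a multiple of 3 and in-frame stop codons are
#' rejected (the offending taxon and codon are named).
#'
#' @param path file path.
#' @param format `"fasta"` or `"phylip"` (relaxed sequential).
#' @param alphabet `"nucleotide"` or `"codon"`.
#' @return a `seq_alignment`.
#' @export
read_alignment <- function(path, format = c("fasta", "phylip"),
                           alphabet = c("nucleotide", "codon")) {
  format <- match.arg(format)
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  seqs <- if (format == "fasta") {
    x <- Biostrings::readBStringSet(path)
    stats::setNames(as.character(x), sub("\\s.*$", "", names(x)))
  } else {
    read_relaxed_phylip(path)
  }
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L)
    stop(sprintf("ragged alignment: sequence lengths %s",
                 paste(sort(unique(lens)), collapse = ", ")))
  if (anyDuplicated(names(seqs)))
    stop("duplicate sequence names")
  mat <- do.call(rbind, strsplit(toupper(seqs), ""))
  rownames(mat) <- names(seqs)
  unknown <- !(mat %in% rownames(IUPAC_PARTIALS))
  if (any(unknown)) mat[unknown] <- "N"
  aln <- new_alignment(mat, alphabet)
  if (alphabet == "codon") check_stop_codons(aln)
  aln
}

# relaxed sequential PHYLIP: header "ntax nchar", then one name + sequence
# per record, the sequence possibly wrapped over several lines
read_relaxed_phylip <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(hdr) < 2L || anyNA(suppressWarnings(as.integer(hdr[1:2]))))
    stop("malformed PHYLIP header (expected 'ntaxa nchar')")
  ntax <- as.integer(hdr[1]); nchar_exp <- as.integer(hdr[2])
  seqs <- character(0)
  i <- 2L
  while (length(seqs) < ntax && i <= length(lines)) {
    tok <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    nm <- tok[1]
    s <- paste(tok[-1], collapse = "")
    i <- i + 1L
    while (nchar(s) < nchar_exp && i <= length(lines)) {
      s <- paste0(s, gsub("\\s+", "", lines[i]))
      i <- i + 1L
    }
    seqs[nm] <- s
  }
  if (length(seqs) != ntax)
    stop(sprintf("PHYLIP file declares %d taxa but %d were read",
                 ntax, length(seqs)))
  seqs
}

#' Write an alignment to FASTA or relaxed sequential PHYLIP
#' @export
write_alignment <- function(aln, path, format = c("fasta", "phylip")) {
  format <- match.arg(format)
  seqs <- apply(aln, 1, paste, collapse = "")
  lines <- if (format == "fasta") {
    as.vector(rbind(paste0(">", rownames(aln)), seqs))
  } else {
    c(sprintf("%d %d", nrow(aln), ncol(aln)),
      paste(rownames(aln), seqs, sep = "  "))
  }
  writeLines(lines, path)
  invisible(path)
}

check_stop_codons <- function(aln) {
  stops <- c("TAA", "TAG", "TGA")
  nc <- ncol(aln) %/% 3L
  for (i in seq_len(nrow(aln))) {
    cod <- codon_strings(aln[i, ])
    bad <- which(cod %in% stops)
    if (length(bad))
      stop(sprintf("in-frame stop codon %s in taxon '%s' at codon %d",
                   cod[bad[1]], rownames(aln)[i], bad[1]))
  }
  invisible(aln)
}

codon_strings <- function(chars) {
  n <- length(chars) %/% 3L
  paste0(chars[3 * seq_len(n) - 2], chars[3 * seq_len(n) - 1],
         chars[3 * seq_len(n)])
}

#' Compress an alignment into unique site patterns
#'
#' The pattern unit is one column for nucleotide alignments and one codon for
#' codon alignments.  Likelihoods computed over patterns weighted by their
#' multiplicities equal likelihoods over raw columns.
#'
#' @param aln a `seq_alignment`.
#' @param gap `"missing"` keeps gapped columns as fully ambiguous states;
#'   `"strict"` drops any column (codon) containing a gap character.
#' @return a list with `patterns` (taxa x n_patterns character matrix of
#'   pattern units), `counts`, `index` (unit -> pattern), `taxa`, `alphabet`.
#' @export
compress_patterns <- function(aln, gap = c("missing", "strict")) {
  gap <- match.arg(gap)
  if (ncol(aln) == 0L) stop("empty alignment")
  alphabet <- aln_alphabet(aln)
  units <- if (alphabet == "codon") {
    apply(aln, 1, codon_strings)  # n_codons x taxa
  } else {
    t(unclass(aln))
  }
  if (gap == "strict") {
    has_gap <- apply(units, 1, function(u) any(grepl("[-?N]", u)))
    units <- units[!has_gap, , drop = FALSE]
    if (nrow(units) == 0L) stop("no columns left after strict gap filtering")
  }
  key <- apply(units, 1, paste, collapse = "\r")
  idx <- match(key, unique(key))
  first <- !duplicated(key)
  pat <- t(units[first, , drop = FALSE])
  rownames(pat) <- rownames(aln)
  list(patterns = pat,
       counts = as.integer(tabulate(idx, max(idx))),
       index = idx,
       taxa = rownames(aln),
       alphabet = alphabet)
}

#' Observed base frequencies of an alignment (ambiguity ignored)
#'
#' Bases absent from the data are floored at 1e-6 (and the vector
#' renormalized) so downstream reversible-model algebra stays finite.
#' @export
base_frequencies <- function(aln) {
  tab <- table(factor(unclass(aln)[unclass(aln) %in% NUC], levels = NUC))
  p <- as.numeric(tab)
  if (sum(p) == 0) stop("alignment has no unambiguous bases")
  p <- pmax(p / sum(p), 1e-6)
  stats::setNames(p / sum(p), NUC)
}
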