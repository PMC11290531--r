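#' Read a DNA alignment
#'
#' Reads FASTA or relaxed sequential PHYLIP into an `ape::DNAbin` matrix.
#' Sequences must all have the same length; gaps (`-`), `N`/`?` and IUPAC
#' ambiguity codes are allowed and are treated as partially observed states by
#' the likelihood machinery.
#'
#' @param file path to the alignment.
#' @param format `"fasta"` or `"phylip"` (guessed from the first character
#'   when `"auto"`).
#' @return a `DNAbin` matrix (taxa x sites).
#' @export
read_alignment <- function(file, format = c("auto", "fasta", "phylip")) {
  format <- match.arg(format)
  if (format == "auto") {
    first <- substr(readLines(file, n = 1L), 1, 1)
    format <- if (first == ">") "fasta" else "phylip"
  }
  aln <- switch(format,
    fasta = ape::read.FASTA(file),
    phylip = ape::read.dna(file, format = "sequential"))
  aln <- as.matrix(aln)
  if (is.null(rownames(aln))) stop("alignment has no taxon names")
  if (anyDuplicated(rownames(aln))) stop("duplicate taxon names in alignment")
  aln
}

#' Write an alignment to FASTA
#' @param aln `DNAbin` matrix.
#' @param file output path.
#' @export
write_alignment <- function(aln, file) {
  ape::write.FASTA(aln, file)
}

#' Compress alignment columns into unique site patterns
#'
#' Restricts the alignment to `taxa` and collapses identical columns into
#' weighted patterns (the standard pruning-algorithm optimization). Backed by
#' [phangorn::phyDat], whose contrast matrix supplies the partial-likelihood
#' rows for ambiguity codes.
#'
#' @param aln `DNAbin` matrix (or anything `phangorn::phyDat` accepts).
#' @param taxa taxa to keep, in the desired order; defaults to all.
#' @return a `phyDat` object; `sum(attr(x, "weight"))` equals the alignment
#'   length.
#' @export
compress_patterns <- function(aln, taxa = NULL) {
  aln <- as.matrix(aln)
  if (is.null(taxa)) taxa <- rownames(aln)
  missing <- setdiff(taxa, rownames(aln))
  if (length(missing))
    stop("taxa absent from alignment: ", paste(missing, collapse = ", "))
  phangorn::phyDat(aln[taxa, , drop = FALSE], type = "DNA")
}

#' Empirical base frequencies of an alignment subset
#'
#' Counts A/C/G/T only (gaps and ambiguity codes excluded) over the given
#' taxa and normalizes. A small floor `eps` guards fully degenerate
#' compositions so downstream logarithms stay finite.
#'
#' @param aln `DNAbin` matrix.
#' @param taxa taxa to count over (default: all).
#' @param eps frequency floor applied before renormalization; 0 disables.
#' @return named numeric vector (A, C, G, T) summing to 1.
#' @export
empirical_frequencies <- function(aln, taxa = NULL, eps = 1e-6) {
  aln <- as.matrix(aln)
  if (!is.null(taxa)) aln <- aln[taxa, , drop = FALSE]
  f <- ape::base.freq(aln, freq = TRUE)
  if (sum(f) == 0) stop("no countable A/C/G/T characters")
  f <- f / sum(f)
  if (eps > 0) {
    f <- pmax(f, eps)
    f <- f / sum(f)
  }
  stats::setNames(as.numeric(f), c("A", "C", "G", "T"))
}

# internal: DNAbin from an integer state matrix (1=A,2=C,3=G,4=T)
states_to_dnabin <- function(states, labels) {
  chars <- c("a", "c", "g", "t")[states]
  m <- matrix(chars, nrow = nrow(states), ncol = ncol(states),
              dimnames = list(labels, NULL))
  ape::as.DNAbin(m)
}
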