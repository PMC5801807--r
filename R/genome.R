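#' Read a reference genome from FASTA
#'
#' Loads every contig of a FASTA file into an in-memory genome object used
#' throughout the package. Sequences are held as plain uppercase character
#' strings so that base access during normalization and codon extraction is a
#' cheap `substr()`.
#'
#' @param path Path to a FASTA file (plain or gzip-compressed).
#' @return An object of class `aq_genome`: a named list of contig sequences
#'   with a `lengths` attribute.
#' @export
read_genome <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  seqs <- toupper(as.character(ss))
  # FASTA headers may carry descriptions after the first whitespace
  names(seqs) <- sub("\\s.*$", "", names(ss))
  as_genome(seqs)
}

#' Build a genome object from named sequence strings
#'
#' @param seqs Named character vector, one uppercase sequence per contig.
#' @return An `aq_genome`.
#' @export
as_genome <- function(seqs) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  g <- as.list(seqs)
  attr(g, "lengths") <- vapply(g, nchar, integer(1))
  class(g) <- "aq_genome"
  g
}

#' @export
print.aq_genome <- function(x, ...) {
  len <- attr(x, "lengths")
  cat("<aq_genome> ", length(x), " contig(s): ",
      paste0(names(x), " (", len, " bp)", collapse = ", "), "\n", sep = "")
  invisible(x)
}

contig_length <- function(genome, contig) {
  len <- attr(genome, "lengths")[[contig]]
  if (is.null(len)) stop("unknown contig: ", contig)
  len
}

#' Extract a slice of reference sequence
#'
#' @param genome An `aq_genome`.
#' @param contig Contig name.
#' @param start,end 1-based inclusive coordinates, clipped to the contig.
#' @return Character scalar (possibly empty at a degenerate range).
#' @export
genome_slice <- function(genome, contig, start, end) {
  seq <- genome[[contig]]
  if (is.null(seq)) stop("unknown contig: ", contig)
  if (end < start) return("")
  substr(seq, max(1L, start), min(nchar(seq), end))
}

#' Apply one variant allele to a reference sequence
#'
#' Brute-force sequence editor used as the independent oracle for variant
#' normalization: replaces the `ref` bases at `pos` with `alt` and returns the
#' edited sequence. Errors if `ref` does not match the sequence at `pos`.
#'
#' @param seq Reference sequence (character scalar).
#' @param pos 1-based position of the first `ref` base.
#' @param ref,alt Reference and alternate allele strings.
#' @return The edited sequence.
#' @export
apply_allele <- function(seq, pos, ref, alt) {
  n <- nchar(seq)
  if (pos < 1 || pos + nchar(ref) - 1 > n)
    stop("allele out of bounds (pos=", pos, ", ref=", ref, ")")
  if (substr(seq, pos, pos + nchar(ref) - 1) != ref)
    stop("ref allele does not match sequence at pos ", pos)
  paste0(substr(seq, 1, pos - 1), alt, substr(seq, pos + nchar(ref), n))
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Write sequences as wrapped FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line wrap width (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  ss <- Biostrings::DNAStringSet(unlist(seqs))
  names(ss) <- names(seqs)
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}
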