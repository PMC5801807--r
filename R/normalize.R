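#' Parsimonious, left-shifted variant normalization
#'
#' Reduces one (contig, pos, ref, alt) allele to its canonical form: redundant
#' shared suffix and prefix bases are trimmed, and pure insertions/deletions
#' are shifted to the smallest genomic coordinate among all equivalent
#' representations (the classic ambiguity of indels inside homopolymers and
#' short tandem repeats). The result keeps exactly one shared leading padding
#' base for indels, VCF style.
#'
#' The algorithm works to a fixed point:
#' \enumerate{
#'   \item while both alleles are longer than 1 and end with the same base,
#'     drop that base; if one allele has length 1 but both still end with the
#'     same base, extend both to the left with the reference base preceding
#'     `pos` (this is the left shift) and re-trim;
#'   \item trim shared leading bases down to the single indel padding base,
#'     advancing `pos`.
#' }
#' Shifting stops at the contig start; the representation anchored there is
#' kept as-is.
#'
#' @param contig Contig name.
#' @param pos 1-based position of the first `ref` base.
#' @param ref,alt Reference and alternate allele strings (A/C/G/T/N).
#' @param genome An `aq_genome` (used for the left-shift context).
#' @return A list of class `normalized_allele` with elements `contig`, `pos`,
#'   `ref`, `alt`, `type` (one of `"SNP"`, `"MNP"`, `"INS"`, `"DEL"`) and
#'   `compact` (SNP/MNP: the alt bases; INS: `"+<inserted>"`; DEL:
#'   `"-<length>"`), or `NULL` when ref and alt are identical after trimming
#'   (no variant).
#' @export
normalize_allele <- function(contig, pos, ref, alt, genome) {
  seq <- genome[[contig]]
  if (is.null(seq)) stop("unknown contig: ", contig)
  ref <- toupper(ref); alt <- toupper(alt)
  if (ref == alt) return(NULL)

  last <- function(x) substr(x, nchar(x), nchar(x))

  repeat {
    # suffix trim, with left extension when an allele bottoms out at 1 base
    repeat {
      if (nchar(ref) == 0L || nchar(alt) == 0L) break
      if (last(ref) != last(alt)) break
      if (nchar(ref) > 1L && nchar(alt) > 1L) {
        ref <- substr(ref, 1L, nchar(ref) - 1L)
        alt <- substr(alt, 1L, nchar(alt) - 1L)
      } else if (pos > 1L) {
        prev <- substr(seq, pos - 1L, pos - 1L)
        ref <- paste0(prev, substr(ref, 1L, nchar(ref) - 1L))
        alt <- paste0(prev, substr(alt, 1L, nchar(alt) - 1L))
        pos <- pos - 1L
      } else break  # contig start: keep representation here
    }
    # prefix trim down to one shared base
    while (nchar(ref) > 1L && nchar(alt) > 1L &&
           substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
      ref <- substr(ref, 2L, nchar(ref))
      alt <- substr(alt, 2L, nchar(alt))
      pos <- pos + 1L
    }
    break
  }

  if (ref == alt) return(NULL)

  type <-
    if (nchar(ref) == 1L && nchar(alt) == 1L) "SNP"
    else if (nchar(ref) == nchar(alt)) "MNP"
    else if (nchar(alt) > nchar(ref)) "INS"
    else "DEL"

  compact <- switch(type,
    SNP = alt,
    MNP = alt,
    INS = paste0("+", substr(alt, nchar(ref) + 1L, nchar(alt))),
    DEL = paste0("-", nchar(ref) - nchar(alt)))

  structure(
    list(contig = contig, pos = as.integer(pos), ref = ref, alt = alt,
         type = type, compact = compact),
    class = "normalized_allele")
}

#' @export
print.normalized_allele <- function(x, ...) {
  cat(sprintf("<%s> %s:%d %s>%s (%s)\n", x$type, x$contig, x$pos,
              x$ref, x$alt, x$compact))
  invisible(x)
}

#' Check a variant's reference allele against the genome
#'
#' @param contig,pos,ref Allele coordinates and reference string.
#' @param genome An `aq_genome`.
#' @return One of `"ok"`, `"warn_n"` (genome base is N: pass with warning
#'   tally) or `"mismatch"`.
#' @export
check_reference <- function(contig, pos, ref, genome) {
  g <- genome_slice(genome, contig, pos, pos + nchar(ref) - 1L)
  if (nchar(g) != nchar(ref)) return("mismatch")
  if (identical(g, toupper(ref))) return("ok")
  if (grepl("N", g, fixed = TRUE)) {
    # N-masked genome bases pass with a warning; any other difference fails
    gg <- strsplit(g, "")[[1]]; rr <- strsplit(toupper(ref), "")[[1]]
    if (all(gg == rr | gg == "N")) return("warn_n")
  }
  "mismatch"
}

#' Classify a single-base substitution as transition or transversion
#'
#' @param ref,alt Single reference and alternate bases.
#' @return Integer code: 0 = not a SNP, 1 = transition (A<->G, C<->T),
#'   2 = transversion.
#' @export
tr_tv_code <- function(ref, alt) {
  if (nchar(ref) != 1L || nchar(alt) != 1L || ref == alt) return(0L)
  purine <- c("A", "G")
  if ((ref %in% purine) == (alt %in% purine)) 1L else 2L
}
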