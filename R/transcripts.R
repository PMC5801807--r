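#' Parse genePredExt gene models
#'
#' Reads 15- or 16-column genePredExt (tab-delimited, coordinates 0-based
#' half-open; a 16th column is taken as a free-text transcript description)
#' into transcript models with precomputed spliced CDS information used by
#' the effect annotator.
#'
#' @param path genePredExt file.
#' @param genome An `aq_genome` (for CDS sequence extraction).
#' @return List of transcript models. Each model carries: `name`, `name2`,
#'   `desc`, `contig`, `strand`, `txStart`/`txEnd`/`cdsStart`/`cdsEnd`
#'   (0-based half-open), `exonStarts`/`exonEnds`, `coding`, and for coding
#'   transcripts `cds_gpos` (1-based genomic positions of CDS bases in
#'   transcript orientation) and `cds_seq` (the spliced CDS, transcript
#'   orientation).
#' @export
read_genepred <- function(path, genome) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  lapply(seq_along(lines), function(i) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 15L)
      stop(sprintf("%s line %d: expected >= 15 genePredExt columns, got %d",
                   path, i, length(f)))
    ints <- function(x) as.integer(strsplit(sub(",$", "", x), ",", fixed = TRUE)[[1L]])
    tx <- list(
      name = f[[1L]], contig = f[[2L]], strand = f[[3L]],
      txStart = as.integer(f[[4L]]), txEnd = as.integer(f[[5L]]),
      cdsStart = as.integer(f[[6L]]), cdsEnd = as.integer(f[[7L]]),
      exonStarts = ints(f[[9L]]), exonEnds = ints(f[[10L]]),
      name2 = f[[12L]],
      desc = if (length(f) >= 16L) f[[16L]] else "")
    if (is.na(tx$txStart) || length(tx$exonStarts) != length(tx$exonEnds))
      stop(sprintf("%s line %d: malformed genePredExt record", path, i))
    tx$coding <- tx$cdsEnd > tx$cdsStart
    if (tx$coding && !is.null(genome)) {
      exonic <- unlist(Map(function(s, e) seq.int(s + 1L, e),
                           tx$exonStarts, tx$exonEnds))
      cds <- exonic[exonic > tx$cdsStart & exonic <= tx$cdsEnd]
      if (tx$strand == "-") cds <- rev(cds)
      tx$cds_gpos <- cds
      seq <- genome[[tx$contig]]
      if (!is.null(seq)) {
        bases <- vapply(if (tx$strand == "-") rev(cds) else cds,
                        function(p) substr(seq, p, p), character(1))
        s <- paste(bases, collapse = "")
        tx$cds_seq <- if (tx$strand == "-") revcomp(s) else s
      }
    }
    tx
  })
}

#' Enumerate single-base substitutions within the CDS of given transcripts
#'
#' Utility for building dense coding-SNP test sets: for every CDS base of
#' every coding transcript (or until `n` is reached), emits the reference
#' base and each possible alternate.
#'
#' @param txs Transcript models from [read_genepred()].
#' @param genome An `aq_genome`.
#' @param n Maximum number of SNPs to return.
#' @return data.frame with columns contig, pos (1-based), ref, alt, tx.
#' @export
cds_snps <- function(txs, genome, n = Inf) {
  out <- list()
  for (tx in txs) {
    if (!isTRUE(tx$coding)) next
    for (g in tx$cds_gpos) {
      ref <- genome_slice(genome, tx$contig, g, g)
      for (alt in setdiff(c("A", "C", "G", "T"), ref)) {
        out[[length(out) + 1L]] <- data.frame(
          contig = tx$contig, pos = g, ref = ref, alt = alt, tx = tx$name,
          stringsAsFactors = FALSE)
        if (length(out) >= n) return(do.call(rbind, out))
      }
    }
  }
  if (length(out) == 0L) return(NULL)
  do.call(rbind, out)
}
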