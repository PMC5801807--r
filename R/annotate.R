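# Effect annotation and per-sample statistics.

GENETIC_CODE_TBL <- NULL

aa_of <- function(codon) {
  code <- Biostrings::GENETIC_CODE
  v <- code[codon]
  v[is.na(v)] <- "X"
  unname(v)
}

# classify one 1-based genomic base relative to a transcript
classify_base <- function(tx, p, spliceWindow = 2L) {
  if (p <= tx$txStart || p > tx$txEnd) return("intergenic")
  es <- tx$exonStarts; ee <- tx$exonEnds
  inex <- which(p > es & p <= ee)
  if (length(inex)) {
    if (!tx$coding) return("ncRNA")
    if (p > tx$cdsStart && p <= tx$cdsEnd) return("exonic")
    left <- p <= tx$cdsStart
    if (tx$strand == "+") return(if (left) "UTR5" else "UTR3")
    return(if (left) "UTR3" else "UTR5")
  }
  # intronic: which intron?
  k <- max(which(ee < p))      # exon genomic-left of p
  dl <- p - ee[k]              # 1 = first intron base after exon k
  dr <- es[k + 1L] + 1L - p    # 1 = last intron base before next exon
  if (dl <= spliceWindow)
    return(if (tx$strand == "+") "spliceDonor" else "spliceAcceptor")
  if (dr <= spliceWindow)
    return(if (tx$strand == "+") "spliceAcceptor" else "spliceDonor")
  "intronic"
}

#' Per-transcript consequence of a normalized allele
#'
#' Positional class (exonic, intronic, splice donor/acceptor within
#' `spliceWindow` intronic bases of an exon boundary, UTR5/UTR3
#' strand-aware, ncRNA for non-coding transcripts) plus the coding
#' consequence for CDS variants: SNP/MNP ref-vs-alt codon translation
#' (reverse-complemented on minus-strand transcripts; codons counted from
#' the CDS start in transcript orientation), insertions/deletions classed
#' frameshift / non-frameshift by length modulo 3. An insertion anchored at
#' the last base of an exon is exonic, never a splice call: the inserted
#' bases sit between exon and intron and do not disrupt the splice site.
#'
#' @param allele A `normalized_allele`.
#' @param tx A transcript model from [read_genepred()].
#' @param spliceWindow Intronic bases at each exon boundary called splice
#'   (default 2, the canonical donor/acceptor dinucleotide).
#' @return A list: `transcript`, `siteType`, `exonicFunction`, `refCodon`,
#'   `altCodon`, `refAA`, `altAA`, `codonNumber`, `posInCodon` (codon fields
#'   NA unless a SNP/MNP hits the CDS). `siteType = "intergenic"` when the
#'   allele lies outside the transcript entirely.
#' @export
transcript_effect <- function(allele, tx, spliceWindow = 2L) {
  span <- allele_span(allele)
  bases <- span[1]:span[2]
  cls <- vapply(bases, function(p) classify_base(tx, p, spliceWindow), character(1))
  if (allele$type == "INS") {
    # anchor rule: exonic anchor wins over a splice/intron call 3' of it
    if (cls[1] %in% c("spliceDonor", "spliceAcceptor", "intronic", "intergenic")) {
      anc <- classify_base(tx, allele$pos, spliceWindow)
      if (anc %in% c("exonic", "UTR5", "UTR3", "ncRNA")) cls <- anc
    }
  }
  pr <- c(exonic = 1, spliceDonor = 2, spliceAcceptor = 2, UTR5 = 3, UTR3 = 3,
          ncRNA = 3, intronic = 4, intergenic = 5)
  site <- cls[order(pr[cls])][1]
  eff <- list(transcript = tx$name, siteType = site, exonicFunction = "none",
              refCodon = NA_character_, altCodon = NA_character_,
              refAA = NA_character_, altAA = NA_character_,
              codonNumber = NA_integer_, posInCodon = NA_integer_)
  if (site != "exonic" || !tx$coding) return(eff)

  if (allele$type %in% c("INS", "DEL")) {
    varlen <- abs(nchar(allele$alt) - nchar(allele$ref))
    eff$exonicFunction <- if (varlen %% 3L == 0L) "indel-nonFrameshift"
                          else "indel-frameshift"
    return(eff)
  }

  # SNP/MNP: substitute affected CDS bases, translate per affected codon
  cds <- tx$cds_gpos
  alt_bases <- strsplit(allele$alt, "")[[1L]]
  idx <- match(bases, cds)
  keep <- !is.na(idx)
  if (!any(keep)) { eff$siteType <- site; return(eff) }
  idx <- idx[keep]; ab <- alt_bases[keep]
  if (tx$strand == "-") ab <- comp_base(ab)
  codons <- unique(ceiling(idx / 3L))
  refC <- character(0); altC <- character(0)
  for (cn in codons) {
    rc <- substr(tx$cds_seq, 3L * cn - 2L, 3L * cn)
    ac <- rc
    for (j in seq_along(idx)) {
      if (ceiling(idx[j] / 3L) == cn) {
        k <- ((idx[j] - 1L) %% 3L) + 1L
        substr(ac, k, k) <- ab[j]
      }
    }
    refC <- c(refC, rc); altC <- c(altC, ac)
  }
  refA <- aa_of(refC); altA <- aa_of(altC)
  fun <-
    if (1L %in% codons && refC[match(1L, codons)] == "ATG" &&
        altC[match(1L, codons)] != "ATG") "startLoss"
    else if (any(altA == "*" & refA != "*")) "stopGain"
    else if (any(refA == "*" & altA != "*")) "stopLoss"
    else if (all(refA == altA)) "synonymous"
    else "nonsynonymous"
  eff$exonicFunction <- fun
  eff$refCodon <- paste(refC, collapse = "|")
  eff$altCodon <- paste(altC, collapse = "|")
  eff$refAA <- paste(refA, collapse = "|")
  eff$altAA <- paste(altA, collapse = "|")
  eff$codonNumber <- codons[1L]
  eff$posInCodon <- ((idx[1L] - 1L) %% 3L) + 1L
  eff
}

#' Independent full-CDS translation classifier
#'
#' Reference oracle for the codon logic in [transcript_effect()]: builds the
#' complete alternate CDS by substituting the variant bases, translates both
#' CDS sequences end-to-end with the standard genetic code, and classifies
#' the difference. Shares no code with the per-codon path.
#'
#' @param allele A `normalized_allele` (SNP/MNP fully inside the CDS).
#' @param tx Transcript model.
#' @return One of `"synonymous"`, `"nonsynonymous"`, `"stopGain"`,
#'   `"stopLoss"`, `"startLoss"`, or NA when the allele is not a CDS
#'   substitution.
#' @export
translate_classify <- function(allele, tx) {
  if (!tx$coding || !allele$type %in% c("SNP", "MNP")) return(NA_character_)
  span <- allele_span(allele)
  bases <- span[1]:span[2]
  idx <- match(bases, tx$cds_gpos)
  if (all(is.na(idx))) return(NA_character_)
  ab <- strsplit(allele$alt, "")[[1L]]
  if (tx$strand == "-") ab <- comp_base(ab)
  alt_cds <- tx$cds_seq
  for (j in seq_along(idx))
    if (!is.na(idx[j])) substr(alt_cds, idx[j], idx[j]) <- ab[j]
  tr <- function(s) as.character(Biostrings::translate(
    Biostrings::DNAString(s), if.fuzzy.codon = "X", no.init.codon = TRUE))
  p0 <- tr(tx$cds_seq); p1 <- tr(alt_cds)
  a0 <- strsplit(p0, "")[[1L]]; a1 <- strsplit(p1, "")[[1L]]
  if (substr(alt_cds, 1L, 3L) != "ATG" && substr(tx$cds_seq, 1L, 3L) == "ATG")
    return("startLoss")
  diff <- which(a0 != a1)
  if (length(diff) == 0L) return("synonymous")
  if (any(a1[diff] == "*")) return("stopGain")
  if (any(a0[diff] == "*")) return("stopLoss")
  "nonsynonymous"
}

#' Per-sample genotype statistics for one allele
#'
#' @param classes Character vector of per-sample classes (`refHom`, `het`,
#'   `altHom`, `missing`), parallel to `samples`.
#' @param samples Sample ids.
#' @return List: `heterozygotes`, `homozygotes`, `missingGenos` (sample id
#'   vectors), `heterozygosity` (|het|/n), `homozygosity` (|altHom|/n),
#'   `missingness` (|missing|/n), `sampleMaf`
#'   ((|het| + 2|altHom|) / (2 (n - |missing|)); NA when all samples are
#'   missing). With zero samples every field is empty/NA.
#' @export
compute_sample_stats <- function(classes, samples) {
  n <- length(samples)
  if (n == 0L)
    return(list(heterozygotes = character(0), homozygotes = character(0),
                missingGenos = character(0), heterozygosity = NA_real_,
                homozygosity = NA_real_, missingness = NA_real_,
                sampleMaf = NA_real_))
  het <- samples[classes == "het"]
  hom <- samples[classes == "altHom"]
  mis <- samples[classes == "missing"]
  callable <- n - length(mis)
  list(heterozygotes = het, homozygotes = hom, missingGenos = mis,
       heterozygosity = length(het) / n,
       homozygosity = length(hom) / n,
       missingness = length(mis) / n,
       sampleMaf = if (callable == 0L) NA_real_
                   else (length(het) + 2L * length(hom)) / (2L * callable))
}

#' Transition/transversion ratio over annotated rows
#'
#' @param rows Annotation data.frame (needs `trTv`, and the sample-carrier
#'   columns when `sample` is given).
#' @param sample Optional sample id: restrict to rows where the sample
#'   carries the alternate allele (heterozygote or homozygote).
#' @return nTs / nTv, or NA when there are no transversions.
#' @export
ts_tv_ratio <- function(rows, sample = NULL) {
  if (nrow(rows) == 0L) return(NA_real_)
  code <- as.integer(rows$trTv)
  if (!is.null(sample)) {
    carrier <- mapply(function(h, a) {
      sample %in% c(strsplit(h, ";", fixed = TRUE)[[1L]],
                    strsplit(a, ";", fixed = TRUE)[[1L]])
    }, rows$heterozygotes, rows$homozygotes)
    code <- code[carrier]
  }
  nts <- sum(code == 1L, na.rm = TRUE)
  ntv <- sum(code == 2L, na.rm = TRUE)
  if (ntv == 0L) return(NA_real_)
  nts / ntv
}

join_arr <- function(x) {
  if (length(x) == 0L) return("NA")
  x <- as.character(x)
  x[is.na(x)] <- "NA"
  paste(gsub(";", ",", x, fixed = TRUE), collapse = ";")
}

#' Annotate normalized alleles against the store
#'
#' Joins every allele to each overlapping transcript (parallel ;-separated
#' arrays of effects), to score tracks over its affected span, to sparse
#' tracks by canonical key, and to its per-sample statistics; assigns the
#' transition/transversion code (0 = not a SNP, 1 = transition,
#' 2 = transversion).
#'
#' @param alleles List of `list(allele = normalized_allele, classes)` as from
#'   [intake_vcf()].
#' @param store A `genome_store`.
#' @param samples Sample ids (parallel to each `classes`).
#' @param spliceWindow Passed to [transcript_effect()].
#' @return data.frame, one row per allele, all columns character except
#'   `position`.
#' @export
annotate_variants <- function(alleles, store, samples, spliceWindow = 2L) {
  gene <- store$gene_track
  score_tracks <- names(store$score)
  sparse_tracks <- store$sparse_tracks
  eff_fields <- c("name", "siteType", "exonicFunction", "refCodon", "altCodon",
                  "refAA", "altAA", "codonNumber")
  rows <- lapply(alleles, function(x) {
    al <- x$allele
    row <- list(fragment = al$contig, position = al$pos, type = al$type,
                ref = al$ref, alt = al$compact,
                trTv = as.character(if (al$type == "SNP")
                  tr_tv_code(al$ref, al$alt) else 0L))
    # transcripts
    if (!is.null(gene)) {
      ti <- store$tx_index[[al$contig]]
      span <- allele_span(al)
      hits <- integer(0)
      if (!is.null(ti)) {
        ov <- IRanges::overlapsAny(
          ti$ranges, IRanges::IRanges(min(al$pos, span[1]), span[2]))
        hits <- ti$idx[ov]
      }
      if (length(hits) == 0L) {
        vals <- stats::setNames(
          as.list(rep(NA_character_, length(eff_fields))),
          paste0(gene, ".", eff_fields))
        vals[[paste0(gene, ".siteType")]] <- "intergenic"
        vals[[paste0(gene, ".name2")]] <- NA_character_
        vals[[paste0(gene, ".description")]] <- NA_character_
        row <- c(row, vals)
      } else {
        effs <- lapply(store$tx[hits], function(tx)
          transcript_effect(al, tx, spliceWindow))
        get <- function(fld) join_arr(vapply(effs, function(e)
          as.character(e[[if (fld == "name") "transcript" else fld]]), character(1)))
        vals <- stats::setNames(lapply(eff_fields, get),
                                paste0(gene, ".", eff_fields))
        vals[[paste0(gene, ".name2")]] <-
          join_arr(vapply(store$tx[hits], `[[`, character(1), "name2"))
        vals[[paste0(gene, ".description")]] <-
          join_arr(vapply(store$tx[hits], `[[`, character(1), "desc"))
        row <- c(row, vals)
      }
    }
    for (trk in score_tracks)
      row[[trk]] <- join_arr(scores_for_allele(store, al, trk))
    for (trk in sparse_tracks) {
      ent <- sparse_for_allele(store, al, trk)
      flds <- unname(store$sparse_fields[[trk]])
      for (fl in flds)
        row[[paste0(trk, ".", fl)]] <-
          if (is.null(ent)) NA_character_ else join_arr(ent[[fl]])
    }
    st <- compute_sample_stats(x$classes, samples)
    row$heterozygotes <- join_arr(st$heterozygotes)
    row$homozygotes <- join_arr(st$homozygotes)
    row$missingGenos <- join_arr(st$missingGenos)
    row$heterozygosity <- as.character(round(st$heterozygosity, 6))
    row$homozygosity <- as.character(round(st$homozygosity, 6))
    row$missingness <- as.character(round(st$missingness, 6))
    row$sampleMaf <- as.character(round(st$sampleMaf, 6))
    row
  })
  if (length(rows) == 0L) return(NULL)
  cols <- names(rows[[1L]])
  df <- as.data.frame(lapply(cols, function(cn)
    vapply(rows, function(r) {
      v <- r[[cn]]
      if (is.null(v) || length(v) == 0L || is.na(v)) "NA" else as.character(v)
    }, character(1))), stringsAsFactors = FALSE)
  names(df) <- cols
  df$position <- as.integer(df$position)
  df
}

#' Write an annotation as gzip-compressed tab-delimited text
#'
#' Streams directly through a gzip connection (no uncompressed
#' intermediate). Arrays are ;-joined, missing values are `NA`. A sidecar
#' `<path>.meta.json` records the sample list and provenance; a plain-text
#' `<path>.log` records store metadata, drop tallies and the row count.
#'
#' @param rows Annotation data.frame from [annotate_variants()] (NULL/empty
#'   allowed: header-only output).
#' @param path Output path (`.gz` recommended).
#' @param samples Sample ids.
#' @param meta Optional named list merged into the sidecar (e.g. drop
#'   tallies, parent annotation, query string).
#' @return `path`, invisibly.
#' @export
write_annotation <- function(rows, path, samples = character(0), meta = list()) {
  if (is.null(rows))
    rows <- data.frame(fragment = character(0), position = integer(0))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  ok <- FALSE
  on.exit({
    close(con)
    if (!ok && file.exists(path)) unlink(path)  # no partial outputs
  })
  utils::write.table(rows, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  ok <- TRUE
  meta$samples <- samples
  meta$nrow <- nrow(rows)
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       null = "null")
  logp <- paste0(path, ".log")
  tallies <- meta$tallies
  writeLines(c(
    paste("rows:", nrow(rows)),
    paste("samples:", length(samples)),
    if (!is.null(meta$assembly)) paste("assembly:", meta$assembly),
    if (!is.null(tallies))
      paste0("drop tallies: ",
             paste(names(tallies), unlist(tallies), sep = "=", collapse = " "))),
    logp)
  invisible(path)
}

#' Read back a written annotation
#'
#' @param path Path written by [write_annotation()].
#' @return data.frame with attributes `samples` and `meta`.
#' @export
read_annotation <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                          colClasses = "character", check.names = FALSE,
                          na.strings = NULL, comment.char = "")
  if ("position" %in% names(df)) df$position <- as.integer(df$position)
  mp <- paste0(path, ".meta.json")
  meta <- if (file.exists(mp)) jsonlite::read_json(mp, simplifyVector = TRUE)
          else list()
  attr(df, "samples") <- meta$samples %||% character(0)
  attr(df, "meta") <- meta
  df
}

`%||%` <- function(a, b) if (is.null(a)) b else a
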