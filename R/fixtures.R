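#' Fixture specification for the synthetic test-data generator
#'
#' Everything the toolkit consumes — reference genome, gene models, score
#' tracks, sparse annotation tracks and a multi-sample cohort VCF with
#' planted truth — is generated from one of these specs, so the whole
#' pipeline is exercisable offline. One RNG stream per artifact kind is
#' derived from `seed`, so adding a fixture kind never changes earlier
#' outputs.
#'
#' @param seed Integer master seed.
#' @param contigs Named integer vector of contig lengths (each >= 200).
#' @param nTranscripts Number of gene models (>= 0).
#' @param nTrackVariants Entries per sparse annotation track.
#' @param nCohortVariants Planted cohort variants.
#' @param samples Character vector of sample ids.
#' @param trio Optional named character vector
#'   `c(proband = ..., mother = ..., father = ...)`; ids must appear in
#'   `samples`.
#' @param nDeNovo Number of proband-only (de novo) alleles to plant.
#' @param hweDeviation Optional `list(count, counts3)` where `counts3` is an
#'   integer triple (nRefHom, nHet, nAltHom) summing to `length(samples)`.
#' @param missingRate Fraction of genotype calls set to `./.` (never on
#'   planted de novo rows, which stay fully called).
#' @return A list of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L,
                         contigs = c(chr1 = 60000L, chr2 = 60000L),
                         nTranscripts = 6L,
                         nTrackVariants = 200L,
                         nCohortVariants = 300L,
                         samples = c("S_child", "S_mom", "S_dad",
                                     paste0("S", 4:10)),
                         trio = c(proband = "S_child", mother = "S_mom",
                                  father = "S_dad"),
                         nDeNovo = 3L,
                         hweDeviation = NULL,
                         missingRate = 0) {
  stopifnot(all(contigs >= 200L), nTranscripts >= 0L, nTrackVariants >= 0L,
            nCohortVariants >= 0L, missingRate >= 0, missingRate <= 1)
  if (!is.null(trio) && !all(trio %in% samples))
    stop("trio sample ids must be members of samples")
  if (nDeNovo > nCohortVariants)
    stop("nDeNovo exceeds nCohortVariants")
  if (!is.null(hweDeviation)) {
    if (sum(hweDeviation[[2]]) != length(samples))
      stop("hweDeviation genotype counts must sum to the sample count")
  }
  structure(list(seed = as.integer(seed), contigs = contigs,
                 nTranscripts = as.integer(nTranscripts),
                 nTrackVariants = as.integer(nTrackVariants),
                 nCohortVariants = as.integer(nCohortVariants),
                 samples = samples, trio = trio,
                 nDeNovo = as.integer(nDeNovo),
                 hweDeviation = hweDeviation,
                 missingRate = missingRate),
            class = "fixture_spec")
}

# deterministic sub-seed per artifact kind (kept below 2^31)
sub_seed <- function(spec, what) {
  h <- sum(utf8ToInt(what) * seq_along(utf8ToInt(what)))
  as.integer((abs(spec$seed) %% 1000000L) * 2039L + h %% 100000L)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  expr
}

BASES <- c("A", "C", "G", "T")
STOPS <- c("TAA", "TAG", "TGA")

rand_dna <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")

rand_cds <- function(n_codons) {
  all_cod <- apply(expand.grid(BASES, BASES, BASES), 1, paste, collapse = "")
  sense <- setdiff(all_cod, STOPS)
  paste0("ATG", paste(sample(sense, n_codons, replace = TRUE), collapse = ""),
         sample(STOPS, 1))
}

# ---- deterministic transcript layout ---------------------------------------

# One shared planner: make_genome() embeds each planned CDS in the reference,
# make_transcripts() emits the matching genePredExt lines. Both re-derive the
# identical plan from the spec seed alone.
plan_layout <- function(spec) {
  with_seed(sub_seed(spec, "layout"), {
    contigs <- names(spec$contigs)
    lens <- spec$contigs
    cursor <- stats::setNames(rep(2000L, length(contigs)), contigs)

    gene_pool <- list(
      list(name2 = "BRCA2", desc = "Homo sapiens breast cancer 2, early onset (BRCA2), mRNA"),
      list(name2 = "PLOD1", desc = "Homo sapiens procollagen-lysine 1, 2-oxoglutarate 5-dioxygenase 1 (PLOD1), mRNA"),
      list(name2 = "LINC01", desc = "long intergenic non-protein coding RNA 1"),
      list(name2 = "BRCA1", desc = "Homo sapiens breast cancer 1, early onset (BRCA1), mRNA"))

    txs <- list()
    add_tx <- function(tx) txs[[length(txs) + 1L]] <<- tx

    # template: 3 exons; tx-order exon lengths (300, 120, cdsRest + 90);
    # UTRs 90 nt each; CDS = 210 + 120 + cdsRest, codon-aligned at exon 2
    build_tx <- function(name, name2, desc, contig, strand, cdsRest,
                         introns, coding = TRUE, skip_mid = FALSE,
                         share = NULL) {
      exlen_tx <- c(300L, 120L, cdsRest + 90L)
      s <- cursor[[contig]]
      gl <- if (strand == "+") exlen_tx else rev(exlen_tx)
      starts <- integer(3); ends <- integer(3)
      p <- s
      for (k in 1:3) {
        starts[k] <- p; ends[k] <- p + gl[k]
        p <- ends[k] + if (k < 3) introns[k] else 0L
      }
      txStart <- s; txEnd <- ends[3]
      if (txEnd + 300L > lens[[contig]])
        stop("contig overflow: transcript ", name, " does not fit on ",
             contig, " (needs ", txEnd + 300L, " > ", lens[[contig]], ")")
      if (is.null(share)) cursor[[contig]] <<- txEnd + 800L

      L <- 210L + 120L + cdsRest
      seq_tx <- if (coding)
        paste0(rand_dna(90L), rand_cds((L - 6L) / 3L), rand_dna(90L))
      else rand_dna(sum(exlen_tx))

      list(name = name, name2 = name2, desc = desc, contig = contig,
           strand = strand, txStart = txStart, txEnd = txEnd,
           cdsStart = if (coding) txStart + 90L else txStart,
           cdsEnd = if (coding) txEnd - 90L else txStart,
           exonStarts = starts, exonEnds = ends,
           coding = coding, seq_tx = seq_tx, skip_mid = skip_mid,
           share = share)
    }

    n <- spec$nTranscripts
    if (n >= 1L) {
      g <- gene_pool[[1]]
      add_tx(build_tx("NM_000001", g$name2, g$desc, contigs[1], "+",
                      cdsRest = 180L, introns = c(450L, 520L)))
    }
    if (n >= 2L) {
      # alternate-splicing isoform: same locus, middle (all-CDS, codon-aligned)
      # exon skipped; CDS stays in frame with the same stop codon
      a <- txs[[1]]
      b <- a
      b$name <- "NM_000001b"
      b$exonStarts <- a$exonStarts[c(1, 3)]
      b$exonEnds <- a$exonEnds[c(1, 3)]
      b$skip_mid <- TRUE
      b$share <- "NM_000001"
      add_tx(b)
    }
    if (n >= 3L) {
      g <- gene_pool[[2]]
      ctg <- if (length(contigs) > 1) contigs[2] else contigs[1]
      add_tx(build_tx("NM_000002", g$name2, g$desc, ctg, "-",
                      cdsRest = 150L, introns = c(400L, 480L)))
    }
    if (n >= 4L) {
      g <- gene_pool[[3]]
      add_tx(build_tx("NR_000003", g$name2, g$desc, contigs[1], "+",
                      cdsRest = 90L, introns = c(350L, 350L), coding = FALSE))
    }
    if (n >= 5L) {
      g <- gene_pool[[4]]
      ctg <- if (length(contigs) > 1) contigs[2] else contigs[1]
      add_tx(build_tx("NM_000004", g$name2, g$desc, ctg, "+",
                      cdsRest = 3L * sample(40:70, 1), introns = sample(300:600, 2)))
    }
    if (n >= 6L) {
      for (i in 6:n) {
        ctg <- contigs[((i - 1L) %% length(contigs)) + 1L]
        strand <- if (i %% 2L == 0L) "-" else "+"
        add_tx(build_tx(sprintf("NM_%06d", i), sprintf("GENE%d", i),
                        sprintf("Homo sapiens example kinase %d (GENE%d), mRNA", i, i),
                        ctg, strand,
                        cdsRest = 3L * sample(40:70, 1),
                        introns = sample(300:600, 2)))
      }
    }

    # homopolymer runs: one fixed 8-bp A-run near each contig start, plus a
    # 7-bp T-run midway, to exercise indel left-shifting
    hp <- lapply(contigs, function(ctg) {
      mid <- as.integer(lens[[ctg]] * 0.9)
      data.frame(contig = ctg, start = c(101L, mid), len = c(8L, 7L),
                 base = c("A", "T"), stringsAsFactors = FALSE)
    })
    list(tx = txs, hp = do.call(rbind, hp))
  })
}

# 1-based genomic positions of exonic bases, in transcript orientation
tx_gpos <- function(tx) {
  g <- unlist(Map(function(s, e) seq.int(s + 1L, e), tx$exonStarts, tx$exonEnds))
  if (tx$strand == "-") rev(g) else g
}

# ---- genome -----------------------------------------------------------------

#' Generate the synthetic reference genome
#'
#' Random A/C/G/T sequence per contig with the planned transcript sequences
#' (valid CDS: ATG start, in-frame, terminal stop codon) embedded at their
#' exonic positions, and at least one homopolymer run of >= 6 bp per contig
#' for left-shift exercises. Deterministic for a fixed spec.
#'
#' @param spec A [fixture_spec()].
#' @param path Output FASTA path.
#' @return The path, invisibly; the genome is also returned via attribute
#'   `"genome"` on the path for convenience.
#' @export
make_genome <- function(spec, path) {
  layout <- plan_layout(spec)
  seqs <- with_seed(sub_seed(spec, "genome"), {
    out <- list()
    for (ctg in names(spec$contigs)) {
      v <- sample(BASES, spec$contigs[[ctg]], replace = TRUE)
      runs <- layout$hp[layout$hp$contig == ctg, ]
      for (r in seq_len(nrow(runs)))
        v[runs$start[r]:(runs$start[r] + runs$len[r] - 1L)] <- runs$base[r]
      # guard bases flanking each run must differ from the run base
      for (r in seq_len(nrow(runs))) {
        a <- runs$start[r] - 1L; b <- runs$start[r] + runs$len[r]
        nb <- setdiff(BASES, runs$base[r])
        if (v[a] == runs$base[r]) v[a] <- nb[1]
        if (v[b] == runs$base[r]) v[b] <- nb[1]
      }
      out[[ctg]] <- v
    }
    out
  })
  # overlay transcript exonic sequence (shared-locus isoforms reuse it)
  for (tx in layout$tx) {
    if (!is.null(tx$share)) next
    v <- seqs[[tx$contig]]
    gseq <- if (tx$strand == "+") tx$seq_tx else revcomp(tx$seq_tx)
    chars <- strsplit(gseq, "")[[1]]
    gp <- unlist(Map(function(s, e) seq.int(s + 1L, e), tx$exonStarts, tx$exonEnds))
    v[gp] <- chars
    seqs[[tx$contig]] <- v
  }
  seqs <- vapply(seqs, paste, character(1), collapse = "")
  write_fasta(seqs, path)
  invisible(structure(path, genome = as_genome(seqs)))
}

# ---- transcripts ------------------------------------------------------------

#' Emit the planned gene models as genePredExt
#'
#' Sixteen tab-separated columns: the 15 standard genePredExt columns
#' (name, chrom, strand, txStart, txEnd, cdsStart, cdsEnd, exonCount,
#' exonStarts, exonEnds, score, name2, cdsStartStat, cdsEndStat, exonFrames;
#' coordinates 0-based half-open) plus a free-text transcript description.
#'
#' @param genome An `aq_genome` produced by [make_genome()] from the same spec
#'   (checked: the embedded CDS must match).
#' @param spec The same [fixture_spec()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
make_transcripts <- function(genome, spec, path) {
  layout <- plan_layout(spec)
  lines <- vapply(layout$tx, function(tx) {
    # sanity: genome must carry the planned sequence
    gp <- tx_gpos(tx)
    if (tx$coding && is.null(tx$share)) {
      got <- genome_slice(genome, tx$contig, gp[91], gp[91])
      want <- if (tx$strand == "+") "A" else revcomp(substr(tx$seq_tx, 91, 91))
      if (!identical(got, if (tx$strand == "+") "A" else want))
        stop("genome does not match planned transcripts; ",
             "regenerate with make_genome() from the same spec")
    }
    frames <- rep(-1L, length(tx$exonStarts))
    paste(tx$name, tx$contig, tx$strand, tx$txStart, tx$txEnd,
          tx$cdsStart, tx$cdsEnd, length(tx$exonStarts),
          paste0(paste(tx$exonStarts, collapse = ","), ","),
          paste0(paste(tx$exonEnds, collapse = ","), ","),
          0L, tx$name2, "cmpl", "cmpl",
          paste0(paste(frames, collapse = ","), ","),
          tx$desc, sep = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

# ---- score tracks -----------------------------------------------------------

#' Generate a fixed-step score track (wigFix)
#'
#' Per-base float scores over the first 80% of each contig, deterministic per
#' (spec seed, track name). Positions listed in `force` (a data.frame with
#' columns contig, pos, value) are overridden, so specific variants can be
#' given known scores.
#'
#' @param genome An `aq_genome`.
#' @param spec A [fixture_spec()].
#' @param path Output path.
#' @param name Track name (selects the RNG stream and value range).
#' @param range Numeric length-2 score range.
#' @param digits Rounding for emitted values.
#' @param force Optional data.frame of forced (contig, pos, value).
#' @return The path, invisibly.
#' @export
make_score_track <- function(genome, spec, path, name = "phyloP",
                             range = c(-3, 7), digits = 3, force = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  with_seed(sub_seed(spec, paste0("score_", name)), {
    for (ctg in names(spec$contigs)) {
      span <- as.integer(spec$contigs[[ctg]] * 0.8)
      vals <- round(stats::runif(span, range[1], range[2]), digits)
      if (!is.null(force)) {
        f <- force[force$contig == ctg & force$pos <= span, ]
        if (nrow(f)) vals[f$pos] <- f$value
      }
      writeLines(sprintf("fixedStep chrom=%s start=1 step=1", ctg), con)
      writeLines(format(vals, trim = TRUE, scientific = FALSE), con)
    }
  })
  invisible(path)
}

#' Generate a BED interval track with scores
#'
#' 0-based half-open intervals with a name and score column, usable as a
#' score-category track source.
#'
#' @inheritParams make_score_track
#' @param n Number of intervals.
#' @return The path, invisibly.
#' @export
make_bed_track <- function(genome, spec, path, name = "repeatScore", n = 20L) {
  with_seed(sub_seed(spec, paste0("bed_", name)), {
    rows <- lapply(seq_len(n), function(i) {
      ctg <- sample(names(spec$contigs), 1)
      len <- spec$contigs[[ctg]]
      s <- sample.int(len - 600L, 1)
      sprintf("%s\t%d\t%d\t%s_%d\t%s", ctg, s, s + sample(50:400, 1),
              name, i, format(round(stats::runif(1, 0, 100), 2)))
    })
    writeLines(unlist(rows), path)
  })
  invisible(path)
}
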