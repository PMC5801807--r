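test_that("codon-logic classification equals full-CDS translation oracle", {
  pl <- default_pipeline()
  txs <- Filter(function(t) t$coding, pl$store$tx)
  strands <- vapply(txs, `[[`, character(1), "strand")
  # both strands represented
  expect_true(all(c("+", "-") %in% strands))
  set.seed(11)
  snps <- cds_snps(txs, pl$store$genome)
  snps <- snps[sample.int(nrow(snps), 600), ]
  for (i in seq_len(nrow(snps))) {
    s <- snps[i, ]
    tx <- txs[[match(s$tx, vapply(txs, `[[`, character(1), "name"))]]
    al <- normalize_allele(s$contig, s$pos, s$ref, s$alt, pl$store$genome)
    eff <- transcript_effect(al, tx)
    oracle <- translate_classify(al, tx)
    expect_equal(eff$exonicFunction, oracle,
                 label = paste(s$tx, s$pos, s$ref, ">", s$alt))
    expect_equal(eff$siteType, "exonic")
  }
})

test_that("insertions far from any intron are exonic frameshifts, never splice", {
  pl <- default_pipeline()
  tx <- pl$store$tx[[1]]                   # plus strand, middle exon all-CDS
  e2 <- tx$exonStarts[2]                   # 0-based start of middle exon
  anchor <- e2 + 37L                       # 1-based pos 37 bp into the exon
  g <- pl$store$genome
  ref <- genome_slice(g, tx$contig, anchor, anchor)
  al <- normalize_allele(tx$contig, anchor, ref, paste0(ref, "T"), g)
  eff <- transcript_effect(al, tx)
  expect_equal(eff$siteType, "exonic")
  expect_equal(eff$exonicFunction, "indel-frameshift")
  # insertion anchored at the very last base of the exon is still exonic
  last <- tx$exonEnds[2]
  ref2 <- genome_slice(g, tx$contig, last, last)
  al2 <- normalize_allele(tx$contig, last, ref2, paste0(ref2, "T"), g)
  # (guard: if normalization shifted it away from the boundary, re-anchor)
  if (al2$pos == last) {
    eff2 <- transcript_effect(al2, tx)
    expect_equal(eff2$siteType, "exonic")
  }
  # a 3-bp insertion is non-frameshift
  al3 <- normalize_allele(tx$contig, anchor, ref, paste0(ref, "TAG"), g)
  expect_equal(transcript_effect(al3, tx)$exonicFunction, "indel-nonFrameshift")
})

test_that("site types cover splice, intron, UTRs, ncRNA, intergenic — strand aware", {
  pl <- default_pipeline()
  g <- pl$store$genome
  mk <- function(tx, pos1) {
    ref <- genome_slice(g, tx$contig, pos1, pos1)
    alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
    list(contig = tx$contig, pos = pos1, ref = ref, alt = alt, type = "SNP")
  }
  tx <- pl$store$tx[[1]]  # plus strand
  # first two intronic bases after exon 1 = splice donor on plus strand
  expect_equal(transcript_effect(mk(tx, tx$exonEnds[1] + 1L), tx)$siteType,
               "spliceDonor")
  expect_equal(transcript_effect(mk(tx, tx$exonEnds[1] + 2L), tx)$siteType,
               "spliceDonor")
  expect_equal(transcript_effect(mk(tx, tx$exonEnds[1] + 3L), tx)$siteType,
               "intronic")
  expect_equal(transcript_effect(mk(tx, tx$exonStarts[2]), tx)$siteType,
               "spliceAcceptor")
  expect_equal(transcript_effect(mk(tx, tx$txStart + 5L), tx)$siteType, "UTR5")
  expect_equal(transcript_effect(mk(tx, tx$txEnd - 5L), tx)$siteType, "UTR3")
  expect_equal(transcript_effect(mk(tx, 50L), tx)$siteType, "intergenic")
  # minus strand: donor/acceptor and UTRs swap orientation
  txm <- Filter(function(t) t$strand == "-" && t$coding, pl$store$tx)[[1]]
  expect_equal(transcript_effect(mk(txm, txm$exonEnds[1] + 1L), txm)$siteType,
               "spliceAcceptor")
  expect_equal(transcript_effect(mk(txm, txm$exonStarts[2]), txm)$siteType,
               "spliceDonor")
  expect_equal(transcript_effect(mk(txm, txm$txStart + 5L), txm)$siteType, "UTR3")
  expect_equal(transcript_effect(mk(txm, txm$txEnd - 5L), txm)$siteType, "UTR5")
  # non-coding transcript exons are ncRNA
  txn <- Filter(function(t) !t$coding, pl$store$tx)[[1]]
  expect_equal(transcript_effect(mk(txn, txn$exonStarts[1] + 5L), txn)$siteType,
               "ncRNA")
})

test_that("a plus-strand transcript and its reverse-complement mirror give identical effects", {
  # hand-built 84-bp gene on a 120-bp genome, then the mirrored genome
  set.seed(31)
  utr <- "TTCCA"
  cds <- paste0("ATG", "AAA", "TAC", "GGA", "TTG", "CCC", "TAA")  # 21 bp
  left <- paste(sample(c("A", "C", "G", "T"), 40, TRUE), collapse = "")
  right <- paste(sample(c("A", "C", "G", "T"), 49, TRUE), collapse = "")
  seq_p <- paste0(left, utr, cds, utr, right)   # tx at 41..71 (1-based)
  L <- nchar(seq_p)
  seq_m <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq_p)))
  gp <- as_genome(c(cP = seq_p))
  gm <- as_genome(c(cM = seq_m))
  # single-exon models: plus on seq_p, minus on the mirrored genome
  gp_line <- paste("TXP", "cP", "+", 40, 71, 45, 66, 1, "40,", "71,", 0,
                   "G", "cmpl", "cmpl", "-1,", "d", sep = "\t")
  gm_line <- paste("TXM", "cM", "-", L - 71, L - 40, L - 66, L - 45, 1,
                   paste0(L - 71, ","), paste0(L - 40, ","), 0,
                   "G", "cmpl", "cmpl", "-1,", "d", sep = "\t")
  fp <- tempfile(); fm <- tempfile()
  writeLines(gp_line, fp); writeLines(gm_line, fm)
  txp <- read_genepred(fp, gp)[[1]]
  txm <- read_genepred(fm, gm)[[1]]
  expect_equal(txp$cds_seq, txm$cds_seq)  # same CDS in transcript orientation
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  for (pos in 46:66) {
    ref <- substr(seq_p, pos, pos)
    for (alt in setdiff(c("A", "C", "G", "T"), ref)) {
      ap <- normalize_allele("cP", pos, ref, alt, gp)
      am <- normalize_allele("cM", L - pos + 1L, comp[[ref]], comp[[alt]], gm)
      ep <- transcript_effect(ap, txp)
      em <- transcript_effect(am, txm)
      expect_equal(ep$exonicFunction, em$exonicFunction,
                   label = paste(pos, ref, ">", alt))
      expect_equal(ep$codonNumber, em$codonNumber)
    }
  }
})

test_that("sample statistics follow the defining formulas", {
  st <- compute_sample_stats(c("het", "refHom", "altHom", "missing"),
                             c("S1", "S2", "S3", "S4"))
  expect_equal(st$heterozygotes, "S1")
  expect_equal(st$homozygotes, "S3")
  expect_equal(st$missingGenos, "S4")
  expect_equal(st$heterozygosity, 0.25)
  expect_equal(st$homozygosity, 0.25)
  expect_equal(st$missingness, 0.25)
  expect_equal(st$sampleMaf, (1 + 2) / (2 * 3))
  all_ref <- compute_sample_stats(rep("refHom", 4), paste0("S", 1:4))
  expect_equal(all_ref$sampleMaf, 0)
  expect_length(all_ref$heterozygotes, 0)
  all_mis <- compute_sample_stats(rep("missing", 4), paste0("S", 1:4))
  expect_equal(all_mis$missingness, 1)
  expect_true(is.na(all_mis$sampleMaf))
  none <- compute_sample_stats(character(0), character(0))
  expect_true(is.na(none$sampleMaf))
})

test_that("annotated rows satisfy the genotype conservation identity", {
  pl <- default_pipeline()
  rows <- pl$rows
  n <- length(pl$intake$samples)
  cnt <- function(col) {
    el <- strsplit(as.character(col), ";", fixed = TRUE)
    k <- lengths(el)
    k[col == "NA"] <- 0L
    k
  }
  nref <- n - cnt(rows$heterozygotes) - cnt(rows$homozygotes) -
    cnt(rows$missingGenos)
  lhs <- as.numeric(rows$heterozygosity) + as.numeric(rows$homozygosity) +
    as.numeric(rows$missingness) + nref / n
  expect_equal(lhs, rep(1, nrow(rows)), tolerance = 1e-9)
})

test_that("ts_tv_ratio counts transitions over transversions, with per-sample restriction", {
  rows <- data.frame(
    trTv = c("1", "1", "2", "0"),
    heterozygotes = c("S1;S2", "NA", "S1", "S1"),
    homozygotes = c("NA", "S2", "NA", "NA"),
    stringsAsFactors = FALSE)
  expect_equal(ts_tv_ratio(rows), 2 / 1)
  expect_equal(ts_tv_ratio(rows, sample = "S1"), 1 / 1)
  expect_true(is.na(ts_tv_ratio(rows, sample = "S3")))
  expect_true(is.na(ts_tv_ratio(rows[rows$trTv != "2", ])))  # no transversions
})

test_that("per-transcript effect arrays are complete and parallel", {
  pl <- default_pipeline()
  rows <- pl$rows
  narr <- function(col) lengths(strsplit(as.character(col), ";", fixed = TRUE))
  with_tx <- rows[rows$refSeq.siteType != "intergenic", ]
  expect_gt(nrow(with_tx), 0)
  expect_equal(narr(with_tx$refSeq.siteType), narr(with_tx$refSeq.name))
  expect_equal(narr(with_tx$refSeq.siteType), narr(with_tx$refSeq.exonicFunction))
  # the shared-locus isoform pair: a variant in the shared exon reports both
  iso_rows <- with_tx[grepl("NM_000001;NM_000001b", with_tx$refSeq.name), ]
  if (nrow(iso_rows) > 0)
    expect_equal(narr(iso_rows$refSeq.siteType), rep(2L, nrow(iso_rows)))
})

test_that("annotation writes compressed output that round-trips exactly", {
  pl <- default_pipeline()
  # gzip magic bytes, no uncompressed intermediate left behind
  con <- file(pl$ann, "rb")
  magic <- readBin(con, "raw", 2)
  close(con)
  expect_identical(as.integer(magic), c(0x1fL, 0x8bL))
  back <- read_annotation(pl$ann)
  expect_equal(nrow(back), nrow(pl$rows))
  expect_identical(names(back), names(pl$rows))
  expect_identical(back$refSeq.siteType, pl$rows$refSeq.siteType)
  expect_identical(back$gnomad.af, pl$rows$gnomad.af)
  expect_identical(attr(back, "samples"), pl$intake$samples)
  # empty annotation: header-only, still parseable
  p0 <- tempfile(fileext = ".tsv.gz")
  write_annotation(pl$rows[0, ], p0, samples = pl$intake$samples)
  b0 <- read_annotation(p0)
  expect_equal(nrow(b0), 0L)
  expect_identical(names(b0), names(pl$rows))
})
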