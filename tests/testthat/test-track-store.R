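test_that("score-track values round-trip from wigFix through the store", {
  pl <- default_pipeline()
  # re-read the raw wigFix and compare a block of positions per contig
  lines <- readLines(file.path(pl$dir, "phyloP.wigfix"))
  hdr <- which(startsWith(lines, "fixedStep"))
  for (h in seq_along(hdr)) {
    ctg <- sub(".*chrom=(\\S+).*", "\\1", lines[hdr[h]])
    end <- if (h < length(hdr)) hdr[h + 1] - 1L else length(lines)
    vals <- as.numeric(lines[(hdr[h] + 1L):end])
    probe <- c(1L, 57L, 1000L, length(vals))
    recs <- lapply(probe, function(p) lookup(pl$store, ctg, p - 1L, 1L)[[1]])
    for (k in seq_along(probe))
      expect_equal(unname(recs[[k]]$scores[["phyloP"]]), vals[probe[k]])
  }
})

test_that("lookup returns reference bases, bounds markers, and errors on unknown contigs", {
  pl <- default_pipeline()
  g <- pl$store$genome
  ctg <- names(g)[1]
  rec <- lookup(pl$store, ctg, 0L, 1L)[[1]]
  expect_equal(rec$refBase, substr(g[[ctg]], 1, 1))
  # k-record lookup over a deletion span matches the FASTA slice
  recs <- lookup(pl$store, ctg, 499L, 5L)
  expect_equal(paste(vapply(recs, `[[`, character(1), "refBase"), collapse = ""),
               substr(g[[ctg]], 500, 504))
  # out-of-bounds suffix positions are explicit markers
  n <- nchar(g[[ctg]])
  tail2 <- lookup(pl$store, ctg, n - 1L, 3L)
  expect_false(tail2[[1]]$oob)
  expect_true(tail2[[2]]$oob && tail2[[3]]$oob)
  expect_error(lookup(pl$store, "chrNOPE", 0L, 1L), "chrNOPE")
})

test_that("duplicate track names and missing reference are rejected", {
  pl <- default_pipeline()
  cfgs <- pl$cfg$configs
  dup <- cfgs
  dup[[3]]$name <- dup[[4]]$name
  expect_error(build_store(dup), "duplicate track name")
  expect_error(build_store(cfgs[-1]), "reference track")
  expect_error(track_config("x", "score", "vcf", "f"), "incompatible")
})

test_that("sparse QC: FILTER-failed records are excluded and tallied", {
  pl <- default_pipeline()
  # the gnomad fixture plants 5 RF-failed records
  expect_equal(pl$store$log[["gnomad"]]$qcExcluded, 5L)
  gl <- readLines(file.path(pl$dir, "build.log"))
  expect_true(any(grepl("gnomad.*qcExcluded=5", gl)))
  # none of the RF records are reachable: every stored gnomad entry is PASS
  raw <- readLines(file.path(pl$dir, "gnomad.vcf"))
  body <- raw[!startsWith(raw, "#")]
  f <- strsplit(body, "\t")
  rf <- Filter(function(x) x[[7]] == "RF", f)
  for (r in rf) {
    na <- normalize_allele(r[[1]], as.integer(r[[2]]), r[[4]], r[[5]],
                           pl$store$genome)
    expect_null(sparse_for_allele(pl$store, na, "gnomad"))
  }
})

test_that("right-shifted sparse entries are retrievable by their canonical key", {
  pl <- default_pipeline()
  hp <- pl$fx$truth[pl$fx$truth$label == "hpIns", ]
  al <- normalize_allele(hp$contig, hp$pos, hp$ref, hp$alt, pl$store$genome)
  ent <- sparse_for_allele(pl$store, al, "gnomad")
  expect_false(is.null(ent))
  expect_equal(ent$af, "0.002")  # the value planted on the shifted record
})

test_that("multi-ALT sparse records key one entry per alternate allele", {
  d <- tempdir()
  fa <- file.path(d, "ms.fa")
  write_fasta(c(c1 = paste(rep("ACGT", 30), collapse = "")), fa)
  sv <- file.path(d, "ms.vcf")
  writeLines(c("##fileformat=VCFv4.1",
               '##INFO=<ID=AF,Number=A,Type=Float,Description="af">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO"), collapse = "\t"),
               "c1\t10\t.\tG\tA,C\t50\tPASS\tAF=0.5"), sv)
  st <- build_store(list(
    track_config("ref", "reference", "fasta", fa),
    track_config("pop", "sparse", "vcf", sv, fields = c(AF = "af"))))
  for (alt in c("A", "C")) {
    na <- normalize_allele("c1", 10, "G", alt, st$genome)
    expect_false(is.null(sparse_for_allele(st, na, "pop")), label = alt)
  }
  # empty sparse track: lookups return empty entry lists, no error
  sv2 <- file.path(d, "empty.vcf")
  writeLines(c("##fileformat=VCFv4.1",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO"), collapse = "\t")), sv2)
  st2 <- suppressWarnings(build_store(list(
    track_config("ref", "reference", "fasta", fa),
    track_config("pop", "sparse", "vcf", sv2, fields = c(AF = "af")))))
  rec <- lookup(st2, "c1", 9L, 1L)[[1]]
  expect_identical(rec$sparse$pop, list())
})

test_that("configured INFO fields absent from the source warn and emit missing", {
  d <- tempdir()
  fa <- file.path(d, "w.fa")
  write_fasta(c(c1 = strrep("ACGT", 30)), fa)
  sv <- file.path(d, "w.vcf")
  writeLines(c("##fileformat=VCFv4.1",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO"), collapse = "\t"),
               "c1\t10\t.\tG\tA\t50\tPASS\tAF=0.5"), sv)
  expect_warning(
    st <- build_store(list(
      track_config("ref", "reference", "fasta", fa),
      track_config("pop", "sparse", "vcf", sv,
                   fields = c(AF = "af", MISSING_FIELD = "mf")))),
    "MISSING_FIELD")
  na <- normalize_allele("c1", 10, "G", "A", st$genome)
  ent <- sparse_for_allele(st, na, "pop")
  expect_true(is.na(ent$mf))
})

test_that("scores_for_allele spans match variant type", {
  pl <- default_pipeline()
  st <- pl$store
  ctg <- names(st$genome)[1]
  g <- st$genome[[ctg]]
  snp <- normalize_allele(ctg, 500L, substr(g, 500, 500),
                          setdiff(c("A", "C", "G", "T"),
                                  substr(g, 500, 500))[1], st$genome)
  expect_length(scores_for_allele(st, snp, "phyloP"), 1L)
  # 3-bp deletion over a scored span returns a 3-value array
  del <- list(contig = ctg, pos = 600L,
              ref = substr(g, 600, 603), alt = substr(g, 600, 600),
              type = "DEL")
  expect_length(scores_for_allele(st, del, "phyloP"), 3L)
  # variant beyond the scored 80% of the contig yields an empty vector
  far <- nchar(g) - 50L
  snp2 <- list(contig = ctg, pos = far, ref = substr(g, far, far),
               alt = "A", type = "SNP")
  expect_length(scores_for_allele(st, snp2, "phyloP"), 0L)
})

test_that("BED score tracks spread interval scores per base", {
  pl <- default_pipeline()
  bed <- read.table(file.path(pl$dir, "repeatScore.bed"), sep = "\t")
  r <- bed[1, ]
  rec <- lookup(pl$store, r$V1, r$V2, 1L)[[1]]   # first base of interval
  expect_equal(unname(rec$scores[["repeatScore"]]), r$V5)
  rec2 <- lookup(pl$store, r$V1, r$V3, 1L)[[1]]  # first base past the end
  val2 <- rec2$scores[["repeatScore"]]
  in_other <- any(bed$V1 == r$V1 & bed$V2 <= r$V3 & bed$V3 > r$V3)
  if (!in_other) expect_true(is.na(val2))
})
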