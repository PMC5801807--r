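# Shared fixtures: the full pipeline is expensive enough to build once per
# session and reuse across test files.

.pipeline_cache <- new.env(parent = emptyenv())

run_pipeline <- function(spec, tag) {
  key <- paste0(tag, "_", spec$seed)
  got <- .pipeline_cache[[key]]
  if (!is.null(got)) return(got)
  d <- file.path(tempdir(), paste0("aqfix_", key))
  fx <- cmd_fixtures(spec, d)
  cfg <- load_config(fx$config)
  store <- cmd_build(cfg, out_log = file.path(d, "build.log"))
  res <- intake_vcf(fx$cohort, store$genome)
  rows <- annotate_variants(res$alleles, store, res$samples)
  ann <- file.path(d, "cohort.annotated.tsv.gz")
  write_annotation(rows, ann, samples = res$samples,
                   meta = list(assembly = store$assembly,
                               tallies = as.list(res$log)))
  idx <- cmd_index(ann, cfg)
  out <- list(dir = d, fx = fx, cfg = cfg, store = store, intake = res,
              rows = rows, ann = ann, idx = idx)
  .pipeline_cache[[key]] <- out
  out
}

default_pipeline <- function() run_pipeline(fixture_spec(seed = 7L), "default")

trio_index <- function(pl) {
  idx <- define_custom_synonym(pl$idx, "proband", list(samples = "S_child"))
  define_custom_synonym(idx, "parents", list(samples = c("S_mom", "S_dad")))
}

variant_keys <- function(contig, pos) sort(paste(contig, pos))

# ---- independent representation oracle --------------------------------------

# All VCF-representable (pos, ref, alt) triples, within a +/- `win` bp
# window, whose application to `seq` reproduces `target`. Pure enumeration;
# shares nothing with normalize_allele().
equivalent_reps <- function(seq, target, pos, win = 20L, max_len = 12L) {
  n <- nchar(seq); m <- nchar(target)
  reps <- list()
  for (p2 in max(1L, pos - win):min(n, pos + win)) {
    for (rl in 1L:max_len) {
      if (p2 + rl - 1L > n) break
      al <- m - n + rl
      if (al < 1L || al > max_len) next
      if (p2 + al - 1L > m) next
      # unedited flanks must agree
      if (p2 > 1L && substr(seq, 1L, p2 - 1L) != substr(target, 1L, p2 - 1L))
        next
      if (substr(seq, p2 + rl, n) != substr(target, p2 + al, m)) next
      ref2 <- substr(seq, p2, p2 + rl - 1L)
      alt2 <- substr(target, p2, p2 + al - 1L)
      if (ref2 == alt2) next
      reps[[length(reps) + 1L]] <- list(pos = p2, ref = ref2, alt = alt2)
    }
  }
  reps
}

# random small genome with guaranteed homopolymer structure
random_mini_genome <- function(len = 120L) {
  v <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
  s <- sample.int(len - 12L, 1L) + 2L
  v[s:(s + sample(5:8, 1L))] <- sample(c("A", "C", "G", "T"), 1L)
  paste(v, collapse = "")
}

# a raw record guaranteed to be an edit of the mini genome (possibly messy:
# shared affixes, right-shifted, multi-base)
random_raw_record <- function(seq) {
  n <- nchar(seq)
  pos <- sample(10:(n - 15L), 1L)
  rl <- sample(1:5, 1L)
  ref <- substr(seq, pos, pos + rl - 1L)
  alt <- switch(sample(3L, 1L),
    paste0(substr(ref, 1L, 1L),
           paste(sample(c("A", "C", "G", "T"), sample(0:4, 1L), replace = TRUE),
                 collapse = "")),
    paste(sample(c("A", "C", "G", "T"), sample(1:5, 1L), replace = TRUE),
          collapse = ""),
    { k <- sample(0:2, 1L)  # embed genome suffix to force redundant tails
      paste0(paste(sample(c("A", "C", "G", "T"), sample(1:3, 1L), replace = TRUE),
                   collapse = ""),
             substr(seq, pos + rl - k, pos + rl - 1L)) })
  list(pos = pos, ref = ref, alt = alt)
}
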