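# Cohort-variant planning and emission for the fixture generator.
#
# plan_cohort() derives the complete variant plan (canonical alleles,
# genotypes, adversarial VCF representations, truth labels) from the spec
# seed; make_cohort_vcf() and make_sparse_track() both re-derive the same
# plan so the cohort file and the annotation tracks agree on positions.

comp_base <- function(b) chartr("ACGT", "TGCA", b)

# scan a planned transcript's CDS for a single-base change with the requested
# coding consequence; returns genomic (contig, pos, ref, alt)
scan_cds_snp <- function(tx, genome, want = "nonsynonymous", skip = 0L) {
  stopifnot(tx$coding)
  cds <- substr(tx$seq_tx, 91L, nchar(tx$seq_tx) - 90L)
  gpos <- tx_gpos(tx)
  code <- Biostrings::GENETIC_CODE
  ncod <- nchar(cds) / 3L
  found <- 0L
  for (j in 2:(ncod - 1L)) {
    codon <- substr(cds, 3L * j - 2L, 3L * j)
    aa0 <- code[[codon]]
    for (k in 1:3) {
      cur <- substr(codon, k, k)
      for (b in setdiff(BASES, cur)) {
        nc <- codon
        substr(nc, k, k) <- b
        aa1 <- code[[nc]]
        cls <- if (aa1 == "*" && aa0 != "*") "stopGain"
               else if (aa0 == aa1) "synonymous"
               else "nonsynonymous"
        if (cls == want) {
          found <- found + 1L
          if (found > skip) {
            t <- 90L + 3L * (j - 1L) + k
            g <- gpos[t]
            ref <- genome_slice(genome, tx$contig, g, g)
            alt <- if (tx$strand == "+") b else comp_base(b)
            return(list(contig = tx$contig, pos = g, ref = ref, alt = alt))
          }
        }
      }
    }
  }
  stop("no ", want, " SNP found in transcript ", tx$name)
}

# equivalent non-parsimonious representation of a pure indel inside a
# homopolymer: shift the anchor right within the run and append one shared
# suffix base (the documented adversarial generator)
rightshift_rep <- function(genome, contig, pos, ref, alt, shift = 3L) {
  seq <- genome[[contig]]
  ins <- nchar(alt) > nchar(ref)
  p2 <- pos + shift
  ref2 <- substr(seq, p2, p2 + nchar(ref) - 1L)
  varlen <- abs(nchar(alt) - nchar(ref))
  runbase <- substr(if (ins) alt else ref, 2L, 2L)
  alt2 <- if (ins) paste0(substr(ref2, 1L, 1L), strrep(runbase, varlen),
                          substr(ref2, 2L, nchar(ref2)))
          else substr(ref2, 1L, nchar(ref2) - varlen)
  # redundant shared suffix base
  nxt <- substr(seq, p2 + nchar(ref2), p2 + nchar(ref2))
  list(pos = p2, ref = paste0(ref2, nxt), alt = paste0(alt2, nxt))
}

# genotype classes for one biallelic variant under Hardy-Weinberg sampling,
# Mendelian-consistent within the configured trio
hw_classes <- function(spec, maf) {
  n <- length(spec$samples)
  draw <- function() sum(stats::rbinom(2L, 1L, maf))
  cnt <- vapply(seq_len(n), function(i) draw(), integer(1))
  names(cnt) <- spec$samples
  if (!is.null(spec$trio)) {
    m <- cnt[[spec$trio[["mother"]]]]
    f <- cnt[[spec$trio[["father"]]]]
    pick <- function(c2) if (c2 == 0L) 0L else if (c2 == 2L) 1L
            else stats::rbinom(1L, 1L, 0.5)
    cnt[[spec$trio[["proband"]]]] <- pick(m) + pick(f)
  }
  c("refHom", "het", "altHom")[cnt + 1L]
}

class_to_gt <- function(cls, allele_idx = 1L) {
  switch(cls,
         refHom = "0/0",
         het = paste0("0/", allele_idx),
         altHom = paste0(allele_idx, "/", allele_idx),
         missing = "./.")
}

.plan_cache <- new.env(parent = emptyenv())

plan_cohort <- function(spec, genome) {
  ck <- paste(deparse(spec), collapse = "")
  hit <- .plan_cache[[ck]]
  if (!is.null(hit)) return(hit)
  out <- plan_cohort_impl(spec, genome)
  .plan_cache[[ck]] <- out
  out
}

plan_cohort_impl <- function(spec, genome) {
  layout <- plan_layout(spec)
  with_seed(sub_seed(spec, "cohort"), {
    ctgs <- names(spec$contigs)
    vars <- list()
    used <- new.env(parent = emptyenv())
    add_var <- function(contig, pos, ref, alt, label,
                        vcfPos = NULL, vcfRef = NULL, vcfAlt = NULL,
                        group = NA_integer_) {
      na <- normalize_allele(contig, pos, ref, alt, genome)
      if (is.null(na)) return(invisible(FALSE))
      key <- paste(na$contig, na$pos, na$ref, na$alt, sep = ":")
      if (!is.null(used[[key]])) return(invisible(FALSE))
      used[[key]] <- TRUE
      vars[[length(vars) + 1L]] <<- list(
        contig = na$contig, pos = na$pos, ref = na$ref, alt = na$alt,
        type = na$type, compact = na$compact, label = label,
        vcfPos = if (is.null(vcfPos)) na$pos else vcfPos,
        vcfRef = if (is.null(vcfRef)) na$ref else vcfRef,
        vcfAlt = if (is.null(vcfAlt)) na$alt else vcfAlt,
        group = group)
      invisible(TRUE)
    }

    # --- designed variants ---------------------------------------------------
    ntx <- length(layout$tx)
    if (ntx >= 3L) {
      s <- scan_cds_snp(layout$tx[[3L]], genome, "stopGain")
      add_var(s$contig, s$pos, s$ref, s$alt, "edsStopGain")
    }
    if (ntx >= 1L) {
      for (sk in 0:1) {
        s <- scan_cds_snp(layout$tx[[1L]], genome, "nonsynonymous", skip = sk * 7L)
        add_var(s$contig, s$pos, s$ref, s$alt, "rareDeleterious")
      }
    }
    # homopolymer indels, emitted right-shifted with a redundant suffix base
    hp1 <- layout$hp[layout$hp$contig == ctgs[1] & layout$hp$start == 101L, ]
    anchor <- 100L
    pad <- genome_slice(genome, ctgs[1], anchor, anchor)
    ins <- list(contig = ctgs[1], pos = anchor, ref = pad,
                alt = paste0(pad, hp1$base))
    rr <- rightshift_rep(genome, ins$contig, ins$pos, ins$ref, ins$alt)
    add_var(ins$contig, ins$pos, ins$ref, ins$alt, "hpIns",
            vcfPos = rr$pos, vcfRef = rr$ref, vcfAlt = rr$alt)
    if (length(ctgs) > 1L) {
      hp2 <- layout$hp[layout$hp$contig == ctgs[2] & layout$hp$start == 101L, ]
      pad2 <- genome_slice(genome, ctgs[2], 100L, 100L)
      del <- list(contig = ctgs[2], pos = 100L,
                  ref = paste0(pad2, hp2$base), alt = pad2)
      rr <- rightshift_rep(genome, del$contig, del$pos, del$ref, del$alt)
      add_var(del$contig, del$pos, del$ref, del$alt, "hpDel",
              vcfPos = rr$pos, vcfRef = rr$ref, vcfAlt = rr$alt)
    }
    # multiallelic record with two complex indel alleles at the T-run
    trun <- layout$hp[layout$hp$contig == ctgs[1] & layout$hp$base == "T", ]
    ma_anchor <- trun$start - 1L
    mx <- genome_slice(genome, ctgs[1], ma_anchor, ma_anchor)
    ma_win <- genome_slice(genome, ctgs[1], ma_anchor, ma_anchor + 2L)  # X T T
    ma_del <- list(pos = ma_anchor, ref = paste0(mx, "T"), alt = mx)
    ma_ins <- list(pos = ma_anchor, ref = mx, alt = paste0(mx, "T"))
    alt1 <- apply_allele(ma_win, 1L, ma_del$ref, ma_del$alt)   # XT
    alt2 <- apply_allele(ma_win, 1L, ma_ins$ref, ma_ins$alt)   # XTTT
    add_var(ctgs[1], ma_del$pos, ma_del$ref, ma_del$alt, "multiDel",
            vcfPos = ma_anchor, vcfRef = ma_win, vcfAlt = alt1, group = 1L)
    add_var(ctgs[1], ma_ins$pos, ma_ins$ref, ma_ins$alt, "multiIns",
            vcfPos = ma_anchor, vcfRef = ma_win, vcfAlt = alt2, group = 1L)

    # --- de novo -------------------------------------------------------------
    n_dn <- spec$nDeNovo
    # --- HWE-deviating variants ---------------------------------------------
    n_hwe <- if (is.null(spec$hweDeviation)) 0L else spec$hweDeviation[[1L]]

    # --- random fill ---------------------------------------------------------
    n_designed <- length(vars)
    n_random <- max(0L, spec$nCohortVariants - n_designed - n_dn - n_hwe)
    rand_pos <- function() {
      ctg <- sample(ctgs, 1L)
      list(ctg = ctg, pos = sample(300:(spec$contigs[[ctg]] - 300L), 1L))
    }
    plant_random <- function(label) {
      for (try in 1:50) {
        rp <- rand_pos()
        ref1 <- genome_slice(genome, rp$ctg, rp$pos, rp$pos)
        kind <- sample(c("SNP", "INS", "DEL"), 1L, prob = c(0.75, 0.12, 0.13))
        ok <- switch(kind,
          SNP = add_var(rp$ctg, rp$pos, ref1, sample(setdiff(BASES, ref1), 1L), label),
          INS = add_var(rp$ctg, rp$pos, ref1, paste0(ref1, rand_dna(sample(1:3, 1L))), label),
          DEL = {
            k <- sample(1:3, 1L)
            add_var(rp$ctg, rp$pos,
                    genome_slice(genome, rp$ctg, rp$pos, rp$pos + k), ref1, label)
          })
        if (ok) return(TRUE)
      }
      FALSE
    }
    for (i in seq_len(n_dn)) plant_random("deNovo")
    for (i in seq_len(n_hwe)) plant_random("hweDev")
    for (i in seq_len(n_random)) plant_random("random")

    # --- genotypes -----------------------------------------------------------
    nS <- length(spec$samples)
    trio <- spec$trio
    for (i in seq_along(vars)) {
      v <- vars[[i]]
      maf <- stats::runif(1L, 0.08, 0.5)
      cls <- if (identical(v$label, "deNovo") && !is.null(trio)) {
        cl <- rep("refHom", nS)
        cl[match(trio[["proband"]], spec$samples)] <- "het"
        cl
      } else if (identical(v$label, "hweDev")) {
        cnts <- spec$hweDeviation[[2L]]
        cl <- rep(c("refHom", "het", "altHom"), times = cnts)
        # trio members take the leading (refHom-first) slots so a deviating
        # row can never mimic a de novo transmission pattern
        ord <- seq_len(nS)
        if (!is.null(trio)) {
          tidx <- match(unname(trio[c("proband", "mother", "father")]), spec$samples)
          ord <- c(tidx, setdiff(ord, tidx))
        }
        out <- character(nS); out[ord] <- cl
        out
      } else if (nS > 0L) {
        hw_classes(spec, maf)
      } else character(0)
      vars[[i]]$maf <- maf
      vars[[i]]$classes <- cls
    }

    # --- missingness ---------------------------------------------------------
    if (spec$missingRate > 0 && nS > 0L) {
      forced <- 0L
      for (i in seq_along(vars)) {
        v <- vars[[i]]
        if (identical(v$label, "deNovo")) next  # de novo rows stay fully called
        cls <- v$classes
        if (!is.null(trio) && forced < 2L &&
            cls[match(trio[["proband"]], spec$samples)] %in% c("het", "altHom")) {
          # deliberately hide both parents at a transmitted site: a naive
          # proband -parents query now yields a false positive that the
          # missingness < .1 clause must remove
          cls[match(unname(trio[c("mother", "father")]), spec$samples)] <- "missing"
          forced <- forced + 1L
        }
        drop <- stats::runif(nS) < spec$missingRate
        cls[drop] <- "missing"
        vars[[i]]$classes <- cls
      }
    }
    list(layout = layout, vars = vars)
  })
}

#' Generate the multi-sample cohort VCF with planted truth
#'
#' Emits SNPs, insertions and deletions (some deliberately right-shifted and
#' suffix-padded inside homopolymer runs), one multiallelic record carrying
#' two complex indel alleles, one reference-only record (ALT `.`), one
#' FILTER-failed record, Mendelian-consistent trio genotypes with the
#' configured number of proband-only (de novo) alleles, optional
#' HWE-deviating genotype rows and optional missingness. The returned truth
#' table records the canonical (parsimonious, left-shifted) form, the emitted
#' VCF form, per-sample genotype classes, de novo flags and Ts/Tv class of
#' every planted variant.
#'
#' @param genome An `aq_genome` from [make_genome()] (same spec).
#' @param spec A [fixture_spec()].
#' @param path Output path; a `.gz` suffix writes gzip directly.
#' @return Invisibly, a list with `path` and `truth` (data.frame).
#' @export
make_cohort_vcf <- function(genome, spec, path) {
  plan <- plan_cohort(spec, genome)
  vars <- plan$vars
  nS <- length(spec$samples)

  # emission records: one per variant, except grouped multiallelic alleles
  recs <- list()
  grouped <- Filter(function(v) !is.na(v$group), vars)
  single <- Filter(function(v) is.na(v$group), vars)
  for (v in single) {
    gts <- vapply(v$classes, class_to_gt, character(1), allele_idx = 1L)
    recs[[length(recs) + 1L]] <- list(
      contig = v$contig, pos = v$vcfPos, id = ".", ref = v$vcfRef,
      alts = v$vcfAlt, filter = "PASS", gts = unname(gts))
  }
  if (length(grouped) == 2L) {
    g1 <- grouped[[1L]]; g2 <- grouped[[2L]]
    gts <- vapply(seq_len(nS), function(i) {
      c1 <- g1$classes[[i]]; c2 <- g2$classes[[i]]
      if (c1 == "missing" || c2 == "missing") return("./.")
      n1 <- switch(c1, refHom = 0L, het = 1L, altHom = 2L)
      n2 <- switch(c2, refHom = 0L, het = 1L, altHom = 2L)
      if (n1 + n2 > 2L) { n1 <- min(n1, 1L); n2 <- min(n2, 2L - n1) }
      al <- c(rep(1L, n1), rep(2L, n2), rep(0L, 2L - n1 - n2))
      paste(sort(al), collapse = "/")
    }, character(1))
    # grouped classes may have been clipped to a representable diploid GT;
    # recompute truth classes from the emitted genotypes
    for (k in 1:2) {
      idx <- if (k == 1L) g1 else g2
      cl <- vapply(gts, function(g) {
        a <- strsplit(g, "/", fixed = TRUE)[[1L]]
        if (any(a == ".")) return("missing")
        n <- sum(a == as.character(k))
        if (n == 2L) "altHom" else if (n == 1L) "het" else "refHom"
      }, character(1))
      if (k == 1L) g1$classes <- unname(cl) else g2$classes <- unname(cl)
    }
    for (i in seq_along(vars)) {
      if (!is.na(vars[[i]]$group)) {
        if (vars[[i]]$label == "multiDel") vars[[i]]$classes <- g1$classes
        else vars[[i]]$classes <- g2$classes
      }
    }
    recs[[length(recs) + 1L]] <- list(
      contig = g1$contig, pos = g1$vcfPos, id = ".", ref = g1$vcfRef,
      alts = c(g1$vcfAlt, g2$vcfAlt), filter = "PASS", gts = unname(gts))
  }
  # junk records: a reference site and a FILTER-failed site
  ctg1 <- names(spec$contigs)[1]
  refsite_pos <- 150L
  recs[[length(recs) + 1L]] <- list(
    contig = ctg1, pos = refsite_pos, id = ".",
    ref = genome_slice(genome, ctg1, refsite_pos, refsite_pos),
    alts = ".", filter = "PASS", gts = rep("0/0", nS))
  q10_pos <- 170L
  q10_ref <- genome_slice(genome, ctg1, q10_pos, q10_pos)
  recs[[length(recs) + 1L]] <- list(
    contig = ctg1, pos = q10_pos, id = ".", ref = q10_ref,
    alts = setdiff(BASES, q10_ref)[1L], filter = "q10",
    gts = rep("0/1", nS))

  ord <- order(vapply(recs, `[[`, character(1), "contig"),
               vapply(recs, `[[`, integer(1), "pos"))
  recs <- recs[ord]

  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  writeLines("##fileformat=VCFv4.1", con)
  for (ctg in names(spec$contigs))
    writeLines(sprintf("##contig=<ID=%s,length=%d>", ctg, spec$contigs[[ctg]]), con)
  writeLines('##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">', con)
  hdr <- c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO")
  if (nS > 0L) hdr <- c(hdr, "FORMAT", spec$samples)
  writeLines(paste(hdr, collapse = "\t"), con)
  for (r in recs) {
    f <- c(r$contig, r$pos, r$id, r$ref, paste(r$alts, collapse = ","),
           "100", r$filter, ".")
    if (nS > 0L) f <- c(f, "GT", r$gts)
    writeLines(paste(f, collapse = "\t"), con)
  }
  close(con)

  truth <- do.call(rbind, lapply(vars, function(v) {
    tstv <- if (v$type == "SNP") {
      if (tr_tv_code(v$ref, v$alt) == 1L) "ts" else "tv"
    } else "none"
    row <- data.frame(
      label = v$label, contig = v$contig, pos = v$pos, ref = v$ref,
      alt = v$alt, type = v$type, compact = v$compact,
      deNovo = identical(v$label, "deNovo"),
      hweDev = identical(v$label, "hweDev"), tstv = tstv,
      vcfPos = v$vcfPos, vcfRef = v$vcfRef, vcfAlt = v$vcfAlt,
      stringsAsFactors = FALSE)
    for (i in seq_len(nS))
      row[[paste0("gt_", spec$samples[i])]] <- v$classes[[i]]
    row
  }))
  invisible(list(path = path, truth = truth))
}

#' Generate a sparse annotation track (VCF with INFO fields)
#'
#' Entries cover a fraction of the planted cohort variants (so annotation
#' round-trips are testable) plus novel alleles. The gnomAD-like track plants
#' FILTER-failed records (random-forest QC failures, which the store must
#' exclude) and one deliberately right-shifted representation of a cohort
#' indel (which the store must still key canonically).
#'
#' @param genome,spec As elsewhere.
#' @param path Output path.
#' @param kind `"clinvar"`, `"gnomad"` or `"dbsnp"`.
#' @return Invisibly, the emitted record count.
#' @export
make_sparse_track <- function(genome, spec, path, kind = c("clinvar", "gnomad", "dbsnp")) {
  kind <- match.arg(kind)
  plan <- plan_cohort(spec, genome)
  vars <- plan$vars
  with_seed(sub_seed(spec, paste0("sparse_", kind)), {
    recs <- list()
    add <- function(contig, pos, ref, alt, filter, info, id = ".")
      recs[[length(recs) + 1L]] <<- list(contig = contig, pos = pos, id = id,
                                         ref = ref, alt = alt,
                                         filter = filter, info = info)
    sigs <- c("benign", "uncertain_significance", "likely_benign", "pathogenic")
    revs <- c("criteria_provided", "no_assertion", "expert_review")
    dis <- c("hereditary_cancer-predisposing_syndrome", "not_provided")

    if (kind == "clinvar") {
      for (v in vars) {
        if (v$label == "edsStopGain") {
          add(v$contig, v$pos, v$ref, v$alt, "PASS",
              "SIG=pathogenic;REVSTAT=expert_review;DISEASE=Ehlers-Danlos_syndrome_type_4")
        } else if (v$label == "rareDeleterious") {
          add(v$contig, v$pos, v$ref, v$alt, "PASS",
              "SIG=pathogenic;REVSTAT=expert_review;DISEASE=hereditary_cancer-predisposing_syndrome")
        } else if (stats::runif(1) < 0.3) {
          add(v$contig, v$pos, v$ref, v$alt, "PASS",
              sprintf("SIG=%s;REVSTAT=%s;DISEASE=%s", sample(sigs, 1L),
                      sample(revs, 1L), sample(dis, 1L)))
        }
      }
    } else if (kind == "gnomad") {
      hp_skip <- vapply(vars, function(v) v$label == "hpIns", logical(1))
      for (v in vars[!hp_skip]) {
        if (v$label %in% c("edsStopGain", "rareDeleterious")) {
          add(v$contig, v$pos, v$ref, v$alt, "PASS", "AF=0.0001")
        } else if (stats::runif(1) < 0.7) {
          add(v$contig, v$pos, v$ref, v$alt, "PASS",
              sprintf("AF=%.3g", 10^stats::runif(1, -4.5, -0.4)))
        }
      }
      # right-shifted representation of the homopolymer insertion: the store
      # must normalize before keying so cohort lookups still hit it
      hp <- Filter(function(v) v$label == "hpIns", vars)
      if (length(hp)) {
        v <- hp[[1L]]
        add(v$contig, v$vcfPos, v$vcfRef, v$vcfAlt, "PASS", "AF=0.002")
      }
      # QC-failed records (random-forest failures): must be excluded
      ctgs <- names(spec$contigs)
      for (i in 1:5) {
        ctg <- sample(ctgs, 1L)
        p <- sample(300:(spec$contigs[[ctg]] - 300L), 1L)
        r <- genome_slice(genome, ctg, p, p)
        add(ctg, p, r, sample(setdiff(BASES, r), 1L), "RF",
            sprintf("AF=%.3g", 10^stats::runif(1, -4, -1)))
      }
      # novel PASS entries up to nTrackVariants
      extra <- max(0L, spec$nTrackVariants - length(recs))
      ctgs <- names(spec$contigs)
      for (i in seq_len(extra)) {
        ctg <- sample(ctgs, 1L)
        p <- sample(300:(spec$contigs[[ctg]] - 300L), 1L)
        r <- genome_slice(genome, ctg, p, p)
        add(ctg, p, r, sample(setdiff(BASES, r), 1L), "PASS",
            sprintf("AF=%.3g", 10^stats::runif(1, -4.5, -0.4)))
      }
    } else { # dbsnp
      rs <- 760000000L
      for (v in vars) {
        if (stats::runif(1) < 0.8) {
          rs <- rs + sample(1:500, 1L)
          add(v$contig, v$pos, v$ref, v$alt, "PASS", ".",
              id = paste0("rs", rs))
        }
      }
    }

    ord <- order(vapply(recs, `[[`, character(1), "contig"),
                 vapply(recs, `[[`, numeric(1), "pos"))
    recs <- recs[ord]
    con <- file(path, "wt")
    writeLines("##fileformat=VCFv4.1", con)
    info_hdr <- switch(kind,
      clinvar = c('##INFO=<ID=SIG,Number=1,Type=String,Description="Clinical significance">',
                  '##INFO=<ID=REVSTAT,Number=1,Type=String,Description="Review status">',
                  '##INFO=<ID=DISEASE,Number=1,Type=String,Description="Condition">'),
      gnomad = '##INFO=<ID=AF,Number=1,Type=Float,Description="Allele frequency">',
      dbsnp = character(0))
    if (length(info_hdr)) writeLines(info_hdr, con)
    writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO"), collapse = "\t"), con)
    for (r in recs)
      writeLines(paste(r$contig, r$pos, r$id, r$ref, r$alt, "100",
                       r$filter, r$info, sep = "\t"), con)
    close(con)
    invisible(length(recs))
  })
}
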