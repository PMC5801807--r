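#' Stream a cohort VCF (or SNP-format) file into raw records
#'
#' Line-based streaming reader for multi-sample VCF 4.x, plain or
#' gzip-compressed (`gzfile()` handles both transparently). Malformed body
#' lines — too few columns, empty REF, unparsable POS — are skipped and
#' tallied rather than aborting the run, so one truncated line does not cost
#' the cohort. A simple tab-delimited "SNP format" dialect
#' (contig, pos, ref, alt, genotypes...) is accepted behind the same record
#' contract via `format = "snp"`.
#'
#' @param path Input file path.
#' @param format `"vcf"` (default) or `"snp"`.
#' @return A list of class `raw_vcf`: `records` (list of raw records:
#'   `contig`, `pos`, `id`, `ref`, `alts` (character vector, `"."` kept
#'   as-is), `qual`, `filter`, `info`, `gts` (character vector of genotype
#'   strings)), `samples`, and `log` (named tallies, including
#'   `skippedMalformed`).
#' @export
parse_vcf <- function(path, format = c("vcf", "snp")) {
  format <- match.arg(format)
  con <- gzfile(path, open = "rt")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  if (format == "snp") return(parse_snp_lines(lines))

  hdr <- grep("^#CHROM\t", lines)
  if (length(hdr) == 0L) stop("not a VCF: missing #CHROM header line in ", path)
  hdr <- hdr[[1L]]
  cols <- strsplit(lines[[hdr]], "\t", fixed = TRUE)[[1L]]
  samples <- if (length(cols) > 9L) cols[10:length(cols)] else character(0)
  body <- lines[seq_along(lines) > hdr]
  body <- body[nzchar(body) & !startsWith(body, "#")]

  skipped <- 0L
  records <- vector("list", length(body))
  n <- 0L
  for (ln in body) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(f) < 8L ||
        (length(samples) > 0L && length(f) < 9L + length(samples))) {
      skipped <- skipped + 1L; next
    }
    pos <- suppressWarnings(as.integer(f[[2L]]))
    if (is.na(pos) || pos < 1L || !nzchar(f[[4L]])) { skipped <- skipped + 1L; next }
    gts <- if (length(samples)) sub(":.*$", "", f[10:(9L + length(samples))]) else character(0)
    n <- n + 1L
    records[[n]] <- list(
      contig = f[[1L]], pos = pos, id = f[[3L]], ref = toupper(f[[4L]]),
      alts = strsplit(f[[5L]], ",", fixed = TRUE)[[1L]],
      qual = f[[6L]], filter = f[[7L]], info = f[[8L]], gts = gts)
  }
  structure(list(records = records[seq_len(n)], samples = samples,
                 log = c(skippedMalformed = skipped)),
            class = "raw_vcf")
}

parse_snp_lines <- function(lines) {
  lines <- lines[nzchar(lines)]
  header <- startsWith(lines[1], "#")
  samples <- character(0)
  if (header) {
    cols <- strsplit(sub("^#", "", lines[1]), "\t", fixed = TRUE)[[1L]]
    if (length(cols) > 4L) samples <- cols[5:length(cols)]
    lines <- lines[-1L]
  }
  skipped <- 0L
  records <- list()
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(f) < 4L) { skipped <- skipped + 1L; next }
    pos <- suppressWarnings(as.integer(f[[2L]]))
    if (is.na(pos)) { skipped <- skipped + 1L; next }
    gts <- if (length(f) > 4L) f[5:length(f)] else character(0)
    records[[length(records) + 1L]] <- list(
      contig = f[[1L]], pos = pos, id = ".", ref = toupper(f[[3L]]),
      alts = strsplit(toupper(f[[4L]]), ",", fixed = TRUE)[[1L]],
      qual = ".", filter = "PASS", info = ".", gts = gts)
  }
  structure(list(records = records, samples = samples,
                 log = c(skippedMalformed = skipped)),
            class = "raw_vcf")
}

#' Site-level quality control for one raw record
#'
#' Low-quality and non-variant sites are removed before annotation: a record
#' is dropped when its FILTER column is neither `PASS` nor `.` (e.g. a
#' failed random-forest or quality filter in the source), when its ALT is `.`
#' (a reference site — calling such loci variant is an annotation error), or
#' when every ALT is a symbolic/breakend allele.
#'
#' @param rec A raw record from [parse_vcf()].
#' @param keep_filtered If `TRUE`, FILTER-failed sites are kept (for inputs
#'   already filtered upstream); reference sites are still dropped.
#' @return `NULL` to keep, or a character drop reason:
#'   `"failedFilter"`, `"referenceSite"`, `"symbolicAlt"`.
#' @export
filter_low_quality <- function(rec, keep_filtered = FALSE) {
  if (!keep_filtered && !(rec$filter %in% c("PASS", ".")))
    return("failedFilter")
  alts <- setdiff(rec$alts, ".")
  if (length(alts) == 0L) return("referenceSite")
  if (all(grepl("[][<>]", alts))) return("symbolicAlt")
  NULL
}

#' Split a multiallelic record into biallelic children with recoded genotypes
#'
#' One child is produced per (non-symbolic) ALT allele. For each child, each
#' sample is classed with respect to that single alternate allele: any `.`
#' allele in the genotype makes the sample `missing` at the site; otherwise
#' the sample is `het` (allele present once), `altHom` (twice), or `refHom`.
#' Non-diploid genotypes or allele indexes beyond the ALT count flag the whole
#' record as malformed (skipped, tallied by the caller).
#'
#' @param rec A raw record that passed QC.
#' @return A list of children, each `list(contig, pos, ref, alt, classes)`
#'   where `classes` is a character vector (one of `"refHom"`, `"het"`,
#'   `"altHom"`, `"missing"`) named by nothing but parallel to the sample
#'   order; or `NULL` when the record's genotypes are malformed.
#' @export
split_multiallelic <- function(rec) {
  alts <- rec$alts[rec$alts != "." & !grepl("[][<>]", rec$alts)]
  if (length(alts) == 0L) return(list())
  nalt <- length(rec$alts)

  # parse genotypes once: matrix of two allele indexes per sample (NA = ".")
  ngt <- length(rec$gts)
  a1 <- integer(ngt); a2 <- integer(ngt); bad <- FALSE
  if (ngt) {
    parts <- strsplit(rec$gts, "[/|]")
    for (i in seq_len(ngt)) {
      p <- parts[[i]]
      if (length(p) != 2L) { bad <- TRUE; break }  # diploid assumed
      v <- suppressWarnings(as.integer(p))
      v[p == "."] <- NA_integer_
      if (any(!is.na(v) & (v < 0L | v > nalt))) { bad <- TRUE; break }
      if (anyNA(v) && any(p != "." & is.na(v))) { bad <- TRUE; break }
      a1[[i]] <- v[[1L]]; a2[[i]] <- v[[2L]]
    }
  }
  if (bad) return(NULL)

  lapply(alts, function(alt) {
    k <- match(alt, rec$alts)
    classes <- if (ngt) {
      cnt <- (ifelse(is.na(a1), 0L, a1 == k)) + (ifelse(is.na(a2), 0L, a2 == k))
      cls <- ifelse(is.na(a1) | is.na(a2), "missing",
                    ifelse(cnt == 2L, "altHom", ifelse(cnt == 1L, "het", "refHom")))
      as.character(cls)
    } else character(0)
    list(contig = rec$contig, pos = rec$pos, id = rec$id,
         ref = rec$ref, alt = toupper(alt), classes = classes)
  })
}

#' Run the full intake stage on one cohort file
#'
#' Parse, QC-filter, split, reference-check and normalize every allele of a
#' cohort VCF. Alleles identical to the reference after trimming are dropped;
#' drop reasons are tallied for the run manifest.
#'
#' @param path Cohort VCF (or SNP-format) file.
#' @param genome An `aq_genome` matching the file's assembly.
#' @param keep_filtered Passed to [filter_low_quality()].
#' @param format Passed to [parse_vcf()].
#' @param contig_alias Optional named character vector mapping VCF contig
#'   names to store contig names (e.g. `c("15" = "chr15")`).
#' @return List: `alleles` (list of `list(allele = normalized_allele,
#'   classes)`), `samples`, `log` (named drop tallies).
#' @export
intake_vcf <- function(path, genome, keep_filtered = FALSE, format = "vcf",
                       contig_alias = NULL) {
  vcf <- parse_vcf(path, format = format)
  tally <- c(vcf$log, failedFilter = 0L, referenceSite = 0L, symbolicAlt = 0L,
             refMismatch = 0L, refWarnN = 0L, identicalAfterTrim = 0L,
             badGenotype = 0L, unknownContig = 0L, kept = 0L)
  out <- list()
  for (rec in vcf$records) {
    if (!is.null(contig_alias) && rec$contig %in% names(contig_alias))
      rec$contig <- contig_alias[[rec$contig]]
    reason <- filter_low_quality(rec, keep_filtered)
    if (!is.null(reason)) { tally[[reason]] <- tally[[reason]] + 1L; next }
    if (is.null(genome[[rec$contig]])) {
      tally[["unknownContig"]] <- tally[["unknownContig"]] + 1L; next
    }
    chk <- check_reference(rec$contig, rec$pos, rec$ref, genome)
    if (chk == "mismatch") { tally[["refMismatch"]] <- tally[["refMismatch"]] + 1L; next }
    if (chk == "warn_n") tally[["refWarnN"]] <- tally[["refWarnN"]] + 1L
    children <- split_multiallelic(rec)
    if (is.null(children)) { tally[["badGenotype"]] <- tally[["badGenotype"]] + 1L; next }
    for (ch in children) {
      na <- normalize_allele(ch$contig, ch$pos, ch$ref, ch$alt, genome)
      if (is.null(na)) {
        tally[["identicalAfterTrim"]] <- tally[["identicalAfterTrim"]] + 1L
        next
      }
      tally[["kept"]] <- tally[["kept"]] + 1L
      out[[length(out) + 1L]] <- list(allele = na, classes = ch$classes, id = ch$id)
    }
  }
  list(alleles = out, samples = vcf$samples, log = tally)
}
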