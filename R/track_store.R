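#' Declare one annotation track
#'
#' @param name Short identifier used as the output field prefix (must be
#'   unique within a build).
#' @param category One of `"reference"`, `"gene"`, `"score"`, `"sparse"`.
#' @param sourceFormat One of `"fasta"`, `"genePredExt"`, `"wigFix"`,
#'   `"bed"`, `"vcf"`; must be compatible with the category
#'   (reference-fasta, gene-genePredExt, score-wigFix/bed, sparse-vcf/bed).
#' @param file Source file path.
#' @param fields Named character vector mapping source field names (VCF INFO
#'   keys, or `"ID"` for the VCF ID column) to output field names. Ignored
#'   for non-sparse tracks.
#' @param version Free-text provenance string recorded in the build log.
#' @return A `track_config` list.
#' @export
track_config <- function(name, category, sourceFormat, file,
                         fields = NULL, version = "fixture-1") {
  category <- match.arg(category, c("reference", "gene", "score", "sparse"))
  sourceFormat <- match.arg(sourceFormat,
                            c("fasta", "genePredExt", "wigFix", "bed", "vcf"))
  compat <- list(reference = "fasta", gene = "genePredExt",
                 score = c("wigFix", "bed"), sparse = c("vcf", "bed"))
  if (!sourceFormat %in% compat[[category]])
    stop("track ", name, ": sourceFormat '", sourceFormat,
         "' incompatible with category '", category, "'")
  structure(list(name = name, category = category,
                 sourceFormat = sourceFormat, file = file,
                 fields = fields, version = version),
            class = "track_config")
}

#' Build the per-position annotation store from configured tracks
#'
#' Creates an in-memory genome store: the reference sequence, per-base score
#' tracks, interval-indexed gene models with precomputed CDS structure, and
#' sparse annotation entries keyed by the canonical (normalized,
#' left-shifted) form of each allele. Sparse records whose FILTER is neither
#' `PASS` nor `.` fail source quality control and are excluded (tallied in
#' the build log), mirroring the exclusion of e.g. random-forest QC failures
#' from population frequency sources.
#'
#' @param configs List of [track_config()]s; exactly one reference track.
#' @param out_log Optional path for the plain-text build log.
#' @param assembly Assembly label recorded in metadata.
#' @return An environment of class `genome_store`.
#' @export
build_store <- function(configs, out_log = NULL, assembly = "custom") {
  nm <- vapply(configs, `[[`, character(1), "name")
  if (anyDuplicated(nm))
    stop("duplicate track name: ", nm[duplicated(nm)][1])
  refs <- Filter(function(cc) cc$category == "reference", configs)
  if (length(refs) != 1L)
    stop("exactly one reference track is required (got ", length(refs), ")")
  for (cc in configs)
    if (!file.exists(cc$file)) stop("track ", cc$name, ": missing file ", cc$file)

  store <- new.env(parent = emptyenv())
  store$assembly <- assembly
  store$built <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  store$genome <- read_genome(refs[[1L]]$file)
  store$ref_name <- refs[[1L]]$name
  store$score <- list()      # track -> contig -> numeric vector (NA absent)
  store$sparse <- new.env(parent = emptyenv())  # "trk\tctg\tpos\tref\talt" -> fields
  store$sparse_pos <- new.env(parent = emptyenv())  # "trk\tctg\tpos" -> keys
  store$sparse_tracks <- character(0)
  store$sparse_fields <- list()
  store$tx <- list()
  store$tx_index <- list()   # contig -> IRanges + model index
  store$gene_track <- NULL
  store$log <- list()
  store$versions <- vapply(configs, `[[`, character(1), "version")
  names(store$versions) <- nm

  for (cc in configs) {
    switch(cc$category,
      reference = NULL,
      score = ingest_score(store, cc),
      gene = ingest_genes(store, cc),
      sparse = ingest_sparse(store, cc))
  }
  class(store) <- "genome_store"
  if (!is.null(out_log)) write_build_log(store, out_log)
  store
}

#' @export
print.genome_store <- function(x, ...) {
  cat("<genome_store> assembly", x$assembly, "|",
      length(x$genome), "contigs |", length(x$score), "score tracks |",
      length(x$sparse_tracks), "sparse tracks |", length(x$tx),
      "transcripts\n")
  invisible(x)
}

write_build_log <- function(store, path) {
  lines <- c(
    paste("assembly:", store$assembly),
    paste("built:", store$built),
    "track versions:",
    paste0("  ", names(store$versions), " = ", store$versions),
    "ingest tallies:",
    unlist(lapply(names(store$log), function(k)
      paste0("  ", k, ": ",
             paste(names(store$log[[k]]), unlist(store$log[[k]]),
                   sep = "=", collapse = " ")))))
  writeLines(lines, path)
  invisible(path)
}

ingest_score <- function(store, cc) {
  vals <- lapply(store$genome, function(s) rep(NA_real_, nchar(s)))
  if (cc$sourceFormat == "wigFix") {
    lines <- readLines(cc$file)
    ctg <- NULL; at <- 0L; step <- 1L
    blocks <- grepl("^fixedStep", lines)
    idx <- which(blocks)
    if (length(idx) == 0L) stop(cc$file, " line 1: no fixedStep header")
    bounds <- c(idx, length(lines) + 1L)
    for (b in seq_along(idx)) {
      h <- lines[[idx[b]]]
      gv <- function(key) sub(paste0(".*", key, "="), "", h)
      ctg <- sub("\\s.*", "", gv("chrom"))
      at <- as.integer(sub("\\s.*", "", gv("start")))
      step <- as.integer(sub("\\s.*", "", gv("step")))
      if (is.na(at) || is.na(step))
        stop(cc$file, " line ", idx[b], ": malformed fixedStep header")
      if (is.null(vals[[ctg]]))
        stop(cc$file, " line ", idx[b], ": unknown contig ", ctg)
      body <- lines[seq.int(idx[b] + 1L, bounds[b + 1L] - 1L)]
      v <- suppressWarnings(as.numeric(body))
      if (anyNA(v))
        stop(cc$file, " line ", idx[b] + which(is.na(v))[1],
             ": non-numeric score value")
      pos <- at + step * (seq_along(v) - 1L)
      keep <- pos <= length(vals[[ctg]])
      vals[[ctg]][pos[keep]] <- v[keep]
    }
  } else { # bed: per-interval score (column 5) spread per base
    lines <- readLines(cc$file)
    for (i in seq_along(lines)) {
      f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
      if (length(f) < 5L)
        stop(cc$file, " line ", i, ": BED score track needs 5 columns")
      ctg <- f[[1L]]
      if (is.null(vals[[ctg]])) stop(cc$file, " line ", i, ": unknown contig ", ctg)
      s <- as.integer(f[[2L]]); e <- as.integer(f[[3L]])
      v <- as.numeric(f[[5L]])
      if (is.na(s) || is.na(e) || is.na(v))
        stop(cc$file, " line ", i, ": malformed BED line")
      vals[[ctg]][(s + 1L):e] <- v
    }
  }
  store$score[[cc$name]] <- vals
  invisible(store)
}

ingest_genes <- function(store, cc) {
  txs <- read_genepred(cc$file, store$genome)
  store$tx <- txs
  store$gene_track <- cc$name
  bycontig <- split(seq_along(txs),
                    vapply(txs, `[[`, character(1), "contig"))
  store$tx_index <- lapply(bycontig, function(ii) {
    st <- vapply(txs[ii], `[[`, integer(1), "txStart")
    en <- vapply(txs[ii], `[[`, integer(1), "txEnd")
    list(ranges = IRanges::IRanges(start = st + 1L, end = en), idx = ii)
  })
  invisible(store)
}

#' Merge a sparse VCF/BED track into the store
#'
#' VCF records with FILTER outside \{PASS, .\} are excluded and tallied; kept
#' records are split per ALT and normalized before keying, so lookups during
#' annotation always match on the canonical left-shifted form.
#' @param store A `genome_store` under construction.
#' @param cc The track's [track_config()].
#' @return The store, invisibly.
#' @export
ingest_sparse <- function(store, cc) {
  tally <- c(kept = 0L, qcExcluded = 0L, refMismatch = 0L, identical = 0L)
  store$sparse_tracks <- c(store$sparse_tracks, cc$name)
  store$sparse_fields[[cc$name]] <- cc$fields
  if (cc$sourceFormat == "vcf") {
    vcf <- parse_vcf(cc$file)
    # warn once per configured INFO field never seen in the file
    seen_info <- unique(unlist(lapply(vcf$records, function(r)
      sub("=.*", "", strsplit(r$info, ";", fixed = TRUE)[[1L]]))))
    for (sf in setdiff(names(cc$fields), c("ID", seen_info)))
      warning("track ", cc$name, ": INFO field '", sf,
              "' absent from source; emitted as missing", call. = FALSE)
    for (rec in vcf$records) {
      if (!(rec$filter %in% c("PASS", "."))) {
        tally[["qcExcluded"]] <- tally[["qcExcluded"]] + 1L
        next
      }
      info <- strsplit(rec$info, ";", fixed = TRUE)[[1L]]
      ikeys <- sub("=.*", "", info)
      ivals <- sub("^[^=]*=?", "", info)
      for (alt in setdiff(rec$alts, ".")) {
        if (is.null(store$genome[[rec$contig]])) next
        na <- normalize_allele(rec$contig, rec$pos, rec$ref, alt, store$genome)
        if (is.null(na)) { tally[["identical"]] <- tally[["identical"]] + 1L; next }
        vals <- lapply(names(cc$fields), function(sf) {
          if (sf == "ID") rec$id
          else if (sf %in% ikeys) ivals[[match(sf, ikeys)]]
          else NA_character_
        })
        names(vals) <- unname(cc$fields)
        key <- paste(cc$name, na$contig, na$pos, na$ref, na$alt, sep = "\t")
        store$sparse[[key]] <- c(list(ref = na$ref, alt = na$alt), vals)
        pkey <- paste(cc$name, na$contig, na$pos, sep = "\t")
        store$sparse_pos[[pkey]] <- union(store$sparse_pos[[pkey]], key)
        tally[["kept"]] <- tally[["kept"]] + 1L
      }
    }
  } else { # bed sparse: positional entries carrying the name column
    lines <- readLines(cc$file)
    for (i in seq_along(lines)) {
      f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
      if (length(f) < 4L) stop(cc$file, " line ", i, ": BED sparse needs 4 columns")
      s <- as.integer(f[[2L]]); e <- as.integer(f[[3L]])
      for (p in (s + 1L):e) {
        key <- paste(cc$name, f[[1L]], p, "", "", sep = "\t")
        store$sparse[[key]] <- list(ref = "", alt = "", name = f[[4L]])
        pkey <- paste(cc$name, f[[1L]], p, sep = "\t")
        store$sparse_pos[[pkey]] <- union(store$sparse_pos[[pkey]], key)
        tally[["kept"]] <- tally[["kept"]] + 1L
      }
    }
  }
  store$log[[cc$name]] <- as.list(tally)
  invisible(store)
}

#' Per-position record lookup
#'
#' @param store A `genome_store`.
#' @param contig Contig name (error if unknown).
#' @param start 0-based start position.
#' @param length Number of consecutive positions.
#' @return A list of `length` position records, each with `pos` (1-based),
#'   `refBase`, `scores` (named numeric, NA where unscored), `sparse` (per
#'   sparse track: list of entries), `transcripts` (transcript names
#'   overlapping the base). Out-of-bounds positions yield records with
#'   `refBase = NA` and a `oob = TRUE` marker.
#' @export
lookup <- function(store, contig, start, length = 1L) {
  seq <- store$genome[[contig]]
  if (is.null(seq)) stop("unknown contig: ", contig)
  n <- nchar(seq)
  lapply(seq.int(start + 1L, start + length), function(p) {
    if (p < 1L || p > n)
      return(list(pos = p, refBase = NA_character_, oob = TRUE))
    scores <- vapply(store$score, function(tr) tr[[contig]][[p]], numeric(1))
    sp <- lapply(store$sparse_tracks, function(trk) {
      keys <- store$sparse_pos[[paste(trk, contig, p, sep = "\t")]]
      if (is.null(keys)) list() else lapply(keys, function(k) store$sparse[[k]])
    })
    names(sp) <- store$sparse_tracks
    txn <- character(0)
    ti <- store$tx_index[[contig]]
    if (!is.null(ti)) {
      hit <- IRanges::overlapsAny(ti$ranges, IRanges::IRanges(p, p))
      txn <- vapply(store$tx[ti$idx[hit]], `[[`, character(1), "name")
    }
    list(pos = p, refBase = substr(seq, p, p), scores = scores,
         sparse = sp, transcripts = txn, oob = FALSE)
  })
}

#' Sparse-track entry for a canonical allele
#'
#' @param store A `genome_store`.
#' @param allele A `normalized_allele`.
#' @param track Sparse track name.
#' @return Named list of the track's configured output fields (NULL when the
#'   allele has no entry).
#' @export
sparse_for_allele <- function(store, allele, track) {
  key <- paste(track, allele$contig, allele$pos, allele$ref, allele$alt,
               sep = "\t")
  store$sparse[[key]]
}

#' Score-track values over an allele's affected reference span
#'
#' SNP/MNP: the per-base scores of the substituted bases. Deletions: scores
#' of every deleted base. Insertions: the score at the base 3' of the anchor
#' (the single affected reference position). Missing (unscored) positions
#' are omitted, so an allele in an unscored region yields an empty vector —
#' multi-base alleles naturally produce array values.
#'
#' @param store A `genome_store`.
#' @param allele A `normalized_allele`.
#' @param track Score track name.
#' @return Numeric vector (possibly empty).
#' @export
scores_for_allele <- function(store, allele, track) {
  tr <- store$score[[track]]
  if (is.null(tr)) return(numeric(0))
  v <- tr[[allele$contig]]
  if (is.null(v)) return(numeric(0))
  span <- allele_span(allele)
  pos <- span[1]:span[2]
  pos <- pos[pos >= 1L & pos <= length(v)]
  out <- v[pos]
  out[!is.na(out)]
}

# 1-based inclusive affected reference span of a canonical allele
allele_span <- function(allele) {
  switch(allele$type,
    SNP = c(allele$pos, allele$pos),
    MNP = c(allele$pos, allele$pos + nchar(allele$ref) - 1L),
    INS = c(allele$pos + 1L, allele$pos + 1L),
    DEL = c(allele$pos + 1L, allele$pos + nchar(allele$ref) - 1L))
}
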