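#' Build text and numeric indexes over annotation rows
#'
#' Text fields get an inverted index from analyzed tokens (raw value, word
#' tokens, stems, left-edge n-grams) to row ids, with per-row stem sequences
#' retained for phrase queries. Numeric fields get sorted (value, row)
#' postings; multi-valued rows appear once per element, giving
#' "any element matches" semantics.
#'
#' @param rows Annotation data.frame (character columns, `NA` missing,
#'   `;`-joined arrays) as produced by [annotate_variants()] /
#'   [read_annotation()].
#' @param schema Optional schema from [infer_schema()] (inferred if NULL).
#' @param samples Sample ids of the annotation.
#' @param aliases Named character vector of query-field aliases
#'   (e.g. `c(maf = "gnomad.af")`).
#' @param synonyms Named list of built-in/custom term synonyms.
#' @return A `search_index` list.
#' @export
build_index <- function(rows, schema = NULL, samples = character(0),
                        aliases = NULL, synonyms = default_synonyms()) {
  if (is.null(schema)) schema <- infer_schema(rows)
  if (!all(schema$field %in% names(rows)))
    stop("schema/row mismatch: field ",
         setdiff(schema$field, names(rows))[1], " not in rows")
  n <- nrow(rows)
  text <- new.env(parent = emptyenv())
  stems <- list()
  vocab <- list()
  num <- list()
  for (i in seq_len(nrow(schema))) {
    fn <- schema$field[i]
    col <- as.character(rows[[fn]])
    el <- strsplit(col, ";", fixed = TRUE)
    if (schema$kind[i] %in% c("integer", "float")) {
      vals <- lapply(el, function(e) {
        v <- suppressWarnings(as.numeric(e))
        v[!is.na(v)]
      })
      len <- lengths(vals)
      num[[fn]] <- list(values = unlist(vals), rows = rep(seq_len(n), len))
      o <- order(num[[fn]]$values)
      num[[fn]]$values <- num[[fn]]$values[o]
      num[[fn]]$rows <- num[[fn]]$rows[o]
    } else {
      # analyze unique values once; map back to rows
      flat <- unlist(el)
      ridx <- rep(seq_len(n), lengths(el))
      keep <- !is.na(flat) & flat != "NA" & nzchar(flat)
      flat <- flat[keep]; ridx <- ridx[keep]
      uv <- unique(flat)
      postings <- new.env(parent = emptyenv())
      rows_of <- split(ridx, factor(flat, levels = uv))
      # analyze each distinct value once, then group value-ids per token so
      # postings are assembled in one pass (no quadratic appends)
      tok_list <- lapply(uv, analyze_text)
      tokmap <- split(rep(seq_along(uv), lengths(tok_list)),
                      unlist(tok_list, use.names = FALSE))
      for (tok in names(tokmap))
        postings[[tok]] <- sort(unique(
          unlist(rows_of[tokmap[[tok]]], use.names = FALSE)))
      text[[fn]] <- postings
      # per-row stem sequences (per element) for phrase matching
      stem_of_value <- lapply(uv, function(v)
        vapply(word_tokens(v), stem_token, character(1), USE.NAMES = FALSE))
      names(stem_of_value) <- uv
      seqs <- vector("list", n)
      for (j in seq_along(flat))
        seqs[[ridx[j]]] <- c(seqs[[ridx[j]]], stem_of_value[flat[j]])
      stems[[fn]] <- seqs
      # word-token vocabulary: the candidate set for fuzzy matching
      vocab[[fn]] <- unique(unlist(lapply(uv, word_tokens)))
    }
  }
  structure(list(rows = rows, schema = schema, n = n, text = text,
                 stems = stems, vocab = vocab, num = num, samples = samples,
                 aliases = aliases, synonyms = synonyms),
            class = "search_index")
}

#' @export
print.search_index <- function(x, ...) {
  cat("<search_index>", x$n, "rows,", nrow(x$schema), "fields (",
      sum(x$schema$kind %in% c("integer", "float")), "numeric )\n")
  invisible(x)
}

text_fields <- function(index)
  index$schema$field[!index$schema$kind %in% c("integer", "float")]

# resolve a user-facing field name: case-insensitive, through aliases
resolve_field <- function(index, name) {
  nm <- tolower(name)
  al <- index$aliases
  if (!is.null(al) && nm %in% tolower(names(al)))
    nm <- tolower(al[[match(nm, tolower(names(al)))]])
  hit <- match(nm, tolower(index$schema$field))
  if (is.na(hit)) {
    near <- utils::head(index$schema$field[
      order(utils::adist(nm, tolower(index$schema$field)))], 3L)
    stop("unknown field '", name, "'; nearest: ", paste(near, collapse = ", "))
  }
  index$schema$field[hit]
}

#' Built-in synonym dictionary
#'
#' Term equivalences demonstrated by common clinical-genetics usage:
#' stopgain/nonsense, missense/nonsynonymous, and the EDS acronym. Users
#' extend it with [define_custom_synonym()].
#'
#' @return Named list: token -> character vector of equivalent terms, or a
#'   `list(samples = ...)` sample-set expansion.
#' @export
default_synonyms <- function() {
  list(
    stopgain = "nonsense", nonsense = "stopgain",
    missense = "nonsynonymous", nonsynonymous = "missense",
    eds = c("ehlers", "danlos", "syndrome"))
}

#' Register a custom synonym or sample-set label
#'
#' @param index A `search_index`.
#' @param label Single-token label (rejected if it collides with a schema
#'   field name — fields win).
#' @param expansion Character vector of terms, or `list(samples = c(...))`
#'   to create a carrier predicate (used e.g. to label trio members so that
#'   "proband -parents" finds de novo candidates).
#' @return The updated index.
#' @export
define_custom_synonym <- function(index, label, expansion) {
  if (length(word_tokens(label)) != 1L)
    stop("synonym label must be a single token: ", label)
  if (tolower(label) %in% tolower(index$schema$field))
    stop("label '", label, "' collides with a schema field name")
  index$synonyms[[tolower(label)]] <- expansion
  index
}
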