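# Text analysis: light English suffix stemming plus left-edge n-grams.
# Matching is therefore insensitive to capitalization, punctuation,
# possessives, plural/tense variation, and supports partial-word prefixes.

#' Stem one lowercase token
#'
#' Suffix-stripping stemmer: plural (-sses, -ies, -s), past/gerund
#' (-ed, -ing), and terminal -y to -i (so "early" and "earli(-er)" agree).
#' Applied identically at index and query time, so only consistency — not
#' linguistic perfection — matters.
#'
#' @param tok Lowercase token.
#' @return Stemmed token.
#' @export
stem_token <- function(tok) {
  n <- nchar(tok)
  if (n > 4L && endsWith(tok, "sses")) tok <- substr(tok, 1L, n - 2L)
  else if (n > 4L && endsWith(tok, "ies")) tok <- paste0(substr(tok, 1L, n - 3L), "i")
  else if (n > 3L && endsWith(tok, "s") && !endsWith(tok, "ss"))
    tok <- substr(tok, 1L, n - 1L)
  n <- nchar(tok)
  if (n > 4L && endsWith(tok, "ing")) tok <- substr(tok, 1L, n - 3L)
  else if (n > 4L && endsWith(tok, "ed")) tok <- substr(tok, 1L, n - 2L)
  n <- nchar(tok)
  if (n > 2L && endsWith(tok, "y")) tok <- paste0(substr(tok, 1L, n - 1L), "i")
  tok
}

#' Split free text into lowercase word tokens
#'
#' Lowercases, deletes periods and apostrophes ("E.D.S" becomes "eds",
#' "expert's" becomes "experts"), then splits on every remaining
#' non-alphanumeric character (hyphen, slash, comma, parentheses,
#' underscore, whitespace).
#'
#' @param value Free text.
#' @return Character vector of tokens (possibly empty).
#' @export
word_tokens <- function(value) {
  v <- tolower(value)
  v <- gsub("[.']", "", v)
  toks <- strsplit(v, "[^a-z0-9]+")[[1L]]
  toks[nzchar(toks)]
}

edge_ngrams <- function(stem, lo = 2L, hi = 20L) {
  n <- nchar(stem)
  if (n < lo) return(character(0))
  vapply(lo:min(n, hi), function(k) substr(stem, 1L, k), character(1))
}

#' Analyze a value into its index tokens
#'
#' Emits the raw lowercased value, each word token, each word's stem, and
#' the left-edge n-grams (lengths 2..20) of each stem.
#'
#' @param value Free text value.
#' @return Unique character vector of index tokens.
#' @export
analyze_text <- function(value) {
  toks <- word_tokens(value)
  stems <- vapply(toks, stem_token, character(1), USE.NAMES = FALSE)
  unique(c(tolower(value), toks, stems,
           unlist(lapply(unique(stems), edge_ngrams))))
}

# keys a query-side token is looked up under (raw + stem; postings carry
# the n-grams, so a partial query word hits longer indexed words)
query_keys <- function(token) unique(c(token, stem_token(token)))

#' Infer the typed field schema of annotation rows
#'
#' A field is numeric iff every non-missing element (after ;-splitting
#' multi-values) parses as a number; integer iff additionally all values are
#' integral, stored at the smallest width that accommodates them (8/16/32/64
#' bits; floats use 32 bits only when every value survives a 32-bit
#' round-trip within relative error 1e-6). Fields whose values are all
#' true/false are boolean. Everything else is text.
#'
#' @param rows Annotation data.frame (character columns; `NA` literal means
#'   missing; `;` separates array elements).
#' @return data.frame: field, kind, width, multiValued.
#' @export
infer_schema <- function(rows) {
  stopifnot(nrow(rows) >= 1L)
  res <- lapply(names(rows), function(fn) {
    col <- as.character(rows[[fn]])
    el <- strsplit(col, ";", fixed = TRUE)
    multi <- any(lengths(el) > 1L)
    flat <- unlist(el)
    flat <- flat[!is.na(flat) & flat != "NA" & nzchar(flat)]
    if (length(flat) == 0L)
      return(data.frame(field = fn, kind = "text", width = NA_integer_,
                        multiValued = multi, stringsAsFactors = FALSE))
    if (all(tolower(flat) %in% c("true", "false")))
      return(data.frame(field = fn, kind = "boolean", width = 1L,
                        multiValued = multi, stringsAsFactors = FALSE))
    num <- suppressWarnings(as.numeric(flat))
    if (anyNA(num))
      return(data.frame(field = fn, kind = "text", width = NA_integer_,
                        multiValued = multi, stringsAsFactors = FALSE))
    if (all(num == trunc(num)) && all(abs(num) < 2^63)) {
      a <- max(abs(num))
      width <- if (a < 2^7) 8L else if (a < 2^15) 16L else if (a < 2^31) 32L else 64L
      return(data.frame(field = fn, kind = "integer", width = width,
                        multiValued = multi, stringsAsFactors = FALSE))
    }
    # 32-bit float round-trip via base R's size-4 binary write
    f32 <- readBin(writeBin(num, raw(), size = 4L), "numeric", n = length(num),
                   size = 4L)
    rel <- abs(f32 - num) / pmax(abs(num), .Machine$double.eps)
    width <- if (all(rel <= 1e-6)) 32L else 64L
    data.frame(field = fn, kind = "float", width = width,
               multiValued = multi, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
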