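# Natural-language-style query engine: parser, set-semantics executor over
# the indexes, and an independent row-scan reference evaluator.

tok_stream <- function(q) {
  toks <- list()
  i <- 1L; n <- nchar(q)
  push <- function(kind, val = NULL)
    toks[[length(toks) + 1L]] <<- list(kind = kind, val = val)
  while (i <= n) {
    ch <- substr(q, i, i)
    if (grepl("\\s", ch)) { i <- i + 1L; next }
    if (ch == "(") { push("LP"); i <- i + 1L; next }
    if (ch == ")") { push("RP"); i <- i + 1L; next }
    if (substr(q, i, i + 1L) == "||") { push("OR"); i <- i + 2L; next }
    if (ch == "\"") {
      j <- regexpr("\"", substr(q, i + 1L, n), fixed = TRUE)
      if (j < 0L) stop("unterminated quote in query")
      push("QUOTED", substr(q, i + 1L, i + j - 1L))
      i <- i + j + 1L; next
    }
    if (ch == "/") {
      j <- regexpr("/", substr(q, i + 1L, n), fixed = TRUE)
      if (j < 0L) stop("unterminated /regex/ in query")
      push("REGEX", substr(q, i + 1L, i + j - 1L))
      i <- i + j + 1L; next
    }
    two <- substr(q, i, i + 1L)
    if (two %in% c("<=", ">=")) { push("OP", two); i <- i + 2L; next }
    if (ch %in% c("<", ">", "=")) { push("OP", ch); i <- i + 1L; next }
    m <- regexpr("^[^\\s()\"<>=|/]+", substr(q, i, n), perl = TRUE)
    w <- regmatches(substr(q, i, n), m)
    push("WORD", w)
    i <- i + attr(m, "match.length")
  }
  toks
}

node <- function(kind, ...) c(list(kind = kind), list(...))

#' Parse a query string into a typed AST
#'
#' Grammar: whitespace-separated clauses combine with implicit AND;
#' `OR`/`||` group alternatives (binding inside parentheses); `-term` /
#' `NOT term` negate; `+term` is plain AND; `field:value` and
#' `field:(a || b)` scope a clause to a field; `field op number` (ops `<`,
#' `<=`, `>`, `>=`, `=`, numbers accepting leading-dot forms like `.001`)
#' is a numeric range; `"quoted text"` is a contiguous phrase;
#' `field:/pat/` a regular expression; `term~N` a Levenshtein fuzzy match
#' (N <= 2). Unscoped terms are analyzed (stem + n-grams) and searched
#' across all text fields. Synonyms — built-in and custom — expand at parse
#' time; sample-set labels expand to carrier predicates. The empty query is
#' MatchAll.
#'
#' @param q Query string.
#' @param index A `search_index` (schema, aliases and synonyms are taken
#'   from it).
#' @return AST (nested lists with a `kind` element).
#' @export
parse_query <- function(q, index) {
  q <- trimws(q)
  if (!nzchar(q)) return(node("matchall"))
  toks <- tok_stream(q)
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[[pos]] else list(kind = "EOF")
  advance <- function() { t <- peek(); pos <<- pos + 1L; t }
  expect <- function(kind) {
    t <- advance()
    if (t$kind != kind) stop("query syntax: expected ", kind)
    t
  }

  syn_node <- function(token) {
    syn <- index$synonyms[[token]]
    base <- node("term", token = token)
    if (is.null(syn)) return(base)
    if (is.list(syn) && !is.null(syn$samples))
      return(node("carrier", samples = syn$samples))
    alts <- c(list(base), lapply(syn, function(s) node("term", token = s)))
    node("bool", op = "OR", children = alts)
  }

  term_node <- function(word) {
    wt <- word_tokens(word)
    if (length(wt) == 0L) return(node("matchall"))
    if (length(wt) == 1L) return(syn_node(wt[[1L]]))
    # hyphen/punctuation compounds match either as separate words or as the
    # joined token ("non-synonymous" also hits values annotated
    # "nonsynonymous")
    parts <- node("bool", op = "AND", children = lapply(wt, syn_node))
    node("bool", op = "OR",
         children = list(parts, syn_node(paste(wt, collapse = ""))))
  }

  scoped_value_node <- function(field, value) {
    fz <- regmatches(value, regexec("^(.*)~([0-9])$", value))[[1L]]
    if (length(fz) == 3L)
      return(node("fuzzy", field = field, token = tolower(fz[2L]),
                  maxEdits = min(2L, as.integer(fz[3L]))))
    wt <- word_tokens(value)
    if (length(wt) == 0L) return(node("matchall"))
    parts <- lapply(wt, function(t) node("term", token = t, field = field))
    if (length(parts) == 1L) parts[[1L]]
    else node("bool", op = "AND", children = parts)
  }

  scope_fields <- function(ast, field) {
    if (ast$kind %in% c("term", "phrase", "fuzzy")) ast$field <- field
    if (ast$kind == "bool")
      ast$children <- lapply(ast$children, scope_fields, field = field)
    if (ast$kind == "not") ast$child <- scope_fields(ast$child, field)
    ast
  }

  parse_word <- function(w) {
    # range: word (a field name) followed by an op token
    if (peek()$kind == "OP") {
      op <- advance()$val
      numtok <- advance()
      num <- suppressWarnings(as.numeric(numtok$val))
      if (numtok$kind != "WORD" || is.na(num))
        stop("query syntax: '", w, " ", op, "' needs a number")
      fld <- resolve_field(index, w)
      kind <- index$schema$kind[index$schema$field == fld]
      if (!kind %in% c("integer", "float"))
        stop("range query on non-numeric field '", fld, "' (kind ", kind, ")")
      return(node("range", field = fld, op = op, value = num))
    }
    if (grepl(":", w, fixed = TRUE)) {
      cut <- regexpr(":", w, fixed = TRUE)
      fname <- substr(w, 1L, cut - 1L)
      rest <- substr(w, cut + 1L, nchar(w))
      fld <- resolve_field(index, fname)
      if (!nzchar(rest)) {
        t <- peek()
        if (t$kind == "LP") {
          advance()
          sub <- parse_expr()
          expect("RP")
          return(scope_fields(sub, fld))
        }
        if (t$kind == "REGEX") {
          advance()
          return(node("regex", field = fld, pattern = t$val))
        }
        if (t$kind == "QUOTED") {
          advance()
          return(scope_fields(phrase_node(t$val), fld))
        }
        stop("query syntax: dangling '", w, "'")
      }
      return(scoped_value_node(fld, rest))
    }
    fz <- regmatches(w, regexec("^(.*)~([0-9])$", w))[[1L]]
    if (length(fz) == 3L)
      return(node("fuzzy", field = NULL, token = tolower(fz[2L]),
                  maxEdits = min(2L, as.integer(fz[3L]))))
    term_node(w)
  }

  phrase_node <- function(txt) {
    stems <- vapply(word_tokens(txt), stem_token, character(1), USE.NAMES = FALSE)
    if (length(stems) == 0L) return(node("matchall"))
    node("phrase", stems = stems, field = NULL)
  }

  parse_atom <- function() {
    t <- advance()
    switch(t$kind,
      LP = { e <- parse_expr(); expect("RP"); e },
      QUOTED = phrase_node(t$val),
      REGEX = stop("bare /regex/ must be field-scoped (field:/pat/)"),
      WORD = parse_word(t$val),
      stop("query syntax: unexpected ", t$kind))
  }

  parse_unary <- function() {
    t <- peek()
    if (t$kind == "WORD") {
      if (identical(t$val, "NOT")) {
        advance()
        return(node("not", child = parse_unary()))
      }
      if (startsWith(t$val, "-") && nchar(t$val) > 1L) {
        advance()
        return(node("not", child = parse_word(substr(t$val, 2L, nchar(t$val)))))
      }
      if (startsWith(t$val, "+") && nchar(t$val) > 1L) {
        advance()
        return(parse_word(substr(t$val, 2L, nchar(t$val))))
      }
    }
    parse_atom()
  }

  parse_and_seq <- function() {
    cl <- list()
    while (!peek()$kind %in% c("EOF", "RP", "OR"))
      cl[[length(cl) + 1L]] <- parse_unary()
    if (length(cl) == 0L) return(node("matchall"))
    if (length(cl) == 1L) cl[[1L]] else node("bool", op = "AND", children = cl)
  }

  parse_expr <- function() {
    parts <- list(parse_and_seq())
    while (peek()$kind == "OR") {
      advance()
      parts[[length(parts) + 1L]] <- parse_and_seq()
    }
    if (length(parts) == 1L) parts[[1L]] else node("bool", op = "OR", children = parts)
  }

  ast <- parse_expr()
  if (peek()$kind != "EOF") stop("query syntax: trailing ", peek()$kind)
  ast
}

# ---- index-backed execution -------------------------------------------------

postings_lookup <- function(index, field, keys) {
  flds <- if (is.null(field)) text_fields(index) else field
  out <- integer(0)
  for (fn in flds) {
    p <- index$text[[fn]]
    if (is.null(p)) next
    for (k in keys) {
      v <- p[[k]]
      if (!is.null(v)) out <- c(out, v)
    }
  }
  sort(unique(out))
}

phrase_rows <- function(index, stems, field) {
  cand <- NULL
  for (s in stems) {
    r <- postings_lookup(index, field, s)
    cand <- if (is.null(cand)) r else intersect(cand, r)
    if (length(cand) == 0L) return(integer(0))
  }
  flds <- if (is.null(field)) text_fields(index) else field
  has_contig <- function(vec, pat) {
    lv <- length(vec); lp <- length(pat)
    if (lv < lp) return(FALSE)
    for (s in seq_len(lv - lp + 1L))
      if (all(vec[s:(s + lp - 1L)] == pat)) return(TRUE)
    FALSE
  }
  keep <- vapply(cand, function(r) {
    for (fn in flds) {
      seqs <- index$stems[[fn]][[r]]
      if (is.null(seqs)) next
      for (v in seqs) if (has_contig(v, stems)) return(TRUE)
    }
    FALSE
  }, logical(1))
  cand[keep]
}

carrier_rows <- function(index, samples) {
  rows <- index$rows
  if (!all(c("heterozygotes", "homozygotes") %in% names(rows)))
    return(integer(0))
  hit <- rep(FALSE, index$n)
  for (cn in c("heterozygotes", "homozygotes")) {
    el <- strsplit(as.character(rows[[cn]]), ";", fixed = TRUE)
    hit <- hit | vapply(el, function(e) any(samples %in% e), logical(1))
  }
  which(hit)
}

eval_ast <- function(ast, index) {
  u <- seq_len(index$n)
  switch(ast$kind,
    matchall = u,
    term = postings_lookup(index, ast$field, query_keys(ast$token)),
    phrase = phrase_rows(index, ast$stems, ast$field),
    range = {
      nx <- index$num[[ast$field]]
      if (is.null(nx)) integer(0)
      else {
        sel <- switch(ast$op,
          "<" = nx$values < ast$value, "<=" = nx$values <= ast$value,
          ">" = nx$values > ast$value, ">=" = nx$values >= ast$value,
          "=" = nx$values == ast$value)
        sort(unique(nx$rows[sel]))
      }
    },
    regex = {
      el <- strsplit(as.character(index$rows[[ast$field]]), ";", fixed = TRUE)
      hit <- vapply(el, function(e)
        any(grepl(ast$pattern, tolower(e), perl = TRUE)), logical(1))
      which(hit)
    },
    fuzzy = {
      flds <- if (is.null(ast$field)) text_fields(index) else ast$field
      out <- integer(0)
      for (fn in flds) {
        p <- index$text[[fn]]
        voc <- index$vocab[[fn]]
        if (is.null(p) || length(voc) == 0L) next
        near <- voc[utils::adist(ast$token, voc) <= ast$maxEdits]
        for (k in near) out <- c(out, p[[k]])
      }
      sort(unique(out))
    },
    carrier = carrier_rows(index, ast$samples),
    not = setdiff(u, eval_ast(ast$child, index)),
    bool = {
      kids <- lapply(ast$children, eval_ast, index = index)
      if (ast$op == "AND") Reduce(intersect, kids) else sort(unique(unlist(kids)))
    },
    stop("unknown AST node: ", ast$kind))
}

#' Execute a parsed query against the index
#'
#' @param ast AST from [parse_query()] (or a query string, parsed for you).
#' @param index A `search_index`.
#' @return A `search_result`: `ids` (sorted row ids), `count`, `tstv`
#'   (transition/transversion ratio of the result set), `query`.
#' @export
execute <- function(ast, index) {
  if (is.character(ast)) {
    q <- ast
    ast <- parse_query(ast, index)
  } else q <- NA_character_
  ids <- sort(unique(eval_ast(ast, index)))
  structure(list(ids = ids, count = length(ids),
                 tstv = ts_tv_ratio(index$rows[ids, , drop = FALSE]),
                 query = q, parent = attr(index, "source") %||% NA_character_),
            class = "search_result")
}

#' @export
print.search_result <- function(x, ...) {
  cat("<search_result>", x$count, "rows; Ts:Tv =",
      if (is.na(x$tstv)) "NA" else format(round(x$tstv, 3)), "\n")
  invisible(x)
}

# ---- independent row-scan reference evaluator -------------------------------

.scan_cache <- new.env(parent = emptyenv())

cached_tokens <- function(v) {
  r <- .scan_cache[[v]]
  if (is.null(r)) {
    r <- analyze_text(v)
    .scan_cache[[v]] <- r
  }
  r
}

# evaluate a per-cell predicate over a column, computing each distinct cell
# once (annotation columns are highly repetitive)
scan_col <- function(col, pred) {
  uv <- unique(col)
  hit_uv <- vapply(uv, pred, logical(1), USE.NAMES = FALSE)
  hit_uv[match(col, uv)]
}

cell_elements <- function(cell) {
  e <- strsplit(cell, ";", fixed = TRUE)[[1L]]
  e[!is.na(e) & e != "NA" & nzchar(e)]
}

#' Reference evaluator: brute-force row scan
#'
#' Evaluates the same AST with per-row predicates over the raw annotation
#' rows — no postings, no numeric index — serving as the correctness
#' reference for [execute()].
#'
#' @inheritParams execute
#' @return Sorted integer row ids.
#' @export
execute_scan <- function(ast, index) {
  if (is.character(ast)) ast <- parse_query(ast, index)
  rows <- index$rows
  n <- nrow(rows)
  flds_of <- function(field) if (is.null(field)) text_fields(index) else field
  ev <- function(ast) {
    switch(ast$kind,
      matchall = rep(TRUE, n),
      term = {
        keys <- query_keys(ast$token)
        hit <- rep(FALSE, n)
        for (fn in flds_of(ast$field)) {
          hit <- hit | scan_col(as.character(rows[[fn]]), function(cell) {
            any(vapply(cell_elements(cell),
                       function(v) any(keys %in% cached_tokens(v)),
                       logical(1)))
          })
        }
        hit
      },
      phrase = {
        hit <- rep(FALSE, n)
        pat <- ast$stems
        for (fn in flds_of(ast$field)) {
          hit <- hit | scan_col(as.character(rows[[fn]]), function(cell) {
            for (v in cell_elements(cell)) {
              st <- vapply(word_tokens(v), stem_token, character(1),
                           USE.NAMES = FALSE)
              if (length(st) >= length(pat))
                for (s in seq_len(length(st) - length(pat) + 1L))
                  if (all(st[s:(s + length(pat) - 1L)] == pat)) return(TRUE)
            }
            FALSE
          })
        }
        hit
      },
      range = {
        scan_col(as.character(rows[[ast$field]]), function(cell) {
          v <- suppressWarnings(as.numeric(cell_elements(cell)))
          v <- v[!is.na(v)]
          if (length(v) == 0L) return(FALSE)
          any(switch(ast$op,
            "<" = v < ast$value, "<=" = v <= ast$value,
            ">" = v > ast$value, ">=" = v >= ast$value,
            "=" = v == ast$value))
        })
      },
      regex = {
        scan_col(as.character(rows[[ast$field]]), function(cell)
          any(grepl(ast$pattern,
                    tolower(strsplit(cell, ";", fixed = TRUE)[[1L]]),
                    perl = TRUE)))
      },
      fuzzy = {
        hit <- rep(FALSE, n)
        for (fn in flds_of(ast$field)) {
          hit <- hit | scan_col(as.character(rows[[fn]]), function(cell) {
            any(vapply(cell_elements(cell), function(v) {
              wt <- word_tokens(v)
              length(wt) > 0L && any(utils::adist(ast$token, wt) <= ast$maxEdits)
            }, logical(1)))
          })
        }
        hit
      },
      carrier = {
        hit <- rep(FALSE, n)
        for (cn in c("heterozygotes", "homozygotes")) {
          el <- strsplit(as.character(rows[[cn]]), ";", fixed = TRUE)
          hit <- hit | vapply(el, function(e) any(ast$samples %in% e), logical(1))
        }
        hit
      },
      not = !ev(ast$child),
      bool = {
        kids <- lapply(ast$children, ev)
        Reduce(if (ast$op == "AND") `&` else `|`, kids)
      },
      stop("unknown AST node: ", ast$kind))
  }
  which(ev(ast))
}

# ---- aggregations, filters, statistical filters, tools ----------------------

#' Summarize a field over a result set
#'
#' Text fields: up to the top 200 (value, count) pairs, count-descending,
#' ties lexicographic. Numeric fields: count, min, max, mean, population
#' standard deviation.
#'
#' @param index A `search_index`.
#' @param field Field name (alias-resolved, case-insensitive).
#' @param result A `search_result` (defaults to all rows).
#' @return data.frame (text) or named list (numeric).
#' @export
aggregate_field <- function(index, field, result = NULL) {
  fld <- resolve_field(index, field)
  ids <- if (is.null(result)) seq_len(index$n) else result$ids
  el <- strsplit(as.character(index$rows[[fld]][ids]), ";", fixed = TRUE)
  flat <- unlist(el)
  flat <- flat[!is.na(flat) & flat != "NA" & nzchar(flat)]
  kind <- index$schema$kind[index$schema$field == fld]
  if (kind %in% c("integer", "float")) {
    v <- as.numeric(flat)
    if (length(v) == 0L)
      return(list(count = 0L, min = NA_real_, max = NA_real_,
                  mean = NA_real_, sd = NA_real_))
    return(list(count = length(v), min = min(v), max = max(v),
                mean = mean(v),
                sd = sqrt(mean((v - mean(v))^2))))  # population sd
  }
  if (length(flat) == 0L)
    return(data.frame(value = character(0), count = integer(0)))
  tab <- table(flat)
  df <- data.frame(value = names(tab), count = as.integer(tab),
                   stringsAsFactors = FALSE)
  df <- df[order(-df$count, df$value), , drop = FALSE]
  utils::head(df, 200L)
}

#' Exact-match include/exclude filter over a result
#'
#' Non-analyzed element-wise matching (the complement to free-text search):
#' rows are kept when any element of `field` is in `include` (if given) and
#' no element is in `exclude`.
#'
#' @param result A `search_result`.
#' @param index A `search_index`.
#' @param field Field name.
#' @param include,exclude Character vectors of exact values.
#' @return A new `search_result`.
#' @export
apply_filter <- function(result, index, field, include = NULL, exclude = NULL) {
  fld <- resolve_field(index, field)
  ids <- result$ids
  el <- strsplit(as.character(index$rows[[fld]][ids]), ";", fixed = TRUE)
  keep <- rep(TRUE, length(ids))
  if (!is.null(include))
    keep <- keep & vapply(el, function(e) any(e %in% include), logical(1))
  if (!is.null(exclude))
    keep <- keep & !vapply(el, function(e) any(e %in% exclude), logical(1))
  ids <- ids[keep]
  structure(list(ids = ids, count = length(ids),
                 tstv = ts_tv_ratio(index$rows[ids, , drop = FALSE]),
                 query = result$query, parent = result$parent),
            class = "search_result")
}

#' Hardy-Weinberg chi-square for one genotype count triple
#'
#' Expected counts from the estimated allele frequency
#' p = (2 nRefHom + nHet) / 2n; chi-square with 1 df, no continuity
#' correction.
#'
#' @param nRefHom,nHet,nAltHom Genotype counts among non-missing samples.
#' @return List: `chisq`, `p` (NA for n = 0 or monomorphic sites, which are
#'   untestable).
#' @export
hwe_chisq <- function(nRefHom, nHet, nAltHom) {
  n <- nRefHom + nHet + nAltHom
  if (n == 0L) return(list(chisq = NA_real_, p = NA_real_))
  p <- (2 * nRefHom + nHet) / (2 * n)
  if (p == 0 || p == 1) return(list(chisq = NA_real_, p = NA_real_))
  e <- c(n * p^2, 2 * n * p * (1 - p), n * (1 - p)^2)
  o <- c(nRefHom, nHet, nAltHom)
  x2 <- sum((o - e)^2 / e)
  list(chisq = x2, p = stats::pchisq(x2, df = 1, lower.tail = FALSE))
}

#' Exclude result rows out of Hardy-Weinberg equilibrium
#'
#' Per variant, genotype counts among non-missing samples give the HWE
#' chi-square (1 df); rows with p-value below `alpha` are excluded.
#' Monomorphic and fully-missing rows are untestable and retained.
#'
#' @param result A `search_result`.
#' @param index A `search_index`.
#' @param alpha Significance level in (0, 1).
#' @return A new `search_result`; attribute `"hweExcluded"` counts the rows
#'   removed.
#' @export
hwe_filter <- function(result, index, alpha = 1e-6) {
  stopifnot(alpha > 0, alpha < 1)
  nS <- length(index$samples)
  rows <- index$rows[result$ids, , drop = FALSE]
  nhet <- lengths(strsplit(as.character(rows$heterozygotes), ";", fixed = TRUE))
  nhet[rows$heterozygotes == "NA"] <- 0L
  nhom <- lengths(strsplit(as.character(rows$homozygotes), ";", fixed = TRUE))
  nhom[rows$homozygotes == "NA"] <- 0L
  nmis <- lengths(strsplit(as.character(rows$missingGenos), ";", fixed = TRUE))
  nmis[rows$missingGenos == "NA"] <- 0L
  nref <- nS - nhet - nhom - nmis
  keep <- vapply(seq_along(result$ids), function(i) {
    h <- hwe_chisq(nref[i], nhet[i], nhom[i])
    is.na(h$p) || h$p >= alpha
  }, logical(1))
  ids <- result$ids[keep]
  out <- structure(list(ids = ids, count = length(ids),
                        tstv = ts_tv_ratio(index$rows[ids, , drop = FALSE]),
                        query = result$query, parent = result$parent),
                   class = "search_result")
  attr(out, "hweExcluded") <- sum(!keep)
  out
}

#' Identify compound heterozygotes within a result set
#'
#' Phase-unaware: a (sample, gene) pair is reported when the sample is
#' heterozygous at two or more distinct result variants annotated to that
#' gene. Homozygous calls do not count.
#'
#' @param result A `search_result`.
#' @param index A `search_index`.
#' @param gene_field Gene symbol field (default: the first field ending in
#'   `.name2`).
#' @return data.frame: sample, gene, nVariants, variantIds (;-joined row
#'   ids).
#' @export
compound_het_tool <- function(result, index, gene_field = NULL) {
  if (is.null(gene_field)) {
    cand <- grep("\\.name2$", index$schema$field, value = TRUE)
    if (length(cand) == 0L) stop("no gene symbol field found")
    gene_field <- cand[[1L]]
  }
  rows <- index$rows
  pairs <- list()
  for (id in result$ids) {
    hets <- strsplit(as.character(rows$heterozygotes[id]), ";", fixed = TRUE)[[1L]]
    hets <- hets[!is.na(hets) & hets != "NA"]
    genes <- strsplit(as.character(rows[[gene_field]][id]), ";", fixed = TRUE)[[1L]]
    genes <- unique(genes[!is.na(genes) & genes != "NA"])
    for (s in hets) for (g in genes)
      pairs[[paste(s, g, sep = "\r")]] <-
        c(pairs[[paste(s, g, sep = "\r")]], id)
  }
  out <- lapply(names(pairs), function(k) {
    ids <- unique(pairs[[k]])
    if (length(ids) < 2L) return(NULL)
    sg <- strsplit(k, "\r", fixed = TRUE)[[1L]]
    data.frame(sample = sg[1L], gene = sg[2L], nVariants = length(ids),
               variantIds = paste(ids, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- Filter(Negate(is.null), out)
  if (length(out) == 0L)
    return(data.frame(sample = character(0), gene = character(0),
                      nVariants = integer(0), variantIds = character(0)))
  do.call(rbind, out)
}

#' Save a result set as a new, re-indexed annotation
#'
#' Writes the subset through [write_annotation()] (gzip, no uncompressed
#' intermediate), records provenance (parent annotation, query string), and
#' rebuilds the search index over the subset — enabling recursive filtering.
#'
#' @param result A `search_result`.
#' @param index The parent `search_index`.
#' @param path Output path for the saved annotation.
#' @param source Label for the parent annotation.
#' @return List: `path`, `index` (the new `search_index`), `provenance`.
#' @export
save_results <- function(result, index, path, source = "annotation") {
  rows <- index$rows[result$ids, , drop = FALSE]
  prov <- list(parent = source, query = result$query, count = result$count)
  write_annotation(rows, path, samples = index$samples,
                   meta = list(provenance = prov))
  back <- read_annotation(path)
  idx2 <- if (nrow(back) > 0L)
    build_index(back, samples = index$samples, aliases = index$aliases,
                synonyms = index$synonyms)
  else {
    structure(list(rows = back, schema = index$schema, n = 0L,
                   text = new.env(parent = emptyenv()),
                   stems = list(), vocab = list(), num = list(),
                   samples = index$samples, aliases = index$aliases,
                   synonyms = index$synonyms),
              class = "search_index")
  }
  attr(idx2, "source") <- path
  list(path = path, index = idx2, provenance = prov)
}
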