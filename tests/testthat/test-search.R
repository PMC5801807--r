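test_that("the analyzer normalizes case, punctuation, possessives, tense and partial words", {
  toks <- analyze_text("Homo sapiens breast cancer 2, early onset (BRCA2), mRNA")
  expect_true(all(c("breast", "cancer", "earli", "onset", "brca2") %in% toks))
  # possessive: expert's and expert share a token
  expect_true("expert" %in% analyze_text("expert's"))
  expect_true("expert" %in% analyze_text("expert"))
  # acronym: E.D.S collapses to eds
  expect_true("eds" %in% analyze_text("E.D.S"))
  # partial word: "pathogen" is an edge n-gram of "pathogenic"
  expect_true("pathogen" %in% analyze_text("pathogenic"))
  # tense/plural variants meet at the stem
  expect_equal(stem_token("reviews"), "review")
  expect_equal(stem_token("reviewed"), "review")
  expect_equal(stem_token("cancers"), "cancer")
  expect_equal(stem_token("early"), "earli")
  # analyzer stability: re-analyzing a token keeps it reachable
  for (t in c("cancer", "earli", "brca2"))
    expect_true(t %in% analyze_text(t))
})

test_that("schema inference types fields and picks minimal widths", {
  rows <- data.frame(
    small = c("1", "2", "3"),
    wide = c("1", "70000", "3"),
    frac = c("0.001", "20.5", "NA"),
    text = c("abc", "1", "z"),
    multi = c("1;2", "3", "NA"),
    flag = c("true", "false", "true"),
    stringsAsFactors = FALSE)
  sc <- infer_schema(rows)
  get <- function(f) sc[sc$field == f, ]
  expect_equal(get("small")$kind, "integer")
  expect_equal(get("small")$width, 8L)
  expect_equal(get("wide")$width, 32L)
  expect_equal(get("frac")$kind, "float")
  expect_equal(get("frac")$width, 32L)  # survives 32-bit round-trip
  expect_equal(get("text")$kind, "text")
  expect_true(get("multi")$multiValued)
  expect_equal(get("multi")$kind, "integer")
  expect_equal(get("flag")$kind, "boolean")
  # a value outside float32 range falls back to 64-bit
  rows2 <- data.frame(x = c("1e40", "2.5"), stringsAsFactors = FALSE)
  expect_equal(infer_schema(rows2)$kind, "float")
  expect_equal(infer_schema(rows2)$width, 64L)
})

test_that("queries parse into the documented AST shapes", {
  pl <- default_pipeline()
  idx <- pl$idx
  ast <- parse_query("cadd > 20 maf < .001 pathogenic missense", idx)
  expect_equal(ast$kind, "bool"); expect_equal(ast$op, "AND")
  kinds <- vapply(ast$children, `[[`, character(1), "kind")
  expect_equal(kinds[1:2], c("range", "range"))
  expect_equal(ast$children[[1]]$field, "cadd")
  expect_equal(ast$children[[2]]$field, "gnomad.af")  # maf alias
  expect_equal(ast$children[[2]]$value, 0.001)        # leading-dot number
  # synonym expansion: missense becomes an OR group
  expect_equal(ast$children[[4]]$kind, "bool")
  expect_equal(ast$children[[4]]$op, "OR")
  # field-scoped OR group
  ast2 <- parse_query("alt:(a || c || t || g)", idx)
  expect_equal(ast2$op, "OR")
  expect_true(all(vapply(ast2$children, `[[`, character(1), "field") == "alt"))
  # exact dotted path, case-insensitive
  ast3 <- parse_query("REFSEQ.SITETYPE:intergenic", idx)
  expect_equal(ast3$field, "refSeq.siteType")
  # empty query is MatchAll
  expect_equal(parse_query("   ", idx)$kind, "matchall")
  # errors name the offending field
  expect_error(parse_query("refSeq.siteType > 3", idx), "non-numeric")
  expect_error(parse_query("nosuchfield:x", idx), "nearest")
})

test_that("a 30+ query battery matches the brute-force scan evaluator exactly", {
  pl <- default_pipeline()
  idx <- trio_index(default_pipeline())
  battery <- c(
    "exonic", "intergenic", "intronic", "pathogenic", "benign",
    "stopgain", "nonsense", "missense", "nonsynonymous", "synonymous",
    "breast cancer", "early onset breast cancer", "kinase",
    "cadd > 20", "cadd > 35", "cadd <= 10", "phyloP > 0", "phyloP < -1",
    "maf < .001", "maf < .01", "gnomad.af >= 0.0001", "position > 30000",
    "sampleMaf > .3", "missingness = 0", "heterozygosity >= .5",
    "refSeq.siteType:intergenic", "refSeq.siteType:exonic",
    "clinvar.sig:pathogenic", "alt:(a || c || t || g)", "alt:/^[acgt]$/",
    "type:SNP", "type:(INS || DEL)", "-exonic", "NOT intergenic",
    "exonic -synonymous", "pathogenic +exonic",
    "cadd > 20 maf < .001 pathogenic expert review missense",
    "\"early onset\"", "\"onset early\"", "pathogen", "patogenic~1",
    "proband -parents", "proband -parents missingness < .1")
  for (q in battery) {
    r <- execute(q, idx)
    s <- execute_scan(q, idx)
    expect_identical(r$ids, s, label = q)
  }
})

test_that("phrasing variations return pairwise-identical result sets", {
  idx <- default_pipeline()$idx
  triplets <- list(
    c("cadd > 20 maf < .001 pathogenic expert review missense",
      "cadd > 20 maf < .001 pathogenic expert's review non-synonymous",
      "cadd > 20 maf < .001 pathogen expert-reviewed nonsynonymous"),
    c("Early onset breast cancer",
      "Early-onset breast cancer",
      "Early onset breast cancers"),
    c("Pathogenic nonsense Ehlers-Danlos",
      "Pathogenic nonsense E.D.S",
      "Pathogenic stopgain eds"))
  for (tr in triplets) {
    sets <- lapply(tr, function(q) execute(q, idx)$ids)
    expect_gt(length(sets[[1]]), 0, label = tr[1])
    expect_identical(sets[[1]], sets[[2]], label = paste(tr[1], "vs", tr[2]))
    expect_identical(sets[[1]], sets[[3]], label = paste(tr[1], "vs", tr[3]))
  }
  # synonym equivalence on a corpus annotated only with "nonsynonymous"
  expect_identical(execute("missense", idx)$ids,
                   execute("nonsynonymous", idx)$ids)
  # prefix n-gram rescue of a truncated word
  expect_identical(execute("earl-onset breast cancer", idx)$ids,
                   execute("early onset breast cancer", idx)$ids)
})

test_that("set complement and range monotonicity laws hold", {
  idx <- default_pipeline()$idx
  for (q in c("exonic", "pathogenic", "type:SNP")) {
    a <- execute(q, idx)$count
    b <- execute(paste("NOT", q), idx)$count
    expect_equal(a + b, idx$n, label = q)
  }
  r1 <- execute("cadd > 10", idx)$ids
  r2 <- execute("cadd > 25", idx)$ids
  expect_true(all(r2 %in% r1))
})

test_that("multi-valued numeric fields match when any element qualifies", {
  rows <- data.frame(id = c("a", "b", "c"),
                     cadd = c("3.5;16.2;1.0", "2.0", "NA"),
                     stringsAsFactors = FALSE)
  idx <- build_index(rows)
  expect_equal(execute("cadd > 15", idx)$ids, 1L)
  expect_equal(execute("cadd < 3", idx)$ids, c(1L, 2L))
  expect_equal(execute("NOT cadd > 15", idx)$ids, c(2L, 3L))
})

test_that("aggregations summarize text and numeric fields as specified", {
  rows <- data.frame(v = c("1", "2", "3"), t = c("x", "y", "x"),
                     stringsAsFactors = FALSE)
  idx <- build_index(rows)
  agg <- aggregate_field(idx, "v")
  expect_equal(agg$count, 3L)
  expect_equal(agg$min, 1); expect_equal(agg$max, 3); expect_equal(agg$mean, 2)
  expect_equal(agg$sd, sqrt(2 / 3), tolerance = 1e-12)  # population sd 0.8165
  tag <- aggregate_field(idx, "t")
  expect_equal(tag$value, c("x", "y"))
  expect_equal(tag$count, c(2L, 1L))
  # 300 distinct values cap at the top 200
  rows2 <- data.frame(t = sprintf("val%03d", 1:300), stringsAsFactors = FALSE)
  idx2 <- build_index(rows2)
  expect_equal(nrow(aggregate_field(idx2, "t")), 200L)
  # empty result: empty summary
  r0 <- execute("t:nomatchhere", idx)
  expect_equal(nrow(aggregate_field(idx, "t", r0)), 0L)
  expect_error(aggregate_field(idx, "nope"), "unknown field")
})

test_that("exact-match filters compose with queries like scoped conjunctions", {
  pl <- default_pipeline()
  idx <- pl$idx
  all_rows <- execute("", idx)
  f <- apply_filter(all_rows, idx, "refSeq.siteType", include = "intergenic")
  expect_identical(f$ids, execute("refSeq.siteType:intergenic", idx)$ids)
  # exclude all values of a field empties the result
  vals <- unique(unlist(strsplit(idx$rows$refSeq.siteType, ";")))
  f2 <- apply_filter(all_rows, idx, "refSeq.siteType", exclude = vals)
  expect_equal(f2$count, 0L)
  # filter composed with a query equals the brute-force conjunction
  q <- execute("cadd > 15", idx)
  f3 <- apply_filter(q, idx, "clinvar.sig", include = "pathogenic")
  scan <- execute_scan("cadd > 15 clinvar.sig:pathogenic", idx)
  expect_identical(f3$ids, scan)
})
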