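Package: annoquery
Title: Variant Annotation and Natural-Language Filtering at Desk Scale
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale genome variant annotation and filtering toolkit.
    Builds a per-position annotation store from standard track formats
    (FASTA reference, genePredExt gene models, wigFix score tracks, BED
    intervals, VCF sparse tracks), ingests multi-sample cohort VCFs with
    guaranteed parsimonious left-shifted variant normalization,
    multiallelic decomposition and reference checking, annotates every
    allele against each overlapping transcript with per-sample genotype
    statistics, and exposes the annotated rows through a typed
    natural-language query engine with edge n-gram text matching,
    synonyms, aggregations, Hardy-Weinberg filtering, compound
    heterozygote detection and saved recursive result sets. A synthetic
    fixture generator produces every input format with planted truth so
    the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
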