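# annoquery

Desk-scale variant annotation and natural-language filtering for genetic
sequencing experiments.

Finding the alleles that matter in a cohort VCF takes two steps: describing
every variant (annotation) and selecting variants and samples by those
descriptions (filtering). `annoquery` implements both as a single R
toolchain for method development and teaching at laptop scale:

* **Track store** — a per-position annotation database built from the
  field's standard formats: a FASTA reference, genePredExt gene models,
  wigFix per-base score tracks (PhyloP/CADD-style), BED intervals, and
  VCF sparse tracks (dbSNP/ClinVar/gnomAD-style INFO fields). Sparse
  records failing their source's FILTER are excluded, and every entry is
  keyed by its *canonical* allele so differently-shifted representations
  still match.
* **VCF intake** — streaming multi-sample VCF (plain or gzip) with strict
  site QC (reference sites `ALT=.`, FILTER-failed and symbolic-ALT records
  dropped and tallied), multiallelic decomposition with per-allele
  genotype recoding, reference checking, and *guaranteed parsimonious,
  left-shifted* variant normalization.
* **Annotator** — every allele is annotated against **each** overlapping
  transcript (alternate-splicing aware): site type (exonic, splice
  donor/acceptor, intron, UTR5/UTR3, ncRNA, intergenic) and coding
  consequence from ref-vs-alt codon translation (synonymous,
  nonsynonymous, stopGain, stopLoss, startLoss, frameshift /
  non-frameshift indels), plus per-sample genotype statistics and the
  transition/transversion class. Output is gzip TSV written with no
  uncompressed intermediate.
* **Search engine** — a typed schema is inferred from the annotation
  (smallest integer/float widths for accurate range queries), text is
  stemmed and indexed as left-edge n-grams, and a natural-language query
  parser supports implicit AND, `OR`/`||`, negation, field scoping,
  numeric ranges, quoted phrases, regex and fuzzy terms, a synonym
  dictionary (`stopgain` = `nonsense`, `missense` = `nonsynonymous`,
  `eds` = Ehlers-Danlos syndrome), aggregations, exact-match filters, a
  Hardy-Weinberg equilibrium filter, compound-heterozygote detection,
  trio labels for de novo discovery, and saved, re-indexed result sets for
  recursive filtering.
* **Fixtures** — a deterministic generator that produces *every* input
  (genome, transcripts, score/sparse tracks, cohort VCF) with planted
  truth, so the whole pipeline is testable offline.

## The statistics in brief

Normalization trims shared suffix/prefix bases and left-aligns pure indels
to a fixed point, keeping one padding base: the result is the
minimal-length representation at the smallest genomic coordinate among all
sequence-equivalent representations.

Per allele with `n` samples, `h` heterozygotes, `a` alternate homozygotes
and `m` missing genotypes:

```
heterozygosity = h/n     homozygosity = a/n     missingness = m/n
sampleMaf      = (h + 2a) / (2 (n - m))
```

The HWE filter estimates `p = (2 nRefHom + nHet) / 2n` among non-missing
samples and excludes variants whose chi-square
`sum((obs - exp)^2 / exp)` (1 df, expected counts `n p^2, 2 n p (1-p),
n (1-p)^2`) has a tail probability below `alpha`. Ts:Tv is the ratio of
transitions (A<->G, C<->T) to transversions over SNP rows, per experiment
or restricted to one sample's carried alleles.

## Worked example

```r
library(annoquery)

spec  <- fixture_spec(seed = 7)                  # trio + 7 cohort samples
fx    <- cmd_fixtures(spec, "fixtures")          # genome, tracks, cohort VCF
cfg   <- load_config(fx$config)
store <- cmd_build(cfg, out_log = "build.log")
ann   <- cmd_annotate(fx$cohort, store, "cohort.annotated.tsv.gz", cfg)
idx   <- cmd_index(ann, cfg)

execute("exonic", idx)
#> <search_result> 9 rows; Ts:Tv = 0.4

execute("cadd > 20 maf < .001 pathogenic expert review missense", idx)
#> <search_result> 2 rows; Ts:Tv = 0

idx <- define_custom_synonym(idx, "proband", list(samples = "S_child"))
idx <- define_custom_synonym(idx, "parents",
                             list(samples = c("S_mom", "S_dad")))
execute("proband -parents", idx)
#> <search_result> 3 rows; Ts:Tv = 0
```

The first query returns the nine coding alleles in the 300-variant default
cohort. The second is a rare-deleterious search: CADD-style score above
20, population frequency below 0.1% (`maf` is an alias for `gnomad.af`),
ClinVar-style significance "pathogenic" with expert review, and a missense
consequence — `missense` matching rows annotated `nonsynonymous` through
the synonym dictionary. The last uses trio labels to return exactly the
three de novo alleles planted by the generator (the proband carries them;
neither parent does).

`normalize_allele` reproduces textbook indel ambiguity resolution:

```r
g <- as_genome(c(chr15 = paste0(strrep("T", 42679998), "GCATTTT")))
normalize_allele("chr15", 42680000, "CA", "CAA", g)
#> <INS> chr15:42680000 C>CA (+A)
```

the insertion is anchored at the `C` with a single padding base — not
after the downstream `A` with two.

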