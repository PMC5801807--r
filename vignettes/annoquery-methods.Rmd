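---
title: "annoquery: models, algorithms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{annoquery: models, algorithms and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains what `annoquery` computes, the assumptions behind
each stage, and the choices we made where the design space was genuinely
open. Nothing here states an empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## Variant normalization

A VCF record describes an edit of the reference, but the same edit admits
many representations: indels inside homopolymers and short tandem repeats
can be anchored at any repeat unit, and records may carry redundant shared
prefix/suffix bases. Two annotation sources that represent the same allele
differently will silently fail to join. `annoquery` therefore reduces every
allele — cohort and sparse-track alike — to a canonical form before any
matching:

1. While both alleles are longer than one base and end with the same base,
   drop that base. If one allele has bottomed out at a single base but the
   last bases still agree (a pure indel inside a repeat), extend both
   alleles to the left with the reference base preceding the anchor and
   re-trim; this walks the indel leftward one base at a time.
2. Trim shared leading bases down to the single VCF-style padding base,
   advancing the position.

Run to a fixed point this yields the *parsimonious* (minimal `|ref|+|alt|`,
exactly one padding base for pure indels) and *left-aligned* (smallest
coordinate among sequence-equivalent forms) representation. Alleles equal
to the reference after trimming are dropped as non-variants. Shifting
stops at the contig start; the representation anchored there is kept, even
though it cannot carry the usual preceding padding base.

The test suite verifies all three claimed properties against an
independent brute-force oracle that enumerates *every* representation
within a ±20 bp window reproducing the same edited sequence
(`equivalent_reps` in the tests and in `scripts/acceptance.R`), on 1,000
randomized records that include deliberately right-shifted homopolymer
indels and redundant suffixes.

Classification follows length arithmetic after normalization: equal
lengths of one → SNP, equal lengths >1 → MNP (we do not decompose MNPs
into SNPs — decomposition would lose phase within the MNP), alt longer →
INS, ref longer → DEL. The compact form (`G`, `+AT`, `-2`) is what the
`alt` output column and the query engine see.

## Intake quality control

Sites are dropped (and tallied, per reason, into the run log) when FILTER
is neither `PASS` nor `.`, when ALT is `.` (a reference site is not a
variant), or when every ALT is symbolic (`<DEL>`, breakends) — structural
alleles are out of scope. The same FILTER rule governs sparse-track
ingestion, which is how QC-failed population-frequency records (e.g.
random-forest failures) are kept out of annotations. A `keep_filtered`
flag exists for pre-filtered inputs.

Genotypes are diploid; any `.` allele in a genotype makes that sample
*missing* for the site (half-calls do not count as carriers), and
non-diploid or out-of-range genotypes flag the whole record as malformed
(skipped, logged). When a multiallelic record is split, each sample is
re-classed per alternate allele: present twice → `altHom`, once → `het`,
else `refHom`. Splitting therefore conserves the sample count per child,
and the multiset of haplotypes implied by the children equals that of the
raw record (tested property). Alleles carried by zero samples are retained
(they may still be annotated) and are recognizable by `sampleMaf = 0`.

## Transcript effects

Gene models are genePredExt (0-based half-open, like the UCSC source
files); all user-facing coordinates are 1-based VCF-style, giving one
documented conversion boundary. Every allele is annotated against *each*
overlapping transcript in parallel arrays — there is no "worst
consequence" ranking, by design.

Site types are assigned per affected base with severity preference
exonic > splice > UTR/ncRNA > intronic. The splice window is the first
`spliceWindow` (default 2, the canonical donor/acceptor dinucleotide)
intronic bases at each exon boundary, transcript-strand aware. UTR5/UTR3
swap ends on minus-strand transcripts. An insertion's affected span is the
single base 3' of its anchor, with one override: an insertion anchored at
the last base of an exon is *exonic*, never a splice call — the inserted
bases fall between exon and intron and leave the splice site intact. This
is also why a coding insertion 37 bp from the nearest intron can never be
mis-called as splice-site disrupting.

Coding SNP/MNP consequences come from ref-vs-alt codon translation, with
codons counted from the CDS start in transcript orientation and
reverse-complemented alleles on minus-strand transcripts. Priority:
startLoss (codon 1 ATG disrupted), stopGain, stopLoss, synonymous,
nonsynonymous. An MNP spanning several codons reports one entry per
affected codon, positionally joined with `|` — a choice we document
because either convention is defensible. CDS indels are classed
frameshift / non-frameshift by inserted or deleted length modulo 3.

The correctness argument is dual-route: the per-codon logic is compared,
over hundreds of CDS SNPs on both strands, with an independent oracle
(`translate_classify`) that rebuilds and translates the *entire* alternate
CDS with the standard genetic code and classifies the protein difference.

Score tracks return per-base values over the allele's affected reference
span — one value for a SNP, one per deleted base for deletions (so
multi-base alleles naturally yield array values), the anchor-adjacent base
for insertions; unscored positions are omitted rather than emitted as NA.

## Per-sample statistics

With `n` samples, `h` heterozygotes, `a` alternate homozygotes, `m`
missing: heterozygosity `h/n`, homozygosity `a/n`, missingness `m/n`,
`sampleMaf = (h + 2a) / (2(n - m))`, undefined when all samples are
missing. `sampleMaf` is the alternate-allele frequency among called
alleles and may exceed 0.5; the field name is kept for familiarity despite
the "minor" in its expansion. The conservation identity
`heterozygosity + homozygosity + missingness + |refHom|/n = 1` is asserted
row-wise in the tests.

## The annotation store

The store is an in-memory per-position database rebuilt from source files
at run time: the reference as plain strings, score tracks as per-contig
numeric vectors, gene models interval-indexed via `IRanges`, and sparse
entries in a hash keyed by the canonical `(contig, pos, ref, alt)`. We
deliberately rebuild rather than serialize: at the scale this package
targets a build takes seconds, a serialized binary store would be a second
source of truth to version, and the contract that matters — read-only
lookups, any in-bounds position resolving, canonical-key matching — is
independent of the on-disk layout. Build provenance (assembly, per-track
version strings, ingest tallies) goes to a plain-text log.

## Text analysis and search

The schema is inferred from the data: a field is numeric iff every
non-missing element parses as a number, integer iff all are integral, and
stored widths are minimal (8/16/32/64-bit integers; 32-bit floats only
when every value survives a 32-bit round-trip within relative error 1e-6
— in practice this means only values outside float32 range force 64
bits). Mixed fields stay text; numbers inside text are not promoted.

Text analysis lowercases, deletes periods and apostrophes (so `E.D.S` →
`eds`, `expert's` → `experts`), splits on remaining non-alphanumerics,
and applies a light suffix stemmer (plural, `-ed`/`-ing`, terminal `-y` →
`-i`) written in-package; full lemmatization is out of scope and the
synonym table covers irregular equivalences. Postings are built from the
raw value, word tokens, stems, and left-edge n-grams of each stem (lengths
2–20: 2 admits short gene symbols, 20 bounds index size). Partial-word
queries (`pathogen`) match through the n-grams; misspellings that share a
prefix (`earl-onset`) match the same way; explicit fuzzy matching
(`term~N`, Levenshtein ≤ 2) matches against the word-token vocabulary
only, so n-grams never inflate fuzzy hits.

The query grammar combines whitespace-separated clauses with implicit AND
(multi-clause searches are conjunctive refinements — OR semantics could
not produce the small result sets such queries are for), `OR`/`||` for
alternatives, `-`/`NOT` for negation, `field:value` scoping with
case-insensitive dotted paths and a configurable alias map (`maf` →
the designated population-frequency field), numeric ranges with
leading-dot numbers, quoted phrases (contiguous stem sequences), regex and
fuzzy terms. Hyphenated compounds match either as separate words or as the
joined token, so `non-synonymous` finds values annotated
`nonsynonymous`. Synonyms expand at parse time into OR groups; custom
labels may name sample sets, which become carrier predicates — labelling a
trio (`proband`, `parents`) turns de novo discovery into
`proband -parents`. Negation over multi-valued fields means "no element
matches", and complements are taken against the full row universe, so
`|Q| + |NOT Q|` equals the corpus size.

Every primitive has two implementations: the index path (postings, sorted
numeric arrays) and a brute-force row scanner (`execute_scan`) used as the
correctness reference; the test battery asserts identical result sets over
a 10,000-row corpus.

Aggregations give the top-200 value counts for text fields (ties broken
lexicographically) and count/min/max/mean/population-SD for numeric
fields. Exact-match filters are non-analyzed element-wise
include/exclude, composable with any query. The HWE filter computes the
1-df chi-square from genotype counts among non-missing samples with no
continuity correction (an exact test is future work); monomorphic and
untestable rows are retained. Compound-heterozygote detection is
phase-unaware: two or more distinct heterozygous variants per (sample,
gene). Saved results re-write the subset through the same compressed
writer, re-index it, and record parent + query provenance, enabling
recursive filtering; the statistical-filter/tool surface is a plain
function interface so further tools can be added without touching the
engine.

## The fixture generator

The generator *defines* the study conditions. Defaults: two 60 kb contigs;
6 transcripts built from one planner shared with the genome writer (the
genome embeds each planned CDS, so every coding model starts with ATG, is
in frame, ends with a stop, and contains no premature in-frame stop);
alternate splicing is a codon-aligned skipped middle exon, so both
isoforms keep valid CDS; one non-coding transcript; 300 cohort variants
(~75% SNP / 25% indel) over a 10-sample cohort containing one trio with
Mendelian-consistent genotypes and exactly 3 planted de novo alleles;
allele frequencies uniform on (0.08, 0.5); missingness 0 by default.
Two wigFix score tracks (conservation-like on (-3, 7), deleteriousness-like
on (0, 40)) cover the first 80% of each contig — the uncovered tail
exercises unscored-region behaviour. Sparse tracks cover a planted subset
of cohort variants plus novel alleles, with five FILTER-failed records and
one deliberately right-shifted representation to exercise QC exclusion and
canonical keying. Designed variants guarantee non-empty result sets for
the demonstration queries regardless of seed: a stop-gain SNP with a
pathogenic/expert-review Ehlers-Danlos-style entry, and two low-frequency
nonsynonymous SNPs with forced high deleteriousness scores.

Ten samples is deliberate: one hidden genotype then yields row missingness
0.1, which the strict `missingness < .1` clause excludes — the mechanism
by which injected missingness is filtered back out of de novo queries.
De novo truth rows are never given missing genotypes, so recall is a clean
property of the query, not of the injection.

What the generator does *not* emulate: linkage disequilibrium, demography,
sequencing error profiles, read-level evidence, structural variation, and
real annotation databases. Passing tests therefore demonstrate algorithmic
correctness on well-formed inputs and adversarial representations, not
robustness to every artifact of production VCFs.

## Numerical and scale choices

Problem sizes in the suite — 1,000 records for the normalization
properties (±20 bp enumeration window, allele length cap 12), 550 CDS
SNPs for the translation oracle, 10,000 rows and 43 queries for search
concordance, 2,000 simulated variants × 200 samples for HWE type-I
control — are chosen so the whole suite runs in minutes on one core while
keeping each property statistically meaningful. The HWE null simulation
draws allele frequencies from U(0.2, 0.5), where the 1-df chi-square tail
approximation is comfortably accurate at n = 200; the observed exclusion
rate is required to sit within three binomial standard errors of alpha.
Determinism: every generator artifact derives from per-artifact sub-seeds
of one spec seed, so adding an artifact kind never perturbs earlier
outputs, and identical specs produce byte-identical files.

## Known limitations

* Diploid genotypes only; sex chromosomes and mosaicism are not modelled.
* MNPs are not decomposed; effects spanning a splice boundary report the
  dominant site type rather than a compound consequence.
* The stemmer is a deliberately small suffix-stripper; irregular English
  morphology must go through the synonym table.
* The HWE test is asymptotic; very small cohorts should use an exact test.
* The store lives in memory: genomes far beyond desk scale would need the
  bucketed on-disk layout sketched above, which we left out of scope.
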