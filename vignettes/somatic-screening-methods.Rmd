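---
title: "Methods: somatic variant screening from paired tumor/normal RNA-Seq callsets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: somatic variant screening from paired tumor/normal RNA-Seq callsets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnasomatic)
```

## The problem

Variant calls made from RNA-Seq read alignments are a cheap by-product of
expression studies, but they are noisy: PCR duplicates inflate coverage at
some sites, misalignment around indels produces clustered false calls, and
A-to-I RNA editing shows up as spurious A>G (and, on the other strand,
T>C) changes. When a tumor sample and a matched normal sample from the
same individual are both available, a cascade of set-based filters can
nevertheless extract a credible list of *tissue-specific somatic*
variants: changes seen in the tumor callset, absent from the matched
normal, absent from a population database of known (germline) variation,
and not explainable by the artifact modes above.

`rnasomatic` implements that cascade, the descriptive statistics used to
sanity-check its output (mutation spectrum, transition/transversion
ratio, exact 2x2 tests, rank-sum coverage comparison), coding-consequence
annotation of the surviving variants, gene ontology enrichment of the
disruptively hit genes, and a fully deterministic simulator that plants
each variant class with a ground-truth label so that the whole pipeline
can be validated end to end.

## The filter cascade

Six stages are applied per sample in a fixed order. For a call $v$ with
phred quality $Q(v)$ and site depth $d(v)$:

1. **Quality (1.1)** — keep $Q(v) \ge q_{\min}$ (default 20, i.e.
   mis-call probability $\le$ 0.01).
2. **Coverage ceiling (1.2)** — train a per-sample cutoff $c$ as the
   nearest-rank 97.5% quantile of $d$ over the calls that are members of
   the known-variant database (sorted depths, element
   $\lceil 0.975\,n\rceil$), then keep $d(v) \le c$. Known variants are
   overwhelmingly real, so the upper tail of their coverage distribution
   marks duplicate-inflated and collapsed-repeat sites. The boundary is
   inclusive: the cutoff value itself was observed at trusted sites.
3. **Paired coverage (2.1)** — keep calls whose position has at least
   `min_depth_both` reads (default 1) in *both* members of the pair;
   a site covered in only one tissue cannot be interpreted.
4. **Known-variant subtraction (2.2)** — drop calls present in the
   database. Matching is exact on (chrom, pos, ref, alt) by default; the
   source study never states whether its matching was allele-aware, so a
   positional mode is exposed as a configuration switch
   (`db_positional`) but is not the default — allele-aware matching is
   the conservative reading.
5. **Shared-call subtraction (2.3)** — drop calls whose key also occurs
   in the partner tissue. The partner reference set is the partner's
   *quality-filtered* (post-1.1) callset: a quality-credible call in the
   other tissue disqualifies somatic status even if the partner's
   coverage filters would later have discarded it. This keeps the filter
   symmetric: a shared call disappears from both sides.
6. **Local mismatch cluster (2.4)** — for each call, count *other*
   called variant sites within ±`flank` bp (default 10) on the same
   chromosome; the rate is count/(2·flank). Discard when rate ≥ 0.1 *or*
   count ≥ 2 — with the default window of 20 flanking bases the two
   thresholds coincide (2/20 = 0.1), which is why both are kept
   configurable. "Mismatch" is operationalized as neighboring *called
   sites* rather than read-level mismatches: the cascade consumes
   callsets, not alignments, and clustered calls are the callset-level
   signature of indel-adjacent misalignment. The neighbor universe is
   the same sample's post-2.1, *pre-2.2* callset, so that known variants
   still flag misalignment-prone regions even though stage 2.2 removes
   them from the candidate list.

`run_cascade()` returns the two tissue-specific callsets plus a
`FilterReport` recording in/out counts for every stage and the trained
cutoffs — the audit trail mirrors how such cascades are reported in
practice (one shrinking count per stage).

## Statistics

- `fisher_exact_two_sided()` is the exact conditional test with the
  point-probability rule: with margins fixed, it sums hypergeometric
  probabilities of all tables at most as probable as the observed one
  (relative tolerance 1e-7 on the comparison). The test suite checks it
  against a binomial-coefficient enumeration oracle for every 2x2 table
  with total ≤ 30.
- `rank_sum_test()` enumerates all rank assignments exactly when both
  samples have ≤ 8 observations (ties via mid-ranks) and otherwise uses
  the normal approximation with tie and continuity correction.
- Spectrum classes use the pyrimidine-reference convention (C>A, C>G,
  C>T, T>A, T>C, T>G): a substitution and its reverse complement are the
  same event. The uncollapsed 12-class view is available via
  `classify_substitution(collapse = FALSE)`.
- `count_ratio()` and the percentage helpers round half-up, the
  convention used for printed ratios. One consequence worth documenting:
  23,549/19,383 = 1.2149 rounds to 1.21 under a single half-up rounding;
  printing 1.22 for that quotient requires rounding twice (1.2149 →
  1.215 → 1.22). The package rounds once.

## Consequence classification

Gene models come from an Ensembl-style GTF plus reference FASTA
(`index_gene_models()`, built on rtracklayer/Biostrings). A variant is
assigned to a transcript when its reference footprint intersects any
exon. Within the CDS, SNVs are classified by translating only the
affected codon before and after the change (strand-aware, standard
genetic code): synonymous, missense, stop_gain, stop_loss. Indels are
frameshift when the length difference is not a multiple of 3, otherwise
inframe_indel. Exonic-but-noncoding positions are `noncoding`.
"Disruptive" = {missense, stop_gain, stop_loss, inframe_indel,
frameshift}: everything that changes encoded amino acids or the reading
frame, read inclusively so that in-frame indels (which add or remove
amino acids) count. Splice-site effects are *not* modeled — the inputs
carry no read evidence — and variants are applied to the reference CDS
one at a time, with no haplotype-aware co-application. A gene counts as
disruptively hit if any of its transcripts yields a disruptive call.

The correctness argument is a dual route: the per-codon implementation
is tested against an oracle that rebuilds the entire mutant chromosome,
shifts the downstream CDS coordinates, re-splices, translates both full
proteins and compares them, across ≥ 1000 random toy transcripts on both
strands.

## GO enrichment

Annotations are propagated under the true-path rule (a gene annotated to
a term is annotated to all its is_a ancestors; diamonds collapse by set
union). Each term with ≥ 1 annotated universe gene gets a one-sided
hypergeometric upper-tail p-value; namespaces are tested separately and
corrected separately (Benjamini–Hochberg by default, Bonferroni
optionally). The "classic" per-term test is intentional — decorrelation
algorithms in the topGO family (elim/weight) are out of scope. The
universe is the set of annotated genes supplied; the expected column is
the hypergeometric mean `annotated · study/universe`.

## The simulator: a stated world

`simulation_config()` describes the world the tests assume; its defaults
are fixed, not tuned:

| parameter | default | rationale |
|---|---|---|
| genome | 2 × 100 kb | desk-scale; whole pipeline in seconds |
| genes | 20 non-overlapping multi-exon ORFs, both strands | consequence classes all reachable |
| germline rate | 1e-3/bp (≈200 calls, both tissues) | enough to train the coverage ceiling |
| known-DB fraction | 0.6 | leaves ~40% of germline novel, matching the novel-variant proportions RNA-seq callsets show |
| somatic rate | 2.5e-4/bp | exactly 50 tumor-only variants at the default genome (counts are round(rate·size), deterministic) |
| artifact rates | 5e-5 each (cluster 2e-5) | ~10 per class; each class violates exactly one filter |
| editing rate | 5e-4 per transcribed base | A>G excess on the transcribed strand, both tissues |
| coverage | NB(mean 20, size 5) + 1% ×10 duplicate spikes | heavy upper tail for stage 1.2 to remove |
| QUAL | real ~N(60,10) ≥ 25; lowqual ~N(8,4) < 20 | clean separation at the 20 threshold by construction |

All planted variants keep a pairwise distance > 10 bp (except the
deliberately clustered class), somatic depths are clamped inside the
ceiling the cascade will train, and call depths always equal the
coverage-track depths — so on a clean simulation the cascade provably
returns exactly the planted somatic set, and each artifact class dies at
its targeted stage. The truth table labels every planted variant
(germline_known/novel, somatic, editing, and five artifact classes — the
artifact panel is finer-grained than a three-label scheme so the labels
stay mutually exclusive and exhaustive).

What the simulator does *not* emulate — and what a green test therefore
does not establish: read-level evidence (no FASTQ/BAM; "mismatch" is
call-level), mapping bias, allele-specific expression, subclonal
fraction, real human repeat structure, chimeric transcripts, and
coverage–expression correlation beyond "expressed everywhere ≥ 1 read".
Recovery of 100% of planted somatic variants is a statement about filter
logic, not about sensitivity on real tumors.

## Numerical choices and degenerate inputs

- Nearest-rank (ceiling) quantile for the ceiling: deterministic and
  integer-valued; matches "97.5% of known variants have lower coverage".
- Depth ≤ cutoff retained (inclusive boundary), see above.
- Missing VCF `DP` → depth 0: the call then fails paired-coverage checks
  rather than silently passing (fail-safe).
- Missing QUAL (`.`) → 0 → removed at stage 1.1.
- Alleles are trimmed to minimal representation (shared suffix, then
  shared prefix, shifting pos) before any key comparison; full
  reference-based left-alignment is not attempted because readers cannot
  assume the FASTA is present.
- Training the ceiling with no known calls in the callset is an error
  instructing the caller to supply a manual cutoff; an *empty* callset
  short-circuits to cutoff 0 so an empty pair still reports all-zero
  stage counts.
- Ti/Tv with zero transversions is an error (undefined), not Inf.
- The config file is JSON rather than YAML: it round-trips through
  jsonlite, which is guaranteed present, and the CLI flags override it.

## Known limitations

- Filter 2.4 counts called neighbors, not read mismatches; with BAM
  input the original read-level definition could be stricter.
- Multi-sample VCFs are rejected rather than split; run per-sample
  files.
- The enrichment universe must be supplied (or defaults to the annotated
  genes); no attempt is made to reconstruct an expression-filtered
  universe.
- Recurrence tables flag genes hit in all *supplied* tumor samples; with
  a single pair that is one sample, so "recurrent" is only meaningful
  when several pairs' consequence tables are passed in.
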