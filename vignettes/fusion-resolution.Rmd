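---
title: "Resolving gene fusions with structural variant support"
author: "fuseSV"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resolving gene fusions with structural variant support}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fuseSV)
```

## The model

A gene fusion is created at the DNA level by a structural variant (SV)
whose two breakends fall inside (or near) two genes with orientations
that splice the upstream exons of one onto the downstream exons of the
other. RNA-seq fusion callers observe the *spliced* product, so the RNA
breakpoints sit on exon boundaries while the causal DNA breakends sit
anywhere in the adjacent introns. `fuseSV` encodes exactly this
relationship:

* For the 5′ partner, the retained portion is everything upstream of the
  RNA breakpoint in transcript orientation; the DNA break must therefore
  lie in the intron immediately following the last retained exon, and the
  breakend must *retain* the side pointing back at those exons (its
  genomic left on a plus-strand gene, right on minus).
* For the 3′ partner the statement is mirrored: intron preceding the
  first retained exon, retained side pointing downstream.

Both conditions together form the orientation contract. Deletion,
duplication, inversion and translocation junctions are all instances of
it — the SV type is itself derived from the two breakend orientations
(left+right in genome order = DEL, right+left = DUP, equal = INV,
different chromosomes = CTX), so no per-type special cases exist in the
matcher.

### The matching-interval hierarchy

Matching is expressed as membership of a breakend footprint in a
hierarchy of intervals derived from one canonical transcript per gene:

| level | interval | meaning |
|---|---|---|
| `intron_exact` | the adjacent intron (exclusive of its flanking exon-boundary bases) | RNA breakpoint on an exon boundary, DNA break exactly where splicing predicts |
| `gene_body` | the transcript span | breakend in the right gene, structure less certain |
| `gene_flank` | transcript span ± `flank_bp` | promoter-proximal or near-gene breaks |

The exact set of agreement levels between RNA and DNA breakpoints is an
open design point; this three-level reconstruction orders levels by
specificity and records the achieved level on every reported fusion, so
stricter post-hoc filtering is always possible. When the RNA breakpoint
does not coincide with any exon boundary (tolerance
`exon_boundary_tolerance_bp`, default ±3 bp — splice-aware aligners
occasionally shift junctions a few bases), the first level degrades to a
window of ±`noncanonical_window_bp` (default 1000 bp) around the
breakpoint and the fusion is flagged non-canonical. Intervals are
clipped to the gene body so the nesting invariant
`intron_exact ⊆ gene_body ⊆ gene_flank` holds unconditionally.

A fixed-size window mode (`interval_mode = "fixed_window"`, total
`fixed_window_bp` = 10 kb centered on the RNA breakpoint) is provided
purely as a comparison baseline: it has no knowledge of gene structure
and loses every event whose breakend lies deeper than 5 kb into an
intron. The synthetic cohort plants such events deliberately (intron
lengths up to 40 kb, offsets over 12 kb).

### Canonical transcript choice

One transcript per gene is selected by stepwise filtering, each step
retained only when at least one transcript survives it: MANE Select tag;
`basic`; `CCDS`; any `appris_principal*` tag; protein-coding biotype;
minimum transcript support level (missing TSL ranks worst); maximum
coding-sequence length; final ties broken by the lexicographically
smallest transcript id. The tie-break makes the choice deterministic and
permutation-invariant, which the tests verify against an exhaustive
re-implementation over all 2⁴ tag combinations.

### Consensus and classification

Calls from the three SV-caller dialects are clustered per fusion:
intrachromosomal calls join when reciprocal overlap exceeds `min_recip`
(0.5); translocations, which have no span, when both breakend pairs lie
within `ctx_max_dist` (default 1000 bp — in practice concordant callers
agree within ~10 bp, so this is deliberately permissive). The largest
cluster by distinct callers wins; ties prefer more specific match levels,
then smaller RNA–DNA distances. Consensus breakend positions and allele
fractions are *medians* across callers, robust to a single outlier
assembly footprint (broad footprints of several hundred bp do occur).
Clusters mixing SV types, or containing several calls from one caller,
are flagged `composite` — the single-SV model is then doubtful and a
rearrangement chain is likely. A consensus made solely of
FILTER-failing calls is kept but flagged `filtered_only`; filtering is
the consensus layer's decision, not the reader's.

High confidence requires both RNA callers *and* at least `min_callers`
(2) SV callers. Somatic status uses the paired allele fractions with
AF = variant/(variant+reference), variant and reference evidence each
summed over paired-end and split-read counts per sample (the exact
caller formulas differ; the per-dialect FORMAT mapping is isolated in
`sv_dialects()`): normal AF ≥ `germline_normal_af_min` → germline,
else tumor AF ≥ `tumor_af_min` → tumor-specific, else low AF. The 0.10
defaults are exposed in the configuration and echoed into every report
header; they are boundary parameters, and the tests verify that sweeping
them moves only events whose AF lies between the old and new cutoffs.

### Expression and copy-number context

Expression z-scores are computed per gene against the samples of the
same cancer-type supergroup, by default on log2(FPKM+1): FPKM is heavily
right-skewed and raw-scale z-scores overweight highly expressed genes;
the raw scale remains selectable (`zfpkm_log = FALSE`) and the choice is
recorded in output. |z| > 1.96 flags over/under-expression; the reported
per-gene p-value is the two-sided normal tail of the z-score and is
labeled as such — it is a descriptive quantity, not a calibrated test.
Copy-number status uses log2 fold-change cutoffs 0.58 (gain) and 1.58
(amplified); the loss cutoff −0.58 mirrors the gain threshold. Fusion
burden (≥ `high_burden_min` = 5 high-confidence fusions) is compared
against the fraction of genome altered with a two-sided Wilcoxon
rank-sum test; an optional helper computes FGA from a segment table as
the fraction of segmented bases with |l2fc| > 0.58.

## What the synthetic cohort emulates

`run_simulate()` generates a toy genome (invented contigs `tg1…`, so no
real reference can leak in) and plants six event kinds: tumor-specific
fusions with true SVs (including four with FFPM below the conventional
0.1 cutoff and four with breakends > 10 kb into long introns), germline
SV chimera with matching normal-sample support, low-allele-fraction
events in amplified regions (high reference depth, CN l2fc > 1.58,
16-fold overexpressed 3′ partners), read-through chimera with RNA rows
in both dialects but no SV (on contigs that carry no SVs at all),
single-RNA-caller false positives, and intergenic population SVs that
appear in every caller's VCF and in the population resource. Event
counts, read-support ranges, footprint widths and the three-patient
high-burden structure are the study conditions of the generator's
defaults; per-caller breakpoint jitter defaults to 0 (noise-free).
Four true fusions are deliberately reported by only one SV caller so the
high-confidence rule has genuine negatives; this is a fixed count rather
than a per-caller dropout probability, keeping the expected
high-confidence set deterministic for any seed.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: alignment artifacts and mapping ambiguity in
repetitive regions, caller-specific systematic biases beyond FORMAT
dialects and footprint widths, multi-SV rearrangement chains (only
flagged, never reconstructed), subclonal heterogeneity, and
read-level noise (no FASTQ simulation). Recall/precision of 1.0 on the
synthetic cohort demonstrates the integration logic, not caller
performance on real tumors.

## Numerical and degenerate-input choices

* Coordinates are 1-based inclusive throughout, the native convention of
  GTF, VCF and the IRanges containers used internally; all emitted
  coordinates stay 1-based.
* `intron_exact` excludes the flanking exon-boundary bases themselves (an
  interval written "(1000, 5000)" contains 1001–4999): the boundary bases
  are exonic and belong to the retained sequence.
* Zero-depth samples give a missing allele fraction and the record is
  flagged, not dropped; fusions with both AFs missing classify as
  `unclassified` rather than silently defaulting.
* Breakend mates lacking their partner record, and single-breakend
  records, are dropped with warnings — one breakend cannot link two
  genes.
* Consensus positions use medians, rounded to integer bases.
* Cluster ties are resolved by (callers, level specificity, summed
  distance), in that order; remaining ambiguity cannot change the
  high-confidence decision, only the representative breakpoints.
* Chromosome names are harmonized by stripping a `chr` prefix at parse
  time.
* The repeat track is pre-filtered at load time to classes
  LINE/SINE/LTR and by completeness. "Fewer than 50 bp missing" (keep
  near-complete elements) is the default reading; the opposite predicate
  is selectable via `repeat_completeness_mode` because the criterion is
  ambiguous in prose.

## Problem sizes

The shipped tests and the acceptance script run the full pipeline on a
20-patient cohort with 60 planted events over a 150-gene toy genome —
small enough to resolve in well under a minute on one core while still
exercising every event kind, caller dialect and interval-hierarchy
regime. The oracle comparisons run on deliberately small instances
(≤ 50 SVs × 20 predictions for the matching scan, n ≤ 12 for the exact
permutation test) where exhaustive enumeration is feasible.

## Known limitations

* One canonical transcript per gene: isoform-specific fusions whose
  breakpoints only make sense on a non-canonical isoform can degrade to
  the non-canonical window.
* Intergenic/enhancer-hijacking events are out of scope: both breakends
  must fall within a gene's flank.
* The composite flag marks multi-SV junctions but no chain
  reconstruction is attempted.
* Allele-fraction read summation is one documented convention among the
  callers' several; it is isolated in `sv_dialects()` for replacement.
* The distinct-fusion mapping is by oriented gene-symbol pair; paralog
  renames across annotation versions are not reconciled.
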