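---
title: "Methods: integrating somatic alterations with germline risk regions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrating somatic alterations with germline risk regions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(germsoma)
```

This vignette documents the models, parameters, and design choices
behind `germsoma` — what each stage assumes, why the defaults are what
they are, and what the synthetic-data tests do and do not demonstrate
about real data.

## The scientific question

Germline GWAS have mapped dozens of epithelial ovarian cancer (EOC) risk
loci, most of them noncoding; tumour sequencing has catalogued somatic
SNVs, copy-number alterations (CNAs), and mutational-signature
activities. The pipeline asks two linked questions: (i) is the
expression of germline susceptibility genes correlated with somatic
mutational-signature activity across tumours, beyond what random gene
sets show; and (ii) within the 1 Mb risk regions around GWAS index SNPs,
are somatic point mutations and CNAs concentrated in functionally
annotated elements — promoters, enhancers, chromatin states — and do
germline and somatic variants converge on the same transcription-factor
binding sites (TFBSs)?

## Signature–gene association

For each (gene, signature) pair, signature activity is regressed on
gene expression by simple OLS; the reported p-value is the two-sided
t-test on the slope. Design choices:

* **Direction.** Activity is the response: signature burden is the
  outcome being explained. For simple OLS the slope-test p-value is
  identical in the reverse direction, so significance counts do not
  depend on this choice.
* **Expression transform.** Expression is log2(x + 1)-transformed by
  default (`log2_expr = TRUE`); RNA-seq abundance is heavy-tailed and
  the transform stabilises leverage. It can be switched off.
* **No multiplicity correction in the scan.** Per-signature counts use
  the nominal p < 0.05. The gene-set question is instead answered by the
  permutation test, which compares whole lists and is immune to the
  per-pair multiplicity. BH-adjusted q-values are available behind
  `bh = TRUE`.
* **Degenerate inputs.** Zero expression variance yields slope 0,
  p = 1, and a `degenerate` flag; constant activity yields slope 0,
  p = 1. Samples with missing values are dropped pairwise; fits require
  at least 3 complete pairs.

The permutation test draws, in each of `n_iter` iterations (default
10,000), a random gene list of the same size, uniformly **without**
replacement from all expression genes (the susceptibility genes
included), and recounts significant pairs. The p-value is the fraction
of iterations whose count **strictly exceeds** the observed count. With
fixed expression and activity matrices the per-gene significant-pair
counts are themselves fixed, so each iteration reduces to summing a
precomputed vector over a random subset; this is mathematically
identical to rerunning the scan per iteration and is what makes
10,000 iterations effectively free. An optional (N+1)/(n+1) small-sample
correction is off by default, matching the strict-exceedance
definition; note that under the strict rule a list that beats every
random draw reports p = 0.

Signatures are annotated with their proposed COSMIC etiology
(`default_etiology_map()`): mismatch repair deficiency (SBS26, DBS7),
homologous recombination deficiency (SBS3, ID1, ID2, ID6, ID8),
age-related mutagenesis (SBS40, SBS5, SBS1, ID4, ID5, DBS4), platinum
chemotherapy treatment (SBS35, DBS5), environmental factors (SBS18,
DBS2), APOBEC mutagenesis (SBS2, SBS13, DBS11); anything else maps to
"unassigned". No covariates (purity, age) are included in the
regressions.

## Intervals and risk loci

All intervals are 0-based half-open in memory; 1-based conventions (VCF
positions, SEG starts) are converted exactly once at the I/O boundary.
Abutting intervals do not overlap; merging joins overlapping *and*
abutting pieces, so coverage is computed on a disjoint union.
Chromosome names are matched with the leading `chr` stripped (PCAWG
vs UCSC dialects) but preserved on output.

A risk locus is the index SNP ± 500 kb. "1 Mb" is ambiguous at the
±1 bp level; here it is realized as exactly 1,000,000 bp with the index
base the last base of the upstream half: with p0 the 0-based index
position, the region is [p0 − 500,000, p0 + 500,000), clipped to the
chromosome. Loci may overlap each other (distinct histotype signals can
share a cytoband); an element inside several loci is counted once per
locus and flagged. "In a locus" means ≥ 1 bp overlap by default.

The engine is backed by IRanges/GenomicRanges; its contract — not the
backend — is what the tests pin down, by comparing intersection,
merging, and coverage against a per-base brute-force oracle on random
tracks.

## Frequently mutated elements

Each element of an annotation track is tested against a uniform
Poisson background: with pooled background rate r (mutations per bp
across all samples) and element width w, p = P(Poisson(rw) ≥ observed),
inclusive upper tail. The default rate is estimated as SNVs overlapping
the track's merged footprint divided by the merged width — a rate *on
the track*, slightly conservative when hotspots inflate the numerator.
BH adjustment is applied within each track (tracks differ in element
length distributions); `significant` means q below the FDR threshold
(default 0.05).

This burden model is deliberately minimal — no trinucleotide context,
replication timing, or expression covariates — and is a stand-in for
full driver-discovery machinery. The quantity the pipeline actually
reports is the enrichment layer above it: the percentage of
significantly mutated elements among all elements of an annotation
(two decimals; an empty denominator is reported as undefined, never
as 0), stratified genome-wide, per chromosome, or per risk locus.

The recurrence tally counts, for every mutated position, the number of
*distinct* samples mutated there; duplicate records from one sample
count once for recurrence, and the totals obey
total = Σ k·count(k), unique positions = Σ count(k).
`tally_from_histogram()` applies the same invariants to a printed
recurrence distribution.

## Recurrent CNAs

Segments with seg.mean ≥ +0.3 (amplification) or ≤ −0.3 (deletion) are
binarised per 10 kb bin; the observed per-bin frequency is the fraction
of samples altered there. The null circularly rotates each sample's
altered-interval layout by an independent uniform offset per chromosome
— preserving that sample's total altered bp exactly — and the per-bin
p-value is (1 + #{permuted frequency ≥ observed}) / (1 + n_perm),
so p is never exactly 0. BH is applied across bins per direction
(default q < 0.25, the customary recurrent-CNA convention), and
adjacent significant bins merge into regions carrying the maximum bin
frequency and minimum p/q. Thresholds ±0.3, 10 kb bins, and the 0.25
FDR are conventional defaults, all configurable. Regions from an
external caller can be supplied directly (config `cna$regions`),
skipping the caller while keeping the annotation and locus-intersection
stages.

Chromatin-state coverage uses the seven-state vocabulary (active
region, active/weak promoter, active/weak enhancer, transcribed,
insulator); low-signal states are excluded upstream because, without
repressive marks, low-signal cannot be distinguished from poised
chromatin. Coverage rows are descriptive — no significance test is
attached — matching how state coverage of CNAs is conventionally
reported.

## TFBS disruption

PWM probabilities come from JASPAR-style counts with a pseudocount
(default 0.8) added per cell before column normalization. A window's
raw score is Σ log2 p(base); normalization maps the per-column best
(consensus) to 1 and worst (anti-consensus) to 0. Both strands are
scanned; the reverse strand scores the reverse complement.

A variant is scored by taking, separately for the reference and
alternate alleles, the best score over *all* windows (both strands)
overlapping the variant base — the best window may differ between
alleles. The call is `disrupting` when max(ref, alt) ≥ 0.85 and
|ref − alt| ≥ 0.10. These two thresholds are this package's defaults:
the strong-site threshold keeps calls to near-consensus sites, and the
delta threshold corresponds to roughly one high-information column of
an 8–10 bp motif (a single consensus→worst substitution in an 8-column
motif shifts the normalized score by ≈ 1/8). They are calibrated on the
synthetic planted sites (sensitivity ≥ 0.95, false-call rate ≤ 0.05 at
defaults) and should be revisited for substantially longer motifs,
where a one-column change moves the normalized score by less.

Somatic burden is counted per (TF, element): SNVs falling inside the
TF's predicted sites (windows scoring ≥ 0.85) within the element, with
the ≥ 3-mutation filter applied per element, not genome-wide. The
germline and somatic TF lists are intersected by whole-name matching,
so dimer motifs ("PPARA::RXRA") are atomic.

## The synthetic-data generators

The generators define the study conditions under which the pipeline is
tested:

* **Expression/activity** (`gen_signature_expression`): expression is
  lognormal (meanlog 1, sdlog 0.5); activities are non-negative
  continuous scores, max(0, intercept + slope·expr + noise) for planted
  pairs and max(0, intercept + noise) otherwise, with intercept 5 and
  baseline noise sd 1 so clipping at zero is a ~5σ event and the null
  calibration is clean. Signature scores are modelled as non-negative
  continuous values; nothing downstream depends on whether they are
  counts or proportions. The default association scan uses 89 samples,
  the size of a matched expression/signature cohort in this setting.
* **SNVs** (`gen_snvs`): per-sample Poisson background over a uniform
  genome, hotspot intervals multiply the local rate; ref/alt drawn from
  {A, C, G, T} with ref ≠ alt. A zero background rate returns an empty
  table (not an error), and every downstream stage tolerates empty
  tables. No indels are generated: indel signatures enter the analysis
  only through the activity matrix.
* **CNA segments** (`gen_cna_segments`): per sample and chromosome,
  random breakpoints tile the chromosome exactly once; background
  seg.mean is N(0, 0.05), and each planted region is altered with its
  penetrance at a magnitude uniform in [0.5, 1.5] of the planted sign.
  Overlapping recurrent regions of opposite sign are rejected.
* **PWMs and variants** (`gen_pwms_and_variants`): one dominant base
  per column (counts 90 vs 3, pseudocount 0.8 → dominant probability
  ≈ 0.89), perfect-consensus sites planted non-overlapping with a
  motif-length buffer; disruptive variants change the most informative
  column of a planted site from consensus to the worst base, neutral
  variants land at least one motif length from every planted site.

All generators are byte-deterministic under a fixed seed.

What passing on these conditions does **not** show: real mutation rates
vary with trinucleotide context, replication timing, and chromatin —
the uniform-background burden test will be miscalibrated on real data
in ways the synthetic tests cannot reveal; real signature activities
are estimated (not generated) quantities with their own uncertainty;
real binding-site disruption depends on cooperative binding and
chromatin context that PWM deltas ignore. The synthetic results
validate the machinery — coordinate handling, statistics, recovery of
planted structure — not the biology.

## Problem sizes and numerical choices

The test suite and the acceptance script run the generators at
deliberately modest scale — 200 kb–2 Mb toy genomes, 100-element
tracks, 20–100 samples, 300–1,000 permutation iterations, 50-seed
replications — sizes chosen so the full suite completes in about a
minute while keeping Monte-Carlo error well inside the asserted
margins (e.g. the null-calibration check uses 200 lists, giving a
binomial standard error of ≈ 0.015 on the 0.05 target).

Ties and edge cases: the permutation counter uses strict ">", so p = 0
is attainable; Poisson tails are inclusive (P(X ≥ 0) = 1); BH never
reorders a within-track ranking; perfect OLS fits report p at the
numerical floor rather than NaN; enrichment with an empty denominator
is NA; interval construction rejects zero-width regions outright.

The pipeline fans one global seed into fixed per-stage sub-seeds
(`seed·131 + stage_index·10007 mod 2^31`), so each stage is
reproducible in isolation and two runs with one config are
byte-identical — the determinism the manifest checksums assert.

## Known limitations

* The burden and recurrent-CNA callers are stand-ins; their outputs
  should not be compared against full driver/GISTIC-class callers on
  real data without recalibration. The consume-path for external
  region lists exists for exactly that reason.
* Locus definitions other than ±500 kb (1 cM, ±1 Mb) are not
  implemented.
* The variant model is SNV-only; multi-allelic VCF rows are split and
  indels skipped (with a count).
* PWM disruption thresholds are tuned for short, high-information
  motifs; users comparing against published disruption-tool output
  should expect threshold-dependent differences.
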