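---
title: "Methods: PDX somatic, copy-number and expression post-processing"
author: "pdxsoma"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PDX somatic, copy-number and expression post-processing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdxsoma)
```

# The problem

Patient-derived xenografts (PDXs) are human tumors engrafted in
immunodeficient mice. Sequencing libraries from engrafted tumors mix graft
(human tumor) and host (mouse stroma) DNA or RNA, and paired normal tissue
from the patient is usually unavailable. Three analytical consequences
drive this package's design:

1. **Host reads masquerade as somatic variants.** Mouse and human coding
   sequence is roughly 85% identical, so mouse reads align to the human
   reference with mismatches that surface as low-quality variant calls.
2. **Germline variants cannot be subtracted with a matched normal.**
   Tumor-only calling must instead lean on population databases and a
   normal-sample compendium, at a cost in sensitivity for true somatic
   events that happen to coincide with known polymorphisms.
3. **Systematic errors recur across unrelated samples.** Sequencing and
   alignment artifacts produce positions "mutated" in a large fraction of
   a cohort, far above what somatic biology produces.

`pdxsoma` implements the post-alignment computations that address these:
k-mer host/graft read separation, a tumor-only somatic filter-and-rescue
engine, gene-level copy-number/LOH annotation against a ploidy baseline,
an EBV-lymphoma expression classifier, and benchmarking statistics — plus
seeded generators that emulate every input, so the whole pipeline is
exercisable and testable without any external data.

# Read preprocessing and host separation

`preprocessReads()` applies, per read: discard when at least 70% of bases
are below Q30 (computed on the untrimmed read, inclusive at the
boundary); otherwise trim the maximal *trailing* run of sub-Q30 bases
from the 3' end (internal low-quality bases are left alone — the most
literal reading of 3'-end trimming); discard when fewer than 70% of the
original bases remain; discard the pair when either mate is discarded.
`sampleReadGate()` drops a sample when under half its reads survive
(exactly half passes).

`buildKmerIndex()` partitions the canonical k-mers (lexicographic minimum
of a k-mer and its reverse complement, so classification is
strand-agnostic) of the graft and host references into graft-only,
host-only and shared sets; `k = 25` follows the convention of the Xenome
classifier whose behavior this emulates. `classifyRead()` counts a read's
k-mers in each partition (`g`, `h`, `s`) and applies: `g>0, h=0` → human;
`h>0, g=0` → mouse; only shared hits → both; hits on both sides →
ambiguous; nothing → neither (including reads shorter than k). This
five-way rule is a deliberate simplification of Xenome's marginal/
ambiguous semantics; the category names are preserved but bit-exact
replication is a non-goal. `filterReadPairs()` keeps only pairs with
*both* mates human — a pair with one mate classified "both" is discarded.
`coverageGate()` removes samples with less than 75% of target bases at
≥100X human coverage.

# The somatic filter-and-rescue engine

Variants enter as per-sample tables (VCF 4.2 or TSV) with depth `DP`,
alternate allele fraction `ALT_AF` and GATK-style annotations. Filtering
proceeds quality → germline → recurrence → rescue
(`runSomaticPipeline()`), and each call ends in exactly one final status
with a full audit trace.

**Quality** (`applyQualityFilters()`): hard filters for SNVs
(QD < 2.0, FS > 60.0, MQ < 40.0, MQRankSum < −12.5,
ReadPosRankSum < −8.0) and indels (QD < 2.0, FS > 200.0,
ReadPosRankSum < −20.0); then DP ≥ 140 and ALT_AF ≥ 5% (both
inclusive). Missing annotations never fail a call, matching GATK
filter-expression semantics at, e.g., homozygous sites.

**Germline** (`buildGermlineResource()`, `flagGermline()`): the resource
is the union of dbSNP/1000 Genomes/ExAC (MAF ≥ 1%) entries and a
compendium of variants from 20 normal blood samples, admitted when seen
in ≥2 normals, or in ≥1 normal and ≥2 PDX cohort samples. Those counts
are the published absolute thresholds for a 20-normal compendium;
proportional scaling to other compendium sizes is opt-in. A call is
flagged germline only when it matches the resource at allele resolution
*and* its allele fraction lies in 40–60% (closed window) or strictly
above 90% — outside those windows a known polymorphism may still be a
somatic event sitting on a copy-number-unbalanced region.

**Recurrence** (`computeRecurrence()`, `flagRecurrentFp()`): positions —
not alleles, since systematic errors recur at mutated base positions —
carrying non-germline variants in ≥25% of cohort samples are putative
false positives (somatic recurrence tops out around 6% in large tumor
compendia). Recurrence is computed after quality filtering and before
rescue. One design addition: with fewer than `ceiling(1/0.25) = 4`
samples, every singleton variant would exceed the threshold, so the
filter is skipped for cohorts smaller than `fpMinCohort` (default 4,
configurable).

**Rescue** (`ClinicalKB`): GATK calls filtered as germline or recurrent
are reinstated when curated as clinically relevant (gain/loss of
function, treatment approach, or drug sensitivity/resistance) — many
actionable mutations (BRAF V600E, KRAS G12C) are in dbSNP at germline-
compatible frequencies. Pindel calls are kept *only* with a
knowledgebase hit, since unfiltered Pindel output is false-positive-rich;
unmatched Pindel calls are assigned `filtered_fp` (or
`filtered_germline` when germline-flagged). Quality-failed calls are
never rescued by default; the published description ("rescued any
filtered variants") is ambiguous on this point, so a
`rescueQualityFailed` flag exposes the permissive reading.

# Copy-number and LOH annotation

Allele-specific segments (chrom, start, end, nMajor, nMinor; 1-based
inclusive, fractional values accepted unrounded) plus a per-sample ploidy
are the inputs; segmentation itself (ASCAT-style) is out of scope. A
segment is LOH when nMajor ≥ 0.5 and nMinor ≤ 0.1 (`callLoh()`). Gene
annotation (`geneCopyNumber()`) intersects gene models with segments via
`GenomicRanges`; when a boundary falls inside a gene the most
conservative (lowest) total copy number represents the whole gene, the
overlapping-segment count is recorded, and a gene is LOH when *any*
overlapping segment is LOH (the per-segment definition does not dictate a
gene-level rule; any-segment is the conservative choice). Genes
overlapping no segment get missing copy number.

Gain/loss calls (`callGainLoss()`) use `r = log2(CN / baseline)` with the
published thresholds: ±0.4 for low-level gain/loss and ±1 for high-level
states; the `normal` band includes exactly ±0.4 and the high states are
strictly beyond ±1. CN = 0 maps to `high_loss` without evaluating
log2(0). The recommended baseline is the sample's mean cancer-genome
ploidy — against a diploid baseline aneuploid tumors misclassify wholesale
(a triploid genome at CN 3 is "normal" vs ploidy but "gain" vs diploid) —
and ploidy-relative calls are invariant to a common rescaling of all
copy numbers and the ploidy, which makes them robust to inconsistent
absolute scaling across samples of one model.

`cnExpressionConcordance()` classifies samples per gene into high-level
states (|log2(CN/ploidy)| > 1), references expression to the mean
log2(TPM+1) of samples in the *stringent* normal state (within ±0.4), and
compares gain- or loss-state fold changes with normal-state fold changes
by a two-sided pooled-variance Student's t-test; a state with fewer than
two samples is untestable (NA). Two degenerate branches are fixed
deliberately: identical constant groups give t = 0, p = 1; distinct
constant groups give |t| = ∞, p = 0.

# EBV-lymphoma classification

Expression analysis requires ≥1 million human reads per sample
(`humanReadGate()`, inclusive). Counts are upper-quartile normalized
(`upperQuantileNormalize()`): each sample is divided by the 75th
percentile of its *non-zero* counts (linear interpolation between order
statistics) and scaled to 1000, so the per-sample 75th percentile of
non-zero normalized values is exactly 1000. Per-gene z-scores
(`zscoreByGene()`) use the sample standard deviation (n−1); constant
genes get z = 0.

`deriveSignature()` ranks genes by the difference of group mean z-scores
between EBV-associated lymphomas and the rest — "fold change based on the
z-score transformation" is ill-defined for signed values, and the group
mean-z difference is the monotone statistic that matches the intent —
after removing genes whose mean normalized count is at or below 1 (the
published work does not state its expressed-gene floor; mean normalized
count > 1 is the package's choice). The top 24 and bottom 24 genes form
the signature. `scoreSamples()` computes the raw *sum* (not mean) of
sign-corrected z-scores, exactly as published, and calls a sample a
putative EBV lymphoma when the score strictly exceeds 3.0. The threshold
looks low against a 48-term sum — on well-separated synthetic cohorts EBV
scores land near 50–100 — but it is preserved verbatim and configurable,
and a sum-vs-mean alternative is a one-line change at the call site.

# Benchmarking and cohort statistics

`benchmarkCalls()` computes confusion counts at (chrom, pos, alt)
resolution over an explicit universe of assessable loci — the published
description leaves the true-negative universe implicit, so it is an
explicit argument here — with precision, recall,
F1 = 2·(Recall·Precision)/(Recall+Precision), and the Pearson correlation
of predicted vs true allele fractions over true positives.
`mutationalLoad()` counts non-silent coding passing calls in panel genes.
Overlap significance uses the one-sided (enrichment) Fisher exact test
over a 2×2 table on the gene universe, and the hypergeometric upper tail
for gene-set overlaps; both are verified against direct enumeration in
the tests. `expressionFrequencies()` uses strict z > +1 / z < −1.
`topVaryingGenes()` ranks by variance across samples with lexicographic
tie-breaks; note that a matrix z-normalized per gene over the same
samples has unit variance everywhere, so the ranking is meant for
log2-scale expression or z-scores standardized on a wider sample set.

# What the generators emulate — and what they do not

The generators define the package's study conditions:

* `simulateReferencePair()` — i.i.d. substitutions at 15% divergence, the
  average mouse/human coding-sequence divergence.
* `simulateReadSet()` — 150 bp paired-end reads; host pairs at 10/15/25%
  of total coverage; coverage grid 500/1000/1500; per-base substitution
  errors (default 0.001) and a configurable fraction of low-quality 3'
  tails so the trimming rules are exercised.
* `simulateVariantCohort()` — cohort-level germline loci (allele
  fractions 0.5/1.0 for heterozygous/homozygous states, present in the
  generated germline resource; the published spike-in grid is not
  stated, so the canonical het/hom pair is used), private somatic loci
  with allele fractions uniform in [0.05, 1], and artifact loci planted
  in at least `fpRecurrence` (default 30%) of samples at mid-range allele
  fraction and absent from the resource. Observed allele fractions are
  binomial at Poisson-distributed depth; quality annotations come from a
  "clean" regime inside the hard-filter pass region or a "failing" regime
  with one annotation pushed outside it — the published work gives only
  the thresholds, so uniform draws inside/outside the pass region are
  used.
* `simulateExpressionCohort()` — negative-binomial counts (size 10), a
  planted 24-up/24-down signature shifted by ±2 on the log2 scale in 20
  EBV vs 100 non-EBV samples.
* `simulateCnProfiles()` — integer allele-specific segments tiling each
  chromosome; ploidy is the length-weighted mean total copy number by
  construction; optionally expression coupled as baseline +
  log2(CN/ploidy) + Gaussian noise.

Each generator draws from a private RNG stream seeded as
`seed + fixed offset`, and restores the caller's RNG state, so equal
seeds give bit-identical outputs and adding one generator call never
perturbs another.

Deliberately **not** emulated: indel and quality-by-cycle error models,
PCR duplicates, structural variants, subclonal phylogenies, tumor-purity
effects on allele fractions, and real database content (dbSNP/ExAC/
knowledgebase files are format-compatible stand-ins). Passing tests
therefore demonstrate the correctness of the filtering logic and its
statistical behavior under idealized noise — not performance on real
xenograft libraries, where alignment artifacts, mappability and purity
all bite.

# Problem sizes and numerical choices

The test suite and the acceptance script run at desk scale, chosen so the
statistical assertions have comfortable margins: allele-fraction recovery
uses one sample with ~200 somatic spikes at depth ~500 over three seeds
(binomial sampling at that depth bounds the AF standard error at ~0.022,
so the true-AF spread of ~0.27 yields Pearson r ≈ 0.998); the classifier
check uses the published 20-vs-100 cohort with 2000 genes; k-mer oracle
equivalence uses k ≤ 8 on references ≤ 2 kb; read-level simulations use
2 kb references at 20–125X. Boundary conventions are tested on exactly
representable ratios to avoid asserting on floating-point artifacts of
irrational thresholds.

# Known limitations

* The k-mer classifier holds k-mer sets as plain character vectors —
  fine for targeted panels and test scale, not for whole genomes;
  succinct k-mer structures are a non-goal.
* The recurrence filter needs a cohort; single-sample studies get no
  false-positive filtering (by design, see `fpMinCohort`).
* `effect` annotations (silent/non-silent) are consumed, not computed; a
  consequence predictor is out of scope.
* The pipeline reports what it was given: it does not recalibrate allele
  fractions for tumor purity or copy number.
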