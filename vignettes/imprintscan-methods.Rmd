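---
title: "Detecting mono- versus bi-allelic expression at imprinted loci: methods and design"
author: "imprintscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting mono- versus bi-allelic expression at imprinted loci}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imprintscan)
```

## The model

An imprinted gene carries parent-of-origin epigenetic marks that silence one
parental allele, so its mature transcripts derive (almost) entirely from the
other.  In bulk RNA-seq this is visible wherever the individual is
heterozygous inside the transcript: reads over such a site carry the variant
allele at a fraction (VAF) near 0 or 1, whereas a gene transcribed from both
alleles yields VAFs concentrated around 0.5.  `imprintscan` turns this into
a per-gene, per-sample statistic and a class-level test:

1. **Pileup and calling.**  Aligned reads are summarised as samtools-mpileup
   text.  At each site, bases with Phred quality below `min_avg_qual`
   (default 20) are masked; the candidate variant is the most frequent
   remaining non-reference base (ties broken to the alphabetically smallest,
   so at most one call per site feeds the statistic); a SNP is called when
   it is supported by at least `min_reads2 = 10` reads at a VAF of at least
   `min_var_freq = 0.01`.  Calls at sites with 25 or fewer quality-passing
   reads are flagged and removed (`min_site_reads = 26`, a strict
   "more than 25" rule).  These four thresholds are the whole caller; other
   thresholds of general-purpose callers (coverage floors, p-value models,
   strand-bias filters) are deliberately not reproduced, and indel tokens in
   the pileup are skipped because only SNPs are informative here.
2. **Transcript filter cascade.**  Calls are assigned to every panel gene
   whose exons contain them (intronic calls drop; genes sharing exonic
   positions each receive the call).  A transcript keeps its calls only if
   it carries at least `min_confident_snps = 3` of them — isolated calls
   are more likely PCR/sequencing artefacts than genuine heterozygosity.
   Confident SNPs with VAF in the inclusive 20–80% window are *bi-allelic
   SNPs*.
3. **The statistic.**  `snp_freq_per_kb` = bi-allelic SNP count divided by
   the representative transcript's exonic length in kb.  Genes with fewer
   than `min_transcript_reads = 15000` reads in a sample are excluded from
   modelling, so both gene classes face the same power floor.
4. **Inference.**  Per tissue, `snp_freq_per_kb ~ imprinted * group + sex`
   is fitted on included gene × sample rows; per-term F tests use Type II
   sums of squares; Tukey HSD over the six (group × imprinting status)
   cells provides the family-wise-corrected within-group contrasts that the
   jittered box plot displays.

The biological read-out is the interaction pattern: with imprinting intact
the imprinted class sits near zero in every group and the within-group
contrast is significant everywhere; loss of imprinting in specific groups
lifts the imprinted class towards its neighbours and erases the contrast in
exactly those groups.

## The analysis panel

Imprinted anchor genes are taken from a user-supplied list; each anchor
defines a locus window spanning its transcript ±2 Mb, windows overlapping
on one chromosome are merged into a single locus (several imprinted genes
can share a locus), and the panel is the imprinted genes plus every gene
whose transcript span intersects a window.  Comparing imprinted genes with
their *cis* neighbours, rather than with all genes, controls for regional
effects on SNP density and expression.

One transcript represents each gene: the longest by exonic length, ties
broken by smallest transcript id.  Annotation sources rarely say which
isoform a published transcript-length total refers to; the longest-isoform
rule is the common default and is deterministic under input reordering,
which the tests require.  Coordinates are 1-based closed throughout; BED12
input is converted on read.

## What the simulator emulates

`sim_config()` describes a cohort of 9 pigs — 3 control, 3 autologous and
3 heterologous mtDNA-supplemented, sexes alternating so both are
represented — with one sample per pig and tissue.  Defaults are the
conditions the package is designed around:

| parameter | default | meaning |
|---|---|---|
| `n_loci`, `n_neighbours_per_locus` | 8, 10 | panel geometry (88 genes) |
| `transcript_length_bp` | 2000 | exonic length of every simulated gene |
| `het_snp_density_per_kb` | 2 | Poisson rate of heterozygous sites per pig |
| `mean_coverage`, `depth_dispersion` | 200, 0.1 | negative-binomial site depth (Poisson at 0); mild overdispersion is typical of RNA-seq coverage |
| `base_error_rate` | 0.002 | per-read substitution error, uniform over the three other bases |
| `base_quality_mean`, `low_qual_read_fraction`, `low_qual_value` | 35, 0, 10 | read qualities; a configurable fraction of deliberately low-quality reads exercises the caller's mask (quality is independent of error status) |
| `leakage_by_group` | 0 / 0.35 / 0.35 | fraction *L* of an imprinted gene's reads from the silenced allele |

Heterozygous sites are properties of the pig (shared across a pig's
samples, independent across pigs), placed by a Poisson process over exonic
positions; which haplotype carries the alt allele is Bernoulli(0.5) per
site, fixed within the pig, as inherited variants are phased within an
individual.  At a het site the expected alt fraction is 0.5 (bi-allelic
gene) or *L* / 1 − *L* (imprinted gene, silenced/expressed haplotype).
*L* = 0 is strict imprinting; *L* = 0.5 makes imprinted genes
distributionally indistinguishable from bi-allelic ones — the degenerate
limit used as the null in the calibration tests.  All exonic positions are
emitted (homozygous ones as reference plus errors) since the analysis works
in transcript space; nothing intronic or intergenic is simulated.

The simulator works at count level: per-site depth, allele counts, error
counts and quality strata are drawn directly, which makes a full cohort a
few vectorised draws per site and keeps replicate studies cheap.  Written
output is standard 6-column mpileup text plus read-total, truth, metadata
and panel TSVs; identical configurations (including the seed) give
byte-identical files (the run manifest, which carries a timestamp, is the
one exception in a pipeline run).

**What passing tests do and do not show.**  The generator reproduces the
statistical skeleton the method assumes — cohort design, panel geometry,
heterozygosity rates, allele-specific counts, sequencing error, coverage
variation.  It does not emulate alignment artefacts, reference bias at
variant sites, allele-specific mapping loss, splice isoform switching,
indels, position-correlated error, or population LD structure.  Tests
passing here validate the machinery (parsing, thresholds, cascade,
inference) under the intended generative model, not robustness of the
statistic to every artefact of real sequencing.

## Numerical and design choices

* **"More than three SNPs" versus "fewer than three discarded".**  The
  operational rule is *keep if count ≥ 3* (a transcript with exactly three
  calls is kept); the discard clause is the sharper statement of intent and
  the boundary is exposed as `min_confident_snps`.
* **20–80% window inclusivity.**  "Between 20–80%" is read inclusively —
  the weaker filter — and `vaf_bounds_inclusive = FALSE` is available.
* **Cascade order.**  The ≥3-call rule is applied to *all* calls of a
  transcript before the VAF window, so a gene with three mono-allelic-like
  calls is "confident" but still scores zero bi-allelic SNPs.
* **Depth for VAF** is quality-passing depth, not raw depth, so the
  fraction is consistent with the counts that produced the call; the >25
  site filter is likewise evaluated on quality-passing reads.
* **Read-total threshold for all panel genes.**  The 15,000-read inclusion
  rule is applied to neighbours as well as imprinted genes: comparing the
  two classes fairly requires a common inclusion rule.
* **ANOVA specification.**  The interaction term is included by default
  because the scientific display is the *within-group* contrast, which a
  main-effects model cannot express; Type II sums of squares keep main
  effects interpretable under the mild imbalance that gene exclusions
  introduce.  Both choices are knobs (`include_interaction`,
  `sex_covariate`).  Genes are treated as exchangeable replicates within
  class; a gene-level random effect is left out deliberately — with a
  handful of imprinted genes per locus the class-level fixed-effect model
  is the more honest claim.
* **Degenerate inputs.**  A constant response yields F = 0, p = 1 for every
  term and unit Tukey p-values (a flat response is evidence for nothing),
  single-level factors are an error naming the factor, and an empty
  included set is an error rather than an empty table.
* **Tie-breaks.**  Everywhere a tie is possible (candidate alt base,
  representative transcript, site ordering) the rule is lexicographic /
  positional and therefore deterministic under reordering.

## Problem sizes used in the validation suite

The acceptance-style tests run the full pipeline at the design conditions:
the recovery and power checks use the 88-gene panel at 200× coverage (the
filter cascade annihilates strictly imprinted het sites, leaving the
neighbour mean within ±0.4 of the simulated 2/kb density after the ≥3-SNP
rule's truncation, analytically ≈ 1.82); the null-calibration study uses
200 replicates of a 24-gene, 1 kb, 60× cohort with *L* = 0.5 everywhere;
the loss-of-imprinting pattern check uses 100 replicates with *L* = 0 in
controls and 0.35 in supplemented groups.  These sizes were chosen once as
a realistic desk-scale study design.

## Known limitations

* The caller is a faithful implementation of four thresholds, not a
  reimplementation of a general variant caller; sites with more than one
  genuine non-reference allele yield at most one call.
* Reference bases in simulation are drawn uniformly; real transcript
  composition and CpG structure are not modelled.
* The pipeline analyses each tissue independently and does not model
  pig-level correlation across tissues.
* No parent-of-origin assignment is attempted: the method detects loss of
  *mono-allelic* expression at class level, not which allele is silenced,
  and makes no per-gene imprinting call for an individual pig.
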