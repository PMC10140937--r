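# imprintscan

Detection of mono- versus bi-allelic expression at imprinted loci from bulk
RNA-seq read pileups.

## The problem

Genomic imprinting silences one parental copy of a gene, so an imprinted
gene is transcribed from (almost) only one allele.  At a heterozygous coding
site this leaves a tell-tale signature in RNA-seq reads: the variant allele
fraction (VAF) sits near 0 or 1 for a mono-allelically expressed gene, but
near 0.5 for a gene transcribed from both alleles.  Loss of imprinting — as
suspected, for instance, in pigs derived from oocytes that received
supplementary mitochondrial DNA — shifts imprinted genes towards the
bi-allelic signature.

`imprintscan` quantifies this with a per-gene, per-sample statistic:

> **SNP frequency (per kb)** = number of *bi-allelic* SNPs called in a
> gene's representative transcript, divided by transcript length in kb,

where a SNP is *bi-allelic* when its VAF lies in the 20–80% window, calls
come from samtools-mpileup pileups under VarScan-style thresholds
(`--min-avg-qual 20 --min-var-freq 0.01 --min-reads2 10`, plus a >25
quality-passing-reads site filter), transcripts with fewer than three called
SNPs are discarded as likely PCR/sequencing artefacts, and only genes with
≥ 15,000 reads enter the analysis.  Low values indicate mono-allelic
expression; imprinted genes drifting up to the level of their non-imprinted
neighbours (all genes within ±2 Mb of each imprinted locus) indicate loss of
imprinting.  Class- and group-level differences are tested by ANOVA
(`snp_freq_per_kb ~ imprinted * group + sex`, Type II tests) with Tukey HSD
contrasts over the six (group × imprinting status) cells.

Because real cohorts of this kind are not reproducible at desk scale, the
package ships a seeded allele-specific pileup simulator that emulates the
cohort structure (3 groups × 3 pigs, mixed sex), the locus panel, and the
generative signal — including a *leakage* parameter `L` (fraction of an
imprinted gene's transcripts from the silenced allele, 0 = strict
imprinting, 0.5 = fully bi-allelic) — so every stage of the analysis can be
exercised and validated end to end.

## Worked example

Simulate a cohort with strict imprinting in controls and leakage
`L = 0.35` in both mtDNA-supplemented groups (the default configuration),
call SNPs, score genes, and test:

```r
library(imprintscan)

cfg    <- sim_config(seed = 7, n_loci = 4, n_neighbours_per_locus = 6,
                     transcript_length_bp = 2000, mean_coverage = 120)
cohort <- simulate_cohort(cfg)
calls  <- lapply(cohort$pileups, call_sample)
summ   <- summarize_cohort(calls, cohort$panel, cohort$read_totals,
                           analysis_params())
fit    <- imprinting_anova(summ, cohort$metadata)
fit
```

```
Imprinting ANOVA -- tissue 'brain' (252 gene x sample rows)
         term    sum_sq df          F        p
       status  5.063657  1  3.5635547   0.0602
        group  6.771776  2  2.3828225   0.0944
          sex  1.341270  1  0.9439202   0.3322
 status:group 36.588624  2 12.8746431 4.82e-06

Within-group imprinted vs non-imprinted (Tukey HSD):
        group       diff        p_adj
      control -1.8541667 1.697807e-05
   autologous  0.7708333 3.044621e-01
 heterologous -0.1319444 9.992535e-01
```

Read-out: in controls, imprinted genes have a SNP frequency near 0 while
their neighbours sit near the simulated heterozygous-SNP density
(~2 SNPs/kb), a strongly significant within-group contrast.  In both
supplemented groups the imprinted genes have shifted into the bi-allelic
range and the contrast vanishes — the loss-of-imprinting pattern, carried
by the significant `status:group` interaction.

The same run is available as a config-driven pipeline with per-stage logs,
VCF/TSV outputs, a jittered box plot, and a manifest:

```r
run_full(list(seed = 7, out_dir = "out",
              simulate = list(n_loci = 4, n_neighbours_per_locus = 6,
                              transcript_length_bp = 2000,
                              mean_coverage = 120)))
```

or from the shell via `inst/cli/imprintscan.R
(simulate | call | score | test | run-all | make-fixtures)`.

Real data enter through the same surface: `load_gene_models()` (GFF3,
BED12, or TSV) + `build_panel()` for the annotation, per-sample mpileup
files for `call_sample()`, and TSVs for read totals and sample metadata.

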