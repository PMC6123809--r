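# utrscan

Somatic mutation analysis of untranslated regions (UTRs) in circulating
tumor DNA.

Most cancer gene panels and exome protocols stop at the coding sequence,
so localized mutational processes in UTRs go unseen. In metastatic
prostate cancer, targeted liquid-biopsy sequencing of driver-gene UTRs
revealed one striking exception to the otherwise low non-coding mutation
rate: an indel-dominant hypermutation process spanning an entire 3′-UTR,
detectable in roughly one patient in eight. `utrscan` reimplements the
computational machinery behind that kind of discovery as a tested,
reusable R package for anyone analyzing paired cfDNA/WBC targeted
sequencing: variant callers working at ~750× depth against a cohort
background-error model, split-read detection of large indels, region-aware
mutation-rate statistics, and clonality analyses — together with a fully
synthetic cohort generator, so every stage is testable without access to
controlled patient data.

## The core methods

**Five-condition somatic caller.** A non-reference allele in a cfDNA
pileup is called somatic iff all of:

1. allele fraction ≥ 1%,
2. ≥ 10 supporting reads,
3. AF ≥ 25 × the background error rate — the average allele fraction of
   that allele across all white-blood-cell (WBC) samples in the cohort,
   estimated with a +1/+1 pseudocount so unseen alleles never pass on a
   zero background,
4. AF ≥ 3 × the allele fraction in the patient's paired WBC sample
   (which blocks germline heterozygous SNPs at AF ≈ 0.5),
5. paired WBC depth ≥ 20 at the site.

**Split-read large-indel caller.** Unaligned reads are split into two
30 bp anchors, placed by unique exact match, and discordant anchor pairs
are refined to a junction and clustered by breakpoint signature.
Deletions and insertions of 1–500 bp supported by ≥ 3 unique cfDNA
fragments (deduplicated by read start) are called, with insertion
sequence reconstructed from the reads or from tandem-duplication
geometry.

**Region statistics.** UTRs are derived from the predominantly expressed
transcript, and a UTR call is vetoed by *any* annotated CDS of the gene.
The regional mutation rate is

```
rate = mutations / megabases with depth > 200× / ctDNA-positive samples (ctDNA > 2%)
```

**Clonality.** ctDNA-corrected allele fraction `AF / ctDNA-fraction`
maps a clonal heterozygous mutation to ≈ 0.5; longitudinal trajectories
classify mutations as persistent, late-rising, or lost, scoring absence
only at 0 supporting reads with ≥ 200× depth.

Exact statistics (two-sided Fisher by hypergeometric enumeration in log
space, conditional binomial rate comparison, Wilcoxon rank-sum), indel
sequence-context profiling (GC windows, 4-mer neighborhoods,
tandem-repeat mechanism classification, conservation contrast) and an
RPKM / AR-activity expression layer complete the pipeline.

## Worked example

Simulate a 40-patient cfDNA cohort on a 6-gene panel (gene 1 carries the
planted 3′-UTR hypermutation process at 12% patient prevalence, 81%
indels) and run the full pipeline:

```r
library(utrscan)
cfg <- sim_config(seed = 42, n_genes = 6, n_patients = 40,
                  ctdna_fractions = rep(c(0.15, 0.3, 0.45, 0.6), 10))
rp <- run_pipeline(cfg)
subset(rp$summary, region == "UTR3")
#>      gene region n_mutations n_indels n_substitutions covered_mb n_samples rate  n_patients patient_pct
#> 3  GENE01   UTR3           5        4               1    0.00181        40 68.9           5        12.5
#> 6  GENE02   UTR3           0        0               0    0.00152        40  0.0           0         0.0
#> 9  GENE03   UTR3           0        0               0    0.00080        40  0.0           0         0.0
#> ...
```

The hypermutated gene is recovered at rank 1 by 3′-UTR mutation rate
(68.9 mutations/Mb/sample vs 0 elsewhere), in 12.5% of patients — the
planted prevalence — and its mutations are indel-dominant:

```r
rp$indel_fraction$hypermut_contrast$table
#>        indel substitution
#> GENE01     4            1
#> other      0            0
```

The exact tests reproduce published cohort-level contrasts; for example
the indel-enrichment comparison of 30/37 vs 19/141 indels:

```r
signif(fisher_exact(matrix(c(30, 7, 19, 122), 2, byrow = TRUE),
                    method = "central"), 2)
#> [1] 1.6e-14
```

Every call in `rp$table` carries its five filter quantities, region
class, consequence, and ctDNA-corrected allele fraction; `write_vcf()`
emits VCF 4.2 with the filter provenance in INFO.

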