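---
title: "Detecting UTR hypermutation in cell-free DNA: models and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting UTR hypermutation in cell-free DNA: models and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(utrscan)
```

`utrscan` analyzes targeted liquid-biopsy sequencing of cancer driver
genes for somatic mutations in untranslated regions. This vignette is
the package's own account of the models it implements, the parameters
that matter, the places where the design was genuinely open and what we
chose, and what the synthetic-cohort tests do and do not demonstrate.

## The measurement problem

Plasma cell-free DNA (cfDNA) from a cancer patient is a mixture: a
tumor-derived fraction (ctDNA, often 2–60% in metastatic disease) on a
background of normal DNA. A somatic mutation that is heterozygous and
clonal in the tumor therefore appears at allele fraction

$$\mathrm{AF} \approx \frac{\mathrm{ctDNA} \times \mathrm{clonality}}{2},$$

which at 10% ctDNA is 5% — close enough to sequencing error that naive
thresholding fails. Two controls make calling feasible: the patient's
white-blood-cell (WBC) DNA, which carries the germline but not the
tumor genotype, and the *cohort* of all WBC samples, which measures the
position- and allele-specific background error of the assay itself.

## The five-condition caller

A candidate allele in a cfDNA pileup is somatic iff

1. AF ≥ 1%;
2. supporting reads ≥ 10;
3. AF ≥ 25 × background error rate, the mean allele fraction across all
   WBC samples;
4. AF ≥ 3 × the paired WBC allele fraction;
5. paired WBC depth ≥ 20.

Conditions 1–2 set a detection floor, 3 removes recurrent assay
artifacts, 4 removes the patient's own germline (a heterozygous SNP has
cfDNA AF ≈ 0.5 and WBC AF ≈ 0.5, failing 3×), and 5 ensures condition 4
is actually informative.

Two numerical choices were open and are resolved as follows:

* **Zero background.** The background rate of an allele never seen in
  any WBC sample would be 0, and any AF trivially exceeds 25 × 0. We
  estimate the background from pooled cohort counts with a +1/+1
  pseudocount, `(alt + 1) / (depth + 1)`, which is bounded, monotone in
  the data, and at a pooled WBC depth of ~15,000× (20 samples at 751×)
  sets an effective floor of 25/15001 ≈ 0.17% — below the 1% AF floor,
  so it only bites for poorly covered cohorts, which is the intent.
* **Paired-WBC zero.** No pseudocount is applied to the paired sample:
  with WBC AF = 0 the 3× condition is vacuous by design, because the
  cohort background rule is the noise guard.

Indel alleles are left-aligned and reduced to the parsimonious VCF-style
representation before counting, so that the several CIGAR placements a
deletion can take inside a microsatellite collapse to one allele.
Multi-allelic sites are evaluated per allele; strand is ignored (no
strand-bias filter is part of the model).

## The split-read large-indel caller

Pileup columns cannot represent indels much longer than a read's
alignment tolerates, so large events (the package routes ≥ 30 bp by
default) are recovered from *unaligned* reads: each read is split into
two 30 bp terminal anchors; anchors are placed on the reference by
unique exact match (zero or multiple hits are dropped with counters);
and for each same-strand discordant pair the implied event size is
`delta = reference gap − read gap` (positive: deletion; negative:
insertion). The junction is refined by maximal forward extension of the
5′ anchor, pairs are clustered by breakpoint signature within a
position tolerance (default 5 bp — the clustering granularity was an
open choice), fragments are deduplicated on read start positions, and
events with ≥ 3 unique fragments and length 1–500 bp are emitted.
Events longer than 500 bp are excluded to keep the focus on localized
mutational processes; manual inspection of the original workflow is
replaced by a machine-readable evidence table per event.

One geometric subtlety deserves note. A tandem-duplication insertion
left-aligned through its own repeat context has its inserted copy
*matching the reference in place*; the discordant junction then sits at
the 3′ end of the duplicated unit, and junction placement within a
repeat is cyclically ambiguous. The caller therefore guarantees
recovery of the planted *haplotype* (and event length ±tolerance), not
a unique (position, sequence) representation; tests compare haplotypes.
Insertion sequence is reconstructed by majority vote over members that
fully contain it, falling back to the reference segment implied by
tandem-duplication geometry for insertions longer than the reads can
span. Exact-match anchor placement is a deliberate simplification that
is sufficient on panel-scale references; genome-scale use would swap in
a spaced-seed or BWT aligner behind the same interface.

## Regions, UTRs and the mutation-rate statistic

UTRs are computed from the predominantly expressed transcript (chosen
by expression when provided, else the annotated default): exonic
sequence outside the CDS, 5′/3′ by strand. Classification applies the
priority CDS > UTR > intron > intergenic, and — critically — a UTR call
is vetoed if the position overlaps *any* annotated CDS of the gene in
any transcript, so alternative coding isoforms are never misattributed
to a UTR process. The minimal consequence classifier translates CDS
SNVs through the standard genetic code and labels CDS indels frameshift
iff length mod 3 ≠ 0; UTR indels are `utr` by construction (they cannot
shift a reading frame).

The regional mutation rate is
`mutations / covered Mb / eligible samples`, where covered Mb counts
positions with depth strictly above 200× and eligible samples have
ctDNA fraction strictly above 2%. The depth track used for the
denominator is the pooled (mean) per-position depth across eligible
samples; computing it per sample instead would change the denominator
only where coverage hovers near the floor. Mutations are deduplicated
to one per (patient, allele) before counting, matching patient-level
reporting; a region with no covered positions reports an undefined
rate, never 0 or infinity.

## Statistics

**Fisher's exact test** is enumerated in log space from the
hypergeometric mass. Exact 2×2 tests admit more than one two-sided
definition, and published values may follow either, so both standard
conventions are provided: `minlike` (default; the sum of all tables
with probability ≤ the observed, as in `stats::fisher.test`) and
`central` (twice the smaller one-sided tail, capped at 1). On sharp
contrasts the two differ by up to a factor of two; the package reports
which convention a number came from rather than pretending the choice
away. **The binomial rate comparison** conditions on the total count
`n`: under equal rates, the first count is Binomial(n, e1/(e1+e2)) with
exposure weights e, and the two-sided p sums outcome probabilities not
exceeding the observed one. Both match independent enumeration oracles
exactly in the test suite. **The rank-sum test** uses midranks, exact
enumeration for small tie-free samples and the continuity-corrected
normal approximation otherwise.

**Corrected allele fractions** divide AF by the ctDNA fraction, mapping
a clonal heterozygous mutation to 0.5 and making loss-of-heterozygosity
visible as values above 0.5; this convention (rather than dividing by
ctDNA/2) was chosen because cohort medians for positively selected
coding mutations sit near 0.5–0.55 under it, consistent with
clonal-plus-LOH interpretation. The alternative is available via
`convention = "diploid"`. Samples at or below 2% ctDNA are suppressed.
For split-read calls the AF is estimated as unique junction fragments
over the expected number of junction-spanning read slots at the local
depth; because fragments are deduplicated by start position, this
estimator saturates once every slot is occupied (~0.2 at 150 bp reads
and 30 bp anchors), so clonality summaries are computed from
pileup-channel calls.

**Clone tracking** classifies each (patient, mutation) across
ctDNA-positive (> 5%) timepoints as persistent, late-rising, or lost.
Absence is only scored at 0 supporting reads with ≥ 200× depth;
anything between 1 and 9 reads, or lower depth, is indeterminate and
never forced into a loss or gain narrative.

## Sequence context

GC content uses 20 bp sliding windows (ambiguous bases excluded from
numerator and denominator); breakpoint profiles average the GC
indicator at each signed distance from the left breakpoint of the
normalized indel (the anchor choice for multi-base events was open and
is documented here); 4-mer composition contrasts pooled ±20 bp
neighborhoods against the whole region, counted on the reference strand
only. Mechanism classification calls a deletion a *repeat-unit
deletion* iff the deleted bases equal the adjacent same-length segment
on either side, and an insertion a *tandem duplication* iff the
inserted bases equal the adjacent reference segment (either side, so
the call is invariant under left-alignment, which moves the matching
copy from 5′ to 3′ of the insertion point). The conservation contrast
reports the neighborhood mean against the whole-region mean but runs
the rank-sum test against the *disjoint* background, so null p-values
are exactly uniform — a property the test suite verifies at 500
replicates.

## The synthetic cohort: what it emulates, and what it does not

The generator reproduces the statistical structure the analysis
assumes, with defaults fixed at the emulated study conditions:

* targeted panel of ~10 gene loci with annotated UTR5/CDS/UTR3
  structure (one minus-strand gene; one gene with an alternative
  transcript whose CDS invades the predominant 3′-UTR; embedded
  microsatellite motifs in the hypermutated UTR);
* per-position depth Poisson with mean 751×; per-base substitution
  error 0.001 i.i.d. in both channels (the platform's true error model
  is not published, so this is a conventional short-read figure, fixed
  once); a separate WBC-channel 1 bp indel-noise knob (2 × 10⁻⁴)
  exercises the background model's indel path;
* germline heterozygous SNPs at 10⁻³/bp in both channels of a patient,
  binomially sampled at AF 0.5;
* planted somatic events at AF = ctDNA × clonality / 2, in cfDNA only;
  the hypermutated gene receives events in a deterministically rounded
  12% of eligible patients, 81% indels, deletions 1–89 bp (log-normal
  around a median of 8), insertions 1–99 bp (median 18) planted as
  short-tandem duplications — so planted prevalence and indel fraction
  are exact by construction, and recovery error is attributable to the
  caller, not planting noise;
* events ≥ 30 bp are carried by unaligned junction-spanning reads with
  distinct start positions; smaller events and SNVs live in the pileup
  channel. Read-level simulation (150 bp fixed-length paired fragments,
  uniform starts) is available for the preprocessing and pileup
  builders at small scale; cohort-scale runs stream per-sample pileups
  from per-sample seeds, so any sample regenerates bit-identically and
  whole-cohort reruns are byte-identical.

Not emulated: fragment-length biology and fragmentomics, GC-coverage
bias, UMI error correction, mapping artifacts near repeats, strand
bias, contamination, and the true position-specific error spectrum of
any real instrument. Passing the suite therefore demonstrates that the
implementations are faithful to their definitions and recover planted
truth under the stated noise model — it does not certify performance on
real cfDNA, where background modeling carries the burden the simulator
deliberately makes tractable.

## Problem sizes and reproducibility

The test suite runs the full pipeline on a 290-patient, 10-gene cohort
(~31 kb of panel territory, 580 samples at 751× in silico) for the
prevalence-recovery check, a 500-site benchmark for caller sensitivity,
and 10,000-column randomized batteries for oracle equivalence; these
sizes give the prevalence estimate a binomial 95% interval of ±4
percentage points around the planted 12% and keep a complete run in the
low minutes on one core. All randomness flows from explicit seeds;
`scripts/acceptance.R --seed N` re-derives every reported number from
scratch.

## Known limitations

* Exact-match anchors cannot place reads whose anchors straddle a
  junction or carry errors inside the anchor; sensitivity for large
  insertions of non-duplicative sequence beyond read span is
  structurally limited (only tandem-consistent geometry is
  reconstructible there).
* The background model treats WBC samples as exchangeable; batch
  structure within a cohort is not modeled.
* The consequence classifier handles one predominant transcript per
  gene and flags splice-region variants without codon-level calls.
* `track_clones` assumes calls at different timepoints of a patient are
  already normalized to a shared allele representation (the pipeline
  guarantees this; external call sets must be normalized first).
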