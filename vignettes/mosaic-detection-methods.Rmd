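---
title: "Methods: detecting low-level somatic mosaicism from ultra-deep amplicon sequencing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting low-level somatic mosaicism from ultra-deep amplicon sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mosaicamp)
```

## Scientific setting

Somatic mosaicism — a pathogenic variant present in only a fraction of a
tissue's cells — produces variant allele frequencies (VAFs) far below the
50% expected for a constitutional heterozygous change. Port-wine-stain
vascular malformations are the motivating case: activating substitutions
in G-protein subunit genes (a *GNAQ* c.548G>A type change, and a *GNB2*
c.232A>G type change) are found in lesional skin at VAFs from a fraction
of a percent up to tens of percent, enriched in endothelial cells, and
absent from unaffected tissue from the same individual. Detecting a 0.2%
allele reliably requires sequencing a short targeted amplicon to depths
around 10^5 and separating true mutant reads from polymerase and
sequencing errors that occur at comparable rates.

`mosaicamp` implements that measurement chain end to end, plus two
companion analyses used in this setting: an exome-style
affected-versus-unaffected filtration cascade for discovering candidate
genes in the first place, and a protein-structure salt-bridge check for
interpreting candidate interface mutations. Because real ultra-deep data
cannot ship with a package, every stage is driven by a synthetic read
generator that records ground truth, so the full pipeline is verifiable
at desk scale.

## The measurement chain

### Read simulation

`simulate_amplicon_reads()` draws, for each sample, a configured number
of reads from an amplicon design. Each read is independently mutant with
probability equal to the sample's true VAF (a binomial model of template
sampling), and every base is independently substituted with probability
`error_rate`, choosing uniformly among the three alternative bases. A
sample barcode is prepended error-free. The exact RNG consumption order
is part of the function's contract (documented in its help page), so
tests can re-derive expected draws independently of the implementation.
Truth records report, per sample, the realized number of mutant templates
actually emitted — the denominator-level truth that recovery is measured
against.

### Demultiplexing

`demux_reads()` partitions reads by exact barcode prefix match (an `N`
never matches). Every read lands in exactly one bin, including
`UNASSIGNED`; assigned reads have the barcode stripped. An optional
`max_mismatch` mode assigns to the unique barcode at minimum Hamming
distance when that distance is within tolerance and unique.

### Alignment and cleaning

Amplicon reads need no gapped aligner: `align_reads()` performs an
exhaustive gapless scan of both strands over the short reference
(implemented in C++ for speed), keeping the placement with fewest
mismatches; ties are broken toward the smaller start and the forward
strand, and ambiguous placements receive a mapping-quality proxy of 0.
Reads whose best placement still exceeds `max_mismatch_frac` of their
length are rejected. `clean_alignments()` then removes duplicates,
improper records and low-mapping-quality records, tallying what was
removed.

### Pileup

`count_bases_at()` tallies A/C/G/T/N at one reference column from the
oriented aligned sequences; `pileup_all()` does so at every column. Depth
at a column is the sum of all base counts there — the same convention
used in published per-sample count tables.

## VAF estimation and the positivity rule

`compute_vaf()` reports mutant count over depth. Display percentages are
rounded half-up in exact integer arithmetic (`round_percent()`), which
reproduces published two-decimal tables digit for digit — floating-point
`round()` does not, because values like 0.125 have no exact binary
representation.

The error model is local: the two bases that are neither reference nor
expected mutant can only be errors, so their pooled count over twice the
depth (`estimate_error_rate()`) estimates the rate of any one specific
substitution at that locus. Under a uniform substitution model with total
per-base error $e$, this statistic targets $e/3$. The error-corrected VAF
inverts the mixing of true mutant fraction and error flow,
$\hat v = \max\!\left(0, \frac{v_{\mathrm{raw}} - \hat e}{1 - 4\hat e}\right)$.

`classify_mosaic()` calls a sample positive only if two independent
conditions hold:

1. **Error arm.** The observed mutant count is inconsistent with
   background error: the binomial upper tail
   $P(X \ge k \mid n, \max(\hat e, 10^{-4}))$ falls below
   $\alpha / n_{\text{loci}}$ (default $\alpha = 0.01$, Bonferroni over
   loci tested). The floor of $10^{-4}$ on the error rate guards against
   a lucky error-free off-target pair.
2. **Quantification floor arm.** The count is consistent with a true VAF
   of at least `min_vaf` (default 0.002): a true mosaic at the floor
   would produce a count this small with probability at least $\beta$
   (default $10^{-3}$).

The floor of 0.2% reflects the smallest mosaic fraction this assay
family reliably quantifies; samples in the ~0.1–0.15% range sit in a
gray zone where a nominally significant count cannot be distinguished
from slightly elevated local error, and the two-arm rule classifies them
negative. Expressed as a test rather than a hard threshold on the point
estimate, the rule remains correct under sampling noise: a true 0.2%
mosaic whose estimate fluctuates slightly below 0.002 is still called.

```{r}
# A 0.24% sample at depth ~114k is positive ...
classify_mosaic(c(A = 269, C = 3, G = 113714, T = 5), "G", "A")[
  c("vaf_percent_2dp", "classification")]
# ... a 0.15% sample at depth ~133k is not.
classify_mosaic(c(A = 133264, C = 1, G = 206, T = 15), "A", "G")[
  c("vaf_percent_2dp", "classification")]
```

## End-to-end recovery experiment

`run_recovery_experiment()` runs the whole chain once per seed and
compares, for every sample-by-seed cell, the pipeline's error-corrected
VAF with the realized mutant-template fraction from the generator's
truth records. `study_condition_samples()` fixes twelve conditions at
depth 20,000 spanning the ladder seen in this assay family: 0 (error
only), 0.1% and 0.2% (around the floor), 3% and 9% (bulk lesional
dermis), 21% and 30% (endothelial enrichment). Depth 20,000 is a
package-level choice balancing fidelity to the study regime against test
runtime; the binomial error band simply widens at lower depth.

Recovery is assessed against a 3-sigma binomial band at the nominal
VAF, $3\sqrt{v(1-v)/n}$, for cells with $v > 0$. At $v = 0$ that band is
degenerate (zero width) while error inflation is strictly positive, so
zero-VAF cells are instead required to classify negative — which is the
scientifically meaningful statement about them.

```{r, eval = FALSE}
cells <- run_recovery_experiment(example_designs()$GNB2_like,
                                 study_condition_samples(), seeds = 1:20)
aggregate(cbind(vaf_corrected, realized_fraction) ~ true_vaf, cells, mean)
```

## Exome-style candidate discovery

`call_candidate_sites()` applies the discovery-stage rule — any
non-reference base seen in at least 3 reads is a candidate variant.
`run_cascade()` then mirrors the affected-versus-unaffected design:
candidates in affected tissue must reach 15 supporting reads, have
population allele frequency below 1% (strict; missing frequency counts
as novel and passes), and conservation score above 5 (strict; missing
fails); any candidate whose site shows more than 5 supporting reads in
the matched unaffected sample is subtracted. `simulate_variant_table()`
plants a truth table through this cascade so its exactness is testable.

## Structure stage

For candidate mutations at protein–protein interfaces,
`parse_pdb_atoms()` reads fixed-column ATOM records,
`find_salt_bridges()` reports cation–anion side-chain atom pairs across
two chains within 4.0 Å (inclusive; Lys NZ, Arg NH1/NH2/NE, and His
ND1/NE2 flagged as conditional, against Asp OD1/OD2 and Glu OE1/OE2),
and `charge_reversal_report()` states how a point substitution changes
each contact — a K78E type change turns an attractive bridge repulsive.

## Orchestration

`run_pipeline()` chains the stages from a `run_config()`, writes
TSV/FASTQ/VCF artifacts with provenance headers (package version, seed,
MD5 of the analytic settings), and exposes the cascade and structure
stages as stand-alone entry points. `inst/scripts/mosaicamp.R` wraps it
for the command line.

## Limitations

The generator models substitution errors only (no indels, no quality
ramps, no strand bias), reflecting the gapless aligner's scope. The
error model assumes uniform substitution flow; systematic
context-specific errors would bias $\hat e$ low or high. The positivity
rule is per-locus and does not borrow strength across samples. The
filtration cascade operates on simulated site tables, not on BAM-scale
data.
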