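# mosaicamp

Detection of low-level somatic mosaicism from ultra-deep targeted
amplicon sequencing, at desk scale and fully testable offline.

## Background

Somatic mosaic variants — present in only a fraction of a tissue's cells
— appear at variant allele frequencies (VAFs) far below the 50% of a
constitutional heterozygous change. The motivating application is
port-wine-stain vascular malformations, where activating G-protein
substitutions (a *GNAQ* c.548G>A type change and a *GNB2* c.232A>G type
change) occur in lesional skin at VAFs from ~0.2% to ~30%, enrich in
endothelial cells, and are absent from unaffected tissue of the same
individual. Quantifying a 0.2% allele requires depths around 10^5 over a
short amplicon and a principled way to separate mutant reads from
sequencing/PCR errors occurring at comparable rates.

`mosaicamp` implements the full measurement chain:

- **Simulation** (`simulate_amplicon_reads`): barcoded amplicon reads
  with binomial mutant-template sampling and uniform substitution
  errors, plus ground-truth records, so every downstream stage is
  verifiable without external data.
- **Demultiplexing** (`demux_reads`): exact barcode prefix match
  (optionally unique-nearest within a Hamming tolerance); every read
  lands in exactly one bin.
- **Alignment** (`align_reads`, C++ core): exhaustive gapless placement
  on both strands, mismatch minimization, deterministic tie-breaking,
  ambiguity flagged via a mapping-quality proxy; `clean_alignments`
  removes duplicates/improper/ambiguous records.
- **Pileup** (`count_bases_at`, `pileup_all`): per-column A/C/G/T/N
  counts; depth is the sum of all bases at the column.
- **Mosaic calling** (`classify_mosaic`): VAF with exact half-up
  rounding for display; a locally estimated error rate from the two
  off-target bases; error-corrected VAF; and a two-arm binomial
  positivity rule (count inconsistent with background error AND
  consistent with a true VAF at or above the 0.2% quantification floor).
- **Exome-style discovery** (`run_cascade`): ≥3-read candidate calling,
  affected-tissue filters (≥15 reads, population AF < 1%, conservation
  > 5), and subtraction of sites with > 5 supporting reads in matched
  unaffected tissue.
- **Structure check** (`find_salt_bridges`, `charge_reversal_report`):
  inter-chain salt bridges within 4.0 Å from fixed-column PDB ATOM
  records, and the effect of a charge-reversing point mutation.
- **Orchestration** (`run_pipeline`, `inst/scripts/mosaicamp.R`):
  seeded, stage-wise runs with provenance-stamped artifacts.

## Worked example

```r
library(mosaicamp)

cfg <- run_config(
  example_designs()["GNB2_like"],
  data.frame(sample_id = c("lesional_dermis", "endothelial_culture",
                           "unaffected_skin"),
             barcode  = example_barcodes(3),
             true_vaf = c(0.04, 0.21, 0),
             depth    = 5000),
  out_dir = tempfile(), seed = 42)

res <- run_pipeline(cfg)
res$report[, c("sample", "frequency_pct", "depth", "alt_count",
               "classification")]
#>               sample frequency_pct depth alt_count classification
#>  endothelial_culture         21.12  5000      1056       positive
#>      lesional_dermis          4.14  5000       207       positive
#>      unaffected_skin          0.06  5000         3       negative
```

Classification also works directly from published-style count rows — a
0.24% mosaic at depth ~114,000:

```r
classify_mosaic(c(A = 269, C = 3, G = 113714, T = 5),
                ref_base = "G", alt_base = "A")[
  c("vaf_percent_2dp", "error_rate_hat", "classification")]
#>   vaf_percent_2dp error_rate_hat classification
#> 1            0.24   3.509049e-05       positive
```

`run_pipeline` writes `reads.fastq`, `truth.tsv`, `pileup.tsv`,
`report.tsv`, and `calls.vcf` (positives only) into `out_dir`, each with
a provenance header recording the package version, seed and a hash of
the analytic settings; reruns with the same configuration are
byte-identical.

## Testing

```sh
Rscript -e 'testthat::test_dir("tests/testthat", package = "mosaicamp",
                               load_package = "installed")'
```

The suite checks each stage against independent brute-force oracles
(sliding-window alignment, per-column recounts, keyed set differences,
all-pairs distance search), verifies the display rounding against exact
long division, and runs a 20-seed end-to-end recovery experiment at
study-scale depth (see `run_recovery_experiment`). A full run takes a
few minutes, dominated by the end-to-end experiments.

## Vignette

`vignettes/mosaic-detection-methods.Rmd` describes the statistical model,
the rationale for the two-arm positivity rule and the 0.2% floor, the
simulator's RNG contract, and the package's limitations.
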