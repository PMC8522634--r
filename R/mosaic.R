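# Accepts either a one-row pileup_counts frame or a named vector/list with
# A,C,G,T (depth derived if absent). Returns list(counts=named int, depth).
.mosaic_counts <- function(counts) {
  if (is.data.frame(counts)) counts <- as.list(counts[1L, ])
  counts <- as.list(counts)
  cc <- vapply(DNA_BASES, function(b) as.numeric(counts[[b]] %||% 0),
               numeric(1))
  nn <- as.numeric(counts[["N"]] %||% 0)
  depth <- as.numeric(counts[["depth"]] %||% (sum(cc) + nn))
  list(counts = cc, n_count = nn, depth = depth)
}

#' Mutant-allele frequency from pileup counts
#'
#' The VAF is the exact ratio of mutant-base count to depth; the display
#' percentage is rounded half-up to 2 decimals in integer arithmetic
#' (see [round_percent()]), reproducing printed mutation-frequency tables
#' digit for digit.
#'
#' @param counts One-row `pileup_counts` frame or named vector/list with
#'   `A`, `C`, `G`, `T` (and optionally `depth`, `N`).
#' @param alt_base The mutant base.
#' @return `list(vaf =, vaf_percent_2dp =, mutant_count =, depth =)`.
#' @export
compute_vaf <- function(counts, alt_base) {
  x <- .mosaic_counts(counts)
  if (x$depth < 1) stop("VAF undefined at depth 0")
  alt <- x$counts[[alt_base]]
  list(vaf = alt / x$depth,
       vaf_percent_2dp = round_percent(alt, x$depth, 2),
       mutant_count = alt, depth = x$depth)
}

#' Background per-substitution error rate from the two off-target bases
#'
#' The two bases that are neither reference nor expected mutant can only
#' arise from sequencing/PCR error, so their pooled count divided by
#' `2 * depth` estimates the background rate of any one specific
#' substitution at the locus. Under a uniform substitution error model with
#' total per-base error e, each specific alternative is hit at rate e/3,
#' which is what this statistic estimates.
#'
#' @inheritParams compute_vaf
#' @param ref_base Reference base.
#' @param alt_base Expected mutant base.
#' @return Estimated per-substitution error rate (fraction; 0 when the
#'   off-target bases have no reads).
#' @export
estimate_error_rate <- function(counts, ref_base, alt_base) {
  x <- .mosaic_counts(counts)
  if (x$depth < 1) stop("error rate undefined at depth 0")
  off <- setdiff(DNA_BASES, c(ref_base, alt_base))
  sum(x$counts[off]) / (2 * x$depth)
}

#' Classify a sample x locus as mosaic-positive or negative
#'
#' Two-arm rule. Arm 1 (signal above error): the one-sided binomial tail
#' `P[X >= mutant_count | depth, p0]` with
#' `p0 = max(error_rate_hat, floor_error)` must fall below `alpha`
#' (Bonferroni-adjusted by `n_loci` when several loci are tested per
#' sample). Arm 2 (not below the detection floor): the sample must not sit
#' significantly below the mosaic detection floor `min_vaf`, i.e.
#' `P[X <= mutant_count | depth, min_vaf] >= beta`. A sample is positive
#' only when both arms hold. The floor is a detection-limit convention
#' (default 0.2%, the lower end of the mutation-frequency range reported
#' positive in this assay family), and arm 2 tests it statistically rather
#' than cutting on the point estimate so that samples whose true VAF is at
#' or above the floor are not misclassified by sampling noise at moderate
#' depth.
#'
#' @inheritParams estimate_error_rate
#' @param alpha Significance level of the error-model test (default 0.01).
#' @param min_vaf Mosaic detection floor as a fraction (default 0.002).
#' @param beta Significance level of the below-floor test (default 1e-3).
#' @param floor_error Lower bound for the error-rate null (default 1e-4),
#'   guarding against zero off-target counts at modest depth.
#' @param sample_id,locus Labels echoed into the call record.
#' @param n_loci Number of loci tested for this sample (Bonferroni divisor
#'   for `alpha`; default 1).
#' @return One-row data frame of class `mosaic_call` with fields
#'   `sample_id`, `locus`, `vaf`, `vaf_percent_2dp`, `vaf_corrected`
#'   (error-corrected VAF estimate, see Details), `error_rate_hat`,
#'   `p_value`, `below_floor_p`, `classification`, `mutant_count`, `depth`,
#'   plus the echoed parameters.
#'
#' @details The error-corrected VAF subtracts the locally estimated
#' per-substitution error rate and rescales for the loss of mutant
#' templates to other bases: `(vaf - e_hat) / (1 - 4 * e_hat)`, truncated
#' at 0. It is the estimate to use when comparing against a known spike-in
#' fraction; the raw `vaf` remains the exact count ratio.
#' @export
classify_mosaic <- function(counts, ref_base, alt_base, alpha = 0.01,
                            min_vaf = 0.002, beta = 1e-3,
                            floor_error = 1e-4, sample_id = NA_character_,
                            locus = NA_character_, n_loci = 1L) {
  x <- .mosaic_counts(counts)
  if (x$depth < 1) stop("classification undefined at depth 0")
  alt <- x$counts[[alt_base]]
  vaf <- alt / x$depth
  e_hat <- estimate_error_rate(counts, ref_base, alt_base)
  p0 <- max(e_hat, floor_error)
  p_value <- pbinom(alt - 1, x$depth, p0, lower.tail = FALSE)
  below_floor_p <- pbinom(alt, x$depth, min_vaf)
  positive <- (p_value < alpha / n_loci) && (below_floor_p >= beta)
  out <- data.frame(
    sample_id = sample_id, locus = locus,
    vaf = vaf,
    vaf_percent_2dp = round_percent(alt, x$depth, 2),
    vaf_corrected = max(0, (vaf - e_hat) / (1 - 4 * e_hat)),
    error_rate_hat = e_hat,
    p_value = p_value,
    below_floor_p = below_floor_p,
    classification = if (positive) "positive" else "negative",
    mutant_count = alt, depth = x$depth,
    ref_base = ref_base, alt_base = alt_base,
    alpha = alpha, min_vaf = min_vaf, beta = beta,
    floor_error = floor_error, n_loci = n_loci)
  out <- cbind(out, as.data.frame(as.list(x$counts)))
  class(out) <- c("mosaic_call", "data.frame")
  out
}

#' Assemble mosaic calls into a report table
#'
#' One row per sample x locus with the display columns of a
#' mutation-frequency table: frequency (percent, 2 decimals), depth,
#' reference and mutant counts, the two off-target base counts, and the
#' classification; sorted by sample then locus.
#'
#' @param calls A data frame of stacked [classify_mosaic()] rows (possibly
#'   empty).
#' @return Data frame with columns `sample`, `locus`, `frequency_pct`,
#'   `depth`, `ref_base`, `ref_count`, `alt_base`, `alt_count`,
#'   `other1_base`, `other1_count`, `other2_base`, `other2_count`,
#'   `classification`.
#' @export
make_report <- function(calls) {
  cols <- c("sample", "locus", "frequency_pct", "depth", "ref_base",
            "ref_count", "alt_base", "alt_count", "other1_base",
            "other1_count", "other2_base", "other2_count",
            "classification")
  if (is.null(calls) || nrow(calls) == 0L) {
    out <- as.data.frame(setNames(rep(list(character(0)), length(cols)),
                                  cols))
    return(out)
  }
  rows <- lapply(seq_len(nrow(calls)), function(i) {
    r <- calls[i, ]
    off <- setdiff(DNA_BASES, c(r$ref_base, r$alt_base))
    cc <- r[, DNA_BASES]
    data.frame(sample = r$sample_id, locus = r$locus,
               frequency_pct = r$vaf_percent_2dp, depth = r$depth,
               ref_base = r$ref_base,
               ref_count = as.integer(cc[[r$ref_base]]),
               alt_base = r$alt_base, alt_count = as.integer(r$mutant_count),
               other1_base = off[1], other1_count = as.integer(cc[[off[1]]]),
               other2_base = off[2], other2_count = as.integer(cc[[off[2]]]),
               classification = r$classification)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$sample, out$locus), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Call one demultiplexed sample's pileup at the target locus
#'
#' Convenience wrapper combining [count_bases_at()] and [classify_mosaic()],
#' keeping the per-base counts alongside the call so [make_report()] can
#' show the off-target columns.
#'
#' @param records Cleaned alignment frame for one sample.
#' @param design The [amplicon_design()].
#' @param sample_id Sample label.
#' @param ... Passed to [classify_mosaic()].
#' @return One-row `mosaic_call` data frame with the four base counts
#'   appended.
#' @export
call_sample_locus <- function(records, design, sample_id, ...) {
  pc <- count_bases_at(records, design, design$target_offset)
  classify_mosaic(pc, design$ref_base, design$alt_base,
                  sample_id = sample_id,
                  locus = design$amplicon_id, ...)
}

#' Write positive mosaic calls as a minimal VCF 4.2
#'
#' One record per positive call: CHROM is the amplicon id, POS the target
#' offset, with `AF` (raw VAF) and `DP` in INFO. Contig header lines come
#' from the designs.
#'
#' @param calls Stacked [classify_mosaic()] rows (needs `locus` matching a
#'   design's amplicon id).
#' @param designs List of [amplicon_design()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(calls, designs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  by_id <- setNames(designs, vapply(designs, `[[`, character(1),
                                    "amplicon_id"))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=mosaicamp",
    sprintf("##contig=<ID=%s,length=%d>", names(by_id),
            vapply(by_id, function(d) nchar(d$reference), integer(1))),
    "##INFO=<ID=AF,Number=A,Type=Float,Description=\"Mutant allele frequency\">",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  pos_calls <- calls[calls$classification == "positive", , drop = FALSE]
  if (nrow(pos_calls)) {
    d <- by_id[pos_calls$locus]
    writeLines(sprintf(
      "%s\t%d\t.\t%s\t%s\t.\tPASS\tAF=%.6g;DP=%d",
      pos_calls$locus,
      vapply(d, `[[`, integer(1), "target_offset"),
      pos_calls$ref_base, pos_calls$alt_base,
      pos_calls$vaf, as.integer(pos_calls$depth)), con)
  }
  invisible(path)
}
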