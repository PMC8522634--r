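#' Align a table of reads to an amplicon reference (gapless, both strands)
#'
#' Evaluates every gapless placement of each read and of its reverse
#' complement within the amplicon reference and keeps the placement with the
#' minimum mismatch count (ties broken by smaller start, then the `+`
#' strand). A read is reported unaligned when its best placement exceeds
#' `max_mismatch_frac * read_length` mismatches, or when it is empty or
#' longer than the reference. The mapping-quality proxy is 60 when the best
#' placement is unique and 0 otherwise (an ambiguous placement mirrors the
#' "zero or low mapping quality" removal class).
#'
#' @param reads Data frame with `read_id`, `sequence` (and optionally
#'   `quality`; qualities are not consulted).
#' @param design An [amplicon_design()].
#' @param max_mismatch_frac Maximum tolerated mismatch fraction of the read
#'   length (default 0.1).
#' @return Data frame of class `alignment_frame` with columns `read_id`,
#'   `amplicon_id`, `start` (1-based), `strand`, `mismatch_count`,
#'   `mapq_proxy`, `is_duplicate`, `proper`, `seq_ref` (the read in
#'   reference orientation). Unaligned reads are dropped from the frame and
#'   recorded in `attr(, "unaligned")` (character vector of read ids).
#' @export
align_reads <- function(reads, design, max_mismatch_frac = 0.1) {
  stopifnot(inherits(design, "amplicon_design"))
  hits <- gapless_align_cpp(reads$sequence, design$reference)
  rl <- nchar(reads$sequence)
  ok <- !is.na(hits$start) & hits$mismatch_count <= max_mismatch_frac * rl
  out <- data.frame(
    read_id = reads$read_id[ok],
    amplicon_id = rep(design$amplicon_id, sum(ok)),
    start = hits$start[ok],
    strand = hits$strand[ok],
    mismatch_count = hits$mismatch_count[ok],
    mapq_proxy = ifelse(hits$n_best[ok] == 1L, 60L, 0L),
    is_duplicate = rep(FALSE, sum(ok)),
    proper = rep(TRUE, sum(ok)),
    seq_ref = hits$seq_ref[ok])
  rownames(out) <- NULL
  attr(out, "unaligned") <- reads$read_id[!ok]
  class(out) <- c("alignment_frame", "data.frame")
  out
}

#' Align a single read, returning aligned pairs or `"UNALIGNED"`
#'
#' Single-read counterpart of [align_reads()], additionally materializing
#' the per-base `aligned_pairs` (1-based reference position, read base in
#' reference orientation).
#'
#' @param read One-row data frame or list with `read_id` and `sequence`.
#' @inheritParams align_reads
#' @return A list with `read_id`, `amplicon_id`, `start`, `strand`,
#'   `mismatch_count`, `mapq_proxy`, `is_duplicate`, `proper`, `seq_ref`
#'   and `aligned_pairs`, or the string `"UNALIGNED"`.
#' @export
align_read <- function(read, design, max_mismatch_frac = 0.1) {
  df <- data.frame(read_id = read$read_id %||% "read",
                   sequence = read$sequence)
  aln <- align_reads(df, design, max_mismatch_frac)
  if (nrow(aln) == 0L) return("UNALIGNED")
  rec <- as.list(aln[1L, ])
  bases <- strsplit(rec$seq_ref, "")[[1]]
  rec$aligned_pairs <- data.frame(
    ref_pos = rec$start + seq_along(bases) - 1L,
    read_base = bases)
  rec
}

#' Remove low-quality alignment records (read-cleaning predicates)
#'
#' Drops records flagged as PCR duplicates, records without a proper
#' pairing flag, and records whose mapping-quality proxy is below
#' `min_mapq`; the order of surviving records is preserved, and the
#' operation is idempotent. The removal tally attributes each removed
#' record to the first failing rule in the order duplicate, improper,
#' low_mapq.
#'
#' @param records An alignment data frame (see [align_reads()]).
#' @param min_mapq Minimum mapping-quality proxy to keep (default 1).
#' @return The surviving records, with `attr(, "removed")` a named integer
#'   tally `c(duplicate =, improper =, low_mapq =)`.
#' @export
clean_alignments <- function(records, min_mapq = 1L) {
  dup <- records$is_duplicate
  imp <- !records$proper & !dup
  lowq <- records$mapq_proxy < min_mapq & !dup & records$proper
  keep <- !(records$is_duplicate | !records$proper |
              records$mapq_proxy < min_mapq)
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removed") <- c(duplicate = sum(dup), improper = sum(imp),
                            low_mapq = sum(lowq))
  attr(out, "unaligned") <- attr(records, "unaligned")
  class(out) <- class(records)
  out
}

#' Write alignments as a minimal SAM file
#'
#' Minimal dialect: QNAME/FLAG/RNAME/POS/MAPQ/CIGAR columns, CIGAR always
#' `<len>M` (the aligner is gapless), SEQ in reference orientation, QUAL
#' `*`. Suitable for inspection with standard tools; not a full SAM
#' implementation.
#'
#' @param records Alignment data frame.
#' @param design The [amplicon_design()] aligned against (for the `@SQ`
#'   header line).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(records, design, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("@HD\tVN:1.6\tSO:unknown",
               sprintf("@SQ\tSN:%s\tLN:%d", design$amplicon_id,
                       nchar(design$reference))), con)
  if (nrow(records)) {
    flag <- ifelse(records$strand == "-", 16L, 0L) +
      ifelse(records$is_duplicate, 1024L, 0L)
    writeLines(sprintf("%s\t%d\t%s\t%d\t%d\t%dM\t*\t0\t0\t%s\t*",
                       records$read_id, flag, records$amplicon_id,
                       records$start, records$mapq_proxy,
                       nchar(records$seq_ref), records$seq_ref), con)
  }
  invisible(path)
}
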