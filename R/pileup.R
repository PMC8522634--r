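#' Count read bases covering one reference position
#'
#' Tallies, over all alignment records covering `position`, the base each
#' read shows there. Minus-strand reads are already stored in reference
#' orientation (`seq_ref`), so their bases are complemented back before
#' tallying by construction. Counts are exact integers; no sampling,
#' quality filtering or strand-bias filtering is applied — the tallies are
#' raw, and depth always equals the sum of the A/C/G/T counts plus the N
#' count.
#'
#' @param records Alignment data frame (see [align_reads()]), normally
#'   after [clean_alignments()].
#' @param design The [amplicon_design()].
#' @param position 1-based reference position.
#' @return One-row data frame of class `pileup_counts` with columns
#'   `amplicon_id`, `pos`, `ref`, `depth`, `A`, `C`, `G`, `T`, `N`.
#' @export
count_bases_at <- function(records, design, position) {
  n <- nchar(design$reference)
  if (position < 1 || position > n)
    stop("position ", position, " outside reference 1..", n)
  counts <- c(A = 0L, C = 0L, G = 0L, T = 0L, N = 0L)
  if (nrow(records)) {
    end <- records$start + nchar(records$seq_ref) - 1L
    cov <- records$start <= position & end >= position
    if (any(cov)) {
      base <- substr(records$seq_ref[cov],
                     position - records$start[cov] + 1L,
                     position - records$start[cov] + 1L)
      tab <- table(factor(base, levels = names(counts)))
      counts <- counts + as.integer(tab)
      names(counts) <- c("A", "C", "G", "T", "N")
    }
  }
  out <- data.frame(amplicon_id = design$amplicon_id,
                    pos = as.integer(position),
                    ref = substr(design$reference, position, position),
                    depth = as.integer(sum(counts)),
                    A = counts[["A"]], C = counts[["C"]],
                    G = counts[["G"]], T = counts[["T"]],
                    N = counts[["N"]])
  class(out) <- c("pileup_counts", "data.frame")
  out
}

#' Pileup base counts for every reference position
#'
#' [count_bases_at()] applied to each position of the amplicon. The summed
#' depth over positions equals the summed aligned length of the input
#' records (conservation).
#'
#' @inheritParams count_bases_at
#' @return Data frame of class `pileup_counts` with one row per reference
#'   position.
#' @export
pileup_all <- function(records, design) {
  n <- nchar(design$reference)
  out <- do.call(rbind, lapply(seq_len(n), function(p)
    count_bases_at(records, design, p)))
  rownames(out) <- NULL
  class(out) <- c("pileup_counts", "data.frame")
  out
}

#' Write pileup counts as TSV
#'
#' Fixed column order: amplicon, pos, ref, depth, A, C, G, T, N.
#'
#' @param pile A `pileup_counts` data frame.
#' @param path Output path.
#' @param header_lines Optional character vector of `#`-prefixed provenance
#'   lines written before the column header.
#' @return `path`, invisibly.
#' @export
write_pileup_tsv <- function(pile, path, header_lines = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header_lines)) writeLines(header_lines, con)
  writeLines(paste(c("amplicon", "pos", "ref", "depth",
                     "A", "C", "G", "T", "N"), collapse = "\t"), con)
  if (nrow(pile))
    writeLines(sprintf("%s\t%d\t%s\t%d\t%d\t%d\t%d\t%d\t%d",
                       pile$amplicon_id, pile$pos, pile$ref, pile$depth,
                       pile$A, pile$C, pile$G, pile$T, pile$N), con)
  invisible(path)
}
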