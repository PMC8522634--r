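#' Barcode map
#'
#' @param sample_id Character vector of sample labels.
#' @param barcode Character vector of A/C/G/T barcodes, all the same length,
#'   pairwise distinct.
#' @return Object of class `barcode_map` (data frame `sample_id`, `barcode`
#'   with attribute `barcode_length`).
#' @export
barcode_map <- function(sample_id, barcode) {
  stopifnot(length(sample_id) == length(barcode), length(barcode) >= 1)
  if (anyDuplicated(barcode)) stop("barcodes must be pairwise distinct")
  if (anyDuplicated(sample_id)) stop("sample ids must be distinct")
  if (!all(is_dna(barcode))) stop("barcodes must be A/C/G/T strings")
  bl <- unique(nchar(barcode))
  if (length(bl) != 1L) stop("all barcodes must have the same length")
  structure(data.frame(sample_id = sample_id, barcode = barcode),
            barcode_length = as.integer(bl),
            class = c("barcode_map", "data.frame"))
}

#' Read a barcode map from a two-column TSV (sample_id, barcode)
#'
#' @param path TSV file path (header optional; columns `sample_id`,
#'   `barcode` or unnamed).
#' @return A [barcode_map()].
#' @export
read_barcode_map <- function(path) {
  first <- readLines(path, n = 1L)
  has_header <- grepl("sample_id", first, fixed = TRUE)
  df <- read.table(path, sep = "\t", header = has_header,
                   stringsAsFactors = FALSE)
  barcode_map(df[[1]], df[[2]])
}

#' Assign a single read to a sample by exact barcode prefix match
#'
#' The read's first `barcode_length` bases are compared against every
#' barcode; an exact match (no mismatches, N never matches) assigns the
#' read, anything else goes to `"UNASSIGNED"`. A read shorter than the
#' barcode is routed to `"UNASSIGNED"` with a warning rather than an error.
#'
#' @param read One-row data frame (or list) with `sequence`.
#' @param map A [barcode_map()].
#' @param max_mismatch Allowed barcode mismatches (default 0, the
#'   conservative exact-match policy). When > 0, the read is assigned to the
#'   unique barcode at minimum Hamming distance <= `max_mismatch`; distance
#'   ties are unassigned.
#' @return `list(sample_id =, read =)` where `read` has the barcode prefix
#'   stripped from sequence and quality (unchanged for unassigned reads).
#' @export
assign_barcode <- function(read, map, max_mismatch = 0L) {
  out <- demux_reads(as.data.frame(read), map, max_mismatch)
  sid <- names(out$tally)[out$tally > 0L][1]
  list(sample_id = sid, read = out$bins[[sid]][1, , drop = FALSE])
}

#' Demultiplex a read table by barcode
#'
#' Partitions reads into one bin per sample plus `UNASSIGNED`; every input
#' read lands in exactly one bin. Assigned reads have the barcode prefix
#' stripped from sequence and quality.
#'
#' @param reads Data frame with `read_id`, `sequence`, `quality`.
#' @param map A [barcode_map()].
#' @inheritParams assign_barcode
#' @return List with `bins` (named list of data frames, always including
#'   `UNASSIGNED`) and `tally` (named integer vector of bin sizes).
#' @export
demux_reads <- function(reads, map, max_mismatch = 0L) {
  stopifnot(inherits(map, "barcode_map"))
  bl <- attr(map, "barcode_length")
  n <- nrow(reads)
  assigned <- rep("UNASSIGNED", n)

  short <- nchar(reads$sequence) < bl
  if (any(short))
    warning(sum(short), " read(s) shorter than the barcode length ",
            "routed to UNASSIGNED")
  prefix <- substr(reads$sequence, 1L, bl)

  if (max_mismatch == 0L) {
    hit <- match(prefix, map$barcode)
    ok <- !short & !is.na(hit)
    assigned[ok] <- map$sample_id[hit[ok]]
  } else {
    pref_mat <- do.call(rbind, strsplit(prefix, ""))
    dist <- sapply(map$barcode, function(b) {
      bc <- strsplit(b, "")[[1]]
      rowSums(pref_mat != matrix(bc, n, bl, byrow = TRUE))
    })
    dist <- matrix(dist, nrow = n)
    best <- apply(dist, 1L, min)
    nbest <- rowSums(dist == best)
    ok <- !short & best <= max_mismatch & nbest == 1L
    assigned[ok] <- map$sample_id[apply(dist[ok, , drop = FALSE], 1L,
                                        which.min)]
  }

  bins <- lapply(c(map$sample_id, "UNASSIGNED"), function(s) {
    sel <- reads[assigned == s, , drop = FALSE]
    if (s != "UNASSIGNED" && nrow(sel)) {
      sel$sequence <- substr(sel$sequence, bl + 1L, nchar(sel$sequence))
      sel$quality <- substr(sel$quality, bl + 1L, nchar(sel$quality))
    }
    rownames(sel) <- NULL
    sel
  })
  names(bins) <- c(map$sample_id, "UNASSIGNED")
  list(bins = bins,
       tally = vapply(bins, nrow, integer(1)))
}

#' Write demultiplexed bins to one FASTQ per sample
#'
#' Emits `<sample_id>.fastq` per sample plus `unassigned.fastq` in `dir`.
#'
#' @param bins The `bins` element of [demux_reads()] output.
#' @param dir Output directory (created if needed).
#' @return Named character vector of written paths, invisibly.
#' @export
write_demux_fastq <- function(bins, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(names(bins), function(s) {
    fn <- file.path(dir, paste0(
      if (s == "UNASSIGNED") "unassigned" else s, ".fastq"))
    if (nrow(bins[[s]])) write_fastq(bins[[s]], fn) else file.create(fn)
    fn
  }, character(1))
  invisible(paths)
}
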