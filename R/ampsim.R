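#' Amplicon design: reference, target locus and expected substitution
#'
#' Describes one targeted amplicon in amplicon-local coordinates: the
#' reference sequence, the 1-based offset of the interrogated base, and the
#' expected mutant base at that offset. All downstream stages (alignment,
#' pileup, mosaic calling) work in these coordinates; mapping to genomic
#' (hg19/HGVS) coordinates is configuration metadata kept outside the
#' package.
#'
#' @param amplicon_id Text label, e.g. `"GNAQ_c548"`.
#' @param reference Uppercase A/C/G/T string.
#' @param target_offset 1-based position of the interrogated base.
#' @param alt_base Expected mutant base (single character, != reference base).
#' @return An object of class `amplicon_design` (a named list with the
#'   fields above plus `ref_base`, the reference base at `target_offset`).
#' @export
amplicon_design <- function(amplicon_id, reference, target_offset, alt_base) {
  stopifnot(is.character(amplicon_id), length(amplicon_id) == 1L,
            is.character(reference), length(reference) == 1L)
  if (!is_dna(reference))
    stop("reference must contain only A/C/G/T")
  n <- nchar(reference)
  if (target_offset < 1 || target_offset > n)
    stop("target_offset out of range 1..", n)
  ref_base <- substr(reference, target_offset, target_offset)
  if (!alt_base %in% DNA_BASES || alt_base == ref_base)
    stop("alt_base must be a base different from the reference base (",
         ref_base, ")")
  structure(
    list(amplicon_id = amplicon_id, reference = reference,
         target_offset = as.integer(target_offset),
         ref_base = ref_base, alt_base = alt_base),
    class = "amplicon_design"
  )
}

#' @export
print.amplicon_design <- function(x, ...) {
  cat(sprintf("<amplicon_design> %s (%d bp), target %d %s>%s\n",
              x$amplicon_id, nchar(x$reference), x$target_offset,
              x$ref_base, x$alt_base))
  invisible(x)
}

#' Two bundled synthetic amplicon designs
#'
#' Synthetic 72-bp references (randomly generated, fixed once) emulating the
#' two interrogated loci of the study design: a G>A substitution (the
#' GNAQ-like locus) and an A>G substitution (the GNB2-like locus), each at
#' offset 30. They are stand-ins for the real amplicons, whose primer-bound
#' sequences are not shipped.
#'
#' @return Named list of two [amplicon_design()] objects.
#' @export
example_designs <- function() {
  list(
    GNAQ_like = amplicon_design(
      "GNAQ_like",
      paste0("AAAACTCCATGTGTAACTCCGGAAGTAGA", "G",
             "TCTTGCACTCGGCCTTTCCATATCTCGTGAACCCCCTGCACG"),
      target_offset = 30, alt_base = "A"),
    GNB2_like = amplicon_design(
      "GNB2_like",
      paste0("CCCTAAAGTACAATTAGGATATTCATCCC", "A",
             "ACACTGTATATGCCGAACGTTCTAATAAACGACTTAGCAACA"),
      target_offset = 30, alt_base = "G")
  )
}

#' Deterministic sample barcodes
#'
#' Encodes sample indices 1..n in base 4 over A/C/G/T, giving pairwise
#' distinct fixed-length barcodes without randomness.
#'
#' @param n Number of barcodes.
#' @param length Barcode length in bases (default 6; must satisfy
#'   `4^length >= n`).
#' @return Character vector of `n` distinct barcodes.
#' @export
example_barcodes <- function(n, length = 6) {
  stopifnot(n >= 1, 4^length >= n)
  vapply(seq_len(n) - 1L, function(i) {
    digits <- integer(length)
    for (j in seq_len(length)) {
      digits[j] <- i %% 4L
      i <- i %/% 4L
    }
    paste(DNA_BASES[rev(digits) + 1L], collapse = "")
  }, character(1))
}

#' Simulation configuration for the amplicon read generator
#'
#' @param designs List of [amplicon_design()] objects.
#' @param samples Data frame with columns `sample_id`, `barcode`,
#'   `true_vaf` (fraction in \[0,1\]) and `depth` (reads per
#'   sample x amplicon).
#' @param error_rate Per-base substitution probability in \[0, 0.05\].
#' @param read_length Read length in bases (<= every amplicon length).
#' @param seed Integer RNG seed; identical configs give byte-identical
#'   output.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(designs, samples, error_rate = 1e-3,
                       read_length = 50, seed = 1) {
  if (inherits(designs, "amplicon_design")) designs <- list(designs)
  stopifnot(length(designs) >= 1,
            all(vapply(designs, inherits, logical(1), "amplicon_design")))
  req <- c("sample_id", "barcode", "true_vaf", "depth")
  if (!all(req %in% names(samples)))
    stop("samples must have columns: ", paste(req, collapse = ", "))
  if (anyDuplicated(samples$barcode))
    stop("barcodes must be unique across samples")
  if (!all(is_dna(samples$barcode)) ||
      length(unique(nchar(samples$barcode))) != 1L)
    stop("barcodes must be A/C/G/T strings of one common length")
  stopifnot(all(samples$true_vaf >= 0), all(samples$true_vaf <= 1),
            all(samples$depth >= 1),
            error_rate >= 0, error_rate <= 0.05)
  min_ref <- min(vapply(designs, function(d) nchar(d$reference), integer(1)))
  if (read_length < 1 || read_length > min_ref)
    stop("read_length must be in 1..", min_ref,
         " (shortest amplicon reference)")
  structure(
    list(designs = designs, samples = as.data.frame(samples),
         error_rate = error_rate, read_length = as.integer(read_length),
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Simulate barcoded amplicon reads with spiked mosaic variants
#'
#' Emulates ultra-deep single-end amplicon sequencing of a two-step PCR
#' library: for each sample x amplicon, exactly `depth` reads are emitted
#' from position 1 of the reference. Each read's template carries the
#' design's mutant base at the target offset with probability `true_vaf`;
#' every template base is then independently substituted to one of the three
#' other bases (uniformly) with probability `error_rate`; finally the
#' sample's barcode is prepended error-free. Qualities are a constant Q30
#' placeholder (no stage consumes them).
#'
#' The RNG recipe is part of the contract so an independent re-implementation
#' reproduces the realized mutant-template counts: after `set.seed(seed)`,
#' for each sample in row order and each design in list order, the generator
#' draws (1) `depth` uniforms for the mutant-template flags
#' (`u < true_vaf`), (2) a `depth x read_length` uniform matrix
#' (column-major) for error positions (`u < error_rate`), and (3) a
#' `depth x read_length` uniform matrix (column-major) whose entries at
#' error positions select the substituted base via
#' `1 + floor(3u)` into the alphabetically ordered alternatives of the
#' current base.
#'
#' @param config A [sim_config()].
#' @return List with `reads` (data frame: `read_id`, `sequence`, `quality`)
#'   and `truth` (data frame: `sample_id`, `amplicon_id`, `true_vaf`,
#'   `n_reads_emitted`, `n_mutant_templates`).
#' @export
simulate_amplicon_reads <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  rl <- config$read_length
  reads_list <- list()
  truth_list <- list()
  k <- 0L
  for (si in seq_len(nrow(config$samples))) {
    smp <- config$samples[si, ]
    for (d in config$designs) {
      k <- k + 1L
      depth <- smp$depth
      template <- substr(d$reference, 1L, rl)
      tmpl_chars <- strsplit(template, "")[[1]]
      mat <- matrix(tmpl_chars, nrow = depth, ncol = rl, byrow = TRUE)

      mutant <- runif(depth) < smp$true_vaf
      if (d$target_offset <= rl && any(mutant))
        mat[mutant, d$target_offset] <- d$alt_base

      if (config$error_rate > 0) {
        u_err <- matrix(runif(depth * rl), nrow = depth)
        u_sub <- matrix(runif(depth * rl), nrow = depth)
        hit <- which(u_err < config$error_rate)
        if (length(hit)) {
          cur <- mat[hit]
          col <- pmin(2L, floor(3 * u_sub[hit])) + 1L
          mat[hit] <- DNA_ALTERNATIVES[cbind(match(cur, DNA_BASES), col)]
        }
      }

      seqs <- do.call(paste0, lapply(seq_len(rl), function(j) mat[, j]))
      seqs <- paste0(smp$barcode, seqs)
      qual <- strrep("?", nchar(smp$barcode) + rl)  # Phred+33 Q30
      ids <- sprintf("%s:%s:%06d", smp$sample_id, d$amplicon_id,
                     seq_len(depth))
      reads_list[[k]] <- data.frame(read_id = ids, sequence = seqs,
                                    quality = qual)
      truth_list[[k]] <- data.frame(
        sample_id = smp$sample_id, amplicon_id = d$amplicon_id,
        true_vaf = smp$true_vaf, n_reads_emitted = depth,
        n_mutant_templates = sum(mutant))
    }
  }
  list(reads = do.call(rbind, reads_list),
       truth = do.call(rbind, truth_list))
}

#' Write reads to a FASTQ file
#'
#' @param reads Data frame with `read_id`, `sequence`, `quality`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads$sequence)
  names(x) <- reads$read_id
  Biostrings::writeXStringSet(
    x, path, format = "fastq",
    qualities = Biostrings::BStringSet(reads$quality))
  invisible(path)
}

#' Read a FASTQ file into the pipeline's read table
#'
#' @param path FASTQ file path.
#' @return Data frame with `read_id`, `sequence`, `quality`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  data.frame(read_id = names(x), sequence = as.character(x),
             quality = as.character(S4Vectors::mcols(x)$qualities))
}

#' Simulate annotated site tables with known filter-survival truth
#'
#' Generates paired affected/unaffected site-count tables plus annotations
#' (population allele frequency, conservation score) emulating the inputs to
#' the exome-stage filtration cascade, together with the ground truth of
#' which (site, alt base) keys should survive. The truth is computed by a
#' direct row-wise application of the thresholds, independent of the staged
#' cascade implementation.
#'
#' Site composition: a fraction of sites carry only sequencing noise
#' (alt ~ Poisson(1)), the rest carry a real alternate allele whose affected
#' count spans the calling and filtration thresholds; about half the real
#' variants are germline-like (present in unaffected tissue at similar
#' count), the rest somatic-like (unaffected count 0-5). Annotations mix
#' novel (pop AF 0), low-frequency and common variants, conservation scores
#' spanning the cutoff, and a small missing fraction of each.
#'
#' @param n_sites Number of simulated sites (>= 1).
#' @param seed Integer RNG seed.
#' @param config A [filter_config()] giving the cascade thresholds used to
#'   compute the truth.
#' @return List with `affected_sites`, `unaffected_sites` (data frames:
#'   `contig`, `pos`, `ref`, `A`, `C`, `G`, `T`), `annotations` (data frame:
#'   `contig`, `pos`, `alt`, `pop_af`, `conservation_score`, `gene`,
#'   `effect`), and `truth` (data frame of all simulated alt keys with
#'   logical `survives`).
#' @export
simulate_variant_table <- function(n_sites, seed = 1,
                                   config = filter_config()) {
  stopifnot(n_sites >= 1)
  set.seed(seed)
  contig <- "sim_contig"
  pos <- seq_len(n_sites) * 10L
  ref <- sample(DNA_BASES, n_sites, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(DNA_BASES, b), 1L),
                character(1))
  depth_aff <- sample(300:600, n_sites, replace = TRUE)
  depth_unaff <- sample(300:600, n_sites, replace = TRUE)

  kind <- sample(c("noise", "real"), n_sites, replace = TRUE,
                 prob = c(0.3, 0.7))
  alt_aff <- ifelse(kind == "noise",
                    stats::rpois(n_sites, 1),
                    sample(0:60, n_sites, replace = TRUE))
  alt_aff <- pmin(alt_aff, depth_aff)
  germline <- kind == "real" & runif(n_sites) < 0.5
  alt_unaff <- ifelse(germline,
                      pmax(0L, alt_aff + sample(-3:3, n_sites, TRUE)),
                      sample(0:5, n_sites, replace = TRUE))
  alt_unaff <- pmin(alt_unaff, depth_unaff)

  pop_af <- ifelse(runif(n_sites) < 0.5, 0,
                   runif(n_sites, 0, 0.05))
  pop_af[runif(n_sites) < 0.05] <- NA            # absent from the database
  cons <- runif(n_sites, -2, 8)
  cons[runif(n_sites) < 0.05] <- NA              # unscorable site

  make_sites <- function(alt_n, depth) {
    m <- matrix(0L, n_sites, 4, dimnames = list(NULL, DNA_BASES))
    m[cbind(seq_len(n_sites), match(ref, DNA_BASES))] <- depth - alt_n
    m[cbind(seq_len(n_sites), match(alt, DNA_BASES))] <-
      m[cbind(seq_len(n_sites), match(alt, DNA_BASES))] + alt_n
    data.frame(contig = contig, pos = pos, ref = ref, m)
  }

  # Independent row-wise truth: thresholds applied directly, not via the
  # staged cascade code path.
  called <- alt_aff >= config$call_min_alt
  passes_aff <- alt_aff >= config$affected_min_alt &
    (ifelse(is.na(pop_af), 0, pop_af) < config$max_pop_af) &
    (!is.na(cons) & cons > config$min_conservation)
  removed_by_unaff <- alt_unaff > config$unaffected_subtract_min_alt
  survives <- called & passes_aff & !removed_by_unaff

  list(
    affected_sites = make_sites(alt_aff, depth_aff),
    unaffected_sites = make_sites(alt_unaff, depth_unaff),
    annotations = data.frame(
      contig = contig, pos = pos, alt = alt, pop_af = pop_af,
      conservation_score = cons,
      gene = sprintf("GENE%04d", seq_len(n_sites)),
      effect = "missense"),
    truth = data.frame(contig = contig, pos = pos, ref = ref, alt = alt,
                       alt_count_affected = alt_aff,
                       alt_count_unaffected = alt_unaff,
                       survives = survives)
  )
}
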