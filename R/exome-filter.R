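#' Filtration cascade thresholds
#'
#' Defaults follow the exome-stage discovery rules: a variant is called
#' from >= 3 reads of the same non-reference allele; affected-tissue
#' variants are kept with alternative read count at least 15 (inclusive),
#' population allele frequency below 1% (strict) and conservation score
#' above 5 (strict); variants also seen in unaffected tissue with an
#' alternative read count over 5 (strict) are subtracted.
#'
#' @param call_min_alt Calling rule threshold (default 3, inclusive).
#' @param affected_min_alt Affected-tissue alt-count threshold (default 15,
#'   inclusive).
#' @param max_pop_af Population-AF ceiling (default 0.01, strict `<`).
#' @param min_conservation Conservation-score floor (default 5, strict `>`).
#' @param unaffected_subtract_min_alt Unaffected alt count beyond which a
#'   shared variant is subtracted (default 5, strict `>`).
#' @return Object of class `filter_config`.
#' @export
filter_config <- function(call_min_alt = 3L, affected_min_alt = 15L,
                          max_pop_af = 0.01, min_conservation = 5,
                          unaffected_subtract_min_alt = 5L) {
  stopifnot(call_min_alt >= 0, affected_min_alt >= 0, max_pop_af >= 0,
            unaffected_subtract_min_alt >= 0)
  structure(list(call_min_alt = as.integer(call_min_alt),
                 affected_min_alt = as.integer(affected_min_alt),
                 max_pop_af = max_pop_af,
                 min_conservation = min_conservation,
                 unaffected_subtract_min_alt =
                   as.integer(unaffected_subtract_min_alt)),
            class = "filter_config")
}

#' Call candidate variants from per-site base counts
#'
#' Emits one variant per (site, non-reference base) whose count reaches
#' `call_min_alt`; a site can yield up to three variants. Annotation fields
#' are left missing (`NA`) for a later join.
#'
#' @param sites Data frame with columns `contig`, `pos`, `ref`, `A`, `C`,
#'   `G`, `T`.
#' @param call_min_alt Minimum supporting reads (default 3).
#' @return Data frame of variants: `contig`, `pos`, `ref`, `alt`,
#'   `alt_count`, `depth`, `pop_af`, `conservation_score`, `gene`,
#'   `effect` (annotations `NA`).
#' @export
call_candidate_sites <- function(sites, call_min_alt = 3L) {
  empty <- data.frame(contig = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      alt_count = integer(0), depth = integer(0),
                      pop_af = numeric(0), conservation_score = numeric(0),
                      gene = character(0), effect = character(0))
  if (nrow(sites) == 0L) return(empty)
  depth <- rowSums(sites[, DNA_BASES])
  out <- lapply(DNA_BASES, function(b) {
    hit <- sites$ref != b & sites[[b]] >= call_min_alt
    if (!any(hit)) return(NULL)
    data.frame(contig = sites$contig[hit], pos = sites$pos[hit],
               ref = sites$ref[hit], alt = b,
               alt_count = as.integer(sites[[b]][hit]),
               depth = as.integer(depth[hit]),
               pop_af = NA_real_, conservation_score = NA_real_,
               gene = NA_character_, effect = NA_character_)
  })
  out <- do.call(rbind, c(list(empty), out))
  out <- out[order(out$contig, out$pos, out$alt), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Join annotations onto called variants by (contig, pos, alt)
#'
#' @param variants Output of [call_candidate_sites()].
#' @param annotations Data frame with `contig`, `pos`, `alt` plus any of
#'   `pop_af`, `conservation_score`, `gene`, `effect`.
#' @return `variants` with annotation columns filled where a key matches.
#' @export
annotate_variants <- function(variants, annotations) {
  if (nrow(variants) == 0L) return(variants)
  key <- function(d) paste(d$contig, d$pos, d$alt, sep = "\r")
  i <- match(key(variants), key(annotations))
  for (col in intersect(c("pop_af", "conservation_score", "gene", "effect"),
                        names(annotations)))
    variants[[col]] <- annotations[[col]][i]
  variants
}

#' Filter affected-tissue variants on alt count, population AF and
#' conservation
#'
#' Keeps variants with `alt_count >= affected_min_alt` (inclusive),
#' `pop_af < max_pop_af` (strict; a missing population AF is treated as 0 —
#' absence from the population database implies rarity) and
#' `conservation_score > min_conservation` (strict; a missing score fails —
#' an unscorable site cannot certify the threshold).
#'
#' @param variants Annotated variant data frame.
#' @param config A [filter_config()].
#' @return Survivors in input order, with `attr(, "removed")` a named tally
#'   of removals attributed to the first failing rule in the order
#'   `low_alt`, `common`, `low_conservation`.
#' @export
filter_affected <- function(variants, config = filter_config()) {
  af <- ifelse(is.na(variants$pop_af), 0, variants$pop_af)
  ok_alt <- variants$alt_count >= config$affected_min_alt
  ok_af <- af < config$max_pop_af
  ok_cons <- !is.na(variants$conservation_score) &
    variants$conservation_score > config$min_conservation
  keep <- ok_alt & ok_af & ok_cons
  out <- variants[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removed") <- c(
    low_alt = sum(!ok_alt),
    common = sum(ok_alt & !ok_af),
    low_conservation = sum(ok_alt & ok_af & !ok_cons))
  out
}

#' Subtract variants shared with unaffected tissue
#'
#' Removes an affected variant when the same (contig, pos, alt) key appears
#' in the unaffected list with `alt_count > unaffected_subtract_min_alt`
#' (strict). Order of survivors is preserved. Duplicate keys within either
#' list are a validation error.
#'
#' @param affected,unaffected Variant data frames keyed by
#'   (contig, pos, alt).
#' @param config A [filter_config()].
#' @return Surviving affected variants with `attr(, "removed")`
#'   `c(shared_with_unaffected = n)`.
#' @export
subtract_unaffected <- function(affected, unaffected,
                                config = filter_config()) {
  key <- function(d) paste(d$contig, d$pos, d$alt, sep = "\r")
  if (anyDuplicated(key(affected)) || anyDuplicated(key(unaffected)))
    stop("duplicate (contig, pos, alt) keys in variant list")
  bad <- unaffected$alt_count > config$unaffected_subtract_min_alt
  drop <- key(affected) %in% key(unaffected)[bad]
  out <- affected[!drop, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removed") <- c(shared_with_unaffected = sum(drop))
  out
}

#' Run the full candidate-discovery cascade
#'
#' Composition: call candidates in affected and unaffected site tables,
#' annotate the affected candidates, filter them on alt count / population
#' AF / conservation, then subtract those shared with unaffected tissue
#' (in that order — the subtraction applies to the variants remaining after
#' the annotation filters).
#'
#' @param affected_sites,unaffected_sites Site-count tables (see
#'   [call_candidate_sites()]).
#' @param annotations Annotation table (see [annotate_variants()]).
#' @param config A [filter_config()].
#' @return List with `candidates` (the surviving variant data frame) and
#'   `tallies` (named integer vector of counts after each stage plus the
#'   per-rule removal tallies).
#' @export
run_cascade <- function(affected_sites, unaffected_sites, annotations,
                        config = filter_config()) {
  called_aff <- call_candidate_sites(affected_sites, config$call_min_alt)
  called_unaff <- call_candidate_sites(unaffected_sites,
                                       config$call_min_alt)
  annotated <- annotate_variants(called_aff, annotations)
  filtered <- filter_affected(annotated, config)
  final <- subtract_unaffected(filtered, called_unaff, config)
  list(candidates = final,
       tallies = c(called_affected = nrow(called_aff),
                   called_unaffected = nrow(called_unaff),
                   after_affected_filters = nrow(filtered),
                   attr(filtered, "removed"),
                   after_unaffected_subtraction = nrow(final),
                   attr(final, "removed")))
}

#' Read a site-count TSV (contig, pos, ref, A, C, G, T)
#'
#' @param path TSV path with header.
#' @return Site-count data frame.
#' @export
read_site_counts <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE,
                   stringsAsFactors = FALSE, comment.char = "#")
  stopifnot(all(c("contig", "pos", "ref", DNA_BASES) %in% names(df)))
  df
}
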