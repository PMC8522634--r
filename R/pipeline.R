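STAGES <- c("simulate", "demux", "align", "pileup", "call",
            "filter-exome", "salt-bridges")

# Dependency of each amplicon stage on the previous one's artifact.
.stage_needs <- c(demux = "simulate", align = "demux", pileup = "align",
                  call = "pileup")

.provenance <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  # hash only the analytic settings: the output path varies per run
  jsonlite::write_json(config[setdiff(names(config),
                                      c("designs", "out_dir"))], tmp,
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  c(sprintf("# mosaicamp %s",
            as.character(utils::packageVersion("mosaicamp"))),
    sprintf("# seed=%d config_md5=%s", config$seed,
            unname(tools::md5sum(tmp))))
}

#' Build a pipeline run configuration
#'
#' One flat configuration shared by all stages. Stage parameters mirror the
#' defaults of the underlying functions; the seed is recorded in every
#' output header so a rerun with an identical configuration reproduces
#' byte-identical TSV artifacts.
#'
#' @param designs List of [amplicon_design()] objects.
#' @param samples Sample sheet as for [sim_config()] (used by the simulate
#'   stage and as the barcode map).
#' @param out_dir Output directory for artifacts.
#' @param seed Integer seed.
#' @param error_rate,read_length Simulator parameters (see [sim_config()]).
#' @param max_mismatch_frac Aligner tolerance (see [align_reads()]).
#' @param min_mapq Read-cleaning threshold (see [clean_alignments()]).
#' @param alpha,min_vaf,beta,floor_error Mosaic-call parameters (see
#'   [classify_mosaic()]).
#' @param filter Filtration thresholds, a [filter_config()].
#' @return Object of class `run_config`.
#' @export
run_config <- function(designs, samples, out_dir = tempfile("mosaicamp_"),
                       seed = 1, error_rate = 1e-3, read_length = 50,
                       max_mismatch_frac = 0.1, min_mapq = 1L,
                       alpha = 0.01, min_vaf = 0.002, beta = 1e-3,
                       floor_error = 1e-4, filter = filter_config()) {
  if (inherits(designs, "amplicon_design")) designs <- list(designs)
  structure(list(designs = designs, samples = samples, out_dir = out_dir,
                 seed = as.integer(seed), error_rate = error_rate,
                 read_length = read_length,
                 max_mismatch_frac = max_mismatch_frac,
                 min_mapq = min_mapq, alpha = alpha, min_vaf = min_vaf,
                 beta = beta, floor_error = floor_error, filter = filter),
            class = "run_config")
}

#' Run pipeline stages in dependency order
#'
#' Executes the requested subset of stages (`simulate`, `demux`, `align`,
#' `pileup`, `call`; plus the stand-alone `filter-exome` and
#' `salt-bridges`, which need their own inputs in `extra`). Each amplicon
#' stage consumes the previous stage's in-memory artifact; requesting a
#' stage without its dependency (and without the artifact supplied in
#' `extra`) is an error naming the missing stage. TSV artifacts carry a
#' provenance header (tool version, seed, configuration hash).
#'
#' @param config A [run_config()].
#' @param stages Character vector, subset of
#'   `c("simulate","demux","align","pileup","call","filter-exome","salt-bridges")`.
#' @param extra Optional named list supplying inputs for stand-alone stages
#'   (`affected_sites`, `unaffected_sites`, `annotations` for
#'   `filter-exome`; `atoms`, `chain_a`, `chain_b`, `max_dist` for
#'   `salt-bridges`) or a precomputed artifact for a skipped dependency
#'   (`reads`, `bins`, `alignments`, `pileups`).
#' @return Named list of stage artifacts (`sim`, `bins`, `alignments`,
#'   `pileups`, `calls`, `report`, `cascade`, `salt_bridges` as
#'   applicable), with `out_dir` attached.
#' @export
run_pipeline <- function(config, stages = c("simulate", "demux", "align",
                                            "pileup", "call"),
                         extra = list()) {
  stopifnot(inherits(config, "run_config"))
  bad <- setdiff(stages, STAGES)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  hdr <- .provenance(config)
  state <- extra
  art <- list(out_dir = config$out_dir)

  amp_stages <- intersect(STAGES[1:5], stages)
  for (st in amp_stages) {
    need <- .stage_needs[st]
    if (!is.na(need) && !(need %in% amp_stages)) {
      have <- switch(st,
                     demux = "reads", align = "bins",
                     pileup = "alignments", call = "pileups")
      if (is.null(state[[have]]))
        stop("stage '", st, "' requires stage '", need,
             "' (or a precomputed '", have, "' artifact)")
    }
    if (st == "simulate") {
      sc <- sim_config(config$designs, config$samples,
                       error_rate = config$error_rate,
                       read_length = config$read_length,
                       seed = config$seed)
      sim <- simulate_amplicon_reads(sc)
      state$reads <- sim$reads
      art$sim <- sim
      write_fastq(sim$reads, file.path(config$out_dir, "reads.fastq"))
      .write_tsv(sim$truth, file.path(config$out_dir, "truth.tsv"), hdr)
    } else if (st == "demux") {
      map <- barcode_map(config$samples$sample_id, config$samples$barcode)
      dm <- demux_reads(state$reads, map)
      state$bins <- dm$bins
      art$bins <- dm$bins
      art$demux_tally <- dm$tally
    } else if (st == "align") {
      state$alignments <- lapply(state$bins[setdiff(names(state$bins),
                                                    "UNASSIGNED")],
        function(bin) {
          per_design <- lapply(config$designs, function(d)
            clean_alignments(align_reads(bin, d, config$max_mismatch_frac),
                             config$min_mapq))
          names(per_design) <- vapply(config$designs, `[[`, character(1),
                                      "amplicon_id")
          per_design
        })
      art$alignments <- state$alignments
    } else if (st == "pileup") {
      state$pileups <- lapply(state$alignments, function(per_design)
        lapply(names(per_design), function(id) {
          d <- Find(function(x) x$amplicon_id == id, config$designs)
          pileup_all(per_design[[id]], d)
        }))
      state$pileups <- lapply(state$pileups, function(x) {
        names(x) <- vapply(config$designs, `[[`, character(1),
                           "amplicon_id")
        x
      })
      art$pileups <- state$pileups
      flat <- do.call(rbind, unlist(state$pileups, recursive = FALSE))
      .write_tsv(stats::setNames(flat, c("amplicon", names(flat)[-1])),
                 file.path(config$out_dir, "pileup.tsv"), hdr)
    } else if (st == "call") {
      calls <- do.call(rbind, lapply(names(state$pileups), function(s) {
        do.call(rbind, lapply(config$designs, function(d) {
          pc <- state$pileups[[s]][[d$amplicon_id]]
          classify_mosaic(pc[pc$pos == d$target_offset, ],
                          d$ref_base, d$alt_base,
                          alpha = config$alpha, min_vaf = config$min_vaf,
                          beta = config$beta,
                          floor_error = config$floor_error,
                          sample_id = s, locus = d$amplicon_id,
                          n_loci = length(config$designs))
        }))
      }))
      art$calls <- calls
      art$report <- make_report(calls)
      .write_tsv(art$report, file.path(config$out_dir, "report.tsv"), hdr)
      write_vcf(calls, config$designs,
                file.path(config$out_dir, "calls.vcf"))
    }
  }

  if ("filter-exome" %in% stages) {
    need <- c("affected_sites", "unaffected_sites", "annotations")
    miss <- need[!need %in% names(state)]
    if (length(miss))
      stop("stage 'filter-exome' requires input(s): ",
           paste(miss, collapse = ", "))
    art$cascade <- run_cascade(state$affected_sites,
                               state$unaffected_sites,
                               state$annotations, config$filter)
    .write_tsv(art$cascade$candidates,
               file.path(config$out_dir, "candidates.tsv"), hdr)
    jsonlite::write_json(as.list(art$cascade$tallies),
                         file.path(config$out_dir, "cascade_tallies.json"),
                         auto_unbox = TRUE)
  }
  if ("salt-bridges" %in% stages) {
    if (is.null(state$atoms))
      stop("stage 'salt-bridges' requires input 'atoms'")
    art$salt_bridges <- find_salt_bridges(
      state$atoms, state$chain_a, state$chain_b,
      state$max_dist %||% 4.0)
    .write_tsv(art$salt_bridges,
               file.path(config$out_dir, "salt_bridges.tsv"), hdr)
  }
  art
}

.write_tsv <- function(df, path, header_lines = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header_lines)) writeLines(header_lines, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
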