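## Pipeline orchestration: simulate -> infer -> classify -> enrich ->
## consequences -> quant, each stage re-runnable from its predecessor's
## files alone, with a manifest recording parameters, seed and output
## checksums.

PIPELINE_STAGES <- c("simulate", "infer", "classify", "enrich",
                     "consequences", "quant")

#' Pipeline configuration
#'
#' Collects paths, thresholds and the simulation config.  Every
#' threshold default is the analysis default: discovery BF 5 (inclusive),
#' SE validation |delta PSI| > 0.5 and BF > 10, RI validation BF > 5,
#' motif pre-filter BF >= 10, BH q <= 0.05, minimum trusted reads 20, 5
#' GC bins, NMD distance 50 nt.
#'
#' @param out_dir Output directory (created on demand).
#' @param seed Master seed; forwarded to the simulation config.
#' @param sim A [sim_config()] (defaults to `sim_config(seed = seed)`).
#' @param motif_table Path to an RBP pentamer TSV; defaults to the
#'   packaged illustrative table.
#' @param bf_discovery,bf_validation_se,delta_psi_validation,bf_validation_ri
#'   Classification thresholds.
#' @param bf_motif,q_cutoff,gc_bins Motif-enrichment parameters.
#' @param min_reads,nmd_distance Inference / consequence parameters.
#' @param ct_targets Named numeric vector of true qPCR fold changes used
#'   by the simulate stage's Ct table.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir, seed = 1, sim = NULL,
                            motif_table = NULL,
                            bf_discovery = 5, bf_validation_se = 10,
                            delta_psi_validation = 0.5, bf_validation_ri = 5,
                            bf_motif = 10, q_cutoff = 0.05, min_reads = 20,
                            gc_bins = 5, nmd_distance = 50,
                            ct_targets = c(Arc = 3.2, target_a = 0.3,
                                           target_b = 1)) {
  if (is.null(sim)) sim <- sim_config(seed = seed)
  if (is.null(motif_table))
    motif_table <- system.file("extdata", "rbp_pentamers_synthetic.tsv",
                               package = "psikit")
  cfg <- list(out_dir = out_dir, seed = as.integer(seed), sim = sim,
              motif_table = motif_table, bf_discovery = bf_discovery,
              bf_validation_se = bf_validation_se,
              delta_psi_validation = delta_psi_validation,
              bf_validation_ri = bf_validation_ri, bf_motif = bf_motif,
              q_cutoff = q_cutoff, min_reads = min_reads, gc_bins = gc_bins,
              nmd_distance = nmd_distance, ct_targets = ct_targets)
  for (nm in c("bf_discovery", "bf_validation_se", "delta_psi_validation",
               "bf_validation_ri", "bf_motif", "q_cutoff", "min_reads",
               "gc_bins", "nmd_distance"))
    pk_assert(is.numeric(cfg[[nm]]) && length(cfg[[nm]]) == 1 && cfg[[nm]] > 0,
              "threshold '", nm, "' must be a single positive number")
  pk_assert(inherits(sim, "sim_config"), "sim must come from sim_config()")
  structure(cfg, class = "pipeline_config")
}

.out <- function(config, ...) file.path(config$out_dir, ...)

.load_events <- function(config) {
  ev_tab <- read_tsv(.out(config, "events.tsv"))
  evs <- lapply(seq_len(nrow(ev_tab)), function(i)
    parse_miso_event(ev_tab$event_id[i], gene = ev_tab$gene[i]))
  names(evs) <- ev_tab$event_id
  evs
}

#' Run one pipeline stage
#'
#' Each stage reads only its predecessors' files under
#' `config$out_dir` and writes its own TSV/JSON outputs, so any stage
#' can be re-run in isolation.  Stages: `simulate`, `infer`, `classify`,
#' `enrich`, `consequences`, `quant`.
#'
#' @param stage Stage name.
#' @param config A [pipeline_config()].
#' @return Invisibly, a character vector of the files written.
#' @export
run_stage <- function(stage, config) {
  pk_assert(inherits(config, "pipeline_config"),
            "config must come from pipeline_config()")
  pk_assert(stage %in% PIPELINE_STAGES,
            "unknown stage '", stage, "'")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- switch(stage,
    simulate = {
      sim <- simulate_genome_and_events(config$sim)
      Biostrings::writeXStringSet(sim$genome, .out(config, "genome.fa"),
                                  width = 70)
      gr <- GenomicRanges::GRanges(
        seqnames = "chrS",
        ranges = IRanges::IRanges(start = sim$gtf$start + 1,
                                  end = sim$gtf$end),
        strand = sim$gtf$strand)
      gr$type <- sim$gtf$type
      gr$phase <- as.integer(sim$gtf$phase)
      gr$gene_id <- sim$gtf$gene_id
      gr$transcript_id <- sim$gtf$transcript_id
      rtracklayer::export(gr, .out(config, "annotation.gtf"), format = "gtf")
      write_tsv(sim$truth$events[, c("event_id", "event_type", "gene")],
                .out(config, "events.tsv"))
      counts <- simulate_counts(sim$truth$events, config$sim)
      write_counts_table(counts, .out(config, "counts.tsv"))
      write_bed(sim$u12_introns, .out(config, "u12.bed"))
      ct <- simulate_ct_table(config$ct_targets, config$sim)
      write_tsv(ct, .out(config, "ct.tsv"))
      truth <- list(events = sim$truth$events,
                    consequences = sim$truth$consequences,
                    planted = sim$truth$planted,
                    ct_folds = as.list(attr(ct, "true_folds")),
                    ct_reference = attr(ct, "reference"))
      jsonlite::write_json(truth, .out(config, "truth.json"),
                           auto_unbox = TRUE, digits = NA, null = "null",
                           pretty = TRUE)
      c("genome.fa", "annotation.gtf", "events.tsv", "counts.tsv",
        "u12.bed", "ct.tsv", "truth.json")
    },
    infer = {
      counts <- read_counts_table(.out(config, "counts.tsv"))
      ev_tab <- read_tsv(.out(config, "events.tsv"))
      types <- setNames(ev_tab$event_type, ev_tab$event_id)
      calls <- call_events(counts, events = types,
                           min_reads = config$min_reads)
      write_tsv(calls, .out(config, "calls.tsv"))
      "calls.tsv"
    },
    classify = {
      calls <- read_tsv(.out(config, "calls.tsv"))
      events <- .load_events(config)
      u12 <- read_bed(.out(config, "u12.bed"))
      classified <- classify_events(calls, events = events,
                                    u12_introns = u12,
                                    bf_discovery = config$bf_discovery)
      write_tsv(classified, .out(config, "classified.tsv"))
      jsonlite::write_json(attr(classified, "summary"),
                           .out(config, "summary.json"), auto_unbox = TRUE,
                           digits = NA, pretty = TRUE)
      c("classified.tsv", "summary.json")
    },
    enrich = {
      classified <- read_tsv(.out(config, "classified.tsv"))
      events <- .load_events(config)
      genome <- read_genome(.out(config, "genome.fa"))
      motifs <- read_motif_table(config$motif_table)
      res <- suppressWarnings(
        enrich(classified, events, genome, motif_table = motifs,
               bf_cutoff = config$bf_motif, q_cutoff = config$q_cutoff,
               n_bins = config$gc_bins))
      write_tsv(res$enrichment, .out(config, "enrichment.tsv"))
      write_tsv(res$significant, .out(config, "significant.tsv"))
      jsonlite::write_json(list(rbp_summary = res$rbp_summary,
                                shared_rbps = res$shared_rbps),
                           .out(config, "rbp_summary.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      c("enrichment.tsv", "significant.tsv", "rbp_summary.json")
    },
    consequences = {
      classified <- read_tsv(.out(config, "classified.tsv"))
      events <- .load_events(config)
      genome <- read_genome(.out(config, "genome.fa"))
      annotation <- read_annotation(.out(config, "annotation.gtf"))
      cons <- annotate_group3(classified, annotation, genome, events,
                              nmd_distance = config$nmd_distance)
      write_tsv(cons, .out(config, "consequences.tsv"))
      "consequences.tsv"
    },
    quant = {
      ct <- read_tsv(.out(config, "ct.tsv"))
      targets <- setdiff(unique(ct$gene), "ref5s")
      folds <- do.call(rbind, lapply(targets, function(g) {
        d <- delta_delta_ct(ct, g, "ref5s", control_condition = "control")
        d$gene <- g
        d
      }))
      write_tsv(folds, .out(config, "foldchange.tsv"))
      "foldchange.tsv"
    })
  invisible(file.path(config$out_dir, written))
}

#' Run the whole pipeline
#'
#' Runs all stages in order and writes `manifest.json`: stage list,
#' parameter values (so deviations from the default thresholds are
#' auditable), the master seed, and an md5 checksum per output file.
#' Identical config and seed produce byte-identical outputs.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, the manifest list.
#' @export
run_all <- function(config) {
  pk_assert(inherits(config, "pipeline_config"),
            "config must come from pipeline_config()")
  files <- character(0)
  for (stage in PIPELINE_STAGES) {
    t0 <- proc.time()[["elapsed"]]
    files <- c(files, run_stage(stage, config))
    message(sprintf("[psikit] stage %-12s done (%.2fs)", stage,
                    proc.time()[["elapsed"]] - t0))
  }
  params <- unclass(config)
  params$sim <- unclass(params$sim)
  params$out_dir <- NULL  # keep the manifest path-independent
  manifest <- list(stages = PIPELINE_STAGES, seed = config$seed,
                   parameters = params,
                   outputs = as.list(setNames(unname(tools::md5sum(files)),
                                              basename(files))))
  jsonlite::write_json(manifest, .out(config, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
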