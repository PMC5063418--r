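## Ground-truth simulator.
##
## Emulates the downstream products of a two-condition (control vs
## SMN-depleted), three-replicate splicing study: a synthetic genome with
## one gene per event, MISO-style SE and RI event definitions, junction
## read counts drawn binomially from known per-condition PSI, flanking
## sequences with controllable GC content and optionally planted pentamer
## motifs, a U12-intron interval list, and qPCR Ct tables.  All
## randomness derives from a single seed; per-stage sub-seeds are fixed
## functions of it so stages can be re-run independently.

.STAGE_OFFSETS <- c(genome = 11L, counts = 23L, plant = 37L, ct = 53L)

stage_seed <- function(seed, stage) {
  (as.integer(seed) %% 2100000L) * 1009L + .STAGE_OFFSETS[[stage]]
}

#' Simulation configuration
#'
#' Defaults state the simulated world once: 2 conditions x 3 replicates
#' with 100 informative reads per event and replicate (the study shape),
#' 200 bp flanking exons and 1000 bp introns (room for the full 150/300
#' bp motif windows), 150 bp cassettes, genome GC 0.5, and Ct noise SD
#' 0.25 cycles.  When `psi_control`/`psi_depleted` are not given, half
#' the events are null and half differential with `|delta PSI|` drawn in
#' 0.3-0.8, mirroring the validated range.
#'
#' @param seed Integer master seed; all stage randomness derives from it.
#' @param n_se_events,n_ri_events Number of SE and RI events (one gene
#'   each).
#' @param psi_control,psi_depleted Optional per-event true PSI vectors of
#'   length `n_se_events + n_ri_events` (SE events first).
#' @param coverage Informative reads per event per replicate.
#' @param n_replicates Replicates per condition.
#' @param gc_content Base-composition parameter in (0, 1).
#' @param exon_length,intron_length,cassette_length Gene geometry (bp).
#' @param utr_length 5' UTR length inside the first exon of RI genes.
#' @param cds_codons Coding length (amino acids) of RI-gene transcripts.
#' @param frame_preserving_fraction Fraction of RI introns built to be
#'   frame preserving (length divisible by 3, no in-frame stop).
#' @param u12_fraction Fraction of RI introns listed as U12 dependent.
#' @param planted_motif Optional ACGT pentamer to plant.
#' @param plant_region Region label receiving the planted motif.
#' @param plant_fold Expected-count multiplier (>= 1) for the planted
#'   motif relative to its composition background.
#' @param ct_noise_sd Gaussian noise SD on simulated Ct values (cycles).
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(seed = 1, n_se_events = 20, n_ri_events = 10,
                       psi_control = NULL, psi_depleted = NULL,
                       coverage = 100, n_replicates = 3, gc_content = 0.5,
                       exon_length = 200, intron_length = 1000,
                       cassette_length = 150, utr_length = 30,
                       cds_codons = 100, frame_preserving_fraction = 0.2,
                       u12_fraction = 0.2, planted_motif = NULL,
                       plant_region = "up_intron_3p_300", plant_fold = 1,
                       ct_noise_sd = 0.25) {
  cfg <- list(seed = as.integer(seed), n_se_events = n_se_events,
              n_ri_events = n_ri_events, psi_control = psi_control,
              psi_depleted = psi_depleted, coverage = coverage,
              n_replicates = n_replicates, gc_content = gc_content,
              exon_length = exon_length, intron_length = intron_length,
              cassette_length = cassette_length, utr_length = utr_length,
              cds_codons = cds_codons,
              frame_preserving_fraction = frame_preserving_fraction,
              u12_fraction = u12_fraction, planted_motif = planted_motif,
              plant_region = plant_region, plant_fold = plant_fold,
              ct_noise_sd = ct_noise_sd)
  pk_assert(cfg$n_se_events >= 0 && cfg$n_ri_events >= 0 &&
              cfg$n_se_events + cfg$n_ri_events >= 1,
            "need at least one event")
  pk_assert(cfg$coverage >= 0, "coverage must be >= 0")
  pk_assert(cfg$n_replicates >= 1, "need at least one replicate")
  pk_assert(cfg$gc_content > 0 && cfg$gc_content < 1,
            "gc_content must lie in (0, 1)")
  pk_assert(cfg$ct_noise_sd >= 0, "ct_noise_sd must be >= 0")
  pk_assert(cfg$plant_fold >= 1, "plant_fold must be >= 1")
  if (!is.null(cfg$planted_motif))
    pk_assert(grepl("^[ACGT]{5}$", cfg$planted_motif),
              "planted_motif must be a 5-letter ACGT string")
  n <- cfg$n_se_events + cfg$n_ri_events
  for (nm in c("psi_control", "psi_depleted")) {
    v <- cfg[[nm]]
    if (!is.null(v))
      pk_assert(length(v) == n && all(v >= 0 & v <= 1),
                nm, " must have one value in [0,1] per event")
  }
  ## geometry feasibility
  pk_assert(cfg$exon_length >= cfg$utr_length + 10,
            "exon_length too short for the 5' UTR (infeasible geometry)")
  pk_assert(cfg$intron_length >= 20 && cfg$cassette_length >= 10,
            "intron/cassette lengths below minimum (infeasible geometry)")
  cds_nt <- 3 * (cfg$cds_codons + 1)
  part2 <- cds_nt - (cfg$exon_length - cfg$utr_length)
  pk_assert(part2 >= 1 && part2 <= cfg$exon_length - 1,
            "cds_codons incompatible with exon_length (infeasible geometry)")
  structure(cfg, class = "sim_config")
}

.base_probs <- function(gc) c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2,
                              T = (1 - gc) / 2)

random_seq <- function(n, gc) {
  if (n == 0) return("")
  paste(sample(names(.base_probs(gc)), n, replace = TRUE,
               prob = .base_probs(gc)), collapse = "")
}

.revcomp <- function(s)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))

## non-stop codon sampler (uniform over the 61 sense codons)
.SENSE_CODONS <- local({
  all3 <- apply(expand.grid(rep(list(c("A", "C", "G", "T")), 3),
                            stringsAsFactors = FALSE), 1, paste, collapse = "")
  setdiff(all3, c("TAA", "TAG", "TGA"))
})

random_cds <- function(n_codons) {
  paste(c("ATG", sample(setdiff(.SENSE_CODONS, "ATG"), n_codons - 1,
                        replace = TRUE), "TAA"), collapse = "")
}

## frame-preserving intron: length rounded down to a multiple of 3, all
## internal bases in {A,C} with C clamps at both ends, so no reading
## frame through it can hit a stop codon (stops require a T)
.fp_intron <- function(len) {
  len3 <- max(6, (len %/% 3) * 3)
  paste0("CC", paste(sample(c("A", "C"), len3 - 4, replace = TRUE),
                     collapse = ""), "CC")
}

## first in-frame stop of a CDS string (1-based codon index, NA if none)
.first_stop <- function(cds) {
  for (i in seq_len(nchar(cds) %/% 3)) {
    if (substr(cds, 3 * i - 2, 3 * i) %in% STOP_CODONS) return(i)
  }
  NA_integer_
}

## default PSI scheme: half null, half differential at |delta| 0.3-0.8
.default_psi <- function(n) {
  diff <- runif(n) < 0.5
  delta <- ifelse(diff, sample(c(-1, 1), n, replace = TRUE) *
                    runif(n, 0.3, 0.8), 0)
  psi_c <- ifelse(delta >= 0, runif(n, 0.05, 0.95 - delta),
                  runif(n, 0.05 - delta, 0.95))
  list(control = psi_c, depleted = psi_c + delta)
}

#' Simulate a genome, annotation, events and ground truth
#'
#' Builds one gene per event on a single synthetic chromosome (strands
#' alternate): SE genes are exon-intron-cassette-intron-exon, RI genes
#' are two coding exons around the retained intron, with a designed CDS
#' whose retention consequence (PTC codon index or frame preservation)
#' the generator records as truth.  When `planted_motif` is set, motif
#' copies are written into the designated region of every SE event at
#' `plant_fold` times the composition-background expectation.
#'
#' @param config A [sim_config()].
#' @return List with `genome` ([Biostrings::DNAStringSet]), `annotation`
#'   (list of `transcript_model`s), `events` (named list of
#'   `splicing_event`s), `u12_introns` (data frame), `truth` (a
#'   `ground_truth` list: `$events`, `$consequences`, `$planted`).
#' @export
simulate_genome_and_events <- function(config) {
  pk_assert(inherits(config, "sim_config"), "config must come from sim_config()")
  set.seed(stage_seed(config$seed, "genome"))
  gc <- config$gc_content
  Le <- config$exon_length; Li <- config$intron_length
  Lc <- config$cassette_length; Lu <- config$utr_length
  n <- config$n_se_events + config$n_ri_events
  types <- c(rep("SE", config$n_se_events), rep("RI", config$n_ri_events))

  psi <- if (is.null(config$psi_control)) .default_psi(n)
         else list(control = config$psi_control, depleted = config$psi_depleted)
  pk_assert(!is.null(psi$depleted), "psi_depleted required when psi_control given")

  fp_flags <- rep(FALSE, n)
  ri_idx <- which(types == "RI")
  n_fp <- round(config$frame_preserving_fraction * length(ri_idx))
  if (n_fp > 0) fp_flags[ri_idx[seq_len(n_fp)]] <- TRUE
  u12_flags <- rep(FALSE, n)
  n_u12 <- round(config$u12_fraction * length(ri_idx))
  if (n_u12 > 0) u12_flags[rev(ri_idx)[seq_len(n_u12)]] <- TRUE

  spacer <- 100L
  chrom <- "chrS"
  offset <- spacer
  segs <- list(random_seq(spacer, gc))
  gtf_rows <- list()
  events <- list()
  truth_events <- list()
  truth_cons <- list()
  annotation <- list()
  u12_rows <- list()

  for (i in seq_len(n)) {
    strand <- if (i %% 2 == 1) "+" else "-"
    gene_id <- sprintf("gene%03d", i)
    tx_id <- sprintf("tx%03d", i)
    if (types[i] == "SE") {
      pieces <- c(e1 = random_seq(Le, gc), i1 = random_seq(Li, gc),
                  cas = random_seq(Lc, gc), i2 = random_seq(Li, gc),
                  e3 = random_seq(Le, gc))
      lens <- nchar(pieces)
      bounds <- cumsum(c(0, lens))  # transcript-coordinate piece bounds
      Tt <- sum(lens)
      gmap <- function(a, b) {
        if (strand == "+") c(offset + a, offset + b)
        else c(offset + Tt - b, offset + Tt - a)
      }
      ex_iv <- lapply(c(1, 3, 5), function(p) gmap(bounds[p], bounds[p + 1]))
      ev_str <- paste(vapply(ex_iv, function(g)
        sprintf("%s:%d:%d:%s", chrom, g[1] + 1, g[2], strand), character(1)),
        collapse = "@")
      ev <- parse_miso_event(ev_str, gene = gene_id)
      events[[ev_str]] <- ev
      seg <- paste(pieces, collapse = "")
      if (strand == "-") seg <- .revcomp(seg)
      exon_rows <- lapply(ex_iv, function(g)
        data.frame(start = g[1], end = g[2], type = "exon"))
      model_ex <- do.call(rbind, lapply(ex_iv, function(g)
        data.frame(start = g[1], end = g[2])))
      model_ex <- model_ex[order(model_ex$start, decreasing = (strand == "-")), ]
      rownames(model_ex) <- NULL
      annotation[[tx_id]] <- structure(
        list(id = tx_id, gene = gene_id, chrom = chrom, strand = strand,
             exons = model_ex, cds_start = NA_real_, cds_end = NA_real_),
        class = "transcript_model")
      gtf_rows[[length(gtf_rows) + 1L]] <- data.frame(
        start = vapply(ex_iv, `[`, numeric(1), 1),
        end = vapply(ex_iv, `[`, numeric(1), 2),
        type = "exon", phase = NA, gene_id = gene_id, transcript_id = tx_id,
        strand = strand, stringsAsFactors = FALSE)
      truth_events[[i]] <- data.frame(
        event_id = ev_str, event_type = "SE", gene = gene_id,
        transcript_id = tx_id, strand = strand,
        psi_control = psi$control[i], psi_depleted = psi$depleted[i],
        delta_psi = psi$depleted[i] - psi$control[i], is_u12 = FALSE,
        stringsAsFactors = FALSE)
    } else {
      ## RI gene: exon1 = UTR5 + CDS part 1; exon2 = CDS part 2 + UTR3
      cds <- random_cds(config$cds_codons)
      cds_nt <- nchar(cds)                 # 3 * (cds_codons + 1), incl. stop
      c1 <- Le - Lu                        # coding nt inside exon 1
      part2 <- cds_nt - c1
      utr3 <- Le - part2
      exon1 <- paste0(random_seq(Lu, gc), substr(cds, 1, c1))
      exon2 <- paste0(substr(cds, c1 + 1, cds_nt), random_seq(utr3, gc))
      intron <- if (fp_flags[i]) .fp_intron(Li) else random_seq(Li, gc)
      Li_i <- nchar(intron)
      ## generator's own truth: codon-walk the retention-edited CDS
      edited_cds <- paste0(substr(cds, 1, c1), intron,
                           substr(cds, c1 + 1, cds_nt))
      s <- .first_stop(edited_cds)
      ref_len <- config$cds_codons
      true_ptc <- !is.na(s) && s <= ref_len
      lens <- c(nchar(exon1), Li_i, nchar(exon2))
      bounds <- cumsum(c(0, lens))
      Tt <- sum(lens)
      gmap <- function(a, b) {
        if (strand == "+") c(offset + a, offset + b)
        else c(offset + Tt - b, offset + Tt - a)
      }
      ex_iv <- list(gmap(bounds[1], bounds[2]), gmap(bounds[3], bounds[4]))
      in_iv <- gmap(bounds[2], bounds[3])
      ev_str <- paste(vapply(ex_iv, function(g)
        sprintf("%s:%d:%d:%s", chrom, g[1] + 1, g[2], strand), character(1)),
        collapse = "@")
      ev <- parse_miso_event(ev_str, gene = gene_id)
      events[[ev_str]] <- ev
      seg <- paste(c(exon1, intron, exon2), collapse = "")
      if (strand == "-") seg <- .revcomp(seg)
      model_ex <- do.call(rbind, lapply(ex_iv, function(g)
        data.frame(start = g[1], end = g[2])))
      model_ex <- model_ex[order(model_ex$start, decreasing = (strand == "-")), ]
      rownames(model_ex) <- NULL
      annotation[[tx_id]] <- structure(
        list(id = tx_id, gene = gene_id, chrom = chrom, strand = strand,
             exons = model_ex, cds_start = Lu + 1, cds_end = Lu + cds_nt),
        class = "transcript_model")
      ## genomic CDS pieces for the GTF
      cds_iv <- list(gmap(Lu, Lu + c1), gmap(bounds[3], bounds[3] + part2))
      gtf_rows[[length(gtf_rows) + 1L]] <- data.frame(
        start = c(vapply(ex_iv, `[`, numeric(1), 1),
                  vapply(cds_iv, `[`, numeric(1), 1)),
        end = c(vapply(ex_iv, `[`, numeric(1), 2),
                vapply(cds_iv, `[`, numeric(1), 2)),
        type = c("exon", "exon", "CDS", "CDS"),
        phase = c(NA, NA, 0, (3 - c1 %% 3) %% 3),
        gene_id = gene_id, transcript_id = tx_id, strand = strand,
        stringsAsFactors = FALSE)
      if (u12_flags[i])
        u12_rows[[length(u12_rows) + 1L]] <- data.frame(
          chrom = chrom, start = in_iv[1], end = in_iv[2],
          name = paste0(gene_id, "_u12"), score = 0, strand = strand,
          stringsAsFactors = FALSE)
      truth_events[[i]] <- data.frame(
        event_id = ev_str, event_type = "RI", gene = gene_id,
        transcript_id = tx_id, strand = strand,
        psi_control = psi$control[i], psi_depleted = psi$depleted[i],
        delta_psi = psi$depleted[i] - psi$control[i], is_u12 = u12_flags[i],
        stringsAsFactors = FALSE)
      truth_cons[[length(truth_cons) + 1L]] <- data.frame(
        event_id = ev_str, transcript_id = tx_id,
        intron_length = Li_i, frame_preserving = fp_flags[i],
        true_ptc_present = true_ptc,
        true_ptc_codon_index = if (true_ptc) s else NA_integer_,
        true_truncated_length = if (true_ptc) s - 1L else NA_integer_,
        stringsAsFactors = FALSE)
    }
    segs[[length(segs) + 1L]] <- seg
    segs[[length(segs) + 1L]] <- random_seq(spacer, gc)
    offset <- offset + nchar(seg) + spacer
  }

  genome_str <- paste(unlist(segs), collapse = "")
  genome <- Biostrings::DNAStringSet(setNames(genome_str, chrom))
  truth <- structure(list(
    events = { d <- do.call(rbind, truth_events); rownames(d) <- NULL; d },
    consequences = if (length(truth_cons)) {
      d <- do.call(rbind, truth_cons); rownames(d) <- NULL; d
    } else NULL,
    planted = NULL), class = "ground_truth")
  u12_introns <- if (length(u12_rows)) do.call(rbind, u12_rows)
                 else data.frame(chrom = character(0), start = numeric(0),
                                 end = numeric(0), name = character(0),
                                 score = numeric(0), strand = character(0))
  out <- list(genome = genome, annotation = annotation, events = events,
              u12_introns = u12_introns, gtf = do.call(rbind, gtf_rows),
              truth = truth)

  if (!is.null(config$planted_motif) && config$plant_fold > 1 &&
      config$n_se_events > 0) {
    se_ids <- truth$events$event_id[truth$events$event_type == "SE"]
    regions <- extract_regions_all(events[se_ids], genome)
    fg <- regions[regions$region == config$plant_region, , drop = FALSE]
    pk_assert(nrow(fg) > 0, "plant_region '", config$plant_region,
              "' is not a valid region label")
    pl <- plant_motifs(fg$seq, config$planted_motif, config$plant_fold,
                       gc_content = gc,
                       seed = stage_seed(config$seed, "plant"))
    gstr <- as.character(genome[[chrom]])
    planted_rows <- list()
    if (nrow(pl$positions)) for (r in seq_len(nrow(pl$positions))) {
      j <- pl$positions$seq_index[r]; o <- pl$positions$start[r]
      if (fg$strand[j] == "+") {
        g1 <- fg$start[j] + o          # 1-based genomic start of the motif
        substr(gstr, g1, g1 + 4) <- config$planted_motif
      } else {
        g1 <- fg$end[j] - o - 3        # 1-based genomic start, minus strand
        substr(gstr, g1, g1 + 4) <- .revcomp(config$planted_motif)
      }
      planted_rows[[r]] <- data.frame(
        event_id = fg$event_id[j], region = config$plant_region,
        chrom = chrom, start = g1 - 1, end = g1 + 4,
        strand = fg$strand[j], motif = config$planted_motif,
        stringsAsFactors = FALSE)
    }
    out$genome <- Biostrings::DNAStringSet(setNames(gstr, chrom))
    out$truth$planted <- if (length(planted_rows))
      do.call(rbind, planted_rows) else NULL
  }
  out
}

#' Plant pentamer copies into foreground sequences
#'
#' Overwrites non-overlapping windows at uniform random positions so that
#' the planted pentamer's expected total count becomes `fold` times its
#' composition-background expectation `positions * P_bg(motif)`; i.e.
#' `round((fold - 1) * positions * P_bg)` copies are written.
#'
#' @param seqs Character vector of sequences to edit.
#' @param motif ACGT pentamer.
#' @param fold Expected-count multiplier, >= 1 (1 plants nothing).
#' @param gc_content Background base composition for `P_bg`.
#' @param seed Optional RNG seed for placement.
#' @return List with `seqs` (edited) and `positions` (data frame
#'   `seq_index`, `start` (1-based within the sequence), `motif`).
#' @export
plant_motifs <- function(seqs, motif, fold, gc_content = 0.5, seed = NULL) {
  pk_assert(grepl("^[ACGT]{5}$", motif), "motif must be a 5-letter ACGT string")
  pk_assert(fold >= 1, "fold must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  pb <- .base_probs(gc_content)
  p_bg <- prod(pb[strsplit(motif, "")[[1L]]])
  win <- pmax(nchar(seqs) - 4L, 0L)
  n_insert <- round((fold - 1) * sum(win) * p_bg)
  positions <- data.frame(seq_index = integer(0), start = integer(0),
                          motif = character(0))
  if (n_insert > 0) {
    taken <- lapply(seq_along(seqs), function(i) integer(0))
    placed <- 0L
    guard <- 0L
    while (placed < n_insert && guard < 100L * n_insert) {
      guard <- guard + 1L
      i <- sample.int(length(seqs), 1L, prob = win)
      o <- sample.int(win[i], 1L)
      if (any(abs(taken[[i]] - o) < 5L)) next  # keep copies non-overlapping
      substr(seqs[i], o, o + 4L) <- motif
      taken[[i]] <- c(taken[[i]], o)
      positions <- rbind(positions,
                         data.frame(seq_index = i, start = o, motif = motif,
                                    stringsAsFactors = FALSE))
      placed <- placed + 1L
    }
  }
  list(seqs = seqs, positions = positions)
}

#' Simulate a two-condition junction-count table
#'
#' Per replicate, `inclusion_reads ~ Binomial(coverage, psi')` with
#' `psi'` the length-adjusted inclusion-read probability (`psi' = psi`
#' for equal effective lengths); `exclusion = coverage - inclusion`.
#'
#' @param truth_events Data frame with `event_id`, `psi_control`,
#'   `psi_depleted` (e.g. `truth$events` from
#'   [simulate_genome_and_events()]).
#' @param config A [sim_config()].
#' @param l_inc,l_exc Effective length model matching the inference.
#' @return Counts data frame in the [read_counts_table()] schema.
#' @export
simulate_counts <- function(truth_events, config, l_inc = 1, l_exc = 1) {
  pk_assert(inherits(config, "sim_config"), "config must come from sim_config()")
  set.seed(stage_seed(config$seed, "counts"))
  rows <- list()
  for (cond in c("control", "depleted")) {
    psi <- truth_events[[paste0("psi_", cond)]]
    psi_read <- psi * l_inc / (psi * l_inc + (1 - psi) * l_exc)
    for (rep_i in seq_len(config$n_replicates)) {
      inc <- rbinom(nrow(truth_events), config$coverage, psi_read)
      rows[[length(rows) + 1L]] <- data.frame(
        event_id = truth_events$event_id, condition = cond,
        replicate = rep_i, inclusion_reads = inc,
        exclusion_reads = config$coverage - inc, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  validate_counts_table(out)
}

#' Simulate a qPCR Ct table with known fold changes
#'
#' Per-gene baseline Ct values are drawn once; `Ct = baseline -
#' log2(expression) + N(0, ct_noise_sd)`, expression 1 in the control
#' condition and `fold` in the treated condition.  The reference gene's
#' fold is fixed at 1.
#'
#' @param true_folds Named positive numeric vector of treated/control
#'   fold changes per target gene.
#' @param config A [sim_config()].
#' @param reference Name of the internal reference gene added to the
#'   table.
#' @param conditions Length-2 vector, control first.
#' @return Data frame with `sample`, `condition`, `gene`, `ct`; attribute
#'   `true_folds` records the generator truth.
#' @export
simulate_ct_table <- function(true_folds, config, reference = "ref5s",
                              conditions = c("control", "treated")) {
  pk_assert(inherits(config, "sim_config"), "config must come from sim_config()")
  pk_assert(length(true_folds) >= 1 && all(true_folds > 0),
            "fold changes must be positive")
  pk_assert(!is.null(names(true_folds)), "true_folds must be named by gene")
  set.seed(stage_seed(config$seed, "ct"))
  folds <- c(true_folds, setNames(1, reference))
  genes <- names(folds)
  baseline <- setNames(runif(length(genes), 18, 28), genes)
  rows <- list()
  for (ci in seq_along(conditions)) {
    for (rep_i in seq_len(config$n_replicates)) {
      expr <- if (ci == 1) rep(1, length(genes)) else unname(folds)
      ct <- baseline - log2(expr) + rnorm(length(genes), 0, config$ct_noise_sd)
      rows[[length(rows) + 1L]] <- data.frame(
        sample = sprintf("%s_rep%d", conditions[ci], rep_i),
        condition = conditions[ci], gene = genes, ct = unname(ct),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "true_folds") <- folds
  attr(out, "reference") <- reference
  out
}
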