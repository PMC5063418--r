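## Pentamer RBP-motif enrichment around splicing events.
##
## Each SE event is partitioned into 7 transcript-oriented regions: the
## last 150 bp of the upstream exon, the first and last 300 bp of the
## upstream intron, the whole cassette exon, the first and last 300 bp of
## the downstream intron, and the first 150 bp of the downstream exon.
## RI events get the analogous 4-region partition around the retained
## intron.  Within each (region, direction) stratum, sequences are GC
## binned, a first-order Markov background is fit per bin, and every
## pentamer is tested for enrichment with a one-sided binomial test and
## BH correction.

SE_REGION_LABELS <- c("up_exon_150", "up_intron_5p_300", "up_intron_3p_300",
                      "cassette_exon_full", "down_intron_5p_300",
                      "down_intron_3p_300", "down_exon_150")
RI_REGION_LABELS <- c("up_exon_150", "intron_5p_300", "intron_3p_300",
                      "down_exon_150")

## windows at the transcript 5' / 3' end of an interval, as genomic
## sub-intervals; width truncated to what is available
.tx_window_5p <- function(iv, width) {
  w <- min(width, interval_length(iv))
  if (iv$strand == "+") genomic_interval(iv$chrom, iv$start, iv$start + w, "+")
  else genomic_interval(iv$chrom, iv$end - w, iv$end, "-")
}
.tx_window_3p <- function(iv, width) {
  w <- min(width, interval_length(iv))
  if (iv$strand == "+") genomic_interval(iv$chrom, iv$end - w, iv$end, "+")
  else genomic_interval(iv$chrom, iv$start, iv$start + w, "-")
}
## short introns (< 2*width): disjoint first half / second half
.intron_windows <- function(iv, width) {
  len <- interval_length(iv)
  if (len >= 2 * width) {
    list(p5 = .tx_window_5p(iv, width), p3 = .tx_window_3p(iv, width))
  } else {
    h <- floor(len / 2)
    pk_assert(h >= 1, "intron too short to split")
    list(p5 = .tx_window_5p(iv, h), p3 = .tx_window_3p(iv, len - h))
  }
}

#' Partition a splicing event into its motif-scanning regions
#'
#' SE events yield 7 labeled regions, RI events 4 (see the label
#' constants `SE_REGION_LABELS` / `RI_REGION_LABELS`).  All sequences are
#' transcript-oriented (reverse complemented on the minus strand).  Exon
#' windows are truncated to the exon (they never cross a splice site);
#' an intron shorter than twice the intron window contributes its
#' disjoint first and second halves.
#'
#' @param event A `splicing_event`.
#' @param genome A named [Biostrings::DNAStringSet].
#' @param exon_window,intron_window Nominal window sizes (150 / 300 bp).
#' @return Data frame with one row per region: `event_id`, `region`,
#'   `chrom`, `start`, `end` (genomic, 0-based half-open), `strand`,
#'   `seq`.
#' @export
extract_regions <- function(event, genome, exon_window = 150,
                            intron_window = 300) {
  pk_assert(inherits(event, "splicing_event"), "not a splicing_event")
  if (event$event_type == "SE") {
    up_i <- .intron_windows(event_intron(event, 1), intron_window)
    dn_i <- .intron_windows(event_intron(event, 2), intron_window)
    ivs <- list(.tx_window_3p(event_exon(event, 1), exon_window),
                up_i$p5, up_i$p3,
                event_exon(event, 2),
                dn_i$p5, dn_i$p3,
                .tx_window_5p(event_exon(event, 3), exon_window))
    labels <- SE_REGION_LABELS
  } else {
    iw <- .intron_windows(event_intron(event, 1), intron_window)
    ivs <- list(.tx_window_3p(event_exon(event, 1), exon_window),
                iw$p5, iw$p3,
                .tx_window_5p(event_exon(event, 2), exon_window))
    labels <- RI_REGION_LABELS
  }
  seqs <- vapply(ivs, function(iv) fetch_sequence(genome, iv), character(1))
  data.frame(event_id = event$event_id, region = labels,
             chrom = event$chrom,
             start = vapply(ivs, `[[`, numeric(1), "start"),
             end = vapply(ivs, `[[`, numeric(1), "end"),
             strand = event$strand, seq = seqs, stringsAsFactors = FALSE)
}

#' @rdname extract_regions
#' @param events A list of `splicing_event` objects.
#' @export
extract_regions_all <- function(events, genome, exon_window = 150,
                                intron_window = 300) {
  out <- do.call(rbind, lapply(events, extract_regions, genome = genome,
                               exon_window = exon_window,
                               intron_window = intron_window))
  rownames(out) <- NULL
  out
}

#' Assign sequences to equal-occupancy GC-content bins
#'
#' Sequences are binned by GC fraction at empirical quantile boundaries.
#' Duplicate boundaries collapse (identical GC content puts everything in
#' one bin); fewer sequences than bins yields fewer bins, with a message.
#'
#' @param seqs Character vector of sequences (N bases are ignored in the
#'   GC fraction).
#' @param n_bins Requested number of bins (default 5).
#' @return Integer vector of bin ids in `1..n_bins`.
#' @export
assign_gc_bins <- function(seqs, n_bins = 5) {
  pk_assert(length(seqs) >= 1, "no sequences to bin")
  pk_assert(n_bins >= 1, "n_bins must be >= 1")
  gc <- gc_fraction(seqs)
  k <- min(n_bins, length(seqs))
  breaks <- unique(quantile(gc, probs = seq(0, 1, length.out = k + 1),
                            names = FALSE))
  if (length(breaks) < 2) {
    if (n_bins > 1) message("GC binning collapsed to a single bin")
    return(rep(1L, length(seqs)))
  }
  bins <- cut(gc, breaks = breaks, include.lowest = TRUE, labels = FALSE)
  if (max(bins) < n_bins && length(seqs) >= n_bins)
    message("GC binning collapsed to ", max(bins), " bins")
  as.integer(bins)
}

#' @rdname assign_gc_bins
#' @export
gc_fraction <- function(seqs) {
  x <- Biostrings::DNAStringSet(seqs)
  af <- Biostrings::alphabetFrequency(x)
  acgt <- af[, c("A", "C", "G", "T"), drop = FALSE]
  tot <- rowSums(acgt)
  ifelse(tot > 0, (acgt[, "C"] + acgt[, "G"]) / tot, 0)
}

#' Fit a first-order Markov background model
#'
#' The initial distribution comes from smoothed mononucleotide counts and
#' the transition matrix from smoothed adjacent-pair counts; pairs or
#' bases involving N are excluded from training.
#'
#' @param seqs Character vector of training sequences.
#' @param pseudocount Add-k smoothing constant (default 1), keeping every
#'   probability positive.
#' @return A `markov_background`: list with `initial` (length-4 named
#'   vector summing to 1), `transition` (4x4 row-stochastic matrix) and
#'   `n_train` (training positions).
#' @export
fit_markov <- function(seqs, pseudocount = 1) {
  pk_assert(length(seqs) >= 1 && sum(nchar(seqs)) >= 2,
            "need at least 2 training bases")
  x <- Biostrings::DNAStringSet(seqs)
  bases <- c("A", "C", "G", "T")
  mono <- colSums(Biostrings::oligonucleotideFrequency(x, width = 1))[bases]
  di <- colSums(Biostrings::oligonucleotideFrequency(x, width = 2))
  trans <- matrix(0, 4, 4, dimnames = list(bases, bases))
  for (i in bases) for (j in bases) trans[i, j] <- di[[paste0(i, j)]]
  initial <- (mono + pseudocount) / sum(mono + pseudocount)
  transition <- (trans + pseudocount) /
    (rowSums(trans) + 4 * pseudocount)
  structure(list(initial = initial, transition = transition,
                 n_train = sum(mono), pseudocount = pseudocount),
            class = "markov_background")
}

#' Probability of a k-mer under a first-order Markov background
#'
#' `P(w) = P(w1) * prod_i P(w_i | w_{i-1})`.  Vectorized over k-mers.
#'
#' @param model A `markov_background` from [fit_markov()].
#' @param kmers Character vector of ACGT k-mers.
#' @param log If `TRUE`, return log probabilities.
#' @return Numeric vector of probabilities.
#' @export
kmer_probability <- function(model, kmers, log = FALSE) {
  pk_assert(inherits(model, "markov_background"), "not a markov_background")
  pk_assert(all(grepl("^[ACGT]+$", kmers)), "k-mers must be ACGT strings")
  lp <- vapply(kmers, function(w) {
    ch <- strsplit(w, "")[[1L]]
    l <- base::log(model$initial[[ch[1L]]])
    for (i in seq_along(ch)[-1L])
      l <- l + base::log(model$transition[ch[i - 1L], ch[i]])
    l
  }, numeric(1), USE.NAMES = FALSE)
  if (log) lp else exp(lp)
}

#' Count overlapping k-mer windows in a sequence set
#'
#' Windows containing N are excluded from both the per-k-mer counts and
#' the scanned-positions denominator.
#'
#' @param seqs Character vector of uppercase sequences.
#' @param k Word size (default 5).
#' @return List with `counts` (named integer vector over all `4^k`
#'   k-mers) and `positions` (total N-free windows scanned).
#' @export
count_kmers <- function(seqs, k = 5) {
  x <- Biostrings::DNAStringSet(seqs)
  counts <- colSums(Biostrings::oligonucleotideFrequency(x, width = k))
  list(counts = counts, positions = sum(counts))
}

#' One-sided binomial enrichment p-value
#'
#' Upper-tail probability `P(X >= observed)` for `X ~ Binomial(positions,
#' expected_p)`; tests enrichment only.  Vectorized.
#'
#' @param observed Observed k-mer count.
#' @param positions Number of scanned windows.
#' @param expected_p Background probability per window, in (0, 1).
#' @return p-values in `[0, 1]`.
#' @export
binomial_enrichment <- function(observed, positions, expected_p) {
  m <- max(length(observed), length(positions), length(expected_p))
  observed <- rep_len(observed, m); positions <- rep_len(positions, m)
  expected_p <- rep_len(expected_p, m)
  pk_assert(all(observed >= 0 & observed <= positions),
            "need 0 <= observed <= positions")
  pk_assert(all(expected_p > 0 & expected_p < 1),
            "expected_p must be in (0, 1)")
  pbinom(observed - 1, positions, expected_p, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Standard step-up adjustment with enforced monotonicity, capped at 1.
#' The multiple-testing family is all pentamers within one
#' (region, direction) stratum.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return q-values of the same length.
#' @export
bh_adjust <- function(p) {
  pk_assert(all(is.finite(p) & p >= 0 & p <= 1), "p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

ALL_PENTAMERS <- sort(apply(expand.grid(rep(list(c("A", "C", "G", "T")), 5),
                                        stringsAsFactors = FALSE),
                            1, paste, collapse = ""))

#' Pentamer enrichment within region strata
#'
#' The workhorse behind [enrich()]: takes labeled region sequences for
#' one direction, GC-bins them per region label, fits a per-bin Markov
#' background (self-background: the stratum's own sequences), pools the
#' expected probability across bins as a positions-weighted mean, applies
#' the one-sided binomial test to every pentamer and BH-adjusts within
#' the stratum.
#'
#' @param regions Data frame with at least `region` and `seq` columns
#'   (e.g. from [extract_regions_all()]).
#' @param k Word size (pentamers by default).
#' @param n_bins GC bins per region label.
#' @param q_cutoff Significance threshold on the BH-adjusted p-value.
#' @param pseudocount Markov smoothing constant.
#' @param background Optional data frame of control regions (same
#'   columns); when supplied, backgrounds are trained on the control
#'   sequences of each region label instead of the foreground itself.
#' @return Data frame: `region`, `kmer`, `observed`, `positions`,
#'   `expected_p`, `p_value`, `q_value`, `significant`.
#' @export
enrich_regions <- function(regions, k = 5, n_bins = 5, q_cutoff = 0.05,
                           pseudocount = 1, background = NULL) {
  pk_assert(all(c("region", "seq") %in% names(regions)),
            "regions needs 'region' and 'seq' columns")
  kmers <- if (k == 5) ALL_PENTAMERS else
    sort(apply(expand.grid(rep(list(c("A", "C", "G", "T")), k),
                           stringsAsFactors = FALSE), 1, paste, collapse = ""))
  out <- lapply(unique(regions$region), function(lab) {
    seqs <- regions$seq[regions$region == lab]
    if (is.null(background)) {
      bins <- assign_gc_bins(seqs, n_bins)
      per_bin <- lapply(sort(unique(bins)), function(b) {
        sub <- seqs[bins == b]
        ck <- count_kmers(sub, k)
        model <- fit_markov(sub, pseudocount)
        list(counts = ck$counts, positions = ck$positions,
             p = kmer_probability(model, kmers))
      })
    } else {
      bg_seqs <- background$seq[background$region == lab]
      pk_assert(length(bg_seqs) > 0,
                "no background sequences for region ", lab)
      ck <- count_kmers(seqs, k)
      model <- fit_markov(bg_seqs, pseudocount)
      per_bin <- list(list(counts = ck$counts, positions = ck$positions,
                           p = kmer_probability(model, kmers)))
    }
    positions_b <- vapply(per_bin, `[[`, numeric(1), "positions")
    total_pos <- sum(positions_b)
    observed <- Reduce(`+`, lapply(per_bin, `[[`, "counts"))[kmers]
    p_hat <- if (total_pos > 0)
      Reduce(`+`, Map(function(pb, w) pb$p * w, per_bin, positions_b)) / total_pos
    else rep(NA_real_, length(kmers))
    pv <- if (total_pos > 0)
      binomial_enrichment(observed, total_pos, pmin(pmax(p_hat, 1e-300), 1 - 1e-12))
    else rep(1, length(kmers))
    qv <- bh_adjust(pv)
    data.frame(region = lab, kmer = kmers, observed = as.integer(observed),
               positions = total_pos, expected_p = p_hat, p_value = pv,
               q_value = qv, significant = qv <= q_cutoff,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Read an RBP motif lookup table
#'
#' @param path TSV with columns `rbp` and `pentamer` (one pentamer per
#'   row; an RBP may own several pentamers and vice versa).
#' @return Validated data frame.
#' @export
read_motif_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  pk_assert(all(c("rbp", "pentamer") %in% names(tab)),
            "motif table needs 'rbp' and 'pentamer' columns")
  tab$pentamer <- toupper(tab$pentamer)
  pk_assert(all(grepl("^[ACGT]{5}$", tab$pentamer)),
            "pentamers must be 5-letter ACGT strings")
  tab
}

#' RBP pentamer-motif enrichment around differentially spliced events
#'
#' The full enrichment analysis: calls are pre-filtered at `BF >=
#' bf_cutoff`, split by delta-PSI sign into up-regulated (increased
#' inclusion) and down-regulated sets which are analyzed separately; per
#' (region, direction) stratum, [enrich_regions()] computes GC-binned
#' Markov-background binomial enrichment with BH correction; significant
#' pentamers are mapped to RBPs.
#'
#' @param calls A `psi_calls` (or classified) data frame.
#' @param events Named list of `splicing_event` objects covering the
#'   calls' event ids.
#' @param genome Named [Biostrings::DNAStringSet].
#' @param motif_table RBP lookup data frame (see [read_motif_table()]);
#'   may be `NULL` to skip RBP mapping.
#' @param bf_cutoff Bayes-factor pre-filter (inclusive, default 10).
#' @param q_cutoff BH significance threshold (default 0.05).
#' @param n_bins GC bins (default 5).
#' @param background Optional control region data frame forwarded to
#'   [enrich_regions()].
#' @return List with `enrichment` (per-stratum pentamer table with a
#'   `direction` column), `significant` (significant rows only),
#'   `rbp_summary` (per RBP and direction: significant pentamers and
#'   their total observed sites), and `shared_rbps` (RBPs significant in
#'   both directions).
#' @export
enrich <- function(calls, events, genome, motif_table = NULL,
                   bf_cutoff = 10, q_cutoff = 0.05, n_bins = 5,
                   background = NULL) {
  pk_assert(all(c("event_id", "delta_psi", "bayes_factor") %in% names(calls)),
            "calls need event_id/delta_psi/bayes_factor")
  strong <- calls[calls$bayes_factor >= bf_cutoff & calls$delta_psi != 0, ,
                  drop = FALSE]
  directions <- list(up = strong$event_id[strong$delta_psi > 0],
                     down = strong$event_id[strong$delta_psi < 0])
  enr <- list()
  for (dir in names(directions)) {
    ids <- directions[[dir]]
    if (length(ids) == 0) {
      warning("no ", dir, "-regulated events above BF cutoff; direction skipped",
              call. = FALSE)
      next
    }
    regions <- extract_regions_all(events[ids], genome)
    tab <- enrich_regions(regions, n_bins = n_bins, q_cutoff = q_cutoff,
                          background = background)
    tab$direction <- dir
    enr[[dir]] <- tab
  }
  enrichment <- do.call(rbind, enr)
  rownames(enrichment) <- NULL
  sig <- enrichment[enrichment$significant, , drop = FALSE]
  rbp_summary <- NULL; shared <- character(0)
  if (!is.null(motif_table) && !is.null(sig) && nrow(sig) > 0) {
    hits <- merge(sig, motif_table, by.x = "kmer", by.y = "pentamer")
    if (nrow(hits) > 0) {
      rbp_summary <- aggregate(observed ~ rbp + direction, data = hits, FUN = sum)
      names(rbp_summary)[names(rbp_summary) == "observed"] <- "motif_sites"
      rbp_summary$n_pentamers <- aggregate(kmer ~ rbp + direction, data = hits,
                                           FUN = function(x) length(unique(x)))$kmer
      both <- split(rbp_summary$rbp, rbp_summary$direction)
      if (length(both) == 2) shared <- sort(intersect(both[[1]], both[[2]]))
    }
  }
  list(enrichment = enrichment, significant = sig,
       rbp_summary = rbp_summary, shared_rbps = shared)
}
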