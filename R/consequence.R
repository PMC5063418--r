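## Reading-frame consequences of intron retention.
##
## A retained intron inserts sequence into the CDS; most retained introns
## carry an in-frame stop, yielding a premature termination codon (PTC)
## and a predicted truncated protein.  A PTC lying more than `nmd_distance`
## (canonically 50) nt upstream of the last exon-exon junction of the
## edited transcript marks the transcript an NMD *candidate* - a
## prediction reported alongside the calls, never used to filter, since
## intron-retained transcripts in neurons are frequently stable.

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Build the mRNA of a transcript with one intron retained
#'
#' Exon sequences are concatenated 5'->3' in transcript orientation
#' (reverse complemented on the minus strand) with the retained intron's
#' sequence inserted in place; `retained_intron_index = 0` (or `NA`)
#' returns the normally spliced mRNA.
#'
#' @param model A `transcript_model` (see [read_annotation()]).
#' @param genome Named [Biostrings::DNAStringSet].
#' @param retained_intron_index Index of the intron (1 = between exons 1
#'   and 2 in transcript order) to retain, or 0 for none.
#' @return The mRNA sequence as a character scalar.
#' @export
splice_with_retention <- function(model, genome, retained_intron_index = 0) {
  pk_assert(inherits(model, "transcript_model"), "not a transcript_model")
  n_ex <- nrow(model$exons)
  n_in <- n_ex - 1L
  idx <- retained_intron_index
  if (is.na(idx)) idx <- 0
  pk_assert(idx >= 0 && idx <= n_in,
            sprintf("retained_intron_index %s out of range (transcript has %d introns)",
                    format(retained_intron_index), n_in))
  exon_seq <- function(i)
    fetch_sequence(genome, genomic_interval(model$chrom, model$exons$start[i],
                                            model$exons$end[i], model$strand))
  intron_iv <- function(i) {
    if (model$strand == "+")
      genomic_interval(model$chrom, model$exons$end[i], model$exons$start[i + 1], "+")
    else
      genomic_interval(model$chrom, model$exons$end[i + 1], model$exons$start[i], "-")
  }
  pieces <- character(0)
  for (i in seq_len(n_ex)) {
    pieces <- c(pieces, exon_seq(i))
    if (i == idx) pieces <- c(pieces, fetch_sequence(genome, intron_iv(i)))
  }
  paste(pieces, collapse = "")
}

## intron length of transcript intron i (transcript order)
.intron_length <- function(model, i) {
  if (model$strand == "+")
    model$exons$start[i + 1] - model$exons$end[i]
  else
    model$exons$start[i] - model$exons$end[i + 1]
}

#' Scan a retention-edited mRNA for reading-frame consequences
#'
#' Translation starts at `cds_start` (transcript-relative, 1-based) and
#' walks codons until the first stop (`TAA`/`TAG`/`TGA`).  A stop at a
#' codon index at or before the reference protein length is a premature
#' termination codon.  The NMD-candidate rule compares the PTC position
#' (last nt of the stop codon) with the last exon-exon junction of the
#' edited transcript: more than `nmd_distance` nt upstream flags a
#' candidate.
#'
#' @param mrna Edited mRNA sequence (character scalar).
#' @param cds_start 1-based transcript position of the first coding base.
#' @param reference_protein_length Amino acids of the unedited protein
#'   (stop codon excluded).
#' @param last_junction_pos 1-based transcript position of the last nt
#'   before the final exon-exon junction of the edited transcript (`NA`
#'   if the edited transcript has a single exonic block).
#' @param intron_length Length of the retained intron (used for the
#'   frame-preservation call); `NA` if unknown.
#' @param nmd_distance PTC-to-last-junction distance threshold (nt).
#' @return A `consequence_call`: list with `ptc_present`,
#'   `ptc_codon_index`, `truncated_protein_length`, `lost_cterm_length`,
#'   `frame_preserving`, `nmd_candidate`, `stop_codon_index` (first stop,
#'   premature or not).
#' @export
scan_consequence <- function(mrna, cds_start, reference_protein_length,
                             last_junction_pos = NA, intron_length = NA,
                             nmd_distance = 50) {
  pk_assert(is.character(mrna) && length(mrna) == 1, "mrna must be a string")
  pk_assert(cds_start >= 1 && cds_start <= nchar(mrna),
            "cds_start outside the mRNA")
  n_codons <- (nchar(mrna) - cds_start + 1) %/% 3
  stop_idx <- NA_integer_
  for (i in seq_len(n_codons)) {
    codon <- substr(mrna, cds_start + 3 * (i - 1), cds_start + 3 * i - 1)
    if (codon %in% STOP_CODONS) { stop_idx <- i; break }
  }
  ## reference stop sits at codon reference_protein_length + 1
  ptc <- !is.na(stop_idx) && stop_idx <= reference_protein_length
  trunc_len <- if (ptc) stop_idx - 1L else NA_integer_
  lost <- if (ptc) reference_protein_length - trunc_len else NA_integer_
  frame_preserving <- !ptc && !is.na(intron_length) && intron_length %% 3 == 0
  nmd <- FALSE
  if (ptc && !is.na(last_junction_pos)) {
    ptc_end_nt <- cds_start + 3 * stop_idx - 1
    nmd <- (last_junction_pos - ptc_end_nt) > nmd_distance
  }
  structure(list(ptc_present = ptc,
                 ptc_codon_index = if (ptc) stop_idx else NA_integer_,
                 truncated_protein_length = trunc_len,
                 lost_cterm_length = lost,
                 frame_preserving = frame_preserving,
                 nmd_candidate = nmd,
                 stop_codon_index = stop_idx),
            class = "consequence_call")
}

#' Annotate group-3 (intron retained upon depletion) events
#'
#' Maps each G3 call to a transcript model whose adjacent exon pair
#' matches the event's retained intron exactly, rebuilds the
#' retention-edited mRNA and runs [scan_consequence()].  When several
#' transcripts match, the one with the longest CDS is used.  A retained
#' intron downstream of the reference stop codon is reported as UTR
#' retention (`ptc_present = FALSE`, `utr_retention = TRUE`).
#'
#' @param calls Classified calls data frame; rows with
#'   `group == "G3_intron_retained_on_depletion"` are annotated.
#' @param annotation Named list of `transcript_model`s.
#' @param genome Named [Biostrings::DNAStringSet].
#' @param events Named list of `splicing_event`s covering the calls.
#' @param nmd_distance NMD rule threshold in nt (default 50).
#' @return Data frame, one row per annotated (event, transcript) pair:
#'   event/transcript ids, intron index, `ptc_present`,
#'   `ptc_codon_index`, `truncated_protein_length`, `lost_cterm_length`,
#'   `frame_preserving`, `nmd_candidate`, `utr_retention`.
#' @export
annotate_group3 <- function(calls, annotation, genome, events,
                            nmd_distance = 50) {
  g3 <- calls[!is.na(calls$group) &
                calls$group == "G3_intron_retained_on_depletion", ,
              drop = FALSE]
  empty <- data.frame(event_id = character(0), transcript_id = character(0),
                      intron_index = integer(0), ptc_present = logical(0),
                      ptc_codon_index = integer(0),
                      truncated_protein_length = integer(0),
                      lost_cterm_length = integer(0),
                      frame_preserving = logical(0), nmd_candidate = logical(0),
                      utr_retention = logical(0), stringsAsFactors = FALSE)
  if (nrow(g3) == 0) return(empty)
  rows <- lapply(g3$event_id, function(id) {
    ev <- events[[id]]
    if (is.null(ev)) {
      warning("event '", id, "' not found among parsed events; skipped",
              call. = FALSE)
      return(NULL)
    }
    target <- c(ev$introns$start[1], ev$introns$end[1])
    ## transcripts with an intron exactly matching the retained one
    hits <- list()
    for (model in annotation) {
      if (model$chrom != ev$chrom || model$strand != ev$strand) next
      for (i in seq_len(max(nrow(model$exons) - 1, 0))) {
        s <- if (model$strand == "+") model$exons$end[i] else model$exons$end[i + 1]
        e <- if (model$strand == "+") model$exons$start[i + 1] else model$exons$start[i]
        if (s == target[1] && e == target[2])
          hits[[length(hits) + 1L]] <- list(model = model, intron = i)
      }
    }
    hits <- Filter(function(h) !is.na(h$model$cds_start), hits)
    if (length(hits) == 0) {
      warning("event '", id, "' maps to no CDS-bearing transcript; skipped",
              call. = FALSE)
      return(NULL)
    }
    cds_len <- vapply(hits, function(h) h$model$cds_end - h$model$cds_start + 1,
                      numeric(1))
    hit <- hits[[which.max(cds_len)]]
    model <- hit$model; idx <- hit$intron
    ref_protein_len <- as.integer((model$cds_end - model$cds_start + 1) / 3) - 1L
    mrna <- splice_with_retention(model, genome, idx)
    ilen <- .intron_length(model, idx)
    ## transcript position where the retained intron begins (1-based)
    exon_lens <- model$exons$end - model$exons$start
    intron_tx_start <- sum(exon_lens[seq_len(idx)]) + 1
    ## positions downstream of the intron shift by its length
    shift_after <- function(pos) if (pos >= intron_tx_start) pos + ilen else pos
    ref_stop_end <- model$cds_start + 3 * (ref_protein_len + 1) - 1
    utr <- intron_tx_start > ref_stop_end
    ## junctions of the edited transcript: all exon-exon junctions except
    ## the retained one, positions shifted past the intron
    junctions <- cumsum(exon_lens)[seq_len(nrow(model$exons) - 1)]
    junctions <- junctions[seq_along(junctions) != idx]
    junctions <- vapply(junctions, shift_after, numeric(1))
    last_junction <- if (length(junctions)) max(junctions) else NA_real_
    cons <- scan_consequence(mrna, model$cds_start, ref_protein_len,
                             last_junction_pos = last_junction,
                             intron_length = ilen, nmd_distance = nmd_distance)
    data.frame(event_id = id, transcript_id = model$id, intron_index = idx,
               ptc_present = cons$ptc_present && !utr,
               ptc_codon_index = if (utr) NA_integer_ else cons$ptc_codon_index,
               truncated_protein_length =
                 if (utr) NA_integer_ else cons$truncated_protein_length,
               lost_cterm_length = if (utr) NA_integer_ else cons$lost_cterm_length,
               frame_preserving = cons$frame_preserving,
               nmd_candidate = cons$nmd_candidate && !utr,
               utr_retention = utr, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(empty)
  rownames(out) <- NULL
  attr(out, "ptc_fraction") <- mean(out$ptc_present)
  out
}
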