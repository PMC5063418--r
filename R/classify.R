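## Threshold classification of called events.
##
## PSI orientation: for SE events PSI is the cassette-inclusion fraction;
## for RI events PSI is the spliced (intron-removed) fraction, so that
## intron retention upon depletion gives delta_psi < 0.  delta_psi is
## always depleted minus control.  The four groups:
##   G1  SE, delta < 0   exon skipped upon depletion
##   G2  SE, delta > 0   exon retained upon depletion
##   G3  RI, delta < 0   intron retained upon depletion
##   G4  RI, delta > 0   intron retained at normal SMN levels
##                       (intron spliced out more upon depletion)

GROUP_LEVELS <- c("G1_exon_skipped_on_depletion",
                  "G2_exon_retained_on_depletion",
                  "G3_intron_retained_on_depletion",
                  "G4_intron_retained_at_normal_smn")

#' Assign a called event to one of the four regulatory groups
#'
#' @param event_type `"SE"` or `"RI"` (vectorized).
#' @param delta_psi Depleted-minus-control PSI difference in `[-1, 1]`.
#' @return Character vector of group labels; events with `delta_psi == 0`
#'   get `"unchanged"`.
#' @examples
#' assign_group("SE", -0.73)  # G1: exon skipped upon depletion
#' assign_group("RI", -0.37)  # G3: intron retained upon depletion
#' @export
assign_group <- function(event_type, delta_psi) {
  m <- max(length(event_type), length(delta_psi))
  event_type <- rep_len(event_type, m); delta_psi <- rep_len(delta_psi, m)
  pk_assert(all(event_type %in% c("SE", "RI")), "event_type must be SE or RI")
  pk_assert(all(is.finite(delta_psi) & delta_psi >= -1 & delta_psi <= 1),
            "delta_psi must lie in [-1, 1]")
  out <- rep("unchanged", m)
  out[event_type == "SE" & delta_psi < 0] <- GROUP_LEVELS[1L]
  out[event_type == "SE" & delta_psi > 0] <- GROUP_LEVELS[2L]
  out[event_type == "RI" & delta_psi < 0] <- GROUP_LEVELS[3L]
  out[event_type == "RI" & delta_psi > 0] <- GROUP_LEVELS[4L]
  out
}

#' Discovery filter: keep events with Bayes factor at or above a cutoff
#'
#' The boundary is inclusive (`BF >= cutoff`), matching the use of BF = 5
#' as a discovery cutoff.
#'
#' @param calls A `psi_calls` data frame (needs a `bayes_factor` column).
#' @param bf_cutoff Cutoff, default 5.
#' @return The kept subset, with attribute `n_discovered`.
#' @export
filter_discovery <- function(calls, bf_cutoff = 5) {
  pk_assert("bayes_factor" %in% names(calls), "calls lack bayes_factor")
  pk_assert(is.numeric(bf_cutoff) && bf_cutoff > 0, "bf_cutoff must be > 0")
  keep <- calls[calls$bayes_factor >= bf_cutoff, , drop = FALSE]
  rownames(keep) <- NULL
  attr(keep, "n_discovered") <- nrow(keep)
  keep
}

#' Validation filter applied to individual calls
#'
#' Candidates suitable for wet-lab validation: SE events need
#' `|delta_psi| > 0.5` and `BF > 10` (strict, "greater than"); RI events
#' need `BF > 5`.  RI candidates are conventionally ranked by
#' `|delta_psi|` afterwards.  An optional q-value predicate (`q <=
#' fdr_cutoff`) can be enabled when the calls carry an FDR column; it is
#' off by default.
#'
#' @param calls A `psi_calls` data frame (or any data frame with
#'   `event_type`, `delta_psi`, `bayes_factor`).
#' @param fdr_cutoff Optional FDR threshold applied to a `q_value` column
#'   when non-`NULL`.
#' @return Logical vector, one element per call.
#' @export
filter_validation <- function(calls, fdr_cutoff = NULL) {
  need <- c("event_type", "delta_psi", "bayes_factor")
  pk_assert(all(need %in% names(calls)),
            "calls need event_type/delta_psi/bayes_factor")
  ok <- ifelse(calls$event_type == "SE",
               abs(calls$delta_psi) > 0.5 & calls$bayes_factor > 10,
               calls$bayes_factor > 5)
  if (!is.null(fdr_cutoff)) {
    pk_assert("q_value" %in% names(calls),
              "fdr_cutoff given but calls lack a q_value column")
    ok <- ok & calls$q_value <= fdr_cutoff
  }
  ok
}

#' Flag events whose intron is in a U12 (minor spliceosome) interval list
#'
#' Membership is an exact interval match on (chrom, intron start, intron
#' end, strand) against the supplied list (e.g. a U12 database export).
#'
#' @param events List of `splicing_event` objects.
#' @param u12_introns Data frame with `chrom`, `start`, `end`, `strand`
#'   in internal 0-based half-open coordinates (see [read_bed()]).
#' @return Data frame with `event_id` and logical `is_u12`.
#' @export
flag_u12 <- function(events, u12_introns) {
  keyify <- function(chrom, start, end, strand)
    paste(chrom, start, end, strand, sep = "|")
  u12_keys <- if (is.null(u12_introns) || nrow(u12_introns) == 0) character(0)
              else keyify(u12_introns$chrom, u12_introns$start,
                          u12_introns$end, u12_introns$strand)
  rows <- lapply(events, function(ev) {
    pk_assert(inherits(ev, "splicing_event"), "events must be splicing_event objects")
    hit <- any(keyify(ev$chrom, ev$introns$start, ev$introns$end, ev$strand)
               %in% u12_keys)
    data.frame(event_id = ev$event_id, is_u12 = hit, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(event_id = character(0), is_u12 = logical(0))
  rownames(out) <- NULL
  out
}

#' Classify called events: groups, validation flag, U12 membership
#'
#' Convenience wrapper combining [filter_discovery()], [assign_group()],
#' [filter_validation()] and [flag_u12()] into one annotated table.
#'
#' @param calls A `psi_calls` data frame.
#' @param events Optional named list of `splicing_event` objects (needed
#'   for U12 flagging).
#' @param u12_introns Optional U12 interval data frame (see [flag_u12()]).
#' @param bf_discovery Discovery Bayes-factor cutoff (inclusive).
#' @return The discovery-filtered calls with added `group`,
#'   `passes_validation` and `is_u12` columns; attribute `summary` holds
#'   per-group counts.
#' @export
classify_events <- function(calls, events = NULL, u12_introns = NULL,
                            bf_discovery = 5) {
  kept <- filter_discovery(calls, bf_discovery)
  kept$group <- if (nrow(kept)) assign_group(kept$event_type, kept$delta_psi)
                else character(0)
  kept$passes_validation <- if (nrow(kept)) filter_validation(kept) else logical(0)
  kept$is_u12 <- FALSE
  if (!is.null(events) && !is.null(u12_introns) && nrow(kept)) {
    fl <- flag_u12(events[intersect(names(events), kept$event_id)], u12_introns)
    kept$is_u12 <- fl$is_u12[match(kept$event_id, fl$event_id)]
    kept$is_u12[is.na(kept$is_u12)] <- FALSE
  }
  counts <- table(factor(kept$group, levels = c(GROUP_LEVELS, "unchanged")))
  attr(kept, "summary") <- list(
    n_discovered = nrow(kept),
    n_validation = sum(kept$passes_validation),
    n_u12 = sum(kept$is_u12),
    per_group = as.list(counts))
  kept
}
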