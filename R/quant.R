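## qPCR and densitometry arithmetic.

#' Relative expression by the delta-delta-Ct method
#'
#' Replicate Ct values are averaged on the Ct scale within each
#' (condition, gene); `dCt = Ct_target - Ct_reference` per condition,
#' `ddCt = dCt_condition - dCt_control`, and the fold change is
#' `2^(-ddCt)`.  The control condition's fold is identically 1, and the
#' result is invariant to adding a constant to every Ct (machine
#' offsets cancel).
#'
#' @param ct_table Data frame with columns `sample`, `condition`, `gene`,
#'   `ct` (finite cycle thresholds).
#' @param target Target gene name.
#' @param reference Internal reference gene (e.g. a 5S or 18S rRNA
#'   assay), which must be present in every condition.
#' @param control_condition Condition whose fold is set to 1.
#' @return Data frame with `condition`, `delta_ct`, `delta_delta_ct`,
#'   `fold`.
#' @examples
#' tab <- data.frame(sample = c("s1", "s1", "s2", "s2"),
#'                   condition = c("control", "control", "treated", "treated"),
#'                   gene = c("TGT", "REF", "TGT", "REF"),
#'                   ct = c(24, 15, 23, 15))
#' delta_delta_ct(tab, "TGT", "REF")   # treated fold = 2
#' @export
delta_delta_ct <- function(ct_table, target, reference,
                           control_condition = "control") {
  need <- c("sample", "condition", "gene", "ct")
  pk_assert(all(need %in% names(ct_table)),
            "ct_table needs sample/condition/gene/ct columns")
  pk_assert(all(is.finite(ct_table$ct)), "Ct values must be finite")
  conditions <- unique(ct_table$condition)
  pk_assert(control_condition %in% conditions,
            "control condition '", control_condition, "' absent from table")
  mean_ct <- function(cond, gene) {
    v <- ct_table$ct[ct_table$condition == cond & ct_table$gene == gene]
    if (length(v) == 0)
      pk_stop("no Ct rows for gene '", gene, "' in condition '", cond, "'")
    mean(v)
  }
  dct <- vapply(conditions, function(cond)
    mean_ct(cond, target) - mean_ct(cond, reference), numeric(1))
  ddct <- dct - dct[[control_condition]]
  data.frame(condition = conditions, delta_ct = unname(dct),
             delta_delta_ct = unname(ddct), fold = unname(2^(-ddct)),
             stringsAsFactors = FALSE)
}

#' Isoform fraction from gel-band densitometry
#'
#' The fraction of signal in the alternative (e.g. intron-retained or
#' exon-skipped) band: `alt / (alt + canonical)`.
#'
#' @param alt_band,canonical_band Non-negative band intensities, not both
#'   zero.  Vectorized.
#' @return Fractions in `[0, 1]`.
#' @export
isoform_fraction <- function(alt_band, canonical_band) {
  m <- max(length(alt_band), length(canonical_band))
  alt_band <- rep_len(alt_band, m); canonical_band <- rep_len(canonical_band, m)
  pk_assert(all(alt_band >= 0 & canonical_band >= 0),
            "band intensities must be non-negative")
  pk_assert(all(alt_band + canonical_band > 0),
            "both band intensities are zero: fraction undefined")
  alt_band / (alt_band + canonical_band)
}
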