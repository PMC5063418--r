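## Readers and writers: FASTA (Biostrings), GTF (rtracklayer), BED6
## (rtracklayer), and the junction-count TSV schema shared by the
## simulator and the inference stage.

#' Read a genome FASTA into an indexed sequence store
#'
#' Sequences are uppercased on read; any character outside `{A,C,G,T,N}`
#' is rejected.
#'
#' @param path FASTA file.
#' @return A named [Biostrings::DNAStringSet].
#' @export
read_genome <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  g <- Biostrings::DNAStringSet(toupper(as.character(g)))
  af <- Biostrings::alphabetFrequency(g)
  bad <- rowSums(af) - rowSums(af[, c("A", "C", "G", "T", "N"), drop = FALSE])
  if (any(bad > 0))
    pk_stop("genome contains characters outside {A,C,G,T,N} in: ",
            paste(names(g)[bad > 0], collapse = ", "))
  g
}

#' Fetch the transcript-oriented sequence of an interval
#'
#' Returns the plus-strand substring for `+` intervals and its reverse
#' complement for `-` intervals, always uppercase, with
#' `nchar(result) == end - start`.
#'
#' @param genome A named [Biostrings::DNAStringSet] (see [read_genome()]).
#' @param interval A [genomic_interval()].
#' @return A character scalar.
#' @export
fetch_sequence <- function(genome, interval) {
  pk_assert(inherits(interval, "genomic_interval"), "not a genomic_interval")
  if (!interval$chrom %in% names(genome))
    pk_stop(sprintf("unknown chromosome '%s'", interval$chrom))
  len <- length(genome[[interval$chrom]])
  if (interval$end > len)
    pk_stop(sprintf("interval [%d,%d) out of bounds on %s (length %d)",
                    interval$start, interval$end, interval$chrom, len))
  s <- Biostrings::subseq(genome[[interval$chrom]],
                          start = interval$start + 1, end = interval$end)
  if (interval$strand == "-") s <- Biostrings::reverseComplement(s)
  as.character(s)
}

#' Read transcript models from a GTF annotation
#'
#' GTF coordinates (1-based inclusive) are converted to internal 0-based
#' half-open.  Exons are ordered 5'->3' in transcript orientation; CDS
#' features, when present, are mapped to transcript-relative 1-based
#' positions `cds_start`..`cds_end` (first to last coding base, including
#' the stop codon when the GTF covers it).
#'
#' @param path GTF file with `exon` (and optionally `CDS`) features
#'   carrying `gene_id` and `transcript_id` attributes.
#' @return A named list of `transcript_model` objects: `id`, `gene`,
#'   `chrom`, `strand`, `exons` (0-based half-open data frame in
#'   transcript order), `cds_start`, `cds_end` (NA for non-coding).
#' @export
read_annotation <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  df <- as.data.frame(gr)
  df <- df[df$type %in% c("exon", "CDS"), , drop = FALSE]
  pk_assert(nrow(df) > 0, "annotation contains no exon features")
  pk_assert(!is.null(df$transcript_id), "GTF lacks transcript_id attributes")
  out <- list()
  for (tx in unique(df$transcript_id[df$type == "exon"])) {
    sub <- df[df$transcript_id == tx & df$type == "exon", , drop = FALSE]
    strand <- as.character(sub$strand[1L])
    pk_assert(strand %in% c("+", "-"), "transcript has undefined strand: ", tx)
    ## internal: start0 = start-1, end0 = end
    ex <- data.frame(start = sub$start - 1, end = sub$end)
    ex <- ex[order(ex$start, decreasing = (strand == "-")), , drop = FALSE]
    rownames(ex) <- NULL
    model <- structure(list(
      id = tx,
      gene = if (!is.null(sub$gene_id)) sub$gene_id[1L] else NA_character_,
      chrom = as.character(sub$seqnames[1L]),
      strand = strand, exons = ex,
      cds_start = NA_real_, cds_end = NA_real_), class = "transcript_model")
    cds <- df[df$transcript_id == tx & df$type == "CDS", , drop = FALSE]
    if (nrow(cds) > 0) {
      gstart <- min(cds$start) - 1
      gend <- max(cds$end)
      model$cds_start <- .tx_position(model, if (strand == "+") gstart else gend - 1)
      model$cds_end <- .tx_position(model, if (strand == "+") gend - 1 else gstart)
    }
    out[[tx]] <- model
  }
  out
}

## transcript-relative 1-based position of a 0-based genomic position
.tx_position <- function(model, gpos) {
  off <- 0
  for (i in seq_len(nrow(model$exons))) {
    s <- model$exons$start[i]; e <- model$exons$end[i]
    if (gpos >= s && gpos < e) {
      within <- if (model$strand == "+") gpos - s else e - 1 - gpos
      return(off + within + 1)
    }
    off <- off + (e - s)
  }
  pk_stop("genomic position not contained in any exon of ", model$id)
}

spliced_length <- function(model) sum(model$exons$end - model$exons$start)

#' Write and read BED6 region files
#'
#' `regions` uses internal 0-based half-open coordinates, which are also
#' BED's convention; the round trip through rtracklayer is the identity.
#'
#' @param regions Data frame with columns `chrom`, `start`, `end` and
#'   optionally `name`, `score`, `strand`.
#' @param path Output / input file.
#' @return `write_bed()` returns `path` invisibly; `read_bed()` a data
#'   frame with the six BED columns in internal coordinates.
#' @export
write_bed <- function(regions, path) {
  pk_assert(all(c("chrom", "start", "end") %in% names(regions)),
            "regions needs chrom/start/end columns")
  n <- nrow(regions)
  gr <- GenomicRanges::GRanges(
    seqnames = regions$chrom,
    ranges = IRanges::IRanges(start = regions$start + 1, end = regions$end),
    strand = if ("strand" %in% names(regions)) regions$strand else "*")
  gr$name <- if ("name" %in% names(regions)) regions$name else paste0("region_", seq_len(n))
  gr$score <- if ("score" %in% names(regions)) regions$score else 0
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' @rdname write_bed
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1,
             end = GenomicRanges::end(gr),
             name = if (!is.null(gr$name)) gr$name else NA_character_,
             score = if (!is.null(gr$score)) gr$score else 0,
             strand = as.character(GenomicRanges::strand(gr)),
             stringsAsFactors = FALSE)
}

#' Read or write a junction-count table
#'
#' The shared TSV schema is one row per (event, condition, replicate) with
#' non-negative integer `inclusion_reads` / `exclusion_reads`; duplicate
#' keys and negative counts are rejected.
#'
#' @param path TSV file with header
#'   `event_id condition replicate inclusion_reads exclusion_reads`.
#' @return A validated data frame.
#' @export
read_counts_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_counts_table(tab)
}

#' @rdname read_counts_table
#' @param counts A counts data frame in the same schema.
#' @export
write_counts_table <- function(counts, path) {
  validate_counts_table(counts)
  write_tsv(counts, path)
}

#' @rdname read_counts_table
#' @export
validate_counts_table <- function(counts) {
  need <- c("event_id", "condition", "replicate", "inclusion_reads",
            "exclusion_reads")
  missing <- setdiff(need, names(counts))
  pk_assert(length(missing) == 0,
            "counts table lacks columns: ", paste(missing, collapse = ", "))
  for (col in c("inclusion_reads", "exclusion_reads")) {
    v <- counts[[col]]
    pk_assert(is.numeric(v) && all(is.finite(v)) && all(v >= 0) &&
                all(v == round(v)),
              col, " must be non-negative integers")
  }
  key <- paste(counts$event_id, counts$condition, counts$replicate)
  if (anyDuplicated(key))
    pk_stop("duplicate (event, condition, replicate) rows: ",
            paste(unique(key[duplicated(key)]), collapse = "; "))
  counts
}

## deterministic TSV writers used across the pipeline
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
read_tsv <- function(path) utils::read.delim(path, stringsAsFactors = FALSE)
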