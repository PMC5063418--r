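## Coordinate conventions, genomic intervals and splicing events.
##
## Internal coordinates are always 0-based half-open [start, end) on the +
## reference strand.  Event strings and GTF are 1-based inclusive; BED is
## 0-based half-open.  Each format boundary is crossed in exactly one
## function so the conversions can be round-trip tested.

#' Construct a genomic interval
#'
#' A minimal strand-aware interval in internal 0-based half-open
#' coordinates.  `start` is 0-based inclusive, `end` is exclusive, so the
#' interval length is `end - start`.
#'
#' @param chrom Chromosome / sequence name.
#' @param start 0-based inclusive start.
#' @param end 0-based exclusive end; must satisfy `start < end`.
#' @param strand `"+"` or `"-"`.
#' @return An object of class `genomic_interval` (a named list with
#'   `chrom`, `start`, `end`, `strand`).
#' @examples
#' gi <- genomic_interval("chr1", 10, 20, "+")
#' interval_length(gi)  # 10
#' @export
genomic_interval <- function(chrom, start, end, strand) {
  pk_assert(is.character(chrom) && length(chrom) == 1L && nzchar(chrom),
            "chrom must be a non-empty string")
  start <- as.numeric(start); end <- as.numeric(end)
  pk_assert(length(start) == 1L && length(end) == 1L && is.finite(start) &&
              is.finite(end), "start/end must be single finite numbers")
  pk_assert(start >= 0 && start < end,
            sprintf("invalid interval [%s, %s): need 0 <= start < end",
                    format(start), format(end)))
  pk_assert(strand %in% c("+", "-"), "strand must be '+' or '-'")
  structure(list(chrom = chrom, start = start, end = end, strand = strand),
            class = "genomic_interval")
}

#' @rdname genomic_interval
#' @param x A `genomic_interval`.
#' @export
interval_length <- function(x) x$end - x$start

#' @export
print.genomic_interval <- function(x, ...) {
  cat(sprintf("%s:[%d,%d):%s\n", x$chrom, x$start, x$end, x$strand))
  invisible(x)
}

## split one "chrom:start:end:strand" block; printed coords are 1-based
## inclusive, converted here to internal 0-based half-open
.parse_block <- function(block) {
  parts <- strsplit(block, ":", fixed = TRUE)[[1L]]
  if (length(parts) != 4L)
    pk_stop(sprintf("malformed event block '%s': expected chrom:start:end:strand",
                    block))
  start1 <- suppressWarnings(as.numeric(parts[2L]))
  end1 <- suppressWarnings(as.numeric(parts[3L]))
  if (is.na(start1) || is.na(end1))
    pk_stop(sprintf("malformed event block '%s': non-numeric coordinates", block))
  if (!parts[4L] %in% c("+", "-"))
    pk_stop(sprintf("malformed event block '%s': bad strand '%s'", block, parts[4L]))
  if (start1 > end1)
    pk_stop(sprintf("malformed event block '%s': start > end", block))
  genomic_interval(parts[1L], start1 - 1, end1, parts[4L])
}

#' Parse a MISO-style splicing-event string
#'
#' Event identifiers are `@`-joined `chrom:start:end:strand` exon blocks
#' printed in transcript orientation with 1-based inclusive coordinates: 3
#' blocks describe a skipped-exon (SE) event (upstream exon, cassette,
#' downstream exon), 2 blocks a retained-intron (RI) event (the retained
#' intron is the gap between them).  On the `-` strand the blocks are
#' genomically descending, the first printed block being the
#' transcript-upstream (genomically rightmost) exon.
#'
#' @param event_string The event identifier.
#' @param gene Optional gene symbol carried through.
#' @return A `splicing_event`: list with `event_id`, `event_type`
#'   (`"SE"`/`"RI"`), `chrom`, `strand`, `gene`, `exons` and `introns`
#'   (data frames of 0-based half-open `start`/`end`, rows in transcript
#'   5'->3' order).
#' @seealso [event_string()] for the inverse operation.
#' @examples
#' ev <- parse_miso_event("chr3:88529917:88529990:+@chr3:88530202:88530393:+")
#' ev$event_type   # "RI"
#' ev$introns      # the retained intron, [88529990, 88530201)
#' @export
parse_miso_event <- function(event_string, gene = NA_character_) {
  pk_assert(is.character(event_string) && length(event_string) == 1L,
            "event_string must be a single string")
  blocks <- strsplit(event_string, "@", fixed = TRUE)[[1L]]
  if (!length(blocks) %in% c(2L, 3L))
    pk_stop(sprintf("event '%s': expected 2 or 3 blocks, found %d",
                    event_string, length(blocks)))
  ivs <- lapply(blocks, .parse_block)
  chrom <- ivs[[1L]]$chrom
  strand <- ivs[[1L]]$strand
  for (i in seq_along(ivs)) {
    if (ivs[[i]]$chrom != chrom)
      pk_stop(sprintf("event '%s': block %d on a different chromosome",
                      event_string, i))
    if (ivs[[i]]$strand != strand)
      pk_stop(sprintf("event '%s': block %d has a mixed strand", event_string, i))
  }
  starts <- vapply(ivs, `[[`, numeric(1), "start")
  ends <- vapply(ivs, `[[`, numeric(1), "end")
  ## transcript order == printed order; genomically ascending on +, descending on -
  for (i in seq_len(length(ivs) - 1L)) {
    gap_ok <- if (strand == "+") starts[i + 1L] >= ends[i]
              else starts[i] >= ends[i + 1L]
    if (!gap_ok)
      pk_stop(sprintf("event '%s': blocks %d and %d overlap or are out of transcript order",
                      event_string, i, i + 1L))
  }
  exons <- data.frame(start = starts, end = ends)
  introns <- data.frame(
    start = if (strand == "+") ends[-length(ends)] else ends[-1L],
    end   = if (strand == "+") starts[-1L] else starts[-length(starts)]
  )
  if (any(introns$end - introns$start < 1))
    pk_stop(sprintf("event '%s': adjacent exons leave no intron", event_string))
  structure(list(event_id = event_string,
                 event_type = if (length(ivs) == 3L) "SE" else "RI",
                 chrom = chrom, strand = strand, gene = gene,
                 exons = exons, introns = introns),
            class = "splicing_event")
}

#' Serialize a splicing event back to its MISO-style string
#'
#' Inverse of [parse_miso_event()]: internal 0-based half-open exon
#' coordinates are printed 1-based inclusive in transcript order, so that
#' `event_string(parse_miso_event(s)) == s` for every well-formed `s`.
#'
#' @param event A `splicing_event`.
#' @return The canonical event identifier string.
#' @export
event_string <- function(event) {
  pk_assert(inherits(event, "splicing_event"), "not a splicing_event")
  paste(sprintf("%s:%d:%d:%s", event$chrom,
                as.integer(event$exons$start + 1), as.integer(event$exons$end),
                event$strand),
        collapse = "@")
}

#' @export
print.splicing_event <- function(x, ...) {
  cat(sprintf("<%s event> %s\n", x$event_type, x$event_id))
  invisible(x)
}

## interval accessors in transcript order
event_exon <- function(event, i)
  genomic_interval(event$chrom, event$exons$start[i], event$exons$end[i],
                   event$strand)
event_intron <- function(event, i)
  genomic_interval(event$chrom, event$introns$start[i], event$introns$end[i],
                   event$strand)
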