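## two-exon toy gene on either strand: returns genome + transcript model
## + the literal exon/intron strings used to build it
make_toy_gene <- function(exon1, intron, exon2, strand = "+", pad = 20,
                          cds_start = NA, cds_end = NA) {
  pre <- paste0(exon1, intron, exon2)
  seg <- if (strand == "-") revcomp_oracle(pre) else pre
  chrom_seq <- paste0(random_dna(pad), seg, random_dna(pad))
  L <- nchar(pre)
  gmap <- function(a, b) if (strand == "+") c(pad + a, pad + b)
          else c(pad + L - b, pad + L - a)
  e1 <- gmap(0, nchar(exon1))
  e2 <- gmap(nchar(exon1) + nchar(intron), L)
  ex <- data.frame(start = c(e1[1], e2[1]), end = c(e1[2], e2[2]))
  ex <- ex[order(ex$start, decreasing = (strand == "-")), ]
  rownames(ex) <- NULL
  model <- structure(list(id = "toy", gene = "toy", chrom = "chrT",
                          strand = strand, exons = ex,
                          cds_start = cds_start, cds_end = cds_end),
                     class = "transcript_model")
  list(genome = Biostrings::DNAStringSet(c(chrT = chrom_seq)), model = model)
}

test_that("splice_with_retention inserts the intron in place, both strands", {
  set.seed(71)
  exon1 <- "ATGGCC"; intron <- "GTAAGTAG"; exon2 <- "TTTTAA"
  for (strand in c("+", "-")) {
    toy <- make_toy_gene(exon1, intron, exon2, strand)
    expect_identical(splice_with_retention(toy$model, toy$genome, 0),
                     paste0(exon1, exon2))
    expect_identical(splice_with_retention(toy$model, toy$genome, 1),
                     paste0(exon1, intron, exon2))
  }
  toy <- make_toy_gene(exon1, intron, exon2)
  expect_error(splice_with_retention(toy$model, toy$genome, 2), "out of range")
  ## conservation: edited length = spliced + intron, for random genes
  for (rep_i in 1:5) {
    toy <- make_toy_gene(random_dna(30), random_dna(17), random_dna(24),
                         sample(c("+", "-"), 1))
    expect_equal(nchar(splice_with_retention(toy$model, toy$genome, 1)),
                 30 + 17 + 24)
  }
})

test_that("a 3 bp retained intron lengthens the mRNA by 3", {
  toy <- make_toy_gene("ATGAAA", "AAA", "TAA")
  expect_equal(nchar(splice_with_retention(toy$model, toy$genome, 1)),
               nchar(splice_with_retention(toy$model, toy$genome, 0)) + 3)
})

test_that("scan_consequence finds PTCs, frame preservation and the NMD rule", {
  ## CDS ATG AAA TAA with intron TAGTAG retained after codon 1:
  ## edited CDS = ATG TAG TAG AAA TAA -> PTC at codon 2, 1 aa retained
  cons <- scan_consequence("ATGTAGTAGAAATAA", cds_start = 1,
                           reference_protein_length = 2,
                           intron_length = 6)
  expect_true(cons$ptc_present)
  expect_equal(cons$ptc_codon_index, 2)
  expect_equal(cons$truncated_protein_length, 1)
  expect_equal(cons$lost_cterm_length, 1)
  expect_false(cons$frame_preserving)

  ## length-9 stop-free intron: frame preserved, protein 3 aa longer
  mrna <- paste0("ATG", "AAA", "CCCCCCCCC", "GGG", "TAA")
  cons <- scan_consequence(mrna, 1, reference_protein_length = 3,
                           intron_length = 9)
  expect_false(cons$ptc_present)
  expect_true(cons$frame_preserving)
  expect_equal(cons$stop_codon_index, 3 + 3 + 1)  # ref codons + 3 + stop

  ## NMD: PTC ends at nt 6; last junction 60 nt further -> candidate,
  ## 10 nt -> not
  mrna <- paste0("ATGTAA", paste(rep("C", 200), collapse = ""))
  expect_true(scan_consequence(mrna, 1, 50, last_junction_pos = 66,
                               intron_length = 4)$nmd_candidate)
  expect_false(scan_consequence(mrna, 1, 50, last_junction_pos = 16,
                                intron_length = 4)$nmd_candidate)
  ## monotone in the distance threshold: raising it never adds candidates
  flags <- vapply(c(10, 50, 58, 59, 60, 100), function(d)
    scan_consequence(mrna, 1, 50, last_junction_pos = 66, intron_length = 4,
                     nmd_distance = d)$nmd_candidate, logical(1))
  expect_true(all(diff(as.integer(flags)) <= 0))
  expect_error(scan_consequence("ATG", 10, 5), "cds_start")
})

test_that("scan_consequence agrees with the naive codon-walk oracle", {
  set.seed(77)
  for (rep_i in 1:40) {
    mrna <- random_dna(sample(60:300, 1))
    cds_start <- sample(1:9, 1)
    ref_len <- sample(5:40, 1)
    cons <- scan_consequence(mrna, cds_start, ref_len)
    oracle_stop <- codon_walk_oracle(mrna, cds_start)
    expect_identical(cons$stop_codon_index, oracle_stop)
    expect_identical(cons$ptc_present,
                     !is.na(oracle_stop) && oracle_stop <= ref_len)
    if (cons$ptc_present)
      expect_identical(cons$truncated_protein_length, oracle_stop - 1L)
  }
})

test_that("annotate_group3 recovers generator-planted consequences", {
  cfg <- sim_config(seed = 19, n_se_events = 0, n_ri_events = 20,
                    psi_control = rep(0.9, 20), psi_depleted = rep(0.15, 20))
  sim <- simulate_genome_and_events(cfg)
  counts <- simulate_counts(sim$truth$events, cfg)
  calls <- call_events(counts)
  cl <- classify_events(calls, events = sim$events,
                        u12_introns = sim$u12_introns)
  expect_true(all(cl$group == "G3_intron_retained_on_depletion"))
  cons <- annotate_group3(cl, sim$annotation, sim$genome, sim$events)
  m <- merge(cons, sim$truth$consequences, by = "event_id")
  expect_equal(nrow(m), 20)
  expect_identical(m$ptc_present, m$true_ptc_present)
  expect_identical(m$ptc_codon_index, m$true_ptc_codon_index)
  expect_identical(m$truncated_protein_length, m$true_truncated_length)
  ## frame-preserving introns are never PTC-flagged
  expect_identical(m$frame_preserving.x, m$frame_preserving.y)
  expect_true(all(!m$ptc_present[m$frame_preserving.x]))
})

test_that("3' UTR intron retention is reported as UTR, not PTC", {
  set.seed(79)
  ## CDS lives entirely in exon 1; the intron sits in the 3' UTR
  cds <- "ATGAAACCCTAA"
  exon1 <- paste0(cds, "GGGG")
  toy <- make_toy_gene(exon1, "GTTTTAAAG", "CCCCCC", "+",
                       cds_start = 1, cds_end = nchar(cds))
  ev_str <- sprintf("chrT:%d:%d:+@chrT:%d:%d:+",
                    toy$model$exons$start[1] + 1, toy$model$exons$end[1],
                    toy$model$exons$start[2] + 1, toy$model$exons$end[2])
  ev <- parse_miso_event(ev_str)
  calls <- data.frame(event_id = ev_str, event_type = "RI",
                      delta_psi = -0.4, bayes_factor = 100,
                      group = "G3_intron_retained_on_depletion")
  cons <- annotate_group3(calls, list(toy = toy$model), toy$genome,
                          setNames(list(ev), ev_str))
  expect_equal(nrow(cons), 1)
  expect_true(cons$utr_retention)
  expect_false(cons$ptc_present)
  ## empty G3 input gives an empty frame
  empty <- annotate_group3(calls[0, , drop = FALSE], list(toy = toy$model),
                           toy$genome, list())
  expect_equal(nrow(empty), 0)
  ## unmappable events are skipped with a warning
  calls2 <- calls; calls2$event_id <- "chrT:1:5:+@chrT:9:12:+"
  ev2 <- parse_miso_event(calls2$event_id)
  expect_warning(
    out <- annotate_group3(calls2, list(toy = toy$model), toy$genome,
                           setNames(list(ev2), calls2$event_id)),
    "skipped")
  expect_equal(nrow(out), 0)
})
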