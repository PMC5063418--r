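## a genome with one plus- and one minus-strand SE event whose region
## boundaries are easy to reason about by hand
make_region_fixture <- function(exon = 200, intron = 1000, cassette = 150,
                                seed = 17) {
  set.seed(seed)
  chrom_seq <- random_dna(2 * (2 * exon + 2 * intron + cassette) + 300)
  genome <- Biostrings::DNAStringSet(c(chrF = chrom_seq))
  len <- 2 * exon + 2 * intron + cassette
  mk <- function(off, strand) {
    if (strand == "+") {
      b <- cumsum(c(off, exon, intron, cassette, intron, exon))
      sprintf("chrF:%d:%d:+@chrF:%d:%d:+@chrF:%d:%d:+",
              b[1] + 1, b[2], b[3] + 1, b[4], b[5] + 1, b[6])
    } else {
      b <- cumsum(c(off, exon, intron, cassette, intron, exon))
      sprintf("chrF:%d:%d:-@chrF:%d:%d:-@chrF:%d:%d:-",
              b[5] + 1, b[6], b[3] + 1, b[4], b[1] + 1, b[2])
    }
  }
  list(genome = genome, chrom_seq = chrom_seq,
       ev_plus = parse_miso_event(mk(100, "+")),
       ev_minus = parse_miso_event(mk(len + 200, "-")))
}

test_that("SE events split into the 7 regions at the stated window sizes", {
  fx <- make_region_fixture()
  regs <- extract_regions(fx$ev_plus, fx$genome)
  expect_equal(regs$region, c("up_exon_150", "up_intron_5p_300",
                              "up_intron_3p_300", "cassette_exon_full",
                              "down_intron_5p_300", "down_intron_3p_300",
                              "down_exon_150"))
  expect_equal(nchar(regs$seq), c(150, 300, 300, 150, 300, 300, 150))
  ## plus strand: regions are literal substrings of the chromosome
  expect_identical(regs$seq[1], substr(fx$chrom_seq, 151, 300))
  expect_identical(regs$seq[2], substr(fx$chrom_seq, 301, 600))
  expect_identical(regs$seq[3], substr(fx$chrom_seq, 1001, 1300))
  expect_identical(regs$seq[4], substr(fx$chrom_seq, 1301, 1450))
})

test_that("short introns contribute disjoint halves; short exons truncate", {
  ev <- parse_miso_event("chr1:101:300:+@chr1:701:850:+@chr1:1251:1450:+")
  ## introns are 400 bp -> two windows of 200 + 200
  set.seed(3)
  genome <- Biostrings::DNAStringSet(c(chr1 = random_dna(1500)))
  regs <- extract_regions(ev, genome)
  expect_equal(nchar(regs$seq), c(150, 200, 200, 150, 200, 200, 150))
  ## the two halves are disjoint and cover the whole intron
  expect_identical(paste0(regs$seq[2], regs$seq[3]),
                   fetch_sequence(genome, genomic_interval("chr1", 300, 700, "+")))
  ## exon shorter than 150 is used whole
  ev2 <- parse_miso_event("chr1:101:150:+@chr1:701:850:+@chr1:1251:1450:+")
  regs2 <- extract_regions(ev2, genome)
  expect_equal(nchar(regs2$seq[1]), 50)
})

test_that("minus-strand regions equal the brute-force strand oracle", {
  fx <- make_region_fixture()
  regs <- extract_regions(fx$ev_minus, fx$genome)
  expect_equal(nchar(regs$seq), c(150, 300, 300, 150, 300, 300, 150))
  ## upstream exon is genomically rightmost; its transcript-3' 150 bp are
  ## the genomically leftmost 150 bp of that exon, reverse complemented
  e1 <- fx$ev_minus$exons[1, ]
  expect_identical(regs$seq[regs$region == "up_exon_150"],
                   revcomp_oracle(substr(fx$chrom_seq, e1$start + 1,
                                         e1$start + 150)))
  ## upstream intron transcript-5' window: genomically rightmost 300 bp
  i1 <- fx$ev_minus$introns[1, ]
  expect_identical(regs$seq[regs$region == "up_intron_5p_300"],
                   revcomp_oracle(substr(fx$chrom_seq, i1$end - 300 + 1,
                                         i1$end)))
  ## RI events give the 4-region partition
  ri <- parse_miso_event("chrF:201:400:+@chrF:1401:1600:+")
  regs_ri <- extract_regions(ri, fx$genome)
  expect_equal(regs_ri$region, c("up_exon_150", "intron_5p_300",
                                 "intron_3p_300", "down_exon_150"))
})

test_that("GC binning yields equal-occupancy quantile bins with sane collapse", {
  seqs <- vapply(1:10 / 10, function(gc)
    paste(c(rep("G", round(100 * gc)), rep("A", 100 - round(100 * gc))),
          collapse = ""), character(1))
  bins <- assign_gc_bins(seqs, 5)
  expect_equal(unname(table(bins)), rep(2L, 5), ignore_attr = TRUE)
  expect_true(all(diff(bins[order(gc_fraction(seqs))]) >= 0))
  ## identical GC -> one bin
  expect_message(b1 <- assign_gc_bins(rep("ACGT", 8), 5), "single bin")
  expect_equal(b1, rep(1L, 8))
  ## fewer sequences than bins -> as many bins as sequences
  b2 <- assign_gc_bins(c("AAAA", "GGCC", "GAAA"), 5)
  expect_equal(length(unique(b2)), 3)
})

test_that("first-order Markov background reproduces direct count arithmetic", {
  ## training on 100 A's: 99 AA pairs; add-1 smoothing over 4 successors
  m <- fit_markov(paste(rep("A", 100), collapse = ""))
  expect_equal(m$transition["A", "A"], 100 / 103)
  expect_equal(m$transition["A", "C"], 1 / 103)
  expect_equal(unname(m$initial["A"]), 101 / 104)
  expect_equal(kmer_probability(m, "AAAAA"),
               (101 / 104) * (100 / 103)^4)
  ## every transition row and the initial distribution are normalized
  expect_equal(rowSums(m$transition), rep(1, 4), ignore_attr = TRUE)
  expect_equal(sum(m$initial), 1)
  expect_error(fit_markov(character(0)), "training")
})

test_that("uniform model: P(pentamer) = 1/1024 and probabilities sum to 1", {
  uniform <- structure(list(
    initial = setNames(rep(0.25, 4), c("A", "C", "G", "T")),
    transition = matrix(0.25, 4, 4, dimnames = list(c("A", "C", "G", "T"),
                                                    c("A", "C", "G", "T"))),
    n_train = 0, pseudocount = 0), class = "markov_background")
  expect_equal(kmer_probability(uniform, "ACGTA"), 4^-5)
  expect_equal(kmer_probability(uniform, "AAAAA"), 1 / 1024)
  ## normalization holds for any fitted model too
  set.seed(8)
  m <- fit_markov(replicate(5, random_dna(200)))
  kmers <- psikit:::ALL_PENTAMERS
  expect_equal(sum(kmer_probability(uniform, kmers)), 1, tolerance = 1e-12)
  expect_equal(sum(kmer_probability(m, kmers)), 1, tolerance = 1e-12)
})

test_that("k-mer counting uses overlapping windows and skips N windows", {
  ck <- count_kmers("ACGTACGT")
  expect_equal(ck$positions, 4)
  expect_equal(unname(ck$counts[c("ACGTA", "CGTAC", "GTACG", "TACGT")]),
               rep(1, 4))
  expect_equal(sum(ck$counts), 4)
  expect_equal(unname(count_kmers("AAAAAA")$counts["AAAAA"]), 2)
  ## N windows drop from numerator and denominator alike
  withN <- count_kmers("ACGTNACGTACGT")
  oracle <- count_kmers_oracle("ACGTNACGTACGT")
  expect_equal(withN$positions, oracle$positions)
  expect_equal(withN$counts[names(oracle$counts)], oracle$counts,
               ignore_attr = TRUE)
  ## random cross-check against the naive counter
  set.seed(21)
  seqs <- replicate(4, random_dna(60))
  a <- count_kmers(seqs); b <- count_kmers_oracle(seqs)
  expect_equal(a$positions, b$positions)
  expect_equal(a$counts[names(b$counts)], b$counts, ignore_attr = TRUE)
})

test_that("binomial enrichment is an exact upper tail, monotone in observed", {
  expect_equal(binomial_enrichment(0, 10, 0.3), 1)
  expect_equal(binomial_enrichment(10, 10, 0.5), 2^-10)
  ## P(X >= 2), X ~ Bin(10, 0.01): 1 - P(0) - P(1)
  expect_equal(binomial_enrichment(2, 10, 0.01),
               1 - 0.99^10 - 10 * 0.01 * 0.99^9)
  p <- binomial_enrichment(0:20, 20, 0.2)
  expect_true(all(diff(p) < 0))
  expect_error(binomial_enrichment(5, 3, 0.5), "observed <= positions")
  expect_error(binomial_enrichment(1, 3, 1.5), "\\(0, 1\\)")
})

test_that("BH adjustment matches the brute-force step-up oracle", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  set.seed(33)
  for (rep_i in 1:20) {
    p <- runif(sample(1:12, 1))
    expect_equal(bh_adjust(p), bh_oracle(p))
  }
  expect_error(bh_adjust(c(0.2, 1.4)), "\\[0, 1\\]")
})

test_that("a planted pentamer is recovered as the top enriched motif", {
  set.seed(55)
  seqs <- replicate(100, random_dna(300))
  planted <- plant_motifs(seqs, "GCATG", fold = 5, gc_content = 0.5,
                          seed = 56)
  regions <- data.frame(region = "up_intron_3p_300", seq = planted$seqs)
  res <- enrich_regions(regions)
  hit <- res[res$kmer == "GCATG", ]
  expect_lte(hit$q_value, 0.05)
  expect_equal(res$kmer[which.min(res$p_value)], "GCATG")
  ## conservation: expected counts over all pentamers = scanned positions
  expect_equal(sum(res$positions[1] * res$expected_p), res$positions[1],
               tolerance = 1e-9)
})

test_that("enrich ties strata together and finds shared RBPs", {
  set.seed(60)
  cfg <- sim_config(seed = 21, n_se_events = 10, n_ri_events = 0,
                    psi_control = rep(c(0.2, 0.8), 5),
                    psi_depleted = rep(c(0.8, 0.2), 5),
                    planted_motif = "GCATG", plant_fold = 8)
  sim <- simulate_genome_and_events(cfg)
  counts <- simulate_counts(sim$truth$events, cfg)
  calls <- call_events(counts)
  motifs <- data.frame(rbp = c("RBP_A", "RBP_B"),
                       pentamer = c("GCATG", "TTTTT"))
  res <- enrich(calls, sim$events, sim$genome, motif_table = motifs,
                bf_cutoff = 10)
  expect_true(all(c("up", "down") %in% res$enrichment$direction))
  ## the motif was planted in every SE event's designated region, so both
  ## directions should report it and RBP_A is shared
  sig_regions <- res$significant[res$significant$kmer == "GCATG", ]
  expect_true(nrow(sig_regions) >= 1)
  expect_true("RBP_A" %in% res$rbp_summary$rbp)
  ## empty direction warns and is skipped
  one_sided <- calls[calls$delta_psi > 0, , drop = FALSE]
  expect_warning(enrich(one_sided, sim$events, sim$genome,
                        motif_table = motifs, bf_cutoff = 10),
                 "skipped")
})
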