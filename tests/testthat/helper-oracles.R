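## Independent oracles and shared fixtures.  Every oracle here is a
## deliberately naive implementation, kept free of the package's own
## code paths.

## the packaged corpus of published SE/RI events (144 rows)
load_event_corpus <- function() {
  path <- system.file("extdata", "smn_event_tables.tsv", package = "psikit")
  utils::read.delim(path, stringsAsFactors = FALSE)
}

## brute-force Benjamini-Hochberg step-up with monotonicity enforcement
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  q_sorted <- p[o] * n / seq_len(n)
  for (i in seq(n - 1, 1, length.out = max(n - 1, 0)))
    q_sorted[i] <- min(q_sorted[i], q_sorted[i + 1])
  q <- numeric(n)
  q[o] <- pmin(q_sorted, 1)
  q
}

## naive codon walk: first stop codon index from position cds_start
codon_walk_oracle <- function(mrna, cds_start) {
  chars <- strsplit(mrna, "")[[1]]
  i <- cds_start
  idx <- 0L
  while (i + 2 <= length(chars)) {
    idx <- idx + 1L
    codon <- paste(chars[i:(i + 2)], collapse = "")
    if (codon %in% c("TAA", "TAG", "TGA")) return(idx)
    i <- i + 3
  }
  NA_integer_
}

## character-level reverse complement, independent of Biostrings
revcomp_oracle <- function(s) {
  map <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(map[strsplit(s, "")[[1]]]), collapse = "")
}

## naive overlapping k-mer counter (N windows dropped)
count_kmers_oracle <- function(seqs, k = 5) {
  counts <- new.env()
  positions <- 0L
  for (s in seqs) {
    if (nchar(s) < k) next
    for (i in seq_len(nchar(s) - k + 1)) {
      w <- substr(s, i, i + k - 1)
      if (grepl("N", w, fixed = TRUE)) next
      positions <- positions + 1L
      counts[[w]] <- (if (is.null(counts[[w]])) 0L else counts[[w]]) + 1L
    }
  }
  list(counts = unlist(as.list(counts)), positions = positions)
}

## numerical-integration oracle for the Bayes factor: log of
## integral(theta^a (1-theta)^b dtheta) by adaptive quadrature
log_beta_integral_oracle <- function(a, b) {
  log(stats::integrate(function(t) t^a * (1 - t)^b, 0, 1,
                       rel.tol = 1e-10, abs.tol = 0)$value)
}

bf_integration_oracle <- function(k_c, n_c, k_d, n_d) {
  exp(log_beta_integral_oracle(k_c, n_c - k_c) +
        log_beta_integral_oracle(k_d, n_d - k_d) -
        log_beta_integral_oracle(k_c + k_d, n_c + n_d - k_c - k_d))
}

## random ACGT string via base R only
random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")
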