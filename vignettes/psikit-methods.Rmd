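---
title: "psikit: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{psikit: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psikit)
```

psikit analyzes condition-dependent alternative splicing — the kind of
dataset produced when a splicing-relevant factor such as SMN (the survival
motor neuron protein, whose deficiency causes spinal muscular atrophy) is
depleted in a neuronal cell line and transcriptomes are sequenced in
control and depleted conditions with a few biological replicates.  This
vignette explains the models the package implements, the defaults it
ships, and what its synthetic-data tests do and do not establish.

## Events and coordinates

Two event classes are modeled.  A skipped-exon (SE) event is an exon trio
(upstream exon, cassette, downstream exon); a retained-intron (RI) event
is an exon pair around one intron.  Events are identified by `@`-joined
`chrom:start:end:strand` blocks printed 1-based inclusive in transcript
orientation (on the minus strand the blocks descend genomically).
Internally every interval is 0-based half-open; GTF input (1-based
inclusive) and BED output (0-based half-open) each cross that boundary in
exactly one reader/writer, and round-trip identity on both conversions is
tested.  Sequences are uppercased on read and restricted to
`{A,C,G,T,N}`; k-mer windows containing N are dropped from both the
numerator and the denominator of every scan.

## The PSI model

Reads informative for an event support either the inclusion or the
exclusion isoform.  With a Uniform(0,1) prior on the read-origin fraction
$\theta$, observing $k$ of $n$ inclusion reads gives
$\theta \mid k,n \sim \mathrm{Beta}(k+1,\,n-k+1)$.  Percent spliced in is
the monotone length correction

$$\Psi(\theta) \;=\; \frac{\theta/\ell_{inc}}
  {\theta/\ell_{inc} + (1-\theta)/\ell_{exc}},$$

so with equal effective lengths $\Psi=\theta$ and the posterior mean is
$(k+1)/(n+2)$.  For unequal lengths the posterior mean is computed by
quadrature and the equal-tailed 95% interval by mapping the Beta
quantiles through the transform.  Replicates are pooled by summation
before inference — the analysis reports one $\Psi$ per condition — and a
per-replicate hierarchical extension is deliberately not attempted.

PSI orientation: for SE events $\Psi$ is the cassette-inclusion
fraction.  For RI events $\Psi$ is the *spliced* (intron-removed)
fraction, so that intron retention upon depletion yields
$\Delta\Psi < 0$.  This is the only orientation under which the four
published event groups carry consistent signs (retention events negative,
intron-skipping events positive); note that some tools define the RI
$\Psi$ as the retained fraction instead.  $\Delta\Psi$ is always depleted
minus control.

## The Bayes factor

Differential splicing is scored by comparing M1 (each condition has its
own uniform-prior $\theta$) with M0 (a single shared $\theta$).  Both
marginal likelihoods are Beta integrals, so

$$\mathrm{BF} \;=\;
 \frac{B(k_c{+}1,\,n_c{-}k_c{+}1)\;B(k_d{+}1,\,n_d{-}k_d{+}1)}
      {B(k_c{+}k_d{+}1,\,n_c{+}n_d{-}k_c{-}k_d{+}1)},$$

evaluated in log space.  It is symmetric in the conditions, equals 1 with
no data, and is computed in $\theta$-space: with the default equal
effective lengths this is exact for $\Psi$, and with unequal lengths the
monotone transform preserves the hypothesis "changed vs unchanged" (a
documented approximation).  This closed-form two-isoform model is a
deliberate simplification of full posterior-sampling isoform
quantification frameworks; correctness is established against a
numerical-integration oracle over the whole small-count grid rather than
against any external tool's output.

Thresholds (all auditable in the pipeline manifest): discovery keeps
`BF >= 5` (boundary inclusive); validation candidates require
`|delta PSI| > 0.5` and `BF > 10` for SE, `BF > 5` for RI (strict, as
"greater than"); motif analysis uses `BF >= 10`.  Events with fewer than
`min_reads = 20` pooled informative reads are flagged `low_coverage` but
never silently dropped — no minimum is inherent to the model, so the flag
is advisory.

## Motif enrichment

Candidate RNA-binding-protein (RBP) involvement is assessed by pentamer
enrichment.  Each SE event contributes 7 transcript-oriented regions: the
last 150 bp of the upstream exon, the first and last 300 bp of the
upstream intron, the whole cassette exon, the first and last 300 bp of
the downstream intron, and the first 150 bp of the downstream exon.  The
"which 7 regions" question admits exactly one reading that produces seven
windows from exon flanks, intron flanks and the cassette, and that is the
partition implemented; exon windows never cross splice sites, and introns
shorter than 600 bp contribute their disjoint first and second halves.
RI events get the analogous 4-region partition (a documented extension —
the region scheme was originally stated for exon events only).

Up-regulated (`delta PSI > 0`) and down-regulated events are analyzed
separately.  Within each (region, direction) stratum the sequences are
cut into 5 equal-occupancy GC bins (quantile boundaries; duplicate
boundaries collapse, so identical-GC degenerate input lands in a single
bin), and a first-order Markov background with add-1 smoothing is fitted
per bin from the stratum's own sequences.  Self-background is the
parameter-free default — it asks "is this pentamer more frequent than
local composition predicts" — and an external control-event set can be
supplied instead.  The expected probability of a pentamer is pooled
across bins as a positions-weighted mean (a binomial approximation to the
exact Poisson–binomial mixture; the approximation error is negligible at
these scales and the expected-count total is conserved exactly).  Each
pentamer then gets a one-sided binomial upper-tail p-value (enrichment
only) and Benjamini–Hochberg correction within its stratum; `q <= 0.05`
is called significant.  The BH family choice (per stratum) and the bin
count (5) are analysis defaults, not externally fixed constants.

Significant pentamers are mapped to RBPs through a user-supplied lookup
table.  The packaged `rbp_pentamers_synthetic.tsv` is **illustrative
only**: it pairs well-known splicing regulators with plausible
literature-style motifs so the mapping code is exercised, and is not a
curated motif resource.

## Intron-retention consequences

For each group-3 event (intron retained upon depletion) the package
rebuilds the retention-edited mRNA from the annotation and genome,
translates from the annotated CDS start, and reports the first in-frame
stop.  A stop at a codon index at or before the reference protein length
is a premature termination codon (PTC); the truncated protein length,
lost C-terminal length, and frame preservation (intron length divisible
by 3 with no in-frame stop) are derived from it.  The NMD-candidate flag
applies the canonical 50-nt rule — a PTC more than 50 nt upstream of the
last exon–exon junction of the *edited* transcript — and is a prediction
only, reported alongside and never used to filter: intron-retained
transcripts in neuronal cells are frequently stable, which is exactly why
the flag must stay advisory.  When several transcripts contain the
retained intron, the one with the longest CDS is used (and recorded); an
intron downstream of the reference stop is reported as 3' UTR retention.
Only single-intron retention edits are modeled.

## qPCR and densitometry arithmetic

`delta_delta_ct()` implements relative quantification against an internal
reference assay (a 5S or 18S rRNA assay in the motivating experiments):
replicates are averaged on the Ct scale (the averaging order is an
explicit choice), $\Delta Ct = Ct_{target} - Ct_{ref}$ per condition,
$\Delta\Delta Ct$ is taken against the control condition, and the fold is
$2^{-\Delta\Delta Ct}$ with the control fixed at 1.  The computation is
invariant to adding a constant to every Ct.  Significance testing of the
folds is intentionally out of scope.  `isoform_fraction()` is the
band-densitometry ratio `alt / (alt + canonical)`.

## The simulated world

The generator's defaults are stated once and not revisited: 2 conditions
x 3 replicates; 100 informative reads per event per replicate; 200 bp
flanking exons, 1000 bp introns and 150 bp cassettes (large enough for
full 150/300 bp windows); genome GC 0.5; Ct noise SD 0.25 cycles.  When
no PSI vectors are supplied, half the events are null and half
differential with $|\Delta\Psi|$ uniform in 0.3–0.8, mirroring the range
of validated events.  Counts are simulated at the event level —
`Binomial(coverage, psi')` with `psi'` the length-adjusted inclusion-read
probability — because the inference consumes inclusion/exclusion counts
and positional read simulation would add no test power.  RI genes carry a
designed CDS whose retention consequence the generator knows exactly: PTC
introns are random sequence whose first in-frame stop the generator
records by its own codon walk on the assembled pre-mRNA (independent of
the annotation/FASTA path the pipeline exercises), and frame-preserving
introns are built from a stop-free alphabet with boundary clamps.  A
fraction of RI introns (default 0.2) is listed in the emitted U12
interval file.  Motif planting overwrites non-overlapping windows at
uniform positions until the planted pentamer's expected count is
`plant_fold` times its composition-background expectation.

What a green test establishes: coordinate plumbing, strand arithmetic,
the inference/classification/enrichment/consequence code paths, and their
calibration under the binomial read model.  What it does not: robustness
to mapping artifacts, positional read biases, overdispersion across
replicates, paired-end effects, or annotation errors — none of which the
generator emulates.

## Numerical choices and degenerate inputs

* Bayes factors and Markov probabilities are computed in log space.
* `k = n = 0` yields the prior (mean 0.5, interval 0.025–0.975) and BF 1.
* Quantile GC bins break ties deterministically via boundary collapse.
* Expected probabilities entering the binomial test are clamped away from
  0 and 1 by machine-epsilon guards.
* Events observed in only one condition are skipped with a warning;
  events with zero reads are called, flagged, and assigned BF 1.
* The pipeline derives fixed per-stage sub-seeds from the master seed, so
  any stage can be re-run in isolation and two runs with the same seed
  are byte-identical.

## Known limitations

The two-isoform model cannot deconvolve multi-isoform loci; RI
$\Psi$-orientation is a convention that must be matched when importing
external calls; the packaged RBP table is illustrative; U12 flagging is
exact-interval membership and will miss introns whose annotated
boundaries differ by even one base; and headline biological findings of
any particular depletion study (event counts, specific RBP lists, snRNA
levels) are functions of the original sequencing data and annotation
stack, which this package does not attempt to reproduce.
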