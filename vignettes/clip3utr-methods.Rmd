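---
title: "Methods: colocalizing CLIP crosslink peaks with 3'-UTR polyadenylation sites"
author: "clip3utr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: colocalizing CLIP crosslink peaks with 3'-UTR polyadenylation sites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clip3utr)
```

## The scientific question

Translation-initiation factors are classically pictured at the 5' end of an
mRNA, yet crosslinking assays can find them bound elsewhere. A recurring
observation in CLIP experiments on initiation-factor complexes is strong
crosslinking at the *termini of 3'-UTRs*, immediately upstream of the
poly(A) tail, where the polyadenylation signal (PAS; canonical hexamer
AAUAAA) sits. `clip3utr` provides the statistical machinery to ask, on any
matched pair of peak sets, three questions:

1. **Colocalization.** Is the presence of a CLIP peak in a 3'-UTR
   associated with the presence of a polyadenylation-site (APA-seq) peak in
   the same UTR?
2. **Motif proximity.** Do CLIP peaks sit near PAS hexamers more often than
   chance placement within the same UTRs would produce?
3. **Translation.** How does 3'-UTR CLIP signal relate to ribosome
   occupancy and translation efficiency, measured by P1-nuclease ribosome
   profiling?

A fully seeded synthetic-data generator plants known answers to all three
questions, so every stage of the pipeline is validated by parameter
recovery rather than by eyeballing.

## Coordinate conventions

Genomic intervals are held in `GRanges` (1-based, closed), the standard
Bioconductor container, because every interval operation the package needs
(reduce, coverage, overlap counting) is already correct and fast there.
All on-disk formats — BED, bedGraph, and the transcript TSV — use 0-based
half-open coordinates and are converted exactly once, at the I/O boundary
(`read_bed_peaks()`, `write_bed_peaks()`, `read_transcript_table()`).
Transcript-local coordinates (footprint 5' ends, motif hit positions,
UTR-local peaks) are 0-based offsets from the transcript or UTR 5' end,
matching the on-disk TSV dialects. This split keeps both worlds internally
consistent: no half-open/closed arithmetic ever crosses a function
boundary unannotated.

## Reproducible peaks

`reproducible_peaks()` defines a reproducible region as a maximal run of
bases covered by at least one peak in *every* replicate. Each replicate is
first merged to its covered base set; a base is then reproducible iff its
pooled coverage equals the number of replicates. This base-level
intersection is deterministic and order-independent, and adding a
replicate can only shrink the result — properties a pairwise "any overlap"
matching rule does not have. Peak scores are deliberately not propagated:
scores are caller-specific, and the downstream association statistic is
presence/absence based.

## The colocalization statistic

The analysis universe is built by `select_analysis_utr3s()`: transcripts
expressed above TPM 1 (strict inequality), with 3'-UTRs longer than 50 nt,
whose 3'-UTR genomic intervals do not overlap any other candidate's. Every
member of an overlapping cluster is dropped — not just the shorter one —
because with peak data alone one cannot attribute a peak to one of two
overlapping isoform UTRs; removing the whole cluster is symmetric and
bias-free. Overlap is tested irrespective of strand by default
(conservative; `same_strand = TRUE` relaxes it).

`build_contingency()` scores each analysis UTR for the presence of at
least one base of a reproducible APA peak and of a reproducible CLIP peak,
giving the 2x2 table (both / APA only / CLIP only / neither). The sample
odds ratio is `ad/bc` with no continuity correction (a Haldane option
exists); `fisher_exact()` computes the conditional hypergeometric test
with both margins fixed. The two-sided p-value sums the probabilities of
all tables whose point probability is at most the observed one, compared
with an absolute tolerance of 1e-12 so that ties in the hypergeometric
mass are included deterministically. The default is two-sided, with
one-sided alternatives available: when the direction of association is
genuinely pre-specified a one-sided test is defensible, but two-sided is
the safer default and the one the package reports.

The test suite checks `fisher_exact()` against a full enumeration oracle
(binomial-coefficient arithmetic, no shared code) for *every* 2x2 table
with total at most 40, and against `stats::fisher.test()` on random
tables.

## PAS motif proximity

Motif discovery is out of scope; the package scans directly for a
configurable PAS set (default the canonical AAUAAA; `T` and `U` are
interchangeable, `N` never matches, overlapping occurrences all count).
A peak "has" a PAS if at least one occurrence lies fully inside the peak
interval extended by a flank on both sides, clipped to the UTR. The flank
defaults to 25 nt: together with a typical 20-40 nt peak this makes a
70-90 nt window, the scale at which cleavage/polyadenylation elements
cluster around the PAS; it is a package convention, not a measured
quantity, and is exposed as a parameter.

Significance comes from a within-UTR shuffle null
(`pas_positional_enrichment()`): each peak's start is redrawn uniformly
within its own UTR, preserving per-UTR peak count, width, and sequence
composition. Cross-UTR shuffling was rejected because UTRs differ in
composition and length, which would confound positional enrichment with
sequence availability. The empirical p-value uses the add-one convention,
`(1 + #{null >= observed}) / (n_shuffles + 1)`, so it is never zero and
its floor is `1/(n_shuffles+1)`.

`terminal_distance_distribution()` reports the strand-aware distance from
each peak's 3' edge to its UTR terminus, the direct geometric readout of
"peaks at the ends of 3'-UTRs".

## Ribosome profiling

P1-nuclease footprints are classified by length: 32-40 nt monosome
footprints in a monosome library; in a disome library, 60 nt and longer
are the true-disome population (colliding ribosome pairs) and shorter
footprints sub-disomes. Boundaries are closed on the stated endpoints and
tested exhaustively.

A-site assignment follows the 5'-end frame rule: `frame =
(five_prime_pos - utr5_len) mod 3`, A-site nucleotide `= five_prime_pos +
offset[frame]`, codon `= floor((a_site - utr5_len)/3)`. The default offset
map (15, 16, 17) nt for frames (0, 1, 2) maps all three frames of one
footprint population onto a single codon, which is the property the
pipeline needs; the true offsets of any particular library chemistry must
be calibrated by the user and passed in — every consumer takes an
`offsets` argument.

Occupancy counting (`cds_occupancy_counts()`) keeps a read iff its A-site
codon lies in the inclusive 1-based window `[15, n_codons - 10]`. The
window is applied to the A-site, not to the read's span: A-site-based
exclusion is deterministic per read and is what occupancy means
mechanistically. A uniform one-read-per-codon gene of 100 codons therefore
counts exactly 76 reads.

Metagene profiles (`metagene_profile()`) consider genes with at least
50 nt of annotated 5'-UTR, 450 nt of CDS, 50 nt of 3'-UTR, and a mean of
at least one CDS read per codon. "Reads per codon" is interpreted as the
mean (`CDS-mapped reads / codons`), not as every codon being covered —
coverage-based filtering would couple the filter to the very pausing
structure the profile is meant to show. Each read contributes the
reciprocal of its gene's mean reads-per-codon at its (length, 5'-end
position relative to the anchor) cell; cells are summed and divided by the
number of genes. This per-gene rescaling makes the profile exactly
invariant to any gene's sequencing depth (tested to 1e-9 under a 10x
change). Read-length bins (`bin_profile_lengths()`) are inclusive,
non-overlapping ranges summed row-wise, e.g. 58-60 nt.

## Normalization and translation efficiency

Size factors are classic median-of-ratios: per sample, the median over
genes positive in all samples of the ratio to the gene's geometric mean.
The median is taken in log space, so an even number of usable genes
averages the two middle ratios geometrically — the same convention as the
standard count-normalization implementations, against which the package is
cross-checked. Only normalization, condition means, TE ratios and log2
fold changes are computed; dispersion estimation and differential testing
are out of scope by design.

`translation_efficiency()` normalizes RPF and mRNA matrices
independently, averages replicates per condition, and reports
`TE = RPF / mRNA` per gene, flagging (and excluding from TE) genes with a
zero mRNA mean. `spearman_trimmed()` implements the correlation used to
relate CLIP 3'-UTR signal (as `utr3_rpkm()`) to TE: pairs above the 99th
percentile of the y variable (linear-interpolation percentile) are
dropped, and Spearman's rho is computed with average ranks. Only y is
trimmed, matching the purpose of removing TE outliers.

## The synthetic-data generator

`generate_transcriptome()` emulates the features the pipeline is
sensitive to: lognormal segment lengths (5'-UTR ~ 120 nt, CDS ~ 400
codons with a 150-codon floor so most genes pass the 450-nt metagene
filter, 3'-UTR ~ 450 nt with a 60-nt floor), uniform base composition,
and — for a configurable polyadenylated fraction, default 0.7 — one
canonical PAS planted with its start 10-40 nt upstream of the transcript
3' end. Non-polyadenylated transcripts model the histone-like class and
receive no planted motif (chance hexamers can still occur, as they do in
real sequence). 3'-UTRs are laid out non-overlapping on one synthetic
chromosome with alternating strands, so the non-overlap filter is
exercised but not stressed.

`simulate_peaks()` plants the colocalization truth at the presence/absence
level — the level at which the Fisher construction operates. APA peaks
cover the planted PAS of every polyadenylated UTR. CLIP presence is
Bernoulli per UTR with log-odds shifted by `log(target_odds_ratio)` for
polyadenylated UTRs, with the marginal CLIP rate held at a configured base
rate (default 0.1) by solving for the intercept. Replicate noise is
normal position jitter plus independent per-peak dropout.

One generator design choice deserves emphasis: **replicate dropout is a
CLIP-side noise model; APA detection at a planted poly(A) site is treated
as reliable (default dropout 0).** The reason is statistical, decided
analytically before any experiment was run: requiring presence in all
three replicates turns per-replicate dropout `q` into a per-UTR
false-negative rate `1-(1-q)^3` on the *conditioning* variable, and such
nondifferential misclassification attenuates the sample odds ratio toward
1 — severely for large planted odds ratios at realistic polyadenylated
fractions. That attenuation is a property of the estimator under
conditioning-variable noise, not of the planted association, so the
recovery experiments keep the conditioning assay clean and put the noise
where the assay is actually noisy (sparse crosslink peaks). Users
simulating APA dropout will observe the attenuation — which is itself a
correct and instructive output.

`simulate_footprints()` draws per-gene abundance (lognormal, sd 1.2 on the
log scale) and TE (lognormal, sd 1.0), negative-binomial mRNA counts
(dispersion 0.05), and multinomial footprints with mass proportional to
abundance x TE. Each read picks a CDS codon uniformly, a 5'-end frame
uniformly, a length from the library distribution (monosome: 32-40 nt,
peaked at 36; disome: a 40/60 mixture of 45-59 nt and 60-75 nt — generator
defaults, not assay measurements), and a 5' position constructed so that
`assign_a_site()` with the same offsets inverts exactly. These defaults
are chosen once as plausible bulk-transcriptome magnitudes; none of them
is revisited per experiment.

What the generator does *not* emulate: read sequences and sequencing
error, crosslink-induced truncations/mutations, UMI and ligation
artifacts, multi-exon UTRs, isoform mixtures beyond two same-gene
transcripts, and coverage-level peak structure. Passing recovery tests
therefore demonstrates the correctness of the statistics and bookkeeping
on idealized inputs, not robustness to upstream artifacts — those live
upstream of this package's inputs (trimming, alignment, peak calling are
consumed, not performed).

## Validation experiment sizes

The packaged experiments use problem sizes chosen to give tight recovery
checks at interactive runtimes: odds-ratio recovery on 5000 UTRs with 200
simulations per planted value (and 500 null runs for p-value uniformity);
PAS-fraction recovery with 1000 peaks; A-site/metagene recovery at 200,000
footprints over 200 genes; TE recovery at 1000 genes and 200,000 reads per
assay; the exhaustive Fisher sweep covers every table with total at most
40. The demo configuration (`run_config()`) simulates 2000 genes with a
planted odds ratio of 5.6.

## Numerical and degenerate-input conventions

* Fisher tie comparison: absolute tolerance 1e-12 on the point-probability
  inequality; p-values are clamped to at most 1.
* Odds ratio: `Inf` when only `bc = 0`; `NaN` sentinel when `ad = bc = 0`.
* Spearman: ties get average ranks; constant vectors yield `NA` with a
  warning (`signal_vs_utr3_length()`) or are the user's responsibility
  (`spearman_trimmed()` errors below 3 usable pairs).
* `compute_tpm()` refuses all-zero counts (undefined normalization);
  `size_factors_median_of_ratios()` refuses matrices with no all-positive
  gene.
* All generators call `set.seed(seed)` on entry; identical
  (seed, configuration) pairs reproduce outputs byte-identically.

## Known limitations

* The PAS-window fraction depends on the flank convention; absolute
  fractions are comparable only within one convention.
* Peak-level simulation cannot exercise read-level coverage shapes;
  `write_bedgraph()`/`cpm_normalize()` are tested on constructed coverage.
* The colocalization test conditions on marginal totals; it does not model
  UTR length or expression as covariates (a UTR-length independence check
  is provided separately via `signal_vs_utr3_length()`).
* Single-isoform transcripts only; alternative-polyadenylation isoform
  pairs are emulated as two transcripts sharing a gene identifier.
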