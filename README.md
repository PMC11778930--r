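# clip3utr

Statistical toolkit linking protein–RNA crosslinking (CLIP) peaks to the
polyadenylation-site termini of 3'-UTRs and to translation activity.

## The problem

CLIP experiments on translation-initiation factors repeatedly find
crosslink peaks not only in 5'-UTRs but at the *ends of 3'-UTRs*, next to
the poly(A) tail and the polyadenylation signal (PAS, canonical hexamer
AAUAAA). Deciding whether that pattern reflects a real coupling between
factor binding and polyadenylation — rather than peak-calling artifacts or
UTR-length confounding — needs three quantitative ingredients, which this
package provides for anyone with replicate peak sets (BED), a transcript
annotation, footprint alignments, and count matrices:

1. **Replicate-reproducible peaks.** A reproducible region is a maximal
   run of bases covered by at least one peak in *every* biological
   replicate (`reproducible_peaks()`).
2. **Colocalization statistic.** Over non-overlapping, expressed 3'-UTRs
   (TPM > 1, length > 50 nt), each UTR is scored for the presence of a
   reproducible APA-seq peak and a reproducible CLIP peak; the resulting
   2×2 table (a = both, b = APA only, c = CLIP only, d = neither) is
   summarized by the sample odds ratio `ad/bc` and Fisher's exact
   conditional test (`associate()`).
3. **PAS proximity and translation.** A direct hexamer scan with a
   within-UTR shuffle null quantifies PAS enrichment around peaks
   (`pas_positional_enrichment()`); P1-nuclease ribosome-profiling
   machinery (frame-based A-site offsets, codon-window occupancy,
   depth-invariant metagene profiles) and median-of-ratios normalization
   connect CLIP signal to translation efficiency TE = RPF/mRNA
   (`metagene_profile()`, `translation_efficiency()`).

A seeded synthetic-data generator (`generate_transcriptome()`,
`simulate_peaks()`, `simulate_footprints()`, `plant_pas_peaks()`) plants
known odds ratios, PAS fractions, A-site offsets and per-gene TE, so every
stage is validated by recovering what was planted. See the methods
vignette (`vignettes/clip3utr-methods.Rmd`) for the full model and design
rationale.

## Worked example

Simulate a 2000-gene transcriptome with a planted CLIP/APA odds ratio of
5.6, derive reproducible peaks, and test the association:

```r
library(clip3utr)

tx   <- generate_transcriptome(n_genes = 2000, seed = 42)
apa  <- simulate_peaks(tx, "APA",  jitter_sd = 2, seed = 43)
clip <- simulate_peaks(tx, "CLIP", target_odds_ratio = 5.6, clip_rate = 0.1,
                       jitter_sd = 2, dropout_rate = 0.05, seed = 44)

mrna <- simulate_footprints(tx, reads_total = 2e5, seed = 45)$mrna_counts
tpm  <- compute_tpm(rowSums(mrna), tx$annotations$transcript_length)
names(tpm) <- tx$annotations$transcript_id
utrs <- select_analysis_utr3s(tx$annotations, tpm)   # 1996 analysis UTRs

associate(utrs, apa, clip)
#> 2x2 contingency table (n = 1996 UTRs)
#>      APA
#> CLIP   yes  no
#>   yes  165  11
#>   no  1232 588
#> odds ratio = 7.159, Fisher two.sided p = 1.609e-12
```

The planted association is detected decisively; the point estimate sits
above the planted 5.6 within this single simulation's sampling spread
(the packaged recovery experiment shows the median estimate over 200
simulations lands within 15% of the planted value).

PAS enrichment of the reproducible CLIP peaks inside the analysis UTRs:

```r
res   <- associate(utrs, apa, clip)
local <- map_peaks_to_utr3(res$clip_reproducible, utrs)
pas_positional_enrichment(local, utr3_sequences(tx), seed = 46)
#> PAS window enrichment: observed fraction 0.938 over 176 peaks (flank 25 nt)
#> empirical p = 0.000999 (1000 shuffles, null mean 0.143)
```

93.8% of reproducible CLIP peaks carry a PAS within their 25-nt flanked
window versus 14.3% under within-UTR shuffling — an empirical p at the
floor of 1000 shuffles (0.000999), i.e. no shuffle matched the observed
fraction.

`run_full(run_config(...))` chains every stage (simulation, file I/O
round-trips, colocalization, PAS, metagene, TE, correlations) and writes
a JSON report; `inst/scripts/run_pipeline.R` wraps it for the shell.

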