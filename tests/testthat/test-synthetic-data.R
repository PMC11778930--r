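test_that("transcriptome generation is deterministic and plants PAS truth", {
  tx1 <- generate_transcriptome(40, seed = 19)
  tx2 <- generate_transcriptome(40, seed = 19)
  expect_identical(tx1$sequences, tx2$sequences)
  expect_identical(tx1$annotations, tx2$annotations)
  expect_identical(tx1$truth$transcripts, tx2$truth$transcripts)
  expect_false(identical(tx1$sequences,
                         generate_transcriptome(40, seed = 20)$sequences))

  # every polyadenylated transcript carries the motif at its recorded spot
  tr <- tx1$truth$transcripts
  for (i in which(tr$polyadenylated)) {
    s <- tx1$sequences[[tr$transcript_id[i]]]
    expect_equal(substr(s, tr$pas_local[i] + 1, tr$pas_local[i] + 6),
                 "AATAAA")
  }
  # planted distance lies in the terminal window
  d <- tr$pas_distance[tr$polyadenylated]
  expect_true(all(d >= 10 & d <= 40))

  all_pa <- generate_transcriptome(30, seed = 1, frac_polyadenylated = 1)
  expect_true(all(all_pa$truth$transcripts$polyadenylated))
  none <- generate_transcriptome(30, seed = 1, frac_polyadenylated = 0)
  expect_true(all(is.na(none$truth$transcripts$pas_local)))

  # 3'-UTR genomic intervals never overlap
  u <- utr3_granges(tx1$annotations)
  expect_true(GenomicRanges::isDisjoint(u))
})

test_that("CDS lengths are multiples of 3 and segment sums hold", {
  tx <- generate_transcriptome(50, seed = 4)
  a <- tx$annotations
  expect_true(all(a$cds_len %% 3 == 0))
  expect_equal(nchar(tx$sequences[a$transcript_id]),
               setNames(a$transcript_length, a$transcript_id))
  expect_equal(a$utr3_end - a$utr3_start, a$utr3_len)
})

test_that("noiseless peak simulation is exactly recovered as reproducible", {
  tx <- generate_transcriptome(60, seed = 9)
  ps <- simulate_peaks(tx, "APA", jitter_sd = 0, dropout_rate = 0, seed = 2)
  repro <- reproducible_peaks(ps)
  # one reproducible interval per planted APA-positive UTR
  expect_equal(length(repro), sum(ps$present))
  expect_identical(bases_of(repro), bases_of(ps$replicates[[1]]))
  tab <- build_contingency(tx$annotations, repro, repro)
  expect_equal(tab$a, sum(ps$present))
  expect_equal(tab$b + tab$c, 0L)
})

test_that("per-replicate dropout shrinks the reproducible set binomially", {
  tx <- generate_transcriptome(400, seed = 13)
  full <- simulate_peaks(tx, "APA", dropout_rate = 0, seed = 5)
  half <- simulate_peaks(tx, "APA", dropout_rate = 0.5, n_replicates = 1L,
                         seed = 5)
  n_full <- length(reproducible_peaks(full))
  n_half <- length(reproducible_peaks(half))
  expect_lt(abs(n_half - 0.5 * n_full), 3 * sqrt(n_full * 0.25))
  expect_error(simulate_peaks(tx, "CLIP", dropout_rate = 1), "< 1")
})

test_that("planted null odds ratio is recovered near 1", {
  tx <- generate_transcriptome(1500, seed = 77)
  ors <- vapply(1:20, function(i) {
    clip <- simulate_peaks(tx, "CLIP", target_odds_ratio = 1,
                           clip_rate = 0.15, seed = 100 + i)
    apa <- simulate_peaks(tx, "APA", seed = 200 + i)
    odds_ratio(build_contingency(tx$annotations,
                                 reproducible_peaks(apa),
                                 reproducible_peaks(clip)))
  }, numeric(1))
  expect_lt(abs(median(ors) - 1), 0.25)
})

test_that("marginal CLIP rate is held at the configured base rate", {
  tx <- generate_transcriptome(3000, seed = 3)
  for (or in c(1, 4)) {
    clip <- simulate_peaks(tx, "CLIP", target_odds_ratio = or,
                           clip_rate = 0.1, seed = or)
    expect_lt(abs(mean(clip$present) - 0.1), 3 * sqrt(0.1 * 0.9 / 3000))
  }
})

test_that("footprint generation inverts A-site assignment exactly", {
  tx <- generate_transcriptome(40, seed = 6)
  sim <- simulate_footprints(tx, reads_total = 2e4, seed = 8)
  codons <- assign_a_site(sim$footprints, tx$annotations)
  expect_equal(mean(codons == sim$footprints$codon), 1)
  # monosome length support
  expect_true(all(sim$footprints$length >= 32 & sim$footprints$length <= 40))
  # determinism
  sim2 <- simulate_footprints(tx, reads_total = 2e4, seed = 8)
  expect_identical(sim$footprints, sim2$footprints)
  expect_identical(sim$mrna_counts, sim2$mrna_counts)
})

test_that("degenerate TE distribution gives estimated TE near 1", {
  tx <- generate_transcriptome(150, seed = 10)
  sim <- simulate_footprints(tx, reads_total = 1.5e5, te_sdlog = 0,
                             abundance_sdlog = 0.3, seed = 12)
  occ <- cds_occupancy_counts(sim$footprints, tx$annotations)
  te <- translation_efficiency(occ, sim$mrna_counts)
  est <- te$te_all[te$te_defined]
  # with constant planted TE the estimates are near-constant; the exact
  # centre depends on per-assay normalization scale and window attrition
  expect_gt(median(est), 0.5)
  expect_lt(median(est), 1.5)
  expect_lt(stats::mad(log(est)), 0.25)
})

test_that("disome library lengths follow the configured mixture", {
  tx <- generate_transcriptome(40, seed = 2)
  sim <- simulate_footprints(tx, reads_total = 2e4, library = "disome_lib",
                             seed = 3)
  cls <- classify_footprint(sim$footprints$length, "disome_lib")
  frac_true <- mean(cls == "true_disome")
  expect_gt(frac_true, 0.45)
  expect_lt(frac_true, 0.75)
  expect_true(all(sim$footprints$length >= 45 & sim$footprints$length <= 75))
})

test_that("PAS-planted peaks realize the requested fraction exactly", {
  tx <- generate_transcriptome(100, seed = 15)
  pl <- plant_pas_peaks(tx, n_peaks = 400, fraction_with_pas = 0.58,
                        seed = 44)
  est <- peak_pas_fraction(pl$peaks, pl$utr_seqs)
  # estimator recovers the realized planting indicator exactly
  expect_equal(est$fraction, pl$fraction_planted)
  expect_equal(est$hit, pl$peaks$planted)
})
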