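test_that("footprint class boundaries are exact over lengths 1..100", {
  mono <- classify_footprint(1:100, "monosome_lib")
  expect_equal(mono, ifelse(1:100 >= 32 & 1:100 <= 40,
                            "monosome", "unassigned"))
  diso <- classify_footprint(1:100, "disome_lib")
  expect_equal(diso, ifelse(1:100 >= 60, "true_disome", "sub_disome"))
  expect_equal(classify_footprint(35, "monosome_lib"), "monosome")
  expect_equal(classify_footprint(60, "disome_lib"), "true_disome")
  expect_equal(classify_footprint(59, "disome_lib"), "sub_disome")
  expect_error(classify_footprint(0, "monosome_lib"), ">= 1")
})

test_that("A-site assignment follows the 5'-end frame arithmetic", {
  ann <- make_annotation("t1", utr5_len = 50L, cds_len = 300L)
  fp <- data.frame(transcript_id = "t1",
                   five_prime_pos = c(50L, 52L, 20L),
                   length = 34L, sample = "s")
  codons <- assign_a_site(fp, ann)
  expect_equal(codons, c(5L, 6L, -5L))
  # named offset map is accepted
  expect_equal(assign_a_site(fp, ann,
                             offsets = c(`2` = 17, `0` = 15, `1` = 16)),
               codons)
  expect_error(assign_a_site(
    data.frame(transcript_id = "zz", five_prime_pos = 1L, length = 30L,
               sample = "s"), ann), "no annotation")
})

test_that("occupancy window counts codons 15..(n-10) inclusive", {
  ann <- make_annotation("t1", utr5_len = 50L, cds_len = 300L)  # 100 codons
  mk <- function(codon1) {
    # frame-0 read whose A-site is the given 1-based codon
    data.frame(transcript_id = "t1",
               five_prime_pos = 50L + 3L * (codon1 - 1L) - 15L,
               length = 34L, sample = "s")
  }
  expect_equal(cds_occupancy_counts(mk(15), ann)["t1", "s"], 1L)
  expect_equal(cds_occupancy_counts(mk(14), ann)["t1", "s"], 0L)
  expect_equal(cds_occupancy_counts(mk(90), ann)["t1", "s"], 1L)
  expect_equal(cds_occupancy_counts(mk(91), ann)["t1", "s"], 0L)

  uniform <- do.call(rbind, lapply(1:100, mk))
  expect_equal(cds_occupancy_counts(uniform, ann)["t1", "s"], 76L)
})

test_that("one read per codon start yields a self-normalized flat profile", {
  ann <- make_annotation("t1", utr5_len = 60L, cds_len = 450L,
                         utr3_len = 60L)
  fp <- data.frame(transcript_id = "t1",
                   five_prime_pos = 60L + 3L * (0:149),
                   length = 33L, sample = "s")
  mg <- metagene_profile(fp, ann, anchor = "start_codon",
                         offsets = c(0L, 1L, 2L), min_utr5 = 50L,
                         position_range = c(-30L, 90L))
  expect_equal(mg$n_genes, 1L)
  prof <- mg$profile["33", ]
  r <- as.integer(names(prof))
  expect_true(all(prof[r >= 0 & r %% 3 == 0] == 1))
  expect_true(all(prof[r < 0 | r %% 3 != 0] == 0))
})

test_that("per-gene rescaling removes depth differences", {
  ann <- rbind(
    make_annotation("a", utr5_len = 60L, cds_len = 450L, utr3_len = 60L,
                    utr3_start = 1000L),
    make_annotation("b", utr5_len = 60L, cds_len = 450L, utr3_len = 60L,
                    utr3_start = 3000L))
  shape <- data.frame(five_prime_pos = 60L + 3L * (0:149), length = 33L)
  fp_a <- data.frame(transcript_id = "a", shape, sample = "s")
  fp_b <- data.frame(transcript_id = "b",
                     shape[rep(seq_len(nrow(shape)), 10), ], sample = "s")
  both <- metagene_profile(rbind(fp_a, fp_b), ann, min_reads_per_codon = 0.5)
  alone <- metagene_profile(fp_a, ann[1, ], min_reads_per_codon = 0.5)
  expect_equal(both$profile, alone$profile, tolerance = 1e-12)

  # scaling one gene's reads by k leaves the profile unchanged
  fp_b2 <- data.frame(transcript_id = "b",
                      shape[rep(seq_len(nrow(shape)), 2), ], sample = "s")
  p1 <- metagene_profile(rbind(fp_a, fp_b), ann, min_reads_per_codon = 0.5)
  p2 <- metagene_profile(rbind(fp_a, fp_b2), ann, min_reads_per_codon = 0.5)
  expect_equal(p1$profile, p2$profile, tolerance = 1e-9)
})

test_that("a constructed 3-gene instance equals a direct summation oracle", {
  ann <- do.call(rbind, lapply(1:3, function(i) {
    make_annotation(paste0("g", i), utr5_len = 60L, cds_len = 450L,
                    utr3_len = 60L, utr3_start = 2000L * i)
  }))
  set.seed(31)
  fp <- do.call(rbind, lapply(1:3, function(i) {
    n <- c(200L, 350L, 500L)[i]
    data.frame(transcript_id = paste0("g", i),
               five_prime_pos = sample(40:430, n, replace = TRUE),
               length = sample(32:40, n, replace = TRUE),
               sample = "s")
  }))
  rng <- c(-30L, 90L)
  mg <- metagene_profile(fp, ann, position_range = rng,
                         min_reads_per_codon = 0.1)

  # oracle: direct tally with scale = in-CDS A-site reads / codons
  offsets <- c(15L, 16L, 17L)
  oracle <- matrix(0, length(32:40), rng[2] - rng[1] + 1,
                   dimnames = list(as.character(32:40),
                                   as.character(rng[1]:rng[2])))
  for (g in paste0("g", 1:3)) {
    sub <- fp[fp$transcript_id == g, ]
    frame <- (sub$five_prime_pos - 60L) %% 3L
    codon <- (sub$five_prime_pos + offsets[frame + 1L] - 60L) %/% 3L
    scale <- sum(codon >= 0 & codon < 150) / 150
    r <- sub$five_prime_pos - 60L
    for (k in seq_len(nrow(sub))) {
      if (r[k] >= rng[1] && r[k] <= rng[2]) {
        row <- as.character(sub$length[k]); col <- as.character(r[k])
        oracle[row, col] <- oracle[row, col] + 1 / scale
      }
    }
  }
  expect_equal(mg$profile, oracle / 3, tolerance = 1e-12)

  # metagene conservation for a single gene: sum(profile * scale) over
  # in-range cells equals the raw read count restricted to that range
  one <- fp[fp$transcript_id == "g1", ]
  m1 <- metagene_profile(one, ann[1, ], position_range = rng,
                         min_reads_per_codon = 0.1)
  frame <- (one$five_prime_pos - 60L) %% 3L
  codon <- (one$five_prime_pos + offsets[frame + 1L] - 60L) %/% 3L
  scale <- sum(codon >= 0 & codon < 150) / 150
  r <- one$five_prime_pos - 60L
  expect_equal(sum(m1$profile) * scale, sum(r >= rng[1] & r <= rng[2]))
})

test_that("metagene filters reject genes and report attrition", {
  ann <- make_annotation("t1", utr5_len = 20L, cds_len = 450L,
                         utr3_len = 60L)
  fp <- data.frame(transcript_id = "t1", five_prime_pos = 100L,
                   length = 33L, sample = "s")
  expect_error(metagene_profile(fp, ann), "utr5>=50: 0")
  fp_bad <- data.frame(transcript_id = "t1", five_prime_pos = 520L,
                       length = 33L, sample = "s")
  expect_error(metagene_profile(fp_bad, ann), "past their transcript")
})

test_that("length binning sums rows and rejects overlapping bins", {
  ann <- make_annotation("t1", utr5_len = 60L, cds_len = 450L,
                         utr3_len = 60L)
  fp <- do.call(rbind, lapply(58:60, function(L) {
    data.frame(transcript_id = "t1", five_prime_pos = 60L + 3L * (0:149),
               length = L, sample = "s")
  }))
  mg <- metagene_profile(fp, ann, min_reads_per_codon = 0.5)
  binned <- bin_profile_lengths(mg, list(c(58L, 60L), c(61L, 70L)))
  expect_equal(rownames(binned$profile), c("58-60", "61-70"))
  expect_equal(binned$profile["58-60", "0"],
               sum(mg$profile[, "0"]))
  expect_equal(unname(binned$profile["61-70", ]),
               numeric(ncol(mg$profile)))
  # singleton bins are the identity
  single <- bin_profile_lengths(mg, list(c(58L, 58L), c(59L, 59L),
                                         c(60L, 60L)))
  expect_equal(unname(single$profile), unname(mg$profile))
  expect_error(bin_profile_lengths(mg, list(c(58L, 60L), c(60L, 62L))),
               "overlap")
})
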