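test_that("median-of-ratios size factors satisfy the analytic identities", {
  k <- matrix(c(10, 20, 30, 10, 20, 30), ncol = 2,
              dimnames = list(paste0("g", 1:3), c("s1", "s2")))
  expect_equal(unname(size_factors_median_of_ratios(k)), c(1, 1))

  k2 <- cbind(A = c(10, 20, 30), B = c(20, 40, 60))
  sf <- size_factors_median_of_ratios(k2)
  expect_equal(unname(sf), c(1 / sqrt(2), sqrt(2)), tolerance = 1e-10)
  norm <- normalize_counts(k2, sf)
  expect_equal(norm[, "A"], norm[, "B"], tolerance = 1e-10)

  # scale equivariance
  set.seed(17)
  base <- matrix(rpois(400, 50) + 1, ncol = 4)
  sf0 <- size_factors_median_of_ratios(base)
  for (c_mult in c(2, 5)) {
    scaled <- base
    scaled[, 2] <- scaled[, 2] * c_mult
    sf1 <- size_factors_median_of_ratios(scaled)
    expect_equal(sf1[2] / sf0[2], c_mult *
                   (sf1[1] / sf0[1]) / 1, tolerance = 1e-10)
  }
  expect_error(size_factors_median_of_ratios(matrix(c(0, 1, 1, 0), 2)),
               "strictly positive")
})

test_that("size factors match the median-of-log-ratios oracle and DESeq2", {
  set.seed(23)
  # odd gene count: the natural-space median of ratios coincides exactly
  # with the exponentiated log-space median (no two-value averaging)
  k <- matrix(rnbinom(404, mu = 100, size = 5) + 1, ncol = 4,
              dimnames = list(sprintf("g%03d", 1:101), paste0("s", 1:4)))
  sf <- size_factors_median_of_ratios(k)
  # alternate-formula oracle: median of ratios in natural space
  geo <- exp(rowMeans(log(k)))
  oracle <- apply(k / geo, 2, median)
  expect_equal(unname(sf), unname(oracle), tolerance = 1e-10)
  skip_if_not_installed("DESeq2")
  expect_equal(unname(sf),
               unname(DESeq2::estimateSizeFactorsForMatrix(k)),
               tolerance = 1e-8)
})

test_that("translation efficiency is RPF/mRNA after per-assay normalization", {
  set.seed(41)
  k <- matrix(rpois(300, 80) + 1, ncol = 3,
              dimnames = list(sprintf("g%03d", 1:100), paste0("r", 1:3)))
  te <- translation_efficiency(k, k)
  expect_equal(te$te_all, rep(1, 100))

  # gene with all-zero mRNA is flagged and excluded from TE
  rpf <- k; mrna <- k
  mrna["g001", ] <- 0
  te2 <- translation_efficiency(rpf, mrna)
  expect_false(te2$te_defined[te2$gene_id == "g001"])
  expect_true(is.na(te2$te_all[te2$gene_id == "g001"]))
  expect_error(translation_efficiency(
    matrix(1, 1, 1, dimnames = list("x", "s")),
    matrix(1, 1, 1, dimnames = list("y", "s"))), "shared gene")
})

test_that("doubling RPF in one condition doubles that condition's TE", {
  # 90% invariant genes keep the size factors fixed between conditions
  set.seed(55)
  n <- 100
  base <- matrix(rpois(n * 4, 100) + 1, ncol = 4)
  rownames(base) <- sprintf("g%03d", 1:n)
  colnames(base) <- c("u1", "u2", "d1", "d2")
  rpf <- base
  boosted <- sprintf("g%03d", 1:10)
  rpf[boosted, c("d1", "d2")] <- rpf[boosted, c("d1", "d2")] * 2L
  conditions <- c(u1 = "undiff", u2 = "undiff", d1 = "diff", d2 = "diff")
  te <- translation_efficiency(rpf, base, conditions = conditions,
                               contrast = c("diff", "undiff"))
  expect_equal(te$log2fc_te[te$gene_id %in% boosted], rep(1, 10),
               tolerance = 0.05)
  expect_equal(median(te$log2fc_te[!te$gene_id %in% boosted]), 0,
               tolerance = 0.05)
})

test_that("3'-UTR RPKM applies the strict >50 nt filter and the formula", {
  counts <- c(g1 = 10, g2 = 0, g3 = 4)
  lens <- c(1000L, 200L, 50L)
  out <- utr3_rpkm(counts, lens, library_size = 1e6)
  expect_equal(out$gene_id, c("g1", "g2"))
  expect_equal(out$rpkm, c(10, 0))
  expect_error(utr3_rpkm(counts, lens, library_size = 0), "positive")
})

test_that("trimmed Spearman matches the closed-form rank formula", {
  x <- 1:20
  expect_equal(spearman_trimmed(x, x^3)$rho, 1)
  expect_equal(spearman_trimmed(x, rev(x))$rho, -1)
  set.seed(61)
  for (i in 1:20) {
    n <- sample(5:10, 1)
    a <- rnorm(n); b <- rnorm(n)  # continuous: no ties
    got <- spearman_trimmed(a, b, trim_pct = 100)
    d <- rank(a) - rank(b)
    expect_equal(got$rho, 1 - 6 * sum(d^2) / (n * (n^2 - 1)),
                 tolerance = 1e-12)
  }
  # invariance under strictly monotone transforms of x
  set.seed(62)
  a <- rnorm(50); b <- rnorm(50)
  expect_equal(spearman_trimmed(exp(a), b)$rho, spearman_trimmed(a, b)$rho)
  # trimming drops y above the 99th percentile only
  y <- c(rnorm(99), 1000)
  got <- spearman_trimmed(seq_along(y), y)
  expect_equal(got$n_trimmed, 1L)
  expect_error(spearman_trimmed(1:3, c(1, 2, 300), trim_pct = 50),
               "fewer than 3")
})

test_that("top-n intersections match hand-computed sets", {
  l1 <- sprintf("g%02d", 1:15)
  l2 <- sprintf("g%02d", c(1:5, 20:29))
  l3 <- sprintf("g%02d", c(3:8, 30:38))
  out <- top_n_intersection(list(a = l1, b = l2, c = l3), n = 10)
  expect_setequal(out$common, c("g03", "g04", "g05"))
  expect_equal(out$pairwise["a", "b"], 5L)
  expect_equal(out$pairwise["a", "c"], 6L)
  expect_equal(out$pairwise["b", "c"], 3L)

  expect_equal(top_n_intersection(list(l1, l1), 10)$n_common, 10L)
  expect_equal(top_n_intersection(list(l1, sprintf("x%d", 1:9)), 5)$n_common,
               0L)
  expect_error(top_n_intersection(list(c("a", "a"), l1), 2), "duplicate")
})
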