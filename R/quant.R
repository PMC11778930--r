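# Normalization, translation-efficiency and CLIP-signal quantification,
# and ranked-set intersection utilities.

#' Median-of-ratios size factors
#'
#' For each sample `j`, the size factor is the median over genes (restricted
#' to genes with strictly positive counts in every sample) of
#' `K_gj / (prod_j' K_gj')^(1/m)` — the classic median-of-ratios estimator.
#' Computed in log space, so with an even number of usable genes the two
#' middle ratios are averaged geometrically (the convention the standard
#' count-normalization implementations follow). Size factors are
#' scale-equivariant: multiplying one sample's counts by `c` multiplies its
#' factor by `c`.
#'
#' @param counts Non-negative numeric matrix, genes x samples.
#' @return Named positive numeric vector of per-sample size factors.
#' @examples
#' k <- matrix(c(10, 20, 30, 20, 40, 60), ncol = 2) # sample B = 2 x A
#' size_factors_median_of_ratios(k)                 # 1/sqrt(2), sqrt(2)
#' @export
size_factors_median_of_ratios <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  lk <- log(counts)
  all_pos <- rowSums(is.finite(lk)) == ncol(counts)
  if (!any(all_pos)) {
    stop("no gene has strictly positive counts in all samples")
  }
  lk <- lk[all_pos, , drop = FALSE]
  loggeo <- rowMeans(lk)
  sf <- exp(apply(lk - loggeo, 2L, stats::median))
  stats::setNames(sf, colnames(counts))
}

#' Normalize a count matrix by median-of-ratios size factors
#'
#' @param counts Non-negative numeric matrix, genes x samples.
#' @param size_factors Optional precomputed factors; computed with
#'   [size_factors_median_of_ratios()] when absent.
#' @return Matrix of normalized counts (`K_gj / sf_j`).
#' @export
normalize_counts <- function(counts, size_factors = NULL) {
  if (is.null(size_factors)) {
    size_factors <- size_factors_median_of_ratios(counts)
  }
  sweep(as.matrix(counts), 2L, size_factors, "/")
}

#' Translation efficiency from RPF and mRNA count matrices
#'
#' Each assay is normalized independently by median-of-ratios; replicate
#' means are taken per condition; `TE = mean normalized RPF / mean
#' normalized mRNA` per gene and condition. Genes whose mRNA condition mean
#' is zero are flagged and excluded from TE (their TE is `NA`). With a
#' two-condition `contrast`, per-gene log2 fold changes of RPF, mRNA and TE
#' are added.
#'
#' @param rpf,mrna Count matrices (genes x samples); gene universes are
#'   intersected.
#' @param conditions Named character vector mapping sample name to
#'   condition. Defaults to a single condition `"all"` for every sample.
#' @param contrast Length-2 character vector `(numerator, denominator)` of
#'   condition names for the log2 fold changes (e.g. differentiated vs
#'   undifferentiated), or `NULL`.
#' @return A `te_table` data frame: `gene_id`, per-condition
#'   `rpf_mean_*`, `mrna_mean_*`, `te_*` columns, optional `log2fc_rpf`,
#'   `log2fc_mrna`, `log2fc_te`, and a logical `te_defined`.
#' @export
translation_efficiency <- function(rpf, mrna, conditions = NULL,
                                   contrast = NULL) {
  genes <- intersect(rownames(rpf), rownames(mrna))
  if (length(genes) == 0L) stop("empty shared gene set between RPF and mRNA")
  rpf <- as.matrix(rpf)[genes, , drop = FALSE]
  mrna <- as.matrix(mrna)[genes, , drop = FALSE]
  if (is.null(conditions)) {
    conditions <- stats::setNames(
      rep("all", ncol(rpf) + ncol(mrna)),
      c(colnames(rpf), colnames(mrna)))
  }
  cond_of <- function(m) {
    cc <- conditions[colnames(m)]
    if (anyNA(cc)) stop("sample(s) without a condition label")
    cc
  }
  cond_means <- function(m) {
    cc <- cond_of(m)
    vapply(unique(cc), function(cnd) {
      rowMeans(m[, cc == cnd, drop = FALSE])
    }, numeric(nrow(m)))
  }
  rpf_means <- cond_means(normalize_counts(rpf))
  mrna_means <- cond_means(normalize_counts(mrna))
  conds <- intersect(colnames(rpf_means), colnames(mrna_means))
  if (length(conds) == 0L) stop("no condition shared between assays")
  out <- data.frame(gene_id = genes, stringsAsFactors = FALSE)
  te <- matrix(NA_real_, length(genes), length(conds),
               dimnames = list(genes, conds))
  for (cnd in conds) {
    defined <- mrna_means[, cnd] > 0
    te[defined, cnd] <- rpf_means[defined, cnd] / mrna_means[defined, cnd]
    out[[paste0("rpf_mean_", cnd)]] <- rpf_means[, cnd]
    out[[paste0("mrna_mean_", cnd)]] <- mrna_means[, cnd]
    out[[paste0("te_", cnd)]] <- te[, cnd]
  }
  out$te_defined <- rowSums(is.na(te)) == 0L
  if (!is.null(contrast)) {
    if (!all(contrast %in% conds)) {
      stop("contrast conditions not present in both assays")
    }
    num <- contrast[1L]; den <- contrast[2L]
    out$log2fc_rpf <- log2(rpf_means[, num] / rpf_means[, den])
    out$log2fc_mrna <- log2(mrna_means[, num] / mrna_means[, den])
    out$log2fc_te <- log2(te[, num] / te[, den])
  }
  class(out) <- c("te_table", "data.frame")
  out
}

#' 3'-UTR CLIP RPKM
#'
#' `RPKM = count * 1e9 / (library_size * utr3_len)` for genes whose 3'-UTR
#' is strictly longer than 50 nt; shorter genes are excluded (not an
#' error).
#'
#' @param clip_counts Named numeric vector of per-gene 3'-UTR CLIP read
#'   counts.
#' @param utr3_len Named (or parallel) vector of 3'-UTR lengths in nt.
#' @param library_size Total mapped reads; must be positive.
#' @param min_len Strict length threshold (default 50 nt).
#' @return Data frame `gene_id, count, utr3_len, rpkm` for included genes.
#' @export
utr3_rpkm <- function(clip_counts, utr3_len, library_size, min_len = 50L) {
  if (library_size <= 0) stop("library_size must be positive")
  if (length(clip_counts) != length(utr3_len)) {
    stop("clip_counts and utr3_len differ in length")
  }
  ids <- names(clip_counts)
  if (is.null(ids)) ids <- as.character(seq_along(clip_counts))
  keep <- utr3_len > min_len
  data.frame(
    gene_id = ids[keep],
    count = as.numeric(clip_counts[keep]),
    utr3_len = as.integer(utr3_len[keep]),
    rpkm = as.numeric(clip_counts[keep]) * 1e9 /
      (library_size * as.numeric(utr3_len[keep])),
    stringsAsFactors = FALSE
  )
}

#' Spearman correlation with upper-percentile trimming of y
#'
#' Drops pairs whose `y` strictly exceeds the `trim_pct` percentile of `y`
#' (linear-interpolation percentile, R quantile type 7), then computes
#' Spearman's rho with average ranks for ties. Only the `y` variable is
#' trimmed.
#'
#' @param x,y Paired numeric vectors.
#' @param trim_pct Percentile (default 99).
#' @return List with `rho`, `n_used`, `n_trimmed`.
#' @export
spearman_trimmed <- function(x, y, trim_pct = 99) {
  if (length(x) != length(y)) stop("x and y differ in length")
  cutoff <- stats::quantile(y, trim_pct / 100, type = 7, names = FALSE)
  keep <- y <= cutoff
  if (sum(keep) < 3L) stop("fewer than 3 pairs remain after trimming")
  list(rho = stats::cor(x[keep], y[keep], method = "spearman"),
       n_used = sum(keep), n_trimmed = sum(!keep))
}

#' Intersection of top-n ranked gene lists
#'
#' Truncates each rank-ordered, duplicate-free list to its first `n`
#' elements and reports the common set across all lists plus every pairwise
#' intersection size.
#'
#' @param ranked_lists List (>= 2) of rank-ordered character vectors.
#' @param n Truncation depth.
#' @return List with `common` (character vector), `n_common`, and
#'   `pairwise` (integer matrix of pairwise intersection sizes).
#' @export
top_n_intersection <- function(ranked_lists, n) {
  if (length(ranked_lists) < 2L) stop("need at least two ranked lists")
  for (i in seq_along(ranked_lists)) {
    if (anyDuplicated(ranked_lists[[i]])) {
      stop("list ", i, " contains duplicate identifiers")
    }
  }
  tops <- lapply(ranked_lists, utils::head, n)
  common <- Reduce(intersect, tops)
  k <- length(tops)
  lbl <- names(ranked_lists)
  if (is.null(lbl)) lbl <- paste0("list", seq_len(k))
  pairwise <- matrix(0L, k, k, dimnames = list(lbl, lbl))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      pairwise[i, j] <- length(intersect(tops[[i]], tops[[j]]))
    }
  }
  list(common = common, n_common = length(common), pairwise = pairwise)
}
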