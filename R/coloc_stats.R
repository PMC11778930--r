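# The central colocalization statistic: association between CLIP-peak
# presence and APA-peak presence within analysis 3'-UTRs, tested with an
# exact conditional (hypergeometric) Fisher test.

#' Construct a 2x2 contingency table object
#'
#' @param a UTRs with both an APA and a CLIP reproducible peak.
#' @param b UTRs with an APA peak only.
#' @param c UTRs with a CLIP peak only.
#' @param d UTRs with neither.
#' @return An object of class `contingency_2x2`.
#' @export
contingency_2x2 <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(is.na(cells)) || any(cells < 0) || any(cells != floor(cells))) {
    stop("contingency cells must be non-negative integers")
  }
  structure(as.list(cells), class = "contingency_2x2")
}

#' @export
print.contingency_2x2 <- function(x, ...) {
  m <- matrix(c(x$a, x$b, x$c, x$d), 2, 2,
              dimnames = list(CLIP = c("yes", "no"), APA = c("yes", "no")))
  cat("2x2 contingency table (n =", x$a + x$b + x$c + x$d, "UTRs)\n")
  print(m)
  invisible(x)
}

.as_cells <- function(table) {
  if (inherits(table, "contingency_2x2")) {
    c(table$a, table$b, table$c, table$d)
  } else if (is.numeric(table) && length(table) == 4L) {
    as.vector(table)
  } else {
    stop("expected a contingency_2x2 or a numeric vector (a, b, c, d)")
  }
}

#' Tally peak presence per 3'-UTR into a 2x2 table
#'
#' A UTR "has" a peak iff at least one base of a reproducible peak interval
#' lies within its 3'-UTR genomic interval (half-open boundary semantics: a
#' peak abutting the UTR end does not overlap). Strand is ignored, matching
#' the presence/absence construction.
#'
#' @param utrs Analysis annotation set (pairwise non-overlapping 3'-UTRs,
#'   see [select_analysis_utr3s()]).
#' @param apa_peaks,clip_peaks `GRanges` of reproducible intervals per assay.
#' @return A `contingency_2x2` with attribute `transcripts`, a data frame of
#'   per-UTR presence indicators.
#' @export
build_contingency <- function(utrs, apa_peaks, clip_peaks) {
  u <- utr3_granges(utrs)
  has_apa <- GenomicRanges::countOverlaps(u, apa_peaks,
                                          ignore.strand = TRUE) > 0L
  has_clip <- GenomicRanges::countOverlaps(u, clip_peaks,
                                           ignore.strand = TRUE) > 0L
  tab <- contingency_2x2(
    a = sum(has_apa & has_clip),
    b = sum(has_apa & !has_clip),
    c = sum(!has_apa & has_clip),
    d = sum(!has_apa & !has_clip)
  )
  attr(tab, "transcripts") <- data.frame(
    transcript_id = names(u), has_apa = has_apa, has_clip = has_clip,
    stringsAsFactors = FALSE)
  tab
}

#' Sample odds ratio of a 2x2 table
#'
#' `(a*d)/(b*c)`, with `+Inf` when `b*c == 0` and `a*d > 0`, and `NaN` (the
#' undefined sentinel) when both products are zero. No continuity correction
#' is applied by default; `haldane = TRUE` adds 0.5 to every cell.
#'
#' @param table A `contingency_2x2` or numeric vector `(a, b, c, d)`.
#' @param haldane Apply the Haldane-Anscombe 0.5 correction.
#' @return A single numeric value in `[0, Inf]`, or `NaN` when undefined.
#' @examples
#' odds_ratio(c(10, 5, 3, 12)) # 8
#' @export
odds_ratio <- function(table, haldane = FALSE) {
  cells <- .as_cells(table)
  if (haldane) cells <- cells + 0.5
  ad <- cells[1] * cells[4]
  bc <- cells[2] * cells[3]
  if (bc > 0) ad / bc else if (ad > 0) Inf else NaN
}

#' Fisher's exact test for a 2x2 table
#'
#' Conditional exact test with both margins fixed. The two-sided p-value is
#' the sum of hypergeometric probabilities of all tables (same margins) whose
#' point probability does not exceed the observed one, with an absolute
#' tolerance of `tol` on that comparison; one-sided alternatives sum the
#' corresponding tail.
#'
#' @param table A `contingency_2x2` or numeric vector `(a, b, c, d)`.
#' @param alternative `"two.sided"` (default), `"greater"` (positive
#'   association), or `"less"`.
#' @param tol Absolute tolerance on the point-probability comparison.
#' @return The p-value.
#' @examples
#' fisher_exact(c(3, 1, 1, 3)) # 34/70
#' @export
fisher_exact <- function(table, alternative = c("two.sided", "greater", "less"),
                         tol = 1e-12) {
  alternative <- match.arg(alternative)
  cells <- .as_cells(table)
  a <- cells[1]; b <- cells[2]; c <- cells[3]; d <- cells[4]
  m <- a + b           # APA-positive margin
  n <- c + d           # APA-negative margin
  k <- a + c           # CLIP-positive margin
  if (m + n == 0) return(1)
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  p <- switch(alternative,
    two.sided = sum(probs[probs <= p_obs + tol]),
    greater = sum(probs[support >= a]),
    less = sum(probs[support <= a])
  )
  min(p, 1)
}

#' Full colocalization association analysis
#'
#' The pipeline's central statistic: reproducible peaks are derived per
#' assay, tallied per analysis 3'-UTR into a 2x2 table, and tested with
#' [fisher_exact()]; the sample [odds_ratio()] quantifies the association
#' between CLIP 3'-UTR binding and polyadenylation.
#'
#' @param utrs Analysis annotation set from [select_analysis_utr3s()].
#' @param apa_replicates,clip_replicates Lists of per-replicate peak
#'   `GRanges` (or `replicate_peakset` objects).
#' @param alternative Sidedness of the Fisher test (default two-sided).
#' @return An `association_result`: list with `table`, `odds_ratio`,
#'   `p_value`, `n_utrs`, and the reproducible interval sets.
#' @export
associate <- function(utrs, apa_replicates, clip_replicates,
                      alternative = "two.sided") {
  apa <- reproducible_peaks(apa_replicates)
  clip <- reproducible_peaks(clip_replicates)
  tab <- build_contingency(utrs, apa, clip)
  structure(list(
    table = tab,
    odds_ratio = odds_ratio(tab),
    p_value = fisher_exact(tab, alternative = alternative),
    alternative = alternative,
    n_utrs = tab$a + tab$b + tab$c + tab$d,
    apa_reproducible = apa,
    clip_reproducible = clip
  ), class = "association_result")
}

#' @export
print.association_result <- function(x, ...) {
  print(x$table)
  cat(sprintf("odds ratio = %.4g, Fisher %s p = %.4g\n",
              x$odds_ratio, x$alternative, x$p_value))
  invisible(x)
}

#' Terminal CLIP signal versus 3'-UTR length
#'
#' Spearman correlation between per-UTR terminal-window signal and 3'-UTR
#' length — the independence check for whether short UTRs carry more signal
#' at their termini than long ones.
#'
#' @param per_utr_terminal_signal Numeric vector of terminal-window signal.
#' @param utr3_lengths Paired numeric vector of 3'-UTR lengths (nt).
#' @return List with `rho` (NA with a warning when either vector is
#'   constant) and `n`.
#' @export
signal_vs_utr3_length <- function(per_utr_terminal_signal, utr3_lengths) {
  if (length(per_utr_terminal_signal) != length(utr3_lengths)) {
    stop("signal and length vectors differ in length")
  }
  n <- length(utr3_lengths)
  if (n < 3L) stop("need at least 3 paired observations")
  if (stats::sd(per_utr_terminal_signal) == 0 || stats::sd(utr3_lengths) == 0) {
    warning("constant vector: Spearman correlation undefined")
    return(list(rho = NA_real_, n = n))
  }
  list(rho = stats::cor(per_utr_terminal_signal, utr3_lengths,
                        method = "spearman"),
       n = n)
}
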