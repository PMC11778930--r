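# Polyadenylation-signal hexamer scanning and crosslink-to-terminus
# geometry. The canonical PAS is AAUAAA; motif sets are configurable.
# Sequences may be written in RNA (U) or DNA (T) alphabet interchangeably.

.normalize_seq <- function(x) toupper(chartr("Uu", "Tt", x))

# per-sequence 0-based motif start positions, as a list parallel to `seqs`
.motif_positions <- function(seqs, motifs) {
  motifs <- .normalize_seq(motifs)
  subject <- Biostrings::DNAStringSet(.normalize_seq(seqs))
  hits <- vector("list", length(seqs))
  for (i in seq_along(hits)) hits[[i]] <- integer(0)
  for (motif in motifs) {
    mstarts <- Biostrings::startIndex(
      Biostrings::vmatchPattern(motif, subject))
    for (i in seq_along(hits)) {
      if (!is.null(mstarts[[i]])) {
        hits[[i]] <- c(hits[[i]], mstarts[[i]] - 1L)
      }
    }
  }
  lapply(hits, function(p) sort(unique(p)))
}

#' Find polyadenylation-signal motifs in a sequence
#'
#' Scans a nucleotide sequence for every (possibly overlapping) occurrence of
#' the given hexamers. `T` and `U` are equivalent in both sequence and
#' motifs; `N` never matches.
#'
#' @param sequence A single nucleotide string over `A, C, G, T, U, N`.
#' @param motifs Character vector of motifs (default the canonical PAS
#'   `AAUAAA`).
#' @return Sorted integer vector of 0-based start positions.
#' @examples
#' find_pas("GGAATAAAGC")  # 2
#' find_pas("AATAAATAAA")  # 0 4
#' @export
find_pas <- function(sequence, motifs = .canonical_pas) {
  stopifnot(length(sequence) == 1L)
  .motif_positions(sequence, motifs)[[1L]]
}

# Shared hit machinery: peak i (0-based half-open [start, end) in UTR-local
# coordinates) "hits" iff >= 1 motif occurrence lies fully inside the window
# [start - flank, end + flank) clipped to the UTR.
.pas_window_hits <- function(starts, ends, tx_idx, pos_flat, len_flat,
                             peak_of_pos, utr_len, flank) {
  w0 <- pmax(0L, starts - flank)
  w1 <- pmin(utr_len[tx_idx], ends + flank)
  hit <- logical(length(starts))
  if (length(pos_flat)) {
    ok <- pos_flat >= w0[peak_of_pos] & pos_flat + len_flat <= w1[peak_of_pos]
    hit[peak_of_pos[ok]] <- TRUE
  }
  hit
}

# Precompute the flattened (peak -> candidate motif position) map used by
# both the observed statistic and the shuffle null.
.pas_scan_setup <- function(peaks, utr_seqs, motifs) {
  tx <- unique(peaks$transcript_id)
  pos_by_tx <- .motif_positions(utr_seqs[tx], motifs)
  names(pos_by_tx) <- tx
  # motif length per position (motifs may in principle differ in length)
  len_by_tx <- lapply(tx, function(t) {
    p <- pos_by_tx[[t]]
    if (!length(p)) return(integer(0))
    s <- .normalize_seq(utr_seqs[[t]])
    vapply(p, function(q) {
      ok <- vapply(.normalize_seq(motifs), function(m) {
        substring(s, q + 1L, q + nchar(m)) == m
      }, logical(1))
      max(nchar(motifs)[ok])
    }, integer(1))
  })
  tx_idx <- match(peaks$transcript_id, tx)
  npos <- lengths(pos_by_tx)[tx_idx]
  peak_of_pos <- rep(seq_len(nrow(peaks)), npos)
  list(
    tx_idx = tx_idx,
    utr_len = nchar(utr_seqs[tx]),
    pos_flat = unlist(pos_by_tx[tx_idx], use.names = FALSE),
    len_flat = unlist(len_by_tx[tx_idx], use.names = FALSE),
    peak_of_pos = peak_of_pos
  )
}

#' Fraction of peaks with a PAS in their flanked window
#'
#' For each UTR-local peak, the window `[start - flank, end + flank)` clipped
#' to the UTR is scanned for a motif occurrence; the fraction of peaks with
#' at least one hit is returned. Peaks on transcripts without an available
#' sequence are excluded and counted.
#'
#' @param peaks Data frame with columns `transcript_id`, `start`, `end`
#'   (0-based half-open, local to the 3'-UTR sequence).
#' @param utr_seqs Named character vector of 3'-UTR sequences (names =
#'   `transcript_id`).
#' @param flank Flank width in nt added on each side of the peak
#'   (default 25).
#' @param motifs Motif set (default canonical PAS).
#' @return List with `fraction`, `n_peaks` (scored), `n_excluded`, and the
#'   per-peak logical vector `hit`.
#' @export
peak_pas_fraction <- function(peaks, utr_seqs, flank = 25L,
                              motifs = .canonical_pas) {
  have <- peaks$transcript_id %in% names(utr_seqs)
  n_excluded <- sum(!have)
  peaks <- peaks[have, , drop = FALSE]
  if (nrow(peaks) == 0L) {
    return(list(fraction = NaN, n_peaks = 0L, n_excluded = n_excluded,
                hit = logical(0)))
  }
  setup <- .pas_scan_setup(peaks, utr_seqs, motifs)
  hit <- .pas_window_hits(peaks$start, peaks$end, setup$tx_idx,
                          setup$pos_flat, setup$len_flat, setup$peak_of_pos,
                          setup$utr_len, flank)
  list(fraction = mean(hit), n_peaks = nrow(peaks),
       n_excluded = n_excluded, hit = hit)
}

#' Positional PAS enrichment with a within-UTR shuffle null
#'
#' Compares the observed PAS-window fraction of peaks against a null in
#' which each peak's start is redrawn uniformly within its own UTR (same
#' peak width), preserving per-UTR peak count, width, and sequence
#' composition. The empirical p-value is
#' `(1 + #\{null fraction >= observed\}) / (n_shuffles + 1)`, so its floor is
#' `1 / (n_shuffles + 1)`. Deterministic given `seed`.
#'
#' @inheritParams peak_pas_fraction
#' @param n_shuffles Number of shuffles (>= 100).
#' @param seed Integer seed for the shuffle draws.
#' @return A `pas_enrichment` object: list with `observed_fraction`,
#'   `null_fractions`, `empirical_p`, `window` (the flank), `n_peaks`, and
#'   `n_skipped` (peaks wider than their UTR).
#' @export
pas_positional_enrichment <- function(peaks, utr_seqs, flank = 25L,
                                      motifs = .canonical_pas,
                                      n_shuffles = 1000L, seed = 1L) {
  if (n_shuffles < 100L) stop("n_shuffles must be >= 100")
  have <- peaks$transcript_id %in% names(utr_seqs)
  peaks <- peaks[have, , drop = FALSE]
  width <- peaks$end - peaks$start
  utr_len_all <- nchar(utr_seqs)[peaks$transcript_id]
  fits <- width <= utr_len_all
  n_skipped <- sum(!fits) + sum(!have)
  if (n_skipped > 0L) {
    warning(n_skipped, " peak(s) skipped (no sequence or wider than UTR)")
  }
  peaks <- peaks[fits, , drop = FALSE]
  width <- width[fits]
  if (nrow(peaks) == 0L) stop("no scorable peaks")
  setup <- .pas_scan_setup(peaks, utr_seqs, motifs)
  observed <- mean(.pas_window_hits(peaks$start, peaks$end, setup$tx_idx,
                                    setup$pos_flat, setup$len_flat,
                                    setup$peak_of_pos, setup$utr_len, flank))
  L <- setup$utr_len[setup$tx_idx]
  n <- nrow(peaks)
  set.seed(seed)
  null_fractions <- vapply(seq_len(n_shuffles), function(i) {
    s <- as.integer(floor(stats::runif(n) * (L - width + 1L)))
    mean(.pas_window_hits(s, s + width, setup$tx_idx, setup$pos_flat,
                          setup$len_flat, setup$peak_of_pos,
                          setup$utr_len, flank))
  }, numeric(1))
  structure(list(
    observed_fraction = observed,
    null_fractions = null_fractions,
    empirical_p = (1 + sum(null_fractions >= observed)) / (n_shuffles + 1),
    window = flank,
    n_peaks = n,
    n_skipped = n_skipped,
    motifs = motifs,
    seed = seed
  ), class = "pas_enrichment")
}

#' @export
print.pas_enrichment <- function(x, ...) {
  cat(sprintf(
    "PAS window enrichment: observed fraction %.3f over %d peaks (flank %d nt)\n",
    x$observed_fraction, x$n_peaks, x$window))
  cat(sprintf("empirical p = %.4g (%d shuffles, null mean %.3f)\n",
              x$empirical_p, length(x$null_fractions),
              mean(x$null_fractions)))
  invisible(x)
}

#' Distance from each peak's 3' edge to its UTR terminus
#'
#' Strand-aware distance in nucleotides between a peak's 3' edge and the 3'
#' terminus of the UTR containing it: on `+` the UTR end minus the peak end,
#' on `-` the peak start minus the UTR start. Peaks must lie entirely within
#' a UTR.
#'
#' @param peaks `GRanges` of peaks.
#' @param utrs Transcript annotation data frame (3'-UTR intervals and
#'   strands are taken from it).
#' @return Integer vector of non-negative distances, one per peak, named by
#'   the containing `transcript_id`.
#' @export
terminal_distance_distribution <- function(peaks, utrs) {
  u <- utr3_granges(utrs)
  hits <- GenomicRanges::findOverlaps(peaks, u, type = "within",
                                      ignore.strand = TRUE)
  found <- S4Vectors::queryHits(hits)
  if (length(unique(found)) < length(peaks)) {
    miss <- setdiff(seq_along(peaks), found)[1L]
    stop("peak ", miss, " (", as.character(peaks[miss]),
         ") is not contained in any 3'-UTR")
  }
  first <- !duplicated(found)
  qi <- found[first]
  si <- S4Vectors::subjectHits(hits)[first]
  strand <- as.character(GenomicRanges::strand(u))[si]
  dist <- ifelse(strand == "+",
                 GenomicRanges::end(u)[si] - GenomicRanges::end(peaks)[qi],
                 GenomicRanges::start(peaks)[qi] - GenomicRanges::start(u)[si])
  stats::setNames(as.integer(dist)[order(qi)], names(u)[si][order(qi)])
}
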