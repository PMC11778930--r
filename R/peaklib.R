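# Replicate-reproducible peak derivation and coverage normalization.

#' Reproducible peaks across biological replicates
#'
#' Computes the maximal contiguous genomic runs of bases covered by at least
#' one peak in *every* replicate: each replicate's peaks are merged to their
#' covered base set, the base sets are intersected across replicates, and
#' the intersection is reported as merged intervals. With a single replicate
#' this reduces to merging touching/overlapping peaks. The operation is
#' deterministic and order-independent, and adding a replicate can only
#' shrink (or preserve) the result.
#'
#' @param replicates List of `GRanges` (one per replicate), or the
#'   `replicate_peakset` returned by [simulate_peaks()].
#' @param ignore_strand Intersect base sets regardless of strand
#'   (default `TRUE`).
#' @return A `GRanges` of non-overlapping reproducible intervals.
#' @examples
#' r1 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 120))
#' r2 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(111, 130))
#' r3 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(116, 125))
#' reproducible_peaks(list(r1, r2, r3)) # 1-based [116,120] == BED [115,120)
#' @export
reproducible_peaks <- function(replicates, ignore_strand = TRUE) {
  if (inherits(replicates, "replicate_peakset")) {
    replicates <- replicates$replicates
  }
  if (length(replicates) < 1L) stop("need at least one replicate")
  covered <- lapply(replicates, function(g) {
    GenomicRanges::reduce(GenomicRanges::granges(g),
                          ignore.strand = ignore_strand)
  })
  if (!ignore_strand) {
    out <- Reduce(function(x, y) {
      GenomicRanges::intersect(x, y, ignore.strand = FALSE)
    }, covered)
    return(GenomicRanges::reduce(out))
  }
  # a base is reproducible iff covered in every replicate: with each
  # replicate reduced first, that is exactly coverage >= n_replicates
  pooled <- suppressWarnings(do.call(c, covered))
  if (length(pooled) == 0L) return(GenomicRanges::granges(pooled))
  cov <- GenomicRanges::coverage(pooled)
  hits <- IRanges::slice(cov, lower = length(replicates), rangesOnly = TRUE)
  methods::as(hits, "GRanges")
}

#' Counts-per-million normalization
#'
#' Multiplies per-base counts by `1e6 / library_size`.
#'
#' @param raw_coverage Numeric vector (or list of numeric vectors, e.g. per
#'   chromosome) of non-negative per-base counts.
#' @param library_size Total mapped reads; must be positive.
#' @return Normalized coverage with the same shape as the input.
#' @export
cpm_normalize <- function(raw_coverage, library_size) {
  if (length(library_size) != 1L || is.na(library_size) || library_size <= 0) {
    stop("library_size must be a single positive number")
  }
  if (is.list(raw_coverage)) {
    return(lapply(raw_coverage, cpm_normalize, library_size = library_size))
  }
  if (any(raw_coverage < 0)) stop("coverage values must be non-negative")
  raw_coverage * 1e6 / library_size
}
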