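# Gene-architecture logic: expression units, analysis-set 3'-UTR selection,
# and region classification of crosslink positions.

#' Transcripts-per-million from counts and lengths
#'
#' `TPM_i = 1e6 * (c_i / L_i) / sum_j (c_j / L_j)`. The output always sums to
#' one million.
#'
#' @param counts Non-negative per-transcript counts (at least one positive).
#' @param lengths Positive per-transcript lengths in nucleotides.
#' @return Numeric vector of TPM values, named like `counts`.
#' @examples
#' compute_tpm(c(10, 10), c(1000, 2000))
#' @export
compute_tpm <- function(counts, lengths) {
  if (length(counts) != length(lengths)) {
    stop("counts and lengths differ in length")
  }
  if (any(lengths <= 0)) stop("all lengths must be > 0")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (all(counts == 0)) stop("all counts are zero: TPM undefined")
  rate <- counts / lengths
  tpm <- 1e6 * rate / sum(rate)
  names(tpm) <- names(counts)
  tpm
}

#' Select the non-overlapping expressed 3'-UTR analysis set
#'
#' Keeps transcripts that are expressed (`TPM > tpm_min`), carry a 3'-UTR
#' longer than `min_len` nucleotides, and whose 3'-UTR genomic interval does
#' not overlap (>= 1 shared base) the 3'-UTR of any other kept candidate.
#' Every member of an overlapping cluster is discarded — the conservative
#' resolution of isoform ambiguity: no arbitrary representative is kept.
#'
#' @param annotations Transcript annotation data frame
#'   (see [read_transcript_table()]).
#' @param tpm Named numeric vector of TPM values covering every
#'   `transcript_id` in `annotations`.
#' @param tpm_min Strict expression threshold (default 1: keeps TPM > 1).
#' @param min_len Strict 3'-UTR length threshold in nt (default 50).
#' @param same_strand If `TRUE`, only same-strand overlaps disqualify; the
#'   default ignores strand (more conservative).
#' @return The subset of `annotations` passing all filters.
#' @export
select_analysis_utr3s <- function(annotations, tpm, tpm_min = 1.0,
                                  min_len = 50L, same_strand = FALSE) {
  missing <- setdiff(annotations$transcript_id, names(tpm))
  if (length(missing)) {
    stop("no expression value for transcript(s): ",
         paste(utils::head(missing, 3), collapse = ", "))
  }
  expr <- tpm[annotations$transcript_id]
  cand <- annotations[expr > tpm_min & annotations$utr3_len > min_len, ,
                      drop = FALSE]
  if (nrow(cand) == 0L) return(cand)
  gr <- utr3_granges(cand)
  hits <- GenomicRanges::findOverlaps(gr, drop.self = TRUE,
                                      ignore.strand = !same_strand)
  clustered <- unique(names(gr)[S4Vectors::queryHits(hits)])
  cand[!cand$transcript_id %in% clustered, , drop = FALSE]
}

#' Classify transcript positions into 5'-UTR / CDS / 3'-UTR
#'
#' Tallies 0-based transcript-coordinate positions (e.g. crosslink sites)
#' into the three mRNA regions. Positions falling outside their transcript's
#' bounds are counted as `unassigned` and reported with a warning; fractions
#' are computed over assigned positions only and sum to 1.
#'
#' @param positions Data frame with columns `transcript_id` and `pos`
#'   (0-based transcript coordinate).
#' @param annotations Transcript annotation data frame.
#' @return List with `counts` (named integer vector over
#'   `utr5, cds, utr3, unassigned`), `fractions` (over the three regions),
#'   and `n` (assigned positions).
#' @export
classify_positions <- function(positions, annotations) {
  idx <- match(positions$transcript_id, annotations$transcript_id)
  if (anyNA(idx)) {
    stop("position references unknown transcript '",
         positions$transcript_id[which(is.na(idx))[1L]], "'")
  }
  utr5 <- annotations$utr5_len[idx]
  cds_end <- utr5 + annotations$cds_len[idx]
  total <- annotations$transcript_length[idx]
  pos <- positions$pos
  region <- rep("unassigned", length(pos))
  inside <- pos >= 0L & pos < total
  region[inside & pos < utr5] <- "utr5"
  region[inside & pos >= utr5 & pos < cds_end] <- "cds"
  region[inside & pos >= cds_end] <- "utr3"
  counts <- vapply(c("utr5", "cds", "utr3", "unassigned"),
                   function(r) sum(region == r), integer(1))
  n_assigned <- sum(counts[c("utr5", "cds", "utr3")])
  if (counts[["unassigned"]] > 0L) {
    warning(counts[["unassigned"]],
            " position(s) outside transcript bounds counted as unassigned")
  }
  fractions <- if (n_assigned > 0L) {
    counts[c("utr5", "cds", "utr3")] / n_assigned
  } else {
    stats::setNames(rep(NA_real_, 3), c("utr5", "cds", "utr3"))
  }
  list(counts = counts, fractions = fractions, n = n_assigned)
}
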