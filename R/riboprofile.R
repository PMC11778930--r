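# P1-nuclease ribosome-profiling computation: footprint classes, frame-based
# A-site assignment, CDS occupancy windowing, and length-stratified rescaled
# metagene profiles.

.default_offsets <- c(15L, 16L, 17L)

# accept c(15,16,17) or c(`0`=15, `1`=16, `2`=17)
.as_offsets <- function(offsets) {
  if (!is.null(names(offsets)) && all(c("0", "1", "2") %in% names(offsets))) {
    offsets <- offsets[c("0", "1", "2")]
  }
  offsets <- as.integer(offsets)
  if (length(offsets) != 3L || any(is.na(offsets)) || any(offsets < 0L)) {
    stop("offsets must map frames 0,1,2 to non-negative integers")
  }
  offsets
}

#' Classify a footprint by length and library
#'
#' In a monosome library, footprints of 32-40 nt are monosomes and anything
#' else is unassigned. In a disome library, footprints of >= 60 nt are the
#' true-disome population (colliding ribosome pairs) and shorter ones the
#' sub-disome population.
#'
#' @param length Integer vector of footprint lengths (nt, >= 1).
#' @param library `"monosome_lib"` or `"disome_lib"`.
#' @return Character vector of classes: `monosome`, `sub_disome`,
#'   `true_disome`, or `unassigned`.
#' @examples
#' classify_footprint(c(31, 32, 40, 41), "monosome_lib")
#' classify_footprint(c(59, 60), "disome_lib")
#' @export
classify_footprint <- function(length, library = c("monosome_lib", "disome_lib")) {
  library <- match.arg(library)
  if (any(length < 1L)) stop("footprint length must be >= 1")
  if (library == "monosome_lib") {
    ifelse(length >= 32L & length <= 40L, "monosome", "unassigned")
  } else {
    ifelse(length >= 60L, "true_disome", "sub_disome")
  }
}

#' Assign the A-site codon of each footprint
#'
#' The reading frame of the footprint's 5' end relative to the start codon
#' determines the A-site offset: `frame = (five_prime_pos - utr5_len) mod 3`
#' (mathematical mod, in `{0,1,2}`), the A-site nucleotide is
#' `five_prime_pos + offsets[frame]`, and the codon index is
#' `floor((a_site_nt - utr5_len) / 3)`. Codons may be negative (A-site in
#' the 5'-UTR) or beyond the CDS (3'-UTR) and are returned as-is.
#'
#' @param footprints Data frame with `transcript_id`, `five_prime_pos`
#'   (0-based transcript coordinate), `length`.
#' @param annotations Transcript annotation data frame; every footprint's
#'   transcript must be present.
#' @param offsets Frame-to-offset map, either `c(15, 16, 17)` (frames
#'   0, 1, 2) or a vector named `"0","1","2"`.
#' @return Integer vector of 0-based A-site codon indices.
#' @examples
#' ann <- data.frame(transcript_id = "t1", gene_id = "g1", chrom = "chr1",
#'                   strand = "+", utr5_len = 50L, cds_len = 300L,
#'                   utr3_len = 100L, utr3_start = 350L, utr3_end = 450L,
#'                   transcript_length = 450L)
#' fp <- data.frame(transcript_id = "t1", five_prime_pos = c(50L, 52L),
#'                  length = 34L, sample = "s")
#' assign_a_site(fp, ann)  # codons 5 and 6
#' @export
assign_a_site <- function(footprints, annotations,
                          offsets = .default_offsets) {
  offsets <- .as_offsets(offsets)
  idx <- match(footprints$transcript_id, annotations$transcript_id)
  if (anyNA(idx)) {
    stop("no annotation for transcript '",
         footprints$transcript_id[which(is.na(idx))[1L]], "'")
  }
  utr5 <- annotations$utr5_len[idx]
  frame <- (footprints$five_prime_pos - utr5) %% 3L
  a_site_nt <- footprints$five_prime_pos + offsets[frame + 1L]
  as.integer((a_site_nt - utr5) %/% 3L)
}

#' CDS occupancy counts inside a codon window
#'
#' Counts a read for its gene iff its A-site codon `c` (1-based) satisfies
#' `first_codon <= c <= n_codons - last_codon_from_end`. The default window
#' (15th codon to 10th-from-last) excludes initiation and termination
#' regions from occupancy quantification.
#'
#' @inheritParams assign_a_site
#' @param first_codon First counted codon, 1-based (default 15).
#' @param last_codon_from_end Codons excluded at the CDS 3' end
#'   (default 10).
#' @return Integer matrix of counts, genes x samples (all annotated genes
#'   and all observed samples appear, zero-filled).
#' @export
cds_occupancy_counts <- function(footprints, annotations,
                                 offsets = .default_offsets,
                                 first_codon = 15L, last_codon_from_end = 10L) {
  idx <- match(footprints$transcript_id, annotations$transcript_id)
  codon1 <- assign_a_site(footprints, annotations, offsets) + 1L
  n_codons <- annotations$cds_len[idx] %/% 3L
  keep <- codon1 >= first_codon & codon1 <= n_codons - last_codon_from_end
  genes <- unique(annotations$gene_id)
  samples <- sort(unique(footprints$sample))
  counts <- table(
    factor(annotations$gene_id[idx][keep], levels = genes),
    factor(footprints$sample[keep], levels = samples)
  )
  m <- matrix(as.integer(counts), nrow = length(genes),
              dimnames = list(genes, samples))
  m
}

#' Length-stratified rescaled metagene profile
#'
#' For each gene passing the architecture and depth filters, every read
#' contributes `1 / scale_g` to the cell (read length, 5'-end position
#' relative to the anchor base), where `scale_g` is the gene's mean CDS
#' reads per codon (CDS-mapped read count over codon count); cells are then
#' summed over genes and divided by the number of passing genes. The
#' per-gene rescaling removes sequencing-depth differences: a gene 10x
#' deeper than another with the same footprint distribution contributes
#' identically.
#'
#' @inheritParams assign_a_site
#' @param anchor `"start_codon"` or `"stop_codon"`; position 0 is the first
#'   nucleotide of the anchor codon.
#' @param min_utr5,min_cds,min_utr3 Minimum annotated segment lengths in nt
#'   (defaults 50 / 450 / 50).
#' @param min_reads_per_codon Minimum mean CDS reads per codon (default 1).
#' @param position_range Length-2 integer vector: range of 5'-end positions
#'   relative to the anchor (default `c(-30, 90)`).
#' @return A `metagene_profile`: list with `anchor`, `positions`, `profile`
#'   (matrix, length bins x positions), `n_genes`, `n_reads_used`.
#' @export
metagene_profile <- function(footprints, annotations,
                             anchor = c("start_codon", "stop_codon"),
                             offsets = .default_offsets,
                             min_utr5 = 50L, min_cds = 450L, min_utr3 = 50L,
                             min_reads_per_codon = 1.0,
                             position_range = c(-30L, 90L)) {
  anchor <- match.arg(anchor)
  idx <- match(footprints$transcript_id, annotations$transcript_id)
  if (anyNA(idx)) {
    stop("no annotation for transcript '",
         footprints$transcript_id[which(is.na(idx))[1L]], "'")
  }
  total <- annotations$transcript_length[idx]
  bad <- footprints$five_prime_pos + footprints$length > total
  if (any(bad)) {
    stop(sum(bad), " footprint(s) extend past their transcript 3' end ",
         "(first: row ", which(bad)[1L], ")")
  }
  # per-transcript CDS-mapped read counts (A-site codon inside the CDS)
  codon0 <- assign_a_site(footprints, annotations, offsets)
  n_codons <- annotations$cds_len %/% 3L
  in_cds <- codon0 >= 0L & codon0 < n_codons[idx]
  cds_count <- table(factor(footprints$transcript_id[in_cds],
                            levels = annotations$transcript_id))
  cds_count <- as.numeric(cds_count)
  scale <- cds_count / n_codons
  pass <- annotations$utr5_len >= min_utr5 &
    annotations$cds_len >= min_cds &
    annotations$utr3_len >= min_utr3 &
    scale >= min_reads_per_codon
  if (!any(pass)) {
    stop("no gene passes the metagene filters (utr5>=", min_utr5,
         ": ", sum(annotations$utr5_len >= min_utr5),
         "; cds>=", min_cds, ": ", sum(annotations$cds_len >= min_cds),
         "; utr3>=", min_utr3, ": ", sum(annotations$utr3_len >= min_utr3),
         "; reads/codon>=", min_reads_per_codon, ": ",
         sum(scale >= min_reads_per_codon), ")")
  }
  anchor_pos <- if (anchor == "start_codon") {
    annotations$utr5_len
  } else {
    annotations$utr5_len + annotations$cds_len - 3L
  }
  use <- pass[idx]
  r <- footprints$five_prime_pos[use] - anchor_pos[idx][use]
  in_range <- r >= position_range[1L] & r <= position_range[2L]
  r <- r[in_range]
  len <- footprints$length[use][in_range]
  w <- 1 / scale[idx][use][in_range]
  positions <- seq(position_range[1L], position_range[2L])
  lengths_seen <- sort(unique(len))
  if (length(lengths_seen) == 0L) lengths_seen <- integer(0)
  acc <- stats::xtabs(w ~ factor(len, levels = lengths_seen) +
                        factor(r, levels = positions))
  profile <- matrix(as.numeric(acc), nrow = length(lengths_seen),
                    dimnames = list(as.character(lengths_seen),
                                    as.character(positions)))
  structure(list(
    anchor = anchor,
    positions = positions,
    profile = profile / sum(pass),
    n_genes = sum(pass),
    n_reads_used = length(r),
    transcripts = annotations$transcript_id[pass]
  ), class = "metagene_profile")
}

#' @export
print.metagene_profile <- function(x, ...) {
  cat(sprintf(
    "metagene profile at %s: %d genes, %d reads, positions %d..%d, %d length bin(s)\n",
    x$anchor, x$n_genes, x$n_reads_used, min(x$positions), max(x$positions),
    nrow(x$profile)))
  invisible(x)
}

#' Bin a metagene profile by read length
#'
#' Sums profile rows within inclusive length ranges (e.g. 58, 59, 60 nt
#' binned to 58-60 nt); positions are untouched. Bins must not overlap.
#'
#' @param profile A `metagene_profile`.
#' @param bins List of length-2 inclusive ranges, e.g.
#'   `list(c(58, 60), c(61, 63))`.
#' @return A `metagene_profile` whose rows are the bins.
#' @export
bin_profile_lengths <- function(profile, bins) {
  lo <- vapply(bins, function(b) as.integer(b[1L]), integer(1))
  hi <- vapply(bins, function(b) as.integer(b[2L]), integer(1))
  if (any(hi < lo)) stop("bin upper bound below lower bound")
  ord <- order(lo)
  if (any(lo[ord][-1L] <= hi[ord][-length(ord)])) {
    stop("length bins overlap")
  }
  lens <- as.integer(rownames(profile$profile))
  binned <- t(vapply(seq_along(bins), function(i) {
    rows <- lens >= lo[i] & lens <= hi[i]
    if (any(rows)) {
      colSums(profile$profile[rows, , drop = FALSE])
    } else {
      numeric(ncol(profile$profile))
    }
  }, numeric(ncol(profile$profile))))
  rownames(binned) <- ifelse(lo == hi, as.character(lo),
                             sprintf("%d-%d", lo, hi))
  colnames(binned) <- colnames(profile$profile)
  out <- profile
  out$profile <- binned
  out
}
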