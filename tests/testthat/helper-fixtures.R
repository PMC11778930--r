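# Shared fixture builders and independent oracles. Oracles are deliberately
# naive (per-base membership, O(n^2) scans, full enumeration) and stay
# independent of the implementation paths they check.

make_annotation <- function(transcript_id = "t1", gene_id = transcript_id,
                            chrom = "chr1", strand = "+",
                            utr5_len = 50L, cds_len = 300L, utr3_len = 200L,
                            utr3_start = 1000L,
                            utr3_end = utr3_start + utr3_len) {
  validate_transcript_annotations(data.frame(
    transcript_id = transcript_id, gene_id = gene_id, chrom = chrom,
    strand = strand, utr5_len = utr5_len, cds_len = cds_len,
    utr3_len = utr3_len, utr3_start = utr3_start, utr3_end = utr3_end,
    stringsAsFactors = FALSE))
}

gr <- function(chrom, start0, end0, strand = "+") {
  GenomicRanges::GRanges(chrom,
                         IRanges::IRanges(start0 + 1L, end0),
                         strand = strand)
}

# per-base membership oracle for reproducible peaks: enumerate every base
# covered in all replicates
oracle_reproducible_bases <- function(replicates) {
  per_rep <- lapply(replicates, function(g) {
    unique(as.character(unlist(mapply(function(chr, s, e) {
      paste0(chr, ":", seq(s, e))
    }, as.character(GenomicRanges::seqnames(g)),
    GenomicRanges::start(g), GenomicRanges::end(g),
    SIMPLIFY = FALSE), use.names = FALSE)))
  })
  sort(as.character(Reduce(intersect, per_rep)))
}

bases_of <- function(g) {
  if (length(g) == 0L) return(character(0))
  sort(unique(unlist(mapply(function(chr, s, e) paste0(chr, ":", seq(s, e)),
                            as.character(GenomicRanges::seqnames(g)),
                            GenomicRanges::start(g),
                            GenomicRanges::end(g),
                            SIMPLIFY = FALSE), use.names = FALSE)))
}

# full-enumeration Fisher oracle computed from binomial coefficients, not
# from dhyper
oracle_fisher_two_sided <- function(a, b, c, d, tol = 1e-12) {
  m <- a + b; n <- c + d; k <- a + c
  support <- max(0, k - n):min(k, m)
  prob <- choose(m, support) * choose(n, k - support) / choose(m + n, k)
  p_obs <- choose(m, a) * choose(n, k - a) / choose(m + n, k)
  min(1, sum(prob[prob <= p_obs + tol]))
}

# naive sliding-window motif scan (0-based starts, T/U equivalent)
oracle_find_motif <- function(sequence, motif) {
  s <- toupper(chartr("Uu", "Tt", sequence))
  m <- toupper(chartr("Uu", "Tt", motif))
  k <- nchar(m)
  hits <- integer(0)
  if (nchar(s) >= k) {
    for (i in 0:(nchar(s) - k)) {
      if (substr(s, i + 1, i + k) == m) hits <- c(hits, i)
    }
  }
  hits
}

random_peak_granges <- function(n, chrom = "chr1", max_pos = 500L,
                                max_width = 30L) {
  s <- sample.int(max_pos, n, replace = TRUE)
  w <- sample.int(max_width, n, replace = TRUE)
  GenomicRanges::GRanges(chrom, IRanges::IRanges(s, s + w - 1L))
}
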