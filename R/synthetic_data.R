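# Synthetic-data generator with planted, recorded ground truth. Every
# output is a pure function of (seed, configuration); regeneration from the
# same seed is byte-identical. The generator emulates the study conditions:
# 3'-UTRs carrying a canonical PAS hexamer near the terminus, APA peaks at
# poly(A) sites, CLIP peaks whose presence is associated with
# polyadenylation at a controllable odds ratio, three replicates per assay
# with jitter/dropout noise, P1-nuclease footprint length distributions
# with frame-dependent 5'-end offsets, and negative-binomial mRNA counts
# with per-gene translation efficiency.

#' Generate a synthetic transcriptome with planted PAS hexamers
#'
#' Draws single-isoform transcripts with lognormal segment lengths
#' (CDS lengths as multiples of 3), random-composition sequences, and — for
#' the polyadenylated fraction — a canonical PAS hexamer planted with its
#' start uniformly in a terminal window of the 3'-UTR. Non-polyadenylated
#' (histone-like) transcripts receive no planted motif and are flagged.
#' 3'-UTR genomic intervals are placed non-overlapping along one synthetic
#' chromosome, alternating strands.
#'
#' @param n_genes Number of transcripts/genes.
#' @param seed Integer seed; the generator is a pure function of
#'   `(seed, parameters)`.
#' @param frac_polyadenylated Fraction of transcripts carrying a planted
#'   PAS (default 0.7).
#' @param pas_terminal_window Length-2 integer vector: the planted motif
#'   start lies this many nt upstream of the transcript 3' end
#'   (default `c(10, 40)`).
#' @param utr5_meanlog,utr5_sdlog,utr5_min Lognormal parameters and floor
#'   for 5'-UTR lengths.
#' @param cds_codons_meanlog,cds_codons_sdlog,cds_codons_min Lognormal
#'   parameters and floor for CDS length in codons (floor 150 keeps most
#'   CDSs >= 450 nt so metagene filters retain genes).
#' @param utr3_meanlog,utr3_sdlog,utr3_min Lognormal parameters and floor
#'   for 3'-UTR lengths; the floor (60 nt) always accommodates the terminal
#'   window, and any infeasible draw is resampled.
#' @return A `synthetic_transcriptome`: list with `annotations` (transcript
#'   table data frame), `sequences` (named character vector of full
#'   transcript sequences, DNA alphabet), and `truth` (seed, parameters,
#'   and a per-transcript data frame with `polyadenylated`, `pas_local`
#'   (0-based transcript coordinate of the planted motif start, NA when
#'   absent) and `pas_distance` (motif start to transcript 3' end)).
#' @export
generate_transcriptome <- function(n_genes = 2000L, seed = 1L,
                                   frac_polyadenylated = 0.7,
                                   pas_terminal_window = c(10L, 40L),
                                   utr5_meanlog = log(120), utr5_sdlog = 0.4,
                                   utr5_min = 30L,
                                   cds_codons_meanlog = log(400),
                                   cds_codons_sdlog = 0.5,
                                   cds_codons_min = 150L,
                                   utr3_meanlog = log(450), utr3_sdlog = 0.6,
                                   utr3_min = 60L) {
  stopifnot(frac_polyadenylated >= 0, frac_polyadenylated <= 1,
            pas_terminal_window[1L] >= 6L,
            pas_terminal_window[2L] >= pas_terminal_window[1L])
  set.seed(seed)
  n <- as.integer(n_genes)
  utr5 <- pmax(utr5_min, as.integer(round(
    stats::rlnorm(n, utr5_meanlog, utr5_sdlog))))
  codons <- pmax(cds_codons_min, as.integer(round(
    stats::rlnorm(n, cds_codons_meanlog, cds_codons_sdlog))))
  cds <- 3L * codons
  utr3 <- pmax(utr3_min, as.integer(round(
    stats::rlnorm(n, utr3_meanlog, utr3_sdlog))))
  # resample any 3'-UTR too short for the terminal window (floor makes this
  # rare, but the guarantee is explicit)
  short <- utr3 < pas_terminal_window[2L] + 6L
  while (any(short)) {
    utr3[short] <- pmax(utr3_min, as.integer(round(
      stats::rlnorm(sum(short), utr3_meanlog, utr3_sdlog))))
    short <- utr3 < pas_terminal_window[2L] + 6L
  }
  total <- utr5 + cds + utr3
  polyadenylated <- stats::runif(n) < frac_polyadenylated

  bases <- c("A", "C", "G", "T")
  all_seq <- sample(bases, sum(total), replace = TRUE)
  ends <- cumsum(total)
  starts <- ends - total + 1L
  sequences <- vapply(seq_len(n), function(i) {
    paste(all_seq[starts[i]:ends[i]], collapse = "")
  }, character(1))

  # plant the PAS: motif start `d` nt upstream of the 3' end
  d <- as.integer(sample(seq(pas_terminal_window[1L],
                             pas_terminal_window[2L]), n, replace = TRUE))
  pas_local <- ifelse(polyadenylated, total - d, NA_integer_)
  for (i in which(polyadenylated)) {
    substr(sequences[i], pas_local[i] + 1L, pas_local[i] + 6L) <- "AATAAA"
  }

  ids <- sprintf("tx%05d", seq_len(n))
  gene_ids <- sprintf("g%05d", seq_len(n))
  names(sequences) <- ids
  strand <- sample(c("+", "-"), n, replace = TRUE)
  gap <- 300L
  tx_start <- cumsum(c(0L, utils::head(total + gap, -1L)))  # 0-based genomic
  utr3_start <- ifelse(strand == "+", tx_start + utr5 + cds, tx_start)
  utr3_end <- utr3_start + utr3

  annotations <- validate_transcript_annotations(data.frame(
    transcript_id = ids, gene_id = gene_ids, chrom = "chrS",
    strand = strand, utr5_len = utr5, cds_len = cds, utr3_len = utr3,
    utr3_start = utr3_start, utr3_end = utr3_end,
    stringsAsFactors = FALSE
  ), context = "generate_transcriptome")
  annotations$tx_start <- tx_start
  annotations$tx_end <- tx_start + total

  truth <- list(
    seed = seed,
    frac_polyadenylated = frac_polyadenylated,
    pas_terminal_window = pas_terminal_window,
    transcripts = data.frame(
      transcript_id = ids, gene_id = gene_ids,
      polyadenylated = polyadenylated,
      pas_local = pas_local,
      pas_distance = ifelse(polyadenylated, d, NA_integer_),
      stringsAsFactors = FALSE
    )
  )
  structure(list(annotations = annotations, sequences = sequences,
                 truth = truth),
            class = "synthetic_transcriptome")
}

#' 3'-UTR sequences of a synthetic transcriptome
#'
#' @param transcriptome A `synthetic_transcriptome`.
#' @return Named character vector of 3'-UTR sequences (UTR-local, 5' to 3').
#' @export
utr3_sequences <- function(transcriptome) {
  a <- transcriptome$annotations
  s <- substring(transcriptome$sequences[a$transcript_id],
                 a$utr5_len + a$cds_len + 1L, a$transcript_length)
  stats::setNames(s, a$transcript_id)
}

# transcript-local 0-based half-open [s, e) -> genomic 0-based half-open
.local_to_genomic <- function(annotations, idx, s_local, e_local) {
  gs <- annotations$tx_start[idx]
  total <- annotations$transcript_length[idx]
  plus <- annotations$strand[idx] == "+"
  g_start <- ifelse(plus, gs + s_local, gs + total - e_local)
  g_end <- ifelse(plus, gs + e_local, gs + total - s_local)
  cbind(start = g_start, end = g_end)
}

#' Simulate replicate peak sets with a planted colocalization odds ratio
#'
#' APA peaks are placed over the planted PAS of every polyadenylated UTR —
#' 3'-end capture at an annotated poly(A) site is treated as reliable, so
#' the APA assay's default dropout is 0 (presence/absence misclassification
#' of the conditioning assay would attenuate the recoverable odds ratio; see
#' the methods vignette). CLIP presence per UTR is Bernoulli with log-odds
#' shifted by `log(target_odds_ratio)` for polyadenylated UTRs, with the
#' *marginal* CLIP rate held at `clip_rate`; present peaks sit near the UTR
#' terminus. Each replicate applies normal position jitter (sd `jitter_sd`,
#' rounded) and independent Bernoulli dropout.
#'
#' @param transcriptome A `synthetic_transcriptome`.
#' @param assay `"CLIP"` or `"APA"`.
#' @param n_replicates Number of biological replicates (default 3).
#' @param target_odds_ratio Planted CLIP/APA odds ratio (> 0; CLIP assay
#'   only).
#' @param clip_rate Marginal CLIP presence rate across UTRs (CLIP only).
#' @param peak_width Length-2 range; widths drawn uniformly (default
#'   `c(20, 40)` nt).
#' @param jitter_sd Per-replicate positional jitter sd in nt (default 0).
#' @param dropout_rate Per-replicate, per-peak dropout probability in
#'   `[0, 1)`.
#' @param seed Integer seed.
#' @return A `replicate_peakset`: list with `assay`, `replicates` (list of
#'   `GRanges` with `score` and `replicate` columns), and `present` (named
#'   logical vector — the planted per-UTR presence truth, before replicate
#'   noise).
#' @export
simulate_peaks <- function(transcriptome, assay = c("CLIP", "APA"),
                           n_replicates = 3L, target_odds_ratio = 1,
                           clip_rate = 0.1, peak_width = c(20L, 40L),
                           jitter_sd = 0, dropout_rate = 0, seed = 1L) {
  assay <- match.arg(assay)
  if (target_odds_ratio <= 0) stop("target_odds_ratio must be > 0")
  if (dropout_rate >= 1) stop("dropout_rate must be < 1")
  set.seed(seed)
  ann <- transcriptome$annotations
  tr <- transcriptome$truth$transcripts
  n <- nrow(ann)
  total <- ann$transcript_length
  cds_end <- ann$utr5_len + ann$cds_len

  if (assay == "APA") {
    present <- tr$polyadenylated
    idx <- which(present)
    w <- sample(seq(peak_width[1L], peak_width[2L]), length(idx),
                replace = TRUE)
    center <- tr$pas_local[idx] + 3L
    s_local <- pmax(cds_end[idx], center - w %/% 2L)
    e_local <- pmin(total[idx], s_local + w)
  } else {
    f <- mean(tr$polyadenylated)
    p0 <- .solve_base_rate(clip_rate, f, target_odds_ratio)
    p1 <- stats::plogis(stats::qlogis(p0) + log(target_odds_ratio))
    p <- ifelse(tr$polyadenylated, p1, p0)
    present <- stats::runif(n) < p
    idx <- which(present)
    w <- sample(seq(peak_width[1L], peak_width[2L]), length(idx),
                replace = TRUE)
    gap_to_end <- sample(0:25, length(idx), replace = TRUE)
    e_local <- total[idx] - gap_to_end
    s_local <- pmax(cds_end[idx], e_local - w)
  }

  g <- .local_to_genomic(ann, idx, s_local, e_local)
  replicates <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    shift <- if (jitter_sd > 0) {
      as.integer(round(stats::rnorm(length(idx), 0, jitter_sd)))
    } else {
      integer(length(idx))
    }
    keep <- stats::runif(length(idx)) >= dropout_rate
    gs <- pmax(0L, g[keep, "start", drop = TRUE] + shift[keep])
    ge <- g[keep, "end", drop = TRUE] + shift[keep]
    replicates[[r]] <- GenomicRanges::GRanges(
      seqnames = "chrS",
      ranges = IRanges::IRanges(start = gs + 1L, end = ge),
      strand = ann$strand[idx][keep],
      score = round(stats::runif(sum(keep), 1, 100), 2),
      replicate = sprintf("%s_rep%d", assay, r)
    )
  }
  structure(list(
    assay = assay,
    replicates = replicates,
    present = stats::setNames(present, ann$transcript_id),
    target_odds_ratio = if (assay == "CLIP") target_odds_ratio else NA_real_,
    seed = seed
  ), class = "replicate_peakset")
}

# intercept of the presence model: find the APA-negative CLIP rate p0 such
# that the marginal CLIP rate equals `marginal` given the planted odds ratio
.solve_base_rate <- function(marginal, f, odds_target) {
  stopifnot(marginal > 0, marginal < 1)
  if (f == 0 || odds_target == 1) return(marginal)
  fn <- function(p0) {
    p1 <- stats::plogis(stats::qlogis(p0) + log(odds_target))
    f * p1 + (1 - f) * p0 - marginal
  }
  stats::uniroot(fn, c(1e-9, 1 - 1e-9), tol = 1e-12)$root
}

#' Plant peaks with a controlled PAS-window fraction
#'
#' Generates `n_peaks` UTR-local peaks of which a Bernoulli(`fraction_with_pas`)
#' subset is placed over a planted PAS (their flanked window is guaranteed
#' to contain the motif) and the rest at rejection-sampled positions whose
#' flanked window contains no motif occurrence. The realized planted
#' fraction is recorded, so [peak_pas_fraction()] recovery can be tested
#' against the exact generative truth.
#'
#' @param transcriptome A `synthetic_transcriptome`.
#' @param n_peaks Number of peaks.
#' @param fraction_with_pas Probability a peak is PAS-targeted.
#' @param flank Flank used downstream (hit geometry must match).
#' @param width Peak width in nt.
#' @param motifs Motif set.
#' @param seed Integer seed.
#' @return List with `peaks` (data frame `transcript_id, start, end,
#'   planted`), `utr_seqs`, and `fraction_planted` (realized).
#' @export
plant_pas_peaks <- function(transcriptome, n_peaks = 1000L,
                            fraction_with_pas = 0.58, flank = 25L,
                            width = 20L, motifs = .canonical_pas,
                            seed = 1L) {
  set.seed(seed)
  ann <- transcriptome$annotations
  tr <- transcriptome$truth$transcripts
  seqs <- utr3_sequences(transcriptome)
  pos_all <- .motif_positions(seqs, motifs)
  names(pos_all) <- names(seqs)
  utr_len <- nchar(seqs)
  pa_idx <- which(tr$polyadenylated)
  if (length(pa_idx) == 0L && fraction_with_pas > 0) {
    stop("no polyadenylated transcript to target")
  }
  planted <- stats::runif(n_peaks) < fraction_with_pas
  out <- data.frame(transcript_id = character(n_peaks),
                    start = integer(n_peaks), end = integer(n_peaks),
                    planted = planted, stringsAsFactors = FALSE)
  k <- max(nchar(motifs))
  for (i in seq_len(n_peaks)) {
    if (planted[i]) {
      j <- sample(pa_idx, 1L)
      id <- ann$transcript_id[j]
      # PAS position local to the UTR
      p <- tr$pas_local[j] - (ann$utr5_len[j] + ann$cds_len[j])
      s <- min(max(0L, p - width %/% 2L), utr_len[[id]] - width)
      out$transcript_id[i] <- id
      out$start[i] <- s
      out$end[i] <- s + width
    } else {
      repeat {
        j <- sample(nrow(ann), 1L)
        id <- ann$transcript_id[j]
        L <- utr_len[[id]]
        if (L < width) next
        pos <- pos_all[[id]]
        placed <- FALSE
        for (try in seq_len(50L)) {
          s <- as.integer(floor(stats::runif(1) * (L - width + 1L)))
          w0 <- max(0L, s - flank)
          w1 <- min(L, s + width + flank)
          if (!any(pos >= w0 & pos + k <= w1)) {
            out$transcript_id[i] <- id
            out$start[i] <- s
            out$end[i] <- s + width
            placed <- TRUE
            break
          }
        }
        if (placed) break
      }
    }
  }
  list(peaks = out, utr_seqs = seqs, fraction_planted = mean(planted))
}

#' Simulate ribosome footprints and count matrices with planted TE
#'
#' Per-gene abundance and translation efficiency are lognormal; mRNA counts
#' are negative binomial around abundance; RPF reads are multinomial with
#' per-gene mass proportional to abundance x TE. Each footprint picks a CDS
#' codon uniformly, a 5'-end frame uniformly, and a length from the library
#' class distribution; its 5' position is constructed so that
#' [assign_a_site()] with the same offsets inverts exactly to the
#' generating codon.
#'
#' @param transcriptome A `synthetic_transcriptome`.
#' @param offsets Frame-to-offset map planted into the reads
#'   (default `c(15, 16, 17)`).
#' @param reads_total Total footprint reads across replicates.
#' @param n_replicates Replicates per assay (default 3).
#' @param library `"monosome_lib"` (lengths 32-40, unimodal) or
#'   `"disome_lib"` (a 40/60 mixture of sub-disome 45-59 nt and true-disome
#'   60-75 nt — generator defaults, not assay measurements).
#' @param te_sdlog Lognormal sd of planted per-gene TE (0 plants TE = 1 for
#'   every gene).
#' @param abundance_sdlog Lognormal sd of per-gene mRNA abundance.
#' @param mrna_dispersion Negative-binomial dispersion of mRNA counts
#'   (`size = 1/dispersion`).
#' @param mrna_reads_total Total mRNA reads across replicates.
#' @param seed Integer seed.
#' @return List with `footprints` (data frame
#'   `transcript_id, five_prime_pos, length, sample, codon`), `mrna_counts`
#'   (genes x replicates matrix), `rpf_gene_counts` (raw per-gene footprint
#'   tallies), and `truth` (per-gene `abundance`, `te`, the offsets, and
#'   `n_dropped` out-of-bounds reads).
#' @export
simulate_footprints <- function(transcriptome, offsets = .default_offsets,
                                reads_total = 2e5, n_replicates = 3L,
                                library = c("monosome_lib", "disome_lib"),
                                te_sdlog = 1.0, abundance_sdlog = 1.2,
                                mrna_dispersion = 0.05,
                                mrna_reads_total = reads_total, seed = 1L) {
  library <- match.arg(library)
  if (reads_total < 1) stop("reads_total must be >= 1")
  offsets <- .as_offsets(offsets)
  set.seed(seed)
  ann <- transcriptome$annotations
  n <- nrow(ann)
  n_codons <- ann$cds_len %/% 3L
  abundance <- stats::rlnorm(n, 0, abundance_sdlog)
  te <- if (te_sdlog > 0) stats::rlnorm(n, 0, te_sdlog) else rep(1, n)

  mrna_per_rep <- round(mrna_reads_total / n_replicates)
  mu <- abundance / sum(abundance) * mrna_per_rep
  mrna <- vapply(seq_len(n_replicates), function(r) {
    stats::rnbinom(n, mu = mu, size = 1 / mrna_dispersion)
  }, numeric(n))
  dimnames(mrna) <- list(ann$gene_id,
                         sprintf("mrna_rep%d", seq_len(n_replicates)))

  if (library == "monosome_lib") {
    len_values <- 32:40
    len_weights <- c(1, 2, 4, 8, 10, 8, 4, 2, 1)
  } else {
    len_values <- c(45:59, 60:75)
    len_weights <- c(0.4 * stats::dnorm(45:59, 54, 4),
                     0.6 * stats::dnorm(60:75, 63, 4))
  }
  w_gene <- abundance * te
  reads_per_rep <- round(reads_total / n_replicates)
  fp_list <- vector("list", n_replicates)
  n_dropped <- 0L
  for (r in seq_len(n_replicates)) {
    g <- sample.int(n, reads_per_rep, replace = TRUE, prob = w_gene)
    codon <- as.integer(floor(stats::runif(reads_per_rep) * n_codons[g]))
    frame <- sample(0:2, reads_per_rep, replace = TRUE)
    fpp <- ann$utr5_len[g] + 3L * codon + frame -
      3L * ((frame + offsets[frame + 1L]) %/% 3L)
    len <- sample(len_values, reads_per_rep, replace = TRUE,
                  prob = len_weights)
    ok <- fpp >= 0L & fpp + len <= ann$transcript_length[g]
    n_dropped <- n_dropped + sum(!ok)
    fp_list[[r]] <- data.frame(
      transcript_id = ann$transcript_id[g[ok]],
      five_prime_pos = fpp[ok],
      length = len[ok],
      sample = sprintf("rpf_rep%d", r),
      codon = codon[ok],
      stringsAsFactors = FALSE
    )
  }
  footprints <- do.call(rbind, fp_list)
  rpf_gene_counts <- table(
    factor(footprints$transcript_id, levels = ann$transcript_id),
    footprints$sample)
  rpf_gene_counts <- matrix(as.integer(rpf_gene_counts), nrow = n,
                            dimnames = list(ann$gene_id,
                                            colnames(rpf_gene_counts)))
  list(
    footprints = footprints,
    mrna_counts = mrna,
    rpf_gene_counts = rpf_gene_counts,
    truth = list(
      abundance = stats::setNames(abundance, ann$gene_id),
      te = stats::setNames(te, ann$gene_id),
      offsets = offsets,
      library = library,
      n_dropped = n_dropped,
      seed = seed
    )
  )
}

#' Serialize generator truth to JSON
#'
#' @param truth A truth list from any generator.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
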