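# Orchestration: a single configuration object and a full-run driver that
# simulates (optionally), writes and re-reads every interchange format, and
# executes colocalization, PAS, ribosome-profiling and TE/correlation
# stages, emitting one machine-readable JSON report.

#' Map genomic peaks to 3'-UTR-local coordinates
#'
#' Converts peak intervals overlapping annotated 3'-UTRs into 0-based
#' half-open coordinates local to the UTR 5' end (strand-aware), clipped to
#' the UTR; peaks overlapping no analysis UTR are dropped.
#'
#' @param peaks `GRanges` of peaks.
#' @param annotations Transcript annotation data frame.
#' @return Data frame `transcript_id, start, end` (UTR-local).
#' @export
map_peaks_to_utr3 <- function(peaks, annotations) {
  u <- utr3_granges(annotations)
  hits <- GenomicRanges::findOverlaps(peaks, u, ignore.strand = TRUE)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  strand <- as.character(GenomicRanges::strand(u))[si]
  u_start0 <- GenomicRanges::start(u)[si] - 1L
  u_end0 <- GenomicRanges::end(u)[si]
  p_start0 <- GenomicRanges::start(peaks)[qi] - 1L
  p_end0 <- GenomicRanges::end(peaks)[qi]
  s <- ifelse(strand == "+", p_start0 - u_start0, u_end0 - p_end0)
  e <- ifelse(strand == "+", p_end0 - u_start0, u_end0 - p_start0)
  len <- u_end0 - u_start0
  data.frame(
    transcript_id = names(u)[si],
    start = pmax(0L, as.integer(s)),
    end = pmin(len, as.integer(e)),
    stringsAsFactors = FALSE
  )
}

#' Default run configuration
#'
#' Collects every tunable threshold of the pipeline with its default:
#' expression filter TPM > 1, 3'-UTR length > 50 nt, PAS flank 25 nt, 1000
#' shuffles, A-site offsets (15, 16, 17) for frames (0, 1, 2), metagene
#' filters 50/450/50 nt and >= 1 read per codon, occupancy window codon 15
#' to 10th-from-last, TE trim at the 99th percentile.
#'
#' @param outdir Output directory for all files the run writes.
#' @param seed Master seed; stage seeds are derived as small fixed offsets.
#' @param n_genes,target_odds_ratio,clip_rate,frac_polyadenylated,
#'   jitter_sd,clip_dropout,apa_dropout,n_replicates Generator settings.
#' @param reads_total,mrna_reads_total Footprint/mRNA read depths.
#' @param tpm_min,utr3_min_len,flank,n_shuffles,offsets,metagene_filters,
#'   occupancy_window,trim_pct,alternative Analysis thresholds.
#' @return A named list of class `run_config`.
#' @export
run_config <- function(outdir = tempfile("clip3utr_run_"), seed = 1L,
                       n_genes = 2000L, target_odds_ratio = 5.6,
                       clip_rate = 0.1, frac_polyadenylated = 0.7,
                       jitter_sd = 2, clip_dropout = 0.05, apa_dropout = 0,
                       n_replicates = 3L, reads_total = 2e5,
                       mrna_reads_total = 2e5, tpm_min = 1.0,
                       utr3_min_len = 50L, flank = 25L, n_shuffles = 1000L,
                       offsets = c(15L, 16L, 17L),
                       metagene_filters = c(min_utr5 = 50L, min_cds = 450L,
                                            min_utr3 = 50L,
                                            min_reads_per_codon = 1.0),
                       occupancy_window = c(first_codon = 15L,
                                            last_codon_from_end = 10L),
                       trim_pct = 99, alternative = "two.sided") {
  cfg <- as.list(environment())
  class(cfg) <- "run_config"
  cfg
}

#' Run the full synthetic-to-report pipeline
#'
#' Executes simulate -> write/read interchange files -> reproducible peaks
#' -> colocalization Fisher test -> PAS positional enrichment -> metagene
#' and occupancy -> TE -> CLIP-RPKM/TE correlations, writing every
#' intermediate table plus a JSON report to `config$outdir`. The run is a
#' pure function of the configuration (no timestamps in the report), so
#' reruns are byte-identical.
#'
#' @param config A [run_config()] list.
#' @return The report, invisibly (also written to
#'   `file.path(config$outdir, "report.json")`).
#' @export
run_full <- function(config = run_config()) {
  cfg <- config
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  path <- function(...) file.path(cfg$outdir, ...)

  ## --- simulate ---------------------------------------------------------
  tx <- generate_transcriptome(cfg$n_genes, seed = cfg$seed,
                               frac_polyadenylated = cfg$frac_polyadenylated)
  write_transcript_table(tx$annotations, path("transcripts.tsv"))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(tx$sequences),
                              path("transcripts.fa"))
  write_truth(tx$truth, path("truth_transcriptome.json"))

  apa <- simulate_peaks(tx, "APA", n_replicates = cfg$n_replicates,
                        jitter_sd = cfg$jitter_sd,
                        dropout_rate = cfg$apa_dropout, seed = cfg$seed + 1L)
  clip <- simulate_peaks(tx, "CLIP", n_replicates = cfg$n_replicates,
                         target_odds_ratio = cfg$target_odds_ratio,
                         clip_rate = cfg$clip_rate,
                         jitter_sd = cfg$jitter_sd,
                         dropout_rate = cfg$clip_dropout,
                         seed = cfg$seed + 2L)
  bed_paths <- list()
  for (ps in list(apa, clip)) {
    for (r in seq_along(ps$replicates)) {
      p <- path(sprintf("%s_rep%d.bed", tolower(ps$assay), r))
      write_bed_peaks(ps$replicates[[r]], p)
      bed_paths[[sprintf("%s_rep%d", ps$assay, r)]] <- p
    }
  }

  sim <- simulate_footprints(tx, offsets = cfg$offsets,
                             reads_total = cfg$reads_total,
                             n_replicates = cfg$n_replicates,
                             mrna_reads_total = cfg$mrna_reads_total,
                             seed = cfg$seed + 3L)
  write_footprint_table(sim$footprints, path("footprints.tsv"))
  utils::write.table(data.frame(gene_id = rownames(sim$mrna_counts),
                                sim$mrna_counts, check.names = FALSE),
                     path("mrna_counts.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)

  ## --- read everything back (round-trips the interchange formats) -------
  ann <- read_transcript_table(path("transcripts.tsv"))
  ann$tx_start <- tx$annotations$tx_start  # genomic layout kept for mapping
  fp <- read_footprint_table(path("footprints.tsv"))
  apa_reps <- lapply(seq_len(cfg$n_replicates), function(r) {
    read_bed_peaks(path(sprintf("apa_rep%d.bed", r)), sprintf("APA_rep%d", r))
  })
  clip_reps <- lapply(seq_len(cfg$n_replicates), function(r) {
    read_bed_peaks(path(sprintf("clip_rep%d.bed", r)),
                   sprintf("CLIP_rep%d", r))
  })

  ## --- expression filter and colocalization -----------------------------
  mrna_pooled <- rowSums(sim$mrna_counts)
  tpm <- compute_tpm(mrna_pooled, ann$transcript_length)
  names(tpm) <- ann$transcript_id
  utrs <- select_analysis_utr3s(ann, tpm, tpm_min = cfg$tpm_min,
                                min_len = cfg$utr3_min_len)
  assoc <- associate(utrs, apa_reps, clip_reps,
                     alternative = cfg$alternative)

  ## --- PAS enrichment on reproducible CLIP peaks in analysis UTRs -------
  clip_repro <- assoc$clip_reproducible
  local_peaks <- map_peaks_to_utr3(clip_repro, utrs)
  seqs <- utr3_sequences(tx)
  enrich <- pas_positional_enrichment(local_peaks, seqs, flank = cfg$flank,
                                      n_shuffles = cfg$n_shuffles,
                                      seed = cfg$seed + 4L)
  distances <- terminal_distance_distribution(
    clip_repro[GenomicRanges::countOverlaps(
      clip_repro, utr3_granges(utrs), type = "within",
      ignore.strand = TRUE) > 0L], utrs)

  ## --- ribosome profiling ------------------------------------------------
  mg <- metagene_profile(
    fp, ann, anchor = "start_codon", offsets = cfg$offsets,
    min_utr5 = cfg$metagene_filters[["min_utr5"]],
    min_cds = cfg$metagene_filters[["min_cds"]],
    min_utr3 = cfg$metagene_filters[["min_utr3"]],
    min_reads_per_codon = cfg$metagene_filters[["min_reads_per_codon"]])
  profile_out <- data.frame(position = mg$positions,
                            t(mg$profile), check.names = FALSE)
  utils::write.table(profile_out, path("metagene_start.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  occ <- cds_occupancy_counts(
    fp, ann, offsets = cfg$offsets,
    first_codon = cfg$occupancy_window[["first_codon"]],
    last_codon_from_end = cfg$occupancy_window[["last_codon_from_end"]])
  utils::write.table(data.frame(gene_id = rownames(occ), occ,
                                check.names = FALSE),
                     path("rpf_occupancy_counts.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  ## --- TE and correlations ----------------------------------------------
  te <- translation_efficiency(occ, sim$mrna_counts)
  utils::write.table(te, path("te_table.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)

  # CLIP 3'-UTR signal: reproducible peak bases per analysis UTR stand in
  # for read counts (the generator emits peak-level data)
  u <- utr3_granges(utrs)
  ov <- GenomicRanges::findOverlaps(u, clip_repro, ignore.strand = TRUE)
  wid <- GenomicRanges::width(GenomicRanges::pintersect(
    u[S4Vectors::queryHits(ov)], clip_repro[S4Vectors::subjectHits(ov)],
    ignore.strand = TRUE))
  clip_base_count <- numeric(length(u))
  if (length(ov)) {
    per_u <- tapply(wid, S4Vectors::queryHits(ov), sum)
    clip_base_count[as.integer(names(per_u))] <- per_u
  }
  gid <- utrs$gene_id[match(names(u), utrs$transcript_id)]
  utr_len <- utrs$utr3_len[match(names(u), utrs$transcript_id)]
  rpkm <- utr3_rpkm(stats::setNames(clip_base_count, gid), utr_len,
                    library_size = max(1, sum(clip_base_count)),
                    min_len = cfg$utr3_min_len)
  te_all <- stats::setNames(te$te_all, te$gene_id)
  shared <- intersect(rpkm$gene_id[rpkm$rpkm > 0],
                      te$gene_id[!is.na(te_all[te$gene_id])])
  corr <- if (length(shared) >= 3L) {
    spearman_trimmed(rpkm$rpkm[match(shared, rpkm$gene_id)],
                     te_all[shared], trim_pct = cfg$trim_pct)
  } else {
    list(rho = NA_real_, n_used = length(shared), n_trimmed = 0L)
  }
  # terminal signal vs UTR length independence check
  term_sig <- clip_base_count
  lencor <- signal_vs_utr3_length(term_sig[term_sig > 0],
                                  utrs$utr3_len[term_sig > 0])

  report <- list(
    config = cfg[setdiff(names(cfg), "outdir")],
    n_analysis_utrs = assoc$n_utrs,
    association = list(
      table = unclass(assoc$table)[c("a", "b", "c", "d")],
      odds_ratio = assoc$odds_ratio,
      p_value = assoc$p_value,
      alternative = assoc$alternative
    ),
    pas_enrichment = list(
      observed_fraction = enrich$observed_fraction,
      null_mean_fraction = mean(enrich$null_fractions),
      empirical_p = enrich$empirical_p,
      n_peaks = enrich$n_peaks,
      flank = enrich$window
    ),
    terminal_distance = list(
      median_nt = stats::median(distances),
      n_peaks = length(distances)
    ),
    metagene = list(
      anchor = mg$anchor,
      n_genes = mg$n_genes,
      n_reads_used = mg$n_reads_used,
      profile_path = "metagene_start.tsv"
    ),
    te = list(
      table_path = "te_table.tsv",
      n_genes = nrow(te),
      n_te_defined = sum(te$te_defined)
    ),
    correlations = list(
      clip_rpkm_vs_te = corr,
      terminal_signal_vs_utr3_length = lencor
    )
  )
  jsonlite::write_json(report, path("report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  invisible(report)
}
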