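# Readers/writers for every external representation the pipeline touches.
# On-disk coordinates are 0-based half-open (BED convention); in-memory
# genomic intervals are GRanges (1-based closed). Conversion happens here
# and only here.

#' Read peak intervals from a BED file
#'
#' Parses a BED file (>= 3 columns) into a `GRanges` of peaks. Column 5, when
#' present and numeric, becomes the peak `score` (defaulting to 0); column 6
#' the strand (defaulting to `+`). Malformed lines (non-integer or negative
#' coordinates, `start >= end`) reject the whole file with the offending line
#' number, so silent coordinate corruption cannot propagate.
#'
#' @param path Path to a BED file. `#` comments and `track`/`browser` lines
#'   are ignored.
#' @param replicate_label Label stored in the `replicate` metadata column,
#'   identifying the biological replicate the peaks came from. Defaults to
#'   the file name.
#' @return A `GRanges` with metadata columns `score` and `replicate`.
#' @examples
#' bed <- tempfile(fileext = ".bed")
#' writeLines("chr1\t100\t150\tp1\t7.5\t+", bed)
#' read_bed_peaks(bed, "rep1")
#' @export
read_bed_peaks <- function(path, replicate_label = basename(path)) {
  lines <- readLines(path)
  idx <- which(!grepl("^\\s*(#|$)", lines) &
                 !grepl("^(track|browser)\\b", lines))
  if (length(idx) == 0L) {
    return(GenomicRanges::GRanges(score = numeric(0),
                                  replicate = character(0)))
  }
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    stop("malformed BED line ", idx[which(nf < 3L)[1L]],
         " in '", path, "': fewer than 3 columns")
  }
  col <- function(j) vapply(fields, function(x) if (length(x) >= j) x[[j]] else NA_character_,
                            character(1))
  chrom <- col(1L)
  start0 <- suppressWarnings(as.numeric(col(2L)))
  end0 <- suppressWarnings(as.numeric(col(3L)))
  bad <- is.na(start0) | is.na(end0) |
    start0 != floor(start0) | end0 != floor(end0) | start0 < 0
  if (any(bad)) {
    stop("malformed BED line ", idx[which(bad)[1L]],
         " in '", path, "': non-integer or negative coordinate")
  }
  if (any(start0 >= end0)) {
    stop("malformed BED line ", idx[which(start0 >= end0)[1L]],
         " in '", path, "': start >= end")
  }
  score <- rep(0, length(idx))
  if (any(nf >= 5L)) {
    raw <- col(5L)
    has <- nf >= 5L & !is.na(raw) & raw != "." & raw != ""
    val <- suppressWarnings(as.numeric(raw[has]))
    if (anyNA(val)) {
      stop("malformed BED line ", idx[has][which(is.na(val))[1L]],
           " in '", path, "': non-numeric score")
    }
    score[has] <- val
  }
  strand <- rep("+", length(idx))
  if (any(nf >= 6L)) {
    raw <- col(6L)
    has <- nf >= 6L & !is.na(raw) & raw %in% c("+", "-")
    strand[has] <- raw[has]
  }
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start0 + 1L, end = end0),
    strand = strand
  )
  S4Vectors::mcols(gr)$score <- score
  S4Vectors::mcols(gr)$replicate <- replicate_label
  if (any(nf >= 4L)) {
    nm <- col(4L)
    nm[is.na(nm)] <- ""
    names(gr) <- nm
  }
  gr
}

#' Write peaks to a BED6 file
#'
#' Inverse of [read_bed_peaks()]: coordinates are converted back to 0-based
#' half-open. Reading the written file reproduces intervals and scores
#' exactly.
#'
#' @param peaks A `GRanges`; an optional `score` metadata column is written
#'   to BED column 5 (0 when absent).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed_peaks <- function(peaks, path) {
  n <- length(peaks)
  score <- S4Vectors::mcols(peaks)$score
  if (is.null(score)) score <- rep(0, n)
  nm <- names(peaks)
  if (is.null(nm)) nm <- sprintf("peak_%d", seq_len(n))
  strand <- as.character(GenomicRanges::strand(peaks))
  strand[strand == "*"] <- "+"
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(peaks)),
    start = GenomicRanges::start(peaks) - 1L,
    end = GenomicRanges::end(peaks),
    name = nm,
    score = format(score, trim = TRUE, digits = 15),
    strand = strand,
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

.transcript_table_columns <- c(
  "transcript_id", "gene_id", "chrom", "strand",
  "utr5_len", "cds_len", "utr3_len", "utr3_start", "utr3_end"
)

#' Read a transcript annotation table
#'
#' Reads the simplified transcript TSV that stands in for a full GTF: one row
#' per (single-isoform) transcript carrying its segment lengths and the
#' genomic extent of its 3'-UTR in 0-based half-open coordinates.
#'
#' Validation is strict: a `cds_len` that is not a positive multiple of 3, a
#' duplicated `transcript_id`, or a `utr3_start`/`utr3_end` span that
#' disagrees with `utr3_len` rejects the file.
#'
#' @param path Path to a tab-separated file with header columns
#'   `transcript_id, gene_id, chrom, strand, utr5_len, cds_len, utr3_len,
#'   utr3_start, utr3_end`. `#` comment lines are ignored.
#' @return A `data.frame` of annotations with an added `transcript_length`
#'   column (`utr5_len + cds_len + utr3_len`).
#' @seealso [utr3_granges()] to extract 3'-UTR intervals as a `GRanges`.
#' @export
read_transcript_table <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  missing <- setdiff(.transcript_table_columns, names(df))
  if (length(missing)) {
    stop("transcript table '", path, "' lacks column(s): ",
         paste(missing, collapse = ", "))
  }
  validate_transcript_annotations(df, context = path)
}

#' Validate a transcript annotation data frame
#'
#' Applies the same invariants as [read_transcript_table()] to an in-memory
#' annotation table and returns it with `transcript_length` attached.
#'
#' @param df Data frame with the transcript-table columns.
#' @param context Label used in error messages.
#' @return The validated data frame.
#' @export
validate_transcript_annotations <- function(df, context = "annotations") {
  dup <- duplicated(df$transcript_id)
  if (any(dup)) {
    stop("duplicate transcript_id '", df$transcript_id[dup][1L],
         "' in ", context)
  }
  for (column in c("utr5_len", "cds_len", "utr3_len", "utr3_start", "utr3_end")) {
    df[[column]] <- as.integer(df[[column]])
  }
  bad <- df$cds_len < 3L | df$cds_len %% 3L != 0L
  if (any(bad)) {
    stop("transcript '", df$transcript_id[bad][1L], "' in ", context,
         ": cds_len ", df$cds_len[bad][1L], " is not a positive multiple of 3")
  }
  if (any(df$utr5_len < 0L | df$utr3_len < 0L)) {
    stop("negative UTR length in ", context)
  }
  if (!all(df$strand %in% c("+", "-"))) {
    stop("strand must be '+' or '-' in ", context)
  }
  span <- df$utr3_end - df$utr3_start
  bad <- df$utr3_len > 0L & span != df$utr3_len
  if (any(bad)) {
    stop("transcript '", df$transcript_id[bad][1L], "' in ", context,
         ": utr3 interval span ", span[bad][1L],
         " != utr3_len ", df$utr3_len[bad][1L])
  }
  df$transcript_length <- df$utr5_len + df$cds_len + df$utr3_len
  df
}

#' Write a transcript annotation table
#'
#' @param annotations Data frame as returned by [read_transcript_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_transcript_table <- function(annotations, path) {
  utils::write.table(annotations[, .transcript_table_columns],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Extract 3'-UTR genomic intervals from an annotation table
#'
#' @param annotations Transcript annotation data frame.
#' @return A `GRanges` named by `transcript_id`, one range per transcript
#'   with `utr3_len > 0`, with a `transcript_id` metadata column.
#' @export
utr3_granges <- function(annotations) {
  keep <- annotations$utr3_len > 0L
  a <- annotations[keep, , drop = FALSE]
  gr <- GenomicRanges::GRanges(
    seqnames = a$chrom,
    ranges = IRanges::IRanges(start = a$utr3_start + 1L, end = a$utr3_end),
    strand = a$strand
  )
  names(gr) <- a$transcript_id
  S4Vectors::mcols(gr)$transcript_id <- a$transcript_id
  gr
}

#' Read a footprint alignment table
#'
#' Reads transcript-coordinate ribosome footprint alignments: one row per
#' aligned read with its transcript, 0-based 5'-end position, length and
#' sample label. Positions are deliberately not validated against transcript
#' lengths here; that happens downstream when an annotation is attached.
#'
#' @param path Tab-separated file with header columns
#'   `transcript_id, five_prime_pos, length, sample`.
#' @return A `data.frame` with those columns plus `class` set to
#'   `"unassigned"`.
#' @export
read_footprint_table <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  required <- c("transcript_id", "five_prime_pos", "length", "sample")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("footprint table '", path, "' lacks column(s): ",
         paste(missing, collapse = ", "))
  }
  df$five_prime_pos <- as.integer(df$five_prime_pos)
  df$length <- as.integer(df$length)
  bad <- is.na(df$five_prime_pos) | df$five_prime_pos < 0L
  if (any(bad)) {
    stop("footprint row ", which(bad)[1L], " in '", path,
         "': negative or non-integer five_prime_pos")
  }
  bad <- is.na(df$length) | df$length < 1L
  if (any(bad)) {
    stop("footprint row ", which(bad)[1L], " in '", path,
         "': length < 1")
  }
  df$class <- "unassigned"
  df
}

#' Write a footprint alignment table
#'
#' @param footprints Data frame with columns
#'   `transcript_id, five_prime_pos, length, sample`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_footprint_table <- function(footprints, path) {
  utils::write.table(
    footprints[, c("transcript_id", "five_prime_pos", "length", "sample")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write per-base coverage as bedGraph
#'
#' Writes a 4-column bedGraph in which adjacent equal-valued runs are merged
#' and zero-valued bases are omitted (the sparse convention). Values are
#' written with at least 6 significant digits.
#'
#' @param coverage Named list of numeric vectors, one per chromosome; element
#'   `i` of a vector is the coverage of 0-based position `origin + i - 1`.
#' @param path Output path.
#' @param origin 0-based genomic position of the first vector element.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(coverage, path, origin = 0L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (chrom in names(coverage)) {
    v <- coverage[[chrom]]
    if (any(v < 0)) stop("negative coverage on ", chrom)
    if (length(v) == 0L) next
    r <- rle(v)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values != 0
    if (!any(keep)) next
    writeLines(sprintf("%s\t%d\t%d\t%s", chrom,
                       origin + starts[keep], origin + ends[keep],
                       sprintf("%.6g", r$values[keep])), con)
  }
  invisible(path)
}
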