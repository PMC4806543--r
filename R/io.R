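## annotation tibble -> GRanges
ann_to_granges <- function(annotations) {
  GenomicRanges::GRanges(
    seqnames = annotations$seq_id,
    ranges = IRanges::IRanges(annotations$start, annotations$end),
    strand = annotations$strand
  )
}

#' Write repeat annotations to GFF3
#'
#' Internal coordinates are 1-based closed and map directly onto GFF3.
#' The `Target` attribute records the matched consensus span.
#'
#' @param annotations tibble from [scan_repeats()] / [competitive_assign()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_annotations_gff3 <- function(annotations, path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    abort("rtracklayer is required for GFF3 export")
  }
  gr <- ann_to_granges(annotations)
  S4Vectors::mcols(gr)$source <- "cenarch"
  S4Vectors::mcols(gr)$type <- "repeat_region"
  S4Vectors::mcols(gr)$score <- annotations$score
  S4Vectors::mcols(gr)$ID <- sprintf("rep%05d", seq_len(nrow(annotations)))
  S4Vectors::mcols(gr)$Name <- annotations$family
  if (all(c("consensus_start", "consensus_end") %in% names(annotations))) {
    S4Vectors::mcols(gr)$Target <- sprintf(
      "%s %d %d", annotations$family,
      annotations$consensus_start, annotations$consensus_end)
  }
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Write repeat annotations to BED6
#'
#' BED is 0-based half-open; the conversion from the package's 1-based
#' closed intervals happens here.
#'
#' @param annotations annotation tibble.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_annotations_bed <- function(annotations, path) {
  df <- data.frame(
    chrom = annotations$seq_id,
    chromStart = annotations$start - 1L,
    chromEnd = annotations$end,
    name = annotations$family,
    score = pmin(1000L, as.integer(round(annotations$score))),
    strand = annotations$strand
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a bedGraph coverage file into a coverage track
#'
#' Expands interval scores to per-base coverage. Bases not covered by any
#' interval get 0.
#'
#' @param path bedGraph file (0-based half-open intervals).
#' @param total_read_pairs library size to record on the track.
#' @param length track length; defaults to the largest interval end.
#' @return a [coverage_track()].
#' @export
read_bedgraph_track <- function(path, total_read_pairs, length = NULL) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "start", "end", "score"))
  length <- length %||% max(df$end)
  v <- numeric(length)
  for (i in seq_len(nrow(df))) {
    v[(df$start[i] + 1L):df$end[i]] <- df$score[i]
  }
  coverage_track(v, total_read_pairs = total_read_pairs,
                 seq_id = as.character(df$chrom[1]))
}

#' Write an enrichment profile as bedGraph
#'
#' One interval per step (undefined ratios are skipped).
#'
#' @param profile an `enrichment_profile`.
#' @param path output file.
#' @param seq_id chromosome name for column 1.
#' @return `path`, invisibly.
#' @export
write_enrichment_bedgraph <- function(profile, path, seq_id = "seq") {
  cfg <- attr(profile, "config")
  keep <- !is.na(profile$enrichment)
  df <- data.frame(
    chrom = seq_id,
    start = profile$pos[keep] - 1L,
    end = profile$pos[keep] - 1L + cfg$step,
    score = profile$enrichment[keep]
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
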