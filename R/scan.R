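#' Build a repeat consensus library
#'
#' @param family character vector of unique family names.
#' @param sequence DNA consensus sequences, one per family.
#' @return tibble with columns `family`, `sequence`, `unit_length`.
#' @export
repeat_library <- function(family, sequence) {
  stopifnot(length(family) == length(sequence))
  if (anyDuplicated(family)) abort("family names must be unique within a library")
  sequence <- vapply(sequence, as_dna, character(1), allow_empty = FALSE,
                     USE.NAMES = FALSE)
  tibble(family = as.character(family), sequence = sequence,
         unit_length = nchar(sequence))
}

## one (consensus, strand) scan pass: iterative best-local-hit + masking.
## subject is modified in place (hit regions -> N) so each hit is found once.
scan_one <- function(subject_chr, consensus, family, strand,
                     min_identity, min_length, seq_id) {
  pattern <- if (strand == "-") revcomp(consensus) else consensus
  pat <- Biostrings::DNAString(pattern)
  unit_len <- nchar(consensus)
  submat <- dna_submat(match = 2, mismatch = -3)
  hits <- list()
  ## score below which no acceptable hit can exist
  min_score <- 2 * min_length * min_identity - 3 * min_length * (1 - min_identity)
  repeat {
    subj <- Biostrings::DNAString(subject_chr)
    aln <- Biostrings::pairwiseAlignment(
      pat, subj, type = "local",
      substitutionMatrix = submat, gapOpening = 5, gapExtension = 2
    )
    if (Biostrings::score(aln) < min_score) break
    sr <- aln@subject@range
    pr <- aln@pattern@range
    nd <- Biostrings::nindel(aln)
    gap_cols <- unname(Biostrings::insertion(nd)[, "WidthSum"] +
                         Biostrings::deletion(nd)[, "WidthSum"])
    cols <- Biostrings::nmatch(aln) + Biostrings::nmismatch(aln) + gap_cols
    identity <- Biostrings::nmatch(aln) / cols
    start <- BiocGenerics::start(sr)
    end <- BiocGenerics::end(sr)
    span <- BiocGenerics::width(pr)
    if (identity >= min_identity && (end - start + 1L) >= min_length) {
      cons_start <- BiocGenerics::start(pr)
      cons_end <- BiocGenerics::end(pr)
      if (strand == "-") { # map back to consensus coordinates
        tmp <- unit_len - cons_end + 1L
        cons_end <- unit_len - cons_start + 1L
        cons_start <- tmp
      }
      hits[[length(hits) + 1L]] <- tibble(
        seq_id = seq_id, start = start, end = end, strand = strand,
        family = family, identity = identity,
        score = Biostrings::score(aln),
        consensus_span = span, consensus_start = cons_start,
        consensus_end = cons_end
      )
    }
    ## mask regardless of acceptance so the loop terminates
    substr(subject_chr, start, end) <- paste(rep("N", end - start + 1L),
                                             collapse = "")
    if (length(hits) > 50000L) abort("scan did not converge (too many hits)")
  }
  dplyr::bind_rows(hits)
}

#' Scan a sequence for repeat-family instances
#'
#' Locates local alignments of each consensus in `library` against both
#' strands of `seq`, by repeated best-local-alignment with masking (a
#' self-contained stand-in for a RepeatMasker-style homology scan).
#' `N` bases never match; identity is computed over aligned columns.
#' Overlapping hits from different families are all retained — resolve them
#' with [competitive_assign()].
#'
#' @param seq DNA string to scan (character or DNAString).
#' @param library consensus library from [repeat_library()].
#' @param min_identity minimum alignment identity in (0, 1]; default 0.7.
#' @param min_length minimum hit length in nt (default 30).
#' @param seq_id identifier recorded in the output.
#' @return tibble of annotations (`seq_id`, `start`, `end` 1-based closed,
#'   `strand`, `family`, `identity`, `score`, `consensus_span`,
#'   `consensus_start`, `consensus_end`), in coordinate order.
#' @export
scan_repeats <- function(seq, library, min_identity = 0.7, min_length = 30L,
                         seq_id = "seq") {
  seq <- as_dna(seq)
  stopifnot(is.data.frame(library), nrow(library) >= 1L,
            min_identity > 0, min_identity <= 1)
  empty <- tibble(
    seq_id = character(), start = integer(), end = integer(),
    strand = character(), family = character(), identity = double(),
    score = double(), consensus_span = integer(),
    consensus_start = integer(), consensus_end = integer()
  )
  if (nchar(seq) == 0L) return(empty)
  res <- purrr::map_dfr(seq_len(nrow(library)), function(i) {
    purrr::map_dfr(c("+", "-"), function(s) {
      scan_one(seq, library$sequence[i], library$family[i], s,
               min_identity, min_length, seq_id)
    })
  })
  if (nrow(res) == 0L) return(empty)
  dplyr::arrange(res, .data$start, .data$end, .data$family)
}

#' Resolve overlapping annotations competitively
#'
#' Assigns every base to at most one annotation: annotations are ranked by
#' score (ties: earlier start, then lexicographic family name) and each is
#' trimmed to the bases not already claimed by a higher-ranked annotation.
#' An annotation split into several fragments by trimming yields one row
#' per retained fragment. The summed nt per family of the result is the
#' "repeat content" statistic (see [repeat_content()]).
#'
#' @param annotations tibble from [scan_repeats()] (one sequence).
#' @return tibble of non-overlapping annotations, sorted by start.
#' @export
competitive_assign <- function(annotations) {
  if (nrow(annotations) == 0L) return(annotations)
  if (length(unique(annotations$seq_id)) > 1L) {
    abort("competitive_assign expects annotations over one sequence")
  }
  ord <- order(-annotations$score, annotations$start, annotations$family)
  claimed <- IRanges::IRanges()
  out <- list()
  for (i in ord) {
    r <- IRanges::IRanges(annotations$start[i], annotations$end[i])
    keep <- IRanges::setdiff(r, claimed)
    if (length(keep) == 0L) next
    claimed <- IRanges::reduce(c(claimed, keep))
    for (j in seq_along(keep)) {
      row <- annotations[i, ]
      row$start <- BiocGenerics::start(keep)[j]
      row$end <- BiocGenerics::end(keep)[j]
      out[[length(out) + 1L]] <- row
    }
  }
  dplyr::arrange(dplyr::bind_rows(out), .data$start, .data$end)
}

#' Per-family assigned repeat content
#'
#' @param assigned output of [competitive_assign()].
#' @param total_length sequence length for the percentage column (optional).
#' @return tibble with `family`, `nt`, and `pct` when `total_length` given.
#' @export
repeat_content <- function(assigned, total_length = NULL) {
  out <- assigned |>
    dplyr::group_by(.data$family) |>
    dplyr::summarise(nt = sum(.data$end - .data$start + 1L), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$nt))
  if (!is.null(total_length)) out$pct <- 100 * out$nt / total_length
  out
}

#' Extract tandem-repeat monomers from a sequence
#'
#' Runs [scan_repeats()] with a single monomer consensus and numbers the
#' monomer instances 5' to 3' on the forward coordinate of the input
#' (monomers on the minus strand keep their forward-coordinate rank).
#' A monomer is full-length when it aligns to at least `min_full_span` nt
#' of the consensus.
#'
#' @param seq DNA string containing the array.
#' @param consensus monomer consensus (character), e.g. a 156-nt satellite
#'   monomer.
#' @param min_full_span full-length threshold in consensus nt (default 147).
#' @param min_identity passed to [scan_repeats()].
#' @param seq_id identifier recorded in the output.
#' @return a `monomer_set`: tibble of monomer annotations with `index`,
#'   `full_length` and `sequence` (forward-strand substring) columns, plus
#'   attributes `consensus` and `seq`.
#' @export
extract_monomers <- function(seq, consensus, min_full_span = 147L,
                             min_identity = 0.7, seq_id = "seq") {
  seq <- as_dna(seq)
  consensus <- as_dna(consensus, allow_empty = FALSE)
  if (nchar(consensus) < min_full_span) {
    abort("consensus unit_length must be >= min_full_span")
  }
  lib <- repeat_library("monomer", consensus)
  ann <- scan_repeats(seq, lib, min_identity = min_identity,
                      min_length = min(50L, min_full_span), seq_id = seq_id)
  ann <- dplyr::arrange(ann, .data$start)
  ann$index <- seq_len(nrow(ann))
  ann$full_length <- ann$consensus_span >= min_full_span
  ann$sequence <- vapply(seq_len(nrow(ann)), function(i) {
    subseq_chr(seq, ann$start[i], ann$end[i])
  }, character(1))
  structure(ann, class = c("monomer_set", class(ann)),
            consensus = consensus, seq = seq)
}

#' Monomer sequences in a common orientation
#'
#' Returns the monomer sequences of a `monomer_set`, reverse-complementing
#' minus-strand monomers so that all read in consensus orientation
#' (inverted satellite arrays point in opposite directions on the assembly).
#'
#' @param monomers a `monomer_set` from [extract_monomers()].
#' @param full_length_only drop truncated monomers (default `FALSE`).
#' @return named character vector (names are monomer indices).
#' @export
monomer_seqs <- function(monomers, full_length_only = FALSE) {
  m <- monomers
  if (full_length_only) m <- m[m$full_length, ]
  s <- ifelse(m$strand == "-", vapply(m$sequence, revcomp, character(1)),
              m$sequence)
  stats::setNames(unname(s), as.character(m$index))
}
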