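#' @importFrom rlang abort warn %||%
#' @importFrom tibble tibble as_tibble
#' @import dplyr
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' Coerce input to an uppercase DNA character string
#'
#' Accepts a plain character scalar, a [Biostrings::DNAString] or a
#' length-one [Biostrings::DNAStringSet]. The returned string is validated
#' against the `A/C/G/T/N` alphabet.
#'
#' @param x sequence input.
#' @param allow_empty if `FALSE`, an empty sequence is an error.
#' @return character scalar.
#' @export
as_dna <- function(x, allow_empty = TRUE) {
  if (inherits(x, "DNAStringSet")) {
    if (length(x) != 1L) abort("expected a single sequence")
    x <- as.character(x)
  } else if (inherits(x, "XString")) {
    x <- as.character(x)
  }
  if (!is.character(x) || length(x) != 1L || is.na(x)) {
    abort("sequence must be a single character string (or DNAString)")
  }
  x <- toupper(x)
  if (!allow_empty && nchar(x) == 0L) abort("sequence is empty")
  if (grepl("[^ACGTN]", x)) {
    abort("sequence contains characters outside the A/C/G/T/N alphabet")
  }
  x
}

#' Reverse complement of a DNA string
#'
#' @param x DNA string (character or DNAString).
#' @return character scalar.
#' @export
revcomp <- function(x) {
  x <- as_dna(x)
  if (nchar(x) == 0L) return(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Random DNA string
#'
#' Bases are drawn i.i.d. uniformly from A/C/G/T. Uses the current RNG
#' state; wrap in [withr::with_seed()] (as the `simulate_*` generators do)
#' for reproducibility.
#'
#' @param n length in nt.
#' @return character scalar of length-`n` DNA.
#' @export
random_dna <- function(n) {
  stopifnot(n >= 0)
  if (n == 0L) return("")
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

## substring that tolerates out-of-range gracefully only when asked
subseq_chr <- function(x, start, end) {
  n <- nchar(x)
  if (start < 1L || end > n || start > end + 1L) {
    abort(sprintf("subsequence [%d,%d] out of range for length %d", start, end, n))
  }
  if (start > end) return("")
  substr(x, start, end)
}

chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

## scoring matrix over A/C/G/T/N where N never matches anything (incl. N);
## cached, as pairwiseAlignment is called in tight loops
.submat_cache <- new.env(parent = emptyenv())
dna_submat <- function(match = 1, mismatch = -1) {
  key <- paste(match, mismatch)
  hit <- .submat_cache[[key]]
  if (!is.null(hit)) return(hit)
  b <- c(DNA_BASES, "N")
  m <- matrix(mismatch, 5, 5, dimnames = list(b, b))
  diag(m) <- match
  m["N", ] <- mismatch
  m[, "N"] <- mismatch
  .submat_cache[[key]] <- m
  m
}

## global pairwise alignment -> list(a=, b=) of equal-length gapped strings
align_global <- function(a, b, match = 1, mismatch = -1,
                         gap_open = 4, gap_extend = 1) {
  a <- as_dna(a, allow_empty = FALSE)
  b <- as_dna(b, allow_empty = FALSE)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b),
    type = "global",
    substitutionMatrix = dna_submat(match, mismatch),
    gapOpening = gap_open, gapExtension = gap_extend
  )
  ## pattern()/subject() give the gapped rows far faster than the
  ## alignedPattern()/alignedSubject() padding path
  list(
    a = as.character(Biostrings::pattern(aln)),
    b = as.character(Biostrings::subject(aln)),
    score = Biostrings::score(aln)
  )
}

#' Read sequences from a FASTA file
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()] returning a tibble so
#' downstream calls can stay in data-frame space.
#'
#' @param path FASTA file.
#' @return tibble with columns `id`, `sequence`, `length`.
#' @export
read_fasta_tbl <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  tibble(
    id = sub("\\s.*$", "", names(x)),
    sequence = unname(as.character(x)),
    length = Biostrings::width(x)
  )
}

#' Write sequences to a FASTA file
#'
#' @param x tibble with columns `id` and `sequence` (as from
#'   [read_fasta_tbl()]), or a named character vector.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta_tbl <- function(x, path) {
  if (is.data.frame(x)) {
    seqs <- Biostrings::DNAStringSet(x$sequence)
    names(seqs) <- x$id
  } else {
    seqs <- Biostrings::DNAStringSet(x)
  }
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}
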