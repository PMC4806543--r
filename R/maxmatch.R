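## maximal exact matches between two strings, one strand, via diagonal runs
mem_one_strand <- function(ca, cb, min_len) {
  n <- length(ca)
  m <- length(cb)
  out <- list()
  for (d in (1L - n):(m - 1L)) {
    i0 <- max(1L, 1L - d)
    i1 <- min(n, m - d)
    if (i1 - i0 + 1L < min_len) next
    idx <- i0:i1
    eq <- ca[idx] == cb[idx + d]
    ## N never matches, not even N==N
    eq[ca[idx] == "N" | cb[idx + d] == "N"] <- FALSE
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    hit <- which(r$values & r$lengths >= min_len)
    for (h in hit) {
      i <- idx[starts[h]]
      out[[length(out) + 1L]] <- c(i, i + d, r$lengths[h])
    }
  }
  out
}

#' Find maximal exact matches between two sequences
#'
#' Reports every exact match of length at least `min_len` between `a` and
#' `b` that cannot be extended by one nt on either side (the maximal-match
#' set a MUMmer `--maxmatch` run would report; matches need not be unique
#' in either sequence). With `both_strands = TRUE`, matches between `a`
#' and the reverse complement of `b` are also reported, with `pos_b` giving
#' the forward-strand start in `b` and `strand = "-"`.
#'
#' @param a,b DNA strings.
#' @param min_len minimum match length (>= 2; default 20).
#' @param both_strands also search the reverse complement of `b`.
#' @return tibble `pos_a`, `pos_b` (1-based starts), `length`, `strand`,
#'   sorted by `pos_a` then `pos_b`.
#' @export
find_maximal_matches <- function(a, b, min_len = 20L, both_strands = FALSE) {
  a <- as_dna(a)
  b <- as_dna(b)
  stopifnot(min_len >= 2L)
  empty <- tibble(pos_a = integer(), pos_b = integer(),
                  length = integer(), strand = character())
  if (nchar(a) < min_len || nchar(b) < min_len) return(empty)
  ca <- chars(a)
  res <- mem_one_strand(ca, chars(b), min_len)
  fwd <- if (length(res)) {
    mm <- do.call(rbind, res)
    tibble(pos_a = mm[, 1], pos_b = mm[, 2], length = mm[, 3], strand = "+")
  } else empty
  rev <- empty
  if (both_strands) {
    m <- nchar(b)
    res2 <- mem_one_strand(ca, chars(revcomp(b)), min_len)
    if (length(res2)) {
      mm <- do.call(rbind, res2)
      ## map start in revcomp(b) back to forward-strand start in b
      rev <- tibble(pos_a = mm[, 1],
                    pos_b = m - (mm[, 2] + mm[, 3] - 1L) + 1L,
                    length = mm[, 3], strand = "-")
    }
  }
  dplyr::arrange(dplyr::bind_rows(fwd, rev), .data$pos_a, .data$pos_b)
}
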