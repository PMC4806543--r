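#' Compare two independently assembled overlapping sequences
#'
#' Globally aligns the two sequences and reports single-nucleotide
#' discrepancies (mismatched columns) and indel events (maximal gap runs;
#' an indel of any length counts as one event), with rates per aligned nt
#' (alignment columns).
#'
#' @param a,b DNA strings (the two assemblies of the same region).
#' @param min_identity sequences must align at or above this identity
#'   (default 0.95) or the comparison errors out (not an overlap).
#' @return object of class `overlap_comparison`: list with `events`
#'   (tibble: `pos_a`, `type` in snp/ins/del, `length`, `a`, `b`),
#'   `aligned_nt`, `snp_count`, `indel_event_count`, `snp_rate`,
#'   `indel_rate`.
#' @export
compare_overlap <- function(a, b, min_identity = 0.95) {
  a <- as_dna(a, allow_empty = FALSE)
  b <- as_dna(b, allow_empty = FALSE)
  aln <- align_global(a, b, match = 1, mismatch = -2,
                      gap_open = 6, gap_extend = 1)
  ca <- chars(aln$a)
  cb <- chars(aln$b)
  both <- ca != "-" & cb != "-"
  if (mean(ca[both] == cb[both]) < min_identity) {
    abort("sequences differ too much to be the same overlap region")
  }
  cols <- length(ca)
  pa <- cumsum(ca != "-")
  snp_idx <- which(both & ca != cb)
  snps <- tibble(pos_a = pa[snp_idx], type = "snp", length = 1L,
                 a = ca[snp_idx], b = cb[snp_idx])
  gaps <- ca == "-" | cb == "-"
  r <- rle(gaps)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  indels <- purrr::map_dfr(which(r$values), function(h) {
    i <- starts[h]
    j <- ends[h]
    type <- if (ca[i] == "-") "ins" else "del" # relative to a
    tibble(pos_a = if (i > 1L) pa[i - 1L] else 0L, type = type,
           length = j - i + 1L,
           a = paste(ca[i:j], collapse = ""),
           b = paste(cb[i:j], collapse = ""))
  })
  events <- dplyr::arrange(dplyr::bind_rows(snps, indels), .data$pos_a)
  structure(
    list(events = events, aligned_nt = cols,
         snp_count = nrow(snps), indel_event_count = nrow(indels),
         snp_rate = nrow(snps) / cols, indel_rate = nrow(indels) / cols),
    class = "overlap_comparison"
  )
}

#' @export
print.overlap_comparison <- function(x, ...) {
  cat(sprintf(
    "overlap of %d aligned nt: %d SNPs (1 per %s nt), %d indel events (1 per %s nt)\n",
    x$aligned_nt, x$snp_count,
    if (x$snp_count) format(round(x$aligned_nt / x$snp_count), big.mark = ",") else "Inf",
    x$indel_event_count,
    if (x$indel_event_count) format(round(x$aligned_nt / x$indel_event_count), big.mark = ",") else "Inf"))
  invisible(x)
}

#' @rdname tidy_cenarch
#' @export
tidy.overlap_comparison <- function(x, ...) x$events

#' @rdname tidy_cenarch
#' @export
glance.overlap_comparison <- function(x, ...) {
  tibble(aligned_nt = x$aligned_nt, snp_count = x$snp_count,
         indel_event_count = x$indel_event_count,
         snp_rate = x$snp_rate, indel_rate = x$indel_rate)
}

## maximal mononucleotide run containing position p of seq (returns
## c(base, run_start, run_end) or NULL)
run_at <- function(cs, p) {
  if (p < 1L || p > length(cs)) return(NULL)
  b <- cs[p]
  s <- p
  while (s > 1L && cs[s - 1L] == b) s <- s - 1L
  e <- p
  while (e < length(cs) && cs[e + 1L] == b) e <- e + 1L
  list(base = b, start = s, end = e, len = e - s + 1L)
}

#' Classify indel context at mononucleotide runs
#'
#' Annotates each indel event with the maximal mononucleotide run it
#' abuts, if any of length at least `min_run`. The summary fraction is the
#' proportion of single-nucleotide indels sitting at the end of such a
#' run — the signature of residual homopolymer sequencing error.
#'
#' @param seq the sequence the indel positions refer to (`pos_a`
#'   coordinates from [compare_overlap()]).
#' @param events indel events (tibble with `pos_a`, `type`, `length`; SNP
#'   rows are ignored).
#' @param min_run minimum run length to call a run context (default 5).
#' @return list with `contexts` (tibble: `pos_a`, `indel_length`,
#'   `run_base`, `run_length`, `at_run_end`) and `fraction_single_nt_at_run_end`.
#' @export
classify_indel_context <- function(seq, events, min_run = 5L) {
  seq <- as_dna(seq)
  cs <- chars(seq)
  ev <- events[events$type %in% c("ins", "del"), , drop = FALSE]
  ctx <- purrr::map_dfr(seq_len(nrow(ev)), function(i) {
    p <- ev$pos_a[i]
    ## candidate runs: ending at the junction base or starting just after
    cands <- list(run_at(cs, p), run_at(cs, p + 1L))
    cands <- cands[!vapply(cands, is.null, logical(1))]
    best <- NULL
    for (r in cands) if (is.null(best) || r$len > best$len) best <- r
    if (is.null(best) || best$len < min_run) {
      tibble(pos_a = p, indel_length = ev$length[i],
             run_base = NA_character_, run_length = NA_integer_,
             at_run_end = FALSE)
    } else {
      tibble(pos_a = p, indel_length = ev$length[i],
             run_base = best$base, run_length = best$len, at_run_end = TRUE)
    }
  })
  frac <- if (nrow(ctx)) mean(ctx$indel_length == 1L & ctx$at_run_end) else NA_real_
  list(contexts = ctx, fraction_single_nt_at_run_end = frac)
}

#' Inversion rate from an inversion count and elapsed time
#'
#' `elapsed_years / n_inversions`: the mean time per inversion. With 9
#' centromere-proximal inversions since a split ~350,000 years ago this
#' gives one inversion per ~38,889 years.
#'
#' @param n_inversions number of inversions (>= 1).
#' @param elapsed_years elapsed time in years (> 0).
#' @return years per inversion.
#' @examples
#' inversion_rate(9, 350000) # 38888.9
#' @export
inversion_rate <- function(n_inversions, elapsed_years) {
  if (n_inversions < 1) abort("n_inversions must be at least 1")
  if (elapsed_years <= 0) abort("elapsed_years must be positive")
  elapsed_years / n_inversions
}
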