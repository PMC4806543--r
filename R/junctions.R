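common_prefix_len <- function(x, y) {
  n <- min(nchar(x), nchar(y))
  if (n == 0L) return(0L)
  a <- chars(substr(x, 1L, n))
  b <- chars(substr(y, 1L, n))
  neq <- which(a != b)
  if (length(neq) == 0L) n else neq[1L] - 1L
}

common_suffix_len <- function(x, y) {
  n <- min(nchar(x), nchar(y))
  if (n == 0L) return(0L)
  a <- chars(substr(x, nchar(x) - n + 1L, nchar(x)))
  b <- chars(substr(y, nchar(y) - n + 1L, nchar(y)))
  neq <- which(rev(a) != rev(b))
  if (length(neq) == 0L) n else neq[1L] - 1L
}

## longest k with suffix(x, k) == prefix(y, k), k strictly below the
## shorter length (KMP prefix function; for identical tandem copies the
## full-length trivial "overlap" is the duplication itself, not a motif)
overlap_len <- function(x, y) {
  s <- paste0(y, "\x01", x)
  cs <- chars(s)
  n <- length(cs)
  pi <- integer(n)
  k <- 0L
  for (i in 2:n) {
    while (k > 0L && cs[k + 1L] != cs[i]) k <- pi[k]
    if (cs[k + 1L] == cs[i]) k <- k + 1L
    pi[i] <- k
  }
  k <- pi[n]
  lim <- min(nchar(x), nchar(y))
  while (k >= lim && k > 0L) k <- pi[k]
  k
}

#' Measure microhomology at a deletion junction
#'
#' For a deletion that removed `reference[left_break + 1 .. right_break]`,
#' the microhomology is the longest sequence shared by the two breakpoint
#' flanks: the maximal common suffix of the two left flanks (ending at
#' `left_break` and at `right_break`) plus the maximal common prefix of
#' the two right flanks. Its total length is invariant to where within the
#' ambiguity window the breakpoint is placed. Length 0 (blunt junction) is
#' allowed.
#'
#' @param reference DNA string.
#' @param left_break last retained base of the left flank (0 allowed).
#' @param right_break last deleted base.
#' @return list with `microhomology` (string), `length`, and the
#'   `left_extent`/`right_extent` split around the canonical breakpoint.
#' @export
measure_microhomology <- function(reference, left_break, right_break) {
  reference <- as_dna(reference)
  n <- nchar(reference)
  stopifnot(left_break >= 0L, right_break >= left_break, right_break <= n)
  s <- common_suffix_len(substr(reference, 1L, left_break),
                         substr(reference, 1L, right_break))
  p <- common_prefix_len(substr(reference, left_break + 1L, n),
                         substr(reference, right_break + 1L, n))
  mh <- if (s + p == 0L) "" else
    subseq_chr(reference, left_break - s + 1L, left_break + p)
  list(microhomology = mh, length = s + p, left_extent = s, right_extent = p)
}

## shift a deletion interval [ds, de] on ref as far left/right as sequence
## equality allows; returns c(leftmost_ds, rightmost_ds)
deletion_window <- function(ref, ds, de) {
  n <- nchar(ref)
  l <- ds
  e <- de
  while (l > 1L && substr(ref, l - 1L, l - 1L) == substr(ref, e, e)) {
    l <- l - 1L
    e <- e - 1L
  }
  r <- ds
  e <- de
  while (e < n && substr(ref, e + 1L, e + 1L) == substr(ref, r, r)) {
    r <- r + 1L
    e <- e + 1L
  }
  c(l, r)
}

empty_events <- function() {
  tibble(kind = character(), ref_start = integer(), ref_end = integer(),
         query_junction = integer(), length = integer(),
         microhomology = character(), microhomology_length = integer(),
         window_left = integer(), window_right = integer())
}

## parse large-gap events out of a global alignment (gq = gapped query row,
## gr = gapped reference row)
alignment_events <- function(gq, gr, reference, query, min_event) {
  cq <- chars(gq)
  cr <- chars(gr)
  pr <- cumsum(cr != "-")
  pq <- cumsum(cq != "-")
  evs <- list()
  for (kind in c("deletion", "insertion")) {
    gaps <- if (kind == "deletion") cq == "-" else cr == "-"
    r <- rle(gaps)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (h in which(r$values & r$lengths >= min_event)) {
      if (kind == "deletion") {
        ds <- pr[starts[h]]
        de <- pr[ends[h]]
        win <- deletion_window(reference, ds, de)
        dsl <- win[1L]
        del <- dsl + (de - ds)
        mh <- measure_microhomology(reference, dsl - 1L, del)
        evs[[length(evs) + 1L]] <- tibble(
          kind = "deletion", ref_start = dsl, ref_end = del,
          query_junction = if (starts[h] > 1L) pq[starts[h] - 1L] else 0L,
          length = de - ds + 1L,
          microhomology = mh$microhomology,
          microhomology_length = mh$length,
          window_left = win[1L], window_right = win[2L]
        )
      } else {
        qs <- pq[starts[h]]
        qe <- pq[ends[h]]
        win <- deletion_window(query, qs, qe)
        evs[[length(evs) + 1L]] <- tibble(
          kind = "insertion",
          ref_start = if (starts[h] > 1L) pr[starts[h] - 1L] else 0L,
          ref_end = if (starts[h] > 1L) pr[starts[h] - 1L] else 0L,
          query_junction = win[1L],
          length = qe - qs + 1L,
          microhomology = NA_character_,
          microhomology_length = NA_integer_,
          window_left = win[1L], window_right = win[2L]
        )
      }
    }
  }
  dplyr::bind_rows(empty_events(), dplyr::bind_rows(evs)) |>
    dplyr::arrange(.data$ref_start)
}

#' Localize a deletion and its microhomology
#'
#' Places the breakpoints of a deletion of `query` relative to
#' `reference` at the maximal-identity position. When the two flanks share
#' homology the placement is ambiguous over a window; the canonical report
#' is the leftmost placement (homology tract attached to the left flank)
#' and the window (`window_left`..`window_right`, leftmost and rightmost
#' deletion starts) is always reported.
#'
#' A fast exact scan over every split point is used when the length
#' difference equals one clean deletion and the flanks align without
#' indels; otherwise a global alignment with a cheap long-gap model is
#' used, which also detects multiple events (status `"multi"`) and
#' insertions.
#'
#' @param query derived sequence (carries the deletion).
#' @param reference ancestral/complete sequence.
#' @param min_deletion smallest reportable event in nt (default 50);
#'   smaller gaps are treated as alignment noise.
#' @param min_flank_identity required identity of the aligned flanks
#'   (default 0.9); lower identity is an error, not a deletion call.
#' @return tibble of events (possibly 0 rows) with attribute `status` one
#'   of `"no-event"`, `"single"`, `"multi"` (see [deletion_status()]).
#' @export
locate_deletion <- function(query, reference, min_deletion = 50L,
                            min_flank_identity = 0.9) {
  query <- as_dna(query, allow_empty = FALSE)
  reference <- as_dna(reference, allow_empty = FALSE)
  d <- nchar(reference) - nchar(query)
  if (d >= min_deletion) {
    fast <- locate_deletion_fast(query, reference, d, min_flank_identity)
    if (!is.null(fast)) return(fast)
  }
  if (identical(query, reference)) {
    return(structure(empty_events(), status = "no-event"))
  }
  aln <- align_global(query, reference, match = 2, mismatch = -2,
                      gap_open = 25, gap_extend = 0.05)
  cq <- chars(aln$a)
  cr <- chars(aln$b)
  both <- cq != "-" & cr != "-"
  ## matching fraction of the shorter sequence: robust to the cheap-gap
  ## scoring aligning only scattered high-identity columns
  matches <- sum(cq[both] == cr[both])
  if (matches / min(nchar(query), nchar(reference)) < min_flank_identity) {
    abort("sequences do not align at the required flank identity")
  }
  ev <- alignment_events(aln$a, aln$b, reference, query, min_deletion)
  status <- if (nrow(ev) == 0L) "no-event" else if (nrow(ev) == 1L) "single" else "multi"
  structure(ev, status = status)
}

## O(n) single-deletion scan: assumes substitution-only flanks; returns
## NULL when the residual flank identity says the model does not fit
locate_deletion_fast <- function(query, reference, d, min_flank_identity) {
  m <- nchar(query)
  cq <- chars(query)
  cr <- chars(reference)
  left_mis <- cumsum(cq != cr[seq_len(m)])
  right_vec <- cq != cr[seq_len(m) + d]
  right_tail <- rev(cumsum(rev(right_vec)))
  cost <- c(right_tail[1L], left_mis + c(right_tail[-1L], 0L)) # j = 0..m
  best <- min(cost)
  if (1 - best / m < min_flank_identity) return(NULL)
  ties <- which(cost == best) - 1L
  ## flank mutations can create isolated cost ties outside the homology
  ## window; the junction placement is the tie with maximal reference
  ## homology, and the window is its contiguous sequence-equality shift
  mhs <- vapply(ties, function(j) {
    measure_microhomology(reference, j, j + d)$length
  }, integer(1))
  jstar <- ties[which.max(mhs)]
  win <- deletion_window(reference, jstar + 1L, jstar + d)
  jl <- win[1L] - 1L
  mh <- measure_microhomology(reference, jl, jl + d)
  structure(
    tibble(kind = "deletion", ref_start = jl + 1L, ref_end = jl + d,
           query_junction = jl, length = d,
           microhomology = mh$microhomology,
           microhomology_length = mh$length,
           window_left = win[1L], window_right = win[2L]),
    status = "single"
  )
}

#' Status of a deletion scan
#'
#' @param events result of [locate_deletion()] or [diff_monomer_arrays()].
#' @return `"no-event"`, `"single"` or `"multi"`.
#' @export
deletion_status <- function(events) attr(events, "status") %||% NA_character_

#' Characterize the junction of an adjacent segmental duplication
#'
#' For adjacent duplicated segments L = `[l_start, l_end]` and
#' R = `[l_end + 1, r_end]`, the junction microhomology is the longest
#' sequence shared by the end of L and the start of R — the motif at which
#' alternative end-joining rejoined the broken ends. Consistency with a
#' single alternative end-joining repair additionally requires the same
#' motif at the 5' end of L and the 3' end of R (as the two segments are
#' copies, the motif must be both a prefix and a suffix of the duplicated
#' unit).
#'
#' @param seq DNA string containing the duplication.
#' @param l_start,l_end,r_start,r_end 1-based closed segment coordinates;
#'   the segments must be adjacent (`r_start == l_end + 1`).
#' @return one-row tibble: `junction_pos`, `microhomology`,
#'   `microhomology_length`, `consistent_mmej`.
#' @export
analyze_duplication <- function(seq, l_start, l_end, r_start, r_end) {
  seq <- as_dna(seq)
  if (r_start != l_end + 1L) abort("segments must be adjacent")
  L <- subseq_chr(seq, l_start, l_end)
  R <- subseq_chr(seq, r_start, r_end)
  k <- overlap_len(L, R) # suffix(L) == prefix(R)
  motif <- if (k > 0L) substr(R, 1L, k) else ""
  consistent <- k > 0L &&
    identical(substr(L, 1L, k), motif) &&
    identical(substr(R, nchar(R) - k + 1L, nchar(R)), motif)
  tibble(junction_pos = l_end, microhomology = motif,
         microhomology_length = k, consistent_mmej = consistent)
}

drop_masked <- function(seq, seg_start, seg_end, mask) {
  keep <- IRanges::IRanges(seg_start, seg_end)
  if (!is.null(mask) && nrow(mask) > 0L) {
    hit <- mask$start <= seg_end & mask$end >= seg_start
    if (any(hit)) {
      m <- IRanges::IRanges(pmax(mask$start[hit], seg_start),
                            pmin(mask$end[hit], seg_end))
      keep <- IRanges::setdiff(keep, m)
    }
  }
  paste(vapply(seq_along(keep), function(i) {
    subseq_chr(seq, BiocGenerics::start(keep)[i], BiocGenerics::end(keep)[i])
  }, character(1)), collapse = "")
}

#' Date an adjacent segmental duplication
#'
#' Aligns the two duplicated copies after removing masked intervals
#' (post-duplication insertions such as retroelements that landed in one
#' copy) and converts the K2p distance to years. Fewer than `min_aligned`
#' unmasked gap-free columns yields status `"low_confidence"`.
#'
#' @param seq DNA string containing the duplication.
#' @param l_start,l_end,r_start,r_end segment coordinates (1-based closed).
#' @param mask optional tibble with `start`, `end` columns of intervals to
#'   exclude (genomic coordinates).
#' @param clock a [molecular_clock()].
#' @param min_aligned minimum gap-free aligned columns (default 200).
#' @return a `dated_event` of kind `"duplication"`.
#' @export
date_duplication <- function(seq, l_start, l_end, r_start, r_end,
                             mask = NULL, clock = molecular_clock(),
                             min_aligned = 200L) {
  seq <- as_dna(seq)
  L <- drop_masked(seq, l_start, l_end, mask)
  R <- drop_masked(seq, r_start, r_end, mask)
  aln <- align_global(L, R)
  k <- k2p_distance(aln$a, aln$b)
  status <- if (k$aligned_sites < min_aligned) "low_confidence" else "ok"
  new_dated_event("duplication", k2p = k, clock = clock, status = status)
}

#' Compare two homologous satellite monomer arrays
#'
#' Globally aligns array `b` (query) against array `a` (reference) and
#' reports monomer-level differences: deletions (with the microhomology at
#' each junction and, where the breakpoints fall inside two different
#' reference monomers, the resulting chimeric monomer), and insertions
#' (e.g. a retroelement present in one array only; the hosting reference
#' monomer is flagged disrupted).
#'
#' @param seq_a,seq_b the two array sequences (a = reference).
#' @param monomers_a `monomer_set` of `seq_a` (for monomer-level calls);
#'   optional.
#' @param min_event smallest reportable indel in nt (default 50).
#' @param chimera_window maximum breakpoint ambiguity window width for a
#'   chimeric-monomer call (default 40 nt).
#' @param min_identity arrays must align at or above this identity
#'   (default 0.5) or the comparison is an error.
#' @return events tibble (see [locate_deletion()]) with added columns
#'   `monomer_first`, `monomer_last`, `monomer_equivalents`, `chimeric`,
#'   `chimera_5p`, `chimera_3p`, `disrupted_monomer`; attribute `status`.
#' @export
diff_monomer_arrays <- function(seq_a, seq_b, monomers_a = NULL,
                                min_event = 50L, chimera_window = 40L,
                                min_identity = 0.5) {
  seq_a <- as_dna(seq_a, allow_empty = FALSE)
  seq_b <- as_dna(seq_b, allow_empty = FALSE)
  aln <- align_global(seq_b, seq_a, match = 2, mismatch = -2,
                      gap_open = 25, gap_extend = 0.05)
  cq <- chars(aln$a)
  cr <- chars(aln$b)
  both <- cq != "-" & cr != "-"
  matches <- sum(cq[both] == cr[both])
  if (matches / min(nchar(seq_a), nchar(seq_b)) < min_identity) {
    abort("arrays do not align; are they homologous?")
  }
  ev <- alignment_events(aln$a, aln$b, seq_a, seq_b, min_event)
  n <- nrow(ev)
  ev$monomer_first <- NA_integer_
  ev$monomer_last <- NA_integer_
  ev$monomer_equivalents <- NA_real_
  ev$chimeric <- FALSE
  ev$chimera_5p <- NA_integer_
  ev$chimera_3p <- NA_integer_
  ev$disrupted_monomer <- NA_integer_
  if (n > 0L && !is.null(monomers_a)) {
    mono_w <- stats::median(monomers_a$end - monomers_a$start + 1)
    for (i in seq_len(n)) {
      if (ev$kind[i] == "deletion") {
        hit <- which(monomers_a$end >= ev$ref_start[i] &
                       monomers_a$start <= ev$ref_end[i])
        if (length(hit)) {
          ev$monomer_first[i] <- monomers_a$index[min(hit)]
          ev$monomer_last[i] <- monomers_a$index[max(hit)]
        }
        ev$monomer_equivalents[i] <- round(ev$length[i] / mono_w, 2)
        i5 <- which(monomers_a$start < ev$ref_start[i] &
                      monomers_a$end >= ev$ref_start[i])
        i3 <- which(monomers_a$start <= ev$ref_end[i] &
                      monomers_a$end > ev$ref_end[i])
        if (length(i5) == 1L && length(i3) == 1L && i3 > i5 &&
            (ev$window_right[i] - ev$window_left[i] + 1L) <= chimera_window) {
          ev$chimeric[i] <- TRUE
          ev$chimera_5p[i] <- monomers_a$index[i5]
          ev$chimera_3p[i] <- monomers_a$index[i3]
        }
      } else {
        host <- which(monomers_a$start <= ev$ref_start[i] &
                        monomers_a$end > ev$ref_start[i])
        if (length(host)) ev$disrupted_monomer[i] <- monomers_a$index[min(host)]
      }
    }
  }
  status <- if (n == 0L) "no-event" else if (n == 1L) "single" else "multi"
  structure(ev, status = status)
}
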