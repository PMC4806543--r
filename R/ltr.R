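#' LTR pairing criteria
#'
#' The filters that decide whether two LTR annotations are the intact
#' termini of a single retroelement insertion and can be dated: identical
#' (or near-identical) flanking target site duplications (TSDs), reverse
#' complement terminal edges (canonically 5'-TG ... CA-3'), same subfamily,
#' same orientation, and LTR lengths within a ratio bound.
#'
#' @param tsd_length TSD length in nt (default 5).
#' @param tsd_max_edits maximum Levenshtein distance between the two TSDs:
#'   0 (strict) or 1 (relaxed, tolerating one mismatch or indel).
#' @param edge_min_match number of terminal nt that must be reverse
#'   complement matches between the LTR ends (default 2, i.e. TG/CA).
#' @param min_length_ratio smaller LTR length over larger (default 0.90).
#' @param require_same_subfamily,require_same_orientation logical filters.
#' @return object of class `ltr_criteria`.
#' @export
ltr_criteria <- function(tsd_length = 5L, tsd_max_edits = 0L,
                         edge_min_match = 2L, min_length_ratio = 0.90,
                         require_same_subfamily = TRUE,
                         require_same_orientation = TRUE) {
  stopifnot(tsd_max_edits %in% c(0L, 1L),
            min_length_ratio > 0, min_length_ratio <= 1)
  structure(
    list(tsd_length = as.integer(tsd_length),
         tsd_max_edits = as.integer(tsd_max_edits),
         edge_min_match = as.integer(edge_min_match),
         min_length_ratio = min_length_ratio,
         require_same_subfamily = require_same_subfamily,
         require_same_orientation = require_same_orientation),
    class = "ltr_criteria"
  )
}

#' Construct an LTR element table
#'
#' One row per candidate element. `ltr5_*` is the left (upstream in
#' forward coordinates) LTR interval and `ltr3_*` the right one; for a
#' minus-strand element the biological 5' LTR is the right interval, which
#' the pairing and dating code handles via `strand`.
#'
#' @param seq_id,element_id identifiers.
#' @param family,subfamily repeat family (e.g. a centromeric retroelement
#'   family) and subfamily labels.
#' @param strand `"+"` or `"-"`.
#' @param ltr5_start,ltr5_end,ltr3_start,ltr3_end 1-based closed intervals.
#' @return tibble of elements.
#' @export
ltr_elements <- function(seq_id, element_id, family, subfamily, strand,
                         ltr5_start, ltr5_end, ltr3_start, ltr3_end) {
  out <- tibble(
    seq_id = seq_id, element_id = element_id, family = family,
    subfamily = subfamily, strand = strand,
    ltr5_start = as.integer(ltr5_start), ltr5_end = as.integer(ltr5_end),
    ltr3_start = as.integer(ltr3_start), ltr3_end = as.integer(ltr3_end)
  )
  bad <- out$ltr5_start > out$ltr5_end | out$ltr3_start > out$ltr3_end |
    out$ltr5_end >= out$ltr3_start
  if (any(bad)) abort("LTR intervals must be ordered and non-overlapping")
  out
}

## oriented LTR sequences of one element row: list(l5, l3) such that l5 is
## the element's biological 5' LTR read in element orientation
oriented_ltrs <- function(seq, el) {
  left <- subseq_chr(seq, el$ltr5_start, el$ltr5_end)
  right <- subseq_chr(seq, el$ltr3_start, el$ltr3_end)
  if (identical(el$strand, "-")) {
    list(l5 = revcomp(right), l3 = revcomp(left))
  } else {
    list(l5 = left, l3 = right)
  }
}

#' Extract target site duplications flanking an element
#'
#' Returns the `tsd_length` nt immediately upstream of the left LTR and
#' immediately downstream of the right LTR, in forward coordinates. The TSD
#' is a direct duplication of host sequence, so forward-strand flanks are
#' comparable regardless of element orientation.
#'
#' @param seq DNA string of the locus.
#' @param elements element table (see [ltr_elements()]).
#' @param tsd_length TSD length in nt.
#' @return `elements` with `tsd5` and `tsd3` columns appended.
#' @export
extract_tsds <- function(seq, elements, tsd_length = 5L) {
  seq <- as_dna(seq)
  n <- nchar(seq)
  if (any(elements$ltr5_start - tsd_length < 1L) ||
      any(elements$ltr3_end + tsd_length > n)) {
    abort("element too close to the sequence edge: TSD flank unavailable")
  }
  elements$tsd5 <- vapply(seq_len(nrow(elements)), function(i) {
    subseq_chr(seq, elements$ltr5_start[i] - tsd_length,
               elements$ltr5_start[i] - 1L)
  }, character(1))
  elements$tsd3 <- vapply(seq_len(nrow(elements)), function(i) {
    subseq_chr(seq, elements$ltr3_end[i] + 1L,
               elements$ltr3_end[i] + tsd_length)
  }, character(1))
  elements
}

tsd_edit_distance <- function(a, b) {
  as.integer(utils::adist(a, b))
}

#' Filter LTR pairs for dating
#'
#' Applies the pairing criteria in order: (a) TSD edit distance, (b)
#' reverse complement terminal edges, (c) same subfamily, (d) same
#' orientation, (e) length ratio. Each rejected element records the first
#' criterion it failed; this is filtering, not failure.
#'
#' Per-LTR subfamily/strand columns (`subfamily5`/`subfamily3`,
#' `strand5`/`strand3`) are used when present; otherwise the element-level
#' `subfamily` and `strand` are assumed to hold for both LTRs.
#'
#' @param seq DNA string of the locus.
#' @param elements element table; TSD columns are computed when absent.
#' @param criteria an [ltr_criteria()].
#' @return `elements` with `tsd5`, `tsd3`, `tsd_edits`, `length_ratio`,
#'   `accepted` and `rejection_reason` columns.
#' @export
pair_ltrs <- function(seq, elements, criteria = ltr_criteria()) {
  seq <- as_dna(seq)
  if (!all(c("tsd5", "tsd3") %in% names(elements))) {
    elements <- extract_tsds(seq, elements, criteria$tsd_length)
  }
  sub5 <- elements[["subfamily5"]] %||% elements$subfamily
  sub3 <- elements[["subfamily3"]] %||% elements$subfamily
  str5 <- elements[["strand5"]] %||% elements$strand
  str3 <- elements[["strand3"]] %||% elements$strand
  n <- nrow(elements)
  edits <- integer(n)
  ratio <- double(n)
  reason <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    el <- elements[i, ]
    edits[i] <- tsd_edit_distance(el$tsd5, el$tsd3)
    len5 <- el$ltr5_end - el$ltr5_start + 1L
    len3 <- el$ltr3_end - el$ltr3_start + 1L
    ratio[i] <- min(len5, len3) / max(len5, len3)
    ltrs <- oriented_ltrs(seq, el)
    m <- criteria$edge_min_match
    head5 <- substr(ltrs$l5, 1L, m)
    tail3 <- substr(ltrs$l3, nchar(ltrs$l3) - m + 1L, nchar(ltrs$l3))
    if (edits[i] > criteria$tsd_max_edits) {
      reason[i] <- "tsd"
    } else if (!identical(head5, revcomp(tail3))) {
      reason[i] <- "edge"
    } else if (criteria$require_same_subfamily && !identical(sub5[i], sub3[i])) {
      reason[i] <- "subfamily"
    } else if (criteria$require_same_orientation && !identical(str5[i], str3[i])) {
      reason[i] <- "orientation"
    } else if (ratio[i] < criteria$min_length_ratio) {
      reason[i] <- "ratio"
    }
  }
  elements$tsd_edits <- edits
  elements$length_ratio <- ratio
  elements$accepted <- is.na(reason)
  elements$rejection_reason <- reason
  elements
}

#' Date one LTR pair under the molecular clock
#'
#' Globally aligns the element's two LTRs (in element orientation),
#' computes the K2p distance over gap-free columns and converts it to
#' years. For identical LTRs (K = 0) the event carries
#' `upper_bound_years`, the age at which one substitution would be
#' expected over the aligned sites.
#'
#' @param seq DNA string of the locus.
#' @param element one-row element table (ideally accepted by [pair_ltrs()]).
#' @param clock a [molecular_clock()].
#' @return a `dated_event` of kind `"insertion"`.
#' @export
date_ltr_pair <- function(seq, element, clock = molecular_clock()) {
  seq <- as_dna(seq)
  stopifnot(nrow(element) == 1L)
  ltrs <- oriented_ltrs(seq, element)
  aln <- align_global(ltrs$l5, ltrs$l3)
  k <- k2p_distance(aln$a, aln$b)
  new_dated_event("insertion", k2p = k, clock = clock,
                  extra = list(element_id = element$element_id,
                               ltr_lengths = c(nchar(ltrs$l5), nchar(ltrs$l3))))
}

#' Date all accepted LTR pairs in an element table
#'
#' @param seq DNA string of the locus.
#' @param elements output of [pair_ltrs()] (rows with `accepted == FALSE`
#'   are carried through undated, keeping their rejection reason).
#' @param clock a [molecular_clock()].
#' @return tibble: one row per element with dating columns (`K`, `P`, `Q`,
#'   `aligned_sites`, `years`, `upper_bound_years`) joined on.
#' @export
date_ltr_pairs <- function(seq, elements, clock = molecular_clock()) {
  rows <- purrr::map_dfr(seq_len(nrow(elements)), function(i) {
    el <- elements[i, ]
    if (!isTRUE(el$accepted)) {
      return(tibble(element_id = el$element_id, K = NA_real_, P = NA_real_,
                    Q = NA_real_, aligned_sites = NA_integer_,
                    years = NA_real_, upper_bound_years = NA_real_))
    }
    ev <- date_ltr_pair(seq, el, clock)
    tibble(element_id = el$element_id, K = ev$k2p$K, P = ev$k2p$P,
           Q = ev$k2p$Q, aligned_sites = ev$k2p$aligned_sites,
           years = ev$years, upper_bound_years = ev$upper_bound_years)
  })
  dplyr::left_join(elements, rows, by = "element_id")
}

#' Flag chimeric elements by mismatched TSDs
#'
#' A structurally complete element (both LTRs present) whose flanking TSDs
#' differ by more edits than the pairing tolerance is the product of two
#' independent insertions recombined into one apparent element.
#'
#' @param seq DNA string of the locus.
#' @param elements element table; TSDs computed when absent.
#' @param criteria an [ltr_criteria()]; `tsd_max_edits` sets the tolerance.
#' @return `elements` with `tsd_edits` and logical `chimeric` columns.
#' @export
detect_chimeric <- function(seq, elements, criteria = ltr_criteria()) {
  seq <- as_dna(seq)
  if (!all(c("tsd5", "tsd3") %in% names(elements))) {
    elements <- extract_tsds(seq, elements, criteria$tsd_length)
  }
  elements$tsd_edits <- vapply(seq_len(nrow(elements)), function(i) {
    tsd_edit_distance(elements$tsd5[i], elements$tsd3[i])
  }, integer(1))
  elements$chimeric <- elements$tsd_edits > criteria$tsd_max_edits
  elements
}
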