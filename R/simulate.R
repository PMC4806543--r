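#' Simulation configuration
#'
#' Holds the seed and the mutational parameters shared by all generators.
#' The seed fully determines every output (bit-identical across runs).
#'
#' @param seed integer RNG seed.
#' @param rate molecular-clock substitution rate (substitutions/site/year;
#'   default 3.3e-8, the rate used for dating).
#' @param transition_fraction probability that a substitution is a
#'   transition (default 2/3, twice as likely as either transversion).
#' @param monomer_length satellite monomer length in nt (default 156).
#' @param tsd_length target site duplication length in nt (default 5).
#' @return object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, rate = 3.3e-8, transition_fraction = 2 / 3,
                       monomer_length = 156L, tsd_length = 5L) {
  stopifnot(transition_fraction >= 0, transition_fraction <= 1, rate >= 0)
  structure(list(seed = as.integer(seed), rate = rate,
                 transition_fraction = transition_fraction,
                 monomer_length = as.integer(monomer_length),
                 tsd_length = as.integer(tsd_length)),
            class = "sim_config")
}

TRANSITION <- c(A = "G", G = "A", C = "T", T = "C")

## substitution process on a char vector; uses current RNG state
mutate_chars <- function(cs, subs_per_site, transition_fraction,
                         exclude = integer(0)) {
  L <- length(cs)
  n <- stats::rpois(1L, subs_per_site * L)
  if (n == 0L) return(cs)
  pos <- sample.int(L, n, replace = TRUE) # back-mutation possible
  if (length(exclude)) pos <- pos[!(pos %in% exclude)]
  for (p in pos) {
    b <- cs[p]
    if (stats::runif(1) < transition_fraction) {
      cs[p] <- TRANSITION[[b]]
    } else {
      cs[p] <- sample(setdiff(DNA_BASES, c(b, TRANSITION[[b]])), 1L)
    }
  }
  cs
}

#' Mutate a sequence under the K2p substitution process
#'
#' Applies `Poisson(substitutions_per_site * length)` substitution events
#' at uniformly drawn positions (with replacement, so back-mutations can
#' occur, matching the assumptions under which the K2p distance is an
#' unbiased estimator). Each event is a transition with probability
#' `transition_fraction`, otherwise a uniformly chosen transversion.
#'
#' @param seq DNA string.
#' @param substitutions_per_site expected substitutions per site (>= 0).
#' @param cfg a [sim_config()]; its seed makes the call deterministic.
#' @return mutated DNA string.
#' @export
mutate_k2p <- function(seq, substitutions_per_site, cfg = sim_config()) {
  stopifnot(substitutions_per_site >= 0)
  seq <- as_dna(seq)
  withr::with_seed(cfg$seed, {
    paste(mutate_chars(chars(seq), substitutions_per_site,
                       cfg$transition_fraction), collapse = "")
  })
}

#' Simulate an LTR retroelement insertion of known age
#'
#' Builds a locus: random flank, a target site duplication (TSD) on both
#' sides of the element, two LTRs (identical at insertion, with canonical
#' TG...CA termini) around an internal region, then mutates each LTR
#' independently with `rate * age_years` substitutions/site, so the
#' expected pairwise LTR divergence is `2 * rate * age_years`.
#'
#' @param age_years true insertion age.
#' @param ltr_length,internal_length,flank element geometry in nt.
#' @param chimeric if `TRUE`, the two TSDs are drawn independently
#'   (guaranteed different), emulating a recombined chimera of two
#'   insertions.
#' @param cfg a [sim_config()].
#' @return list with `sequence`, `elements` (one-row [ltr_elements()]
#'   table with TSD columns precomputable from the sequence) and `truth`
#'   (list: `age_years`, `tsd5`, `tsd3`, `chimeric`).
#' @export
simulate_ltr_insertion <- function(age_years, ltr_length = 1000L,
                                   internal_length = 3000L, flank = 500L,
                                   chimeric = FALSE, cfg = sim_config()) {
  stopifnot(age_years >= 0, ltr_length >= 10L)
  withr::with_seed(cfg$seed, {
    ltr <- chars(random_dna(ltr_length))
    ltr[1:2] <- c("T", "G")
    ltr[(ltr_length - 1L):ltr_length] <- c("C", "A")
    tsd5 <- random_dna(cfg$tsd_length)
    tsd3 <- tsd5
    if (chimeric) {
      repeat {
        tsd3 <- random_dna(cfg$tsd_length)
        if (tsd3 != tsd5) break
      }
    }
    per_ltr <- cfg$rate * age_years
    l5 <- paste(mutate_chars(ltr, per_ltr, cfg$transition_fraction), collapse = "")
    l3 <- paste(mutate_chars(ltr, per_ltr, cfg$transition_fraction), collapse = "")
    fl <- random_dna(flank)
    fr <- random_dna(flank)
    internal <- random_dna(internal_length)
    sequence <- paste0(fl, tsd5, l5, internal, l3, tsd3, fr)
    ltr5_start <- flank + cfg$tsd_length + 1L
    ltr5_end <- ltr5_start + ltr_length - 1L
    ltr3_start <- ltr5_end + internal_length + 1L
    ltr3_end <- ltr3_start + ltr_length - 1L
    elements <- ltr_elements(
      seq_id = "sim", element_id = "el1", family = "CR", subfamily = "CR-R1",
      strand = "+", ltr5_start = ltr5_start, ltr5_end = ltr5_end,
      ltr3_start = ltr3_start, ltr3_end = ltr3_end
    )
    list(sequence = sequence, elements = elements,
         truth = list(age_years = age_years, tsd5 = tsd5, tsd3 = tsd3,
                      chimeric = chimeric, ltr_length = ltr_length))
  })
}

#' Simulate a satellite array containing an adjacent duplication
#'
#' Generates `n_monomers` ancestral monomers, each at `monomer_divergence`
#' substitutions/site from a common random consensus, duplicates the run
#' of `dup_length` monomers starting at `dup_start` adjacently (the copy
#' follows immediately), then mutates each copy independently with
#' `rate * age_years` substitutions/site. Optionally a foreign insertion
#' is planted inside the downstream copy.
#'
#' @param n_monomers ancestral monomer count (before duplication).
#' @param dup_start,dup_length duplicated run (ancestral indices).
#' @param age_years true duplication age.
#' @param monomer_divergence substitutions/site of each ancestral monomer
#'   from the array consensus (default 0.08).
#' @param insert optional list `list(after_monomer =, length =)` planting
#'   a random foreign insertion after that monomer (final numbering).
#' @param cfg a [sim_config()].
#' @return list with `sequence`, `consensus`, `monomer_table` (tibble:
#'   `index`, `start`, `end`) and `truth` (list: `L_first`, `L_last`,
#'   `R_first`, `R_last`, `offset`, `age_years`, `insert_start`,
#'   `insert_end`).
#' @export
simulate_hor_array <- function(n_monomers, dup_start, dup_length, age_years,
                               monomer_divergence = 0.08, insert = NULL,
                               cfg = sim_config()) {
  stopifnot(dup_start >= 1L, dup_start + dup_length - 1L <= n_monomers,
            age_years >= 0)
  withr::with_seed(cfg$seed, {
    consensus <- random_dna(cfg$monomer_length)
    anc <- lapply(seq_len(n_monomers), function(i) {
      mutate_chars(chars(consensus), monomer_divergence, cfg$transition_fraction)
    })
    s <- dup_start
    e <- dup_start + dup_length - 1L
    per_copy <- cfg$rate * age_years
    copyL <- lapply(anc[s:e], mutate_chars, subs_per_site = per_copy,
                    transition_fraction = cfg$transition_fraction)
    copyR <- lapply(anc[s:e], mutate_chars, subs_per_site = per_copy,
                    transition_fraction = cfg$transition_fraction)
    mono <- c(anc[seq_len(s - 1L)], copyL, copyR,
              if (e < n_monomers) anc[(e + 1L):n_monomers] else list())
    mono_str <- vapply(mono, paste, character(1), collapse = "")
    n_final <- length(mono_str)
    ins_after <- if (!is.null(insert)) insert$after_monomer else NA_integer_
    ins_len <- if (!is.null(insert)) insert$length else 0L
    ins_seq <- if (!is.null(insert)) random_dna(ins_len) else ""
    pieces <- character(0)
    starts <- integer(n_final)
    pos <- 1L
    ins_start <- NA_integer_
    for (i in seq_len(n_final)) {
      starts[i] <- pos
      pieces <- c(pieces, mono_str[i])
      pos <- pos + nchar(mono_str[i])
      if (!is.na(ins_after) && i == ins_after) {
        ins_start <- pos
        pieces <- c(pieces, ins_seq)
        pos <- pos + ins_len
      }
    }
    sequence <- paste(pieces, collapse = "")
    monomer_table <- tibble(
      index = seq_len(n_final), start = starts,
      end = starts + nchar(mono_str) - 1L
    )
    list(sequence = sequence, consensus = consensus,
         monomer_table = monomer_table,
         truth = list(L_first = s, L_last = e, R_first = e + 1L,
                      R_last = e + dup_length, offset = dup_length,
                      age_years = age_years,
                      insert_start = ins_start,
                      insert_end = if (is.na(ins_start)) NA_integer_
                                   else ins_start + ins_len - 1L))
  })
}

#' Simulate a microhomology-mediated deletion
#'
#' Writes an exact `microhomology_length`-nt block at both chosen
#' breakpoints of the reference, then derives a sequence with the
#' intervening segment plus one homology copy deleted — the alternative
#' end-joining geometry. So that the planted microhomology length stays
#' well defined (and recoverable exactly), the bases bounding both
#' homology copies are forced to mismatch, and flank-divergence mutations
#' are excluded from the junction neighbourhood (homology tract plus 2 nt
#' each side).
#'
#' @param deletion_length nt removed (must exceed the microhomology).
#' @param microhomology_length planted homology length k (>= 0).
#' @param ref_length reference length when `reference` is not supplied.
#' @param reference optional reference DNA string to plant into.
#' @param flank_divergence substitutions/site applied to the derived
#'   sequence's flanks (default 0).
#' @param cfg a [sim_config()].
#' @return list with `reference`, `derived` and `truth` (list:
#'   `left_break`, `right_break`, `microhomology_length`,
#'   `deletion_length`, `window_left`, `window_right` — leftmost and
#'   rightmost deletion starts of the ambiguity window).
#' @export
simulate_mmej_deletion <- function(deletion_length, microhomology_length = 0L,
                                   ref_length = 6000L, reference = NULL,
                                   flank_divergence = 0, cfg = sim_config()) {
  k <- as.integer(microhomology_length)
  stopifnot(k >= 0L, deletion_length > k)
  withr::with_seed(cfg$seed, {
    ref <- if (is.null(reference)) random_dna(ref_length) else as_dna(reference)
    n <- nchar(ref)
    margin <- k + 3L
    if (n < deletion_length + 2L * margin + 10L) {
      abort("reference too short for the requested deletion")
    }
    a <- sample(seq.int(margin + 1L, n - deletion_length - margin), 1L)
    b <- a + deletion_length
    cs <- chars(ref)
    if (k > 0L) cs[(b - k + 1L):b] <- cs[(a - k + 1L):a]
    force_diff <- function(i, j) {
      if (cs[i] == cs[j]) cs[j] <<- sample(setdiff(DNA_BASES, cs[i]), 1L)
    }
    if (k > 0L) force_diff(a - k, b - k) else force_diff(a, b)
    force_diff(a + 1L, b + 1L)
    ref <- paste(cs, collapse = "")
    der <- c(cs[1:a], cs[(b + 1L):n])
    if (flank_divergence > 0) {
      exclude <- max(1L, a - k - 2L):min(length(der), a + 2L)
      der <- mutate_chars(der, flank_divergence, cfg$transition_fraction,
                          exclude = exclude)
    }
    list(reference = ref, derived = paste(der, collapse = ""),
         truth = list(left_break = a, right_break = b,
                      microhomology_length = k,
                      deletion_length = deletion_length,
                      window_left = a - k + 1L, window_right = a + 1L))
  })
}

#' Simulate a paired ChIP/input coverage track
#'
#' Per-base input coverage is Poisson(`depth`); ChIP coverage is
#' Poisson(`depth * fold(x)`) with `fold(x)` given by `enriched` intervals
#' (1 elsewhere). `total_read_pairs` on both tracks is the genome-scale
#' library equivalent `depth * length / 200` (2 x 100 nt read pairs):
#' the simulated region stands for a small slice of a genome-wide library
#' of matched depth, so depth normalization leaves the planted fold
#' recoverable.
#'
#' @param length track length in nt.
#' @param enriched tibble with `start`, `end`, `fold` columns (may be
#'   empty for a flat track).
#' @param depth mean per-base input coverage.
#' @param cfg a [sim_config()].
#' @return list with `chip`, `input` ([coverage_track()]s) and `truth`.
#' @export
simulate_coverage_pair <- function(length, enriched = NULL, depth = 20,
                                   cfg = sim_config()) {
  stopifnot(length >= 1L, depth >= 0)
  withr::with_seed(cfg$seed, {
    fold <- rep(1, length)
    if (!is.null(enriched) && nrow(enriched) > 0L) {
      stopifnot(all(enriched$fold > 0))
      for (i in seq_len(nrow(enriched))) {
        fold[enriched$start[i]:enriched$end[i]] <- enriched$fold[i]
      }
    }
    input <- stats::rpois(length, depth)
    chip <- stats::rpois(length, depth * fold)
    pairs <- depth * length / 200
    list(
      chip = coverage_track(chip, total_read_pairs = pairs, seq_id = "sim"),
      input = coverage_track(input, total_read_pairs = pairs, seq_id = "sim"),
      truth = list(enriched = enriched, depth = depth)
    )
  })
}
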