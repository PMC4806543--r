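#' Kimura two-parameter distance from a pairwise alignment
#'
#' Computes transition (`P`) and transversion (`Q`) proportions over the
#' gap-free columns of two equal-length gapped sequences and the K2p
#' distance
#' \deqn{K = -\tfrac{1}{2}\ln(1 - 2P - Q) - \tfrac{1}{4}\ln(1 - 2Q).}
#' Columns containing a gap (`-`) or an `N` in either row are excluded.
#'
#' @param aligned_a,aligned_b equal-length gapped DNA strings (gaps as `-`).
#' @return object of class `k2p`: list with `P`, `Q`, `K`, `aligned_sites`,
#'   `transitions`, `transversions`.
#' @examples
#' a <- paste(rep("A", 100), collapse = "")
#' k2p_distance(a, a)$K  # 0
#' @export
k2p_distance <- function(aligned_a, aligned_b) {
  if (!is.character(aligned_a) || !is.character(aligned_b) ||
      length(aligned_a) != 1L || length(aligned_b) != 1L) {
    abort("aligned sequences must be single character strings")
  }
  aligned_a <- toupper(aligned_a)
  aligned_b <- toupper(aligned_b)
  if (nchar(aligned_a) != nchar(aligned_b)) {
    abort("aligned sequences must have equal length")
  }
  ca <- chars(aligned_a)
  cb <- chars(aligned_b)
  ok <- ca %in% DNA_BASES & cb %in% DNA_BASES
  n <- sum(ok)
  if (n < 1L) abort("alignment has no gap-free A/C/G/T column")
  ca <- ca[ok]
  cb <- cb[ok]
  diff <- ca != cb
  ## transitions: A<->G, C<->T; everything else differing is a transversion
  purine <- c("A", "G")
  is_ts <- diff & ((ca %in% purine) == (cb %in% purine))
  ts <- sum(is_ts)
  tv <- sum(diff) - ts
  P <- ts / n
  Q <- tv / n
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) {
    abort("K2p distance is saturated (1 - 2P - Q <= 0 or 1 - 2Q <= 0)",
          class = "cenarch_saturation")
  }
  structure(
    list(P = P, Q = Q, K = -0.5 * log(w1) - 0.25 * log(w2),
         aligned_sites = n, transitions = ts, transversions = tv),
    class = "k2p"
  )
}

#' @export
print.k2p <- function(x, ...) {
  cat(sprintf("K2p distance: K = %.6g (P = %.4g, Q = %.4g, %d sites)\n",
              x$K, x$P, x$Q, x$aligned_sites))
  invisible(x)
}

#' @rdname tidy_cenarch
#' @export
tidy.k2p <- function(x, ...) {
  tibble(P = x$P, Q = x$Q, K = x$K, aligned_sites = x$aligned_sites,
         transitions = x$transitions, transversions = x$transversions)
}

#' Molecular clock specification
#'
#' The default substitution rate, 3.3e-8 substitutions/site/year, is the
#' maize nuclear rate classically used to date LTR retroelement insertions;
#' the divergence divisor is 2 because two copies that were identical at the
#' event (the two LTRs of one element, or the two copies of a duplication)
#' accumulate substitutions along two independent lineages.
#'
#' @param rate substitutions/site/year (> 0).
#' @param divergence_divisor number of diverging lineages (default 2).
#' @return object of class `molecular_clock`.
#' @export
molecular_clock <- function(rate = 3.3e-8, divergence_divisor = 2) {
  stopifnot(rate > 0, divergence_divisor > 0)
  structure(list(rate = rate, divergence_divisor = divergence_divisor),
            class = "molecular_clock")
}

#' Convert a K2p distance to an age in years
#'
#' `years = K / (divergence_divisor * rate)`.
#'
#' @param k2p a `k2p` object (from [k2p_distance()]) or a bare numeric K.
#' @param clock a [molecular_clock()].
#' @return age in years (numeric scalar).
#' @examples
#' k2p_to_years(0.0066)  # 100,000
#' @export
k2p_to_years <- function(k2p, clock = molecular_clock()) {
  K <- if (inherits(k2p, "k2p")) k2p$K else as.numeric(k2p)
  stopifnot(is.finite(K))
  K / (clock$divergence_divisor * clock$rate)
}

## internal constructor for dated events
new_dated_event <- function(kind, k2p = NULL, clock = molecular_clock(),
                            status = "ok", extra = list()) {
  years <- NA_real_
  upper <- NA_real_
  if (!is.null(k2p)) {
    years <- k2p_to_years(k2p, clock)
    if (k2p$K == 0) {
      ## age at which one substitution would be expected across the
      ## compared sites: an upper bound, not a point estimate
      upper <- (1 / k2p$aligned_sites) / (clock$divergence_divisor * clock$rate)
    }
  }
  structure(
    c(list(kind = kind, years = years, upper_bound_years = upper,
           k2p = k2p, clock = clock, status = status), extra),
    class = "dated_event"
  )
}

#' @export
print.dated_event <- function(x, ...) {
  if (!is.na(x$years)) {
    cat(sprintf("Dated %s: %.1f years (%.1f kya)", x$kind, x$years, x$years / 1e3))
    if (!is.na(x$upper_bound_years)) {
      cat(sprintf(" [identical copies; upper bound %.1f kya]",
                  x$upper_bound_years / 1e3))
    }
    cat("\n")
  } else {
    cat(sprintf("Dated %s: status '%s'\n", x$kind, x$status))
  }
  invisible(x)
}

#' Tidy and glance methods for cenarch result objects
#'
#' Broom-style accessors: `tidy()` returns per-record rows, `glance()` a
#' one-row summary.
#'
#' @param x a cenarch result object.
#' @param ... unused.
#' @return a tibble.
#' @name tidy_cenarch
NULL

#' @rdname tidy_cenarch
#' @export
tidy.dated_event <- function(x, ...) {
  tibble(
    kind = x$kind,
    years = x$years,
    upper_bound_years = x$upper_bound_years,
    K = if (is.null(x$k2p)) NA_real_ else x$k2p$K,
    P = if (is.null(x$k2p)) NA_real_ else x$k2p$P,
    Q = if (is.null(x$k2p)) NA_real_ else x$k2p$Q,
    aligned_sites = if (is.null(x$k2p)) NA_integer_ else x$k2p$aligned_sites,
    status = x$status
  )
}

#' Date two homologous sequences under the molecular clock
#'
#' Globally aligns the two sequences, computes the K2p distance over
#' gap-free columns and converts it to years. Used directly for pairs such
#' as orthologous satellite segments from two inbreds, and as the engine
#' behind LTR, HOR and duplication dating.
#'
#' @param a,b DNA strings (character or DNAString).
#' @param clock a [molecular_clock()].
#' @param kind label stored on the resulting event.
#' @return a `dated_event`.
#' @export
date_sequence_pair <- function(a, b, clock = molecular_clock(),
                               kind = "divergence") {
  aln <- align_global(a, b)
  k <- k2p_distance(aln$a, aln$b)
  new_dated_event(kind, k2p = k, clock = clock)
}
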