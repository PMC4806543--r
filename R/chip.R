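#' Coverage track constructor
#'
#' @param values per-base coverage (non-negative numeric vector).
#' @param total_read_pairs read pairs in the originating library (used for
#'   depth normalization; for a track covering a sub-region of a genome
#'   this is the genome-wide library size).
#' @param seq_id sequence identifier.
#' @return object of class `coverage_track`.
#' @export
coverage_track <- function(values, total_read_pairs, seq_id = "seq") {
  stopifnot(is.numeric(values), all(values >= 0), total_read_pairs >= 0)
  structure(list(seq_id = seq_id, values = as.numeric(values),
                 total_read_pairs = total_read_pairs),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("coverage_track '%s': %d nt, mean %.2fx, %g read pairs\n",
              x$seq_id, length(x$values), mean(x$values), x$total_read_pairs))
  invisible(x)
}

#' Enrichment windowing configuration
#'
#' @param window_size window in nt (default 100,000).
#' @param step step between window starts in nt (default 10,000);
#'   `window_size` must be a multiple of `step`.
#' @param smooth_windows odd number of consecutive windows averaged
#'   (default 9).
#' @param pseudocount added to both normalized signals before the ratio
#'   (default 0: the ratio is undefined where the input signal is 0).
#' @return object of class `enrichment_config`.
#' @export
enrichment_config <- function(window_size = 100000L, step = 10000L,
                              smooth_windows = 9L, pseudocount = 0) {
  stopifnot(window_size %% step == 0, smooth_windows %% 2L == 1L,
            pseudocount >= 0)
  structure(list(window_size = as.integer(window_size),
                 step = as.integer(step),
                 smooth_windows = as.integer(smooth_windows),
                 pseudocount = pseudocount),
            class = "enrichment_config")
}

#' Windowed coverage sums
#'
#' Sums coverage in sliding windows of `window_size` nt advancing by
#' `step` nt. Trailing windows that extend past the end of the track are
#' reported with their true (shorter) span and flagged `partial`.
#'
#' @param track a [coverage_track()].
#' @param cfg an [enrichment_config()].
#' @return tibble with `pos` (window start, 1-based), `sum`, `span`,
#'   `partial`.
#' @export
window_coverage <- function(track, cfg = enrichment_config()) {
  v <- track$values
  n <- length(v)
  cs <- c(0, cumsum(v))
  starts <- seq.int(1L, max(n - cfg$step + 1L, 1L), by = cfg$step)
  ends <- pmin(starts + cfg$window_size - 1L, n)
  tibble(
    pos = starts,
    sum = cs[ends + 1L] - cs[starts],
    span = ends - starts + 1L,
    partial = (ends - starts + 1L) < cfg$window_size
  )
}

## centered moving average; edge positions average the available neighbors
moving_average_partial <- function(x, k) {
  h <- (k - 1L) %/% 2L
  n <- length(x)
  cs <- c(0, cumsum(x))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Smooth and depth-normalize windowed coverage
#'
#' Applies a centered moving average over `smooth_windows` consecutive
#' window sums (edge windows average over the windows available) and
#' scales by `1e6 / total_read_pairs` (counts per million read pairs; any
#' fixed constant cancels in the ChIP/input ratio).
#'
#' @param windowed output of [window_coverage()].
#' @param cfg an [enrichment_config()].
#' @param total_read_pairs library size of the corresponding dataset.
#' @return `windowed` with a `signal` column appended.
#' @export
smooth_and_normalize <- function(windowed, cfg, total_read_pairs) {
  if (total_read_pairs <= 0) abort("total_read_pairs must be positive")
  sm <- moving_average_partial(windowed$sum, cfg$smooth_windows)
  windowed$signal <- sm * 1e6 / total_read_pairs
  windowed
}

#' ChIP/input enrichment profile
#'
#' Computes the windowed, smoothed, depth-normalized ChIP and input
#' signals and their ratio at each step across the sequence. Where the
#' normalized input signal is 0 and `pseudocount` is 0 the ratio is
#' undefined (`NA`).
#'
#' @param chip,input [coverage_track()]s of equal length.
#' @param cfg an [enrichment_config()].
#' @return `enrichment_profile` tibble: `pos`, `chip`, `input`,
#'   `enrichment`, `partial`.
#' @export
compute_enrichment <- function(chip, input, cfg = enrichment_config()) {
  if (length(chip$values) != length(input$values)) {
    abort("chip and input tracks must have equal length")
  }
  wc <- smooth_and_normalize(window_coverage(chip, cfg), cfg,
                             chip$total_read_pairs)
  wi <- smooth_and_normalize(window_coverage(input, cfg), cfg,
                             input$total_read_pairs)
  num <- wc$signal + cfg$pseudocount
  den <- wi$signal + cfg$pseudocount
  ratio <- ifelse(den > 0, num / den, NA_real_)
  out <- tibble(pos = wc$pos, chip = wc$signal, input = wi$signal,
                enrichment = ratio, partial = wc$partial)
  structure(out, class = c("enrichment_profile", class(out)), config = cfg)
}

#' @rdname tidy_cenarch
#' @export
glance.enrichment_profile <- function(x, ...) {
  tibble(
    n_steps = nrow(x),
    median_enrichment = stats::median(x$enrichment, na.rm = TRUE),
    max_enrichment = max(x$enrichment, na.rm = TRUE),
    undefined_steps = sum(is.na(x$enrichment))
  )
}

#' Plot an enrichment profile
#'
#' @param object an `enrichment_profile`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.enrichment_profile <- function(object, ...) {
  cfg <- attr(object, "config")
  ggplot2::ggplot(object, ggplot2::aes(x = .data$pos + cfg$window_size / 2,
                                       y = .data$enrichment)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed", colour = "grey50") +
    ggplot2::labs(x = "position (window centre, nt)",
                  y = "ChIP / input enrichment") +
    ggplot2::theme_minimal()
}
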