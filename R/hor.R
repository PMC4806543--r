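## run mafft on a named character vector of sequences; returns gapped rows
## in input order. Deterministic for fixed input.
mafft_align <- function(seqs) {
  if (Sys.which("mafft") == "") {
    abort("the 'mafft' executable is required for multiple alignment but was not found on PATH")
  }
  tmp <- tempfile(fileext = ".fa")
  on.exit(unlink(tmp), add = TRUE)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), tmp)
  out <- system2("mafft", c("--retree", "2", "--inputorder", "--quiet", tmp),
                 stdout = TRUE, stderr = FALSE)
  hdr <- grepl("^>", out)
  ids <- sub("^>", "", out[hdr])
  grp <- cumsum(hdr)
  body <- vapply(split(out[!hdr], grp[!hdr]), paste, character(1), collapse = "")
  stats::setNames(toupper(unname(body)), ids)
}

#' Multiple alignment of tandem-repeat monomers
#'
#' Aligns the (strand-normalized) monomer sequences of a `monomer_set`
#' with a progressive aligner. Rows come back in input order; ungapping a
#' row reproduces its input sequence.
#'
#' @param monomers a `monomer_set` from [extract_monomers()], or a named
#'   character vector of sequences.
#' @param full_length_only use only full-length monomers (default `TRUE`).
#' @return named character vector of equal-length gapped rows, class
#'   `cen_msa`.
#' @export
align_monomers <- function(monomers, full_length_only = TRUE) {
  seqs <- if (inherits(monomers, "monomer_set")) {
    monomer_seqs(monomers, full_length_only = full_length_only)
  } else {
    monomers
  }
  if (length(seqs) < 2L) abort("need at least 2 monomers to align")
  aln <- mafft_align(seqs)
  stopifnot(length(unique(nchar(aln))) == 1L)
  structure(aln, class = "cen_msa")
}

k2p_or_cap <- function(a, b, cap = 5) {
  tryCatch(k2p_distance(a, b)$K,
           cenarch_saturation = function(e) cap)
}

#' K2p distance matrix from a multiple alignment
#'
#' Pairwise K2p over the gap-free column pairs of each row pair.
#'
#' @param aln gapped rows (equal length), e.g. from [align_monomers()].
#' @param saturate `"error"` to fail on saturated pairs, `"cap"` to record
#'   a large finite distance instead (used by the bootstrap, where a rare
#'   saturated resample should not abort the replicate).
#' @param cap distance recorded for saturated pairs when capping.
#' @return symmetric numeric matrix with zero diagonal, dimnames = ids.
#' @export
k2p_matrix <- function(aln, saturate = c("error", "cap"), cap = 5) {
  saturate <- match.arg(saturate)
  n <- length(aln)
  ids <- names(aln) %||% as.character(seq_len(n))
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d[i, j] <- d[j, i] <- if (saturate == "cap") {
        k2p_or_cap(aln[[i]], aln[[j]], cap)
      } else {
        k2p_distance(aln[[i]], aln[[j]])$K
      }
    }
  }
  d
}

#' Pairwise K2p distances between monomers
#'
#' Either from a single multiple alignment (`method = "msa"`) or from
#' independent pairwise global alignments (`method = "pairwise"`, no
#' external aligner needed).
#'
#' @param monomers a `monomer_set` or named character vector.
#' @param method `"pairwise"` or `"msa"`.
#' @param full_length_only use only full-length monomers. Default `FALSE`
#'   so the matrix indices line up with the full monomer numbering that
#'   [identify_hors()] expects.
#' @return symmetric distance matrix.
#' @export
monomer_distances <- function(monomers, method = c("pairwise", "msa"),
                              full_length_only = FALSE) {
  method <- match.arg(method)
  seqs <- if (inherits(monomers, "monomer_set")) {
    monomer_seqs(monomers, full_length_only = full_length_only)
  } else {
    monomers
  }
  if (method == "msa") return(k2p_matrix(align_monomers(seqs)))
  n <- length(seqs)
  ids <- names(seqs) %||% as.character(seq_len(n))
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  pairs <- which(upper.tri(d), arr.ind = TRUE)
  ## all monomer pairs aligned in a single vectorized call
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAStringSet(seqs[pairs[, 1]]),
    Biostrings::DNAStringSet(seqs[pairs[, 2]]),
    type = "global", substitutionMatrix = dna_submat(1, -1),
    gapOpening = 4, gapExtension = 1
  )
  ga <- as.character(Biostrings::pattern(aln))
  gb <- as.character(Biostrings::subject(aln))
  for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, 1]
    j <- pairs[k, 2]
    d[i, j] <- d[j, i] <- k2p_distance(ga[[k]], gb[[k]])$K
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Canonical Saitou–Nei neighbor joining; tiny negative branch lengths are
#' clamped to zero.
#'
#' @param d symmetric distance matrix with ids as dimnames.
#' @return an [ape::phylo] tree (unrooted).
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) < 3L) abort("need at least 3 taxa for a neighbor-joining tree")
  if (!isSymmetric(unname(d), tol = 1e-8)) abort("distance matrix must be symmetric")
  tr <- ape::nj(stats::as.dist(d))
  tr$edge.length <- pmax(tr$edge.length, 0)
  tr
}

#' Bootstrap support values for a neighbor-joining tree
#'
#' Resamples alignment columns with replacement `n` times, rebuilds the NJ
#' tree for each replicate (K2p distances; rare saturated replicate pairs
#' are capped) and reports, for each internal edge of the full-data tree,
#' the percentage of replicates containing that bipartition. Deterministic
#' given `seed`.
#'
#' @param aln a `cen_msa` from [align_monomers()].
#' @param n number of replicates (default 1000).
#' @param seed RNG seed.
#' @return the full-data NJ tree with `node.label` set to support
#'   percentages (in 0..100; the basal node is `NA`).
#' @export
bootstrap_supports <- function(aln, n = 1000L, seed = 1L) {
  mat <- do.call(rbind, lapply(aln, chars))
  rownames(mat) <- names(aln)
  full <- nj_tree(k2p_matrix(as_msa_rows(mat), saturate = "cap"))
  boot <- withr::with_seed(seed, {
    lapply(seq_len(n), function(r) {
      idx <- sample.int(ncol(mat), ncol(mat), replace = TRUE)
      nj_tree(k2p_matrix(as_msa_rows(mat[, idx, drop = FALSE]), saturate = "cap"))
    })
  })
  counts <- ape::prop.clades(full, boot, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  support <- round(100 * counts / n)
  support[1L] <- NA # basal node: not an internal bipartition
  full$node.label <- support
  full
}

as_msa_rows <- function(mat) {
  stats::setNames(apply(mat, 1L, paste, collapse = ""), rownames(mat))
}

#' Identify higher-order repeats from monomer distance structure
#'
#' A higher-order repeat (HOR) is a block of consecutive monomers
#' duplicated as a unit: corresponding monomers of the two copies are each
#' other's closest relatives. For each positional offset `off > 0`, maximal
#' runs of at least 2 consecutive indices `i` are found where monomers `i`
#' and `i + off` are reciprocal nearest neighbours (ties broken toward the
#' smaller index) with distance below `ratio_threshold` times the median
#' pairwise distance. Runs are trimmed so the two copies do not overlap;
#' overlapping candidates are resolved longest-run-first, then earliest
#' start.
#'
#' @param monomers a `monomer_set` (ordered 5' to 3').
#' @param d distance matrix over the same monomers (e.g.
#'   [monomer_distances()]). Row order must match `monomers` order.
#' @param ratio_threshold pair distance must be below this fraction of the
#'   median off-pair distance (default 0.5).
#' @return a `hor_set` tibble: `offset`, `L_first`, `L_last`, `R_first`,
#'   `R_last` (monomer indices), `n_monomers`, `mean_pair_dist`, and nt
#'   coordinates `L_start_nt`, `L_end_nt`, `R_start_nt`, `R_end_nt`.
#' @export
identify_hors <- function(monomers, d, ratio_threshold = 0.5) {
  d <- as.matrix(d)
  n <- nrow(d)
  stopifnot(n == nrow(monomers))
  empty <- tibble(
    offset = integer(), L_first = integer(), L_last = integer(),
    R_first = integer(), R_last = integer(), n_monomers = integer(),
    mean_pair_dist = double(), L_start_nt = integer(), L_end_nt = integer(),
    R_start_nt = integer(), R_end_nt = integer()
  )
  if (n < 4L) return(structure(empty, class = c("hor_set", class(empty))))
  thr <- ratio_threshold * stats::median(d[upper.tri(d)])
  nn <- vapply(seq_len(n), function(i) {
    v <- d[i, ]
    v[i] <- Inf
    which.min(v) # ties -> smallest index
  }, integer(1))
  cand <- list()
  for (off in 1L:(n - 1L)) {
    i_max <- n - off
    ok <- vapply(seq_len(i_max), function(i) {
      nn[i] == i + off && nn[i + off] == i && d[i, i + off] < thr
    }, logical(1))
    r <- rle(ok)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (h in which(r$values & r$lengths >= 2L)) {
      i <- starts[h]
      j <- ends[h]
      if (j - i + 1L > off) j <- i + off - 1L # copies must not overlap
      if (j - i + 1L < 2L) next
      cand[[length(cand) + 1L]] <- tibble(
        offset = off, L_first = i, L_last = j,
        R_first = i + off, R_last = j + off,
        n_monomers = j - i + 1L,
        mean_pair_dist = mean(d[cbind(i:j, (i:j) + off)])
      )
    }
  }
  if (length(cand) == 0L) return(structure(empty, class = c("hor_set", class(empty))))
  cand <- dplyr::bind_rows(cand) |>
    dplyr::arrange(dplyr::desc(.data$n_monomers), .data$L_first, .data$offset)
  used <- logical(n)
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    idx <- c(cand$L_first[i]:cand$L_last[i], cand$R_first[i]:cand$R_last[i])
    if (!any(used[idx])) {
      keep[i] <- TRUE
      used[idx] <- TRUE
    }
  }
  out <- cand[keep, ]
  out$L_start_nt <- monomers$start[out$L_first]
  out$L_end_nt <- monomers$end[out$L_last]
  out$R_start_nt <- monomers$start[out$R_first]
  out$R_end_nt <- monomers$end[out$R_last]
  out <- dplyr::arrange(out, .data$L_first)
  structure(out, class = c("hor_set", class(out)))
}

#' Date a higher-order repeat duplication
#'
#' Concatenates the internal full-length monomers of each copy (excluding
#' the first and last monomer of each copy, which may be recombinant at
#' the duplication breakpoints), globally aligns the two concatenations
#' and converts the K2p distance to years. An HOR with fewer than 3
#' monomers per copy has no internal monomer and is reported with status
#' `"undatable"`.
#'
#' @param hor one row of a `hor_set`.
#' @param monomers the `monomer_set` the HOR indices refer to.
#' @param clock a [molecular_clock()].
#' @return a `dated_event` of kind `"duplication"`.
#' @export
date_hor <- function(hor, monomers, clock = molecular_clock()) {
  stopifnot(nrow(hor) == 1L)
  n_mon <- hor$n_monomers
  if (n_mon < 3L) {
    return(new_dated_event("duplication", status = "undatable"))
  }
  seqs <- monomer_seqs(monomers)
  pos <- 2L:(n_mon - 1L) # internal positions within the run
  iL <- hor$L_first + pos - 1L
  iR <- hor$R_first + pos - 1L
  usable <- monomers$full_length[iL] & monomers$full_length[iR]
  if (!any(usable)) {
    return(new_dated_event("duplication", status = "undatable"))
  }
  catL <- join_monomer_run(monomers, iL[usable], seqs)
  catR <- join_monomer_run(monomers, iR[usable], seqs)
  aln <- align_global(catL, catR)
  k <- k2p_distance(aln$a, aln$b)
  new_dated_event("duplication", k2p = k, clock = clock,
                  extra = list(internal_monomers = sum(usable)))
}

## concatenate a run of monomers, bridging small (<= 20 nt) genomic gaps
## between consecutive plus-strand annotations with the intervening bases:
## homology-scan boundaries trim terminal mismatches, and dropping those
## joint bases would preferentially exclude diverged sites and bias dates
## downward. Larger gaps (e.g. an inserted retroelement) are not bridged.
join_monomer_run <- function(monomers, idx, seqs) {
  seq <- attr(monomers, "seq")
  rows <- match(idx, monomers$index)
  plus <- all(monomers$strand[rows] == "+")
  if (is.null(seq) || !plus || length(idx) == 1L) {
    return(paste(seqs[as.character(idx)], collapse = ""))
  }
  out <- seqs[[as.character(idx[1L])]]
  for (k in 2L:length(idx)) {
    gap <- monomers$start[rows[k]] - monomers$end[rows[k - 1L]] - 1L
    if (gap > 0L && gap <= 20L) {
      out <- paste0(out, subseq_chr(seq, monomers$end[rows[k - 1L]] + 1L,
                                    monomers$start[rows[k]] - 1L))
    }
    out <- paste0(out, seqs[[as.character(idx[k])]])
  }
  out
}

#' Refine HOR boundaries with maximal exact matches
#'
#' Moves the nt boundaries of an HOR from the monomer-run ends to the
#' endpoints of the longest chain of maximal exact matches between the two
#' copies' neighbourhoods, so that a duplication breakpoint falling inside
#' a monomer (or in flanking non-monomer sequence) is recovered at nt
#' resolution. Matches must be consistent with the duplication offset
#' (within `offset_tol` nt). If no qualifying match of length `min_len`
#' exists, the boundaries are unchanged.
#'
#' @param hor one row of a `hor_set`.
#' @param monomers the `monomer_set` (carries the array sequence).
#' @param min_len minimum exact match length (default 20).
#' @param window how far beyond the monomer runs to search, in nt
#'   (default: twice the median monomer length).
#' @param offset_tol tolerated deviation from the copy offset, in nt
#'   (default: half the median monomer length).
#' @return the HOR row with (possibly) updated `L_start_nt`, `L_end_nt`,
#'   `R_start_nt`, `R_end_nt` and a logical `refined` column.
#' @export
refine_hor_boundaries <- function(hor, monomers, min_len = 20L,
                                  window = NULL, offset_tol = NULL) {
  stopifnot(nrow(hor) == 1L)
  seq <- attr(monomers, "seq")
  if (is.null(seq)) abort("monomer_set carries no sequence; use extract_monomers()")
  mono_w <- stats::median(monomers$end - monomers$start + 1)
  window <- window %||% as.integer(2L * mono_w)
  offset_tol <- offset_tol %||% as.integer(mono_w / 2)
  n <- nchar(seq)
  off_nt <- hor$R_start_nt - hor$L_start_nt
  a1 <- max(1L, hor$L_start_nt - window)
  a2 <- min(hor$L_end_nt + window, hor$R_start_nt - 1L)
  b1 <- max(hor$R_start_nt - window, hor$L_end_nt + 1L)
  b2 <- min(n, hor$R_end_nt + window)
  mm <- find_maximal_matches(subseq_chr(seq, a1, a2),
                             subseq_chr(seq, b1, b2), min_len = min_len)
  hor$refined <- FALSE
  if (nrow(mm) == 0L) return(hor)
  ga <- a1 + mm$pos_a - 1L
  gb <- b1 + mm$pos_b - 1L
  keep <- abs((gb - ga) - off_nt) <= offset_tol
  if (!any(keep)) return(hor)
  ## borders move according to the longest offset-consistent match only:
  ## shorter matches at the right offset also arise between non-copy
  ## monomers of the same satellite family and must not drag the borders
  best <- which(keep)[which.max(mm$length[keep])]
  la <- ga[best]
  lb <- gb[best]
  len <- mm$length[best]
  hor$L_start_nt <- min(hor$L_start_nt, la)
  hor$L_end_nt <- max(hor$L_end_nt, la + len - 1L)
  hor$R_start_nt <- min(hor$R_start_nt, lb)
  hor$R_end_nt <- max(hor$R_end_nt, lb + len - 1L)
  hor$refined <- TRUE
  hor
}

#' Date every HOR in a `hor_set`
#'
#' @param hors a `hor_set` from [identify_hors()].
#' @param monomers the `monomer_set`.
#' @param clock a [molecular_clock()].
#' @return the `hor_set` with `years`, `upper_bound_years`, `K` and
#'   `status` columns appended.
#' @export
date_hors <- function(hors, monomers, clock = molecular_clock()) {
  res <- purrr::map_dfr(seq_len(nrow(hors)), function(i) {
    ev <- date_hor(hors[i, ], monomers, clock)
    tibble(years = ev$years, upper_bound_years = ev$upper_bound_years,
           K = if (is.null(ev$k2p)) NA_real_ else ev$k2p$K,
           status = ev$status)
  })
  out <- dplyr::bind_cols(hors, res)
  structure(out, class = c("hor_set", class(tibble())))
}

#' @rdname tidy_cenarch
#' @export
glance.hor_set <- function(x, ...) {
  tibble(
    n_hors = nrow(x),
    n_monomers_total = sum(x$n_monomers) * 2L,
    youngest_years = if ("years" %in% names(x) && any(!is.na(x$years)))
      min(x$years, na.rm = TRUE) else NA_real_,
    oldest_years = if ("years" %in% names(x) && any(!is.na(x$years)))
      max(x$years, na.rm = TRUE) else NA_real_
  )
}

#' Bootstrap support of a given leaf bipartition
#'
#' Returns the support value attached to the internal edge separating
#' `tips` from the remaining leaves, handling the case where that edge is
#' adjacent to the (arbitrary) basal node of the stored unrooted tree.
#'
#' @param tree tree with `node.label` supports, from [bootstrap_supports()].
#' @param tips character vector of leaf labels forming one side of the
#'   bipartition.
#' @return support percentage, or `NA` if the bipartition is not in the
#'   tree.
#' @export
clade_support <- function(tree, tips) {
  ntip <- length(tree$tip.label)
  grab <- function(tp) {
    if (length(tp) < 2L || length(tp) > ntip - 2L) return(NA_real_)
    node <- ape::getMRCA(tree, tp)
    if (length(unlist(phangorn_free_desc(tree, node))) != length(tp)) {
      return(NA_real_) # not monophyletic here
    }
    as.numeric(tree$node.label[node - ntip])
  }
  s <- grab(tips)
  if (!is.na(s)) return(s)
  grab(setdiff(tree$tip.label, tips))
}

## tips descending from node (self-contained; avoids a hard phangorn dep)
phangorn_free_desc <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(list(tree$tip.label[node]))
  kids <- tree$edge[tree$edge[, 1] == node, 2]
  list(unlist(lapply(kids, function(k) phangorn_free_desc(tree, k)[[1]])))
}

#' Plot a `hor_set` along the array
#'
#' Draws the two copies of each HOR as paired horizontal segments, at
#' their estimated age when dated.
#'
#' @param object a `hor_set` (ideally after [date_hors()]).
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.hor_set <- function(object, ...) {
  df <- tibble(
    hor = rep(seq_len(nrow(object)), 2L),
    copy = rep(c("L", "R"), each = nrow(object)),
    start = c(object$L_start_nt, object$R_start_nt),
    end = c(object$L_end_nt, object$R_end_nt),
    years = if ("years" %in% names(object)) rep(object$years, 2L) else
      rep(NA_real_, 2L * nrow(object))
  )
  y <- if (all(is.na(df$years))) ggplot2::aes(y = factor(.data$hor)) else
    ggplot2::aes(y = .data$years / 1e3)
  ggplot2::ggplot(df) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$start, xend = .data$end,
                                       colour = .data$copy,
                                       !!!y[1]),
                          linewidth = 3) +
    ggplot2::labs(x = "array position (nt)",
                  y = if (all(is.na(df$years))) "HOR" else "age (kya)",
                  colour = "copy") +
    ggplot2::theme_minimal()
}

#' Age track of dated insertion/duplication events
#'
#' Fig-style age-by-position plot: each dated element is drawn at the
#' midpoint of its locus against its estimated age.
#'
#' @param dated tibble with `years` and either `pos` or
#'   `ltr5_start`/`ltr3_end` columns (e.g. from [date_ltr_pairs()]).
#' @return a ggplot.
#' @export
plot_age_track <- function(dated) {
  pos <- dated[["pos"]] %||% ((dated$ltr5_start + dated$ltr3_end) / 2)
  df <- tibble(pos = pos, years = dated$years)
  ggplot2::ggplot(df[!is.na(df$years), ],
                  ggplot2::aes(x = .data$pos, y = .data$years / 1e3)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "position (nt)", y = "estimated age (kya)") +
    ggplot2::theme_minimal()
}
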