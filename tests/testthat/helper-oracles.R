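# Independent oracles used to freeze expected values. These deliberately
# use different algorithms from the package implementations.

# O(n^2) maximal-exact-match enumeration via a full DP extension table:
# L[i,j] = length of the exact match starting at (i,j). A match is maximal
# iff its start is not left-extendable and its length is given by L.
bf_maximal_matches <- function(a, b, min_len) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  n <- length(ca)
  m <- length(cb)
  M <- outer(ca, cb, "==") & outer(ca != "N", cb != "N", "&")
  L <- matrix(0L, n + 1L, m + 1L)
  for (i in n:1) {
    L[i, 1:m] <- ifelse(M[i, ], L[i + 1L, 2:(m + 1L)] + 1L, 0L)
  }
  ## start (i,j) is left-extendable iff i>1, j>1 and M[i-1, j-1]
  le <- matrix(FALSE, n, m)
  if (n > 1 && m > 1) le[2:n, 2:m] <- M[1:(n - 1), 1:(m - 1)]
  starts <- which(M & !le & L[1:n, 1:m] >= min_len, arr.ind = TRUE)
  if (nrow(starts) == 0L) {
    return(tibble::tibble(pos_a = integer(), pos_b = integer(),
                          length = integer()))
  }
  out <- tibble::tibble(
    pos_a = as.integer(starts[, 1]),
    pos_b = as.integer(starts[, 2]),
    length = L[cbind(starts[, 1], starts[, 2])]
  )
  out[order(out$pos_a, out$pos_b), ]
}

# closed-form K2p from raw counts, evaluated directly
k2p_closed_form <- function(transitions, transversions, sites) {
  P <- transitions / sites
  Q <- transversions / sites
  -0.5 * log(1 - 2 * P - Q) - 0.25 * log(1 - 2 * Q)
}

# exhaustive minimum-evolution search: all unrooted topologies, ordinary
# least-squares branch lengths, minimal total length wins
me_tree_oracle <- function(d) {
  ids <- rownames(d)
  n <- length(ids)
  stopifnot(n <= 6)
  topos <- phangorn::allTrees(n, rooted = FALSE, tip.label = ids)
  pairs <- t(combn(n, 2))
  obs <- d[pairs]
  best <- NULL
  best_score <- Inf
  for (ti in seq_along(topos)) {
    tr <- topos[[ti]] # [[ restores compressed multiPhylo tip labels
    X <- path_matrix(tr, ids, pairs)
    fit <- stats::lm.fit(X, obs)
    score <- sum(fit$coefficients)
    if (score < best_score - 1e-12) {
      best_score <- score
      best <- tr
    }
  }
  best
}

# pair x edge incidence matrix: 1 if the edge lies on the path between the
# two leaves (edges identified by the bipartition they induce)
path_matrix <- function(tree, ids, pairs) {
  ntip <- length(tree$tip.label)
  tipsets <- lapply(seq_len(nrow(tree$edge)), function(e) {
    node <- tree$edge[e, 2]
    tips_below(tree, node)
  })
  X <- matrix(0, nrow(pairs), nrow(tree$edge))
  for (e in seq_along(tipsets)) {
    inset <- ids %in% tipsets[[e]]
    X[, e] <- as.numeric(xor(inset[pairs[, 1]], inset[pairs[, 2]]))
  }
  X
}

tips_below <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(tree$tip.label[node])
  kids <- tree$edge[tree$edge[, 1] == node, 2]
  unlist(lapply(kids, tips_below, tree = tree))
}

# unrooted topology equality
same_topology <- function(t1, t2) {
  isTRUE(ape::all.equal.phylo(ape::unroot(t1), ape::unroot(t2),
                              use.edge.length = FALSE))
}

# hand moving average with partial edges (oracle for the smoother)
bf_moving_average <- function(x, k) {
  h <- (k - 1) %/% 2
  vapply(seq_along(x), function(i) {
    mean(x[max(1, i - h):min(length(x), i + h)])
  }, numeric(1))
}
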