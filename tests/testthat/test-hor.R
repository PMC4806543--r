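test_that("identical and near-identical monomers align trivially", {
  cons <- withr::with_seed(501, random_dna(156))
  aln <- align_monomers(c(m1 = cons, m2 = cons))
  expect_equal(unname(nchar(aln)), c(156L, 156L))
  expect_false(any(grepl("-", aln, fixed = TRUE)))

  one_sub <- cons
  substr(one_sub, 60, 60) <- setdiff(c("A", "C", "G", "T"),
                                     substr(cons, 60, 60))[1]
  aln2 <- align_monomers(c(m1 = cons, m2 = one_sub))
  expect_false(any(grepl("-", aln2, fixed = TRUE)))
  expect_equal(sum(strsplit(aln2[[1]], "")[[1]] != strsplit(aln2[[2]], "")[[1]]), 1)
  # ungapping reproduces the input
  expect_equal(gsub("-", "", aln2[[2]]), one_sub)
  expect_error(align_monomers(c(m1 = cons)), "at least 2")
})

test_that("alignment-derived identities track the planted divergences", {
  seqs <- withr::with_seed(502, {
    cons <- random_dna(156)
    stats::setNames(
      c(cons, vapply(1:9, function(i)
        mutate_k2p(cons, stats::runif(1, 0, 0.05),
                   sim_config(seed = 5000 + i)), character(1))),
      paste0("m", 0:9))
  })
  aln <- align_monomers(seqs)
  for (i in 2:10) {
    true_p <- mean(strsplit(seqs[[1]], "")[[1]] != strsplit(seqs[[i]], "")[[1]])
    cc <- strsplit(aln[[1]], "")[[1]]
    mm <- strsplit(aln[[i]], "")[[1]]
    keep <- cc != "-" & mm != "-"
    aln_p <- mean(cc[keep] != mm[keep])
    expect_equal(aln_p, true_p, tolerance = 0.011)
  }
})

test_that("NJ reconstructs additive trees exactly", {
  # ((A:1,B:2):1,(C:3,D:4)) as an unrooted additive metric
  d <- matrix(c(0, 3, 5, 6,
                3, 0, 6, 7,
                5, 6, 0, 7,
                6, 7, 7, 0), 4, 4,
              dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  tr <- nj_tree(d)
  expect_true(same_topology(tr, ape::read.tree(text = "((A:1,B:2):1,(C:3,D:4):0);")))
  # recovered path lengths reproduce the matrix exactly
  expect_equal(unname(as.matrix(ape::cophenetic.phylo(tr))[rownames(d), rownames(d)]),
               unname(d), tolerance = 1e-10)

  expect_error(nj_tree(d[1:2, 1:2]), "at least 3")
  d_bad <- d
  d_bad[1, 2] <- 99
  expect_error(nj_tree(d_bad), "symmetric")
})

test_that("NJ equals the exhaustive minimum-evolution oracle on additive matrices", {
  for (seed in 1:6) {
    n <- sample(4:6, 1)
    tr0 <- withr::with_seed(600 + seed, {
      n <- sample(4:6, 1)
      t <- ape::rtopology(n, rooted = FALSE, tip.label = letters[1:n])
      t$edge.length <- stats::runif(nrow(t$edge), 0.3, 2)
      t
    })
    d <- as.matrix(ape::cophenetic.phylo(tr0))
    d <- d[order(rownames(d)), order(colnames(d))]
    nj <- nj_tree(d)
    me <- me_tree_oracle(d)
    expect_true(same_topology(nj, tr0))
    expect_true(same_topology(nj, me))
  }
  # and on larger additive matrices NJ still recovers the generator
  for (seed in 1:4) {
    tr0 <- withr::with_seed(700 + seed, {
      n <- sample(7:8, 1)
      t <- ape::rtopology(n, rooted = FALSE, tip.label = letters[1:n])
      t$edge.length <- stats::runif(nrow(t$edge), 0.3, 2)
      t
    })
    d <- as.matrix(ape::cophenetic.phylo(tr0))
    expect_true(same_topology(nj_tree(d), tr0))
  }
})

test_that("bootstrap supports separate planted clades and respect n = 1", {
  seqs <- withr::with_seed(503, {
    anc1 <- random_dna(400)
    anc2 <- mutate_k2p(anc1, 0.10, sim_config(seed = 5031))
    c(stats::setNames(vapply(1:5, function(i)
        mutate_k2p(anc1, 0.005, sim_config(seed = 5100 + i)), ""), paste0("a", 1:5)),
      stats::setNames(vapply(1:5, function(i)
        mutate_k2p(anc2, 0.005, sim_config(seed = 5200 + i)), ""), paste0("b", 1:5)))
  })
  aln <- align_monomers(seqs)
  tr <- bootstrap_supports(aln, n = 200, seed = 9)
  expect_gte(clade_support(tr, paste0("a", 1:5)), 95)
  expect_gte(clade_support(tr, paste0("b", 1:5)), 95)

  tr1 <- bootstrap_supports(aln, n = 1, seed = 9)
  sup <- tr1$node.label[!is.na(tr1$node.label)]
  expect_true(all(sup %in% c(0, 100)))

  # label invariance: permuting input rows leaves the clade support intact
  tr_p <- bootstrap_supports(align_monomers(seqs[sample(10)]), n = 200, seed = 9)
  expect_gte(clade_support(tr_p, paste0("a", 1:5)), 95)
})

test_that("a planted adjacent duplication is identified as one HOR", {
  sim <- simulate_hor_array(10, dup_start = 1, dup_length = 5,
                            age_years = 100000, monomer_divergence = 0.08,
                            cfg = sim_config(seed = 510))
  m <- extract_monomers(sim$sequence, sim$consensus)
  h <- identify_hors(m, monomer_distances(m))
  expect_equal(nrow(h), 1)
  expect_equal(h$offset, 5)
  expect_equal(c(h$L_first, h$L_last, h$R_first, h$R_last), c(1, 5, 6, 10))
})

test_that("i.i.d. monomer arrays yield no HOR calls", {
  for (seed in 1:20) {
    seqs <- withr::with_seed(800 + seed, {
      cons <- random_dna(156)
      vapply(1:10, function(i)
        mutate_k2p(cons, 0.04, sim_config(seed = 8000 + 10 * seed + i)),
        character(1)) # ~8% pairwise divergence
    })
    arr <- paste(seqs, collapse = "")
    cons <- withr::with_seed(800 + seed, random_dna(156))
    m <- extract_monomers(arr, cons)
    h <- identify_hors(m, monomer_distances(m))
    expect_equal(nrow(h), 0)
  }
})

test_that("an insertion between the copies does not break HOR pairing", {
  sim <- simulate_hor_array(10, dup_start = 2, dup_length = 4,
                            age_years = 100000, monomer_divergence = 0.08,
                            insert = list(after_monomer = 7, length = 2000),
                            cfg = sim_config(seed = 511))
  m <- extract_monomers(sim$sequence, sim$consensus)
  expect_equal(nrow(m), 14) # insertion adds sequence, not monomers
  h <- identify_hors(m, monomer_distances(m))
  expect_equal(nrow(h), 1)
  expect_equal(h$offset, sim$truth$offset)
  expect_equal(h$L_first, sim$truth$L_first)
})

test_that("HOR dating recovers planted ages and flags undatable HORs", {
  est <- vapply(1:25, function(i) {
    sim <- simulate_hor_array(12, dup_start = 2, dup_length = 5,
                              age_years = 100000, monomer_divergence = 0.08,
                              cfg = sim_config(seed = 900 + i))
    m <- extract_monomers(sim$sequence, sim$consensus)
    h <- identify_hors(m, monomer_distances(m))
    if (nrow(h) != 1) return(NA_real_)
    date_hor(h[1, ], m)$years
  }, numeric(1))
  est <- est[!is.na(est)]
  expect_gt(length(est), 20)
  # per-trial SD ~57 kya; mean over >20 trials tested at ~3 sigma
  expect_equal(mean(est), 100000, tolerance = 0.40)

  # 2-monomer copies have no internal monomer
  sim2 <- simulate_hor_array(6, dup_start = 2, dup_length = 2,
                             age_years = 0, monomer_divergence = 0.08,
                             cfg = sim_config(seed = 950))
  m2 <- extract_monomers(sim2$sequence, sim2$consensus)
  h2 <- tibble::tibble(offset = 2L, L_first = 2L, L_last = 3L,
                       R_first = 4L, R_last = 5L, n_monomers = 2L)
  ev <- date_hor(h2, m2)
  expect_equal(ev$status, "undatable")
  expect_true(is.na(ev$years))
})

test_that("identical HOR copies date to zero with an upper bound", {
  sim <- simulate_hor_array(9, dup_start = 2, dup_length = 5,
                            age_years = 0, monomer_divergence = 0.08,
                            cfg = sim_config(seed = 512))
  mono <- sim$monomer_table
  mono$full_length <- TRUE
  mono$strand <- "+"
  mono$sequence <- vapply(seq_len(nrow(mono)), function(i)
    substr(sim$sequence, mono$start[i], mono$end[i]), character(1))
  h <- tibble::tibble(offset = 5L, L_first = 2L, L_last = 6L,
                      R_first = 7L, R_last = 11L, n_monomers = 5L)
  ev <- date_hor(h, mono)
  expect_equal(ev$years, 0)
  expect_false(is.na(ev$upper_bound_years))
})

test_that("HOR and sequence-pair dating compose K2p with the clock", {
  sim <- simulate_hor_array(9, dup_start = 2, dup_length = 5,
                            age_years = 150000, monomer_divergence = 0.08,
                            cfg = sim_config(seed = 513))
  m <- extract_monomers(sim$sequence, sim$consensus)
  h <- identify_hors(m, monomer_distances(m))
  ev <- date_hor(h[1, ], m)
  expect_equal(ev$years, k2p_to_years(ev$k2p), tolerance = 1e-12)

  a <- withr::with_seed(514, random_dna(2000))
  b <- mutate_k2p(a, 0.01, sim_config(seed = 515))
  ev2 <- date_sequence_pair(a, b)
  expect_equal(ev2$years, k2p_to_years(ev2$k2p$K), tolerance = 1e-12)
  expect_equal(date_sequence_pair(a, a)$years, 0)
})

test_that("a planted monomer deletion does not bias sequence-pair dating", {
  years <- vapply(1:10, function(i) {
    a <- withr::with_seed(1600 + i, random_dna(3000))
    b <- mutate_k2p(a, 0.00448, sim_config(seed = 1700 + i)) # ~67.9 kya
    b_del <- paste0(substr(b, 1, 1400), substr(b, 1557, 3000))
    c(date_sequence_pair(a, b)$years, date_sequence_pair(a, b_del)$years)
  }, numeric(2))
  # gapped columns are excluded, so the deletion only removes sites
  expect_equal(mean(years[2, ]), mean(years[1, ]), tolerance = 0.10)
})
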