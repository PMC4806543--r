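test_that("microhomology measurement is exact on constructed flanks", {
  # identical flanks around both breaks: full left tract returned
  ref <- paste0("TTTT", "GATTACA", "CCCCGGGG", "GATTACA", "AAAA")
  # deletion of [12, 26]: left flank ends ...GATTACA at 11, and the
  # sequence ending at 26 also ends GATTACA
  mh <- measure_microhomology(ref, 11, 26)
  expect_equal(mh$microhomology, "GATTACA")
  expect_equal(mh$length, 7)

  # single shared terminal nt
  ref2 <- paste0("AAGTAC", "GGTTGGTT", "TTTGC", "ACCA")
  # flanks end ...AC (6) and ...GC (19)
  mh2 <- measure_microhomology(ref2, 6, 19)
  expect_equal(mh2$left_extent + mh2$right_extent, mh2$length)
  expect_gte(mh2$length, 1) # shares at least the terminal C

  # no shared sequence at all
  ref3 <- paste0("AAAA", "CCCC")
  mh3 <- measure_microhomology(ref3, 2, 6) # ...AA | ...CC, next A vs C
  expect_equal(mh3$length, 0)
  expect_equal(mh3$microhomology, "")
})

test_that("identical breakpoints return the full common flank, maximally", {
  ref <- withr::with_seed(550, random_dna(200))
  mh <- measure_microhomology(ref, 80, 80)
  expect_equal(mh$length, nchar(ref)) # suffix + prefix cover everything
})

test_that("a planted deletion with 11 nt of homology is recovered exactly", {
  sim <- simulate_mmej_deletion(2000, 11, ref_length = 5000,
                                cfg = sim_config(seed = 551))
  ev <- locate_deletion(sim$derived, sim$reference)
  expect_equal(deletion_status(ev), "single")
  expect_equal(ev$length, 2000)
  expect_equal(ev$microhomology_length, 11)
  expect_equal(nchar(ev$microhomology), 11)
  expect_equal(c(ev$window_left, ev$window_right),
               c(sim$truth$window_left, sim$truth$window_right))
  # canonical placement is leftmost
  expect_equal(ev$ref_start, sim$truth$window_left)
})

test_that("query identical to reference is a no-event", {
  s <- withr::with_seed(552, random_dna(1000))
  ev <- locate_deletion(s, s)
  expect_equal(deletion_status(ev), "no-event")
  expect_equal(nrow(ev), 0)
})

test_that("microhomology recovery is exact across lengths and flank noise", {
  lens <- round(seq(500, 3000, length.out = 10))
  for (k in c(0L, 3L, 17L, 28L)) {
    for (i in 1:10) {
      sim <- simulate_mmej_deletion(
        deletion_length = lens[i], microhomology_length = k,
        ref_length = 6000, flank_divergence = 0.02,
        cfg = sim_config(seed = 10000 + 100 * k + i))
      ev <- locate_deletion(sim$derived, sim$reference)
      expect_equal(ev$microhomology_length, k)
      expect_equal(ev$length, sim$truth$deletion_length)
    }
  }
})

test_that("breakpoint windows mirror under reverse complement", {
  sim <- simulate_mmej_deletion(800, 9, ref_length = 4000,
                                cfg = sim_config(seed = 553))
  fwd <- locate_deletion(sim$derived, sim$reference)
  rev <- locate_deletion(revcomp(sim$derived), revcomp(sim$reference))
  n <- nchar(sim$reference)
  expect_equal(rev$microhomology_length, fwd$microhomology_length)
  expect_equal(rev$length, fwd$length)
  # leftmost start in rc coordinates mirrors the rightmost end forward
  expect_equal(n - rev$window_left + 1, fwd$window_right + fwd$length - 1)
  expect_equal(rev$window_right - rev$window_left,
               fwd$window_right - fwd$window_left)
})

test_that("multiple large deletions are decomposed as multi-events", {
  ref <- withr::with_seed(554, random_dna(6000))
  der <- paste0(substr(ref, 1, 1000), substr(ref, 1501, 3800),
                substr(ref, 4201, 6000))
  ev <- locate_deletion(der, ref)
  expect_equal(deletion_status(ev), "multi")
  expect_equal(nrow(ev), 2)
  expect_equal(sort(ev$length), c(400, 500))
  # sub-threshold deletions are alignment noise, not events
  der2 <- paste0(substr(ref, 1, 1000), substr(ref, 1021, 6000))
  ev2 <- locate_deletion(der2, ref, min_deletion = 50)
  expect_equal(deletion_status(ev2), "no-event")
})

test_that("duplication junction motifs are detected and consistency-checked", {
  withr::with_seed(555, {
    motif <- "GATCC"
    core <- random_dna(500)
    unit <- paste0(motif, core, motif)
    seqq <- paste0(random_dna(200), unit, unit, random_dna(200))
  })
  l_start <- 201L
  l_end <- l_start + nchar(unit) - 1L
  dup <- analyze_duplication(seqq, l_start, l_end, l_end + 1L,
                             l_end + nchar(unit))
  expect_gte(dup$microhomology_length, 5)
  expect_match(dup$microhomology, "^GATCC")
  expect_true(dup$consistent_mmej)

  # perfect tandem duplication without a junction motif
  withr::with_seed(556, {
    unit2 <- paste0("AC", random_dna(300), "GG") # prefix != suffix
    seq2 <- paste0(random_dna(100), unit2, unit2, random_dna(100))
  })
  dup2 <- analyze_duplication(seq2, 101L, 100L + nchar(unit2),
                              101L + nchar(unit2), 100L + 2L * nchar(unit2))
  expect_equal(dup2$microhomology_length, 0)
  expect_false(dup2$consistent_mmej)

  # motif at the junction but absent at the segment 5' end
  withr::with_seed(557, {
    L <- paste0("TTAA", random_dna(200), "GATCC")
    R <- paste0("GATCC", random_dna(200), "CCCTT")
    seq3 <- paste0(random_dna(50), L, R, random_dna(50))
  })
  dup3 <- analyze_duplication(seq3, 51L, 50L + nchar(L),
                              51L + nchar(L), 50L + nchar(L) + nchar(R))
  expect_gte(dup3$microhomology_length, 5)
  expect_false(dup3$consistent_mmej)

  expect_error(analyze_duplication(seq3, 51L, 100L, 110L, 200L), "adjacent")
})

test_that("duplication dating recovers the planted age, with masking exact", {
  res <- vapply(1:5, function(i) {
    withr::with_seed(5580 + i, {
      unit <- random_dna(4000)
      ins <- random_dna(1500)
    })
    L <- mutate_k2p(unit, 3.3e-8 * 121000, sim_config(seed = 55810 + i))
    R <- mutate_k2p(unit, 3.3e-8 * 121000, sim_config(seed = 55820 + i))
    Rins <- paste0(substr(R, 1, 2000), ins, substr(R, 2001, 4000))
    seqq <- paste0(L, Rins)
    masked <- date_duplication(seqq, 1L, 4000L, 4001L, 4000L + nchar(Rins),
                               mask = tibble::tibble(start = 6001L, end = 7500L))
    clean <- date_sequence_pair(L, R)
    c(masked$years, clean$years)
  }, numeric(2))
  # masking excises the foreign insertion exactly: the masked estimate is
  # the clean two-copy estimate, and the mean recovers the planted age
  # (per-trial SD ~21 kya; 5-trial mean tested at ~3 sigma)
  expect_equal(res[1, ], res[2, ], tolerance = 0.02)
  expect_equal(mean(res[1, ]), 121000, tolerance = 0.25)

  unit <- withr::with_seed(558, random_dna(4000))
  ident <- date_duplication(paste0(unit, unit), 1L, 4000L, 4001L, 8000L)
  expect_equal(ident$years, 0)
  expect_false(is.na(ident$upper_bound_years))

  short <- date_duplication(paste0(substr(unit, 1, 150), substr(unit, 1, 150)),
                            1L, 150L, 151L, 300L)
  expect_equal(short$status, "low_confidence")
})

test_that("array diffing finds a fused chimeric monomer with its microhomology", {
  sim <- simulate_hor_array(30, dup_start = 1, dup_length = 2, age_years = 0,
                            monomer_divergence = 0.05,
                            cfg = sim_config(seed = 560))
  arr_b <- sim$sequence
  mono <- sim$monomer_table
  cons <- sim$consensus
  # fuse monomers 11 and 12 through a planted 28-nt shared block: write
  # the block at the end of M11 and M12, then delete one monomer length
  cs <- strsplit(arr_b, "")[[1]]
  e11 <- mono$end[11]
  e12 <- mono$end[12]
  cs[(e12 - 27):e12] <- cs[(e11 - 27):e11]
  if (cs[e11 - 28] == cs[e12 - 28]) cs[e12 - 28] <- setdiff(c("A","C","G","T"), cs[e12 - 28])[1]
  if (cs[e11 + 1] == cs[e12 + 1]) cs[e12 + 1] <- setdiff(c("A","C","G","T"), cs[e12 + 1])[1]
  arr_b <- paste(cs, collapse = "")
  arr_m <- paste0(substr(arr_b, 1, e11), substr(arr_b, e12 + 1, nchar(arr_b)))

  mb <- extract_monomers(arr_b, cons)
  ev <- diff_monomer_arrays(arr_b, arr_m, monomers_a = mb)
  expect_equal(deletion_status(ev), "single")
  expect_equal(ev$kind, "deletion")
  expect_equal(ev$length, 156)
  expect_equal(ev$microhomology_length, 28)
  expect_equal(ev$monomer_equivalents, 1)
  expect_true(ev$chimeric)
  expect_equal(c(ev$chimera_5p, ev$chimera_3p), c(11L, 12L))
})

test_that("array diffing reports foreign insertions and identical arrays", {
  sim <- simulate_hor_array(20, dup_start = 1, dup_length = 2, age_years = 0,
                            monomer_divergence = 0.05,
                            cfg = sim_config(seed = 561))
  arr_b <- sim$sequence
  ins_at <- sim$monomer_table$start[15] + 70
  ins <- withr::with_seed(562, random_dna(3000))
  arr_m <- paste0(substr(arr_b, 1, ins_at), ins,
                  substr(arr_b, ins_at + 1, nchar(arr_b)))
  mb <- extract_monomers(arr_b, sim$consensus)
  ev <- diff_monomer_arrays(arr_b, arr_m, monomers_a = mb)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$kind, "insertion")
  expect_equal(ev$length, 3000)
  expect_equal(ev$disrupted_monomer, 15L)

  ev0 <- diff_monomer_arrays(arr_b, arr_b, monomers_a = mb)
  expect_equal(deletion_status(ev0), "no-event")
  expect_equal(nrow(ev0), 0)

  expect_error(diff_monomer_arrays(arr_b, withr::with_seed(563, random_dna(3000))),
               "homologous|align")
})
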