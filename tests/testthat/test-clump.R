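test_that("greedy clumping handles the canonical toy cases", {
  # one isolated significant variant -> a single one-member clump
  st <- make_stats(nlp = c(10, 3), pos = c(1000, 5e6), id = c("a", "b"))
  r2 <- tibble::tibble(id_a = "a", id_b = "b", r2 = 0.9)
  cl <- greedy_clump(st, r2)
  expect_equal(nrow(cl), 1)
  expect_equal(cl$index_id, "a")
  expect_equal(cl$n_members, 1)
  expect_false(cl$ld_absent)

  # nothing reaches the index threshold -> empty set
  st2 <- make_stats(nlp = c(6, 5))
  expect_equal(nrow(greedy_clump(st2, r2)), 0)

  # five-variant block with a printed r2 matrix: two index candidates share
  # correlated secondaries; the smaller-p variant wins and absorbs them
  st5 <- make_stats(
    nlp = c(12, 9, 6.5, 6.2, 5),
    pos = c(1000, 2000, 3000, 4000, 900000),
    id = paste0("v", 1:5)
  )
  r2_5 <- tibble::tibble(
    id_a = c("v1", "v1", "v1", "v2", "v2", "v3"),
    id_b = c("v2", "v3", "v4", "v3", "v4", "v4"),
    r2 = c(0.9, 0.5, 0.15, 0.6, 0.3, 0.8)
  ) # v5 unlisted pairs -> r2 = 0 with everyone
  cl5 <- greedy_clump(st5, r2_5)
  # v1 (smallest p) takes v2 and v3 (r2 >= 0.2, in window); v4 fails r2 with
  # v1; v2 is absorbed so cannot index; no other index candidate reaches 5e-8
  expect_equal(nrow(cl5), 1)
  expect_equal(cl5$index_id, "v1")
  expect_equal(sort(cl5$members[[1]]$id), c("v1", "v2", "v3"))
  expect_equal(cl5$bound_lo, 1000)
  expect_equal(cl5$bound_hi, 3000)

  # index variant absent from the LD provider: single-variant clump, flagged
  st6 <- make_stats(nlp = c(10, 9), pos = c(1000, 2000), id = c("x", "v1"))
  cl6 <- greedy_clump(st6, r2_5)
  expect_true(cl6$ld_absent[cl6$index_id == "x"])
  expect_equal(cl6$n_members[cl6$index_id == "x"], 1)
})

test_that("greedy clumping equals an exhaustive-rescan reference on random instances", {
  set.seed(91)
  for (i in 1:100) {
    inst <- random_instance(m = sample(10:30, 1))
    got <- greedy_clump(inst$stats, inst$r2)
    want <- reference_clump(inst$stats, inst$r2)
    expect_equal(nrow(got), length(want))
    if (length(want)) {
      want_sig <- purrr::map(want, "members")[order(purrr::map_chr(want, "index"))]
      expect_equal(clump_signature(got), want_sig)
    }
  }
})

test_that("clump output is row-order invariant and respects its invariants", {
  set.seed(92)
  inst <- random_instance(m = 30)
  base <- greedy_clump(inst$stats, inst$r2)
  perm <- greedy_clump(inst$stats[sample.int(30), ], inst$r2)
  expect_equal(clump_signature(base), clump_signature(perm))

  members <- dplyr::bind_rows(base$members)
  # partition: no variant in two clumps
  expect_equal(anyDuplicated(members$id), 0)
  # index threshold and membership threshold
  expect_true(all(base$index_nlp >= -log10(5e-8)))
  expect_true(all(members$neg_log10_p >= -log10(5e-6)))
  # bounds contain every member, index within bounds
  bd <- clump_bounds(base)
  expect_equal(bd$bound_lo, base$bound_lo)
  expect_equal(bd$bound_hi, base$bound_hi)
  for (i in seq_len(nrow(base))) {
    expect_true(all(base$members[[i]]$pos >= base$bound_lo[i]))
    expect_true(all(base$members[[i]]$pos <= base$bound_hi[i]))
    expect_gte(base$index_pos[i], base$bound_lo[i])
    expect_lte(base$index_pos[i], base$bound_hi[i])
  }

  # window: members within +-500 kb of the index
  for (i in seq_len(nrow(base))) {
    expect_true(all(abs(base$members[[i]]$pos - base$index_pos[i]) <= 5e5))
  }
})

test_that("clump bounds come from member positions", {
  st <- make_stats(nlp = c(10, 7, 6), pos = c(700, 500, 900), id = c("a", "b", "c"))
  r2 <- tibble::tibble(id_a = c("a", "a"), id_b = c("b", "c"), r2 = c(0.5, 0.5))
  cl <- greedy_clump(st, r2)
  expect_equal(nrow(cl), 1)
  expect_equal(clump_bounds(cl)$bound_lo, 500)
  expect_equal(clump_bounds(cl)$bound_hi, 900)

  one <- greedy_clump(make_stats(nlp = 10, pos = 1000, id = "a"), r2)
  expect_equal(clump_bounds(one)$bound_lo, 1000)
  expect_equal(clump_bounds(one)$bound_hi, 1000)
})

test_that("index-variant tagging is by membership and idempotent", {
  st <- make_stats(
    nlp = c(10, 7, 9, 6),
    chrom = c("1", "1", "2", "2"), pos = c(1000, 2000, 1000, 2000),
    id = paste0("v", 1:4)
  )
  r2 <- tibble::tibble(
    id_a = c("v1", "v3"), id_b = c("v2", "v4"), r2 = c(0.8, 0.8)
  )
  cl <- greedy_clump(st, r2)
  expect_equal(nrow(cl), 2)

  # tagging by the clump's own index
  tg <- map_index_to_clumps(tibble::tibble(chrom = "1", pos = 1000L), cl)
  expect_equal(tg$tags$tagged, cl$chrom == "1")
  expect_equal(nrow(tg$unplaced), 0)

  # tagging by a secondary member, plus an unplaced index variant
  tg2 <- map_index_to_clumps(
    tibble::tibble(chrom = c("2", "5"), pos = c(2000L, 999L)), cl
  )
  expect_equal(tg2$tags$tagged, cl$chrom == "2")
  expect_equal(tg2$unplaced$chrom, "5")

  # two index variants in one clump tag it once
  tg3 <- map_index_to_clumps(
    tibble::tibble(chrom = c("1", "1"), pos = c(1000L, 2000L)), cl
  )
  expect_equal(sum(tg3$tags$tagged), 1)
})

test_that("the loci-loss report applies MHC, single-clump and tagging rules", {
  # clumps: one tagged, one untagged, one LD-absent single
  st <- make_stats(
    nlp = c(10, 9, 8, 9),
    chrom = c("1", "1", "6", "2"), pos = c(1000, 600000, 1000, 1000),
    id = paste0("v", 1:4)
  )
  r2 <- tibble::tibble(
    id_a = c("v1", "v3"), id_b = c("v2", "v1"), r2 = c(0.1, 0)
  ) # v4 absent from provider
  cl <- greedy_clump(st, r2)
  tg <- map_index_to_clumps(tibble::tibble(chrom = "1", pos = 1000L), cl)

  lost <- tibble::tibble(
    chrom = c("1", "1", "6", "2"),
    pos = c(600000L, 600000L, 30000000L, 1000L)
  )
  # (duplicate rows stand for multiple lost associations in one clump)
  rep <- lost_loci_report(lost, cl, tg, n_loci_identified = 3)
  expect_equal(rep$n_mhc_excluded, 1) # chr6:30,000,000 inside the MHC window
  expect_equal(rep$n_single_excluded, 1) # v4's LD-absent single clump
  expect_equal(rep$n_lost_robust_untagged, 2) # both hits in v2's clump
  expect_equal(rep$n_lost_loci, 1) # one unique untagged clump
  expect_equal(rep$pct_lost, 100 * 1 / 4)

  # every lost association inside tagged clumps -> zero loci lost
  rep0 <- lost_loci_report(
    tibble::tibble(chrom = "1", pos = 1000L), cl, tg, 3
  )
  expect_equal(rep0$n_lost_loci, 0)
  expect_equal(rep0$pct_lost, 0)

  # undefined percentage flagged when both terms are zero
  rep_na <- lost_loci_report(lost[0, ], cl, tg, 0)
  expect_true(is.na(rep_na$pct_lost))
})

test_that("the lost-loci percentage uses the lost-plus-identified denominator", {
  expect_equal(round(percent_lost_loci(149, 231), 1), 39.2)
  expect_equal(round(percent_lost_loci(170, 277), 1), 38.0)
  expect_equal(percent_lost_loci(0, 231), 0)
  expect_equal(percent_lost_loci(149, 231), 100 * 149 / 380, tolerance = 1e-12)
  expect_error(percent_lost_loci(0, 0), "> 0")
})
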