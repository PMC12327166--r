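test_that("LD scores match hand cases and a brute-force double loop", {
  # isolated variants, no bias adjustment: the self term alone gives l = 1
  set.seed(71)
  H <- matrix(rbinom(200 * 3, 1, 0.4), 200, 3)
  panel <- make_manual_panel(H, pos = c(1e6, 5e6, 9e6)) # far apart
  sc <- compute_ld_scores(panel, window_kb = 1000, adjust_bias = FALSE)
  expect_equal(sc$l2, rep(1, 3), tolerance = 1e-12)

  # two perfectly correlated variants 1 kb apart: l = 2 each
  H2 <- cbind(H[, 1], H[, 1])
  panel2 <- make_manual_panel(H2, pos = c(1000, 2000))
  sc2 <- compute_ld_scores(panel2, window_kb = 500, adjust_bias = FALSE)
  expect_equal(sc2$l2, c(2, 2), tolerance = 1e-12)

  # windowing: the same pair beyond the window -> self term only
  panel3 <- make_manual_panel(H2, pos = c(1000, 2e6))
  sc3 <- compute_ld_scores(panel3, window_kb = 500, adjust_bias = FALSE)
  expect_equal(sc3$l2, c(1, 1), tolerance = 1e-12)

  # brute-force O(m^2) oracle on a realistic block panel
  cfg <- synth_config(
    m_variants = 300, n_chromosomes = 1, block_size = 25,
    n_hap = 150, seed = 72
  )
  bp <- simulate_panel(cfg)
  for (adjust in c(FALSE, TRUE)) {
    got <- compute_ld_scores(bp, window_kb = 1000, adjust_bias = adjust)
    H <- bp$haplotypes[["1"]]
    pos <- bp$variants$pos
    n <- nrow(H)
    R2 <- cor(H)^2
    if (adjust) R2 <- R2 - (1 - R2) / (n - 2)
    want <- vapply(seq_along(pos), function(j) {
      sum(R2[j, abs(pos - pos[j]) <= 1e6])
    }, numeric(1))
    expect_equal(got$l2, want, tolerance = 1e-8)
  }

  expect_error(
    compute_ld_scores(make_manual_panel(H2[1:2, ], c(1, 2)), adjust_bias = TRUE),
    "3 haplotypes"
  )
})

test_that("the LDSR fit recovers exact linear inputs", {
  set.seed(73)
  m <- 200
  scores <- tibble::tibble(id = paste0("rs", 1:m), l2 = runif(m, 1, 30))
  base <- tibble::tibble(
    id = scores$id, chrom = "1", pos = seq_len(m) * 1000
  )

  # constant response: intercept = the constant, slope = 0
  fit <- ldsr_fit(dplyr::mutate(base, chisq = 1.5), scores, n = 10000, m = m)
  expect_equal(fit$intercept, 1.5, tolerance = 1e-9)
  expect_equal(fit$slope, 0, tolerance = 1e-9)
  expect_equal(fit$n_used + fit$n_filtered, m)

  # noiseless line: chisq = 1 + 0.002 * l
  fit2 <- ldsr_fit(
    dplyr::mutate(base, chisq = 1 + 0.002 * scores$l2),
    scores,
    n = 10000, m = 20000
  )
  expect_equal(fit2$intercept, 1, tolerance = 1e-9)
  expect_equal(fit2$h2_est, 0.002 * 20000 / 10000, tolerance = 1e-9)

  # h2_est consistency invariant
  expect_equal(fit2$h2_est, fit2$slope * 20000 / 10000, tolerance = 1e-12)

  # chi-square cap max(80, 0.001 n) filters before fitting
  capped <- dplyr::mutate(base, chisq = 1.5)
  capped$chisq[1:3] <- 200
  fit3 <- ldsr_fit(capped, scores, n = 10000, m = m)
  expect_equal(fit3$n_filtered, 3)
  expect_equal(fit3$intercept, 1.5, tolerance = 1e-9)

  # hard errors: too few variants, degenerate LD scores
  expect_error(
    ldsr_fit(dplyr::mutate(base[1:10, ], chisq = 1), scores, n = 1e4),
    "at least 50"
  )
  flat <- tibble::tibble(id = base$id, l2 = rep(2, m))
  expect_error(
    ldsr_fit(dplyr::mutate(base, chisq = rchisq(m, 1)), flat, n = 1e4),
    "zero variance"
  )

  # tidiers
  expect_equal(tidy(fit2)$estimate[1], 1, tolerance = 1e-9)
  expect_named(
    glance(fit2),
    c("intercept", "slope", "h2_est", "n_used", "n_filtered", "jackknife_se_intercept")
  )
})

test_that("intercept estimation is calibrated at the null and order-invariant", {
  panel <- shared_panel()
  scores <- shared_scores()
  fits <- purrr::map(1:5, function(s) {
    st <- simulate_sumstats(panel, n = 50000, c = 1, h2 = 0, seed = 7200 + s)
    ldsr_fit(st, scores, n = 50000, m = 20000)
  })
  ints <- vapply(fits, function(f) f$intercept, numeric(1))
  slopes <- vapply(fits, function(f) f$slope, numeric(1))
  expect_equal(mean(ints), 1, tolerance = 0.03)
  expect_equal(mean(slopes), 0, tolerance = 0.02)

  # permutation invariance of the estimate
  st <- simulate_sumstats(panel, n = 50000, c = 1.2, h2 = 0.2,
    seed = 7300, scores = scores
  )
  perm <- st[sample.int(nrow(st)), ]
  f1 <- ldsr_fit(st, scores, n = 50000, m = 20000)
  f2 <- ldsr_fit(perm, scores, n = 50000, m = 20000)
  expect_equal(f2$intercept, f1$intercept, tolerance = 1e-9)

  # jackknife SE present and positive when requested
  fj <- ldsr_fit(st, scores, n = 50000, m = 20000, jackknife = TRUE)
  expect_gt(fj$jackknife_se_intercept, 0)
  expect_lt(fj$jackknife_se_intercept, 0.5)
})

test_that("intercept correction mirrors GC correction with a smaller divisor", {
  st <- make_stats(nlp = c(2, 5, -log10(5e-8), 10))

  expect_equal(intercept_correct(st, 1), st)

  one <- make_stats(nlp = -log10(5e-8))
  corr <- intercept_correct(one, 1.097)
  expect_equal(corr$chisq, p_to_chisq(-log10(5e-8)) / 1.097, tolerance = 1e-12)
  expect_equal(
    10^(-corr$neg_log10_p),
    pchisq(corr$chisq, 1, lower.tail = FALSE),
    tolerance = 1e-12
  )

  # a smaller divisor removes fewer significant variants than a larger one
  set.seed(74)
  big <- make_stats(nlp = -log10(runif(2000)) * 2.2)
  thr <- -log10(5e-8)
  n_ldsr <- sum(intercept_correct(big, 1.097)$neg_log10_p >= thr)
  n_gc <- sum(gc_correct(big, 1.387)$neg_log10_p >= thr)
  expect_gte(n_ldsr, n_gc)

  # intercept correction then lambda: never above the uncorrected lambda
  lam0 <- compute_lambda(big)$lambda
  expect_lte(compute_lambda(intercept_correct(big, 1.2))$lambda, lam0)

  expect_error(intercept_correct(st, -1), "> 0")
})

test_that("the polygenicity proxy behaves like a correlation and grows with N", {
  m <- 100
  scores <- tibble::tibble(id = paste0("rs", 1:m), l2 = seq(1, 20, length.out = m))
  base <- tibble::tibble(id = scores$id)

  # strictly increasing affine function -> exactly 1
  expect_equal(
    polygenicity_proxy(dplyr::mutate(base, chisq = 0.5 + 2 * scores$l2), scores),
    1,
    tolerance = 1e-12
  )

  # independence -> near zero
  set.seed(75)
  expect_lt(
    abs(polygenicity_proxy(dplyr::mutate(base, chisq = rchisq(m, 1)), scores)),
    0.3
  )

  # zero variance flagged as undefined
  expect_warning(
    out <- polygenicity_proxy(dplyr::mutate(base, chisq = 1), scores),
    "zero variance"
  )
  expect_true(is.na(out))

  # rises with effective sample size on simulated statistics
  panel <- shared_panel()
  sc <- shared_scores()
  corrs <- vapply(c(20000, 100000, 400000), function(n) {
    st <- simulate_sumstats(panel, n = n, c = 1, h2 = 0.3, seed = 7400, scores = sc)
    polygenicity_proxy(st, sc)
  }, numeric(1))
  expect_true(all(diff(corrs) > 0))
})

test_that("effective sample size follows the harmonic form", {
  expect_equal(effective_sample_size(5000, 5000), 10000)
  # published case/control counts, against direct arithmetic
  expect_equal(
    effective_sample_size(74124, 824006),
    4 / (1 / 74124 + 1 / 824006),
    tolerance = 1e-12
  )
  # huge control arm: approaches 4 * n_cases
  expect_equal(effective_sample_size(1000, 1e12), 4000, tolerance = 1e-4)
  expect_error(effective_sample_size(0, 10), "> 0")
})
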