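#' Compute LD scores from a haplotype panel
#'
#' The LD score of variant j is the sum of squared correlations with every
#' variant within a physical window of it (self term included):
#' `l_j = sum_k r2_jk` over `|pos_k - pos_j| <= window`. With
#' `adjust_bias = TRUE` each squared correlation is replaced by the
#' finite-panel unbiased form `r2 - (1 - r2) / (n_hap - 2)`, so scores can dip
#' slightly below 1.
#'
#' @param panel An [simulate_panel()] object (any list with per-chromosome
#'   0/1 haplotype matrices and a `variants` tibble works).
#' @param window_kb Window radius in kb (default 1000, a physical stand-in
#'   for the conventional 1 cM).
#' @param adjust_bias Apply the small-sample r2 bias adjustment.
#' @return A tibble with `chrom`, `id`, `pos`, `l2`, in panel variant order.
#' @export
compute_ld_scores <- function(panel, window_kb = 1000, adjust_bias = TRUE) {
  stopifnot(inherits(panel, "ld_panel") || is.list(panel))
  n <- panel$n_hap
  if (adjust_bias && n < 3) {
    stop("bias adjustment needs at least 3 haplotypes", call. = FALSE)
  }
  if (n < 2) stop("panel needs at least 2 haplotypes", call. = FALSE)
  window <- window_kb * 1000
  out <- vector("list", length(panel$haplotypes))
  for (ci in seq_along(panel$haplotypes)) {
    chrom <- names(panel$haplotypes)[ci]
    H <- panel$haplotypes[[ci]]
    v <- panel$variants[panel$variants$chrom == chrom, , drop = FALSE]
    pos <- v$pos
    mc <- ncol(H)
    Z <- scale(H) # centred, unit sample sd columns
    l2 <- numeric(mc)
    chunk <- 256L
    starts <- seq(1L, mc, by = chunk)
    for (s in starts) {
      e <- min(s + chunk - 1L, mc)
      lo <- findInterval(pos[s] - window - 1L, pos) + 1L
      hi <- findInterval(pos[e] + window, pos)
      R <- crossprod(Z[, s:e, drop = FALSE], Z[, lo:hi, drop = FALSE]) / (n - 1)
      r2 <- R^2
      if (adjust_bias) r2 <- r2 - (1 - r2) / (n - 2)
      inwin <- abs(outer(pos[s:e], pos[lo:hi], "-")) <= window
      r2[!inwin] <- 0
      l2[s:e] <- rowSums(r2)
    }
    out[[ci]] <- tibble::tibble(chrom = chrom, id = v$id, pos = pos, l2 = l2)
  }
  dplyr::bind_rows(out)
}

#' Fit the LD-score regression
#'
#' Weighted least-squares regression of per-variant chi-square statistics on
#' LD scores, following the standard LDSC procedure: variants with
#' `chisq > max(80, 0.001 * N)` are removed first; an initial fit (weighted by
#' the reciprocal LD score, which counteracts over-counting of correlated
#' variants) supplies fitted expected chi-squares; the final fit uses weights
#' `1 / (2 * expected^2 * max(l, 1))` combining heteroskedasticity and
#' over-counting terms. The intercept estimates confounding (target 1 in its
#' absence); the slope times `M / N` estimates heritability.
#'
#' @param stats Summary-statistics tibble with `chisq` (joined to scores by
#'   `id`).
#' @param scores LD-score tibble with `id`, `l2`.
#' @param n Sample size used for the chi-square cap and `h2_est`; defaults to
#'   the median of the per-variant `n` column.
#' @param m Variant count entering `h2_est = slope * m / n`; defaults to the
#'   number of variants in `scores`.
#' @param jackknife Compute a delete-a-block jackknife standard error of the
#'   intercept over contiguous blocks.
#' @param n_blocks Number of jackknife blocks (default 200).
#' @return An object of class `ldsr_fit`; see [tidy.ldsr_fit()] and
#'   [glance.ldsr_fit()].
#' @export
ldsr_fit <- function(stats, scores, n = NULL, m = NULL,
                     jackknife = FALSE, n_blocks = 200) {
  joined <- dplyr::inner_join(
    dplyr::select(stats, "id", "chrom", "pos", "chisq"),
    dplyr::select(scores, "id", "l2"),
    by = "id"
  )
  if (nrow(joined) < 50) {
    stop("need at least 50 variants joining statistics and LD scores, got ",
      nrow(joined),
      call. = FALSE
    )
  }
  if (is.null(n)) {
    if (!"n" %in% names(stats)) {
      stop("supply `n` or a per-variant `n` column", call. = FALSE)
    }
    n <- stats::median(stats$n)
  }
  if (is.null(m)) m <- nrow(scores)

  cap <- max(80, 0.001 * n)
  keep <- joined$chisq <= cap
  n_filtered <- sum(!keep)
  joined <- joined[keep, , drop = FALSE]
  joined <- dplyr::arrange(joined, .data$chrom, .data$pos)
  if (stats::var(joined$l2) == 0) {
    stop("LD scores have zero variance; slope unidentifiable", call. = FALSE)
  }

  fit_wls <- function(dat, w) {
    fit <- stats::lm(chisq ~ l2, data = dat, weights = w)
    unname(stats::coef(fit))
  }
  two_step <- function(dat) {
    w0 <- 1 / pmax(dat$l2, 1)
    cf0 <- fit_wls(dat, w0)
    expected <- pmax(cf0[1] + cf0[2] * dat$l2, 0.1)
    w1 <- 1 / (2 * expected^2 * pmax(dat$l2, 1))
    fit_wls(dat, w1)
  }

  cf <- two_step(joined)
  jk_se <- NA_real_
  if (jackknife) {
    nb <- min(n_blocks, nrow(joined))
    block <- ceiling(seq_len(nrow(joined)) / (nrow(joined) / nb))
    ints <- vapply(
      seq_len(nb),
      function(b) two_step(joined[block != b, , drop = FALSE])[1],
      numeric(1)
    )
    jk_se <- sqrt((nb - 1) / nb * sum((ints - mean(ints))^2))
  }

  structure(
    list(
      intercept = cf[1],
      slope = cf[2],
      h2_est = cf[2] * m / n,
      n_used = nrow(joined),
      n_filtered = n_filtered,
      chisq_cap = cap,
      n = n, m = m,
      jackknife_se_intercept = jk_se,
      data = joined
    ),
    class = "ldsr_fit"
  )
}

#' @export
print.ldsr_fit <- function(x, ...) {
  cat("LD-score regression fit\n")
  cat(sprintf("  intercept: %.4f", x$intercept))
  if (is.finite(x$jackknife_se_intercept)) {
    cat(sprintf(" (jackknife SE %.4f)", x$jackknife_se_intercept))
  }
  cat("\n")
  cat(sprintf("  slope:     %.3e   h2 estimate: %.4f\n", x$slope, x$h2_est))
  cat(sprintf(
    "  variants:  %d used, %d removed by chisq cap %.1f\n",
    x$n_used, x$n_filtered, x$chisq_cap
  ))
  invisible(x)
}

#' Tidy an LD-score regression fit
#'
#' @param x An [ldsr_fit()] object.
#' @param ... Unused.
#' @return A tibble with one row per model term (`intercept`, `slope`).
#' @method tidy ldsr_fit
#' @export
tidy.ldsr_fit <- function(x, ...) {
  tibble::tibble(
    term = c("intercept", "slope"),
    estimate = c(x$intercept, x$slope),
    std.error = c(x$jackknife_se_intercept, NA_real_)
  )
}

#' One-row summary of an LD-score regression fit
#'
#' @param x An [ldsr_fit()] object.
#' @param ... Unused.
#' @return A one-row tibble: `intercept`, `slope`, `h2_est`, `n_used`,
#'   `n_filtered`, `jackknife_se_intercept`.
#' @method glance ldsr_fit
#' @export
glance.ldsr_fit <- function(x, ...) {
  tibble::tibble(
    intercept = x$intercept,
    slope = x$slope,
    h2_est = x$h2_est,
    n_used = x$n_used,
    n_filtered = x$n_filtered,
    jackknife_se_intercept = x$jackknife_se_intercept
  )
}

#' LDSR intercept correction
#'
#' Divides chi-square statistics by the LDSR intercept and recomputes
#' p-values, exactly as [gc_correct()] does with lambda. Because the
#' intercept excludes the polygenic contribution to inflation it is typically
#' smaller than lambda, making this the less conservative correction.
#'
#' @param stats Summary-statistics tibble.
#' @param intercept LDSR intercept (> 0).
#' @param force Apply even when `intercept <= 1`.
#' @return Corrected tibble.
#' @export
intercept_correct <- function(stats, intercept, force = FALSE) {
  .divide_chisq(stats, intercept, force = force)
}

#' Polygenicity proxy: correlation of chi-square with LD scores
#'
#' Pearson correlation between per-variant chi-square statistics and LD
#' scores, a proxy for the share of test-statistic variance explained by
#' polygenic signal; it rises with effective sample size as polygenicity is
#' increasingly captured.
#'
#' @param stats Summary-statistics tibble with `id`, `chisq`.
#' @param scores LD-score tibble with `id`, `l2`.
#' @return A length-one numeric correlation (`NA` with a warning when either
#'   side has zero variance).
#' @export
polygenicity_proxy <- function(stats, scores) {
  joined <- dplyr::inner_join(
    dplyr::select(stats, "id", "chisq"),
    dplyr::select(scores, "id", "l2"),
    by = "id"
  )
  if (nrow(joined) < 3) stop("need at least 3 joined variants", call. = FALSE)
  if (stats::var(joined$chisq) == 0 || stats::var(joined$l2) == 0) {
    warning("zero variance; correlation undefined", call. = FALSE)
    return(NA_real_)
  }
  stats::cor(joined$chisq, joined$l2)
}

#' Effective sample size of a case-control study
#'
#' The balanced-design equivalent sample size,
#' `Neff = 4 / (1 / Ncases + 1 / Ncontrols)`.
#'
#' @param n_cases,n_controls Positive counts.
#' @return A numeric value.
#' @export
#' @examples
#' effective_sample_size(74124, 824006)
effective_sample_size <- function(n_cases, n_controls) {
  if (any(n_cases <= 0) || any(n_controls <= 0)) {
    stop("case and control counts must be > 0", call. = FALSE)
  }
  4 / (1 / n_cases + 1 / n_controls)
}
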