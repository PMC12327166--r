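#' Median of the chi-square distribution with one degree of freedom
#'
#' The denominator of the genomic inflation factor lambda. Kept at full double
#' precision (0.4549364...); the commonly printed 0.454 is a truncated display
#' value and must not be used in computation if lambda is to be reproducible
#' beyond three decimals.
#'
#' @return A length-one numeric, `qchisq(0.5, df = 1)`.
#' @export
#' @examples
#' chisq1_median()
chisq1_median <- function() {
  stats::qchisq(0.5, df = 1)
}

#' Convert -log10 p-values to chi-square statistics (1 df)
#'
#' Inverse survival function of the chi-square distribution with one degree of
#' freedom, evaluated on the log scale so that p-values far below the smallest
#' representable double (p ~ 1e-300 and beyond, stored as -log10 p) convert
#' without underflow.
#'
#' @param neg_log10_p Numeric vector of -log10 p-values, all >= 0.
#' @return Numeric vector of chi-square statistics.
#' @seealso [chisq_to_p()] for the inverse.
#' @export
#' @examples
#' p_to_chisq(-log10(0.5))   # the chi-square(1 df) median, ~0.455
#' p_to_chisq(-log10(5e-8))  # genome-wide significance, ~29.72
p_to_chisq <- function(neg_log10_p) {
  if (any(!is.finite(neg_log10_p))) {
    stop("`neg_log10_p` must be finite", call. = FALSE)
  }
  if (any(neg_log10_p < 0)) {
    stop("`neg_log10_p` must be >= 0", call. = FALSE)
  }
  # log(p) = -neg_log10_p * log(10); survival-scale quantile on the log scale
  stats::qchisq(-neg_log10_p * log(10), df = 1, lower.tail = FALSE, log.p = TRUE)
}

#' Convert chi-square statistics (1 df) to -log10 p-values
#'
#' Survival function of the chi-square distribution with one degree of freedom
#' on the log scale; exact round trip with [p_to_chisq()] for -log10 p up to
#' several hundred.
#'
#' @param chisq Numeric vector of chi-square statistics, all >= 0.
#' @return Numeric vector of -log10 p-values.
#' @export
#' @examples
#' chisq_to_p(0)                 # p = 1
#' 10^(-chisq_to_p(1))           # ~0.3173
chisq_to_p <- function(chisq) {
  if (any(!is.finite(chisq))) {
    stop("`chisq` must be finite", call. = FALSE)
  }
  if (any(chisq < 0)) {
    stop("`chisq` must be >= 0", call. = FALSE)
  }
  -stats::pchisq(chisq, df = 1, lower.tail = FALSE, log.p = TRUE) / log(10)
}

#' Genomic inflation factor (lambda)
#'
#' lambda = median(observed chi-square) / median(chi-square with 1 df). Values
#' above 1 indicate inflation of the association test statistics, whether from
#' confounding or from polygenic signal captured at large sample size. The
#' median of an even-length sample is the midpoint of the two central order
#' statistics.
#'
#' @param stats A summary-statistics tibble with a `chisq` column (as returned
#'   by [read_sumstats()] or [simulate_sumstats()]).
#' @return A one-row tibble with columns `lambda`, `n_variants`,
#'   `median_chisq`.
#' @export
#' @examples
#' x <- tibble::tibble(chisq = c(0.1, 0.90988, 2.0))
#' compute_lambda(x)
compute_lambda <- function(stats) {
  chisq <- .get_chisq(stats)
  if (length(chisq) == 0) {
    stop("cannot compute lambda on an empty table", call. = FALSE)
  }
  med <- stats::median(chisq)
  tibble::tibble(
    lambda = med / chisq1_median(),
    n_variants = length(chisq),
    median_chisq = med
  )
}

.get_chisq <- function(stats) {
  if (!is.data.frame(stats) || !"chisq" %in% names(stats)) {
    stop("`stats` must be a data frame with a `chisq` column", call. = FALSE)
  }
  stats$chisq
}

# Shared correction kernel: divide chi-square by a divisor, recompute p.
# By default the correction is applied only when the divisor exceeds 1 (the
# standard GC convention: never inflate deflated statistics); `force = TRUE`
# applies it unconditionally, which the un-correct/re-correct round trip needs.
.divide_chisq <- function(stats, divisor, force = FALSE) {
  if (!is.finite(divisor) || divisor <= 0) {
    stop("correction factor must be > 0", call. = FALSE)
  }
  eff <- if (divisor > 1 || force) divisor else 1
  out <- stats
  out$chisq <- stats$chisq / eff
  out$neg_log10_p <- chisq_to_p(out$chisq)
  out
}

#' Genomic control correction
#'
#' Divides every chi-square statistic by `lambda` and recomputes p-values.
#' Effect sizes and standard errors are left untouched: GC correction operates
#' on the test statistics only. By default the division is applied only when
#' `lambda > 1` (no deflation correction); set `force = TRUE` to apply it
#' unconditionally.
#'
#' @param stats Summary-statistics tibble with `chisq` and `neg_log10_p`.
#' @param lambda Genomic inflation factor (> 0). If `NULL`, computed from
#'   `stats` via [compute_lambda()].
#' @param force Apply the correction even when `lambda <= 1`.
#' @return The corrected tibble (same rows and columns).
#' @export
gc_correct <- function(stats, lambda = NULL, force = FALSE) {
  if (is.null(lambda)) lambda <- compute_lambda(stats)$lambda
  .divide_chisq(stats, lambda, force = force)
}

#' Undo a genomic control correction
#'
#' Multiplies every chi-square statistic by the lambda that was used to correct
#' it and recomputes p-values; the inverse of [gc_correct()] (with
#' `force = TRUE` in the round trip when `lambda <= 1`).
#'
#' @inheritParams gc_correct
#' @param lambda The lambda value that was applied (for published studies, the
#'   value reported by the study authors).
#' @return The un-corrected tibble.
#' @export
gc_uncorrect <- function(stats, lambda) {
  if (!is.finite(lambda) || lambda <= 0) {
    stop("correction factor must be > 0", call. = FALSE)
  }
  out <- stats
  out$chisq <- stats$chisq * lambda
  out$neg_log10_p <- chisq_to_p(out$chisq)
  out
}

#' Lambda across minor-allele-frequency thresholds
#'
#' Recomputes the genomic inflation factor after removing variants with MAF
#' below each threshold. In well-powered meta-analyses lambda typically rises
#' as rare and low-frequency variants (where power is limited) are removed.
#'
#' @param stats Summary-statistics tibble with `chisq` and either `maf` or
#'   `eaf`.
#' @param thresholds Ordered numeric vector of MAF cutoffs (defaults to the
#'   conventional 0.5%, 1%, 5%, 10%).
#' @return A tibble of class `maf_lambda_profile` with columns `threshold`,
#'   `lambda`, `n_variants` (`lambda` is `NA` where no variant survives).
#' @export
lambda_maf_profile <- function(stats, thresholds = c(0.005, 0.01, 0.05, 0.10)) {
  if (!"maf" %in% names(stats)) {
    if (!"eaf" %in% names(stats)) {
      stop("`stats` must carry `maf` or `eaf`", call. = FALSE)
    }
    stats$maf <- pmin(stats$eaf, 1 - stats$eaf)
  }
  thresholds <- sort(thresholds)
  rows <- purrr::map(thresholds, function(t) {
    sub <- stats[stats$maf >= t, , drop = FALSE]
    if (nrow(sub) == 0) {
      tibble::tibble(threshold = t, lambda = NA_real_, n_variants = 0L)
    } else {
      lr <- compute_lambda(sub)
      tibble::tibble(threshold = t, lambda = lr$lambda, n_variants = lr$n_variants)
    }
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("maf_lambda_profile", class(out))
  out
}
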