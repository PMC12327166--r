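#' Per-chromosome confirmation rates
#'
#' For each chromosome, the confirmation rate is `TP / (TP + FP)` over the
#' earlier study's genome-wide significant variants on that chromosome.
#' Chromosomes with no earlier-significant variant are omitted from the
#' result (flagged absent rather than reported as zero).
#'
#' @param labels A labelled pair tibble from [classify_pair()] (needs `chrom`
#'   and `label`).
#' @return A tibble with `chrom`, `n_sig` (earlier-significant count),
#'   `n_confirmed`, `rate`.
#' @export
chr_confirmation_rates <- function(labels) {
  sig <- labels[labels$label %in% c("TP", "FP"), , drop = FALSE]
  out <- dplyr::summarise(
    dplyr::group_by(sig, .data$chrom),
    n_sig = dplyr::n(),
    n_confirmed = sum(.data$label == "TP"),
    rate = .data$n_confirmed / .data$n_sig,
    .groups = "drop"
  )
  dplyr::arrange(out, suppressWarnings(as.integer(.data$chrom)), .data$chrom)
}

#' Leave-one-chromosome-out null confirmation rates
#'
#' For the chromosome of interest, repeatedly samples (without replacement)
#' the same number of earlier-significant variants from the rest of the
#' genome and records each sample's confirmation rate. Because every sampled
#' variant is either confirmed (TP) or not (FP), the number confirmed in a
#' draw of size k from the off-chromosome pool follows the hypergeometric
#' distribution, which is how the draws are generated.
#'
#' @param labels A labelled pair tibble from [classify_pair()].
#' @param chrom Chromosome label to leave out.
#' @param n_samp Number of samplings (default 100,000).
#' @param seed Integer seed; `NULL` continues the current RNG stream.
#' @return Numeric vector of `n_samp` null confirmation rates.
#' @export
loco_null_samples <- function(labels, chrom, n_samp = 100000, seed = NULL) {
  .maybe_seed(seed)
  sig <- labels[labels$label %in% c("TP", "FP"), , drop = FALSE]
  k <- sum(sig$chrom == chrom)
  if (k == 0) {
    stop("chromosome ", chrom, " has no earlier-significant variants", call. = FALSE)
  }
  rest <- sig[sig$chrom != chrom, , drop = FALSE]
  if (nrow(rest) < k) {
    stop(
      "rest of genome has ", nrow(rest), " significant variants, fewer than the ",
      k, " required for chromosome ", chrom,
      call. = FALSE
    )
  }
  n_tp <- sum(rest$label == "TP")
  stats::rhyper(n_samp, m = n_tp, n = nrow(rest) - n_tp, k = k) / k
}

#' Empirical LOCO p-value
#'
#' Two-tail minimum empirical p:
#' `p_chr = min(#{C_s <= c_obs}, #{C_s > c_obs}) / n_samp`, with ties counted
#' in the lower tail. Its maximum attainable value is 0.5 (an observed rate
#' at the null median).
#'
#' @param null_rates Vector of sampled null confirmation rates.
#' @param c_obs Observed confirmation rate of the chromosome.
#' @return The empirical p-value in `[0, 0.5]`.
#' @export
loco_empirical_p <- function(null_rates, c_obs) {
  if (length(null_rates) == 0) stop("`null_rates` is empty", call. = FALSE)
  lo <- sum(null_rates <= c_obs)
  hi <- sum(null_rates > c_obs)
  min(lo, hi) / length(null_rates)
}

#' Full leave-one-chromosome-out analysis
#'
#' Runs [loco_null_samples()] and [loco_empirical_p()] for every chromosome
#' carrying at least one earlier-significant variant.
#'
#' @inheritParams loco_null_samples
#' @param bonferroni Reporting threshold for the `significant` flag; defaults
#'   to 0.05 divided by the number of testable chromosomes.
#' @return A tibble with one row per testable chromosome: `chrom`, `n_sig`,
#'   `c_obs`, `mean_null`, `p_chr`, `significant` (the threshold used is in
#'   the `bonferroni` attribute). Chromosomes holding more significant
#'   variants than the rest of the genome get `NA` null summaries.
#' @export
loco_analysis <- function(labels, n_samp = 100000, seed = NULL,
                          bonferroni = NULL) {
  .maybe_seed(seed)
  rates <- chr_confirmation_rates(labels)
  empty <- tibble::tibble(
    chrom = character(), n_sig = integer(), c_obs = numeric(),
    mean_null = numeric(), p_chr = numeric(), significant = logical()
  )
  if (nrow(rates) == 0) {
    return(empty)
  }
  if (is.null(bonferroni)) bonferroni <- 0.05 / nrow(rates)
  total_sig <- sum(rates$n_sig)
  rows <- purrr::map(seq_len(nrow(rates)), function(i) {
    # a chromosome holding over half of the significant variants cannot be
    # resampled from the rest of the genome; report it without a null
    feasible <- total_sig - rates$n_sig[i] >= rates$n_sig[i]
    if (feasible) {
      nr <- loco_null_samples(labels, rates$chrom[i], n_samp = n_samp, seed = NULL)
      mean_null <- mean(nr)
      p_chr <- loco_empirical_p(nr, rates$rate[i])
    } else {
      mean_null <- NA_real_
      p_chr <- NA_real_
    }
    tibble::tibble(
      chrom = rates$chrom[i],
      n_sig = rates$n_sig[i],
      c_obs = rates$rate[i],
      mean_null = mean_null,
      p_chr = p_chr
    )
  })
  out <- dplyr::bind_rows(rows)
  out$significant <- out$p_chr < bonferroni
  attr(out, "bonferroni") <- bonferroni
  out
}
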