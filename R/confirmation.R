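#' Genome-wide significance on the -log10 scale
#'
#' Threshold comparisons are done as `neg_log10_p >= -log10(threshold)`;
#' boundary equality counts as significant, avoiding float ambiguity at
#' p = 5e-8.
#' @noRd
.nlp_threshold <- function(threshold) -log10(threshold)

#' Harmonize an earlier/later summary-statistics pair
#'
#' Inner-joins two studies on (chromosome, position) and aligns alleles:
#' identical effect/other alleles are kept as-is; a swapped pair flips the
#' later study onto the earlier study's effect allele (beta negated, EAF
#' complemented, `flipped = TRUE`); mismatched allele sets are dropped and
#' tallied.
#'
#' @param earlier,later Validated summary-statistics tibbles.
#' @return A tibble with one row per shared variant: `chrom`, `pos`, `id`,
#'   `ea`, `oa`, earlier fields (`beta_e`, `se_e`, `nlp_e`, `chisq_e`,
#'   `eaf_e`, `maf_e`), aligned later fields (`beta_l`, `se_l`, `nlp_l`,
#'   `chisq_l`, `eaf_l`) and `flipped`; attribute `drop_tally` counts
#'   allele-mismatch drops.
#' @export
harmonize_pair <- function(earlier, later) {
  if (nrow(earlier) == 0 || nrow(later) == 0) {
    stop("both studies must be non-empty", call. = FALSE)
  }
  e <- dplyr::select(
    earlier, "chrom", "pos", "id", "ea", "oa",
    eaf_e = "eaf", beta_e = "beta", se_e = "se",
    nlp_e = "neg_log10_p", chisq_e = "chisq"
  )
  l <- dplyr::select(
    later, "chrom", "pos",
    ea_l = "ea", oa_l = "oa",
    eaf_l = "eaf", beta_l = "beta", se_l = "se",
    nlp_l = "neg_log10_p", chisq_l = "chisq"
  )
  j <- dplyr::inner_join(e, l, by = c("chrom", "pos"))
  if (nrow(j) == 0) stop("no shared variants between the two studies", call. = FALSE)

  same <- j$ea == j$ea_l & j$oa == j$oa_l
  swapped <- j$ea == j$oa_l & j$oa == j$ea_l
  tally <- c()
  n_drop <- sum(!(same | swapped))
  if (n_drop > 0) tally["allele_mismatch"] <- n_drop
  j <- j[same | swapped, , drop = FALSE]
  if (nrow(j) == 0) stop("no shared variants after allele alignment", call. = FALSE)
  flip <- j$ea == j$oa_l & j$oa == j$ea_l
  j$beta_l[flip] <- -j$beta_l[flip]
  j$eaf_l[flip] <- 1 - j$eaf_l[flip]
  j$flipped <- flip
  j$maf_e <- pmin(j$eaf_e, 1 - j$eaf_e)
  out <- dplyr::select(j, -"ea_l", -"oa_l")
  attr(out, "drop_tally") <- if (length(tally)) tally else integer(0)
  out
}

#' Classify a harmonized pair into the replication confusion matrix
#'
#' Per-variant labels against the genome-wide significance threshold:
#' * `TP` (robust): significant in both studies with the same effect
#'   direction;
#' * `FP`: significant in the earlier study only, or in both with opposite
#'   directions;
#' * `FN`: significant in the later study only;
#' * `TN`: significant in neither.
#' A beta of exactly zero on a doubly-significant variant counts as an
#' inconsistent direction (hence `FP`) by default.
#'
#' @param pair A [harmonize_pair()] tibble (significance is read from `nlp_e`
#'   / `nlp_l`; direction from `beta_e` / `beta_l`).
#' @param threshold Significance level (default 5e-8); equality at the
#'   boundary counts as significant.
#' @return A list: `labels`, the pair tibble plus a `label` factor column;
#'   `confusion`, a one-row tibble with `tp`, `fp`, `fn`, `tn`, `threshold`.
#' @export
classify_pair <- function(pair, threshold = 5e-8) {
  thr <- .nlp_threshold(threshold)
  sig_e <- pair$nlp_e >= thr
  sig_l <- pair$nlp_l >= thr
  same_dir <- sign(pair$beta_e) * sign(pair$beta_l) > 0
  label <- dplyr::case_when(
    sig_e & sig_l & same_dir ~ "TP",
    sig_e ~ "FP", # earlier-only, or both-significant with inconsistent direction
    sig_l ~ "FN",
    TRUE ~ "TN"
  )
  labels <- pair
  labels$label <- factor(label, levels = c("TP", "FP", "FN", "TN"))
  confusion <- tibble::tibble(
    tp = sum(label == "TP"), fp = sum(label == "FP"),
    fn = sum(label == "FN"), tn = sum(label == "TN"),
    threshold = threshold
  )
  list(labels = labels, confusion = confusion)
}

#' Percentage of robust associations
#'
#' `100 * n_robust / n_significant_earlier`: the share of the earlier study's
#' genome-wide significant associations confirmed (significant, same
#' direction) in the later study.
#'
#' @param n_robust Robust (confirmed) association count.
#' @param n_significant_earlier Significant associations in the earlier study
#'   (> 0).
#' @return A percentage.
#' @export
percent_robust <- function(n_robust, n_significant_earlier) {
  if (n_significant_earlier <= 0) {
    stop("earlier-study significant count must be > 0", call. = FALSE)
  }
  100 * n_robust / n_significant_earlier
}

#' Robust associations lost to correction
#'
#' @param n_before Robust associations before correcting the earlier study.
#' @param n_after Robust associations after correction (cannot exceed
#'   `n_before`: correction only removes earlier-study significance).
#' @return A one-row tibble with `n_lost` and `pct_lost` (percent of
#'   `n_before`).
#' @export
#' @examples
#' percent_lost(20405, 10390) # 49.08% lost
percent_lost <- function(n_before, n_after) {
  if (n_after > n_before) {
    stop("correction cannot create robust associations (n_after > n_before)",
      call. = FALSE
    )
  }
  if (n_before <= 0) stop("`n_before` must be > 0", call. = FALSE)
  n_lost <- n_before - n_after
  tibble::tibble(n_lost = n_lost, pct_lost = 100 * n_lost / n_before)
}

#' False positive and true positive rates of a confusion table
#'
#' `FPR = FP / (FP + TN)`, `TPR = TP / (TP + FN)`. A zero denominator yields
#' `NA` (flagged, not an error).
#'
#' @param confusion A one-row tibble with `tp`, `fp`, `fn`, `tn` (as returned
#'   by [classify_pair()]).
#' @return A one-row tibble with `fpr`, `tpr`.
#' @export
confusion_rates <- function(confusion) {
  fpr_den <- confusion$fp + confusion$tn
  tpr_den <- confusion$tp + confusion$fn
  tibble::tibble(
    fpr = ifelse(fpr_den > 0, confusion$fp / fpr_den, NA_real_),
    tpr = ifelse(tpr_den > 0, confusion$tp / tpr_den, NA_real_)
  )
}
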