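#' Plot a lambda-by-MAF-threshold profile
#'
#' Line-and-point plot of the genomic inflation factor against the MAF
#' cutoff applied before recomputing it.
#'
#' @param object A [lambda_maf_profile()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot maf_lambda_profile
#' @export
autoplot.maf_lambda_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$threshold, y = .data$lambda)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed", colour = "grey60") +
    ggplot2::labs(
      x = "MAF threshold", y = expression(lambda),
      title = "Genomic inflation across MAF cutoffs"
    ) +
    ggplot2::theme_minimal()
}

#' Plot an LD-score regression fit
#'
#' Mean chi-square within LD-score quantile bins, with the fitted regression
#' line; the intercept (expected chi-square at LD score zero) estimates
#' confounding.
#'
#' @param object An [ldsr_fit()] object.
#' @param bins Number of LD-score quantile bins (default 50).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ldsr_fit
#' @export
autoplot.ldsr_fit <- function(object, bins = 50, ...) {
  d <- object$data
  brk <- unique(stats::quantile(d$l2, probs = seq(0, 1, length.out = bins + 1)))
  d$bin <- cut(d$l2, breaks = brk, include.lowest = TRUE)
  binned <- dplyr::summarise(
    dplyr::group_by(d, .data$bin),
    l2 = mean(.data$l2), chisq = mean(.data$chisq), .groups = "drop"
  )
  ggplot2::ggplot(binned, ggplot2::aes(x = .data$l2, y = .data$chisq)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_abline(
      intercept = object$intercept, slope = object$slope, colour = "firebrick"
    ) +
    ggplot2::labs(
      x = "LD score", y = expression(chi^2),
      title = sprintf(
        "LD-score regression (intercept %.3f, h2 %.3f)",
        object$intercept, object$h2_est
      )
    ) +
    ggplot2::theme_minimal()
}

#' Plot robust associations before and after correction
#'
#' Bar chart of robust-association counts before and after each correction
#' method in a pairwise report.
#'
#' @param object A [run_pairwise()] report.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pairwise_report
#' @export
autoplot.pairwise_report <- function(object, ...) {
  d <- tidyr::pivot_longer(
    dplyr::select(object$robust, "method", "robust_before", "robust_after"),
    cols = c("robust_before", "robust_after"),
    names_to = "state", values_to = "robust"
  )
  d$state <- factor(d$state,
    levels = c("robust_before", "robust_after"),
    labels = c("before", "after")
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$method, y = .data$robust, fill = .data$state)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(
      x = "correction method", y = "robust associations", fill = NULL,
      title = "Robust associations lost to inflation correction"
    ) +
    ggplot2::theme_minimal()
}
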