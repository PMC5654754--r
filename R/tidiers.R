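#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy the per-k score curve of a region test
#'
#' @param x An `adabf_test` from [adabf_test_region()] or [artp_pvalue()].
#' @param ... Unused.
#' @return A tibble with one row per `k`: the k-th selected `variant_id`,
#'   the summary score `s_k` and its resampling p-value `p_k`.
#' @export
tidy.adabf_test <- function(x, ...) {
  x$score_curve %>% mutate(selected = k <= x$selected_k)
}

#' One-row summary of a region test
#'
#' @param x An `adabf_test`.
#' @param ... Unused.
#' @return A tibble: `method`, `prior_sd`, `L`, `minp`, `adjusted_p`,
#'   `b_used`, `selected_k`, `floor`.
#' @export
glance.adabf_test <- function(x, ...) {
  tibble(method = x$method, prior_sd = sqrt(x$prior_w), L = x$L,
         minp = x$minp, adjusted_p = x$adjusted_p, b_used = x$B,
         selected_k = x$selected_k, floor = x$floor)
}

#' Plot the adaptive per-k p-value curve
#'
#' Shows the resampling p-value of the top-k summary score against `k`; the
#' selected `k` (the curve's minimum) is highlighted. A flat-bottomed curve
#' means the signal is spread over several variants; a sharp minimum at
#' small `k` means a few variants carry it.
#'
#' @param object An `adabf_test`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.adabf_test <- function(object, ...) {
  dat <- tidy(object)
  ggplot2::ggplot(dat, ggplot2::aes(x = k, y = p_k)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(colour = selected), size = 2) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "firebrick",
                                            `FALSE` = "grey60"),
                                 guide = "none") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "k (top-k variants combined)",
                  y = "per-k resampling p-value",
                  title = sprintf("%s: adjusted p = %.3g (B = %g)",
                                  object$method, object$adjusted_p, object$B)) +
    ggplot2::theme_minimal()
}

#' Plot the allele-frequency spectrum of a haplotype pool
#'
#' @param object A [make_pool()] result.
#' @param bins Histogram bins (default 30).
#' @param ... Unused.
#' @return A ggplot of the realized minor-allele-frequency distribution; the
#'   characteristic L-shape concentrates mass below 1%.
#' @export
autoplot.haplotype_pool <- function(object, bins = 30, ...) {
  ggplot2::ggplot(tibble(maf = object$maf), ggplot2::aes(x = maf)) +
    ggplot2::geom_histogram(bins = bins, fill = "steelblue", colour = "white") +
    ggplot2::labs(x = "minor allele frequency", y = "variant sites",
                  title = "L-shaped MAF spectrum") +
    ggplot2::theme_minimal()
}

#' Plot a stratified ranking comparison
#'
#' @param summary Output of [summarize_ranking()].
#' @return A ggplot of mean causal-variant rank by MAF stratum, Bayes-factor
#'   versus p-value ordering.
#' @export
plot_ranking <- function(summary) {
  long <- summary %>%
    select(stratum, mean_rank_bf, mean_rank_p) %>%
    tidyr::pivot_longer(-stratum, names_to = "ordering", values_to = "rank") %>%
    mutate(ordering = if_else(ordering == "mean_rank_bf",
                              "Bayes factor", "p-value"))
  ggplot2::ggplot(long, ggplot2::aes(x = stratum, y = rank, fill = ordering)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "causal-variant MAF stratum",
                  y = "mean rank (smaller is better)") +
    ggplot2::theme_minimal()
}

#' Plot rejection rates with calibration bounds
#'
#' @param summary Output of [summarize_rejection()].
#' @return A ggplot of empirical rejection rate per method and level, with
#'   the 99% binomial band around the nominal level.
#' @export
plot_rejection <- function(summary) {
  ggplot2::ggplot(summary, ggplot2::aes(x = method, y = rate)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = lo, ymax = hi), width = 0.2,
                           colour = "grey50") +
    ggplot2::geom_hline(ggplot2::aes(yintercept = alpha), linetype = 2) +
    ggplot2::facet_wrap(~alpha, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "empirical rejection rate") +
    ggplot2::theme_minimal()
}
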