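#' Tidy a fusion result into one row per call
#'
#' @param x A `fusion_result`.
#' @param ... Unused.
#' @return The fusion-call tibble.
#' @method tidy fusion_result
#' @export
tidy.fusion_result <- function(x, ...) {
  tibble::as_tibble(x$calls)
}

#' One-row summary of a pipeline run
#'
#' @param x A `fusion_result`.
#' @param ... Unused.
#' @return One-row tibble with read, evidence and call counts.
#' @method glance fusion_result
#' @export
glance.fusion_result <- function(x, ...) {
  tibble::tibble(
    n_libraries = nrow(x$insert_stats),
    n_pairs = sum(vapply(x$report$stage_counts, function(s) s[["pairs"]],
                         numeric(1))),
    n_span_dedup = x$report$n_span_dedup,
    n_candidate_pairs = x$report$n_pairs_postfilter,
    n_uum = x$report$n_uum,
    n_calls = nrow(x$calls))
}

#' Tidy an evaluation into one row per truth fusion
#'
#' @param x A `fusion_evaluation`.
#' @param ... Unused.
#' @return The per-fusion match tibble.
#' @method tidy fusion_evaluation
#' @export
tidy.fusion_evaluation <- function(x, ...) {
  tibble::as_tibble(x$per_fusion)
}

#' One-row summary of an evaluation
#'
#' @param x A `fusion_evaluation`.
#' @param ... Unused.
#' @return One-row tibble with FN/FP rates and counts.
#' @method glance fusion_evaluation
#' @export
glance.fusion_evaluation <- function(x, ...) {
  tibble::tibble(fn_rate = x$fn_rate, fp_rate = x$fp_rate,
                 n_truth = x$n_truth, n_calls = x$n_calls)
}

#' Plot span versus junction support of fusion calls
#'
#' @param object A `fusion_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot fusion_result
#' @export
autoplot.fusion_result <- function(object, ...) {
  calls <- object$calls
  calls$label <- paste0(calls$up_symbol, "-", calls$down_symbol)
  ggplot2::ggplot(calls, ggplot2::aes(x = .data$span_count,
                                      y = .data$junc_count,
                                      label = .data$label)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_text(vjust = -0.6, size = 3) +
    ggplot2::labs(x = "span-read support", y = "junc-read support",
                  title = "Fusion call support") +
    ggplot2::theme_minimal()
}

#' Plot detection status of truth fusions by expression fold
#'
#' @param object A `fusion_evaluation`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot fusion_evaluation
#' @export
autoplot.fusion_evaluation <- function(object, ...) {
  pf <- object$per_fusion
  rates <- pf |>
    dplyr::group_by(.data$fold) |>
    dplyr::summarise(fn_rate = mean(!.data$detected), n = dplyr::n(),
                     .groups = "drop")
  ggplot2::ggplot(rates, ggplot2::aes(x = .data$fold, y = 100 * .data$fn_rate)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "expression fold coverage", y = "FN rate (%)",
                  title = "False-negative rate by expression level") +
    ggplot2::theme_minimal()
}

#' Plot FN/FP rates across expression tiers
#'
#' @param tier_rates Tibble with columns `fold`, `fn_rate`, `fp_rate`
#'   (rates in `[0, 1]`), e.g. assembled from per-tier
#'   [evaluate_calls()] results.
#' @return A ggplot object with one line per rate.
#' @export
plot_rate_curves <- function(tier_rates) {
  long <- tidyr::pivot_longer(tier_rates, c("fn_rate", "fp_rate"),
                              names_to = "metric", values_to = "rate")
  long$metric <- ifelse(long$metric == "fn_rate", "FN rate", "FP rate")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$fold, y = 100 * .data$rate,
                                     colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "expression fold coverage", y = "rate (%)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
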