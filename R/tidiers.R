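#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL

#' Tidy an intensity-binned null fold-change model
#'
#' @param x A [fit_null_model()] object.
#' @param ... Unused.
#' @return One row per intensity bin.
#' @export
tidy.null_fc_model <- function(x, ...) x$bins

#' @rdname tidy.null_fc_model
#' @export
glance.null_fc_model <- function(x, ...) {
  tibble::tibble(n_bins = x$n_bins,
                 n_pairs = sum(x$bins$n),
                 mean_abs_bias = mean(abs(x$bins$mean_lfc)),
                 median_sd = stats::median(x$bins$sd_lfc))
}

#' Tidy a spike-in regression fit
#'
#' @param x A [spikein_regression()] object.
#' @param ... Unused.
#' @return `tidy()`: per-level medians and s.d.; `glance()`: slope and R2.
#' @export
tidy.spikein_fit <- function(x, ...) x$per_level

#' @rdname tidy.spikein_fit
#' @export
glance.spikein_fit <- function(x, ...) {
  tibble::tibble(slope = x$slope, r_squared = x$r_squared,
                 n_points = nrow(x$points),
                 n_excluded = nrow(x$excluded))
}

#' Long-format view of a quantification matrix
#'
#' @param x A [quant_matrix()].
#' @param ... Unused.
#' @return Tibble (`feature`, `cell`, `value`) joined with both metadata
#'   tables; missing entries are kept as `NA` rows.
#' @export
tidy.quant_matrix <- function(x, ...) {
  tibble::as_tibble(x$values, rownames = "feature") |>
    tidyr::pivot_longer(-"feature", names_to = "cell",
                        values_to = "value") |>
    dplyr::left_join(x$features, by = "feature") |>
    dplyr::left_join(x$cells, by = "cell")
}

#' @rdname tidy.quant_matrix
#' @export
glance.quant_matrix <- function(x, ...) {
  tibble::tibble(
    n_features = nrow(x$values), n_cells = ncol(x$values),
    n_controls = sum(x$cells$control),
    missing_fraction = mean(is.na(x$values)))
}

#' @export
print.quant_matrix <- function(x, ...) {
  cat(sprintf(
    "<quant_matrix> %d features x %d cells (%d controls), %.1f%% missing\n",
    nrow(x$values), ncol(x$values), sum(x$cells$control),
    100 * mean(is.na(x$values))))
  invisible(x)
}

#' @export
print.null_fc_model <- function(x, ...) {
  cat(sprintf(
    "<null_fc_model> %d equal-count intensity bins over %d precursor pairs\n",
    x$n_bins, sum(x$bins$n)))
  invisible(x)
}

#' @export
print.spikein_fit <- function(x, ...) {
  cat(sprintf("<spikein_fit> slope %.3f, R^2 %.3f over %d points\n",
              x$slope, x$r_squared, nrow(x$points)))
  invisible(x)
}

#' Plot per-tier acquisition metrics
#'
#' Dot plot of MS1 detection, MS2 send, and identification rates per
#' initial-priority tier, mirroring the standard per-tier rate panels of
#' prioritized-acquisition benchmarks.
#'
#' @param metrics Output of [run_metrics()].
#' @return A ggplot object.
#' @export
plot_tier_metrics <- function(metrics) {
  long <- tidyr::pivot_longer(metrics, c("detect_pct", "send_pct", "id_pct"),
                              names_to = "metric", values_to = "pct")
  ggplot2::ggplot(long, ggplot2::aes(factor(.data$priority), .data$pct,
                                     colour = .data$metric,
                                     group = .data$metric)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "initial priority tier", y = "% of tier entries",
                  colour = NULL) +
    ggplot2::ylim(0, 100) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.run_log <- function(object, ...) {
  ms2 <- object[object$event_kind == "ms2", , drop = FALSE]
  ggplot2::ggplot(ms2, ggplot2::aes(.data$scan_time_min,
                                    .data$priority_at_selection)) +
    ggplot2::geom_point(alpha = 0.4,
                        ggplot2::aes(colour = .data$identified)) +
    ggplot2::labs(x = "scan time (min)", y = "priority at selection") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.null_fc_model <- function(object, ...) {
  ggplot2::ggplot(object$bins,
                  ggplot2::aes(log10((.data$intensity_min +
                                        .data$intensity_max) / 2))) +
    ggplot2::geom_pointrange(ggplot2::aes(
      y = .data$mean_lfc, ymin = .data$mean_lfc - .data$sd_lfc,
      ymax = .data$mean_lfc + .data$sd_lfc)) +
    ggplot2::labs(x = "log10 mean precursor intensity",
                  y = "replicate log2 fold change (mean +/- sd)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.spikein_fit <- function(object, ...) {
  ggplot2::ggplot(object$points, ggplot2::aes(.data$log2_level,
                                              .data$log2_intensity)) +
    ggplot2::geom_jitter(width = 0.05, alpha = 0.3) +
    ggplot2::geom_abline(slope = object$slope, intercept = 0,
                         colour = "red") +
    ggplot2::labs(x = "log2 spike-in level",
                  y = "log2 normalized reporter intensity") +
    ggplot2::theme_minimal()
}

#' Completeness distribution per tier
#'
#' @param comp Output of [completeness()].
#' @return A ggplot box plot of per-cell completeness by tier.
#' @export
plot_completeness <- function(comp) {
  ggplot2::ggplot(comp$per_cell,
                  ggplot2::aes(.data$tier, .data$completeness_pct)) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = NULL, y = "% features observed per cell") +
    ggplot2::theme_minimal()
}
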