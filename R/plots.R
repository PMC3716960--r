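#' Ratio-versus-abundance plot of a quantified table
#'
#' MA-style view of a two-group spectral-count comparison: log2 NSC
#' ratio against mean NSC (log10 scale), with the fold-change
#' significance boundaries drawn and points coloured by call when the
#' table has been classified. Group-exclusive proteins have no finite
#' ratio and are omitted from the panel.
#'
#' @param object An `nsc_quant` or `sc_differential` table.
#' @param fold_threshold Threshold lines to draw (taken from the
#'   classification if present; default 2).
#' @param ... Unused.
#' @return A ggplot object.
#' @examples
#' read_quant_table(scquant_example("two_group_spectral_counts.tsv")) |>
#'   quantify_nsc() |>
#'   classify_differential() |>
#'   autoplot()
#' @method autoplot nsc_quant
#' @export
autoplot.nsc_quant <- function(object, fold_threshold = NULL, ...) {
  fold_threshold <- fold_threshold %||% attr(object, "fold_threshold") %||% 2
  df <- as_tibble(object) |>
    filter(.data$detection == "both") |>
    mutate(
      mean_nsc = (.data$nsc_a + .data$nsc_b) / 2,
      log2_ratio = log2(.data$ratio)
    )
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$mean_nsc, y = .data$log2_ratio))
  if ("call" %in% names(df)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = .data$call), alpha = 0.8)
  } else {
    p <- p + ggplot2::geom_point(alpha = 0.8)
  }
  labs <- group_labels(object)
  p +
    ggplot2::geom_hline(yintercept = c(-1, 1) * log2(fold_threshold), linetype = "dashed") +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.2) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = "mean normalized spectral count",
      y = paste0("log2 NSC ratio (", labs[["b"]], " / ", labs[["a"]], ")"),
      colour = "call"
    ) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.nsc_quant
#' @method autoplot sc_differential
#' @export
autoplot.sc_differential <- autoplot.nsc_quant

#' Power-curve plot
#'
#' Detection power and false-call rate against sequencing depth, one
#' line per true fold change.
#'
#' @param object An `sc_power` table from [power_curve()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot sc_power
#' @export
autoplot.sc_power <- function(object, ...) {
  df <- as_tibble(object) |>
    tidyr::pivot_longer(c("power", "false_call_rate"),
      names_to = "metric", values_to = "rate"
    ) |>
    filter(!is.na(.data$rate))
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$depth, y = .data$rate,
    colour = factor(.data$true_fold), group = factor(.data$true_fold)
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~metric) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = "spectral counts per group", y = "rate",
      colour = "true fold"
    ) +
    ggplot2::theme_minimal()
}

#' Bar chart of a GO term roll-up
#'
#' @param rollup Output of [rollup_distribution()].
#' @return A ggplot object.
#' @export
plot_rollup <- function(rollup) {
  lab_col <- if ("term_name" %in% names(rollup)) "term_name" else "go_id"
  df <- filter(rollup, !is.na(.data$percent))
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data[[lab_col]], .data$percent),
    y = .data$percent
  )) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "% of annotation assignments") +
    ggplot2::theme_minimal()
}
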