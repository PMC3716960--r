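#' Fold-change classification of NSC ratios
#'
#' Applies the fold-change significance rule of spectral-count studies:
#' a protein is overexpressed in group B when its (unrounded) NSC ratio
#' is at least the fold threshold, underexpressed when the ratio is at
#' most the reciprocal, and unchanged otherwise. Group-exclusive
#' proteins pass through as their own categories (`b_only` / `a_only`)
#' and are not counted among the over/under calls, matching how
#' "ROS+ only" rows are reported separately in study tables.
#' Classification always uses raw ratios, never display-rounded ones:
#' a protein printing 0.5 but computing 0.54 is unchanged.
#'
#' @param ratio Numeric vector of NSC ratios (`NA` where undefined).
#' @param detection Character vector from [compute_ratio()]
#'   (`"both"`, `"a_only"`, `"b_only"`, `"absent"`).
#' @param fold_threshold Fold-change cut, `> 1` (default 2; boundaries
#'   inclusive).
#' @return Factor with levels `over`, `under`, `unchanged`, `b_only`,
#'   `a_only`, `absent`.
#' @examples
#' classify_calls(c(2.16, 0.54, NA), c("both", "both", "b_only"))
#' @export
classify_calls <- function(ratio, detection, fold_threshold = 2) {
  if (length(fold_threshold) != 1 || !is.finite(fold_threshold) || fold_threshold <= 1) {
    stop_config("fold_threshold must be a single value greater than 1.")
  }
  stopifnot(length(ratio) == length(detection))
  lab <- dplyr::case_when(
    detection == "b_only" ~ "b_only",
    detection == "a_only" ~ "a_only",
    detection == "absent" ~ "absent",
    ratio >= fold_threshold ~ "over",
    ratio <= 1 / fold_threshold ~ "under",
    TRUE ~ "unchanged"
  )
  factor(lab, levels = c("over", "under", "unchanged", "b_only", "a_only", "absent"))
}

#' Classify every protein of a quantified table
#'
#' Adds a `call` column ([classify_calls()]) to the output of
#' [quantify_nsc()].
#'
#' @param x An `nsc_quant` table.
#' @inheritParams classify_calls
#' @return The table with a `call` column; class `sc_differential`.
#' @examples
#' read_quant_table(scquant_example("two_group_spectral_counts.tsv")) |>
#'   quantify_nsc() |>
#'   classify_differential() |>
#'   summarize_differential()
#' @export
classify_differential <- function(x, fold_threshold = 2) {
  if (!all(c("ratio", "detection") %in% names(x))) {
    stop_config("classify_differential() expects a quantified table; run quantify_nsc() first.")
  }
  out <- mutate(as_tibble(x), call = classify_calls(.data$ratio, .data$detection, fold_threshold))
  structure(out,
    class = c("sc_differential", setdiff(class(x), "sc_differential")),
    group_a_label = attr(x, "group_a_label"), group_b_label = attr(x, "group_b_label"),
    method = attr(x, "method"), total_a = attr(x, "total_a"), total_b = attr(x, "total_b"),
    fold_threshold = fold_threshold
  )
}

#' Summarize differential-expression calls
#'
#' Counts the classification outcomes of a table with calls: proteins
#' overexpressed and underexpressed at the fold threshold (whose sum is
#' the number of significant proteins), group-exclusive proteins, and —
#' over all finite ratios regardless of threshold — proteins with any
#' increase (`ratio > 1`) or decrease (`ratio < 1`).
#'
#' @param x An `sc_differential` table (from [classify_differential()]).
#' @return A one-row tibble with columns `n_total`, `n_over`, `n_under`,
#'   `n_significant`, `n_b_only`, `n_a_only`, `n_up_any`, `n_down_any`.
#' @export
summarize_differential <- function(x) {
  if (!"call" %in% names(x)) {
    stop_config("summarize_differential() expects a classified table; run classify_differential().")
  }
  if (anyNA(x$call)) {
    bad <- x$accession[is.na(x$call)]
    stop_validation(paste0("Missing call for accession(s): ", paste(bad, collapse = ", "), "."))
  }
  tibble(
    n_total = nrow(x),
    n_over = sum(x$call == "over"),
    n_under = sum(x$call == "under"),
    n_significant = sum(x$call %in% c("over", "under")),
    n_b_only = sum(x$call == "b_only"),
    n_a_only = sum(x$call == "a_only"),
    n_up_any = sum(x$ratio > 1, na.rm = TRUE),
    n_down_any = sum(x$ratio < 1, na.rm = TRUE)
  )
}

#' Ranked differential-expression report
#'
#' Orders proteins by call category (over, under, exclusives, then
#' unchanged) and, within a category, by decreasing absolute log2
#' ratio, and adds display-rounded NSC and ratio strings (3 and 1
#' decimals by default, ties away from zero). Exclusive proteins print
#' the group label instead of a ratio.
#'
#' @param x An `sc_differential` table.
#' @param nsc_decimals,ratio_decimals Display precision.
#' @return A tibble with display columns `nsc_a_disp`, `nsc_b_disp`,
#'   `ratio_disp`, ordered for reporting.
#' @export
report_differential <- function(x, nsc_decimals = 3, ratio_decimals = 1) {
  if (!"call" %in% names(x)) {
    stop_config("report_differential() expects a classified table; run classify_differential().")
  }
  labs <- group_labels(x)
  out <- as_tibble(x) |>
    mutate(
      nsc_a_disp = display_round(.data$nsc_a, nsc_decimals),
      nsc_b_disp = display_round(.data$nsc_b, nsc_decimals),
      ratio_disp = dplyr::case_when(
        .data$detection == "b_only" ~ paste(labs[["b"]], "only"),
        .data$detection == "a_only" ~ paste(labs[["a"]], "only"),
        .data$detection == "absent" ~ "absent",
        TRUE ~ display_round(.data$ratio, ratio_decimals)
      ),
      .rank = dplyr::coalesce(abs(log2(.data$ratio)), Inf)
    ) |>
    arrange(factor(.data$call, levels = c("over", "under", "b_only", "a_only", "unchanged", "absent")),
      desc(.data$.rank)
    ) |>
    select(-".rank")
  out
}
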