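#' Normalized spectral count of a single protein
#'
#' The normalized spectral count (NSC) of a protein is its spectral
#' count divided by the total number of spectral counts over all
#' proteins in that group, so per-group NSC values sum to one. This is
#' the per-value primitive; use [quantify_nsc()] to normalize a whole
#' table (including the length-corrected NSAF variant, which needs
#' whole-table context).
#'
#' @param sc Integer vector of spectral counts.
#' @param group_total Total spectral counts of the group (single
#'   positive integer, `>= max(sc)`).
#' @return Numeric vector of fractions in `[0, 1]`.
#' @examples
#' compute_nsc(497, 3434) # 0.1447...
#' @export
compute_nsc <- function(sc, group_total) {
  stopifnot(is.numeric(sc), length(group_total) == 1)
  if (is.na(group_total) || group_total <= 0) {
    stop_validation("Group total must be positive; cannot normalize an empty group.")
  }
  if (any(sc < 0, na.rm = TRUE)) stop_validation("Spectral counts must be non-negative.")
  if (any(sc > group_total, na.rm = TRUE)) {
    stop_validation("A spectral count exceeds its group total.")
  }
  sc / group_total
}

#' Between-group NSC ratio with group-exclusive handling
#'
#' Forms the differential-expression statistic NSC(B)/NSC(A) per protein
#' (with group B conventionally the ROS+ group). Proteins detected in
#' only one group have no finite ratio and are flagged by a detection
#' marker instead, matching the "ROS+ only" / "ROS- only" notation of
#' spectral-count reports. An optional pseudocount can be added to both
#' counts to force finite ratios.
#'
#' @param sc_a,sc_b Integer vectors of spectral counts in groups A and B.
#' @param total_a,total_b Positive per-group totals.
#' @param pseudocount Non-negative value added to each count before the
#'   ratio is formed (default 0, i.e. exclusives stay marked).
#' @return A tibble with columns `ratio` (numeric, `NA` where undefined)
#'   and `detection` (one of `"both"`, `"a_only"`, `"b_only"`, `"absent"`).
#' @examples
#' compute_ratio(17, 27, 3434, 3173) # ACPP-style ratio 1.72
#' compute_ratio(0, 8, 3434, 3173)   # detected in group B only
#' @export
compute_ratio <- function(sc_a, sc_b, total_a, total_b, pseudocount = 0) {
  stopifnot(length(sc_a) == length(sc_b), pseudocount >= 0)
  if (total_a <= 0 || total_b <= 0) stop_validation("Group totals must be positive.")
  detection <- dplyr::case_when(
    sc_a > 0 & sc_b > 0 ~ "both",
    sc_a > 0 ~ "a_only",
    sc_b > 0 ~ "b_only",
    TRUE ~ "absent"
  )
  a <- sc_a + pseudocount
  b <- sc_b + pseudocount
  ratio <- if_else(a > 0 & b > 0, (b / total_b) / (a / total_a), NA_real_)
  tibble(ratio = ratio, detection = detection)
}

#' Quantify a two-group spectral-count table
#'
#' Adds normalized spectral counts for both groups and the
#' between-group ratio to every protein of a [quant_table()]. Two
#' normalization modes are available: `"total"` divides each count by
#' the group total (NSC, the default), `"nsaf"` first divides each
#' count by the protein length in amino acids and then by the group sum
#' of length-corrected counts (the normalized spectral abundance
#' factor). Input counts are never modified.
#'
#' @param x A `quant_tbl` (or data frame coercible via [quant_table()]).
#' @param method `"total"` (NSC) or `"nsaf"`.
#' @param length_col Column holding protein lengths in amino acids;
#'   required for `method = "nsaf"`.
#' @param pseudocount Passed to [compute_ratio()].
#' @return The table with added columns `nsc_a`, `nsc_b`, `ratio`,
#'   `detection`; class `nsc_quant`. Normalization metadata is attached
#'   as attributes.
#' @examples
#' read_quant_table(scquant_example("two_group_spectral_counts.tsv")) |>
#'   quantify_nsc() |>
#'   dplyr::filter(gene_symbol == "MDH2")
#' @export
quantify_nsc <- function(x, method = c("total", "nsaf"), length_col = "length_aa",
                         pseudocount = 0) {
  method <- match.arg(method)
  if (!inherits(x, "quant_tbl")) x <- quant_table(x)
  tot <- group_totals(x)
  if (any(tot == 0)) stop_validation("Cannot normalize a group with zero total spectral counts.")
  out <- as_tibble(x)
  if (method == "total") {
    out$nsc_a <- compute_nsc(out$sc_a, tot[["total_a"]])
    out$nsc_b <- compute_nsc(out$sc_b, tot[["total_b"]])
  } else {
    if (!length_col %in% names(out)) {
      stop_config(paste0("NSAF normalization needs a protein length column '", length_col, "'."))
    }
    len <- out[[length_col]]
    if (any(is.na(len)) || any(len <= 0)) {
      stop_config("Protein lengths must be positive for NSAF normalization.")
    }
    out$nsc_a <- (out$sc_a / len) / sum(out$sc_a / len)
    out$nsc_b <- (out$sc_b / len) / sum(out$sc_b / len)
  }
  rat <- compute_ratio(out$sc_a, out$sc_b, tot[["total_a"]], tot[["total_b"]],
    pseudocount = pseudocount
  )
  out$ratio <- if (method == "nsaf") {
    if_else(rat$detection == "both", out$nsc_b / out$nsc_a, NA_real_)
  } else {
    rat$ratio
  }
  out$detection <- rat$detection
  labs <- group_labels(x)
  structure(out,
    class = c("nsc_quant", "quant_tbl", class(as_tibble(out))),
    group_a_label = labs[["a"]], group_b_label = labs[["b"]],
    method = method, total_a = unname(tot[["total_a"]]), total_b = unname(tot[["total_b"]]),
    pseudocount = pseudocount
  )
}
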