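#' Tidy a simulated experiment
#'
#' Returns the per-protein ground truth joined with the realized counts
#' — one row per protein, ready for joining against pipeline calls.
#'
#' @param x An `sc_sim` object.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy sc_sim
#' @export
tidy.sc_sim <- function(x, ...) {
  as_tibble(x$truth)
}

#' One-row summary of a simulated experiment
#'
#' @param x An `sc_sim` object.
#' @param ... Unused.
#' @return A one-row tibble of the realized design: protein and depth
#'   totals and injected-truth counts.
#' @method glance sc_sim
#' @export
glance.sc_sim <- function(x, ...) {
  tibble(
    n_proteins = nrow(x$truth),
    depth_a = sum(x$truth$sc_a),
    depth_b = sum(x$truth$sc_b),
    n_over = sum(x$truth$true_label == "over"),
    n_under = sum(x$truth$true_label == "under"),
    n_b_only = sum(x$truth$true_label == "b_only"),
    n_a_only = sum(x$truth$true_label == "a_only"),
    true_fold = x$config$true_fold,
    seed = x$config$seed %||% NA_integer_
  )
}

#' Tidy a quantified spectral-count table
#'
#' Strips result classes so the per-protein table is a plain tibble.
#'
#' @param x An `nsc_quant` (or `sc_differential`) table.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy nsc_quant
#' @export
tidy.nsc_quant <- function(x, ...) {
  as_tibble(x)
}

#' @rdname tidy.nsc_quant
#' @method tidy sc_differential
#' @export
tidy.sc_differential <- function(x, ...) {
  as_tibble(x)
}

#' One-row summary of a quantified table
#'
#' @param x An `nsc_quant` table.
#' @param ... Unused.
#' @return A one-row tibble with the normalization method, group totals
#'   and protein counts by detection class.
#' @method glance nsc_quant
#' @export
glance.nsc_quant <- function(x, ...) {
  tibble(
    n_proteins = nrow(x),
    total_a = attr(x, "total_a"),
    total_b = attr(x, "total_b"),
    method = attr(x, "method"),
    n_shared = sum(x$detection == "both"),
    n_a_only = sum(x$detection == "a_only"),
    n_b_only = sum(x$detection == "b_only")
  )
}

#' One-row summary of a classified table
#'
#' Equivalent to [summarize_differential()] plus the fold threshold.
#'
#' @param x An `sc_differential` table.
#' @param ... Unused.
#' @return A one-row tibble.
#' @method glance sc_differential
#' @export
glance.sc_differential <- function(x, ...) {
  mutate(summarize_differential(x), fold_threshold = attr(x, "fold_threshold"))
}
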