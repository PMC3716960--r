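#' Monte-Carlo power curve for the fold-change rule
#'
#' Estimates, over a grid of sequencing depths and true fold changes,
#' how often the two-fold (or other threshold) classification recovers
#' injected proteins (power) and how often true-unchanged proteins are
#' falsely called significant (false-call rate). Each grid point is
#' estimated from independent replicate simulations; binomial
#' Monte-Carlo standard errors are attached. At `true_fold = 1` no
#' proteins are injected, so the power column is `NA` and only the
#' false-call rate is meaningful.
#'
#' @param depths Integer vector of per-group total spectral counts
#'   (applied to both groups).
#' @param true_folds Numeric vector of fold changes (`1` allowed, and
#'   means "no injection").
#' @param replicates Replicate simulations per grid point (default 20).
#' @param fold_threshold Classification threshold (default 2).
#' @param n_proteins,n_over,n_under,abundance_shape,min_inject_abundance,max_inject_abundance
#'   Passed to [simulate_spectral_counts()].
#' @param seed Optional integer seed for the whole grid.
#' @return A tibble of class `sc_power` with columns `depth`,
#'   `true_fold`, `power`, `power_se`, `false_call_rate`,
#'   `false_call_se`, `replicates`.
#' @examples
#' power_curve(depths = 2000, true_folds = c(1, 4), replicates = 5, seed = 1)
#' @export
power_curve <- function(depths, true_folds, replicates = 20, fold_threshold = 2,
                        n_proteins = 74, n_over = 10, n_under = 5,
                        abundance_shape = 0.3, min_inject_abundance = 0.003,
                        max_inject_abundance = 0.02, seed = NULL) {
  if (replicates < 1) stop_validation("replicates must be at least 1.")
  if (!is.null(seed)) withr::local_seed(seed)
  grid <- tidyr::expand_grid(depth = depths, true_fold = true_folds)
  res <- purrr::pmap(grid, function(depth, true_fold) {
    inject <- true_fold > 1
    hit_frac <- double(replicates)
    false_frac <- double(replicates)
    for (r in seq_len(replicates)) {
      sim <- simulate_spectral_counts(
        n_proteins = n_proteins, depth_a = depth, depth_b = depth,
        n_over = if (inject) n_over else 0, n_under = if (inject) n_under else 0,
        n_b_only = 0, n_a_only = 0,
        true_fold = if (inject) true_fold else 2, # ignored when nothing injected
        abundance_shape = abundance_shape,
        min_inject_abundance = if (inject) min_inject_abundance else 0,
        max_inject_abundance = if (inject) max_inject_abundance else Inf
      )
      calls <- sim$counts |>
        quantify_nsc() |>
        classify_differential(fold_threshold = fold_threshold)
      joined <- left_join(sim$truth[, c("accession", "true_label")],
        as_tibble(calls)[, c("accession", "call")],
        by = "accession"
      )
      sig <- joined$call %in% c("over", "under")
      injected <- joined$true_label %in% c("over", "under")
      hit_frac[r] <- if (inject) mean(sig[injected]) else NA_real_
      false_frac[r] <- mean(sig[joined$true_label == "unchanged"])
    }
    pw <- mean(hit_frac)
    fc <- mean(false_frac)
    tibble(
      depth = depth, true_fold = true_fold,
      power = pw,
      power_se = if (inject) stats::sd(hit_frac) / sqrt(replicates) else NA_real_,
      false_call_rate = fc,
      false_call_se = stats::sd(false_frac) / sqrt(replicates),
      replicates = replicates
    )
  })
  out <- bind_rows(res)
  structure(out, class = c("sc_power", class(out)))
}
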