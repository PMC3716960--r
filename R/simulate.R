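#' Simulate a two-group spectral-count experiment with known truth
#'
#' Generates a synthetic dataset with the structure of a pooled
#' two-group shotgun proteomics experiment: a heavy-tailed baseline
#' relative-abundance profile (a symmetric Dirichlet draw with small
#' concentration, so a handful of proteins dominate the counts as the
#' major sperm proteins do in real data), a configurable set of true
#' fold changes applied multiplicatively in group B (divided for
#' underexpressed proteins), group-exclusive proteins zeroed out in one
#' group, and counts realized as one multinomial draw per group at a
#' fixed sequencing depth — spectral counting competes for a fixed
#' number of acquired spectra, so counts are compositional, not
#' independent Poisson.
#'
#' The defaults mirror the scale of the bundled sperm study dataset:
#' 74 proteins, total depths 3434 (group A, ROS-) and 3173 (group B,
#' ROS+), 10 overexpressed, 5 underexpressed and one exclusive protein
#' per group.
#'
#' @param n_proteins Number of proteins (default 74).
#' @param depth_a,depth_b Total spectral counts per group (defaults
#'   3434 / 3173).
#' @param n_over,n_under Number of true over-/underexpressed proteins
#'   (defaults 10 / 5).
#' @param n_b_only,n_a_only Number of group-exclusive proteins
#'   (defaults 1 / 1).
#' @param true_fold Fold change applied to injected proteins (default
#'   2.5, must be `> 1`).
#' @param abundance_shape Gamma shape of the Dirichlet baseline draw
#'   (default 0.3; smaller is heavier-tailed).
#' @param min_inject_abundance,max_inject_abundance Injected (over/under)
#'   proteins are drawn from the baseline-abundance band between these
#'   bounds (defaults 0.003 and 0.02). The floor keeps fold changes on
#'   quantifiable proteins (about ten expected counts at the default
#'   depths); the ceiling leaves the dominant structural proteins
#'   unperturbed so that the compositional renormalization stays close
#'   to one and the nominal fold change is (approximately) realized on
#'   the NSC scale. If a draw yields too few proteins in the band, the
#'   band is extended upwards with the least abundant proteins above the
#'   ceiling. Exclusives are drawn from the remaining proteins.
#' @param length_range Integer bounds for simulated protein lengths in
#'   amino acids (used by the NSAF variant; default `c(100, 1000)`).
#' @param seed Optional integer seed making the whole draw reproducible.
#' @return An object of class `sc_sim`: a list with `$truth` (per-protein
#'   tibble: accession, length, baseline and per-group true relative
#'   abundances, `true_label`, realized counts), `$counts` (the realized
#'   [quant_table()]) and `$config`.
#' @examples
#' sim <- simulate_spectral_counts(seed = 1)
#' sum(sim$counts$sc_a) # equals depth_a
#' dplyr::count(sim$truth, true_label)
#' @export
simulate_spectral_counts <- function(n_proteins = 74, depth_a = 3434, depth_b = 3173,
                                     n_over = 10, n_under = 5,
                                     n_b_only = 1, n_a_only = 1,
                                     true_fold = 2.5, abundance_shape = 0.3,
                                     min_inject_abundance = 0.003,
                                     max_inject_abundance = 0.02,
                                     length_range = c(100, 1000), seed = NULL) {
  if (n_proteins < 1) stop_validation("n_proteins must be at least 1.")
  if (depth_a <= 0 || depth_b <= 0) stop_validation("Depths must be positive.")
  if (true_fold <= 1) stop_validation("true_fold must exceed 1.")
  n_inject <- n_over + n_under + n_b_only + n_a_only
  if (n_inject > n_proteins) {
    stop_validation("More injected proteins than proteins in the experiment.")
  }
  if (!is.null(seed)) withr::local_seed(seed)

  accession <- sprintf("SIM%04d", seq_len(n_proteins))
  length_aa <- sample(length_range[1]:length_range[2], n_proteins, replace = TRUE)
  base <- rgamma(n_proteins, shape = abundance_shape, rate = 1)
  base <- pmax(base, .Machine$double.xmin)
  base <- base / sum(base)

  # fold changes go to mid-abundance proteins (observable but not
  # composition-dominating); exclusives to the remainder
  eligible <- which(base >= min_inject_abundance & base <= max_inject_abundance)
  n_fold <- n_over + n_under
  if (length(eligible) < n_fold) {
    above <- setdiff(which(base > max_inject_abundance), eligible)
    above <- above[order(base[above])]
    eligible <- c(eligible, head(above, n_fold - length(eligible)))
  }
  if (length(eligible) < n_fold) {
    stop_validation("Not enough proteins in the injectable abundance band to place fold changes.")
  }
  fold_idx <- resample(eligible, n_fold)
  rest <- setdiff(seq_len(n_proteins), fold_idx)
  excl_idx <- resample(rest, n_b_only + n_a_only)
  idx_over <- fold_idx[seq_len(n_over)]
  idx_under <- fold_idx[n_over + seq_len(n_under)]
  idx_b_only <- excl_idx[seq_len(n_b_only)]
  idx_a_only <- excl_idx[n_b_only + seq_len(n_a_only)]

  true_label <- rep("unchanged", n_proteins)
  true_label[idx_over] <- "over"
  true_label[idx_under] <- "under"
  true_label[idx_b_only] <- "b_only"
  true_label[idx_a_only] <- "a_only"

  abund_a <- base
  abund_b <- base
  abund_b[idx_over] <- abund_b[idx_over] * true_fold
  abund_b[idx_under] <- abund_b[idx_under] / true_fold
  abund_a[idx_b_only] <- 0
  abund_b[idx_a_only] <- 0
  abund_a <- abund_a / sum(abund_a)
  abund_b <- abund_b / sum(abund_b)

  sc_a <- as.integer(rmultinom(1, size = depth_a, prob = abund_a)[, 1])
  sc_b <- as.integer(rmultinom(1, size = depth_b, prob = abund_b)[, 1])

  truth <- tibble(
    accession = accession, length_aa = length_aa,
    base_abund = base, abund_a = abund_a, abund_b = abund_b,
    true_label = factor(true_label,
      levels = c("over", "under", "unchanged", "b_only", "a_only")
    ),
    sc_a = sc_a, sc_b = sc_b
  )
  counts <- quant_table(tibble(
    accession = accession, gene_symbol = accession,
    length_aa = length_aa, sc_a = sc_a, sc_b = sc_b
  ))
  config <- list(
    n_proteins = n_proteins, depth_a = depth_a, depth_b = depth_b,
    n_over = n_over, n_under = n_under, n_b_only = n_b_only, n_a_only = n_a_only,
    true_fold = true_fold, abundance_shape = abundance_shape,
    min_inject_abundance = min_inject_abundance,
    max_inject_abundance = max_inject_abundance,
    length_range = length_range, seed = seed
  )
  structure(list(truth = truth, counts = counts, config = config), class = "sc_sim")
}

# size-safe sampling without the scalar-x expansion of sample()
resample <- function(x, size) x[sample.int(length(x), size)]

#' @export
print.sc_sim <- function(x, ...) {
  cfg <- x$config
  cat(
    "Simulated two-group spectral-count experiment\n",
    " proteins: ", cfg$n_proteins,
    "; depths: ", cfg$depth_a, "/", cfg$depth_b,
    "; true fold: ", cfg$true_fold, "\n",
    " injected: ", cfg$n_over, " over, ", cfg$n_under, " under, ",
    cfg$n_b_only, " B-only, ", cfg$n_a_only, " A-only\n",
    sep = ""
  )
  invisible(x)
}

#' Expand realized spectral counts to synthetic peptide-spectrum matches
#'
#' Emits exactly one PSM row per counted spectrum: a protein with a
#' spectral count of 3 in group A yields three rows labelled group A,
#' with synthetic spectrum identifiers and random tryptic-like peptide
#' strings (uppercase 20-letter amino-acid alphabet, ending in K or R).
#' [aggregate_psms()] inverts this expansion exactly.
#'
#' @param x An `sc_sim` object or a `quant_tbl`.
#' @param seed Optional integer seed for the random peptide strings.
#' @return A tibble with columns `spectrum_id`, `peptide_sequence`,
#'   `accession`, `sample_group`.
#' @examples
#' sim <- simulate_spectral_counts(
#'   n_proteins = 5, depth_a = 20, depth_b = 20,
#'   n_over = 1, n_under = 1, n_b_only = 0, n_a_only = 0, seed = 2
#' )
#' psms <- expand_to_psms(sim)
#' nrow(psms) == 40
#' @export
expand_to_psms <- function(x, seed = NULL) {
  counts <- if (inherits(x, "sc_sim")) x$counts else x
  if (!inherits(counts, "quant_tbl")) counts <- quant_table(counts)
  if (!is.null(seed)) withr::local_seed(seed)
  labs <- group_labels(counts)
  long <- tibble(
    accession = rep(counts$accession, times = counts$sc_a + counts$sc_b),
    sample_group = unlist(purrr::map2(
      counts$sc_a, counts$sc_b,
      function(a, b) c(rep(labs[["a"]], a), rep(labs[["b"]], b))
    ), use.names = FALSE) %||% character()
  )
  n <- nrow(long)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  peptide <- vapply(seq_len(n), function(i) {
    len <- sample(7:15, 1)
    paste0(paste(sample(aa, len - 1, replace = TRUE), collapse = ""), sample(c("K", "R"), 1))
  }, character(1))
  tibble(
    spectrum_id = sprintf("S%06d", seq_len(n)),
    peptide_sequence = peptide,
    accession = long$accession,
    sample_group = long$sample_group
  )
}
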