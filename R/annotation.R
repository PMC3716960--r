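#' Read a minimal two-column protein-to-GO annotation map
#'
#' The roll-up functions consume a pre-slimmed annotation map: one row
#' per (protein accession, GO term) assignment. No ontology-graph
#' propagation is performed — slimming tools have already mapped
#' annotations up to the broad terms.
#'
#' @param path Path to a TSV with columns `accession` and `go_id`.
#' @return A tibble with character columns `accession`, `go_id`.
#' @examples
#' read_annotation_tsv(scquant_example("synthetic_go_cc_map.tsv"))
#' @export
read_annotation_tsv <- function(path) {
  if (!file.exists(path)) stop_config(paste0("File not found: ", path))
  df <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()))
  for (col in c("accession", "go_id")) {
    if (!col %in% names(df)) stop_config(paste0("Annotation map is missing column '", col, "'."))
  }
  distinct(df[, c("accession", "go_id")])
}

#' Read a GAF 2.x gene association file into an annotation map
#'
#' Parses the tab-separated Gene Association File format (17 columns,
#' comment lines starting with `!`), keeping the object identifier
#' (column 2), GO ID (column 5) and aspect (column 9).
#'
#' @param path Path to an uncompressed GAF file.
#' @param aspect Optional filter: `"C"` (cellular component), `"P"`
#'   (biological process) or `"F"` (molecular function).
#' @return A tibble with columns `accession`, `go_id`, `aspect`.
#' @export
read_gaf <- function(path, aspect = NULL) {
  if (!file.exists(path)) stop_config(paste0("File not found: ", path))
  df <- readr::read_tsv(path,
    comment = "!", col_names = FALSE,
    col_types = readr::cols(.default = readr::col_character())
  )
  if (ncol(df) < 9) stop_parse("Not a GAF 2.x file: fewer than 9 columns.")
  out <- tibble(accession = df$X2, go_id = df$X5, aspect = df$X9)
  if (!is.null(aspect)) {
    aspect <- match.arg(aspect, c("C", "P", "F"))
    out <- filter(out, .data$aspect == !!aspect)
  }
  distinct(out)
}

#' Read a GO term-name table
#'
#' @param path Path to a TSV with columns `go_id` and `term_name`.
#' @return A tibble mapping term identifiers to labels.
#' @export
read_term_names <- function(path) {
  if (!file.exists(path)) stop_config(paste0("File not found: ", path))
  df <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()))
  for (col in c("go_id", "term_name")) {
    if (!col %in% names(df)) stop_config(paste0("Term table is missing column '", col, "'."))
  }
  distinct(df[, c("go_id", "term_name")])
}

#' GO term distribution of a protein list
#'
#' Counts, for each term of the annotation map, how many of the given
#' proteins carry it, and expresses the count as a percentage of all
#' annotation assignments (not of proteins: a multi-annotated protein
#' contributes to several terms, so percentages over terms sum to 100 —
#' the convention of GO slim pie charts). Proteins with no annotation
#' are reported in an explicit `"unannotated"` bucket row whose count is
#' outside the percentage base (`percent` is `NA` there).
#'
#' @param proteins Character vector of accessions.
#' @param map Annotation map tibble (`accession`, `go_id`).
#' @param term_names Optional term-name tibble (see [read_term_names()]).
#' @return A tibble with columns `go_id`, `term_name` (if supplied),
#'   `n_proteins`, `percent`, sorted by decreasing count.
#' @examples
#' map <- read_annotation_tsv(scquant_example("synthetic_go_cc_map.tsv"))
#' rollup_distribution(unique(map$accession), map)
#' @export
rollup_distribution <- function(proteins, map, term_names = NULL) {
  proteins <- unique(as.character(proteins))
  hits <- map |>
    filter(.data$accession %in% proteins) |>
    distinct(.data$accession, .data$go_id)
  dist <- hits |>
    count(.data$go_id, name = "n_proteins") |>
    mutate(percent = 100 * .data$n_proteins / sum(.data$n_proteins)) |>
    arrange(desc(.data$n_proteins), .data$go_id)
  n_unannot <- sum(!proteins %in% map$accession)
  if (length(proteins) && n_unannot > 0) {
    dist <- bind_rows(dist, tibble(
      go_id = "unannotated",
      n_proteins = n_unannot, percent = NA_real_
    ))
  }
  if (!is.null(term_names)) {
    dist <- left_join(dist, term_names, by = "go_id") |>
      relocate("term_name", .after = "go_id")
  }
  dist
}

#' Compare the GO distributions of two protein sets
#'
#' Pairs, per term, the protein counts of two sets (typically the over-
#' and underexpressed proteins) and flags terms exclusive to one set —
#' the comparison behind "term X shows only overexpressed proteins"
#' statements.
#'
#' @param set_over,set_under Character vectors of accessions.
#' @param map Annotation map tibble.
#' @param term_names Optional term-name tibble.
#' @return A tibble with `go_id`, `count_over`, `count_under` and
#'   `status` in `"shared"`, `"over_only"`, `"under_only"`.
#' @export
compare_rollups <- function(set_over, set_under, map, term_names = NULL) {
  cnt <- function(proteins, nm) {
    map |>
      filter(.data$accession %in% unique(as.character(proteins))) |>
      distinct(.data$accession, .data$go_id) |>
      count(.data$go_id, name = nm)
  }
  out <- dplyr::full_join(cnt(set_over, "count_over"), cnt(set_under, "count_under"),
    by = "go_id"
  ) |>
    mutate(
      count_over = dplyr::coalesce(.data$count_over, 0L),
      count_under = dplyr::coalesce(.data$count_under, 0L),
      status = dplyr::case_when(
        .data$count_over > 0 & .data$count_under > 0 ~ "shared",
        .data$count_over > 0 ~ "over_only",
        TRUE ~ "under_only"
      )
    ) |>
    arrange(desc(.data$count_over + .data$count_under), .data$go_id)
  if (!is.null(term_names)) {
    out <- left_join(out, term_names, by = "go_id") |>
      relocate("term_name", .after = "go_id")
  }
  out
}

#' Hypergeometric GO term enrichment
#'
#' Tests, for every term annotating the study set, whether the term is
#' over-represented relative to a population: with `N` population
#' proteins of which `K` carry the term, and `n` study proteins of which
#' `k` carry it, the p-value is the upper hypergeometric tail
#' `P(X >= k)`. Multiplicity correction over the tested terms is
#' Benjamini-Hochberg by default.
#'
#' @param study Character vector of study-set accessions (must be a
#'   subset of `population`).
#' @param population Character vector of population accessions.
#' @param map Annotation map tibble.
#' @param correction `"BH"`, `"bonferroni"` or `"none"`.
#' @param term_names Optional term-name tibble.
#' @return A tibble with columns `go_id`, `k`, `n`, `K`, `N`, `p_value`,
#'   `q_value`, sorted by increasing p-value.
#' @examples
#' map <- read_annotation_tsv(scquant_example("synthetic_go_cc_map.tsv"))
#' enrich_terms(c("21735621", "75709200"), unique(map$accession), map)
#' @export
enrich_terms <- function(study, population, map,
                         correction = c("BH", "bonferroni", "none"),
                         term_names = NULL) {
  correction <- match.arg(correction)
  study <- unique(as.character(study))
  population <- unique(as.character(population))
  if (!all(study %in% population)) {
    stop_validation("Study set must be a subset of the population.")
  }
  ann <- map |>
    filter(.data$accession %in% population) |>
    distinct(.data$accession, .data$go_id)
  N <- length(population)
  n <- length(study)
  terms <- ann |>
    group_by(.data$go_id) |>
    summarise(
      K = dplyr::n_distinct(.data$accession),
      k = dplyr::n_distinct(intersect(.data$accession, study)),
      .groups = "drop"
    ) |>
    filter(.data$k > 0)
  out <- terms |>
    mutate(
      n = n, N = N,
      p_value = phyper(.data$k - 1, .data$K, N - .data$K, n, lower.tail = FALSE),
      q_value = switch(correction,
        BH = p.adjust(.data$p_value, method = "BH"),
        bonferroni = p.adjust(.data$p_value, method = "bonferroni"),
        none = .data$p_value
      )
    ) |>
    select("go_id", "k", "n", "K", "N", "p_value", "q_value") |>
    arrange(.data$p_value, .data$go_id)
  if (!is.null(term_names)) {
    out <- left_join(out, term_names, by = "go_id") |>
      relocate("term_name", .after = "go_id")
  }
  out
}
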