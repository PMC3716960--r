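#' Read an accession synonym map
#'
#' A two-column (plus optional note) tab-separated table mapping alias
#' accessions to the canonical accession used in the consolidated
#' quantification table. Needed when the two groups' identification
#' tables report different isoforms of the same gene under different
#' accessions (e.g. pyruvate kinase muscle isoforms M1/M2).
#'
#' @param path Path to a TSV with columns `alias` and `canonical`.
#' @return A tibble with character columns `alias`, `canonical`.
#' @examples
#' read_synonym_map(scquant_example("accession_synonyms.tsv"))
#' @export
read_synonym_map <- function(path) {
  if (!file.exists(path)) stop_config(paste0("File not found: ", path))
  df <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()))
  for (col in c("alias", "canonical")) {
    if (!col %in% names(df)) stop_config(paste0("Synonym map is missing column '", col, "'."))
  }
  df[, intersect(c("alias", "canonical", "note"), names(df))]
}

#' Resolve accessions through a synonym map
#'
#' Follows alias -> canonical chains to a fixed point; a cyclic map is a
#' configuration error.
#'
#' @param accessions Character vector.
#' @param synonym_map Tibble from [read_synonym_map()], or `NULL` for the
#'   identity mapping.
#' @return Character vector of canonical accessions.
#' @export
resolve_synonyms <- function(accessions, synonym_map = NULL) {
  accessions <- as.character(accessions)
  if (is.null(synonym_map) || nrow(synonym_map) == 0) {
    return(accessions)
  }
  lut <- setNames(as.character(synonym_map$canonical), as.character(synonym_map$alias))
  out <- accessions
  for (step in seq_len(length(lut) + 1)) {
    nxt <- if_else(out %in% names(lut), unname(lut[out]), out)
    if (identical(nxt, out)) {
      return(out)
    }
    out <- nxt
  }
  stop_config("Synonym map contains a cycle.")
}

#' Consolidate the accessions of two identification tables
#'
#' Harmonizes accessions via a synonym map and reports, for the union of
#' proteins, which are shared between the groups and which are exclusive
#' to one. This mirrors how per-group search reports are merged into a
#' single two-group quantification table.
#'
#' @param table_a,table_b Identification tables (anything with an
#'   `accession` column, e.g. from [read_identification_table()]), or
#'   bare character vectors of accessions.
#' @param synonym_map Optional synonym map (see [read_synonym_map()]).
#' @return A tibble with columns `accession`, `in_a`, `in_b` (logical)
#'   and `status` in `"shared"`, `"a_only"`, `"b_only"`.
#' @export
consolidate_groups <- function(table_a, table_b, synonym_map = NULL) {
  acc <- function(x) if (is.data.frame(x)) as.character(x$accession) else as.character(x)
  a <- unique(resolve_synonyms(acc(table_a), synonym_map))
  b <- unique(resolve_synonyms(acc(table_b), synonym_map))
  all <- sort(union(a, b))
  tibble(
    accession = all,
    in_a = all %in% a,
    in_b = all %in% b,
    status = dplyr::case_when(
      all %in% a & all %in% b ~ "shared",
      all %in% a ~ "a_only",
      TRUE ~ "b_only"
    )
  )
}
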