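#' Path to a bundled example data file
#'
#' The package ships a worked example dataset: a 74-protein two-group
#' spectral-count table from a shotgun (LC-MS/MS) study of human sperm
#' proteins in pooled semen samples with high versus physiological levels of
#' reactive oxygen species (ROS+ / ROS-), together with the per-group
#' protein identification tables, an accession synonym map used to
#' harmonize isoform accessions between the groups, and a small
#' synthetic GO cellular-component map constructed for documentation
#' and tests.
#'
#' @param file File name within the package's `extdata` directory. If
#'   missing, all available example files are listed.
#' @return A file path (or a character vector of file names).
#' @examples
#' scquant_example()
#' scquant_example("two_group_spectral_counts.tsv")
#' @export
scquant_example <- function(file = NULL) {
  if (is.null(file)) {
    return(dir(system.file("extdata", package = "scquant")))
  }
  path <- system.file("extdata", file, package = "scquant")
  if (!nzchar(path)) stop_config(paste0("No example file '", file, "' in scquant."))
  path
}

#' Build a validated two-group spectral-count table
#'
#' Coerces a data frame to the canonical spectral-count layout used
#' throughout the package: one row per protein with columns `accession`,
#' `gene_symbol`, optionally `protein_name`, and the integer spectral
#' counts `sc_a` and `sc_b` for the two sample groups. Group display
#' labels (defaults `"ROS-"` / `"ROS+"`) are carried as attributes.
#'
#' @param df Data frame with at least `accession`, `sc_a` and `sc_b`.
#' @param group_a_label,group_b_label Display labels for the two groups.
#' @return A tibble of class `quant_tbl`.
#' @export
quant_table <- function(df, group_a_label = "ROS-", group_b_label = "ROS+") {
  df <- as_tibble(df)
  for (col in c("accession", "sc_a", "sc_b")) {
    if (!col %in% names(df)) stop_config(paste0("Missing required column '", col, "'."))
  }
  df$accession <- as.character(df$accession)
  if (anyDuplicated(df$accession)) {
    dup <- unique(df$accession[duplicated(df$accession)])
    stop_validation(paste0("Duplicate accession(s): ", paste(dup, collapse = ", "), "."))
  }
  if (any(!nzchar(df$accession)) || anyNA(df$accession)) {
    stop_validation("Empty accession identifier.")
  }
  check_count_col(df$sc_a, "sc_a")
  check_count_col(df$sc_b, "sc_b")
  df$sc_a <- as.integer(df$sc_a)
  df$sc_b <- as.integer(df$sc_b)
  if (!"gene_symbol" %in% names(df)) df$gene_symbol <- NA_character_
  df <- relocate(df, "accession", "gene_symbol")
  structure(df,
    class = c("quant_tbl", class(df)),
    group_a_label = group_a_label, group_b_label = group_b_label
  )
}

#' Per-group total spectral counts of a quant table
#'
#' Totals are always recomputed from the count columns, never trusted
#' from file metadata.
#'
#' @param x A `quant_tbl` (or any data frame with `sc_a`, `sc_b`).
#' @return Named integer vector `c(total_a, total_b)`.
#' @export
group_totals <- function(x) {
  c(total_a = sum(as.integer(x$sc_a)), total_b = sum(as.integer(x$sc_b)))
}

group_labels <- function(x) {
  c(
    a = attr(x, "group_a_label") %||% "ROS-",
    b = attr(x, "group_b_label") %||% "ROS+"
  )
}

#' Read a two-group spectral-count table
#'
#' Reads a tab-delimited table of per-protein spectral counts for two
#' pooled groups. The reader accepts either the package's own dialect
#' (columns `sc_a` / `sc_b`) or any header with exactly two columns whose
#' names start with `sc_` (taken in order of appearance as group A then
#' group B; in the bundled dataset `sc_ros_minus` then `sc_ros_plus`).
#' Pre-computed NSC or ratio columns — including textual exclusivity
#' cells such as `"ROS+ only"` — are tolerated and ignored: all derived
#' quantities are recomputed from the raw counts.
#'
#' @param path Path to a tab-separated file with a header row.
#' @param group_a_label,group_b_label Display labels for the two groups.
#' @return A `quant_tbl` tibble (see [quant_table()]).
#' @examples
#' counts <- read_quant_table(scquant_example("two_group_spectral_counts.tsv"))
#' nrow(counts)
#' group_totals(counts)
#' @export
read_quant_table <- function(path, group_a_label = "ROS-", group_b_label = "ROS+") {
  if (!file.exists(path)) stop_config(paste0("File not found: ", path))
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()))
  if (!"accession" %in% names(raw)) stop_config("Missing required column 'accession'.")
  if (all(c("sc_a", "sc_b") %in% names(raw))) {
    sc_cols <- c("sc_a", "sc_b")
  } else {
    sc_cols <- grep("^sc_", names(raw), value = TRUE)
    if (length(sc_cols) != 2) {
      stop_config("Expected exactly two spectral-count columns (prefix 'sc_').")
    }
  }
  keep <- intersect(c("accession", "gene_symbol", "protein_name"), names(raw))
  df <- raw[, keep, drop = FALSE]
  df$sc_a <- suppressWarnings(as.numeric(raw[[sc_cols[1]]]))
  df$sc_b <- suppressWarnings(as.numeric(raw[[sc_cols[2]]]))
  quant_table(df, group_a_label = group_a_label, group_b_label = group_b_label)
}

#' Write a two-group spectral-count table
#'
#' Writes the package dialect (`accession`, `gene_symbol`, optional
#' `protein_name`, `sc_a`, `sc_b`) so that [read_quant_table()] round-trips
#' counts and accessions exactly.
#'
#' @param x A `quant_tbl`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_quant_table <- function(x, path) {
  keep <- intersect(c("accession", "gene_symbol", "protein_name", "sc_a", "sc_b"), names(x))
  readr::write_tsv(as_tibble(x)[, keep], path)
  invisible(path)
}

#' Read a protein identification table
#'
#' Reads the tab-delimited per-group protein identification tables of a
#' database-search report: protein name, accession (NCBI GI-style),
#' calculated molecular weight (kDa), isoelectric point, an LTQ peptide
#' cell of the form `"34 (54%)"` combining peptide count and percent
#' sequence coverage, and the Mascot search score.
#'
#' @param path Path to a tab-separated file with a header row.
#' @param dialect Optional named character vector remapping the expected
#'   column names (`protein_name`, `accession`, `mw_kda`, `pi`,
#'   `peptides`, `mascot_score`) to the names used in the file, e.g.
#'   `c(accession = "NCBI")`.
#' @return A tibble with columns `accession`, `protein_name`, `mw_kda`,
#'   `pi`, `peptide_count`, `coverage_pct`, `mascot_score`.
#' @examples
#' ids <- read_identification_table(scquant_example("ros_pos_identifications.tsv"))
#' ids[1, c("accession", "peptide_count", "coverage_pct")]
#' @export
read_identification_table <- function(path, dialect = NULL) {
  if (!file.exists(path)) stop_config(paste0("File not found: ", path))
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()))
  expected <- c("protein_name", "accession", "mw_kda", "pi", "peptides", "mascot_score")
  cols <- setNames(expected, expected)
  if (!is.null(dialect)) cols[names(dialect)] <- unname(dialect)
  missing <- cols[!cols %in% names(raw)]
  if (length(missing)) {
    stop_config(paste0(
      "Missing column(s) in identification table: ",
      paste(missing, collapse = ", "), "."
    ))
  }
  df <- tibble(
    accession = as.character(raw[[cols[["accession"]]]]),
    protein_name = raw[[cols[["protein_name"]]]]
  )
  num_field <- function(field) {
    x <- suppressWarnings(as.numeric(raw[[cols[[field]]]]))
    bad <- which(is.na(x) & !is.na(raw[[cols[[field]]]]))
    if (length(bad)) {
      stop_parse(paste0("Non-numeric value in column '", cols[[field]], "', row ", bad[1], "."))
    }
    x
  }
  df$mw_kda <- num_field("mw_kda")
  df$pi <- num_field("pi")
  df$mascot_score <- num_field("mascot_score")
  pep <- parse_peptide_cell(raw[[cols[["peptides"]]]])
  df$peptide_count <- pep$peptide_count
  df$coverage_pct <- pep$coverage_pct
  if (anyDuplicated(df$accession)) {
    dup <- unique(df$accession[duplicated(df$accession)])
    stop_validation(paste0("Duplicate accession(s): ", paste(dup, collapse = ", "), "."))
  }
  validate_identifications(df)
  df[, c(
    "accession", "protein_name", "mw_kda", "pi",
    "peptide_count", "coverage_pct", "mascot_score"
  )]
}

# "34 (54%)" -> peptide_count 34, coverage_pct 54 (tolerates "11(24%)")
parse_peptide_cell <- function(x) {
  m <- stringr::str_match(x, "^\\s*(\\d+)\\s*\\(\\s*(\\d+(?:\\.\\d+)?)\\s*%\\s*\\)\\s*$")
  bad <- which(is.na(m[, 1]) & !is.na(x))
  if (length(bad)) {
    stop_parse(paste0("Cannot parse peptide cell '", x[bad[1]], "', row ", bad[1], "."))
  }
  list(
    peptide_count = as.integer(m[, 2]),
    coverage_pct = as.numeric(m[, 3])
  )
}

validate_identifications <- function(df) {
  if (any(df$mw_kda <= 0, na.rm = TRUE)) stop_validation("Molecular weight must be positive.")
  if (any(df$coverage_pct < 0 | df$coverage_pct > 100, na.rm = TRUE)) {
    stop_validation("Coverage percent must lie in [0, 100].")
  }
  if (any(df$peptide_count < 0, na.rm = TRUE)) stop_validation("Peptide count must be non-negative.")
  if (any(df$mascot_score < 0, na.rm = TRUE)) stop_validation("Search score must be non-negative.")
  invisible(df)
}
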