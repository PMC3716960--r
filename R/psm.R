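#' Aggregate peptide-spectrum matches to per-protein spectral counts
#'
#' The spectral count of a protein in a group is the number of
#' peptide-spectrum matches (PSMs) attributed to it. This collapses a
#' PSM-level table (one row per identified spectrum) into the two-group
#' per-protein count table the rest of the pipeline consumes; proteins
#' absent from one group receive a count of zero there.
#'
#' @param psms Data frame with columns `accession` and `sample_group`
#'   (and typically `spectrum_id`, `peptide_sequence`). At most two
#'   distinct group labels may be present.
#' @param group_labels Optional length-2 character vector fixing which
#'   label is group A and which group B (in that order). Defaults to the
#'   sorted labels found in the data, with `"ROS-"`/`"ROS+"` recognised
#'   and ordered ROS- first.
#' @return A `quant_tbl` (see [quant_table()]); empty input yields an
#'   empty table with totals (0, 0).
#' @examples
#' psms <- tibble::tibble(
#'   accession = c("P1", "P1", "P1", "P2", "P2"),
#'   sample_group = c("A", "A", "A", "A", "B")
#' )
#' aggregate_psms(psms)
#' @export
aggregate_psms <- function(psms, group_labels = NULL) {
  psms <- as_tibble(psms)
  for (col in c("accession", "sample_group")) {
    if (!col %in% names(psms)) stop_config(paste0("PSM table is missing column '", col, "'."))
  }
  found <- sort(unique(as.character(psms$sample_group)))
  if (length(found) > 2) {
    stop_validation(paste0(
      "More than two sample groups in PSM table: ",
      paste(found, collapse = ", "), "."
    ))
  }
  if (is.null(group_labels)) {
    group_labels <- if (setequal(found, c("ROS-", "ROS+"))) c("ROS-", "ROS+") else found
    if (length(group_labels) == 0) group_labels <- c("ROS-", "ROS+")
    if (length(group_labels) == 1) group_labels <- c(group_labels, NA_character_)
  }
  if (!all(found %in% group_labels)) {
    stop_validation("PSM group labels do not match the requested group_labels.")
  }
  wide <- psms |>
    count(accession = as.character(.data$accession), .data$sample_group) |>
    tidyr::pivot_wider(
      names_from = "sample_group", values_from = "n",
      values_fill = 0L
    )
  for (lab in group_labels) {
    if (!is.na(lab) && !lab %in% names(wide)) wide[[lab]] <- integer(nrow(wide))
  }
  df <- tibble(
    accession = if (nrow(wide)) wide$accession else character(),
    sc_a = if (nrow(wide)) as.integer(wide[[group_labels[1]]]) else integer(),
    sc_b = if (nrow(wide) && !is.na(group_labels[2])) as.integer(wide[[group_labels[2]]]) else integer(nrow(wide))
  )
  df <- arrange(df, .data$accession)
  quant_table(df,
    group_a_label = group_labels[1] %||% "ROS-",
    group_b_label = if (is.na(group_labels[2])) "ROS+" else group_labels[2]
  )
}
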