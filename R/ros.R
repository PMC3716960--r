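#' Classify samples as ROS+ or ROS- from chemiluminescence readings
#'
#' Seminal reactive oxygen species (ROS) are measured by luminol
#' chemiluminescence and expressed in relative light units per second per
#' million sperm (RLU/s/10^6 sperm). Readings strictly above the
#' reference threshold (default 20) are classified ROS+, all others
#' ROS-; a reading exactly at the threshold is therefore ROS-.
#'
#' @param ros_rlu Numeric vector of non-negative readings.
#' @param threshold Positivity threshold in the same units (default 20).
#' @return Character vector of `"ROS+"` / `"ROS-"` labels.
#' @examples
#' classify_ros(c(2236, 4, 20))
#' @export
classify_ros <- function(ros_rlu, threshold = 20) {
  stopifnot(is.numeric(ros_rlu), length(threshold) == 1, threshold >= 0)
  if (any(ros_rlu < 0, na.rm = TRUE)) {
    stop_validation("ROS readings must be non-negative (RLU/s/10^6 sperm).")
  }
  if_else(ros_rlu > threshold, "ROS+", "ROS-")
}

#' Assign group labels to a table of ROS readings
#'
#' Data-frame wrapper around [classify_ros()]: adds a `group` column to a
#' table of per-sample readings.
#'
#' @param df Data frame with a numeric ROS reading column.
#' @param reading_col Name of that column (default `"ros_rlu"`).
#' @inheritParams classify_ros
#' @return The input as a tibble with an added `group` column.
#' @export
assign_ros_groups <- function(df, reading_col = "ros_rlu", threshold = 20) {
  if (!reading_col %in% names(df)) {
    stop_config(paste0("Missing ROS reading column '", reading_col, "'."))
  }
  mutate(as_tibble(df), group = classify_ros(.data[[reading_col]], threshold = threshold))
}
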