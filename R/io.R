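# Delimited-text table I/O. All tables are UTF-8 with a mandatory
# header; the delimiter defaults to comma.

read_table_checked <- function(path, required, what, sep = ",") {
  if (!file.exists(path))
    lc_stop(sprintf("cannot read %s: no such file '%s'", what, path), "io")
  df <- utils::read.csv(path, sep = sep, fileEncoding = "UTF-8")
  missing <- setdiff(required, names(df))
  if (length(missing))
    lc_stop(sprintf("%s '%s' lacks required column(s): %s",
                    what, path, paste(missing, collapse = ", ")),
            "schema")
  df
}

#' Read a sensor-readings table
#'
#' Delimited text with required columns
#' `sample_id, replicate, r_raw, g_raw, b_raw, c_raw`.
#'
#' @param path File path.
#' @param sep Field delimiter (default comma).
#' @return Data frame of readings.
#' @export
read_readings_table <- function(path, sep = ",") {
  read_table_checked(path, c("sample_id", "replicate", channel_names()),
                     "readings table", sep)
}

#' Read a calibration table
#'
#' A readings-or-features table paired with reference contents:
#' required columns are the 20 canonical feature columns (or the four
#' raw channels, from which features are completed automatically) plus
#' `cla_mg_g, clb_mg_g, tcl_mg_g, crop`. An optional `spad` column
#' supports single-index baselines.
#'
#' @inheritParams read_readings_table
#' @return Data frame with the full 20-feature schema plus references.
#' @export
read_calibration_table <- function(path, sep = ",") {
  df <- read_table_checked(path,
                           c("sample_id", "cla_mg_g", "clb_mg_g",
                             "tcl_mg_g", "crop"),
                           "calibration table", sep)
  if (!all(feature_names() %in% names(df))) {
    if (!all(channel_names() %in% names(df)))
      lc_stop("calibration table needs either the 20 feature columns or the 4 raw channel columns",
              "schema")
    df <- complete_features(df)
  }
  df
}

#' Complete the 20 feature columns from the raw channel columns
#'
#' @param df Data frame with `r_raw, g_raw, b_raw, c_raw` columns.
#' @return The same data frame with all 20 canonical feature columns.
#' @export
complete_features <- function(df) {
  feats <- do.call(rbind, lapply(seq_len(nrow(df)), function(i) {
    unclass(extract_features(as_sensor_reading(df[i, ])))
  }))
  for (nm in setdiff(feature_names(), channel_names()))
    df[[nm]] <- feats[, nm]
  df
}

#' Write a feature table
#'
#' `sample_id` plus the 20 canonical feature columns in fixed order.
#'
#' @param features Data frame with `sample_id` and the feature columns.
#' @param path Output path.
#' @export
write_features_table <- function(features, path) {
  utils::write.csv(features[c("sample_id", feature_names())], path,
                   row.names = FALSE)
  invisible(path)
}
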