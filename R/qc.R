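# Instrument QC: repeatability (replicate measurements on one spot) and
# stability (repeated measurements across a day) summarized per channel
# as mean, SD and coefficient of variation.
#
# All CVs use the population (divide-by-n) standard deviation: that is
# the convention that reproduces the instrument validation tables this
# package ships as example data.

pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Coefficient of variation of a measurement series
#'
#' `100 * population SD / mean`, in percent.
#'
#' @param values Non-empty numeric vector with non-zero mean.
#' @return CV in percent.
#' @export
#' @examples
#' cv_percent(c(69.2, 71.0, 70.0, 70.0))
cv_percent <- function(values) {
  if (length(values) == 0) lc_stop("empty measurement series", "empty_input")
  m <- mean(values)
  if (m == 0) lc_stop("CV undefined for zero-mean series", "undefined_cv")
  100 * pop_sd(values) / m
}

#' Coefficient of variation from a printed mean and SD
#'
#' `100 * sd / mean`. For checking tabulated summaries only: published
#' SDs are typically rounded, so CVs recomputed this way can disagree
#' in the last digit with CVs computed from the raw replicates.
#'
#' @param mean Mean (non-zero).
#' @param sd Standard deviation (>= 0).
#' @return CV in percent.
#' @export
#' @examples
#' cv_from_summary(19.2, 0.4)
cv_from_summary <- function(mean, sd) {
  if (any(mean == 0)) lc_stop("CV undefined for zero mean", "undefined_cv")
  if (any(sd < 0)) lc_stop("sd must be non-negative", "parameter")
  100 * sd / mean
}

new_qc_report <- function(per_group, kind) {
  structure(list(per_group = per_group,
                 overall_mean_cv = mean(per_group$cv_percent),
                 kind = kind),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report> %s: %d group x channel cells, mean CV %.3f%%\n",
              x$kind, nrow(x$per_group), x$overall_mean_cv))
  print(utils::head(x$per_group, 12), row.names = FALSE)
  if (nrow(x$per_group) > 12) cat("...\n")
  invisible(x)
}

#' Repeatability report from replicate readings
#'
#' Per-sample, per-channel mean, SD and CV for replicate measurements
#' on the same leaf spot, plus the overall mean CV (arithmetic mean of
#' all sample x channel CV cells). CVs are computed from the raw
#' replicates, never from rounded summaries.
#'
#' @param readings Data frame with columns `sample_id`, the four raw
#'   channels, and (optionally) `replicate`; at least 2 replicates per
#'   sample.
#' @return Object of class `"qc_report"` with `per_group`
#'   (`sample_id, channel, mean, sd, cv_percent`) and
#'   `overall_mean_cv`.
#' @export
repeatability_report <- function(readings) {
  need <- c("sample_id", channel_names())
  if (!all(need %in% names(readings)))
    lc_stop(sprintf("readings table lacks column(s): %s",
                    paste(setdiff(need, names(readings)), collapse = ", ")),
            "schema")
  counts <- table(readings$sample_id)
  if (any(counts < 2))
    lc_stop("each sample needs at least 2 replicates", "insufficient_replicates")
  groups <- split(readings, readings$sample_id)
  per <- do.call(rbind, lapply(names(groups), function(sid) {
    g <- groups[[sid]]
    do.call(rbind, lapply(channel_names(), function(ch) {
      x <- g[[ch]]
      data.frame(sample_id = sid, channel = ch, mean = mean(x),
                 sd = pop_sd(x), cv_percent = cv_percent(x))
    }))
  }))
  new_qc_report(per, "repeatability")
}

#' Stability report from per-timepoint channel means
#'
#' CV of each channel's mean value across timepoints (e.g. morning to
#' evening measurements of reference color cards), quantifying drift of
#' the instrument over a day. Environmental columns such as temperature
#' or humidity are carried as annotation and ignored.
#'
#' @param timepoint_means Data frame with a `timepoint` column and the
#'   four raw channel columns, one row per timepoint; at least 2 rows.
#' @return Object of class `"qc_report"`; `per_group` has one row per
#'   channel with `timepoint = "all"`.
#' @export
stability_report <- function(timepoint_means) {
  need <- channel_names()
  if (!all(need %in% names(timepoint_means)))
    lc_stop(sprintf("timepoint table lacks column(s): %s",
                    paste(setdiff(need, names(timepoint_means)),
                          collapse = ", ")),
            "schema")
  if (nrow(timepoint_means) < 2)
    lc_stop("need at least 2 timepoints", "insufficient_data")
  per <- do.call(rbind, lapply(channel_names(), function(ch) {
    x <- timepoint_means[[ch]]
    data.frame(sample_id = "all", channel = ch, mean = mean(x),
               sd = pop_sd(x), cv_percent = cv_percent(x))
  }))
  new_qc_report(per, "stability")
}
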