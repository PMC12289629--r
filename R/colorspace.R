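# Color-feature extraction from raw four-channel sensor readings.
#
# The sensor reports broadband ("clear", C) plus filtered red/green/blue
# intensities. Normalized indices rescale each filtered channel by the
# clear channel onto a 0-255 scale; HSV and ten ratio/product indices are
# derived from the normalized triple.

#' Canonical channel and feature names
#'
#' The fixed, ordered vocabulary of the package: four raw channels, three
#' clear-normalized indices, three HSV indices, and ten ratio/product
#' combinations — twenty features in all. All tables, models and feature
#' vectors use these names in this order.
#'
#' @return Character vector of names.
#' @export
#' @examples
#' feature_names()
channel_names <- function() c("r_raw", "g_raw", "b_raw", "c_raw")

#' @rdname channel_names
#' @export
feature_names <- function() {
  c(channel_names(),
    "r", "g", "b",
    "h", "s", "v",
    "r_over_b", "r_over_g", "g_over_r", "g_over_b", "b_over_r", "b_over_g",
    "r_times_g", "r_times_b", "g_times_b", "r_times_g_times_b")
}

#' Construct a validated sensor reading
#'
#' One raw measurement from the four-channel color sensor. Channel
#' intensities are in counts/uW/cm2; all four must be finite and
#' non-negative. A positive clear channel is required only when the
#' reading is normalized, so it is checked there, not here.
#'
#' @param r_raw,g_raw,b_raw,c_raw Raw channel intensities (counts/uW/cm2).
#' @return Named numeric vector of class `"sensor_reading"`.
#' @export
#' @examples
#' sensor_reading(27.9, 27.0, 18.8, 80.9)
sensor_reading <- function(r_raw, g_raw, b_raw, c_raw) {
  x <- c(r_raw = as.numeric(r_raw), g_raw = as.numeric(g_raw),
         b_raw = as.numeric(b_raw), c_raw = as.numeric(c_raw))
  if (length(x) != 4L || anyNA(x) || any(!is.finite(x)))
    lc_stop("all four channel intensities must be finite numbers",
            "invalid_reading")
  if (any(x < 0))
    lc_stop("channel intensities must be non-negative", "invalid_reading")
  structure(x, class = "sensor_reading")
}

as_sensor_reading <- function(x) {
  if (inherits(x, "sensor_reading")) return(x)
  x <- unlist(x)
  if (!all(channel_names() %in% names(x)))
    lc_stop("a sensor reading needs r_raw, g_raw, b_raw and c_raw",
            "invalid_reading")
  sensor_reading(x[["r_raw"]], x[["g_raw"]], x[["b_raw"]], x[["c_raw"]])
}

#' Normalize filtered channels by the clear channel
#'
#' Each filtered channel is divided by the clear channel and scaled to
#' 0-255: `r = r_raw / c_raw * 255`, likewise for g and b. No rounding is
#' applied; values can exceed 255 only if a filtered channel exceeds the
#' clear channel (not physical for this sensor, but not forbidden here).
#'
#' @param reading A [sensor_reading()] (or coercible named vector).
#' @return Named numeric vector `c(r =, g =, b =)`.
#' @export
#' @examples
#' normalize_channels(sensor_reading(27.9, 27.0, 18.8, 80.9))
normalize_channels <- function(reading) {
  reading <- as_sensor_reading(reading)
  if (reading[["c_raw"]] <= 0)
    lc_stop("clear channel must be > 0 to normalize", "invalid_reading")
  out <- reading[c("r_raw", "g_raw", "b_raw")] / reading[["c_raw"]] * 255
  names(out) <- c("r", "g", "b")
  unclass(out)
}

#' Convert normalized RGB indices to HSV
#'
#' Standard hexcone conversion. Hue is in degrees on `[0, 360)`,
#' saturation and value on `[0, 1]` (value is `max(r, g, b) / 255`).
#' Achromatic inputs (max = min, including all-zero) get h = 0 and s = 0
#' by convention. Hue and saturation are computed with
#' [grDevices::rgb2hsv()]; value is taken against the fixed 255 full
#' scale so that inputs above 255 simply yield v > 1.
#'
#' @param r,g,b Normalized color indices (non-negative; nominally 0-255).
#' @return Named numeric vector `c(h =, s =, v =)`.
#' @export
#' @examples
#' to_hsv(255, 0, 0)       # pure red: h = 0, s = 1, v = 1
#' to_hsv(100, 100, 100)   # grey: s = 0
to_hsv <- function(r, g, b) {
  x <- c(r, g, b)
  if (anyNA(x) || any(!is.finite(x)) || any(x < 0))
    lc_stop("normalized indices must be finite and non-negative",
            "invalid_reading")
  mx <- max(x)
  if (mx <= 0) return(c(h = 0, s = 0, v = 0))
  # rgb2hsv needs inputs within [0, maxColorValue]; h and s are
  # scale-invariant so the adaptive full scale only affects its v,
  # which we discard in favor of the fixed-scale definition.
  hs <- grDevices::rgb2hsv(matrix(x, nrow = 3), maxColorValue = mx)
  h <- hs["h", 1] * 360
  if (h >= 360) h <- 0
  c(h = unname(h), s = unname(hs["s", 1]), v = mx / 255)
}

#' Ratio and product color indices
#'
#' The ten pairwise/triple combinations of the normalized indices, in
#' canonical order: R/B, R/G, G/R, G/B, B/R, B/G, R*G, R*B, G*B, R*G*B.
#' A zero denominator raises an error naming the undefined feature:
#' real leaf readings never have a zero channel, and a silent NaN would
#' corrupt downstream calibration matrices.
#'
#' @inheritParams to_hsv
#' @return Named numeric vector of the ten indices.
#' @export
#' @examples
#' derived_indices(87.94, 85.10, 59.26)
derived_indices <- function(r, g, b) {
  x <- c(r, g, b)
  if (anyNA(x) || any(!is.finite(x)) || any(x < 0))
    lc_stop("normalized indices must be finite and non-negative",
            "invalid_reading")
  ratios <- list(r_over_b = c(r, b), r_over_g = c(r, g),
                 g_over_r = c(g, r), g_over_b = c(g, b),
                 b_over_r = c(b, r), b_over_g = c(b, g))
  for (nm in names(ratios)) {
    if (ratios[[nm]][2] == 0)
      lc_stop(sprintf("feature '%s' is undefined: zero denominator", nm),
              "undefined_feature")
  }
  c(vapply(ratios, function(p) p[1] / p[2], numeric(1)),
    r_times_g = r * g, r_times_b = r * b, g_times_b = g * b,
    r_times_g_times_b = r * g * b)
}

#' Extract the canonical 20-feature color vector
#'
#' Composes [normalize_channels()], [to_hsv()] and [derived_indices()]
#' into the fixed-order feature vector used by the prediction models and
#' the calibration workflow: the four raw channels carried through, the
#' three normalized indices, HSV, and the ten combinations.
#'
#' @inheritParams normalize_channels
#' @return Named numeric vector of length 20, class `"color_features"`.
#' @export
#' @examples
#' extract_features(sensor_reading(27.9, 27.0, 18.8, 80.9))
extract_features <- function(reading) {
  reading <- as_sensor_reading(reading)
  rgb <- normalize_channels(reading)
  out <- c(unclass(reading), rgb,
           to_hsv(rgb[["r"]], rgb[["g"]], rgb[["b"]]),
           derived_indices(rgb[["r"]], rgb[["g"]], rgb[["b"]]))
  stopifnot(identical(names(out), feature_names()))
  structure(out, class = "color_features")
}

#' Average replicate readings channel-wise
#'
#' Replicate measurements of one sample are averaged on the raw channels
#' first; features are then extracted once from the mean reading. (The
#' alternative — extracting features per replicate and averaging those —
#' is not equivalent for the nonlinear features.)
#'
#' @param readings Non-empty list of [sensor_reading()]s (or a data frame
#'   with the four channel columns, one row per replicate).
#' @return A single [sensor_reading()].
#' @export
#' @examples
#' average_replicates(list(sensor_reading(10, 10, 10, 30),
#'                         sensor_reading(30, 10, 10, 30)))
average_replicates <- function(readings) {
  if (is.data.frame(readings)) {
    readings <- lapply(seq_len(nrow(readings)),
                       function(i) as_sensor_reading(readings[i, ]))
  }
  if (length(readings) == 0)
    lc_stop("no readings to average", "empty_input")
  m <- colMeans(do.call(rbind, lapply(readings, as_sensor_reading)))
  sensor_reading(m[["r_raw"]], m[["g_raw"]], m[["b_raw"]], m[["c_raw"]])
}
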