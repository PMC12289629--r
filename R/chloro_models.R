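# Calibrated linear prediction models for chlorophyll content.
#
# The shipped defaults are the device's five-feature models: content is
# an affine function of the normalized blue index (b), the raw blue
# channel (b_raw), hue (h, degrees), saturation (s) and value (v). Note
# the two "blue" predictors are distinct: b is clear-normalized on the
# 0-255 scale, b_raw is the raw channel intensity.

#' Construct a linear chlorophyll prediction model
#'
#' An intercept plus named feature coefficients, predicting one of the
#' three chlorophyll targets in mg/g fresh leaf. Coefficient names must
#' come from the canonical feature set (see [feature_names()]) unless
#' `allow_extra` is set, which admits auxiliary predictors such as a
#' SPAD column for baseline comparisons.
#'
#' @param target One of `"chlorophyll_a"`, `"chlorophyll_b"`,
#'   `"total_chlorophyll"`.
#' @param intercept Numeric intercept (mg/g).
#' @param coefficients Named numeric vector, feature name -> weight.
#' @param feature_order Evaluation order; defaults to coefficient names.
#' @param metadata Free-form provenance text.
#' @param allow_extra Permit coefficient names outside the canonical set.
#' @return Object of class `"chloro_model"`.
#' @export
#' @examples
#' linear_model("chlorophyll_a", 0, c(b = 1))
linear_model <- function(target, intercept, coefficients,
                         feature_order = names(coefficients),
                         metadata = "", allow_extra = FALSE) {
  target <- match.arg(target, chlorophyll_targets())
  coefficients <- unlist(coefficients)
  if (is.null(names(coefficients)) || any(!nzchar(names(coefficients))))
    lc_stop("coefficients must be named", "invalid_model")
  if (!allow_extra && !all(names(coefficients) %in% feature_names()))
    lc_stop(sprintf("unknown feature name(s): %s",
                    paste(setdiff(names(coefficients), feature_names()),
                          collapse = ", ")),
            "invalid_model")
  if (anyDuplicated(feature_order) ||
      !setequal(feature_order, names(coefficients)))
    lc_stop("feature_order must cover exactly the coefficient names",
            "invalid_model")
  structure(list(target = target,
                 intercept = as.numeric(intercept),
                 coefficients = coefficients[feature_order],
                 feature_order = feature_order,
                 metadata = metadata),
            class = "chloro_model")
}

#' @rdname linear_model
#' @export
chlorophyll_targets <- function() {
  c("chlorophyll_a", "chlorophyll_b", "total_chlorophyll")
}

#' The device's default five-feature prediction models
#'
#' Returns the three calibrated models (chlorophyll-a, chlorophyll-b,
#' total chlorophyll), each an affine function of the features
#' `b, b_raw, h, s, v`. The coefficients are fixed constants of the
#' device firmware. Their structure is nearly additive: the
#' total-chlorophyll coefficients equal the a + b sums exactly on
#' h, s, v and the intercept, and differ by 0.001 on b and b_raw
#' (third-decimal rounding of the published fits).
#'
#' @return Named list of three [linear_model()] objects.
#' @export
#' @examples
#' m <- default_models()
#' predict(m$chlorophyll_a, c(b = 0, b_raw = 0, h = 0, s = 0, v = 0))
default_models <- function() {
  mk <- function(target, intercept, b, b_raw, h, s, v) {
    linear_model(target, intercept,
                 c(b = b, b_raw = b_raw, h = h, s = s, v = v),
                 metadata = "device default five-feature model")
  }
  list(
    chlorophyll_a = mk("chlorophyll_a", -30.623,
                       1.143, -0.225, 0.008, 85.096, -170.899),
    chlorophyll_b = mk("chlorophyll_b", -13.164,
                       0.467, -0.052, 0.005, 35.536, -72.08),
    total_chlorophyll = mk("total_chlorophyll", -43.787,
                           1.609, -0.276, 0.013, 120.632, -242.979)
  )
}

#' Evaluate a linear model on a feature vector
#'
#' `intercept + sum(coefficient * feature)` over the model's features.
#' All features the model names must be present in `newdata`.
#'
#' @param object A [linear_model()].
#' @param newdata Named numeric vector (e.g. a [extract_features()]
#'   result) or a data frame with one column per feature, in which case
#'   one prediction per row is returned.
#' @param ... Unused.
#' @return Numeric prediction(s), mg/g.
#' @export
predict.chloro_model <- function(object, newdata, ...) {
  need <- object$feature_order
  if (is.data.frame(newdata)) {
    if (!all(need %in% names(newdata)))
      lc_stop(sprintf("model needs feature(s) missing from data: %s",
                      paste(setdiff(need, names(newdata)), collapse = ", ")),
              "model_mismatch")
    x <- as.matrix(newdata[need])
    return(drop(object$intercept + x %*% object$coefficients[need]))
  }
  newdata <- unlist(newdata)
  if (!all(need %in% names(newdata)))
    lc_stop(sprintf("model needs feature(s) missing from input: %s",
                    paste(setdiff(need, names(newdata)), collapse = ", ")),
            "model_mismatch")
  object$intercept + sum(object$coefficients[need] * newdata[need])
}

#' @export
print.chloro_model <- function(x, ...) {
  terms <- paste(sprintf("%+.3f*%s", x$coefficients, x$feature_order),
                 collapse = " ")
  cat(sprintf("<chloro_model> %s = %.3f %s (mg/g)\n",
              x$target, x$intercept, terms))
  invisible(x)
}

#' Default plausibility window for predictions
#'
#' The device flags a measurement as a detection error when a predicted
#' content is physically implausible. The defaults — any negative
#' content, or total chlorophyll above 6 mg/g — bracket the contents
#' observed on wheat and maize leaves (total chlorophyll up to
#' ~4.9 mg/g) with headroom.
#'
#' @return List with elements `lower` (mg/g, applied to all three
#'   contents) and `tcl_upper` (mg/g, total chlorophyll only).
#' @export
plausibility_window <- function() list(lower = 0, tcl_upper = 6)

#' Predict all three chlorophyll contents with the abnormality guard
#'
#' Evaluates the chlorophyll-a, chlorophyll-b and total-chlorophyll
#' models on one feature vector and applies the plausibility guard:
#' status is `"detection_error"` when any content falls outside the
#' window, `"ok"` otherwise. Abnormality is a status, never an error.
#'
#' @param features Named numeric vector covering the models' features.
#' @param models List of three models as from [default_models()].
#' @param window Plausibility window, see [plausibility_window()].
#' @return List of class `"chloro_estimate"` with `cla`, `clb`, `tcl`
#'   (mg/g, full precision) and `status`.
#' @export
#' @examples
#' predict_all(extract_features(sensor_reading(27.9, 27.0, 18.8, 80.9)))
predict_all <- function(features, models = default_models(),
                        window = plausibility_window()) {
  cla <- predict(models$chlorophyll_a, features)
  clb <- predict(models$chlorophyll_b, features)
  tcl <- predict(models$total_chlorophyll, features)
  abnormal <- cla < window$lower || clb < window$lower ||
    tcl < window$lower || tcl > window$tcl_upper
  structure(list(cla = cla, clb = clb, tcl = tcl,
                 status = if (abnormal) "detection_error" else "ok"),
            class = "chloro_estimate")
}

#' @export
print.chloro_estimate <- function(x, ...) {
  # 3-decimal rounding is display-only; stored values keep full precision
  if (x$status == "ok") {
    cat(sprintf("CL-a %.3f  CL-b %.3f  TCL %.3f mg/g\n",
                x$cla, x$clb, x$tcl))
  } else {
    cat("detection error\n")
  }
  invisible(x)
}

#' Read and write model documents
#'
#' Models serialize to a small JSON document with fields `target`,
#' `intercept`, `coefficients`, `feature_order` and `metadata`. A file
#' may hold one model or a list of them. The shipped default document
#' (`system.file("extdata", "chlorophyll_models.json", package =
#' "leafchroma")`) reproduces [default_models()] coefficient-for-
#' coefficient.
#'
#' @param models A [linear_model()] or list of them.
#' @param path File path.
#' @return `read_models()` returns a named list of models.
#' @export
write_models <- function(models, path) {
  if (inherits(models, "chloro_model")) models <- list(models)
  doc <- lapply(unname(models), function(m) {
    list(target = m$target, intercept = m$intercept,
         coefficients = as.list(m$coefficients),
         feature_order = as.list(m$feature_order),
         metadata = m$metadata)
  })
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_models
#' @export
read_models <- function(path) {
  doc <- jsonlite::read_json(path)
  out <- lapply(doc, function(d) {
    linear_model(d$target, d$intercept, unlist(d$coefficients),
                 feature_order = unlist(d$feature_order),
                 metadata = d$metadata %||% "")
  })
  names(out) <- vapply(out, `[[`, character(1), "target")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
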