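# Model-building workflow: fit MLR and PLSR calibrations of chlorophyll
# content on color features, screen coefficient significance, and
# evaluate with R2 / RMSE / MAE.

target_column <- function(target) {
  c(chlorophyll_a = "cla_mg_g", chlorophyll_b = "clb_mg_g",
    total_chlorophyll = "tcl_mg_g")[[match.arg(target,
                                               chlorophyll_targets())]]
}

check_calibration_data <- function(data, target, features) {
  col <- target_column(target)
  missing <- setdiff(c(col, features), names(data))
  if (length(missing))
    lc_stop(sprintf("calibration table lacks column(s): %s",
                    paste(missing, collapse = ", ")),
            "schema")
  if (nrow(data) == 0) lc_stop("calibration table is empty", "empty_input")
  y <- data[[col]]
  if (anyNA(y) || any(!is.finite(y)))
    lc_stop("reference contents must be finite", "invalid_reference")
  col
}

#' Fit a multivariate linear regression calibration
#'
#' Ordinary least squares of one chlorophyll target on the named color
#' features, with per-coefficient two-sided t-test p-values
#' (homoscedastic, classical). R2, RMSE and MAE are fitting-set
#' statistics, not cross-validated.
#'
#' @param data Calibration table: one row per sample with the feature
#'   columns plus `cla_mg_g`, `clb_mg_g`, `tcl_mg_g` (see
#'   [read_calibration_table()]).
#' @param target One of [chlorophyll_targets()].
#' @param features Character vector of predictor column names
#'   (defaults to the full canonical 20-feature set).
#' @return List of class `"fit_result"`: `model` (a [linear_model()]),
#'   `pvalues`, `r2`, `rmse`, `mae`, `method`, `n`.
#' @export
fit_mlr <- function(data, target, features = feature_names()) {
  col <- check_calibration_data(data, target, features)
  n <- nrow(data); p <- length(features)
  if (n <= p + 1)
    lc_stop(sprintf("need more than %d samples to fit %d coefficients",
                    p + 1, p + 1), "sample_size")
  X <- as.matrix(data[features])
  if (qr(cbind(1, X))$rank < p + 1)
    lc_stop("design matrix is rank deficient (collinear features)",
            "collinearity")
  df <- data.frame(.y = data[[col]], X, check.names = FALSE)
  fit <- stats::lm(stats::reformulate(sprintf("`%s`", features), ".y"),
                   data = df)
  coefs <- stats::coef(fit)
  pv <- summary(fit)$coefficients[, "Pr(>|t|)"][-1]
  names(pv) <- features
  model <- linear_model(target, coefs[[1]],
                        stats::setNames(coefs[-1], features),
                        metadata = sprintf("MLR fit, n = %d", n),
                        allow_extra = TRUE)
  new_fit_result(model, pvalues = pv, y = df$.y,
                 yhat = stats::fitted(fit), method = "mlr", n = n)
}

new_fit_result <- function(model, pvalues, y, yhat, method, n,
                           n_components = NULL) {
  err <- y - yhat
  structure(list(model = model, pvalues = pvalues,
                 r2 = 1 - sum(err^2) / sum((y - mean(y))^2),
                 rmse = sqrt(mean(err^2)), mae = mean(abs(err)),
                 method = method, n = n, n_components = n_components),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> %s on %s: n = %d, R2 = %.3f, RMSE = %.3f, MAE = %.3f\n",
              toupper(x$method), x$model$target, x$n, x$r2, x$rmse, x$mae))
  if (!is.null(x$n_components))
    cat(sprintf("  components: %d\n", x$n_components))
  invisible(x)
}

#' Fit a partial least squares regression calibration
#'
#' PLSR of one chlorophyll target on the named features, via
#' [mixOmics::pls()] in regression mode (unscaled, centered). When
#' `n_components` is `NULL` it is chosen by leave-one-out
#' cross-validated RMSE over 1..`max_components`, ties broken toward
#' fewer components. The fitted latent-variable model is reduced to its
#' equivalent affine form, so the returned `model` is a plain
#' [linear_model()]. With as many components as (independent) features,
#' PLSR reproduces the OLS solution.
#'
#' @inheritParams fit_mlr
#' @param n_components Number of latent components, or `NULL` to select
#'   by leave-one-out cross-validation.
#' @param max_components Upper bound for the component search.
#' @return A `"fit_result"` (see [fit_mlr()]) with `n_components` set;
#'   `pvalues` is `NULL` (no classical tests for PLSR).
#' @export
fit_plsr <- function(data, target, features = feature_names(),
                     n_components = NULL, max_components = 10) {
  col <- check_calibration_data(data, target, features)
  n <- nrow(data); p <- length(features)
  kmax <- min(max_components, p, n - 1)
  if (!is.null(n_components) &&
      (n_components < 1 || n_components > min(n - 1, p)))
    lc_stop(sprintf("n_components must be in 1..%d", min(n - 1, p)),
            "parameter")
  X <- as.matrix(data[features])
  y <- data[[col]]
  if (p == 1) {
    # one centered predictor: the single PLS component spans it, so the
    # fit is ordinary least squares on that feature
    n_components <- n_components %||% 1L
    xc <- X[, 1] - mean(X[, 1])
    beta <- sum(xc * (y - mean(y))) / sum(xc^2)
    intercept <- mean(y) - beta * mean(X[, 1])
    model <- linear_model(target, intercept,
                          stats::setNames(beta, features),
                          metadata = sprintf("PLSR fit, n = %d, 1 component", n),
                          allow_extra = TRUE)
    return(new_fit_result(model, pvalues = NULL, y = y,
                          yhat = intercept + beta * X[, 1],
                          method = "plsr", n = n, n_components = 1L))
  }
  if (is.null(n_components)) {
    press <- numeric(kmax)
    for (i in seq_len(n)) {
      f <- mixOmics::pls(X[-i, , drop = FALSE], y[-i], ncomp = kmax,
                         mode = "regression", scale = FALSE)
      pr <- stats::predict(f, X[i, , drop = FALSE])$predict[1, 1, ]
      press <- press + (y[i] - pr)^2
    }
    n_components <- which.min(round(sqrt(press / n), 12))
  }
  fit <- mixOmics::pls(X, y, ncomp = n_components, mode = "regression",
                       scale = FALSE)
  beta <- stats::predict(fit, X[1, , drop = FALSE])$B.hat[, 1, n_components]
  intercept <- mean(y) - sum(colMeans(X) * beta)
  model <- linear_model(target, intercept, stats::setNames(beta, features),
                        metadata = sprintf("PLSR fit, n = %d, %d components",
                                           n, n_components),
                        allow_extra = TRUE)
  new_fit_result(model, pvalues = NULL, y = y,
                 yhat = intercept + drop(X %*% beta),
                 method = "plsr", n = n, n_components = n_components)
}

#' Screen features by coefficient significance
#'
#' Keeps features whose p-value is below `alpha`, preserving the
#' canonical feature order. Raw p-values are used; no multiple-testing
#' correction is applied in this workflow.
#'
#' @param pvalues Named numeric vector of p-values (e.g. from
#'   [fit_mlr()]).
#' @param alpha Significance threshold in (0, 1).
#' @return Character vector of retained feature names.
#' @export
#' @examples
#' select_significant(c(b = 0.001, b_raw = 0.004, h = 0.012,
#'                      s = 0.060, v = 0.087), alpha = 0.05)
select_significant <- function(pvalues, alpha = 0.05) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha > 1)
    lc_stop("alpha must be in (0, 1]", "parameter")
  # NA p-values (degenerate fits) are treated as not significant
  keep <- names(pvalues)[!is.na(pvalues) & pvalues < alpha]
  canonical <- intersect(feature_names(), keep)
  c(canonical, setdiff(keep, canonical))
}

#' Evaluate a model against reference contents
#'
#' Computes the fitting-set style metrics on arbitrary data:
#' `rmse = sqrt(mean((y - yhat)^2))`, `mae = mean(|y - yhat|)`,
#' `r2 = 1 - SSE/SST`.
#'
#' @param model A [linear_model()].
#' @param data Calibration table carrying the model's features and the
#'   reference column for `target`.
#' @param target One of [chlorophyll_targets()]; defaults to the
#'   model's own target.
#' @return List with `r2`, `rmse`, `mae`, `n`.
#' @export
evaluate_model <- function(model, data, target = model$target) {
  col <- check_calibration_data(data, target, model$feature_order)
  y <- data[[col]]
  yhat <- predict(model, data)
  err <- y - yhat
  sst <- sum((y - mean(y))^2)
  list(r2 = if (sst > 0) 1 - sum(err^2) / sst else NA_real_,
       rmse = sqrt(mean(err^2)), mae = mean(abs(err)), n = length(y))
}

#' Single-index baseline regression
#'
#' Fits a one-predictor linear calibration — e.g. a SPAD-value baseline
#' when the table carries a `spad` column — by delegating to
#' [fit_mlr()] with a single feature.
#'
#' @inheritParams fit_mlr
#' @param feature Single predictor column name.
#' @return A `"fit_result"`.
#' @export
compare_single_index <- function(data, feature, target) {
  if (length(feature) != 1)
    lc_stop("compare_single_index takes exactly one feature", "parameter")
  fit_mlr(data, target, features = feature)
}

#' Write a fit report document
#'
#' Serializes a `"fit_result"` (model, p-values, metrics) to JSON;
#' `read_fit_report()` restores it. Round-trip stable.
#'
#' @param fit A `"fit_result"`.
#' @param path File path.
#' @export
write_fit_report <- function(fit, path) {
  doc <- list(method = fit$method, n = fit$n,
              n_components = fit$n_components,
              metrics = list(r2 = fit$r2, rmse = fit$rmse, mae = fit$mae),
              pvalues = if (!is.null(fit$pvalues)) as.list(fit$pvalues),
              model = list(target = fit$model$target,
                           intercept = fit$model$intercept,
                           coefficients = as.list(fit$model$coefficients),
                           feature_order = as.list(fit$model$feature_order),
                           metadata = fit$model$metadata))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_fit_report
#' @export
read_fit_report <- function(path) {
  d <- jsonlite::read_json(path)
  model <- linear_model(d$model$target, d$model$intercept,
                        unlist(d$model$coefficients),
                        feature_order = unlist(d$model$feature_order),
                        metadata = d$model$metadata %||% "",
                        allow_extra = TRUE)
  structure(list(model = model,
                 pvalues = if (!is.null(d$pvalues)) unlist(d$pvalues),
                 r2 = d$metrics$r2, rmse = d$metrics$rmse,
                 mae = d$metrics$mae, method = d$method, n = d$n,
                 n_components = d$n_components),
            class = "fit_result")
}
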