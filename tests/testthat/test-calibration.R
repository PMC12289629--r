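five <- c("b", "b_raw", "h", "s", "v")

test_that("MLR on noiseless planted data recovers the model exactly", {
  data <- planted_table(60, seed = 101, noise_sd = 0)
  fit <- fit_mlr(data, "chlorophyll_a", five)
  planted <- default_models()$chlorophyll_a
  expect_equal(fit$model$intercept, planted$intercept, tolerance = 1e-6)
  expect_equal(fit$model$coefficients, planted$coefficients,
               tolerance = 1e-6)
  expect_lt(fit$rmse, 1e-8)
  expect_equal(fit$r2, 1, tolerance = 1e-8)
  # cross-check against an explicit normal-equations solve
  beta <- oracle_ols(as.matrix(data[five]), data$cla_mg_g)
  expect_equal(unname(c(fit$model$intercept, fit$model$coefficients)),
               unname(beta), tolerance = 1e-8)
})

test_that("MLR handles degenerate designs with structured errors", {
  data <- planted_table(30, seed = 102, noise_sd = 0.05)
  # constant target: intercept only, zero slopes, zero error
  const <- data
  const$cla_mg_g <- 1.7
  fit <- suppressWarnings(fit_mlr(const, "chlorophyll_a", five))
  expect_equal(fit$model$intercept, 1.7)
  expect_equal(unname(fit$model$coefficients), rep(0, 5), tolerance = 1e-12)
  expect_equal(fit$rmse, 0, tolerance = 1e-12)
  # duplicated feature column is rank deficient
  dup <- data
  dup$b2 <- dup$b
  expect_error(fit_mlr(dup, "chlorophyll_a", c(five, "b2")),
               class = "leafchroma_collinearity")
  expect_error(fit_mlr(data[1:5, ], "chlorophyll_a", five),
               class = "leafchroma_sample_size")
})

test_that("MLR p-values follow classical t-tests", {
  data <- planted_table(80, seed = 103, noise_sd = 0.1)
  fit <- fit_mlr(data, "chlorophyll_a", five)
  expect_true(all(fit$pvalues >= 0 & fit$pvalues <= 1))
  # planted predictors with strong effects must screen as significant
  expect_true(all(c("b", "s", "v") %in% select_significant(fit$pvalues, 0.05)))
  # oracle p for one coefficient from the explicit t statistic
  X <- cbind(1, as.matrix(data[five]))
  y <- data$cla_mg_g
  beta <- solve(t(X) %*% X, t(X) %*% y)
  res <- y - X %*% beta
  s2 <- sum(res^2) / (nrow(X) - ncol(X))
  se <- sqrt(diag(s2 * solve(t(X) %*% X)))
  p_b <- 2 * pt(abs(beta[2] / se[2]), df = nrow(X) - ncol(X),
                lower.tail = FALSE)
  expect_equal(unname(fit$pvalues["b"]), unname(p_b), tolerance = 1e-10)
})

test_that("significance screening keeps p < alpha in canonical order", {
  pv <- c(b = 0.0005, b_raw = 0.004, h = 0.012, s = 0.060, v = 0.087)
  # canonical order lists the raw channel before the normalized index
  expect_identical(select_significant(pv, 0.05), c("b_raw", "b", "h"))
  expect_length(select_significant(setNames(rep(0.5, 5), five), 0.05), 0)
  expect_setequal(select_significant(pv, 1), five)
  # order is canonical regardless of input order
  expect_identical(select_significant(rev(pv), 0.05), c("b_raw", "b", "h"))
  expect_error(select_significant(pv, 0), class = "leafchroma_parameter")
})

test_that("PLSR with all components reproduces the OLS fit", {
  data <- planted_table(40, seed = 104, noise_sd = 0.1)
  mlr <- fit_mlr(data, "chlorophyll_a", five)
  plsr <- fit_plsr(data, "chlorophyll_a", five, n_components = 5)
  expect_equal(predict(plsr$model, data), predict(mlr$model, data),
               tolerance = 1e-8)
  expect_equal(plsr$rmse, mlr$rmse, tolerance = 1e-8)
})

test_that("PLSR handles single-component and out-of-range cases", {
  data <- planted_table(30, seed = 105, noise_sd = 0.1)
  # y exactly proportional to one feature: one component suffices
  prop <- data
  prop$cla_mg_g <- 3 * prop$b
  fit <- fit_plsr(prop, "chlorophyll_a", "b", n_components = 1)
  expect_lt(fit$rmse, 1e-8)
  expect_error(fit_plsr(data, "chlorophyll_a", five, n_components = 6),
               class = "leafchroma_parameter")
  expect_error(fit_plsr(data, "chlorophyll_a", five, n_components = 0),
               class = "leafchroma_parameter")
})

test_that("PLSR fitting-set RMSE is non-increasing in component count", {
  data <- planted_table(40, seed = 106, noise_sd = 0.15)
  rmse <- vapply(1:5, function(k) {
    fit_plsr(data, "chlorophyll_a", five, n_components = k)$rmse
  }, numeric(1))
  expect_true(all(diff(rmse) <= 1e-10))
})

test_that("leave-one-out component selection picks a sensible count", {
  data <- planted_table(35, seed = 107, noise_sd = 0.1)
  fit <- fit_plsr(data, "chlorophyll_a", five)
  expect_true(fit$n_components >= 1 && fit$n_components <= 5)
})

test_that("evaluation metrics agree with a two-pass oracle", {
  # tiny fixed fixture
  data <- planted_table(5, seed = 108, noise_sd = 0.3)
  model <- default_models()$chlorophyll_a
  got <- evaluate_model(model, data, "chlorophyll_a")
  want <- oracle_metrics(data$cla_mg_g, predict(model, data))
  expect_equal(got$rmse, want$rmse, tolerance = 1e-12)
  expect_equal(got$mae, want$mae, tolerance = 1e-12)
  expect_equal(got$r2, want$r2, tolerance = 1e-12)
  expect_true(got$mae <= got$rmse)
  expect_error(evaluate_model(model, data[0, ], "chlorophyll_a"),
               class = "leafchroma_empty_input")
})

test_that("a constant prediction bias gives rmse = mae = bias", {
  data <- planted_table(20, seed = 109, noise_sd = 0)
  shifted <- default_models()$chlorophyll_a
  shifted$intercept <- shifted$intercept + 0.25
  got <- evaluate_model(shifted, data, "chlorophyll_a")
  expect_equal(got$rmse, 0.25, tolerance = 1e-10)
  expect_equal(got$mae, 0.25, tolerance = 1e-10)
})

test_that("large-sample RMSE estimates the noise scale", {
  sigma <- 0.2
  data <- planted_table(10000, seed = 110, noise_sd = sigma)
  got <- evaluate_model(default_models()$chlorophyll_a, data,
                        "chlorophyll_a")
  expect_equal(got$rmse, sigma, tolerance = 0.05)
})

test_that("the five-feature refit cannot out-fit the 20-feature model", {
  data <- planted_table(60, seed = 111, noise_sd = 0.1)
  full <- fit_mlr(data, "chlorophyll_a", feature_names())
  sub <- fit_mlr(data, "chlorophyll_a", five)
  expect_gte(sub$rmse, full$rmse - 1e-12)
  expect_lte(sub$r2, full$r2 + 1e-12)
})

test_that("single-index baselines delegate to one-predictor OLS", {
  data <- planted_table(30, seed = 112, noise_sd = 0.05)
  # exact line through an auxiliary index column
  data$spad <- seq_len(nrow(data))
  data$tcl_mg_g <- 2 * data$spad + 1
  fit <- suppressWarnings(compare_single_index(data, "spad", "total_chlorophyll"))
  expect_equal(unname(fit$model$coefficients["spad"]), 2, tolerance = 1e-10)
  expect_equal(fit$model$intercept, 1, tolerance = 1e-8)
  expect_lt(fit$rmse, 1e-8)
  # a single index can never beat the five-feature fit on the same data
  single <- compare_single_index(data, "b", "chlorophyll_a")
  multi <- fit_mlr(data, "chlorophyll_a", five)
  expect_gte(single$rmse, multi$rmse - 1e-12)
})

test_that("planted coefficients are recovered within 3 SE almost always", {
  planted <- default_models()$chlorophyll_b
  hits <- 0L
  reps <- 100L
  for (r in seq_len(reps)) {
    data <- planted_table(200, seed = 200 + r, noise_sd = 0.05,
                          model = planted)
    fit <- fit_mlr(data, "chlorophyll_b", five)
    X <- cbind(1, as.matrix(data[five]))
    res <- data$clb_mg_g - predict(fit$model, data)
    s2 <- sum(res^2) / (nrow(X) - ncol(X))
    se <- sqrt(diag(s2 * solve(t(X) %*% X)))[-1]
    ok <- all(abs(fit$model$coefficients - planted$coefficients) <= 3 * se)
    hits <- hits + ok
  }
  expect_gte(hits / reps, 0.95)
})

test_that("fit reports round-trip through the document format", {
  data <- planted_table(40, seed = 113, noise_sd = 0.1)
  fit <- fit_mlr(data, "chlorophyll_a", five)
  path <- withr::local_tempfile(fileext = ".json")
  write_fit_report(fit, path)
  back <- read_fit_report(path)
  expect_equal(back$model$coefficients, fit$model$coefficients)
  expect_equal(back$pvalues, fit$pvalues)
  expect_equal(back$rmse, fit$rmse)
  expect_identical(back$method, "mlr")
})
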