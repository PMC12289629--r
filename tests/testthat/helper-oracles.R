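# Independent oracles used across the suite. These deliberately avoid
# the package's own code paths.

# brute-force hexcone RGB -> HSV (h degrees, s/v unit interval)
oracle_hsv <- function(r, g, b) {
  mx <- max(r, g, b); mn <- min(r, g, b); d <- mx - mn
  v <- mx / 255
  s <- if (mx > 0) d / mx else 0
  h <- if (d == 0) 0
       else if (mx == r) 60 * (((g - b) / d) %% 6)
       else if (mx == g) 60 * ((b - r) / d + 2)
       else 60 * ((r - g) / d + 4)
  if (h >= 360) h <- h - 360
  c(h = h, s = s, v = v)
}

# OLS by explicit normal equations (no lm)
oracle_ols <- function(X, y) {
  Xi <- cbind(intercept = 1, X)
  drop(solve(t(Xi) %*% Xi, t(Xi) %*% y))
}

# two-pass metric computation with explicit loops
oracle_metrics <- function(y, yhat) {
  n <- length(y)
  se <- 0; ae <- 0
  for (i in seq_len(n)) {
    se <- se + (y[i] - yhat[i])^2
    ae <- ae + abs(y[i] - yhat[i])
  }
  ybar <- sum(y) / n
  sst <- 0
  for (i in seq_len(n)) sst <- sst + (y[i] - ybar)^2
  list(rmse = sqrt(se / n), mae = ae / n, r2 = 1 - se / sst)
}

# uniform random readings within the leaf-like channel ranges
random_readings_df <- function(n, seed) {
  set.seed(seed)
  data.frame(r_raw = runif(n, 24, 32), g_raw = runif(n, 22, 30),
             b_raw = runif(n, 17, 22), c_raw = runif(n, 70, 90))
}

# calibration table generated from a planted model with optional noise,
# built without generate_calibration_dataset (for tests of that module)
planted_table <- function(n, seed, noise_sd = 0,
                          model = default_models()$chlorophyll_a) {
  df <- complete_features(random_readings_df(n, seed))
  y <- predict(model, df) + rnorm(n, sd = noise_sd)
  df$cla_mg_g <- df$clb_mg_g <- df$tcl_mg_g <- y
  df$crop <- "wheat"
  df$sample_id <- sprintf("S%03d", seq_len(n))
  df
}

extdata <- function(name) {
  system.file("extdata", name, package = "leafchroma", mustWork = TRUE)
}
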