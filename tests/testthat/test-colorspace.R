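test_that("channel normalization rescales by the clear channel onto 0-255", {
  r <- normalize_channels(sensor_reading(27.9, 27.0, 18.8, 80.9))
  expect_equal(unname(r["r"]), 87.94, tolerance = 1e-4)
  expect_equal(unname(r["g"]), 85.11, tolerance = 1e-4)
  expect_equal(unname(r["b"]), 59.26, tolerance = 1e-4)
  # zero numerator and full-scale identity
  expect_equal(unname(normalize_channels(sensor_reading(0, 1, 1, 100))["r"]), 0)
  expect_equal(unname(normalize_channels(sensor_reading(50, 1, 1, 50))["r"]), 255)
})

test_that("invalid readings are rejected with structured errors", {
  expect_error(sensor_reading(-1, 1, 1, 10), class = "leafchroma_invalid_reading")
  expect_error(sensor_reading(NA, 1, 1, 10), class = "leafchroma_invalid_reading")
  expect_error(normalize_channels(sensor_reading(1, 1, 1, 0)),
               class = "leafchroma_invalid_reading")
  expect_error(to_hsv(-1, 0, 0), class = "leafchroma_invalid_reading")
  expect_error(derived_indices(1, -1, 1), class = "leafchroma_invalid_reading")
})

test_that("HSV conversion follows the hexcone convention", {
  expect_equal(to_hsv(255, 0, 0), c(h = 0, s = 1, v = 1))
  expect_equal(to_hsv(100, 100, 100), c(h = 0, s = 0, v = 100 / 255))
  expect_equal(to_hsv(0, 0, 0), c(h = 0, s = 0, v = 0))
  got <- to_hsv(87.94, 85.10, 59.26)
  expect_equal(unname(got["h"]), 54.059, tolerance = 1e-4)
  expect_equal(unname(got["s"]), 0.3261, tolerance = 1e-3)
  expect_equal(unname(got["v"]), 0.3449, tolerance = 1e-3)
})

test_that("HSV conversion matches a brute-force oracle on random triples", {
  set.seed(7)
  triples <- matrix(runif(3e4, 0, 255), ncol = 3)
  # ties and degenerate cases the uniform draws never hit
  triples <- rbind(triples, c(0, 0, 0), c(10, 10, 10), c(255, 255, 0),
                   c(0, 255, 255), c(1, 1, 255))
  worst <- 0
  for (i in seq_len(nrow(triples))) {
    got <- to_hsv(triples[i, 1], triples[i, 2], triples[i, 3])
    want <- oracle_hsv(triples[i, 1], triples[i, 2], triples[i, 3])
    worst <- max(worst, max(abs(got - want)))
  }
  expect_lt(worst, 1e-9)
})

test_that("ratio and product indices are computed in canonical order", {
  idx <- derived_indices(87.94, 85.10, 59.26)
  expect_equal(unname(idx["r_over_b"]), 1.4840, tolerance = 1e-4)
  expect_equal(unname(derived_indices(1, 1, 1)), rep(1, 10))
  expect_equal(unname(derived_indices(2, 3, 4)["r_times_g_times_b"]), 24)
  err <- tryCatch(derived_indices(1, 0, 2), condition = identity)
  expect_s3_class(err, "leafchroma_undefined_feature")
  expect_match(conditionMessage(err), "r_over_g")
})

test_that("reciprocal ratio pairs multiply to one", {
  set.seed(11)
  for (i in 1:50) {
    x <- runif(3, 1, 255)
    idx <- derived_indices(x[1], x[2], x[3])
    expect_equal(unname(idx["g_over_r"] * idx["r_over_g"]), 1)
    expect_equal(unname(idx["b_over_g"] * idx["g_over_b"]), 1)
  }
})

test_that("feature extraction emits the canonical 20-feature vector", {
  f <- extract_features(sensor_reading(27.9, 27.0, 18.8, 80.9))
  expect_length(f, 20)
  expect_identical(names(f), feature_names())
  expect_equal(unname(f["h"]), 54.066, tolerance = 1e-4)
  # achromatic input: equal normalized channels, zero saturation
  g <- extract_features(sensor_reading(10, 10, 10, 30))
  expect_equal(unname(g[c("r", "g", "b")]), rep(85, 3))
  expect_equal(unname(g["s"]), 0)
  # purity: identical input gives bitwise-identical output
  expect_identical(f, extract_features(sensor_reading(27.9, 27.0, 18.8, 80.9)))
})

test_that("normalized and angular features are invariant to overall gain", {
  base <- c(27.9, 27.0, 18.8, 80.9)
  f1 <- extract_features(do.call(sensor_reading, as.list(base)))
  f2 <- extract_features(do.call(sensor_reading, as.list(base * 3.7)))
  stable <- c("r", "g", "b", "h", "s", "v", "r_over_b", "r_over_g",
              "g_over_r", "g_over_b", "b_over_r", "b_over_g")
  expect_equal(unclass(f1)[stable], unclass(f2)[stable], tolerance = 1e-12)
  expect_false(isTRUE(all.equal(f1[["r_raw"]], f2[["r_raw"]])))
})

test_that("normalized channels sum to 255 when clear equals their raw sum", {
  rd <- sensor_reading(30, 25, 20, 75)
  expect_equal(sum(normalize_channels(rd)), 255)
})

test_that("replicate averaging is channel-wise and raw-first", {
  r <- sensor_reading(10, 10, 10, 30)
  expect_equal(average_replicates(list(r, r, r)), r)
  mixed <- list(sensor_reading(10, 1, 1, 10), sensor_reading(20, 1, 1, 10),
                sensor_reading(30, 1, 1, 10))
  expect_equal(average_replicates(mixed)[["r_raw"]], 20)
  # data-frame input (one row per replicate)
  df <- data.frame(r_raw = c(10, 20), g_raw = c(2, 4), b_raw = c(1, 1),
                   c_raw = c(10, 10))
  expect_equal(unclass(average_replicates(df)),
               c(r_raw = 15, g_raw = 3, b_raw = 1, c_raw = 10))
  expect_error(average_replicates(list()), class = "leafchroma_empty_input")
})
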