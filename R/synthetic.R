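# Synthetic leaf readings and calibration datasets with planted models.
#
# The generator draws raw channels uniformly within the intensity
# ranges observed on wheat and maize leaves with this sensor head, and
# derives chlorophyll contents FROM the default prediction models plus
# Gaussian noise — so the shipped models are the ground truth that
# recovery tests can check against. It emulates channel-level ranges
# and measurement noise, not leaf optics.

#' Configuration for the synthetic-data generator
#'
#' Defaults reflect the study conditions the package's example data come
#' from: raw channel ranges spanning the leaf readings observed with the
#' instrument (R' 24-32, G' 22-30, B' 17-22, C 70-90 counts/uW/cm2), a
#' modeling-set size of 132 leaves (71 wheat + 61 maize), chlorophyll
#' noise of 0.1 mg/g (the order of the calibrated models' fitting
#' RMSEs), and replicate jitter of 0.3 counts (the typical replicate SD
#' seen in the repeatability data).
#'
#' @param n_samples Number of leaf samples.
#' @param crop `"wheat"`, `"maize"`, or `"mixed"` (71:61 wheat:maize
#'   proportions).
#' @param r_range,g_range,b_range,c_range Raw-channel ranges
#'   (counts/uW/cm2), each `c(min, max)` with min < max.
#' @param noise_sd SD of Gaussian noise added to each generated
#'   chlorophyll content (mg/g).
#' @param replicate_jitter SD of per-channel replicate noise (counts).
#' @param seed Integer seed; same seed, same dataset.
#' @return List of class `"generator_config"`.
#' @export
generator_config <- function(n_samples = 132, crop = "mixed",
                             r_range = c(24, 32), g_range = c(22, 30),
                             b_range = c(17, 22), c_range = c(70, 90),
                             noise_sd = 0.1, replicate_jitter = 0.3,
                             seed = NULL) {
  crop <- match.arg(crop, c("wheat", "maize", "mixed"))
  for (rg in list(r_range, g_range, b_range, c_range)) {
    if (length(rg) != 2 || rg[1] >= rg[2] || any(rg < 0))
      lc_stop("channel ranges must be non-degenerate c(min, max), min >= 0",
              "config")
  }
  if (n_samples < 0 || noise_sd < 0 || replicate_jitter < 0)
    lc_stop("n_samples, noise_sd and replicate_jitter must be >= 0",
            "config")
  structure(list(n_samples = as.integer(n_samples), crop = crop,
                 r_range = r_range, g_range = g_range,
                 b_range = b_range, c_range = c_range,
                 noise_sd = noise_sd, replicate_jitter = replicate_jitter,
                 seed = seed),
            class = "generator_config")
}

with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", globalenv())) {
      old <- get(".Random.seed", globalenv())
      on.exit(assign(".Random.seed", old, globalenv()))
    } else {
      on.exit(rm(".Random.seed", envir = globalenv()))
    }
    set.seed(seed)
  }
  expr
}

draw_channels <- function(config, n) {
  r <- stats::runif(n, config$r_range[1], config$r_range[2])
  g <- stats::runif(n, config$g_range[1], config$g_range[2])
  b <- stats::runif(n, config$b_range[1], config$b_range[2])
  cc <- stats::runif(n, config$c_range[1], config$c_range[2])
  # filtered channels never exceed the broadband clear channel
  data.frame(r_raw = pmin(r, cc), g_raw = pmin(g, cc),
             b_raw = pmin(b, cc), c_raw = cc)
}

#' Generate synthetic sensor readings
#'
#' Uniform draws of the four raw channels within the configured ranges,
#' each filtered channel capped at the clear channel. Deterministic
#' under the config's seed.
#'
#' @param config A [generator_config()].
#' @return Data frame `sample_id, replicate, r_raw, g_raw, b_raw,
#'   c_raw` with one row per sample.
#' @export
#' @examples
#' generate_readings(generator_config(n_samples = 3, seed = 1))
generate_readings <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  with_seed(config$seed, {
    ch <- draw_channels(config, config$n_samples)
    cbind(data.frame(sample_id = sprintf("S%03d", seq_len(config$n_samples)),
                     replicate = rep(1L, config$n_samples)),
          ch)
  })
}

crop_labels <- function(crop, n) {
  if (crop != "mixed") return(rep(crop, n))
  # modeling-set proportions: 71 wheat to 61 maize
  sample(c("wheat", "maize"), n, replace = TRUE, prob = c(71, 61) / 132)
}

#' Generate a calibration dataset with planted models
#'
#' Draws readings, extracts the 20 features, and sets each reference
#' content to the corresponding default-model prediction plus
#' `N(0, noise_sd)` noise. Rows are redrawn until both the noisy
#' contents and the noise-free model predictions fall inside the
#' plausibility window, so generated leaves both carry in-range
#' references and measure `"ok"` end-to-end. With `noise_sd = 0` the default models are recovered
#' exactly by [fit_mlr()] on the five model features.
#'
#' @inheritParams generate_readings
#' @param models Planted truth; defaults to [default_models()].
#' @return Calibration table: `sample_id`, the 20 feature columns,
#'   `cla_mg_g, clb_mg_g, tcl_mg_g, crop`.
#' @export
generate_calibration_dataset <- function(config,
                                         models = default_models()) {
  stopifnot(inherits(config, "generator_config"))
  window <- plausibility_window()
  with_seed(config$seed, {
    n <- config$n_samples
    out <- NULL
    tries <- 0
    while ((is.null(out) || nrow(out) < n) && tries < 50) {
      tries <- tries + 1
      m <- n - if (is.null(out)) 0 else nrow(out)
      ch <- draw_channels(config, m)
      feats <- complete_features(ch)
      pa <- predict(models$chlorophyll_a, feats)
      pb <- predict(models$chlorophyll_b, feats)
      pt <- predict(models$total_chlorophyll, feats)
      cla <- pa + stats::rnorm(m, sd = config$noise_sd)
      clb <- pb + stats::rnorm(m, sd = config$noise_sd)
      tcl <- pt + stats::rnorm(m, sd = config$noise_sd)
      # both the noisy reference contents and the noise-free model
      # predictions must be plausible, so a generated row measures
      # "ok" end-to-end as well as carrying in-range references
      in_win <- function(a, b, t) {
        a >= window$lower & b >= window$lower &
          t >= window$lower & t <= window$tcl_upper
      }
      ok <- in_win(cla, clb, tcl) & in_win(pa, pb, pt)
      keep <- cbind(feats[ok, , drop = FALSE],
                    data.frame(cla_mg_g = cla[ok], clb_mg_g = clb[ok],
                               tcl_mg_g = tcl[ok]))
      out <- if (is.null(out)) keep else rbind(out, keep)
    }
    if (nrow(out) < n)
      lc_stop("could not generate enough in-window samples; widen ranges or lower noise_sd",
              "config")
    out <- out[seq_len(n), , drop = FALSE]
    out$crop <- crop_labels(config$crop, n)
    cbind(data.frame(sample_id = sprintf("S%03d", seq_len(n))), out)
  })
}

#' Generate replicate readings around a base measurement
#'
#' Adds independent Gaussian noise of scale `jitter` to each channel of
#' the base reading, clipped at zero. Emulates re-measuring the same
#' leaf spot.
#'
#' @param base A [sensor_reading()].
#' @param n Number of replicates (>= 1).
#' @param jitter Noise SD in counts (>= 0).
#' @param seed Optional integer seed.
#' @return Data frame `sample_id, replicate` + channel columns.
#' @export
generate_replicates <- function(base, n, jitter, seed = NULL) {
  base <- as_sensor_reading(base)
  if (n < 1) lc_stop("need at least one replicate", "config")
  if (jitter < 0) lc_stop("jitter must be >= 0", "config")
  with_seed(seed, {
    noise <- matrix(stats::rnorm(4 * n, sd = jitter), ncol = 4)
    ch <- sweep(noise, 2, unclass(base), "+")
    ch[ch < 0] <- 0
    colnames(ch) <- channel_names()
    cbind(data.frame(sample_id = "S001", replicate = seq_len(n)),
          as.data.frame(ch))
  })
}
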