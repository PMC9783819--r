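test_that("above-noise detection implements mean > mean + k*SD", {
  bg <- chronogram(0:99, c(rep(1, 50), rep(1.2, 50)))
  expect_false(detect_above_noise(bg, bg))
  sig <- chronogram(0:99, rep(5, 100))
  expect_true(detect_above_noise(sig, bg))
  const <- chronogram(0:9, rep(1, 10))
  expect_error(detect_above_noise(sig, const),
               class = "ppchron_error_degenerate_background")
})

test_that("simulated conditions detect as the study expects", {
  hits_plant <- hits_fungus <- 0L
  for (s in seq_len(20)) {
    bg <- simulate_replicate_set(default_config("medium", seed = 1000 + s))
    pl <- simulate_replicate_set(default_config("plant", seed = s))
    fu <- simulate_replicate_set(default_config("fungus", seed = s))
    hits_plant <- hits_plant +
      detect_above_noise(pl$replicates$mean, bg$replicates$mean)
    hits_fungus <- hits_fungus +
      detect_above_noise(fu$replicates$mean, bg$replicates$mean)
  }
  expect_lte(hits_plant / 20, 0.05)   # background vs background: not detected
  expect_gte(hits_fungus / 20, 0.95)  # constitutive emission: detected
})

test_that("circadian summary maps clock hours, peaks and day/night contrast", {
  t <- 0:191
  # pure sinusoid peaking at 20:00 with inoculation at 08:00
  x <- 2 + cos(2 * pi * ((8 + t) %% 24 - 20) / 24)
  cs <- circadian_summary(chronogram(t, x))
  expect_identical(cs$peak_hour, 20L)

  const <- circadian_summary(chronogram(t, rep(3, 192)))
  expect_identical(const$peak_hour, 0L)      # tie broken to earliest hour
  expect_equal(const$night_day_ratio, 1)

  expect_error(circadian_summary(chronogram(0:10, rnorm(11))),
               class = "ppchron_error_insufficient_span")
})

test_that("night/day ratio is invariant under positive rescaling", {
  sim <- simulate_replicate_set(default_config("fungus", seed = 21))
  m <- sim$replicates$mean
  cs1 <- circadian_summary(m)
  cs2 <- circadian_summary(chronogram(m$times, 37 * m$intensities))
  expect_equal(cs1$night_day_ratio, cs2$night_day_ratio)
  expect_identical(cs1$peak_hour, cs2$peak_hour)
})

test_that("production fold change is an AUC ratio with the right edge cases", {
  a <- chronogram(0:10, rep(2, 11))
  expect_equal(production_fold_change(a, a), 1)
  b <- chronogram(0:10, rep(1, 11))
  expect_equal(production_fold_change(a, b), 2)  # a = 2b pointwise
  zero <- chronogram(0:10, rep(0, 11))
  expect_error(production_fold_change(a, zero),
               class = "ppchron_error_undefined_ratio")
})

test_that("the rule table classifies the three default conditions", {
  # seed-averaged descriptors: the classification contract of the study
  avg_desc <- function(cond, n = 15) {
    fields <- c("mean_intensity", "sd_intensity", "skewness",
                "excess_kurtosis", "acf1")
    acc <- stats::setNames(numeric(length(fields)), fields)
    for (s in seq_len(n)) {
      d <- describe(simulate_replicate_set(
        default_config(cond, seed = s))$replicates$mean)
      for (f in fields) acc[f] <- acc[f] + d[[f]]
    }
    out <- describe(simulate_replicate_set(
      default_config(cond, seed = 1))$replicates$mean)
    for (f in fields) out[[f]] <- acc[[f]] / n
    out
  }
  th <- classification_thresholds()
  plant <- avg_desc("plant")
  fungus <- avg_desc("fungus")
  inter <- avg_desc("interaction")

  expect_identical(classify_variable(plant, plant, th)$label, "background")
  expect_identical(classify_variable(fungus, plant, th)$label, "physiological")
  res <- classify_variable(inter, plant, th, reference = fungus)
  expect_identical(res$label, "stabilized")
  expect_true(all(c("criterion", "value", "threshold", "passed") %in%
                    names(res$evidence)))

  # purity: same inputs, same label
  expect_identical(classify_variable(inter, plant, th, reference = fungus)$label,
                   res$label)

  # qualitative ordering of the three conditions
  expect_gt(fungus$skewness, inter$skewness)
  expect_gt(inter$skewness, plant$skewness)
  expect_gt(fungus$excess_kurtosis, inter$excess_kurtosis)
  expect_gt(inter$excess_kurtosis, plant$excess_kurtosis)
  expect_gt(inter$acf1, fungus$acf1)
})

test_that("classification validates its inputs", {
  d <- describe(simulate_replicate_set(default_config("fungus", seed = 2))$replicates$mean)
  flat <- describe(chronogram(0:10, rep(2, 11)))
  th <- classification_thresholds()
  expect_error(classify_variable(flat, d, th),
               class = "ppchron_error_incomplete_evidence")
  expect_error(classify_variable(d, d, list(s0 = 1)),
               class = "ppchron_error_configuration")
  expect_error(classification_thresholds(s0 = NA),
               class = "ppchron_error_configuration")
})
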