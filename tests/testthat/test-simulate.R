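test_that("identical (config, seed) pairs are bit-identical; seeds differ", {
  cfg <- default_config("fungus", seed = 11)
  a <- simulate_replicate_set(cfg)
  b <- simulate_replicate_set(cfg)
  expect_identical(
    lapply(a$replicates$chronograms, `[[`, "intensities"),
    lapply(b$replicates$chronograms, `[[`, "intensities")
  )
  expect_identical(a$truth$noiseless, b$truth$noiseless)
  c2 <- simulate_replicate_set(default_config("fungus", seed = 12))
  expect_false(identical(a$replicates$mean$intensities,
                         c2$replicates$mean$intensities))
})

test_that("technical-replicate count does not perturb biological draws", {
  cfg3 <- default_config("interaction", seed = 4)
  full <- as.list(cfg3)
  full$n_technical <- 1L
  cfg1 <- do.call(simulation_config, full)
  expect_identical(simulate_replicate_set(cfg3)$truth$noiseless,
                   simulate_replicate_set(cfg1)$truth$noiseless)
})

test_that("configuration errors are caught", {
  expect_error(default_config("weeds"), class = "ppchron_error_configuration")
  expect_error(simulation_config("plant", noise_sd = NaN),
               class = "ppchron_error_configuration")
  expect_error(simulation_config("plant", ar1_coeff = 1),
               class = "ppchron_error_configuration")
  expect_error(simulation_config("plant", emission_onset_day = 9,
                                 emission_offset_day = 8),
               class = "ppchron_error_configuration")
  expect_error(simulate_replicate_set(list(condition = "plant")),
               class = "ppchron_error_configuration")
})

test_that("non-emitting conditions have identically zero noiseless signal and
           near-Gaussian pooled values", {
  skews <- kurts <- numeric(30)
  for (s in seq_len(30)) {
    sim <- simulate_replicate_set(default_config("plant", seed = s))
    expect_true(all(sim$truth$noiseless == 0))
    pooled <- unlist(lapply(sim$replicates$chronograms, `[[`, "intensities"))
    skews[s] <- skewness(pooled)
    kurts[s] <- excess_kurtosis(pooled)
  }
  n <- 9 * 192
  expect_lt(abs(mean(skews)), 4 * sqrt(6 / n))
  expect_lt(abs(mean(kurts)), 4 * sqrt(24 / n))
})

test_that("noiseless emission is zero outside the emission window", {
  for (cond in c("fungus", "interaction")) {
    cfg <- default_config(cond, seed = 2)
    sim <- simulate_replicate_set(cfg)
    t0 <- (cfg$emission_onset_day - 1) * 24
    t1 <- cfg$emission_offset_day * 24
    times <- sim$replicates$mean$times
    outside <- times < t0 | times > t1
    expect_true(all(sim$truth$noiseless[outside, ] == 0))
    expect_true(any(sim$truth$noiseless[!outside, ] > 0))
  }
})

test_that("degenerate configuration yields i.i.d. Gaussian noise", {
  # burst_rate = 0, circadian_amplitude = 0, ar1_coeff = 0: plain white noise
  # around the baseline; Kolmogorov-Smirnov and white-noise ACF band checks.
  ks_ok <- 0L
  acf_hits <- 0L; acf_n <- 0L
  for (s in seq_len(25)) {
    cfg <- simulation_config("plant", ar1_coeff = 0, baseline = 10,
                             noise_sd = 1, seed = s)
    sim <- simulate_replicate_set(cfg)
    x <- sim$replicates$chronograms[[1]]$intensities
    ks_ok <- ks_ok + (stats::ks.test(x, "pnorm", mean = 10, sd = 1)$p.value > 0.01)
    rho <- signal_acf(x, 30)[-1]
    acf_hits <- acf_hits + sum(abs(rho) < 2 / sqrt(length(x)))
    acf_n <- acf_n + length(rho)
  }
  expect_gte(ks_ok / 25, 0.9)
  expect_gte(acf_hits / acf_n, 0.93)
})

test_that("ar1_coeff is recovered from the lag-1 ACF of burst-free runs", {
  for (phi in c(0.25, 0.5)) {
    est <- vapply(seq_len(100), function(s) {
      cfg <- simulation_config("plant", ar1_coeff = phi, baseline = 10,
                               noise_sd = 1, n_biological = 1,
                               n_technical = 1, seed = s)
      # single replicate: the SD-missing warning is expected here
      sim <- suppressWarnings(simulate_replicate_set(cfg))
      signal_acf(sim$replicates$chronograms[[1]]$intensities, 1)[2]
    }, numeric(1))
    expect_lt(abs(mean(est) - phi), 0.05)
  }
})

test_that("pooled tail weight is non-decreasing in burst_scale", {
  grid <- c(0.001, 0.005, 0.02)
  stats_at <- vapply(grid, function(bs) {
    sk <- ku <- numeric(50)
    for (s in seq_len(50)) {
      cfg <- default_config("fungus", seed = s)
      full <- as.list(cfg); full$burst_scale <- bs
      sim <- simulate_replicate_set(do.call(simulation_config, full))
      pooled <- unlist(lapply(sim$replicates$chronograms, `[[`, "intensities"))
      sk[s] <- skewness(pooled); ku[s] <- excess_kurtosis(pooled)
    }
    c(mean(sk), mean(ku))
  }, numeric(2))
  expect_true(all(diff(stats_at[1, ]) >= 0))
  expect_true(all(diff(stats_at[2, ]) >= 0))
})

test_that("the seed-averaged noiseless hour-of-day profile peaks at the
           configured circadian peak hour", {
  cfg <- default_config("fungus", seed = 1)
  prof <- rep(0, 24)
  for (s in seq_len(20)) {
    full <- as.list(default_config("fungus", seed = s))
    sim <- simulate_replicate_set(do.call(simulation_config, full))
    m <- rowMeans(sim$truth$noiseless)
    hr <- floor((cfg$inoculation_clock_hour + sim$replicates$mean$times) %% 24)
    prof <- prof + vapply(0:23, function(h) mean(m[hr == h]), numeric(1))
  }
  expect_identical((0:23)[which.max(prof)], as.integer(cfg$circadian_peak_hour))
})
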