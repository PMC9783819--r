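test_that("skewness matches the direct moment formula and known cases", {
  expect_equal(skewness(c(1, 2, 3, 4, 5)), 0)
  # frozen value from the hand-evaluated formula m3 / m2^1.5 on
  # x = (1,2,3,4,100): m2 = 1522, m3 = 88920
  expect_equal(skewness(c(1, 2, 3, 4, 100)), 88920 / 1522^1.5)
  set.seed(7)
  expect_lt(abs(skewness(rexp(1e5)) - 2), 0.05)  # analytic skewness of Exp
  expect_equal(skewness(-c(1, 2, 3, 4, 100)), -skewness(c(1, 2, 3, 4, 100)))
})

test_that("excess kurtosis matches the direct moment formula and known cases", {
  # frozen: m4 = 7520966.8, m2 = 1522 for x = (1,2,3,4,100)
  expect_equal(excess_kurtosis(c(1, 2, 3, 4, 100)), 7520966.8 / 1522^2 - 3)
  expect_equal(excess_kurtosis(rep(c(-1, 1), 10)), -2)  # analytic minimum
  set.seed(8)
  expect_lt(abs(excess_kurtosis(rnorm(1e5))), 0.05)
})

test_that("moment estimators agree with the independent e1071 implementation", {
  set.seed(9)
  for (x in list(rexp(200), rnorm(150), rgamma(300, 0.5))) {
    expect_equal(skewness(x), e1071::skewness(x, type = 1))
    expect_equal(excess_kurtosis(x), e1071::kurtosis(x, type = 1))
  }
})

test_that("moments are affine invariant and fail informatively", {
  set.seed(10)
  x <- rexp(100)
  expect_equal(skewness(2.5 * x + 7), skewness(x))
  expect_equal(excess_kurtosis(2.5 * x + 7), excess_kurtosis(x))
  expect_error(skewness(rep(1, 10)), class = "ppchron_error_zero_variance")
  expect_error(skewness(c(1, 2)), class = "ppchron_error_insufficient_data")
  expect_error(excess_kurtosis(c(1, 2, 3)),
               class = "ppchron_error_insufficient_data")
})

test_that("the ACF estimator is the biased demeaned form", {
  set.seed(11)
  x <- rnorm(300)
  ours <- signal_acf(x, 20)
  expect_equal(ours[1], 1)
  # stats::acf uses the same denominator-n pooled-variance estimator
  ref <- as.numeric(stats::acf(x, lag.max = 20, plot = FALSE)$acf)
  expect_equal(ours, ref)
  expect_true(all(abs(ours) <= 1))
  expect_error(signal_acf(x, 300), class = "ppchron_error_argument")
  expect_error(signal_acf(rep(2, 10), 2), class = "ppchron_error_zero_variance")
})

test_that("ACF of an AR(1) process follows phi^k and is monotone in phi", {
  est_rho1 <- numeric(3)
  phis <- c(0.1, 0.5, 0.9)
  for (i in seq_along(phis)) {
    rho1 <- numeric(20)
    for (s in seq_len(20)) {
      set.seed(100 + s)
      x <- as.numeric(stats::arima.sim(list(ar = phis[i]), n = 4000))
      ac <- signal_acf(x, 5)
      if (i == 2 && s == 1) {
        expect_true(all(abs(ac[-1] - phis[i]^(1:5)) < 0.05))
      }
      rho1[s] <- ac[2]
    }
    est_rho1[i] <- mean(rho1)
  }
  expect_true(all(diff(est_rho1) > 0))
})

test_that("Poincare descriptors satisfy the exact algebraic identities", {
  set.seed(12)
  for (x in list(rnorm(100), cumsum(rnorm(200)), rexp(50))) {
    pc <- poincare(x)
    a <- x[-1]; b <- x[-length(x)]
    pop_var <- function(v) mean((v - mean(v))^2)
    pop_cov <- function(u, v) mean((u - mean(u)) * (v - mean(v)))
    vbar <- (pop_var(a) + pop_var(b)) / 2
    cab <- pop_cov(a, b)
    # SD1^2 = Vbar - C, SD2^2 = Vbar + C (brute-force covariance oracle)
    expect_equal(pc$sd1^2, vbar - cab)
    expect_equal(pc$sd2^2, vbar + cab)
    expect_equal(pc$sd1^2 + pc$sd2^2, pop_var(a) + pop_var(b))
    expect_equal(pc$ratio^2, (vbar - cab) / (vbar + cab))
  }
})

test_that("Poincare identity links the ratio to lag-1 autocorrelation", {
  # (SD1/SD2)^2 ~ (1 - rho1)/(1 + rho1) for long stationary series; this is
  # the identity used to read lag-1 autocorrelation off the printed ratios.
  set.seed(13)
  x <- as.numeric(stats::arima.sim(list(ar = 0.6), n = 20000))
  pc <- poincare(x)
  expect_lt(abs(pc$ratio - sqrt((1 - 0.6) / (1 + 0.6))), 0.02)
})

test_that("Poincare edge cases are flagged", {
  pc <- poincare(rep(5, 10))
  expect_equal(pc$sd1, 0)
  expect_equal(pc$sd2, 0)
  expect_true(is.na(pc$ratio))
  # 21 points -> 20 successive pairs, half +2 and half -2: SD1 exactly sqrt(2)
  alt <- poincare(rep(c(1, -1), length.out = 21))
  expect_equal(alt$sd2, 0)
  expect_equal(alt$sd1, sqrt(2))
  expect_true(is.na(alt$ratio))
  expect_error(poincare(c(1, 2)), class = "ppchron_error_insufficient_data")
})

test_that("AUC is the trapezoidal integral with exact additivity", {
  expect_equal(auc(chronogram(0:2, c(0, 1, 0))), 1)
  expect_equal(auc(chronogram(c(0, 7), c(3, 3))), 21)  # constant c over [0, T]
  set.seed(14)
  t <- sort(runif(60, 0, 30)); v <- rnorm(60)
  expect_equal(auc(t, v), pracma::trapz(t, v), tolerance = 1e-12)
  k <- 25
  expect_equal(auc(t[1:k], v[1:k]) + auc(t[k:60], v[k:60]), auc(t, v))
  expect_error(auc(chronogram(0, 1)), class = "ppchron_error_insufficient_data")
})

test_that("histograms cover [min, max] with closed rightmost bin", {
  h <- intensity_histogram(c(0, 0.5, 1), 2)
  expect_equal(h$counts, c(1, 2))
  expect_equal(h$edges, c(0, 0.5, 1))
  hh <- intensity_histogram(rep(3, 7), 4)
  expect_equal(sum(hh$counts), 7)
  expect_equal(sum(hh$counts > 0), 1L)
  set.seed(15)
  x <- rnorm(1e4)
  hx <- intensity_histogram(x, 50)
  expect_equal(sum(hx$counts), length(x))
  mids <- (head(hx$edges, -1) + tail(hx$edges, -1)) / 2
  wskew <- sum(hx$counts * (mids - mean(x))^3) / length(x) /
    (sum(hx$counts * (mids - mean(x))^2) / length(x))^1.5
  expect_lt(abs(wskew), 0.1)
  expect_error(intensity_histogram(numeric(0)), class = "ppchron_error_empty_input")
})

test_that("describe() populates all descriptors and survives partial failure", {
  sim <- simulate_replicate_set(default_config("fungus", seed = 6))
  d <- describe(sim$replicates$mean, max_lag = 48, n_bins = 30)
  expect_s3_class(d, "descriptor_set")
  expect_equal(d$acf[1], 1)
  expect_equal(d$acf1, d$acf[2])
  expect_equal(d$n_points, 192L)
  expect_equal(sum(d$histogram$counts), 192)
  expect_equal(d$skewness, skewness(sim$replicates$mean$intensities))
  expect_equal(d$auc, auc(sim$replicates$mean))
  expect_length(d$errors, 0L)

  flat <- chronogram(0:10, rep(2, 11), condition = "flat")
  dflat <- describe(flat)
  expect_true(is.na(dflat$skewness))
  expect_true(is.na(dflat$sd_ratio))
  expect_equal(dflat$auc, 20)
  expect_true(all(c("skewness", "excess_kurtosis", "acf") %in%
                    names(dflat$errors)))
})
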