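#' Simulate a replicate hierarchy of synthetic chronograms
#'
#' Draws `n_biological x n_technical` chronograms from the stochastic
#' emission model described in [simulation_config()], together with the
#' generating ground truth (per-replicate noiseless signals and burst
#' times) for parameter-recovery checks.
#'
#' Random streams are split per biological replicate: each biological
#' replicate's noiseless signal (bursts) is drawn from its own
#' deterministic substream, and each technical replicate's noise from a
#' further substream, so changing `n_technical` never perturbs the
#' biological draws and identical `(config, seed)` pairs are
#' bit-identical.
#'
#' @param config A [simulation_config()].
#' @return A list with components
#'   \describe{
#'     \item{replicates}{A [replicate_set()] holding the raw chronograms
#'       plus the aggregated biological mean and SD series.}
#'     \item{truth}{A `synthetic_truth` list: `config`, `noiseless` (an
#'       `n_time x n_biological` matrix of noiseless signals, zero outside
#'       the emission window and identically zero for the non-emitting
#'       conditions), and `burst_times` (per-biological-replicate arrival
#'       times, hours).}
#'   }
#' @export
#' @examples
#' sim <- simulate_replicate_set(default_config("fungus", seed = 7))
#' sim$replicates$mean
simulate_replicate_set <- function(config) {
  if (!inherits(config, "simulation_config")) {
    stop_ppchron("configuration",
                 "`config` must be built with simulation_config()")
  }
  validate_simulation_config(config)

  n <- as.integer(round(config$duration_days * 24 / config$sampling_interval_h))
  times <- seq(0, by = config$sampling_interval_h, length.out = n)
  env <- emission_envelope(times, config)

  emitting <- config$condition %in% c("fungus", "interaction")
  chrons <- vector("list", config$n_biological * config$n_technical)
  noiseless <- matrix(0, nrow = n, ncol = config$n_biological)
  burst_times <- vector("list", config$n_biological)
  k <- 0L
  for (i in seq_len(config$n_biological)) {
    bio_seed <- substream_seed(config$seed, i, 0L)
    if (emitting) {
      set.seed(bio_seed)
      bp <- draw_bursts(times, config)
      noiseless[, i] <- config$amplitude_scale * env *
        (config$baseline_emission + bp$series)
      burst_times[[i]] <- bp$times
    } else {
      burst_times[[i]] <- numeric(0)
    }
    for (j in seq_len(config$n_technical)) {
      set.seed(substream_seed(config$seed, i, j))
      eps <- ar1_noise(n, config$ar1_coeff, 1) *
        (config$noise_sd + config$noise_cv * noiseless[, i])
      y <- pmax(noiseless[, i] + config$baseline + eps, 0)
      k <- k + 1L
      chrons[[k]] <- chronogram(
        times, y, condition = config$condition, provenance = "raw",
        bio_rep = i, tech_rep = j
      )
    }
  }

  truth <- structure(
    list(config = config, noiseless = noiseless, burst_times = burst_times),
    class = "synthetic_truth"
  )
  set <- aggregate_replicates(replicate_set(chrons, condition = config$condition))
  list(replicates = set, truth = truth)
}

# Deterministic integer substream seed; stays below 2^31 - 1.
substream_seed <- function(seed, bio, tech) {
  as.integer((abs(as.numeric(seed)) * 100003 + bio * 10007 + tech * 313 + 17) %%
               2147483647)
}

# Smooth emission-window envelope times circadian modulation.
# The window is a trapezoid with half-cosine ramps of `ramp_h` hours at
# the start of the onset day and the end of the offset day (smooth
# onset/offset avoids discontinuity artifacts in the ACF), multiplied by
# an optional dome that peaks in the middle of the peak day: the colony's
# slow growth-decline of productivity.  Exactly zero outside the window.
emission_envelope <- function(times, config) {
  t0 <- (config$emission_onset_day - 1) * 24
  t1 <- config$emission_offset_day * 24
  r <- min(config$ramp_h, (t1 - t0) / 2)
  w <- numeric(length(times))
  inside <- times >= t0 & times <= t1
  w[inside] <- 1
  rise <- times >= t0 & times < t0 + r
  fall <- times > t1 - r & times <= t1
  w[rise] <- 0.5 * (1 - cos(pi * (times[rise] - t0) / r))
  w[fall] <- 0.5 * (1 + cos(pi * (t1 - times[fall]) / r))
  if (config$peak_prominence > 0) {
    tp <- (config$emission_peak_day - 1) * 24 + 12
    tp <- min(max(tp, t0 + 1e-9), t1 - 1e-9)
    dome <- numeric(length(times))
    up <- times >= t0 & times <= tp
    down <- times > tp & times <= t1
    dome[up] <- 0.5 * (1 - cos(pi * (times[up] - t0) / (tp - t0)))
    dome[down] <- 0.5 * (1 + cos(pi * (times[down] - tp) / (t1 - tp)))
    w <- w * (1 + config$peak_prominence * dome)
  }
  w * circadian_factor(times, config)
}

circadian_factor <- function(times, config) {
  h <- (config$inoculation_clock_hour + times) %% 24
  dark <- is_dark_hour(h, config$lights_on_hour, config$lights_off_hour)
  # Night elevation is a pulse that is maximal at dark onset and decays
  # to zero over dark_pulse_h hours as (1 - u/W)^q: exponents q < 1 give
  # a flat-topped, switch-like pulse, q > 1 a fast early decay.
  # Inf keeps the elevation flat across the whole dark phase.
  since_off <- (h - config$lights_off_hour) %% 24
  pulse <- if (is.finite(config$dark_pulse_h)) {
    ifelse(since_off < config$dark_pulse_h,
           (1 - since_off / config$dark_pulse_h)^config$dark_pulse_shape, 0)
  } else {
    1
  }
  f <- 1 + config$circadian_amplitude *
    cos(2 * pi * (h - config$circadian_peak_hour) / 24) +
    config$dark_elevation * pulse * dark
  pmax(f, 0)
}

is_dark_hour <- function(h, lights_on, lights_off) {
  if (lights_on < lights_off) {
    as.numeric(h < lights_on | h >= lights_off)
  } else {
    as.numeric(h >= lights_off & h < lights_on)
  }
}

# Shot-noise burst process: Poisson arrivals over the emission window,
# gamma amplitudes (mean burst_scale), exponential decay.
draw_bursts <- function(times, config) {
  t0 <- (config$emission_onset_day - 1) * 24
  t1 <- config$emission_offset_day * 24
  series <- numeric(length(times))
  if (config$burst_rate <= 0 || config$burst_scale <= 0) {
    return(list(series = series, times = numeric(0)))
  }
  n_burst <- rpois(1, config$burst_rate * (t1 - t0))
  if (n_burst == 0) {
    return(list(series = series, times = numeric(0)))
  }
  arr <- sort(runif(n_burst, t0, t1))
  amp <- rgamma(n_burst, shape = config$burst_shape,
                scale = config$burst_scale / config$burst_shape)
  for (b in seq_len(n_burst)) {
    after <- times >= arr[b]
    series[after] <- series[after] +
      amp[b] * exp(-(times[after] - arr[b]) / config$burst_decay_h)
  }
  list(series = series, times = arr)
}

# Stationary AR(1) Gaussian noise with marginal standard deviation `sd`.
ar1_noise <- function(n, phi, sd) {
  z <- rnorm(n)
  if (sd <= 0) return(numeric(n))
  if (phi == 0) return(sd * z)
  e <- numeric(n)
  e[1] <- rnorm(1)           # stationary start
  innov_sd <- sqrt(1 - phi^2)
  for (t in 2:n) e[t] <- phi * e[t - 1] + innov_sd * z[t]
  sd * e
}
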