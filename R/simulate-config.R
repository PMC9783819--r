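#' Simulation configuration for the synthetic chronogram generator
#'
#' Full parameterization of the stochastic emission model used to emulate
#' the three experimental regimes of a plant-fungus volatile monitoring
#' study: a non-emitting background (`"medium"`, `"plant"`), constitutive
#' low-level bursty circadian fungal emission (`"fungus"`), and a
#' higher-amplitude, less skewed, more autocorrelated co-culture regime
#' (`"interaction"`).
#'
#' The generative model for one biological replicate is
#' \deqn{y(t) = A \, w(t) \, c(t) \, [b_0 + B(t)] + \beta + \epsilon(t),}
#' clipped at zero, where `w(t)` is a smooth emission-window envelope
#' rising from `emission_onset_day` to a maximum on `emission_peak_day`
#' and falling back to zero at `emission_offset_day`; `c(t)` is a
#' circadian factor peaking at `circadian_peak_hour` and additively
#' elevated during the dark phase of the photoperiod; `b_0` is the
#' constitutive emission level; `B(t)` is a shot-noise burst process
#' (Poisson arrivals, gamma amplitudes, exponential decay); `A` is
#' `amplitude_scale`; `beta` is the instrument baseline; and `epsilon` is
#' stationary AR(1) Gaussian instrument noise.  Technical replicates share
#' the biological replicate's noiseless signal and differ only in noise
#' draws.
#'
#' @param condition One of `"medium"`, `"plant"`, `"fungus"`,
#'   `"interaction"`.
#' @param duration_days Monitoring span, days (default 8).
#' @param sampling_interval_h Sampling interval, hours (default 1: hourly
#'   scans starting at inoculation).
#' @param n_biological,n_technical Replicate counts (defaults 3 and 3).
#' @param n_microscans Micro-scans averaged into each stored measurement
#'   (default 10); recorded for provenance, the generator emits the
#'   already-averaged intensity.
#' @param baseline Instrument baseline intensity (relative units).
#' @param noise_sd Marginal standard deviation of the AR(1) instrument
#'   noise on each technical replicate (additive floor).
#' @param noise_cv Proportional component of the measurement noise: the
#'   marginal noise SD at time t is `noise_sd + noise_cv * signal(t)`,
#'   the usual two-component intensity-variance model of MS quantitation
#'   (ambient plasma ionization is strongly intensity-dependent).
#' @param ar1_coeff Lag-1 autoregressive coefficient of the noise,
#'   strictly inside (-1, 1).
#' @param baseline_emission Constitutive noiseless emission level inside
#'   the emission window, before scaling.
#' @param burst_rate Expected burst arrivals per hour inside the window.
#' @param burst_scale Mean burst amplitude (gamma mean).
#' @param burst_shape Gamma shape of the burst-amplitude distribution;
#'   small values give heavier tails.
#' @param burst_decay_h Exponential decay time of a burst, hours.
#' @param circadian_amplitude Relative amplitude of the cosine circadian
#'   modulation (0 disables it).
#' @param circadian_peak_hour Clock hour of the circadian maximum
#'   (default 20, i.e. 20:00 at the onset of the dark phase).
#' @param dark_elevation Additive elevation of the envelope at the onset
#'   of the dark phase, as a fraction of the circadian mean level.
#' @param dark_pulse_h Width (hours) of the night emission pulse: the
#'   dark elevation is maximal at lights-off and decays to zero over this
#'   many hours; `Inf` keeps it flat across the night.
#' @param dark_pulse_shape Exponent of the pulse decay
#'   `(1 - u/dark_pulse_h)^shape`: values below 1 give a flat-topped,
#'   switch-like pulse, above 1 a fast early decay (default 1, linear).
#' @param lights_on_hour,lights_off_hour Clock hours delimiting the light
#'   phase of the 16:8 photoperiod (defaults 4 and 20: lights on
#'   04:00-20:00, dark 20:00-04:00, so the dark phase opens at the
#'   circadian emission peak).
#' @param emission_onset_day,emission_offset_day First and last day of
#'   emission (the window spans the start of the onset day to the end of
#'   the offset day); must satisfy
#'   `emission_onset_day < emission_offset_day <= duration_days`.
#' @param emission_peak_day Day on which the envelope is maximal (via
#'   the dome, see `peak_prominence`).
#' @param ramp_h Length of the half-cosine onset/offset ramps, hours
#'   (default 12): a smooth rise avoids discontinuity artifacts in the
#'   autocorrelation function.
#' @param peak_prominence Relative height of the slow productivity dome
#'   superimposed on the emission window (0 = flat plateau between the
#'   ramps; 1 doubles emission at the peak day relative to the plateau).
#' @param amplitude_scale Overall multiplier of the emission term.
#' @param inoculation_clock_hour Clock time of inoculation (default 8,
#'   i.e. 08:00 during lights-on), used to map elapsed hours to clock
#'   hours.
#' @param seed Integer seed; identical `(config, seed)` pairs yield
#'   bit-identical output.
#'
#' @return An object of class `simulation_config` (a validated named list).
#' @seealso [default_config()] for the calibrated per-condition defaults,
#'   [simulate_replicate_set()] for the generator itself.
#' @export
simulation_config <- function(condition,
                              duration_days = 8,
                              sampling_interval_h = 1,
                              n_biological = 3,
                              n_technical = 3,
                              n_microscans = 10,
                              baseline = 1e-3,
                              noise_sd = 2.7e-4,
                              noise_cv = 0,
                              ar1_coeff = 0.25,
                              baseline_emission = 0,
                              burst_rate = 0,
                              burst_scale = 0,
                              burst_shape = 1,
                              burst_decay_h = 2,
                              circadian_amplitude = 0,
                              circadian_peak_hour = 20,
                              dark_elevation = 0,
                              dark_pulse_h = Inf,
                              dark_pulse_shape = 1,
                              lights_on_hour = 4,
                              lights_off_hour = 20,
                              emission_onset_day = 3,
                              emission_offset_day = 8,
                              emission_peak_day = NULL,
                              ramp_h = 12,
                              peak_prominence = 0,
                              amplitude_scale = 1,
                              inoculation_clock_hour = 8,
                              seed = 1L) {
  conditions <- c("medium", "plant", "fungus", "interaction")
  if (length(condition) != 1L || !condition %in% conditions) {
    stop_ppchron("configuration", sprintf(
      "`condition` must be one of %s", paste(sQuote(conditions), collapse = ", ")
    ))
  }
  cfg <- list(
    condition = condition,
    duration_days = duration_days,
    sampling_interval_h = sampling_interval_h,
    n_biological = as.integer(n_biological),
    n_technical = as.integer(n_technical),
    n_microscans = as.integer(n_microscans),
    baseline = baseline,
    noise_sd = noise_sd,
    noise_cv = noise_cv,
    ar1_coeff = ar1_coeff,
    baseline_emission = baseline_emission,
    burst_rate = burst_rate,
    burst_scale = burst_scale,
    burst_shape = burst_shape,
    burst_decay_h = burst_decay_h,
    circadian_amplitude = circadian_amplitude,
    circadian_peak_hour = circadian_peak_hour,
    dark_elevation = dark_elevation,
    dark_pulse_h = dark_pulse_h,
    dark_pulse_shape = dark_pulse_shape,
    lights_on_hour = lights_on_hour,
    lights_off_hour = lights_off_hour,
    emission_onset_day = emission_onset_day,
    emission_offset_day = emission_offset_day,
    emission_peak_day = emission_peak_day %||%
      ((emission_onset_day + emission_offset_day) / 2),
    ramp_h = ramp_h,
    peak_prominence = peak_prominence,
    amplitude_scale = amplitude_scale,
    inoculation_clock_hour = inoculation_clock_hour,
    seed = as.integer(seed)
  )
  validate_simulation_config(cfg)
  structure(cfg, class = "simulation_config")
}

validate_simulation_config <- function(cfg) {
  num <- cfg[!(names(cfg) %in% c("condition", "dark_pulse_h"))]
  bad <- names(num)[!vapply(num, function(v) {
    is.numeric(v) && length(v) == 1L && is.finite(v)
  }, logical(1))]
  if (length(bad)) {
    stop_ppchron("configuration", sprintf(
      "non-finite or non-scalar parameter(s): %s", paste(bad, collapse = ", ")
    ))
  }
  if (!is.numeric(cfg$dark_pulse_h) || length(cfg$dark_pulse_h) != 1L ||
      is.na(cfg$dark_pulse_h) || cfg$dark_pulse_h <= 0) {
    stop_ppchron("configuration", "`dark_pulse_h` must be a positive number (Inf allowed)")
  }
  pos <- c("duration_days", "sampling_interval_h", "n_biological",
           "n_technical", "n_microscans", "burst_shape", "burst_decay_h",
           "amplitude_scale", "ramp_h", "dark_pulse_shape")
  for (p in pos) if (cfg[[p]] <= 0) {
    stop_ppchron("configuration", sprintf("`%s` must be > 0", p))
  }
  nonneg <- c("baseline", "noise_sd", "noise_cv", "baseline_emission", "burst_rate",
              "burst_scale", "circadian_amplitude", "dark_elevation",
              "emission_onset_day", "peak_prominence")
  for (p in nonneg) if (cfg[[p]] < 0) {
    stop_ppchron("configuration", sprintf("`%s` must be >= 0", p))
  }
  if (abs(cfg$ar1_coeff) >= 1) {
    stop_ppchron("configuration", "`ar1_coeff` must lie strictly in (-1, 1)")
  }
  if (!(cfg$emission_onset_day < cfg$emission_offset_day &&
        cfg$emission_offset_day <= cfg$duration_days)) {
    stop_ppchron(
      "configuration",
      "need emission_onset_day < emission_offset_day <= duration_days"
    )
  }
  if (cfg$circadian_peak_hour < 0 || cfg$circadian_peak_hour >= 24) {
    stop_ppchron("configuration", "`circadian_peak_hour` must lie in [0, 24)")
  }
  n <- cfg$duration_days * 24 / cfg$sampling_interval_h
  if (abs(n - round(n)) > 1e-8) {
    stop_ppchron("configuration",
                 "duration must be an integer multiple of the sampling interval")
  }
  invisible(cfg)
}

#' @export
print.simulation_config <- function(x, ...) {
  cat(sprintf(
    "<simulation_config> condition = %s, %d days @ %.2g h, %d bio x %d tech, seed %d\n",
    x$condition, x$duration_days, x$sampling_interval_h,
    x$n_biological, x$n_technical, x$seed
  ))
  invisible(x)
}

#' Calibrated per-condition simulator defaults
#'
#' Returns the package's calibrated [simulation_config()] for one of the
#' four experimental conditions.  The defaults encode the study
#' conditions the generator emulates — hourly sampling for 8 days, 3
#' biological x 3 technical replicates — and are calibrated so the
#' biological-mean chronogram of each condition reproduces the
#' descriptor values characteristic of its regime:
#'
#' * `"medium"`, `"plant"`: no emission; mildly autocorrelated
#'   instrument noise (AR(1) coefficient 0.25, which yields a Poincare
#'   SD1/SD2 ratio near 0.78).
#' * `"fungus"`: constitutive low-level circadian emission from day 2 to
#'   day 6, peaking on day 4, with heavy-tailed bursts; seed-averaged
#'   skewness near 3.5 and excess kurtosis near 11.7, SD1/SD2 near 0.59,
#'   hour-of-day maximum at 20:00 with night emission above day emission.
#' * `"interaction"`: emission from day 3 to day 8 peaking on day 5,
#'   with `amplitude_scale` set so total production (AUC of the
#'   biological-mean chronogram) is about five-fold the fungus-alone
#'   default; skewness near 2.4, excess kurtosis near 6.0, SD1/SD2 near
#'   0.52.
#'
#' @param condition One of `"medium"`, `"plant"`, `"fungus"`,
#'   `"interaction"`.
#' @param seed Integer seed stored in the returned config.
#' @return A [simulation_config()].
#' @export
#' @examples
#' default_config("fungus")
default_config <- function(condition, seed = 1L) {
  if (length(condition) != 1L ||
      !condition %in% c("medium", "plant", "fungus", "interaction")) {
    stop_ppchron("configuration", sprintf(
      "unknown condition %s", sQuote(as.character(condition)[1])
    ))
  }
  switch(condition,
    medium = ,
    plant = simulation_config(
      condition = condition,
      baseline = 1e-3, noise_sd = 2.7e-4, ar1_coeff = 0.25,
      baseline_emission = 0, burst_rate = 0, burst_scale = 0,
      circadian_amplitude = 0, dark_elevation = 0,
      amplitude_scale = 1, seed = seed
    ),
    fungus = simulation_config(
      condition = "fungus",
      baseline = 1e-3, noise_sd = 2.7e-4, noise_cv = 0.1, ar1_coeff = 0.25,
      baseline_emission = 0.008, burst_rate = 0.2,
      burst_scale = 0.003, burst_shape = 2, burst_decay_h = 0.5,
      circadian_amplitude = 0.15, dark_elevation = 6.3,
      dark_pulse_h = 2.65, dark_pulse_shape = 1,
      emission_onset_day = 2, emission_offset_day = 6,
      emission_peak_day = 4, peak_prominence = 0,
      amplitude_scale = 1, seed = seed
    ),
    interaction = simulation_config(
      condition = "interaction",
      baseline = 1e-3, noise_sd = 2.7e-4, noise_cv = 0.1, ar1_coeff = 0.25,
      baseline_emission = 0.008, burst_rate = 0.2,
      burst_scale = 0.0015, burst_shape = 2, burst_decay_h = 0.5,
      circadian_amplitude = 0.15, dark_elevation = 7.25,
      dark_pulse_h = 3, dark_pulse_shape = 0.12,
      emission_onset_day = 3, emission_offset_day = 8,
      emission_peak_day = 5, peak_prominence = 0.4,
      amplitude_scale = 3.117, seed = seed
    )
  )
}
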