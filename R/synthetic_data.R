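#' Configuration for a synthetic flow-cell release experiment
#'
#' Study conditions mirror the flow-cell protocol: spectra every 10 s, a 2 h
#' neutral (pH 7.4) stabilization phase followed by 10 h at pH 5.0, preceded
#' by a wetting segment in which the pores are still dry (air medium). The
#' ground truth is the characteristic decay time of the in-pore cargo volume
#' fraction once the acidic phase starts.
#'
#' @param design A [gif_design()]; the default uses a pore-widened structure
#'   (20% porosity) so the air-to-water wetting redshift is in the tens of
#'   nanometres, as observed for such filters.
#' @param true_t_release Characteristic decay time (s) of the cargo fraction
#'   during release.
#' @param true_amplitude_f_drug Initial in-pore cargo volume fraction.
#' @param sampling_interval Spectrum sampling interval (s).
#' @param total_duration Duration (s) from t = 0 (stabilization start) to the
#'   end of the experiment; default 12 h.
#' @param wetting_duration Duration (s) of the pre-wetting segment (negative
#'   times); default 30 min.
#' @param stabilization_duration Duration (s) at the neutral pH before the
#'   acid switch; default 2 h.
#' @param noise_sigma Gaussian noise s.d. as a fraction of the maximum clean
#'   intensity.
#' @param seed Integer seed for the noise generator.
#' @return An object of class `synthetic_release_config`.
#' @export
synthetic_release_config <- function(design = gif_design(f_host_avg = 0.8),
                                     true_t_release = 17289,
                                     true_amplitude_f_drug = 0.001,
                                     sampling_interval = 10,
                                     total_duration = 43200,
                                     wetting_duration = 1800,
                                     stabilization_duration = 7200,
                                     noise_sigma = 0.01,
                                     seed = 0) {
  stopifnot(inherits(design, "gif_design"))
  if (!is_scalar_num(true_t_release) || true_t_release <= 0)
    err_invalid("`true_t_release` must be > 0")
  for (nm in c("sampling_interval", "total_duration", "wetting_duration",
               "stabilization_duration")) {
    v <- get(nm)
    if (!is_scalar_num(v) || v <= 0) err_invalid(sprintf("`%s` must be > 0", nm))
  }
  if (stabilization_duration >= total_duration)
    err_invalid("`stabilization_duration` must be shorter than `total_duration`")
  if (!is_scalar_num(noise_sigma) || noise_sigma < 0)
    err_invalid("`noise_sigma` must be >= 0")
  if (true_amplitude_f_drug < 0 ||
      design$f_host_avg + design$f_ampl + true_amplitude_f_drug > 1)
    err_invalid("`true_amplitude_f_drug` inadmissible for the design")
  structure(list(design = design, true_t_release = true_t_release,
                 true_amplitude_f_drug = true_amplitude_f_drug,
                 sampling_interval = sampling_interval,
                 total_duration = total_duration,
                 wetting_duration = wetting_duration,
                 stabilization_duration = stabilization_duration,
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "synthetic_release_config")
}

# Replace the drug fraction of a design (re-validating).
.with_f_drug <- function(design, f_drug, surface = NULL, medium = NULL) {
  args <- unclass(design)
  args$f_drug <- f_drug
  if (!is.null(surface)) args$surface_layer_thickness <- surface
  if (!is.null(medium)) args$medium_index <- medium
  do.call(gif_design, args)
}

#' Synthetic drop/dry loading series
#'
#' Emulates successive drop/dry loading cycles: one forward-simulated
#' spectrum per cargo volume fraction in `f_drug_sequence` (nondecreasing,
#' as each cycle adds cargo), with optional seeded Gaussian noise. With
#' rising loading both stopbands lose height, the signal band faster, so the
#' band ratio falls over the series.
#'
#' @param design A [gif_design()] (its `f_drug` is overridden per cycle).
#' @param f_drug_sequence Nondecreasing cargo volume fractions, one per
#'   cycle.
#' @param materials Material set.
#' @param wavelengths Grid (nm).
#' @param noise_sigma Gaussian noise s.d. as a fraction of each spectrum's
#'   maximum; 0 gives the exact forward simulation.
#' @param seed Integer seed.
#' @param angle Incidence angle (degrees).
#' @return List of [spectrum()] objects (reflectance when `noise_sigma = 0`,
#'   intensity otherwise).
#' @export
generate_dropdry_series <- function(design, f_drug_sequence,
                                    materials = default_materials(),
                                    wavelengths = seq(400, 900, by = 1),
                                    noise_sigma = 0, seed = 0, angle = 0) {
  if (length(f_drug_sequence) < 1 || any(diff(f_drug_sequence) < 0))
    err_invalid("`f_drug_sequence` must be nondecreasing")
  set.seed(as.integer(seed))
  lapply(f_drug_sequence, function(fd) {
    sp <- simulate_gif_spectrum(.with_f_drug(design, fd), materials,
                                wavelengths, angle = angle)
    if (noise_sigma > 0) {
      v <- sp$value + stats::rnorm(nrow(sp), sd = noise_sigma * max(sp$value))
      sp <- spectrum(sp$wavelength_nm, v, "intensity")
    }
    sp
  })
}

#' Synthetic flow-cell release time series
#'
#' Generates the spectral time series of a full flow-cell run: a wetting
#' segment with air-filled pores (t < 0), a neutral-pH stabilization phase
#' with water-filled pores and the full cargo loading, and a release phase
#' in which the in-pore cargo fraction decays exponentially with the
#' configured characteristic time, which the optics converts into a rising
#' signal/reference band ratio. Switching the pore medium from air to water
#' at t = 0 produces the wetting redshift of both stopbands. Seeded Gaussian
#' noise is added to the intensities.
#'
#' To keep long series tractable the noise-free spectrum is tabulated at
#' `f_drug_knots` equally spaced cargo fractions spanning the release range
#' and interpolated linearly in the cargo fraction in between (exact at the
#' knots; the interpolation error is second order in the knot spacing).
#'
#' @param config A [synthetic_release_config()].
#' @param materials Material set.
#' @param wavelengths Grid (nm).
#' @param f_drug_knots Number of tabulation knots (>= 2).
#' @param angle Incidence angle (degrees).
#' @return A [spectral_time_series()] with the pH schedule attached
#'   (NA during wetting, 7.4 during stabilization, 5.0 during release).
#' @export
generate_release_timeseries <- function(config,
                                        materials = default_materials(),
                                        wavelengths = seq(400, 1000, by = 2),
                                        f_drug_knots = 25, angle = 0) {
  stopifnot(inherits(config, "synthetic_release_config"))
  if (f_drug_knots < 2) err_invalid("`f_drug_knots` must be >= 2")
  dt <- config$sampling_interval
  times <- seq(-config$wetting_duration, config$total_duration, by = dt)
  t_switch <- config$stabilization_duration
  f0 <- config$true_amplitude_f_drug
  f_t <- ifelse(times < t_switch, f0,
                f0 * exp(-(times - t_switch) / config$true_t_release))

  # base spectra: dry (air medium) at full loading, and wet knots in f_drug
  dry <- simulate_gif_spectrum(.with_f_drug(config$design, f0, medium = 1.0),
                               materials, wavelengths, angle = angle)
  f_end <- min(f_t)
  knots <- seq(f_end, f0, length.out = f_drug_knots)
  wet_tab <- vapply(knots, function(fd) {
    simulate_gif_spectrum(.with_f_drug(config$design, fd, medium = 1.33),
                          materials, wavelengths, angle = angle)$value
  }, numeric(length(wavelengths)))

  W <- length(wavelengths)
  intens <- matrix(0, W, length(times))
  pre <- times < 0
  intens[, pre] <- dry$value
  for (i in which(!pre)) {
    f <- f_t[i]
    if (f <= knots[1]) { intens[, i] <- wet_tab[, 1]; next }
    if (f >= knots[f_drug_knots]) { intens[, i] <- wet_tab[, f_drug_knots]; next }
    k <- findInterval(f, knots)
    w <- (f - knots[k]) / (knots[k + 1] - knots[k])
    intens[, i] <- (1 - w) * wet_tab[, k] + w * wet_tab[, k + 1]
  }
  sched <- data.frame(start_time_s = c(-config$wetting_duration, 0, t_switch),
                      ph = c(NA, 7.4, 5.0))
  series <- spectral_time_series(times, wavelengths, intens, sched, "intensity")
  if (config$noise_sigma > 0)
    series <- add_intensity_noise(series, config$noise_sigma, config$seed)
  series
}

#' Add seeded Gaussian intensity noise to a spectral time series
#'
#' Adds i.i.d. Gaussian noise with standard deviation
#' `noise_sigma * max(intensities)` to every intensity sample (floored just
#' above zero). This is exactly the noise model of
#' [generate_release_timeseries()], exposed separately so replicate studies
#' can reuse one noise-free series: adding noise with seed `s` to the clean
#' series is bit-identical to generating the whole series with
#' `noise_sigma` and seed `s`.
#'
#' @param series A [spectral_time_series()] (noise-free).
#' @param noise_sigma Noise s.d. as a fraction of the maximum intensity.
#' @param seed Integer seed.
#' @return A [spectral_time_series()] with noisy intensities.
#' @export
add_intensity_noise <- function(series, noise_sigma, seed = 0) {
  stopifnot(inherits(series, "spectral_time_series"))
  if (!is_scalar_num(noise_sigma) || noise_sigma < 0)
    err_invalid("`noise_sigma` must be >= 0")
  if (noise_sigma == 0) return(series)
  set.seed(as.integer(seed))
  intens <- series$intensities +
    stats::rnorm(length(series$intensities),
                 sd = noise_sigma * max(series$intensities))
  intens[intens < 1e-9] <- 1e-9
  spectral_time_series(series$times, series$wavelengths, intens,
                       series$ph_schedule, series$kind)
}

#' Sample the anchored exponential release model directly
#'
#' Evaluates `R(t) = r_max + amplitude * (1 - exp(-(t - t_max)/t_release))`
#' at the given times, adds seeded Gaussian noise, and labels every point as
#' release phase. Useful for fitting round-trips and parameter-recovery
#' studies without the optics in the loop.
#'
#' @param r_max,t_max Anchor ratio and time.
#' @param amplitude Ratio amplitude A.
#' @param t_release Characteristic release time (s), > 0.
#' @param times Sampling times (s).
#' @param noise_sigma Gaussian noise s.d. (absolute, on the ratio).
#' @param seed Integer seed.
#' @return A [band_ratio_trace()] with all points labelled `"release"`.
#' @export
generate_ratio_trace <- function(r_max, t_max, amplitude, t_release, times,
                                 noise_sigma = 0, seed = 0) {
  if (!is_scalar_num(t_release) || t_release <= 0)
    err_invalid("`t_release` must be > 0")
  r <- r_max + amplitude * (1 - exp(-(times - t_max) / t_release))
  if (noise_sigma > 0) {
    set.seed(as.integer(seed))
    r <- r + stats::rnorm(length(times), sd = noise_sigma)
  }
  band_ratio_trace(times, pmax(r, 1e-12), rep("release", length(times)))
}
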