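coarse_wl <- seq(420, 1000, 4)

test_that("drop/dry generator is seed-deterministic and trend-correct", {
  d <- small_design()
  fseq <- c(0, 0.02, 0.04, 0.06)
  a <- generate_dropdry_series(d, fseq, wavelengths = coarse_wl,
                               noise_sigma = 0.01, seed = 5)
  b <- generate_dropdry_series(d, fseq, wavelengths = coarse_wl,
                               noise_sigma = 0.01, seed = 5)
  expect_identical(a, b)
  c2 <- generate_dropdry_series(d, fseq, wavelengths = coarse_wl,
                                noise_sigma = 0.01, seed = 6)
  expect_false(identical(a, c2))

  # noise-free series: band ratio strictly decreasing with loading
  clean <- generate_dropdry_series(d, fseq, wavelengths = coarse_wl)
  bands <- oracle_bands(d)
  ratios <- vapply(clean, band_ratio, 0, bands = bands)
  expect_true(all(diff(ratios) < 0))
  # and the noise-free spectra are the forward simulation itself
  expect_equal(clean[[1]]$value,
               simulate_gif_spectrum(d, wavelengths = coarse_wl)$value,
               tolerance = 1e-12)

  expect_error(generate_dropdry_series(d, c(0.05, 0.02)),
               class = "naagif_invalid_parameter")
})

test_that("flow-cell series shows wetting redshift and rising release ratio", {
  d <- small_design(f_host_avg = 0.8)
  cfg <- synthetic_release_config(design = d, true_t_release = 9000,
                                  true_amplitude_f_drug = 0.004,
                                  sampling_interval = 300,
                                  total_duration = 21600,
                                  wetting_duration = 1200,
                                  stabilization_duration = 3600,
                                  noise_sigma = 0, seed = 1)
  ser <- generate_release_timeseries(cfg, wavelengths = coarse_wl,
                                     f_drug_knots = 9)
  # container invariants hold by construction
  expect_s3_class(ser, "spectral_time_series")
  expect_true(all(diff(ser$times) > 0))
  expect_equal(dim(ser$intensities),
               c(length(coarse_wl), length(ser$times)))
  labels <- segment_phases(ser)
  expect_equal(length(labels), length(ser$times))
  expect_setequal(unique(labels), c("wetting", "stabilization", "release"))

  # wetting: air -> water produces a positive signal-band redshift
  iw <- max(which(ser$times < 0))
  i0 <- min(which(ser$times >= 0))
  br <- bragg_wavelengths(d)
  expect_gt(redshift(series_spectrum(ser, iw), series_spectrum(ser, i0),
                     br[["top"]] + c(-60, 40)), 0)

  # release phase: monotone rising band ratio (noise-free)
  tr <- extract_ratio_trace(ser, oracle_bands(d))
  rel <- tr$ratio[tr$phase == "release"]
  expect_true(all(diff(rel) > -1e-12))
  expect_gt(rel[length(rel)], rel[1])
  # stabilization phase is flat
  stab <- tr$ratio[tr$phase == "stabilization"]
  expect_lt(diff(range(stab)), 1e-9)
})

test_that("intensity noise injection is the generator's own noise model", {
  d <- small_design(f_host_avg = 0.8)
  base_args <- list(design = d, true_t_release = 9000,
                    true_amplitude_f_drug = 0.004, sampling_interval = 600,
                    total_duration = 14400, wetting_duration = 1200,
                    stabilization_duration = 3600)
  clean_cfg <- do.call(synthetic_release_config,
                       c(base_args, noise_sigma = 0))
  noisy_cfg <- do.call(synthetic_release_config,
                       c(base_args, noise_sigma = 0.02, seed = 17))
  clean <- generate_release_timeseries(clean_cfg, wavelengths = coarse_wl,
                                       f_drug_knots = 5)
  direct <- generate_release_timeseries(noisy_cfg, wavelengths = coarse_wl,
                                        f_drug_knots = 5)
  via_helper <- add_intensity_noise(clean, 0.02, seed = 17)
  expect_identical(direct$intensities, via_helper$intensities)
})

test_that("sampled release model hits its anchor and round-trips", {
  t <- seq(0, 36000, 60)
  tr <- generate_ratio_trace(1.4, 36000, 0.05, 17289, t)
  expect_equal(tr$ratio[tr$time_s == 36000], 1.4, tolerance = 1e-12)

  fit <- fit_release(tr)
  expect_lt(abs(fit$amplitude / 0.05 - 1), 1e-3)
  expect_lt(abs(fit$t_release / 17289 - 1), 1e-3)

  n1 <- generate_ratio_trace(1.4, 36000, 0.05, 17289, t, 0.01, seed = 3)
  n2 <- generate_ratio_trace(1.4, 36000, 0.05, 17289, t, 0.01, seed = 3)
  expect_identical(n1, n2)
})

test_that("inadmissible synthetic configurations are rejected", {
  expect_error(synthetic_release_config(true_t_release = -5),
               class = "naagif_invalid_parameter")
  expect_error(synthetic_release_config(true_amplitude_f_drug = 0.3,
                                        design = gif_design(f_host_avg = 0.9)),
               class = "naagif_invalid_parameter")
  expect_error(synthetic_release_config(stabilization_duration = 50000,
                                        total_duration = 40000),
               class = "naagif_invalid_parameter")
})
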