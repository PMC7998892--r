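# A minimal constant-spectrum series with the standard flow-cell schedule:
# wetting before t = 0, pH 7.4 from 0 to t_switch, pH 5.0 afterwards.
constant_series <- function(times, t_switch = 7200) {
  wl <- seq(400, 800, 10)
  vals <- exp(-(wl - 500)^2 / 800) + 0.8 * exp(-(wl - 700)^2 / 800)
  sched <- data.frame(start_time_s = c(min(times, 0), 0, t_switch),
                      ph = c(NA, 7.4, 5.0))
  spectral_time_series(times, wl, matrix(vals, length(wl), length(times)),
                       sched)
}

test_that("phases partition the flow-cell timeline per the pH schedule", {
  times <- seq(-1800, 43200, 600)
  labels <- segment_phases(constant_series(times))
  expect_equal(sum(labels == "wetting"), sum(times < 0))
  expect_equal(sum(labels == "stabilization"), sum(times >= 0 & times < 7200))
  expect_equal(sum(labels == "release"), sum(times >= 7200))
  expect_equal(length(labels), length(times))      # a partition

  # single-pH schedule: no release phase
  sched1 <- data.frame(start_time_s = 0, ph = 7.4)
  lab1 <- segment_phases(seq(0, 5000, 500), sched1)
  expect_true(all(lab1 == "stabilization"))

  # schedule gap is a configuration error
  bad <- data.frame(start_time_s = 100, ph = 7.4)
  expect_error(segment_phases(seq(0, 500, 100), bad),
               class = "naagif_config_error")
})

test_that("ratio traces of constant series are constant and label-complete", {
  times <- seq(-600, 21600, 300)
  ser <- constant_series(times)
  tr <- extract_ratio_trace(ser, band_definition(c(430, 560), c(600, 800)))
  expect_equal(nrow(tr), length(times))
  expect_equal(diff(range(tr$ratio)), 0, tolerance = 1e-12)
  expect_equal(tr$phase, segment_phases(ser))
})

test_that("noise-free anchored traces are recovered to 0.1%", {
  t <- seq(7200, 43200, 10)
  # anchored at the trace end; A small enough that the early ratio stays
  # positive (the anchored amplitude is the asymptotic rise scaled by
  # exp(-span/tau))
  true_A <- 0.04; true_tau <- 17289
  tr <- generate_ratio_trace(1.30, max(t), true_A, true_tau, t)
  fit <- fit_release(tr)
  expect_equal(fit$r_max, 1.30, tolerance = 1e-9)   # anchor fixed, not fitted
  expect_equal(fit$t_max, 43200)
  expect_lt(abs(fit$amplitude / true_A - 1), 1e-3)
  expect_lt(abs(fit$t_release / true_tau - 1), 1e-3)
  # fitted curve passes exactly through the anchor
  expect_equal(predict_release(fit, fit$t_max), fit$r_max, tolerance = 1e-12)
  # and the fitted-anchor variant agrees on noise-free data
  fit3 <- fit_release(tr, anchor = "fitted")
  expect_lt(abs(fit3$t_release / true_tau - 1), 1e-3)
  expect_equal(fit3$r_anchor_fit, 1.30, tolerance = 1e-6)
})

test_that("fits are invariant under uniform time translation", {
  t <- seq(0, 36000, 60)
  tr <- generate_ratio_trace(1.2, max(t), 0.02, 13588, t)
  shifted <- band_ratio_trace(tr$time_s + 5e4, tr$ratio, tr$phase)
  f1 <- fit_release(tr)
  f2 <- fit_release(shifted)
  expect_equal(f1$t_release, f2$t_release, tolerance = 1e-9)
  expect_equal(f1$amplitude, f2$amplitude, tolerance = 1e-9)
  expect_equal(f2$t_max - f1$t_max, 5e4)
})

test_that("flat traces report a degenerate fit instead of a spurious time", {
  t <- seq(0, 10000, 100)
  tr <- band_ratio_trace(t, rep(1.1, length(t)), rep("release", length(t)))
  fit <- fit_release(tr)
  expect_true(fit$degenerate)
  expect_true(is.na(fit$t_release))
  expect_equal(fit$amplitude, 0)
})

test_that("too few release points is an explicit error", {
  tr <- band_ratio_trace(c(0, 100, 200), c(1, 1.01, 1.02),
                         c("stabilization", "stabilization", "release"))
  expect_error(fit_release(tr), class = "naagif_insufficient_data")
})

test_that("stabilization points on the curve do not change the fit", {
  t_rel <- seq(7200, 36000, 30)
  tr_rel <- generate_ratio_trace(1.25, max(t_rel), 0.1, 20000, t_rel)
  # prepend stabilization points lying exactly on the model curve
  t_stab <- seq(0, 7170, 30)
  r_stab <- 1.25 + 0.1 * (1 - exp(-(t_stab - max(t_rel)) / 20000))
  tr_all <- band_ratio_trace(c(t_stab, tr_rel$time_s),
                             c(r_stab, tr_rel$ratio),
                             c(rep("stabilization", length(t_stab)),
                               tr_rel$phase))
  f_rel <- fit_release(tr_rel)
  f_all <- fit_release(tr_all)
  expect_equal(f_all$t_release, f_rel$t_release, tolerance = 1e-9)
  expect_equal(f_all$n_points_fit, nrow(tr_rel))   # others were excluded
})

test_that("release times across 5,000-50,000 s are recovered from noisy traces", {
  # 1% noise on the ratio, 10 s sampling over the 10 h release window;
  # fitted-anchor mode for noisy data (see vignette)
  t <- seq(7200, 43200, 10)
  for (tau in c(5000, 13588, 25000, 50000)) {
    # asymptotic ratio rise of 0.35, expressed as the anchored amplitude
    A_anch <- 0.35 * exp(-(max(t) - min(t)) / tau)
    errs <- vapply(1:25, function(k) {
      tr <- generate_ratio_trace(1.3, max(t), A_anch, tau, t,
                                 noise_sigma = 0.013, seed = 1000 + k)
      fit_release(tr, anchor = "fitted")$t_release / tau - 1
    }, 0)
    expect_lt(median(abs(errs)), 0.05)
  }
})

test_that("percent change reproduces the printed comparisons", {
  expect_equal(percent_change(13588, 17289), 27)
  expect_equal(percent_change(17289, 47038), 172)
  expect_equal(percent_change(123.4, 123.4), 0)
  expect_error(percent_change(0, 10), class = "naagif_invalid_parameter")
})
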