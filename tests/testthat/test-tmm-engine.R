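test_that("zero-contrast stacks do not reflect", {
  wl <- seq(400, 900, 25)
  idx <- matrix(1.33 + 0i, length(wl), 5)
  st <- optical_stack(wl, rep(100, 5), idx, 1.33, 1.33)
  expect_equal(compute_reflectance(st)$value, rep(0, length(wl)),
               tolerance = 1e-12)
})

test_that("bare interface matches the Fresnel closed form to 1e-10", {
  wl <- seq(400, 900, 10)
  st <- optical_stack(wl, numeric(0), numeric(0), 1.33, 1.66)
  R <- compute_reflectance(st)$value
  expect_true(all(abs(R - ((1.33 - 1.66) / (1.33 + 1.66))^2) < 1e-10))

  # oblique s and p against the analytic Fresnel coefficients
  th0 <- 35 * pi / 180
  th1 <- asin(1.33 * sin(th0) / 1.66)
  rs <- ((1.33 * cos(th0) - 1.66 * cos(th1)) /
         (1.33 * cos(th0) + 1.66 * cos(th1)))^2
  rp <- ((1.66 * cos(th0) - 1.33 * cos(th1)) /
         (1.66 * cos(th0) + 1.33 * cos(th1)))^2
  expect_lt(max(abs(compute_reflectance(st, 35, "s")$value - rs)), 1e-10)
  expect_lt(max(abs(compute_reflectance(st, 35, "p")$value - rp)), 1e-10)
})

test_that("single films match the Airy closed form to 1e-10", {
  wl <- seq(400, 900, 5)
  # lossless film
  st <- optical_stack(wl, 180, matrix(2.1 + 0i, length(wl), 1), 1.0, 1.52)
  expect_lt(max(abs(compute_reflectance(st)$value -
                    airy_reflectance(1.0, 2.1 + 0i, 1.52, 180, wl))), 1e-10)
  # absorbing film
  n1 <- 1.9 + 0.04i
  st2 <- optical_stack(wl, 250, matrix(n1, length(wl), 1), 1.33, 1.33)
  expect_lt(max(abs(compute_reflectance(st2)$value -
                    airy_reflectance(1.33, n1, 1.33, 250, wl))), 1e-10)
})

test_that("random multilayers agree with an independent Parratt recursion", {
  set.seed(11)
  for (rep in 1:5) {
    L <- sample(5:40, 1)
    ns <- complex(real = stats::runif(L, 1.3, 2.3),
                  imaginary = stats::runif(L, 0, 0.05))
    ds <- stats::runif(L, 20, 250)
    lam <- stats::runif(1, 420, 880)
    st <- optical_stack(lam, ds, matrix(ns, 1, L), 1.33, 1.52)
    expect_equal(compute_reflectance(st)$value,
                 parratt_reflectance(ns, ds, 1.33 + 0i, 1.52 + 0i, lam),
                 tolerance = 1e-9)
  }
})

test_that("energy is conserved for lossless stacks and dissipated otherwise", {
  wl <- seq(400, 900, 7)
  set.seed(3)
  L <- 25
  ns <- stats::runif(L, 1.35, 2.2)
  ds <- stats::runif(L, 30, 200)
  st <- optical_stack(wl, ds, matrix(rep(as.complex(ns), each = length(wl)),
                                     length(wl), L), 1.33, 1.52)
  for (ang in c(0, 8, 40)) for (pol in c("s", "p")) {
    sp <- compute_reflectance(st, ang, pol, keep_transmittance = TRUE)
    expect_lt(max(abs(sp$value + attr(sp, "transmittance") - 1)), 1e-9)
  }
  # absorbing version: R + T strictly below 1
  nsa <- ns + 0.02i
  sta <- optical_stack(wl, ds, matrix(rep(nsa, each = length(wl)),
                                      length(wl), L), 1.33, 1.52)
  spa <- compute_reflectance(sta, keep_transmittance = TRUE)
  expect_true(all(spa$value + attr(spa, "transmittance") < 1))
})

test_that("lossless stacks are reciprocal and polarization-degenerate at 0 deg", {
  wl <- seq(450, 850, 10)
  set.seed(5)
  L <- 12
  ns <- as.complex(stats::runif(L, 1.35, 2.2))
  ds <- stats::runif(L, 40, 180)
  fwd <- optical_stack(wl, ds, matrix(rep(ns, each = length(wl)),
                                      length(wl), L), 1.33, 1.66)
  rev <- optical_stack(wl, rev(ds), matrix(rep(rev(ns), each = length(wl)),
                                           length(wl), L), 1.66, 1.33)
  expect_equal(compute_reflectance(fwd)$value, compute_reflectance(rev)$value,
               tolerance = 1e-9)
  expect_equal(compute_reflectance(fwd, 0, "s")$value,
               compute_reflectance(fwd, 0, "p")$value, tolerance = 1e-12)
})

test_that("simulated GIF shows one stopband per stack at the Bragg positions", {
  d <- small_design()
  wl <- seq(420, 1000, 2)
  sp <- simulate_gif_spectrum(d, wavelengths = wl)
  br <- bragg_wavelengths(d)
  bands <- oracle_bands(d)
  sig <- locate_band_max(sp, bands$signal)
  ref <- locate_band_max(sp, bands$reference)
  # band maxima lie within a 25-period stack's bandwidth of the Bragg
  # estimates (the finite stack broadens and slightly skews the bands)
  expect_lt(abs(sig$peak_wavelength - br[["top"]]), 25)
  expect_lt(abs(ref$peak_wavelength - br[["bottom"]]), 25)
  # the stopbands dominate the fringe background away from the bands
  bg <- sp$value[abs(sp$wavelength_nm - br[["top"]]) > 60 &
                 abs(sp$wavelength_nm - br[["bottom"]]) > 60]
  expect_gt(sig$peak_height, 2.5 * max(bg))
  expect_gt(ref$peak_height, 1.5 * max(bg))
})

test_that("band maxima converge as the discretization is refined", {
  # Richardson-style check: the staircase approximation weakens the index
  # modulation's first harmonic by sinc(pi/m), so the band maximum
  # converges as the layers-per-period count doubles
  wl <- seq(500, 570, 0.5)
  m <- vapply(c(8L, 16L, 32L), function(lpp)
    max(simulate_gif_spectrum(small_design(layers_per_period = lpp),
                              wavelengths = wl)$value), 0)
  err8 <- abs(m[1] - m[3]) / m[3]
  err16 <- abs(m[2] - m[3]) / m[3]
  expect_lt(err16, err8)       # refinement shrinks the error
  expect_lt(err16, 0.01)       # 16 layers/period within 1% of converged
  expect_lt(err8, 0.03)        # 8 layers/period already close
})

test_that("stacks validate their structure", {
  wl <- seq(400, 500, 10)
  expect_error(optical_stack(wl, c(100, -5), matrix(1.5 + 0i, length(wl), 2),
                             1, 1), class = "naagif_invalid_parameter")
  expect_error(optical_stack(wl, 100, matrix(1.5 + 0i, 3, 1), 1, 1),
               class = "naagif_structural_error")
  st <- optical_stack(wl, 100, matrix(1.5 + 0i, length(wl), 1), 1, 1)
  expect_error(compute_reflectance(st, angle = 95),
               class = "naagif_invalid_parameter")
})
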