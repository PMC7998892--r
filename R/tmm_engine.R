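#' Spectrum container
#'
#' A wavelength-indexed spectrum: calibrated reflectance (values in
#' `[0, 1]`) or raw intensity (arbitrary units).
#'
#' @param wavelengths Strictly increasing grid (nm).
#' @param values Reflectance or intensity values.
#' @param kind Either "reflectance" or "intensity".
#' @return An object of class `naagif_spectrum` (also a data.frame with
#'   columns `wavelength_nm`, `value`).
#' @export
spectrum <- function(wavelengths, values, kind = c("reflectance", "intensity")) {
  kind <- match.arg(kind)
  .check_grid(wavelengths)
  if (length(values) != length(wavelengths))
    err_invalid("values and wavelengths must have equal length")
  if (kind == "reflectance" && (any(values < -1e-9) || any(values > 1 + 1e-9)))
    err_invalid("reflectance values must lie in [0, 1]")
  s <- data.frame(wavelength_nm = as.numeric(wavelengths),
                  value = as.numeric(values))
  attr(s, "kind") <- kind
  class(s) <- c("naagif_spectrum", "data.frame")
  s
}

#' @export
print.naagif_spectrum <- function(x, ...) {
  cat(sprintf("%s spectrum: %d points, %g-%g nm, values [%.4g, %.4g]\n",
              attr(x, "kind"), nrow(x), min(x$wavelength_nm),
              max(x$wavelength_nm), min(x$value), max(x$value)))
  invisible(x)
}

#' Optical stack for the transfer-matrix method
#'
#' @param wavelengths Grid (nm).
#' @param thicknesses Layer thicknesses (nm), incidence-side first; may be
#'   empty (bare interface).
#' @param indices Complex matrix `length(wavelengths) x length(thicknesses)`
#'   of layer refractive indices (`Im >= 0`), or a vector of
#'   wavelength-independent layer indices.
#' @param incident_index,exit_index Complex index of the incident and exit
#'   media, scalar or one value per wavelength.
#' @return An object of class `optical_stack`.
#' @export
optical_stack <- function(wavelengths, thicknesses, indices,
                          incident_index, exit_index) {
  .check_grid(wavelengths)
  W <- length(wavelengths)
  L <- length(thicknesses)
  if (L > 0 && any(thicknesses <= 0)) err_invalid("all thicknesses must be > 0")
  if (L == 0) {
    idx <- matrix(complex(0), W, 0)
  } else if (is.matrix(indices)) {
    if (nrow(indices) != W || ncol(indices) != L)
      err_structural("index matrix must be length(wavelengths) x n_layers")
    idx <- indices
  } else {
    if (length(indices) != L)
      err_structural("per-layer index vector must match the number of layers")
    idx <- matrix(rep(as.complex(indices), each = W), W, L)
  }
  if (L > 0 && any(Im(idx) < -1e-12)) err_invalid("layer indices must have Im >= 0")
  expand <- function(v) {
    v <- as.complex(v)
    if (length(v) == 1) rep(v, W)
    else if (length(v) == W) v
    else err_structural("incident/exit index must be scalar or match the grid")
  }
  structure(list(wavelengths = as.numeric(wavelengths),
                 thicknesses = as.numeric(thicknesses),
                 indices = idx,
                 incident_index = expand(incident_index),
                 exit_index = expand(exit_index)),
            class = "optical_stack")
}

# cos(theta) in a layer from Snell's law. The recursion below works in the
# e^{i(omega t - k z)} convention where absorbing indices are n - ik, so the
# decaying-evanescent branch is the one with Im(n cos) <= 0; for lossless
# propagating waves the positive real branch.
.cos_theta <- function(n, kx) {
  ct <- sqrt(1 - (kx / n)^2)
  flip <- Im(n * ct) > 1e-14 | (abs(Im(n * ct)) <= 1e-14 & Re(ct) < 0)
  ct[flip] <- -ct[flip]
  ct
}

# Characteristic-matrix recursion for one polarization, vectorized over
# wavelengths. Returns list(R, T). Public containers carry n + ik; indices
# are conjugated here to match the matrix convention (R and T are
# convention-independent magnitudes).
.tmm_pol <- function(stack, angle_rad, pol) {
  lam <- stack$wavelengths
  n0 <- Conj(stack$incident_index)
  ns <- Conj(stack$exit_index)
  kx <- n0 * sin(angle_rad)
  ct0 <- .cos_theta(n0, kx)
  cts <- .cos_theta(ns, kx)
  eta0 <- if (pol == "s") n0 * ct0 else n0 / ct0
  etas <- if (pol == "s") ns * cts else ns / cts
  B <- rep(1 + 0i, length(lam))
  C <- etas
  L <- length(stack$thicknesses)
  if (L > 0) {
    for (j in rev(seq_len(L))) {
      nj <- Conj(stack$indices[, j])
      ctj <- .cos_theta(nj, kx)
      delta <- 2 * pi * nj * stack$thicknesses[j] * ctj / lam
      etaj <- if (pol == "s") nj * ctj else nj / ctj
      cd <- cos(delta)
      sd <- 1i * sin(delta)
      Bn <- cd * B + (sd / etaj) * C
      C <- etaj * sd * B + cd * C
      B <- Bn
    }
  }
  denom <- eta0 * B + C
  r <- (eta0 * B - C) / denom
  R <- Mod(r)^2
  T <- 4 * Re(eta0) * Re(etas) / Mod(denom)^2
  list(R = R, T = T)
}

#' Reflectance of a layered stack by the transfer-matrix method
#'
#' Builds each layer's 2x2 characteristic matrix from its phase thickness
#' `(2*pi/lambda) * n * d * cos(theta)` (complex Snell law) and optical
#' admittance, multiplies the matrices in order, applies the incident and
#' exit media, and returns `R = |r|^2`. Unpolarized light is the mean of the
#' s and p reflectances (identical at normal incidence).
#'
#' @param stack An [optical_stack()].
#' @param angle Angle of incidence in degrees, `0 <= angle < 90`.
#' @param polarization "s", "p" or "unpolarized".
#' @param keep_transmittance If TRUE, attach the transmittance as attribute
#'   `"transmittance"` (for lossless stacks `R + T = 1`).
#' @return A reflectance [spectrum()].
#' @examples
#' st <- optical_stack(seq(400, 900, 10), numeric(0), numeric(0), 1.33, 1.66)
#' max(compute_reflectance(st)$value)  # single-interface Fresnel, ~0.0122
#' @export
compute_reflectance <- function(stack, angle = 0,
                                polarization = c("unpolarized", "s", "p"),
                                keep_transmittance = FALSE) {
  stopifnot(inherits(stack, "optical_stack"))
  polarization <- match.arg(polarization)
  if (!is_scalar_num(angle) || angle < 0 || angle >= 90)
    err_invalid("`angle` must satisfy 0 <= angle < 90 degrees")
  a <- angle * pi / 180
  if (polarization == "unpolarized" && angle == 0) {
    out <- .tmm_pol(stack, a, "s")       # s = p at normal incidence
  } else if (polarization == "unpolarized") {
    s <- .tmm_pol(stack, a, "s")
    p <- .tmm_pol(stack, a, "p")
    out <- list(R = (s$R + p$R) / 2, T = (s$T + p$T) / 2)
  } else {
    out <- .tmm_pol(stack, a, polarization)
  }
  if (any(out$R < -1e-9) || any(out$R > 1 + 1e-9))
    err_numerical("reflectance left [0, 1] beyond numerical tolerance")
  sp <- spectrum(stack$wavelengths, pmin(pmax(out$R, 0), 1), "reflectance")
  if (keep_transmittance) attr(sp, "transmittance") <- out$T
  sp
}

#' Forward simulation of a NAA-GIF reflectance spectrum
#'
#' Full forward model: discretizes the design into a composition profile,
#' converts every distinct layer composition to an effective complex index
#' with the Bruggeman rule (pure-cargo surface film uses the cargo index
#' directly), and computes the reflectance by the transfer-matrix method
#' with the release medium as both incident and exit medium (the structure
#' is free-standing: no substrate). The result exhibits one photonic
#' stopband per rugate stack.
#'
#' @param design A [gif_design()].
#' @param materials Material set ([default_materials()]); the medium entry
#'   is overridden by `design$medium_index`.
#' @param wavelengths Grid (nm); default 400-900 nm in 1 nm steps.
#' @param angle Incidence angle in degrees (default 0).
#' @param polarization "unpolarized" (default), "s" or "p".
#' @return A reflectance [spectrum()].
#' @examples
#' d <- gif_design(n_periods_top = 20, n_periods_bottom = 20)
#' s <- simulate_gif_spectrum(d, wavelengths = seq(420, 1000, 4))
#' @export
simulate_gif_spectrum <- function(design, materials = default_materials(),
                                  wavelengths = seq(400, 900, by = 1),
                                  angle = 0,
                                  polarization = "unpolarized") {
  stopifnot(inherits(design, "gif_design"))
  materials$medium <- material_constant(design$medium_index, label = "medium")
  profile <- build_composition_profile(design)
  stack <- .stack_from_profile(profile, materials, wavelengths,
                               design$medium_index)
  compute_reflectance(stack, angle = angle, polarization = polarization)
}

# Build an optical_stack from a composition profile, caching the Bruggeman
# mix over the distinct compositions (a rugate stack has only
# layers_per_period distinct ones).
.stack_from_profile <- function(profile, materials, wavelengths, medium_index) {
  W <- length(wavelengths)
  key <- paste(signif(profile$f_host, 12), signif(profile$f_drug, 12),
               signif(profile$f_medium, 12))
  uk <- !duplicated(key)
  n_drug <- NULL
  idx <- matrix(0 + 0i, W, nrow(profile))
  cache <- new.env(parent = emptyenv())
  for (i in which(uk)) {
    fh <- profile$f_host[i]; fd <- profile$f_drug[i]; fm <- profile$f_medium[i]
    n_layer <- if (fd >= 1 - 1e-12) {
      if (is.null(n_drug)) n_drug <- material_index(materials$drug, wavelengths)
      n_drug
    } else {
      eps <- effective_permittivity(fh, fd, fm, materials, wavelengths)
      nl <- sqrt(eps)
      ifelse(Im(nl) < 0, -nl, nl)
    }
    assign(key[i], n_layer, envir = cache)
  }
  for (i in seq_len(nrow(profile))) idx[, i] <- get(key[i], envir = cache)
  optical_stack(wavelengths, profile$thickness_nm, idx,
                incident_index = medium_index, exit_index = medium_index)
}

#' Bragg-condition stopband positions
#'
#' First-order Bragg estimate of the two stopband centres,
#' `lambda = 2 * n_eff * period`, where `n_eff` is the Bruggeman effective
#' index of the average layer composition evaluated self-consistently at the
#' band position (fixed-point iteration to absorb host dispersion). Used as
#' an independent cross-check on the transfer-matrix stopband positions.
#'
#' @param design A [gif_design()].
#' @param materials Material set.
#' @return Named numeric vector `c(top = , bottom = )` of wavelengths (nm).
#' @export
bragg_wavelengths <- function(design, materials = default_materials()) {
  materials$medium <- material_constant(design$medium_index, label = "medium")
  f_h <- design$f_host_avg
  f_d <- design$f_drug
  f_m <- 1 - f_h - f_d
  one <- function(period) {
    lam <- 2 * 1.6 * period
    for (i in 1:20) {
      lam_clamped <- min(max(lam, 301), 999)
      eps <- effective_permittivity(f_h, f_d, f_m, materials, lam_clamped)
      n_eff <- Re(sqrt(eps))
      lam_new <- 2 * n_eff * period
      if (abs(lam_new - lam) < 1e-6) { lam <- lam_new; break }
      lam <- lam_new
    }
    lam
  }
  c(top = one(design$period_top), bottom = one(design$period_bottom))
}
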