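#' Material models
#'
#' Constructors for the wavelength-dependent complex refractive index models
#' used by the optics engine: a constant index, a two-term Cauchy law
#' (normal dispersion), a single Lorentz oscillator (absorbing cargo
#' molecule), and a tabulated index interpolated from data.
#'
#' @param n,k Real and imaginary parts for the constant model (`k >= 0`).
#' @param A,B Cauchy coefficients, `n(lambda) = A + B/lambda^2` with lambda
#'   in nm.
#' @param eps_inf High-frequency permittivity (>= 1).
#' @param resonance_wavelength Oscillator resonance position lambda0 (nm).
#' @param strength Dimensionless oscillator strength (>= 0); in the
#'   long-wavelength limit the permittivity tends to `eps_inf + strength`.
#' @param damping Dimensionless damping ratio gamma/omega0 (> 0); sets the
#'   absorption bandwidth (FWHM in wavelength approximately
#'   `damping * resonance_wavelength`).
#' @param wavelengths,n_values,k_values Grid and values for the tabulated
#'   model.
#' @param label Short text label.
#' @return An object of class `naagif_material`.
#' @name materials
NULL

.material <- function(type, params, label) {
  structure(list(type = type, params = params, label = label),
            class = "naagif_material")
}

#' @rdname materials
#' @export
material_constant <- function(n, k = 0, label = "constant") {
  if (!is_scalar_num(n) || n < 1) err_invalid("constant index `n` must be >= 1")
  if (!is_scalar_num(k) || k < 0) err_invalid("`k` must be >= 0 (passive material)")
  .material("constant", list(n = n, k = k), label)
}

#' @rdname materials
#' @export
material_cauchy <- function(A = 1.62, B = 12000, label = "cauchy") {
  if (!is_scalar_num(A) || !is_scalar_num(B) || A <= 0 || B < 0)
    err_invalid("Cauchy coefficients must be positive")
  .material("cauchy", list(A = A, B = B), label)
}

#' @rdname materials
#' @export
material_lorentz <- function(eps_inf = 1.96, resonance_wavelength = 530,
                             strength = 0.05, damping = 0.17,
                             label = "lorentz") {
  if (!is_scalar_num(eps_inf) || eps_inf < 1) err_invalid("`eps_inf` must be >= 1")
  if (!is_scalar_num(resonance_wavelength) || resonance_wavelength <= 0)
    err_invalid("`resonance_wavelength` must be > 0")
  if (!is_scalar_num(strength) || strength < 0) err_invalid("`strength` must be >= 0")
  if (!is_scalar_num(damping) || damping <= 0) err_invalid("`damping` must be > 0")
  .material("lorentz", list(eps_inf = eps_inf,
                            resonance_wavelength = resonance_wavelength,
                            strength = strength, damping = damping), label)
}

#' @rdname materials
#' @export
material_table <- function(wavelengths, n_values, k_values = 0,
                           label = "table") {
  if (length(wavelengths) < 2 || any(diff(wavelengths) <= 0))
    err_invalid("table wavelengths must be strictly increasing")
  k_values <- rep_len(k_values, length(wavelengths))
  if (length(n_values) != length(wavelengths))
    err_invalid("`n_values` must match `wavelengths` in length")
  if (any(k_values < 0)) err_invalid("k must be >= 0 everywhere (passive material)")
  .material("table", list(wavelengths = wavelengths, n = n_values, k = k_values),
            label)
}

.check_grid <- function(wavelengths) {
  if (!is.numeric(wavelengths) || length(wavelengths) < 1 || any(!is.finite(wavelengths)))
    err_invalid("wavelength grid must be finite numeric")
  if (length(wavelengths) > 1 && any(diff(wavelengths) <= 0))
    err_invalid("wavelength grid must be strictly increasing")
}

#' Complex refractive index of a material on a wavelength grid
#'
#' @param material A `naagif_material`.
#' @param wavelengths Strictly increasing grid (nm).
#' @return Complex vector n + ik, one value per wavelength.
#' @export
material_index <- function(material, wavelengths) {
  stopifnot(inherits(material, "naagif_material"))
  .check_grid(wavelengths)
  p <- material$params
  switch(material$type,
    constant = rep(complex(real = p$n, imaginary = p$k), length(wavelengths)),
    cauchy = complex(real = p$A + p$B / wavelengths^2,
                     imaginary = rep(0, length(wavelengths))),
    lorentz = {
      tab <- lorentz_index(p, wavelengths)
      complex(real = tab$n, imaginary = tab$k)
    },
    table = {
      if (min(wavelengths) < min(p$wavelengths) ||
          max(wavelengths) > max(p$wavelengths))
        err_range("requested wavelengths outside tabulated range")
      complex(real = stats::approx(p$wavelengths, p$n, wavelengths)$y,
              imaginary = stats::approx(p$wavelengths, p$k, wavelengths)$y)
    },
    err_invalid(sprintf("unknown material type '%s'", material$type))
  )
}

#' Lorentz-oscillator complex refractive index
#'
#' Single-oscillator dielectric function
#' `eps(omega) = eps_inf + strength * omega0^2 / (omega0^2 - omega^2 - i*gamma*omega)`
#' evaluated on a wavelength grid (omega = 2*pi*c/lambda), returning the
#' principal square root with non-negative imaginary part. With
#' `damping = gamma/omega0` the expression reduces to
#' `eps_inf + strength / (1 - x^2 - i*damping*x)` with `x = lambda0/lambda`.
#' The extinction coefficient k peaks near the resonance wavelength.
#'
#' @param params A [material_lorentz()] object or a plain list with fields
#'   `eps_inf`, `resonance_wavelength`, `strength`, `damping`.
#' @param wavelengths Strictly increasing grid (nm).
#' @return A data.frame (material table) with columns `wavelength_nm`, `n`,
#'   `k`.
#' @examples
#' tab <- lorentz_index(material_lorentz(), seq(400, 900, 5))
#' tab$wavelength_nm[which.max(tab$k)]   # close to 530 nm
#' @export
lorentz_index <- function(params, wavelengths) {
  if (inherits(params, "naagif_material")) {
    if (params$type != "lorentz") err_invalid("material is not a Lorentz model")
    params <- params$params
  }
  .check_grid(wavelengths)
  x <- params$resonance_wavelength / wavelengths  # omega / omega0
  eps <- params$eps_inf + params$strength / (1 - x^2 - 1i * params$damping * x)
  nk <- sqrt(eps)
  nk <- ifelse(Im(nk) < 0, -nk, nk)
  data.frame(wavelength_nm = wavelengths, n = Re(nk), k = Im(nk))
}

#' Refractive index of the aluminium oxide host
#'
#' Real, weakly dispersive index of anodic alumina in the visible,
#' represented by a two-term Cauchy law `n = A + B/lambda^2` whose default
#' coefficients give n close to 1.66 across the visible with normal
#' dispersion, and k = 0. A constant-index override is available.
#'
#' @param wavelengths Grid (nm), restricted to 300-1000 nm.
#' @param coefficients Named vector `c(A =, B =)` of Cauchy coefficients.
#' @param constant If non-NULL, return this constant index instead.
#' @return A data.frame (material table) with columns `wavelength_nm`, `n`,
#'   `k`.
#' @examples
#' range(alumina_index(seq(400, 900, 10))$n)   # within (1.60, 1.75)
#' @export
alumina_index <- function(wavelengths, coefficients = c(A = 1.62, B = 12000),
                          constant = NULL) {
  .check_grid(wavelengths)
  if (min(wavelengths) < 300 || max(wavelengths) > 1000)
    err_range("alumina index supported only on 300-1000 nm")
  n <- if (!is.null(constant)) rep(constant, length(wavelengths))
       else unname(coefficients["A"] + coefficients["B"] / wavelengths^2)
  data.frame(wavelength_nm = wavelengths, n = n, k = 0)
}

#' Default material set
#'
#' The host / medium / cargo triple used throughout: Cauchy alumina host,
#' constant-index release medium, and a Lorentz-oscillator cargo molecule
#' whose absorption band is centred inside the signal stopband.
#'
#' @param medium_index Refractive index of the release medium (1.33 = water).
#' @param drug A `naagif_material` for the cargo molecule.
#' @param host A `naagif_material` for the oxide host.
#' @return Named list of `naagif_material` objects (host, medium, drug).
#' @export
default_materials <- function(medium_index = 1.33,
                              drug = material_lorentz(label = "cargo"),
                              host = material_cauchy(label = "alumina")) {
  list(host = host,
       medium = material_constant(medium_index, label = "medium"),
       drug = drug)
}

# Bruggeman residual S(eps) = sum f_i (eps_i - eps)/(eps_i + 2 eps) and its
# derivative; used for root polishing and the self-consistency check.
.bg_residual <- function(eps, f, e) sum(f * (e - eps) / (e + 2 * eps))
.bg_dresidual <- function(eps, f, e) sum(f * (-3 * e) / (e + 2 * eps)^2)

#' Bruggeman effective-medium mixing
#'
#' Solves the self-consistent Bruggeman condition
#' `sum_i f_i (eps_i - eps_eff) / (eps_i + 2 eps_eff) = 0`
#' for the effective permittivity of a composite of two or more components.
#' The condition is cleared to a degree-n polynomial whose roots are found
#' exactly (Jenkins-Traub via `stats::polyroot`) and polished by one or two Newton steps;
#' among physically admissible roots (positive real part, non-negative
#' imaginary part) the one with the largest real part is returned, and the
#' residual of the mixing condition at the returned root is verified to be
#' at most `1e-10`.
#'
#' @param fractions Volume fractions, summing to 1 within 1e-9.
#' @param permittivities Complex permittivities, one per component
#'   (`Im >= 0`).
#' @return A single complex effective permittivity.
#' @examples
#' bruggeman_mix(c(0.9, 0.1), c(2.7556, 1.7689))
#' @export
bruggeman_mix <- function(fractions, permittivities) {
  f <- as.numeric(fractions)
  e <- as.complex(permittivities)
  if (length(f) != length(e)) err_invalid("fractions and permittivities must have equal length")
  if (length(f) < 2) err_invalid("need at least 2 components")
  if (any(f < -1e-12)) err_invalid("fractions must be non-negative")
  if (abs(sum(f) - 1) > 1e-9) err_invalid("fractions must sum to 1 within 1e-9")
  if (any(Im(e) < -1e-12)) err_invalid("component permittivities must have Im >= 0")

  keep <- f > 0
  if (sum(keep) == 1L) return(e[keep])
  if (max(abs(e[keep] - e[keep][1])) < 1e-14) return(e[keep][1])

  # polynomial sum_i f_i (e_i - x) prod_{j != i} (e_j + 2x) = 0, ascending coeffs
  poly_mul <- function(a, b) {
    out <- rep(0 + 0i, length(a) + length(b) - 1L)
    for (i in seq_along(a)) out[i:(i + length(b) - 1L)] <- out[i:(i + length(b) - 1L)] + a[i] * b
    out
  }
  coefs <- 0 + 0i
  for (i in seq_along(f)) {
    if (f[i] == 0) next
    term <- f[i] * c(e[i], -1 + 0i)          # f_i (e_i - x)
    for (j in seq_along(e)) if (j != i) term <- poly_mul(term, c(e[j], 2 + 0i))
    n_new <- max(length(coefs), length(term))
    coefs <- c(coefs, rep(0 + 0i, n_new - length(coefs))) +
             c(term, rep(0 + 0i, n_new - length(term)))
  }
  while (length(coefs) > 1 && abs(coefs[length(coefs)]) < 1e-300)
    coefs <- coefs[-length(coefs)]
  roots <- polyroot(coefs)  # base R, Jenkins-Traub

  # Newton polish on the rational residual; accept a step only if it
  # improves, so spurious pole roots (cancelled factors of the cleared
  # polynomial) cannot wander into the admissible region.
  resid <- abs(vapply(roots, .bg_residual, 0i, f = f, e = e))
  for (k in seq_along(roots)) {
    for (it in 1:4) {
      if (!is.finite(resid[k]) || resid[k] < 1e-15) break
      d <- .bg_dresidual(roots[k], f, e)
      if (!is.finite(abs(d)) || abs(d) < 1e-300) break
      cand <- roots[k] - .bg_residual(roots[k], f, e) / d
      rc <- abs(.bg_residual(cand, f, e))
      if (!is.finite(rc) || rc >= resid[k]) break
      roots[k] <- cand
      resid[k] <- rc
    }
  }

  scale <- max(abs(e))
  admissible <- is.finite(resid) & resid <= 1e-10 &
    Re(roots) > 0 & Im(roots) >= -1e-10 * scale
  if (!any(admissible)) {
    err_numerical(sprintf(
      "no physically admissible Bruggeman root (roots: %s; residuals: %s)",
      paste(format(roots, digits = 4), collapse = ", "),
      paste(format(resid, digits = 3), collapse = ", ")))
  }
  root <- roots[admissible][which.max(Re(roots[admissible]))]
  if (abs(Im(root)) < 1e-12 * scale && all(Im(e[keep]) == 0))
    root <- complex(real = Re(root), imaginary = 0)
  if (Im(root) < 0) root <- complex(real = Re(root), imaginary = 0)
  res <- abs(.bg_residual(root, f, e))
  if (res > 1e-10)
    err_numerical(sprintf("Bruggeman residual %.3e exceeds 1e-10 at root %s",
                          res, format(root, digits = 6)))
  root
}

#' Effective permittivity of a composition over a wavelength grid
#'
#' Applies [bruggeman_mix()] at every wavelength for a single layer
#' composition (host / drug / medium volume fractions).
#'
#' @param f_host,f_drug,f_medium Volume fractions (closing to 1).
#' @param materials Material set from [default_materials()].
#' @param wavelengths Grid (nm).
#' @return Complex vector of effective permittivities.
#' @export
effective_permittivity <- function(f_host, f_drug, f_medium, materials,
                                   wavelengths) {
  eh <- material_index(materials$host, wavelengths)^2
  ed <- material_index(materials$drug, wavelengths)^2
  em <- material_index(materials$medium, wavelengths)^2
  vapply(seq_along(wavelengths), function(i) {
    bruggeman_mix(c(f_host, f_drug, f_medium), c(eh[i], ed[i], em[i]))
  }, complex(1))
}
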