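# Shared fixtures: small, fast structures for unit tests. Acceptance tests
# use the full study-scale parameters instead.

small_design <- function(...) {
  gif_design(n_periods_top = 25, n_periods_bottom = 25, ...)
}

# band windows centred on the package's own Bragg estimates
oracle_bands <- function(design, half_width = 30,
                         materials = default_materials()) {
  br <- bragg_wavelengths(design, materials)
  band_definition(signal = br[["top"]] + c(-1, 1) * half_width,
                  reference = br[["bottom"]] + c(-1, 1) * half_width)
}

# Independent single-film (Airy) reflectance oracle, normal incidence,
# e^{-i omega t} convention (index n + ik).
airy_reflectance <- function(n0, n1, n2, d, lambda) {
  beta <- 2 * pi * n1 * d / lambda
  r01 <- (n0 - n1) / (n0 + n1)
  r12 <- (n1 - n2) / (n1 + n2)
  Mod((r01 + r12 * exp(2i * beta)) / (1 + r01 * r12 * exp(2i * beta)))^2
}

# Independent multilayer oracle: Parratt recursion, normal incidence.
parratt_reflectance <- function(ns, ds, n0, nm, lambda) {
  L <- length(ns)
  rcum <- (ns[L] - nm) / (ns[L] + nm)
  if (L >= 2) for (j in (L - 1):1) {
    ph <- exp(2i * 2 * pi * ns[j + 1] * ds[j + 1] / lambda)
    rj <- (ns[j] - ns[j + 1]) / (ns[j] + ns[j + 1])
    rcum <- (rj + rcum * ph) / (1 + rj * rcum * ph)
  }
  ph <- exp(2i * 2 * pi * ns[1] * ds[1] / lambda)
  r0 <- (n0 - ns[1]) / (n0 + ns[1])
  Mod((r0 + rcum * ph) / (1 + r0 * rcum * ph))^2
}

bruggeman_residual_at <- function(eps, fractions, permittivities) {
  abs(sum(fractions * (permittivities - eps) / (permittivities + 2 * eps)))
}
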