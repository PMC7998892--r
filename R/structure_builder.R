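#' Sinusoidal anodization profile
#'
#' Parameters of the two-phase sinusoidal current-density program used to
#' grow a stacked gradient-index filter: a constant average current plus a
#' sinusoidal term, applied for `n_cycles` cycles of period `period_1` and
#' then `n_cycles` cycles of period `period_2`.
#'
#' @param j_average Average current density (mA/cm^2), > 0.
#' @param j_amplitude Amplitude of the sinusoidal term (mA/cm^2); must lie in
#'   `[0, j_average]` so the applied current never goes negative.
#' @param period_1,period_2 Periods of the two phases (s), > 0.
#' @param n_cycles Number of cycles N applied in each phase, >= 1.
#' @return An object of class `anodization_profile`.
#' @examples
#' prof <- anodization_profile(2.6, 1.3, 152, 210, 150)
#' @export
anodization_profile <- function(j_average, j_amplitude, period_1, period_2,
                                n_cycles) {
  for (nm in c("j_average", "j_amplitude", "period_1", "period_2", "n_cycles")) {
    if (!is_scalar_num(get(nm))) err_invalid(sprintf("`%s` must be a finite numeric scalar", nm))
  }
  if (j_average <= 0) err_invalid("`j_average` must be > 0")
  if (j_amplitude < 0 || j_amplitude > j_average)
    err_invalid("`j_amplitude` must be in [0, j_average] (current never negative)")
  if (period_1 <= 0 || period_2 <= 0) err_invalid("periods must be > 0")
  if (n_cycles < 1 || n_cycles != round(n_cycles)) err_invalid("`n_cycles` must be an integer >= 1")
  structure(
    list(j_average = j_average, j_amplitude = j_amplitude,
         period_1 = period_1, period_2 = period_2, n_cycles = as.integer(n_cycles)),
    class = "anodization_profile"
  )
}

#' Sample the applied current-density waveform
#'
#' Evaluates the two-phase sinusoidal anodization program on a regular time
#' grid. During the first phase (`0 <= t <= N*T1`) the current is
#' `j_average + j_amplitude * sin(2*pi*t/T1)`; the second phase repeats the
#' same waveform with period `T2`, with its sine restarting at phase zero at
#' `t = N*T1`. Samples are taken at `t = k * time_step`, inclusive of 0; the
#' total duration `N*(T1 + T2)` is appended if the grid does not land on it.
#'
#' @param profile An [anodization_profile()].
#' @param time_step Sampling interval (s); must be positive and no larger than
#'   a quarter of the shorter period, so the sinusoid is resolved.
#' @return A data.frame with columns `time_s` and `j_mA_cm2`.
#' @examples
#' wf <- generate_current_waveform(anodization_profile(2.6, 1.3, 152, 210, 2), 1)
#' @export
generate_current_waveform <- function(profile, time_step) {
  stopifnot(inherits(profile, "anodization_profile"))
  if (!is_scalar_num(time_step) || time_step <= 0)
    err_invalid("`time_step` must be a positive number")
  if (time_step > min(profile$period_1, profile$period_2) / 4)
    err_invalid("`time_step` must be <= min(period_1, period_2)/4")
  t1 <- profile$n_cycles * profile$period_1
  total <- t1 + profile$n_cycles * profile$period_2
  times <- seq(0, total, by = time_step)
  if (times[length(times)] < total) times <- c(times, total)
  phase1 <- times <= t1
  j <- numeric(length(times))
  j[phase1] <- profile$j_average +
    profile$j_amplitude * sin(2 * pi * times[phase1] / profile$period_1)
  j[!phase1] <- profile$j_average +
    profile$j_amplitude * sin(2 * pi * (times[!phase1] - t1) / profile$period_2)
  data.frame(time_s = times, j_mA_cm2 = j)
}

#' Gradient-index filter design
#'
#' Structural and physical parameterization of a two-stack NAA gradient-index
#' filter: two sinusoidal rugate stacks (top and bottom), an optional uniform
#' cargo film on the incidence side, and the compact alumina barrier layer at
#' the pore bottoms. Defaults follow the simulation study conditions: periods
#' 164 / 284 nm, 100 periods per stack discretized into 8 layers per period,
#' average host fraction 0.9 modulated by +/- 0.025, 40 nm barrier, pores and
#' incident medium filled with water (n = 1.33).
#'
#' @param period_top,period_bottom Modulation period lengths (nm) of the two
#'   rugate stacks.
#' @param n_periods_top,n_periods_bottom Number of periods per stack.
#' @param layers_per_period Number of uniform sub-layers used to discretize
#'   each sinusoidal period (>= 2).
#' @param f_host_avg Average volume fraction of the aluminium oxide host.
#' @param f_ampl Amplitude of the sinusoidal modulation of the host fraction.
#' @param f_drug Volume fraction of cargo molecule in the pores (constant with
#'   depth: the cargo coats the pore walls conformally).
#' @param barrier_thickness Thickness (nm) of the compact barrier layer.
#' @param surface_layer_thickness Thickness (nm) of a uniform cargo film on
#'   the top surface; 0 means none.
#' @param medium_index Refractive index of the release medium filling the
#'   remaining pore volume and surrounding the filter.
#' @return An object of class `gif_design`.
#' @examples
#' d <- gif_design()            # simulation defaults
#' d2 <- gif_design(f_drug = 0.05)
#' @export
gif_design <- function(period_top = 164, period_bottom = 284,
                       n_periods_top = 100, n_periods_bottom = 100,
                       layers_per_period = 8,
                       f_host_avg = 0.9, f_ampl = 0.025, f_drug = 0,
                       barrier_thickness = 40, surface_layer_thickness = 0,
                       medium_index = 1.33) {
  d <- list(period_top = period_top, period_bottom = period_bottom,
            n_periods_top = n_periods_top, n_periods_bottom = n_periods_bottom,
            layers_per_period = layers_per_period,
            f_host_avg = f_host_avg, f_ampl = f_ampl, f_drug = f_drug,
            barrier_thickness = barrier_thickness,
            surface_layer_thickness = surface_layer_thickness,
            medium_index = medium_index)
  for (nm in names(d)) if (!is_scalar_num(d[[nm]]))
    err_invalid(sprintf("`%s` must be a finite numeric scalar", nm))
  if (d$period_top <= 0 || d$period_bottom <= 0) err_invalid("periods must be > 0")
  if (d$n_periods_top < 1 || d$n_periods_bottom < 1) err_invalid("period counts must be >= 1")
  if (d$layers_per_period < 2) err_invalid("`layers_per_period` must be >= 2")
  fr <- c(d$f_host_avg, d$f_ampl, d$f_drug)
  if (any(fr < 0) || any(fr > 1)) err_invalid("volume fractions must lie in [0, 1]")
  if (d$f_host_avg + d$f_ampl + d$f_drug > 1)
    err_invalid("f_host_avg + f_ampl + f_drug must be <= 1 (medium fraction never negative)")
  if (d$barrier_thickness <= 0) err_invalid("`barrier_thickness` must be > 0")
  if (d$surface_layer_thickness < 0) err_invalid("`surface_layer_thickness` must be >= 0")
  if (d$medium_index < 1) err_invalid("`medium_index` must be >= 1")
  d$n_periods_top <- as.integer(d$n_periods_top)
  d$n_periods_bottom <- as.integer(d$n_periods_bottom)
  d$layers_per_period <- as.integer(d$layers_per_period)
  structure(d, class = "gif_design")
}

# One rugate stack: m layers per period, f_host sampled at sub-layer midpoints
# of f(z) = f_avg + f_ampl*sin(2*pi*z/period), z measured from the stack start
# (each stack restarts the sinusoid at phase zero).
.rugate_layers <- function(period, n_periods, m, f_avg, f_ampl, f_drug, tag) {
  dz <- period / m
  z_mid <- (seq_len(n_periods * m) - 0.5) * dz
  f_host <- f_avg + f_ampl * sin(2 * pi * z_mid / period)
  f_medium <- 1 - f_host - f_drug
  bad <- which(f_host < 0 | f_host > 1 | f_medium < 0 | f_medium > 1)
  if (length(bad))
    err_invalid(sprintf("composition outside [0, 1] in %s layer %d", tag, bad[1]))
  data.frame(tag = tag, thickness_nm = dz, f_host = f_host,
             f_drug = f_drug, f_medium = f_medium)
}

#' Discretize a GIF design into a layered composition profile
#'
#' Converts a [gif_design()] into the ordered stack of uniform layers the
#' optics modules consume: an optional pure-cargo surface film, the top rugate
#' stack, the bottom rugate stack, and a pure-host barrier layer. Each rugate
#' period is cut into `layers_per_period` equal slabs and the host fraction is
#' sampled at each slab's midpoint (second-order accurate for the smooth
#' sinusoid). The cargo fraction is constant through both stacks and the
#' medium fraction closes each layer to 1. Layers are ordered incidence-side
#' first.
#'
#' @param design A [gif_design()].
#' @return A data.frame of class `composition_profile` with columns
#'   `layer_index`, `tag` (surface / rugate_top / rugate_bottom / barrier),
#'   `thickness_nm`, `f_host`, `f_drug`, `f_medium`.
#' @examples
#' prof <- build_composition_profile(gif_design())
#' nrow(prof)               # 1601 layers for the default design
#' sum(prof$thickness_nm)   # 44840 nm
#' @export
build_composition_profile <- function(design) {
  stopifnot(inherits(design, "gif_design"))
  parts <- list()
  if (design$surface_layer_thickness > 0) {
    parts$surface <- data.frame(tag = "surface",
                                thickness_nm = design$surface_layer_thickness,
                                f_host = 0, f_drug = 1, f_medium = 0)
  }
  parts$top <- .rugate_layers(design$period_top, design$n_periods_top,
                              design$layers_per_period, design$f_host_avg,
                              design$f_ampl, design$f_drug, "rugate_top")
  parts$bottom <- .rugate_layers(design$period_bottom, design$n_periods_bottom,
                                 design$layers_per_period, design$f_host_avg,
                                 design$f_ampl, design$f_drug, "rugate_bottom")
  parts$barrier <- data.frame(tag = "barrier",
                              thickness_nm = design$barrier_thickness,
                              f_host = 1, f_drug = 0, f_medium = 0)
  prof <- do.call(rbind, parts)
  rownames(prof) <- NULL
  prof <- cbind(layer_index = seq_len(nrow(prof)), prof)
  class(prof) <- c("composition_profile", "data.frame")
  prof
}

#' Write a composition profile to CSV
#'
#' @param profile A `composition_profile` from [build_composition_profile()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_composition_csv <- function(profile, path) {
  stopifnot(inherits(profile, "composition_profile"))
  utils::write.csv(as.data.frame(profile), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.gif_design <- function(x, ...) {
  cat("NAA-GIF design\n")
  cat(sprintf("  top stack:    %d periods x %g nm (%d layers/period)\n",
              x$n_periods_top, x$period_top, x$layers_per_period))
  cat(sprintf("  bottom stack: %d periods x %g nm\n",
              x$n_periods_bottom, x$period_bottom))
  cat(sprintf("  fractions:    host %g +/- %g, drug %g\n",
              x$f_host_avg, x$f_ampl, x$f_drug))
  cat(sprintf("  barrier %g nm, surface film %g nm, medium n = %g\n",
              x$barrier_thickness, x$surface_layer_thickness, x$medium_index))
  invisible(x)
}
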