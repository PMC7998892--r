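#' Read a spectrum from a two-column CSV
#'
#' Parses a `wavelength_nm, value` CSV (header optional), sorts by
#' wavelength (with a warning if the file was unsorted) and rejects
#' duplicate wavelengths.
#'
#' @param path File path.
#' @param kind "intensity" (default, safe for raw flow-cell data) or
#'   "reflectance".
#' @return A [spectrum()].
#' @export
read_spectrum <- function(path, kind = "intensity") {
  if (!file.exists(path)) err_io(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) err_parse(sprintf("%s: empty file", path))
  first_num <- suppressWarnings(as.numeric(strsplit(lines[1], ",")[[1]][1]))
  skip <- if (is.na(first_num)) 1L else 0L
  rows <- lines[(skip + 1L):length(lines)]
  if (length(rows) == 0) err_parse(sprintf("%s: no data rows", path))
  parts <- strsplit(rows, ",")
  wl <- val <- numeric(length(rows))
  for (i in seq_along(rows)) {
    p <- suppressWarnings(as.numeric(parts[[i]]))
    if (length(p) < 2 || any(is.na(p[1:2])))
      err_parse(sprintf("%s: malformed row at line %d: '%s'",
                        path, i + skip, rows[i]))
    wl[i] <- p[1]; val[i] <- p[2]
  }
  if (anyDuplicated(wl))
    err_parse(sprintf("%s: duplicate wavelength %g", path,
                      wl[duplicated(wl)][1]))
  if (is.unsorted(wl)) {
    warning(sprintf("%s: rows not sorted by wavelength; sorting", path))
    o <- order(wl); wl <- wl[o]; val <- val[o]
  }
  spectrum(wl, val, kind)
}

#' Write a spectrum to CSV
#'
#' Writes `wavelength_nm, value` rows at 6 significant digits, so
#' `read_spectrum(write_spectrum(s))` round-trips within 1e-6 relative.
#'
#' @param spec A [spectrum()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spec, path) {
  stopifnot(inherits(spec, "naagif_spectrum"))
  if (nrow(spec) == 0) err_invalid("refusing to write an empty spectrum")
  con <- tryCatch(file(path, "w"), error = function(e)
    err_io(sprintf("cannot open %s for writing", path)),
    warning = function(w) err_io(sprintf("cannot open %s for writing", path)))
  on.exit(close(con))
  writeLines("wavelength_nm,value", con)
  writeLines(sprintf("%.9g,%.6g", spec$wavelength_nm, spec$value), con)
  invisible(path)
}

#' Read / write a flow-cell manifest
#'
#' A manifest CSV (`time_s, path, ph`) lists the per-time spectrum files of
#' a flow-cell run; paths are relative to the manifest's directory.
#'
#' @param path Manifest path.
#' @return `read_manifest`: data.frame with columns `time_s`, `path`, `ph`.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) err_io(sprintf("file not found: %s", path))
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("time_s", "path", "ph") %in% names(m)))
    err_parse("manifest needs columns time_s, path, ph")
  m[order(m$time_s), , drop = FALSE]
}

#' Assemble a spectral time series from a manifest
#'
#' @param manifest_path Path to a manifest CSV (`time_s, path, ph`).
#' @param ph_schedule Optional explicit schedule; by default it is derived
#'   from the manifest's `ph` column (consecutive runs of equal pH).
#' @return A [spectral_time_series()].
#' @export
read_series <- function(manifest_path, ph_schedule = NULL) {
  m <- read_manifest(manifest_path)
  base <- dirname(manifest_path)
  specs <- lapply(m$path, function(p) {
    fp <- if (file.exists(p)) p else file.path(base, p)
    read_spectrum(fp)
  })
  wl <- specs[[1]]$wavelength_nm
  for (s in specs) if (!isTRUE(all.equal(s$wavelength_nm, wl)))
    err_structural("spectra in the manifest are not on a common grid")
  intens <- vapply(specs, function(s) s$value, numeric(length(wl)))
  if (is.null(ph_schedule)) {
    change <- c(TRUE, diff(as.numeric(factor(paste(m$ph)))) != 0)
    ph_schedule <- data.frame(start_time_s = m$time_s[change],
                              ph = m$ph[change])
  }
  spectral_time_series(m$time_s, wl, intens, ph_schedule, "intensity")
}

# ---- run configuration --------------------------------------------------

.design_keys <- c("period_top", "period_bottom", "n_periods_top",
                  "n_periods_bottom", "layers_per_period", "f_host_avg",
                  "f_ampl", "f_drug", "barrier_thickness",
                  "surface_layer_thickness", "medium_index")
.anodization_keys <- c("j_average", "j_amplitude", "period_1", "period_2",
                       "n_cycles")
.top_keys <- c("design", "anodization", "materials", "bands", "grid",
               "angle", "schedule", "seed", "dropdry", "synth")

#' Build a material from a config entry
#'
#' Config entries are flat maps with a `type` key: `constant` (n, k),
#' `cauchy` (A, B), `lorentz` (eps_inf, resonance_wavelength, strength,
#' damping), or `table` (path to a 2/3-column CSV `wavelength_nm, n[, k]`).
#'
#' @param entry Named list from the config file.
#' @param base_dir Directory for resolving relative table paths.
#' @return A `naagif_material`.
#' @export
material_from_config <- function(entry, base_dir = ".") {
  if (is.null(entry$type)) err_config("material entry missing `type`")
  known <- switch(entry$type,
    constant = c("type", "n", "k"),
    cauchy = c("type", "A", "B"),
    lorentz = c("type", "eps_inf", "resonance_wavelength", "strength", "damping"),
    table = c("type", "path"),
    err_config(sprintf("unknown material type '%s'", entry$type)))
  extra <- setdiff(names(entry), known)
  if (length(extra))
    err_config(sprintf("unknown material keys: %s", paste(extra, collapse = ", ")))
  args <- entry[setdiff(names(entry), c("type", "path"))]
  switch(entry$type,
    constant = do.call(material_constant, args),
    cauchy = do.call(material_cauchy, args),
    lorentz = do.call(material_lorentz, args),
    table = {
      fp <- if (file.exists(entry$path)) entry$path
            else file.path(base_dir, entry$path)
      tab <- utils::read.csv(fp)
      material_table(tab[[1]], tab[[2]],
                     if (ncol(tab) >= 3) tab[[3]] else 0)
    })
}

#' Read and validate a run configuration
#'
#' Reads a YAML (or JSON) configuration describing a run: `design` (the
#' [gif_design()] fields), optional `anodization` ([anodization_profile()]
#' fields), `materials` (host / medium / drug entries for
#' [material_from_config()]), `bands` (signal / reference windows), `grid`
#' (`min`, `max`, `step` in nm), `angle`, `seed`, and subcommand-specific
#' blocks. Unknown keys are rejected before any computation.
#'
#' @param path Config file path.
#' @return A named list of class `run_config` with constructed objects
#'   (`design`, `bands`, `materials`, `wavelengths`, ...).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) err_io(sprintf("config not found: %s", path))
  raw <- tryCatch(yaml::read_yaml(path),
                  error = function(e) err_parse(paste("config parse error:",
                                                      conditionMessage(e))))
  if (!is.list(raw)) err_config("config must be a key/value document")
  extra <- setdiff(names(raw), .top_keys)
  if (length(extra))
    err_config(sprintf("unknown config keys: %s", paste(extra, collapse = ", ")))
  cfg <- list()
  if (!is.null(raw$design)) {
    extra <- setdiff(names(raw$design), .design_keys)
    if (length(extra))
      err_config(sprintf("unknown design keys: %s", paste(extra, collapse = ", ")))
    cfg$design <- do.call(gif_design, raw$design)
  } else cfg$design <- gif_design()
  if (!is.null(raw$anodization)) {
    extra <- setdiff(names(raw$anodization), .anodization_keys)
    if (length(extra))
      err_config(sprintf("unknown anodization keys: %s",
                         paste(extra, collapse = ", ")))
    cfg$anodization <- do.call(anodization_profile, raw$anodization)
  }
  base_dir <- dirname(path)
  mats <- default_materials(medium_index = cfg$design$medium_index)
  if (!is.null(raw$materials)) {
    extra <- setdiff(names(raw$materials), c("host", "medium", "drug"))
    if (length(extra))
      err_config(sprintf("unknown materials keys: %s",
                         paste(extra, collapse = ", ")))
    for (nm in names(raw$materials))
      mats[[nm]] <- material_from_config(raw$materials[[nm]], base_dir)
  }
  cfg$materials <- mats
  cfg$bands <- if (!is.null(raw$bands)) {
    extra <- setdiff(names(raw$bands), c("signal", "reference"))
    if (length(extra))
      err_config(sprintf("unknown bands keys: %s", paste(extra, collapse = ", ")))
    do.call(band_definition, lapply(raw$bands, unlist))
  } else band_definition()
  cfg$wavelengths <- if (!is.null(raw$grid)) {
    extra <- setdiff(names(raw$grid), c("min", "max", "step"))
    if (length(extra))
      err_config(sprintf("unknown grid keys: %s", paste(extra, collapse = ", ")))
    seq(raw$grid$min, raw$grid$max, by = if (!is.null(raw$grid$step)) raw$grid$step else 1)
  } else seq(400, 900, by = 1)
  cfg$angle <- if (!is.null(raw$angle)) raw$angle else 0
  cfg$seed <- if (!is.null(raw$seed)) as.integer(raw$seed) else 0L
  cfg$schedule <- if (!is.null(raw$schedule))
    data.frame(start_time_s = vapply(raw$schedule, `[[`, 0, "start_time_s"),
               ph = vapply(raw$schedule, function(e)
                 if (is.null(e$ph)) NA_real_ else as.numeric(e$ph), 0))
    else NULL
  cfg$dropdry <- raw$dropdry
  cfg$synth <- raw$synth
  class(cfg) <- "run_config"
  cfg
}
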