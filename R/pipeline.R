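#' Default run configuration
#'
#' Nested key-value configuration driving the simulate / reconstruct /
#' analyze pipeline. Unknown keys in a user file are rejected on load.
#'
#' @return nested named list.
#' @export
default_config <- function() {
  list(
    scene = list(type = "phantom",       # "phantom" or "retina"
                 c_mg_ml = 10,
                 pigmented = TRUE,
                 n_ascans = 96,
                 surface_z_um = 20,
                 rpe_z_um = 30,
                 seed = 1),
    simulator = list(n_pixels = 1024,
                     snr_db = 45,
                     a2 = 0, a3 = 0,
                     repeats = 1,
                     suppression = 0.65,
                     rolloff = 0),
    bands = list(center_min_nm = 440, center_max_nm = 700, step_nm = 10,
                 target_res_um = 6, n_tissue = 1.38),
    analysis = list(min_area_um2 = 8, k = 3, window_um = 50,
                    exclusion_um = 6),
    mie = list(diameters_um = c(0.3, 0.5, 0.7, 1.0),
               medium = "rpe_medium",
               number_density = 1e-3)
  )
}

#' Load and validate a YAML configuration
#'
#' Reads a YAML file and merges it over [default_config()]. Keys not in
#' the default schema raise an error naming the offending key.
#'
#' @param path YAML file path, or NULL for defaults.
#' @return validated configuration list.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  merge_validate <- function(base, upd, prefix = "") {
    for (key in names(upd)) {
      if (!key %in% names(base))
        stop(sprintf("unknown configuration key: %s%s", prefix, key))
      if (is.list(base[[key]]) && is.list(upd[[key]]))
        base[[key]] <- merge_validate(base[[key]], upd[[key]],
                                      paste0(prefix, key, "."))
      else base[[key]] <- upd[[key]]
    }
    base
  }
  merge_validate(cfg, user)
}

config_models <- function(config) {
  sim <- config$simulator
  list(source = source_model(suppression = sim$suppression),
       spectrometer = spectrometer_model(n_pixels = sim$n_pixels,
                                         rolloff = sim$rolloff),
       dispersion = dispersion_model(a2 = sim$a2, a3 = sim$a3),
       bands = band_config(centers_nm = seq(config$bands$center_min_nm,
                                            config$bands$center_max_nm,
                                            by = config$bands$step_nm),
                           target_res_um = config$bands$target_res_um,
                           n_tissue = config$bands$n_tissue))
}

config_scene <- function(config) {
  sc <- config$scene
  if (sc$type == "phantom")
    make_phantom_scene(sc$c_mg_ml, seed = sc$seed,
                       surface_z_um = sc$surface_z_um,
                       n_ascans = sc$n_ascans)
  else if (sc$type == "retina")
    make_retina_scene(pigmented = isTRUE(sc$pigmented), seed = sc$seed,
                      rpe_z_um = sc$rpe_z_um, n_ascans = sc$n_ascans)
  else stop("scene$type must be 'phantom' or 'retina'")
}

#' Write / read a raw interferogram archive
#'
#' The detector spectra are stored as a little-endian float64 binary
#' array beside a JSON manifest carrying dimensions, the pixel-wavelength
#' calibration, reference spectrum, dispersion coefficients and seed; the
#' ground-truth scene is a CSV table.
#'
#' @param raw a [simulate_bscan()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly (writer); a `raw_interferogram` (reader).
#' @export
write_interferogram <- function(raw, dir) {
  stopifnot(inherits(raw, "raw_interferogram"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  con <- file(file.path(dir, "spectra.bin"), "wb")
  writeBin(as.numeric(raw$spectra), con, size = 8, endian = "little")
  close(con)
  manifest <- list(dims = dim(raw$spectra),
                   lambda_px = raw$lambda_px,
                   reference = raw$reference,
                   r_ref = raw$r_ref,
                   read_sd = raw$read_sd,
                   dispersion = list(a2 = raw$dispersion$a2,
                                     a3 = raw$dispersion$a3),
                   seed = raw$seed,
                   rolloff = raw$spectrometer$rolloff,
                   suppression = raw$source$suppression,
                   scene = list(medium = raw$scene$medium,
                                n_group = raw$scene$n_group,
                                n_ascans = raw$scene$n_ascans,
                                lateral_pitch_um = raw$scene$lateral_pitch_um,
                                extra = raw$scene$extra))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.csv(raw$scene$scatterers, file.path(dir, "scene.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' @rdname write_interferogram
#' @export
read_interferogram <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  dims <- as.integer(manifest$dims)
  con <- file(file.path(dir, "spectra.bin"), "rb")
  v <- readBin(con, numeric(), n = prod(dims), size = 8, endian = "little")
  close(con)
  scat <- utils::read.csv(file.path(dir, "scene.csv"),
                          colClasses = c(label = "character"))
  scene <- oct_scene(scat, medium = manifest$scene$medium,
                     n_group = manifest$scene$n_group,
                     n_ascans = manifest$scene$n_ascans,
                     lateral_pitch_um = manifest$scene$lateral_pitch_um,
                     extra = as.list(manifest$scene$extra))
  spectrometer <- spectrometer_model(
    n_pixels = dims[1],
    lambda_range_nm = range(manifest$lambda_px),
    rolloff = manifest$rolloff)
  structure(list(spectra = array(v, dim = dims),
                 lambda_px = as.numeric(manifest$lambda_px),
                 reference = as.numeric(manifest$reference),
                 source = source_model(suppression = manifest$suppression),
                 spectrometer = spectrometer,
                 dispersion = dispersion_model(a2 = manifest$dispersion$a2,
                                               a3 = manifest$dispersion$a3),
                 scene = scene, seed = manifest$seed,
                 read_sd = manifest$read_sd, r_ref = manifest$r_ref),
            class = "raw_interferogram")
}

#' Write / read a hyperspectral stack
#'
#' Multi-page 32-bit float TIFF (one page per band, linear intensity) plus
#' a JSON sidecar with band centres, pixel pitches and registration
#' shifts.
#'
#' @param stack a `hyperstack`.
#' @param dir output directory.
#' @export
write_hyperstack <- function(stack, dir) {
  stopifnot(inherits(stack, "hyperstack"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  nb <- dim(stack$intensity)[1]
  # TIFF float pages are defined on [0, 1]; store a global scale in the
  # sidecar so linear intensities round-trip
  scale <- max(stack$intensity, 1e-300)
  pages <- lapply(seq_len(nb), function(b) stack$intensity[b, , ] / scale)
  tiff::writeTIFF(pages, file.path(dir, "hyperstack.tiff"),
                  bits.per.sample = 32, reduce = FALSE)
  side <- list(intensity_scale = scale,
               band_centers_nm = stack$band_centers_nm,
               axial_pitch_um = stack$axial_pitch_um,
               axial_pitch_opt_um = stack$axial_pitch_opt_um,
               lateral_pitch_um = stack$lateral_pitch_um,
               shifts = stack$shifts,
               dispersion_used = stack$dispersion_used,
               n_group = stack$n_group)
  jsonlite::write_json(side, file.path(dir, "hyperstack.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_hyperstack
#' @export
read_hyperstack <- function(dir) {
  side <- jsonlite::read_json(file.path(dir, "hyperstack.json"),
                              simplifyVector = TRUE)
  pages <- tiff::readTIFF(file.path(dir, "hyperstack.tiff"), all = TRUE)
  nb <- length(pages)
  arr <- array(0, dim = c(nb, dim(pages[[1]])))
  for (b in seq_len(nb)) arr[b, , ] <- pages[[b]] * side$intensity_scale
  structure(list(intensity = arr,
                 band_centers_nm = as.numeric(side$band_centers_nm),
                 axial_pitch_um = side$axial_pitch_um,
                 axial_pitch_opt_um = side$axial_pitch_opt_um,
                 lateral_pitch_um = side$lateral_pitch_um,
                 shifts = as.integer(side$shifts),
                 dispersion_used = as.numeric(side$dispersion_used),
                 n_group = side$n_group,
                 band_config = band_config(as.numeric(side$band_centers_nm))),
            class = "hyperstack")
}

resolve_out <- function(out) {
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  out
}

echo_config <- function(config, out) {
  yaml::write_yaml(config, file.path(out, "config_resolved.yaml"))
}

#' Pipeline commands
#'
#' Thin command-style wrappers tying the pipeline together; each takes a
#' configuration (list or YAML path), writes its outputs under `out` along
#' with the resolved configuration, and returns its main result invisibly.
#' `cmd_simulate` writes a raw-interferogram archive; `cmd_reconstruct`
#' turns an archive into a registered 27-page hyperspectral TIFF;
#' `cmd_analyze` emits the per-basin CSV, DFM/binary/RGB images and a
#' summary JSON; `cmd_mie` writes backscattering spectra for a set of
#' granule diameters.
#'
#' @param config configuration list from [load_config()], or a YAML path.
#' @param out output directory.
#' @param seed optional seed overriding `config$scene$seed`.
#' @return see above.
#' @export
cmd_simulate <- function(config = default_config(), out, seed = NULL) {
  if (is.character(config)) config <- load_config(config)
  if (!is.null(seed)) config$scene$seed <- seed
  out <- resolve_out(out)
  scene <- config_scene(config)
  mods <- config_models(config)
  raw <- simulate_bscan(scene, mods$source, mods$spectrometer,
                        mods$dispersion,
                        noise = list(snr_db = config$simulator$snr_db),
                        repeats = config$simulator$repeats,
                        seed = config$scene$seed)
  write_interferogram(raw, out)
  echo_config(config, out)
  message(sprintf("simulate: seed %d, %d scatterers (%d granules)",
                  config$scene$seed, nrow(scene$scatterers),
                  sum(scene$scatterers$label == "granule")))
  invisible(raw)
}

#' @rdname cmd_simulate
#' @param archive directory written by [cmd_simulate()].
#' @export
cmd_reconstruct <- function(archive, config = default_config(), out) {
  if (is.character(config)) config <- load_config(config)
  out <- resolve_out(out)
  raw <- read_interferogram(archive)
  mods <- config_models(config)
  rng <- range(raw$lambda_px)
  if (min(mods$bands$centers_nm) < rng[1] || max(mods$bands$centers_nm) > rng[2])
    stop("band centres outside the calibrated wavelength range")
  stack <- reconstruct_stack(raw, mods$bands, dispersion = "truth")
  write_hyperstack(stack, out)
  echo_config(config, out)
  message(sprintf("reconstruct: %d bands, shifts [%d, %d] px, a2=%.3g a3=%.3g",
                  length(stack$band_centers_nm), min(stack$shifts),
                  max(stack$shifts), stack$dispersion_used[1],
                  stack$dispersion_used[2]))
  invisible(stack)
}

#' @rdname cmd_simulate
#' @param stack_dir directory written by [cmd_reconstruct()].
#' @export
cmd_analyze <- function(stack_dir, config = default_config(), out) {
  if (is.character(config)) config <- load_config(config)
  out <- resolve_out(out)
  stack <- read_hyperstack(stack_dir)
  an <- dfm_analyze(stack,
                    min_area_um2 = config$analysis$min_area_um2,
                    k = config$analysis$k,
                    window_um = config$analysis$window_um,
                    exclusion_um = config$analysis$exclusion_um)
  basin_df <- data.frame(id = seq_len(an$seg$n_basins),
                         area_um2 = an$seg$area_um2,
                         dfm = an$dfm_values)
  sp <- as.data.frame(an$spectra)
  names(sp) <- sprintf("I_%dnm", an$band_centers_nm)
  utils::write.csv(cbind(basin_df, sp), file.path(out, "basins.csv"),
                   row.names = FALSE)
  norm01 <- function(m) {
    r <- range(m)
    if (diff(r) == 0) m * 0 else (m - r[1]) / diff(r)
  }
  tiff::writeTIFF(norm01(an$mip), file.path(out, "mip.tiff"),
                  bits.per.sample = 32)
  tiff::writeTIFF(norm01(an$map), file.path(out, "dfm.tiff"),
                  bits.per.sample = 32)
  tiff::writeTIFF(an$binary * 1, file.path(out, "binary.tiff"),
                  bits.per.sample = 32)
  tiff::writeTIFF(rgb_encode(stack), file.path(out, "rgb.tiff"),
                  bits.per.sample = 32)
  jsonlite::write_json(
    list(n_basins = an$seg$n_basins,
         noise_sd_intensity = an$noise_sd_intensity,
         noise_sd_dfm = an$noise_sd_dfm,
         threshold_intensity = an$threshold_intensity,
         threshold_dfm = an$threshold_dfm,
         fraction_intensity_pct = an$fraction_intensity,
         fraction_dfm_pct = an$fraction_dfm,
         k = an$k),
    file.path(out, "summary.json"), auto_unbox = TRUE, digits = NA)
  echo_config(config, out)
  invisible(an)
}

#' @rdname cmd_simulate
#' @export
cmd_mie <- function(config = default_config(), out) {
  if (is.character(config)) config <- load_config(config)
  out <- resolve_out(out)
  med <- material_index(config$mie$medium)
  lam <- seq(440, 700, by = 1)
  spectra <- lapply(config$mie$diameters_um, function(d)
    mu_b_spectrum(granule_population(d, config$mie$number_density), med, lam))
  write_mie_csv(spectra, file.path(out, "mu_b.csv"))
  grDevices::png(file.path(out, "mu_b.png"), width = 800, height = 500)
  cols <- grDevices::hcl.colors(length(spectra), "Dark 3")
  ylim <- range(sapply(spectra, function(s) range(s$mu_b_mm)))
  graphics::plot(NULL, xlim = range(lam), ylim = ylim,
                 xlab = "wavelength (nm)", ylab = expression(mu[b] ~ (mm^-1)))
  for (i in seq_along(spectra))
    graphics::lines(spectra[[i]]$lambda_nm, spectra[[i]]$mu_b_mm,
                    col = cols[i], lwd = 2)
  graphics::legend("topright", sprintf("%g um", config$mie$diameters_um),
                   col = cols, lwd = 2)
  grDevices::dev.off()
  echo_config(config, out)
  invisible(spectra)
}
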