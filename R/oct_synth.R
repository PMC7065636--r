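#' White-light source spectrum model
#'
#' Smooth broadband spectral power density covering 440-700 nm with an
#' optional mid-band (green) suppression emulating a magenta colour filter,
#' which boosts the relative intensity at the band edges. The density is
#' positive over the whole detector range.
#'
#' @param suppression depth of the mid-band dip, 0 (none) to < 1.
#' @param suppression_center_nm,suppression_width_nm dip centre and Gaussian
#'   width in nm.
#' @return object of class `source_model`: list with function `S(lambda_nm)`.
#' @export
source_model <- function(suppression = 0.65,
                         suppression_center_nm = 565,
                         suppression_width_nm = 55) {
  stopifnot(suppression >= 0, suppression < 1)
  S <- function(lambda_nm) {
    base <- exp(-((lambda_nm - 480) / 55)^2) +
      exp(-((lambda_nm - 650) / 50)^2) + 0.30
    dip <- 1 - suppression *
      exp(-((lambda_nm - suppression_center_nm) / suppression_width_nm)^2)
    base * dip
  }
  structure(list(S = S, suppression = suppression), class = "source_model")
}

#' Spectrometer model
#'
#' Detector pixel to wavelength calibration. The default mapping is uniform
#' in wavelength, hence nonlinear in wavenumber, as in grating spectrometers
#' without prism linearization; an optional Gaussian pixel-integration
#' envelope models depth-dependent sensitivity roll-off. The range extends
#' slightly beyond the 440-700 nm band set so edge sub-band windows are not
#' truncated.
#'
#' @param n_pixels detector pixel count (default 2048).
#' @param lambda_range_nm wavelength span covered by the detector.
#' @param rolloff roll-off envelope strength, 0 disables.
#' @return object of class `spectrometer_model` with `lambda_px` (nm per
#'   pixel, increasing) and `k_px` (rad/um per pixel).
#' @export
spectrometer_model <- function(n_pixels = 2048,
                               lambda_range_nm = c(425, 730),
                               rolloff = 0) {
  stopifnot(n_pixels >= 64, diff(lambda_range_nm) > 0)
  lambda_px <- seq(lambda_range_nm[1], lambda_range_nm[2],
                   length.out = n_pixels)
  structure(list(n_pixels = n_pixels, lambda_px = lambda_px,
                 k_px = 2 * pi / (lambda_px / 1000), rolloff = rolloff),
            class = "spectrometer_model")
}

#' Dispersion model
#'
#' Second- and third-order dispersion phase
#' \eqn{\phi(k) = a_2 (k-k_0)^2 + a_3 (k-k_0)^3} added to the interference
#' term, with k in rad/um. `k0 = NULL` means the centre of the detector's
#' wavenumber range.
#'
#' @param a2 quadratic coefficient, rad (rad/um)^-2.
#' @param a3 cubic coefficient, rad (rad/um)^-3.
#' @param k0 reference wavenumber in rad/um, or NULL.
#' @return object of class `dispersion_model`.
#' @export
dispersion_model <- function(a2 = 0, a3 = 0, k0 = NULL) {
  stopifnot(is.finite(a2), is.finite(a3))
  structure(list(a2 = a2, a3 = a3, k0 = k0), class = "dispersion_model")
}

dispersion_k0 <- function(dispersion, spectrometer) {
  if (!is.null(dispersion$k0)) dispersion$k0 else mean(range(spectrometer$k_px))
}

#' Scene of point scatterers
#'
#' A scene is a table of scatterers: depth `z_um` (physical, in the
#' propagation medium, >= 0), fractional lateral A-scan position `x`,
#' ground-truth `label` ("granule", "interface" or "tissue"), diameter
#' `d_um` (NA for flat-spectrum scatterers) and reflectivity scale
#' `r_scale`. Granules get a Mie backscattering reflectivity spectrum
#' r(lambda) proportional to Q_b; interface and tissue scatterers are
#' flat in wavelength.
#'
#' @param scatterers data.frame with columns z_um, x, label, d_um, r_scale.
#' @param medium name of the propagation medium material.
#' @param n_group group refractive index used for optical path lengths.
#' @param n_ascans lateral A-scan count.
#' @param lateral_pitch_um lateral spacing between A-scans in um.
#' @param extra named list of ground-truth metadata (e.g. RPE depth band).
#' @return object of class `oct_scene`.
#' @export
oct_scene <- function(scatterers, medium, n_group, n_ascans,
                      lateral_pitch_um = 2, extra = list()) {
  need <- c("z_um", "x", "label", "d_um", "r_scale")
  stopifnot(all(need %in% names(scatterers)))
  if (nrow(scatterers) && any(scatterers$z_um < 0))
    stop("scatterer depths must be non-negative")
  if (nrow(scatterers) && any(scatterers$r_scale < 0))
    stop("reflectivities must be non-negative")
  structure(list(scatterers = scatterers, medium = medium, n_group = n_group,
                 n_ascans = n_ascans, lateral_pitch_um = lateral_pitch_um,
                 extra = extra),
            class = "oct_scene")
}

#' @export
print.oct_scene <- function(x, ...) {
  cat(sprintf("<oct_scene> %d scatterers, %d A-scans x %g um, medium %s\n",
              nrow(x$scatterers), x$n_ascans, x$lateral_pitch_um, x$medium))
  print(table(x$scatterers$label))
  invisible(x)
}

#' Melanin-in-silicone phantom scene
#'
#' Granule positions are a homogeneous Poisson process over the simulated
#' slab volume with number density derived from the mass concentration
#' (peak diameter 2.4 um, melanosome density 1.7 g/cm^3); diameters are
#' log-normal with mode 2.4 um. A flat-spectrum bright interface line sits
#' at the lens-silicone surface depth.
#'
#' @param c_mg_ml melanin mass concentration in mg/mL, >= 0.
#' @param seed RNG seed (integer); the scene is deterministic given it.
#' @param surface_z_um depth of the lens-silicone interface, um.
#' @param depth_extent_um depth extent of the granule-bearing slab below
#'   the interface, um.
#' @param slice_um out-of-plane thickness of the simulated slab (the beam
#'   collects scatterers over roughly three lateral resolution widths), um.
#' @param n_ascans,lateral_pitch_um lateral geometry.
#' @param sdlog log-normal shape of the diameter distribution.
#' @param d_peak_um mode of the diameter distribution, um.
#' @param granule_r,interface_r reflectivity scales.
#' @return an [oct_scene()].
#' @export
make_phantom_scene <- function(c_mg_ml, seed,
                               surface_z_um = 20, depth_extent_um = 70,
                               slice_um = 7.5,
                               n_ascans = 96, lateral_pitch_um = 2,
                               sdlog = 0.25, d_peak_um = 2.4,
                               granule_r = 4e-4, interface_r = 4e-3) {
  stopifnot(c_mg_ml >= 0)
  N <- concentration_to_number_density(c_mg_ml, d_peak_um)
  vol <- n_ascans * lateral_pitch_um * depth_extent_um * slice_um
  old <- .Random.seed_save()
  set.seed(seed)
  n_gran <- stats::rpois(1, N * vol)
  z0 <- surface_z_um + 4
  gran <- data.frame(
    z_um = stats::runif(n_gran, z0, z0 + depth_extent_um),
    x = stats::runif(n_gran, 0.5, n_ascans + 0.5),
    label = rep("granule", n_gran),
    d_um = stats::rlnorm(n_gran, meanlog = log(d_peak_um) + sdlog^2,
                         sdlog = sdlog),
    r_scale = rep(granule_r, n_gran)
  )
  .Random.seed_restore(old)
  iface <- data.frame(z_um = rep(surface_z_um, n_ascans),
                      x = seq_len(n_ascans), label = "interface",
                      d_um = NA_real_, r_scale = interface_r)
  n_group <- Re(silicone_index(550))
  oct_scene(rbind(iface, gran), medium = "silicone", n_group = n_group,
            n_ascans = n_ascans, lateral_pitch_um = lateral_pitch_um,
            extra = list(c_mg_ml = c_mg_ml, surface_z_um = surface_z_um,
                         n_granules = n_gran, seed = seed))
}

#' Rodent retina scene
#'
#' Layered flat-spectrum tissue scatterers (weakly backscattering retinal
#' layers plus choroid) and, when pigmented, sparse melanin granules in the
#' RPE depth band -- around one to two granules per A-scan, as in the Brown
#' Norway rat. The albino variant shares the identical tissue geometry and
#' seed, differing only by the absence of granules. The RPE is placed
#' nearest the zero delay (enhanced-depth convention).
#'
#' @param pigmented logical; include RPE granules.
#' @param seed RNG seed; tissue layers use it directly so pigmented/albino
#'   pairs are matched.
#' @param rpe_z_um centre depth of the RPE band, um.
#' @param d_range_um granule diameter range, um.
#' @param granules_per_ascan mean granule count per A-scan in the RPE band.
#' @param tissue_density_um3 tissue scatterer number density, um^-3.
#' @param tissue_r,granule_r reflectivity scales.
#' @inheritParams make_phantom_scene
#' @return an [oct_scene()].
#' @export
make_retina_scene <- function(pigmented, seed,
                              rpe_z_um = 30,
                              d_range_um = c(0.3, 1.0),
                              granules_per_ascan = 1.5,
                              n_ascans = 96, lateral_pitch_um = 2,
                              slice_um = 7.5,
                              tissue_density_um3 = 0.015,
                              tissue_r = 4e-7, granule_r = 4e-4) {
  layers <- data.frame(z_lo = c(rpe_z_um + 12, rpe_z_um + 45, rpe_z_um + 80),
                       z_hi = c(rpe_z_um + 35, rpe_z_um + 70, rpe_z_um + 115))
  old <- .Random.seed_save()
  set.seed(seed)
  tis <- do.call(rbind, lapply(seq_len(nrow(layers)), function(i) {
    vol <- n_ascans * lateral_pitch_um * slice_um *
      (layers$z_hi[i] - layers$z_lo[i])
    n <- stats::rpois(1, tissue_density_um3 * vol)
    data.frame(z_um = stats::runif(n, layers$z_lo[i], layers$z_hi[i]),
               x = stats::runif(n, 0.5, n_ascans + 0.5),
               label = "tissue", d_um = NA_real_,
               r_scale = tissue_r * stats::rexp(n))
  }))
  set.seed(seed + 1L)
  gran <- if (pigmented) {
    n <- stats::rpois(1, granules_per_ascan * n_ascans)
    data.frame(z_um = stats::runif(n, rpe_z_um - 3, rpe_z_um + 3),
               x = stats::runif(n, 0.5, n_ascans + 0.5),
               label = "granule",
               d_um = stats::runif(n, d_range_um[1], d_range_um[2]),
               r_scale = granule_r)
  } else {
    data.frame(z_um = numeric(), x = numeric(), label = character(),
               d_um = numeric(), r_scale = numeric())
  }
  .Random.seed_restore(old)
  oct_scene(rbind(tis, gran), medium = "rpe_medium", n_group = 1.38,
            n_ascans = n_ascans, lateral_pitch_um = lateral_pitch_um,
            extra = list(pigmented = pigmented, rpe_z_um = rpe_z_um,
                         rpe_band_um = c(rpe_z_um - 5, rpe_z_um + 5),
                         seed = seed))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}

# Reflectivity spectra r(lambda) for all scatterers of a scene on the
# detector wavelength grid. Granule Mie spectra are evaluated on a coarse
# wavelength grid and spline-interpolated (the spectra are smooth on the
# nanometre scale); diameters are quantized to 0.01 um for caching.
scene_reflectivity <- function(scene, lambda_nm, n_coarse = 256) {
  sc <- scene$scatterers
  out <- matrix(0, nrow = length(lambda_nm), ncol = nrow(sc))
  if (!nrow(sc)) return(out)
  flat <- sc$label != "granule"
  if (any(flat))
    out[, flat] <- matrix(rep(sc$r_scale[flat], each = length(lambda_nm)),
                          nrow = length(lambda_nm))
  gi <- which(!flat)
  if (length(gi)) {
    med <- material_index(scene$medium)
    mel <- material_index("melanin")
    lam_c <- seq(min(lambda_nm), max(lambda_nm), length.out = n_coarse)
    lam_eval <- pmin(pmax(lam_c, 400), 700)  # index fits valid to 400-700
    n_med <- med$n(lam_eval)
    m <- index_eval(mel, lam_eval) / n_med
    cache <- new.env(parent = emptyenv())
    for (j in gi) {
      key <- sprintf("%.2f", sc$d_um[j])
      if (is.null(cache[[key]])) {
        d <- as.numeric(key)
        x <- size_parameter(d, lam_eval, n_med)
        qb <- backscattering_efficiency(x, m) * pi * (d / 2)^2
        cache[[key]] <- stats::splinefun(lam_c, qb)(lambda_nm)
      }
      out[, j] <- sc$r_scale[j] * pmax(cache[[key]], 0)
    }
  }
  out
}

#' Simulate one spectral-domain OCT detector spectrum
#'
#' Forward model for a single A-scan:
#' \deqn{I(px) = S(\lambda)[R_{ref} + \sum_j r_j(\lambda) +
#'   2\sum_j \sqrt{R_{ref} r_j(\lambda)}
#'   \cos(2 k n_g z_j + a_2 (k-k_0)^2 + a_3 (k-k_0)^3)] + noise}
#' evaluated at each pixel's wavelength. Scatterers near the requested
#' lateral position contribute with a Gaussian lateral point-spread weight
#' whose width scales linearly with wavelength. Deterministic given `seed`.
#'
#' @param scene an [oct_scene()].
#' @param x_index lateral A-scan index to simulate.
#' @param source a [source_model()].
#' @param spectrometer a [spectrometer_model()].
#' @param dispersion a [dispersion_model()].
#' @param noise list: `read_sd` (detector counts) and/or `shot` (logical);
#'   NULL for noise-free.
#' @param seed RNG seed for the noise.
#' @param r_ref reference-arm reflectivity.
#' @param lateral_res550_um lateral resolution (FWHM) at 550 nm, um.
#' @return numeric detector spectrum of length `spectrometer$n_pixels`.
#' @export
simulate_ascan <- function(scene, x_index, source, spectrometer,
                           dispersion = dispersion_model(),
                           noise = NULL, seed = 1, r_ref = 1,
                           lateral_res550_um = 2.5) {
  raw <- simulate_bscan(scene, source, spectrometer, dispersion,
                        noise = noise, repeats = 1, seed = seed,
                        r_ref = r_ref, lateral_res550_um = lateral_res550_um,
                        columns = x_index)
  raw$spectra[, 1, 1]
}

#' Simulate a raw spectral-domain OCT B-scan
#'
#' Sweeps [simulate_ascan()]'s forward model across the scene's A-scans;
#' `repeats` adds independent noise realizations of the same deterministic
#' fringe pattern (motion-free repeated B-scans for averaging). Noise can
#' be specified as an absolute detector read-noise SD (`read_sd`) or as a
#' target image-domain SNR in dB (`snr_db`, peak reconstructed single-
#' scatterer magnitude over the Rayleigh noise scale), from which the
#' detector SD is calibrated through the normalization and FFT gain.
#'
#' @inheritParams simulate_ascan
#' @param repeats number of repeated B-scans.
#' @param columns subset of A-scan indices (default all).
#' @return object of class `raw_interferogram`: list with `spectra`
#'   (pixels x A-scans x repeats), `lambda_px`, `reference` (per-pixel
#'   reference intensity), calibration models, the ground-truth scene and
#'   the seed.
#' @export
simulate_bscan <- function(scene, source = source_model(),
                           spectrometer = spectrometer_model(),
                           dispersion = dispersion_model(),
                           noise = list(snr_db = 45), repeats = 1, seed = 1,
                           r_ref = 1, lateral_res550_um = 2.5,
                           columns = NULL) {
  stopifnot(inherits(scene, "oct_scene"), inherits(source, "source_model"),
            inherits(spectrometer, "spectrometer_model"))
  lambda <- spectrometer$lambda_px
  k <- spectrometer$k_px
  S <- source$S(lambda)
  if (spectrometer$rolloff > 0) {
    kc <- mean(range(k))
    S <- S * exp(-spectrometer$rolloff * ((k - kc) / diff(range(k)))^2)
  }
  if (is.null(columns)) columns <- seq_len(scene$n_ascans)
  sc <- scene$scatterers
  rmat <- scene_reflectivity(scene, lambda)
  k0 <- dispersion_k0(dispersion, spectrometer)
  phi_disp <- dispersion$a2 * (k - k0)^2 + dispersion$a3 * (k - k0)^3
  # depth aliasing guard: local Nyquist for the nonuniform k sampling
  if (nrow(sc)) {
    dk_max <- max(abs(diff(k)))
    z_max <- pi / (2 * scene$n_group * dk_max)
    if (any(sc$z_um > z_max))
      warning(sprintf(
        "scatterers beyond the unambiguous depth (%.0f um) will alias", z_max))
  }
  sigma_lat <- lateral_res550_um / 2.3548 * (lambda / 550)  # per wavelength
  pitch <- scene$lateral_pitch_um
  n_px <- spectrometer$n_pixels
  base <- S * r_ref
  clean <- matrix(0, nrow = n_px, ncol = length(columns))
  max_amp_sum <- 0
  for (ci in seq_along(columns)) {
    col <- columns[ci]
    I <- base
    if (nrow(sc)) {
      dx_um <- (sc$x - col) * pitch
      near <- which(abs(dx_um) < 3 * max(sigma_lat))
      for (j in near) {
        g2 <- exp(-dx_um[j]^2 / (2 * sigma_lat^2))  # intensity PSF weight
        r_eff <- rmat[, j] * g2
        amp <- 2 * sqrt(r_ref * r_eff)
        I <- I + S * (r_eff + amp *
                        cos(2 * k * scene$n_group * sc$z_um[j] + phi_disp))
        max_amp_sum <- max(max_amp_sum, sum(amp * 0.5 / r_ref))
      }
    }
    clean[, ci] <- I
  }
  read_sd <- 0
  if (!is.null(noise)) {
    if (!is.null(noise$read_sd)) read_sd <- noise$read_sd
    else if (!is.null(noise$snr_db) && max_amp_sum > 0) {
      # image-domain Rayleigh noise scale after divide-by-reference and FFT
      gain <- sqrt(sum((1 / pmax(base, 0.05 * max(base)))^2) / 2)
      read_sd <- max_amp_sum * 10^(-noise$snr_db / 20) / gain
    }
  }
  spectra <- array(0, dim = c(n_px, length(columns), repeats))
  old <- .Random.seed_save()
  set.seed(seed)
  for (rep_i in seq_len(repeats)) {
    I <- clean
    if (!is.null(noise) && isTRUE(noise$shot))
      I <- I * (1 + stats::rnorm(length(I), sd = 0.02 / sqrt(pmax(I, 1e-6))))
    if (read_sd > 0)
      I <- I + stats::rnorm(length(I), sd = read_sd)
    spectra[, , rep_i] <- pmax(I, 0)
  }
  .Random.seed_restore(old)
  structure(list(spectra = spectra, lambda_px = lambda,
                 reference = base, source = source,
                 spectrometer = spectrometer, dispersion = dispersion,
                 scene = scene, seed = seed, read_sd = read_sd,
                 r_ref = r_ref),
            class = "raw_interferogram")
}

#' @export
print.raw_interferogram <- function(x, ...) {
  d <- dim(x$spectra)
  cat(sprintf(
    "<raw_interferogram> %d px x %d A-scans x %d repeats, seed %d\n",
    d[1], d[2], d[3], x$seed))
  cat(sprintf("  lambda %g-%g nm, read noise SD %.3g, %d scatterers\n",
              min(x$lambda_px), max(x$lambda_px), x$read_sd,
              nrow(x$scene$scatterers)))
  invisible(x)
}
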