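single_reflector_scene <- function(z = 60, x = 2, n_ascans = 3, r = 1e-4,
                                   medium = "rpe_medium", n_group = 1.38) {
  oct_scene(data.frame(z_um = z, x = x, label = "interface",
                       d_um = NA_real_, r_scale = r),
            medium = medium, n_group = n_group, n_ascans = n_ascans)
}

test_that("empty scene without noise returns exactly the reference spectrum", {
  sc <- oct_scene(data.frame(z_um = numeric(), x = numeric(),
                             label = character(), d_um = numeric(),
                             r_scale = numeric()),
                  medium = "rpe_medium", n_group = 1.38, n_ascans = 2)
  spm <- spectrometer_model(512)
  src <- source_model()
  raw <- simulate_bscan(sc, src, spm, noise = NULL, seed = 1)
  expect_equal(raw$spectra[, 1, 1], src$S(spm$lambda_px), tolerance = 1e-12)
  expect_equal(raw$spectra[, 2, 1], raw$reference, tolerance = 1e-12)
})

test_that("interference terms superpose linearly over scatterers", {
  spm <- spectrometer_model(512)
  mk <- function(zs) {
    n <- length(zs)
    oct_scene(data.frame(z_um = zs, x = rep(2, n), label = "interface",
                         d_um = NA_real_, r_scale = 1e-4),
              medium = "rpe_medium", n_group = 1.38, n_ascans = 3)
  }
  i1 <- simulate_ascan(mk(25), 2, source_model(), spm, noise = NULL)
  i2 <- simulate_ascan(mk(45), 2, source_model(), spm, noise = NULL)
  i12 <- simulate_ascan(mk(c(25, 45)), 2, source_model(), spm, noise = NULL)
  ref <- source_model()$S(spm$lambda_px)
  expect_equal(i12, i1 + i2 - ref, tolerance = 1e-10)
})

test_that("simulation is bit-identical under a fixed seed", {
  sc <- make_phantom_scene(5, seed = 3, n_ascans = 8,
                           surface_z_um = 8, depth_extent_um = 20)
  spm <- spectrometer_model(512)
  r1 <- simulate_bscan(sc, spectrometer = spm, noise = list(snr_db = 30),
                       repeats = 2, seed = 9)
  r2 <- simulate_bscan(sc, spectrometer = spm, noise = list(snr_db = 30),
                       repeats = 2, seed = 9)
  expect_identical(r1$spectra, r2$spectra)
  r3 <- simulate_bscan(sc, spectrometer = spm, noise = list(snr_db = 30),
                       repeats = 2, seed = 10)
  expect_false(identical(r1$spectra, r3$spectra))
  # scene generation is deterministic too
  expect_identical(make_phantom_scene(5, seed = 3, n_ascans = 8,
                                      surface_z_um = 8,
                                      depth_extent_um = 20)$scatterers,
                   sc$scatterers)
})

test_that("phantom granule counts follow the Poisson scene model", {
  c_mg <- 10; n_asc <- 64
  counts <- vapply(1:100, function(s)
    make_phantom_scene(c_mg, seed = s, n_ascans = n_asc)$extra$n_granules,
    numeric(1))
  N <- concentration_to_number_density(c_mg, 2.4)
  vol <- n_asc * 2 * 70 * 7.5
  mu <- N * vol
  expect_lt(abs(mean(counts) - mu), 3 * sqrt(mu / 100))
  # zero concentration leaves only the interface line
  sc0 <- make_phantom_scene(0, seed = 1, n_ascans = 16)
  expect_true(all(sc0$scatterers$label == "interface"))
  expect_equal(nrow(sc0$scatterers), 16)
})

test_that("interface scatterers are wavelength-flat, granules are not", {
  sc <- make_phantom_scene(10, seed = 2, n_ascans = 8)
  lam <- seq(440, 700, length.out = 64)
  r <- hsoct:::scene_reflectivity(sc, lam)
  iface <- sc$scatterers$label == "interface"
  expect_true(all(apply(r[, iface, drop = FALSE], 2,
                        function(v) diff(range(v)) == 0)))
  gran <- which(!iface)
  if (length(gran))
    expect_gt(diff(range(r[, gran[1]])), 0)
})

test_that("retina scenes: albino has no granules, pigmented confines them to the RPE", {
  sa <- make_retina_scene(FALSE, seed = 4, n_ascans = 32)
  sp <- make_retina_scene(TRUE, seed = 4, n_ascans = 32)
  expect_equal(sum(sa$scatterers$label == "granule"), 0)
  g <- sp$scatterers[sp$scatterers$label == "granule", ]
  expect_gt(nrow(g), 0)
  band <- sp$extra$rpe_band_um
  expect_true(all(g$z_um >= band[1] & g$z_um <= band[2]))
  expect_true(all(g$d_um >= 0.3 & g$d_um <= 1.0))
  # sparse density: about one to two granules per A-scan
  expect_lt(nrow(g) / 32, 3)
  expect_gt(nrow(g) / 32, 0.5)
  # matched tissue geometry between the pigmented/albino pair
  expect_identical(sa$scatterers,
                   sp$scatterers[sp$scatterers$label == "tissue", ])
})

test_that("scatterers beyond the unambiguous depth raise an aliasing warning", {
  sc <- single_reflector_scene(z = 400)
  expect_warning(simulate_bscan(sc, spectrometer = spectrometer_model(512),
                                noise = NULL), "alias")
})

test_that("averaging repeats improves SNR at the expected root-n rate", {
  sc <- single_reflector_scene(z = 40, n_ascans = 4)
  spm <- spectrometer_model(512)
  raw <- simulate_bscan(sc, spectrometer = spm, noise = list(snr_db = 25),
                        repeats = 30, seed = 6)
  cfg <- band_config()
  noise_sd_of <- function(reps) {
    acc <- 0
    for (r in reps) {
      norm <- remove_background(raw$spectra[, , r], raw$reference)
      rs <- resample_linear_k(norm, raw$lambda_px)
      acc <- acc + Mod(reconstruct_band(rs$spectra))^2
    }
    img <- acc / length(reps)
    sd(img[140:250, ])  # rows well away from the reflector (peak ~ row 109)
  }
  s1 <- noise_sd_of(1)
  s30 <- noise_sd_of(1:30)
  # pixelwise mean of 30 iid exponential intensity-noise images shrinks the
  # fluctuation SD by sqrt(30) ~ 5.5
  expect_gt(s1 / s30, 4)
  expect_lt(s1 / s30, 7.5)
})

test_that("detector counts stay non-negative with physical noise levels", {
  sc <- make_phantom_scene(5, seed = 8, n_ascans = 6,
                           surface_z_um = 8, depth_extent_um = 20)
  raw <- simulate_bscan(sc, spectrometer = spectrometer_model(512),
                        noise = list(snr_db = 20), seed = 8)
  expect_true(all(raw$spectra >= 0))
  expect_true(all(is.finite(raw$spectra)))
})
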