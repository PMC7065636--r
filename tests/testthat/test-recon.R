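test_that("background removal cancels the source envelope", {
  ref <- c(0, 0.5, 2, 4, 3)
  raw <- matrix(ref, ncol = 1)
  out <- remove_background(raw, ref)
  expect_true(all(out == 0))
  expect_equal(attr(out, "n_masked"), 1)  # the zero-reference pixel
  # multiplicative fringe recovered exactly: raw = ref (1 + eps cos phi)
  ref2 <- rep(2, 64)
  phi <- seq(0, 6 * pi, length.out = 64)
  raw2 <- matrix(ref2 * (1 + 0.1 * cos(phi)), ncol = 1)
  out2 <- remove_background(raw2, ref2)
  expect_equal(out2[, 1], 0.1 * cos(phi), tolerance = 1e-12)
  expect_error(remove_background(raw2, rep(0, 64)), "all-zero")
})

test_that("k-linearization is an identity on already-uniform input and
           sharpens tones sampled nonuniformly", {
  # uniform-in-k calibration: lambda = 2 pi / k with k equally spaced
  k <- seq(9, 14, length.out = 256)
  lam <- 2 * pi / k * 1000
  y <- cos(2 * k * 40)
  rs <- resample_linear_k(y, lam)
  expect_equal(rs$spectra[, 1], y, tolerance = 1e-10)
  expect_equal(rs$k, k, tolerance = 1e-12)
  # nonuniform (uniform-in-lambda) sampling of a pure k-tone: resampling
  # raises the peak-to-sidelobe ratio of the transform
  spm <- spectrometer_model(512)
  tone <- cos(2 * spm$k_px * 60)
  psr <- function(v) {
    a <- Mod(stats::fft(v))[2:200]
    p <- which.max(a)
    max(a) / max(a[-((p - 4):(p + 4))])
  }
  rs2 <- resample_linear_k(tone, spm$lambda_px)
  expect_gt(psr(rs2$spectra[, 1]), 2 * psr(tone))
  # decreasing calibrations are orientation-normalized
  rs3 <- resample_linear_k(rev(tone), rev(spm$lambda_px))
  expect_equal(rs3$spectra, rs2$spectra, tolerance = 1e-9)
  expect_error(resample_linear_k(tone, sort(c(500, 500, 600))), "monotone")
})

test_that("band configuration: 27 bands sharing one wavenumber FWHM", {
  cfg <- band_config()
  expect_length(cfg$centers_nm, 27)
  expect_equal(cfg$centers_nm, seq(440, 700, by = 10))
  expect_equal(cfg$fwhm_k, 4 * log(2) / (1.38 * 6), tolerance = 1e-12)
  expect_equal(cfg$fwhm_k, 0.3348538, tolerance = 1e-6)
  k <- seq(2 * pi / 0.730, 2 * pi / 0.425, length.out = 4096)
  W <- band_windows(cfg, k)
  expect_equal(ncol(W), 27)
  # unit peak up to grid sampling of the window centre
  expect_true(all(apply(W, 2, max) > 0.9999))
  expect_true(all(W <= 1))
  # identical FWHM for every band, measured on the grid
  widths <- apply(W, 2, function(w) diff(range(k[w >= 0.5])))
  expect_lt(diff(range(widths)) / mean(widths), 0.05)
  expect_equal(mean(widths), cfg$fwhm_k, tolerance = 0.01)
  # a grid that clips a window warns
  k_narrow <- seq(2 * pi / 0.700, 2 * pi / 0.440, length.out = 256)
  expect_warning(band_windows(cfg, k_narrow), "truncated")
})

test_that("dispersion compensation phase algebra", {
  k <- seq(9, 14, length.out = 128)
  y <- cos(2 * k * 30)
  expect_equal(compensate_dispersion(y, k, 0, 0, 11.5), y + 0i)
  # compensating with negated coefficients doubles the residual phase:
  # the PSF is strictly wider than with no compensation at all
  psf_width <- function(spec) {
    a <- Mod(reconstruct_band(spec))
    sum(a > max(a) / 2)
  }
  disp <- cos(2 * k * 30 + 1.5 * (k - 11.5)^2)   # dispersed fringe
  w_comp <- psf_width(compensate_dispersion(disp, k, 1.5, 0, 11.5))
  w_un <- psf_width(disp + 0i)
  w_neg <- psf_width(compensate_dispersion(disp, k, -1.5, 0, 11.5))
  expect_lt(w_comp, w_un)
  expect_gt(w_neg, w_un)
})

test_that("sub-band reconstruction: tone location, Parseval, axial resolution", {
  k <- seq(8.6, 14.8, length.out = 1024)
  dk <- k[2] - k[1]
  z0 <- 55  # optical path, um
  y <- cos(2 * k * z0)
  A <- reconstruct_band(y)
  pk <- which.max(Mod(A[, 1]))
  dz <- pi / (length(k) * dk)
  expect_equal((pk - 1) * dz, z0, tolerance = dz)
  # Parseval: FFT energy equals windowed-spectrum energy
  W <- band_windows(band_config(), k)
  Af <- stats::mvfft(matrix(y * W[, 14], ncol = 1))
  expect_equal(sum(Mod(Af)^2) / length(k), sum((y * W[, 14])^2),
               tolerance = 1e-10)
  # every band reconstructs the design axial resolution in tissue
  fw <- vapply(seq_len(27), function(b) {
    a <- Mod(reconstruct_band(y, W[, b]))[, 1]
    peak_fwhm(a, dz) / 1.38
  }, numeric(1))
  expect_true(all(abs(fw - 6) / 6 < 0.1))
})

test_that("registration recovers constructed axial shifts", {
  nz <- 128; nx <- 6; nb <- 5
  base <- exp(-((seq_len(nz) - 50) / 4)^2)
  stack <- array(0, dim = c(nb, nz, nx))
  for (b in seq_len(nb)) for (j in seq_len(nx)) stack[b, , j] <- base
  # identical bands: all shifts zero
  reg <- register_stack(stack)
  expect_equal(reg$shifts, rep(0L, nb))
  # shift band 5 by +3 px and recover it
  shifted <- stack
  shifted[5, , ] <- 0
  shifted[5, 4:nz, ] <- stack[5, 1:(nz - 3), ]
  reg2 <- register_stack(shifted)
  expect_equal(abs(reg2$shifts[5]), 3L)
  expect_equal(which.max(reg2$stack[5, , 1]), which.max(base))
})

test_that("dispersion estimation recovers injected coefficients and the
           compensated PSF matches the dispersion-free width", {
  sc <- oct_scene(data.frame(z_um = 60, x = 2, label = "interface",
                             d_um = NA_real_, r_scale = 1e-4),
                  medium = "rpe_medium", n_group = 1.38, n_ascans = 3)
  spm <- spectrometer_model(2048)
  a2 <- 1.5; a3 <- 0.4
  raw <- simulate_bscan(sc, spectrometer = spm,
                        dispersion = dispersion_model(a2 = a2, a3 = a3),
                        noise = list(snr_db = 40), seed = 21)
  norm <- remove_background(raw$spectra[, , 1], raw$reference)
  rs <- resample_linear_k(norm, raw$lambda_px)
  est <- estimate_dispersion(rs$spectra, rs$k)
  expect_equal(unname(est["a2"]), a2, tolerance = 0.1)
  expect_equal(unname(est["a3"]), a3, tolerance = 0.1)
  # closed loop through the band pipeline
  st_c <- reconstruct_stack(raw, band_config(), dispersion = "truth")
  raw0 <- simulate_bscan(sc, spectrometer = spm, noise = list(snr_db = 40),
                         seed = 21)
  st_0 <- reconstruct_stack(raw0, band_config(), dispersion = NULL)
  f_c <- peak_fwhm(sqrt(st_c$intensity[14, , 2]), st_c$axial_pitch_opt_um)
  f_0 <- peak_fwhm(sqrt(st_0$intensity[14, , 2]), st_0$axial_pitch_opt_um)
  expect_equal(f_c / f_0, 1, tolerance = 0.05)
  # flat input has no structure to focus on
  expect_error(estimate_dispersion(matrix(0, 64, 2), seq(9, 14, length.out = 64)),
               "no structure")
})

test_that("forward model and reconstruction round-trip peak positions", {
  spm <- spectrometer_model(1024)
  cfg <- band_config()
  set.seed(31)
  for (i in 1:8) {
    z <- runif(3, 20, 80)
    sc <- oct_scene(data.frame(z_um = z, x = 2, label = "interface",
                               d_um = NA_real_, r_scale = 1e-4),
                    medium = "rpe_medium", n_group = 1.38, n_ascans = 3)
    raw <- simulate_bscan(sc, spectrometer = spm, noise = NULL)
    st <- reconstruct_stack(raw, cfg, dispersion = NULL, register = FALSE)
    prof <- st$intensity[14, , 2]
    for (zz in z) {
      row <- round(zz * 1.38 / st$axial_pitch_opt_um) + 1
      win <- prof[max(1, row - 3):min(length(prof), row + 3)]
      expect_gt(max(win), 0.25 * max(prof))
    }
  }
})

test_that("hyperstack reconstruction is deterministic and non-negative", {
  sc <- make_phantom_scene(5, seed = 13, n_ascans = 8,
                           surface_z_um = 8, depth_extent_um = 20)
  raw <- simulate_bscan(sc, spectrometer = spectrometer_model(1024),
                        noise = list(snr_db = 30), seed = 13)
  s1 <- reconstruct_stack(raw, band_config())
  s2 <- reconstruct_stack(raw, band_config())
  expect_identical(s1$intensity, s2$intensity)
  expect_true(all(s1$intensity >= 0))
  expect_equal(dim(s1$intensity)[1], 27)
})
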