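two_blob_image <- function(nz = 60, nx = 60) {
  z <- matrix(rep(seq_len(nz), nx), nz)
  x <- matrix(rep(seq_len(nx), each = nz), nz)
  exp(-((z - 18)^2 + (x - 18)^2) / 30) +
    exp(-((z - 42)^2 + (x - 42)^2) / 30) + 1e-3
}

test_that("MIP dominates every band and preserves single-band features", {
  a <- array(runif(4 * 10 * 8), dim = c(4, 10, 8))
  m <- mip_across_bands(a)
  for (b in 1:4) expect_true(all(m >= a[b, , ]))
  same <- array(rep(a[1, , ], each = 4), dim = c(4, 10, 8))
  expect_equal(mip_across_bands(same), same[1, , ])
  # a feature present in only one band appears in the MIP
  a[3, 5, 5] <- 10
  expect_equal(mip_across_bands(a)[5, 5], 10)
})

test_that("watershed produces exhaustive basins above the minimum area", {
  expect_warning(seg0 <- watershed_basins(matrix(1, 20, 20), 1), "constant")
  expect_equal(seg0$n_basins, 1L)
  img <- two_blob_image()
  seg <- watershed_basins(img, pixel_area_um2 = 1, min_area_um2 = 8)
  expect_equal(seg$n_basins, 2L)
  expect_true(all(seg$labels >= 1))
  # speckle-like image: every pixel labeled, no basin below the floor
  set.seed(7)
  noise <- matrix(runif(80 * 60), 80, 60)
  seg2 <- watershed_basins(noise, pixel_area_um2 = 0.74, min_area_um2 = 8)
  expect_true(all(seg2$area_um2 >= 8))
  expect_equal(sum(tabulate(seg2$labels)), length(noise))
  expect_identical(sort(unique(as.vector(seg2$labels))),
                   seq_len(seg2$n_basins))
})

test_that("basin spectra are conservative area-weighted means", {
  set.seed(11)
  a <- array(rexp(3 * 40 * 30), dim = c(3, 40, 30))
  seg <- watershed_basins(mip_across_bands(a), pixel_area_um2 = 1,
                          min_area_um2 = 4)
  sp <- basin_spectra(a, seg)
  expect_equal(dim(sp), c(seg$n_basins, 3))
  areas <- tabulate(seg$labels, seg$n_basins)
  for (b in 1:3)
    expect_equal(sum(sp[, b] * areas), sum(a[b, , ]), tolerance = 1e-9)
  # uniform band: every basin reports the constant
  u <- array(2.5, dim = c(1, 10, 10))
  segu <- suppressWarnings(watershed_basins(matrix(1, 10, 10), 1))
  expect_true(all(basin_spectra(u, segu) == 2.5))
})

test_that("deviation spectrum is exactly mean-centred", {
  expect_true(all(deviation_spectrum(rep(3, 27)) == 0))
  x <- 5 + cos(seq(0, 2 * pi, length.out = 27))
  d <- deviation_spectrum(x)
  expect_equal(d, x - mean(x))
  expect_lt(abs(mean(d)), 1e-12 * max(abs(x)))
  m <- matrix(rexp(4 * 27), 4)
  expect_equal(rowMeans(deviation_spectrum(m)), rep(0, 4), tolerance = 1e-12)
})

test_that("the DFM integral reproduces closed-form trapezoid values", {
  centers <- seq(440, 700, by = 10)
  expect_equal(dfm(rep(0, 27), centers), 0)
  expect_equal(dfm(rep(1, 27), centers), 260)
  expect_equal(dfm(rep(-1, 27), centers), 260)
  ramp <- seq(0, 1, length.out = 27)
  expect_equal(dfm(ramp, centers), 130)
  # positive homogeneity
  set.seed(2)
  v <- deviation_spectrum(rexp(27))
  expect_equal(dfm(3.7 * v, centers), 3.7 * dfm(v, centers), tolerance = 1e-12)
  expect_error(dfm(rep(1, 27), rev(centers)), "increasing")
})

test_that("DFM mapping back to image space is piecewise constant on basins", {
  img <- two_blob_image()
  seg <- watershed_basins(img, pixel_area_um2 = 1, min_area_um2 = 8)
  vals <- c(1.5, 4.2)
  map <- dfm_map(seg, vals)
  expect_equal(dim(map), dim(img))
  for (b in 1:2) expect_true(all(map[seg$labels == b] == vals[b]))
  # area-weighted histogram identity
  expect_equal(sum(map), sum(vals * tabulate(seg$labels)))
  segu <- suppressWarnings(watershed_basins(matrix(1, 5, 5), 1))
  expect_true(all(dfm_map(segu, 7) == 7))
})

test_that("noise SD estimation from a signal-free ROI", {
  img <- matrix(1, 50, 50)
  roi <- img == 1
  expect_equal(estimate_noise_sd(img, roi), 0)
  set.seed(5)
  img2 <- matrix(rnorm(1e4, sd = 2.5), 100, 100)
  expect_equal(estimate_noise_sd(img2, rep(TRUE, 1e4)), 2.5, tolerance = 0.1)
  # order-invariance of the ROI
  idx <- sample(1e4, 500)
  expect_equal(estimate_noise_sd(img2, idx),
               estimate_noise_sd(img2, rev(idx)))
  expect_error(estimate_noise_sd(img2, 1:50), "100")
})

test_that("surface detection tolerates tilt and single-column outliers", {
  nz <- 80; nx <- 40
  img <- matrix(0.01, nz, nx)
  img[30, ] <- 1
  expect_equal(detect_surface(img), rep(30L, nx))
  # tilted interface
  img2 <- matrix(0.01, nz, nx)
  rows <- round(seq(20, 50, length.out = nx))
  img2[cbind(rows, seq_len(nx))] <- 1
  expect_true(all(abs(detect_surface(img2) - rows) <= 1))
  # a single outlier column is repaired by the median filter
  img3 <- img
  img3[30, 20] <- 0.01; img3[5, 20] <- 1
  expect_equal(detect_surface(img3)[20], 30L)
})

test_that("fraction above threshold counts the windowed exceedances", {
  nz <- 200; nx <- 10
  surface <- rep(20L, nx)
  zero <- matrix(0, nz, nx)
  expect_equal(fraction_above_threshold(zero, surface, 1, noise_sd = 1), 0)
  four <- matrix(4, nz, nx)
  expect_equal(fraction_above_threshold(four, surface, 1, noise_sd = 1), 100)
  # noise_mean baseline shifts the threshold
  expect_equal(fraction_above_threshold(four, surface, 1, noise_sd = 1,
                                        noise_mean = 2), 0)
  expect_warning(
    fraction_above_threshold(zero, rep(190L, nx), 1, noise_sd = 1),
    "truncated")
})

test_that("RGB encoding renders flat spectra grey and band-specific features in colour", {
  a <- array(rep(matrix(runif(30 * 20), 30, 20), each = 27),
             dim = c(27, 30, 20))
  st <- structure(list(intensity = a, band_centers_nm = seq(440, 700, 10)),
                  class = "hyperstack")
  rgb <- rgb_encode(st)
  expect_equal(dim(rgb), c(30, 20, 3))
  expect_equal(rgb[, , 1], rgb[, , 2], tolerance = 1e-9)
  expect_equal(rgb[, , 2], rgb[, , 3], tolerance = 1e-9)
  # feature only in the 560 nm band saturates the red channel
  a2 <- a; a2[13, 10, 10] <- 100   # 560 nm
  st2 <- st; st2$intensity <- a2
  rgb2 <- rgb_encode(st2)
  expect_equal(rgb2[10, 10, 1], 1)
  expect_lt(rgb2[10, 10, 3], 1)
  expect_error(rgb_encode(st, bands_nm = c(541, 550, 560)), "not present")
})

test_that("repeat averaging is the pixelwise mean and precedes the MIP", {
  a <- array(runif(3 * 8 * 6), dim = c(3, 8, 6))
  b <- array(runif(3 * 8 * 6), dim = c(3, 8, 6))
  avg <- average_repeats(list(a, b))
  expect_equal(avg, (a + b) / 2)
  expect_equal(average_repeats(list(a, a)), a)
  # averaging then MIP differs from MIP then averaging (pipeline order matters)
  m1 <- mip_across_bands(avg)
  m2 <- (mip_across_bands(a) + mip_across_bands(b)) / 2
  expect_false(isTRUE(all.equal(m1, m2)))
  expect_true(all(m2 >= m1 - 1e-12))
})
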