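#' Maximum intensity projection across bands
#'
#' Per-pixel maximum over the 27 sub-band images. Granules visible in only
#' a few bands (their backscattering oscillates with wavelength) all appear
#' in the MIP, and the wavelength-dependent speckle is suppressed, which is
#' what makes the MIP the right landscape for watershed binning.
#'
#' @param stack a `hyperstack` or a band x depth x lateral array.
#' @return matrix depth x lateral.
#' @export
mip_across_bands <- function(stack) {
  a <- if (inherits(stack, "hyperstack")) stack$intensity else stack
  apply(a, c(2, 3), max)
}

#' Watershed speckle segmentation
#'
#' Watershed transform on the MIP (basins around intensity maxima, i.e. on
#' the inverted topography) defining catchment basins on the order of
#' single speckles. Basins smaller than `min_area_um2` are merged into the
#' neighbouring basin sharing the longest boundary, to avoid
#' oversegmentation; merging runs in rounds until no small basin remains.
#'
#' @param mip non-negative matrix (depth x lateral).
#' @param pixel_area_um2 area of one pixel in um^2.
#' @param min_area_um2 minimum basin area (default 8 um^2, just below the
#'   image resolution).
#' @param tolerance watershed flooding tolerance as a fraction of the
#'   image dynamic range (merges maxima shallower than this); 0 keeps
#'   every local maximum as a seed, with oversegmentation handled by the
#'   minimum-area merge alone.
#' @return object of class `basin_segmentation`: list with integer `labels`
#'   (depth x lateral, every pixel labeled 1..n), `n_basins`, `area_um2`
#'   per basin, and the `mip` used.
#' @export
watershed_basins <- function(mip, pixel_area_um2,
                             min_area_um2 = 8, tolerance = 0) {
  stopifnot(is.matrix(mip), all(mip >= 0))
  rng <- range(mip)
  if (diff(rng) == 0) {
    warning("constant image: single basin")
    labels <- matrix(1L, nrow(mip), ncol(mip))
    return(structure(list(labels = labels, n_basins = 1L,
                          area_um2 = length(mip) * pixel_area_um2,
                          mip = mip, pixel_area_um2 = pixel_area_um2),
                     class = "basin_segmentation"))
  }
  norm <- (mip - rng[1]) / diff(rng)
  lab <- EBImage::imageData(EBImage::watershed(EBImage::as.Image(norm),
                                               tolerance = tolerance,
                                               ext = 1))
  storage.mode(lab) <- "integer"
  lab <- fill_zero_labels(lab)
  min_px <- max(1L, as.integer(ceiling(min_area_um2 / pixel_area_um2)))
  lab <- merge_small_basins(lab, min_px)
  # relabel contiguously 1..n
  u <- sort(unique(as.vector(lab)))
  lab <- matrix(match(lab, u), nrow(lab), ncol(lab))
  areas <- tabulate(lab)
  structure(list(labels = lab, n_basins = length(areas),
                 area_um2 = areas * pixel_area_um2, mip = mip,
                 pixel_area_um2 = pixel_area_um2),
            class = "basin_segmentation")
}

# The flooding transform can leave isolated background (zero-labeled)
# pixels at intensity minima; assign them the strongest neighbouring label
# so that every pixel belongs to a basin.
fill_zero_labels <- function(lab) {
  nr <- nrow(lab); nc <- ncol(lab)
  for (it in seq_len(nr + nc)) {
    z <- which(lab == 0L)
    if (!length(z)) break
    for (p in z) {
      r <- (p - 1L) %% nr + 1L; cc <- (p - 1L) %/% nr + 1L
      nbs <- c(if (r > 1) lab[r - 1, cc], if (r < nr) lab[r + 1, cc],
               if (cc > 1) lab[r, cc - 1], if (cc < nc) lab[r, cc + 1])
      nbs <- nbs[nbs > 0]
      if (length(nbs)) lab[r, cc] <- max(nbs)
    }
  }
  lab
}

# Merge basins smaller than min_px into the neighbour sharing the longest
# boundary. Round-based: each round rebuilds the boundary-length adjacency,
# lets every small basin pick its strongest neighbour, and resolves the
# merges through a union-find (which cannot cycle); repeats until no basin
# is below the floor or nothing changes.
merge_small_basins <- function(lab, min_px) {
  for (round in seq_len(100)) {
    areas <- tabulate(lab)
    small <- which(areas > 0 & areas < min_px)
    if (!length(small)) break
    nr <- nrow(lab); nc <- ncol(lab)
    a <- c(lab[-nr, ], lab[, -nc])
    b <- c(lab[-1, ], lab[, -1])
    keep <- a != b
    if (!any(keep)) break
    i <- pmin(a[keep], b[keep]); j <- pmax(a[keep], b[keep])
    K <- max(lab) + 1L
    cnt <- tabulate(i * K + j)
    codes <- which(cnt > 0)
    ci <- codes %/% K; cj <- codes %% K
    # neighbour lists (both directions) with shared-boundary lengths
    from <- c(ci, cj); to <- c(cj, ci); w <- rep(cnt[codes], 2)
    nb_idx <- split(seq_along(from), from)
    parent <- seq_len(max(lab))
    find <- function(x) {
      while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }
      x
    }
    for (s in small) {
      if (find(s) != s) next            # swallowed earlier this round
      sel <- nb_idx[[as.character(s)]]
      if (is.null(sel)) next
      best <- to[sel][which.max(w[sel])]
      rb <- find(best)
      if (rb != s) parent[s] <- as.integer(rb)
    }
    map <- vapply(seq_len(max(lab)), function(s) as.integer(find(s)),
                  integer(1))
    if (all(map == seq_along(map))) break
    lab <- matrix(map[lab], nr, nc)
  }
  lab
}

#' @export
print.basin_segmentation <- function(x, ...) {
  cat(sprintf("<basin_segmentation> %d basins over %d x %d px\n",
              x$n_basins, nrow(x$labels), ncol(x$labels)))
  cat(sprintf("  basin area: min %.1f, median %.1f, max %.1f um^2\n",
              min(x$area_um2), stats::median(x$area_um2), max(x$area_um2)))
  invisible(x)
}

#' Per-basin band spectra
#'
#' Mean linear intensity over each basin's pixels, for each band.
#'
#' @param stack a `hyperstack` or band x depth x lateral array.
#' @param seg a [watershed_basins()] segmentation matching the stack
#'   geometry.
#' @return matrix basins x bands of mean intensities.
#' @export
basin_spectra <- function(stack, seg) {
  a <- if (inherits(stack, "hyperstack")) stack$intensity else stack
  stopifnot(all(dim(a)[2:3] == dim(seg$labels)))
  idx <- as.vector(seg$labels)
  nb <- dim(a)[1]
  out <- matrix(0, nrow = seg$n_basins, ncol = nb)
  for (b in seq_len(nb)) {
    s <- rowsum(as.vector(a[b, , ]), idx)
    out[, b] <- s / tabulate(idx, nbins = seg$n_basins)
  }
  out
}

#' Deviation spectrum
#'
#' Subtracts the across-band mean from a basin's band spectrum; the result
#' sums to zero. A wavelength-flat backscatterer gives zero everywhere,
#' while Mie-regime granules leave oscillatory residuals.
#'
#' @param spectrum numeric vector of band intensities (or basins x bands
#'   matrix).
#' @return same shape, mean-subtracted along bands.
#' @export
deviation_spectrum <- function(spectrum) {
  if (is.matrix(spectrum)) spectrum - rowMeans(spectrum)
  else spectrum - mean(spectrum)
}

#' Deviation-from-mean statistic
#'
#' \eqn{DFM = \int_{\lambda_1}^{\lambda_{27}} |I_{dev}(\lambda)|\, d\lambda}
#' by the trapezoidal rule on the band-centre grid; units intensity x nm,
#' larger values meaning stronger wavelength dependence of backscattering.
#'
#' @param i_dev deviation spectrum (vector, or basins x bands matrix).
#' @param centers_nm band centre wavelengths (increasing).
#' @return scalar (or vector over basins), >= 0.
#' @export
dfm <- function(i_dev, centers_nm = seq(440, 700, by = 10)) {
  if (is.unsorted(centers_nm, strictly = TRUE))
    stop("band centres must be increasing")
  tr <- function(y) {
    sum(diff(centers_nm) * (abs(y[-1]) + abs(y[-length(y)])) / 2)
  }
  if (is.matrix(i_dev)) {
    stopifnot(ncol(i_dev) == length(centers_nm))
    apply(i_dev, 1, tr)
  } else {
    stopifnot(length(i_dev) == length(centers_nm))
    tr(i_dev)
  }
}

#' Map basin DFM values back to image space
#'
#' @param seg a [watershed_basins()] segmentation.
#' @param values one value per basin.
#' @return matrix depth x lateral, piecewise constant on basins.
#' @export
dfm_map <- function(seg, values) {
  stopifnot(length(values) == seg$n_basins)
  matrix(values[seg$labels], nrow(seg$labels), ncol(seg$labels))
}

#' Noise standard deviation from a signal-free region
#'
#' Sample SD over a region of interest, by default the region anterior to
#' the detected sample surface where only system noise is present.
#'
#' @param img matrix (intensity or DFM map).
#' @param roi logical matrix or index vector selecting >= 100 pixels.
#' @return sample standard deviation.
#' @export
estimate_noise_sd <- function(img, roi) {
  v <- img[roi]
  if (length(v) < 100) stop("noise ROI must contain at least 100 pixels")
  stats::sd(v)
}

#' Detect the sample surface line
#'
#' Per A-scan, the first depth where intensity exceeds 50 percent of that
#' column's maximum; the resulting profile is median-filtered across
#' columns (width 5) to remove single-column outliers. Columns without a
#' crossing are filled from their neighbours.
#'
#' @param mip intensity image (depth x lateral).
#' @param frac threshold as a fraction of the per-column maximum.
#' @return integer vector of surface rows, one per column.
#' @export
detect_surface <- function(mip, frac = 0.5) {
  nc <- ncol(mip)
  s <- vapply(seq_len(nc), function(j) {
    col <- mip[, j]
    i <- which(col > frac * max(col))
    if (length(i)) i[1] else NA_integer_
  }, integer(1))
  if (all(is.na(s))) stop("no surface detected")
  if (any(is.na(s))) s[is.na(s)] <- round(stats::median(s, na.rm = TRUE))
  as.integer(round(stats::runmed(s, 5)))
}

#' Fraction of pixels above a noise threshold in a depth window
#'
#' The concentration metric: excluding the surface line (plus one axial
#' resolution margin), the percentage of pixels whose value exceeds
#' `k * noise_sd` within a depth window below the surface.
#'
#' @param map matrix (DFM map or intensity image).
#' @param surface per-column surface rows (from [detect_surface()]).
#' @param axial_pitch_um axial pixel pitch in the medium, um.
#' @param noise_sd noise standard deviation of `map`'s own noise.
#' @param window_um depth window, um (default 50).
#' @param k threshold multiplier (default 3).
#' @param exclusion_um margin below the surface before the window starts,
#'   um (default 6, one axial resolution).
#' @param noise_mean baseline level of the map in the signal-free region;
#'   the threshold is `noise_mean + k * noise_sd`. Basin-level statistics
#'   of a non-negative map (such as DFM) have a positive noise floor, so
#'   thresholding k standard deviations above that floor is what separates
#'   signal from noise.
#' @return percentage (0-100) of windowed pixels above the threshold.
#' @export
fraction_above_threshold <- function(map, surface, axial_pitch_um, noise_sd,
                                     window_um = 50, k = 3,
                                     exclusion_um = 6, noise_mean = 0) {
  nz <- nrow(map)
  excl_px <- ceiling(exclusion_um / axial_pitch_um)
  win_px <- round(window_um / axial_pitch_um)
  total <- 0L; above <- 0L
  truncated <- FALSE
  for (j in seq_len(ncol(map))) {
    z0 <- surface[j] + excl_px
    z1 <- z0 + win_px - 1L
    if (z1 > nz) { z1 <- nz; truncated <- TRUE }
    if (z0 > nz) next
    v <- map[z0:z1, j]
    total <- total + length(v)
    above <- above + sum(v > noise_mean + k * noise_sd)
  }
  if (truncated) warning("depth window truncated at the image bottom")
  if (total == 0) return(0)
  100 * above / total
}

#' RGB encoding of three consecutive bands
#'
#' Percentile-normalized (0.1-99.9 percent) encoding of three band images
#' into blue, green and red channels (defaults 540, 550, 560 nm).
#' Wavelength-flat structures render grey/white; Mie-regime granules show
#' band-to-band intensity differences as colour.
#'
#' @param stack a `hyperstack`.
#' @param bands_nm three band centres: c(blue, green, red).
#' @return array depth x lateral x 3 (R, G, B in planes 1..3), values 0-1.
#' @export
rgb_encode <- function(stack, bands_nm = c(540, 550, 560)) {
  stopifnot(inherits(stack, "hyperstack"), length(bands_nm) == 3)
  idx <- match(bands_nm, stack$band_centers_nm)
  if (any(is.na(idx)))
    stop("requested band(s) not present in the stack")
  norm <- function(img) {
    q <- stats::quantile(img, c(0.001, 0.999))
    pmin(pmax((img - q[1]) / max(q[2] - q[1], .Machine$double.eps), 0), 1)
  }
  d <- dim(stack$intensity)[2:3]
  out <- array(0, dim = c(d, 3))
  out[, , 1] <- norm(stack$intensity[idx[3], , ])  # red   = 560
  out[, , 2] <- norm(stack$intensity[idx[2], , ])  # green = 550
  out[, , 3] <- norm(stack$intensity[idx[1], , ])  # blue  = 540
  out
}

#' Average repeated B-scan stacks
#'
#' Pixelwise mean of linear intensities across motion-free repeats, per
#' band; applied before the MIP in the analysis pipeline.
#'
#' @param stacks list of `hyperstack` objects (or band x depth x lateral
#'   arrays) with identical geometry.
#' @return object of the same kind as the first element, averaged.
#' @export
average_repeats <- function(stacks) {
  stopifnot(length(stacks) >= 1)
  first <- stacks[[1]]
  arr <- function(s) if (inherits(s, "hyperstack")) s$intensity else s
  acc <- arr(first)
  if (length(stacks) > 1)
    for (s in stacks[-1]) {
      a <- arr(s)
      stopifnot(all(dim(a) == dim(acc)))
      acc <- acc + a
    }
  acc <- acc / length(stacks)
  if (inherits(first, "hyperstack")) { first$intensity <- acc; first }
  else acc
}

#' Full DFM analysis of a hyperspectral stack
#'
#' Runs the image-analysis pipeline: MIP across bands, surface detection,
#' watershed speckle binning with the 8 um^2 floor, per-basin band
#' spectra, deviation spectra and the DFM statistic, mapping back to image
#' space, noise estimation anterior to the surface, 3-sigma thresholding
#' of both the intensity (MIP) and DFM maps, and the depth-windowed
#' fraction-above-threshold metrics.
#'
#' @param stack a `hyperstack`.
#' @param min_area_um2 minimum basin area.
#' @param k threshold multiplier.
#' @param window_um depth window for the concentration metric, um.
#' @param exclusion_um surface exclusion margin, um.
#' @return object of class `dfm_analysis`: list with `mip`, `surface`,
#'   `seg`, `spectra` (basins x bands), `dfm_values`, `map` (DFM image),
#'   `binary` (thresholded DFM), noise SDs and thresholds for both maps,
#'   and `fraction_intensity` / `fraction_dfm` percentages.
#' @export
dfm_analyze <- function(stack, min_area_um2 = 8, k = 3,
                        window_um = 50, exclusion_um = 6) {
  stopifnot(inherits(stack, "hyperstack"))
  mip <- mip_across_bands(stack)
  surface <- detect_surface(mip)
  px_area <- stack$axial_pitch_um * stack$lateral_pitch_um
  seg <- watershed_basins(mip, px_area, min_area_um2 = min_area_um2)
  sp <- basin_spectra(stack, seg)
  dv <- deviation_spectrum(sp)
  vals <- dfm(dv, stack$band_centers_nm)
  map <- dfm_map(seg, vals)
  # noise ROI: anterior to the surface, with a two-resolution margin so
  # surface PSF tails stay out of the noise statistics
  margin_px <- max(2L, ceiling(2 * exclusion_um / stack$axial_pitch_um))
  top <- max(2L, min(surface) - margin_px)
  roi <- matrix(FALSE, nrow(mip), ncol(mip))
  roi[seq_len(top), ] <- TRUE
  if (sum(roi) < 100) stop("too little room above the surface for a noise ROI")
  sd_int <- estimate_noise_sd(mip, roi)
  sd_dfm <- estimate_noise_sd(map, roi)
  mu_int <- mean(mip[roi])
  mu_dfm <- mean(map[roi])
  fi <- fraction_above_threshold(mip, surface, stack$axial_pitch_um, sd_int,
                                 window_um = window_um, k = k,
                                 exclusion_um = exclusion_um,
                                 noise_mean = mu_int)
  fd <- fraction_above_threshold(map, surface, stack$axial_pitch_um, sd_dfm,
                                 window_um = window_um, k = k,
                                 exclusion_um = exclusion_um,
                                 noise_mean = mu_dfm)
  structure(list(mip = mip, surface = surface, seg = seg, spectra = sp,
                 dfm_values = vals, map = map,
                 binary = map > mu_dfm + k * sd_dfm,
                 noise_sd_intensity = sd_int, noise_sd_dfm = sd_dfm,
                 noise_mean_intensity = mu_int, noise_mean_dfm = mu_dfm,
                 threshold_intensity = mu_int + k * sd_int,
                 threshold_dfm = mu_dfm + k * sd_dfm,
                 fraction_intensity = fi, fraction_dfm = fd,
                 band_centers_nm = stack$band_centers_nm,
                 axial_pitch_um = stack$axial_pitch_um,
                 lateral_pitch_um = stack$lateral_pitch_um, k = k),
            class = "dfm_analysis")
}

#' @export
print.dfm_analysis <- function(x, ...) {
  cat(sprintf("<dfm_analysis> %d basins, noise SD (DFM) %.3g, 3-sigma threshold %.3g\n",
              x$seg$n_basins, x$noise_sd_dfm, x$threshold_dfm))
  cat(sprintf("  fraction above threshold: intensity %.2f%%, DFM %.2f%%\n",
              x$fraction_intensity, x$fraction_dfm))
  invisible(x)
}

#' @export
summary.dfm_analysis <- function(object, ...) {
  c(n_basins = object$seg$n_basins,
    noise_sd_intensity = object$noise_sd_intensity,
    noise_sd_dfm = object$noise_sd_dfm,
    fraction_intensity = object$fraction_intensity,
    fraction_dfm = object$fraction_dfm)
}

#' @export
plot.dfm_analysis <- function(x, what = c("dfm", "mip", "binary"), ...) {
  what <- match.arg(what)
  img <- switch(what, dfm = x$map, mip = x$mip, binary = x$binary * 1)
  graphics::image(t(img)[, rev(seq_len(nrow(img)))],
                  col = grDevices::hcl.colors(256, "viridis"),
                  axes = FALSE, xlab = "lateral", ylab = "depth",
                  main = toupper(what), ...)
  invisible(x)
}
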