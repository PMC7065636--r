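#' Paraxial chromatic focal shift of a ball lens
#'
#' Thick-lens paraxial effective focal length of a glass ball,
#' \eqn{f(\lambda) = n(\lambda) D / (4 (n(\lambda) - 1))} measured from the
#' lens centre, evaluated against a reference wavelength. With N-BK7
#' dispersion this reproduces the chromatic focal shift of the ball-lens
#' rodent-eye phantom (about +/-24 um for a 3 mm lens, +/-45 um for 6 mm,
#' relative to 500 nm).
#'
#' @param diameter_mm ball lens diameter in mm, > 0.
#' @param lambda_nm wavelength grid in nm.
#' @param lambda_ref_nm reference wavelength in nm (default 500).
#' @param index function giving the real index vs nm (default [nbk7_index()]).
#' @return data.frame with `lambda_nm`, `f_mm` (focal length from lens
#'   centre), `shift_um` (focal shift relative to the reference).
#' @examples
#' fs <- ball_lens_focal_shift(3)
#' max(abs(fs$shift_um))
#' @export
ball_lens_focal_shift <- function(diameter_mm,
                                  lambda_nm = seq(400, 700, by = 1),
                                  lambda_ref_nm = 500,
                                  index = nbk7_index) {
  stopifnot(diameter_mm > 0)
  if (lambda_ref_nm < min(lambda_nm) || lambda_ref_nm > max(lambda_nm))
    stop("reference wavelength outside the grid range")
  n <- index(lambda_nm)
  if (any(n <= 1)) stop("paraxial ball-lens model requires n > 1")
  f <- n * diameter_mm / (4 * (n - 1))
  n_ref <- index(lambda_ref_nm)
  f_ref <- n_ref * diameter_mm / (4 * (n_ref - 1))
  data.frame(lambda_nm = lambda_nm, f_mm = f,
             shift_um = (f - f_ref) * 1e3)
}

#' Confocal parameter of a Gaussian beam
#'
#' \eqn{b = 2\pi w_0^2 / \lambda}: twice the Rayleigh range, the axial
#' extent over which a focused beam is considered in focus.
#'
#' @param w0_um beam waist in um (half the 1/e^2 diameter at focus), > 0.
#' @param lambda_nm wavelength in nm, > 0.
#' @return confocal parameter in um.
#' @examples confocal_parameter(1, 500)
#' @export
confocal_parameter <- function(w0_um, lambda_nm) {
  if (any(w0_um <= 0) || any(lambda_nm <= 0))
    stop("confocal_parameter: inputs must be positive")
  2 * pi * w0_um^2 / (lambda_nm / 1000)
}

#' Diffraction-limited waist from the Airy radius
#'
#' The phantom's focused spot is diffraction limited, so the Gaussian-waist
#' equivalent is taken as the Airy radius
#' \eqn{r = 1.22 \lambda f / D_{beam}}.
#'
#' @param lambda_nm wavelength in nm.
#' @param f_mm focal length in mm.
#' @param beam_diameter_mm input beam 1/e^2 diameter at the lens in mm.
#' @return waist in um.
#' @export
airy_waist <- function(lambda_nm, f_mm, beam_diameter_mm) {
  if (any(beam_diameter_mm <= 0)) stop("beam diameter must be positive")
  1.22 * (lambda_nm / 1000) * f_mm * 1e3 / (beam_diameter_mm * 1e3)
}

#' Chromatic focus profile of a ball lens
#'
#' Combines the paraxial focal shift with a diffraction-limited waist model
#' to give, per wavelength, the focal position, waist and confocal
#' parameter. The input beam diameter is a free instrument parameter.
#'
#' @inheritParams ball_lens_focal_shift
#' @param beam_diameter_mm input beam diameter at the lens, mm.
#' @return object of class `focus_profile`: data.frame with `lambda_nm`,
#'   `f_mm`, `shift_um`, `w0_um`, `b_um`.
#' @export
focus_profile <- function(diameter_mm, beam_diameter_mm,
                          lambda_nm = seq(400, 700, by = 10),
                          lambda_ref_nm = 500,
                          index = nbk7_index) {
  fs <- ball_lens_focal_shift(diameter_mm, lambda_nm, lambda_ref_nm, index)
  fs$w0_um <- airy_waist(fs$lambda_nm, fs$f_mm, beam_diameter_mm)
  fs$b_um <- confocal_parameter(fs$w0_um, fs$lambda_nm)
  class(fs) <- c("focus_profile", "data.frame")
  fs
}

#' Depth interval where all wavelengths are simultaneously in focus
#'
#' Intersects the per-wavelength in-focus intervals
#' \eqn{[f(\lambda)-b(\lambda)/2,\, f(\lambda)+b(\lambda)/2]}.
#'
#' @param profile a [focus_profile()].
#' @return list with `z_lo_um`, `z_hi_um`, `length_um` (relative to the
#'   reference focal position) and logical `empty`.
#' @export
focus_overlap_interval <- function(profile) {
  stopifnot(inherits(profile, "focus_profile"), nrow(profile) > 0)
  lo <- max(profile$shift_um - profile$b_um / 2)
  hi <- min(profile$shift_um + profile$b_um / 2)
  if (hi <= lo)
    return(list(z_lo_um = NA_real_, z_hi_um = NA_real_,
                length_um = 0, empty = TRUE))
  list(z_lo_um = lo, z_hi_um = hi, length_um = hi - lo, empty = FALSE)
}

#' @export
plot.focus_profile <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2)); on.exit(graphics::par(op))
  graphics::plot(x$lambda_nm, x$shift_um, type = "l",
                 xlab = "wavelength (nm)", ylab = "focal shift (um)",
                 main = "chromatic focal shift")
  graphics::abline(h = 0, lty = 3)
  graphics::plot(x$lambda_nm, x$shift_um, ylim = range(
    x$shift_um - x$b_um / 2, x$shift_um + x$b_um / 2),
    xlab = "wavelength (nm)", ylab = "depth (um)",
    main = "confocal parameter", pch = 20)
  graphics::segments(x$lambda_nm, x$shift_um - x$b_um / 2,
                     x$lambda_nm, x$shift_um + x$b_um / 2)
  ov <- focus_overlap_interval(x)
  if (!ov$empty) graphics::abline(h = c(ov$z_lo_um, ov$z_hi_um), lty = 2)
  invisible(x)
}

#' CSV export of a focus profile
#' @param profile a [focus_profile()].
#' @param path output CSV path.
#' @export
write_focus_csv <- function(profile, path) {
  utils::write.csv(as.data.frame(profile)[, c("lambda_nm", "shift_um",
                                              "w0_um", "b_um")],
                   path, row.names = FALSE)
  invisible(profile)
}
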