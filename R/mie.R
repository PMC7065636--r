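#' Mie size parameter
#'
#' \eqn{x = \pi d n_{med} / \lambda}, the dimensionless scale controlling
#' Mie behaviour, with the granule diameter `d_um` in micrometres and the
#' (vacuum) wavelength in nm.
#'
#' @param d_um sphere diameter in um, > 0.
#' @param lambda_nm vacuum wavelength in nm, > 0.
#' @param n_medium real refractive index of the surrounding medium, > 0.
#' @return dimensionless size parameter.
#' @examples size_parameter(0.7, 550, 1.368)
#' @export
size_parameter <- function(d_um, lambda_nm, n_medium) {
  if (any(d_um <= 0) || any(lambda_nm <= 0) || any(n_medium <= 0))
    stop("size_parameter: all inputs must be positive")
  pi * d_um * n_medium / (lambda_nm / 1000)
}

#' Wiscombe truncation order for the Mie series
#'
#' @param x size parameter.
#' @return integer series length, `ceil(x + 4 x^(1/3) + 2)`.
#' @export
mie_nmax <- function(x) {
  as.integer(ceiling(x + 4 * x^(1 / 3) + 2))
}

#' Mie scattering coefficients for an absorbing sphere
#'
#' Computes the Mie series coefficients a_n, b_n for a sphere of complex
#' relative index `m` in a non-absorbing medium at size parameter `x`,
#' using the downward-recurrence logarithmic derivative of the
#' Riccati-Bessel function for numerical stability (Bohren-Huffman scheme).
#'
#' @param x size parameter (scalar, >= 0).
#' @param m complex relative refractive index (sphere / medium).
#' @param n_max series length; defaults to the Wiscombe criterion.
#' @return list with complex vectors `a` and `b` of length `n_max`.
#' @export
mie_coefficients <- function(x, m, n_max = mie_nmax(x)) {
  if (length(x) != 1L) stop("x must be scalar")
  if (x < 0) stop("x must be non-negative")
  if (x == 0)
    return(list(a = complex(n_max), b = complex(n_max)))
  if (n_max < mie_nmax(x))
    stop("n_max below the Wiscombe truncation criterion")
  m <- as.complex(m)
  z <- m * x
  # logarithmic derivative D_n(mx) by downward recurrence
  nstart <- n_max + 15L
  D <- complex(nstart + 1L)
  for (n in nstart:1) {
    D[n] <- (n + 1) / z - 1 / (D[n + 1L] + (n + 1) / z)
  }
  if (any(!is.finite(Re(D[seq_len(n_max)])) | !is.finite(Im(D[seq_len(n_max)]))))
    stop("mie_coefficients: logarithmic-derivative recurrence diverged")
  # Riccati-Bessel psi_n(x), chi_n(x) by upward recurrence (real argument)
  psi_m1 <- cos(x); psi0 <- sin(x)
  chi_m1 <- -sin(x); chi0 <- cos(x)
  a <- complex(n_max); b <- complex(n_max)
  psi_prev <- psi_m1; psi_cur <- psi0
  chi_prev <- chi_m1; chi_cur <- chi0
  for (n in seq_len(n_max)) {
    psi_n <- (2 * n - 1) / x * psi_cur - psi_prev
    chi_n <- (2 * n - 1) / x * chi_cur - chi_prev
    xi_n <- complex(real = psi_n, imaginary = -chi_n)
    xi_nm1 <- complex(real = psi_cur, imaginary = -chi_cur)
    da <- D[n] / m + n / x
    db <- D[n] * m + n / x
    a[n] <- (da * psi_n - psi_cur) / (da * xi_n - xi_nm1)
    b[n] <- (db * psi_n - psi_cur) / (db * xi_n - xi_nm1)
    psi_prev <- psi_cur; psi_cur <- psi_n
    chi_prev <- chi_cur; chi_cur <- chi_n
  }
  list(a = a, b = b)
}

# Vectorized efficiencies over paired (x, m); shared n_max from the largest x.
# Recurrences run over the series index with vector arithmetic over the grid,
# which is what makes full-spectrum evaluation cheap.
mie_efficiencies_vec <- function(x, m) {
  stopifnot(length(x) == length(m))
  pos <- x > 0
  Qb <- Qsca <- Qext <- numeric(length(x))
  if (!any(pos)) return(list(Qb = Qb, Qsca = Qsca, Qext = Qext))
  xp <- x[pos]; mp <- as.complex(m[pos])
  n_max <- mie_nmax(max(xp))
  z <- mp * xp
  nstart <- n_max + 15L
  D <- matrix(0i, nrow = nstart + 1L, ncol = length(xp))
  for (n in nstart:1) D[n, ] <- (n + 1) / z - 1 / (D[n + 1L, ] + (n + 1) / z)
  psi_prev <- cos(xp); psi_cur <- sin(xp)
  chi_prev <- -sin(xp); chi_cur <- cos(xp)
  sb <- 0i; ssca <- 0; sext <- 0
  for (n in seq_len(n_max)) {
    psi_n <- (2 * n - 1) / xp * psi_cur - psi_prev
    chi_n <- (2 * n - 1) / xp * chi_cur - chi_prev
    xi_n <- complex(real = psi_n, imaginary = -chi_n)
    xi_nm1 <- complex(real = psi_cur, imaginary = -chi_cur)
    da <- D[n, ] / mp + n / xp
    db <- D[n, ] * mp + n / xp
    an <- (da * psi_n - psi_cur) / (da * xi_n - xi_nm1)
    bn <- (db * psi_n - psi_cur) / (db * xi_n - xi_nm1)
    w <- 2 * n + 1
    sb <- sb + w * (-1)^n * (an - bn)
    ssca <- ssca + w * (Mod(an)^2 + Mod(bn)^2)
    sext <- sext + w * Re(an + bn)
    psi_prev <- psi_cur; psi_cur <- psi_n
    chi_prev <- chi_cur; chi_cur <- chi_n
  }
  Qb[pos] <- Mod(sb)^2 / xp^2
  Qsca[pos] <- 2 * ssca / xp^2
  Qext[pos] <- 2 * sext / xp^2
  list(Qb = Qb, Qsca = Qsca, Qext = Qext)
}

#' Radar backscattering efficiency
#'
#' \eqn{Q_b = x^{-2} |\sum_n (2n+1)(-1)^n (a_n - b_n)|^2}, the efficiency for
#' scattering into the exact backward direction, the quantity an OCT system
#' detects from a single sphere.
#'
#' @inheritParams mie_coefficients
#' @param x size parameter(s); vectorized together with `m`.
#' @return dimensionless backscattering efficiency, >= 0.
#' @examples backscattering_efficiency(5.47, complex(real = 1.26, imaginary = 0.008))
#' @export
backscattering_efficiency <- function(x, m) {
  m <- rep_len(as.complex(m), length(x))
  mie_efficiencies_vec(x, m)$Qb
}

# Q_ext and Q_sca, used internally for energy-conservation checks.
mie_efficiencies <- function(x, m) {
  m <- rep_len(as.complex(m), length(x))
  mie_efficiencies_vec(x, m)
}

#' Granule population
#'
#' A monodisperse population of spherical granules of a given material.
#'
#' @param d_um granule diameter in um, > 0.
#' @param number_density granules per um^3, >= 0.
#' @param material an `index_model` (see [material_index()]), default melanin.
#' @return object of class `granule_population`.
#' @export
granule_population <- function(d_um, number_density,
                               material = material_index("melanin")) {
  stopifnot(d_um > 0, number_density >= 0, inherits(material, "index_model"))
  structure(list(d_um = d_um, number_density = number_density,
                 material = material),
            class = "granule_population")
}

#' Backscattering-coefficient spectrum of a granule population
#'
#' For each wavelength: relative index
#' \eqn{m(\lambda) = (n_{gran} + i\kappa_{gran})/n_{med}}, size parameter
#' \eqn{x(\lambda)}, and
#' \eqn{\mu_b(\lambda) = N \, Q_b(x, m) \, \pi (d/2)^2} in mm^-1
#' under the independent-scatterer assumption.
#'
#' @param pop a [granule_population()].
#' @param medium an `index_model` for the surrounding medium.
#' @param lambda_nm wavelength grid in nm (strictly increasing, 400-700).
#' @return object of class `mie_spectrum`: list with `lambda_nm`, `mu_b_mm`
#'   (mm^-1) and metadata.
#' @examples
#' pop <- granule_population(0.7, 1e-3)
#' sp <- mu_b_spectrum(pop, material_index("rpe_medium"), seq(440, 700, 1))
#' @export
mu_b_spectrum <- function(pop, medium, lambda_nm = seq(440, 700, by = 1)) {
  stopifnot(inherits(pop, "granule_population"), inherits(medium, "index_model"))
  if (is.unsorted(lambda_nm, strictly = TRUE))
    stop("lambda_nm must be strictly increasing")
  n_med <- medium$n(lambda_nm)
  m <- index_eval(pop$material, lambda_nm) / n_med
  x <- size_parameter(pop$d_um, lambda_nm, n_med)
  qb <- backscattering_efficiency(x, m)
  sigma_um2 <- qb * pi * (pop$d_um / 2)^2          # backscattering cross-section
  mu_b <- pop$number_density * sigma_um2 * 1e3      # um^-1 -> mm^-1
  structure(list(lambda_nm = lambda_nm, mu_b_mm = mu_b,
                 d_um = pop$d_um, medium = medium$name,
                 number_density = pop$number_density),
            class = "mie_spectrum")
}

#' @export
print.mie_spectrum <- function(x, ...) {
  cat(sprintf("<mie_spectrum> d = %g um in %s, N = %g um^-3\n",
              x$d_um, x$medium, x$number_density))
  cat(sprintf("  %d wavelengths %g-%g nm, mu_b range %.3g-%.3g mm^-1\n",
              length(x$lambda_nm), min(x$lambda_nm), max(x$lambda_nm),
              min(x$mu_b_mm), max(x$mu_b_mm)))
  invisible(x)
}

#' @export
plot.mie_spectrum <- function(x, ...) {
  graphics::plot(x$lambda_nm, x$mu_b_mm, type = "l",
                 xlab = "wavelength (nm)",
                 ylab = expression(mu[b] ~ (mm^-1)),
                 main = sprintf("d = %g um in %s", x$d_um, x$medium), ...)
  invisible(x)
}

#' Granule number density from mass concentration
#'
#' Converts a mass concentration (mg/mL) of monodisperse spheres of
#' diameter `d_um` and mass density `rho_g_cm3` to a number density in
#' granules per um^3: \eqn{N = c / (\rho \, (\pi/6) d^3)}.
#'
#' @param c_mg_ml concentration in mg/mL, >= 0.
#' @param d_um granule diameter in um, > 0.
#' @param rho_g_cm3 granule mass density in g/cm^3 (default 1.7, a literature
#'   value for melanosomes), > 0.
#' @return number density in um^-3.
#' @examples concentration_to_number_density(10, 2.4)
#' @export
concentration_to_number_density <- function(c_mg_ml, d_um, rho_g_cm3 = 1.7) {
  if (any(c_mg_ml < 0)) stop("concentration must be non-negative")
  if (d_um <= 0 || rho_g_cm3 <= 0) stop("d and rho must be positive")
  # mg/mL == 1e-3 g/cm^3; volume fraction = c/rho; granule volume (pi/6) d^3 um^3
  vol_frac <- (c_mg_ml * 1e-3) / rho_g_cm3
  vol_frac / ((pi / 6) * d_um^3)
}

#' Export a set of backscattering spectra as CSV
#'
#' One `lambda_nm` column plus one `mu_b` column per diameter.
#'
#' @param spectra list of `mie_spectrum` objects sharing a wavelength grid.
#' @param path output CSV path.
#' @return the data.frame written, invisibly.
#' @export
write_mie_csv <- function(spectra, path) {
  stopifnot(length(spectra) >= 1)
  lam <- spectra[[1]]$lambda_nm
  df <- data.frame(lambda_nm = lam)
  for (sp in spectra) {
    stopifnot(identical(sp$lambda_nm, lam))
    df[[sprintf("mu_b_per_mm_d%g", sp$d_um)]] <- sp$mu_b_mm
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}
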