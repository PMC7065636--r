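#' Wavelength-dependent complex refractive index models
#'
#' Materials relevant to visible-light OCT imaging of ocular melanin:
#' eumelanin granules, the silicone elastomer used in eye phantoms, the
#' (non-melanin) retinal pigment epithelium medium, and N-BK7 glass.
#' An `index_model` couples a real index \eqn{n(\lambda)} and an extinction
#' coefficient \eqn{\kappa(\lambda)} (both dimensionless, \eqn{\lambda} in nm)
#' with a validity range; evaluation outside the range is an error because
#' the underlying empirical fits diverge there.
#'
#' @param name one of `"melanin"`, `"silicone"`, `"rpe_medium"`, `"nbk7"`.
#' @return an object of class `index_model` with fields `name`, `n` and
#'   `kappa` (functions of wavelength in nm) and `valid_range` (nm).
#' @examples
#' m <- material_index("melanin")
#' index_eval(m, c(440, 550, 700))
#' @export
material_index <- function(name) {
  name <- match.arg(name, c("melanin", "silicone", "rpe_medium", "nbk7"))
  switch(name,
    melanin = new_index_model("melanin", melanin_index_real, melanin_index_imag,
                              c(400, 700)),
    silicone = new_index_model("silicone",
                               function(l) Re(silicone_index(l)),
                               function(l) rep(0, length(l)), c(400, 700)),
    rpe_medium = new_index_model("rpe_medium",
                                 function(l) rep(1.368, length(l)),
                                 function(l) rep(0, length(l)), c(400, 700)),
    nbk7 = new_index_model("nbk7", nbk7_index,
                           function(l) rep(0, length(l)), c(300, 2500))
  )
}

new_index_model <- function(name, n, kappa, valid_range) {
  structure(list(name = name, n = n, kappa = kappa, valid_range = valid_range),
            class = "index_model")
}

#' @rdname material_index
#' @param model an `index_model`.
#' @param lambda_nm wavelength(s) in nm, inside `model$valid_range`.
#' @export
index_eval <- function(model, lambda_nm) {
  stopifnot(inherits(model, "index_model"))
  check_lambda(lambda_nm, model$valid_range)
  complex(real = model$n(lambda_nm), imaginary = model$kappa(lambda_nm))
}

#' @export
print.index_model <- function(x, ...) {
  cat(sprintf("<index_model> %s, valid %g-%g nm\n",
              x$name, x$valid_range[1], x$valid_range[2]))
  mid <- mean(x$valid_range)
  cat(sprintf("  n(%g nm) = %.4f, kappa(%g nm) = %.5f\n",
              mid, x$n(mid), mid, x$kappa(mid)))
  invisible(x)
}

check_lambda <- function(lambda_nm, range) {
  if (!is.numeric(lambda_nm) || any(!is.finite(lambda_nm)))
    stop("wavelength must be finite numeric (nm)")
  if (any(lambda_nm < range[1] | lambda_nm > range[2]))
    stop(sprintf("wavelength outside valid range [%g, %g] nm",
                 range[1], range[2]))
  invisible(lambda_nm)
}

#' Real refractive index of eumelanin
#'
#' Empirical dispersion polynomial for the real part of the eumelanin
#' refractive index over the visible range,
#' \eqn{n(\lambda) = 1.6840 - 1.8723\times10^{4}\lambda^{-2}
#' + 1.0964\times10^{10}\lambda^{-4} - 8.6484\times10^{14}\lambda^{-6}}
#' with \eqn{\lambda} in nm (vacuum wavelength).
#'
#' @param lambda_nm wavelength in nm, 400-700.
#' @return dimensionless real index.
#' @examples melanin_index_real(500)
#' @export
melanin_index_real <- function(lambda_nm) {
  check_lambda(lambda_nm, c(400, 700))
  l2 <- lambda_nm^-2
  1.6840 - 1.8723e4 * l2 + 1.0964e10 * l2^2 - 8.6484e14 * l2^3
}

#' Extinction coefficient of eumelanin
#'
#' Quartic fit to the extinction coefficient of rodent RPE eumelanin,
#' \eqn{\kappa(\lambda) = 9.452\times10^{-13}\lambda^4 - 2.452\times10^{-9}\lambda^3
#' + 2.447\times10^{-6}\lambda^2 - 1.133\times10^{-3}\lambda + 0.2124}
#' (\eqn{\lambda} in nm). The fit is clamped at zero should it undershoot
#' inside the valid range; \eqn{\kappa} relates to the absorption coefficient
#' by \eqn{\kappa = \mu_a \lambda / (4\pi)}.
#'
#' @inheritParams melanin_index_real
#' @return dimensionless extinction coefficient (>= 0).
#' @examples melanin_index_imag(500)
#' @export
melanin_index_imag <- function(lambda_nm) {
  check_lambda(lambda_nm, c(400, 700))
  k <- 9.452e-13 * lambda_nm^4 - 2.452e-9 * lambda_nm^3 +
    2.447e-6 * lambda_nm^2 - 1.133e-3 * lambda_nm + 0.2124
  pmax(k, 0)
}

#' Absorption coefficient from extinction coefficient
#'
#' Inverts \eqn{\kappa = \mu_a \lambda/(4\pi)}: \eqn{\mu_a = 4\pi\kappa/\lambda},
#' returned in nm^-1.
#'
#' @param kappa dimensionless extinction coefficient, >= 0.
#' @param lambda_nm wavelength in nm, > 0.
#' @return absorption coefficient in nm^-1.
#' @export
absorption_from_kappa <- function(kappa, lambda_nm) {
  if (any(lambda_nm <= 0)) stop("wavelength must be positive")
  if (any(kappa < 0)) stop("kappa must be non-negative")
  4 * pi * kappa / lambda_nm
}

#' Complex refractive index of silicone elastomer
#'
#' Quadratic fit to the real index of the cured silicone elastomer used in
#' melanin eye phantoms,
#' \eqn{n(\lambda) = 1.527\times10^{-7}\lambda^2 - 2.260\times10^{-4}\lambda + 1.494}
#' (\eqn{\lambda} in nm); the elastomer is transparent in the visible so the
#' imaginary part is zero.
#'
#' @inheritParams melanin_index_real
#' @return complex index with zero imaginary part.
#' @examples silicone_index(550)
#' @export
silicone_index <- function(lambda_nm) {
  check_lambda(lambda_nm, c(400, 700))
  complex(real = 1.527e-7 * lambda_nm^2 - 2.260e-4 * lambda_nm + 1.494,
          imaginary = 0)
}

#' Complex refractive index of the RPE surrounding medium
#'
#' The non-melanin retinal pigment epithelium medium is modelled as a
#' wavelength-independent real index of 1.368; its small intrinsic
#' absorption is dominated by melanin and set to zero.
#'
#' @inheritParams melanin_index_real
#' @return complex index 1.368 + 0i.
#' @export
rpe_medium_index <- function(lambda_nm) {
  check_lambda(lambda_nm, c(400, 700))
  complex(real = rep(1.368, length(lambda_nm)), imaginary = 0)
}

# Sellmeier coefficients for N-BK7 (lambda in um, B/C dimensionless / um^2)
.nbk7_sellmeier <- list(
  B = c(1.03961212, 0.231792344, 1.01046945),
  C = c(0.00600069867, 0.0200179144, 103.560653)
)

#' Refractive index of N-BK7 glass (Sellmeier)
#'
#' Standard three-term Sellmeier evaluation for N-BK7, the material of the
#' ball lenses used as rodent-eye phantom optics.
#'
#' @param lambda_nm wavelength in nm, 300-2500.
#' @return real refractive index.
#' @examples nbk7_index(587.6)  # n_d line, 1.5168
#' @export
nbk7_index <- function(lambda_nm) {
  check_lambda(lambda_nm, c(300, 2500))
  lu2 <- (lambda_nm / 1000)^2
  s <- .nbk7_sellmeier
  n2 <- 1 + s$B[1] * lu2 / (lu2 - s$C[1]) +
    s$B[2] * lu2 / (lu2 - s$C[2]) +
    s$B[3] * lu2 / (lu2 - s$C[3])
  sqrt(n2)
}
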