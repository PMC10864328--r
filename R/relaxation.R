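#' Spectrometer field specification
#'
#' @param proton_mhz proton Larmor frequency in MHz (e.g. 850).
#' @param temperature sample temperature in K (metadata only).
#' @return An object of class `field_spec`.
#' @export
field_spec <- function(proton_mhz, temperature = NA_real_) {
  if (!is.numeric(proton_mhz) || proton_mhz <= 0)
    stop("'proton_mhz' must be positive")
  structure(list(proton_mhz = proton_mhz, temperature = temperature),
            class = "field_spec")
}

#' Nucleus-specific relaxation constants
#'
#' Community-standard defaults for the interaction constants entering the
#' Redfield expressions; none is fitted. For the backbone amide 15N branch:
#' effective N-H bond length `r_XH` = 1.02 Angstrom and CSA
#' `delta_sigma` = -170 ppm. For the 2H branch: quadrupolar coupling
#' `chi_kHz` = 167 kHz (aliphatic C-D). Gyromagnetic ratios are CODATA
#' values in rad s^-1 T^-1; the negative sign of gamma(15N) is kept and
#' propagates into the heteronuclear NOE. Results scale as `r_XH^-6`, so the
#' bond-length choice matters and every value is overridable.
#'
#' @param nucleus `"15N"` or `"2H"`.
#' @param r_XH X-H bond length in Angstrom (15N branch).
#' @param delta_sigma CSA in ppm (15N branch).
#' @param chi_kHz quadrupolar coupling constant e^2 q Q / h in kHz (2H branch).
#' @param gamma_H,gamma_X gyromagnetic ratios in rad s^-1 T^-1.
#' @return An object of class `nucleus_constants`.
#' @export
nucleus_constants <- function(nucleus = c("15N", "2H"),
                              r_XH = 1.02, delta_sigma = -170,
                              chi_kHz = 167,
                              gamma_H = .gamma[["H1"]],
                              gamma_X = NULL) {
  nucleus <- match.arg(nucleus)
  if (is.null(gamma_X))
    gamma_X <- if (nucleus == "15N") .gamma[["N15"]] else .gamma[["H2"]]
  if (gamma_H == 0 || gamma_X == 0) stop("gyromagnetic ratios must be non-zero")
  if (r_XH <= 0) stop("'r_XH' must be positive")
  if (nucleus == "2H" && chi_kHz <= 0) stop("'chi_kHz' must be positive")
  structure(list(nucleus = nucleus, r_XH = r_XH, delta_sigma = delta_sigma,
                 chi_kHz = chi_kHz, gamma_H = gamma_H, gamma_X = gamma_X,
                 j_normalization = 1 / 5),
            class = "nucleus_constants")
}

#' Larmor and combination frequencies
#'
#' Angular frequencies (rad/s, magnitudes) needed by the Redfield
#' expressions, derived from the proton frequency and gyromagnetic-ratio
#' quotients. For 15N: `omega_H`, `omega_X`, `omega_H - omega_X`,
#' `omega_H + omega_X` (using |omega_X|, so the difference and sum bracket
#' `omega_H` symmetrically); the sign of gamma(15N) is carried separately
#' into the NOE term. For 2H: `omega_X` and `2 omega_X`.
#'
#' @param field a [field_spec()].
#' @param nucleus `"15N"` or `"2H"`.
#' @param constants optional [nucleus_constants()] (for overridden gammas).
#' @return Named numeric vector of angular frequencies in rad/s.
#' @export
larmor_frequencies <- function(field, nucleus = c("15N", "2H"),
                               constants = nucleus_constants(nucleus)) {
  stopifnot(inherits(field, "field_spec"))
  nucleus <- match.arg(nucleus)
  wH <- 2 * pi * field$proton_mhz * 1e6
  wX <- wH * abs(constants$gamma_X / constants$gamma_H)
  if (nucleus == "15N") {
    c(omega_H = wH, omega_X = wX, omega_diff = wH - wX, omega_sum = wH + wX)
  } else {
    c(omega_X = wX, omega_2X = 2 * wX)
  }
}

# J at an angular frequency given in rad/s, converted to the Redfield j(omega)
# in seconds: Eq-3-style J (ps, C(0)=1 convention) is 5x the Lipari-Szabo
# spectral density, hence the 1/5 normalization carried in the constants.
.j_s <- function(fit, omega_rad_s, constants) {
  spectral_density(fit, omega_rad_s * 1e-12) * 1e-12 * constants$j_normalization
}

#' 15N spin relaxation from a fitted spectral density
#'
#' Redfield expressions for backbone amide 15N relaxation by the N-H dipolar
#' interaction and the 15N chemical shift anisotropy (cross-correlated
#' dipole-CSA interference neglected). With
#' d = (mu0/4pi) hbar gamma_H gamma_N / r_NH^3 and
#' c = omega_N * delta_sigma / sqrt(3):
#' \deqn{R_1 = (d^2/4)[j(\omega_H-\omega_N) + 3 j(\omega_N) + 6 j(\omega_H+\omega_N)] + c^2 j(\omega_N)}
#' \deqn{R_2 = (d^2/8)[4 j(0) + j(\omega_H-\omega_N) + 3 j(\omega_N) + 6 j(\omega_H) + 6 j(\omega_H+\omega_N)] + (c^2/6)[4 j(0) + 3 j(\omega_N)]}
#' \deqn{hetNOE = 1 + (\gamma_H/\gamma_N)(d^2/4)[6 j(\omega_H+\omega_N) - j(\omega_H-\omega_N)] T_1}
#' where j(omega) is the spectral density of the C(0) = 1 correlation
#' function divided by 5.
#'
#' @param fit an `expfit` from an N-H correlation function.
#' @param field a [field_spec()].
#' @param constants a [nucleus_constants()] for `"15N"`.
#' @return An object of class `relaxation_result` with `T1`, `T2` (s),
#'   `hetNOE` (dimensionless).
#' @export
relaxation_15N <- function(fit, field, constants = nucleus_constants("15N")) {
  stopifnot(inherits(fit, "expfit"), inherits(field, "field_spec"),
            inherits(constants, "nucleus_constants"))
  if (constants$nucleus != "15N") stop("constants are not for 15N")
  if (all(fit$weights == 0)) stop("fit has all-zero weights")
  w <- larmor_frequencies(field, "15N", constants)
  jw <- function(o) .j_s(fit, o, constants)
  r_m <- constants$r_XH * 1e-10
  d <- .mu0_4pi * .hbar * constants$gamma_H * abs(constants$gamma_X) / r_m^3
  cc <- w[["omega_X"]] * constants$delta_sigma * 1e-6 / sqrt(3)

  j0 <- jw(0); jN <- jw(w[["omega_X"]]); jH <- jw(w[["omega_H"]])
  jD <- jw(w[["omega_diff"]]); jS <- jw(w[["omega_sum"]])

  R1 <- (d^2 / 4) * (jD + 3 * jN + 6 * jS) + cc^2 * jN
  R2 <- (d^2 / 8) * (4 * j0 + jD + 3 * jN + 6 * jH + 6 * jS) +
        (cc^2 / 6) * (4 * j0 + 3 * jN)
  T1 <- 1 / R1
  noe <- 1 + (constants$gamma_H / constants$gamma_X) * (d^2 / 4) *
    (6 * jS - jD) * T1

  structure(list(site_label = fit$site_label, T1 = T1, T2 = 1 / R2,
                 hetNOE = noe, field = field, nucleus = "15N"),
            class = "relaxation_result")
}

#' 2H spin relaxation from a fitted spectral density
#'
#' Quadrupolar relaxation of a deuterium attached to carbon, axially
#' symmetric field gradient (asymmetry 0). With chi = e^2 q Q / h:
#' \deqn{R_1 = (3\pi^2/10)\chi^2[j(\omega_D) + 4 j(2\omega_D)]}
#' \deqn{R_2 = (3\pi^2/20)\chi^2[3 j(0) + 5 j(\omega_D) + 2 j(2\omega_D)]}
#'
#' @inheritParams relaxation_15N
#' @param constants a [nucleus_constants()] for `"2H"`.
#' @return A `relaxation_result`; `hetNOE` is `NA`.
#' @export
relaxation_2H <- function(fit, field, constants = nucleus_constants("2H")) {
  stopifnot(inherits(fit, "expfit"), inherits(field, "field_spec"),
            inherits(constants, "nucleus_constants"))
  if (constants$nucleus != "2H") stop("constants are not for 2H")
  if (all(fit$weights == 0)) stop("fit has all-zero weights")
  w <- larmor_frequencies(field, "2H", constants)
  jw <- function(o) .j_s(fit, o, constants)
  chi <- constants$chi_kHz * 1e3
  j0 <- jw(0); jD <- jw(w[["omega_X"]]); j2D <- jw(w[["omega_2X"]])
  R1 <- (3 * pi^2 / 10) * chi^2 * (jD + 4 * j2D)
  R2 <- (3 * pi^2 / 20) * chi^2 * (3 * j0 + 5 * jD + 2 * j2D)
  structure(list(site_label = fit$site_label, T1 = 1 / R1, T2 = 1 / R2,
                 hetNOE = NA_real_, field = field, nucleus = "2H"),
            class = "relaxation_result")
}

#' @export
print.relaxation_result <- function(x, ...) {
  cat(sprintf("<relaxation_result> '%s' (%s at %g MHz 1H)\n",
              x$site_label, x$nucleus, x$field$proton_mhz))
  cat(sprintf("  T1 = %.6g s   T2 = %.6g s", x$T1, x$T2))
  if (!is.na(x$hetNOE)) cat(sprintf("   hetNOE = %.4f", x$hetNOE))
  cat("\n")
  invisible(x)
}

#' @export
as.data.frame.relaxation_result <- function(x, ...) {
  data.frame(site = x$site_label, nucleus = x$nucleus,
             field_mhz = x$field$proton_mhz,
             T1_s = x$T1, T2_s = x$T2, hetNOE = x$hetNOE,
             stringsAsFactors = FALSE)
}
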