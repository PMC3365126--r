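# Viscoelastic relaxation/creep kernels and the prestin electrical kernel.
#
# The mechanical element is a springpot in parallel with the elastic modulus:
# each *direct* modulus relaxes as  E(t) = C + eta * t^-nu / Gamma(1-nu),
# whose Laplace transform is C/s + eta * s^(nu-1) and whose Fourier-domain
# complex modulus is C + eta * (i omega)^nu (principal branch, phase nu*pi/2).
# The cross modulus C12 is purely elastic, which makes the isotropic
# spherical membrane the exact C11 = C22 = K, C12 = 0 specialization of the
# cylinder (see the methods vignette for why the springpot sits on the
# diagonal).

.springpot_relax <- function(eta, nu, t) eta * t^(-nu) / gamma(1 - nu)

.check_time <- function(t) {
  if (!is.numeric(t) || any(!is.finite(t)) || any(t <= 0))
    stop("t must be > 0 (the power-law kernel is singular at t = 0)",
         call. = FALSE)
  t
}

#' Relaxation kernel
#'
#' Time-domain relaxation kernel of the membrane: the resultant response to a
#' unit strain step. For the orthotropic OHC wall the kernel is the 2x2
#' matrix `E_ij(t) = C_ij + delta_ij * eta * t^-nu / Gamma(1-nu)`; for the
#' isotropic sphere it is the scalar `E(t) = K + eta * t^-nu / Gamma(1-nu)`.
#' As `t -> Inf` the kernel decays to the elastic moduli; with `eta = 0` it
#' equals them for all t.
#'
#' @param params A `membrane_params` object.
#' @param t Times, s; strictly positive.
#' @return For OHC parameters, a `2 x 2 x length(t)` array (N/m); for sphere
#'   parameters, a numeric vector of length `length(t)`.
#' @export
relaxation_kernel <- function(params, t) UseMethod("relaxation_kernel")

#' @rdname relaxation_kernel
#' @export
relaxation_kernel.ohc_params <- function(params, t) {
  .check_time(t)
  v <- .springpot_relax(params$eta, params$nu, t)
  out <- array(0, dim = c(2, 2, length(t)),
               dimnames = list(c("1", "2"), c("1", "2"), NULL))
  out[1, 1, ] <- params$C11 + v
  out[2, 2, ] <- params$C22 + v
  out[1, 2, ] <- out[2, 1, ] <- params$C12
  out
}

#' @rdname relaxation_kernel
#' @export
relaxation_kernel.sphere_params <- function(params, t) {
  .check_time(t)
  params$K + .springpot_relax(params$eta, params$nu, t)
}

#' Laplace transform of the relaxation kernel matrix
#'
#' `Ebar_ij(s) = C_ij / s + delta_ij * eta * s^(nu - 1)` (principal branch
#' of `s^nu`). Used by [creep_kernel_laplace()] and directly testable via
#' the reciprocity identity `s^2 * Jbar(s) %*% Ebar(s) = I`.
#'
#' @param params An `ohc_params` object.
#' @param s A single complex (or real) Laplace variable; typically
#'   `Re(s) > 0`. Any `s` off the branch cut (the closed negative real
#'   axis, where `s^nu` is not single-valued) is accepted so that deformed
#'   inversion contours can be evaluated.
#' @return A 2x2 complex matrix.
#' @export
relaxation_laplace <- function(params, s) {
  stopifnot(inherits(params, "ohc_params"), length(s) == 1L)
  s <- as.complex(s)
  if (s == 0 || (Im(s) == 0 && Re(s) < 0))
    stop("s must lie off the branch cut (negative real axis) and be nonzero",
         call. = FALSE)
  Cm <- matrix(c(params$C11, params$C12, params$C12, params$C22), 2, 2)
  Cm / s + diag(2) * params$eta * s^(params$nu - 1)
}

#' Creep kernel in the Laplace domain
#'
#' The creep (compliance) kernel matrix is defined through the viscoelastic
#' reciprocity `Jbar(s) = Ebar(s)^-1 / s^2`, where `Ebar` is the Laplace
#' transform of the relaxation matrix. In the elastic limit (`eta = 0`) this
#' reduces to `solve(C) / s`, the constant elastic compliance.
#'
#' @inheritParams relaxation_laplace
#' @return A 2x2 complex matrix (Laplace transform of compliance, m/N per s).
#' @export
creep_kernel_laplace <- function(params, s) {
  Eb <- relaxation_laplace(params, s)
  Jb <- tryCatch(solve(Eb), error = function(e)
    stop("relaxation transform matrix is numerically singular at s = ",
         format(s), ": ", conditionMessage(e), call. = FALSE))
  Jb / as.complex(s)^2
}

#' Creep kernel in the time domain
#'
#' Numerical Laplace inversion of [creep_kernel_laplace()], entry by entry.
#' The primary algorithm is the fixed-Talbot contour; `method = "stehfest"`
#' provides an independent Gaver-Stehfest cross-check (the two agree to
#' better than 1e-6 relative on smooth kernels; see the test suite).
#'
#' @param params An `ohc_params` object.
#' @param t Times, s; strictly positive.
#' @param method Inversion algorithm.
#' @return A `2 x 2 x length(t)` array of compliances (m/N).
#' @export
creep_kernel_time <- function(params, t, method = c("talbot", "stehfest")) {
  .check_time(t)
  method <- match.arg(method)
  out <- array(NA_real_, dim = c(2, 2, length(t)))
  for (i in 1:2) for (j in i:2) {
    Fs <- function(s) creep_kernel_laplace(params, s)[i, j]
    out[i, j, ] <- out[j, i, ] <- invert_laplace(Fs, t, method = method)
  }
  out
}

#' Complex modulus in the frequency domain
#'
#' Fourier-domain modulus relating harmonic resultants to harmonic passive
#' strains. Power-law model: direct entries `C_ii + eta * (i omega)^nu`
#' (principal branch, so storage and loss parts are the power functions
#' `eta * omega^nu * cos(nu pi / 2)` and `eta * omega^nu * sin(nu pi / 2)`);
#' cross entry `C12` is purely elastic. The Kelvin-Voigt comparison mode
#' substitutes `nu = 1`, giving `C + i omega eta`.
#'
#' @param params A `membrane_params` object.
#' @param omega Angular frequencies, rad/s, `>= 0`.
#' @param model `"power_law"` (default) or `"kelvin_voigt"`.
#' @param eta Viscous coefficient; defaults to `params$eta`. Exposed so the
#'   Kelvin-Voigt mode can sweep viscosities with all else fixed.
#' @return For OHC parameters a `2 x 2 x length(omega)` complex array; for
#'   sphere parameters a complex vector.
#' @export
complex_modulus <- function(params, omega, model = c("power_law",
                            "kelvin_voigt"), eta = params$eta) {
  UseMethod("complex_modulus")
}

.springpot_omega <- function(eta, nu, omega, model) {
  if (any(omega < 0)) stop("omega must be >= 0", call. = FALSE)
  if (model == "kelvin_voigt") eta * 1i * omega
  else eta * (1i * omega)^nu
}

#' @rdname complex_modulus
#' @export
complex_modulus.ohc_params <- function(params, omega,
                                       model = c("power_law", "kelvin_voigt"),
                                       eta = params$eta) {
  model <- match.arg(model)
  v <- .springpot_omega(eta, params$nu, omega, model)
  out <- array(0i, dim = c(2, 2, length(omega)))
  out[1, 1, ] <- params$C11 + v
  out[2, 2, ] <- params$C22 + v
  out[1, 2, ] <- out[2, 1, ] <- params$C12
  out
}

#' @rdname complex_modulus
#' @export
complex_modulus.sphere_params <- function(params, omega,
                                          model = c("power_law",
                                                    "kelvin_voigt"),
                                          eta = params$eta) {
  model <- match.arg(model)
  params$K + .springpot_omega(eta, params$nu, omega, model)
}

#' Prestin electrical kernel
#'
#' Rate-form (impulse-response) kernel of the series-RC description of
#' prestin charge transfer: `k(t) = (C_sp / tau_e) * exp(-t / tau_e)`, in
#' F/(m^2 s). Its convolution with a voltage step of height V yields the
#' charge `C_sp * V * (1 - exp(-t / tau_e))`, which [electrical_step_response()]
#' returns in closed form.
#'
#' @param tau_e Prestin RC time, s.
#' @param C_sp Specific capacitance, F/m^2.
#' @param t Times, s, strictly positive.
#' @return Kernel values, F/(m^2 s).
#' @export
electrical_kernel <- function(tau_e, C_sp, t) {
  stopifnot(tau_e > 0, C_sp > 0)
  .check_time(t)
  (C_sp / tau_e) * exp(-t / tau_e)
}

#' Step response of the prestin electrical kernel
#'
#' Charge per unit area after a unit voltage step: the hereditary-integral
#' (creep-form) counterpart of [electrical_kernel()].
#'
#' @inheritParams electrical_kernel
#' @return `C_sp * (1 - exp(-t / tau_e))`, F/m^2 (charge per volt).
#' @export
electrical_step_response <- function(tau_e, C_sp, t) {
  stopifnot(tau_e > 0, C_sp > 0, all(t >= 0))
  C_sp * (1 - exp(-t / tau_e))
}
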