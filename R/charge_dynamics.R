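# Time-domain electric charge generated by mechanical loading under voltage
# clamp.
#
# With the membrane potential clamped, the charge per unit area is the
# hereditary integral of the resultant history against the electromechanical
# kernels a_i * (1 - exp(-(t - tau)/tau_e)), a_i = alpha_i * C_sp. For an
# internally pressurized thin shell the resultants are N1 = dP r_c / 2,
# N2 = dP r_c (cylinder) and N = dP r_c / 2 (sphere), so:
#
#   step pressure : q(t) = g * dP0 * r_c * (1 - exp(-t/tau_e))
#   ramp pressure : q(t) = g * P_r * r_c * (t - tau_e (1 - exp(-t/tau_e)))
#
# with coupling g = a1/2 + a2 (cylinder) or a/2 (sphere). For a constant
# axial strain rate on the volume-preserving cylinder the resultant rates
# follow from the relaxation kernels, giving an elastic (linear-in-t) part
# plus a springpot transient that involves the confluent integral
# G(x) = exp(-x) * int_0^x exp(s) s^-nu ds, x = t/tau_e.

#' Charge time course container
#'
#' Validating constructor for a charge-per-unit-area time course: `t`
#' strictly increasing and positive, `q` finite. Returned by all `charge_*`
#' functions.
#'
#' @param t Times, s.
#' @param q Charge per unit area, C/m^2 (signed; figures in the source
#'   literature usually plot the magnitude).
#' @return A data.frame of class `"charge_timecourse"`.
#' @export
charge_timecourse <- function(t, q) {
  stopifnot(is.numeric(t), is.numeric(q), length(t) == length(q),
            length(t) >= 1L, all(t > 0), all(diff(t) > 0), all(is.finite(q)))
  structure(data.frame(t = t, q = q),
            class = c("charge_timecourse", "data.frame"))
}

#' Mechanical loading history
#'
#' Describes one of the three implemented stimuli: a pressure step of
#' magnitude `dP0` (Pa), a constant-rate pressure ramp `P_r` (Pa/s), or a
#' constant axial strain rate `eps1_rate` (1/s; the circumferential rate is
#' derived internally by volume conservation). Exactly one stimulus field
#' may be supplied, matching `kind`.
#'
#' @param kind One of `"step_pressure"`, `"ramp_pressure"`, `"ramp_strain"`.
#' @param dP0 Step pressure, Pa.
#' @param P_r Pressure rate, Pa/s.
#' @param eps1_rate Axial strain rate, 1/s.
#' @return A list of class `"loading_history"`.
#' @export
loading_history <- function(kind = c("step_pressure", "ramp_pressure",
                                     "ramp_strain"),
                            dP0 = NULL, P_r = NULL, eps1_rate = NULL) {
  kind <- match.arg(kind)
  given <- !vapply(list(dP0, P_r, eps1_rate), is.null, logical(1))
  names(given) <- c("dP0", "P_r", "eps1_rate")
  need <- switch(kind, step_pressure = "dP0", ramp_pressure = "P_r",
                 ramp_strain = "eps1_rate")
  if (!identical(names(given)[given], need))
    stop("loading '", kind, "' requires exactly the field '", need, "'",
         call. = FALSE)
  structure(list(kind = kind, dP0 = dP0, P_r = P_r, eps1_rate = eps1_rate),
            class = "loading_history")
}

# pressure-to-charge coupling g (1/V) and resultant factors c_i (N_i = c_i*dP*r_c)
.pressure_coupling <- function(params) {
  if (inherits(params, "ohc_params"))
    params$alpha1_Csp / 2 + params$alpha2_Csp
  else params$alpha_Csp / 2
}

.resultant_factors <- function(params) {
  if (inherits(params, "ohc_params")) c(0.5, 1) else 0.5
}

.coupling_vec <- function(params) {
  if (inherits(params, "ohc_params"))
    c(params$alpha1_Csp, params$alpha2_Csp) else params$alpha_Csp
}

#' Charge generated by step-wise pressure application
#'
#' Closed-form charge per unit area after a pressure step `dP0` applied at
#' t = 0 under voltage clamp. The charge builds exponentially toward its
#' steady value with characteristic time `tau_e` and is linear in `dP0`;
#' with the default couplings it is negative for positive internal pressure,
#' and its steady magnitude is larger for the spherical transfected cell
#' than for a cylindrical outer hair cell of equal radius.
#'
#' @param params A `membrane_params` object (cylinder or sphere).
#' @param dP0 Pressure step, Pa.
#' @param t_grid Times, s, positive and strictly increasing.
#' @return A [charge_timecourse()].
#' @export
charge_step_pressure <- function(params, dP0, t_grid) {
  stopifnot(inherits(params, "membrane_params"), is.numeric(dP0))
  .check_time(t_grid)
  g <- .pressure_coupling(params)
  charge_timecourse(t_grid,
                    g * dP0 * params$r_c * (1 - exp(-t_grid / params$tau_e)))
}

#' Charge generated by constant-rate pressure application
#'
#' Closed-form charge per unit area for pressure growing as `P_r * t` under
#' voltage clamp: an exponential transient followed by a constant-rate
#' regime whose slope is `P_r` times the per-unit-pressure steady charge of
#' the step response. At fixed stimulus and time, a larger `tau_e` gives a
#' smaller charge magnitude.
#'
#' @param params A `membrane_params` object.
#' @param P_r Pressure rate, Pa/s.
#' @inheritParams charge_step_pressure
#' @return A [charge_timecourse()].
#' @export
charge_ramp_pressure <- function(params, P_r, t_grid) {
  stopifnot(inherits(params, "membrane_params"), is.numeric(P_r))
  .check_time(t_grid)
  g <- .pressure_coupling(params)
  tau <- params$tau_e
  charge_timecourse(t_grid,
                    g * P_r * params$r_c *
                      (t_grid - tau * (1 - exp(-t_grid / tau))))
}

#' Circumferential strain rate of a volume-preserving cylinder
#'
#' First-order volume conservation of the cylindrical cell's liquid core
#' (`eps1 + 2 eps2 = 0`) gives `eps2_rate = -eps1_rate / 2`. Kept as its own
#' function so an alternative kinematic relation can be swapped in.
#'
#' @param eps1_rate Axial strain rate, 1/s.
#' @return Circumferential strain rate, 1/s.
#' @export
circumferential_rate <- function(eps1_rate) -eps1_rate / 2

#' Resultant rates under a constant axial strain rate
#'
#' For the cylinder driven at constant axial rate `eps1_rate` (with the
#' circumferential rate from [circumferential_rate()]), the resultant rates
#' follow from the relaxation kernels: `Ndot_i(t) = E_ij(t) epsdot_j`, i.e.
#' an elastic constant plus a decaying springpot term. In the elastic limit
#' (`eta = 0`) the rates are constant in time.
#'
#' @param params An `ohc_params` object.
#' @param eps1_rate Axial strain rate, 1/s.
#' @param t Times, s, strictly positive.
#' @return A matrix with columns `N1dot`, `N2dot` (N/(m s)), rows along `t`.
#' @export
resultant_rates_from_strain <- function(params, eps1_rate, t) {
  stopifnot(inherits(params, "ohc_params"), is.numeric(eps1_rate))
  .check_time(t)
  er <- c(eps1_rate, circumferential_rate(eps1_rate))
  E <- relaxation_kernel(params, t)
  cbind(N1dot = E[1, 1, ] * er[1] + E[1, 2, ] * er[2],
        N2dot = E[2, 1, ] * er[1] + E[2, 2, ] * er[2])
}

# confluent integral G(x) = exp(-x) * int_0^x exp(s) s^-nu ds, 0 < nu < 1.
# All-positive power series for x <= 30, asymptotic series in 1/x beyond.
.gexp_G <- function(nu, x) {
  stopifnot(nu > 0, nu < 1)
  one <- function(x1) {
    if (x1 == 0) return(0)
    if (x1 <= 30) {
      k <- 0; term <- x1^(1 - nu) / (1 - nu); acc <- term
      repeat {
        k <- k + 1
        term <- x1^(k + 1 - nu) / (factorial(k) * (k + 1 - nu))
        acc <- acc + term
        if ((term < acc * 1e-17 && k > x1) || k > 400) break
      }
      exp(-x1) * acc
    } else {
      term <- x1^(-nu); acc <- term; k <- 0
      repeat {
        k <- k + 1
        nt <- term * (nu + k - 1) / x1
        if (nt >= term || k > 60) break   # asymptotic: stop at smallest term
        term <- nt; acc <- acc + term
        if (term < acc * 1e-16) break
      }
      acc
    }
  }
  vapply(x, one, numeric(1))
}

# transient springpot integral T(t) = int_0^t (1 - exp(-(t-u)/tau)) u^-nu du
.ramp_strain_T <- function(nu, tau, t, method = c("series", "quadrature")) {
  method <- match.arg(method)
  if (method == "series")
    return(t^(1 - nu) / (1 - nu) - tau^(1 - nu) * .gexp_G(nu, t / tau))
  vapply(t, function(t1) {
    # substitute u = w^(1/(1-nu)) to remove the endpoint singularity
    f <- function(w) (1 - exp(-(t1 - w^(1 / (1 - nu))) / tau)) / (1 - nu)
    stats::integrate(f, 0, t1^(1 - nu), rel.tol = 1e-12,
                     abs.tol = 1e-15)$value
  }, numeric(1))
}

#' Charge generated by constant-rate axial strain
#'
#' Charge per unit area for the cylindrical cell compressed axially at
#' constant rate under voltage clamp, with the circumferential rate set by
#' volume conservation. The response has a transient (nonlinear) regime
#' governed by `tau_e` and modulated by the membrane viscoelasticity, and a
#' long-time constant-rate regime; for axial compression (`eps1_rate < 0`)
#' the charge is positive, opposite in sign to the pressure-driven cases.
#' The springpot transient is evaluated by a stable series for the confluent
#' integral (`method = "series"`, default) or by adaptive quadrature
#' (`method = "quadrature"`), the two serving as mutual checks; both are
#' validated against a brute-force convolution oracle in the tests.
#'
#' @param params An `ohc_params` object.
#' @param eps1_rate Axial strain rate, 1/s (negative = compression).
#' @inheritParams charge_step_pressure
#' @param method Evaluation route for the springpot transient term.
#' @return A [charge_timecourse()].
#' @export
charge_ramp_strain <- function(params, eps1_rate, t_grid,
                               method = c("series", "quadrature")) {
  stopifnot(inherits(params, "ohc_params"), is.numeric(eps1_rate))
  .check_time(t_grid)
  method <- match.arg(method)
  tau <- params$tau_e
  a <- .coupling_vec(params)
  er <- c(eps1_rate, circumferential_rate(eps1_rate))
  b <- c(params$C11 * er[1] + params$C12 * er[2],     # elastic rate parts
         params$C12 * er[1] + params$C22 * er[2])
  d <- params$eta * er / gamma(1 - params$nu)         # springpot t^-nu parts
  Rt <- t_grid - tau * (1 - exp(-t_grid / tau))
  Tt <- .ramp_strain_T(params$nu, tau, t_grid, method)
  charge_timecourse(t_grid, sum(a * b) * Rt + sum(a * d) * Tt)
}

#' Generalized exponential integral of real order
#'
#' `E_nu(x) = integral_1^Inf exp(-x u) u^-nu du` for real order `nu` and
#' `x > 0`. For `nu < 1` the incomplete-gamma representation
#' `E_nu(x) = x^(nu-1) Gamma(1-nu, x)` is used (via `pgamma`); other orders
#' are reached through the forward recurrence
#' `nu E_(nu+1)(x) = exp(-x) - x E_nu(x)`, with adaptive quadrature as a
#' fallback for integer base orders. Relative accuracy ~1e-10 or better.
#'
#' @param nu Real order (scalar).
#' @param x Evaluation points, strictly positive.
#' @return `E_nu(x)`, same length as `x`.
#' @export
generalized_expint <- function(nu, x) {
  stopifnot(is.numeric(nu), length(nu) == 1L, is.finite(nu))
  if (any(x <= 0)) stop("x must be > 0", call. = FALSE)
  if (nu < 1) return(.expint_base(nu, x))
  # climb by the forward recurrence m * E_{m+1}(x) = exp(-x) - x * E_m(x),
  # starting from a base order in [0+, 1] (the m = 0 step is degenerate, so
  # integer orders start from E_1 itself)
  frac <- nu - floor(nu)
  if (frac < 1e-12) { base <- 1 } else base <- frac
  steps <- round(nu - base)
  val <- .expint_base(base, x)
  m <- base
  for (k in seq_len(steps)) {
    val <- (exp(-x) - x * val) / m
    m <- m + 1
  }
  val
}

.expint_base <- function(nu, x) {
  a <- 1 - nu
  if (a > 1e-8) {
    # E_nu(x) = x^(nu-1) * Gamma(a) * Q(a, x), Q upper regularized gamma
    x^(nu - 1) * gamma(a) * stats::pgamma(x, a, lower.tail = FALSE)
  } else {
    # integer order nu = 1 (a = 0): quadrature on the decaying integrand
    vapply(x, function(x1)
      stats::integrate(function(u) exp(-x1 * u) / u, 1, Inf,
                       rel.tol = 1e-12)$value, numeric(1))
  }
}

#' Brute-force convolution oracle for the charge responses
#'
#' Computes the charge per unit area by direct numerical convolution of the
#' differentiated electromechanical kernel with the analytic resultant
#' history of the given loading:
#' `q(t) = sum_i a_i/tau_e * integral_0^t exp(-(t-s)/tau_e) N_i(s) ds`.
#' This route shares no code with the closed forms in
#' [charge_step_pressure()], [charge_ramp_pressure()] and
#' [charge_ramp_strain()] and exists to validate them (the test suite
#' asserts agreement to much better than 1e-3 relative).
#'
#' @param params A `membrane_params` object (`ramp_strain` requires the
#'   cylinder).
#' @param loading A [loading_history()].
#' @param t_grid Times, s, positive and strictly increasing.
#' @return A [charge_timecourse()].
#' @export
charge_convolve <- function(params, loading, t_grid) {
  stopifnot(inherits(params, "membrane_params"),
            inherits(loading, "loading_history"))
  .check_time(t_grid)
  a <- .coupling_vec(params)
  tau <- params$tau_e
  cfac <- .resultant_factors(params)
  N_of_t <- switch(loading$kind,
    step_pressure = lapply(seq_along(a), function(i) {
      force(i); function(s) cfac[i] * loading$dP0 * params$r_c + 0 * s
    }),
    ramp_pressure = lapply(seq_along(a), function(i) {
      force(i); function(s) cfac[i] * loading$P_r * params$r_c * s
    }),
    ramp_strain = {
      if (!inherits(params, "ohc_params"))
        stop("ramp_strain loading is implemented for the cylinder only",
             call. = FALSE)
      er <- c(loading$eps1_rate, circumferential_rate(loading$eps1_rate))
      b <- c(params$C11 * er[1] + params$C12 * er[2],
             params$C12 * er[1] + params$C22 * er[2])
      cpl <- params$eta / ((1 - params$nu) * gamma(1 - params$nu))
      lapply(1:2, function(i) {
        force(i)
        function(s) b[i] * s + cpl * er[i] * s^(1 - params$nu)
      })
    })
  q <- vapply(t_grid, function(t1) {
    sum(vapply(seq_along(a), function(i) {
      a[i] / tau * stats::integrate(
        function(s) exp(-(t1 - s) / tau) * N_of_t[[i]](s),
        0, t1, rel.tol = 1e-10, abs.tol = 1e-18)$value
    }, numeric(1)))
  }, numeric(1))
  charge_timecourse(t_grid, q)
}
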