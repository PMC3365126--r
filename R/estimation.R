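# Least-squares estimation of the viscoelastic parameters (eta, nu) from
# normalized force-amplitude sweeps, and of the prestin time tau_e from
# filter-amplitude surfaces; synthetic-data generators for both.
#
# Residuals are formed in log-log space (log amplitude vs log frequency),
# matching how broadband force data are presented and fitted. The (eta, nu)
# optimizer is Nelder-Mead on transformed coordinates (log eta, logit nu)
# with a multi-start grid to avoid local minima.

#' Frequency sweep container
#'
#' Validating constructor for a normalized force-frequency sweep: `omega`
#' strictly increasing and positive, `amplitude` positive.
#'
#' @param omega Angular frequencies, rad/s.
#' @param amplitude Normalized force amplitude (dimensionless, > 0).
#' @param phase Force phase, rad (optional; NA if absent).
#' @return A data.frame of class `"frequency_sweep"`.
#' @export
frequency_sweep <- function(omega, amplitude, phase = NULL) {
  stopifnot(is.numeric(omega), all(omega > 0), all(diff(omega) > 0),
            is.numeric(amplitude), length(amplitude) == length(omega),
            all(amplitude > 0))
  if (is.null(phase)) phase <- rep(NA_real_, length(omega))
  stopifnot(length(phase) == length(omega))
  structure(data.frame(omega = omega, amplitude = amplitude, phase = phase),
            class = c("frequency_sweep", "data.frame"))
}

#' Synthetic normalized force-amplitude sweep
#'
#' Generates log-spaced frequencies on [fmin, fmax] and evaluates the
#' isometric-force forward model at `params`, then applies multiplicative
#' lognormal noise to the amplitude (coefficient of variation `noise_cv`)
#' and additive Gaussian noise to the phase. This emulates microchamber-type
#' broadband force data, which are not publicly tabulated; see the methods
#' vignette for what the generator does and does not reproduce.
#'
#' @param params An `ohc_params` object.
#' @param fmin,fmax Frequency range, Hz.
#' @param n Number of frequencies (>= 4).
#' @param noise_cv Coefficient of variation of the multiplicative amplitude
#'   noise (0 = exact forward model).
#' @param seed Integer seed; recorded in the result's `"seed"` attribute.
#' @param phase_sd Standard deviation of additive phase noise, rad.
#' @return A [frequency_sweep()] with attribute `seed`.
#' @export
synth_force_sweep <- function(params, fmin = 10, fmax = 1e5, n = 60,
                              noise_cv = 0, seed = NULL, phase_sd = 0) {
  stopifnot(inherits(params, "ohc_params"), fmin > 0, fmax > fmin, n >= 4,
            noise_cv >= 0, phase_sd >= 0)
  if (!is.null(seed)) set.seed(seed)
  omega <- 2 * pi * exp(seq(log(fmin), log(fmax), length.out = n))
  fr <- isometric_force(params, omega)
  amp <- fr$amplitude_norm
  ph <- fr$phase
  if (noise_cv > 0) {
    sdlog <- sqrt(log(1 + noise_cv^2))
    amp <- amp * exp(stats::rnorm(n, -sdlog^2 / 2, sdlog))  # mean-one noise
  }
  if (phase_sd > 0) ph <- ph + stats::rnorm(n, 0, phase_sd)
  sw <- frequency_sweep(omega, amp, ph)
  attr(sw, "seed") <- seed
  sw
}

.fit_result <- function(eta_hat = NA_real_, nu_hat = NA_real_,
                        tau_e_hat = NA_real_, residual_norm = NA_real_,
                        n_iter = NA_integer_, converged = FALSE,
                        trace = numeric(0), seed = NULL, message = "") {
  structure(list(eta_hat = eta_hat, nu_hat = nu_hat, tau_e_hat = tau_e_hat,
                 residual_norm = residual_norm, n_iter = n_iter,
                 converged = converged, trace = trace, seed = seed,
                 message = message),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("<fit_result>\n")
  for (f in c("eta_hat", "nu_hat", "tau_e_hat"))
    if (is.finite(x[[f]])) cat(sprintf("  %-13s %g\n", f, x[[f]]))
  cat(sprintf("  residual_norm %g\n  n_iter        %d\n  converged     %s\n",
              x$residual_norm, x$n_iter, x$converged))
  if (nzchar(x$message)) cat("  message      ", x$message, "\n")
  invisible(x)
}

#' Fit the power-law viscoelastic parameters to a force sweep
#'
#' Least-squares estimation of `(eta, nu)` by minimizing the sum of squared
#' log-amplitude residuals between the sweep and the normalized
#' isometric-force model, all other parameters held at `params`. Nelder-Mead
#' in `(log eta, logit nu)` coordinates, restarted from a grid of initial
#' values (`multi_start = TRUE`, default) or from `init` alone. The
#' normalized model makes the fit invariant to amplitude rescaling of the
#' data once renormalized. Non-convergence is reported in the returned
#' object (`converged = FALSE`), never as an error.
#'
#' @param sweep A [frequency_sweep()] (or data.frame with `omega`,
#'   `amplitude`).
#' @param params An `ohc_params` object supplying the fixed parameters.
#' @param init Optional `c(eta0, nu0)` initial values.
#' @param bounds List with elements `eta` (length-2, > 0) and `nu`
#'   (length-2 within (0, 1]); estimates at the bounds flag non-convergence.
#' @param multi_start Restart from a 4 x 4 grid over (eta, nu).
#' @return A `fit_result` with `eta_hat`, `nu_hat`, `residual_norm` (sum of
#'   squared log residuals), `n_iter`, `converged`, and the monotone trace
#'   of accepted (improving) objective values.
#' @export
fit_power_law <- function(sweep, params, init = NULL,
                          bounds = list(eta = c(1e-9, 1e-2),
                                        nu = c(0.02, 0.999)),
                          multi_start = TRUE) {
  stopifnot(all(c("omega", "amplitude") %in% names(sweep)),
            all(sweep$amplitude > 0))
  omega <- sweep$omega
  logA <- log(sweep$amplitude)
  trace_env <- new.env(); trace_env$best <- Inf; trace_env$trace <- numeric(0)
  nev <- 0L
  obj <- function(p) {
    nev <<- nev + 1L
    eta <- exp(p[1]); nu <- stats::plogis(p[2])
    pm <- params; pm$eta <- eta; pm$nu <- nu
    r <- sum((logA - log(isometric_force(pm, omega)$amplitude_norm))^2)
    if (is.finite(r) && r < trace_env$best) {
      trace_env$best <- r
      trace_env$trace <- c(trace_env$trace, r)
    }
    if (!is.finite(r)) 1e10 else r
  }
  starts <- if (multi_start) {
    expand.grid(le = log(c(1e-7, 1e-6, 1e-5, 1e-4)),
                lv = stats::qlogis(c(0.3, 0.5, 0.7, 0.9)))
  } else data.frame(le = numeric(0), lv = numeric(0))
  if (!is.null(init))
    starts <- rbind(starts, data.frame(le = log(init[1]),
                                       lv = stats::qlogis(init[2])))
  if (nrow(starts) == 0L)
    starts <- data.frame(le = log(1e-5), lv = stats::qlogis(0.7))
  best <- NULL
  for (k in seq_len(nrow(starts))) {
    o <- stats::optim(c(starts$le[k], starts$lv[k]), obj,
                      method = "Nelder-Mead",
                      control = list(maxit = 1000, reltol = 1e-13))
    if (is.null(best) || o$value < best$value) best <- o
  }
  eta_hat <- exp(best$par[1]); nu_hat <- stats::plogis(best$par[2])
  at_bound <- eta_hat <= bounds$eta[1] * 1.01 ||
    eta_hat >= bounds$eta[2] * 0.99 ||
    nu_hat <= bounds$nu[1] + 1e-3 || nu_hat >= bounds$nu[2] - 1e-4
  .fit_result(eta_hat = eta_hat, nu_hat = nu_hat,
              residual_norm = best$value, n_iter = nev,
              converged = best$convergence == 0L && !at_bound,
              trace = trace_env$trace, seed = attr(sweep, "seed"),
              message = if (at_bound) "estimate at parameter bound" else "")
}

#' Fit the prestin time constant to filter-amplitude samples
#'
#' Least-squares fit of the first-order filter amplitude surface
#' `A0(V_DC) / sqrt(1 + (omega tau_e)^2)` to sampled amplitudes, with the
#' per-`V_DC` scale `A0` profiled out analytically in log space. The samples
#' must span enough of the filter roll-off to identify `tau_e`: if the
#' fitted corner lies far above the sampled frequencies (all
#' `omega * tau_e_hat << 1`, the flat plateau) the fit is flagged
#' `converged = FALSE` with a diagnostic message.
#'
#' @param samples Data frame with columns `omega` (rad/s), `V_DC` (V) and
#'   `amplitude` (> 0).
#' @param tau_bounds Search interval for `tau_e`, s.
#' @return A `fit_result` with `tau_e_hat`.
#' @export
fit_tau_e <- function(samples, tau_bounds = c(1e-9, 1e-2)) {
  stopifnot(all(c("omega", "V_DC", "amplitude") %in% names(samples)),
            all(samples$amplitude > 0), all(samples$omega >= 0))
  g <- factor(samples$V_DC)
  logA <- log(samples$amplitude)
  nev <- 0L
  obj <- function(ltau) {
    nev <<- nev + 1L
    tau <- exp(ltau)
    lgain <- -0.5 * log1p((samples$omega * tau)^2)
    resid <- logA - lgain
    resid <- resid - ave(resid, g)          # profile out log A0 per V_DC
    sum(resid^2)
  }
  o <- stats::optimize(obj, log(tau_bounds), tol = 1e-12)
  tau_hat <- exp(o$minimum)
  plateau <- max(samples$omega) * tau_hat < 0.3
  at_bound <- tau_hat <= tau_bounds[1] * 1.5 || tau_hat >= tau_bounds[2] / 1.5
  .fit_result(tau_e_hat = tau_hat, residual_norm = o$objective, n_iter = nev,
              converged = !plateau && !at_bound,
              message = if (plateau)
                "tau_e unidentifiable: samples lie on the low-frequency plateau"
              else if (at_bound) "estimate at search bound" else "")
}

#' Synthetic prestin filter-amplitude surface
#'
#' Samples the first-order filter amplitude `A0(V_DC) * prestin_gain` on a
#' grid of frequencies and DC potentials, with multiplicative lognormal
#' noise. The voltage profile `A0(V_DC)` is a synthetic bell-shaped stand-in
#' (peak near -40 mV) for the charge-transfer voltage dependence, which is
#' outside the scope of this package; only the frequency axis carries the
#' physics being fitted, and [fit_tau_e()] profiles the voltage scale out.
#'
#' @param tau_e Prestin RC time, s.
#' @param omega Angular frequencies, rad/s.
#' @param V_DC DC potentials, V.
#' @param noise_cv Multiplicative noise CV (0 = exact).
#' @param seed Integer seed.
#' @return Data frame with columns `omega`, `V_DC`, `amplitude`.
#' @export
synth_filter_surface <- function(tau_e, omega, V_DC, noise_cv = 0,
                                 seed = NULL) {
  stopifnot(tau_e > 0, all(omega >= 0), noise_cv >= 0)
  if (!is.null(seed)) set.seed(seed)
  d <- expand.grid(omega = omega, V_DC = V_DC)
  A0 <- 1 / cosh((d$V_DC + 0.04) / 0.05)^2          # synthetic voltage profile
  amp <- A0 * prestin_gain(d$omega, tau_e)
  if (noise_cv > 0) {
    sdlog <- sqrt(log(1 + noise_cv^2))
    amp <- amp * exp(stats::rnorm(nrow(d), -sdlog^2 / 2, sdlog))
  }
  d$amplitude <- amp
  d
}
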