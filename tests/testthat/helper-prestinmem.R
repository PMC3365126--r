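# Shared fixtures and independent oracles for the test suite.
# Frozen reference values were computed with an independent
# arbitrary-precision implementation (40 significant digits) of the stated
# formulas; they are data here, not re-derived from package code.

tp <- function(...) {
  p <- default_ohc_params()
  mods <- list(...)
  for (f in names(mods)) p[[f]] <- mods[[f]]
  validate_params(p)
  p
}

sp <- function(...) {
  p <- default_sphere_params()
  mods <- list(...)
  for (f in names(mods)) p[[f]] <- mods[[f]]
  validate_params(p)
  p
}

# random valid parameter objects for property-style round trips
random_ohc <- function() {
  repeat {
    C11 <- runif(1, 0.01, 0.2); C22 <- runif(1, 0.01, 0.2)
    C12 <- runif(1, -0.5, 0.9) * sqrt(C11 * C22)
    if (C11 * C22 - C12^2 > 1e-6) break
  }
  ohc_params(C11, C12, C22, eta = 10^runif(1, -7, -4), nu = runif(1, 0.1, 0.95),
             tau_e = 10^runif(1, -6.5, -4.5), C_sp = 0.01,
             alpha1_Csp = runif(1, -0.2, -0.01), alpha2_Csp = runif(1, 0.01, 0.1),
             r_c = 5e-6)
}

# direct quadrature of the hereditary integral q(t) for a unit voltage ramp
# against the impulse-response electrical kernel (independent of the closed
# forms under test)
quad_ramp_voltage_charge <- function(tau_e, C_sp, V_rate, t) {
  vapply(t, function(t1)
    stats::integrate(function(u) electrical_kernel(tau_e, C_sp, t1 - u) *
                       V_rate * u, 0, t1, rel.tol = 1e-10)$value,
    numeric(1))
}

expect_rel <- function(x, ref, tol) {
  expect_lt(max(abs(x - ref) / pmax(abs(ref), .Machine$double.xmin)), tol)
}
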