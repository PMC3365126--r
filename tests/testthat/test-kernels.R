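# Frozen reference values: independent 40-digit evaluation of
# E11(t) = C11 + eta * t^-nu / Gamma(1-nu) at C11 = 0.06, eta = 6.5e-6.
.E11_ref <- list(
  `0.7` = c(`1e-06` = 0.094436129647674549, `1e-04` = 0.061370927013884911,
            `1e-02` = 0.060054577587453308),
  `0.9` = c(`1e-06` = 0.23162189091513552, `1e-04` = 0.062720023665887021,
            `1e-02` = 0.060043109469913975))

test_that("relaxation kernel matches the arbitrary-precision oracle", {
  t <- c(1e-6, 1e-4, 1e-2)
  for (nu in c(0.7, 0.9)) {
    E <- relaxation_kernel(tp(nu = nu), t)
    expect_rel(E[1, 1, ], unname(.E11_ref[[as.character(nu)]]), 1e-14)
    expect_equal(E[1, 2, ], rep(0.04, 3))         # cross modulus is elastic
    expect_equal(E[2, 1, ], E[1, 2, ])
  }
})

test_that("relaxation kernel limits: elastic and long-time", {
  p0 <- tp(eta = 0)
  t <- 10^seq(-7, 2, by = 1)
  E <- relaxation_kernel(p0, t)
  expect_equal(E[1, 1, ], rep(p0$C11, length(t)))
  expect_equal(E[2, 2, ], rep(p0$C22, length(t)))
  p <- tp()
  expect_rel(relaxation_kernel(p, 1e6)[1, 1, ], p$C11, 1e-6)
  expect_error(relaxation_kernel(p, 0), "t must be > 0")
  expect_error(relaxation_kernel(p, c(1e-3, -1)), "t must be > 0")
  s0 <- sp(eta = 0)
  expect_equal(relaxation_kernel(s0, t), rep(s0$K, length(t)))
  expect_rel(relaxation_kernel(sp(), 1e6), sp()$K, 1e-6)
})

test_that("isotropic sphere is the C11 = C22 = K, C12 = 0 cylinder", {
  s <- sp()
  cyl <- tp(C11 = s$K, C22 = s$K, C12 = 0)
  t <- 10^seq(-7, -2, length.out = 9)
  E <- relaxation_kernel(cyl, t)
  Es <- relaxation_kernel(s, t)
  expect_equal(E[1, 1, ], Es)
  expect_equal(E[2, 2, ], Es)
  expect_equal(E[1, 2, ], rep(0, length(t)))
  om <- 2 * pi * 10^seq(1, 5, length.out = 9)
  expect_equal(complex_modulus(cyl, om)[1, 1, ], complex_modulus(s, om))
})

test_that("Laplace reciprocity: s^2 * Jbar %*% Ebar = I to 1e-10", {
  p <- tp()
  set.seed(3)
  s_samples <- complex(real = 10^runif(20, 0, 7),
                       imaginary = runif(20, -1, 1) * 10^runif(20, 0, 6))
  for (s in s_samples) {
    R <- creep_kernel_laplace(p, s) %*% relaxation_laplace(p, s) * s^2
    expect_lt(max(Mod(R - diag(2))), 1e-10)
  }
})

test_that("Laplace-domain creep limits", {
  p0 <- tp(eta = 0)
  Cinv <- solve(matrix(c(p0$C11, p0$C12, p0$C12, p0$C22), 2, 2))
  for (s in c(5 + 0i, 1e3 + 2e2i))
    expect_lt(max(Mod(creep_kernel_laplace(p0, s) - Cinv / s)),
              1e-12 * max(Mod(Cinv / s)))
  # initial-value theorem: s * Jbar(s) -> J(0+); the springpot dominates at
  # short time so the instantaneous diagonal compliance is s^-nu / eta
  p <- tp()
  for (s in c(1e10, 1e12)) {
    lhs <- Re((s * creep_kernel_laplace(p, s))[1, 1])
    expect_rel(lhs, s^(-p$nu) / p$eta, 1e-2)
  }
  expect_error(relaxation_laplace(p, -3), "branch cut")
})

test_that("time-domain creep: dual inversion algorithms agree to 1e-6", {
  p <- tp()
  t <- 10^seq(-7, -2, length.out = 11)
  Jt <- creep_kernel_time(p, t, method = "talbot")
  Js <- creep_kernel_time(p, t, method = "stehfest")
  expect_lt(max(abs(Jt - Js) / abs(Jt)), 1e-6)
  # frozen independent inversions (40-digit Talbot) at default parameters
  Jref11 <- c(`1e-06` = 7.59241924120253, `1e-04` = 23.8076522162327,
              `1e-02` = 24.9571720604977)
  Jref12 <- c(`1e-06` = -1.55277854670028, `1e-04` = -11.6581523110292,
              `1e-02` = -12.4700092241998)
  J <- creep_kernel_time(p, c(1e-6, 1e-4, 1e-2))
  expect_rel(J[1, 1, ], unname(Jref11), 1e-8)
  expect_rel(J[1, 2, ], unname(Jref12), 1e-8)
})

test_that("creep is monotone and collapses to elastic compliance at eta = 0", {
  p <- tp()
  t <- 10^seq(-7, -2, length.out = 25)
  J <- creep_kernel_time(p, t)
  expect_true(all(diff(J[1, 1, ]) >= 0))
  expect_true(all(diff(J[2, 2, ]) >= 0))
  p0 <- tp(eta = 0)
  Cinv <- solve(matrix(c(p0$C11, p0$C12, p0$C12, p0$C22), 2, 2))
  J0 <- creep_kernel_time(p0, c(1e-6, 1e-3))
  for (k in 1:2) expect_rel(J0[, , k], Cinv, 1e-9)
})

test_that("creep/relaxation hereditary identity: (E * J)(t) = t", {
  # decoupled C12 = 0 cylinder: component 11 is scalar, E11 analytic,
  # J11 from numerical inversion; their convolution must equal t
  p <- tp(C12 = 0)
  J11 <- function(u) creep_kernel_time(p, u)[1, 1, ]
  for (t1 in c(1e-5, 1e-3)) {
    conv <- stats::integrate(function(u)
      relaxation_kernel(p, u)[1, 1, ] * J11(t1 - u),
      0, t1, rel.tol = 1e-8, subdivisions = 400)$value
    expect_rel(conv, t1, 1e-4)
  }
})

test_that("complex modulus: elastic, Kelvin-Voigt and monotonicity", {
  p <- tp()
  C0 <- matrix(c(p$C11, p$C12, p$C12, p$C22), 2, 2)
  expect_equal(complex_modulus(p, 0)[, , 1], C0 + 0i)
  om <- 2 * pi * 10^seq(0, 5, length.out = 40)
  kv <- complex_modulus(p, om, model = "kelvin_voigt", eta = 1e-4)
  expect_equal(kv[1, 1, ], p$C11 + 1i * om * 1e-4)
  expect_equal(kv[1, 2, ], rep(p$C12 + 0i, length(om)))
  pw <- complex_modulus(p, om)
  expect_true(all(diff(Mod(pw[1, 1, ])) > 0))   # diagonal strictly increasing
  expect_true(all(diff(Mod(pw[2, 2, ])) > 0))
  expect_true(all(Im(pw[1, 1, ]) > 0))          # positive loss part
  # storage/loss parts are the stated power functions of omega
  expect_equal(Re(pw[1, 1, ]), p$C11 + p$eta * om^p$nu * cos(p$nu * pi / 2))
  expect_equal(Im(pw[1, 1, ]), p$eta * om^p$nu * sin(p$nu * pi / 2))
  expect_error(complex_modulus(p, -1), "omega")
})

test_that("electrical kernel is the series-RC impulse response", {
  tau <- 5e-6; Csp <- 0.01
  t <- seq(1e-7, 3e-5, length.out = 30)
  # convolution with a unit voltage step = closed-form step response
  step_num <- vapply(t, function(t1)
    stats::integrate(function(u) electrical_kernel(tau, Csp, u), 0, t1,
                     rel.tol = 1e-11)$value, numeric(1))
  expect_rel(step_num, electrical_step_response(tau, Csp, t), 1e-8)
  expect_equal(electrical_step_response(tau, Csp, tau), Csp * (1 - exp(-1)))
  expect_rel(electrical_step_response(tau, Csp, 1), Csp, 1e-12)
  # ramp voltage: numeric convolution matches the closed-form ramp response
  Vr <- 2e3
  ramp_ref <- Csp * Vr * (t - tau * (1 - exp(-t / tau)))
  expect_rel(quad_ramp_voltage_charge(tau, Csp, Vr, t), ramp_ref, 1e-7)
  expect_error(electrical_kernel(tau, Csp, 0), "t must be > 0")
})
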