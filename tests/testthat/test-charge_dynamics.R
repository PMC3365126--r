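test_that("loading_history enforces exactly one matching stimulus field", {
  expect_s3_class(loading_history("step_pressure", dP0 = 100),
                  "loading_history")
  expect_error(loading_history("step_pressure", P_r = 1), "dP0")
  expect_error(loading_history("ramp_pressure", dP0 = 1, P_r = 1), "P_r")
  expect_error(loading_history("ramp_strain"), "eps1_rate")
})

test_that("step-pressure charge: kinetics, signs, linearity, geometry", {
  p <- default_ohc_params(); s <- default_sphere_params()
  tg <- seq(5e-7, 5e-5, length.out = 50)
  expect_equal(charge_step_pressure(p, 0, tg)$q, rep(0, length(tg)))
  q <- charge_step_pressure(p, 100, tg)$q
  qinf <- q[length(q)] / (1 - exp(-tg[length(tg)] / p$tau_e))
  expect_rel(q / qinf, 1 - exp(-tg / p$tau_e), 1e-12)   # pure RC build-up
  expect_true(all(q < 0))                   # internal pressure -> negative q
  expect_equal(charge_step_pressure(p, 300, tg)$q, 3 * q)     # exact linearity
  qs <- charge_step_pressure(s, 100, tg)$q
  expect_gt(abs(qs[length(qs)]), abs(q[length(q)]))  # sphere exceeds cylinder
  expect_error(charge_step_pressure(p, 100, c(0, 1e-5)), "t must be > 0")
})

test_that("ramp-pressure charge: transient + linear regime, tau_e effect", {
  p <- default_ohc_params()
  tg <- seq(5e-7, 1.2e-4, length.out = 60)
  expect_equal(charge_ramp_pressure(p, 0, tg)$q, rep(0, length(tg)))
  P_r <- 1e6
  q <- charge_ramp_pressure(p, P_r, tg)
  expect_equal(charge_ramp_pressure(p, 5 * P_r, tg)$q, 5 * q$q)
  # long-time slope equals P_r * steady step charge per unit pressure
  t2 <- 20 * p$tau_e; h <- 1e-8
  slope <- (charge_ramp_pressure(p, P_r, t2 + h)$q -
              charge_ramp_pressure(p, P_r, t2 - h)$q) / (2 * h)
  q_step_inf <- charge_step_pressure(p, 1, 60 * p$tau_e)$q
  expect_rel(slope, P_r * q_step_inf, 1e-4)
  # larger tau_e -> smaller |q| at fixed stimulus and time
  q_slow <- charge_ramp_pressure(tp(tau_e = 2e-5), P_r, tg)$q
  expect_true(all(abs(q_slow) < abs(q$q)))
  # Duhamel superposition: ramp = integral of scaled step responses
  qstep1 <- function(u) vapply(u, function(t1)
    charge_step_pressure(p, 1, t1)$q, numeric(1))
  for (t1 in c(1e-5, 6e-5)) {
    duh <- stats::integrate(qstep1, 0, t1, rel.tol = 1e-10)$value * P_r
    expect_rel(charge_ramp_pressure(p, P_r, t1)$q, duh, 1e-6)
  }
})

test_that("resultant rates under constant strain rate follow the kernels", {
  p <- default_ohc_params()
  t <- 10^seq(-6, -3, length.out = 8)
  expect_equal(resultant_rates_from_strain(p, 0, t),
               cbind(N1dot = rep(0, 8), N2dot = rep(0, 8)))
  r0 <- resultant_rates_from_strain(tp(eta = 0), -1, t)
  expect_equal(unname(r0[, "N1dot"]), rep(unname(r0[1, "N1dot"]), 8))
  expect_equal(circumferential_rate(-2), 1)
  # independent check: finite differences of the quadrature-convolved
  # resultant history N_i(t) = int_0^t E_ij(u) du * epsdot_j
  er <- c(-1, circumferential_rate(-1))
  N1 <- function(t1) {
    e11 <- stats::integrate(function(u) relaxation_kernel(p, u)[1, 1, ],
                            0, t1, rel.tol = 1e-11)$value
    e12 <- p$C12 * t1
    e11 * er[1] + e12 * er[2]
  }
  for (t1 in c(2e-6, 5e-4)) {
    h <- t1 * 1e-4
    fd <- (N1(t1 + h) - N1(t1 - h)) / (2 * h)
    expect_rel(resultant_rates_from_strain(p, -1, t1)[, "N1dot"], fd, 1e-5)
  }
})

test_that("ramp-strain charge: sign, regimes, nu ordering, dual evaluation", {
  p <- default_ohc_params()
  tg <- seq(5e-7, 5e-5, length.out = 40)
  expect_equal(charge_ramp_strain(p, 0, tg)$q, rep(0, length(tg)))
  q <- charge_ramp_strain(p, -1, tg)
  expect_true(all(q$q > 0))            # axial compression -> positive charge
  expect_equal(charge_ramp_strain(p, -3, tg)$q, 3 * q$q)      # linearity
  # |q| increases with the power nu at fixed time
  qs <- sapply(c(0.5, 0.7, 0.9), function(nu)
    abs(charge_ramp_strain(tp(nu = nu), -1, tg)$q[20]))
  expect_true(all(diff(qs) > 0))
  # longer tau_e -> smaller charge magnitude
  q_slow <- charge_ramp_strain(tp(tau_e = 2e-5), -1, tg)$q
  expect_true(all(abs(q_slow) < abs(q$q)))
  # series and quadrature evaluations of the springpot transient agree
  qq <- charge_ramp_strain(p, -1, tg, method = "quadrature")
  expect_rel(qq$q, q$q, 1e-9)
})

test_that("all closed-form charges match the brute-force convolution oracle", {
  p <- default_ohc_params(); s <- default_sphere_params()
  tg <- seq(1e-6, 4e-5, length.out = 9)        # coarse grid, slow oracle
  cases <- list(
    list(par = p, ld = loading_history("step_pressure", dP0 = 100),
         f = function() charge_step_pressure(p, 100, tg)),
    list(par = s, ld = loading_history("step_pressure", dP0 = 100),
         f = function() charge_step_pressure(s, 100, tg)),
    list(par = p, ld = loading_history("ramp_pressure", P_r = 1e6),
         f = function() charge_ramp_pressure(p, 1e6, tg)),
    list(par = s, ld = loading_history("ramp_pressure", P_r = 1e6),
         f = function() charge_ramp_pressure(s, 1e6, tg)),
    list(par = p, ld = loading_history("ramp_strain", eps1_rate = -1),
         f = function() charge_ramp_strain(p, -1, tg)))
  for (cs in cases) {
    closed <- cs$f()$q
    oracle <- charge_convolve(cs$par, cs$ld, tg)$q
    expect_lt(max(abs(closed - oracle)) / max(abs(oracle)), 1e-3)
  }
})

test_that("charge vanishes as t -> 0+ for every loading", {
  p <- default_ohc_params()
  t0 <- 1e-12
  expect_lt(abs(charge_step_pressure(p, 100, t0)$q), 1e-12)
  expect_lt(abs(charge_ramp_pressure(p, 1e6, t0)$q), 1e-15)
  expect_lt(abs(charge_ramp_strain(p, -1, t0)$q), 1e-12)
})

test_that("generalized exponential integral: values, recurrence, monotonicity", {
  # frozen 40-digit reference values
  expect_rel(generalized_expint(1, 1), 0.21938393439552027, 1e-10)
  expect_rel(generalized_expint(0.7, 0.5), 0.68574107445947284, 1e-10)
  expect_rel(generalized_expint(1.7, 0.5), 0.37665731783271001, 1e-10)
  expect_rel(generalized_expint(0.3, 2.5), 0.030055389973400437, 1e-10)
  # recurrence nu * E_{nu+1}(x) = exp(-x) - x * E_nu(x)
  for (case in list(c(0.7, 0.5), c(0.3, 2), c(1.2, 0.8))) {
    nu <- case[1]; x <- case[2]
    resid <- nu * generalized_expint(nu + 1, x) -
      (exp(-x) - x * generalized_expint(nu, x))
    expect_lt(abs(resid), 1e-10)
  }
  x <- seq(0.1, 8, length.out = 40)
  expect_true(all(diff(generalized_expint(0.7, x)) < 0))
  expect_error(generalized_expint(0.7, 0), "x must be > 0")
  expect_error(generalized_expint(0.7, c(1, -2)), "x must be > 0")
})

test_that("confluent springpot integral G matches the high-precision oracle", {
  G <- prestinmem:::.gexp_G
  # 50-digit references for exp(-x) int_0^x exp(s) s^-nu ds, cross-checked
  # between an incomplete-gamma continuation and an exact series
  ref <- list(
    `0.5` = c(`0.1` = 0.5919312425456003, `1` = 1.0761590138255368,
              `5` = 0.5174488884253445, `25` = 0.20426814884855367,
              `60` = 0.13020336073307896, `400` = 0.050062735852807344),
    `0.7` = c(`0.1` = 1.5475364867397677, `1` = 1.6120380208750622,
              `5` = 0.41106797821722647, `25` = 0.10822845403656447,
              `60` = 0.057607662882867383, `400` = 0.015111953325226689),
    `0.9` = c(`0.1` = 7.2544695646103651, `1` = 4.125034088017899,
              `5` = 0.3691754922858278, `25` = 0.057347957866912216,
              `60` = 0.025488461699985147, `400` = 0.0045617001805514401))
  for (nu in names(ref)) {
    x <- as.numeric(names(ref[[nu]]))
    expect_rel(G(as.numeric(nu), x), unname(ref[[nu]]), 1e-9)
  }
})
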