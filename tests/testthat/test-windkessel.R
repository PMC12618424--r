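# Windkessel compartment residuals, the flow-eliminated pressure ODE, and
# their One-Step-theta discretizations.

wk_sys <- list(C_ar = 11302, R_ar = 1.392e-4, Z_ar = 1.308e-5,
               C_ven = 339060, R_ven = 1.392e-5)

test_that("3-element windkessel residuals vanish at algebraic steady states", {
  # p_ar = p_ven + (R+Z) q with constant flow solves both balances
  q <- 8.0e4
  p_ven <- 0.6
  p_ar <- p_ven + (wk_sys$R_ar + wk_sys$Z_ar) * q
  expect_equal(p_ar, 12.78, tolerance = 1e-3)   # closed form with printed R, Z
  st <- c(p_ar = p_ar, q_ar = q, p_ven = p_ven)
  r <- wk3_residual(st, st, q, q, wk_sys, dt = 1e-3)
  expect_equal(unname(r), c(0, 0), tolerance = 1e-12)
  # zero flows, equal pressures
  st0 <- c(p_ar = 1.3, q_ar = 0, p_ven = 1.3)
  expect_equal(unname(wk3_residual(st0, st0, 0, 0, wk_sys, dt = 1e-3)),
               c(0, 0))
  expect_error(wk3_residual(st, st, q, q, wk_sys, dt = 0), "dt")
  expect_error(wk3_residual(c(p_ar = NaN, q_ar = 0, p_ven = 0), st0, 0, 0,
                            wk_sys, dt = 1e-3), "finite")
})

test_that("2-element venous residual reproduces the analytic RC relaxation", {
  # steady state
  p_at <- 0.5
  q <- 5e4
  st <- c(p_ven = p_at + wk_sys$R_ven * q, q_ven = q)
  expect_lt(max(abs(wk2_residual(st, st, q, q, p_at, wk_sys, dt = 1e-3))),
            1e-9 * q)
  # step-input inflow: p_ven relaxes toward p_at + R q0 with time constant
  # R_ven C_ven; march the discrete pair and compare to the closed form
  q0 <- 6e4
  RC <- wk_sys$R_ven * wk_sys$C_ven
  dt <- 1e-4
  nt <- 2000
  p <- 0.5   # start at p_at, q_ven(0) from the algebraic row
  for (k in seq_len(nt)) {
    # algebraic row gives q_ven = (p_ven - p_at)/R; substitute into the
    # theta-blended mass row and solve for p+
    qv <- (p - p_at) / wk_sys$R_ven
    a <- wk_sys$C_ven / dt + 0.5 / wk_sys$R_ven
    b <- wk_sys$C_ven / dt * p + q0 - 0.5 * qv + 0.5 * p_at / wk_sys$R_ven
    p <- b / a
  }
  t_end <- nt * dt
  p_inf <- p_at + wk_sys$R_ven * q0
  p_exact <- p_inf + (0.5 - p_inf) * exp(-t_end / RC)
  expect_equal(p, p_exact, tolerance = 1e-6)
})

test_that("One-Step-theta shows second order for theta = 0.5, first for theta = 1", {
  # scalar RC test via the eliminated-flow ODE with constant inputs
  pars <- list(C_ar = 1e4, R_ar = 1e-4, Z_ar = 1e-5)
  q_fun <- function(t, deriv = 0) if (deriv == 0) rep(5e4, length(t)) else rep(0, length(t))
  p_ven_fun <- function(t, deriv = 0) rep(0.5, length(t))
  dq_fun <- function(t) rep(0, length(t))
  RC <- pars$C_ar * pars$R_ar
  p_inf <- 0.5 + (pars$R_ar + pars$Z_ar) * 5e4
  exact <- function(t, p0) p_inf + (p0 - p_inf) * exp(-t / RC)
  err_at <- function(dt, theta) {
    sol <- wk3_pressure_ode_solve(2, q_fun, p_ven_fun, dq_fun, pars,
                                  0, 0.5, dt = dt, theta = theta)
    abs(sol$p_ar[length(sol$p_ar)] - exact(0.5, 2))
  }
  e1 <- err_at(2e-3, 0.5); e2 <- err_at(1e-3, 0.5)
  expect_gt(e1 / e2, 3.5)        # ~4 for order 2
  expect_lt(e1 / e2, 4.5)
  f1 <- err_at(2e-3, 1); f2 <- err_at(1e-3, 1)
  expect_gt(f1 / f2, 1.7)        # ~2 for order 1
  expect_lt(f1 / f2, 2.3)
})

test_that("flow-eliminated ODE matches the discrete 3-element pair", {
  # quadratic flow pulse: its spline and derivative are exact, and the
  # trapezoid of the derivative equals the discrete difference, so the
  # two formulations agree to roundoff
  pars <- list(C_ar = 1.1e4, R_ar = 1.4e-4, Z_ar = 1.3e-5)
  Tc <- 0.75
  q_fun <- function(t, deriv = 0) {
    if (deriv == 0) 2e5 * t * (Tc - t) else 2e5 * (Tc - 2 * t)
  }
  p_ven_fun <- function(t, deriv = 0) rep(0.6, length(t))
  dq_fun <- function(t) q_fun(t, deriv = 1)
  dt <- 1e-3
  sol <- wk3_pressure_ode_solve(9, q_fun, p_ven_fun, dq_fun, pars, 0, Tc,
                                dt = dt)
  # independent oracle: march the (p_ar, q_ar) pair of the two discrete
  # balance rows directly
  n <- length(sol$t) - 1
  p <- 9
  q_ar <- -(0.6 - p + pars$Z_ar * q_fun(0)) / pars$R_ar
  pair <- numeric(n + 1); pair[1] <- p
  for (k in seq_len(n)) {
    t0 <- sol$t[k]; t1 <- sol$t[k + 1]
    qv0 <- q_fun(t0); qv1 <- q_fun(t1)
    # q_ar+ = (p+ - p_ven - Z qv+)/R ; substitute into the theta-blended
    # mass row and solve for p+
    Cz <- pars$C_ar * pars$Z_ar
    a <- pars$C_ar / dt + 0.5 / pars$R_ar
    rhs <- pars$C_ar / dt * p + Cz * (qv1 - qv0) / dt +
      0.5 * (qv1 + (0.6 + pars$Z_ar * qv1) / pars$R_ar) +
      0.5 * (qv0 - q_ar)
    p_new <- rhs / a
    q_ar <- (p_new - 0.6 - pars$Z_ar * qv1) / pars$R_ar
    p <- p_new
    pair[k + 1] <- p
  }
  expect_lt(max(abs(sol$p_ar - pair) / abs(pair)), 1e-8)
})

test_that("compartment residuals are linear in the state (secant equals Jacobian)", {
  set.seed(7)
  for (i in 1:5) {
    s1 <- c(p_ar = runif(1, 5, 15), q_ar = runif(1, 0, 1e5),
            p_ven = runif(1, 0, 2))
    s2 <- c(p_ar = runif(1, 5, 15), q_ar = runif(1, 0, 1e5),
            p_ven = runif(1, 0, 2))
    sp <- c(p_ar = 8, q_ar = 1e4, p_ven = 0.7)
    qv <- runif(2, 0, 2e5)
    r1 <- wk3_residual(s1, sp, qv[1], qv[2], wk_sys, dt = 1e-3)
    r2 <- wk3_residual(s2, sp, qv[1], qv[2], wk_sys, dt = 1e-3)
    rm <- wk3_residual((s1 + s2) / 2, sp, qv[1], qv[2], wk_sys, dt = 1e-3)
    expect_equal(unname(rm), unname((r1 + r2) / 2), tolerance = 1e-10)
  }
})

test_that("pressure ODE relaxes to the steady Ohmic value with constant inputs", {
  pars <- list(C_ar = 1e4, R_ar = 1.2e-4, Z_ar = 1.1e-5)
  q0 <- 4e4
  q_fun <- function(t, deriv = 0) if (deriv == 0) rep(q0, length(t)) else rep(0, length(t))
  pv <- function(t, deriv = 0) rep(0.8, length(t))
  dq <- function(t) rep(0, length(t))
  RC <- pars$C_ar * pars$R_ar
  sol <- wk3_pressure_ode_solve(3, q_fun, pv, dq, pars, 0, 2, dt = 1e-4)
  p_inf <- 0.8 + (pars$R_ar + pars$Z_ar) * q0
  exact <- p_inf + (3 - p_inf) * exp(-2 / RC)
  expect_equal(sol$p_ar[length(sol$p_ar)], exact, tolerance = 1e-5)
  # q_out = 0, p_ven = p0 -> constant
  sol0 <- wk3_pressure_ode_solve(0.9, function(t, deriv = 0) rep(0, length(t)),
                                 function(t, deriv = 0) rep(0.9, length(t)),
                                 function(t) rep(0, length(t)),
                                 pars, 0, 0.5, dt = 1e-3)
  expect_equal(max(abs(sol0$p_ar - 0.9)), 0, tolerance = 1e-12)
})
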