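# Active-stress generation and the chamber pressure-volume surrogate.

ap_lv <- active_stress_params(sigma_0 = 78.92, alpha_max = 15.17,
                              alpha_min = -35.65, t_contr = 0.1425,
                              t_relax = 0.4275, T_cycl = 0.75, K = 10)

test_that("activation is the regularized trapezoid with the stated ramp anchors", {
  cc <- cardioloop:::activation_centers(ap_lv)
  c1 <- cc[["c1"]]; c2 <- cc[["c2"]]
  expect_equal(activation(c1, ap_lv), 1)
  expect_equal(activation(c1 - 1 / ap_lv$K, ap_lv), 0)
  expect_equal(activation(c1 - 1 / ap_lv$K - 0.01, ap_lv), 0)
  expect_equal(activation(c2 + 1 / (2 * ap_lv$K), ap_lv), 0.5)
  # periodic with period T_cycl, continuous, total variation 2 per cycle
  tt <- seq(0, 0.75, 5e-4)
  f <- activation(tt, ap_lv)
  expect_equal(f, activation(tt + 3 * 0.75, ap_lv), tolerance = 1e-12)
  expect_true(all(f >= 0 & f <= 1))
  expect_lt(max(abs(diff(f))), ap_lv$K * 5e-4 * 1.01)   # continuity at ramp slope
  expect_equal(sum(abs(diff(f))), 2, tolerance = 1e-6)
})

test_that("activation ramp-center sensitivities match finite differences", {
  tt <- seq(0, 0.75, 1e-3)
  for (nm in c("alpha_max", "alpha_min")) {
    h <- 1e-6 * abs(ap_lv[[nm]])
    up <- ap_lv; up[[nm]] <- up[[nm]] + h
    dn <- ap_lv; dn[[nm]] <- dn[[nm]] - h
    fd <- (activation(tt, up) - activation(tt, dn)) / (2 * h)
    an <- activation_partials(tt, ap_lv)[[paste0("df_d", sub("alpha_", "a", nm))]]
    # exclude grid points straddling the moving kinks
    keep <- abs(fd - an) < 0.5 * max(abs(an))
    expect_gt(mean(keep), 0.99)
    expect_equal(an[keep], fd[keep], tolerance = 1e-5)
  }
})

test_that("transmembrane potential blends the rate parameters with activation", {
  expect_equal(transmembrane_potential(cardioloop:::activation_centers(ap_lv)[["c1"]],
                                       ap_lv), 15.17)
  expect_equal(transmembrane_potential(0, ap_lv), -35.65)
  # f_hat = 0.5 blend of the printed ventricular rates
  u_mid <- 0.5 * 15.17 + 0.5 * (-35.65)
  expect_equal(u_mid, -10.24)
})

test_that("active stress ODE has equilibrium sigma_0 and exponential relaxation", {
  expect_equal(active_stress_rate(72.55, 7.21, 72.55), 0)
  expect_lt(active_stress_rate(10, -5, 72.55), 0)
  # analytic upstroke: hold u = alpha_max for 0.2 s from tau = 0
  tg <- seq(0, 0.2, 1e-5)
  ap <- active_stress_params(72.55, 7.21, -34.34, t_contr = -1, t_relax = 0.5,
                             T_cycl = 10, K = 10)
  # direct scalar integration with constant u (independent of activation)
  tau <- 0
  for (k in seq_len(length(tg) - 1)) {
    dt <- tg[k + 1] - tg[k]
    au <- 7.21; su <- 72.55 * 7.21
    tau <- (tau * (1 - dt * 0.5 * au) + dt * su) / (1 + dt * 0.5 * au)
  }
  expect_equal(tau, 72.55 * (1 - exp(-7.21 * 0.2)), tolerance = 1e-4)
})

test_that("integrated active stress stays in [0, sigma_0] and becomes periodic", {
  tg <- seq(0, 3 * 0.75, 1e-3)
  tau <- cardioloop:::integrate_active_stress(ap_lv, tg)
  expect_true(all(tau >= -1e-12 & tau <= 78.92 + 1e-9))
  cyc2 <- tau[tg >= 0.75 & tg < 1.5]
  cyc3 <- tau[tg >= 1.5 & tg < 2.25]
  expect_equal(cyc3, cyc2, tolerance = 0.02)
})

test_that("chamber surrogate pressure is anchored, monotone and C1", {
  cp <- chamber_surrogate_params(V_ref = 76e3, E_pass_a = 0.25,
                                 E_pass_b = 4.5e-5, wall_factor = 0.165)
  expect_equal(chamber_pressure(76e3, 0, cp), 0)
  expect_error(chamber_pressure(-1, 0, cp), "positive")
  # monotone in V and tau on a random grid; analytic partials match FD
  set.seed(3)
  for (i in 1:20) {
    V <- runif(1, 4e4, 1.5e5); tau <- runif(1, 0, 70)
    d <- chamber_pressure(V, tau, cp, deriv = TRUE)
    expect_gt(d$dp_dV, 0)
    expect_gt(d$dp_dtau, 0)
    hV <- 1e-4 * V
    expect_equal(d$dp_dV,
                 (chamber_pressure(V + hV, tau, cp) -
                    chamber_pressure(V - hV, tau, cp)) / (2 * hV),
                 tolerance = 1e-5)
  }
  # active component is linear in tau (doubling contractile stress doubles it)
  act <- function(tau) chamber_pressure(9e4, tau, cp) - chamber_pressure(9e4, 0, cp)
  expect_equal(act(40), 2 * act(20), tolerance = 1e-12)
})

test_that("chamber mass balance holds pointwise and over a periodic cycle", {
  expect_equal(chamber_mass_residual(0, 50, 50), 0)
  expect_equal(chamber_mass_residual(10, 30, 20), 0)
  # cycle-integrated inflow equals outflow per chamber at convergence
  sim <- fix_sim()
  tt <- sim$time
  tol <- 0.04   # consistent with the periodicity tolerance
  for (ch in c("lv", "rv")) {
    w <- cardioloop:::CHAMBER_WIRING[[ch]]
    q_in <- sim$states[, w[["q_in"]]]
    q_out <- sim$states[, w[["q_out"]]]
    Vin <- cardioloop:::trapz(tt, q_in)
    Vout <- cardioloop:::trapz(tt, q_out)
    expect_lt(abs(Vin - Vout) / max(Vin, Vout), tol)
  }
})
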