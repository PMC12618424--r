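# Valve effective-orifice-area identification from transvalvular pressure
# and flow.

# module-level synthetic data: prescribe a transvalvular gradient, run the
# valve forward model at the generating areas, report the flow
make_valve_synth <- function(A_max, A_min, valve = "pul", n_flow = 30) {
  Tc <- 0.75
  fixed <- cardioloop:::default_valve_generics(valve)
  tp <- Tc * (0:749) / 750
  dp_wave <- function(t) {
    s <- (t - 0.16) / 0.30
    ifelse(s > 0 & s < 1, 1.4 * sin(pi * s), -0.7)
  }
  vp <- fixed; vp$A_eff_max <- A_max; vp$A_eff_min <- A_min
  dp_fun <- function(t, deriv = 0) dp_wave(t %% Tc)
  attr(dp_fun, "t_range") <- c(-Inf, Inf)
  sim <- simulate_valve_prescribed_dp(dp_fun, vp, 0, Tc, dt = 1e-3,
                                      q0 = if (A_min > 1) -A_min * sqrt(2 * 0.7 / vp$rho) else 0)
  # emulate the two catheter runs and the flow measurement
  pv <- 1.0 + dp_wave(tp)
  pa <- rep(1.0, length(tp))
  tq <- Tc * (0:(n_flow - 1)) / n_flow
  qm <- stats::approx(sim$t, sim$q, xout = tq)$y
  nm <- if (valve == "pul")
    c(p = "p_v_r", a = "p_ar_pul", q = "q_v_out_r") else
    c(p = "p_v_l", a = "p_ar_sys", q = "q_v_out_l")
  series <- list(data.frame(t = tp, value = pv),
                 data.frame(t = tp, value = pa),
                 data.frame(t = tq, value = qm))
  names(series) <- nm
  measurement_set(series, T_cycl = Tc)
}

test_that("forward/backward volume split follows the sign decomposition", {
  Tc <- 0.75
  tt <- seq(0, Tc, length.out = 2001)
  q <- 100 * sin(2 * pi * tt / Tc)       # ml/s scale
  v <- forward_backward_volumes(data.frame(t = tt, value = q))
  expect_equal(v[["V_for"]], 100 * Tc / pi, tolerance = 1e-5)
  expect_equal(v[["V_back"]], 100 * Tc / pi, tolerance = 1e-5)
  vneg <- forward_backward_volumes(data.frame(t = tt, value = -q))
  expect_equal(vneg[["V_for"]], v[["V_back"]])
  expect_equal(vneg[["V_back"]], v[["V_for"]])
  vpos <- forward_backward_volumes(data.frame(t = tt, value = abs(q)))
  expect_equal(vpos[["V_back"]], 0)
})

test_that("valve objective vanishes at the generating areas and flags mismatch", {
  # densely "measured" flow: the volume targets coincide with the model's
  # own integrals, so the objective is zero at the generating areas
  mset <- make_valve_synth(308, 164, "pul", n_flow = 750)
  f0 <- valve_objective(c(A_eff_max = 308, A_eff_min = 164), mset, "pul")
  expect_lt(f0, 1e-4)
  # sealing the leak leaves the squared backward-volume mismatch
  vb <- forward_backward_volumes(mset$series$q_v_out_r)[["V_back"]] / 1000
  f_seal <- valve_objective(c(A_eff_max = 308, A_eff_min = 0), mset, "pul")
  expect_gt(f_seal, 0.5 * vb^2)
  # continuity across the A_min floor
  f_eps <- sapply(c(0, 1e-3, 1e-2, 0.1), function(am)
    valve_objective(c(A_eff_max = 308, A_eff_min = am), mset, "pul"))
  expect_lt(max(abs(diff(f_eps))), 0.05 * f_seal)
})

test_that("backward volume increases monotonically with the minimum area", {
  mset <- make_valve_synth(308, 164, "pul")
  data <- cardioloop:::valve_prepare_data(mset, "pul")
  fixed <- cardioloop:::default_valve_generics("pul")
  vb <- sapply(c(40, 80, 120, 160, 200), function(am) {
    vp <- fixed; vp$A_eff_max <- 308; vp$A_eff_min <- am
    sim <- simulate_valve_prescribed_dp(data$dp_fun, vp, data$t0, data$t_end,
                                        dt = 1e-3, q0 = data$q0)
    forward_backward_volumes(data.frame(t = sim$t, value = sim$q))[["V_back"]]
  })
  expect_true(all(diff(vb) > 0))
})

test_that("noiseless fits recover regurgitant and competent valve areas", {
  mset <- make_valve_synth(308, 164, "pul")
  fit <- fit_valve_eoa(mset, "pul")
  expect_lt(abs(fit$phi[["A_eff_max"]] - 308) / 308, 0.02)
  expect_lt(abs(fit$phi[["A_eff_min"]] - 164) / 164, 0.02)
  # fitted volumes reproduce the measured integrals
  expect_lt(abs(fit$volumes[["V_for"]] - fit$measured[["V_for"]]), 0.5)
  expect_lt(abs(fit$volumes[["V_back"]] - fit$measured[["V_back"]]), 0.5)
  # a competent aortic valve drives the fitted minimum area to the floor
  mset0 <- make_valve_synth(141, 0, "aor")
  fit0 <- fit_valve_eoa(mset0, "aor")
  expect_lt(abs(fit0$phi[["A_eff_max"]] - 141) / 141, 0.02)
  expect_lte(fit0$phi[["A_eff_min"]], 1)
})
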