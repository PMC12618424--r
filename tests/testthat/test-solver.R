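# Coupled residual assembly, Newton stepping, cycle iteration and the
# valve-replacement parameter edit.

test_that("coupled residual vanishes at an exact hydrostatic equilibrium", {
  p <- fix_params()
  x <- numeric(28)
  for (ch in names(cardioloop:::CHAMBER_WIRING)) {
    w <- cardioloop:::CHAMBER_WIRING[[ch]]
    x[w[["V"]]] <- p$chambers[[ch]]$V_ref   # passive pressure zero
  }
  # late diastole: every activation source is zero, so the all-zero
  # (pressures, flows, stresses) state at reference volumes is an exact
  # equilibrium of all 28 rows
  r <- assemble_coupled_residual(x, x, p, dt = 1e-3, t_next = 0.7001,
                                 t_prev = 0.7)
  expect_lt(max(abs(r)), 1e-12)
})

test_that("analytic Jacobians match central finite differences", {
  p <- fix_params()
  xp <- fix_random_state(42)
  xn <- xp * (1 + 0.02 * stats::rnorm(28))
  xn[c(3, 5, 13, 15)] <- pmin(1, pmax(0, xn[c(3, 5, 13, 15)]))
  out <- assemble_coupled_residual(xn, xp, p, 1e-3, 0.201, 0.2,
                                   jacobian = TRUE)
  fdA <- matrix(0, 28, 28); fdB <- matrix(0, 28, 28)
  for (j in 1:28) {
    h <- 1e-6 * max(1, abs(xn[j])); e <- rep(0, 28); e[j] <- h
    fdA[, j] <- (assemble_coupled_residual(xn + e, xp, p, 1e-3, 0.201, 0.2) -
                 assemble_coupled_residual(xn - e, xp, p, 1e-3, 0.201, 0.2)) / (2 * h)
    h <- 1e-6 * max(1, abs(xp[j])); e <- rep(0, 28); e[j] <- h
    fdB[, j] <- (assemble_coupled_residual(xn, xp + e, p, 1e-3, 0.201, 0.2) -
                 assemble_coupled_residual(xn, xp - e, p, 1e-3, 0.201, 0.2)) / (2 * h)
  }
  sc <- max(abs(fdA))
  expect_lt(max(abs(out$A - fdA) / pmax(abs(fdA), 1e-5 * sc)), 1e-5)
  scB <- max(abs(fdB))
  expect_lt(max(abs(out$B - fdB) / pmax(abs(fdB), 1e-5 * scB)), 1e-5)
})

test_that("compiled assembly agrees with the reference implementation", {
  p <- fix_params()
  flat <- cardioloop:::flatten_params(p)
  for (seed in c(1, 2, 3)) {
    xp <- fix_random_state(seed)
    xn <- xp * (1 + 0.01 * stats::rnorm(28))
    xn[c(3, 5, 13, 15)] <- pmin(1, pmax(0, xn[c(3, 5, 13, 15)]))
    un <- cardioloop:::u_tables_at(p, 0.201)
    up <- cardioloop:::u_tables_at(p, 0.2)
    ref <- cardioloop:::assemble_core(xn, xp, p, 1e-3, p$theta, un, up,
                                      want_jac = TRUE)
    cpp <- cardioloop:::.cpp_assemble(xn, xp, flat, 1e-3, un$au, un$su,
                                      up$au, up$su, TRUE)
    expect_equal(as.numeric(cpp$r), ref$r, tolerance = 1e-12)
    expect_equal(cpp$A, ref$A, tolerance = 1e-12)
    expect_equal(cpp$B, ref$B, tolerance = 1e-12)
  }
})

test_that("a Newton step from a converged state returns it unchanged", {
  p <- fix_params()
  sim <- fix_sim()
  x1 <- sim$states[100, ]
  x2 <- sim$states[101, ]
  # stepping again from x1 must reproduce x2
  x2b <- newton_step(x1, p, sim$dt, t_prev = sim$time[100])
  expect_equal(as.numeric(x2b), as.numeric(x2), tolerance = 1e-7)
  # the converged pair satisfies the residual contract in scaled units
  r <- assemble_coupled_residual(x2, x1, p, sim$dt, sim$time[101],
                                 sim$time[100], jacobian = TRUE)
  rs <- pmax(abs(r$A) %*% cardioloop:::STATE_SCALES, 1e-8)
  expect_lt(max(abs(r$r) / rs), 1e-8)
})

test_that("periodicity error is the maximum relative change of the listed set", {
  s <- stats::setNames(fix_random_state(5), cardioloop:::STATE_NAMES)
  expect_equal(periodicity_error(s, s), 0)
  e <- s * 1.02
  expect_equal(periodicity_error(s, e), 0.02, tolerance = 1e-12)
  e2 <- s
  e2[["V_v_r"]] <- s[["V_v_r"]] * 1.10
  expect_equal(periodicity_error(s, e2), 0.10, tolerance = 1e-12)
  # the literal printed set omits the left atrium
  e3 <- s
  e3[["V_at_l"]] <- s[["V_at_l"]] * 1.5
  expect_equal(periodicity_error(s, e3, literal_printed_set = TRUE), 0)
  s0 <- s; s0[["p_ar_sys"]] <- 0
  expect_error(periodicity_error(s0, s0), "denominator")
})

test_that("cycle iteration reaches and recognizes the periodic state", {
  sim <- fix_sim()
  expect_true(sim$report$converged)
  expect_lte(sim$report$E_cycl, 0.04)
  expect_lte(sim$report$n_cycles, 20)
  # restarting from the converged state is periodic within one cycle
  again <- run_cycles(sim$states[nrow(sim$states), ], fix_params(),
                      dt = sim$dt)
  expect_equal(again$report$n_cycles, 1)
  expect_lte(again$report$E_cycl, 0.04)
})

test_that("total blood volume is conserved along the trajectory", {
  sim <- fix_sim()
  p <- fix_params()
  v0 <- total_blood_volume(sim$states[1, ], p)
  vT <- total_blood_volume(sim$states[nrow(sim$states), ], p)
  expect_lt(abs(vT - v0) / v0, 1e-9)
})

test_that("trajectories converge under time-grid refinement", {
  p <- fix_params()
  sim <- fix_sim()
  x0 <- sim$states[nrow(sim$states), ]
  endv <- function(dt) {
    s <- run_cycles(x0, p, dt = dt, max_cycles = 1, warn = FALSE)
    s$states[nrow(s$states), c("V_v_l", "V_v_r", "p_ar_sys")]
  }
  ref <- endv(1.25e-4)
  e1 <- max(abs(endv(1e-3) - ref) / abs(ref))
  e2 <- max(abs(endv(5e-4) - ref) / abs(ref))
  # valve opening/closing events are non-smooth, so the trapezoidal rule
  # degrades locally; require at least first-order global convergence
  expect_gt(e1 / e2, 1.8)
})

test_that("valve replacement seals only the chosen valve and is idempotent", {
  p <- fix_params()
  p2 <- apply_valve_replacement(p, "pul")
  expect_equal(p2$valves$pul$A_eff_min, 0)
  expect_equal(p2$valves$pul$A_eff_max, 308)
  expect_equal(p2$valves$aor$A_eff_min, p$valves$aor$A_eff_min)
  expect_identical(apply_valve_replacement(p2, "pul"), p2)
  expect_error(apply_valve_replacement(p, "foo"), "unknown valve")
})
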