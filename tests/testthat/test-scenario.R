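# Scenario generation, measurement synthesis, serialization, and the
# valve-replacement prediction workflow.

test_that("the regurgitant scenario exhibits the targeted right-heart state", {
  sim <- fix_sim()
  expect_equal(fix_params()$T_cycl, 0.75)
  r <- sim_clinical_metrics(sim, "r")
  l <- sim_clinical_metrics(sim, "l")
  expect_gt(r$RF, 40)
  expect_gt(r$EDV, 1.5 * l$EDV)
})

test_that("scenario and parameter sets round-trip through JSON losslessly", {
  dir <- withr::local_tempdir()
  scen <- make_tof_scenario(3)
  path <- file.path(dir, "scen.json")
  write_scenario_json(scen, path)
  back <- read_scenario_json(path)
  expect_equal(back$seed, 3L)
  expect_equal(unclass(back$params$wk_sys), unclass(scen$params$wk_sys))
  expect_equal(lapply(back$params$valves, unclass),
               lapply(scen$params$valves, unclass))
  expect_equal(lapply(back$params$active, unclass),
               lapply(scen$params$active, unclass))
  expect_equal(lapply(back$params$chambers, unclass),
               lapply(scen$params$chambers, unclass))
})

test_that("measurement synthesis samples the trajectory at clinical rates", {
  sim <- fix_sim_tight()
  m0 <- synthesize_measurements(sim, noise = NULL, seed = 1)
  expect_equal(nrow(m0$series$V_v_r), 25)
  expect_equal(nrow(m0$series$q_v_out_r), 30)
  # zero noise: sampled values equal trajectory values at sample times
  idx <- match(round(m0$series$V_v_r$t, 9), round(sim$time - sim$time[1], 9))
  expect_equal(m0$series$V_v_r$value, unname(sim$states[idx, "V_v_r"]))
  # fixed seed reproducibility
  m1 <- synthesize_measurements(sim, seed = 42)
  m2 <- synthesize_measurements(sim, seed = 42)
  expect_identical(m1, m2)
  m3 <- synthesize_measurements(sim, seed = 43)
  expect_false(identical(m1$series$p_v_l$value, m3$series$p_v_l$value))
})

test_that("time-shifted synthesis is undone by the normalization step", {
  sim <- fix_sim_tight()
  m <- synthesize_measurements(sim, noise = NULL, seed = 1, shift = 0.1)
  norm <- normalize_time_axis(m, 0.75, t0_event = 0.1)
  ref <- synthesize_measurements(sim, noise = NULL, seed = 1)
  f_ref <- spline_series(ref$series$V_v_r, periodic = TRUE, T_cycl = 0.75)
  f_nrm <- spline_series(norm$series$V_v_r, periodic = TRUE, T_cycl = 0.75)
  tt <- seq(0, 0.74, 0.01)
  expect_equal(f_nrm(tt), f_ref(tt), tolerance = 1e-6)
})

test_that("sealing the pulmonary valve abolishes regurgitation and raises output", {
  tw <- fix_twin()
  out <- tw$outcome
  expect_lt(out$post$right$RF, 1)
  expect_lt(out$post$right$EDV, out$pre$right$EDV)
  expect_gte(out$post$left$SV, out$pre$left$SV)
  # metric identities hold in both columns
  for (side in c("right", "left")) for (tab in list(out$pre, out$post)) {
    cm <- tab[[side]]
    expect_equal(cm$SV, cm$EDV - cm$ESV)
    expect_equal(cm$RF, 100 * cm$RV / (cm$FV + cm$RV))
  }
  # removing the leak never increases backward volume
  expect_lte(out$post$right$RV, out$pre$right$RV)
})

test_that("the twin report records each subproblem's measurement requirements", {
  tw <- fix_twin()
  expect_setequal(tw$subproblems$subproblem,
                  c("windkessel_sys", "windkessel_pul", "valve_aor",
                    "valve_pul", "active_stress"))
  expect_true(all(tw$subproblems$available))
  expect_true(all(c("truth", "estimate", "rel_err") %in%
                    names(tw$parameters)))
  dir <- withr::local_tempdir()
  write_twin_report_json(tw, file.path(dir, "tw.json"))
  j <- jsonlite::read_json(file.path(dir, "tw.json"), simplifyVector = TRUE)
  expect_equal(nrow(j$parameters), nrow(tw$parameters))
})

test_that("independently identified parameters remain valid in the coupled model", {
  # the separately fitted windkessel/valve/active-stress parameters,
  # inserted together into the closed loop, reproduce the synthetic
  # measurements they were identified from
  tw <- fix_twin()
  cal <- tw$calibrated
  meas <- measured_volumes(tw$mset)
  x0 <- cardioloop:::initial_state_from_measured(cal, meas, mset = tw$mset)
  sim <- run_cycles(x0, cal, dt = 1e-3, eps_cycl = 1e-3, max_cycles = 60,
                    warn = FALSE)
  # ventricular volume curves within a small fraction of their excursion
  for (side in c("l", "r")) {
    nm <- paste0("V_v_", side)
    mser <- tw$mset$series[[nm]]
    model <- stats::approx(sim$time, sim$states[, nm], xout = mser$t)$y
    expect_lt(max(abs(model - mser$value)) / diff(range(mser$value)), 0.06)
  }
  # arterial pressure traces within a few percent of the measured range
  for (nm in c("p_ar_sys", "p_ar_pul")) {
    mser <- tw$mset$series[[nm]]
    model <- stats::approx(sim$time, sim$states[, nm], xout = mser$t)$y
    expect_lt(max(abs(model - mser$value)) / diff(range(mser$value)), 0.15)
  }
})

test_that("noisy-twin recovery degrades gracefully at clinical noise levels", {
  twn <- run_twin_experiment(seed = 1, noise = "default",
                             with_replacement = FALSE)
  pt <- twn$parameters
  err <- function(nm) pt$rel_err[pt$parameter == nm]
  expect_lt(err("R_ar_sys"), 0.10)
  expect_lt(err("R_ar_pul"), 0.10)
  expect_lt(max(err("A_eff_max_aor"), err("A_eff_max_pul"),
                err("A_eff_min_pul")), 0.10)
  # the effectively sealed aortic minimum area on the absolute scale
  sealed <- pt$parameter == "A_eff_min_aor"
  expect_lt(abs(pt$estimate[sealed] - pt$truth[sealed]), 1)
  # ventricular contractility within 10 %; atrial contractility is only
  # weakly identifiable at a 2 ml volume noise level
  expect_lt(max(err("rv.sigma_0"), err("lv.sigma_0")), 0.10)
})
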