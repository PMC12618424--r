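# Measurement I/O, spline interpolation, time-axis normalization,
# clinical metrics and the mass-consistency check.

test_that("CSV round trip preserves series, units and metadata", {
  dir <- withr::local_tempdir()
  tt <- seq(0, 0.72, 0.03)
  mset <- measurement_set(list(
    q_v_out_r = data.frame(t = tt, value = 1000 * sin(2 * pi * tt / 0.75)),
    V_v_r = data.frame(t = tt, value = 1.5e5 + 2e4 * cos(2 * pi * tt / 0.75))),
    T_cycl = 0.75)
  path <- file.path(dir, "meas.csv")
  write_measurements(mset, path)
  back <- read_measurements(path)
  expect_equal(back$series$q_v_out_r$value, mset$series$q_v_out_r$value,
               tolerance = 1e-9)
  expect_equal(back$series$V_v_r$value, mset$series$V_v_r$value,
               tolerance = 1e-9)
  expect_equal(back$T_cycl, 0.75)
  # a minimal file with only one series parses
  writeLines(c("t,q_v_out_r", "0,0", "0.1,10", "0.2,5"),
             file.path(dir, "min.csv"))
  m2 <- read_measurements(file.path(dir, "min.csv"))
  expect_named(m2$series, "q_v_out_r")
  expect_equal(m2$series$q_v_out_r$value, c(0, 10, 5) * 1000)  # ml/s default
})

test_that("unit declarations convert and malformed series are rejected", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "u.csv")
  writeLines(c("t,q_v_out_r", "0,0", "0.1,10", "0.2,5"), path)
  jsonlite::write_json(list(T_cycl = 0.75,
                            units = list(q_v_out_r = "mm^3/s")),
                       sub("csv$", "json", path), auto_unbox = TRUE)
  m <- read_measurements(path)
  expect_equal(m$series$q_v_out_r$value, c(0, 10, 5))   # already internal
  expect_error(measurement_set(list(
    p_v_l = data.frame(t = c(0, 0.1, 0.1), value = c(1, 2, 3))), 0.75),
    "duplicate")
  expect_error(measurement_set(list(
    p_v_l = data.frame(t = c(0, 0.2, 0.1), value = c(1, 2, 3))), 0.75),
    "increasing")
})

test_that("cubic spline interpolation is exact on cubics with analytic derivative", {
  tt <- seq(0, 1, 0.1)
  cubic <- function(t) 2 - t + 3 * t^2 - 0.5 * t^3
  f <- spline_series(data.frame(t = tt, value = cubic(tt)))
  xs <- seq(0.05, 0.95, 0.017)
  expect_equal(f(xs), cubic(xs), tolerance = 1e-9)
  expect_error(spline_series(data.frame(t = c(0, 1, 2), value = 1:3)),
               "4 samples")
  # periodic boundary: value and slope match across the seam
  ts <- seq(0, 0.75 - 0.025, 0.025)
  g <- spline_series(data.frame(t = ts, value = sin(2 * pi * ts / 0.75)),
                     periodic = TRUE, T_cycl = 0.75)
  expect_equal(g(0), g(0.75), tolerance = 1e-10)
  expect_equal(g(0, deriv = 1), g(0.75, deriv = 1), tolerance = 1e-6)
  # derivative amplitude of a sampled sine at the clinical flow rate
  w <- 2 * pi / 0.75
  expect_equal(max(g(seq(0, 0.75, 1e-4), deriv = 1)), w, tolerance = 0.01)
})

test_that("time-axis normalization rescales cycles and shifts the origin", {
  tt <- seq(0, 0.76, 0.04)
  m <- measurement_set(list(p_v_l = data.frame(t = tt, value = sin(tt))),
                       T_cycl = 0.80)
  same <- normalize_time_axis(m, 0.80)
  expect_equal(same$series$p_v_l, m$series$p_v_l, tolerance = 1e-12)
  scaled <- normalize_time_axis(m, 0.75)
  expect_equal(scaled$series$p_v_l$t[tt == 0.40], 0.375)
  # shifting forward then backward restores the cycle (modulo wrap order)
  sh <- normalize_time_axis(m, 0.80, t0_event = 0.1)
  back <- normalize_time_axis(sh, 0.80, t0_event = 0.80 - 0.1)
  o <- order(back$series$p_v_l$t)
  expect_equal(sort(back$series$p_v_l$t), sort(m$series$p_v_l$t),
               tolerance = 1e-9)
  expect_equal(back$series$p_v_l$value[o][order(m$series$p_v_l$t)],
               m$series$p_v_l$value, tolerance = 1e-9)
})

test_that("clinical metrics reproduce the published preoperative arithmetic", {
  right <- metrics_from_volumes(EDV = 192.3, ESV = 116.3, RV = 43.1)
  expect_equal(right$SV, 76.0, tolerance = 1e-9)
  expect_equal(right$EF, 39.5, tolerance = 0.05)
  expect_equal(right$FV, 32.9, tolerance = 1e-9)
  expect_equal(right$RF, 56.7, tolerance = 0.05)
  left <- metrics_from_volumes(EDV = 99.7, ESV = 59.3, RV = 1.3)
  expect_equal(left$SV, 40.4, tolerance = 1e-9)
  expect_equal(left$EF, 40.5, tolerance = 0.05)
  expect_equal(left$FV, 39.1, tolerance = 1e-9)
  expect_equal(left$RF, 3.2, tolerance = 0.05)
})

test_that("clinical metrics satisfy their invariants on arbitrary series", {
  set.seed(21)
  for (i in 1:10) {
    tt <- seq(0, 0.75, length.out = 40)
    V <- 100 + 40 * sin(2 * pi * tt / 0.75 + runif(1, 0, 2 * pi)) +
      rnorm(40, 0, 2)
    q <- 300 * sin(2 * pi * tt / 0.75) + rnorm(40, 0, 20)
    cm <- clinical_metrics(data.frame(t = tt, value = V),
                           data.frame(t = tt, value = q))
    expect_equal(cm$SV, cm$EDV - cm$ESV)
    expect_equal(cm$EF, 100 * cm$SV / cm$EDV)
    expect_equal(cm$FV + cm$RV, cm$SV)
    expect_gte(cm$RF, 0)
    expect_lte(cm$RF, 100)
  }
  expect_error(clinical_metrics(data.frame(t = numeric(), value = numeric()),
                                data.frame(t = 1, value = 1)), "empty")
})

test_that("mass-consistency check recovers a constructed volume inflation", {
  sim <- fix_sim()
  vol <- data.frame(t = sim$time, value = sim$states[, "V_v_l"])
  flow <- data.frame(t = sim$time, value = sim$states[, "q_aor"])
  ok <- check_mass_consistency(vol, flow)
  expect_lt(abs(ok$factor - 1), 0.05)
  infl <- vol
  infl$value <- infl$value * 1.05
  bad <- check_mass_consistency(infl, flow, adjust = TRUE)
  expect_equal(bad$factor, ok$factor / 1.05, tolerance = 1e-6)
  expect_identical(bad$adjusted_series, "volume")
  # the adjusted excursion matches the flow-implied excursion again
  re <- check_mass_consistency(bad$adjusted_volume, flow)
  expect_lt(abs(re$factor - 1), 0.05)
})
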