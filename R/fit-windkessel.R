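# Identification of arterial 3-element windkessel parameters from one
# cycle of measured arterial pressure, venous pressure, and semilunar
# valve flow, via the flow-eliminated pressure ODE. Optimization runs in
# log-parameter space (positivity without explicit constraints) with
# L-BFGS-B and numeric gradients.

# forward solve + the four objective ingredients for a parameter triple
wk_forward_terms <- function(phi, data, dt, theta) {
  pars <- list(R_ar = phi[["R_ar"]], C_ar = phi[["C_ar"]], Z_ar = phi[["Z_ar"]])
  sol <- wk3_pressure_ode_solve(data$p_ar0, data$q_fun, data$p_ven_fun,
                                data$dq_fun, pars, data$t0, data$t_end,
                                dt = dt, theta = theta)
  # pressure rate from the ODE right-hand side (smooth in the parameters)
  R <- pars$R_ar; C <- pars$C_ar; Z <- pars$Z_ar
  rhs <- data$p_ven_fun(sol$t) + (R + Z) * data$q_fun(sol$t) +
    Z * C * R * data$dq_fun(sol$t)
  dp <- (rhs - sol$p_ar) / (C * R)
  list(sol = sol, p_max = max(sol$p_ar), p_min = min(sol$p_ar),
       p_end = sol$p_ar[length(sol$p_ar)], dp_max = max(dp))
}

#' Arterial windkessel objective function
#'
#' Four normalized squared mismatch terms between the computed and
#' measured arterial pressure over one cycle: the pressure maximum, the
#' pressure minimum, the end-of-cycle value (enforcing periodicity), and
#' the maximum systolic pressure rate. Pressure-extremum normalization
#' uses the measured pressure maximum; the rate term is normalized by the
#' measured maximum rate (from the spline derivative).
#'
#' @param phi named numeric: `R_ar`, `C_ar`, `Z_ar` (internal units).
#' @param mset a [measurement_set()] providing `p_ar`, `p_ven` and the
#'   valve flow for one side; see [fit_arterial_windkessel()] for the
#'   naming convention.
#' @param side `"sys"` or `"pul"`.
#' @param dt forward time step, s.
#' @return scalar objective (dimensionless).
#' @export
windkessel_objective <- function(phi, mset, side = c("sys", "pul"),
                                 dt = 1e-3) {
  side <- match.arg(side)
  data <- wk_prepare_data(mset, side)
  f <- wk_forward_terms(phi, data, dt, theta = 0.5)
  wk_objective_terms(f, data)
}

wk_objective_terms <- function(f, data) {
  n1 <- data$p_meas_max^2
  n4 <- data$dp_meas_max^2
  (f$p_max - data$p_meas_max)^2 / n1 +
    (f$p_min - data$p_meas_min)^2 / n1 +
    (f$p_end - data$p_meas_end)^2 / n1 +
    (f$dp_max - data$dp_meas_max)^2 / n4
}

# assemble splines and measured targets for one circulation side
wk_prepare_data <- function(mset, side) {
  p_ar_name <- paste0("p_ar_", side)
  q_name <- if (side == "sys") "q_v_out_l" else "q_v_out_r"
  p_ven_name <- paste0("p_ven_", side)
  s <- mset$series
  if (is.null(s[[p_ar_name]]) || is.null(s[[q_name]]))
    stop("measurement set lacks ", p_ar_name, " or ", q_name)
  if (is.null(s[[p_ven_name]])) {
    # systemic venous pressure is rarely measured; fall back to the right
    # atrial catheter trace as the venous proxy
    if (side == "sys" && !is.null(s$p_at_r)) p_ven_name <- "p_at_r"
    else stop("measurement set lacks ", p_ven_name)
  }
  t0 <- mset$t0; Tc <- mset$T_cycl
  q_fun <- spline_series(s[[q_name]], periodic = TRUE, T_cycl = Tc)
  # sparse series (clinical flows) are interpolated; dense catheter traces
  # are smoothed before extrema/rate features are extracted, but only when
  # they actually carry noise (third-difference MAD noise estimate) —
  # cross-validated smoothing of a clean trace blunts the systolic kink
  p_spline <- function(ser) {
    noisy <- nrow(ser) > 100 &&
      stats::mad(diff(ser$value, differences = 3)) / sqrt(20) >
        1e-4 * max(abs(ser$value))
    if (noisy) smooth_periodic_series(ser, Tc)
    else spline_series(ser, periodic = TRUE, T_cycl = Tc)
  }
  p_ven_fun <- p_spline(s[[p_ven_name]])
  p_ar_fun <- p_spline(s[[p_ar_name]])
  grid <- seq(t0, t0 + Tc, length.out = 751)
  p_meas <- p_ar_fun(grid)
  dp_meas <- p_ar_fun(grid, deriv = 1)
  list(q_fun = q_fun, dq_fun = function(t) q_fun(t, deriv = 1),
       p_ven_fun = p_ven_fun,
       p_ar0 = p_ar_fun(t0), t0 = t0, t_end = t0 + Tc,
       p_meas_max = max(p_meas), p_meas_min = min(p_meas),
       p_meas_end = p_ar_fun(t0 + Tc), dp_meas_max = max(dp_meas))
}

# Ohmic initial guesses: R+Z from mean pressure drop over mean flow,
# Z = 0.1 R, C from the diastolic pulse-pressure decay time scale.
wk_initial_guess <- function(data) {
  grid <- seq(data$t0, data$t_end, length.out = 301)
  q_mean <- mean(pmax(0, data$q_fun(grid)))
  dp_mean <- mean(data$p_meas_max + data$p_meas_min) / 2 -
    mean(data$p_ven_fun(grid))
  RZ <- max(dp_mean / max(q_mean, 1), 1e-8)
  R <- RZ / 1.1; Z <- 0.1 * R
  # decay p ~ exp(-t/(RC)) over diastole: take RC ~ T/2
  C <- (data$t_end - data$t0) / 2 / R
  c(R_ar = R, C_ar = C, Z_ar = Z)
}

#' Fit arterial 3-element windkessel parameters
#'
#' Minimizes [windkessel_objective()] over `log(R_ar, C_ar, Z_ar)` with
#' L-BFGS-B. The forward model is the flow-eliminated pressure ODE driven
#' by splines of the measured valve flow and venous pressure, started at
#' the measured arterial pressure.
#'
#' @param mset a [measurement_set()].
#' @param side `"sys"` or `"pul"`.
#' @param init optional named numeric initial guess (`R_ar`, `C_ar`,
#'   `Z_ar`); Ohmic estimates by default.
#' @param dt forward time step, s.
#' @param maxit maximum objective evaluations.
#' @return object of class `wk_fit`: `phi` (named parameters), `objective`,
#'   `trace` (per-evaluation objective), `converged`, `fitted` (data frame
#'   `t`, `p_ar`), `side`.
#' @export
fit_arterial_windkessel <- function(mset, side = c("sys", "pul"),
                                    init = NULL, dt = 1e-3, maxit = 500L) {
  side <- match.arg(side)
  data <- wk_prepare_data(mset, side)
  if (is.null(init)) init <- wk_initial_guess(data)
  if (any(init <= 0)) stop("initial guess must be positive")
  trace <- numeric(0)
  fn <- function(lp) {
    phi <- stats::setNames(exp(lp), c("R_ar", "C_ar", "Z_ar"))
    f <- wk_forward_terms(phi, data, dt, theta = 0.5)
    val <- wk_objective_terms(f, data)
    trace[length(trace) + 1] <<- val
    val
  }
  opt <- stats::optim(log(init[c("R_ar", "C_ar", "Z_ar")]), fn,
                      method = "L-BFGS-B",
                      control = list(maxit = maxit, factr = 10))
  phi <- stats::setNames(exp(opt$par), c("R_ar", "C_ar", "Z_ar"))
  f <- wk_forward_terms(phi, data, dt, theta = 0.5)
  structure(list(phi = phi, objective = opt$value, trace = trace,
                 converged = opt$convergence == 0 && opt$value <= trace[1],
                 fitted = data.frame(t = f$sol$t, p_ar = f$sol$p_ar),
                 side = side, n_eval = length(trace)),
            class = "wk_fit")
}

#' @export
print.wk_fit <- function(x, ...) {
  cat(sprintf("3-element windkessel fit (%s side)\n", x$side))
  cat(sprintf("  R_ar = %.4g  C_ar = %.4g  Z_ar = %.4g\n",
              x$phi[["R_ar"]], x$phi[["C_ar"]], x$phi[["Z_ar"]]))
  cat(sprintf("  objective %.3e after %d evaluations (%s)\n", x$objective,
              x$n_eval, if (x$converged) "converged" else "not converged"))
  invisible(x)
}

#' @export
coef.wk_fit <- function(object, ...) object$phi

#' @export
plot.wk_fit <- function(x, mset = NULL, ...) {
  graphics::plot(x$fitted$t, x$fitted$p_ar, type = "l", xlab = "t [s]",
                 ylab = "p_ar [kPa]",
                 main = sprintf("windkessel fit (%s)", x$side), ...)
  if (!is.null(mset)) {
    s <- mset$series[[paste0("p_ar_", x$side)]]
    graphics::points(s$t, s$value, pch = 16, cex = 0.5, col = 2)
  }
  invisible(x)
}
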