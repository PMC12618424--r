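# Identification of semilunar valve effective orifice areas from measured
# transvalvular pressure gradient and flow: the forward problem marches
# the valve flow/state ODE pair under the prescribed gradient; the
# objective matches cycle-integrated forward and backward volumes.

#' Forward and backward volumes of a flow series
#'
#' `V_for` integrates the positive part of the flow over the cycle,
#' `V_back` the magnitude of the negative part (reported positive).
#'
#' @param q_series data frame `t` (s), `value` (flow, mm^3/s or ml/s —
#'   output units follow input units).
#' @return named numeric `c(V_for, V_back)`.
#' @export
forward_backward_volumes <- function(q_series) {
  tt <- q_series$t; q <- q_series$value
  c(V_for = trapz(tt, pmax(0, q)), V_back = abs(trapz(tt, pmin(0, q))))
}

# prescribed-gradient data for one valve
valve_prepare_data <- function(mset, valve = c("aor", "pul")) {
  valve <- match.arg(valve)
  s <- mset$series
  pv_name <- if (valve == "aor") "p_v_l" else "p_v_r"
  par_name <- if (valve == "aor") "p_ar_sys" else "p_ar_pul"
  q_name <- if (valve == "aor") "q_v_out_l" else "q_v_out_r"
  if (is.null(s[[pv_name]]) || is.null(s[[par_name]]) || is.null(s[[q_name]]))
    stop("measurement set lacks ", pv_name, ", ", par_name, " or ", q_name)
  t0 <- mset$t0; Tc <- mset$T_cycl
  # the two pressures may be sampled on different grids (non-simultaneous
  # catheter runs): spline each and difference on a common grid
  pv <- spline_series(s[[pv_name]], periodic = TRUE, T_cycl = Tc)
  pa <- spline_series(s[[par_name]], periodic = TRUE, T_cycl = Tc)
  dp_fun <- function(t, deriv = 0) pv(t, deriv) - pa(t, deriv)
  attr(dp_fun, "t_range") <- c(-Inf, Inf)
  # measured volumes from the cubic-spline interpolant of the measured
  # flow (clinical flows are sparse; integrating the raw samples with the
  # trapezoid rule would bias the targets)
  qf <- spline_series(s[[q_name]], periodic = TRUE, T_cycl = Tc)
  grid <- seq(t0, t0 + Tc, length.out = 1501)
  vol <- forward_backward_volumes(data.frame(t = grid, value = qf(grid)))
  # a regurgitant valve is open to leakage at cycle start: initialize the
  # flow from the measurement, the state from closed (diastasis)
  list(dp_fun = dp_fun, t0 = t0, t_end = t0 + Tc,
       V_for_meas = vol[["V_for"]], V_back_meas = vol[["V_back"]],
       q0 = qf(t0), zeta0 = 0, dp_scale = max(abs(dp_fun(grid))))
}

#' Valve effective-orifice-area objective
#'
#' Simulates the valve under the measured transvalvular gradient (closed
#' initial conditions `q = 0`, `zeta = 0` at cycle start) and returns the
#' squared mismatch of forward and backward volumes against the measured
#' flow integrals, in ml^2.
#'
#' @param phi named numeric `A_eff_max`, `A_eff_min` (mm^2).
#' @param mset a [measurement_set()].
#' @param valve `"aor"` or `"pul"`.
#' @param fixed a [valve_params] supplying `K_vo`, `K_vc`, `l_eff`, `rho`.
#' @param dt forward step, s.
#' @return scalar objective, ml^2.
#' @export
valve_objective <- function(phi, mset, valve = c("aor", "pul"),
                            fixed = NULL, dt = 1e-3) {
  valve <- match.arg(valve)
  data <- valve_prepare_data(mset, valve)
  if (is.null(fixed)) fixed <- default_valve_generics(valve)
  valve_objective_data(phi, data, fixed, dt)
}

valve_objective_data <- function(phi, data, fixed, dt) {
  vp <- fixed
  vp$A_eff_max <- max(phi[["A_eff_max"]], A_EFF_FLOOR)
  vp$A_eff_min <- min(max(phi[["A_eff_min"]], 0), vp$A_eff_max)
  sim <- simulate_valve_prescribed_dp(data$dp_fun, vp, data$t0, data$t_end,
                                      dt = dt,
                                      q0 = clamp_valve_q0(data$q0, vp, data),
                                      zeta0 = data$zeta0)
  vol <- forward_backward_volumes(data.frame(t = sim$t, value = sim$q))
  ((vol[["V_for"]] - data$V_for_meas) / ML)^2 +
    ((vol[["V_back"]] - data$V_back_meas) / ML)^2
}

# The measured flow at cycle start belongs to the true valve; a trial
# valve with a smaller minimum orifice cannot carry it, and forcing it as
# an initial condition makes the trapezoidal scheme ring. Clamp to the
# trial valve's steady-Bernoulli capacity at the cycle's peak gradient
# magnitude (a no-op whenever the initial condition is physically
# consistent; the instantaneous gradient is unusable because cycle start
# sits near a gradient zero crossing).
clamp_valve_q0 <- function(q0, vp, data) {
  A0 <- max(vp$A_eff_min, A_EFF_FLOOR)
  cap <- A0 * sqrt(2 * max(data$dp_scale, 1e-3) / vp$rho)
  sign(q0) * min(abs(q0), cap)
}

# generic opening/closing rates, effective lengths and blood density
default_valve_generics <- function(valve) {
  switch(valve,
         aor = valve_params(0, 141, K_vo = 120, K_vc = 120, l_eff = 39),
         pul = valve_params(0, 308, K_vo = 200, K_vc = 200, l_eff = 61),
         mit = valve_params(0, 288, K_vo = 300, K_vc = 400, l_eff = 54),
         tri = valve_params(0, 346, K_vo = 300, K_vc = 400, l_eff = 63))
}

#' Fit semilunar valve effective orifice areas
#'
#' L-BFGS-B minimization of [valve_objective()] over the logarithms of
#' `A_eff_max` and (shifted) `A_eff_min`. With two parameters matching
#' the two volume targets, the minimum is typically an exact match.
#'
#' @param mset a [measurement_set()].
#' @param valve `"aor"` or `"pul"`.
#' @param init optional named numeric `A_eff_max`, `A_eff_min` (mm^2).
#' @param fixed a [valve_params] for the generic rates; defaults per
#'   valve.
#' @param dt forward step, s.
#' @param maxit maximum evaluations.
#' @return object of class `valve_fit`: `phi`, `objective` (ml^2),
#'   `volumes` (fitted V_for/V_back, ml), `measured` (targets, ml),
#'   `fitted` (data frame `t`, `q`, `zeta`), `converged`.
#' @export
fit_valve_eoa <- function(mset, valve = c("aor", "pul"), init = NULL,
                          fixed = NULL, dt = 1e-3, maxit = 300L) {
  valve <- match.arg(valve)
  data <- valve_prepare_data(mset, valve)
  if (is.null(fixed)) fixed <- default_valve_generics(valve)
  if (is.null(init)) {
    # steady-Bernoulli guesses: A ~ q / sqrt(2 dp / rho) at the flow peaks
    grid <- seq(data$t0, data$t_end, length.out = 301)
    dp <- data$dp_fun(grid)
    A_max0 <- 1.3 * data$V_for_meas /
      max(1e-6, trapz(grid, sqrt(2 * pmax(0, dp) / fixed$rho)))
    A_min0 <- data$V_back_meas /
      max(1e-6, trapz(grid, sqrt(2 * pmax(0, -dp) / fixed$rho)))
    init <- c(A_eff_max = max(A_max0, 10), A_eff_min = max(A_min0, 0.05))
  }
  # A_min is optimized as log(A_min + eps) so a competent valve (A_min = 0)
  # sits at a finite coordinate
  eps <- 0.05
  trace <- numeric(0)
  fn <- function(lp) {
    phi <- c(A_eff_max = exp(lp[1]), A_eff_min = exp(lp[2]) - eps)
    val <- valve_objective_data(phi, data, fixed, dt)
    trace[length(trace) + 1] <<- val
    val
  }
  opt <- stats::optim(c(log(init[["A_eff_max"]]), log(init[["A_eff_min"]] + eps)),
                      fn, method = "L-BFGS-B",
                      lower = c(log(1), log(eps / 10)),
                      control = list(maxit = maxit, factr = 10))
  phi <- c(A_eff_max = exp(opt$par[1]), A_eff_min = max(0, exp(opt$par[2]) - eps))
  vp <- fixed
  vp$A_eff_max <- phi[["A_eff_max"]]; vp$A_eff_min <- phi[["A_eff_min"]]
  sim <- simulate_valve_prescribed_dp(data$dp_fun, vp, data$t0, data$t_end,
                                      dt = dt,
                                      q0 = clamp_valve_q0(data$q0, vp, data))
  vol <- forward_backward_volumes(data.frame(t = sim$t, value = sim$q)) / ML
  structure(list(phi = phi, objective = opt$value,
                 volumes = vol,
                 measured = c(V_for = data$V_for_meas, V_back = data$V_back_meas) / ML,
                 fitted = data.frame(t = sim$t, q = sim$q, zeta = sim$zeta),
                 converged = opt$convergence == 0, valve = valve,
                 n_eval = length(trace)),
            class = "valve_fit")
}

#' @export
print.valve_fit <- function(x, ...) {
  cat(sprintf("valve EOA fit (%s)\n", x$valve))
  cat(sprintf("  A_eff_max = %.4g mm^2, A_eff_min = %.4g mm^2\n",
              x$phi[["A_eff_max"]], x$phi[["A_eff_min"]]))
  cat(sprintf("  V_for %.2f (meas %.2f) ml, V_back %.2f (meas %.2f) ml\n",
              x$volumes[["V_for"]], x$measured[["V_for"]],
              x$volumes[["V_back"]], x$measured[["V_back"]]))
  invisible(x)
}

#' @export
coef.valve_fit <- function(object, ...) object$phi

#' @export
plot.valve_fit <- function(x, mset = NULL, ...) {
  graphics::plot(x$fitted$t, x$fitted$q / ML, type = "l", xlab = "t [s]",
                 ylab = "q [ml/s]", main = sprintf("valve fit (%s)", x$valve),
                 ...)
  if (!is.null(mset)) {
    nm <- if (x$valve == "aor") "q_v_out_l" else "q_v_out_r"
    s <- mset$series[[nm]]
    graphics::points(s$t, s$value / ML, pch = 16, cex = 0.5, col = 2)
  }
  invisible(x)
}
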