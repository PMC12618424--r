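# Windkessel compartments: residual evaluation and time discretization.
#
# ODE (mass) rows are One-Step-theta blended; derivative-free (momentum)
# rows are algebraic and are enforced at the new time level by the coupled
# solver. The standalone residual functions below return both rows so the
# discrete equations can be checked in isolation.

#' One-Step-theta residual of a 3-element arterial windkessel
#'
#' Mass balance `C (dp_ar/dt - Z dq_valve/dt) - q_valve + q_ar = 0` and
#' momentum balance `(p_ven - p_ar + Z q_valve)/R + q_ar = 0` of an
#' arterial compartment fed by a semilunar valve flow `q_valve` and drained
#' by the distal flow `q_ar`.
#'
#' @param state_now,state_prev named numeric with `p_ar`, `q_ar`, `p_ven`
#'   (kPa, mm^3/s, kPa) at the new and old time level.
#' @param q_valve_now,q_valve_prev valve flow at the two levels, mm^3/s.
#' @param params list with `C_ar`, `R_ar`, `Z_ar` (a [windkessel_params]
#'   works).
#' @param dt time step, s.
#' @param theta One-Step-theta weight in (0, 1].
#' @return numeric `c(mass, momentum)`; zero iff the discrete equations
#'   hold. The momentum row is evaluated at the new level (algebraic).
#' @export
wk3_residual <- function(state_now, state_prev, q_valve_now, q_valve_prev,
                         params, dt, theta = 0.5) {
  if (!is.finite(dt) || dt <= 0) stop("dt must be positive")
  vals <- c(unlist(state_now), unlist(state_prev), q_valve_now, q_valve_prev)
  if (any(!is.finite(vals))) stop("non-finite state")
  flux <- function(s, qv) -qv + s[["q_ar"]]
  mass <- params$C_ar * ((state_now[["p_ar"]] - state_prev[["p_ar"]]) / dt -
                         params$Z_ar * (q_valve_now - q_valve_prev) / dt) +
    theta * flux(state_now, q_valve_now) +
    (1 - theta) * flux(state_prev, q_valve_prev)
  mom <- (state_now[["p_ven"]] - state_now[["p_ar"]] +
            params$Z_ar * q_valve_now) / params$R_ar + state_now[["q_ar"]]
  c(mass = unname(mass), momentum = unname(mom))
}

#' One-Step-theta residual of a 2-element venous windkessel
#'
#' Mass balance `C dp_ven/dt - q_in + q_ven = 0` and momentum balance
#' `(p_atrium - p_ven)/R + q_ven = 0` of a venous compartment fed by the
#' upstream arterial flow `q_in` and draining into an atrium.
#'
#' @param state_now,state_prev named numeric with `p_ven`, `q_ven`.
#' @param q_in_now,q_in_prev inflow at the two levels, mm^3/s.
#' @param p_atrium_now downstream atrial pressure at the new level, kPa.
#' @param params list with `C_ven`, `R_ven`.
#' @inheritParams wk3_residual
#' @return numeric `c(mass, momentum)`.
#' @export
wk2_residual <- function(state_now, state_prev, q_in_now, q_in_prev,
                         p_atrium_now, params, dt, theta = 0.5) {
  if (!is.finite(dt) || dt <= 0) stop("dt must be positive")
  vals <- c(unlist(state_now), unlist(state_prev), q_in_now, q_in_prev)
  if (any(!is.finite(vals))) stop("non-finite state")
  flux <- function(s, qi) -qi + s[["q_ven"]]
  mass <- params$C_ven * (state_now[["p_ven"]] - state_prev[["p_ven"]]) / dt +
    theta * flux(state_now, q_in_now) + (1 - theta) * flux(state_prev, q_in_prev)
  mom <- (p_atrium_now - state_now[["p_ven"]]) / params$R_ven +
    state_now[["q_ven"]]
  c(mass = unname(mass), momentum = unname(mom))
}

#' Advance the flow-eliminated arterial pressure ODE by one step
#'
#' The arterial-windkessel inverse subproblem eliminates the distal flow
#' variable and solves the scalar ODE
#' `C R dp/dt + p - p_ven(t) - (R+Z) q(t) - Z C R dq/dt = 0`
#' for the arterial pressure, with the valve flow `q(t)`, its spline
#' derivative, and the venous pressure prescribed from measurements.
#'
#' @param p_ar_prev pressure at `t_prev`, kPa.
#' @param q_fun,p_ven_fun functions of time returning the prescribed flow
#'   (mm^3/s) and venous pressure (kPa); see [spline_series()].
#' @param dq_fun function of time: analytic derivative of the flow spline.
#' @param params list with `C_ar`, `R_ar`, `Z_ar`.
#' @param t_prev start time of the step, s.
#' @param dt step size, s.
#' @param theta One-Step-theta weight.
#' @return `p_ar` at `t_prev + dt`, kPa.
#' @export
wk3_pressure_ode_step <- function(p_ar_prev, q_fun, p_ven_fun, dq_fun,
                                  params, t_prev, dt, theta = 0.5) {
  if (dt <= 0) stop("dt must be positive")
  C <- params$C_ar; R <- params$R_ar; Z <- params$Z_ar
  rhs <- function(t) p_ven_fun(t) + (R + Z) * q_fun(t) + Z * C * R * dq_fun(t)
  tn <- t_prev + dt
  for (f in list(q_fun, p_ven_fun)) {
    rng <- attr(f, "t_range")
    if (!is.null(rng) && (t_prev < rng[1] - 1e-9 || tn > rng[2] + 1e-9))
      stop("prescribed series does not cover [t_prev, t_prev + dt]")
  }
  # C R (p+ - p)/dt + theta (p+ - rhs(tn)) + (1-theta)(p - rhs(t)) = 0
  a <- C * R / dt
  (a * p_ar_prev + theta * rhs(tn) - (1 - theta) * (p_ar_prev - rhs(t_prev))) /
    (a + theta)
}

#' Solve the flow-eliminated arterial pressure ODE over an interval
#'
#' Repeatedly applies [wk3_pressure_ode_step()] on a uniform grid with the
#' measured initial condition `p_ar(t0)`.
#'
#' @inheritParams wk3_pressure_ode_step
#' @param p_ar0 initial pressure, kPa.
#' @param t0,t_end integration interval, s.
#' @param dt step size, s (last step shortened to hit `t_end`).
#' @return list with `t` (grid) and `p_ar` (trajectory).
#' @export
wk3_pressure_ode_solve <- function(p_ar0, q_fun, p_ven_fun, dq_fun, params,
                                   t0, t_end, dt = 1e-3, theta = 0.5) {
  n <- ceiling((t_end - t0) / dt - 1e-12)
  tt <- t0 + c(0, seq_len(n)) * dt
  tt[n + 1] <- t_end
  C <- params$C_ar; R <- params$R_ar; Z <- params$Z_ar
  rhs <- p_ven_fun(tt) + (R + Z) * q_fun(tt) + Z * C * R * dq_fun(tt)
  p <- numeric(n + 1)
  p[1] <- p_ar0
  a <- C * R / dt
  for (k in seq_len(n)) {
    dtk <- tt[k + 1] - tt[k]
    ak <- C * R / dtk
    p[k + 1] <- (ak * p[k] + theta * rhs[k + 1] -
                   (1 - theta) * (p[k] - rhs[k])) / (ak + theta)
  }
  list(t = tt, p_ar = p)
}
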