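# Mynard-type dynamic Bernoulli valve: pressure-flow residual,
# effective-orifice interpolation, valve-state dynamics, and standalone
# time marching under a prescribed transvalvular pressure gradient.

# Floor for the effective area inside 1/A and 1/A^2 terms: keeps the
# Newton Jacobian finite for fully sealing valves (A_eff_min = 0).
A_EFF_FLOOR <- 1e-4

#' Effective orifice area at a given valve state
#'
#' Linear interpolation `A_eff = (A_max - A_min) * zeta + A_min` between
#' the closed (`zeta = 0`) and fully open (`zeta = 1`) configurations.
#'
#' @param zeta valve state in `[0, 1]`.
#' @param params a [valve_params] object (or list with `A_eff_min`,
#'   `A_eff_max`).
#' @return effective orifice area, mm^2.
#' @export
effective_area <- function(zeta, params) {
  if (any(zeta < -1e-12 | zeta > 1 + 1e-12)) stop("zeta must lie in [0, 1]")
  (params$A_eff_max - params$A_eff_min) * zeta + params$A_eff_min
}

# floored area used inside 1/A terms
effective_area_floored <- function(zeta, params)
  pmax(effective_area(zeta, params), A_EFF_FLOOR)

#' One-Step-theta residual of the Bernoulli valve momentum equation
#'
#' Discrete residual of
#' `dp = rho/(2 A_eff^2) q |q| + (rho l_eff / A_eff) dq/dt`,
#' with the inertia coefficient evaluated at the new valve state and the
#' convective/pressure terms theta-blended. The `q |q|` form preserves the
#' flow sign, so reverse (regurgitant) flow satisfies the same relation.
#'
#' @param dp_now,dp_prev transvalvular pressure gradient at the two time
#'   levels, kPa.
#' @param q_now,q_prev flow, mm^3/s.
#' @param zeta_now,zeta_prev valve state.
#' @param params a [valve_params] object.
#' @param dt time step, s.
#' @param theta One-Step-theta weight.
#' @return scalar residual (kPa); zero iff the discrete equation holds.
#' @export
valve_momentum_residual <- function(dp_now, dp_prev, q_now, q_prev,
                                    zeta_now, zeta_prev, params, dt,
                                    theta = 0.5) {
  if (dt <= 0) stop("dt must be positive")
  A_now <- effective_area_floored(zeta_now, params)
  A_prev <- effective_area_floored(zeta_prev, params)
  g <- function(dp, q, A) dp - params$rho / (2 * A^2) * q * abs(q)
  params$rho * params$l_eff / A_now * (q_now - q_prev) / dt -
    theta * g(dp_now, q_now, A_now) -
    (1 - theta) * g(dp_prev, q_prev, A_prev)
}

#' Valve opening/closing rate
#'
#' `dzeta/dt = (1 - zeta) K_vo dp` while the gradient is positive and
#' `zeta K_vc dp` otherwise (the `dp = 0` case uses the closing branch, as
#' printed). The saturating form keeps `zeta` inside `[0, 1]`.
#'
#' @param zeta valve state in `[0, 1]`.
#' @param dp transvalvular pressure gradient, kPa.
#' @param params a [valve_params] object.
#' @return rate `dzeta/dt`, s^-1.
#' @export
valve_state_rate <- function(zeta, dp, params) {
  if (any(zeta < -1e-12 | zeta > 1 + 1e-12)) stop("zeta must lie in [0, 1]")
  ifelse(dp > 0, (1 - zeta) * params$K_vo * dp, zeta * params$K_vc * dp)
}

#' Simulate a valve under a prescribed pressure gradient
#'
#' Time-marches the coupled flow/state ODE pair with the transvalvular
#' gradient prescribed from data, using the One-Step-theta scheme: the
#' valve-state update is linear per step; the momentum equation is solved
#' per step with a damped scalar Newton iteration (`q|q|` linearized as
#' `2 |q| dq`). This is the forward problem of the valve inverse
#' subproblem; when the valve is closed at `t0` the initial conditions are
#' `q = 0`, `zeta = 0`.
#'
#' @param dp_fun function of time returning the prescribed gradient, kPa
#'   (see [spline_series()]); evaluated on the whole grid up front.
#' @param params a [valve_params] object.
#' @param t0,t_end simulation interval, s.
#' @param dt time step, s.
#' @param q0,zeta0 initial flow (mm^3/s) and state.
#' @param theta One-Step-theta weight.
#' @return list with `t`, `q` (mm^3/s), `zeta`.
#' @export
simulate_valve_prescribed_dp <- function(dp_fun, params, t0, t_end,
                                         dt = 1e-3, q0 = 0, zeta0 = 0,
                                         theta = 0.5) {
  rng <- attr(dp_fun, "t_range")
  if (!is.null(rng) && (t0 < rng[1] - 1e-9 || t_end > rng[2] + 1e-9))
    stop("dp series does not cover the simulation interval")
  n <- round((t_end - t0) / dt)
  tt <- t0 + (0:n) * dt
  dp <- dp_fun(tt)
  if (any(!is.finite(dp))) stop("dp series has gaps on the simulation interval")
  q <- numeric(n + 1); z <- numeric(n + 1)
  q[1] <- q0; z[1] <- zeta0
  rho <- params$rho; l <- params$l_eff
  for (k in seq_len(n)) {
    zp <- z[k]
    # state update: dzeta/dt is linear in zeta within a branch; the branch
    # is chosen per time level from the prescribed gradient sign
    r_prev <- valve_state_rate(zp, dp[k], params)
    if (dp[k + 1] > 0) {
      a <- params$K_vo * dp[k + 1]
      zn <- (zp + dt * (theta * a + (1 - theta) * r_prev)) / (1 + dt * theta * a)
    } else {
      a <- params$K_vc * dp[k + 1]
      zn <- (zp + dt * (1 - theta) * r_prev) / (1 - dt * theta * a)
    }
    z[k + 1] <- min(1, max(0, zn))
    A_now <- effective_area_floored(z[k + 1], params)
    A_prev <- effective_area_floored(zp, params)
    g_prev <- dp[k] - rho / (2 * A_prev^2) * q[k] * abs(q[k])
    inert <- rho * l / A_now / dt
    resid <- function(qq) inert * (qq - q[k]) -
      theta * (dp[k + 1] - rho / (2 * A_now^2) * qq * abs(qq)) -
      (1 - theta) * g_prev
    qn <- q[k]
    rn <- resid(qn)
    for (it in 1:60) {
      if (abs(rn) < 1e-10 * max(1, abs(dp[k + 1]))) break
      jac <- inert + theta * rho / A_now^2 * abs(qn)
      dq <- -rn / jac
      # backtrack on the |q| linearization until the residual decreases
      lam <- 1
      for (h in 1:30) {
        rt <- resid(qn + lam * dq)
        if (abs(rt) < abs(rn)) break
        lam <- lam / 2
      }
      qn <- qn + lam * dq
      rn <- resid(qn)
    }
    q[k + 1] <- qn
  }
  list(t = tt, q = q, zeta = z)
}
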