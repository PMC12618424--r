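# Active-stress generation and the 0D pressure-volume chamber surrogate.
#
# The activation is a trapezoid regularized by the parameter K: zero until
# c1 - 1/K, a linear ramp to 1 at c1, a plateau until c2, and a linear
# decay back to zero at c2 + 1/K, with
#   c1 = t_contr + alpha_max / (K (alpha_max - alpha_min)),
#   c2 = t_relax - alpha_max / (K (alpha_max - alpha_min)).
# It is extended periodically with period T_cycl; because c1 - 1/K can be
# negative (atrial contraction begins at cycle start), the evaluation sums
# the base trapezoid over neighboring period shifts.

activation_centers <- function(params) {
  D <- params$alpha_max - params$alpha_min
  off <- params$alpha_max / (params$K * D)
  c(c1 = params$t_contr + off, c2 = params$t_relax - off)
}

# base (non-periodic) trapezoid and its indicator functions
activation_base <- function(t, c1, c2, K) {
  up <- (t > c1 - 1 / K) & (t < c1)
  plateau <- (t >= c1) & (t <= c2)
  down <- (t > c2) & (t < c2 + 1 / K)
  f <- numeric(length(t))
  f[up] <- K * (t[up] - c1) + 1
  f[plateau] <- 1
  f[down] <- 1 - K * (t[down] - c2)
  list(f = f, up = up, down = down)
}

#' Normalized activation function
#'
#' Trapezoidal activation in `[0, 1]`, periodic with period `T_cycl`.
#'
#' @param t time, s (any real; reduced modulo the cycle).
#' @param params an [active_stress_params] object.
#' @return activation value(s) in `[0, 1]`.
#' @export
activation <- function(t, params) {
  activation_partials(t, params)$f
}

#' Activation with sensitivities to the rate parameters
#'
#' Returns the activation and its partial derivatives with respect to
#' `alpha_max` and `alpha_min`, which enter through the ramp centers
#' `c1`, `c2`. Needed by the discrete adjoint of the active-stress
#' identification.
#'
#' @inheritParams activation
#' @return list with `f`, `df_damax`, `df_damin` (vectors along `t`).
#' @export
activation_partials <- function(t, params) {
  cc <- activation_centers(params)
  K <- params$K; Tc <- params$T_cycl
  D <- params$alpha_max - params$alpha_min
  tloc <- (t - 0) %% Tc
  f <- numeric(length(t)); up <- logical(length(t)); down <- logical(length(t))
  for (s in c(-Tc, 0, Tc)) {
    b <- activation_base(tloc + s, cc[["c1"]], cc[["c2"]], K)
    f <- f + b$f
    up <- up | b$up
    down <- down | b$down
  }
  # d c1 / d alpha_max = -alpha_min/(K D^2); d c2/d alpha_max = +alpha_min/(K D^2)
  # d c1 / d alpha_min = +alpha_max/(K D^2); d c2/d alpha_min = -alpha_max/(K D^2)
  # df/dc1 = -K on the up ramp, df/dc2 = +K on the down ramp
  df_damax <- (params$alpha_min / D^2) * (up + down)
  df_damin <- -(params$alpha_max / D^2) * (up + down)
  list(f = pmin(1, pmax(0, f)), df_damax = df_damax, df_damin = df_damin)
}

#' Transmembrane potential driving the active stress
#'
#' `u = f_hat * alpha_max + (1 - f_hat) * alpha_min`, so `u` sweeps from
#' the relaxation rate (rest) to the upstroke rate (full activation).
#'
#' @inheritParams activation
#' @return potential `u`, s^-1.
#' @export
transmembrane_potential <- function(t, params) {
  f <- activation(t, params)
  f * params$alpha_max + (1 - f) * params$alpha_min
}

# u plus its partials wrt (sigma_0, alpha_max, alpha_min); sigma_0 does not
# enter u, it enters the stress ODE source directly.
transmembrane_potential_partials <- function(t, params) {
  a <- activation_partials(t, params)
  D <- params$alpha_max - params$alpha_min
  list(u = a$f * params$alpha_max + (1 - a$f) * params$alpha_min,
       du_damax = a$f + D * a$df_damax,
       du_damin = (1 - a$f) + D * a$df_damin)
}

#' Active fiber stress rate
#'
#' `dtau/dt = -|u| tau + sigma_0 max(0, u)`: relaxation at rate `|u|`
#' toward the equilibrium `sigma_0` while `u > 0`, exponential decay to
#' zero while `u <= 0`. `tau` stays in `[0, sigma_0]` for admissible
#' initial data.
#'
#' @param tau current active stress, kPa.
#' @param u transmembrane potential, s^-1.
#' @param sigma_0 contractility, kPa.
#' @return rate `dtau/dt`, kPa/s.
#' @export
active_stress_rate <- function(tau, u, sigma_0) {
  -abs(u) * tau + sigma_0 * pmax(0, u)
}

# One-Step-theta integration of the active stress ODE on a fixed grid.
# The ODE is decoupled from the circulation state (u depends only on t),
# so the whole trajectory is a scalar linear recursion.
integrate_active_stress <- function(params, t_grid, tau0 = 0, theta = 0.5) {
  u <- transmembrane_potential(t_grid, params)
  n <- length(t_grid)
  tau <- numeric(n)
  tau[1] <- tau0
  au <- abs(u); su <- params$sigma_0 * pmax(0, u)
  for (k in seq_len(n - 1)) {
    dt <- t_grid[k + 1] - t_grid[k]
    tau[k + 1] <- (tau[k] * (1 - dt * (1 - theta) * au[k]) +
                     dt * (theta * su[k + 1] + (1 - theta) * su[k])) /
      (1 + dt * theta * au[k + 1])
  }
  tau
}

#' Chamber pressure from volume and active stress
#'
#' Surrogate pressure-volume law
#' `p = E_pass_a (exp(E_pass_b (V - V_ref)) - 1)
#'      + wall_factor * tau * (V / V_ref)^(1/3)`:
#' an exponential passive end-diastolic relation that vanishes at `V_ref`,
#' plus an active term proportional to the fiber stress with a mild
#' Laplace-type volume dependence, normalized so the active pressure at
#' the reference volume is `wall_factor * tau`. Strictly increasing in
#' both `V` and `tau` and C^1 on `V > 0`.
#'
#' @param V chamber volume, mm^3 (positive).
#' @param tau active fiber stress, kPa.
#' @param params a [chamber_surrogate_params] object.
#' @param deriv if `TRUE`, also return `dp_dV` and `dp_dtau`.
#' @return pressure (kPa), or a list with partials when `deriv = TRUE`.
#' @export
chamber_pressure <- function(V, tau, params, deriv = FALSE) {
  if (any(V <= 0)) stop("chamber volume must be positive")
  e <- exp(params$E_pass_b * (V - params$V_ref))
  ratio <- (V / params$V_ref)^(1 / 3)
  p <- params$E_pass_a * (e - 1) + params$wall_factor * tau * ratio
  if (!deriv) return(p)
  list(p = p,
       dp_dV = params$E_pass_a * params$E_pass_b * e +
         params$wall_factor * tau * ratio / (3 * V),
       dp_dtau = params$wall_factor * ratio)
}

#' Chamber mass-balance residual
#'
#' Kinematic coupling condition `dV/dt - q_in + q_out = 0` for a chamber
#' with inflow `q_in` and outflow `q_out` (for an atrium the inflow is the
#' venous return and the outflow the atrioventricular valve flow).
#'
#' @param dVdt volume rate, mm^3/s.
#' @param q_in,q_out inflow and outflow, mm^3/s.
#' @return scalar residual, mm^3/s.
#' @export
chamber_mass_residual <- function(dVdt, q_in, q_out) {
  dVdt - q_in + q_out
}
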