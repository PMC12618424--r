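# Monolithic implicit time stepping of the coupled 0D system:
# circulation compartments + four dynamic Bernoulli valves + four
# active-stress chamber surrogates. The 28-entry state stacks the 20
# circulation primary variables (pressures, flows, valve states), the four
# chamber volumes and the four active stresses. ODE rows are One-Step-theta
# blended; derivative-free rows (windkessel momentum balances, chamber
# pressure closures) are enforced at the new time level, which makes the
# scheme exactly trapezoidal on the reduced ODE for theta = 0.5.

STATE_NAMES <- c("p_at_l", "q_mit", "z_mit", "q_aor", "z_aor", "p_v_l",
                 "p_ar_sys", "q_ar_sys", "p_ven_sys", "q_ven_sys",
                 "p_at_r", "q_tri", "z_tri", "q_pul", "z_pul", "p_v_r",
                 "p_ar_pul", "q_ar_pul", "p_ven_pul", "q_ven_pul",
                 "V_at_l", "V_v_l", "V_at_r", "V_v_r",
                 "tau_at_l", "tau_v_l", "tau_at_r", "tau_v_r")
N_STATE <- 28L

# index helpers (match STATE_NAMES)
iS <- as.list(seq_len(N_STATE))
names(iS) <- STATE_NAMES

# per-valve wiring: flow, state, upstream and downstream pressure indices
VALVE_WIRING <- list(
  mit = c(q = 2L,  z = 3L,  up = 1L,  dn = 6L),
  aor = c(q = 4L,  z = 5L,  up = 6L,  dn = 7L),
  tri = c(q = 12L, z = 13L, up = 11L, dn = 16L),
  pul = c(q = 14L, z = 15L, up = 16L, dn = 17L))

# per-chamber wiring: volume, stress, pressure, inflow, outflow indices
CHAMBER_WIRING <- list(
  la = c(V = 21L, tau = 25L, p = 1L,  q_in = 20L, q_out = 2L),
  lv = c(V = 22L, tau = 26L, p = 6L,  q_in = 2L,  q_out = 4L),
  ra = c(V = 23L, tau = 27L, p = 11L, q_in = 10L, q_out = 12L),
  rv = c(V = 24L, tau = 28L, p = 16L, q_in = 12L, q_out = 14L))

# typical magnitudes used for diagonal scaling of the Newton residual
STATE_SCALES <- c(rep(c(1, 1e4, 1, 1e4, 1, 1, 1, 1e4, 1, 1e4), 2),
                  rep(1e4, 4), rep(1, 4))

# ---- residual assembly -------------------------------------------------

# Core assembly. xn/xp: state vectors at the new/old level. un/up_: lists
# with per-chamber |u| and sigma_0 |u|_+ at the two levels (order
# la, lv, ra, rv). branch: optional logical[4] freezing the valve branch
# (TRUE = opening) at the new level; default derives it from xn.
assemble_core <- function(xn, xp, params, dt, theta, un, up_,
                          branch = NULL, want_jac = FALSE) {
  if (any(!is.finite(xn)) || any(!is.finite(xp)))
    stop("non-finite state in residual assembly")
  r <- numeric(N_STATE)
  A <- if (want_jac) matrix(0, N_STATE, N_STATE) else NULL
  B <- if (want_jac) matrix(0, N_STATE, N_STATE) else NULL
  th1 <- 1 - theta

  # valves: rows 1-8 (momentum, state) x (mit, aor, tri, pul)
  for (vi in seq_along(VALVE_WIRING)) {
    w <- VALVE_WIRING[[vi]]
    vp <- params$valves[[names(VALVE_WIRING)[vi]]]
    qi <- w[["q"]]; zi <- w[["z"]]; ui <- w[["up"]]; di <- w[["dn"]]
    dpn <- xn[ui] - xn[di]; dpp <- xp[ui] - xp[di]
    dA <- vp$A_eff_max - vp$A_eff_min
    An_raw <- dA * xn[zi] + vp$A_eff_min
    Ap_raw <- dA * xp[zi] + vp$A_eff_min
    An <- max(An_raw, A_EFF_FLOOR); Ap <- max(Ap_raw, A_EFF_FLOOR)
    dAdz_n <- if (An_raw > A_EFF_FLOOR) dA else 0
    dAdz_p <- if (Ap_raw > A_EFF_FLOOR) dA else 0
    rho <- vp$rho; l <- vp$l_eff
    rm <- 2L * vi - 1L; rz <- 2L * vi
    # momentum
    r[rm] <- rho * l / An * (xn[qi] - xp[qi]) / dt -
      theta * (dpn - rho / (2 * An^2) * xn[qi] * abs(xn[qi])) -
      th1 * (dpp - rho / (2 * Ap^2) * xp[qi] * abs(xp[qi]))
    # state
    open_n <- if (is.null(branch)) dpn > 0 else branch[vi]
    open_p <- dpp > 0
    rate_n <- if (open_n) (1 - xn[zi]) * vp$K_vo * dpn else xn[zi] * vp$K_vc * dpn
    rate_p <- if (open_p) (1 - xp[zi]) * vp$K_vo * dpp else xp[zi] * vp$K_vc * dpp
    r[rz] <- (xn[zi] - xp[zi]) / dt - theta * rate_n - th1 * rate_p
    if (want_jac) {
      A[rm, qi] <- rho * l / (An * dt) + theta * rho * abs(xn[qi]) / An^2
      A[rm, ui] <- -theta; A[rm, di] <- theta
      A[rm, zi] <- (-rho * l * (xn[qi] - xp[qi]) / (An^2 * dt) -
                      theta * rho * xn[qi] * abs(xn[qi]) / An^3) * dAdz_n
      B[rm, qi] <- -rho * l / (An * dt) + th1 * rho * abs(xp[qi]) / Ap^2
      B[rm, ui] <- -th1; B[rm, di] <- th1
      B[rm, zi] <- -th1 * rho * xp[qi] * abs(xp[qi]) / Ap^3 * dAdz_p
      drdz_n <- if (open_n) -vp$K_vo * dpn else vp$K_vc * dpn
      drddp_n <- if (open_n) (1 - xn[zi]) * vp$K_vo else xn[zi] * vp$K_vc
      drdz_p <- if (open_p) -vp$K_vo * dpp else vp$K_vc * dpp
      drddp_p <- if (open_p) (1 - xp[zi]) * vp$K_vo else xp[zi] * vp$K_vc
      A[rz, zi] <- 1 / dt - theta * drdz_n
      A[rz, ui] <- -theta * drddp_n; A[rz, di] <- theta * drddp_n
      B[rz, zi] <- -1 / dt - th1 * drdz_p
      B[rz, ui] <- -th1 * drddp_p; B[rz, di] <- th1 * drddp_p
    }
  }

  # windkessels: rows 9-16
  wk_rows <- function(base, C_ar, R_ar, Z_ar, C_ven, R_ven,
                      p_ar, q_valve, q_ar, p_ven, q_ven, p_at_down) {
    # arterial mass (3-element)
    r[base] <<- C_ar * ((xn[p_ar] - xp[p_ar]) / dt -
                          Z_ar * (xn[q_valve] - xp[q_valve]) / dt) +
      theta * (-xn[q_valve] + xn[q_ar]) + th1 * (-xp[q_valve] + xp[q_ar])
    # arterial momentum (algebraic)
    r[base + 1L] <<- (xn[p_ven] - xn[p_ar] + Z_ar * xn[q_valve]) / R_ar +
      xn[q_ar]
    # venous mass (2-element)
    r[base + 2L] <<- C_ven * (xn[p_ven] - xp[p_ven]) / dt +
      theta * (-xn[q_ar] + xn[q_ven]) + th1 * (-xp[q_ar] + xp[q_ven])
    # venous momentum (algebraic)
    r[base + 3L] <<- (xn[p_at_down] - xn[p_ven]) / R_ven + xn[q_ven]
    if (want_jac) {
      A[base, p_ar] <<- C_ar / dt
      A[base, q_valve] <<- -C_ar * Z_ar / dt - theta
      A[base, q_ar] <<- theta
      B[base, p_ar] <<- -C_ar / dt
      B[base, q_valve] <<- C_ar * Z_ar / dt - th1
      B[base, q_ar] <<- th1
      A[base + 1L, p_ven] <<- 1 / R_ar
      A[base + 1L, p_ar] <<- -1 / R_ar
      A[base + 1L, q_valve] <<- Z_ar / R_ar
      A[base + 1L, q_ar] <<- 1
      A[base + 2L, p_ven] <<- C_ven / dt
      A[base + 2L, q_ar] <<- -theta
      A[base + 2L, q_ven] <<- theta
      B[base + 2L, p_ven] <<- -C_ven / dt
      B[base + 2L, q_ar] <<- -th1
      B[base + 2L, q_ven] <<- th1
      A[base + 3L, p_at_down] <<- 1 / R_ven
      A[base + 3L, p_ven] <<- -1 / R_ven
      A[base + 3L, q_ven] <<- 1
    }
  }
  ws <- params$wk_sys; wp <- params$wk_pul
  wk_rows(9L, ws$C_ar, ws$R_ar, ws$Z_ar, ws$C_ven, ws$R_ven,
          p_ar = 7L, q_valve = 4L, q_ar = 8L, p_ven = 9L, q_ven = 10L,
          p_at_down = 11L)
  wk_rows(13L, wp$C_ar, wp$R_ar, wp$Z_ar, wp$C_ven, wp$R_ven,
          p_ar = 17L, q_valve = 14L, q_ar = 18L, p_ven = 19L, q_ven = 20L,
          p_at_down = 1L)

  # chambers: mass rows 17-20, closure rows 21-24, stress rows 25-28
  for (ci in seq_along(CHAMBER_WIRING)) {
    w <- CHAMBER_WIRING[[ci]]
    cp <- params$chambers[[names(CHAMBER_WIRING)[ci]]]
    Vi <- w[["V"]]; ti <- w[["tau"]]; pi <- w[["p"]]
    qin <- w[["q_in"]]; qout <- w[["q_out"]]
    rmass <- 16L + ci; rclos <- 20L + ci; rtau <- 24L + ci
    r[rmass] <- (xn[Vi] - xp[Vi]) / dt +
      theta * (-xn[qin] + xn[qout]) + th1 * (-xp[qin] + xp[qout])
    pc <- chamber_pressure(xn[Vi], xn[ti], cp, deriv = want_jac)
    if (want_jac) {
      r[rclos] <- xn[pi] - pc$p
    } else r[rclos] <- xn[pi] - pc
    aun <- un$au[ci]; sun <- un$su[ci]
    aup <- up_$au[ci]; sup <- up_$su[ci]
    r[rtau] <- (xn[ti] - xp[ti]) / dt -
      theta * (-aun * xn[ti] + sun) - th1 * (-aup * xp[ti] + sup)
    if (want_jac) {
      A[rmass, Vi] <- 1 / dt
      A[rmass, qin] <- -theta; A[rmass, qout] <- theta
      B[rmass, Vi] <- -1 / dt
      B[rmass, qin] <- -th1; B[rmass, qout] <- th1
      A[rclos, pi] <- 1
      A[rclos, Vi] <- -pc$dp_dV
      A[rclos, ti] <- -pc$dp_dtau
      A[rtau, ti] <- 1 / dt + theta * aun
      B[rtau, ti] <- -1 / dt + th1 * aup
    }
  }
  list(r = r, A = A, B = B)
}

# |u| and sigma_0 |u|_+ for the four chambers on a whole grid:
# 4 x (n+1) matrices (chamber order la, lv, ra, rv)
u_table_grid <- function(params, t_grid) {
  keys <- names(CHAMBER_WIRING)
  au <- matrix(0, 4, length(t_grid))
  su <- matrix(0, 4, length(t_grid))
  for (i in 1:4) {
    ap <- params$active[[keys[i]]]
    u <- transmembrane_potential(t_grid, ap)
    au[i, ] <- abs(u)
    su[i, ] <- ap$sigma_0 * pmax(0, u)
  }
  list(au = au, su = su)
}

# |u| and sigma_0 |u|_+ for the four chambers at a given time
u_tables_at <- function(params, t) {
  au <- numeric(4); su <- numeric(4)
  keys <- names(CHAMBER_WIRING)
  for (i in 1:4) {
    ap <- params$active[[keys[i]]]
    u <- transmembrane_potential(t, ap)
    au[i] <- abs(u); su[i] <- ap$sigma_0 * max(0, u)
  }
  list(au = au, su = su)
}

#' Residual of the fully coupled discrete 0D system
#'
#' Stacks (in order) the four valve momentum/state residual pairs, the
#' systemic and pulmonary windkessel mass/momentum residuals, the four
#' chamber mass balances, the four chamber pressure closures, and the four
#' active-stress ODE residuals: 28 entries, zero iff the One-Step-theta
#' discrete coupled system holds between the two states.
#'
#' @param state_next,state_prev numeric[28] states (see `STATE_NAMES`
#'   ordering; [initial_state()] builds one).
#' @param params a [circulation_params] object.
#' @param dt time step, s.
#' @param t_next,t_prev times of the two levels, s (drive the activation).
#' @param jacobian if `TRUE`, also return the Jacobians `A` (wrt
#'   `state_next`) and `B` (wrt `state_prev`).
#' @return numeric[28] residual, or a list `r`, `A`, `B`.
#' @export
assemble_coupled_residual <- function(state_next, state_prev, params, dt,
                                      t_next, t_prev, jacobian = FALSE) {
  if (dt <= 0) stop("dt must be positive")
  out <- assemble_core(as.numeric(state_next), as.numeric(state_prev),
                       params, dt, params$theta,
                       u_tables_at(params, t_next),
                       u_tables_at(params, t_prev),
                       want_jac = jacobian)
  if (jacobian) out else stats::setNames(out$r, NULL)
}

# ---- Newton ------------------------------------------------------------

# flatten a circulation_params object for the compiled core (order fixed:
# windkessels, valves, chamber surrogates, theta)
flatten_params <- function(params) {
  c(with(params$wk_sys, c(C_ar, R_ar, Z_ar, C_ven, R_ven)),
    with(params$wk_pul, c(C_ar, R_ar, Z_ar, C_ven, R_ven)),
    unlist(lapply(params$valves[c("mit", "aor", "tri", "pul")], function(v)
      c(v$A_eff_min, v$A_eff_max, v$K_vo, v$K_vc, v$l_eff, v$rho))),
    unlist(lapply(params$chambers[c("la", "lv", "ra", "rv")], function(ch)
      c(ch$V_ref, ch$E_pass_a, ch$E_pass_b, ch$wall_factor))),
    params$theta)
}

# One implicit step by damped Newton (compiled core) with valve-branch
# freezing at the current iterate and step-halving fallback.
newton_solve_step <- function(xp, params, dt, theta, un, up_,
                              tol = 1e-8, max_iter = 25L, flat = NULL,
                              ...) {
  if (is.null(flat)) flat <- flatten_params(params)
  .cpp_newton_step(as.numeric(xp), flat, dt, un$au, un$su, up_$au, up_$su,
                   tol, max_iter)
}

#' Advance the coupled system by one implicit step
#'
#' Damped Newton iteration on [assemble_coupled_residual()] with the valve
#' branch frozen at the previous iterate (semismooth treatment) and a
#' step-halving fallback when the full step does not converge.
#'
#' @param state_prev numeric[28] previous state.
#' @param params a [circulation_params] object.
#' @param dt time step, s.
#' @param t_prev time of `state_prev`, s.
#' @param tol convergence tolerance on the scaled residual infinity norm.
#' @param max_iter maximum Newton iterations per (sub)step.
#' @return numeric[28] state at `t_prev + dt`.
#' @export
newton_step <- function(state_prev, params, dt, t_prev = 0,
                        tol = 1e-8, max_iter = 25L) {
  un <- u_tables_at(params, t_prev + dt)
  up_ <- u_tables_at(params, t_prev)
  x <- newton_solve_step(as.numeric(state_prev), params, dt, params$theta,
                         un, up_, tol = tol, max_iter = max_iter)
  stats::setNames(x, STATE_NAMES)
}

# ---- initial state and cycle iteration ---------------------------------

#' Build an initial state vector
#'
#' Pressures of the vascular compartments come from the configured initial
#' guesses, chamber pressures from the surrogate closure at the initial
#' volumes, flows and valve states are zero, active stresses zero
#' (diastasis start).
#'
#' @param params a [circulation_params] object.
#' @param volumes named numeric (`la`, `lv`, `ra`, `rv`) of initial chamber
#'   volumes in ml; defaults to each chamber's reference volume.
#' @return named numeric[28] state.
#' @export
initial_state <- function(params, volumes = NULL) {
  x <- numeric(N_STATE)
  ip <- params$init_pressures
  x[7] <- ip[["p_ar_sys"]]; x[17] <- ip[["p_ar_pul"]]
  x[9] <- ip[["p_ven_sys"]]; x[19] <- ip[["p_ven_pul"]]
  keys <- names(CHAMBER_WIRING)
  for (i in 1:4) {
    w <- CHAMBER_WIRING[[keys[i]]]
    V0 <- if (!is.null(volumes) && keys[i] %in% names(volumes))
      volumes[[keys[i]]] * ML else params$chambers[[keys[i]]]$V_ref
    x[w[["V"]]] <- V0
    x[w[["p"]]] <- chamber_pressure(V0, 0, params$chambers[[keys[i]]])
  }
  stats::setNames(x, STATE_NAMES)
}

#' Cycle-to-cycle periodicity error
#'
#' Maximum relative absolute change, between cycle start and cycle end, of
#' the four compartment pressures and the ventricular and atrial volumes.
#' The printed form of the criterion lists the right atrial volume twice
#' and omits the left; the default includes both atria (presumed typo),
#' `literal_printed_set = TRUE` reproduces the printed set.
#'
#' @param cycle_start,cycle_end named numeric[28] states at `t0` and
#'   `t0 + T_cycl`.
#' @param literal_printed_set include only the right atrium, as printed.
#' @return scalar periodicity error (dimensionless).
#' @export
periodicity_error <- function(cycle_start, cycle_end,
                              literal_printed_set = FALSE) {
  fields <- c("p_ar_sys", "p_ar_pul", "p_ven_sys", "p_ven_pul",
              "V_v_l", "V_v_r", "V_at_r",
              if (!literal_printed_set) "V_at_l")
  s <- cycle_start[fields]; e <- cycle_end[fields]
  if (any(abs(s) < 1e-12)) stop("zero denominator in periodicity error")
  max(abs((e - s) / s))
}

#' Run the closed-loop model to a periodic state
#'
#' Repeats the cardiac cycle, restarting each cycle from the last step of
#' the previous one, until the periodicity error drops below `eps_cycl` or
#' `max_cycles` is reached. Because the dynamics are driven by periodic
#' active-stress functions, the limit cycle is independent of the initial
#' conditions (total blood volume excepted).
#'
#' @param initial numeric[28] initial state (see [initial_state()]);
#'   `NULL` builds the default.
#' @param params a [circulation_params] object.
#' @param dt time step, s.
#' @param eps_cycl periodicity tolerance (relative).
#' @param max_cycles maximum number of cycles.
#' @param t0 cycle start time, s.
#' @param warn warn when periodicity is not reached.
#' @return an object of class `cardio_sim`: `time`, `states` (matrix, one
#'   row per step of the final cycle), `report` (class `cycle_report` with
#'   `E_cycl`, `n_cycles`, `converged`, per-cycle start snapshots and the
#'   per-cycle error trace), `params`, `dt`.
#' @export
run_cycles <- function(initial = NULL, params, dt = 1e-3, eps_cycl = 0.04,
                       max_cycles = 50L, t0 = 0, warn = TRUE) {
  if (eps_cycl <= 0) stop("eps_cycl must be positive")
  if (is.null(initial)) initial <- initial_state(params)
  n <- round(params$T_cycl / dt)
  tt <- t0 + (0:n) * dt
  ut <- u_table_grid(params, tt)
  flat <- flatten_params(params)
  x <- as.numeric(initial)
  snapshots <- list()
  e_trace <- numeric(0)
  converged <- FALSE
  n_cycles <- 0L
  for (cyc in seq_len(max_cycles)) {
    n_cycles <- cyc
    snapshots[[cyc]] <- stats::setNames(x, STATE_NAMES)
    states <- .cpp_forward_cycle(x, flat, dt, ut$au, ut$su, 1e-8, 25L)
    colnames(states) <- STATE_NAMES
    x <- states[n + 1, ]
    e <- periodicity_error(states[1, ], states[n + 1, ])
    e_trace <- c(e_trace, e)
    if (e <= eps_cycl) { converged <- TRUE; break }
  }
  if (!converged && warn)
    warning(sprintf("periodicity not reached in %d cycles (E_cycl = %.3g)",
                    max_cycles, e_trace[length(e_trace)]))
  report <- structure(list(E_cycl = e_trace[length(e_trace)],
                           n_cycles = n_cycles, converged = converged,
                           E_trace = e_trace, snapshots = snapshots),
                      class = "cycle_report")
  structure(list(time = tt, states = states, report = report,
                 params = params, dt = dt, theta = params$theta),
            class = "cardio_sim")
}
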