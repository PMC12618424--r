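# Identification of the 12 per-chamber active-stress parameters
# (sigma_0, alpha_max, alpha_min for both ventricles and both atria) by
# minimizing the squared mismatch between measured and computed chamber
# volumes at selected time steps, with the fully coupled closed-loop model
# as the forward problem. Gradients come from a discrete adjoint
# (discretize-then-differentiate) of the One-Step-theta system, so they
# are exact for the implemented forward model at a cost of about one
# additional forward solve. The L-BFGS loop is restarted with updated
# initial conditions every N_f forward evaluations (periodicity gating).

# parameter vector ordering: sigma_0, alpha_max, alpha_min per chamber in
# the order rv, lv, ra, la
PHI_CHAMBERS <- c("rv", "lv", "ra", "la")
PHI_NAMES <- as.vector(t(outer(PHI_CHAMBERS,
                               c("sigma_0", "alpha_max", "alpha_min"),
                               paste, sep = ".")))

phi_from_params <- function(params) {
  stats::setNames(unlist(lapply(PHI_CHAMBERS, function(ch) {
    a <- params$active[[ch]]
    c(a$sigma_0, a$alpha_max, a$alpha_min)
  })), PHI_NAMES)
}

set_active_phi <- function(params, phi) {
  for (i in seq_along(PHI_CHAMBERS)) {
    ch <- PHI_CHAMBERS[i]
    params$active[[ch]]$sigma_0 <- phi[[3 * i - 2]]
    params$active[[ch]]$alpha_max <- phi[[3 * i - 1]]
    params$active[[ch]]$alpha_min <- phi[[3 * i]]
  }
  params
}

#' Optimization stopping threshold from a volume-error budget
#'
#' The objective sums squared volume mismatches over `n_points` selected
#' samples; an acceptable average error of `avg_error` ml per sample
#' translates to the threshold `avg_error^2 * n_points` (ml^2).
#'
#' @param n_points number of measurement points in the objective.
#' @param avg_error acceptable average volume error per point, ml.
#' @return threshold, ml^2.
#' @export
#' @examples
#' stopping_threshold(18, 0.5)  # 4.5
stopping_threshold <- function(n_points, avg_error) {
  if (n_points <= 0 || avg_error <= 0)
    stop("n_points and avg_error must be positive")
  avg_error^2 * n_points
}

# per-chamber activation tables for a forward/adjoint pass:
# u, |u|, sigma_0*|u|_+, H(u>0), sign(u), du/dalpha_max, du/dalpha_min
# at every grid point; list of 4 (order la, lv, ra, rv as CHAMBER_WIRING)
activation_tables <- function(params, t_grid) {
  lapply(names(CHAMBER_WIRING), function(ch) {
    ap <- params$active[[ch]]
    up <- transmembrane_potential_partials(t_grid, ap)
    u <- up$u
    list(u = u, au = abs(u), su = ap$sigma_0 * pmax(0, u),
         H = as.numeric(u > 0), sgn = sign(u),
         du_damax = up$du_damax, du_damin = up$du_damin,
         aup = pmax(0, u), sigma_0 = ap$sigma_0)
  })
}

# forward march of one cycle storing all states; tabs from
# activation_tables(); returns states (n+1) x 28
forward_cycle <- function(params, x0, dt, t_grid, tabs) {
  au <- do.call(rbind, lapply(tabs, `[[`, "au"))
  su <- do.call(rbind, lapply(tabs, `[[`, "su"))
  .cpp_forward_cycle(as.numeric(x0), flatten_params(params), dt, au, su,
                     1e-8, 25L)
}

# measurement bookkeeping: map target times to grid indices and collect
# measured values; meas is a list la/lv/ra/rv of data frames (t, value
# mm^3); T_v / T_at are time vectors (ventricles / atria)
volume_targets <- function(meas, T_v, T_at, t_grid) {
  keys <- names(CHAMBER_WIRING)   # la lv ra rv
  out <- list()
  for (i in seq_along(keys)) {
    ch <- keys[i]
    tsel <- if (ch %in% c("lv", "rv")) T_v else T_at
    if (!length(tsel)) next
    s <- meas[[ch]]
    vals <- stats::approx(s$t, s$value, xout = tsel, rule = 2)$y
    idx <- round((tsel - t_grid[1]) / (t_grid[2] - t_grid[1])) + 1L
    if (any(idx < 1 | idx > length(t_grid)))
      stop("target time outside the simulated cycle")
    out[[ch]] <- list(idx = idx, v_meas = vals,
                      col = CHAMBER_WIRING[[ch]][["V"]])
  }
  out
}

objective_from_states <- function(states, targets) {
  f <- 0
  for (tg in targets)
    f <- f + sum(((states[tg$idx, tg$col] - tg$v_meas) / ML)^2)
  f
}

#' Volume-mismatch objective of the active-stress identification
#'
#' Runs the closed-loop forward model for one cycle with the given
#' active-stress parameter vector and sums squared mismatches between
#' computed and measured chamber volumes over the selected ventricular
#' (`T_v`) and atrial (`T_at`) time steps, for both sides. Units ml^2.
#'
#' @param phi numeric[12], order `sigma_0, alpha_max, alpha_min` for
#'   rv, lv, ra, la.
#' @param params a [circulation_params] (non-active parameters are used
#'   as-is; active ones are overridden by `phi`).
#' @param measured list with elements `la`, `lv`, `ra`, `rv`: data frames
#'   `t` (s), `value` (mm^3).
#' @param T_v,T_at time steps (s) at which ventricular / atrial volumes
#'   enter the objective; must lie inside the contraction/relaxation
#'   phases to be informative.
#' @param init initial state (numeric[28]); default built from the
#'   measured volumes at the cycle start.
#' @param dt time step, s.
#' @param detail return the trajectory and periodicity error as well.
#' @param burn_in number of cardiac cycles marched before the evaluation
#'   cycle; burn-in absorbs the initial-condition transient so the
#'   objective is evaluated near the parameter vector's periodic orbit.
#' @return scalar objective (ml^2), or a list when `detail = TRUE`.
#' @export
volume_objective <- function(phi, params, measured, T_v, T_at,
                             init = NULL, dt = 1e-3, detail = FALSE,
                             burn_in = 0L) {
  if (!length(T_v) && !length(T_at))
    stop("at least one of T_v, T_at must be non-empty")
  params <- set_active_phi(params, phi)
  n <- round(params$T_cycl / dt)
  n_cycles <- burn_in + 1L
  t_grid <- (0:(n_cycles * n)) * dt
  if (is.null(init)) init <- initial_state_from_measured(params, measured)
  tabs <- activation_tables(params, t_grid)
  states <- forward_cycle(params, init, dt, t_grid, tabs)
  # objective lives on the final cycle; burn-in cycles only absorb the
  # initial-condition transient
  targets <- volume_targets(measured, T_v, T_at, (0:n) * dt)
  off <- burn_in * n
  for (i in seq_along(targets)) targets[[i]]$idx <- targets[[i]]$idx + off
  f <- objective_from_states(states, targets)
  if (!detail) return(f)
  list(f = f, states = states, t_grid = t_grid, tabs = tabs,
       targets = targets,
       E_cycl = periodicity_error(
         stats::setNames(states[off + 1, ], STATE_NAMES),
         stats::setNames(states[n_cycles * n + 1, ], STATE_NAMES)))
}

initial_state_from_measured <- function(params, measured, mset = NULL) {
  vols <- vapply(names(CHAMBER_WIRING), function(ch)
    stats::approx(measured[[ch]]$t, measured[[ch]]$value, xout = 0,
                  rule = 2)$y / ML, 0)
  x0 <- initial_state(params, volumes = vols)
  # The closed loop conserves total blood volume, so the limit cycle is
  # set by the initial stored volumes: pin the compartment pressures (and
  # semilunar flows) to their measured values at cycle start when a full
  # measurement set is available, falling back to the configured guesses.
  if (!is.null(mset)) {
    at0 <- function(nm) {
      s <- mset$series[[nm]]
      if (is.null(s)) return(NA_real_)
      stats::approx(s$t, s$value, xout = mset$t0, rule = 2)$y
    }
    for (nm in c("p_ar_sys", "p_ar_pul", "p_ven_pul"))
      if (is.finite(at0(nm))) x0[nm] <- at0(nm)
    pvs <- if (is.finite(at0("p_ven_sys"))) at0("p_ven_sys") else at0("p_at_r")
    if (is.finite(pvs)) x0["p_ven_sys"] <- pvs
    if (is.finite(at0("q_v_out_l"))) x0["q_aor"] <- at0("q_v_out_l")
    if (is.finite(at0("q_v_out_r"))) x0["q_pul"] <- at0("q_v_out_r")
  }
  x0
}

#' Adjoint gradient of the volume objective
#'
#' Discrete adjoint of the One-Step-theta coupled system: one backward
#' sweep of the transposed linearized dynamics accumulates the exact
#' gradient of [volume_objective()] with respect to all 12 active-stress
#' parameters, at a cost comparable to one forward solve. The parameters
#' enter only through the active-stress ODE rows (contractility directly,
#' the rate parameters through the activation ramps, whose centers they
#' shift).
#'
#' @inheritParams volume_objective
#' @param forward optional result of `volume_objective(..., detail =
#'   TRUE)` at the same `phi` (avoids re-running the forward model).
#' @return list with `gradient` (numeric[12]) and `f` (objective value).
#' @export
adjoint_gradient <- function(phi, params, measured, T_v, T_at,
                             init = NULL, dt = 1e-3, forward = NULL,
                             burn_in = 0L) {
  params_phi <- set_active_phi(params, phi)
  if (is.null(forward))
    forward <- volume_objective(phi, params, measured, T_v, T_at,
                                init = init, dt = dt, detail = TRUE,
                                burn_in = burn_in)
  states <- forward$states; t_grid <- forward$t_grid; tabs <- forward$tabs
  n <- nrow(states) - 1L
  # df/dx_k: nonzero only in volume columns at target indices
  gmat <- matrix(0, n + 1, N_STATE)
  for (tg in forward$targets)
    gmat[cbind(tg$idx, tg$col)] <- gmat[cbind(tg$idx, tg$col)] +
      2 * (states[tg$idx, tg$col] - tg$v_meas) / ML^2
  stack <- function(f) do.call(rbind, lapply(tabs, `[[`, f))
  # map chamber order (la lv ra rv) to phi block starts (rv lv ra la)
  phi_block <- match(names(CHAMBER_WIRING), PHI_CHAMBERS)
  grad <- .cpp_adjoint_sweep(states, flatten_params(params_phi), dt,
                             stack("au"), stack("su"), stack("sgn"),
                             stack("H"), stack("aup"),
                             stack("du_damax"), stack("du_damin"),
                             vapply(tabs, `[[`, 0, "sigma_0"),
                             gmat, as.integer(phi_block))
  list(gradient = stats::setNames(grad, PHI_NAMES), f = forward$f)
}

#' Default objective time-step sets
#'
#' All measured volume samples falling inside the active window of the
#' respective chamber type: from contraction onset to relaxation onset
#' plus a relaxation tail (default 0.25 s) during which the decaying
#' stress still shapes the volumes. Cycle start is excluded (the initial
#' state is pinned to the measurements there).
#'
#' @param params a [circulation_params] object.
#' @param sample_times measured volume sample times, s.
#' @param tail relaxation tail appended to the window, s.
#' @return list with `T_v` and `T_at` (time vectors).
#' @export
default_time_sets <- function(params, sample_times, tail = 0.25) {
  av <- params$active$lv; aa <- params$active$la
  w_v <- c(av$t_contr, min(av$t_relax + tail, params$T_cycl))
  w_at <- c(aa$t_contr, min(aa$t_relax + tail, params$T_cycl))
  st <- sample_times[sample_times > 1e-9]
  list(T_v = st[st >= w_v[1] & st <= w_v[2]],
       T_at = st[st >= w_at[1] & st <= w_at[2]])
}

# condition class used to interrupt optim() after N_f evaluations
cl_restart_condition <- function() {
  structure(class = c("cl_restart", "error", "condition"),
            list(message = "periodicity check requested", call = NULL))
}

#' Fit the active-stress parameters of all four chambers
#'
#' L-BFGS minimization of [volume_objective()] with [adjoint_gradient()]
#' gradients, in log-magnitude parameter space (signs fixed: contractility
#' and upstroke rates positive, relaxation rates negative). Every `N_f`
#' forward evaluations (or on optimizer convergence) the periodicity of
#' the current solution is checked, the initial conditions are updated
#' from the last step of the current cycle, and the L-BFGS memory is
#' reset. Termination requires both the objective below `eps_sc` and the
#' periodicity error below `eps_cycl`.
#'
#' @param params a [circulation_params] with all non-active parameters
#'   already identified/fixed.
#' @param measured list `la`, `lv`, `ra`, `rv` of data frames `t`,
#'   `value` (mm^3), e.g. from [measured_volumes()].
#' @param init_phi numeric[12] initial guess (order `sigma_0, alpha_max,
#'   alpha_min` for rv, lv, ra, la); defaults to a generic physiological
#'   start.
#' @param T_v,T_at objective time sets; defaults from
#'   [default_time_sets()].
#' @param eps_sc objective threshold, ml^2; default from
#'   [stopping_threshold()] with a 0.5 ml average error budget.
#' @param eps_cycl periodicity threshold.
#' @param N_f forward evaluations between initial-condition updates.
#' @param max_rounds maximum restart rounds.
#' @param dt time step, s.
#' @param ic_eps periodicity tolerance used when refreshing the initial
#'   conditions between rounds (the forward cycle iteration is cheap, so
#'   the update is driven close to the incumbent's periodic orbit rather
#'   than taking a single cycle).
#' @param burn_in cycles marched before the evaluation cycle of each
#'   forward solve (see [volume_objective()]); 0 reproduces the
#'   single-cycle forward problem of the reference algorithm, small
#'   positive values make the objective insensitive to the remaining
#'   initial-condition transient.
#' @param mset optional [measurement_set()]: its pressures and semilunar
#'   flows at cycle start pin the initial compartment states (and thereby
#'   the conserved total blood volume) to the measurements.
#' @return object of class `active_stress_fit`: `phi`, `objective`,
#'   `E_cycl`, `converged`, `trace` (data frame per evaluation: `eval`,
#'   `f`, `grad_norm`, `E_cycl`, `round`), `n_forward_evals`, `T_v`,
#'   `T_at`, `eps_sc`, `eps_cycl`.
#' @export
fit_active_stress <- function(params, measured, init_phi = NULL,
                              T_v = NULL, T_at = NULL, eps_sc = NULL,
                              eps_cycl = 0.04, N_f = 15L,
                              max_rounds = 20L, dt = 1e-3,
                              ic_eps = 1e-4, burn_in = 0L, mset = NULL) {
  if (is.null(init_phi))
    init_phi <- rep(c(60, 10, -30, 60, 10, -30, 10, 20, -30, 10, 20, -30))[1:12]
  sgn <- sign(init_phi)
  if (any(sgn != rep(c(1, 1, -1), 4)))
    stop("initial phi must have positive sigma_0/alpha_max, negative alpha_min")
  mag0 <- abs(init_phi)
  if (is.null(T_v) || is.null(T_at)) {
    ts <- default_time_sets(params, sort(unique(measured$lv$t)))
    if (is.null(T_v)) T_v <- ts$T_v
    if (is.null(T_at)) T_at <- ts$T_at
  }
  n_points <- 2L * length(T_v) + 2L * length(T_at)
  if (is.null(eps_sc)) eps_sc <- stopping_threshold(n_points, 0.5)

  x0 <- initial_state_from_measured(params, measured, mset = mset)
  trace <- list()
  n_eval <- 0L
  incumbent <- init_phi
  inc_f <- Inf; inc_fwd <- NULL
  round_i <- 0L
  glb_lo <- rep(log(0.1), 12); glb_hi <- rep(log(8), 12)

  to_phi <- function(p) sgn * mag0 * exp(p)
  repeat {
    round_i <- round_i + 1L
    evals_this_round <- 0L
    # best evaluation within this round (objectives are only comparable
    # at a common initial state)
    best <- list(f = Inf, phi = NULL, fwd = NULL)
    cache <- new.env(parent = emptyenv())
    p_start <- log(abs(incumbent) / mag0)
    run_forward <- function(p) {
      key <- paste(signif(p, 12), collapse = ",")
      if (!is.null(cache$key) && identical(cache$key, key)) return(cache$fwd)
      phi <- to_phi(p)
      fwd <- tryCatch(
        volume_objective(phi, params, measured, T_v, T_at,
                         init = x0, dt = dt, detail = TRUE,
                         burn_in = burn_in),
        error = function(e) NULL)
      cache$key <- key; cache$fwd <- fwd; cache$phi <- phi
      n_eval <<- n_eval + 1L
      evals_this_round <<- evals_this_round + 1L
      if (is.null(fwd)) return(NULL)   # solver failure: penalty in fn
      if (fwd$f < best$f)
        best <<- list(f = fwd$f, phi = phi, fwd = fwd)
      trace[[length(trace) + 1L]] <<- data.frame(
        eval = n_eval, f = fwd$f, grad_norm = NA_real_,
        E_cycl = fwd$E_cycl, round = round_i)
      fwd
    }
    fn <- function(p) {
      if (evals_this_round >= N_f) stop(cl_restart_condition())
      fwd <- run_forward(p)
      # failed solves: finite penalty sloping back toward the round start
      if (is.null(fwd)) return(1e6 * (1 + sum((p - p_start)^2)))
      fwd$f
    }
    gr <- function(p) {
      fwd <- run_forward(p)
      if (is.null(fwd)) return(2e6 * (p - p_start))
      ag <- adjoint_gradient(to_phi(p), params, measured, T_v, T_at,
                             init = x0, dt = dt, forward = fwd)

      g <- ag$gradient * to_phi(p)   # chain rule for log-magnitude coords
      trace[[length(trace)]]$grad_norm <<- sqrt(sum(ag$gradient^2))
      g
    }
    # per-round trust bounds around the incumbent keep the line search
    # from escaping to unphysiological corners in one round
    lo <- pmax(glb_lo, p_start - log(2.5))
    hi <- pmin(glb_hi, p_start + log(2.5))
    res <- tryCatch(
      stats::optim(p_start, fn, gr, method = "L-BFGS-B",
                   lower = lo, upper = hi,
                   control = list(maxit = 200L, factr = 1e4)),
      cl_restart = function(e) NULL)
    if (!is.null(best$fwd)) {
      incumbent <- best$phi
      inc_f <- best$f; inc_fwd <- best$fwd
    }
    if (is.null(inc_fwd)) stop("no successful forward evaluation")
    done <- inc_f <= eps_sc && inc_fwd$E_cycl <= eps_cycl
    if (done || round_i >= max_rounds) {
      converged <- done
      break
    }
    # drive the initial conditions to the periodic orbit of the incumbent
    # parameters (cycle iteration as in the forward algorithm) so the next
    # optimization round sees a stationary forward problem
    x1 <- stats::setNames(inc_fwd$states[nrow(inc_fwd$states), ], STATE_NAMES)
    ic <- tryCatch(
      run_cycles(x1, set_active_phi(params, incumbent), dt = dt,
                 eps_cycl = max(ic_eps, 1e-6), max_cycles = 40L,
                 warn = FALSE),
      error = function(e) NULL)
    x0 <- if (!is.null(ic))
      stats::setNames(ic$states[nrow(ic$states), ], STATE_NAMES) else x1
  }
  trace_df <- do.call(rbind, trace)
  structure(list(phi = stats::setNames(incumbent, PHI_NAMES),
                 objective = inc_f, E_cycl = inc_fwd$E_cycl,
                 converged = converged, trace = trace_df,
                 n_forward_evals = n_eval, T_v = T_v, T_at = T_at,
                 eps_sc = eps_sc, eps_cycl = eps_cycl),
            class = "active_stress_fit")
}

#' Extract measured chamber-volume series from a measurement set
#'
#' @param mset a [measurement_set()] with `V_at_l`, `V_v_l`, `V_at_r`,
#'   `V_v_r` series (internal units mm^3).
#' @return list `la`, `lv`, `ra`, `rv` of data frames `t`, `value`.
#' @export
measured_volumes <- function(mset) {
  map <- c(la = "V_at_l", lv = "V_v_l", ra = "V_at_r", rv = "V_v_r")
  out <- lapply(map, function(nm) {
    if (is.null(mset$series[[nm]])) stop("missing volume series ", nm)
    mset$series[[nm]]
  })
  names(out) <- names(map)
  out
}

#' @export
print.active_stress_fit <- function(x, ...) {
  cat("Active-stress parameter fit (closed-loop, adjoint L-BFGS)\n")
  m <- matrix(x$phi, nrow = 3,
              dimnames = list(c("sigma_0", "alpha_max", "alpha_min"),
                              PHI_CHAMBERS))
  print(round(m, 3))
  cat(sprintf("  f = %.4g ml^2 (eps_sc %.3g), E_cycl = %.4g (eps %.3g), %d forward evals, %s\n",
              x$objective, x$eps_sc, x$E_cycl, x$eps_cycl,
              x$n_forward_evals,
              if (x$converged) "converged" else "not converged"))
  invisible(x)
}

#' @export
coef.active_stress_fit <- function(object, ...) object$phi
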