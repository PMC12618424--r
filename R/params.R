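# Internal unit system: mm^3 / kPa / s.  Volumes and flows cross the I/O
# boundary in ml (1 ml = 1000 mm^3); all model code works in mm^3.
ML <- 1000

#' Windkessel parameters of one circulation side
#'
#' Three-element arterial (compliance `C_ar`, peripheral resistance `R_ar`,
#' characteristic impedance `Z_ar`) and two-element venous (`C_ven`,
#' `R_ven`) compartment parameters. Units: compliances mm^3/kPa,
#' resistances and impedance kPa s mm^-3.
#'
#' @param C_ar,R_ar,Z_ar arterial compliance, resistance, impedance.
#' @param C_ven,R_ven venous compliance and resistance.
#' @return an object of class `windkessel_params`.
#' @export
windkessel_params <- function(C_ar, R_ar, Z_ar, C_ven, R_ven) {
  p <- list(C_ar = C_ar, R_ar = R_ar, Z_ar = Z_ar,
            C_ven = C_ven, R_ven = R_ven)
  if (any(!vapply(p, is.finite, logical(1))) || any(unlist(p) <= 0))
    stop("windkessel parameters must be finite and strictly positive")
  if (Z_ar >= R_ar)
    warning("Z_ar >= R_ar: characteristic impedance normally well below peripheral resistance")
  structure(p, class = "windkessel_params")
}

#' Dynamic Bernoulli valve parameters
#'
#' @param A_eff_min,A_eff_max minimum / maximum effective orifice area, mm^2.
#' @param K_vo,K_vc opening / closing rate, s^-1 kPa^-1.
#' @param l_eff effective (inertial) length, mm.
#' @param rho blood density, kg mm^-3.
#' @return an object of class `valve_params`.
#' @export
valve_params <- function(A_eff_min, A_eff_max, K_vo, K_vc, l_eff, rho = 1e-6) {
  if (A_eff_min < 0 || A_eff_max <= 0 || A_eff_min > A_eff_max)
    stop("require 0 <= A_eff_min <= A_eff_max, A_eff_max > 0")
  if (K_vo <= 0 || K_vc <= 0 || l_eff <= 0 || rho <= 0)
    stop("K_vo, K_vc, l_eff, rho must be positive")
  structure(list(A_eff_min = A_eff_min, A_eff_max = A_eff_max,
                 K_vo = K_vo, K_vc = K_vc, l_eff = l_eff, rho = rho),
            class = "valve_params")
}

#' Active-stress parameters of one chamber
#'
#' Trapezoidal activation (regularization K) scaled between upstroke rate
#' `alpha_max` (> 0) and relaxation rate `alpha_min` (< 0) drives the
#' first-order active fiber stress ODE with contractility `sigma_0`.
#'
#' @param sigma_0 contractility, kPa.
#' @param alpha_max upstroke rate, s^-1 (positive).
#' @param alpha_min relaxation rate, s^-1 (negative).
#' @param t_contr,t_relax contraction / relaxation onset, s (relative to t0).
#' @param T_cycl cardiac cycle duration, s.
#' @param K activation regularization parameter (dimensionless).
#' @return an object of class `active_stress_params`.
#' @export
active_stress_params <- function(sigma_0, alpha_max, alpha_min,
                                 t_contr, t_relax, T_cycl = 0.75, K = 10) {
  if (sigma_0 <= 0) stop("sigma_0 must be positive")
  if (alpha_max <= 0) stop("alpha_max must be positive")
  if (alpha_min >= 0) stop("alpha_min must be negative")
  if (!(t_contr < t_relax && t_relax < t_contr + T_cycl))
    stop("require t_contr < t_relax < t_contr + T_cycl")
  if (K <= 0) stop("K must be positive")
  structure(list(sigma_0 = sigma_0, alpha_max = alpha_max,
                 alpha_min = alpha_min, t_contr = t_contr,
                 t_relax = t_relax, T_cycl = T_cycl, K = K),
            class = "active_stress_params")
}

#' Chamber pressure-volume surrogate parameters
#'
#' A 0D stand-in (synthetic; there is no lumped chamber law in the 3D
#' reference formulation) for a contracting chamber: exponential passive
#' end-diastolic pressure-volume relation plus an active term
#' `wall_factor * tau * (V/V_ref)^(1/3)` mapping fiber stress tau (kPa) to
#' chamber pressure.
#'
#' @param V_ref reference (zero passive pressure) volume, mm^3.
#' @param E_pass_a passive stiffness scale, kPa.
#' @param E_pass_b passive exponent, mm^-3.
#' @param wall_factor dimensionless geometry factor mapping fiber stress to
#'   cavity pressure at `V = V_ref`.
#' @return an object of class `chamber_surrogate_params`.
#' @export
chamber_surrogate_params <- function(V_ref, E_pass_a, E_pass_b, wall_factor) {
  p <- list(V_ref = V_ref, E_pass_a = E_pass_a,
            E_pass_b = E_pass_b, wall_factor = wall_factor)
  if (any(unlist(p) <= 0)) stop("all chamber surrogate parameters must be positive")
  structure(p, class = "chamber_surrogate_params")
}

#' Full closed-loop circulation parameter set
#'
#' Bundles systemic and pulmonary windkessel compartments, the four valve
#' models (keyed `mit`, `aor`, `tri`, `pul`), per-chamber active-stress and
#' surrogate pressure-volume parameters (keyed `la`, `lv`, `ra`, `rv`), the
#' cycle duration, and the time-integration weight `theta`.
#'
#' @param wk_sys,wk_pul [windkessel_params] of the two circulations.
#' @param valves named list (`mit`, `aor`, `tri`, `pul`) of [valve_params].
#' @param active named list (`la`, `lv`, `ra`, `rv`) of
#'   [active_stress_params].
#' @param chambers named list (`la`, `lv`, `ra`, `rv`) of
#'   [chamber_surrogate_params].
#' @param T_cycl cardiac cycle duration, s.
#' @param theta One-Step-theta weight in (0, 1]; 0.5 is trapezoidal.
#' @param init_pressures named numeric: initial guesses for `p_ar_sys`,
#'   `p_ar_pul`, `p_ven_sys`, `p_ven_pul` (kPa).
#' @return an object of class `circulation_params`.
#' @export
circulation_params <- function(wk_sys, wk_pul, valves, active, chambers,
                               T_cycl = 0.75, theta = 0.5,
                               init_pressures = c(p_ar_sys = 10, p_ar_pul = 2.5,
                                                  p_ven_sys = 0.8, p_ven_pul = 1.0)) {
  stopifnot(inherits(wk_sys, "windkessel_params"),
            inherits(wk_pul, "windkessel_params"))
  stopifnot(setequal(names(valves), c("mit", "aor", "tri", "pul")),
            setequal(names(active), c("la", "lv", "ra", "rv")),
            setequal(names(chambers), c("la", "lv", "ra", "rv")))
  if (theta <= 0 || theta > 1) stop("theta must be in (0, 1]")
  structure(list(wk_sys = wk_sys, wk_pul = wk_pul, valves = valves,
                 active = active, chambers = chambers, T_cycl = T_cycl,
                 theta = theta, init_pressures = init_pressures),
            class = "circulation_params")
}

#' Derive venous windkessel parameters from arterial ones
#'
#' Venous compartment parameters cannot be identified from routinely
#' available pressure/flow measurements; they are tied to the fitted
#' arterial values by literature-based dependency rules:
#' `R_ven_sys = R_ar_sys / 10`, `C_ven_sys = 30 * C_ar_sys`,
#' `R_ven_pul = R_ar_pul`, `C_ven_pul = 2.5 * C_ar_pul`.
#'
#' @param C_ar,R_ar arterial compliance (mm^3/kPa) and resistance
#'   (kPa s mm^-3).
#' @param side `"sys"` or `"pul"`.
#' @return named numeric vector with `C_ven` and `R_ven`.
#' @export
#' @examples
#' derive_venous_parameters(11302, 1.392e-4, "sys")
derive_venous_parameters <- function(C_ar, R_ar, side = c("sys", "pul")) {
  side <- match.arg(side)
  if (C_ar <= 0 || R_ar <= 0) stop("arterial parameters must be positive")
  if (side == "sys") c(C_ven = 30 * C_ar, R_ven = R_ar / 10)
  else               c(C_ven = 2.5 * C_ar, R_ven = R_ar)
}

#' Model a valve replacement by sealing the valve
#'
#' Returns a copy of the parameter set in which `A_eff_min` of the named
#' valve is set to zero (a competent prosthesis); all other parameters are
#' left unaltered. The Bernoulli momentum equation floors the effective
#' area internally, so a fully sealing valve remains solvable.
#'
#' @param params a [circulation_params] object.
#' @param valve_id one of `"mit"`, `"aor"`, `"tri"`, `"pul"`.
#' @return modified [circulation_params].
#' @export
apply_valve_replacement <- function(params, valve_id = "pul") {
  stopifnot(inherits(params, "circulation_params"))
  if (!valve_id %in% names(params$valves))
    stop("unknown valve: ", valve_id)
  params$valves[[valve_id]]$A_eff_min <- 0
  params
}

# ---- JSON serialization ------------------------------------------------

#' Write a circulation parameter set to JSON
#'
#' Keys follow the field symbols (`C_ar_sys`, `R_ar_sys`, ...); one object
#' per valve (`mit`/`aor`/`tri`/`pul`) and per chamber (`la`/`lv`/`ra`/`rv`).
#' Units are documented in-file under `"units"`.
#'
#' @param params a [circulation_params] object.
#' @param path output file path.
#' @export
write_circulation_json <- function(params, path) {
  stopifnot(inherits(params, "circulation_params"))
  wk <- function(w, side) {
    x <- list(w$C_ar, w$R_ar, w$Z_ar, w$C_ven, w$R_ven)
    names(x) <- paste0(c("C_ar_", "R_ar_", "Z_ar_", "C_ven_", "R_ven_"), side)
    x
  }
  out <- c(wk(params$wk_sys, "sys"), wk(params$wk_pul, "pul"),
           list(valves = lapply(params$valves, unclass),
                active = lapply(params$active, unclass),
                chambers = lapply(params$chambers, unclass),
                T_cycl = params$T_cycl, theta = params$theta,
                init_pressures = as.list(params$init_pressures),
                units = list(volume = "mm^3", pressure = "kPa", time = "s",
                             compliance = "mm^3 kPa^-1",
                             resistance = "kPa s mm^-3", area = "mm^2",
                             valve_rate = "s^-1 kPa^-1", density = "kg mm^-3")))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a circulation parameter set from JSON
#'
#' @param path file written by [write_circulation_json()].
#' @return a [circulation_params] object.
#' @export
read_circulation_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  wk <- function(side) windkessel_params(
    C_ar = j[[paste0("C_ar_", side)]], R_ar = j[[paste0("R_ar_", side)]],
    Z_ar = j[[paste0("Z_ar_", side)]], C_ven = j[[paste0("C_ven_", side)]],
    R_ven = j[[paste0("R_ven_", side)]])
  valves <- lapply(j$valves, function(v)
    valve_params(v$A_eff_min, v$A_eff_max, v$K_vo, v$K_vc, v$l_eff, v$rho))
  active <- lapply(j$active, function(a)
    active_stress_params(a$sigma_0, a$alpha_max, a$alpha_min,
                         a$t_contr, a$t_relax, a$T_cycl, a$K))
  chambers <- lapply(j$chambers, function(ch)
    chamber_surrogate_params(ch$V_ref, ch$E_pass_a, ch$E_pass_b, ch$wall_factor))
  circulation_params(wk("sys"), wk("pul"), valves, active, chambers,
                     T_cycl = j$T_cycl, theta = j$theta,
                     init_pressures = unlist(j$init_pressures))
}

#' @export
print.circulation_params <- function(x, ...) {
  cat("Closed-loop 0D circulation parameters\n")
  cat(sprintf("  T_cycl = %.4g s, theta = %.3g\n", x$T_cycl, x$theta))
  cat(sprintf("  systemic:  C_ar %.4g  R_ar %.4g  Z_ar %.4g  C_ven %.4g  R_ven %.4g\n",
              x$wk_sys$C_ar, x$wk_sys$R_ar, x$wk_sys$Z_ar,
              x$wk_sys$C_ven, x$wk_sys$R_ven))
  cat(sprintf("  pulmonary: C_ar %.4g  R_ar %.4g  Z_ar %.4g  C_ven %.4g  R_ven %.4g\n",
              x$wk_pul$C_ar, x$wk_pul$R_ar, x$wk_pul$Z_ar,
              x$wk_pul$C_ven, x$wk_pul$R_ven))
  for (v in names(x$valves))
    cat(sprintf("  valve %s: A_eff [%.4g, %.4g] mm^2, K_vo/K_vc %g/%g\n", v,
                x$valves[[v]]$A_eff_min, x$valves[[v]]$A_eff_max,
                x$valves[[v]]$K_vo, x$valves[[v]]$K_vc))
  for (ch in names(x$active))
    cat(sprintf("  chamber %s: sigma_0 %.4g kPa, alpha [%.4g, %.4g] 1/s, V_ref %.4g ml\n",
                ch, x$active[[ch]]$sigma_0, x$active[[ch]]$alpha_min,
                x$active[[ch]]$alpha_max, x$chambers[[ch]]$V_ref / ML))
  invisible(x)
}
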