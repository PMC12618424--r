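# S3 methods and small utilities for simulation objects.

#' @export
print.cardio_sim <- function(x, ...) {
  r <- x$report
  cat(sprintf("Closed-loop 0D simulation: %d cycle(s), E_cycl = %.4g (%s)\n",
              r$n_cycles, r$E_cycl,
              if (r$converged) "periodic" else "not periodic"))
  cat(sprintf("  T_cycl = %.3g s, dt = %.3g s, theta = %.2g\n",
              x$params$T_cycl, x$dt, x$theta))
  invisible(x)
}

#' @export
summary.cardio_sim <- function(object, ...) {
  right <- sim_clinical_metrics(object, "r")
  left <- sim_clinical_metrics(object, "l")
  cat("Final-cycle clinical metrics\n  right: ")
  print(right)
  cat("  left:  ")
  print(left)
  rng <- function(col) range(object$states[, col])
  cat(sprintf("  p_v_l %.2f..%.2f kPa, p_v_r %.2f..%.2f kPa\n",
              rng("p_v_l")[1], rng("p_v_l")[2],
              rng("p_v_r")[1], rng("p_v_r")[2]))
  cat(sprintf("  p_ar_sys %.2f..%.2f kPa, p_ar_pul %.2f..%.2f kPa\n",
              rng("p_ar_sys")[1], rng("p_ar_sys")[2],
              rng("p_ar_pul")[1], rng("p_ar_pul")[2]))
  invisible(list(right = right, left = left))
}

#' @export
plot.cardio_sim <- function(x, what = c("pressures", "volumes", "flows", "pv"),
                            ...) {
  what <- match.arg(what)
  tt <- x$time
  s <- x$states
  switch(what,
    pressures = {
      graphics::matplot(tt, s[, c("p_v_l", "p_ar_sys", "p_v_r", "p_ar_pul")],
                        type = "l", lty = 1, xlab = "t [s]", ylab = "p [kPa]",
                        ...)
      graphics::legend("topright", c("p_v_l", "p_ar_sys", "p_v_r", "p_ar_pul"),
                       lty = 1, col = 1:4, cex = 0.8)
    },
    volumes = {
      graphics::matplot(tt, s[, c("V_v_l", "V_v_r", "V_at_l", "V_at_r")] / ML,
                        type = "l", lty = 1, xlab = "t [s]", ylab = "V [ml]",
                        ...)
      graphics::legend("topright", c("V_v_l", "V_v_r", "V_at_l", "V_at_r"),
                       lty = 1, col = 1:4, cex = 0.8)
    },
    flows = {
      graphics::matplot(tt, s[, c("q_aor", "q_pul")] / ML, type = "l",
                        lty = 1, xlab = "t [s]", ylab = "q [ml/s]", ...)
      graphics::legend("topright", c("q_aor", "q_pul"), lty = 1, col = 1:2,
                       cex = 0.8)
    },
    pv = {
      graphics::plot(s[, "V_v_l"] / ML, s[, "p_v_l"], type = "l",
                     xlim = range(s[, c("V_v_l", "V_v_r")]) / ML,
                     ylim = range(s[, c("p_v_l", "p_v_r")]),
                     xlab = "V [ml]", ylab = "p [kPa]", ...)
      graphics::lines(s[, "V_v_r"] / ML, s[, "p_v_r"], col = 2)
      graphics::legend("topright", c("LV", "RV"), lty = 1, col = 1:2,
                       cex = 0.8)
    })
  invisible(x)
}

#' Turn a simulation into a data frame
#'
#' One row per time step, one column per state entry (volumes and flows
#' converted to ml / ml/s), with a leading `t` column.
#'
#' @param x a `cardio_sim`.
#' @param ... ignored.
#' @return data frame.
#' @export
as.data.frame.cardio_sim <- function(x, ...) {
  df <- as.data.frame(x$states)
  vol_cols <- c("V_at_l", "V_v_l", "V_at_r", "V_v_r")
  q_cols <- grep("^q_", names(df), value = TRUE)
  df[vol_cols] <- df[vol_cols] / ML
  df[q_cols] <- df[q_cols] / ML
  cbind(t = x$time, df)
}

#' Write a simulated trajectory to CSV
#'
#' Header comment row documents the units (kPa, ml, ml/s, s).
#'
#' @param sim a `cardio_sim`.
#' @param path output CSV path.
#' @export
write_trajectory_csv <- function(sim, path) {
  df <- as.data.frame(sim)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# units: t s, p_* kPa, q_* ml/s, V_* ml, z_* -, tau_* kPa", con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Total stored blood volume of a state
#'
#' Sum of the four chamber volumes and the compartmental stored volumes
#' `C (p - Z q_valve)` (arterial) and `C p` (venous); conserved along
#' trajectories of the closed loop up to solver tolerance.
#'
#' @param state numeric[28] state vector.
#' @param params a [circulation_params].
#' @return volume, mm^3.
#' @export
total_blood_volume <- function(state, params) {
  s <- stats::setNames(as.numeric(state), STATE_NAMES)
  sum(s[c("V_at_l", "V_v_l", "V_at_r", "V_v_r")]) +
    params$wk_sys$C_ar * (s[["p_ar_sys"]] - params$wk_sys$Z_ar * s[["q_aor"]]) +
    params$wk_sys$C_ven * s[["p_ven_sys"]] +
    params$wk_pul$C_ar * (s[["p_ar_pul"]] - params$wk_pul$Z_ar * s[["q_pul"]]) +
    params$wk_pul$C_ven * s[["p_ven_pul"]]
}
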