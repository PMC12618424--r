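# Measurement-data model: CSV I/O, cubic-spline interpolation with
# analytic derivatives, time-axis normalization, mass-consistency checks,
# and clinical metric computation.
#
# A measurement set holds named series of (t, value) samples. Recognized
# names (units in parentheses): pressures p_v_l, p_v_r, p_ar_sys,
# p_ar_pul, p_at_r, p_ven_sys, p_ven_pul (kPa); flows q_v_out_l,
# q_v_out_r (ml/s at the I/O boundary, mm^3/s internally); volumes
# V_v_l, V_v_r, V_at_l, V_at_r (ml at the boundary, mm^3 internally).

MEAS_PRESSURES <- c("p_v_l", "p_v_r", "p_ar_sys", "p_ar_pul", "p_at_r",
                    "p_ven_sys", "p_ven_pul")
MEAS_FLOWS <- c("q_v_out_l", "q_v_out_r")
MEAS_VOLUMES <- c("V_v_l", "V_v_r", "V_at_l", "V_at_r")

#' Construct a measurement set
#'
#' @param series named list of data frames with columns `t` (s) and
#'   `value`; values in internal units (kPa / mm^3/s / mm^3).
#' @param T_cycl cardiac cycle duration, s.
#' @param t0 time origin (atrial-contraction onset convention).
#' @return an object of class `measurement_set`.
#' @export
measurement_set <- function(series, T_cycl, t0 = 0) {
  for (nm in names(series)) {
    s <- series[[nm]]
    if (!all(c("t", "value") %in% names(s)))
      stop("series '", nm, "' must have columns t and value")
    if (any(duplicated(s$t)))
      stop("series '", nm, "' has duplicate timestamps")
    if (is.unsorted(s$t, strictly = TRUE))
      stop("series '", nm, "' must be strictly increasing in t")
  }
  structure(list(series = series, T_cycl = T_cycl, t0 = t0),
            class = "measurement_set")
}

#' Read measurements from CSV (+ sidecar JSON)
#'
#' The CSV holds a `t` column plus any subset of the recognized series
#' names; missing cells (different sampling rates per series) are `NA`.
#' The sidecar JSON declares `T_cycl` and per-series units (`kPa` or
#' `mmHg` for pressures, `ml/s` or `mm^3/s` for flows, `ml` or `mm^3` for
#' volumes); values are converted to internal units on read.
#'
#' @param path CSV file path.
#' @param sidecar path to the sidecar JSON; defaults to `path` with a
#'   `.json` extension.
#' @return a [measurement_set()].
#' @export
read_measurements <- function(path, sidecar = NULL) {
  if (is.null(sidecar)) sidecar <- sub("\\.csv$", ".json", path)
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar, simplifyVector = TRUE)
          else list(T_cycl = NA_real_, units = list())
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"t" %in% names(df)) stop("CSV must have a 't' column")
  series <- list()
  for (nm in setdiff(names(df), "t")) {
    keep <- !is.na(df[[nm]])
    if (!any(keep)) next
    v <- df[[nm]][keep]; tt <- df$t[keep]
    unit <- meta$units[[nm]]
    fac <- meas_unit_factor(nm, unit)
    series[[nm]] <- data.frame(t = tt, value = v * fac)
  }
  Tc <- meta$T_cycl
  if (is.null(Tc) || is.na(Tc))
    Tc <- max(df$t) - min(df$t)
  measurement_set(series, T_cycl = Tc, t0 = min(df$t))
}

# conversion factor from declared unit to internal units
meas_unit_factor <- function(name, unit) {
  if (is.null(unit)) {
    # default: I/O boundary units ml, ml/s, kPa
    if (name %in% MEAS_VOLUMES) return(ML)
    if (name %in% MEAS_FLOWS || startsWith(name, "q")) return(ML)
    return(1)
  }
  switch(unit,
         "kPa" = 1, "mmHg" = 0.133322,
         "ml" = ML, "mm^3" = 1,
         "ml/s" = ML, "mm^3/s" = 1,
         stop("unknown unit '", unit, "' for series ", name))
}

#' Write a measurement set to CSV (+ sidecar JSON)
#'
#' Inverse of [read_measurements()]; values are written in boundary units
#' (kPa, ml/s, ml).
#'
#' @param mset a [measurement_set()].
#' @param path CSV file path; sidecar written next to it.
#' @export
write_measurements <- function(mset, path) {
  tt <- sort(unique(unlist(lapply(mset$series, function(s) s$t))))
  df <- data.frame(t = tt)
  units <- list()
  for (nm in names(mset$series)) {
    s <- mset$series[[nm]]
    fac <- if (nm %in% MEAS_VOLUMES || startsWith(nm, "q")) 1 / ML else 1
    col <- rep(NA_real_, length(tt))
    col[match(s$t, tt)] <- s$value * fac
    df[[nm]] <- col
    units[[nm]] <- if (nm %in% MEAS_VOLUMES) "ml"
      else if (startsWith(nm, "q")) "ml/s" else "kPa"
  }
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(list(T_cycl = mset$T_cycl, t0 = mset$t0, units = units),
                       sub("\\.csv$", ".json", path),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Cubic-spline interpolant of a sampled series
#'
#' C^2 interpolant through all samples with an analytic first derivative
#' (required by the flow-eliminated windkessel ODE). With
#' `periodic = TRUE` the value and slope match at the two ends of the
#' cycle; the last sample must then equal the first (it is appended at
#' `t[1] + T_cycl` if absent).
#'
#' @param series data frame with columns `t`, `value` (or a list
#'   `list(t=, value=)`).
#' @param periodic use periodic boundary conditions.
#' @param T_cycl cycle duration, required for `periodic` when the series
#'   does not already close the cycle.
#' @return function `f(t, deriv = 0)` with attribute `t_range`; for
#'   periodic splines the argument is reduced modulo the cycle.
#' @export
spline_series <- function(series, periodic = FALSE, T_cycl = NULL) {
  tt <- series$t; v <- series$value
  if (length(tt) < 4) stop("need at least 4 samples for a cubic spline")
  if (periodic) {
    if (abs(v[length(v)] - v[1]) > 1e-9 * max(1, abs(v[1])) ||
        is.null(T_cycl) == FALSE && abs((tt[length(tt)] - tt[1]) - T_cycl) > 1e-9) {
      if (is.null(T_cycl)) stop("periodic spline needs T_cycl to close the cycle")
      tt <- c(tt, tt[1] + T_cycl)
      v <- c(v, v[1])
    }
    sf <- stats::splinefun(tt, v, method = "periodic")
    Tc <- tt[length(tt)] - tt[1]
    f <- function(t, deriv = 0) sf(tt[1] + (t - tt[1]) %% Tc, deriv = deriv)
    attr(f, "t_range") <- c(-Inf, Inf)
  } else {
    sf <- stats::splinefun(tt, v, method = "fmm")
    f <- function(t, deriv = 0) sf(t, deriv = deriv)
    attr(f, "t_range") <- range(tt)
  }
  attr(f, "samples") <- data.frame(t = series$t, value = series$value)
  f
}

#' Smoothing spline of a dense periodic series
#'
#' Catheter pressure traces are densely sampled and noisy; extrema and
#' derivative features taken from an interpolating spline would be
#' dominated by the noise. This fits a cross-validated smoothing spline to
#' the series replicated over three periods (periodic continuation) and
#' evaluates on the central copy, so values and slopes wrap consistently
#' across the cycle seam.
#'
#' @param series data frame with `t`, `value`.
#' @param T_cycl cycle duration, s.
#' @return function `f(t, deriv = 0)` with attribute `t_range` unbounded.
#' @export
smooth_periodic_series <- function(series, T_cycl) {
  t0 <- series$t[1]
  tt <- c(series$t - T_cycl, series$t, series$t + T_cycl)
  vv <- rep(series$value, 3)
  ss <- stats::smooth.spline(tt, vv)
  f <- function(t, deriv = 0) {
    tl <- t0 + (t - t0) %% T_cycl
    stats::predict(ss, tl, deriv = deriv)$y
  }
  attr(f, "t_range") <- c(-Inf, Inf)
  f
}

#' Normalize the time axes of a measurement set
#'
#' Linearly rescales each series' own cycle duration to `target_T_cycl`
#' and circularly shifts so that `t = 0` coincides with the atrial
#' contraction onset. Heart-rate differences between acquisitions are
#' assumed small enough that all phases scale uniformly.
#'
#' @param mset a [measurement_set()].
#' @param target_T_cycl target cycle duration, s.
#' @param t0_event atrial-contraction onset, either a single time or a
#'   named vector per series (in each series' original time axis).
#' @param source_T_cycl optional named vector of per-series cycle
#'   durations; defaults to `mset$T_cycl` for every series.
#' @return normalized [measurement_set()] with `t0 = 0`.
#' @export
normalize_time_axis <- function(mset, target_T_cycl, t0_event = 0,
                                source_T_cycl = NULL) {
  out <- list()
  for (nm in names(mset$series)) {
    s <- mset$series[[nm]]
    Ts <- if (!is.null(source_T_cycl))
      (if (nm %in% names(source_T_cycl)) source_T_cycl[[nm]] else NA_real_)
      else mset$T_cycl
    if (is.na(Ts)) stop("unknown source cycle duration for series ", nm)
    ev <- if (length(t0_event) > 1) {
      if (!nm %in% names(t0_event)) stop("no t0 event for series ", nm)
      t0_event[[nm]]
    } else t0_event
    scale <- target_T_cycl / Ts
    tnew <- ((s$t - ev) %% Ts) * scale
    o <- order(tnew)
    out[[nm]] <- data.frame(t = tnew[o], value = s$value[o])
  }
  measurement_set(out, T_cycl = target_T_cycl, t0 = 0)
}

#' Clinical volumetric metrics of a ventricle
#'
#' EDV and ESV are the extrema of the volume series; SV = EDV - ESV and
#' EF = 100 SV / EDV. The retrograde volume RV is the magnitude of the
#' cycle integral of negative semilunar flow; the forward volume is
#' reported as FV = SV - RV so that FV + RV = SV, and the regurgitation
#' fraction is RF = 100 RV / (FV + RV).
#'
#' @param volume_series data frame `t` (s), `value` (ml) over one cycle.
#' @param flow_series data frame `t` (s), `value` (ml/s) of the
#'   corresponding semilunar valve flow over one cycle.
#' @return object of class `clinical_metrics`: named list with `EDV`,
#'   `ESV`, `SV` (ml), `EF` (%), `FV`, `RV` (ml), `RF` (%).
#' @export
clinical_metrics <- function(volume_series, flow_series) {
  if (!nrow(volume_series) || !nrow(flow_series)) stop("empty series")
  EDV <- max(volume_series$value); ESV <- min(volume_series$value)
  SV <- EDV - ESV
  q <- flow_series$value; tt <- flow_series$t
  RV <- abs(trapz(tt, pmin(0, q)))
  metrics_from_volumes(EDV, ESV, RV = RV)
}

# trapezoidal quadrature
trapz <- function(t, y) sum(diff(t) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)

#' Clinical metrics from tabulated volumes
#'
#' Completes the derived quantities (SV, EF, FV, RF) from end-diastolic /
#' end-systolic volumes and a retrograde (or forward) volume, using
#' SV = EDV - ESV, EF = 100 SV / EDV, FV = SV - RV,
#' RF = 100 RV / (FV + RV).
#'
#' @param EDV,ESV end-diastolic and end-systolic volumes, ml.
#' @param FV,RV forward and retrograde volumes, ml; give either (the other
#'   follows from FV + RV = SV).
#' @return object of class `clinical_metrics`.
#' @export
metrics_from_volumes <- function(EDV, ESV, FV = NULL, RV = NULL) {
  SV <- EDV - ESV
  if (is.null(RV) && is.null(FV)) { RV <- 0 }
  if (is.null(RV)) RV <- SV - FV
  FV <- SV - RV
  if (min(EDV, ESV, FV, RV) < 0)
    warning("negative volume in clinical metrics")
  structure(list(EDV = EDV, ESV = ESV, SV = SV, EF = 100 * SV / EDV,
                 FV = FV, RV = RV, RF = 100 * RV / (FV + RV)),
            class = "clinical_metrics")
}

#' @export
print.clinical_metrics <- function(x, ...) {
  cat(sprintf("EDV %.1f  ESV %.1f  SV %.1f ml   EF %.1f %%   FV %.1f  RV %.1f ml   RF %.1f %%\n",
              x$EDV, x$ESV, x$SV, x$EF, x$FV, x$RV, x$RF))
  invisible(x)
}

#' Check mass consistency between volume and flow measurements
#'
#' Cine-MRI volumes and phase-contrast flows come from different
#' acquisitions and need not satisfy conservation of mass. The check
#' compares, over the ejection window (flow above 5 % of its peak), the
#' cycle-integrated semilunar flow against the ventricular volume drop,
#' and reports the ratio. In adjustment mode the volume excursion is
#' rescaled about its mean by that factor (flows are trusted, volumes
#' adjusted).
#'
#' @param volume_series data frame `t`, `value` (internal units mm^3).
#' @param flow_series data frame `t`, `value` (mm^3/s).
#' @param adjust rescale the volume series.
#' @param tolerance relative discrepancy above which the report flags the
#'   pair as inconsistent.
#' @return list with `factor` (flow-implied over measured excursion),
#'   `max_discrepancy` (relative), `consistent`, `adjusted_volume` (data
#'   frame, only when `adjust = TRUE`), `adjusted_series` (name flag).
#' @export
check_mass_consistency <- function(volume_series, flow_series,
                                   adjust = FALSE, tolerance = 0.02) {
  qf <- spline_series(flow_series)
  vf <- spline_series(volume_series)
  qmax <- max(flow_series$value)
  win <- flow_series$t[flow_series$value > 0.05 * qmax]
  if (length(win) < 2) stop("no ejection window found in flow series")
  t1 <- min(win); t2 <- max(win)
  ejected <- stats::integrate(function(t) pmax(0, qf(t)), t1, t2,
                              subdivisions = 400)$value
  drop <- vf(t1) - vf(t2)
  factor <- ejected / drop
  disc <- abs(factor - 1)
  out <- list(factor = factor, max_discrepancy = disc,
              consistent = disc <= tolerance,
              adjusted_series = if (adjust) "volume" else NA_character_)
  if (adjust) {
    vbar <- mean(volume_series$value)
    out$adjusted_volume <- data.frame(
      t = volume_series$t,
      value = vbar + factor * (volume_series$value - vbar))
  }
  out
}
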