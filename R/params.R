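ctypes <- c("sa", "sv", "ra", "pa", "pv")

deep_merge <- function(base, override) {
  if (is.null(override)) return(base)
  for (nm in names(override)) {
    if (is.list(override[[nm]]) && is.list(base[[nm]]))
      base[[nm]] <- deep_merge(base[[nm]], override[[nm]])
    else
      base[[nm]] <- override[[nm]]
  }
  base
}

#' The frozen default parameter set
#'
#' Reads the calibrated network and controller parameters shipped with the
#' package (`inst/extdata/default_params.json`).  This file is the
#' calibration artifact: its component values were tuned once so that the
#' built-in five-phase protocol reproduces the reference hemodynamic
#' checkpoints, and are not meant to be edited at run time.
#'
#' @return list with elements `network` (a `cv_network`) and `control`
#'   (a `cv_control`).
#' @export
default_params <- function() {
  path <- system.file("extdata", "default_params.json", package = "hemocirc")
  load_params(path)
}

#' Load and validate a parameter file
#'
#' Parameter files are JSON documents with a `network` and a `control`
#' block, all values in physiological units (mmHg, mL, s, U, FGU).  Omitted
#' optional fields are filled from the shipped defaults; every structural
#' invariant (positive compliances and resistances, Sy range inside
#' \[0, 8\] FGU, ...) is checked at load time.
#'
#' @param path path to a JSON parameter document.
#' @return list with validated `network` and `control` components.
#' @export
load_params <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path)
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  is_default <- identical(
    normalizePath(path),
    normalizePath(system.file("extdata", "default_params.json",
                              package = "hemocirc")))
  if (is_default) {
    network <- structure(doc$network, class = "cv_network")
    control <- structure(doc$control, class = "cv_control")
  } else {
    defaults <- default_params()
    network <- structure(deep_merge(unclass(defaults$network), doc$network),
                         class = "cv_network")
    control <- structure(deep_merge(unclass(defaults$control), doc$control),
                         class = "cv_control")
  }
  validate_network(network)
  validate_control(control)
  list(network = network, control = control)
}

#' Save a parameter set to JSON
#'
#' @param params list with `network` and `control` (as from
#'   [default_params()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_params <- function(params, path) {
  jsonlite::write_json(
    list(network = unclass(params$network), control = unclass(params$control)),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
  invisible(path)
}

#' Construct a circulatory network specification
#'
#' The closed loop has seven compliant compartments -- left ventricle,
#' systemic arteries (aorta), systemic veins (with a venoconstriction-
#' controlled unstressed volume), right atrium, right ventricle, pulmonary
#' arteries and pulmonary veins merged with the left atrium -- connected by
#' seven resistors of which four are ideal one-way valves (mitral, aortic,
#' tricuspid, pulmonic).  Arguments override the corresponding entries of
#' the frozen default network.
#'
#' @param ... named blocks to override, e.g.
#'   `ventricles = list(lv = list(nominal_gain = 20))`.
#' @return object of class `cv_network`.
#' @export
cv_network <- function(...) {
  net <- deep_merge(unclass(default_params()$network), list(...))
  net <- structure(net, class = "cv_network")
  validate_network(net)
  net
}

#' Construct a feedback-controller specification
#'
#' Proportional control of mean aortic pressure with a first-order actuator
#' lag: the sympathetic signal Sy relaxes toward
#' `sy_baseline + feedback_gain * (maop_setpoint - MAoP)`, clipped to
#' `sy_range`, and drives heart rate, biventricular inotropy (through the
#' FGU limiter) and venous unstressed volume through monotone affine maps.
#' Per-limb switches freeze an effector at its last commanded value; clamps
#' override heart rate and/or Sy outright (used by [syncope_mode()]).
#'
#' @param ... named fields to override the frozen default controller.
#' @return object of class `cv_control`.
#' @export
cv_control <- function(...) {
  ctl <- deep_merge(unclass(default_params()$control), list(...))
  ctl <- structure(ctl, class = "cv_control")
  validate_control(ctl)
  ctl
}

fail_field <- function(field, constraint) {
  stop("invalid parameter `", field, "`: ", constraint, call. = FALSE)
}

#' Validate a network specification
#'
#' @param net a `cv_network`.
#' @return `net`, invisibly; errors name the offending field and constraint.
#' @export
validate_network <- function(net) {
  for (cc in ctypes) {
    cm <- net$compartments[[cc]]
    if (is.null(cm)) fail_field(paste0("compartments.", cc), "missing")
    if (!is.numeric(cm$compliance) || cm$compliance <= 0)
      fail_field(paste0("compartments.", cc, ".compliance"), "must be > 0")
    if (!is.numeric(cm$unstressed_volume) || cm$unstressed_volume < 0)
      fail_field(paste0("compartments.", cc, ".unstressed_volume"),
                 "must be >= 0")
  }
  for (vv in c("lv", "rv")) {
    v <- net$ventricles[[vv]]
    if (is.null(v)) fail_field(paste0("ventricles.", vv), "missing")
    for (f in c("nominal_gain", "elastance_scale", "passive_compliance",
                "systole_duration", "relaxation_tau"))
      if (!is.numeric(v[[f]]) || v[[f]] <= 0)
        fail_field(paste0(vv, ".", f), "must be > 0")
    if (v$unstressed_volume < 0)
      fail_field(paste0(vv, ".", "unstressed_volume"), "must be >= 0")
    if (v$activation_peak_frac <= 0 || v$activation_peak_frac >= 1)
      fail_field(paste0(vv, ".activation_peak_frac"), "must be in (0, 1)")
  }
  if (net$ventricles$lv$stenosis_severity < 0)
    fail_field("lv.stenosis_severity", "must be >= 0")
  if (net$ventricles$lv$stenosis_scale <= 0)
    fail_field("lv.stenosis_scale", "must be > 0")
  for (rr in names(net$resistors)) {
    r <- net$resistors[[rr]]
    if (!is.numeric(r$resistance) || r$resistance <= 0)
      fail_field(paste0("resistors.", rr, ".resistance"), "must be > 0")
  }
  need <- c("mitral", "aortic", "systemic", "venous_return", "tricuspid",
            "pulmonic", "pulmonary")
  miss <- setdiff(need, names(net$resistors))
  if (length(miss)) fail_field(paste0("resistors.", miss[1]), "missing")
  rp <- net$respiration
  if (rp$mean_itp >= 0)
    fail_field("respiration.mean_itp",
               "must be < 0 (sub-atmospheric thoracic pressure)")
  if (rp$period <= 0) fail_field("respiration.period", "must be > 0")
  if (rp$amplitude < 0) fail_field("respiration.amplitude", "must be >= 0")
  if (!is.null(net$total_blood_volume)) {
    v <- initial_volumes(net)
    if (abs(sum(v) - net$total_blood_volume) > 1e-6)
      fail_field("total_blood_volume",
                 sprintf("must equal the sum of initial compartment volumes (%.3f)",
                         sum(v)))
  }
  invisible(net)
}

#' Validate a controller specification
#'
#' @param ctl a `cv_control`.
#' @return `ctl`, invisibly.
#' @export
validate_control <- function(ctl) {
  if (ctl$maop_setpoint <= 0) fail_field("control.maop_setpoint", "must be > 0")
  for (f in c("maop_filter_tau", "actuator_tau", "feedback_gain"))
    if (ctl[[f]] <= 0) fail_field(paste0("control.", f), "must be > 0")
  sr <- ctl$sy_range
  if (length(sr) != 2 || sr[1] < 0 || sr[2] > 8 || sr[1] >= sr[2])
    fail_field("control.sy_range", "must be an increasing range inside [0, 8] FGU")
  if (ctl$sy_baseline < sr[1] || ctl$sy_baseline > sr[2])
    fail_field("control.sy_baseline", "must lie inside sy_range")
  if (ctl$hr_map$slope < 0) fail_field("control.hr_map.slope", "must be >= 0")
  if (is.null(ctl$venous$sat) || ctl$venous$sat <= 0)
    fail_field("control.venous.sat", "must be > 0")
  if (ctl$inotropic$limiter_max <= 0 || ctl$inotropic$limiter_max > 8)
    fail_field("control.inotropic.limiter_max", "must be in (0, 8] FGU")
  for (f in c("heart_rate", "sy")) {
    cl <- ctl$clamps[[f]]
    if (!is.null(cl) && !is.na(cl) && cl < 0)
      fail_field(paste0("control.clamps.", f), "must be >= 0")
  }
  invisible(ctl)
}

# initial compartment volumes from the configured initial pressures
initial_volumes <- function(net) {
  p <- net$initial_pressures
  v <- c(
    V_lv = net$ventricles$lv$unstressed_volume +
      net$ventricles$lv$passive_compliance * p$lv,
    V_sa = net$compartments$sa$unstressed_volume +
      net$compartments$sa$compliance * p$sa,
    V_sv = net$compartments$sv$unstressed_volume +
      net$compartments$sv$compliance * p$sv,
    V_ra = net$compartments$ra$unstressed_volume +
      net$compartments$ra$compliance * p$ra,
    V_rv = net$ventricles$rv$unstressed_volume +
      net$ventricles$rv$passive_compliance * p$rv,
    V_pa = net$compartments$pa$unstressed_volume +
      net$compartments$pa$compliance * p$pa,
    V_pv = net$compartments$pv$unstressed_volume +
      net$compartments$pv$compliance * p$pv)
  if (any(v < 0)) stop("initial pressures imply a negative compartment volume")
  v
}

# flatten network + control into the named list the C++ core consumes
pack_params <- function(net, ctl) {
  lv <- net$ventricles$lv; rv <- net$ventricles$rv
  list(
    c_sa = net$compartments$sa$compliance,
    v0_sa = net$compartments$sa$unstressed_volume,
    c_sv = net$compartments$sv$compliance,
    v0_sv = net$compartments$sv$unstressed_volume,
    c_ra = net$compartments$ra$compliance,
    v0_ra = net$compartments$ra$unstressed_volume,
    c_pa = net$compartments$pa$compliance,
    v0_pa = net$compartments$pa$unstressed_volume,
    c_pv = net$compartments$pv$compliance,
    v0_pv = net$compartments$pv$unstressed_volume,
    lv_gain = lv$nominal_gain, lv_escale = lv$elastance_scale,
    lv_v0 = lv$unstressed_volume, lv_cpass = lv$passive_compliance,
    rv_gain = rv$nominal_gain, rv_escale = rv$elastance_scale,
    rv_v0 = rv$unstressed_volume, rv_cpass = rv$passive_compliance,
    sys_dur = lv$systole_duration, act_peak_frac = lv$activation_peak_frac,
    r_mit = net$resistors$mitral$resistance,
    r_av = net$resistors$aortic$resistance,
    sten_sev = lv$stenosis_severity, sten_scale = lv$stenosis_scale,
    r_sys = net$resistors$systemic$resistance,
    r_ven = net$resistors$venous_return$resistance,
    r_tri = net$resistors$tricuspid$resistance,
    r_rvout = net$resistors$pulmonic$resistance,
    r_pul = net$resistors$pulmonary$resistance,
    itp_mean = net$respiration$mean_itp,
    itp_amp = net$respiration$amplitude,
    itp_period = net$respiration$period,
    setpoint = ctl$maop_setpoint, tau_maop = ctl$maop_filter_tau,
    gain_fb = ctl$feedback_gain, sy_baseline = ctl$sy_baseline,
    sy_min = ctl$sy_range[1], sy_max = ctl$sy_range[2],
    tau_sy = ctl$actuator_tau,
    hr_base = ctl$hr_map$base, hr_slope = ctl$hr_map$slope,
    hr_min = ctl$hr_map$min, hr_max = ctl$hr_map$max,
    ino_slope = ctl$inotropic$slope, limiter = ctl$inotropic$limiter_max,
    kven = ctl$venous$k, kven_sat = ctl$venous$sat,
    v0sv_min_frac = ctl$venous$min_frac, v0sv_max_frac = ctl$venous$max_frac,
    hr_on = isTRUE(ctl$switches$hr),
    lv_ino_on = isTRUE(ctl$switches$lv_inotropy),
    rv_ino_on = isTRUE(ctl$switches$rv_inotropy),
    ven_on = isTRUE(ctl$switches$venous_tone),
    clamp_hr = if (is.null(ctl$clamps$heart_rate) || is.na(ctl$clamps$heart_rate))
      NA_real_ else as.numeric(ctl$clamps$heart_rate),
    clamp_sy = if (is.null(ctl$clamps$sy) || is.na(ctl$clamps$sy))
      NA_real_ else as.numeric(ctl$clamps$sy))
}

#' @export
print.cv_network <- function(x, ...) {
  lv <- x$ventricles$lv
  cat("<cv_network> 7-compartment closed loop\n")
  cat(sprintf("  LV: nominal gain %g, Emax scale %g mmHg/mL, systole %g s\n",
              lv$nominal_gain, lv$elastance_scale, lv$systole_duration))
  cat(sprintf("  aortic stenosis severity: %g U (hydraulic scale %g)\n",
              lv$stenosis_severity, lv$stenosis_scale))
  cat(sprintf("  systemic resistance: %g U; total blood volume: %g mL\n",
              x$resistors$systemic$resistance, sum(initial_volumes(x))))
  invisible(x)
}

#' @export
print.cv_control <- function(x, ...) {
  cat("<cv_control> proportional MAoP feedback\n")
  cat(sprintf("  setpoint %g mmHg, gain %g FGU/mmHg, Sy baseline %g FGU in [%g, %g]\n",
              x$maop_setpoint, x$feedback_gain, x$sy_baseline,
              x$sy_range[1], x$sy_range[2]))
  sw <- x$switches
  cat(sprintf("  limbs on: hr=%s lv=%s rv=%s venous=%s; clamps: HR=%s Sy=%s\n",
              sw$hr, sw$lv_inotropy, sw$rv_inotropy, sw$venous_tone,
              format(x$clamps$heart_rate), format(x$clamps$sy)))
  invisible(x)
}
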