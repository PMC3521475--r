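#' First-order low-pass filter of aortic pressure (MAoP)
#'
#' Mean aortic pressure as seen by the feedback controller: an exponential
#' first-order filter with time constant `tau`.  For constant input the
#' output converges to that constant; as `tau` approaches zero the filter
#' tracks the instantaneous pressure.
#'
#' @param trace a `cv_trace` (its `AoP` column is filtered) or a numeric
#'   vector of aortic pressures.
#' @param tau filter time constant (s).
#' @param dt sample spacing (s); taken from the trace when omitted.
#' @param init initial filter state; defaults to the first sample.
#' @return numeric vector of filtered pressures, same length as the input.
#' @export
filtered_maop <- function(trace, tau, dt = NULL, init = NULL) {
  aop <- if (is.data.frame(trace)) trace$AoP else trace
  if (length(aop) == 0) stop("empty pressure trace")
  if (is.null(dt)) {
    if (!is.data.frame(trace)) stop("`dt` required for a bare vector")
    dt <- trace$t[2] - trace$t[1]
  }
  stopifnot(tau >= 0, dt > 0)
  if (tau == 0) return(aop)
  alpha <- 1 - exp(-dt / tau)
  out <- numeric(length(aop))
  out[1] <- if (is.null(init)) aop[1] else init
  for (i in seq_along(aop)[-1])
    out[i] <- out[i - 1] + alpha * (aop[i] - out[i - 1])
  out
}

#' One update of the sympathetic modulation signal Sy
#'
#' First-order relaxation of Sy toward the proportional-control target
#' `sy_baseline + feedback_gain * (maop_setpoint - maop)`, clipped to
#' `sy_range`.  The update is the exact exponential solution over `dt`, so
#' arbitrarily large steps remain stable.  A Sy clamp in `spec` overrides
#' the dynamics entirely.
#'
#' @param maop current filtered mean aortic pressure (mmHg).
#' @param spec a [cv_control()].
#' @param sy_prev previous Sy (FGU).
#' @param dt time step (s), > 0.
#' @return updated Sy in FGU, always inside `sy_range`.
#' @export
update_sy <- function(maop, spec, sy_prev, dt) {
  stopifnot(dt > 0)
  cl <- spec$clamps$sy
  if (!is.null(cl) && !is.na(cl)) return(cl)
  target <- spec$sy_baseline + spec$feedback_gain * (spec$maop_setpoint - maop)
  target <- min(max(target, spec$sy_range[1]), spec$sy_range[2])
  sy <- target + (sy_prev - target) * exp(-dt / spec$actuator_tau)
  min(max(sy, spec$sy_range[1]), spec$sy_range[2])
}

#' Map Sy to its effector outputs
#'
#' Monotone effector maps: heart rate
#' `base + slope * (Sy - sy_baseline)` (1/min, clipped to its range),
#' inotropic drive equal to Sy (in FGU, saturated later by the limiter),
#' and venous unstressed-volume reduction
#' `sat * tanh(k * (Sy - sy_baseline) / sat)` (mL: venoconstriction when Sy
#' rises, venodilation below baseline, saturating at `sat` mL).  A limb
#' whose switch is off returns its frozen last-on value; a
#' clamped quantity returns the clamp.
#'
#' @param sy sympathetic modulation (FGU).
#' @param spec a [cv_control()]; its optional `frozen` element (list with
#'   `heart_rate`, `lv_drive`, `rv_drive`, `venous_unstressed_delta`)
#'   supplies the last-on values for switched-off limbs, defaulting to the
#'   baseline operating point.
#' @return list with `heart_rate` (1/min), `lv_drive` and `rv_drive` (FGU)
#'   and `venous_unstressed_delta` (mL).
#' @export
apply_effectors <- function(sy, spec) {
  fr <- spec$frozen
  if (is.null(fr))
    fr <- list(heart_rate = spec$hr_map$base,
               lv_drive = spec$sy_baseline, rv_drive = spec$sy_baseline,
               venous_unstressed_delta = 0)
  hr_map <- function(s)
    min(max(spec$hr_map$base + spec$hr_map$slope * (s - spec$sy_baseline),
            spec$hr_map$min), spec$hr_map$max)
  hr <- if (!is.null(spec$clamps$heart_rate) && !is.na(spec$clamps$heart_rate))
    spec$clamps$heart_rate
  else if (isTRUE(spec$switches$hr)) hr_map(sy) else fr$heart_rate
  list(
    heart_rate = hr,
    lv_drive = if (isTRUE(spec$switches$lv_inotropy)) sy else fr$lv_drive,
    rv_drive = if (isTRUE(spec$switches$rv_inotropy)) sy else fr$rv_drive,
    venous_unstressed_delta = if (isTRUE(spec$switches$venous_tone))
      spec$venous$sat * tanh(spec$venous$k * (sy - spec$sy_baseline) /
                               spec$venous$sat)
    else fr$venous_unstressed_delta)
}

#' Configure a controller for a reflex-syncope variant
#'
#' Models the failure of homeostasis during exertional reflex syncope by
#' clamping the controller outputs: the Sy clamp replaces the feedback
#' dynamics (while still driving all enabled effector maps) and the heart
#' rate clamp overrides the chronotropic limb.
#'
#' Variants: `"a"` heart rate 120/min, Sy 1.0 FGU; `"b"` 120/min, Sy 0.5;
#' `"c"` 45/min, Sy 0.5; `"d"` 45/min, Sy 1.5.
#'
#' @param spec a [cv_control()].
#' @param variant one of `"a"`, `"b"`, `"c"`, `"d"`.
#' @param venous_tone `"follows_sy"` (default: venoconstriction tracks the
#'   clamped Sy) or `"off"` (the venous-tone limb is switched off and holds
#'   its pre-syncope level).
#' @return the modified `cv_control`.
#' @export
syncope_mode <- function(spec, variant,
                         venous_tone = c("follows_sy", "off")) {
  venous_tone <- match.arg(venous_tone)
  clamps <- switch(as.character(variant),
                   a = list(heart_rate = 120, sy = 1.0),
                   b = list(heart_rate = 120, sy = 0.5),
                   c = list(heart_rate = 45, sy = 0.5),
                   d = list(heart_rate = 45, sy = 1.5),
                   stop("unknown syncope variant: ", variant))
  spec$clamps <- clamps
  if (venous_tone == "off") spec$switches$venous_tone <- FALSE
  validate_control(spec)
  spec
}
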