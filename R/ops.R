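#' Flow through a resistive (optionally valved) connection
#'
#' Ohm's-law analogue of a vascular resistance: `(p_upstream -
#' p_downstream) / resistance`.  When `one_way = TRUE` the element behaves as
#' an ideal diode and reverse flow is exactly zero, as for the mitral and
#' aortic valves.
#'
#' @param p_upstream,p_downstream pressures on either side (mmHg).
#' @param resistance flow resistance in U (1 U = 1 mmHg per mL/s); must be
#'   positive.
#' @param one_way logical; if `TRUE`, negative gradients yield zero flow.
#' @return flow in mL/s (vectorised over the pressure arguments).
#' @examples
#' valve_flow(100, 80, 1, one_way = TRUE)   # 20 mL/s forward
#' valve_flow(80, 100, 1, one_way = TRUE)   # 0, no reverse flow
#' @export
valve_flow <- function(p_upstream, p_downstream, resistance, one_way = FALSE) {
  if (!is.numeric(resistance) || any(resistance <= 0))
    stop("`resistance` must be positive (got ", paste(resistance, collapse = ", "), ")")
  q <- (p_upstream - p_downstream) / resistance
  if (isTRUE(one_way)) q <- pmax(q, 0)
  q
}

#' Ventricular activation waveform
#'
#' Normalised activation of the ventricular elastance over the cardiac
#' cycle.  Systole has a fixed duration independent of heart rate; the
#' waveform rises as a quarter-sine to 1 at `peak_frac * systole_duration`
#' and falls as a quarter-cosine back to 0 at `systole_duration`.  Outside
#' (0, `systole_duration`) the activation is exactly zero, so a faster heart
#' rate shortens diastole only.
#'
#' @param phase time since beat onset (s); vectorised.
#' @param systole_duration duration of systole (s), 0.2 by default.
#' @param peak_frac fraction of systole at which activation peaks (0.6 by
#'   default, i.e. 0.12 s into a 0.2 s systole).
#' @return activation in \[0, 1\].
#' @export
ventricular_activation <- function(phase, systole_duration = 0.2,
                                   peak_frac = 0.6) {
  stopifnot(systole_duration > 0, peak_frac > 0, peak_frac < 1)
  if (any(phase < 0)) stop("`phase` must be non-negative")
  tp <- peak_frac * systole_duration
  a <- numeric(length(phase))
  rise <- phase > 0 & phase < tp
  fall <- phase >= tp & phase < systole_duration
  a[rise] <- sin(pi / 2 * phase[rise] / tp)
  a[fall] <- cos(pi / 2 * (phase[fall] - tp) / (systole_duration - tp))
  a
}

#' Effective ventricular gain under inotropic drive
#'
#' Maps the nominal gain of a ventricle and the sympathetic inotropic drive
#' (in FGU) to the effective gain.  The drive saturates at `limiter_max`
#' FGU -- the voltage-limiter analogue -- so any drive at or above the limit
#' yields the same effective gain.  At zero drive the effective gain equals
#' the nominal gain.
#'
#' @param nominal_gain dimensionless nominal gain (100 for a normal left
#'   ventricle; about 20 when contractility is depressed).
#' @param inotropic_drive drive in FGU; negative values are clipped to 0
#'   with a warning.
#' @param limiter_max saturation level in FGU (default 8).
#' @param slope fractional gain increase per FGU of drive (default 0.25).
#' @return effective gain, monotone non-decreasing in the drive.
#' @export
effective_gain <- function(nominal_gain, inotropic_drive, limiter_max = 8,
                           slope = 0.25) {
  if (any(inotropic_drive < 0)) {
    warning("negative inotropic drive clipped to 0")
    inotropic_drive <- pmax(inotropic_drive, 0)
  }
  nominal_gain * (1 + slope * pmin(inotropic_drive, limiter_max))
}

#' Instantaneous ventricular pressure
#'
#' Time-varying elastance law: the active pressure is
#' `activation * E * (volume - unstressed_volume)` with the peak elastance
#' `E` proportional to the effective gain; the passive (diastolic) pressure
#' is `(volume - unstressed_volume) / passive_compliance`; thoracic
#' compartments are referenced to the intrathoracic pressure, which lets
#' early-diastolic ventricular pressure dip slightly below zero.  After
#' systole any residual active component decays with `relaxation_tau`
#' (with the default waveform the activation already reaches zero at end
#' systole, so the decay term matters only for waveforms truncated early).
#'
#' @param volume ventricular volume (mL, non-negative).
#' @param activation activation level in \[0, 1\] (see
#'   [ventricular_activation()]).
#' @param g_eff effective gain (see [effective_gain()]).
#' @param elastance_scale peak elastance (mmHg/mL) at effective gain 100.
#' @param unstressed_volume volume at zero recoil pressure (mL).
#' @param passive_compliance diastolic compliance (mL/mmHg).
#' @param relaxation_tau time constant (s) of post-systolic decay of any
#'   residual activation.
#' @param time_since_systole_end seconds since end of systole (0 during
#'   systole).
#' @param residual_activation activation level at end systole (0 for the
#'   default waveform).
#' @param itp intrathoracic reference pressure (mmHg); use 0 to disable
#'   thoracic referencing.
#' @return pressure in mmHg.
#' @export
ventricular_pressure <- function(volume, activation, g_eff,
                                 elastance_scale, unstressed_volume,
                                 passive_compliance,
                                 relaxation_tau = 0.05,
                                 time_since_systole_end = 0,
                                 residual_activation = 0,
                                 itp = 0) {
  stopifnot(all(volume >= 0), passive_compliance > 0, relaxation_tau > 0)
  act <- activation +
    residual_activation * exp(-time_since_systole_end / relaxation_tau) *
      (activation == 0)
  e_max <- elastance_scale * g_eff / 100
  itp + act * e_max * (volume - unstressed_volume) +
    (volume - unstressed_volume) / passive_compliance
}

#' Intrathoracic pressure waveform
#'
#' Sinusoidal respiration signal: mean `mean_itp` (negative in physiology),
#' peak deviation `amplitude`, period `period` seconds.
#'
#' @param t time (s); vectorised.
#' @param resp list with elements `mean_itp`, `amplitude`, `period`
#'   (a `respiration` block of a [cv_network()]).
#' @return intrathoracic pressure in mmHg.
#' @export
intrathoracic_pressure <- function(t, resp) {
  stopifnot(is.list(resp), resp$period > 0)
  resp$mean_itp + resp$amplitude * sin(2 * pi * t / resp$period)
}

#' Convert between the flow-resistance unit U and its electrical analog
#'
#' In the electrical analogy 1 MOhm corresponds to 1 U
#' (1 U = 100 mmHg per 100 mL/s = 1 mmHg s/mL); a severe aortic stenosis
#' element of 800 kOhm is therefore 0.8 U.
#'
#' @param megaohm,u resistance in megaohms / in U.
#' @return the corresponding value in the other unit system.
#' @export
u_from_megaohm <- function(megaohm) megaohm * 1

#' @rdname u_from_megaohm
#' @export
megaohm_from_u <- function(u) u * 1
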