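trace_columns <- c("t", "AoP", "MAoP", "LVP", "LAtP", "CO", "CVV", "Sy",
                   "HR", "LVV", "ITP")

new_trace <- function(mat, onsets, dt) {
  df <- as.data.frame(mat)
  structure(df, onsets = onsets, dt = dt,
            class = c("cv_trace", "data.frame"))
}

#' Beat onset times of a simulated trace
#'
#' The simulator's pacing clock is authoritative: every beat onset is logged
#' during integration and carried on the trace as an attribute.
#'
#' @param trace a `cv_trace`.
#' @return numeric vector of onset times (s).
#' @export
beat_onsets <- function(trace) {
  on <- attr(trace, "onsets")
  if (is.null(on)) on <- detect_onsets(trace)
  on
}

# fallback onset detection for traces re-imported from CSV: local maxima of
# LVV (the isovolumic plateau right after mitral closure) followed by
# ejection; approximate to within a few ms of the true pacing onset
detect_onsets <- function(trace) {
  v <- trace$LVV
  t <- trace$t
  n <- length(v)
  if (n < 3) return(numeric(0))
  dv <- diff(v)
  # sample where filling (dv >= 0) turns into sustained ejection (dv < 0)
  turn <- which(dv[-1] < 0 & dv[-(n - 1)] >= 0) + 1
  dt <- t[2] - t[1]
  look <- max(1, round(0.1 / dt))
  keep <- vapply(turn, function(i) {
    j <- min(n, i + look)
    (v[i] - v[j]) > 2     # must actually eject
  }, logical(1))
  t[turn[keep]]
}

# initial continuous+discrete state for a fresh run
make_state <- function(net, ctl) {
  vols <- initial_volumes(net)
  sy0 <- ctl$sy_baseline
  eff <- apply_effectors(sy0, ctl)
  list(y = c(vols, MAoP = net$initial_pressures$sa, Sy = sy0),
       phase = 0, period = 60 / eff$heart_rate,
       frozen = c(eff$heart_rate, eff$lv_drive, eff$rv_drive,
                  eff$venous_unstressed_delta),
       co = 0, edv = unname(vols["V_lv"]), minv = unname(vols["V_lv"]))
}

integrate_segment <- function(net, ctl, state, t0, t1, dt) {
  res <- cv_core_integrate(unname(state$y), t0, t1, dt, pack_params(net, ctl),
                           state$phase, state$period, state$frozen,
                           state$co, state$edv, state$minv)
  st <- res$state
  names(st$y) <- names(state$y)
  list(trace = res$trace, volumes = res$volumes, onsets = res$onsets,
       state = st)
}

#' Integrate the closed-loop model over a time span
#'
#' Fixed-step fourth-order Runge-Kutta integration at step `dt` (1 ms by
#' default).  The run is fully deterministic: identical inputs give
#' bitwise-identical traces.  Integration aborts with a diagnostic if any
#' pressure exceeds 1e4 mmHg in magnitude.
#'
#' @param network a [cv_network()].
#' @param control a [cv_control()].
#' @param t_span numeric length-2, increasing time span (s).
#' @param dt step size (s), > 0.
#' @param state optional state carried over from a previous segment
#'   (internal use by [run_scenario()]); by default the configured initial
#'   pressures seed a fresh run with a beat onset at `t_span[1]`.
#' @return a `cv_trace` data frame with columns
#'   `t, AoP, MAoP, LVP, LAtP, CO, CVV, Sy, HR, LVV, ITP`, beat onsets in
#'   `attr(, "onsets")` and the final integrator state in
#'   `attr(, "final_state")`.
#' @export
cv_integrate <- function(network, control, t_span = c(0, 70.5), dt = 1e-3,
                         state = NULL) {
  stopifnot(length(t_span) == 2, t_span[2] > t_span[1], dt > 0)
  validate_network(network)
  validate_control(control)
  fresh <- is.null(state)
  if (fresh) state <- make_state(network, control)
  seg <- integrate_segment(network, control, state, t_span[1], t_span[2], dt)
  onsets <- seg$onsets
  if (fresh) onsets <- c(t_span[1], onsets)
  tr <- new_trace(seg$trace, onsets, dt)
  attr(tr, "volumes") <- seg$volumes
  attr(tr, "final_state") <- seg$state
  tr
}

#' Per-sample compartment volumes of a simulated trace
#'
#' Matrix of all seven compartment volumes (mL) at every sample, recorded
#' alongside the standard trace columns.  Useful for conservation and flow
#' reconstruction checks; `rowSums()` is the total blood volume.
#'
#' @param trace a `cv_trace` produced by [cv_integrate()] or
#'   [run_scenario()].
#' @return numeric matrix with columns
#'   `V_lv, V_sa, V_sv, V_ra, V_rv, V_pa, V_pv`.
#' @export
compartment_volumes <- function(trace) {
  v <- attr(trace, "volumes")
  if (is.null(v)) stop("trace carries no compartment volumes (imported CSV?)")
  v
}

#' Compartmental mass balance (right-hand side of the model ODEs)
#'
#' Computes dV/dt for every compartment from the instantaneous pressures
#' and [valve_flow()] over the network topology, plus the controller state
#' derivatives (filtered MAoP and Sy).  Because the loop is closed, the
#' compartment derivatives sum to zero exactly.
#'
#' @param state list with `volumes` (named vector `V_lv, V_sa, V_sv, V_ra,
#'   V_rv, V_pa, V_pv` in mL), `maop` (mmHg), `sy` (FGU) and
#'   `cardiac_phase` (s since beat onset).
#' @param network a [cv_network()].
#' @param control a [cv_control()].
#' @param t simulation time (s), used for the respiration waveform.
#' @return named vector of derivatives (mL/s for volumes).
#' @export
derivatives <- function(state, network, control, t = 0) {
  v <- state$volumes
  if (length(v) != 7) stop("state must carry 7 compartment volumes")
  if (any(!is.finite(v))) stop("non-finite compartment volume in state")
  if (any(v < 0)) stop("negative compartment volume in state")
  net <- network; ctl <- control
  itp <- intrathoracic_pressure(t, net$respiration)
  lv <- net$ventricles$lv; rv <- net$ventricles$rv
  a <- ventricular_activation(state$cardiac_phase, lv$systole_duration,
                              lv$activation_peak_frac)
  eff <- apply_effectors(if (!is.null(ctl$clamps$sy) && !is.na(ctl$clamps$sy))
    ctl$clamps$sy else state$sy, ctl)
  p_lv <- ventricular_pressure(v["V_lv"], a,
    effective_gain(lv$nominal_gain, eff$lv_drive, ctl$inotropic$limiter_max,
                   ctl$inotropic$slope),
    lv$elastance_scale, lv$unstressed_volume, lv$passive_compliance,
    lv$relaxation_tau, itp = itp)
  p_rv <- ventricular_pressure(v["V_rv"], a,
    effective_gain(rv$nominal_gain, eff$rv_drive, ctl$inotropic$limiter_max,
                   ctl$inotropic$slope),
    rv$elastance_scale, rv$unstressed_volume, rv$passive_compliance,
    rv$relaxation_tau, itp = itp)
  cm <- net$compartments
  v0sv <- cm$sv$unstressed_volume - eff$venous_unstressed_delta
  v0sv <- min(max(v0sv, ctl$venous$min_frac * cm$sv$unstressed_volume),
              ctl$venous$max_frac * cm$sv$unstressed_volume)
  p_sa <- (v["V_sa"] - cm$sa$unstressed_volume) / cm$sa$compliance
  p_sv <- (v["V_sv"] - v0sv) / cm$sv$compliance
  p_ra <- itp + (v["V_ra"] - cm$ra$unstressed_volume) / cm$ra$compliance
  p_pa <- itp + (v["V_pa"] - cm$pa$unstressed_volume) / cm$pa$compliance
  p_pv <- itp + (v["V_pv"] - cm$pv$unstressed_volume) / cm$pv$compliance

  rs <- net$resistors
  q_mit <- valve_flow(p_pv, p_lv, rs$mitral$resistance, TRUE)
  q_av <- valve_flow(p_lv, p_sa,
                     rs$aortic$resistance + lv$stenosis_severity * lv$stenosis_scale,
                     TRUE)
  q_sys <- valve_flow(p_sa, p_sv, rs$systemic$resistance, FALSE)
  q_ven <- valve_flow(p_sv, p_ra, rs$venous_return$resistance, FALSE)
  q_tri <- valve_flow(p_ra, p_rv, rs$tricuspid$resistance, TRUE)
  q_pvl <- valve_flow(p_rv, p_pa, rs$pulmonic$resistance, TRUE)
  q_pul <- valve_flow(p_pa, p_pv, rs$pulmonary$resistance, FALSE)
  flows <- c(q_mit, q_av, q_sys, q_ven, q_tri, q_pvl, q_pul)
  if (any(!is.finite(flows))) {
    bad <- c("mitral", "aortic", "systemic", "venous_return", "tricuspid",
             "pulmonic", "pulmonary")[!is.finite(flows)]
    stop("non-finite flow through resistor(s): ", paste(bad, collapse = ", "))
  }
  syt <- min(max(ctl$sy_baseline + ctl$feedback_gain *
                   (ctl$maop_setpoint - state$maop), ctl$sy_range[1]),
             ctl$sy_range[2])
  c(V_lv = unname(q_mit - q_av), V_sa = unname(q_av - q_sys),
    V_sv = unname(q_sys - q_ven), V_ra = unname(q_ven - q_tri),
    V_rv = unname(q_tri - q_pvl), V_pa = unname(q_pvl - q_pul),
    V_pv = unname(q_pul - q_mit),
    MAoP = unname((p_sa - state$maop) / ctl$maop_filter_tau),
    Sy = if (!is.null(ctl$clamps$sy) && !is.na(ctl$clamps$sy)) 0 else
      unname((syt - state$sy) / ctl$actuator_tau))
}

#' @export
print.cv_trace <- function(x, ...) {
  cat(sprintf("<cv_trace> %d samples, t = %.3f..%.3f s, dt = %g s, %d beats\n",
              nrow(x), x$t[1], x$t[nrow(x)], attr(x, "dt"),
              length(attr(x, "onsets"))))
  print(utils::head(as.data.frame(x), 4))
  invisible(x)
}
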