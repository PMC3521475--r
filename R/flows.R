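#' Reconstruct resistor flows from a simulated trace
#'
#' Recomputes the flow through every resistor/valve at every sample from
#' the recorded compartment volumes, pressures and controller signal,
#' applying the same constitutive laws as the integrator ([valve_flow()],
#' [ventricular_activation()], [effective_gain()]).  Assumes the inotropy
#' limbs follow the recorded `Sy` column (true for all built-in scenarios,
#' where the limbs are either on or driven by a clamped Sy).
#'
#' @param trace a `cv_trace` with compartment volumes (not an imported
#'   CSV).
#' @param network,control the parameter set the trace was produced with.
#' @return matrix (one row per sample) with columns `mitral`, `aortic`,
#'   `systemic`, `venous_return`, `tricuspid`, `pulmonic`, `pulmonary`
#'   (mL/s).
#' @export
reconstruct_flows <- function(trace, network = default_params()$network,
                              control = default_params()$control) {
  v <- compartment_volumes(trace)
  on <- beat_onsets(trace)
  idx <- findInterval(trace$t + 1e-12, on)
  phase <- trace$t - on[pmax(idx, 1)]
  lv <- network$ventricles$lv; rv <- network$ventricles$rv
  cm <- network$compartments
  a <- ventricular_activation(pmax(phase, 0), lv$systole_duration,
                              lv$activation_peak_frac)
  g_rv <- effective_gain(rv$nominal_gain, trace$Sy,
                         control$inotropic$limiter_max,
                         control$inotropic$slope)
  e_rv <- rv$elastance_scale * g_rv / 100
  itp <- trace$ITP
  p_ra <- itp + (v[, "V_ra"] - cm$ra$unstressed_volume) / cm$ra$compliance
  p_rv <- itp + a * e_rv * (v[, "V_rv"] - rv$unstressed_volume) +
    (v[, "V_rv"] - rv$unstressed_volume) / rv$passive_compliance
  p_pa <- itp + (v[, "V_pa"] - cm$pa$unstressed_volume) / cm$pa$compliance
  p_sv <- (v[, "V_sv"] - trace$CVV) / cm$sv$compliance
  rs <- network$resistors
  r_ao <- rs$aortic$resistance + lv$stenosis_severity * lv$stenosis_scale
  cbind(
    mitral = valve_flow(trace$LAtP, trace$LVP, rs$mitral$resistance, TRUE),
    aortic = valve_flow(trace$LVP, trace$AoP, r_ao, TRUE),
    systemic = valve_flow(trace$AoP, p_sv, rs$systemic$resistance, FALSE),
    venous_return = valve_flow(p_sv, p_ra, rs$venous_return$resistance, FALSE),
    tricuspid = valve_flow(p_ra, p_rv, rs$tricuspid$resistance, TRUE),
    pulmonic = valve_flow(p_rv, p_pa, rs$pulmonic$resistance, TRUE),
    pulmonary = valve_flow(p_pa, trace$LAtP, rs$pulmonary$resistance, FALSE))
}
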