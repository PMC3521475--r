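# memoised scenario runs shared across test files (all deterministic)
.run_cache <- new.env(parent = emptyenv())

cached_run <- function(name) {
  if (is.null(.run_cache[[name]]))
    assign(name, run_scenario(name), envir = .run_cache)
  .run_cache[[name]]
}

phase_windows <- list(baseline = c(68.7, 69.3),
                      low_contractility = c(103.7, 104.3),
                      avs = c(148.7, 149.3),
                      exercise = c(233.7, 234.3),
                      syncope = c(543.7, 544.3))

beat_at <- function(trace, window) beat_metrics(trace, window = window)

# degenerate network that reduces to a single RC discharge (systemic
# arteries into systemic veins); all other paths effectively open-circuit
make_rc_setup <- function(r_sys = 1) {
  net <- cv_network(
    ventricles = list(lv = list(nominal_gain = 1e-6),
                      rv = list(nominal_gain = 1e-6)),
    resistors = list(systemic = list(resistance = r_sys),
                     mitral = list(resistance = 1e6),
                     venous_return = list(resistance = 1e6),
                     tricuspid = list(resistance = 1e6),
                     pulmonary = list(resistance = 1e6)),
    respiration = list(amplitude = 0),
    initial_pressures = list(lv = 0),
    total_blood_volume = NULL)
  ctl <- cv_control(switches = list(hr = FALSE, lv_inotropy = FALSE,
                                    rv_inotropy = FALSE, venous_tone = FALSE))
  list(network = net, control = ctl)
}

# width of the interval within one beat where ventricular activation is
# strictly positive, measured by bisection to machine precision
activation_support_width <- function(net, tol = 1e-12) {
  ts <- net$ventricles$lv$systole_duration
  pf <- net$ventricles$lv$activation_peak_frac
  pos <- function(x) ventricular_activation(x, ts, pf) > 0
  bisect <- function(lo, hi, want_pos_above) {
    for (k in 1:60) {
      mid <- (lo + hi) / 2
      if (pos(mid) == want_pos_above) hi <- mid else lo <- mid
    }
    (lo + hi) / 2
  }
  # lower edge between phase 0 (inactive) and mid-systole (active)
  lower <- bisect(0, ts / 2, TRUE)
  # upper edge between mid-systole (active) and well after systole
  upper <- bisect(ts / 2, 2 * ts, FALSE)
  upper - lower
}

# protocol run with respiration silenced (amplitude 0): isolates residual
# transients from the physiological beat-to-beat respiratory variation
cached_still_run <- function() {
  if (is.null(.run_cache[["still"]])) {
    net <- cv_network(respiration = list(amplitude = 0),
                      total_blood_volume = NULL)
    assign("still", run_scenario(builtin_scenario("protocol_a"), network = net),
           envir = .run_cache)
  }
  .run_cache[["still"]]
}
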