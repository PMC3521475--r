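state_from_pressure <- function(net, p, phase = 0.3, t = 1) {
  itp <- intrathoracic_pressure(t, net$respiration)
  cm <- net$compartments
  vols <- c(
    V_lv = net$ventricles$lv$unstressed_volume +
      net$ventricles$lv$passive_compliance * (p - itp),
    V_sa = cm$sa$unstressed_volume + cm$sa$compliance * p,
    V_sv = cm$sv$unstressed_volume + cm$sv$compliance * p,
    V_ra = cm$ra$unstressed_volume + cm$ra$compliance * (p - itp),
    V_rv = net$ventricles$rv$unstressed_volume +
      net$ventricles$rv$passive_compliance * (p - itp),
    V_pa = cm$pa$unstressed_volume + cm$pa$compliance * (p - itp),
    V_pv = cm$pv$unstressed_volume + cm$pv$compliance * (p - itp))
  list(volumes = vols, cardiac_phase = phase, maop = p, sy = 1)
}

test_that("the closed loop conserves volume: derivatives sum to zero", {
  p <- default_params()
  set.seed(42)
  for (k in 1:25) {
    vols <- c(V_lv = 130, V_sa = 580, V_sv = 2590, V_ra = 50, V_rv = 140,
              V_pa = 120, V_pv = 155) * exp(runif(7, -0.3, 0.3))
    st <- list(volumes = vols, cardiac_phase = runif(1, 0, 0.8),
               maop = runif(1, 60, 130), sy = runif(1, 0, 8))
    d <- derivatives(st, p$network, p$control, t = runif(1, 0, 10))
    expect_lt(abs(sum(d[1:7])), 1e-9)
  }
})

test_that("uniform pressure with no activation is an equilibrium", {
  net <- cv_network(respiration = list(amplitude = 0),
                    total_blood_volume = NULL)
  ctl <- default_params()$control
  st <- state_from_pressure(net, 10)
  d <- derivatives(st, net, ctl, t = 1)
  expect_equal(unname(d[1:7]), rep(0, 7), tolerance = 1e-12)
})

test_that("reverse-biased valves conduct nothing", {
  p <- default_params()
  # aorta pressurised far above everything else: only the systemic
  # resistor may conduct out of it; LV must not refill from the aorta
  vols <- c(V_lv = 40, V_sa = 700, V_sv = 2400, V_ra = 30, V_rv = 50,
            V_pa = 80, V_pv = 70)
  st <- list(volumes = vols, cardiac_phase = 0.5, maop = 100, sy = 1)
  d <- derivatives(st, p$network, p$control, t = 0.5)
  # all inflow into the LV can only come through the mitral valve (>= 0)
  expect_gte(d[["V_lv"]], 0)
})

test_that("R and C++ right-hand sides agree", {
  p <- default_params()
  packed <- hemocirc:::pack_params(p$network, p$control)
  set.seed(7)
  for (k in 1:20) {
    vols <- c(130, 580, 2590, 50, 140, 120, 155) * exp(runif(7, -0.2, 0.2))
    maop <- runif(1, 70, 120); sy <- runif(1, 0.2, 7)
    phase <- runif(1, 0, 0.8); t <- runif(1, 0, 8)
    stR <- list(volumes = stats::setNames(vols, c("V_lv", "V_sa", "V_sv",
                                                  "V_ra", "V_rv", "V_pa",
                                                  "V_pv")),
                cardiac_phase = phase, maop = maop, sy = sy)
    dR <- derivatives(stR, p$network, p$control, t = t)
    eff <- apply_effectors(sy, p$control)
    dC <- cv_core_derivs(c(vols, maop, sy), t, phase, packed,
                         c(eff$heart_rate, eff$lv_drive, eff$rv_drive,
                           eff$venous_unstressed_delta))
    expect_equal(unname(dC), unname(dR), tolerance = 1e-10)
  }
})

test_that("an isolated RC pair discharges along the analytic exponential", {
  s <- make_rc_setup(r_sys = 1)
  tr <- cv_integrate(s$network, s$control, c(0, 5), dt = 1e-3)
  c_sa <- s$network$compartments$sa$compliance
  c_sv <- s$network$compartments$sv$compliance
  p0_sa <- s$network$initial_pressures$sa
  p0_sv <- s$network$initial_pressures$sv
  p_eq <- (c_sa * p0_sa + c_sv * p0_sv) / (c_sa + c_sv)
  tau <- 1 * 1 / (1 / c_sa + 1 / c_sv)
  analytic <- p_eq + (p0_sa - p_eq) * exp(-tr$t / tau)
  rel_err <- max(abs(tr$AoP - analytic)) / (p0_sa - p_eq)
  expect_lt(rel_err, 1e-4)
})

test_that("non-finite states are rejected with a clear message", {
  p <- default_params()
  st <- list(volumes = c(V_lv = NaN, V_sa = 580, V_sv = 2590, V_ra = 50,
                         V_rv = 140, V_pa = 120, V_pv = 155),
             cardiac_phase = 0.1, maop = 100, sy = 1)
  expect_error(derivatives(st, p$network, p$control, 0), "volume")
})
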