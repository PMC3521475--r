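test_that("built-in protocols carry the published event sequence", {
  scn <- builtin_scenario("protocol_a")
  expect_equal(sort(unique(scn$events$time)), c(70.5, 110.5, 150.5, 240.5))
  expect_equal(scn$duration, 550)
  ev <- scn$events
  expect_equal(ev$value[ev$target == "lv.nominal_gain"], 20)
  expect_equal(ev$value[ev$target == "lv.stenosis_severity"],
               u_from_megaohm(0.8))
  r0 <- default_params()$network$resistors$systemic$resistance
  expect_equal(ev$value[ev$target == "resistors.systemic.resistance"],
               r0 / 2)
  cc <- builtin_scenario("protocol_c")$events
  expect_equal(cc$value[cc$target == "control.clamps.heart_rate"], 45)
  expect_equal(cc$value[cc$target == "control.clamps.sy"], 0.5)
  b <- builtin_scenario("baseline")
  expect_equal(nrow(b$events), 0)
  expect_equal(b$duration, 70.5)
  expect_error(builtin_scenario("nope"))
})

test_that("scenario documents round-trip and are validated", {
  ev <- data.frame(time = c(10, 5), target = c("lv.nominal_gain",
                                               "control.maop_setpoint"),
                   value = c(20, 90))
  expect_warning(scn <- cv_scenario("demo", 20, events = ev), "sort")
  expect_equal(scn$events$time, c(5, 10))
  f <- tempfile(fileext = ".json")
  save_scenario(scn, f)
  back <- parse_scenario(f)
  expect_equal(back$events, scn$events)
  expect_equal(back$duration, scn$duration)
  expect_equal(back$dt, scn$dt)
  bad <- data.frame(time = 1, target = "lv.bogus", value = 1)
  expect_error(cv_scenario("bad", 10, events = bad), "lv.bogus")
  expect_error(cv_scenario("bad", 10,
                           events = data.frame(time = 1, target = "nonsense",
                                               value = 1)),
               "unresolvable")
  expect_error(cv_scenario("short", 5,
                           events = data.frame(time = 9,
                                               target = "lv.nominal_gain",
                                               value = 20)),
               "duration")
})

test_that("an event-free scenario reproduces plain integration", {
  p <- default_params()
  scn <- cv_scenario("plain", duration = 3)
  tr1 <- run_scenario(scn)
  tr2 <- cv_integrate(p$network, p$control, c(0, 3), dt = 1e-3)
  expect_equal(as.data.frame(tr1)[trace_cols <- names(tr2)],
               as.data.frame(tr2)[trace_cols], tolerance = 0)
})

test_that("events mutate parameters exactly at their time", {
  ev <- data.frame(time = 1, target = "compartments.sv.unstressed_volume",
                   value = 2200)
  tr <- run_scenario(cv_scenario("step", duration = 2, events = ev))
  before <- tr$CVV[abs(tr$t - (1 - 1e-3)) < 1e-9]
  after <- tr$CVV[abs(tr$t - (1 + 1e-3)) < 1e-9]
  expect_equal(before, 2300, tolerance = 30)   # venous tone near baseline
  expect_equal(after - before, -100, tolerance = 1)
})

test_that("repeated runs are bitwise identical", {
  s <- cv_scenario("det", duration = 2,
                   events = data.frame(time = 1, target = "lv.nominal_gain",
                                       value = 20))
  t1 <- run_scenario(s)
  t2 <- run_scenario(s)
  expect_identical(as.data.frame(t1), as.data.frame(t2))
  expect_identical(attr(t1, "onsets"), attr(t2, "onsets"))
})

test_that("each protocol phase settles to a steady rhythm", {
  # measured with respiration silenced: the +/-2 mmHg thoracic swing
  # legitimately modulates stroke volume beat to beat, so residual
  # transients are only visible without it
  tr <- cached_still_run()
  phases <- list(c(50, 70.5), c(70.5, 110.5), c(110.5, 150.5),
                 c(150.5, 240.5), c(240.5, 550))
  bm <- beat_metrics(tr)
  for (ph in phases) {
    # transient decay: MAoP varies less at the end of the phase than at
    # its start
    head_i <- tr$t >= ph[1] & tr$t < ph[1] + 10
    tail_i <- tr$t >= ph[2] - 10 & tr$t < ph[2]
    expect_lt(stats::var(tr$MAoP[tail_i]), stats::var(tr$MAoP[head_i]) + 1e-9)
    # beat-to-beat stroke volume varies < 2% over the last 5 beats
    last5 <- utils::tail(bm$SVLV[bm$t_onset >= ph[1] & bm$t_onset < ph[2] - 0.5], 5)
    expect_lt((max(last5) - min(last5)) / mean(last5), 0.02)
  }
})

test_that("the event log records every applied event", {
  tr <- cached_run("protocol_a")
  log <- attr(tr, "event_log")
  expect_equal(nrow(log), 6)
  expect_setequal(unique(log$time), c(70.5, 110.5, 150.5, 240.5))
})
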