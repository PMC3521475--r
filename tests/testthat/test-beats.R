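# small synthetic trace with a triangular LVV waveform and known onsets
synthetic_trace <- function(hr = 60, n_beats = 3, dt = 1e-3,
                            edv = 138, esv = 51) {
  period <- 60 / hr
  t <- seq(0, n_beats * period, by = dt)
  phase <- t %% period
  lvv <- ifelse(phase < 0.2, edv - (edv - esv) * phase / 0.2,
                esv + (edv - esv) * (phase - 0.2) / (period - 0.2))
  lvv[1] <- edv
  df <- data.frame(t = t, AoP = 100 + 10 * sin(2 * pi * phase / period),
                   MAoP = 100, LVP = ifelse(phase < 0.2, 120, 5),
                   LAtP = 8, CO = 0, CVV = 2300, Sy = 1, HR = hr,
                   LVV = lvv, ITP = -4)
  structure(df, onsets = seq(0, n_beats, by = 1) * period, dt = dt,
            class = c("cv_trace", "data.frame"))
}

test_that("cycle boundaries partition the pacing log", {
  tr <- synthetic_trace(hr = 60, n_beats = 3)
  cb <- cycle_boundaries(tr)
  expect_equal(cb$t_start, c(0, 1, 2))
  expect_equal(cb$t_end, c(1, 2, 3))
  tr2 <- synthetic_trace(hr = 120, n_beats = 4)
  cb2 <- cycle_boundaries(tr2)
  expect_equal(unique(round(diff(cb2$t_start), 9)), 0.5)
  # contiguous partition: each interval starts where the previous ended
  expect_equal(cb2$t_start[-1], cb2$t_end[-nrow(cb2)])
  expect_error(cycle_boundaries(tr, onsets = numeric(0)), "empty")
  expect_error(cycle_boundaries(tr, onsets = 0.5), "two")
})

test_that("beat metrics recover constructed volumes and definitions", {
  tr <- synthetic_trace(edv = 138, esv = 51)
  bm <- beat_metrics(tr)
  expect_equal(bm$EDVLV, rep(138, 3))
  expect_equal(bm$ESVLV, rep(51, 3), tolerance = 1e-6)
  expect_equal(bm$SVLV, rep(87, 3), tolerance = 1e-6)
  expect_equal(bm$EF, rep(87 / 138, 3), tolerance = 1e-6)
  expect_equal(bm$SVLV, bm$EDVLV - bm$ESVLV)   # identity, exact
  expect_equal(bm$CO, bm$SVLV * bm$HR)
  # constant volume means zero stroke volume and zero EF
  flat <- synthetic_trace(edv = 100, esv = 100)
  bmf <- beat_metrics(flat)
  expect_equal(bmf$SVLV, rep(0, 3))
  expect_equal(bmf$EF, rep(0, 3))
  # a cycle shorter than systole is rejected
  expect_error(beat_metrics(tr, cycles = data.frame(t_start = 0,
                                                    t_end = 0.1)),
               "systole")
  expect_error(beat_metrics(data.frame(t = 1:5)), "missing")
})

test_that("P-V loops close and degenerate cycles are rejected", {
  tr <- synthetic_trace()
  lp <- pv_loop(tr, c(0, 1))
  expect_equal(lp[1, ], lp[nrow(lp), ], ignore_attr = TRUE)
  expect_error(pv_loop(tr, c(0, 5e-4)), "degenerate")
})

test_that("loop area matches the shoelace formula and its invariances", {
  rect <- data.frame(volume = c(50, 100, 100, 50, 50),
                     pressure = c(10, 10, 110, 110, 10))
  expect_equal(loop_area(rect), 5000)
  expect_equal(loop_area(rect[rev(seq_len(nrow(rect))), ]), 5000)
  # cyclic rotation leaves the area unchanged
  rot <- rect[c(2, 3, 4, 1, 2), ]
  expect_equal(loop_area(rot), 5000)
  expect_warning(a <- loop_area(rect[1:4, ]), "closed")
  expect_equal(a, 5000)
  expect_error(loop_area(rect[1:2, ]), "3 points")
  # random convex polygons against an independent triangle-fan oracle
  fan_area <- function(v, p) {
    cx <- mean(v[-length(v)]); cy <- mean(p[-length(p)])
    s <- 0
    for (i in seq_len(length(v) - 1))
      s <- s + ((v[i] - cx) * (p[i + 1] - cy) - (v[i + 1] - cx) * (p[i] - cy))
    abs(s) / 2
  }
  set.seed(11)
  for (k in 1:10) {
    ang <- sort(stats::runif(12, 0, 2 * pi))
    r <- stats::runif(1, 10, 60)
    v <- 100 + r * cos(ang); p <- 80 + r * sin(ang)
    v <- c(v, v[1]); p <- c(p, p[1])
    expect_equal(loop_area(data.frame(volume = v, pressure = p)),
                 fan_area(v, p), tolerance = 1e-9)
  }
})

test_that("stroke work equals the trapezoid integral of P dV", {
  tr <- cached_run("baseline")
  cb <- cycle_boundaries(tr)
  k <- nrow(cb) - 2
  lp <- pv_loop(tr, cb[k, ])
  v <- lp$volume; p <- lp$pressure
  trapz <- abs(sum((p[-1] + p[-length(p)]) / 2 * diff(v)))
  expect_equal(loop_area(lp), trapz, tolerance = 5e-3)
})

test_that("every simulated beat has a physical ejection fraction", {
  for (nm in c("protocol_a", "protocol_d")) {
    bm <- beat_metrics(cached_run(nm))
    expect_true(all(bm$EF >= 0 & bm$EF <= 1))
    expect_true(all(bm$ESVLV >= 0))
    expect_equal(bm$SVLV, bm$EDVLV - bm$ESVLV)
  }
})

test_that("P-V loops shift as contractility and load change", {
  tr <- cached_run("protocol_a")
  w <- phase_windows
  vol_range <- function(win) {
    cb <- cycle_boundaries(tr)
    k <- which(cb$t_start <= mean(win) & cb$t_end > mean(win))
    range(pv_loop(tr, cb[k, ])$volume)
  }
  base <- vol_range(w$baseline)
  weak <- vol_range(w$low_contractility)
  avs <- vol_range(w$avs)
  exer <- vol_range(w$exercise)
  # depressed contractility shifts the loop to higher volumes
  expect_gt(weak[1], base[1]); expect_gt(weak[2], base[2])
  # exercise shifts it back toward lower volumes than the AVS phase
  expect_lt(exer[1], avs[1]); expect_lt(exer[2], avs[2])
  # contraction slows when the nominal gain falls 100 -> 20
  expect_gt(beat_at(tr, w$low_contractility)$time_to_peak_LVP,
            beat_at(tr, w$baseline)$time_to_peak_LVP)
})

test_that("the checkpoint report evaluates all reference rows", {
  tr <- cached_run("protocol_a")
  rep <- checkpoint_report(tr)
  expect_equal(nrow(rep), 13)
  expect_true(all(c("metric", "phase", "simulated", "reference_value",
                    "within_tolerance") %in% names(rep)))
  expect_error(checkpoint_report(tr, scenario_name = "baseline"), "requires")
  expect_error(checkpoint_report(synthetic_trace()), "requires")
})
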