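#' Cardiac cycle boundaries of a trace
#'
#' Half-open, contiguous, non-overlapping intervals `[t_start, t_end)`,
#' one per completed beat, taken from the simulator's pacing log (the
#' pacing clock is authoritative; no threshold detection).
#'
#' @param trace a `cv_trace`.
#' @param onsets optional beat onset times; defaults to the trace's log.
#' @return data frame with columns `t_start`, `t_end`.
#' @export
cycle_boundaries <- function(trace, onsets = beat_onsets(trace)) {
  if (length(onsets) == 0) stop("empty pacing log: no beat onsets")
  if (length(onsets) < 2)
    stop("need at least two beat onsets to delimit a cycle")
  if (min(onsets) < trace$t[1] - 1e-9 ||
      max(onsets) > trace$t[nrow(trace)] + 1e-9)
    stop("pacing log extends beyond the trace time span")
  data.frame(t_start = onsets[-length(onsets)], t_end = onsets[-1])
}

cycle_rows <- function(trace, cycle) {
  i <- which(trace$t >= cycle[[1]] - 1e-9 & trace$t < cycle[[2]] - 1e-9)
  if (length(i) < 2) stop("degenerate cycle: fewer than two samples")
  i
}

beat_metrics_one <- function(trace, t_start, t_end, systole_duration = 0.2) {
  if (t_end - t_start < systole_duration)
    stop("cycle shorter than systole (", t_end - t_start, " s)")
  i <- cycle_rows(trace, c(t_start, t_end))
  tt <- trace$t[i]; lvv <- trace$LVV[i]; lvp <- trace$LVP[i]
  aop <- trace$AoP[i]
  edv <- lvv[1]
  esv <- min(lvv)
  sv <- edv - esv
  ipk <- which.max(lvp)
  in_sys <- tt - t_start <= systole_duration
  fwd <- in_sys & lvp > aop        # aortic valve conducting
  grad <- if (any(fwd)) max(lvp[fwd] - aop[fwd]) else 0
  dias <- !in_sys
  loop <- pv_loop(trace, c(t_start, t_end))
  data.frame(
    t_onset = t_start,
    EDVLV = edv, ESVLV = esv, SVLV = sv,
    EF = if (edv > 0) sv / edv else 0,
    EDPLV = lvp[1],
    max_LVP = lvp[ipk],
    time_to_peak_LVP = tt[ipk] - t_start,
    min_diastolic_LVP = if (any(dias)) min(lvp[dias]) else NA_real_,
    peak_gradient = grad,
    MAoP = mean(aop),
    pulse_pressure = max(aop) - min(aop),
    HR = 60 / (t_end - t_start),
    CO = sv * 60 / (t_end - t_start),
    stroke_work = loop_area(loop))
}

#' Per-beat hemodynamic summaries
#'
#' For each cardiac cycle: end-diastolic volume (LVV at the pacing onset,
#' end of diastole by construction), end-systolic volume (minimum LVV),
#' stroke volume `SVLV = EDVLV - ESVLV`, ejection fraction `SVLV/EDVLV`,
#' end-diastolic and peak LV pressures, time to peak LVP, minimum diastolic
#' LVP, peak systolic transvalvular gradient (max of `LVP - AoP` while the
#' aortic valve conducts, i.e. during systole with `LVP > AoP`), per-beat
#' mean aortic pressure (time average over the cycle), pulse pressure,
#' heart rate, cardiac output `SVLV x HR` and stroke work (P-V loop area).
#'
#' @param trace a `cv_trace`.
#' @param cycles data frame of cycle boundaries (default: all complete
#'   cycles of the trace), or a single `c(t_start, t_end)` interval.
#' @param window optional length-2 time window; selects the single cycle
#'   containing the window midpoint.
#' @param systole_duration systole length (s) used to split systole from
#'   diastole.
#' @return data frame with one row per beat.
#' @export
beat_metrics <- function(trace, cycles = NULL, window = NULL,
                         systole_duration = 0.2) {
  need <- c("t", "AoP", "LVP", "LVV")
  miss <- setdiff(need, names(trace))
  if (length(miss))
    stop("trace is missing required variable(s): ",
         paste(miss, collapse = ", "))
  if (!is.null(window)) {
    stopifnot(length(window) == 2)
    cb <- cycle_boundaries(trace)
    mid <- mean(window)
    hit <- which(cb$t_start <= mid & cb$t_end > mid)
    if (!length(hit)) stop("no complete cycle contains the window midpoint")
    cycles <- cb[hit, , drop = FALSE]
  }
  if (is.null(cycles)) cycles <- cycle_boundaries(trace)
  if (is.numeric(cycles) && length(cycles) == 2)
    cycles <- data.frame(t_start = cycles[1], t_end = cycles[2])
  out <- do.call(rbind, lapply(seq_len(nrow(cycles)), function(k)
    beat_metrics_one(trace, cycles$t_start[k], cycles$t_end[k],
                     systole_duration)))
  rownames(out) <- NULL
  out
}

#' Pressure-volume loop of one cardiac cycle
#'
#' Ordered (LVV, LVP) points over a cycle, closed by appending the first
#' point; the enclosed area is the stroke work.
#'
#' @param trace a `cv_trace`.
#' @param cycle length-2 interval `c(t_start, t_end)` or a one-row cycle
#'   data frame.
#' @return data frame (`volume`, `pressure`) of class `cv_pvloop`.
#' @export
pv_loop <- function(trace, cycle) {
  if (is.data.frame(cycle)) cycle <- c(cycle$t_start[1], cycle$t_end[1])
  i <- cycle_rows(trace, cycle)
  loop <- data.frame(volume = trace$LVV[i], pressure = trace$LVP[i])
  loop <- rbind(loop, loop[1, ])   # enforce closure
  rownames(loop) <- NULL
  structure(loop, class = c("cv_pvloop", "data.frame"))
}

#' Area enclosed by a pressure-volume loop (stroke work)
#'
#' Absolute shoelace area of the closed (volume, pressure) polygon, in
#' mmHg mL.  Invariant to cyclic rotation and traversal direction of the
#' points; an unclosed loop is closed automatically with a warning.
#'
#' @param loop a [pv_loop()] or any data frame with `volume` and
#'   `pressure` columns (at least 3 distinct points).
#' @return stroke work in mmHg mL.
#' @export
loop_area <- function(loop) {
  v <- loop$volume; p <- loop$pressure
  n <- length(v)
  if (n < 3) stop("need at least 3 points to define a loop")
  if (v[1] != v[n] || p[1] != p[n]) {
    warning("loop was not closed; closing it")
    v <- c(v, v[1]); p <- c(p, p[1])
    n <- n + 1
  }
  if (n - 1 < 3) stop("need at least 3 distinct points to define a loop")
  abs(sum(v[-n] * p[-1] - v[-1] * p[-n])) / 2
}

checkpoint_table <- function() {
  data.frame(
    phase = c(rep("baseline", 3), rep("low_contractility", 2),
              rep("avs", 3), rep("exercise", 5)),
    window_lo = c(rep(68.7, 3), rep(103.7, 2), rep(148.7, 3), rep(233.7, 5)),
    window_hi = c(rep(69.3, 3), rep(104.3, 2), rep(149.3, 3), rep(234.3, 5)),
    metric = c("SVLV", "EF_pct", "min_diastolic_LVP",
               "EF_pct", "time_to_peak_LVP",
               "peak_gradient", "max_LVP", "EF_pct",
               "peak_gradient", "max_LVP", "SVLV", "EF_pct",
               "time_to_peak_LVP"),
    reference_value = c(87, 63, 0, 30, 0.1, 50, 170, 25, 70, 190, 107, 56, 0.1),
    kind = c("eq", "eq", "lt", "eq", "gt", "eq", "le_approach", "eq",
             "eq", "le_approach", "eq", "eq", "eq"),
    tol = c(87 * 0.05, 3, NA, 5, NA, 10, 15, 5, 10, 15, 107 * 0.10, 5, 0.03))
}

#' Checkpoint report against the published hemodynamic values
#'
#' Evaluates the per-phase hemodynamic checkpoints of the five-phase
#' protocol (stroke volume, ejection fraction, transvalvular gradient,
#' maximum LV pressure, diastolic LVP sign, contraction timing) on a
#' simulated trace and compares each to its reference value at the stated
#' tolerance.
#'
#' @param trace a `cv_trace` produced by running one of the built-in
#'   `protocol_*` scenarios.
#' @param scenario_name the built-in scenario the trace came from; taken
#'   from the trace attribute when omitted.
#' @return data frame with columns `metric`, `phase`, `window`,
#'   `simulated`, `reference_value`, `within_tolerance`.
#' @export
checkpoint_report <- function(trace, scenario_name = attr(trace, "scenario")) {
  builtin <- paste0("protocol_", c("a", "b", "c", "d"))
  if (is.null(scenario_name) || !scenario_name %in% builtin)
    stop("checkpoint_report requires a trace from one of: ",
         paste(builtin, collapse = ", "))
  need <- c("t", "AoP", "LVP", "LVV")
  miss <- setdiff(need, names(trace))
  if (length(miss))
    stop("trace is missing required variable(s): ",
         paste(miss, collapse = ", "))
  ck <- checkpoint_table()
  rows <- lapply(seq_len(nrow(ck)), function(k) {
    bm <- beat_metrics(trace, window = c(ck$window_lo[k], ck$window_hi[k]))
    sim <- switch(ck$metric[k],
                  EF_pct = bm$EF * 100,
                  bm[[ck$metric[k]]])
    ok <- switch(ck$kind[k],
                 eq = abs(sim - ck$reference_value[k]) <= ck$tol[k],
                 lt = sim < ck$reference_value[k],
                 gt = sim > ck$reference_value[k],
                 le_approach = sim <= ck$reference_value[k] &&
                   sim >= ck$reference_value[k] - ck$tol[k])
    data.frame(metric = ck$metric[k], phase = ck$phase[k],
               window = sprintf("%.1f-%.1f s", ck$window_lo[k],
                                ck$window_hi[k]),
               simulated = sim, reference_value = ck$reference_value[k],
               within_tolerance = ok)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
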