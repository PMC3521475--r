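#' Construct a timed-protocol scenario
#'
#' A scenario is an ordered list of instantaneous parameter events applied
#' to the network/controller at fixed times during one continuous
#' simulation.  Event targets are dotted paths into the parameter
#' structure, e.g. `lv.nominal_gain`, `resistors.systemic.resistance`,
#' `control.maop_setpoint`, `control.clamps.sy`.
#'
#' @param name scenario name.
#' @param duration total simulated time (s).
#' @param events data frame with columns `time` (s), `target` (character
#'   path) and `value` (numeric or logical); auto-sorted by time with a
#'   warning if unsorted.
#' @param dt integration step (s).
#' @param record variables to record (the full standard column set by
#'   default).
#' @return object of class `cv_scenario`.
#' @export
cv_scenario <- function(name, duration, events = NULL, dt = 1e-3,
                        record = trace_columns) {
  if (is.null(events))
    events <- data.frame(time = numeric(0), target = character(0),
                         value = numeric(0))
  stopifnot(duration > 0, dt > 0)
  if (nrow(events)) {
    if (any(events$time < 0)) stop("event times must be >= 0")
    if (is.unsorted(events$time)) {
      warning("events were not sorted by time; sorting")
      events <- events[order(events$time), , drop = FALSE]
    }
    if (max(events$time) > duration)
      stop("scenario duration (", duration,
           " s) must cover the last event at ", max(events$time), " s")
    p <- default_params()
    for (tg in events$target) resolve_target(tg, p$network, p$control)
  }
  rownames(events) <- NULL
  structure(list(name = name, duration = duration, dt = dt,
                 events = events, record = record),
            class = "cv_scenario")
}

# walk a dotted target path; errors if it does not resolve
resolve_target <- function(path, network, control) {
  parts <- strsplit(path, ".", fixed = TRUE)[[1]]
  if (length(parts) < 2) stop("unresolvable target path: ", path)
  root <- parts[1]
  idx <- switch(root,
    lv = c("ventricles", "lv", parts[-1]),
    rv = c("ventricles", "rv", parts[-1]),
    compartments = , resistors = , respiration = parts,
    control = parts[-1],
    stop("unresolvable target path: ", path))
  obj <- if (root == "control") control else network
  for (k in seq_len(length(idx) - 1)) {
    obj <- obj[[idx[k]]]
    if (is.null(obj)) stop("unresolvable target path: ", path)
  }
  leaf <- idx[length(idx)]
  leaf_ok <- leaf %in% names(obj) ||
    (identical(idx[length(idx) - 1], "clamps") &&
       leaf %in% c("heart_rate", "sy"))
  if (!leaf_ok) stop("unresolvable target path: ", path)
  list(root = if (root == "control") "control" else "network", idx = idx)
}

apply_event <- function(params, target, value) {
  r <- resolve_target(target, params$network, params$control)
  params[[c(r$root, r$idx)]] <- value
  params
}

#' Built-in scenarios
#'
#' `"baseline"` runs 70.5 s of sedentary normal conditions with no events.
#' `"protocol_a"` .. `"protocol_d"` run the five-phase exertional-
#' syncope protocol (550 s): decreased LV contractility (nominal gain
#' 100 to 20) at 70.5 s; severe aortic stenosis (0.8 U output series
#' resistance) at 110.5 s; exercise (peripheral resistance halved, MAoP
#' setpoint raised by the calibrated reset) at 150.5 s; and at 240.5 s failure of
#' homeostasis as syncope variant a-d (heart-rate and Sy clamps, see
#' [syncope_mode()]).
#'
#' @param name scenario name.
#' @param params parameter set used to derive absolute event values
#'   (defaults to the frozen shipped set).
#' @return a [cv_scenario()].
#' @export
builtin_scenario <- function(name = c("baseline", "protocol_a",
                                      "protocol_b", "protocol_c",
                                      "protocol_d"),
                             params = default_params()) {
  name <- match.arg(name)
  if (name == "baseline")
    return(cv_scenario("baseline", duration = 70.5))
  variant <- sub("protocol_", "", name)
  clamps <- switch(variant,
                   a = c(120, 1.0), b = c(120, 0.5),
                   c = c(45, 0.5), d = c(45, 1.5))
  r_sys <- params$network$resistors$systemic$resistance
  reset <- params$control$exercise_setpoint_reset
  if (is.null(reset)) reset <- 25
  setp <- params$control$maop_setpoint + reset
  ev <- data.frame(
    time = c(70.5, 110.5, 150.5, 150.5, 240.5, 240.5),
    target = c("lv.nominal_gain", "lv.stenosis_severity",
               "resistors.systemic.resistance", "control.maop_setpoint",
               "control.clamps.heart_rate", "control.clamps.sy"),
    value = c(20, 0.8, r_sys * 0.5, setp, clamps[1], clamps[2]))
  cv_scenario(name, duration = 550, events = ev)
}

#' Read a scenario from a JSON document
#'
#' @param path path to a JSON file with fields `name`, `duration`, `dt`,
#'   `events` (array of `{time, target, value}`) and optional `record`.
#' @return a [cv_scenario()].
#' @export
parse_scenario <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("name", "duration"))
    if (is.null(doc[[f]])) stop("scenario document missing field: ", f)
  ev <- doc$events
  if (!is.null(ev) && length(ev)) {
    ev <- as.data.frame(ev)
    if (!all(c("time", "target", "value") %in% names(ev)))
      stop("scenario events need columns time, target, value")
  } else ev <- NULL
  cv_scenario(doc$name, doc$duration, events = ev,
              dt = if (is.null(doc$dt)) 1e-3 else doc$dt,
              record = if (is.null(doc$record)) trace_columns else doc$record)
}

#' Write a scenario to JSON
#'
#' Round-trips with [parse_scenario()] (events normalised to time order).
#'
#' @param scenario a [cv_scenario()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_scenario <- function(scenario, path) {
  jsonlite::write_json(
    list(name = scenario$name, duration = scenario$duration,
         dt = scenario$dt, events = scenario$events,
         record = scenario$record),
    path, auto_unbox = TRUE, digits = NA, dataframe = "rows", pretty = TRUE)
  invisible(path)
}

#' Run a scenario through the simulator
#'
#' Integrates the closed-loop model over the scenario duration, applying
#' each event exactly at its time by restarting the integration with the
#' mutated parameter set (state is carried across seamlessly).  Recording
#' starts at t = 0; the first 50 s of the built-in protocols are settle-in.
#'
#' @param scenario a [cv_scenario()] or the name of a built-in.
#' @param network,control optional parameter overrides (default: the
#'   frozen shipped set).
#' @param verbose if `TRUE`, message each event application.
#' @return a `cv_trace` covering `[0, duration]`, with the applied event
#'   log in `attr(, "event_log")`.
#' @export
run_scenario <- function(scenario, network = NULL, control = NULL,
                         verbose = FALSE) {
  if (is.character(scenario)) scenario <- builtin_scenario(scenario)
  stopifnot(inherits(scenario, "cv_scenario"))
  p <- default_params()
  if (!is.null(network)) p$network <- network
  if (!is.null(control)) p$control <- control
  validate_network(p$network)
  validate_control(p$control)
  dt <- scenario$dt
  ev <- scenario$events
  cuts <- sort(unique(ev$time[ev$time > 0 & ev$time < scenario$duration]))
  bounds <- c(0, cuts, scenario$duration)

  state <- make_state(p$network, p$control)
  pieces <- vector("list", length(bounds) - 1)
  vol_pieces <- vector("list", length(bounds) - 1)
  onsets <- 0
  log <- ev[0, ]
  for (s in seq_len(length(bounds) - 1)) {
    t0 <- bounds[s]; t1 <- bounds[s + 1]
    if (s > 1) {
      due <- ev[ev$time == t0, , drop = FALSE]
      for (k in seq_len(nrow(due))) {
        p <- apply_event(p, due$target[k], due$value[k])
        if (verbose)
          message(sprintf("t = %.3f s: %s <- %g", t0, due$target[k],
                          due$value[k]))
      }
      log <- rbind(log, due)
    }
    seg <- integrate_segment(p$network, p$control, state, t0, t1, dt)
    state <- seg$state
    onsets <- c(onsets, seg$onsets)
    keep <- if (s == 1) TRUE else -1   # drop duplicated boundary sample
    pieces[[s]] <- seg$trace[keep, , drop = FALSE]
    vol_pieces[[s]] <- seg$volumes[keep, , drop = FALSE]
  }
  tr <- new_trace(do.call(rbind, pieces), onsets, dt)
  attr(tr, "volumes") <- do.call(rbind, vol_pieces)
  attr(tr, "scenario") <- scenario$name
  attr(tr, "event_log") <- log
  attr(tr, "final_state") <- state
  tr[scenario$record]  # enforce recorded column set (keeps attributes)
}

#' @export
`[.cv_trace` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out)) {
    for (a in c("onsets", "dt", "scenario", "event_log", "final_state",
                "volumes"))
      attr(out, a) <- attr(x, a)
    class(out) <- class(x)
  }
  out
}

#' @export
print.cv_scenario <- function(x, ...) {
  cat(sprintf("<cv_scenario> %s: %g s at dt = %g s, %d events\n",
              x$name, x$duration, x$dt, nrow(x$events)))
  if (nrow(x$events)) print(x$events)
  invisible(x)
}
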