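#' Piecewise-constant voltage-clamp protocols
#'
#' A protocol is an ordered list of piecewise-constant voltage segments
#' applied after a holding potential, plus a *sweep family*: exactly one slot
#' (one segment's voltage, or one segment's duration) varies across sweeps
#' over a strictly monotone value list. Segments flagged `record = FALSE`
#' contribute only their final state to the simulated trace (used for long
#' recovery intervals whose interior is not analyzed).
#'
#' @param name Protocol name.
#' @param holding Holding potential, mV; sweeps are initialized at its
#'   stationary occupancy (or by an explicit finite hold, see [sim_config()]).
#' @param segments List of `list(duration, voltage, record = TRUE)` entries;
#'   the varying slot takes `NA` for its `duration` or `voltage`.
#' @param sweep `list(segment = <index>, vary = "voltage"|"duration",
#'   values = <numeric>)`.
#' @param dt Sampling interval, ms (default 0.01, i.e. 100 kHz).
#' @return An object of class `voltage_protocol`.
#' @seealso [activation_protocol()], [run_protocol()]
#' @export
voltage_protocol <- function(name, holding, segments, sweep, dt = 0.01) {
  stopifnot(is.character(name), is.numeric(holding), is.finite(holding),
            is.numeric(dt), dt > 0)
  if (!length(segments)) stop("protocol needs at least one segment")
  segments <- lapply(segments, function(s) {
    if (is.null(s$record)) s$record <- TRUE
    s[c("duration", "voltage", "record")]
  })
  if (!is.list(sweep) || !all(c("segment", "vary", "values") %in% names(sweep)))
    stop("'sweep' must supply segment, vary and values")
  sweep$values <- as.numeric(unlist(sweep$values))
  if (!length(sweep$values)) stop("sweep value list must be non-empty")
  if (length(sweep$values) > 1L) {
    d <- diff(sweep$values)
    if (!(all(d > 0) || all(d < 0)))
      stop("sweep values must be strictly monotone")
  }
  if (!sweep$vary %in% c("voltage", "duration"))
    stop("sweep 'vary' must be 'voltage' or 'duration'")
  if (sweep$segment < 1L || sweep$segment > length(segments))
    stop("sweep segment index out of range")
  for (i in seq_along(segments)) {
    s <- segments[[i]]
    fixed_dur <- !(sweep$vary == "duration" && i == sweep$segment)
    fixed_vol <- !(sweep$vary == "voltage" && i == sweep$segment)
    if (fixed_dur && (!is.finite(s$duration) || s$duration <= 0))
      stop("segment ", i, ": duration must be positive")
    if (fixed_vol && !is.finite(s$voltage))
      stop("segment ", i, ": voltage must be finite")
  }
  structure(list(name = name, holding = holding, segments = segments,
                 sweep = sweep, dt = dt),
            class = "voltage_protocol")
}

#' @export
print.voltage_protocol <- function(x, ...) {
  cat(sprintf(
    "<voltage_protocol '%s': hold %g mV, %d segments, %d sweeps (%s of segment %d)>\n",
    x$name, x$holding, length(x$segments), n_sweeps(x), x$sweep$vary,
    x$sweep$segment))
  invisible(x)
}

#' Number of sweeps in a protocol family
#' @param protocol A `voltage_protocol`.
#' @return Integer sweep count.
#' @export
n_sweeps <- function(protocol) length(protocol$sweep$values)

#' Realize the segment table of one sweep
#'
#' @param protocol A `voltage_protocol`.
#' @param sweep Sweep index (1-based).
#' @return Data frame with columns `duration`, `voltage`, `record`.
#' @export
sweep_segments <- function(protocol, sweep) {
  stopifnot(sweep >= 1L, sweep <= n_sweeps(protocol))
  segs <- protocol$segments
  val <- protocol$sweep$values[sweep]
  segs[[protocol$sweep$segment]][[protocol$sweep$vary]] <- val
  data.frame(duration = vapply(segs, `[[`, 0, "duration"),
             voltage = vapply(segs, `[[`, 0, "voltage"),
             record = vapply(segs, `[[`, TRUE, "record"))
}

#' The built-in Nav1.5 voltage-clamp protocols
#'
#' Five protocol builders mirroring the whole-cell characterization of
#' Nav1.5:
#'
#' * `activation_protocol()`: 20 ms depolarizing steps from -90 to +60 mV in
#'   5 mV increments (31 sweeps) from a -120 mV holding potential.
#' * `deactivation_protocol()`: a 0.25 ms activating pulse to -10 mV followed
#'   by 20 ms tail steps from -100 to -30 mV in 10 mV increments (8 sweeps).
#' * `availability_protocol()`: 500 ms conditioning voltages from -120 to
#'   0 mV in 10 mV increments, then a 20 ms test pulse at -10 mV (13 sweeps).
#' * `recovery_protocol()`: two-pulse recovery; prepulse P1, a recovery
#'   interval of varying duration at `recovery_V`, then a 20 ms test pulse
#'   P2. Pulse voltage defaults to -20 mV.
#' * `slow_inactivation_development_protocol()`: -20 mV prepulses of varying
#'   duration, a fixed 30 ms interpulse at -120 mV to clear fast
#'   inactivation, then a 20 ms test pulse at -20 mV.
#'
#' @param dt Sampling interval, ms.
#' @return A [voltage_protocol()].
#' @name nav_protocols
NULL

#' @rdname nav_protocols
#' @export
activation_protocol <- function(dt = 0.01) {
  voltage_protocol(
    name = "activation", holding = -120,
    segments = list(list(duration = 20, voltage = NA)),
    sweep = list(segment = 1L, vary = "voltage", values = seq(-90, 60, by = 5)),
    dt = dt)
}

#' @rdname nav_protocols
#' @export
deactivation_protocol <- function(dt = 0.01) {
  voltage_protocol(
    name = "deactivation", holding = -120,
    segments = list(list(duration = 0.25, voltage = -10),
                    list(duration = 20, voltage = NA)),
    sweep = list(segment = 2L, vary = "voltage",
                 values = seq(-100, -30, by = 10)),
    dt = dt)
}

#' @rdname nav_protocols
#' @export
availability_protocol <- function(dt = 0.01) {
  voltage_protocol(
    name = "availability", holding = -120,
    segments = list(list(duration = 500, voltage = NA),
                    list(duration = 20, voltage = -10)),
    sweep = list(segment = 1L, vary = "voltage",
                 values = seq(-120, 0, by = 10)),
    dt = dt)
}

#' @rdname nav_protocols
#' @param P1 Prepulse duration, ms.
#' @param recovery_V Recovery (interpulse) voltage, mV.
#' @param intervals Recovery interval grid, ms; defaults to a log-spaced grid
#'   covering 0.5–200 ms for short prepulses and 0.5–5000 ms for prepulses of
#'   300 ms and longer (both recovery components resolved).
#' @param pulse_V Voltage of the P1 and P2 pulses, mV.
#' @export
recovery_protocol <- function(P1 = 30, recovery_V = -120, intervals = NULL,
                              pulse_V = -20, dt = 0.01) {
  if (is.null(intervals)) {
    upper <- if (P1 >= 300) 5000 else 200
    intervals <- exp(seq(log(0.5), log(upper), length.out = 25))
  }
  if (!length(intervals)) stop("recovery interval list must be non-empty")
  intervals <- sort(as.numeric(intervals))
  voltage_protocol(
    name = sprintf("recovery_P1_%gms_%gmV", P1, recovery_V), holding = -120,
    segments = list(list(duration = P1, voltage = pulse_V),
                    list(duration = NA, voltage = recovery_V, record = FALSE),
                    list(duration = 20, voltage = pulse_V)),
    sweep = list(segment = 2L, vary = "duration", values = intervals),
    dt = dt)
}

#' @rdname nav_protocols
#' @param durations Prepulse duration grid, ms.
#' @export
slow_inactivation_development_protocol <- function(
    durations = exp(seq(log(10), log(10000), length.out = 20)), dt = 0.01) {
  if (!length(durations)) stop("duration list must be non-empty")
  durations <- sort(as.numeric(durations))
  voltage_protocol(
    name = "slow_inactivation_development", holding = -120,
    segments = list(list(duration = NA, voltage = -20, record = FALSE),
                    list(duration = 30, voltage = -120),
                    list(duration = 20, voltage = -20)),
    sweep = list(segment = 1L, vary = "duration", values = durations),
    dt = dt)
}

#' Read and write protocol files
#'
#' Protocols round-trip losslessly through a structured YAML format.
#'
#' @param path File path.
#' @param protocol A `voltage_protocol`.
#' @return `read_protocol()` returns a `voltage_protocol`; `write_protocol()`
#'   returns `path` invisibly.
#' @export
read_protocol <- function(path) {
  if (!file.exists(path)) stop("protocol file not found: ", path)
  y <- yaml::read_yaml(path)
  segs <- lapply(y$segments, function(s) {
    for (f in c("duration", "voltage"))
      if (is.null(s[[f]]) || identical(s[[f]], "NA")) s[f] <- list(NA_real_)
    s
  })
  voltage_protocol(name = y$name, holding = y$holding, segments = segs,
                   sweep = y$sweep, dt = y$dt)
}

#' @rdname read_protocol
#' @export
write_protocol <- function(protocol, path) {
  stopifnot(inherits(protocol, "voltage_protocol"))
  y <- list(name = protocol$name, holding = protocol$holding,
            segments = protocol$segments,
            sweep = list(segment = protocol$sweep$segment,
                         vary = protocol$sweep$vary,
                         values = as.list(protocol$sweep$values)),
            dt = protocol$dt)
  yaml::write_yaml(y, path, precision = 12L)
  invisible(path)
}
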