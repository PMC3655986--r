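#' Standard kinetic-characterization pipelines
#'
#' Convenience compositions of the protocol builders, the simulator and the
#' curve analyses, returning the headline kinetic characteristics of a model:
#'
#' * `nav_activation_v50()`: Boltzmann midpoint/slope of the normalized peak
#'   G-V curve under the activation protocol.
#' * `nav_availability_v50()`: Boltzmann midpoint/slope of the steady-state
#'   inactivation (availability) curve (500 ms conditioning).
#' * `nav_recovery_fit()`: mono- or bi-exponential fit of fractional recovery
#'   for a two-pulse protocol at a given recovery voltage and prepulse
#'   duration.
#' * `nav_development_fit()`: single-exponential fit of the development of
#'   slow inactivation (normalized remaining test-pulse current vs prepulse
#'   duration).
#'
#' @param scheme A [kinetic_scheme()].
#' @param params A [nav_params()] set.
#' @param config A [sim_config()].
#' @param dt Sampling interval, ms.
#' @return `nav_activation_v50()` and `nav_availability_v50()` return a
#'   `boltzmann_fit`; `nav_recovery_fit()` a `monoexp_fit`/`biexp_fit` (with
#'   the recovery data attached as attribute `data`); `nav_development_fit()`
#'   a `monoexp_fit` (tau in ms).
#' @name nav_pipelines
NULL

#' @rdname nav_pipelines
#' @export
nav_activation_v50 <- function(scheme, params = nav_params(),
                               config = sim_config(), dt = 0.01) {
  traces <- run_protocol(scheme, params, activation_protocol(dt), config)
  pk <- peak_currents(traces, 1L)
  # restrict to voltages below the reversal potential (past it the driving
  # force flips sign and conductance normalization loses meaning)
  pk <- pk[pk$value < config$E_rev - 5, ]
  fit_boltzmann_activation(gv_curve(pk, config$E_rev))
}

#' @rdname nav_pipelines
#' @export
nav_availability_v50 <- function(scheme, params = nav_params(),
                                 config = sim_config(), dt = 0.01) {
  traces <- run_protocol(scheme, params, availability_protocol(dt), config)
  pk <- peak_currents(traces, 2L)
  avail <- data.frame(V = pk$value, I = abs(pk$peak) / max(abs(pk$peak)))
  fit_boltzmann_availability(avail)
}

#' @rdname nav_pipelines
#' @param P1 Prepulse duration, ms.
#' @param recovery_V Recovery voltage, mV.
#' @param intervals Recovery interval grid, ms (default as in
#'   [recovery_protocol()]).
#' @param model `"mono"` or `"bi"`.
#' @export
nav_recovery_fit <- function(scheme, params = nav_params(), P1 = 30,
                             recovery_V = -120, intervals = NULL,
                             model = c("mono", "bi"),
                             config = sim_config(), dt = 0.01) {
  proto <- recovery_protocol(P1 = P1, recovery_V = recovery_V,
                             intervals = intervals, dt = dt)
  traces <- run_protocol(scheme, params, proto, config)
  fr <- fractional_recovery(traces)
  fit <- fit_recovery(fr, model = match.arg(model))
  attr(fit, "data") <- fr
  fit
}

#' @rdname nav_pipelines
#' @param durations Prepulse duration grid, ms.
#' @export
nav_development_fit <- function(scheme, params = nav_params(),
                                durations = exp(seq(log(10), log(10000),
                                                    length.out = 20)),
                                config = sim_config(), dt = 0.01) {
  proto <- slow_inactivation_development_protocol(durations, dt = dt)
  traces <- run_protocol(scheme, params, proto, config)
  pk <- peak_currents(traces, 3L)
  fit <- fit_development(pk)
  attr(fit, "data") <- pk
  fit
}
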