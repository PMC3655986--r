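#' Noise model for synthetic recordings
#'
#' Additive Gaussian current noise scaled to the trace family's peak current,
#' with an optional linear baseline drift.
#'
#' @param sigma Noise standard deviation as a fraction of the family's peak
#'   current magnitude (`sigma >= 0`).
#' @param drift Baseline drift slope, in peak-current fractions per ms.
#' @param seed Integer seed; every synthetic family is deterministic per
#'   seed.
#' @return A list of class `noise_model`.
#' @export
noise_model <- function(sigma = 0.01, drift = 0, seed = 1L) {
  stopifnot(sigma >= 0, is.finite(drift))
  structure(list(sigma = sigma, drift = drift, seed = as.integer(seed)),
            class = "noise_model")
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
          else assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

#' Generate noisy synthetic current traces with known ground truth
#'
#' Runs the simulator and adds i.i.d. Gaussian noise (and optional drift)
#' scaled to the family's peak current magnitude. With `sigma = 0` the output
#' is bit-identical to the clean simulation.
#'
#' @inheritParams run_protocol
#' @param noise A [noise_model()].
#' @return A `nav_trace_set`; the generating truth (parameter values, noise
#'   model) is attached as attribute `truth` and written to the metadata
#'   sidecar by [write_traces()].
#' @export
make_noisy_traces <- function(scheme, params, protocol, noise = noise_model(),
                              config = sim_config()) {
  traces <- run_protocol(scheme, params, protocol, config)
  peak <- max(vapply(traces, function(tr) max(abs(tr$current)), 0))
  if (noise$sigma > 0 || noise$drift != 0) {
    traces[] <- with_seed(noise$seed, lapply(traces, function(tr) {
      eps <- stats::rnorm(length(tr$current), sd = noise$sigma * peak)
      tr$current <- tr$current + eps + noise$drift * peak * tr$time
      tr
    }))
  }
  attr(traces, "truth") <- list(params = lapply(unclass(params), as.list),
                                noise = unclass(noise), peak = peak)
  traces
}

#' Closed-form synthetic fixture curves for the fitters
#'
#' `make_boltzmann_samples()` draws a rising or falling Boltzmann curve at
#' the given voltages; `make_exp_samples()` draws a mono- or bi-exponential
#' recovery/decay curve at the given times. Gaussian noise of standard
#' deviation `sigma` is added (deterministic per seed); the generating truth
#' travels in attribute `truth`.
#'
#' @param V50,k Boltzmann midpoint and slope factor, mV.
#' @param voltages Sample voltages, mV.
#' @param direction `"rising"` (activation) or `"falling"` (availability).
#' @param sigma Gaussian noise standard deviation (same units as the curve).
#' @param seed Integer seed.
#' @return Data frame (`V`, `y`) or (`t`, `y`) with attribute `truth`.
#' @export
make_boltzmann_samples <- function(V50, k, voltages, sigma = 0, seed = 1L,
                                   direction = c("rising", "falling")) {
  direction <- match.arg(direction)
  sgn <- if (direction == "falling") 1 else -1
  y <- 1 / (1 + exp(sgn * (voltages - V50) / k))
  if (sigma > 0)
    y <- y + with_seed(seed, stats::rnorm(length(y), sd = sigma))
  structure(data.frame(V = voltages, y = y),
            truth = list(V50 = V50, k = k, direction = direction,
                         sigma = sigma, seed = seed))
}

#' @rdname make_boltzmann_samples
#' @param taus Time constant(s), ms: length 1 for mono, 2 for bi.
#' @param amplitudes Amplitude(s) matching `taus`.
#' @param times Sample times, ms.
#' @param asymptote Value approached as `t -> Inf`.
#' @export
make_exp_samples <- function(taus, amplitudes, times, asymptote = 1,
                             sigma = 0, seed = 1L) {
  stopifnot(length(taus) %in% 1:2, length(amplitudes) == length(taus),
            all(taus > 0))
  y <- asymptote
  for (i in seq_along(taus)) y <- y - amplitudes[i] * exp(-times / taus[i])
  if (sigma > 0)
    y <- y + with_seed(seed, stats::rnorm(length(y), sd = sigma))
  structure(data.frame(t = times, y = y),
            truth = list(taus = taus, amplitudes = amplitudes,
                         asymptote = asymptote, sigma = sigma, seed = seed))
}
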