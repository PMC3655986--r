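#' Simulator configuration
#'
#' @param Gmax Maximal conductance (arbitrary units), scales the macroscopic
#'   current `I(t) = Gmax * P_open(t) * (V - E_rev)` (inward currents are
#'   negative).
#' @param E_rev Reversal potential, mV. Default +67.5 mV, the Na+ Nernst
#'   potential for 140 mM external / 10 mM internal Na+ at 24 degC.
#' @param propagator `"spectral"` (eigendecomposition of Q, exact for
#'   piecewise-constant voltage, with a scaling-and-squaring matrix
#'   exponential fallback when Q is near-defective) or `"rk"` (adaptive
#'   Dormand-Prince 5th-order Runge-Kutta).
#' @param init `"stationary"` initializes each sweep at the exact stationary
#'   distribution of the holding potential; `"hold"` instead simulates a
#'   finite hold of `hold_ms` from the uniform distribution (validation
#'   mode).
#' @param hold_ms Finite hold duration, ms (only used when `init = "hold"`).
#' @param rk_dt Initial/maximal internal step for the RK propagator, ms.
#' @param tol Relative tolerance for occupancy-conservation checks.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(Gmax = 1, E_rev = 67.5,
                       propagator = c("spectral", "rk"),
                       init = c("stationary", "hold"), hold_ms = 5000,
                       rk_dt = 0.01, tol = 1e-9) {
  stopifnot(Gmax > 0, is.finite(E_rev), rk_dt > 0, hold_ms > 0)
  structure(list(Gmax = Gmax, E_rev = E_rev,
                 propagator = match.arg(propagator),
                 init = match.arg(init), hold_ms = hold_ms,
                 rk_dt = rk_dt, tol = tol),
            class = "sim_config")
}

#' Propagate occupancies through one constant-voltage segment (spectral)
#'
#' Solves `dp/dt = p %*% Q(V)` as `p(t) = p0 %*% expm(Q t)` via the
#' eigendecomposition of `Q`, evaluated at arbitrary sample times. Falls back
#' to a scaling-and-squaring matrix exponential when the eigenvector matrix
#' is ill-conditioned.
#'
#' @param scheme A [kinetic_scheme()].
#' @param params A [nav_params()] set.
#' @param p0 Initial occupancy vector (sums to 1).
#' @param V Segment voltage, mV.
#' @param t Sample times, ms (nonnegative, nondecreasing).
#' @return Occupancy matrix, `length(t)` rows by state columns.
#' @export
propagate_segment_spectral <- function(scheme, params, p0, V, t) {
  Q <- build_generator(scheme, params, V)
  propagate_spectral_Q(Q, p0, V, t)
}

# internal: spectral propagation given a prebuilt Q (optionally a cached
# eigendecomposition attached as attribute "eig")
propagate_spectral_Q <- function(Q, p0, V, t, eig = NULL) {
  check_p0(p0, nrow(Q))
  if (any(t < 0) || is.unsorted(t)) stop("sample times must be nondecreasing and >= 0")
  if (is.null(eig)) eig <- eigen_cache_entry(Q)
  n <- nrow(Q)
  if (eig$ok) {
    a <- as.vector(p0 %*% eig$W)           # coefficients in eigenbasis
    E <- exp(outer(t, eig$lambda))         # |t| x n
    P <- (E * matrix(a, length(t), n, byrow = TRUE)) %*% eig$Winv
    P <- Re(P)
  } else {
    # robust fallback: step with matrix exponentials over the time increments
    P <- matrix(0, length(t), n)
    cur <- as.numeric(p0); last <- 0
    for (i in seq_along(t)) {
      dt <- t[i] - last
      if (dt > 0) cur <- as.numeric(cur %*% as.matrix(Matrix::expm(Q * dt)))
      P[i, ] <- cur; last <- t[i]
    }
  }
  if (any(!is.finite(P)))
    stop("non-finite occupancies while propagating at V = ", V, " mV")
  P[P < 0 & P > -1e-12] <- 0
  drift <- abs(rowSums(P) - 1)
  if (any(drift > 1e-7))
    stop("occupancy conservation lost (drift ", signif(max(drift), 3),
         ") at V = ", V, " mV")
  P <- P / rowSums(P)
  colnames(P) <- rownames(Q)
  P
}

eigen_cache_entry <- function(Q) {
  e <- eigen(Q)
  W <- e$vectors
  ok <- is.finite(rcond(W)) && rcond(W) > 1e-10
  list(ok = ok, lambda = e$values, W = W,
       Winv = if (ok) solve(W) else NULL)
}

#' Propagate occupancies through one segment (Runge-Kutta)
#'
#' Fifth-order Dormand-Prince integration of the master equation
#' `dp/dt = p %*% Q(V)` (via \pkg{deSolve}), with per-segment renormalization
#' drift required to stay below `1e-9`.
#'
#' @inheritParams propagate_segment_spectral
#' @param dt Maximal internal step, ms.
#' @return Occupancy matrix, `length(t)` rows by state columns.
#' @export
propagate_segment_rk <- function(scheme, params, p0, V, t, dt = 0.01) {
  Q <- build_generator(scheme, params, V)
  check_p0(p0, nrow(Q))
  if (any(t < 0) || is.unsorted(t)) stop("sample times must be nondecreasing and >= 0")
  times <- t
  prepend <- times[1] > 0
  if (prepend) times <- c(0, times)
  deriv <- function(tt, y, parms) list(as.vector(y %*% Q))
  sol <- deSolve::ode(y = as.numeric(p0), times = times, func = deriv,
                      parms = NULL, method = "ode45",
                      rtol = 1e-10, atol = 1e-12, hini = dt, hmax = max(dt, 1))
  P <- unname(sol[, -1, drop = FALSE])
  if (prepend) P <- P[-1, , drop = FALSE]
  if (any(!is.finite(P)))
    stop("RK propagation diverged at V = ", V, " mV (step-size underflow?)")
  drift <- abs(rowSums(P) - 1)
  if (any(drift > 1e-9))
    stop("RK occupancy drift ", signif(max(drift), 3), " exceeds 1e-9 at V = ",
         V, " mV; reduce dt")
  P[P < 0 & P > -1e-12] <- 0
  P <- P / rowSums(P)
  colnames(P) <- scheme$states
  P
}

check_p0 <- function(p0, n) {
  if (length(p0) != n) stop("p0 has wrong length")
  if (abs(sum(p0) - 1) > 1e-6) stop("p0 must sum to 1")
  invisible(TRUE)
}

#' Run one sweep of a protocol
#'
#' Initializes at the holding potential, chains segment propagations, and
#' emits the macroscopic current `I(t) = Gmax * P_open(t) * (V - E_rev)`.
#' Segments flagged `record = FALSE` contribute a single sample at their end
#' point. Time is measured from the start of the first segment.
#'
#' @param scheme A [kinetic_scheme()].
#' @param params A [nav_params()] set.
#' @param protocol A [voltage_protocol()].
#' @param sweep Sweep index.
#' @param config A [sim_config()].
#' @param cache Optional environment reused across sweeps to memoize
#'   generator eigendecompositions and repeated identical segments.
#' @return A `nav_trace`: list with `time`, `segment`, `voltage`, `occ`
#'   (occupancy matrix), `current`, `sweep_value`, `states`, `open`.
#' @export
run_sweep <- function(scheme, params, protocol, sweep, config = sim_config(),
                      cache = NULL) {
  if (is.null(cache)) cache <- new.env(parent = emptyenv())
  segs <- sweep_segments(protocol, sweep)
  p0 <- initial_occupancy(scheme, params, protocol, config, cache)
  open <- match(scheme$conducting, scheme$states)
  dt <- protocol$dt
  times <- list(); segid <- list(); volts <- list(); occs <- list()
  t_abs <- 0
  for (i in seq_len(nrow(segs))) {
    dur <- segs$duration[i]; V <- segs$voltage[i]
    tloc <- if (segs$record[i]) {
      m <- max(1L, round(dur / dt))
      seq(0, dur, length.out = m + 1L)
    } else dur
    P <- propagate_cached(scheme, params, p0, V, tloc, config, cache)
    times[[i]] <- t_abs + tloc
    segid[[i]] <- rep.int(i, length(tloc))
    volts[[i]] <- rep.int(V, length(tloc))
    occs[[i]] <- P
    p0 <- P[nrow(P), ]
    t_abs <- t_abs + dur
  }
  occ <- do.call(rbind, occs)
  voltage <- unlist(volts)
  current <- config$Gmax * occ[, open] * (voltage - config$E_rev)
  structure(list(time = unlist(times), segment = unlist(segid),
                 voltage = voltage, occ = occ, current = unname(current),
                 sweep_value = protocol$sweep$values[sweep],
                 states = scheme$states, open = scheme$conducting,
                 protocol = protocol$name),
            class = "nav_trace")
}

initial_occupancy <- function(scheme, params, protocol, config, cache) {
  key <- sprintf("init|%.10g|%s", protocol$holding, config$init)
  if (!is.null(cache[[key]])) return(cache[[key]])
  p0 <- if (config$init == "stationary") {
    stationary_distribution(scheme, params, protocol$holding)
  } else {
    n <- length(scheme$states)
    u <- rep(1 / n, n)
    P <- propagate_cached(scheme, params, u, protocol$holding,
                          config$hold_ms, config, cache)
    P[nrow(P), ]
  }
  cache[[key]] <- p0
  p0
}

propagate_cached <- function(scheme, params, p0, V, tloc, config, cache) {
  if (config$propagator == "rk") {
    P <- propagate_segment_rk(scheme, params, p0, V, tloc, dt = config$rk_dt)
    return(matrix(P, nrow = length(tloc), dimnames = list(NULL, scheme$states)))
  }
  qkey <- sprintf("Q|%.12g", V)
  ent <- cache[[qkey]]
  if (is.null(ent)) {
    Q <- build_generator(scheme, params, V)
    ent <- list(Q = Q, eig = eigen_cache_entry(Q))
    cache[[qkey]] <- ent
  }
  skey <- sprintf("seg|%.12g|%.12g|%d|%s", V, max(tloc), length(tloc),
                  paste(sprintf("%.15g", p0), collapse = ","))
  if (!is.null(cache[[skey]])) return(cache[[skey]])
  P <- propagate_spectral_Q(ent$Q, p0, V, tloc, eig = ent$eig)
  P <- matrix(P, nrow = length(tloc), dimnames = list(NULL, scheme$states))
  cache[[skey]] <- P
  P
}

#' Run all sweeps of a protocol
#'
#' @inheritParams run_sweep
#' @return A `nav_trace_set`: list of `nav_trace` objects (one per sweep, in
#'   sweep order) with the protocol attached as an attribute.
#' @export
run_protocol <- function(scheme, params, protocol, config = sim_config()) {
  cache <- new.env(parent = emptyenv())
  traces <- lapply(seq_len(n_sweeps(protocol)), function(i)
    run_sweep(scheme, params, protocol, i, config, cache = cache))
  structure(traces, class = "nav_trace_set", protocol = protocol,
            config = config, scheme = scheme$name)
}

#' @export
print.nav_trace <- function(x, ...) {
  cat(sprintf("<nav_trace: %s sweep value %g, %d samples, peak current %.4g>\n",
              x$protocol, x$sweep_value, length(x$time),
              x$current[which.max(abs(x$current))]))
  invisible(x)
}

#' @export
print.nav_trace_set <- function(x, ...) {
  cat(sprintf("<nav_trace_set: %d sweeps of '%s'>\n", length(x),
              attr(x, "protocol")$name))
  invisible(x)
}
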