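#' Peak currents of a sweep family
#'
#' Signed extremum (largest `|I|`) of the current within the selected segment
#' of every sweep.
#'
#' @param traces A `nav_trace_set` (or list of `nav_trace`).
#' @param segment Segment index to search.
#' @return Data frame with `value` (the sweep's varying value) and `peak`.
#' @export
peak_currents <- function(traces, segment) {
  out <- lapply(traces, function(tr) {
    idx <- which(tr$segment == segment)
    if (!length(idx)) stop("segment ", segment, " not present in sweep")
    cur <- tr$current[idx]
    data.frame(value = tr$sweep_value, peak = cur[which.max(abs(cur))])
  })
  do.call(rbind, out)
}

#' Normalized conductance-voltage (G-V) curve
#'
#' Converts peak currents to conductances, `G(V) = I_peak / (V - E_rev)`, and
#' normalizes by the maximum.
#'
#' @param peaks Data frame from [peak_currents()] (`value` = test voltage).
#' @param E_rev Reversal potential, mV.
#' @return Data frame with `V` and normalized conductance `G`.
#' @export
gv_curve <- function(peaks, E_rev) {
  if (any(peaks$value == E_rev))
    stop("test voltage equals the reversal potential; conductance undefined")
  G <- peaks$peak / (peaks$value - E_rev)
  data.frame(V = peaks$value, G = G / max(G))
}

boltzmann_seed <- function(V, y, falling) {
  yr <- (y - min(y)) / (max(y) - min(y))
  if (falling) yr <- 1 - yr
  o <- order(V)
  V <- V[o]; yr <- yr[o]
  cross <- function(level) {
    i <- which(yr >= level)[1]
    if (is.na(i) || i == 1L) return(stats::median(V))
    V[i - 1] + (level - yr[i - 1]) * (V[i] - V[i - 1]) / (yr[i] - yr[i - 1])
  }
  v50 <- cross(0.5)
  k <- abs(cross(0.75) - cross(0.25)) / (2 * log(3))
  if (!is.finite(k) || k < 1e-3) k <- diff(range(V)) / 4
  c(V50 = v50, k = k)
}

boltzmann_fit <- function(df, falling, scale_free) {
  stopifnot(all(c("V", "y") %in% names(df)))
  df <- df[is.finite(df$V) & is.finite(df$y), ]
  if (nrow(df) < 4L) stop("need at least 4 points spanning the transition")
  seed <- boltzmann_seed(df$V, df$y, falling)
  sgn <- if (falling) 1 else -1
  form <- if (scale_free)
    y ~ ymax / (1 + exp(sgn * (V - V50) / k))
  else
    y ~ 1 / (1 + exp(sgn * (V - V50) / k))
  start <- list(V50 = unname(seed["V50"]), k = unname(seed["k"]))
  if (scale_free) start$ymax <- max(df$y)
  fit <- tryCatch(
    minpack.lm::nlsLM(form, data = cbind(df, sgn = sgn), start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e)
      stop("Boltzmann fit failed to converge (initial guess V50 = ",
           signif(seed["V50"], 4), ", k = ", signif(seed["k"], 4), "): ",
           conditionMessage(e)))
  cf <- stats::coef(fit)
  if (cf[["V50"]] < min(df$V) - 5 || cf[["V50"]] > max(df$V) + 5)
    warning("fitted V50 lies outside the data voltage range")
  structure(list(V50 = unname(cf["V50"]), k = abs(unname(cf["k"])),
                 scale = if (scale_free) unname(cf["ymax"]) else 1,
                 residual = sqrt(sum(stats::resid(fit)^2)),
                 n = nrow(df), falling = falling),
            class = "boltzmann_fit")
}

#' Boltzmann fits of activation and availability curves
#'
#' `fit_boltzmann_activation()` fits the rising Boltzmann
#' `G/Gmax = 1 / (1 + exp((V50 - V) / k))` to a normalized G-V curve;
#' `fit_boltzmann_availability()` fits the falling form
#' `I/Imax = 1 / (1 + exp((V - V50) / k))` to normalized test-pulse peak
#' currents after conditioning. Deterministic seeding: V50 from the linear
#' interpolation of the half-maximum crossing, k from the quartile crossings.
#'
#' @param gv Data frame with `V` and `G` (activation) — as from
#'   [gv_curve()].
#' @param avail Data frame with `V` and normalized peak `I` (availability).
#' @param scale_free If `TRUE` the saturating level is a free parameter
#'   (default); if `FALSE` it is fixed at 1.
#' @return A `boltzmann_fit` with `V50` (mV), slope factor `k` (mV), `scale`,
#'   and the residual norm.
#' @export
fit_boltzmann_activation <- function(gv, scale_free = TRUE) {
  boltzmann_fit(data.frame(V = gv$V, y = gv$G), falling = FALSE,
                scale_free = scale_free)
}

#' @rdname fit_boltzmann_activation
#' @export
fit_boltzmann_availability <- function(avail, scale_free = TRUE) {
  names(avail)[2] <- "y"
  boltzmann_fit(avail[, c("V", "y")], falling = TRUE, scale_free = scale_free)
}

#' @export
print.boltzmann_fit <- function(x, ...) {
  cat(sprintf("<boltzmann_fit (%s): V50 = %.2f mV, k = %.2f mV, scale %.4g, rss %.3g (n = %d)>\n",
              if (x$falling) "availability" else "activation",
              x$V50, x$k, x$scale, x$residual, x$n))
  invisible(x)
}

#' Fractional recovery from a two-pulse trace family
#'
#' The fractional current is `I(P2, interval) / I(P1)` per sweep, the ratio
#' of the test-pulse peak to the prepulse peak.
#'
#' @param traces A `nav_trace_set` from a [recovery_protocol()] run.
#' @param p1_segment,p2_segment Segment indices of the prepulse and test
#'   pulse (defaults 1 and 3).
#' @return Data frame with `interval` (ms) and `fraction`.
#' @export
fractional_recovery <- function(traces, p1_segment = 1L, p2_segment = 3L) {
  p1 <- peak_currents(traces, p1_segment)
  p2 <- peak_currents(traces, p2_segment)
  if (any(p1$peak == 0)) stop("prepulse peak current is zero")
  data.frame(interval = p2$value, fraction = p2$peak / p1$peak)
}

loglin_tau <- function(t, y) {
  # deterministic seed: log-linear regression on positive residual amplitude
  ok <- y > max(y) * 1e-6 & is.finite(y)
  if (sum(ok) < 2L) return(max(t) / 3)
  fit <- stats::lm(log(y[ok]) ~ t[ok])
  sl <- stats::coef(fit)[2]
  if (!is.finite(sl) || sl >= 0) max(t) / 3 else -1 / unname(sl)
}

#' Exponential fits of recovery time courses
#'
#' Fits fractional-recovery data to the mono-exponential
#' `y(t) = y_inf - A1 * exp(-t / tau)` or the bi-exponential
#' `y(t) = y_inf - A1 * exp(-t / tau1) - A2 * exp(-t / tau2)` (components
#' ordered `tau1 < tau2`; amplitude fractions reported as `A / (A1 + A2)`).
#' Seeding is a deterministic two-stage peel-off: the slow component from a
#' log-linear regression on the late tail, the fast one from the early
#' residual.
#'
#' @param fractions Data frame with `interval` and `fraction` (as from
#'   [fractional_recovery()]).
#' @param model `"mono"` or `"bi"`.
#' @return A `monoexp_fit` (`tau`, amplitude `a`, offset `b`) or `biexp_fit`
#'   (`tau1`, `tau2`, `A1`, `A2`, fractions, asymptote) with residual norms.
#' @export
fit_recovery <- function(fractions, model = c("mono", "bi")) {
  model <- match.arg(model)
  t <- fractions$interval; y <- fractions$fraction
  ok <- is.finite(t) & is.finite(y)
  t <- t[ok]; y <- y[ok]
  if (model == "mono") {
    if (length(t) < 5L) stop("mono-exponential fit needs >= 5 points")
    yinf <- max(y)
    tau0 <- loglin_tau(t, pmax(yinf - y, 0))
    fit <- minpack.lm::nlsLM(
      y ~ yinf - a * exp(-t / tau), data = data.frame(t = t, y = y),
      start = list(yinf = yinf, a = max(yinf - min(y), 1e-6), tau = tau0),
      lower = c(-Inf, 0, 1e-9),
      control = minpack.lm::nls.lm.control(maxiter = 500))
    cf <- stats::coef(fit)
    structure(list(tau = unname(cf["tau"]), a = unname(cf["a"]),
                   b = unname(cf["yinf"]),
                   residual = sqrt(sum(stats::resid(fit)^2)), n = length(t)),
              class = "monoexp_fit")
  } else {
    if (length(t) < 8L) stop("bi-exponential fit needs >= 8 points")
    yinf <- max(y)
    r <- pmax(yinf - y, 0)
    late <- t >= stats::median(t)
    tau2_0 <- loglin_tau(t[late], r[late])
    a2_0 <- mean(pmin(r[late] * exp(pmin(t[late] / tau2_0, 500)), yinf))
    a2_0 <- min(max(a2_0, 1e-4), yinf)
    r1 <- pmax(r - a2_0 * exp(-t / tau2_0), 0)
    early <- t <= stats::median(t)
    tmin <- if (any(t > 0)) min(t[t > 0]) else 1
    tau1_0 <- max(min(loglin_tau(t[early], r1[early]), tau2_0 / 3), tmin / 2)
    a1_0 <- max(max(r) - a2_0, 1e-4)
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ yinf - A1 * exp(-t / tau1) - A2 * exp(-t / tau2),
        data = data.frame(t = t, y = y),
        start = list(yinf = yinf, A1 = a1_0, tau1 = tau1_0,
                     A2 = a2_0, tau2 = tau2_0),
        lower = c(-Inf, 0, 1e-9, 0, 1e-9),
        control = minpack.lm::nls.lm.control(maxiter = 1000)),
      error = function(e) NULL)
    if (is.null(fit)) {
      # the second component is unidentifiable: report the mono-exponential
      # solution with a degenerate (zero-amplitude) slow component rather
      # than a spurious confident second time constant
      warning("bi-exponential components unresolvable; ",
              "returning a degenerate second component")
      mono <- fit_recovery(data.frame(interval = t, fraction = y), "mono")
      return(structure(list(tau1 = mono$tau, tau2 = Inf, A1 = mono$a, A2 = 0,
                            frac1 = 1, frac2 = 0, b = mono$b,
                            residual = mono$residual, n = mono$n,
                            degenerate = TRUE),
                       class = "biexp_fit"))
    }
    cf <- stats::coef(fit)
    tau <- c(cf[["tau1"]], cf[["tau2"]])
    A <- c(cf[["A1"]], cf[["A2"]])
    o <- order(tau)
    tau <- tau[o]; A <- A[o]
    if (tau[2] / tau[1] < 3)
      warning("bi-exponential components unresolvable (tau2/tau1 < 3)")
    structure(list(tau1 = tau[1], tau2 = tau[2], A1 = A[1], A2 = A[2],
                   frac1 = A[1] / sum(A), frac2 = A[2] / sum(A),
                   b = unname(cf["yinf"]),
                   residual = sqrt(sum(stats::resid(fit)^2)), n = length(t),
                   degenerate = FALSE),
              class = "biexp_fit")
  }
}

#' @export
print.monoexp_fit <- function(x, ...) {
  cat(sprintf("<monoexp_fit: tau = %.4g ms, a = %.4g, offset = %.4g, rss %.3g (n = %d)>\n",
              x$tau, x$a, x$b, x$residual, x$n))
  invisible(x)
}

#' @export
print.biexp_fit <- function(x, ...) {
  cat(sprintf("<biexp_fit: tau1 = %.4g ms (%.0f%%), tau2 = %.4g ms (%.0f%%), rss %.3g (n = %d)>\n",
              x$tau1, 100 * x$frac1, x$tau2, 100 * x$frac2, x$residual, x$n))
  invisible(x)
}

#' Fit the development of slow inactivation
#'
#' Normalizes remaining test-pulse peak currents to the shortest prepulse
#' duration and fits `y(t) = a + b * exp(-t / tau)` (plateau `a`, amplitude
#' `b`).
#'
#' @param peaks Data frame with `value` (prepulse duration, ms) and `peak`
#'   (test-pulse peak current), as from [peak_currents()].
#' @return A `monoexp_fit` with `tau` (ms), amplitude `a` = `b` of the
#'   equation, offset `b` = plateau.
#' @export
fit_development <- function(peaks) {
  t <- peaks$value
  if (length(t) < 5L) stop("development fit needs >= 5 durations")
  if (max(t) < 2 * min(t)) stop("durations must span at least a factor of 2")
  y <- abs(peaks$peak) / abs(peaks$peak[which.min(t)])
  if (diff(range(y)) < 1e-7 * max(abs(y))) {
    # no decay to fit: constant remaining current, zero amplitude
    return(structure(list(tau = max(t), a = 0, b = mean(y),
                          residual = sqrt(sum((y - mean(y))^2)),
                          n = length(t)),
                     class = "monoexp_fit"))
  }
  a0 <- min(y)
  tau0 <- loglin_tau(t, pmax(y - a0, 0))
  fit <- minpack.lm::nlsLM(
    y ~ a + b * exp(-t / tau), data = data.frame(t = t, y = y),
    start = list(a = a0, b = max(max(y) - a0, 1e-6), tau = tau0),
    lower = c(-Inf, 0, 1e-9),
    control = minpack.lm::nls.lm.control(maxiter = 500))
  cf <- stats::coef(fit)
  structure(list(tau = unname(cf["tau"]), a = unname(cf["b"]),
                 b = unname(cf["a"]),
                 residual = sqrt(sum(stats::resid(fit)^2)), n = length(t)),
            class = "monoexp_fit")
}

#' Extract a phase time constant from one trace
#'
#' Mono-exponential fit over a phase window of a single sweep:
#' * `activation`: rise from the segment start to the current peak;
#' * `inactivation`: decay from 110% of the time-to-peak to the segment end;
#' * `deactivation`: tail decay from the segment's peak onward.
#'
#' @param trace A `nav_trace`.
#' @param phase `"activation"`, `"inactivation"` or `"deactivation"`.
#' @param segment Segment index holding the phase (default: the last
#'   recorded segment with more than one sample).
#' @return A `monoexp_fit` (`tau` in ms).
#' @export
extract_time_constant <- function(trace,
                                  phase = c("activation", "inactivation",
                                            "deactivation"),
                                  segment = NULL) {
  phase <- match.arg(phase)
  if (is.null(segment)) {
    tab <- table(trace$segment)
    segment <- as.integer(names(tab)[tab > 1])
    segment <- segment[length(segment)]
  }
  idx <- which(trace$segment == segment)
  if (length(idx) < 8L) stop("segment ", segment, " has too few samples")
  t <- trace$time[idx] - trace$time[idx][1]
  I <- trace$current[idx]
  ipk <- which.max(abs(I))
  if (phase == "activation") {
    if (ipk < 5L) stop("activation window degenerate: peak at segment start")
    w <- seq_len(ipk)
    y <- abs(I[w])
    tau0 <- loglin_tau(t[w], pmax(max(y) - y, max(y) * 1e-8))
    fit <- minpack.lm::nlsLM(y ~ A * (1 - exp(-t / tau)),
                             data = data.frame(t = t[w], y = y),
                             start = list(A = max(y), tau = max(tau0, t[w][2])),
                             lower = c(0, 1e-9),
                             control = minpack.lm::nls.lm.control(maxiter = 500))
  } else {
    start_t <- if (phase == "inactivation") 1.1 * t[ipk] else t[ipk]
    w <- which(t >= start_t)
    if (length(w) < 5L)
      stop(phase, " window degenerate: peak too close to segment end")
    y <- abs(I[w]); tw <- t[w] - t[w][1]
    C0 <- min(y)
    tau0 <- loglin_tau(tw, pmax(y - C0, max(y) * 1e-8))
    fit <- minpack.lm::nlsLM(y ~ C + A * exp(-t / tau),
                             data = data.frame(t = tw, y = y),
                             start = list(C = C0, A = max(y) - C0, tau = tau0),
                             lower = c(-Inf, 0, 1e-9),
                             control = minpack.lm::nls.lm.control(maxiter = 500))
  }
  cf <- stats::coef(fit)
  structure(list(tau = unname(cf["tau"]),
                 a = unname(cf[intersect(c("A", "a"), names(cf))[1]]),
                 b = unname(if ("C" %in% names(cf)) cf["C"] else 0),
                 residual = sqrt(sum(stats::resid(fit)^2)), n = length(fit$m$lhs())),
            class = "monoexp_fit")
}
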