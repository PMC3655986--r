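#' Define a rate-constant estimation problem
#'
#' A fit problem bundles a scheme skeleton, one or more (protocol, target
#' trace family) pairs, the free parameters with box bounds, and the fixed
#' parameter set. Free parameters are addressed as `"entry.field"` (e.g.
#' `"alpha1.k"`); rate magnitudes are usually searched in log10 space.
#'
#' @param scheme A [kinetic_scheme()].
#' @param targets List of `list(protocol, traces)` pairs; `traces` are the
#'   target currents (simulated or measured) on the protocol's grid.
#' @param free Data frame (or list coercible to one) with columns `name`,
#'   `lower`, `upper`, `log` (logical: search in log10 space).
#' @param fixed A [nav_params()] set supplying every non-free entry.
#' @param config [sim_config()] used for simulation during fitting.
#' @return A list of class `fit_problem`.
#' @export
fit_problem <- function(scheme, targets, free, fixed = nav_params(),
                        config = sim_config()) {
  free <- as.data.frame(free)
  stopifnot(all(c("name", "lower", "upper") %in% names(free)))
  if (is.null(free$log)) free$log <- TRUE
  if (any(!is.finite(free$lower)) || any(!is.finite(free$upper)) ||
      any(free$lower >= free$upper))
    stop("free-parameter bounds must be finite with lower < upper")
  if (any(free$log & free$lower <= 0))
    stop("log-space parameters need positive lower bounds")
  for (nm in free$name) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    if (length(parts) != 2L || is.null(fixed[[parts[1]]]) ||
        !parts[2] %in% names(fixed[[parts[1]]]))
      stop("free parameter '", nm, "' does not address an entry.field of the ",
           "parameter set")
  }
  for (tg in targets) {
    if (!inherits(tg$protocol, "voltage_protocol") ||
        !length(tg$traces))
      stop("each target needs a voltage_protocol and a non-empty trace set")
    if (length(tg$traces) != n_sweeps(tg$protocol))
      stop("target trace count does not match protocol sweep count")
  }
  structure(list(scheme = scheme, targets = targets, free = free,
                 fixed = fixed, config = config),
            class = "fit_problem")
}

set_param_field <- function(params, name, value) {
  parts <- strsplit(name, ".", fixed = TRUE)[[1]]
  params[[parts[1]]][[parts[2]]] <- value
  params
}

problem_params <- function(problem, theta) {
  p <- problem$fixed
  for (i in seq_len(nrow(problem$free)))
    p <- set_param_field(p, problem$free$name[i], theta[i])
  p
}

#' Cost of a candidate parameter vector
#'
#' Sum over target protocols of the normalized sum of squared errors between
#' simulated and target currents; each protocol's SSE is divided by the
#' squared peak magnitude of its target family, so protocols weigh equally
#' regardless of absolute current scale.
#'
#' @param theta Numeric vector of free-parameter values (natural scale,
#'   ordered as `problem$free$name`).
#' @param problem A [fit_problem()].
#' @return Nonnegative scalar (`Inf` if simulation fails).
#' @export
cost <- function(theta, problem) {
  p <- tryCatch(problem_params(problem, theta), error = function(e) NULL)
  if (is.null(p)) return(Inf)
  total <- 0
  for (tg in problem$targets) {
    sim <- tryCatch(
      run_protocol(problem$scheme, p, tg$protocol, problem$config),
      error = function(e) NULL)
    if (is.null(sim)) return(Inf)
    peak <- max(vapply(tg$traces, function(tr) max(abs(tr$current)), 0))
    if (peak == 0) stop("target trace family has zero current")
    sse <- sum(vapply(seq_along(sim), function(i) {
      d <- sim[[i]]$current - tg$traces[[i]]$current
      sum(d * d)
    }, 0))
    total <- total + sse / peak^2
  }
  total
}

golden_section <- function(f, lo, hi, tol = 1e-6, maxit = 80L) {
  gr <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  x1 <- b - gr * (b - a); x2 <- a + gr * (b - a)
  f1 <- f(x1); f2 <- f(x2)
  for (i in seq_len(maxit)) {
    if (b - a < tol * (abs(a) + abs(b) + 1e-12)) break
    if (f1 <= f2) {
      b <- x2; x2 <- x1; f2 <- f1
      x1 <- b - gr * (b - a); f1 <- f(x1)
    } else {
      a <- x1; x1 <- x2; f1 <- f2
      x2 <- a + gr * (b - a); f2 <- f(x2)
    }
  }
  if (f1 <= f2) c(x = x1, f = f1) else c(x = x2, f = f2)
}

#' Global rate-constant estimation by particle swarm with golden-section
#' refinement
#'
#' Canonical global-best particle swarm optimization (constriction
#' coefficients: inertia 0.729, cognitive = social = 1.49445) over the
#' box-bounded free parameters (log10-transformed where flagged). Every
#' `gss_every` generations, a golden-section line search is run along each
#' coordinate of the global best and the best point found replaces it. The
#' run is fully deterministic given `seed`.
#'
#' @param problem A [fit_problem()].
#' @param swarm Number of particles.
#' @param iterations Number of PSO generations.
#' @param seed Integer seed for swarm initialization and velocity updates.
#' @param inertia,cognitive,social PSO coefficients.
#' @param gss_every Golden-section refinement cadence, in generations
#'   (`Inf` disables it).
#' @return A `fit_report`: `best` (named parameter vector, natural scale),
#'   `best_cost`, `cost_trajectory` (best cost per generation), `swarm_costs`
#'   (final generation), `seed`, `evaluations`.
#' @export
pso_gss_fit <- function(problem, swarm = 20L, iterations = 50L, seed = 1L,
                        inertia = 0.729, cognitive = 1.49445,
                        social = 1.49445, gss_every = 10L) {
  stopifnot(inherits(problem, "fit_problem"), swarm >= 1L, iterations >= 0L)
  free <- problem$free
  d <- nrow(free)
  lo <- ifelse(free$log, log10(free$lower), free$lower)
  hi <- ifelse(free$log, log10(free$upper), free$upper)
  to_nat <- function(z) ifelse(free$log, 10^z, z)
  fz <- function(z) cost(to_nat(z), problem)
  nev <- 0L
  fcount <- function(z) { nev <<- nev + 1L; fz(z) }
  with_seed(seed, {
    X <- matrix(lo, swarm, d, byrow = TRUE) +
      matrix(stats::runif(swarm * d), swarm, d) *
      matrix(hi - lo, swarm, d, byrow = TRUE)
    Vel <- matrix(0, swarm, d)
    costs <- apply(X, 1, fcount)
    if (all(!is.finite(costs)))
      stop("all initial particles returned non-finite cost; ",
           "first particle: ", paste(signif(to_nat(X[1, ]), 4), collapse = ", "))
    Pbest <- X; pcost <- costs
    g <- which.min(pcost)
    gbest <- Pbest[g, ]; gcost <- pcost[g]
    traj <- numeric(0)
    iter <- 0L
    while (iter < iterations) {
      iter <- iter + 1L
      r1 <- matrix(stats::runif(swarm * d), swarm, d)
      r2 <- matrix(stats::runif(swarm * d), swarm, d)
      Vel <- inertia * Vel + cognitive * r1 * (Pbest - X) +
        social * r2 * (matrix(gbest, swarm, d, byrow = TRUE) - X)
      X <- X + Vel
      # reflect at the box bounds
      for (j in seq_len(d)) {
        below <- X[, j] < lo[j]; above <- X[, j] > hi[j]
        X[below, j] <- lo[j] + (lo[j] - X[below, j])
        X[above, j] <- hi[j] - (X[above, j] - hi[j])
        X[, j] <- pmin(pmax(X[, j], lo[j]), hi[j])
        Vel[below | above, j] <- -0.5 * Vel[below | above, j]
      }
      costs <- apply(X, 1, fcount)
      if (all(!is.finite(costs)))
        stop("entire swarm returned non-finite cost at generation ", iter,
             "; global best so far: ",
             paste(signif(to_nat(gbest), 4), collapse = ", "))
      imp <- costs < pcost
      Pbest[imp, ] <- X[imp, ]; pcost[imp] <- costs[imp]
      g <- which.min(pcost)
      if (pcost[g] < gcost) { gbest <- Pbest[g, ]; gcost <- pcost[g] }
      if (is.finite(gss_every) && iter %% gss_every == 0L) {
        for (j in seq_len(d)) {
          fj <- function(x) { z <- gbest; z[j] <- x; fcount(z) }
          r <- golden_section(fj, lo[j], hi[j], tol = 1e-5)
          if (r["f"] < gcost) { gbest[j] <- r["x"]; gcost <- r["f"] }
        }
      }
      traj <- c(traj, gcost)
    }
    structure(list(best = stats::setNames(to_nat(gbest), free$name),
                   best_cost = gcost, cost_trajectory = traj,
                   swarm_costs = costs, seed = seed, evaluations = nev),
              class = "fit_report")
  })
}

#' @export
print.fit_report <- function(x, ...) {
  cat(sprintf("<fit_report: best cost %.4g after %d evaluations (seed %d)>\n",
              x$best_cost, x$evaluations, x$seed))
  for (nm in names(x$best)) cat(sprintf("  %-10s %.6g\n", nm, x$best[[nm]]))
  invisible(x)
}

#' One-dimensional cost profile around a fit
#'
#' Re-evaluates the cost along a grid of one free parameter, holding all
#' others at `best` — a cheap identifiability diagnostic.
#'
#' @param problem A [fit_problem()].
#' @param best Named vector of free-parameter values (natural scale).
#' @param name Free-parameter name to profile.
#' @param grid Numeric grid of values for `name`.
#' @return Data frame with `value` and `cost`.
#' @export
profile_parameter <- function(problem, best, name, grid) {
  i <- match(name, problem$free$name)
  if (is.na(i)) stop("'", name, "' is not a free parameter of this problem")
  theta <- best[problem$free$name]
  data.frame(value = grid, cost = vapply(grid, function(v) {
    th <- theta; th[i] <- v; cost(unname(th), problem)
  }, 0))
}
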