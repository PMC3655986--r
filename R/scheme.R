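#' Declarative kinetic gating schemes
#'
#' A kinetic scheme is a directed transition graph over named channel states,
#' exactly one of which conducts. Each directed transition carries a rate-law
#' specification that is resolved against a parameter set when the generator
#' (Q) matrix is assembled, so the wiring of a model lives in data (a YAML
#' scheme file), not in code.
#'
#' A transition specification is a list with `from` and `to` plus one of:
#' * `param`: name of a parameter entry (exponential `c(k, n)` or sigmoid
#'   `c(g, a, f)`), optionally with `scale` (name of a dimensionless
#'   parameter) and integer `power` for the scale factor;
#' * `k` (and optionally `n`): a literal exponential law;
#' * `mirror = c(from, to)`: this rate is a scaled copy of another
#'   transition's rate (same optional `scale`/`power`);
#' * `derived = "<label>"`: the rate is computed from microscopic
#'   reversibility of a reaction cycle through this edge (the shortest cycle
#'   whose other rates are all independently defined), so that the product of
#'   rates clockwise equals the product counter-clockwise.
#'
#' @param states Character vector of state names (order fixes the matrix
#'   ordering).
#' @param conducting Name of the single open (conducting) state.
#' @param transitions List of transition specifications (see Details).
#' @param name Optional scheme name.
#' @return An object of class `kinetic_scheme`.
#' @seealso [build_generator()], [stationary_distribution()],
#'   [read_scheme()], [build_model_I()]
#' @export
kinetic_scheme <- function(states, conducting, transitions, name = "scheme") {
  stopifnot(is.character(states), length(states) >= 2L, !anyDuplicated(states))
  if (length(conducting) != 1L || !conducting %in% states)
    stop("'conducting' must name exactly one of the states")
  if (!length(transitions)) stop("a scheme needs at least one transition")
  transitions <- lapply(transitions, normalize_transition, states = states)
  keys <- vapply(transitions, function(tr) paste(tr$from, tr$to, sep = ">"), "")
  if (anyDuplicated(keys))
    stop("duplicate transition: ", keys[duplicated(keys)][1])
  sch <- structure(list(name = name, states = states, conducting = conducting,
                        transitions = transitions),
                   class = "kinetic_scheme")
  validate_scheme(sch)
}

normalize_transition <- function(tr, states) {
  if (is.null(tr$from) || is.null(tr$to))
    stop("every transition needs 'from' and 'to'")
  if (!tr$from %in% states || !tr$to %in% states)
    stop("transition references unknown state: ", tr$from, " -> ", tr$to)
  if (tr$from == tr$to) stop("self-transition not allowed: ", tr$from)
  kind <- c(!is.null(tr$param), !is.null(tr$k), !is.null(tr$mirror),
            !is.null(tr$derived))
  if (sum(kind) != 1L)
    stop("transition ", tr$from, " -> ", tr$to,
         ": specify exactly one of param / k / mirror / derived")
  if (!is.null(tr$mirror)) {
    tr$mirror <- unlist(tr$mirror, use.names = FALSE)
    if (length(tr$mirror) != 2L)
      stop("'mirror' must be a (from, to) pair")
  }
  if (!is.null(tr$power) && is.null(tr$scale))
    stop("'power' without 'scale' in ", tr$from, " -> ", tr$to)
  if (is.null(tr$power)) tr$power <- 1L
  tr[c("from", "to", "param", "k", "n", "mirror", "derived", "scale", "power")]
}

validate_scheme <- function(sch) {
  st <- sch$states
  adj <- matrix(FALSE, length(st), length(st), dimnames = list(st, st))
  for (tr in sch$transitions) adj[tr$from, tr$to] <- TRUE
  und <- adj | t(adj)
  # connectivity of the undirected transition graph
  seen <- logical(length(st)); seen[1] <- TRUE; queue <- 1L
  while (length(queue)) {
    i <- queue[1]; queue <- queue[-1]
    nb <- which(und[i, ] & !seen)
    seen[nb] <- TRUE; queue <- c(queue, nb)
  }
  if (!all(seen))
    stop("transition graph is not connected; unreachable: ",
         paste(st[!seen], collapse = ", "))
  # derived edges need a reverse edge and a resolvable cycle
  sch$derived_paths <- derived_cycle_paths(sch)
  sch
}

transition_kind <- function(tr) {
  if (!is.null(tr$derived)) "derived"
  else if (!is.null(tr$mirror)) "mirror"
  else "direct"
}

# For each derived transition, find (once, at validation time) the shortest
# cycle through it whose other edges exist in both directions and are not
# themselves derived. Mirrors are admitted only if their referent is direct.
derived_cycle_paths <- function(sch) {
  st <- sch$states
  kinds <- vapply(sch$transitions, transition_kind, "")
  key <- function(a, b) paste(a, b, sep = ">")
  kmap <- structure(kinds, names = vapply(sch$transitions, function(tr)
    key(tr$from, tr$to), ""))
  trmap <- structure(sch$transitions, names = names(kmap))
  usable <- function(a, b) {
    k <- kmap[key(a, b)]
    if (is.na(k)) return(FALSE)
    if (k == "direct") return(TRUE)
    if (k == "derived") return(FALSE)
    ref <- trmap[[key(a, b)]]$mirror
    identical(unname(kmap[key(ref[1], ref[2])]), "direct")
  }
  out <- list()
  for (tr in sch$transitions) {
    if (is.null(tr$derived)) next
    if (is.na(kmap[key(tr$to, tr$from)]))
      stop("derived transition ", tr$from, " -> ", tr$to,
           " has no reverse transition to balance against")
    if (kmap[key(tr$to, tr$from)] == "derived")
      stop("derived transition ", tr$from, " -> ", tr$to,
           ": its reverse is also derived (circular derivation)")
    # BFS from tr$to to tr$from over edges usable in both directions,
    # excluding the derived edge itself
    prev <- rep(NA_integer_, length(st)); names(prev) <- st
    queue <- tr$to; prev[tr$to] <- 0L
    found <- FALSE
    while (length(queue) && !found) {
      cur <- queue[1]; queue <- queue[-1]
      for (nb in st) {
        if (!is.na(prev[nb]) || nb == cur) next
        if (cur == tr$to && nb == tr$from) next  # skip the reverse edge itself
        if (usable(cur, nb) && usable(nb, cur)) {
          prev[nb] <- match(cur, st)
          if (nb == tr$from) { found <- TRUE; break }
          queue <- c(queue, nb)
        }
      }
    }
    if (!found)
      stop("derived transition ", tr$from, " -> ", tr$to,
           ": no independent reaction cycle available to balance it")
    path <- tr$from
    while (utils::tail(path, 1) != tr$to) {
      path <- c(path, st[prev[utils::tail(path, 1)]])
    }
    # path runs tr$from <- ... <- tr$to following BFS parents; reverse it
    out[[key(tr$from, tr$to)]] <- rev(path)  # tr$to ... tr$from
  }
  out
}

#' @export
print.kinetic_scheme <- function(x, ...) {
  cat(sprintf("<kinetic_scheme '%s': %d states (open: %s), %d transitions>\n",
              x$name, length(x$states), x$conducting, length(x$transitions)))
  invisible(x)
}

resolve_direct_law <- function(tr, params) {
  if (!is.null(tr$param)) {
    param_law(params, tr$param, scale = tr$scale, power = tr$power)
  } else {
    law <- rate_exp(tr$k, if (is.null(tr$n)) Inf else tr$n)
    if (!is.null(tr$scale)) {
      s <- params[[tr$scale]]
      if (is.null(s)) stop("scale parameter '", tr$scale, "' not found")
      law <- rate_scaled(law, unname(s[1])^tr$power)
    }
    law
  }
}

#' Assemble the generator (Q) matrix of a scheme at a voltage
#'
#' Off-diagonal entry `(i, j)` is the transition rate from state `i` to state
#' `j` (0 if the transition is absent); each diagonal entry is minus its row
#' sum, so rows sum to zero and `dp/dt = p %*% Q` conserves probability.
#' Derived (microscopic-reversibility) rates are computed from their cached
#' reaction cycles after all independent rates are evaluated.
#'
#' @param scheme A [kinetic_scheme()].
#' @param params A [nav_params()] parameter set.
#' @param V Membrane voltage, mV (finite scalar).
#' @return Square numeric matrix (1/ms) with state dimnames.
#' @export
build_generator <- function(scheme, params, V) {
  stopifnot(inherits(scheme, "kinetic_scheme"))
  if (!is.numeric(V) || length(V) != 1L || !is.finite(V))
    stop("'V' must be a finite scalar voltage in mV")
  st <- scheme$states
  n <- length(st)
  R <- matrix(0, n, n, dimnames = list(st, st))
  pending <- list()
  for (tr in scheme$transitions) {
    kind <- transition_kind(tr)
    if (kind == "direct") {
      R[tr$from, tr$to] <- eval_rate(resolve_direct_law(tr, params), V)
    } else pending[[length(pending) + 1L]] <- tr
  }
  # iterate mirrors/deriveds until all resolve (order-independent fixed point)
  repeat {
    if (!length(pending)) break
    progress <- FALSE
    still <- list()
    for (tr in pending) {
      if (!is.null(tr$mirror)) {
        ref <- R[tr$mirror[1], tr$mirror[2]]
        if (ref > 0) {
          s <- if (is.null(tr$scale)) 1 else unname(params[[tr$scale]][1])^tr$power
          R[tr$from, tr$to] <- s * ref
          progress <- TRUE
        } else still[[length(still) + 1L]] <- tr
      } else {
        path <- scheme$derived_paths[[paste(tr$from, tr$to, sep = ">")]]
        fr <- mapply(function(a, b) R[a, b], path[-length(path)], path[-1])
        br <- mapply(function(a, b) R[b, a], path[-length(path)], path[-1])
        if (all(fr > 0) && all(br > 0) && R[tr$to, tr$from] > 0) {
          # cycle: from -> to -> path... -> from ; balance forward vs backward
          R[tr$from, tr$to] <- R[tr$to, tr$from] * prod(br) / prod(fr)
          progress <- TRUE
        } else still[[length(still) + 1L]] <- tr
      }
    }
    pending <- still
    if (!progress && length(pending))
      stop("circular rate definitions: could not resolve ",
           paste(vapply(pending, function(tr)
             paste(tr$from, tr$to, sep = " -> "), ""), collapse = ", "))
  }
  if (any(!is.finite(R)) || any(R < 0))
    stop("non-finite or negative rate in generator at V = ", V, " mV")
  diag(R) <- -rowSums(R)
  R
}

#' Derive a balancing rate from microscopic reversibility
#'
#' In a closed reaction cycle at thermodynamic equilibrium, the product of
#' rates traversed clockwise equals the product traversed counter-clockwise.
#' Given all rates of a cycle but one, the missing rate is forced.
#'
#' @param cycle A list of steps, each `list(from, to, forward, backward)`
#'   where `forward`/`backward` are `rate_law` objects or numeric rates; the
#'   single step whose `forward` is `NULL` (or a [rate_derived()] law) is the
#'   one solved for. Steps must chain `from`/`to` into a closed loop.
#' @param V Membrane voltage, mV (used to evaluate `rate_law` entries).
#' @return The derived forward rate (1/ms) of the unknown step.
#' @examples
#' cyc <- list(list(from = "A", to = "B", forward = 2, backward = 1),
#'             list(from = "B", to = "C", forward = 3, backward = 6),
#'             list(from = "C", to = "D", forward = 1, backward = 4),
#'             list(from = "D", to = "A", forward = NULL, backward = 1))
#' derive_reversibility_rate(cyc, V = 0)  # 4: both cycle products equal 24
#' @export
derive_reversibility_rate <- function(cycle, V = 0) {
  if (length(cycle) < 2L) stop("a cycle needs at least two steps")
  froms <- vapply(cycle, function(s) s$from, "")
  tos <- vapply(cycle, function(s) s$to, "")
  if (!all(tos == c(froms[-1], froms[1])))
    stop("cycle is not closed: each step's 'to' must be the next step's 'from'")
  ev <- function(r) {
    if (is.null(r)) return(NA_real_)
    if (inherits(r, "derived_law")) return(NA_real_)
    if (inherits(r, "rate_law")) return(eval_rate(r, V))
    if (is.numeric(r) && length(r) == 1L) return(as.numeric(r))
    stop("cycle rates must be numeric or rate_law objects")
  }
  fwd <- vapply(cycle, function(s) ev(s$forward), 0)
  bwd <- vapply(cycle, function(s) ev(s$backward), 0)
  unknown <- which(is.na(fwd))
  if (length(unknown) != 1L || anyNA(bwd))
    stop("exactly one forward rate may be unknown (NULL or derived), ",
         "all backward rates must be known")
  if (any(bwd <= 0) || any(fwd[-unknown] <= 0))
    stop("cycle rates must be strictly positive")
  prod(bwd) / prod(fwd[-unknown])
}

#' Stationary occupancy distribution of a scheme at a fixed voltage
#'
#' Solves `p %*% Q = 0` with `sum(p) = 1`. Used to initialize sweeps at the
#' holding potential (a hold is equivalent to infinite time at that voltage).
#'
#' @inheritParams build_generator
#' @return Named nonnegative numeric vector summing to 1.
#' @export
stationary_distribution <- function(scheme, params, V) {
  Q <- build_generator(scheme, params, V)
  stationary_from_Q(Q)
}

stationary_from_Q <- function(Q) {
  n <- nrow(Q)
  # strong connectivity on the positive-rate digraph (irreducibility)
  reach <- function(M) {
    seen <- logical(n); seen[1] <- TRUE; queue <- 1L
    while (length(queue)) {
      i <- queue[1]; queue <- queue[-1]
      nb <- which(M[i, ] > 0 & !seen)
      seen[nb] <- TRUE; queue <- c(queue, nb)
    }
    seen
  }
  offQ <- Q; diag(offQ) <- 0
  if (!all(reach(offQ)) || !all(reach(t(offQ))))
    stop("generator is reducible at this voltage; ",
         "no unique stationary distribution")
  A <- rbind(t(Q), rep(1, n))
  b <- c(rep(0, n), 1)
  p <- qr.solve(A, b)
  if (any(p < -1e-8))
    stop("stationary solve produced negative occupancies; ",
         "generator may be defective")
  p[p < 0] <- 0
  p <- p / sum(p)
  names(p) <- rownames(Q)
  p
}

#' Read and write scheme definition files
#'
#' Schemes are stored as YAML: `name`, `states`, `conducting`, and a
#' `transitions` list in the format accepted by [kinetic_scheme()].
#'
#' @param path File path.
#' @param scheme A `kinetic_scheme`.
#' @return `read_scheme()` returns a `kinetic_scheme`; `write_scheme()`
#'   returns `path` invisibly.
#' @export
read_scheme <- function(path) {
  if (!file.exists(path)) stop("scheme file not found: ", path)
  y <- yaml::read_yaml(path)
  kinetic_scheme(states = unlist(y$states), conducting = y$conducting,
                 transitions = y$transitions,
                 name = if (is.null(y$name)) "scheme" else y$name)
}

#' @rdname read_scheme
#' @export
write_scheme <- function(scheme, path) {
  stopifnot(inherits(scheme, "kinetic_scheme"))
  trs <- lapply(scheme$transitions, function(tr) {
    tr <- tr[!vapply(tr, is.null, TRUE)]
    if (identical(tr$power, 1L)) tr$power <- NULL
    tr
  })
  yaml::write_yaml(list(name = scheme$name, states = as.list(scheme$states),
                        conducting = scheme$conducting, transitions = trs),
                   path)
  invisible(path)
}

#' The packaged Nav1.5 gating schemes
#'
#' `build_model_I()` returns the 8-state fast-inactivation scheme (closed
#' states C1–C3, open state O, inactivated states I11–I14);
#' `build_model_II()` returns the 12-state two-step-inactivation scheme that
#' adds a slow-inactivated tier I21–I24. Both are read from the scheme
#' definition files shipped in `inst/extdata` and are parameterized by
#' [nav_params()].
#'
#' @param params Parameter set used to sanity-check the wiring (all referenced
#'   entries must exist). Defaults to the packaged best-fit set.
#' @return A `kinetic_scheme`.
#' @export
build_model_I <- function(params = nav_params()) {
  sch <- read_scheme(system.file("extdata", "model_I.yaml",
                                 package = "navmarkov", mustWork = TRUE))
  invisible(build_generator(sch, params, -120))  # fail fast on missing params
  sch
}

#' @rdname build_model_I
#' @export
build_model_II <- function(params = nav_params()) {
  sch <- read_scheme(system.file("extdata", "model_II.yaml",
                                 package = "navmarkov", mustWork = TRUE))
  invisible(build_generator(sch, params, -120))
  sch
}

#' Check microscopic reversibility of every cycle of a scheme
#'
#' Builds a spanning tree of the (bidirectional) transition graph and, for
#' every non-tree edge, forms the fundamental cycle and compares the product
#' of rates traversed forward with the product traversed backward. At
#' thermodynamic equilibrium the two must be equal for every cycle.
#'
#' @inheritParams build_generator
#' @return The maximum relative detailed-balance residual
#'   `|forward/backward - 1|` over the fundamental cycle basis (0 for a
#'   cycle-free scheme).
#' @export
check_detailed_balance <- function(scheme, params, V) {
  Q <- build_generator(scheme, params, V)
  st <- scheme$states
  n <- length(st)
  bidir <- Q > 0 & t(Q) > 0
  diag(bidir) <- FALSE
  # BFS spanning tree over bidirectional edges
  parent <- rep(NA_integer_, n); parent[1] <- 0L
  queue <- 1L
  while (length(queue)) {
    i <- queue[1]; queue <- queue[-1]
    for (j in which(bidir[i, ])) {
      if (is.na(parent[j])) { parent[j] <- i; queue <- c(queue, j) }
    }
  }
  depth <- function(i) { d <- 0L; while (parent[i] > 0L) { i <- parent[i]; d <- d + 1L }; d }
  tree_path <- function(a, b) {
    pa <- a; pb <- b
    da <- depth(a); db <- depth(b)
    patha <- a; pathb <- b
    while (da > db) { pa <- parent[pa]; patha <- c(patha, pa); da <- da - 1L }
    while (db > da) { pb <- parent[pb]; pathb <- c(pathb, pb); db <- db - 1L }
    while (pa != pb) {
      pa <- parent[pa]; patha <- c(patha, pa)
      pb <- parent[pb]; pathb <- c(pathb, pb)
    }
    c(patha, rev(pathb[-length(pathb)]))
  }
  worst <- 0
  intree <- matrix(FALSE, n, n)
  for (j in which(parent > 0L)) {
    intree[j, parent[j]] <- TRUE; intree[parent[j], j] <- TRUE
  }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j && bidir[i, j] && !intree[i, j]) {
      cyc <- c(tree_path(i, j), i)   # i .. j then close j -> i via the edge
      fwd <- prod(mapply(function(a, b) Q[a, b], cyc[-length(cyc)], cyc[-1]))
      bwd <- prod(mapply(function(a, b) Q[b, a], cyc[-length(cyc)], cyc[-1]))
      worst <- max(worst, abs(fwd / bwd - 1))
    }
  }
  worst
}
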