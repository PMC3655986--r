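# Shared fixtures: tiny schemes built in code, plus cached packaged models.

# two-state C <-> O toy with literal (voltage-independent) rates
toy_two_state <- function(r1 = 1, r2 = 1) {
  kinetic_scheme(
    states = c("C", "O"), conducting = "O",
    transitions = list(list(from = "C", to = "O", k = r1),
                       list(from = "O", to = "C", k = r2)),
    name = "toy2")
}

# four-state ring with one derived (cycle-balancing) rate
toy_ring <- function(f = c(2, 3, 1), b = c(1, 6, 1, 4)) {
  kinetic_scheme(
    states = c("A", "B", "C", "D"), conducting = "A",
    transitions = list(
      list(from = "A", to = "B", k = f[1]), list(from = "B", to = "A", k = b[1]),
      list(from = "B", to = "C", k = f[2]), list(from = "C", to = "B", k = b[2]),
      list(from = "C", to = "D", k = f[3]), list(from = "D", to = "C", k = b[3]),
      list(from = "D", to = "A", derived = "bal"),
      list(from = "A", to = "D", k = b[4])),
    name = "ring4")
}

# cache the packaged models across tests within a file
.model_cache <- new.env(parent = emptyenv())
get_model <- function(which = c("model_I", "model_II")) {
  which <- match.arg(which)
  if (is.null(.model_cache[[which]]))
    .model_cache[[which]] <- switch(which, model_I = build_model_I(),
                                    model_II = build_model_II())
  .model_cache[[which]]
}

# parameter set with the slow tier unreachable: the entry rate is forced to
# (effectively) zero, so no occupancy ever reaches I21..I24 and model II
# collapses onto model I
params_no_slow_tier <- function() {
  nav_params(rho3 = c(k = 1e-300, n = 965.2))
}
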