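p <- nav_params()

test_that("generator of a two-state toy is [[-r1, r1], [r2, -r2]]", {
  sch <- toy_two_state(1.5, 0.5)
  Q <- build_generator(sch, p, 0)
  expect_equal(unname(Q), rbind(c(-1.5, 1.5), c(0.5, -0.5)))
})

test_that("generator rows sum to zero for both models at random voltages", {
  set.seed(42)
  voltages <- runif(200, -140, 60)
  for (which in c("model_I", "model_II")) {
    sch <- get_model(which)
    worst <- max(vapply(voltages, function(V) {
      Q <- build_generator(sch, p, V)
      max(abs(rowSums(Q))) / max(abs(Q))
    }, 0))
    expect_lt(worst, 1e-10)
  }
})

test_that("model II generator entries match per-entry scalar recomputation", {
  sch <- get_model("model_II")
  Q <- build_generator(sch, p, -120)
  cc <- 2.146
  expr_rate <- function(k, n, V = -120) k * exp(V / n)
  # spot-check every named-law class against direct arithmetic
  expect_equal(Q["C1", "C2"], expr_rate(9.435, 39.70))          # alpha1
  expect_equal(Q["C2", "C1"], expr_rate(0.2241, -21.13))        # beta2
  expect_equal(Q["C3", "C2"], expr_rate(0.000037, -7.770))      # beta1
  expect_equal(Q["O", "I14"], cc^-2.5 * expr_rate(1.823, 92.78))
  rho1 <- 0.01296 / (1 + exp(-(-120 + 85.62) / 15.64))
  expect_equal(Q["I14", "O"], rho1 / cc)
  expect_equal(Q["C1", "I11"], cc^0.75 * rho1)
  expect_equal(Q["I11", "I12"], cc * expr_rate(9.435, 39.70))
  expect_equal(Q["I11", "C1"], expr_rate(0.000020, -13.07))     # phi1
  expect_equal(Q["I13", "C3"], expr_rate(0.000302, -47.08))     # phi2
  expect_equal(Q["I14", "I24"], expr_rate(0.000315, 965.2))     # rho3
  expect_equal(Q["I24", "I14"], expr_rate(0.000230, -57.21))    # phi3
  # mirrored slow-tier horizontal equals its fast-tier referent
  expect_identical(Q["I21", "I22"], Q["I11", "I12"])
  expect_identical(Q["I24", "I23"], Q["I14", "I13"])
  # derived balancing rate closes its cycle exactly
  expect_equal(Q["C1", "C2"] * Q["C2", "I12"] * Q["I12", "I11"] * Q["I11", "C1"],
               Q["C2", "C1"] * Q["I12", "C2"] * Q["I11", "I12"] * Q["C1", "I11"],
               tolerance = 1e-12)
})

test_that("reversibility-derived rate balances the cycle products", {
  # forced by detailed balance: both ring products equal 24, derived rate = 4
  cyc <- list(list(from = "A", to = "B", forward = 2, backward = 1),
              list(from = "B", to = "C", forward = 3, backward = 6),
              list(from = "C", to = "D", forward = 1, backward = 4),
              list(from = "D", to = "A", forward = NULL, backward = 1))
  d <- derive_reversibility_rate(cyc, V = 0)
  expect_equal(d, 4)
  expect_equal(2 * 3 * 1 * d, 1 * 6 * 4 * 1)
  # rate_law entries are evaluated at the supplied voltage: the derived rate
  # of a two-step loop is backward-product / known-forward
  cyc2 <- list(list(from = "A", to = "B", forward = rate_exp(2, 25), backward = 1),
               list(from = "B", to = "A", forward = NULL, backward = 1))
  expect_equal(derive_reversibility_rate(cyc2, V = -50),
               1 / (2 * exp(-50 / 25)))
  expect_error(derive_reversibility_rate(cyc[1:3], 0), "not closed")
})

test_that("derived rates are invariant to where the cycle starts", {
  ring <- toy_ring()
  Q <- build_generator(ring, p, 0)
  d <- Q["D", "A"]
  # rotate the state ordering: same graph, same derived value
  ring2 <- kinetic_scheme(
    states = c("C", "D", "A", "B"), conducting = "A",
    transitions = list(
      list(from = "A", to = "B", k = 2), list(from = "B", to = "A", k = 1),
      list(from = "B", to = "C", k = 3), list(from = "C", to = "B", k = 6),
      list(from = "C", to = "D", k = 1), list(from = "D", to = "C", k = 1),
      list(from = "D", to = "A", derived = "bal"),
      list(from = "A", to = "D", k = 4)))
  expect_equal(build_generator(ring2, p, 0)["D", "A"], d)
})

test_that("detailed balance holds on every cycle of both models", {
  for (which in c("model_I", "model_II")) {
    sch <- get_model(which)
    for (V in c(-120, -89, -34.5, 0, 40))
      expect_lt(check_detailed_balance(sch, p, V), 1e-10)
  }
})

test_that("stationary distribution: closed form, conservation, rest state", {
  expect_equal(unname(stationary_distribution(toy_two_state(1, 3), p, 0)),
               c(0.75, 0.25))
  for (which in c("model_I", "model_II")) {
    pi0 <- stationary_distribution(get_model(which), p, -120)
    expect_equal(sum(pi0), 1)
    expect_true(all(pi0 >= 0))
    # hyperpolarized rest: essentially no occupancy in the open state
    expect_lt(pi0[["O"]], 0.01)
  }
})

test_that("stationary distribution matches the long-time limit of propagation", {
  sch <- get_model("model_II")
  pi0 <- stationary_distribution(sch, p, -120)
  n <- length(sch$states)
  P <- propagate_segment_spectral(sch, p, rep(1 / n, n), -120, 1e5)  # 100 s
  expect_lt(max(abs(P[1, ] - pi0)), 1e-8)
})

test_that("invalid schemes are rejected with clear diagnostics", {
  expect_error(kinetic_scheme(c("A", "B"), "A",
                              list(list(from = "A", to = "A", k = 1))),
               "self-transition")
  expect_error(kinetic_scheme(c("A", "B", "X"), "A",
                              list(list(from = "A", to = "B", k = 1),
                                   list(from = "B", to = "A", k = 1))),
               "not connected")
  expect_error(kinetic_scheme(c("A", "B"), "Q",
                              list(list(from = "A", to = "B", k = 1))),
               "conducting")
  # a derived rate with no independent cycle to balance against
  expect_error(kinetic_scheme(c("A", "B"), "A",
                              list(list(from = "A", to = "B", derived = "x"),
                                   list(from = "B", to = "A", k = 1))),
               "cycle")
  expect_error(build_generator(get_model("model_I"), p, NA_real_), "finite")
  # missing parameter entry for a referenced law
  p2 <- nav_params()
  p2$alpha1 <- NULL
  expect_error(build_generator(get_model("model_I"), p2, -120), "alpha1")
})

test_that("scheme files round-trip through YAML", {
  sch <- get_model("model_II")
  f <- withr::local_tempfile(fileext = ".yaml")
  write_scheme(sch, f)
  sch2 <- read_scheme(f)
  expect_equal(sch2$states, sch$states)
  expect_equal(sch2$conducting, sch$conducting)
  Q1 <- build_generator(sch, p, -47.3)
  Q2 <- build_generator(sch2, p, -47.3)
  expect_equal(Q2, Q1)
})

test_that("packaged models have the documented structure", {
  m1 <- get_model("model_I")
  m2 <- get_model("model_II")
  expect_length(m1$states, 8)
  expect_setequal(m1$states, c("C1", "C2", "C3", "O",
                               "I11", "I12", "I13", "I14"))
  expect_identical(m1$conducting, "O")
  expect_length(m2$states, 12)
  expect_setequal(setdiff(m2$states, m1$states),
                  c("I21", "I22", "I23", "I24"))
  # removing the slow tier leaves exactly the 8-state transition graph
  keep <- vapply(m2$transitions, function(tr)
    !grepl("^I2", tr$from) && !grepl("^I2", tr$to), TRUE)
  key <- function(trs) sort(vapply(trs, function(tr)
    paste(tr$from, tr$to, sep = ">"), ""))
  expect_identical(key(m2$transitions[keep]), key(m1$transitions))
})
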