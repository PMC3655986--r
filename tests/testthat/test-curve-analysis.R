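p <- nav_params()

make_flat_trace <- function(current, dt = 0.1, segment = 1L, value = 0) {
  n <- length(current)
  structure(list(time = seq(0, by = dt, length.out = n),
                 segment = rep.int(segment, n),
                 voltage = rep.int(-10, n),
                 occ = matrix(1, n, 1, dimnames = list(NULL, "O")),
                 current = current, sweep_value = value,
                 states = "O", open = "O", protocol = "synthetic"),
            class = "nav_trace")
}

test_that("peak_currents returns the signed extremum of the chosen segment", {
  tr0 <- make_flat_trace(rep(0, 50))
  expect_equal(peak_currents(list(tr0), 1L)$peak, 0)
  cur <- rep(-0.1, 50); cur[7] <- -1.0   # injected peak at 0.6 ms
  tr1 <- make_flat_trace(cur, value = 3)
  pk <- peak_currents(list(tr1), 1L)
  expect_equal(pk$peak, -1.0)
  expect_equal(pk$value, 3)
  expect_error(peak_currents(list(tr1), 5L), "segment")
})

test_that("simulated activation peak is most negative near -20..-10 mV", {
  traces <- run_protocol(get_model("model_I"), p, activation_protocol(dt = 0.05),
                         sim_config())
  pk <- peak_currents(traces, 1L)
  vstar <- pk$value[which.min(pk$peak)]
  expect_gte(vstar, -25)
  expect_lte(vstar, -5)
})

test_that("gv_curve normalizes conductance and flattens ohmic peaks", {
  V <- seq(-60, 20, by = 10)
  peaks <- data.frame(value = V, peak = (V - 67.5) * 0.4)  # exactly ohmic
  gv <- gv_curve(peaks, 67.5)
  expect_equal(gv$G, rep(1, length(V)))
  expect_equal(max(gv$G), 1)
  expect_error(gv_curve(data.frame(value = 67.5, peak = 1), 67.5),
               "reversal")
  # simulated G-V is monotone non-decreasing over -90..0 mV
  traces <- run_protocol(get_model("model_I"), p, activation_protocol(dt = 0.05),
                         sim_config())
  pk <- peak_currents(traces, 1L)
  gv2 <- gv_curve(pk[pk$value <= 0, ], 67.5)
  expect_true(all(diff(gv2$G) > -1e-9))
})

test_that("Boltzmann fitters exactly recover noiseless generating truth", {
  V <- seq(-90, 10, by = 5)
  rising <- make_boltzmann_samples(-34.5, 7.2, V, direction = "rising")
  fa <- fit_boltzmann_activation(data.frame(V = rising$V, G = rising$y))
  expect_equal(fa$V50, -34.5, tolerance = 1e-8)
  expect_equal(fa$k, 7.2, tolerance = 1e-8)
  expect_lt(fa$residual, 1e-8)
  V2 <- seq(-120, -50, by = 5)
  falling <- make_boltzmann_samples(-89.1, 5.5, V2, direction = "falling")
  fb <- fit_boltzmann_availability(data.frame(V = falling$V, I = falling$y))
  expect_equal(fb$V50, -89.1, tolerance = 1e-8)
  expect_equal(fb$k, 5.5, tolerance = 1e-8)
  # permutation invariance: voltage order must not matter
  shuf <- rising[rev(seq_len(nrow(rising))), ]
  fa2 <- fit_boltzmann_activation(data.frame(V = shuf$V, G = shuf$y))
  expect_equal(fa2$V50, fa$V50)
  expect_equal(fa2$k, fa$k)
  expect_error(fit_boltzmann_activation(data.frame(V = 1:3, G = 1:3)),
               "4 points")
})

test_that("recovery fitters recover mono- and bi-exponential truth", {
  tt <- exp(seq(log(0.5), log(50), length.out = 20))
  mono <- make_exp_samples(5.1, 1, tt)
  fm <- fit_recovery(data.frame(interval = mono$t, fraction = mono$y), "mono")
  expect_equal(fm$tau, 5.1, tolerance = 1e-6)
  expect_lt(fm$residual, 1e-8)
  tt2 <- exp(seq(log(0.5), log(5000), length.out = 40))
  bi <- make_exp_samples(c(5.2, 596.3), c(0.78, 0.22), tt2)
  fb <- fit_recovery(data.frame(interval = bi$t, fraction = bi$y), "bi")
  expect_equal(fb$tau1, 5.2, tolerance = 1e-4)
  expect_equal(fb$tau2, 596.3, tolerance = 1e-4)
  expect_equal(fb$frac1, 0.78, tolerance = 1e-4)
  expect_equal(fb$frac2, 0.22, tolerance = 1e-4)
  expect_true(fb$tau1 < fb$tau2)
  # scaling the dependent variable leaves the time constant unchanged
  fm2 <- fit_recovery(data.frame(interval = mono$t, fraction = 2 * mono$y),
                      "mono")
  expect_equal(fm2$tau, fm$tau, tolerance = 1e-6)
})

test_that("bi-exponential fit degenerates gracefully on mono data", {
  tt <- exp(seq(log(0.5), log(200), length.out = 25))
  mono <- make_exp_samples(8, 1, tt)
  fm <- fit_recovery(data.frame(interval = mono$t, fraction = mono$y), "mono")
  fb <- suppressWarnings(
    fit_recovery(data.frame(interval = mono$t, fraction = mono$y), "bi"))
  # one component vanishes (or both collapse onto the true tau)
  small <- min(fb$frac1, fb$frac2)
  collapsed <- abs(fb$tau1 - fb$tau2) < 3 * fb$tau1
  expect_true(small < 0.01 || collapsed)
  dominant <- if (fb$frac1 >= fb$frac2) fb$tau1 else fb$tau2
  expect_equal(dominant, fm$tau, tolerance = 0.05)
})

test_that("fractional recovery behaves at its limits", {
  sch <- get_model("model_I")
  traces <- run_protocol(sch, p,
                         recovery_protocol(30, -120,
                                           intervals = c(0.05, 5000),
                                           dt = 0.05),
                         sim_config())
  fr <- fractional_recovery(traces)
  expect_lt(fr$fraction[1], 0.2)             # essentially nothing recovered
  expect_equal(fr$fraction[2], 1, tolerance = 1e-3)  # full recovery
  # a synthetic family built from a known mono-exponential reproduces it
  tt <- exp(seq(log(0.5), log(60), length.out = 15))
  y <- 1 - exp(-tt / 5.1)
  fake <- lapply(seq_along(tt), function(i) {
    tr <- make_flat_trace(c(rep(-1, 10), rep(0, 5), rep(-y[i], 10)))
    tr$segment <- rep(c(1L, 2L, 3L), c(10, 5, 10))
    tr$sweep_value <- tt[i]
    tr
  })
  fr2 <- fractional_recovery(fake)
  expect_equal(fr2$fraction, y)
  ff <- fit_recovery(fr2, "mono")
  expect_equal(ff$tau, 5.1, tolerance = 1e-6)
})

test_that("development fit recovers its time constant and normalization", {
  tt <- exp(seq(log(20), log(12000), length.out = 16))
  y <- 0.45 + 0.55 * exp(-tt / 1790)
  peaks <- data.frame(value = tt, peak = -y)
  fd <- fit_development(peaks)
  expect_equal(fd$tau, 1790, tolerance = 1e-3)
  # scaling all peaks cancels in the normalization
  fd2 <- fit_development(transform(peaks, peak = 2 * peak))
  expect_equal(fd2$tau, fd$tau)
  # constant peaks: amplitude ~ 0
  fc <- fit_development(data.frame(value = tt, peak = rep(-1, 16)))
  expect_lt(abs(fc$a), 1e-6)
  expect_error(fit_development(peaks[1:3, ]), "5 durations")
})

test_that("extract_time_constant recovers pure-exponential phases", {
  tt <- seq(0, 10, by = 0.02)
  tr <- make_flat_trace(-exp(-tt / 1.0), dt = 0.02)
  fit <- extract_time_constant(tr, "deactivation")
  expect_equal(fit$tau, 1.0, tolerance = 1e-6)
  # invariant to a baseline offset
  tr2 <- tr; tr2$current <- tr2$current - 0.2
  fit2 <- extract_time_constant(tr2, "deactivation")
  expect_equal(fit2$tau, 1.0, tolerance = 1e-6)
})

test_that("model inactivation time constant matches a Q-matrix reduction", {
  sch <- get_model("model_I")
  tr <- run_sweep(sch, p, activation_protocol(), 17, sim_config())  # -10 mV
  fit <- extract_time_constant(tr, "inactivation")
  # oracle: two-state collapse of Q(-10): quasi-equilibrium of the activation
  # manifold draining into the inactivated tier
  Q <- build_generator(sch, p, -10)
  act <- c("C1", "C2", "C3", "O")
  Qa <- Q[act, act]
  diag(Qa) <- 0
  diag(Qa) <- -rowSums(Qa)
  w <- stationary_from_Q(Qa)
  drain <- sum(w * rowSums(Q[act, setdiff(sch$states, act)]))
  expect_equal(fit$tau, 1 / drain, tolerance = 0.3)
})
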