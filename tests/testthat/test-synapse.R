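test_that("magnesium block matches closed-form values and is monotone", {
  expect_equal(mg_block(0, Mg = 1), 3.57 / 4.57)
  expect_equal(mg_block(c(-80, 0, 40), Mg = 0), c(1, 1, 1))
  # direct numeric evaluation of the blocking factor at rest
  expect_equal(mg_block(-65, Mg = 1),
               1 / (1 + exp(-0.062 * -65) / 3.57), tolerance = 1e-12)
  expect_equal(round(mg_block(-65, Mg = 1), 4), 0.0597, tolerance = 1e-3)
  V <- seq(-90, 20, by = 5)
  expect_true(all(diff(mg_block(V, 1)) > 0))          # increasing in V
  for (v in c(-70, -30, 0))
    expect_true(all(diff(mg_block(v, c(0, 0.5, 1, 2))) < 0))  # decreasing in Mg
  expect_true(all(mg_block(V, 1) > 0 & mg_block(V, 1) <= 1))
  expect_error(mg_block(0, Mg = -1), "Mg")
})

test_that("gating decays exponentially at the stated time constants", {
  p <- syn_params()
  st <- gating_state(2, 2)
  st$s_GABA <- c(0.6, 0.2)
  st$s_AMPA_rec <- c(0.5, 0)
  dt <- 0.02
  for (k in seq_len(p$tau_GABA / dt)) st <- update_gating(st, params = p, dt = dt)
  # after one tau_GABA the GABA gate is at 1/e (AMPA long gone)
  expect_equal(st$s_GABA, c(0.6, 0.2) / exp(1), tolerance = 0.01)
  expect_equal(st$s_AMPA_rec[1], 0.5 * exp(-p$tau_GABA / p$tau_AMPA),
               tolerance = 1e-3)
})

test_that("a presynaptic spike increments x which then drives s_NMDA", {
  p <- syn_params()
  st <- gating_state(1, 1)
  st <- update_gating(st, spikes_E = 1, params = p)
  expect_equal(st$x_NMDA, p$w_spike, tolerance = 1e-6)
  x0 <- st$x_NMDA
  for (k in seq_len(p$tau_NMDA_rise / 0.02))
    st <- update_gating(st, params = p)
  expect_equal(st$x_NMDA, x0 / exp(1), tolerance = 0.01)  # tau = 2 ms decay
  expect_gt(st$s_NMDA, 0)                                 # activated by x
})

test_that("s_NMDA saturates below one and decays with tau 100 ms", {
  p <- syn_params()
  st <- gating_state(1, 1)
  st$s_NMDA <- 1
  smax <- 1
  for (k in seq_len(100 / 0.02)) {
    st <- update_gating(st, params = p)
    smax <- max(smax, st$s_NMDA)
  }
  expect_lte(smax, 1)
  expect_equal(st$s_NMDA, exp(-1), tolerance = 0.01)
  # non-negativity for arbitrary event trains
  set.seed(7)
  st <- gating_state(3, 3)
  for (k in 1:500) {
    st <- update_gating(st, spikes_E = rbinom(3, 1, 0.1),
                        spikes_I = rbinom(3, 1, 0.1),
                        bg_events = rpois(3, 0.1), params = p, dt = 0.1)
    expect_true(all(unlist(st) >= 0))
    expect_true(all(st$s_NMDA <= 1))
  }
})

test_that("synaptic current respects sign convention and edge cases", {
  p <- syn_params()
  g0 <- gating_state(3, 2)
  expect_equal(synaptic_current(-65, g0, c(1, 1, 0), c(1, 0), params = p), 0)
  g <- g0
  g$s_AMPA_rec <- c(0.5, 0.5, 0.5)
  g$s_NMDA <- c(0.2, 0, 0)
  # at V_post = V_E the excitatory driving force vanishes
  expect_equal(synaptic_current(p$V_E, g, c(1, 1, 1), c(0, 0), params = p), 0)
  # depolarizing below V_E
  expect_gt(synaptic_current(-65, g, c(1, 1, 1), c(0, 0), params = p), 0)
  # one GABA synapse at s = 1, V = -65: |I| = 0.47 uS * 5 mV = 2.35 nA
  gg <- g0
  gg$s_GABA <- c(1, 0)
  I <- synaptic_current(-65, gg, c(0, 0, 0), c(1, 0), params = p)
  expect_equal(I, -0.47 * 5, tolerance = 1e-12)
  expect_error(synaptic_current(-65, g0, c(1, 1), c(1, 0), params = p),
               "length")
  expect_error(synaptic_current(-65, g0, c(1, 2, 0), c(1, 0), params = p),
               "binary")
})

test_that("unitary EPSC reproduces the calibrated peaks and ratio", {
  u <- unitary_epsc(syn_params())
  expect_equal(u$peak_AMPA_pA, 71, tolerance = 0.10)
  expect_equal(u$peak_NMDA_pA, 19, tolerance = 0.10)
  expect_lt(abs(u$ratio_pct - 26.6), 2)
  # NMDA component outlasts AMPA
  expect_gt(u$t_half_NMDA_ms, u$t_half_AMPA_ms)
  u0 <- unitary_epsc(syn_params(g_NMDA = 0))
  expect_equal(u0$peak_NMDA_pA, 0)
  expect_equal(u0$ratio_pct, 0)
})

test_that("parameter validation rejects bad values", {
  expect_error(syn_params(g_NMDA = -1), "g_NMDA")
  expect_error(syn_params(V_I = 10, V_E = 0), "V_I")
  expect_error(update_gating(gating_state(1, 1), dt = 0), "dt")
})
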